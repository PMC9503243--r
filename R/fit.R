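#' Maximum-likelihood conditional probability tables for a fixed DAG
#'
#' Each CPT row is the empirical conditional frequency of the child given
#' one parent-level combination.  Rows with no observed support are filled
#' with the uniform distribution (and flagged via the `"zero_support"`
#' attribute on the CPT); an optional pseudo-count can be added to every
#' cell.
#'
#' @param dag A [new_dag()] whose nodes are factor columns of `data`.
#' @param data Data frame of factors.
#' @param smooth Nonnegative Laplace/Dirichlet pseudo-count per cell
#'   (default 0: pure maximum likelihood).
#' @return A [new_discrete_bn()] object.
#' @export
fit_cpts <- function(dag, data, smooth = 0) {
  stopifnot(smooth >= 0)
  pa <- dag_parents(dag)
  cpts <- lapply(dag$nodes, function(v) {
    fc <- family_counts(data, v, pa[[v]])
    counts <- fc$counts + smooth
    nj <- colSums(counts)
    zero <- nj == 0
    prob <- counts
    prob[, !zero] <- sweep(counts[, !zero, drop = FALSE], 2L, nj[!zero], "/")
    prob[, zero] <- 1 / fc$r
    lev <- lapply(c(v, pa[[v]]), function(z) levels(data[[z]]))
    names(lev) <- c(v, pa[[v]])
    out <- new_cpt(v, pa[[v]], lev[[v]], lev[-1L], prob)
    attr(out, "zero_support") <- sum(zero)
    out
  })
  names(cpts) <- dag$nodes
  new_discrete_bn(dag, cpts)
}

#' Fit the survival 2-TBN: per-slice transition tables on the at-risk set
#'
#' Estimates, for every slice, the probability of surviving the slice given
#' the covariate parents selected for that slice's survival node, using only
#' subjects at risk entering the slice (alive and uncensored at the end of
#' the previous slice; not censored before slice 1 for the prior factor).
#' Censorship-node tables are estimated analogously among subjects at risk
#' after the slice's events are resolved.  Estimation is pure maximum
#' likelihood, so with no covariate parents the fitted model reproduces the
#' product-limit estimator exactly.
#'
#' @param panel A [encode_states()] state panel (with covariates).
#' @param structure Either a [new_dag()] over the flat node set
#'   (`N@t`, `Q@t`, covariates), e.g. from [hill_climb()] under
#'   [survival_constraints()], or `NULL` for the covariate-free model.
#' @return An object of class `dbn_fit`: the fitted survival model with
#'   per-slice covariate parent sets and survival/censoring tables.
#' @export
fit_transition_cpts <- function(panel, structure = NULL) {
  stopifnot(inherits(panel, "state_panel"))
  T <- ncol(panel$n)
  covs <- panel$covariates
  cov_names <- names(covs)
  parents_n <- rep(list(character()), T)
  parents_q <- rep(list(character()), T)
  if (!is.null(structure)) {
    pa <- dag_parents(structure)
    for (t in seq_len(T)) {
      nn <- paste0("N@", t)
      qn <- paste0("Q@", t)
      if (nn %in% names(pa)) {
        parents_n[[t]] <- intersect(pa[[nn]], cov_names)
      }
      if (qn %in% names(pa)) {
        parents_q[[t]] <- intersect(pa[[qn]], cov_names)
      }
    }
  }
  cov_int <- lapply(covs, as.integer)
  cov_card <- vapply(covs, nlevels, integer(1))
  cfg_index <- function(parents) {
    if (!length(parents)) return(rep(1L, nrow(panel$n)))
    cfg <- rep(1L, nrow(panel$n))
    mult <- 1L
    for (p in parents) {
      cfg <- cfg + (cov_int[[p]] - 1L) * mult
      mult <- mult * cov_card[[p]]
    }
    cfg
  }
  slice_tab <- function(success, at_risk, parents) {
    q <- if (length(parents)) prod(cov_card[parents]) else 1L
    cfg <- cfg_index(parents)
    n_risk <- tabulate(cfg[at_risk], nbins = q)
    n_succ <- tabulate(cfg[at_risk & success], nbins = q)
    pooled <- if (sum(n_risk)) sum(n_succ) / sum(n_risk) else NA_real_
    p <- ifelse(n_risk > 0L, n_succ / pmax(n_risk, 1L), pooled)
    list(parents = parents, p = p, n_risk = n_risk, pooled = pooled,
         zero_support = sum(n_risk == 0L))
  }
  nmat <- panel$n
  qmat <- panel$q
  cpt_n <- vector("list", T)
  cpt_q <- vector("list", T)
  for (t in seq_len(T)) {
    at_risk <- if (t == 1L) panel$q0 == 0L else {
      nmat[, t - 1L] == 1L & qmat[, t - 1L] == 0L
    }
    cpt_n[[t]] <- slice_tab(nmat[, t] == 1L, at_risk, parents_n[[t]])
    # censorship within slice t: among those alive after the slice's events
    risk_q <- at_risk & nmat[, t] == 1L
    cpt_q[[t]] <- slice_tab(qmat[, t] == 1L, risk_q, parents_q[[t]])
  }
  structure(list(grid = panel$grid,
                 covariate_levels = lapply(covs, levels),
                 covariate_table = covs,
                 parents_n = parents_n, parents_q = parents_q,
                 cpt_n = cpt_n, cpt_q = cpt_q,
                 structure = structure),
            class = "dbn_fit")
}

#' @export
print.dbn_fit <- function(x, ...) {
  n_edges <- sum(lengths(x$parents_n)) + sum(lengths(x$parents_q))
  cat("fitted survival 2-TBN:", length(x$grid$times), "slices,",
      length(x$covariate_levels), "covariates,",
      n_edges, "covariate-state dependencies\n")
  invisible(x)
}

#' Serialize a fitted survival model to JSON
#'
#' Writes grid, covariate domains, per-slice parent sets and tables as a
#' plain-text JSON document; [read_dbn_fit()] restores a model whose
#' estimates are bit-identical.
#'
#' @param fit A [fit_transition_cpts()] model.
#' @param path Output path.
#' @export
write_dbn_fit <- function(fit, path) {
  obj <- list(
    times = fit$grid$times,
    covariate_levels = fit$covariate_levels,
    parents_n = fit$parents_n, parents_q = fit$parents_q,
    cpt_n = fit$cpt_n, cpt_q = fit$cpt_q)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE,
                       null = "null")
  invisible(path)
}

#' Restore a fitted survival model written by [write_dbn_fit()]
#'
#' @param path JSON file path.
#' @return A `dbn_fit` object (without the original covariate rows; supply
#'   a covariate table to [dbn_marginal_survival()] explicitly).
#' @export
read_dbn_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tidy_tab <- function(x) {
    lapply(seq_len(nrow_safe(x)), function(i) {
      el <- if (is.data.frame(x)) x[i, ] else x[[i]]
      list(parents = as.character(unlist(el$parents)),
           p = as.numeric(unlist(el$p)),
           n_risk = as.integer(unlist(el$n_risk)),
           pooled = as.numeric(el$pooled)[1],
           zero_support = as.integer(el$zero_support)[1])
    })
  }
  cov_lev <- lapply(obj$covariate_levels, as.character)
  structure(list(grid = structure(list(times = as.numeric(obj$times)),
                                  class = "slice_grid"),
                 covariate_levels = cov_lev,
                 covariate_table = NULL,
                 parents_n = lapply(obj$parents_n, as.character),
                 parents_q = lapply(obj$parents_q, as.character),
                 cpt_n = tidy_tab(obj$cpt_n),
                 cpt_q = tidy_tab(obj$cpt_q),
                 structure = NULL),
            class = "dbn_fit")
}

nrow_safe <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
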