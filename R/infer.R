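#' Posterior inference by likelihood weighting
#'
#' Importance sampling for discrete BNs: non-evidence nodes are sampled
#' forward in topological order from their conditional tables; each sample
#' is weighted by the likelihood of the evidence nodes given their sampled
#' parents.  The weighted frequencies of the query node estimate its
#' posterior.
#'
#' @param bn A [new_discrete_bn()] object.
#' @param evidence Named list/vector of observed levels (may be empty).
#' @param query Name of the query node (must not be in the evidence).
#' @param n_samples Number of weighted samples.
#' @param seed Optional integer seed for reproducibility.
#' @return Named numeric vector over the query's levels, summing to 1; all
#'   `NA` (with a warning) when every sampled weight is zero, i.e. the
#'   evidence is impossible under the network.
#' @export
likelihood_weighting <- function(bn, evidence = list(), query,
                                 n_samples = 5000L, seed = NULL) {
  stopifnot(n_samples >= 1L)
  if (!is.null(seed)) set.seed(seed)
  evidence <- as.list(evidence)
  if (query %in% names(evidence)) stop("query node cannot be evidence")
  ord <- topological_order(bn$dag)
  sampled <- list()
  logw <- rep(0, n_samples)
  for (v in ord) {
    cpt <- bn$cpts[[v]]
    r <- length(cpt$levels)
    if (!length(cpt$parents)) {
      pm <- matrix(as.numeric(cpt$prob), nrow = r, ncol = n_samples)
    } else {
      flat <- matrix(cpt$prob, nrow = r)
      cfg <- rep(1L, n_samples)
      mult <- 1L
      for (p in cpt$parents) {
        cfg <- cfg + (sampled[[p]] - 1L) * mult
        mult <- mult * length(cpt$parent_levels[[p]])
      }
      pm <- flat[, cfg, drop = FALSE]
    }
    if (v %in% names(evidence)) {
      iv <- match(as.character(evidence[[v]]), cpt$levels)
      if (is.na(iv)) stop("evidence level out of domain for '", v, "'")
      sampled[[v]] <- rep(iv, n_samples)
      logw <- logw + log(pm[iv, ])
    } else {
      cum <- apply(pm, 2L, cumsum)
      u <- stats::runif(n_samples)
      sampled[[v]] <- pmin(1L + colSums(cum < rep(u, each = r)), r)
    }
  }
  w <- exp(logw)
  lev <- bn$levels[[query]]
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0) {
    warning("all likelihood weights are zero: evidence impossible under ",
            "the network")
    return(stats::setNames(rep(NA_real_, length(lev)), lev))
  }
  num <- vapply(seq_along(lev), function(l) sum(w[sampled[[query]] == l]),
                numeric(1))
  stats::setNames(num / tot, lev)
}

#' Maximum-posterior classification of one node
#'
#' Argmax of the [likelihood_weighting()] posterior, with deterministic
#' ties broken in favour of the earlier level.
#'
#' @inheritParams likelihood_weighting
#' @return The predicted level, or `NA` (abstention) when the posterior is
#'   undefined.
#' @export
posterior_classify <- function(bn, evidence = list(), query,
                               n_samples = 5000L, seed = NULL) {
  post <- likelihood_weighting(bn, evidence, query, n_samples, seed)
  if (anyNA(post)) return(NA_character_)
  names(post)[which.max(post)]
}

# Batched likelihood weighting under full evidence (all nodes but the query
# observed).  Only the query is sampled -- from P(query | parents) -- and
# each draw is weighted by the query's children's likelihoods; this is
# likelihood weighting specialised to the full-evidence pattern and
# vectorizes over test rows.  Returns an n_rows x n_levels posterior matrix.
lw_posterior_full_evidence <- function(bn, rows, query, n_samples = 500L) {
  cpt <- bn$cpts[[query]]
  r <- length(cpt$levels)
  n <- nrow(rows)
  level_idx <- function(v, vals) {
    match(as.character(vals), bn$levels[[v]])
  }
  cfg_of <- function(cpt, override_var = NULL, override_val = NULL) {
    cfg <- rep(1L, n)
    mult <- 1L
    for (p in cpt$parents) {
      j <- if (!is.null(override_var) && p == override_var) {
        rep(override_val, n)
      } else {
        level_idx(p, rows[[p]])
      }
      cfg <- cfg + (j - 1L) * mult
      mult <- mult * length(cpt$parent_levels[[p]])
    }
    cfg
  }
  # sampling distribution P(query = l | parents) per row
  flat_q <- matrix(cpt$prob, nrow = r)
  p0 <- t(flat_q[, cfg_of(cpt), drop = FALSE])      # n x r
  # weight of a draw depends only on the drawn level: children likelihoods
  children <- bn$dag$edges[bn$dag$edges[, 1L] == query, 2L]
  w_lev <- matrix(1, n, r)
  for (ch in children) {
    cpt_c <- bn$cpts[[ch]]
    flat_c <- matrix(cpt_c$prob, nrow = length(cpt_c$levels))
    iv <- level_idx(ch, rows[[ch]])
    for (l in seq_len(r)) {
      cfg <- cfg_of(cpt_c, override_var = query, override_val = l)
      w_lev[, l] <- w_lev[, l] * flat_c[cbind(iv, cfg)]
    }
  }
  # draw the query for every row
  cum <- t(apply(p0, 1L, cumsum))
  u <- matrix(stats::runif(n * n_samples), n, n_samples)
  counts <- matrix(0, n, r)
  for (l in seq_len(r)) {
    lower <- if (l == 1L) 0 else cum[, l - 1L]
    counts[, l] <- rowSums(u >= lower & u < cum[, l])
  }
  counts[, r] <- counts[, r] + rowSums(u >= cum[, r])  # fp guard
  num <- counts * w_lev
  den <- rowSums(num)
  post <- num / ifelse(den > 0, den, NA_real_)
  colnames(post) <- cpt$levels
  post
}

#' Repeated hold-out validation by posterior classification error
#'
#' Repeatedly holds out a fraction of subjects, relearns the network
#' structure and parameters on the remainder, and scores, for every state
#' node, the fraction of held-out subjects whose maximum-posterior
#' prediction (likelihood weighting, all other variables observed) is
#' wrong.
#'
#' @param data Survival records: data frame with `time`, `event`, and
#'   discrete covariates.
#' @param algorithm `"tabu"` or `"hc"`.
#' @param score Score name, see [local_score()].
#' @param iss Imaginary sample size for `bde`/`bds`.
#' @param k_reps Number of hold-out repetitions.
#' @param test_fraction Held-out fraction of subjects per repetition.
#' @param n_samples Likelihood-weighting samples per posterior.
#' @param seed Integer seed; folds and sampling are reproducible.
#' @param grid Optional [build_slice_grid()]; defaults to the unique event
#'   times of `data`.
#' @return An object of class `validation_report`: data frame of per-node
#'   mean error and SD across repetitions, plus the overall mean and fold
#'   bookkeeping in attributes.
#' @export
repeated_holdout <- function(data, algorithm = c("tabu", "hc"),
                             score = "bde", iss = 1, k_reps = 10L,
                             test_fraction = 0.30, n_samples = 500L,
                             seed = 1L, grid = NULL) {
  algorithm <- match.arg(algorithm)
  stopifnot(k_reps >= 1L, test_fraction > 0, test_fraction < 1)
  if (is.null(grid)) grid <- build_slice_grid(data)
  panel <- encode_states(data, grid)
  flat <- as_panel_frame(panel)
  T <- length(grid$times)
  state_nodes <- c(paste0("N@", seq_len(T)), paste0("Q@", seq_len(T)))
  constraints <- survival_constraints(names(panel$covariates), T)
  n <- nrow(flat)
  n_test <- max(1L, round(test_fraction * n))
  err <- matrix(NA_real_, k_reps, length(state_nodes),
                dimnames = list(NULL, state_nodes))
  set.seed(seed)
  fold_seeds <- sample.int(.Machine$integer.max, k_reps)
  for (k in seq_len(k_reps)) {
    set.seed(fold_seeds[k])
    test_idx <- sample.int(n, n_test)
    train <- flat[-test_idx, , drop = FALSE]
    test <- flat[test_idx, , drop = FALSE]
    dag <- if (algorithm == "hc") {
      hill_climb(train, score = score, iss = iss, constraints = constraints)
    } else {
      tabu_search(train, score = score, iss = iss, constraints = constraints)
    }
    bn <- fit_cpts(dag, train)
    for (v in state_nodes) {
      post <- lw_posterior_full_evidence(bn, test, v, n_samples = n_samples)
      pred <- colnames(post)[max.col(replace(post, is.na(post), -1),
                                     ties.method = "first")]
      pred[rowSums(is.na(post)) > 0] <- NA
      err[k, v] <- mean(pred != as.character(test[[v]]), na.rm = TRUE)
    }
  }
  report <- data.frame(node = state_nodes,
                       mean_error = colMeans(err),
                       sd_error = apply(err, 2L, stats::sd),
                       row.names = NULL)
  structure(report, class = c("validation_report", "data.frame"),
            overall_mean = mean(err), k_reps = k_reps,
            test_fraction = test_fraction, seed = seed,
            fold_seeds = fold_seeds)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("repeated hold-out validation (", attr(x, "k_reps"), " reps, ",
      round(100 * attr(x, "test_fraction")), "% held out)\n", sep = "")
  print.data.frame(x)
  cat("overall mean posterior classification error:",
      format(attr(x, "overall_mean"), digits = 4), "\n")
  invisible(x)
}

#' Flatten a state panel into one discrete data frame
#'
#' Covariates plus one factor column per state node (`N@t`, `Q@t` with
#' levels `0`/`1`), the representation consumed by the structure-learning
#' and validation routines.
#'
#' @param panel A [encode_states()] panel.
#' @return A data frame of factors.
#' @export
as_panel_frame <- function(panel) {
  T <- ncol(panel$n)
  out <- panel$covariates
  for (t in seq_len(T)) {
    out[[paste0("N@", t)]] <- factor(panel$n[, t], levels = c(0L, 1L))
  }
  for (t in seq_len(T)) {
    out[[paste0("Q@", t)]] <- factor(panel$q[, t], levels = c(0L, 1L))
  }
  out
}
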