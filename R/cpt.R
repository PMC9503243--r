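#' Construct a conditional probability table
#'
#' The table is stored as an array whose first dimension indexes the child's
#' levels and whose remaining dimensions index the parents' levels, with
#' dimnames carrying the level labels.  Every column (one per parent-level
#' combination) must sum to one.
#'
#' @param child Child variable name.
#' @param parents Character vector of parent names (possibly empty).
#' @param levels Character vector of the child's levels.
#' @param parent_levels Named list of level vectors, one per parent.
#' @param prob Numeric array of dimension
#'   `c(length(levels), lengths(parent_levels))` (a plain vector for a
#'   parentless node).
#' @return An object of class `cpt`.
#' @export
new_cpt <- function(child, parents, levels, parent_levels, prob) {
  parents <- as.character(parents)
  r <- length(levels)
  dims <- c(r, vapply(parent_levels, length, 1L)[parents])
  prob <- array(as.numeric(prob), dim = dims,
                dimnames = c(list(levels), parent_levels[parents]))
  flat <- matrix(prob, nrow = r)
  if (any(prob < -1e-12 | prob > 1 + 1e-12)) {
    stop("CPT entries must lie in [0, 1]")
  }
  sums <- colSums(flat)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("CPT columns for node '", child, "' do not sum to 1")
  }
  structure(list(child = child, parents = parents, levels = levels,
                 parent_levels = parent_levels[parents], prob = prob),
            class = "cpt")
}

#' @export
print.cpt <- function(x, ...) {
  cat("cpt:", x$child,
      if (length(x$parents)) paste("|", paste(x$parents, collapse = ", ")),
      "\n")
  print(x$prob)
  invisible(x)
}

# P(child = value | parent values) from one CPT. `assignment` is a named
# character vector/list covering the parents.
cpt_lookup <- function(cpt, value, assignment) {
  iv <- match(value, cpt$levels)
  if (is.na(iv)) {
    stop("level '", value, "' not in the domain of node '", cpt$child, "'")
  }
  if (!length(cpt$parents)) return(as.numeric(cpt$prob[iv]))
  idx <- c(list(iv), lapply(cpt$parents, function(p) {
    j <- match(as.character(assignment[[p]]), cpt$parent_levels[[p]])
    if (is.na(j)) {
      stop("level '", assignment[[p]], "' not in the domain of parent '",
           p, "'")
    }
    j
  }))
  as.numeric(do.call(`[`, c(list(cpt$prob), idx)))
}

#' Export a conditional probability table as delimited text
#'
#' One row per parent-level combination; the child's levels are columns.
#'
#' @param cpt A [new_cpt()] object.
#' @param path Output path.
#' @param sep Field delimiter.
#' @export
write_cpt <- function(cpt, path, sep = "\t") {
  r <- length(cpt$levels)
  flat <- t(matrix(cpt$prob, nrow = r))
  colnames(flat) <- cpt$levels
  if (length(cpt$parents)) {
    cfg <- expand.grid(cpt$parent_levels, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
    out <- cbind(cfg, flat)
  } else {
    out <- as.data.frame(flat)
  }
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a discrete Bayesian network
#'
#' @param dag A [new_dag()] object.
#' @param cpts Named list of [new_cpt()] tables, one per node; parent sets
#'   must match the DAG.
#' @return An object of class `discrete_bn` with elements `dag`, `cpts`, and
#'   `levels` (named list of level vectors).
#' @export
new_discrete_bn <- function(dag, cpts) {
  if (!setequal(names(cpts), dag$nodes)) {
    stop("`cpts` must contain exactly one table per DAG node")
  }
  pa <- dag_parents(dag)
  for (v in dag$nodes) {
    if (!setequal(cpts[[v]]$parents, pa[[v]])) {
      stop("CPT parents of '", v, "' do not match the DAG")
    }
  }
  lev <- lapply(cpts, `[[`, "levels")[dag$nodes]
  structure(list(dag = dag, cpts = cpts[dag$nodes], levels = lev),
            class = "discrete_bn")
}

#' @export
print.discrete_bn <- function(x, ...) {
  cat("discrete Bayesian network:", length(x$dag$nodes), "nodes,",
      nrow(x$dag$edges), "edges\n")
  invisible(x)
}

#' Joint probability of a full assignment under a discrete BN
#'
#' The factorization over node families: the product over nodes of
#' `P(node | parents)` read off the conditional probability tables.
#'
#' @param bn A [new_discrete_bn()] object.
#' @param assignment Named list or character vector assigning a level to
#'   every node.
#' @return The joint probability, in `[0, 1]`.
#' @export
joint_probability <- function(bn, assignment) {
  if (!all(bn$dag$nodes %in% names(assignment))) {
    stop("assignment must cover every node")
  }
  p <- 1
  for (v in bn$dag$nodes) {
    p <- p * cpt_lookup(bn$cpts[[v]], as.character(assignment[[v]]),
                        assignment)
  }
  p
}

# All joint assignments of a (small) BN as a data frame plus probabilities;
# enumeration utility used by tests and exact posteriors.
enumerate_joint <- function(bn) {
  grid <- expand.grid(bn$levels, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  p <- vapply(seq_len(nrow(grid)), function(i) {
    joint_probability(bn, as.list(grid[i, , drop = FALSE]))
  }, numeric(1))
  cbind(grid, prob = p)
}

#' Sample observations from a discrete BN by ancestral sampling
#'
#' @param bn A [new_discrete_bn()] object.
#' @param n Number of rows to draw.
#' @return A data frame of factors, one column per node.
#' @export
sample_bn <- function(bn, n) {
  ord <- topological_order(bn$dag)
  out <- vector("list", length(ord))
  names(out) <- ord
  for (v in ord) {
    cpt <- bn$cpts[[v]]
    r <- length(cpt$levels)
    if (!length(cpt$parents)) {
      pm <- matrix(as.numeric(cpt$prob), nrow = r, ncol = n)
    } else {
      flat <- matrix(cpt$prob, nrow = r)
      cfg <- rep(1L, n)
      mult <- 1L
      for (p in cpt$parents) {
        cfg <- cfg + (out[[p]] - 1L) * mult
        mult <- mult * length(cpt$parent_levels[[p]])
      }
      pm <- flat[, cfg, drop = FALSE]
    }
    cum <- apply(pm, 2L, cumsum)
    u <- stats::runif(n)
    out[[v]] <- pmin(1L + colSums(cum < rep(u, each = r)), r)
  }
  df <- as.data.frame(lapply(ord, function(v) {
    factor(bn$levels[[v]][out[[v]]], levels = bn$levels[[v]])
  }), col.names = ord, stringsAsFactors = TRUE)
  names(df) <- ord
  df[bn$dag$nodes]
}
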