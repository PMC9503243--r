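#' Sufficient statistics of one node family
#'
#' Cross-tabulates a child against the joint configurations of its parents.
#' Configurations are indexed over the full declared parent domains (so
#' unobserved combinations appear as zero columns).
#'
#' @param data Data frame of factors.
#' @param child Child column name.
#' @param parents Character vector of parent column names.
#' @return An object of class `family_counts`: list with `counts`
#'   (levels-by-configurations integer matrix), `r` (child cardinality),
#'   `q` (number of parent configurations in the declared domains), and `n`.
#' @export
family_counts <- function(data, child, parents = character()) {
  y <- data[[child]]
  if (!is.factor(y)) stop("column '", child, "' is not discrete (factor)")
  r <- nlevels(y)
  if (!length(parents)) {
    counts <- matrix(tabulate(as.integer(y), nbins = r), ncol = 1L)
  } else {
    cfg <- rep(1L, nrow(data))
    mult <- 1L
    for (p in parents) {
      z <- data[[p]]
      if (!is.factor(z)) stop("column '", p, "' is not discrete (factor)")
      cfg <- cfg + (as.integer(z) - 1L) * mult
      mult <- mult * nlevels(z)
    }
    counts <- matrix(tabulate(as.integer(y) + r * (cfg - 1L),
                              nbins = r * mult), nrow = r)
  }
  structure(list(child = child, parents = parents, counts = counts,
                 r = r, q = ncol(counts), n = nrow(data)),
            class = "family_counts")
}

#' Local (per-family) network score
#'
#' Decomposable scores used by structure search; all are computed in log
#' space and larger is better.  `loglik` is the maximised multinomial
#' log-likelihood; `aic` and `bic` subtract `k` and `(k/2) log n`
#' respectively, with `k = (r - 1) * q` free parameters; `bde` is the BDeu
#' marginal likelihood with imaginary sample size `iss` spread over all
#' configurations; `bds` is its sparse variant assigning imaginary mass only
#' to parent configurations observed in the data; `k2` is the
#' Cooper-Herskovits marginal likelihood.
#'
#' @param score One of `"loglik"`, `"aic"`, `"bic"`, `"bde"`, `"bds"`,
#'   `"k2"`.
#' @param fc A [family_counts()] object.
#' @param iss Imaginary (equivalent) sample size for `bde`/`bds`.
#' @return A finite real number (or `-Inf` for `loglik` in degenerate
#'   cases).
#' @export
local_score <- function(score = c("bic", "loglik", "aic", "bde", "bds", "k2"),
                        fc, iss = 1) {
  score <- match.arg(score)
  counts <- fc$counts
  r <- fc$r
  nj <- colSums(counts)
  if (score %in% c("loglik", "aic", "bic")) {
    nz <- counts > 0L
    ll <- sum(counts[nz] * log(counts[nz] /
                                 rep(nj, each = r)[as.vector(nz)]))
    k <- (r - 1) * fc$q
    return(switch(score,
                  loglik = ll,
                  aic = ll - k,
                  bic = ll - k / 2 * log(fc$n)))
  }
  if (score == "k2") {
    obs <- nj > 0L
    return(sum(lgamma(r) - lgamma(nj[obs] + r)) +
             sum(lgamma(counts[, obs, drop = FALSE] + 1)))
  }
  if (iss <= 0) stop("equivalent sample size `iss` must be positive")
  q_eff <- if (score == "bde") fc$q else max(1L, sum(nj > 0L))
  a_j <- iss / q_eff
  a_jk <- iss / (r * q_eff)
  obs <- if (score == "bde") rep(TRUE, fc$q) else nj > 0L
  sum(lgamma(a_j) - lgamma(a_j + nj[obs])) +
    sum(lgamma(a_jk + counts[, obs, drop = FALSE]) - lgamma(a_jk))
}

#' Whole-network score
#'
#' Sum of [local_score()] over every node family of the DAG; equals the
#' decomposition the search algorithms exploit.
#'
#' @param score Score name, see [local_score()].
#' @param dag A [new_dag()] object whose nodes are columns of `data`.
#' @param data Data frame of factors.
#' @param iss Imaginary sample size for `bde`/`bds`.
#' @return The network score.
#' @export
network_score <- function(score, dag, data, iss = 1) {
  if (!all(dag$nodes %in% names(data))) {
    stop("every DAG node must be a column of `data`")
  }
  pa <- dag_parents(dag)
  sum(vapply(dag$nodes, function(v) {
    local_score(score, family_counts(data, v, pa[[v]]), iss = iss)
  }, numeric(1)))
}
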