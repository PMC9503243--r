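# Shared fixtures, all generated in code.

# Random right-censored dataset; rounding induces ties (events vs censorings
# at the same time), stressing the tie conventions.
random_censored_data <- function(n, p_event = 0.7, rate = 0.3,
                                 digits = 2) {
  data.frame(time = round(stats::rexp(n, rate), digits),
             event = stats::rbinom(n, 1, p_event))
}

# Independent oracle: classic KM risk-set accounting straight from
# (time, event) pairs (events precede censorings at ties; a subject censored
# exactly at an event time stays in the risk set there).
km_counts_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  d <- vapply(ts, function(tt) sum(time == tt & event == 1), 0)
  y <- vapply(ts, function(tt) sum(time > tt | (time == tt)), 0)
  list(times = ts, d = as.integer(d), y = as.integer(y))
}

# A small random discrete BN over `k` binary nodes with CPT entries bounded
# away from 0/1 (so importance weights stay well behaved).
random_binary_bn <- function(k, p_edge = 0.4, lo = 0.15, hi = 0.85) {
  nodes <- paste0("V", seq_len(k))
  edges <- NULL
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      if (stats::runif(1) < p_edge) edges <- rbind(edges,
                                                   c(nodes[i], nodes[j]))
    }
  }
  dag <- new_dag(nodes, edges)
  pa <- dbnsurv:::dag_parents(dag)
  cpts <- lapply(nodes, function(v) {
    q <- 2^length(pa[[v]])
    p1 <- stats::runif(q, lo, hi)
    plev <- stats::setNames(rep(list(c("0", "1")), length(pa[[v]])),
                            pa[[v]])
    new_cpt(v, pa[[v]], c("0", "1"), plev, rbind(1 - p1, p1))
  })
  names(cpts) <- nodes
  new_discrete_bn(dag, cpts)
}

# Exact posterior by enumeration.
enum_posterior <- function(bn, evidence, query) {
  tab <- dbnsurv:::enumerate_joint(bn)
  keep <- rep(TRUE, nrow(tab))
  for (v in names(evidence)) {
    keep <- keep & tab[[v]] == as.character(evidence[[v]])
  }
  tab <- tab[keep, ]
  p <- tapply(tab$prob, tab[[query]], sum)
  p / sum(p)
}

# Generator for the structure-recovery experiments: a three-slice survival
# process over five Bernoulli(1/2) covariates where x1 lowers survival of
# slice 2 and x2 lowers survival of slice 3; constant light censoring.
recovery_data <- function(n) {
  x <- matrix(stats::rbinom(n * 5, 1, 0.5), n, 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  p_surv <- cbind(0.90,
                  ifelse(x[, 1] == 1, 0.45, 0.85),
                  ifelse(x[, 2] == 1, 0.40, 0.80))
  time <- rep(4, n)
  event <- integer(n)
  active <- rep(TRUE, n)
  for (t in 1:3) {
    die <- active & stats::runif(n) > p_surv[, t]
    time[die] <- t
    event[die] <- 1L
    active <- active & !die
    cen <- active & stats::runif(n) < 0.05
    time[cen] <- t
    active <- active & !cen
  }
  data.frame(time = time, event = event, as.data.frame(x))
}
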