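two_node_bn <- function() {
  dag <- new_dag(c("A", "B"), rbind(c("A", "B")))
  new_discrete_bn(dag, list(
    A = new_cpt("A", character(), c("0", "1"), list(), c(0.5, 0.5)),
    B = new_cpt("B", "A", c("0", "1"), list(A = c("0", "1")),
                cbind(c(0.8, 0.2), c(0.1, 0.9)))))
}

test_that("likelihood weighting recovers the exact diagnostic posterior", {
  bn <- two_node_bn()
  post <- likelihood_weighting(bn, list(B = "1"), "A",
                               n_samples = 100000, seed = 1)
  expect_equal(unname(post["1"]), 0.9 / 1.1, tolerance = 0.01)
  expect_equal(sum(post), 1)
  # empty evidence: the marginal, matching enumeration
  marg <- likelihood_weighting(bn, list(), "B", n_samples = 50000,
                               seed = 2)
  exact <- enum_posterior(bn, list(), "B")
  expect_equal(unname(marg["1"]), unname(exact["1"]), tolerance = 0.01)
  # evidence on the only parent: the CPT row itself
  row <- likelihood_weighting(bn, list(A = "1"), "B", n_samples = 50000,
                              seed = 3)
  expect_equal(unname(row["1"]), 0.9, tolerance = 0.01)
})

test_that("likelihood weighting stays within three importance-sampling
           standard errors of enumeration", {
  set.seed(55)
  n_samp <- 20000
  n_checked <- 0
  for (net_i in 1:10) {
    bn <- random_binary_bn(5, p_edge = 0.5)
    for (pat in 1:10) {
      k_ev <- sample(1:2, 1)
      ev_nodes <- sample(bn$dag$nodes, k_ev)
      query <- sample(setdiff(bn$dag$nodes, ev_nodes), 1)
      evidence <- stats::setNames(as.list(sample(c("0", "1"), k_ev,
                                                 replace = TRUE)),
                                  ev_nodes)
      exact <- enum_posterior(bn, evidence, query)
      post <- likelihood_weighting(bn, evidence, query,
                                   n_samples = n_samp, seed = pat)
      # exact importance-sampling SE bound from enumeration: weights are
      # products of evidence-CPT entries over the proposal distribution
      tab <- dbnsurv:::enumerate_joint(bn)
      w_of_row <- rep(1, nrow(tab))
      keep <- rep(TRUE, nrow(tab))
      for (v in names(evidence)) {
        keep <- keep & tab[[v]] == evidence[[v]]
      }
      # proposal = joint of non-evidence nodes with evidence clamped;
      # restricted rows carry q(x) = p(x)/w(x), w = P(e | parents)
      p_e <- sum(tab$prob[keep])
      # importance weights under the likelihood-weighting proposal: the
      # proposal samples non-evidence nodes from the prior with evidence
      # clamped, so on the kept rows w(x) = p(x) / q(x) with q(x) the
      # marginal of the non-evidence configuration
      nonev <- setdiff(bn$dag$nodes, names(evidence))
      key <- do.call(paste, tab[nonev])
      q_marg <- tapply(tab$prob, key, sum)   # P(non-evidence config)
      qx <- as.numeric(q_marg[key[keep]])
      wx <- tab$prob[keep] / qx
      ess_se <- sqrt(max(sum(qx * wx^2) / p_e^2 - 1, 1e-12) / n_samp)
      p1 <- unname(exact["1"])
      tol <- 3 * (ess_se + sqrt(p1 * (1 - p1) / n_samp) * 3)
      expect_lt(abs(unname(post["1"]) - p1), max(tol, 0.02))
      n_checked <- n_checked + 1
    }
  }
  expect_equal(n_checked, 100)
})

test_that("impossible evidence yields a flagged undefined posterior and an
           abstention", {
  dag <- new_dag(c("A", "B"), rbind(c("A", "B")))
  bn <- new_discrete_bn(dag, list(
    A = new_cpt("A", character(), c("0", "1"), list(), c(1, 0)),
    B = new_cpt("B", "A", c("0", "1"), list(A = c("0", "1")),
                cbind(c(1, 0), c(0, 1)))))
  expect_warning(post <- likelihood_weighting(bn, list(B = "1"), "A",
                                              n_samples = 100, seed = 1),
                 "impossible")
  expect_true(all(is.na(post)))
  expect_warning(cls <- posterior_classify(bn, list(B = "1"), "A",
                                           n_samples = 100, seed = 1))
  expect_true(is.na(cls))
})

test_that("classification takes the maximum-posterior level with
           deterministic ties", {
  bn <- two_node_bn()
  expect_equal(posterior_classify(bn, list(B = "1"), "A",
                                  n_samples = 20000, seed = 4), "1")
  # deterministic chain always forces the level
  dag <- new_dag(c("A", "B"), rbind(c("A", "B")))
  det <- new_discrete_bn(dag, list(
    A = new_cpt("A", character(), c("0", "1"), list(), c(0, 1)),
    B = new_cpt("B", "A", c("0", "1"), list(A = c("0", "1")),
                cbind(c(1, 0), c(0, 1)))))
  expect_equal(posterior_classify(det, list(B = "1"), "A",
                                  n_samples = 100, seed = 5), "1")
})

test_that("batched full-evidence posteriors agree with single-case
           likelihood weighting", {
  set.seed(56)
  bn <- random_binary_bn(4, p_edge = 0.6)
  rows <- sample_bn(bn, 20)
  post <- dbnsurv:::lw_posterior_full_evidence(bn, rows, "V2",
                                               n_samples = 20000)
  for (i in c(1, 7, 13)) {
    ev <- as.list(rows[i, setdiff(names(rows), "V2"), drop = FALSE])
    single <- likelihood_weighting(bn, ev, "V2", n_samples = 20000,
                                   seed = i)
    expect_equal(unname(post[i, "1"]), unname(single["1"]),
                 tolerance = 0.03)
  }
})

test_that("repeated hold-out is reproducible and nails deterministic
           data", {
  set.seed(57)
  # deterministic survival: covariate g fixes the failure slice exactly
  g <- rep(c("a", "b"), each = 40)
  d <- data.frame(time = ifelse(g == "a", 1, 2), event = 1, g = factor(g))
  rep1 <- repeated_holdout(d, algorithm = "hc", score = "bic", k_reps = 3,
                           n_samples = 200, seed = 9)
  rep2 <- repeated_holdout(d, algorithm = "hc", score = "bic", k_reps = 3,
                           n_samples = 200, seed = 9)
  expect_identical(rep1$mean_error, rep2$mean_error)
  expect_true(all(rep1$mean_error == 0))
})

test_that("pure-noise nodes sit at chance-level error", {
  set.seed(58)
  n <- 400
  # fair-coin failure at slice 1 vs 2, no covariate signal
  d <- data.frame(time = 1 + rbinom(n, 1, 0.5), event = 1,
                  z = factor(rbinom(n, 1, 0.5)))
  rep1 <- repeated_holdout(d, algorithm = "hc", score = "bic", k_reps = 4,
                           n_samples = 300, seed = 10)
  err_n1 <- rep1$mean_error[rep1$node == "N@1"]
  expect_gt(err_n1, 0.35)
  expect_lt(err_n1, 0.65)
})
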