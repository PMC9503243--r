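toy_counts <- function() {
  d <- data.frame(time = c(1, 2, 3), event = c(1, 0, 1))
  tabulate_counts(encode_states(d, build_slice_grid(d)))
}

test_that("the product-limit estimate matches hand evaluation on the toy
           cohort", {
  km <- km_estimate(toy_counts())
  expect_equal(km$surv, c(2 / 3, 0))
  expect_equal(km$variance[1], (2 / 3)^2 * 1 / (3 * 2))
})

test_that("without censoring the curve telescopes to the empirical
           fraction", {
  d <- data.frame(time = c(1, 1, 2, 3, 3, 3), event = rep(1, 6))
  km <- km_estimate(tabulate_counts(encode_states(d, build_slice_grid(d))))
  expect_equal(km$surv, c(4 / 6, 3 / 6, 0))
})

test_that("Greenwood equals brute-force term-by-term evaluation", {
  set.seed(51)
  for (i in 1:200) {
    d <- random_censored_data(sample(5:100, 1))
    if (sum(d$event) == 0) next
    cn <- tabulate_counts(encode_states(d, build_slice_grid(d)))
    km <- km_estimate(cn)
    brute <- vapply(seq_along(cn$times), function(j) {
      acc <- 0
      for (i2 in seq_len(j)) {
        if (cn$y[i2] > cn$d[i2]) {
          acc <- acc + cn$d[i2] / (cn$y[i2] * (cn$y[i2] - cn$d[i2]))
        } else {
          return(NA_real_)  # exhausted risk set: estimate is zero there
        }
      }
      km$surv[j]^2 * acc
    }, numeric(1))
    defined <- !is.na(brute)
    expect_equal(km$variance[defined], brute[defined], tolerance = 1e-12)
    expect_true(all(km$variance[!defined] == 0))
  }
})

test_that("degenerate single-subject curve has zero flagged variance", {
  d <- data.frame(time = 1, event = 1)
  km <- km_estimate(tabulate_counts(encode_states(d, build_slice_grid(d))))
  expect_equal(km$surv, 0)
  expect_equal(km$variance[1], 0)
  expect_false(attr(km$variance, "greenwood_defined")[1])
})

test_that("step-function lookup is right-continuous", {
  cv <- dbnsurv:::new_survival_curve(c(1, 3), c(0.6, 0.2))
  expect_equal(evaluate_at(cv, 0.5), 1)
  expect_equal(evaluate_at(cv, 1), 0.6)
  expect_equal(evaluate_at(cv, 2.9), 0.6)
  expect_equal(evaluate_at(cv, 3), 0.2)
  expect_equal(evaluate_at(cv, 100), 0.2)
  expect_error(evaluate_at(cv, -1), "nonnegative")
})

test_that("the network estimator reproduces Kaplan-Meier exactly without
           covariates, against the survfit oracle", {
  set.seed(52)
  for (i in 1:100) {
    d <- random_censored_data(sample(5:150, 1))
    if (sum(d$event) == 0) next
    grid <- build_slice_grid(d)
    panel <- encode_states(d, grid)
    km <- km_estimate(tabulate_counts(panel))
    fit <- fit_transition_cpts(panel)
    expect_equal(dbn_survival(fit)$surv, km$surv, tolerance = 1e-15)
    expect_equal(dbn_marginal_survival(fit)$surv, km$surv,
                 tolerance = 1e-15)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    expect_equal(km$surv, summary(sf, times = grid$times,
                                  extend = TRUE)$surv,
                 tolerance = 1e-12)
  }
})

test_that("curves are monotone and in range for random inputs", {
  set.seed(53)
  for (i in 1:50) {
    d <- random_censored_data(sample(10:100, 1))
    if (sum(d$event) == 0) next
    km <- km_estimate(tabulate_counts(encode_states(d,
                                                    build_slice_grid(d))))
    expect_true(all(km$surv >= 0 & km$surv <= 1))
    expect_true(all(diff(km$surv) <= 1e-15))
    expect_true(all(km$variance >= 0))
  }
})

test_that("a covariate parenting one slice splits only the factors from
           that slice on", {
  set.seed(54)
  n <- 400
  z <- rbinom(n, 1, 0.5)
  t1 <- ifelse(z == 1, rbinom(n, 1, 0.5), rbinom(n, 1, 0.05))
  time <- ifelse(t1 == 1, 1, 2 + rbinom(n, 1, 0.5))
  d <- data.frame(time = time, event = 1, z = factor(z))
  grid <- build_slice_grid(d)
  panel <- encode_states(d, grid)
  T <- length(grid$times)
  edges <- rbind(c("z", "N@1"),
                 cbind(paste0("N@", 1:(T - 1)), paste0("N@", 2:T)),
                 cbind(paste0("Q@", 1:(T - 1)), paste0("N@", 2:T)))
  dag <- new_dag(c("z", paste0("N@", 1:T), paste0("Q@", 1:T)), edges)
  fit <- fit_transition_cpts(panel, dag)
  s0 <- dbn_survival(fit, list(z = "0"))
  s1 <- dbn_survival(fit, list(z = "1"))
  r0 <- s0$surv / c(s0$surv[1], head(s0$surv, -1))
  r1 <- s1$surv / c(s1$surv[1], head(s1$surv, -1))
  expect_false(isTRUE(all.equal(s0$surv[1], s1$surv[1])))
  expect_equal(r0[-1], r1[-1], tolerance = 1e-12)
})

test_that("marginal mixtures average profile curves with empirical
           weights", {
  # two equal-weight strata with survival 1 and 0 after slice 1
  d <- data.frame(time = c(rep(1, 5), rep(9, 5)),
                  event = c(rep(1, 5), rep(0, 5)),
                  g = factor(rep(c("a", "b"), each = 5)))
  grid <- build_slice_grid(d)
  panel <- encode_states(d, grid)
  dag <- new_dag(c("g", "N@1", "Q@1"), rbind(c("g", "N@1")))
  fit <- fit_transition_cpts(panel, dag)
  expect_equal(dbn_survival(fit, list(g = "a"))$surv, 0)
  expect_equal(dbn_survival(fit, list(g = "b"))$surv, 1)
  expect_equal(dbn_marginal_survival(fit)$surv, 0.5)
})

test_that("profiles fixing unknown covariates warn and are ignored", {
  d <- data.frame(time = c(1, 2, 3), event = c(1, 0, 1))
  fit <- fit_transition_cpts(encode_states(d, build_slice_grid(d)))
  expect_warning(cv <- dbn_survival(fit, list(nope = "x")), "ignored")
  expect_equal(cv$surv, c(2 / 3, 0))
})

test_that("curve text export round-trips", {
  km <- km_estimate(toy_counts())
  path <- file.path(tempdir(), "curve.tsv")
  write_curve(km, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$survival, km$surv)
  expect_equal(back$time, km$time)
})
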