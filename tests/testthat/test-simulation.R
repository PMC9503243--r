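test_that("covariate draws have the designed marginals and replay under a
           seed", {
  x <- sample_covariates(100000, seed = 61)
  p <- c(0.1, 0.2, 0.5, 0.7, 0.9)
  se <- sqrt(p * (1 - p) / 100000)
  expect_true(all(abs(colMeans(x) - p) < 3 * se))
  expect_identical(sample_covariates(50, seed = 62),
                   sample_covariates(50, seed = 62))
  expect_true(all(sample_covariates(10, probs = rep(1 - 1e-12, 5)) == 1))
  expect_equal(survival_scale(c(0, 1, 0, 1, 1)), 3)
  expect_equal(survival_scale(rep(0, 5)), 0)
})

test_that("the inverse-CDF Weibull sampler matches its closed forms", {
  expect_equal(sample_weibull(3, 0.5, exp(-1)), 3)
  expect_equal(sample_weibull(3, 2, exp(-1)), 3)
  expect_equal(sample_weibull(0, 2, 0.4), 0)
  expect_error(sample_weibull(1, 1, 1.2), "strictly")
  set.seed(63)
  u <- runif(100000)
  s <- sample_weibull(2, 1, u)
  expect_equal(mean(s), 2, tolerance = 0.02)  # exponential mean = theta
  # empirical CDF against F(s) = 1 - exp(-(s/theta)^alpha)
  s2 <- sample_weibull(2, 1.7, runif(100000))
  gridpts <- quantile(s2, seq(0.05, 0.95, by = 0.05))
  emp <- ecdf(s2)(gridpts)
  theo <- 1 - exp(-(gridpts / 2)^1.7)
  expect_lt(max(abs(emp - theo)), 0.005)
})

test_that("censoring-scale calibration solves the competing-risk
           equation", {
  # exponential closed form with a degenerate covariate sum of 3:
  # P(C < S) = theta_s / (theta_s + theta_c)
  th <- calibrate_censor_scale(1, 1, probs = c(1 - 1e-12, 1 - 1e-12,
                                               1 - 1e-12, 1e-12, 1e-12),
                               R = 0.25)
  expect_equal(th, 9, tolerance = 1e-4)
  # achieved censoring within Monte-Carlo tolerance of the target
  th2 <- calibrate_censor_scale(2, 2, R = 0.40)
  set.seed(64)
  n <- 100000
  x <- sample_covariates(n)
  s <- sample_weibull(rowSums(x), 2, runif(n))
  cc <- sample_weibull(th2, 2, runif(n))
  expect_lt(abs(mean(cc < s) - 0.40), 3 * sqrt(0.4 * 0.6 / n))
  # theta_c increases monotonically as the target rate drops
  ths <- vapply(c(0.6, 0.4, 0.25, 0.1), function(R) {
    calibrate_censor_scale(2, 2, R = R)
  }, numeric(1))
  expect_true(all(diff(ths) > 0))
})

test_that("true marginal survival mixes the covariate patterns with an
           atom at zero", {
  probs <- c(0.1, 0.2, 0.5, 0.7, 0.9)
  expect_equal(true_marginal_survival(0, 2, probs), 1)
  p0 <- prod(1 - probs)
  expect_equal(true_marginal_survival(1e-9, 2, probs), 1 - p0,
               tolerance = 1e-6)
  # degenerate single pattern, exponential median
  one <- c(1 - 1e-12, rep(1e-12, 4))
  expect_equal(true_marginal_survival(log(2), 1, one), 0.5,
               tolerance = 1e-6)
  # agreement with simulation
  set.seed(65)
  n <- 200000
  s <- sample_weibull(rowSums(sample_covariates(n, probs)), 2, runif(n))
  for (t in c(0.5, 1.5, 3)) {
    emp <- mean(s > t)
    se <- sqrt(emp * (1 - emp) / n)
    expect_lt(abs(true_marginal_survival(t, 2, probs) - emp), 3 * se)
  }
})

test_that("population percentiles invert the survival mixture", {
  expect_equal(true_percentile(0.5, 1, c(1 - 1e-12, rep(1e-12, 4))),
               log(2), tolerance = 1e-6)
  tps <- vapply(c(0.2, 0.5, 0.8), true_percentile, numeric(1),
                alpha_s = 2)
  expect_true(all(diff(tps) > 0))
  for (i in seq_along(tps)) {
    expect_equal(true_marginal_survival(tps[i], 2),
                 1 - c(0.2, 0.5, 0.8)[i], tolerance = 1e-6)
  }
})

test_that("the Cox comparator recovers effect directions and collapses to
           the baseline without covariates", {
  set.seed(66)
  n <- 2000
  x1 <- rbinom(n, 1, 0.5)
  s <- rexp(n, rate = ifelse(x1 == 1, 0.3, 1))  # x1 protective
  cc <- rexp(n, 0.2)
  d <- data.frame(time = pmin(s, cc), event = as.integer(s <= cc),
                  x1 = x1)
  cf <- cox_marginal_fit(d)
  expect_lt(cf$coef[["x1"]], 0)
  ref <- survival::coxph(survival::Surv(time, event) ~ x1, data = d,
                         ties = "breslow")
  expect_equal(unname(cf$coef), unname(coef(ref)), tolerance = 1e-10)

  # constant covariates: prediction equals the Kaplan-Meier baseline
  d0 <- d
  d0$x1 <- 0L
  cf0 <- cox_marginal_fit(d0)
  km <- km_estimate(tabulate_counts(encode_states(
    d0[c("time", "event")], build_slice_grid(d0))))
  tt <- quantile(d0$time, c(0.2, 0.5), names = FALSE)
  expect_equal(evaluate_at(cf0, tt), evaluate_at(km, tt),
               tolerance = 1e-9)
})

test_that("the simulation network estimator equals Kaplan-Meier on
           covariate-free data", {
  set.seed(67)
  for (i in 1:20) {
    n <- sample(30:150, 1)
    d <- data.frame(time = round(rexp(n, 0.4), 2),
                    event = rbinom(n, 1, 0.7))
    if (sum(d$event) == 0) next
    km <- km_estimate(tabulate_counts(encode_states(
      d, build_slice_grid(d))))
    dbn <- dbn_simulation_estimator(d)      # no x columns: fixed chain
    expect_equal(dbn$surv, km$surv, tolerance = 1e-12)
  }
})

test_that("scenario aggregation satisfies its arithmetic contracts", {
  res <- run_scenario(300, 0.25, 2, 2, n_reps = 8, seed = 68,
                      estimators = c("km", "cox"))
  expect_true(all(res$rmse >= abs(res$bias) - 1e-12))
  expect_true(all(is.finite(res$bias)))
  expect_lt(abs(attr(res, "censor_fraction") - 0.25), 0.08)
  # per-replicate seeding: same seed reproduces, different seed varies
  res2 <- run_scenario(300, 0.25, 2, 2, n_reps = 8, seed = 68,
                       estimators = c("km", "cox"))
  expect_identical(res$bias, res2$bias)
})

test_that("resampling the all-zero covariate pattern removes the atom", {
  res <- run_scenario(200, 0.25, 2, 2, n_reps = 2, seed = 69,
                      estimators = "km", zero_sum = "resample")
  expect_true(all(is.finite(res$bias)))
})
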