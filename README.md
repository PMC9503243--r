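# dbnsurv

Survival analysis with discrete dynamic Bayesian networks, for
biostatisticians and epidemiologists who want Kaplan–Meier's assumptions
with a graphical model's covariate machinery.

Right-censored follow-up is discretized into slices at the unique event
times, and each subject is encoded by two absorbing binary states per
slice: `N@t` (still alive entering slice *t*) and `Q@t` (censored by slice
*t*). A two-slice temporal Bayesian network — a prior network over slice 1
plus a transition network between adjacent slices — then carries the
product-limit computation:

    S(t) = P(N1 = 1 | Z) * prod_{t'=2..t} P(N_t' = 1 | N_{t'-1} = 1, Q_{t'-1} = 0, Z_t')

where the per-slice covariate parents `Z_t'` are chosen by score-based
structure learning (Hill-Climbing or Tabu search over log-likelihood, AIC,
BIC, BDe, BDS or K2, under whitelist/blacklist constraints that enforce
the temporal topology). With no covariate parents the estimator **is** the
Kaplan–Meier product-limit estimator, exactly; with covariates it yields
slice-resolved feature selection, profile-specific curves, a covariate
dependency graph, and posterior prediction of any state via likelihood
weighting. Pointwise variances use the Greenwood formula.

The package also contains:

* a repeated hold-out validator scoring per-node posterior classification
  error,
* a synthetic gastrectomy-like cohort generator (760 subjects, 14 slices,
  calibrated covariate effects) providing ground truth for recovery and
  validation experiments,
* a Weibull simulation engine comparing the network estimator against
  Kaplan–Meier and Cox proportional hazards on bias/RMSE of
  survival-probability estimates, with censoring-rate calibration,
* a command-line front end (`inst/scripts/dbnsurv`) with `fit`,
  `simulate`, `validate` and `fixture` subcommands.

## Worked example

```r
library(dbnsurv)

cohort <- generate_fixture(760, seed = 42)   # synthetic gastrectomy cohort
res <- run_pipeline(cohort, algorithm = "hc", score = "bic", seed = 1)

# covariate-to-state edges selected by the search:
res$dag$edges[grepl("^[a-z]", res$dag$edges[, 1]) &
              grepl("@", res$dag$edges[, 2]), ]
#>      from         to
#> [1,] "age"        "N@1"
#> [2,] "metastasis" "N@4"

# profile-specific survival from the fitted network:
s <- dbn_survival(res$fit, profile = list(age = "<61",
                                          metastasis = "Non-Metastasis"))
evaluate_at(s, c(1, 5, 10))
#> 0.902 0.552 0.347          # vs 0.510 0.313 0.196 for age > 70
```

The search recovers exactly the two covariate effects built into the
generator (age acting on first-year survival, metastasis on year 4), and
the population-level curve agrees with Kaplan–Meier to the third decimal
(`S(5)` = 0.4155 vs 0.4160) while the profile curves separate the risk
groups. On covariate-free data the agreement is exact to machine
precision — that equivalence is the package's central invariant and is
tested as such.

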