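#' Specification of the synthetic gastrectomy-like cohort
#'
#' A generator emulating a post-gastrectomy gastric-cancer cohort: 760
#' subjects followed for up to 15 years with yearly follow-up, no events in
#' year 13 (so the slice grid has 14 slices), eight baseline covariates
#' with marginals close to the published descriptive table plus a TNM node,
#' a dependency chain among covariates (sex to smoking and pathology,
#' smoking to metastasis, metastasis to TNM to stage, site to surgery), and
#' designated covariate effects on the state chain: age on survival in
#' years 1-2, metastasis on survival in year 4, age on censorship in years
#' 6-7 and pathology on censorship in years 3 and 5.  All conditional
#' tables are synthetic (the generator provides known ground truth for
#' structure-recovery and validation experiments); hazards alternate
#' high/low across years so that each state node is highly predictable
#' from its neighbours.
#'
#' @return A list with the covariate network (`covariate_bn`), yearly
#'   baseline event hazards (`h_base`), yearly baseline censoring
#'   probabilities (`c_base`), the effect tables, and the follow-up
#'   horizon.
#' @export
gastric_fixture_spec <- function() {
  cpt0 <- function(child, levels, p) {
    new_cpt(child, character(), levels, list(), p)
  }
  cpt1 <- function(child, parent, levels, plev, rows) {
    new_cpt(child, parent, levels, stats::setNames(list(plev), parent),
            do.call(cbind, rows))
  }
  sex <- cpt0("sex", c("Female", "Male"), c(0.32, 0.68))
  age <- cpt0("age", c("<61", "61-70", ">70"), c(0.24, 0.48, 0.28))
  site <- cpt0("site", c("Cardia", "Antrum", "Other"), c(0.45, 0.20, 0.35))
  smoking <- cpt1("smoking", "sex", c("Non-smoker", "Smoker"),
                  c("Female", "Male"),
                  list(c(0.885, 0.115), c(0.60, 0.40)))
  pathology <- cpt1("pathology", "sex", c("Adeno", "Other"),
                    c("Female", "Male"),
                    list(c(0.8375, 0.1625), c(0.90, 0.10)))
  metastasis <- cpt1("metastasis", "smoking",
                     c("Non-Metastasis", "Metastasis"),
                     c("Non-smoker", "Smoker"),
                     list(c(0.452, 0.548), c(0.35, 0.65)))
  tnm <- cpt1("TNM", "metastasis", c("T1", "T2", "T3", "T4"),
              c("Non-Metastasis", "Metastasis"),
              list(c(0.25, 0.40, 0.25, 0.10), c(0.05, 0.20, 0.40, 0.35)))
  stage_prob <- array(0, c(4, 2, 4),
                      dimnames = list(c("I", "II", "III", "IV"),
                                      c("Non-Metastasis", "Metastasis"),
                                      c("T1", "T2", "T3", "T4")))
  stage_prob[, 1, 1] <- c(0.45, 0.45, 0.09, 0.01)
  stage_prob[, 1, 2] <- c(0.10, 0.62, 0.25, 0.03)
  stage_prob[, 1, 3] <- c(0.02, 0.40, 0.50, 0.08)
  stage_prob[, 1, 4] <- c(0.01, 0.25, 0.55, 0.19)
  stage_prob[, 2, 1] <- c(0.15, 0.50, 0.30, 0.05)
  stage_prob[, 2, 2] <- c(0.03, 0.45, 0.45, 0.07)
  stage_prob[, 2, 3] <- c(0.00, 0.25, 0.55, 0.20)
  stage_prob[, 2, 4] <- c(0.00, 0.08, 0.47, 0.45)
  stage <- new_cpt("stage", c("metastasis", "TNM"),
                   c("I", "II", "III", "IV"),
                   list(metastasis = c("Non-Metastasis", "Metastasis"),
                        TNM = c("T1", "T2", "T3", "T4")),
                   stage_prob)
  surgery <- cpt1("surgery", "site",
                  c("Total gastrectomy", "Subtotal gastrectomy",
                    "Distal gastrectomy", "Partial gastrectomy",
                    "Proximal gastrectomy"),
                  c("Cardia", "Antrum", "Other"),
                  list(c(0.62, 0.17, 0.01, 0.06, 0.14),
                       c(0.38, 0.42, 0.12, 0.05, 0.03),
                       c(0.48, 0.29, 0.04, 0.12, 0.07)))
  dag <- new_dag(c("sex", "age", "site", "smoking", "pathology",
                   "metastasis", "TNM", "stage", "surgery"),
                 rbind(c("sex", "smoking"), c("sex", "pathology"),
                       c("smoking", "metastasis"), c("metastasis", "TNM"),
                       c("metastasis", "stage"), c("TNM", "stage"),
                       c("site", "surgery")))
  covariate_bn <- new_discrete_bn(dag, list(
    sex = sex, age = age, site = site, smoking = smoking,
    pathology = pathology, metastasis = metastasis, TNM = tnm,
    stage = stage, surgery = surgery))
  list(
    n_subjects = 760L,
    horizon = 15L,
    covariate_bn = covariate_bn,
    # yearly event hazards; year 13 is event-free by design, so the unique
    # event years are 1..12, 14, 15 (14 slices)
    h_base = c(0.24, 0.055, 0.20, 0.05, 0.17, 0.045, 0.15, 0.04,
               0.13, 0.035, 0.11, 0.03, 0, 0.10, 0.08),
    c_base = rep(0.025, 15L),
    age_hazard_years = c(1L, 2L),
    age_hazard_mult = c("<61" = 0.45, "61-70" = 1.0, ">70" = 2.0),
    metastasis_hazard_year = 4L,
    metastasis_hazard_mult = c("Non-Metastasis" = 0.3, "Metastasis" = 2.0),
    censor_age = list("6" = c("<61" = 0.02, "61-70" = 0.02, ">70" = 0.12),
                      "7" = c("<61" = 0.15, "61-70" = 0.02, ">70" = 0.005)),
    censor_pathology = list("3" = c("Adeno" = 0.02, "Other" = 0.14),
                            "5" = c("Adeno" = 0.02, "Other" = 0.13)))
}

#' Generate a synthetic gastrectomy-like cohort
#'
#' Ancestral sampling through the covariate network followed by a yearly
#' discrete-time competing draw: in each year a subject still under
#' observation first faces the event hazard (with the designated covariate
#' effects) and, surviving it, the censoring probability; survivors past
#' the horizon are censored there.  Event times are whole years.
#'
#' @param n Number of subjects.
#' @param seed Optional integer seed.
#' @param spec A [gastric_fixture_spec()] list.
#' @return A data frame with `time`, `event`, and the covariate columns.
#' @export
generate_fixture <- function(n = 760L, seed = NULL,
                             spec = gastric_fixture_spec()) {
  if (!is.null(seed)) set.seed(seed)
  covs <- sample_bn(spec$covariate_bn, n)
  horizon <- spec$horizon
  h <- matrix(spec$h_base, n, horizon, byrow = TRUE)
  for (t in spec$age_hazard_years) {
    h[, t] <- h[, t] * spec$age_hazard_mult[as.character(covs$age)]
  }
  t_met <- spec$metastasis_hazard_year
  h[, t_met] <- h[, t_met] *
    spec$metastasis_hazard_mult[as.character(covs$metastasis)]
  cens <- matrix(spec$c_base, n, horizon, byrow = TRUE)
  for (yr in names(spec$censor_age)) {
    cens[, as.integer(yr)] <- spec$censor_age[[yr]][as.character(covs$age)]
  }
  for (yr in names(spec$censor_pathology)) {
    cens[, as.integer(yr)] <-
      spec$censor_pathology[[yr]][as.character(covs$pathology)]
  }
  time <- rep(horizon, n)
  event <- rep(0L, n)
  active <- rep(TRUE, n)
  for (t in seq_len(horizon)) {
    die <- active & stats::runif(n) < h[, t]
    time[die] <- t
    event[die] <- 1L
    active <- active & !die
    cen <- active & stats::runif(n) < cens[, t]
    time[cen] <- t
    active <- active & !cen
  }
  data.frame(time = time, event = event, covs)
}

#' Read right-censored survival records from delimited text
#'
#' @param path File path; header mandatory, columns `time` (numeric) and
#'   `event` (0/1) required, all remaining columns treated as discrete
#'   covariates.
#' @param sep Field delimiter (default tab).
#' @return A data frame with `time`, `event` and factor covariates.
#' @export
read_survival_data <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  check_records(df)
  for (v in setdiff(names(df), c("time", "event"))) {
    df[[v]] <- factor(df[[v]])
  }
  df
}

#' End-to-end survival-network pipeline
#'
#' Encode the records, learn the constrained network structure, fit the
#' per-slice tables, estimate the marginal survival curve, and (optionally)
#' run the repeated hold-out validation.  Outputs (DOT graph, curve table,
#' fitted model, validation report) are written under `out_dir` when given.
#'
#' @param data Survival records (data frame with `time`, `event`,
#'   covariates), e.g. from [read_survival_data()] or [generate_fixture()].
#' @param algorithm `"hc"` or `"tabu"`.
#' @param score Score name, see [local_score()].
#' @param iss Imaginary sample size for `bde`/`bds`.
#' @param validate Run [repeated_holdout()] as well.
#' @param k_reps,n_samples Hold-out repetitions / likelihood-weighting
#'   samples (when `validate = TRUE`).
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @param whitelist,blacklist Optional extra edge matrices (or edge-list
#'   files readable by [read_edge_list()]) merged into the automatic
#'   survival constraints.
#' @return A list with `grid`, `dag`, `fit`, `curve`, and (optionally)
#'   `validation`.
#' @export
run_pipeline <- function(data, algorithm = c("hc", "tabu"), score = "bic",
                         iss = 1, validate = FALSE, k_reps = 10L,
                         n_samples = 500L, seed = 1L, out_dir = NULL,
                         whitelist = NULL, blacklist = NULL) {
  algorithm <- match.arg(algorithm)
  check_records(data)
  set.seed(seed)
  grid <- build_slice_grid(data)
  panel <- encode_states(data, grid)
  flat <- as_panel_frame(panel)
  T <- length(grid$times)
  constraints <- survival_constraints(names(panel$covariates), T)
  as_edges <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      read_edge_list(x)
    } else {
      x
    }
  }
  if (!is.null(whitelist) || !is.null(blacklist)) {
    wl <- rbind(constraints$whitelist, as_edges(whitelist))
    bl_extra <- as_edges(blacklist)
    keep <- !(paste(constraints$blacklist[, 1], constraints$blacklist[, 2])
              %in% paste(wl[, 1], wl[, 2]))
    constraints <- edge_constraints(
      whitelist = wl,
      blacklist = rbind(constraints$blacklist[keep, , drop = FALSE],
                        bl_extra))
  }
  dag <- if (algorithm == "hc") {
    hill_climb(flat, score = score, iss = iss, constraints = constraints)
  } else {
    tabu_search(flat, score = score, iss = iss, constraints = constraints)
  }
  fit <- fit_transition_cpts(panel, dag)
  curve <- dbn_marginal_survival(fit)
  out <- list(grid = grid, dag = dag, fit = fit, curve = curve)
  if (validate) {
    out$validation <- repeated_holdout(
      data, algorithm = algorithm, score = score, iss = iss,
      k_reps = k_reps, n_samples = n_samples, seed = seed, grid = grid)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_dot(dag, file.path(out_dir, "dag.dot"))
    write_edge_list(dag, file.path(out_dir, "dag_edges.tsv"))
    write_curve(curve, file.path(out_dir, "survival_curve.tsv"))
    write_dbn_fit(fit, file.path(out_dir, "model.json"))
    if (validate) {
      utils::write.table(as.data.frame(out$validation),
                         file.path(out_dir, "validation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}
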