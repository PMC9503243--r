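new_survival_curve <- function(times, surv, variance = rep(NA_real_,
                                                           length(times)),
                               n_risk = rep(NA_integer_, length(times)),
                               n_event = rep(NA_integer_, length(times))) {
  stopifnot(length(surv) == length(times))
  structure(list(time = as.numeric(times), surv = as.numeric(surv),
                 variance = as.numeric(variance),
                 n_risk = n_risk, n_event = n_event),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  print(as.data.frame(unclass(x)))
  invisible(x)
}

#' @export
as.data.frame.survival_curve <- function(x, ...) {
  data.frame(time = x$time, survival = x$surv, variance = x$variance,
             n_at_risk = x$n_risk, n_events = x$n_event)
}

#' Product-limit (Kaplan-Meier) survival estimate
#'
#' The step-function estimator: survival is 1 before the first event time
#' and drops by the factor `1 - d_i / Y_i` at each slice time.  Pointwise
#' variances come from [greenwood_variance()].
#'
#' @param counts A [tabulate_counts()] object.
#' @return A `survival_curve`: list with `time`, `surv`, `variance`,
#'   `n_risk`, `n_event`.
#' @export
km_estimate <- function(counts) {
  stopifnot(inherits(counts, "slice_counts"))
  if (any(counts$y == 0L & counts$d > 0L)) {
    stop("event slice with an empty risk set: invalid counts")
  }
  surv <- cumprod(1 - counts$d / pmax(counts$y, 1L))
  curve <- new_survival_curve(counts$times, surv,
                              n_risk = counts$y, n_event = counts$d)
  curve$variance <- greenwood_variance(counts, curve)
  curve
}

#' Greenwood variance of a product-limit curve
#'
#' `V[S(t)] = S(t)^2 * sum_{t_i <= t} d_i / (Y_i (Y_i - d_i))`.  Where the
#' risk set is exhausted by events (`Y_i = d_i`) the estimate has dropped to
#' zero and the variance is reported as 0 with the `"greenwood_defined"`
#' attribute flagging those slices.
#'
#' @param counts A [tabulate_counts()] object.
#' @param curve The [km_estimate()] curve computed from the same counts.
#' @return Numeric vector of per-slice variances.
#' @export
greenwood_variance <- function(counts, curve) {
  d <- counts$d
  y <- counts$y
  term <- ifelse(y > d, d / (y * (y - d)), Inf)
  term[d == 0L] <- 0
  cums <- cumsum(term)
  v <- curve$surv^2 * cums
  undefined <- is.nan(v) | is.infinite(v)
  v[undefined] <- 0
  attr(v, "greenwood_defined") <- !(undefined | cumsum(!is.finite(term)) > 0)
  v
}

#' Evaluate a step survival curve at arbitrary times
#'
#' Right-continuous step lookup: the value at the largest slice time not
#' exceeding `t`; 1 before the first slice time; the last value beyond the
#' last.
#'
#' @param curve A `survival_curve` (or another object with an
#'   `evaluate_at` method, e.g. a fitted Cox comparator).
#' @param t Nonnegative evaluation time(s).
#' @return Numeric vector of survival probabilities.
#' @export
evaluate_at <- function(curve, t) {
  UseMethod("evaluate_at")
}

#' @rdname evaluate_at
#' @export
evaluate_at.survival_curve <- function(curve, t) {
  if (any(t < 0)) stop("evaluation time must be nonnegative")
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0L, 1, curve$surv[pmax(idx, 1L)])
}

# Survival factors for each subject profile at slice t of a dbn_fit.
# Returns a numeric vector over the rows of `covs` (data frame of factors).
profile_factors <- function(fit, t, covs) {
  tab <- fit$cpt_n[[t]]
  if (!length(tab$parents)) return(rep(tab$p[1L], nrow(covs)))
  cfg <- rep(1L, nrow(covs))
  mult <- 1L
  for (p in tab$parents) {
    lev <- fit$covariate_levels[[p]]
    j <- match(as.character(covs[[p]]), lev)
    if (anyNA(j)) stop("covariate '", p, "' has a level outside the model")
    cfg <- cfg + (j - 1L) * mult
    mult <- mult * length(lev)
  }
  tab$p[cfg]
}

#' Survival curve of the fitted dynamic network for one covariate profile
#'
#' The product of the fitted slice factors: the prior survival probability
#' at slice 1 and, for each later slice, the probability of surviving the
#' slice given being at risk, each conditioned only on the covariates that
#' are parents of that slice's survival node.  With no covariate parents
#' anywhere the result equals the product-limit estimator exactly.
#'
#' @param fit A [fit_transition_cpts()] model.
#' @param profile Named list/vector of covariate levels (may be empty or
#'   `NULL`; covariates not in the model are ignored with a warning).
#' @return A `survival_curve` over the slice times.  Variance is the
#'   Greenwood formula applied to the profile-specific risk sets and is
#'   exact in the covariate-free case, approximate otherwise.
#' @export
dbn_survival <- function(fit, profile = NULL) {
  stopifnot(inherits(fit, "dbn_fit"))
  profile <- as.list(profile)
  extra <- setdiff(names(profile), names(fit$covariate_levels))
  if (length(extra)) {
    warning("profile covariates not in the model ignored: ",
            paste(extra, collapse = ", "))
    profile <- profile[setdiff(names(profile), extra)]
  }
  T <- length(fit$grid$times)
  fac <- numeric(T)
  d_eff <- y_eff <- numeric(T)
  for (t in seq_len(T)) {
    tab <- fit$cpt_n[[t]]
    if (!length(tab$parents)) {
      cfg <- 1L
    } else {
      missing <- setdiff(tab$parents, names(profile))
      if (length(missing)) {
        stop("profile must fix covariate(s) ",
             paste(missing, collapse = ", "), " used at slice ", t)
      }
      cfg <- 1L
      mult <- 1L
      for (p in tab$parents) {
        lev <- fit$covariate_levels[[p]]
        j <- match(as.character(profile[[p]]), lev)
        if (is.na(j)) stop("level out of domain for covariate '", p, "'")
        cfg <- cfg + (j - 1L) * mult
        mult <- mult * length(lev)
      }
    }
    fac[t] <- tab$p[cfg]
    y_eff[t] <- tab$n_risk[cfg]
    d_eff[t] <- round((1 - tab$p[cfg]) * tab$n_risk[cfg])
  }
  surv <- cumprod(fac)
  counts <- structure(list(times = fit$grid$times, d = d_eff, y = y_eff,
                           n_total = sum(fit$cpt_n[[1L]]$n_risk)),
                      class = "slice_counts")
  curve <- new_survival_curve(fit$grid$times, surv,
                              n_risk = y_eff, n_event = d_eff)
  curve$variance <- greenwood_variance(counts, curve)
  curve
}

#' Population (marginal) survival curve of the fitted dynamic network
#'
#' Mixes the profile-specific curves over the empirical joint distribution
#' of the covariates (each row of `covariate_table` weighted equally), so
#' covariate dependence present in the data is preserved.  Reduces to
#' [dbn_survival()] (hence to Kaplan-Meier) when no slice has covariate
#' parents.
#'
#' @param fit A [fit_transition_cpts()] model.
#' @param covariate_table Data frame of covariate rows (default: the rows
#'   the model was fitted on).
#' @return A `survival_curve`; `variance` is a weighted within-profile
#'   Greenwood combination and is approximate in the presence of
#'   covariates.
#' @export
dbn_marginal_survival <- function(fit, covariate_table = NULL) {
  stopifnot(inherits(fit, "dbn_fit"))
  covs <- if (is.null(covariate_table)) fit$covariate_table else
    covariate_table
  T <- length(fit$grid$times)
  used <- unique(unlist(fit$parents_n))
  if (length(used) && (is.null(covs) || !nrow(covs))) {
    stop("the model conditions on covariates (", paste(used,
         collapse = ", "), ") but no covariate table is available; ",
         "supply `covariate_table`")
  }
  if (!length(used)) {
    counts <- structure(list(times = fit$grid$times,
                             d = vapply(fit$cpt_n, function(tb) {
                               round((1 - tb$p[1L]) * tb$n_risk[1L])
                             }, 0),
                             y = vapply(fit$cpt_n, function(tb) {
                               tb$n_risk[1L]
                             }, 0),
                             n_total = fit$cpt_n[[1L]]$n_risk[1L]),
                        class = "slice_counts")
    return(km_estimate(counts))
  }
  n <- nrow(covs)
  s_i <- rep(1, n)
  surv <- numeric(T)
  var_within <- numeric(T)
  for (t in seq_len(T)) {
    s_i <- s_i * profile_factors(fit, t, covs)
    surv[t] <- mean(s_i)
  }
  curve <- new_survival_curve(fit$grid$times, surv)
  # approximate variance: weighted within-profile Greenwood combination
  tab1 <- fit$cpt_n
  d_t <- vapply(seq_len(T), function(t) {
    tb <- tab1[[t]]
    sum(round((1 - tb$p) * tb$n_risk))
  }, 0)
  y_t <- vapply(seq_len(T), function(t) sum(tab1[[t]]$n_risk), 0)
  counts <- structure(list(times = fit$grid$times, d = d_t, y = y_t,
                           n_total = y_t[1L]),
                      class = "slice_counts")
  curve$variance <- greenwood_variance(counts, curve)
  curve$n_risk <- y_t
  curve$n_event <- d_t
  curve
}

#' Write a survival curve as delimited text
#'
#' @param curve A `survival_curve`.
#' @param path Output path.
#' @param sep Field delimiter.
#' @export
write_curve <- function(curve, path, sep = "\t") {
  utils::write.table(as.data.frame(curve), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Step plot of one or more survival curves
#'
#' @param curve A `survival_curve` or a named list of them.
#' @param file Optional image path (png); plots to the active device when
#'   `NULL`.
#' @param main Plot title.
#' @export
plot_curves <- function(curve, file = NULL, main = "Survival") {
  curves <- if (inherits(curve, "survival_curve")) list(curve = curve) else
    curve
  if (!is.null(file)) grDevices::png(file, width = 800, height = 600)
  xmax <- max(vapply(curves, function(cv) max(cv$time), 0))
  graphics::plot(NULL, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = "time", ylab = "S(t)", main = main)
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    graphics::lines(stats::stepfun(cv$time, c(1, cv$surv)), col = i,
                    do.points = FALSE)
  }
  graphics::legend("topright", legend = names(curves),
                   col = seq_along(curves), lty = 1, bty = "n")
  if (!is.null(file)) grDevices::dev.off()
  invisible(NULL)
}
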