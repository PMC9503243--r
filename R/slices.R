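#' Build the slice grid of unique event times
#'
#' Survival time is discretized into slices, one per unique observed event
#' time, exactly as the product-limit estimator partitions follow-up.
#' Censoring-only times never create slices.
#'
#' @param data A data frame with numeric column `time` and 0/1 column `event`.
#' @param type `"events"` (default) uses every unique event time;
#'   `"quantile"` builds a coarser grid at `n_slices` event-time quantiles
#'   (always anchored at the earliest event time).
#' @param n_slices Number of slices for `type = "quantile"`.
#' @return An object of class `slice_grid`: a list with element `times`,
#'   the strictly increasing slice times. Slice `j` spans `[t_j, t_{j+1})`,
#'   the last slice extending to infinity.
#' @examples
#' d <- data.frame(time = c(1, 2, 3), event = c(1, 0, 1))
#' build_slice_grid(d)$times  # 1 3
#' @export
build_slice_grid <- function(data, type = c("events", "quantile"),
                             n_slices = 20L) {
  type <- match.arg(type)
  check_records(data)
  ev <- data$time[data$event == 1]
  if (length(ev) == 0L) {
    stop("no events in the data: the survival curve is not estimable and ",
         "no slice grid exists")
  }
  times <- sort(unique(ev))
  if (type == "quantile" && length(times) > n_slices) {
    qs <- unique(stats::quantile(ev, probs = seq_len(n_slices) / n_slices,
                                 type = 1, names = FALSE))
    times <- sort(unique(c(min(times), qs)))
  }
  structure(list(times = as.numeric(times)), class = "slice_grid")
}

#' @export
print.slice_grid <- function(x, ...) {
  cat("slice grid:", length(x$times), "slices,",
      "first", format(x$times[1]), "last", format(x$times[length(x$times)]),
      "\n")
  invisible(x)
}

check_records <- function(data) {
  if (!is.data.frame(data)) stop("`data` must be a data frame")
  if (!all(c("time", "event") %in% names(data))) {
    stop("`data` must contain columns `time` and `event`")
  }
  if (any(is.na(data$time)) || any(data$time < 0)) {
    stop("`time` must be nonnegative and non-missing")
  }
  if (!all(data$event %in% c(0, 1))) stop("`event` must be 0 or 1")
  invisible(TRUE)
}

#' Encode right-censored records as binary survival/censorship states
#'
#' Each subject is expanded over the slice grid into two absorbing binary
#' trajectories: `n[i, t] = 1` while subject `i` is still alive entering
#' slice `t` (it drops to 0 at the slice where the event occurs and stays 0),
#' and `q[i, t] = 1` from the slice whose interval contains the censoring
#' time onwards.  Censoring strictly before the first slice time is recorded
#' in the auxiliary indicator `q0`, so that risk sets reproduce classic
#' Kaplan-Meier accounting exactly.  A subject censored exactly at a slice
#' time remains at risk in that slice (events precede censorings at ties).
#'
#' @param data A data frame with columns `time`, `event`, and any number of
#'   discrete covariate columns.
#' @param grid A [build_slice_grid()] object (built from the same data or a
#'   superset of its event times).
#' @return An object of class `state_panel`: list with binary matrices `n`
#'   and `q` (subjects by slices), integer `q0` (1 = censored before slice 1),
#'   `event_slice`/`censor_slice` indices (`NA` when not applicable),
#'   the `grid`, and `covariates` (a data frame of factors, possibly empty).
#' @export
encode_states <- function(data, grid) {
  check_records(data)
  stopifnot(inherits(grid, "slice_grid"))
  times <- grid$times
  n_sub <- nrow(data)
  T <- length(times)
  ev <- data$event == 1
  sl <- findInterval(data$time, times)

  if (any(ev & sl == 0L)) {
    # only possible with a coarsened grid: attribute the event to slice 1
    sl[ev & sl == 0L] <- 1L
  }
  event_slice <- ifelse(ev, sl, NA_integer_)
  censor_slice <- ifelse(!ev, sl, NA_integer_)
  # censoring strictly after the last slice time leaves the whole observed
  # grid uncensored (Q identically 0); censoring exactly at it sets Q_T = 1
  censor_slice[!ev & data$time > times[T]] <- NA_integer_
  q0 <- as.integer(!ev & sl == 0L)

  slice_idx <- matrix(rep(seq_len(T), each = n_sub), nrow = n_sub)
  nmat <- matrix(1L, n_sub, T)
  has_ev <- which(ev)
  if (length(has_ev)) {
    nmat[has_ev, ] <- (slice_idx[has_ev, , drop = FALSE] <
                         event_slice[has_ev])
  }
  qmat <- matrix(0L, n_sub, T)
  cen <- which(!ev & !is.na(censor_slice))
  if (length(cen)) {
    qmat[cen, ] <- (slice_idx[cen, , drop = FALSE] >=
                      pmax(censor_slice[cen], 1L))
    # censored before slice 1: Q is absorbing from the start
    qmat[q0 == 1L, ] <- 1L
  }
  storage.mode(nmat) <- "integer"
  storage.mode(qmat) <- "integer"

  covs <- data[setdiff(names(data), c("time", "event"))]
  covs[] <- lapply(covs, function(z) if (is.factor(z)) z else factor(z))

  structure(list(n = nmat, q = qmat, q0 = q0,
                 event_slice = event_slice, censor_slice = censor_slice,
                 grid = grid, covariates = covs),
            class = "state_panel")
}

#' @export
print.state_panel <- function(x, ...) {
  cat("state panel:", nrow(x$n), "subjects x", ncol(x$n), "slices;",
      sum(!is.na(x$event_slice)), "events,",
      ncol(x$covariates), "covariates\n")
  invisible(x)
}

#' Risk-set and event counts per slice
#'
#' Tabulates `d_t` (failures in slice `t`) and `Y_t` (subjects at risk
#' entering slice `t`) from the encoded state panel.  A subject is at risk at
#' slice `t` when alive and uncensored at the end of slice `t - 1`; at the
#' first slice, when not censored before it.  This is classic Kaplan-Meier
#' risk-set accounting expressed through the state variables.
#'
#' @param panel A [encode_states()] panel.
#' @return An object of class `slice_counts`: list with numeric `times`,
#'   integer vectors `d` and `y`, and `n_total`.
#' @export
tabulate_counts <- function(panel) {
  stopifnot(inherits(panel, "state_panel"))
  nmat <- panel$n
  qmat <- panel$q
  T <- ncol(nmat)
  at_risk <- matrix(FALSE, nrow(nmat), T)
  at_risk[, 1L] <- panel$q0 == 0L
  if (T > 1L) {
    at_risk[, -1L] <- nmat[, -T, drop = FALSE] == 1L &
      qmat[, -T, drop = FALSE] == 0L
  }
  y <- colSums(at_risk)
  d <- colSums(at_risk & nmat == 0L)
  structure(list(times = panel$grid$times, d = as.integer(d),
                 y = as.integer(y), n_total = nrow(nmat)),
            class = "slice_counts")
}

#' @export
print.slice_counts <- function(x, ...) {
  print(data.frame(time = x$times, n_risk = x$y, n_event = x$d))
  invisible(x)
}

# Fast risk-set accounting straight from (time, event) pairs.  Identical to
# encode_states() + tabulate_counts() (property-tested); used by the
# simulation engine where materializing panels per replicate is wasteful.
# Returns d, y, and the per-subject exit slice (last slice at risk; 0 when
# censored before the first slice time).
slice_counts_fast <- function(time, event, times) {
  sl <- findInterval(time, times)
  ev <- event == 1
  sl[ev & sl == 0L] <- 1L
  exit <- sl  # event: fails in slice sl; censored: leaves after slice sl
  T <- length(times)
  exit_cap <- pmin(exit, T)
  # y_t = #{exit >= t}
  n_exit <- tabulate(exit_cap, nbins = T)
  n_total <- length(time)
  # subjects with exit >= t: remove those exiting before slice 1 and in
  # slices 1..t-1
  y <- n_total - sum(exit_cap == 0L) - c(0L, cumsum(n_exit))[seq_len(T)]
  d <- tabulate(exit_cap[ev], nbins = T)
  list(times = times, d = as.integer(d), y = as.integer(y),
       n_total = n_total, exit = exit_cap, ev = ev)
}
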