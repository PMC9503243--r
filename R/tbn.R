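#' Construct a two-slice temporal Bayesian network
#'
#' A dynamic BN of Markov order 1 is a pair of networks: a prior network
#' over the slice-1 state variables (and time-stationary covariates) and a
#' transition network giving the distribution of slice-`t` states given the
#' slice-`(t-1)` states and covariates.  State nodes are named `X@t` with an
#' integer slice index (e.g. `N@1`, `Q@2`); the transition network is
#' expressed on slices 1 (previous) and 2 (current) and is applied to every
#' later pair of adjacent slices by index shifting.
#'
#' @param prior A [new_discrete_bn()] over covariates and slice-1 state
#'   nodes (`X@1`).
#' @param transition A [new_discrete_bn()] whose nodes include covariates
#'   and state nodes at slices 1 and 2; parents of any slice-2 node must lie
#'   among slice-1 state nodes and covariates.
#' @param covariates Character vector of time-stationary covariate names.
#' @return An object of class `two_slice_tbn`.
#' @export
new_two_slice_tbn <- function(prior, transition, covariates = character()) {
  stopifnot(inherits(prior, "discrete_bn"), inherits(transition, "discrete_bn"))
  cur <- grep("@2$", transition$dag$nodes, value = TRUE)
  if (!length(cur)) stop("transition network has no slice-2 nodes")
  pa <- dag_parents(transition$dag)
  for (v in cur) {
    bad <- setdiff(pa[[v]], c(grep("@1$", transition$dag$nodes, value = TRUE),
                              covariates))
    if (length(bad)) {
      stop("transition parents of '", v, "' outside slice-1 states and ",
           "covariates: ", paste(bad, collapse = ", "))
    }
  }
  structure(list(prior = prior, transition = transition,
                 covariates = covariates,
                 state_vars = sub("@2$", "", cur)),
            class = "two_slice_tbn")
}

#' @export
print.two_slice_tbn <- function(x, ...) {
  cat("2-slice temporal BN: states", paste(x$state_vars, collapse = ", "),
      "| covariates", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

state_name <- function(var, t) paste0(var, "@", t)

#' Joint probability of a state trajectory under a 2-TBN
#'
#' Multiplies the prior-network joint for slice 1 (and covariates) by the
#' transition factors for slices `2..T`: the unrolled Markov factorization
#' of the dynamic network.
#'
#' @param tbn A [new_two_slice_tbn()] object.
#' @param trajectory Named list/vector assigning levels to every covariate
#'   and every state node `X@t` for `t = 1..T`.
#' @param T Number of slices in the trajectory (`T >= 1`).
#' @return The joint probability.
#' @export
unroll_joint <- function(tbn, trajectory, T) {
  stopifnot(T >= 1L)
  need <- c(tbn$covariates,
            unlist(lapply(seq_len(T), function(t) {
              state_name(tbn$state_vars, t)
            })))
  missing <- setdiff(need, names(trajectory))
  if (length(missing)) {
    stop("incomplete trajectory; missing: ", paste(missing, collapse = ", "))
  }
  p <- joint_probability(tbn$prior, trajectory)
  if (T >= 2L) {
    for (t in 2:T) {
      for (v in tbn$state_vars) {
        cpt <- tbn$transition$cpts[[state_name(v, 2L)]]
        # shift slice-1/2 names in the transition family to t-1/t
        lookup <- list()
        for (p_name in cpt$parents) {
          orig <- if (grepl("@1$", p_name)) {
            state_name(sub("@1$", "", p_name), t - 1L)
          } else if (grepl("@2$", p_name)) {
            state_name(sub("@2$", "", p_name), t)
          } else {
            p_name
          }
          lookup[[p_name]] <- trajectory[[orig]]
        }
        p <- p * cpt_lookup(cpt, as.character(trajectory[[state_name(v, t)]]),
                            lookup)
      }
    }
  }
  p
}
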