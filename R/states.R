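#' Compartment names of the neoplasia state model
#'
#' The five modelled states of the adenoma-carcinoma sequence (most advanced
#' lesion present), the absorbing ever-diagnosed tally, plus a bookkeeping
#' compartment for people who die before a CRC diagnosis. Together the six
#' proportions always account for the whole baseline cohort.
#'
#' @return Character vector of the six compartment names, in model order.
#' @export
compartment_names <- function() {
  c("no_neoplasm", "nonadvanced_adenoma", "advanced_adenoma",
    "preclinical_crc", "ever_diagnosed_crc", "dead_undiagnosed")
}

#' Construct a cohort state distribution
#'
#' A `state_distribution` holds the proportions of a baseline cohort across
#' the five neoplasia states plus the cumulative bookkeeping compartments,
#' together with the cohort's attained age and sex. Proportions are relative
#' to the baseline cohort, so `ever_diagnosed_crc` is a cumulative incidence
#' (death acts as a competing event) and `dead_undiagnosed` records the mass
#' removed by general mortality before any CRC diagnosis.
#'
#' @param no_neoplasm,nonadvanced_adenoma,advanced_adenoma,preclinical_crc
#'   Proportions of the baseline cohort currently in each undiagnosed state.
#' @param ever_diagnosed_crc Cumulative proportion ever diagnosed with CRC
#'   (absorbing). Default 0.
#' @param dead_undiagnosed Cumulative proportion dead without a CRC
#'   diagnosis. Default 0.
#' @param attained_age Integer age in years the cohort has attained.
#' @param sex `"men"` or `"women"`.
#' @return An object of class `state_distribution`: a named list with the six
#'   proportions, `attained_age` and `sex`.
#' @examples
#' state_distribution(0.773, 0.163, 0.059, 0.005, attained_age = 55,
#'                    sex = "men")
#' @export
state_distribution <- function(no_neoplasm, nonadvanced_adenoma,
                               advanced_adenoma, preclinical_crc,
                               ever_diagnosed_crc = 0, dead_undiagnosed = 0,
                               attained_age, sex = c("men", "women")) {
  sex <- match.arg(sex)
  x <- structure(
    list(no_neoplasm = no_neoplasm,
         nonadvanced_adenoma = nonadvanced_adenoma,
         advanced_adenoma = advanced_adenoma,
         preclinical_crc = preclinical_crc,
         ever_diagnosed_crc = ever_diagnosed_crc,
         dead_undiagnosed = dead_undiagnosed,
         attained_age = as.integer(attained_age),
         sex = sex),
    class = "state_distribution")
  validate_state_distribution(x)
  x
}

#' Validate a state distribution
#'
#' Checks the compartment invariants: every proportion in \[0, 1\] and the
#' six compartments summing to 1 within `tol`.
#'
#' @param x A `state_distribution`.
#' @param tol Absolute tolerance for the mass-conservation check.
#' @return `x`, invisibly. Errors if an invariant is violated.
#' @export
validate_state_distribution <- function(x, tol = 1e-9) {
  p <- state_proportions(x)
  if (any(!is.finite(p))) stop("non-finite compartment proportion")
  if (any(p < -tol) || any(p > 1 + tol))
    stop("compartment proportions must lie in [0, 1]")
  if (abs(sum(p) - 1) > tol)
    stop(sprintf("compartments sum to %.15f, not 1", sum(p)))
  if (!x$sex %in% c("men", "women")) stop("sex must be 'men' or 'women'")
  invisible(x)
}

#' Extract the six compartment proportions as a named numeric vector
#'
#' @param x A `state_distribution`.
#' @return Named numeric vector over [compartment_names()].
#' @export
state_proportions <- function(x) {
  unlist(x[compartment_names()])
}

#' @export
print.state_distribution <- function(x, ...) {
  cat(sprintf("<state_distribution> %s, age %d\n", x$sex, x$attained_age))
  print(round(state_proportions(x), 6))
  invisible(x)
}
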