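#' One annual cycle of the Markov natural-history model
#'
#' Advances a cohort state distribution by one year. Within the year, by
#' default, general mortality acts first: every undiagnosed compartment (no
#' neoplasm, nonadvanced adenoma, advanced adenoma, preclinical CRC) loses
#' the fraction `q` to `dead_undiagnosed`. Disease progression then moves
#' mass one step along the adenoma-carcinoma sequence, with all four
#' outflows computed simultaneously from the post-mortality masses, so no
#' part of the cohort advances more than one state per year. The
#' `ever_diagnosed_crc` compartment is a cumulative tally of people ever
#' diagnosed and is exempt from the mortality bookkeeping.
#'
#' The within-year event order is a modelling choice the data cannot settle;
#' `order = "transitions_first"` applies progression before mortality for
#' sensitivity checks.
#'
#' @param dist A [state_distribution()].
#' @param rates Numeric vector of the four annual transition probabilities
#'   (fractions) in model order: N->NA, NA->AA, AA->P, P->diagnosed. See
#'   [lookup_rates()].
#' @param q Annual death probability in \[0, 1\].
#' @param order `"mortality_first"` (default) or `"transitions_first"`.
#' @return The updated `state_distribution`, with `attained_age + 1`.
#' @export
annual_step <- function(dist, rates, q = 0,
                        order = c("mortality_first", "transitions_first")) {
  order <- match.arg(order)
  rates <- unname(rates)
  if (length(rates) != 4L || any(!is.finite(rates)) ||
      any(rates < 0) || any(rates > 1))
    stop("rates must be four probabilities in [0, 1]")
  if (!is.finite(q) || q < 0 || q > 1)
    stop("q must be a probability in [0, 1]")

  N <- dist$no_neoplasm; NA_ <- dist$nonadvanced_adenoma
  AA <- dist$advanced_adenoma; P <- dist$preclinical_crc
  C <- dist$ever_diagnosed_crc; D <- dist$dead_undiagnosed

  die <- function() {
    D <<- D + q * (N + NA_ + AA + P)
    N <<- N * (1 - q); NA_ <<- NA_ * (1 - q)
    AA <<- AA * (1 - q); P <<- P * (1 - q)
  }
  progress <- function() {
    f1 <- N * rates[1]; f2 <- NA_ * rates[2]
    f3 <- AA * rates[3]; f4 <- P * rates[4]
    N <<- N - f1; NA_ <<- NA_ + f1 - f2
    AA <<- AA + f2 - f3; P <<- P + f3 - f4
    C <<- C + f4
  }
  if (order == "mortality_first") { die(); progress() } else { progress(); die() }

  state_distribution(N, NA_, AA, P, C, D,
                     attained_age = dist$attained_age + 1L, sex = dist$sex)
}

#' Project a cohort from its baseline age to age 80
#'
#' Iterates [annual_step()] over annual cycles from the baseline attained
#' age (55 or 60) up to age 80, looking up sex- and age-band-specific
#' transition probabilities by the attained age at the start of each model
#' year and the matching annual death probability from the life table. In
#' any year whose starting age appears in the screening schedule, the
#' screening colonoscopy ([apply_screening()]) acts before that year's
#' mortality and transitions; screen-detected preclinical cancers therefore
#' surface in the cumulative incidence recorded at the end of that
#' follow-up year.
#'
#' @param baseline A [state_distribution()] at attained age 55 or 60.
#' @param table A `rate_table` (see [crc_transition_rates()]).
#' @param life A `life_table`, or `NULL` for zero mortality.
#' @param schedule A [screening_schedule()], or `NULL` for no screening.
#' @param variant Rate variant passed to [lookup_rates()]: `"point"`,
#'   `"lower"` or `"upper"`.
#' @param order Within-year event order, see [annual_step()].
#' @param label Scenario label stored with the trajectory.
#' @return A `cohort_trajectory`: data frame with one row per follow-up
#'   year `t = 0 ... 80 - start_age` (t = attained_age - start_age), columns
#'   `follow_up_year`, `attained_age` and the six compartments, with
#'   attributes `sex`, `start_age`, `variant` and `scenario`.
#' @export
project_cohort <- function(baseline, table, life = NULL, schedule = NULL,
                           variant = c("point", "lower", "upper"),
                           order = c("mortality_first", "transitions_first"),
                           label = if (is.null(schedule)) "none" else "screened") {
  variant <- match.arg(variant)
  order <- match.arg(order)
  start_age <- baseline$attained_age
  if (!start_age %in% c(55L, 60L))
    stop("baseline attained_age must be 55 or 60")
  if (!is.null(schedule)) {
    if (any(schedule$screening_ages < start_age |
            schedule$screening_ages > 79))
      stop("screening ages must lie within [start_age, 79]")
  }

  horizon <- 80L - start_age
  rows <- vector("list", horizon + 1L)
  dist <- validate_state_distribution(baseline)
  rows[[1L]] <- c(follow_up_year = 0L, attained_age = start_age,
                  state_proportions(dist))
  for (t in seq_len(horizon)) {
    age <- dist$attained_age
    if (!is.null(schedule) && age %in% schedule$screening_ages)
      dist <- apply_screening(dist, schedule$sensitivity)
    dist <- annual_step(dist, lookup_rates(table, dist$sex, age, variant),
                        lookup_qx(life, dist$sex, age), order = order)
    rows[[t + 1L]] <- c(follow_up_year = t, attained_age = dist$attained_age,
                        state_proportions(dist))
  }
  out <- as.data.frame(do.call(rbind, rows))
  structure(out,
            class = c("cohort_trajectory", "data.frame"),
            sex = baseline$sex, start_age = start_age,
            variant = variant, scenario = label, order = order)
}

#' Cumulative CRC incidence at a follow-up year
#'
#' The proportion of the baseline cohort ever diagnosed with CRC by
#' follow-up year `t`, with death before diagnosis acting as a competing
#' event (the denominator is the baseline cohort, not survivors).
#'
#' @param traj A `cohort_trajectory` from [project_cohort()].
#' @param t Follow-up year, 1 to `80 - start_age`.
#' @return Cumulative incidence as a fraction.
#' @export
cumulative_incidence <- function(traj, t) {
  horizon <- max(traj$follow_up_year)
  if (any(t < 1) || any(t > horizon))
    stop(sprintf("follow-up year must lie in 1..%d", horizon))
  traj$ever_diagnosed_crc[match(t, traj$follow_up_year)]
}

#' @export
print.cohort_trajectory <- function(x, ...) {
  cat(sprintf("<cohort_trajectory> %s, start age %d, scenario '%s', %s rates\n",
              attr(x, "sex"), attr(x, "start_age"), attr(x, "scenario"),
              attr(x, "variant")))
  print.data.frame(utils::head(as.data.frame(x), 3))
  cat(sprintf("... %d rows\n", nrow(x)))
  invisible(x)
}
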