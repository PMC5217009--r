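#' Per-year effect measures from a pair of trajectories
#'
#' Compares the screened and unscreened arms year by year: cumulative CRC
#' incidence of each arm, their ratio (relative risk) and their difference
#' (risk difference, unscreened minus screened, so benefit is positive).
#' The series runs over follow-up years 1 to `80 - start_age` (25 for a
#' start at 55, 20 for a start at 60). Where both cumulative incidences are
#' 0 the relative risk is undefined and reported as `NA`.
#'
#' @param screened,unscreened `cohort_trajectory` objects from
#'   [project_cohort()] with the same sex, start age, rate variant and
#'   event order.
#' @return An `effect_series` data frame: `follow_up_year`,
#'   `cum_inc_screened`, `cum_inc_unscreened`, `relative_risk`,
#'   `risk_difference` (fraction; multiply by 100 for percentage points).
#' @export
effect_series <- function(screened, unscreened) {
  for (a in c("sex", "start_age", "variant", "order")) {
    if (!identical(attr(screened, a), attr(unscreened, a)))
      stop(sprintf("arms differ in %s: cannot be compared", a))
  }
  t <- seq_len(max(screened$follow_up_year))
  ci_s <- cumulative_incidence(screened, t)
  ci_u <- cumulative_incidence(unscreened, t)
  rr <- ifelse(ci_u > 0, ci_s / ci_u, NA_real_)
  structure(
    data.frame(follow_up_year = t,
               cum_inc_screened = ci_s,
               cum_inc_unscreened = ci_u,
               relative_risk = rr,
               risk_difference = ci_u - ci_s),
    class = c("effect_series", "data.frame"),
    sex = attr(screened, "sex"), start_age = attr(screened, "start_age"),
    variant = attr(screened, "variant"),
    scenario = attr(screened, "scenario"))
}

#' First follow-up year at which the screened arm no longer exceeds the
#' unscreened arm
#'
#' Screen-detected prevalent cancers put the screened arm's cumulative
#' incidence above the unscreened arm's for the first few years; the
#' crossing year is the smallest follow-up year t with
#' `cum_inc_screened(t) <= cum_inc_unscreened(t)` (a tie counts as
#' crossed).
#'
#' @param series An `effect_series`.
#' @return Integer follow-up year, or `NA_integer_` if no crossing occurs
#'   within the horizon.
#' @export
crossing_year <- function(series) {
  if (nrow(series) == 0L) stop("empty effect series")
  hit <- which(series$cum_inc_screened <= series$cum_inc_unscreened)
  if (length(hit) == 0L) return(NA_integer_)
  as.integer(series$follow_up_year[hit[1L]])
}

#' Last follow-up year of screening-induced excess incidence
#'
#' The largest follow-up year at which the screened arm's cumulative
#' incidence strictly exceeds the unscreened arm's.
#'
#' @param series An `effect_series`.
#' @return Integer follow-up year, or 0 if the screened arm never exceeds.
#' @export
last_excess_year <- function(series) {
  hit <- which(series$cum_inc_screened > series$cum_inc_unscreened)
  if (length(hit) == 0L) return(0L)
  as.integer(series$follow_up_year[max(hit)])
}

#' Fraction of the long-horizon absolute risk reduction seen by year t
#'
#' RD(t) / RD(T): how much of the risk difference reached at the full
#' horizon T is already visible at follow-up year t. Used to quantify how
#' little of the long-term benefit falls within the 10-12-year follow-up
#' windows of published endoscopy studies.
#'
#' @param series An `effect_series`.
#' @param t Follow-up year, 1 <= t <= T.
#' @param horizon Horizon year T; defaults to the last year of the series.
#' @return RD(t) / RD(T).
#' @export
fraction_of_longterm_benefit <- function(series, t,
                                         horizon = max(series$follow_up_year)) {
  if (t < 1 || t > horizon) stop("need 1 <= t <= horizon")
  rd <- function(y) series$risk_difference[match(y, series$follow_up_year)]
  if (is.na(rd(horizon)) || rd(horizon) <= 0)
    stop("risk difference at the horizon is not positive; fraction undefined")
  rd(t) / rd(horizon)
}

#' Compare a screening scenario against its unscreened comparator
#'
#' Builds the scenario and its matched comparator (same sex, same
#' registry-derived baseline, same rate variant and life table, no
#' screening) and returns the paired trajectories and effect series.
#'
#' @param name Scenario name, see [build_scenario()].
#' @param sex `"men"` or `"women"`.
#' @param life A `life_table` or `NULL` for zero mortality.
#' @param variant Rate variant: `"point"`, `"lower"` or `"upper"`.
#' @param counts Registry count table fixture.
#' @param table Transition-rate table fixture.
#' @param sensitivity Screening sensitivity.
#' @param order Within-year event order, see [annual_step()].
#' @return List with `screened`, `unscreened` (trajectories) and `effects`
#'   (an `effect_series`).
#' @examples
#' cmp <- compare_scenario("single55", "men", life = NULL)
#' crossing_year(cmp$effects)
#' @export
compare_scenario <- function(name = c("single55", "single60", "repeat55_65"),
                             sex = c("men", "women"), life = NULL,
                             variant = c("point", "lower", "upper"),
                             counts = crc_registry_counts(),
                             table = crc_transition_rates(),
                             sensitivity = 1,
                             order = c("mortality_first", "transitions_first")) {
  name <- match.arg(name)
  sex <- match.arg(sex)
  variant <- match.arg(variant)
  order <- match.arg(order)
  start <- scenario_start_age(name)
  arm <- build_scenario(name, sex, counts, sensitivity)
  ref <- build_scenario("none", sex, counts, start_age = start)
  screened <- project_cohort(arm$baseline, table, life, arm$schedule,
                             variant, order, label = name)
  unscreened <- project_cohort(ref$baseline, table, life, NULL,
                               variant, order, label = "none")
  list(screened = screened, unscreened = unscreened,
       effects = effect_series(screened, unscreened))
}

#' Deterministic sensitivity sweep over the rate confidence bounds
#'
#' Re-runs a scenario comparison with all 40 transition-rate entries
#' jointly set to their point estimates, lower 95% bounds, or upper 95%
#' bounds.
#'
#' @inheritParams compare_scenario
#' @return Named list of three `effect_series` (`point`, `lower`,
#'   `upper`).
#' @export
sensitivity_sweep <- function(name = c("single55", "single60", "repeat55_65"),
                              sex = c("men", "women"), life = NULL,
                              counts = crc_registry_counts(),
                              table = crc_transition_rates(),
                              sensitivity = 1) {
  name <- match.arg(name)
  sex <- match.arg(sex)
  variants <- c("point", "lower", "upper")
  out <- lapply(variants, function(v)
    compare_scenario(name, sex, life, v, counts, table, sensitivity)$effects)
  names(out) <- variants
  out
}

#' Format an effect series for reporting
#'
#' Rounds to the reporting granularity used for the published outcomes:
#' relative risk to 2 decimals, risk difference in percentage points to 1
#' decimal.
#'
#' @param series An `effect_series`.
#' @return Data frame with `follow_up_year`, `relative_risk` (2 dp) and
#'   `risk_difference_pp` (1 dp).
#' @export
format_effects <- function(series) {
  data.frame(follow_up_year = series$follow_up_year,
             relative_risk = round(series$relative_risk, 2),
             risk_difference_pp = round(100 * series$risk_difference, 1))
}
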