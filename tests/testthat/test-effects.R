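test_that("identical arms give RR = 1 and RD = 0 everywhere", {
  tab <- crc_transition_rates()
  base <- men55_baseline()
  a <- project_cohort(base, tab)
  e <- effect_series(a, a)
  expect_true(all(e$relative_risk == 1))
  expect_true(all(e$risk_difference == 0))
  expect_equal(e$follow_up_year, 1:25)
})

test_that("effect series refuses mismatched arms", {
  tab <- crc_transition_rates()
  m <- project_cohort(men55_baseline(), tab)
  w <- project_cohort(baseline_from_counts(crc_registry_counts(),
                                           "women", 55), tab)
  expect_error(effect_series(m, w), "differ in sex")
  v <- project_cohort(men55_baseline(), tab, variant = "upper")
  expect_error(effect_series(m, v), "differ in variant")
})

test_that("RR and RD satisfy their defining identities", {
  cmp <- compare_scenario("single55", "men",
                          life = synthetic_german_life_table())
  e <- cmp$effects
  expect_equal(e$relative_risk * e$cum_inc_unscreened, e$cum_inc_screened,
               tolerance = 1e-12)
  expect_equal(e$risk_difference, e$cum_inc_unscreened - e$cum_inc_screened)
  expect_true(all(diff(e$cum_inc_screened) >= 0))
  expect_true(all(diff(e$cum_inc_unscreened) >= 0))
  # RR above 1 before the crossing, at or below 1 from it on
  cross <- crossing_year(e)
  expect_true(all(e$relative_risk[e$follow_up_year < cross] > 1))
  expect_true(all(e$relative_risk[e$follow_up_year >= cross] <= 1))
  # RD non-decreasing after the crossing
  after <- e$risk_difference[e$follow_up_year >= cross]
  expect_true(all(diff(after) >= 0))
})

test_that("crossing year is the first year screened does not exceed unscreened", {
  hand <- function(s, u) {
    structure(data.frame(follow_up_year = seq_along(s),
                         cum_inc_screened = s, cum_inc_unscreened = u,
                         relative_risk = s / u, risk_difference = u - s),
              class = c("effect_series", "data.frame"))
  }
  expect_identical(crossing_year(hand(c(2, 2, 2) / 1000,
                                      c(1, 2, 3) / 1000)), 2L)
  expect_identical(last_excess_year(hand(c(2, 2, 2) / 1000,
                                         c(1, 2, 3) / 1000)), 1L)
  # screened never exceeds: crossing immediately, no excess year
  expect_identical(crossing_year(hand(c(0, 1, 2) / 1000,
                                      c(1, 2, 3) / 1000)), 1L)
  expect_identical(last_excess_year(hand(c(0, 1, 2) / 1000,
                                         c(1, 2, 3) / 1000)), 0L)
  # never crossing within the horizon
  expect_identical(crossing_year(hand(c(2, 3, 4) / 1000,
                                      c(1, 2, 3) / 1000)), NA_integer_)
  expect_error(crossing_year(hand(numeric(0), numeric(0))), "empty")
})

test_that("fraction of long-term benefit is RD(t)/RD(T)", {
  lin <- structure(
    data.frame(follow_up_year = 1:10,
               cum_inc_screened = rep(0, 10),
               cum_inc_unscreened = (1:10) / 100,
               relative_risk = rep(0, 10),
               risk_difference = (1:10) / 100),
    class = c("effect_series", "data.frame"))
  expect_equal(fraction_of_longterm_benefit(lin, 10), 1)
  expect_equal(fraction_of_longterm_benefit(lin, 3), 0.3)
  neg <- lin; neg$risk_difference <- -neg$risk_difference
  expect_error(fraction_of_longterm_benefit(neg, 3), "not positive")
  expect_error(fraction_of_longterm_benefit(lin, 11), "horizon")
})

test_that("mortality nearly cancels in the relative risk", {
  e0 <- compare_scenario("single55", "men", life = NULL)$effects
  eq <- compare_scenario("single55", "men",
                         life = synthetic_german_life_table())$effects
  d <- abs(e0$relative_risk - eq$relative_risk)
  expect_true(all(d[e0$follow_up_year <= 15] < 0.05))
})

test_that("a repeat screening at 65 dominates a single screening once its own transient passes", {
  lt <- synthetic_german_life_table()
  single <- compare_scenario("single55", "men", life = lt)$effects
  rep2 <- compare_scenario("repeat55_65", "men", life = lt)$effects
  # identical arms until the repeat colonoscopy acts in follow-up year 11
  before <- single$follow_up_year <= 10
  expect_equal(rep2$risk_difference[before], single$risk_difference[before])
  # the age-65 detections transiently raise the repeat arm's tally (the
  # same excess-incidence mechanism as at baseline, a few years long);
  # from year 14 on the extra adenoma clearance dominates
  keep <- single$follow_up_year >= 14
  expect_true(all(rep2$risk_difference[keep] >= single$risk_difference[keep]))
  expect_gt(rep2$risk_difference[25] - single$risk_difference[25], 0.01)
})

test_that("the sensitivity sweep brackets the point estimate and collapses with zero-width CIs", {
  sweep <- sensitivity_sweep("single55", "men",
                             life = synthetic_german_life_table())
  expect_named(sweep, c("point", "lower", "upper"))
  for (col in c("cum_inc_screened", "cum_inc_unscreened")) {
    expect_true(all(sweep$upper[[col]] >= sweep$point[[col]]))
    expect_true(all(sweep$point[[col]] >= sweep$lower[[col]]))
  }
  flat <- sensitivity_sweep("single55", "men", life = NULL,
                            table = zero_width_rate_table())
  strip <- function(e) data.frame(unclass(e)[names(e)])
  expect_identical(strip(flat$lower), strip(flat$point))
  expect_identical(strip(flat$upper), strip(flat$point))
})

test_that("reporting granularity is RR to 2 decimals and RD to 0.1 pp", {
  e <- compare_scenario("single55", "men", life = NULL)$effects
  f <- format_effects(e)
  expect_equal(f$relative_risk, round(e$relative_risk, 2))
  expect_equal(f$risk_difference_pp, round(100 * e$risk_difference, 1))
})
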