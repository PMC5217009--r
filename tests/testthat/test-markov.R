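test_that("annual step with zero rates and zero mortality is the identity", {
  d <- state_distribution(0.7, 0.2, 0.05, 0.03, 0.01, 0.01,
                          attained_age = 60, sex = "women")
  out <- annual_step(d, rates = rep(0, 4), q = 0)
  expect_equal(state_proportions(out), state_proportions(d))
  expect_identical(out$attained_age, 61L)
})

test_that("forced absorption: p4 = 1 empties preclinical into diagnosed", {
  d <- state_distribution(0, 0, 0, 1, attained_age = 55, sex = "men")
  out <- annual_step(d, rates = c(0, 0, 0, 1), q = 0)
  expect_equal(out$ever_diagnosed_crc, 1)
  expect_equal(out$preclinical_crc, 0)
})

test_that("one cycle from all-healthy reproduces hand arithmetic", {
  d <- state_distribution(1, 0, 0, 0, attained_age = 55, sex = "men")
  out <- annual_step(d, lookup_rates(crc_transition_rates(), "men", 55), q = 0)
  expect_equal(out$no_neoplasm, 0.976)
  expect_equal(out$nonadvanced_adenoma, 0.024)
})

test_that("mortality drains undiagnosed compartments but not the diagnosed tally", {
  d <- state_distribution(0.5, 0.2, 0.1, 0.1, 0.1, 0,
                          attained_age = 55, sex = "men")
  out <- annual_step(d, rates = rep(0, 4), q = 0.1)
  expect_equal(out$dead_undiagnosed, 0.09)      # 0.1 * (0.5+0.2+0.1+0.1)
  expect_equal(out$ever_diagnosed_crc, 0.1)     # exempt from mortality
  expect_equal(out$no_neoplasm, 0.45)
})

test_that("annual step rejects invalid probabilities", {
  d <- state_distribution(1, 0, 0, 0, attained_age = 55, sex = "men")
  expect_error(annual_step(d, rates = c(0, 0, 0, 1.2), q = 0), "\\[0, 1\\]")
  expect_error(annual_step(d, rates = rep(0, 4), q = -0.1), "\\[0, 1\\]")
  expect_error(annual_step(d, rates = rep(0, 3), q = 0), "four")
})

test_that("projection spans start age to 80 and degenerate inputs behave", {
  base <- men55_baseline()
  tab <- crc_transition_rates()
  # zero rates, zero mortality: nothing ever gets diagnosed
  zero_tab <- as.data.frame(tab)
  zero_tab[, c("point", "lower", "upper")] <- 1e-12
  zero_tab <- crcscreen:::validate_rate_table(zero_tab)
  traj <- project_cohort(base, zero_tab, life = NULL)
  expect_equal(nrow(traj), 26L)
  expect_equal(traj$follow_up_year, 0:25)
  expect_equal(traj$attained_age, 55:80)
  expect_true(all(abs(traj$ever_diagnosed_crc) < 1e-10))
  # q = 1 in the first year: all undiagnosed mass dies, tally frozen
  kill <- data.frame(sex = "men", age = 55:80,
                     qx = c(1, rep(0, 25)))
  kill <- crcscreen:::validate_life_table(kill)
  traj2 <- project_cohort(base, tab, life = kill)
  expect_equal(traj2$dead_undiagnosed[2], 1)
  expect_true(all(traj2$ever_diagnosed_crc[-1] ==
                    traj2$ever_diagnosed_crc[2]))
})

test_that("projection enforces start age and schedule span", {
  tab <- crc_transition_rates()
  d <- state_distribution(1, 0, 0, 0, attained_age = 57, sex = "men")
  expect_error(project_cohort(d, tab), "55 or 60")
  base <- men55_baseline()
  expect_error(project_cohort(base, tab, schedule = screening_schedule(80)),
               "within")
})

test_that("mass is conserved and cumulative compartments are monotone over projections", {
  tab <- crc_transition_rates()
  lt <- synthetic_german_life_table()
  for (sx in c("men", "women")) {
    arm <- build_scenario("repeat55_65", sx)
    traj <- project_cohort(arm$baseline, tab, lt, arm$schedule)
    sums <- rowSums(as.data.frame(traj)[, compartment_names()])
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(diff(traj$ever_diagnosed_crc) >= 0))
    expect_true(all(diff(traj$dead_undiagnosed) >= 0))
  }
})

test_that("upper/lower rate variants bracket the point projection", {
  tab <- crc_transition_rates()
  lt <- synthetic_german_life_table()
  base <- men55_baseline()
  ci <- sapply(c("lower", "point", "upper"), function(v)
    project_cohort(base, tab, lt, variant = v)$ever_diagnosed_crc)
  expect_true(all(ci[, "upper"] >= ci[, "point"]))
  expect_true(all(ci[, "point"] >= ci[, "lower"]))
})

test_that("zero mortality dominates any positive mortality in cumulative incidence", {
  tab <- crc_transition_rates()
  base <- men55_baseline()
  ci0 <- project_cohort(base, tab, life = NULL)$ever_diagnosed_crc
  ciq <- project_cohort(base, tab,
                        life = synthetic_german_life_table())$ever_diagnosed_crc
  expect_true(all(ci0 >= ciq))
})

test_that("the two within-year event orders agree under zero mortality", {
  tab <- crc_transition_rates()
  base <- men55_baseline()
  a <- project_cohort(base, tab, order = "mortality_first")
  b <- project_cohort(base, tab, order = "transitions_first")
  expect_equal(a$ever_diagnosed_crc, b$ever_diagnosed_crc)
  # and differ only slightly under realistic mortality
  lt <- synthetic_german_life_table()
  a <- project_cohort(base, tab, lt, order = "mortality_first")
  b <- project_cohort(base, tab, lt, order = "transitions_first")
  expect_false(identical(a$ever_diagnosed_crc, b$ever_diagnosed_crc))
  expect_true(max(abs(a$ever_diagnosed_crc - b$ever_diagnosed_crc)) < 0.005)
})

test_that("cumulative incidence accessor validates the follow-up year", {
  traj <- project_cohort(men55_baseline(), crc_transition_rates())
  expect_equal(cumulative_incidence(traj, 25),
               traj$ever_diagnosed_crc[traj$follow_up_year == 25])
  expect_error(cumulative_incidence(traj, 0), "1\\.\\.25")
  expect_error(cumulative_incidence(traj, 26), "1\\.\\.25")
})
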