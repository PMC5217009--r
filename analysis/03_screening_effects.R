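#!/usr/bin/env Rscript
# Screening-colonoscopy effect time courses: single colonoscopy at 55, at
# 60, and repeat at 55 + 65, each against its matched unscreened
# comparator, both sexes, point-estimate rates, synthetic life table.

library(crcscreen)

lt <- synthetic_german_life_table()
rows <- list()
for (scen in c("single55", "single60", "repeat55_65"))
  for (sx in c("men", "women")) {
    e <- compare_scenario(scen, sx, life = lt)$effects
    rows[[length(rows) + 1L]] <-
      data.frame(scenario = scen, sex = sx, follow_up_year = e$follow_up_year,
                 cum_inc_screened = e$cum_inc_screened,
                 cum_inc_unscreened = e$cum_inc_unscreened,
                 relative_risk = e$relative_risk,
                 risk_difference_pp = 100 * e$risk_difference)
    if (sx == "men" && scen == "single55") {
      message(sprintf(
        "single55 men: crossing year %d, RR(10) = %.2f, min RR = %.2f (year %d)",
        crossing_year(e), e$relative_risk[10], min(e$relative_risk),
        which.min(e$relative_risk)))
      message(sprintf(
        "  RD(25) = %.1f pp; share of 25-y benefit visible by year 12: %.0f%%",
        100 * e$risk_difference[25],
        100 * fraction_of_longterm_benefit(e, 12)))
    }
  }
out <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(out, "results/screening_effects.csv", row.names = FALSE)

last <- out[out$follow_up_year == ifelse(out$scenario == "single60", 20, 25), ]
message("End-of-horizon risk differences (pp):")
for (i in seq_len(nrow(last)))
  message(sprintf("  %-12s %-5s RD = %.1f, RR = %.2f", last$scenario[i],
                  last$sex[i], last$risk_difference_pp[i],
                  last$relative_risk[i]))
message("A transient incidence excess of 4-5 years is followed by decades of")
message("growing absolute benefit. Written: results/screening_effects.csv")
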