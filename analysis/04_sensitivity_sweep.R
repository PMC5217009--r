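#!/usr/bin/env Rscript
# Deterministic sensitivity sweep: the full replication grid (3 scenarios x
# 2 sexes x 3 joint rate variants = 18 effect series), exported with run
# log via the configuration-driven runner.

library(crcscreen)

res <- run_scenarios(run_config(
  scenarios = c("single55", "single60", "repeat55_65"),
  sexes = c("men", "women"),
  variants = c("point", "lower", "upper"),
  life_table = "synthetic",
  out_dir = "results/replication"))

e <- res$effects
message("Minimum relative risk by scenario and rate variant (men):")
for (scen in unique(e$scenario)) for (v in c("lower", "point", "upper")) {
  sub <- e[e$scenario == scen & e$variant == v & e$sex == "men", ]
  message(sprintf("  %-12s %-6s min RR = %.2f at year %d", scen, v,
                  min(sub$relative_risk),
                  sub$follow_up_year[which.min(sub$relative_risk)]))
}
message("The relative-risk time course is nearly invariant to jointly moving")
message("all 40 transition rates to their CI bounds; absolute incidences and")
message("risk differences shift modestly. Written under results/replication/")
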