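---
title: "A deterministic Markov model of long-term colorectal cancer screening effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A deterministic Markov model of long-term colorectal cancer screening effects}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcscreen)
```

## The question

Endoscopic screening prevents colorectal cancer (CRC) both by detecting
prevalent, still-preclinical cancers and by removing adenomas before they
progress. The two mechanisms act on very different time scales: detection
*raises* observed cumulative incidence for the first few years, while
adenoma removal pays off over decades. Trials and cohort studies rarely
follow participants beyond 10–12 years, so the long-run effect must be
projected from the natural history of the disease. `crcscreen` does this
with a deterministic cohort state-transition model.

## The model

A cohort of one sex is followed from age 55 (or 60) to age 80 in annual
cycles. Each person occupies one of five states ordered along the
adenoma–carcinoma sequence — no neoplasm, nonadvanced adenoma, advanced
adenoma, preclinical CRC, diagnosed CRC — and the model tracks the
*proportions* of the baseline cohort in each state, plus a sixth
bookkeeping compartment for people who die of other causes before any CRC
diagnosis. Writing $N, A_1, A_2, P, C, D$ for the six proportions, one
cycle at attained age $a$ does, in order:

1. **Screening** (only in a year whose starting age is scheduled): a
   fraction $s$ (the screening sensitivity, default 1) of $P$ moves to $C$
   — screen-detected cancers count as incident in the screening year — and
   the same fraction of $A_1$ and $A_2$ returns to $N$ (polypectomy).
2. **Mortality**: every undiagnosed compartment loses the fraction
   $q_a$ (the life-table annual death probability) to $D$. The $C$
   compartment is a cumulative *ever diagnosed* tally, not an
   alive-with-CRC count, so it is exempt.
3. **Progression**: simultaneous single-step flows computed from the
   post-mortality masses, $N \to A_1$ at $p_1$, $A_1 \to A_2$ at $p_2$,
   $A_2 \to P$ at $p_3$, $P \to C$ at $p_4$. Because all four outflows are
   computed from the same starting masses, no mass advances more than one
   state per year.

The four probabilities $p_1 \dots p_4$ are sex- and age-band-specific
(5-year bands, 55–59 through 75–79, looked up by the age at the *start* of
the cycle, so the 75–79 band drives the final transition into age 80).
They ship with the package as `crc_transition_rates()`, each with a point
estimate and 95% confidence bounds; the deterministic sensitivity sweep
re-runs everything with all 40 entries jointly at their lower or upper
bounds.

Cumulative incidence at follow-up year $t$ is simply $C(t)$, with the
baseline cohort as denominator — death is a competing event that removes
people from risk, not a censoring mechanism. Screened and unscreened arms
share the same baseline; their comparison is summarised per year by the
relative risk $RR(t) = C_s(t)/C_u(t)$ and the risk difference
$RD(t) = C_u(t) - C_s(t)$ (positive = benefit, reported in percentage
points to 1 decimal; RR to 2 decimals).

## Inputs and their defaults

* **Baseline prevalences** come from registry counts of the most advanced
  finding at first screening colonoscopy (`crc_registry_counts()`), by sex
  at ages 55 and 60. Raw counts, not the rounded percentage columns,
  define the proportions; the registry "cancer" category enters the model
  as *preclinical* CRC and the ever-diagnosed tally starts at zero.
* **Transition rates** (`crc_transition_rates()`): annual probabilities in
  % per year, e.g. 2.4%/yr for adenoma initiation in men 55–59 up to
  ~20%/yr for the preclinical-to-diagnosed transition, which sets the
  4–5-year time scale of the post-screening incidence excess.
* **Mortality** is any period life table with columns `sex, age, qx`
  (`read_life_table()`). The packaged
  `synthetic_german_life_table()` is a Gompertz stand-in,
  $q(a) = 1 - \exp\{-m\,\alpha\,e^{\beta (a-55)}\}$, with
  $\alpha = 0.006, \beta = 0.095$ for men and
  $\alpha = 0.003, \beta = 0.100$ for women ($m = 1$), chosen once so that
  q rises from ~0.6% (men) at 55 to ~6% at 80 and 25-year survival from 55
  lands in a plausible Western-European range. It is labelled synthetic
  deliberately: absolute cumulative incidences and risk differences
  inherit its survivor curve, and exact reproduction of results tied to a
  specific national table requires supplying that table as a file.
  Relative risks are nearly mortality-invariant (see below).
* **Screening sensitivity** defaults to 1 (every prevalent lesion found
  and removed/diagnosed); it scales the screening flows linearly and is
  configurable throughout.

## Scenarios

`build_scenario()` encodes the three interventions — `single55`,
`single60`, `repeat55_65` — and their matched unscreened comparators
(same baseline, no screening; the `single60` comparator starts at 60).
`compare_scenario()` returns the paired trajectories and the effect
series; `sensitivity_sweep()` adds the CI-bound variants;
`run_scenarios()` drives the full 3 × 2 × 3 grid and exports
plot-ready tables with a run log.

## What the model shows

Run with the packaged fixtures, the model produces the time course
familiar in outline from sigmoidoscopy trials and colonoscopy cohort
studies:
a screened cohort's cumulative incidence exceeds the unscreened cohort's
for 4–5 years (prevalent preclinical cancers surface immediately), then
falls behind; the relative risk drops to about 0.35 by year 10 and to a
minimum near 0.3 around year 15, drifting back toward 0.4 by year 25 as
regrown adenomas mature; the risk difference grows steadily for the whole
horizon, with less than a third of the 25-year absolute benefit visible by
year 12. A repeat colonoscopy at 65 roughly re-runs the mechanism: a
small second detection transient (its RD dips below the single-screening
RD for about three years around year 11–13) followed by much deeper
long-run benefit (RR near 0.15 late in follow-up). These numbers are
computed, not asserted: the test suite and `scripts/acceptance.R`
recompute all of them from the fixtures at run time.

Because general mortality hits both arms almost identically, it nearly
cancels in the ratio: $RR(t)$ with zero mortality and with the synthetic
life table differ by less than 0.05 at every $t \le 15$ (tested). The
relative-risk anchors are therefore checked mortality-free, from in-package
inputs only, while the absolute quantities are checked under the synthetic
life table.

## Numerical and design choices

* The tabulated rates are treated as annual transition *probabilities*
  applied once per cycle, not instantaneous rates needing an exponential
  conversion: the model is an annual-iteration cohort spreadsheet, and its
  inputs were derived on the same annual footing.
* Within-year order screening → mortality → progression is the simplest
  scheme consistent with that reading; `order = "transitions_first"` is
  exposed because the choice is genuinely open. Under zero mortality the
  two orders coincide exactly; under the synthetic life table they differ
  by < 0.5 pp in any compartment (tested at < 0.005).
* Mass conservation is enforced at $10^{-12}$ absolute; compartments are
  plain doubles and each cycle is a handful of multiplications, so 26
  cycles accumulate rounding error orders of magnitude below that.
* $RR$ is reported as missing (`NA`) in any year where both cumulative
  incidences are zero rather than inventing a value; the crossing year
  counts a tie as crossed.
* Screen detections are tallied in the year of screening, which for a
  baseline screening means follow-up year 1, the first reported point.
  The same convention applied to the age-65 repeat places its transient
  at years 11–13; dominance of the repeat strategy over single screening
  therefore holds from year 14, not 11, and the suite tests it that way.

## The synthetic-data generator

`simulate_registry_counts()` draws one multinomial sample of $n$
participants around supplied true prevalences — the sampling structure of
a screening registry — and `synthetic_life_table()` produces Gompertz
mortality. Together they let the whole pipeline (counts → baseline →
projection → effect series) run and be property-tested with no external
files. They emulate sampling noise and smooth adult mortality only: no
registry reporting bias, participation selection, period effects, or
old-age mortality deceleration. Tests passing on synthetic inputs
validate the *arithmetic and invariants* of the pipeline, not the
epidemiological accuracy of any particular input.

## Validation

Beyond unit oracles (hand-computed single cycles, closed-form Gompertz
values, printed-percentage round-trips), the cohort engine is validated
against an independent individual-level simulation: 200,000 persons, each
assigned a baseline state and walked through the same yearly
screening/death/progression rules, with per-state event counts balanced
to their expectations (stratified variance reduction). Agreement is
required within 3 binomial standard errors for every compartment and
year — conservative, since the balanced oracle's Monte-Carlo error is far
smaller. Property tests run 10,000 randomized operations checking mass
conservation and monotonicity of the cumulative tallies, multinomial
recovery at $n = 10^6$, and exact collapse of the sensitivity sweep when
CI widths are zero. Problem sizes (200,000 persons, $10^6$ multinomial
draws, 10,000 operations) were chosen as the smallest that make the
statistical checks sharp.

## Limitations

Only the adenoma–carcinoma pathway is modelled (no serrated or de-novo
routes), so effects on total CRC incidence are slightly overstated.
People whose adenomas are removed re-enter the no-neoplasm state with
standard onward rates: no post-polypectomy excess risk and no surveillance
effect, assumptions that roughly offset but are not modelled. There is no
CRC mortality, no subsite split, no adherence modelling, and a single
scalar sensitivity covers all lesion classes. Note also that the 25-year
screened-arm cumulative incidence under repeat screening is dominated by
the screen detections themselves (the 0.46 pp of baseline preclinical
cancers in men plus the detections at 65) and computes to slightly above
1% in men under any plausible life table — a floor set by the detection
convention, not by the mortality input.
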