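#' Define a screening-colonoscopy schedule
#'
#' @param screening_ages Strictly increasing integer ages at which a
#'   screening colonoscopy is performed.
#' @param sensitivity Probability that prevalent neoplasia or preclinical
#'   CRC is detected (and removed or diagnosed) at the colonoscopy, in
#'   \[0, 1\]. The base case assumes complete detection and removal
#'   (sensitivity 1).
#' @return A `screening_schedule` list.
#' @examples
#' screening_schedule(c(55, 65))
#' @export
screening_schedule <- function(screening_ages, sensitivity = 1) {
  ages <- as.integer(screening_ages)
  if (length(ages) == 0L || any(diff(ages) <= 0))
    stop("screening ages must be non-empty and strictly increasing")
  if (!is.finite(sensitivity) || sensitivity < 0 || sensitivity > 1)
    stop("sensitivity must lie in [0, 1]")
  structure(list(screening_ages = ages, sensitivity = sensitivity),
            class = "screening_schedule")
}

#' Apply a screening colonoscopy to a state distribution
#'
#' The fraction `sensitivity` of the preclinical-CRC compartment is
#' diagnosed (moved to `ever_diagnosed_crc`; screen-detected cancers count
#' as incident in the screening year), and the same fraction of both
#' adenoma compartments is removed by polypectomy, returning that mass to
#' `no_neoplasm` with standard onward transition rates. Remainders stay in
#' place; other compartments are unchanged, so total mass is conserved and
#' `ever_diagnosed_crc` never decreases. At sensitivity 1 the operation is
#' idempotent.
#'
#' @param dist A [state_distribution()].
#' @param sensitivity Detection/removal probability in \[0, 1\].
#' @return The post-screening `state_distribution` (same attained age).
#' @export
apply_screening <- function(dist, sensitivity = 1) {
  if (!is.finite(sensitivity) || sensitivity < 0 || sensitivity > 1)
    stop("sensitivity must lie in [0, 1]")
  s <- sensitivity
  removed <- s * (dist$nonadvanced_adenoma + dist$advanced_adenoma)
  detected <- s * dist$preclinical_crc
  state_distribution(
    no_neoplasm = dist$no_neoplasm + removed,
    nonadvanced_adenoma = dist$nonadvanced_adenoma * (1 - s),
    advanced_adenoma = dist$advanced_adenoma * (1 - s),
    preclinical_crc = dist$preclinical_crc * (1 - s),
    ever_diagnosed_crc = dist$ever_diagnosed_crc + detected,
    dead_undiagnosed = dist$dead_undiagnosed,
    attained_age = dist$attained_age, sex = dist$sex)
}

#' Baseline state distribution from registry counts
#'
#' Converts the raw participant counts (most advanced finding at screening
#' colonoscopy) into baseline compartment proportions. The cancer count is
#' placed in `preclinical_crc` — these are cancers present but not yet
#' clinically diagnosed — and `ever_diagnosed_crc` starts at 0. Raw counts,
#' not the rounded percentage columns, define the proportions.
#'
#' @param counts A registry count table (see [crc_registry_counts()]).
#' @param sex `"men"` or `"women"`.
#' @param age Baseline age, 55 or 60.
#' @return A [state_distribution()].
#' @export
baseline_from_counts <- function(counts, sex = c("men", "women"), age = 55) {
  sex <- match.arg(sex)
  p <- prevalence_from_counts(counts, sex, age)
  state_distribution(
    no_neoplasm = p[["no_neoplasm"]],
    nonadvanced_adenoma = p[["nonadvanced_adenoma"]],
    advanced_adenoma = p[["advanced_adenoma"]],
    preclinical_crc = p[["cancer"]],
    attained_age = age, sex = sex)
}

#' Build one of the named screening scenarios
#'
#' The three modelled interventions are a single screening colonoscopy at
#' age 55 (`"single55"`), a single screening colonoscopy at age 60
#' (`"single60"`, with its unscreened comparator also starting at 60), and
#' an initial screening colonoscopy at 55 with a repeat at 65
#' (`"repeat55_65"`). `"none"` is the unscreened comparator; it shares the
#' SAME registry-derived baseline as the screened arm it is compared with.
#'
#' @param name One of `"none"`, `"single55"`, `"single60"`,
#'   `"repeat55_65"`.
#' @param sex `"men"` or `"women"`.
#' @param counts Registry count table; defaults to the packaged fixture.
#' @param sensitivity Screening sensitivity passed to
#'   [screening_schedule()].
#' @param start_age Baseline age for `"none"` (55 or 60); ignored for the
#'   named interventions, whose start age is fixed by the scenario.
#' @return List with elements `baseline` (a [state_distribution()]) and
#'   `schedule` (a [screening_schedule()], or `NULL` for `"none"`).
#' @examples
#' build_scenario("single55", "men")$schedule
#' @export
build_scenario <- function(name = c("none", "single55", "single60",
                                    "repeat55_65"),
                           sex = c("men", "women"),
                           counts = crc_registry_counts(),
                           sensitivity = 1, start_age = 55) {
  name <- match.arg(name)
  sex <- match.arg(sex)
  def <- switch(name,
    none = list(age = start_age, ages = NULL),
    single55 = list(age = 55, ages = 55),
    single60 = list(age = 60, ages = 60),
    repeat55_65 = list(age = 55, ages = c(55, 65)))
  if (!def$age %in% c(55, 60)) stop("start_age must be 55 or 60")
  schedule <- if (is.null(def$ages)) NULL else
    screening_schedule(def$ages, sensitivity)
  list(baseline = baseline_from_counts(counts, sex, def$age),
       schedule = schedule)
}

#' Start age of a named scenario's projection
#'
#' @param name Scenario name as in [build_scenario()].
#' @return 60 for `"single60"`, otherwise 55.
#' @export
scenario_start_age <- function(name = c("none", "single55", "single60",
                                        "repeat55_65")) {
  if (match.arg(name) == "single60") 60L else 55L
}
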