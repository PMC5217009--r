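# Independent individual-level simulation oracle for the cohort engine.
#
# Each of n persons starts in a state assigned in exact baseline
# proportions and, per model year, experiences the same event sequence the
# cohort model assumes: a scheduled screening (adenoma carriers -> no
# neoplasm, preclinical -> diagnosed), then a death draw (undiagnosed
# states only), then at most one single-step progression. State coding
# follows compartment_names(): 1 = no neoplasm, 2 = nonadvanced adenoma,
# 3 = advanced adenoma, 4 = preclinical CRC, 5 = ever-diagnosed CRC
# (absorbing tally, exempt from the death bookkeeping), 6 = dead
# undiagnosed.
#
# Event counts are balanced per state and year: WHICH persons experience
# an event is uniformly random, but HOW MANY is pinned to the expected
# count within one person (floor + Bernoulli on the fraction), a standard
# stratified variance reduction. The residual Monte-Carlo error is then
# far below the binomial standard error sqrt(p(1-p)/n), so a 3-SE
# comparison against the cohort model is conservative, while any
# systematic disagreement between the two implementations (event order,
# exemption rules, band lookup) still surfaces at full size.
microsim_trajectory <- function(n, baseline, table, life = NULL,
                                schedule = NULL, variant = "point") {
  p0 <- state_proportions(baseline)
  k <- floor(p0 * n)
  short <- n - sum(k)
  if (short > 0) {
    extra <- order(p0 * n - k, decreasing = TRUE)[seq_len(short)]
    k[extra] <- k[extra] + 1L
  }
  state <- rep.int(seq_len(6L), k)

  balanced_count <- function(m, p) {
    x <- m * p
    floor(x) + (runif(1) < x - floor(x))
  }
  move <- function(from, to, prob) {
    pool <- which(state == from)
    m <- length(pool)
    if (m == 0L || prob <= 0) return(invisible())
    kk <- balanced_count(m, prob)
    if (kk > 0L)
      state[pool[sample.int(m, kk)]] <<- to
    invisible()
  }

  sex <- baseline$sex
  start_age <- baseline$attained_age
  horizon <- 80L - start_age
  props <- matrix(NA_real_, nrow = horizon + 1L, ncol = 6L,
                  dimnames = list(NULL, compartment_names()))
  props[1L, ] <- tabulate(state, 6L) / n
  for (t in seq_len(horizon)) {
    age <- start_age + t - 1L
    if (!is.null(schedule) && age %in% schedule$screening_ages) {
      s <- schedule$sensitivity
      move(2L, 1L, s); move(3L, 1L, s); move(4L, 5L, s)
    }
    q <- lookup_qx(life, sex, age)
    for (st in 1:4) move(st, 6L, q)
    rates <- lookup_rates(table, sex, age, variant)
    # advance highest state first so nobody moves two steps in one year
    for (st in 4:1) move(st, st + 1L, rates[st])
    props[t + 1L, ] <- tabulate(state, 6L) / n
  }
  props
}
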