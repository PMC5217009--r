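# Shared fixtures, built in code.

# a random but valid state distribution (uniform on the simplex)
random_state <- function(age = 55L, sex = "men") {
  p <- -log(runif(6))
  p <- p / sum(p)
  state_distribution(p[1], p[2], p[3], p[4], p[5], p[6],
                     attained_age = age, sex = sex)
}

men55_baseline <- function() {
  baseline_from_counts(crc_registry_counts(), "men", 55)
}

# rate table with all CI widths collapsed to zero (lower = point = upper)
zero_width_rate_table <- function() {
  x <- as.data.frame(crc_transition_rates())
  x$lower <- x$point
  x$upper <- x$point
  crcscreen:::validate_rate_table(x)
}
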