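#' @keywords internal
age_bands <- function() c("55-59", "60-64", "65-69", "70-74", "75-79")

#' @keywords internal
transition_names <- function() c("N_to_NA", "NA_to_AA", "AA_to_P", "P_to_C")

#' Registry-derived annual transition rates of the adenoma-carcinoma sequence
#'
#' Sex- and 5-year-age-band-specific annual transition probabilities (in %
#' per year) for the four one-step transitions of the model — no neoplasm to
#' nonadvanced adenoma (`N_to_NA`), nonadvanced to advanced adenoma
#' (`NA_to_AA`), advanced adenoma to preclinical CRC (`AA_to_P`) and
#' preclinical to clinically diagnosed CRC (`P_to_C`) — each with the point
#' estimate and 95% confidence bounds. The table ships as a packaged
#' fixture; it is complete over 2 sexes x 5 age bands (55-59 through 75-79)
#' x 4 transitions.
#'
#' @return A `rate_table`: data frame with columns `sex`, `age_band`,
#'   `transition`, `point`, `lower`, `upper` (percent per year).
#' @seealso [lookup_rates()], [read_rate_table()]
#' @export
crc_transition_rates <- function() {
  path <- system.file("extdata", "transition_rates.csv",
                      package = "crcscreen", mustWork = TRUE)
  read_rate_table(path)
}

#' Read an annual transition-rate table from CSV
#'
#' Expects columns `sex`, `age_band`, `transition`, `point`, `lower`,
#' `upper`, rates in percent per year. The table is validated for
#' completeness (40 entries), CI ordering (`lower <= point <= upper`) and
#' range (all values strictly between 0 and 100).
#'
#' @param path Path to a comma-separated file.
#' @return A validated `rate_table` data frame.
#' @export
read_rate_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_rate_table(x)
}

#' Write a transition-rate table to CSV
#'
#' @param table A `rate_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @keywords internal
validate_rate_table <- function(x) {
  need <- c("sex", "age_band", "transition", "point", "lower", "upper")
  if (!all(need %in% names(x)))
    stop("rate table must have columns: ", paste(need, collapse = ", "))
  key <- expand.grid(sex = c("men", "women"), age_band = age_bands(),
                     transition = transition_names(),
                     stringsAsFactors = FALSE)
  have <- paste(x$sex, x$age_band, x$transition)
  want <- paste(key$sex, key$age_band, key$transition)
  if (nrow(x) != 40L || !all(want %in% have) || anyDuplicated(have))
    stop("incomplete rate table: need exactly 2 sexes x 5 age bands x 4 ",
         "transitions = 40 unique entries")
  vals <- as.matrix(x[, c("point", "lower", "upper")])
  if (any(vals <= 0) || any(vals >= 100))
    stop("all rates must lie strictly between 0 and 100 (% per year)")
  if (any(x$lower > x$point) || any(x$point > x$upper))
    stop("rate table violates lower <= point <= upper")
  class(x) <- c("rate_table", "data.frame")
  x
}

#' Look up the four annual transition probabilities for a given age
#'
#' Returns the probabilities (as fractions, i.e. the tabulated percentages
#' divided by 100) of the 5-year age band containing `age`. The band is
#' chosen by the attained age at the start of the model year, so the 75-79
#' band covers the final transition into age 80.
#'
#' @param table A `rate_table` (see [crc_transition_rates()]).
#' @param sex `"men"` or `"women"`.
#' @param age Integer age in years, 55-79.
#' @param variant Which value to use for all four transitions: the point
#'   estimate (`"point"`) or the lower/upper 95% confidence bound
#'   (`"lower"`, `"upper"`), as used by the deterministic sensitivity sweep.
#' @return Named numeric vector of length 4 (`N_to_NA`, `NA_to_AA`,
#'   `AA_to_P`, `P_to_C`), annual probabilities as fractions.
#' @examples
#' lookup_rates(crc_transition_rates(), "men", 57)
#' @export
lookup_rates <- function(table, sex = c("men", "women"), age,
                         variant = c("point", "lower", "upper")) {
  sex <- match.arg(sex)
  variant <- match.arg(variant)
  if (!is.numeric(age) || length(age) != 1L || age != floor(age))
    stop("age must be a single integer")
  if (age < 55 || age > 79)
    stop(sprintf("age %d outside table coverage (55-79)", as.integer(age)))
  band <- age_bands()[(age - 55) %/% 5 + 1]
  rows <- table[table$sex == sex & table$age_band == band, ]
  if (nrow(rows) != 4L)
    stop(sprintf("incomplete rate table for %s %s", sex, band))
  out <- rows[[variant]][match(transition_names(), rows$transition)] / 100
  if (anyNA(out))
    stop(sprintf("incomplete rate table for %s %s", sex, band))
  names(out) <- transition_names()
  out
}
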