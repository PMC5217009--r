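#' Read a period life table from CSV
#'
#' A life table supplies the competing general-population mortality: one row
#' per sex and single year of age with the annual death probability `qx`.
#' Any period life table can be supplied this way (the packaged synthetic
#' Gompertz tables are only stand-ins; see [synthetic_life_table()]).
#'
#' @param path CSV with columns `sex`, `age`, `qx`.
#' @return A `life_table` data frame.
#' @export
read_life_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_life_table(x)
}

#' Write a life table to CSV
#'
#' @param life A `life_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(life, path) {
  utils::write.csv(as.data.frame(life), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @keywords internal
validate_life_table <- function(x) {
  need <- c("sex", "age", "qx")
  if (!all(need %in% names(x)))
    stop("life table must have columns sex, age, qx")
  if (any(x$qx < 0) || any(x$qx > 1)) stop("qx must lie in [0, 1]")
  if (anyDuplicated(paste(x$sex, x$age))) stop("duplicate (sex, age) rows")
  class(x) <- c("life_table", "data.frame")
  x
}

#' Annual death probability for a given sex and age
#'
#' @param life A `life_table`, or `NULL` for zero mortality.
#' @param sex `"men"` or `"women"`.
#' @param age Integer age in years.
#' @return The annual death probability q for the year of age starting at
#'   `age` (0 when `life` is `NULL`).
#' @export
lookup_qx <- function(life, sex, age) {
  if (is.null(life)) return(0)
  i <- which(life$sex == sex & life$age == age)
  if (length(i) != 1L)
    stop(sprintf("life table has no entry for %s age %d", sex,
                 as.integer(age)))
  life$qx[i]
}

#' Generate a synthetic Gompertz life table
#'
#' Builds a single-sex period life table for ages 55-80 from a Gompertz
#' hazard: q(age) = 1 - exp(-m * a * exp(b * (age - 55))). With `b > 0` the
#' death probability increases strictly with age, the characteristic shape
#' of adult all-cause mortality. This is synthetic plumbing for testing the
#' pipeline without external data, not any country's observed mortality.
#'
#' @param a Baseline hazard scale at age 55 (> 0). Default 0.005.
#' @param b Age slope of the log hazard per year (>= 0). Default 0.09.
#' @param m Sex-specific proportional multiplier (> 0). Default 1.
#' @param sex Label for the `sex` column.
#' @param ages Integer ages to tabulate. Default 55:80.
#' @return A `life_table` data frame.
#' @examples
#' lt <- synthetic_life_table(sex = "men")
#' lt$qx[lt$age == 55]  # 1 - exp(-0.005)
#' @export
synthetic_life_table <- function(a = 0.005, b = 0.09, m = 1,
                                 sex = c("men", "women"), ages = 55:80) {
  sex <- match.arg(sex)
  if (a <= 0 || b < 0 || m <= 0)
    stop("require a > 0, b >= 0, m > 0")
  qx <- 1 - exp(-m * a * exp(b * (ages - 55)))
  if (any(qx <= 0) || any(qx >= 1))
    stop("implied death probabilities fall outside (0, 1)")
  validate_life_table(data.frame(sex = sex, age = as.integer(ages), qx = qx))
}

#' Synthetic stand-in for a contemporary German period life table
#'
#' Both-sex Gompertz life table with parameters calibrated to demographic
#' anchors typical of Western-European all-cause mortality around 2010
#' (men: q rising from about 0.6% at 55 to about 6% at 80; women roughly
#' half as high). It is a labelled SYNTHETIC stand-in: runs aiming to
#' reproduce results that depend on an observed national life table should
#' load that table via [read_life_table()] instead.
#'
#' @return A `life_table` covering men and women, ages 55-80.
#' @export
synthetic_german_life_table <- function() {
  men   <- synthetic_life_table(a = 0.0060, b = 0.095, sex = "men")
  women <- synthetic_life_table(a = 0.0030, b = 0.100, sex = "women")
  validate_life_table(rbind(as.data.frame(men), as.data.frame(women)))
}
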