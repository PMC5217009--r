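#' Registry prevalence counts of most advanced colonoscopy findings
#'
#' Counts of first-time screening-colonoscopy participants by sex, baseline
#' age (55 or 60) and most advanced finding (no neoplasm, nonadvanced
#' adenoma, advanced adenoma, cancer), shipped as a packaged fixture. These
#' raw counts define the model's baseline state prevalences.
#'
#' @return A `registry_counts` data frame with columns `sex`, `age`,
#'   `category`, `n`.
#' @seealso [prevalence_from_counts()], [baseline_from_counts()]
#' @export
crc_registry_counts <- function() {
  path <- system.file("extdata", "registry_counts.csv",
                      package = "crcscreen", mustWork = TRUE)
  read_registry_counts(path)
}

#' Read a registry count table from CSV
#'
#' @param path CSV with columns `sex`, `age`, `category`, `n`.
#' @return A validated `registry_counts` data frame.
#' @export
read_registry_counts <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_registry_counts(x)
}

#' @keywords internal
finding_categories <- function() {
  c("no_neoplasm", "nonadvanced_adenoma", "advanced_adenoma", "cancer")
}

#' @keywords internal
validate_registry_counts <- function(x) {
  need <- c("sex", "age", "category", "n")
  if (!all(need %in% names(x)))
    stop("registry counts must have columns sex, age, category, n")
  if (any(x$n < 0) || any(x$n != floor(x$n)))
    stop("counts must be non-negative integers")
  if (anyDuplicated(paste(x$sex, x$age, x$category)))
    stop("duplicate (sex, age, category) rows")
  class(x) <- c("registry_counts", "data.frame")
  x
}

#' Prevalences of most advanced findings from registry counts
#'
#' Divides each category count by the total for the requested sex and age.
#'
#' @param counts A `registry_counts` table.
#' @param sex `"men"` or `"women"`.
#' @param age Baseline age (55 or 60 in the packaged fixture).
#' @return Named numeric vector of proportions over the four finding
#'   categories, summing to 1.
#' @examples
#' p <- prevalence_from_counts(crc_registry_counts(), "men", 55)
#' round(100 * p[["cancer"]], 2)  # 0.46
#' @export
prevalence_from_counts <- function(counts, sex = c("men", "women"), age) {
  sex <- match.arg(sex)
  rows <- counts[counts$sex == sex & counts$age == age, ]
  n <- rows$n[match(finding_categories(), rows$category)]
  if (anyNA(n))
    stop(sprintf("registry counts incomplete for %s age %d", sex,
                 as.integer(age)))
  total <- sum(n)
  if (total <= 0) stop("zero total count")
  stats::setNames(n / total, finding_categories())
}

#' Simulate a registry-style count table by multinomial sampling
#'
#' Emulates the sampling structure of a screening registry: `n`
#' participants classified into the four most-advanced-finding categories
#' by one multinomial draw around the supplied true prevalences. Used to
#' stress-test the prevalence estimation and downstream plumbing; the
#' packaged fixture, not simulation, supplies the real baseline.
#'
#' @param true_prevalences Named numeric vector over
#'   `no_neoplasm, nonadvanced_adenoma, advanced_adenoma, cancer`, summing
#'   to 1.
#' @param n Total number of participants (> 0).
#' @param sex,age Labels for the output rows.
#' @param seed Optional integer seed for reproducibility.
#' @return A `registry_counts` data frame whose counts sum to `n`.
#' @export
simulate_registry_counts <- function(true_prevalences, n,
                                     sex = "men", age = 55, seed = NULL) {
  p <- true_prevalences[finding_categories()]
  if (anyNA(p) || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("true_prevalences must be non-negative, named by category, and sum to 1")
  if (n <= 0 || n != floor(n)) stop("n must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  draw <- as.vector(stats::rmultinom(1, size = n, prob = p))
  validate_registry_counts(
    data.frame(sex = sex, age = as.integer(age),
               category = finding_categories(), n = draw))
}

#' Write a registry count table to CSV
#'
#' @param counts A `registry_counts` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registry_counts <- function(counts, path) {
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
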