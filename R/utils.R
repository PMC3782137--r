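# Display rounding. Printed index values in ethnomedicinal tables use
# half-away-from-zero rounding (schoolbook rounding), not the IEEE
# round-half-even of base::round(). Every displayed quantity in this package
# is a ratio of integers, so rounding is done on the exact rational
# num/den * 10^digits, avoiding floating-point misclassification at halves.

#' Round an integer ratio for display, half away from zero
#'
#' Computes `num / den` rounded to `digits` decimal places with ties going
#' away from zero, using exact integer arithmetic on the numerator and
#' denominator. All display values in the package (informant consensus
#' factors, fidelity percentages, mention shares) are produced by this rule
#' so that they match the convention of printed survey tables.
#'
#' @param num Integer numerator(s).
#' @param den Integer denominator(s), non-zero.
#' @param digits Number of decimal places.
#' @return Numeric vector of rounded values.
#' @examples
#' ratio_display(6, 7, 2)    # 0.86
#' ratio_display(1, 8, 2)    # 0.13 (0.125 rounds away from zero)
#' @export
ratio_display <- function(num, den, digits = 2) {
  stopifnot(all(den != 0))
  s <- sign(num / den)
  s[s == 0] <- 1
  scaled <- abs(num) * 10^digits / abs(den)
  s * floor(scaled + 0.5) / 10^digits
}

# Seven canonical ailment-category labels of the packaged liver-disorder
# survey. Arbitrary labels (e.g. from simulated surveys) are allowed; these
# only pin the canonical spelling when an input matches case-insensitively.
canonical_disorders <- c(
  "fatigue recovery", "hangover", "hepatitis", "jaundice",
  "liver cancer", "liver cirrhosis", "liver-related ailments"
)

canonicalize_disorder <- function(x) {
  idx <- match(tolower(trimws(x)), canonical_disorders)
  ifelse(is.na(idx), trimws(x), canonical_disorders[idx])
}

squish <- function(x) gsub("\\s+", " ", trimws(x))

eq_abort <- function(message, class, ...) {
  abort(message, class = c(class, "ethnoquant_error"), ...)
}

# dplyr verbs preserve the survey_tbl subclass; strip it at the entry of
# derived computations so results are plain tibbles (plus their own class).
strip_survey <- function(x) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "survey_tbl")
  attr(out, "name_aliases") <- NULL
  out
}
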