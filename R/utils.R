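#' Round half away from zero
#'
#' Claims-study tables conventionally round percentages half-up (2.45 -> 2.5),
#' whereas [base::round()] rounds half to even. All percentages emitted by this
#' package go through this helper.
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @param digits Number of decimal places to keep.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(96.55, 1) # 96.6
#' round_half_up(2.45, 1)  # 2.5
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # small epsilon absorbs binary representation error just below .5 boundaries
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Prevalence as a percentage
#'
#' Converts an instance count and a denominator into the percentage style used
#' throughout the package's tables: `100 * instances / n`, rounded half-up to
#' one decimal.
#'
#' @param instances Count of prescriptions containing the item (or pair).
#' @param n Denominator (number of cohort prescriptions).
#' @return Percentage rounded to one decimal.
#' @examples
#' prevalence_pct(5185, 13820) # 37.5
#' @export
prevalence_pct <- function(instances, n) {
  round_half_up(100 * instances / n, 1)
}

#' Normalize an ICD-9 diagnosis code
#'
#' Claims extracts carry ICD-9 codes with or without the decimal point
#' ("6254" vs "625.4"). Codes are stored canonically WITH the point: a
#' dotless code longer than three characters gets the point inserted after
#' the third character. The transformation is idempotent.
#'
#' @param code Character vector of ICD-9 codes (NA passed through).
#' @return Canonicalized codes.
#' @examples
#' normalize_icd9(c("6254", "625.4", "306")) # "625.4" "625.4" "306"
#' @export
normalize_icd9 <- function(code) {
  code <- trimws(code)
  dotless <- !is.na(code) & !grepl(".", code, fixed = TRUE) & nchar(code) > 3
  code[dotless] <- paste0(
    substr(code[dotless], 1, 3), ".",
    substr(code[dotless], 4, nchar(code[dotless]))
  )
  code
}

# modality strings are a semicolon-joined set over these values
MODALITIES <- c("CHM", "ACUPUNCTURE", "MASSAGE")

modality_list <- function(modality) {
  out <- strsplit(ifelse(is.na(modality), "", modality), ";", fixed = TRUE)
  lapply(out, function(m) m[nzchar(m)])
}

has_modality <- function(modality, which) {
  vapply(modality_list(modality), function(m) which %in% m, logical(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
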