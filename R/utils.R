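# Shared numeric and string helpers.

#' Round half away from zero
#'
#' Standard commercial rounding: exact halves move away from zero, unlike
#' [base::round()] which rounds halves to even. All percentages printed by
#' the reporting functions go through this single formatter so that every
#' table in a run is rounded by the same convention.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.25, 1) # 0.3
#' round(0.25, 1)         # 0.2 (banker's rounding)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage with the central report rounding convention
#'
#' @param numerator,denominator counts; `denominator` must be positive.
#' @param digits decimal places (default 1, the convention used in all
#'   read-count summaries).
#' @return numeric percentage rounded half up.
#' @export
#' @examples
#' pct_round(11292116, 17006629) # 66.4
pct_round <- function(numerator, denominator, digits = 1) {
  if (any(denominator <= 0)) {
    stop("pct_round(): denominator must be positive", call. = FALSE)
  }
  round_half_up(100 * numerator / denominator, digits)
}

#' Reverse complement of DNA strings
#'
#' Vectorised; letters outside ACGT map to N.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  cpp_revcomp(toupper(as.character(x)))
}

# Deterministic per-stream seed fan-out: one user-facing seed plus a stable
# stream name yields an integer seed below 2^31. Polynomial string hash.
derive_seed <- function(seed, name) {
  h <- as.double(abs(as.integer(seed)) %% 2147483647)
  for (b in utf8ToInt(as.character(name))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Phred+33 helpers
phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

qual_sum <- function(qual) {
  vapply(qual, function(q) sum(utf8ToInt(q)) - 33L * nchar(q), numeric(1),
         USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
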