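# Small sequence and numeric helpers shared across modules.

# complement map covering IUPAC ambiguity codes plus inosine (I), which pairs
# universally and therefore complements to itself.
.COMP_FROM <- "ACGTRYSWKMBDHVNIacgtryswkmbdhvni"
.COMP_TO   <- "TGCAYRSWMKVHDBNItgcayrswmkvhdbni"

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`. Handles the full IUPAC alphabet plus inosine (`I`),
#' which is treated as self-complementary because it pairs with all four
#' bases.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr(.COMP_FROM, .COMP_TO, x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Round half away from zero
#'
#' Standard commercial rounding (0.5 always rounds up), as opposed to base R's
#' banker's rounding. Used for all reported percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Percentage with half-up rounding
#'
#' The reporting convention used for every printed proportion: `100 *
#' numerator / denominator`, rounded half-up to `decimals` places.
#'
#' @param numerator,denominator non-negative counts; `denominator` must be
#'   positive.
#' @param decimals decimal places in the result.
#' @return percentage as a number (e.g. `3.5` for 3.5%).
#' @export
#' @examples
#' proportion(1605, 45343, 1) # 3.5
proportion <- function(numerator, denominator, decimals = 1) {
  if (length(denominator) != 1L || !is.finite(denominator) || denominator <= 0)
    stop("denominator must be a single positive number")
  if (any(numerator < 0)) stop("numerator must be non-negative")
  round_half_up(100 * numerator / denominator, decimals)
}

# split a sequence string into a one-character vector
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# mean Phred score and expected errors from a Phred+33 quality string
.phred <- function(qual) utf8ToInt(qual) - 33L

#' Expected number of sequencing errors of a read
#'
#' Sum over positions of the per-base error probability `10^(-Q/10)` implied
#' by the Phred score.
#'
#' @param qual Phred+33 quality string.
#' @return expected error count (numeric scalar).
#' @export
expected_errors <- function(qual) {
  q <- .phred(qual)
  if (any(q < 0 | q > 93)) stop("Phred scores outside [0, 93]; not Phred+33?")
  sum(10^(-q / 10))
}

# deterministic child seed for a named pipeline stage, kept within 32-bit range
.stage_seed <- function(seed, stage) {
  (as.integer(seed) + sum(utf8ToInt(stage)) * 1009L) %% 2147483647L
}
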