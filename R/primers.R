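# Degenerate primer model: IUPAC ambiguity codes plus inosine, window
# matching with a mismatch budget, and the two primer sets used for CO1
# amplicon metabarcoding of lake invertebrates.

#' IUPAC base sets
#'
#' Allowed concrete bases for every IUPAC nucleotide code, plus inosine
#' (`I`), a universal base that pairs with A, C, G and T.
#'
#' @format named list of character vectors.
#' @export
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), I = c("A", "C", "G", "T")
)

#' Construct a degenerate primer
#'
#' @param name primer name (e.g. `"CH181F"`).
#' @param bases primer sequence 5'->3' over IUPAC codes plus `I` (inosine).
#' @return object of class `degenerate_primer` with fields `name`, `bases`,
#'   `length`.
#' @export
degenerate_primer <- function(name, bases) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(bases), length(bases) == 1L, nzchar(bases))
  bases <- toupper(gsub("[ -]", "", bases))
  bad <- setdiff(unique(.chars(bases)), names(IUPAC_SETS))
  if (length(bad))
    stop("invalid primer characters: ", paste(bad, collapse = ", "))
  structure(list(name = name, bases = bases, length = nchar(bases)),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer> %s: 5'-%s-3' (%d nt)\n",
              x$name, x$bases, x$length))
  invisible(x)
}

#' Construct a primer set
#'
#' A forward/reverse primer pair with its expected amplicon geometry. The
#' expected insert length is the amplicon minus both primers; it is kept as a
#' configuration value because published expected lengths sometimes deviate
#' from that arithmetic.
#'
#' @param name short set label (e.g. `"CH"`).
#' @param forward,reverse [degenerate_primer] objects.
#' @param expected_amplicon_len full fragment length in bp, primers included.
#' @param expected_insert_len post-trim insert length in bp.
#' @param reading_frame_offset codon phase of the insert, in `0:2`.
#' @return object of class `primer_set`.
#' @export
primer_set <- function(name, forward, reverse,
                       expected_amplicon_len, expected_insert_len,
                       reading_frame_offset = 0L) {
  stopifnot(inherits(forward, "degenerate_primer"),
            inherits(reverse, "degenerate_primer"),
            reading_frame_offset %in% 0:2)
  arithmetic <- expected_amplicon_len - forward$length - reverse$length
  if (expected_insert_len > arithmetic + 10L)
    stop("expected_insert_len inconsistent with amplicon and primer lengths")
  structure(list(name = name, forward = forward, reverse = reverse,
                 expected_amplicon_len = as.integer(expected_amplicon_len),
                 expected_insert_len = as.integer(expected_insert_len),
                 reading_frame_offset = as.integer(reading_frame_offset)),
            class = "primer_set")
}

#' @export
print.primer_set <- function(x, ...) {
  cat(sprintf("<primer_set> %s: %s / %s, amplicon %d bp, insert %d bp, frame +%d\n",
              x$name, x$forward$name, x$reverse$name,
              x$expected_amplicon_len, x$expected_insert_len,
              x$reading_frame_offset))
  invisible(x)
}

#' Chironomidae-specific CO1 primer set (CH)
#'
#' CH181F/CH181R target a short 181 bp CO1 fragment (139 bp insert) suited to
#' degraded sediment DNA; the reverse primer carries inosine positions.
#'
#' @return a [primer_set].
#' @export
ch_primer_set <- function() {
  primer_set(
    name = "CH",
    forward = degenerate_primer("CH181F", "TAATYTTYTTYATRGTNATRCC"),
    reverse = degenerate_primer("CH181R", "CCNGTICCIGCHCCRTTTTC"),
    expected_amplicon_len = 181L,
    expected_insert_len = 139L,
    reading_frame_offset = 0L
  )
}

#' Freshwater-invertebrate universal CO1 primer set (FWH)
#'
#' fwhF2/fwhR2n target a 254 bp CO1 fragment (205 bp insert), widely used for
#' freshwater macroinvertebrate metabarcoding.
#'
#' @return a [primer_set].
#' @export
fwh_primer_set <- function() {
  primer_set(
    name = "FWH",
    forward = degenerate_primer("fwhF2", "GGDACWGGWTGAACWGTWTAYCCHCC"),
    reverse = degenerate_primer("fwhR2n", "GTRATWGCHCCDGCTARWACWGG"),
    expected_amplicon_len = 254L,
    expected_insert_len = 205L,
    reading_frame_offset = 0L
  )
}

#' Count mismatches between a sequence window and a degenerate primer
#'
#' A position matches at zero cost when the window base is in the primer
#' character's allowed set; `N` or `I` in the primer match any base. An `N`
#' in the window counts as a mismatch against any non-universal primer
#' character.
#'
#' @param window DNA string, same length as the primer.
#' @param primer a [degenerate_primer].
#' @return integer mismatch count.
#' @export
match_primer <- function(window, primer) {
  stopifnot(inherits(primer, "degenerate_primer"))
  if (nchar(window) != primer$length)
    stop("window length (", nchar(window), ") != primer length (",
         primer$length, ")")
  w <- .chars(toupper(window))
  p <- .chars(primer$bases)
  ok <- mapply(function(wb, pb) pb %in% c("N", "I") || wb %in% IUPAC_SETS[[pb]],
               w, p)
  sum(!ok)
}

# all 0-based start offsets in `seq` where the primer matches with at most
# max_mismatch mismatches; vectorised window comparison over offsets
.primer_hits <- function(seq, primer, max_mismatch = 1L) {
  L <- nchar(seq); k <- primer$length
  if (L < k) return(integer(0))
  s <- .chars(toupper(seq))
  p <- .chars(primer$bases)
  universal <- p %in% c("N", "I")
  # per primer position, the allowed base set
  sets <- IUPAC_SETS[p]
  starts <- 0:(L - k)
  mm <- vapply(starts, function(st) {
    w <- s[(st + 1):(st + k)]
    bad <- 0L
    for (i in seq_len(k)) {
      if (!universal[i] && !(w[i] %in% sets[[i]])) {
        bad <- bad + 1L
        if (bad > max_mismatch) break
      }
    }
    bad
  }, integer(1))
  starts[mm <= max_mismatch]
}

#' One concrete expansion of a degenerate primer
#'
#' Replaces every ambiguity code by a concrete base drawn uniformly from its
#' allowed set (or the first set member when `random = FALSE`). Used by the
#' read simulator to build amplicons carrying valid primer sites.
#'
#' @param primer a [degenerate_primer].
#' @param random draw randomly (uses the current RNG stream) or take the
#'   first allowed base.
#' @return concrete DNA string.
#' @export
expand_primer <- function(primer, random = TRUE) {
  sets <- IUPAC_SETS[.chars(primer$bases)]
  paste(vapply(sets, function(s)
    if (random && length(s) > 1L) sample(s, 1L) else s[1L],
    character(1)), collapse = "")
}
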