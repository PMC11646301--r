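# Taxonomic assignment of ESVs: global alignment against the curated
# amplicon database, strict best-hit filtering, LCA of tied hits, and the
# 95% species-identity threshold.

# default Karlin-Altschul constants used to turn raw scores into bit scores
# and e-values; fixed configuration values (the ordering they induce is
# monotone in the raw score for near-equal-length global alignments).
.KARLIN <- list(lambda = 0.625, k = 0.041)

# stats of one pairwise alignment from its aligned (gapped) strings
.aln_stats <- function(p, s) {
  pc <- .chars(p); sc <- .chars(s)
  alen <- length(pc)
  gap_p <- pc == "-"; gap_s <- sc == "-"
  # terminal gap columns: leading/trailing runs of gap in either sequence
  term <- rep(FALSE, alen)
  r <- rle(gap_p | gap_s)
  if (length(r$lengths) && r$values[1])
    term[seq_len(r$lengths[1])] <- TRUE
  if (length(r$lengths) > 1L && r$values[length(r$values)])
    term[(alen - r$lengths[length(r$lengths)] + 1L):alen] <- TRUE
  matches <- sum(!gap_p & !gap_s & pc == sc)
  mismatches <- sum(!gap_p & !gap_s & pc != sc)
  gap_cols <- sum(gap_p | gap_s)
  runs <- function(g) { rr <- rle(g); sum(rr$values) }
  gap_openings <- runs(gap_p) + runs(gap_s)
  denom <- alen - sum(term)
  list(alignment_length = alen, matches = matches, mismatches = mismatches,
       gap_columns = gap_cols, gap_openings = gap_openings,
       identity = if (denom > 0) 100 * matches / denom else 0)
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch optimal global alignment. A gap of length L costs
#' `gap_open + (L - 1) * gap_extend` (both negative), so setting `gap_extend
#' = gap_open` gives plain per-base gap costs. Identity excludes terminal-gap
#' columns (the usual usearch-style definition). Bit score and e-value are
#' derived from the raw score via the Karlin-Altschul formulae with fixed
#' constants.
#'
#' @param query,subject non-empty DNA strings.
#' @param match,mismatch substitution scores.
#' @param gap_open cost of a length-1 gap (negative).
#' @param gap_extend cost per additional gap base (negative).
#' @return one-row data frame: `identity`, `mismatches`, `gap_openings`,
#'   `gap_columns`, `alignment_length`, `score`, `bit_score`, `e_value`.
#' @export
global_align <- function(query, subject, match = 2, mismatch = -4,
                         gap_open = -10, gap_extend = -1) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  hits <- .align_many(query, subject, match, mismatch, gap_open, gap_extend)
  hits
}

# align one query against many subjects in a single vectorised call
.align_many <- function(query, subjects, match = 2, mismatch = -4,
                        gap_open = -10, gap_extend = -1) {
  stopifnot(gap_open <= gap_extend, gap_extend < 0)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(subjects),
    subject = Biostrings::DNAString(query),
    type = "global", substitutionMatrix = submat,
    gapOpening = -(gap_open - gap_extend), gapExtension = -gap_extend)
  ap <- as.character(Biostrings::alignedPattern(aln))
  as_ <- as.character(Biostrings::alignedSubject(aln))
  sc <- Biostrings::score(aln)
  n <- length(subjects)
  rows <- lapply(seq_len(n), function(i) .aln_stats(ap[i], as_[i]))
  m <- nchar(query)
  lens <- nchar(subjects)
  bit <- (.KARLIN$lambda * sc - log(.KARLIN$k)) / log(2)
  ev <- .KARLIN$k * m * lens * exp(-.KARLIN$lambda * sc)
  data.frame(
    identity = vapply(rows, `[[`, numeric(1), "identity"),
    mismatches = vapply(rows, `[[`, numeric(1), "mismatches"),
    gap_openings = vapply(rows, `[[`, numeric(1), "gap_openings"),
    gap_columns = vapply(rows, `[[`, numeric(1), "gap_columns"),
    alignment_length = vapply(rows, `[[`, numeric(1), "alignment_length"),
    score = sc, bit_score = bit, e_value = ev)
}

#' Search an ESV against the curated amplicon database
#'
#' Globally aligns the query against every reference insert and returns all
#' hits with identity at or above `min_identity`, ranked by the best-hit key
#' (e-value ascending, identity descending, bit score descending, gap
#' openings ascending, mismatches ascending) and truncated to `max_hits`.
#'
#' @param query ESV sequence.
#' @param refdb list as returned by [build_refdb()] (`amplicons`,
#'   `lineages`).
#' @param min_identity minimum percent identity for a hit.
#' @param max_hits hit-list cap.
#' @param ... scoring parameters passed to [global_align()].
#' @return data frame of hits with a `ref_id` column (possibly empty).
#' @export
search_refdb <- function(query, refdb, min_identity = 90, max_hits = 5000,
                         ...) {
  amp <- refdb$amplicons
  if (nrow(amp) == 0L)
    return(data.frame(ref_id = character(0), identity = numeric(0),
                      mismatches = numeric(0), gap_openings = numeric(0),
                      gap_columns = numeric(0), alignment_length = numeric(0),
                      score = numeric(0), bit_score = numeric(0),
                      e_value = numeric(0)))
  hits <- .align_many(query, amp$insert, ...)
  hits <- cbind(data.frame(ref_id = amp$seq_id, stringsAsFactors = FALSE),
                hits)
  hits <- hits[hits$identity >= min_identity, , drop = FALSE]
  hits <- hits[.hit_order(hits), , drop = FALSE]
  rownames(hits) <- NULL
  utils::head(hits, max_hits)
}

# strict best-hit ranking key
.hit_order <- function(hits) {
  order(hits$e_value, -hits$identity, -hits$bit_score, hits$gap_openings,
        hits$mismatches, hits$ref_id)
}

#' Assign a lineage from a ranked hit list
#'
#' Retains every hit tied with the best on the full ranking key (lowest
#' e-value, highest identity, highest bit score, fewest gap openings, fewest
#' mismatches), takes the LCA of the retained hits' lineages, and demotes
#' species-level assignments with best identity below `species_threshold` to
#' genus level.
#'
#' @param hits data frame from [search_refdb()].
#' @param lineages lineage data frame (`seq_id` + ranks) for the reference
#'   records; lineages are assumed already sanitised by curation.
#' @param species_threshold minimum percent identity for a species-level
#'   assignment.
#' @return list with `lineage`, `rank`, `best_identity`, `n_best_hits`,
#'   `demoted_from_species`, `assigned`; unassigned when the hit list is
#'   empty.
#' @export
assign_taxonomy <- function(hits, lineages, species_threshold = 95) {
  if (nrow(hits) == 0L) {
    empty <- stats::setNames(rep(NA_character_, 7L), TAX_RANKS)
    return(list(lineage = empty, rank = NA_character_,
                best_identity = NA_real_, n_best_hits = 0L,
                demoted_from_species = FALSE, assigned = FALSE))
  }
  hits <- hits[.hit_order(hits), , drop = FALSE]
  key <- function(h) paste(signif(h$e_value, 12), h$identity, h$bit_score,
                           h$gap_openings, h$mismatches)
  best_key <- key(hits[1, ])
  tied <- hits[key(hits) == best_key, , drop = FALSE]
  lin_rows <- lineages[match(tied$ref_id, lineages$seq_id), , drop = FALSE]
  lin <- lca(lin_rows)
  best_identity <- tied$identity[1]
  demoted <- FALSE
  if (!is.na(lin["species"]) && best_identity < species_threshold) {
    lin["species"] <- NA_character_
    demoted <- TRUE
  }
  list(lineage = lin, rank = assignment_rank(lin),
       best_identity = best_identity, n_best_hits = nrow(tied),
       demoted_from_species = demoted, assigned = TRUE)
}

#' Assign lineages to all ESVs in a set
#'
#' Runs [search_refdb()] and [assign_taxonomy()] for every ESV. ESVs without
#' any hit are retained with rank `NA` and `assigned = FALSE` (reported
#' downstream as unidentified).
#'
#' @param esvs an [esv_set].
#' @param refdb list from [build_refdb()].
#' @param min_identity,max_hits,species_threshold see [search_refdb()] and
#'   [assign_taxonomy()].
#' @param ... scoring parameters passed to [global_align()].
#' @return data frame: `esv_id`, the seven rank columns, `rank`,
#'   `best_identity`, `n_best_hits`, `demoted_from_species`, `assigned`.
#' @export
assign_all <- function(esvs, refdb, min_identity = 90, max_hits = 5000,
                       species_threshold = 95, ...) {
  sq <- esvs$sequences
  rows <- lapply(seq_len(nrow(sq)), function(i) {
    hits <- search_refdb(sq$sequence[i], refdb, min_identity, max_hits, ...)
    a <- assign_taxonomy(hits, refdb$lineages, species_threshold)
    cbind(data.frame(esv_id = sq$esv_id[i], stringsAsFactors = FALSE),
          .lineage_df(list(a$lineage)),
          data.frame(rank = a$rank, best_identity = a$best_identity,
                     n_best_hits = a$n_best_hits,
                     demoted_from_species = a$demoted_from_species,
                     assigned = a$assigned, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
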