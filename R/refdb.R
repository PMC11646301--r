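# Reference database curation: length/N filters, exact dereplication with
# LCA-merged lineages, and restriction to primer-specific amplicon inserts by
# in-silico PCR with a mismatch budget.

#' Curate a reference sequence set
#'
#' Uppercases sequences, strips terminal `N`s, removes records shorter than
#' `min_length` or containing internal `N`s, and dereplicates exact duplicate
#' sequences. Duplicates collapse into a single record (keeping the
#' lexicographically smallest `seq_id`) whose lineage is the lowest common
#' ancestor of the merged records' sanitised lineages.
#'
#' @param records data frame with columns `seq_id`, `sequence`.
#' @param lineages data frame with columns `seq_id` and [TAX_RANKS].
#' @param min_length minimum sequence length in bp after terminal-N
#'   stripping.
#' @param markers uncertainty markers passed to [sanitize_lineage()].
#' @return list with `records` (curated, columns `seq_id`, `sequence`),
#'   `lineages` (matching rows), and `log` (data frame `reason`, `n` counting
#'   `input`, `too_short`, `internal_N`, `duplicate`, `kept`).
#' @export
curate_references <- function(records, lineages, min_length = 200,
                              markers = UNCERTAINTY_MARKERS) {
  stopifnot(all(c("seq_id", "sequence") %in% names(records)))
  n_in <- nrow(records)
  if (n_in == 0L) {
    warning("empty reference input")
    return(list(records = records, lineages = lineages[0, ],
                log = data.frame(reason = c("input", "kept"), n = c(0L, 0L))))
  }
  seqs <- toupper(records$sequence)
  seqs <- gsub("^N+|N+$", "", seqs)

  too_short <- nchar(seqs) < min_length
  internal_n <- !too_short & grepl("N", seqs, fixed = TRUE)
  keep <- !too_short & !internal_n

  kept <- data.frame(seq_id = records$seq_id[keep], sequence = seqs[keep],
                     stringsAsFactors = FALSE)
  lin <- lineages[match(kept$seq_id, lineages$seq_id), , drop = FALSE]

  # dereplicate on the exact sequence string; lineage of a merged record is
  # the LCA of the members' sanitised lineages
  ord <- order(kept$sequence, kept$seq_id)
  kept <- kept[ord, , drop = FALSE]
  lin <- lin[ord, , drop = FALSE]
  grp <- split(seq_len(nrow(kept)), kept$sequence)
  n_dup <- nrow(kept) - length(grp)

  rows <- lapply(grp, function(ix) {
    sanitized <- lapply(ix, function(i) sanitize_lineage(.row_lineage(lin, i),
                                                         markers = markers))
    list(seq_id = kept$seq_id[ix[1]], sequence = kept$sequence[ix[1]],
         lineage = if (length(sanitized) == 1L) sanitized[[1]] else
           lca(sanitized))
  })
  out_records <- data.frame(
    seq_id = vapply(rows, `[[`, character(1), "seq_id"),
    sequence = vapply(rows, `[[`, character(1), "sequence"),
    stringsAsFactors = FALSE)
  out_lineages <- .lineage_df(lapply(rows, `[[`, "lineage"),
                              seq_id = out_records$seq_id)
  ord2 <- order(out_records$seq_id)
  out_records <- out_records[ord2, , drop = FALSE]
  out_lineages <- out_lineages[ord2, , drop = FALSE]
  rownames(out_records) <- rownames(out_lineages) <- NULL

  log <- data.frame(
    reason = c("input", "too_short", "internal_N", "duplicate", "kept"),
    n = c(n_in, sum(too_short), sum(internal_n), n_dup, nrow(out_records)))
  list(records = out_records, lineages = out_lineages, log = log)
}

# search one strand for a qualifying amplicon; returns list(insert, reason)
.pcr_one_strand <- function(seq, primers, max_mismatch, length_tolerance) {
  fwd_hits <- .primer_hits(seq, primers$forward, max_mismatch)
  if (!length(fwd_hits)) return(list(insert = NULL, reason = "no_forward"))
  rc_rev <- degenerate_primer(primers$reverse$name,
                              revcomp(primers$reverse$bases))
  rev_hits <- .primer_hits(seq, rc_rev, max_mismatch)
  lo <- primers$expected_insert_len - length_tolerance
  hi <- primers$expected_insert_len + length_tolerance
  # leftmost forward site with a qualifying downstream reverse site wins;
  # among that site's reverse candidates, the nearest one is taken
  any_rev_downstream <- FALSE
  for (f in sort(fwd_hits)) {
    ins_start <- f + primers$forward$length       # 0-based
    cand <- sort(rev_hits[rev_hits >= ins_start])
    if (!length(cand)) next
    any_rev_downstream <- TRUE
    lens <- cand - ins_start
    ok <- which(lens >= lo & lens <= hi)
    if (length(ok)) {
      r <- cand[ok[1]]
      return(list(insert = substr(seq, ins_start + 1L, r), reason = "ok"))
    }
  }
  list(insert = NULL,
       reason = if (any_rev_downstream) "length_out_of_window" else
         "no_reverse")
}

#' In-silico PCR of one reference sequence
#'
#' Finds a forward-primer site (at most `max_mismatch` mismatches,
#' degenerate-aware) and, downstream of it, the reverse complement of the
#' reverse primer; returns the insert between the primer sites (both primers
#' removed) when its length falls within `expected_insert_len +/-
#' length_tolerance`. Both strands are scanned; when both qualify the
#' plus-strand hit is kept with a warning. With several candidate sites the
#' leftmost forward site and its nearest qualifying reverse site win, which
#' makes the outcome deterministic (no ambiguity rejection is ever emitted).
#'
#' @param sequence DNA string (a curated reference record).
#' @param primers a [primer_set].
#' @param max_mismatch mismatch budget per primer site.
#' @param length_tolerance allowed deviation (bp) of the insert length from
#'   `primers$expected_insert_len`.
#' @return list with `insert` (DNA string or `NULL`), `status` (`"ok"` or a
#'   rejection reason among `no_forward`, `no_reverse`,
#'   `length_out_of_window`), and `strand` (`"+"`, `"-"`, or `NA`).
#' @export
insilico_pcr <- function(sequence, primers, max_mismatch = 1,
                         length_tolerance = 10) {
  stopifnot(inherits(primers, "primer_set"))
  sequence <- toupper(sequence)
  plus <- .pcr_one_strand(sequence, primers, max_mismatch, length_tolerance)
  minus <- .pcr_one_strand(revcomp(sequence), primers, max_mismatch,
                           length_tolerance)
  if (!is.null(plus$insert)) {
    if (!is.null(minus$insert))
      warning("both strands yield a qualifying amplicon; keeping plus strand")
    return(list(insert = plus$insert, status = "ok", strand = "+"))
  }
  if (!is.null(minus$insert))
    return(list(insert = minus$insert, status = "ok", strand = "-"))
  # report the most informative reason: prefer the strand that got furthest
  rank <- c(no_forward = 1L, no_reverse = 2L, length_out_of_window = 3L)
  reason <- if (rank[plus$reason] >= rank[minus$reason]) plus$reason else
    minus$reason
  list(insert = NULL, status = unname(reason), strand = NA_character_)
}

#' Build a curated amplicon reference database
#'
#' Runs [curate_references()] and then restricts every curated record to its
#' primer-specific insert by [insilico_pcr()]; records failing either step
#' are dropped and counted by reason.
#'
#' @inheritParams curate_references
#' @inheritParams insilico_pcr
#' @param primers a [primer_set].
#' @return list with `amplicons` (data frame `seq_id`, `insert`), `lineages`
#'   (matching rows), `log` (curation log plus per-reason PCR rejections).
#' @export
build_refdb <- function(records, lineages, primers, min_length = 200,
                        max_mismatch = 1, length_tolerance = 10,
                        markers = UNCERTAINTY_MARKERS) {
  cur <- curate_references(records, lineages, min_length, markers)
  res <- lapply(cur$records$sequence, insilico_pcr, primers = primers,
                max_mismatch = max_mismatch,
                length_tolerance = length_tolerance)
  status <- vapply(res, `[[`, character(1), "status")
  ok <- status == "ok"
  amplicons <- data.frame(
    seq_id = cur$records$seq_id[ok],
    insert = vapply(res[ok], `[[`, character(1), "insert"),
    stringsAsFactors = FALSE)
  rej <- table(factor(status[!ok],
                      levels = c("no_forward", "no_reverse",
                                 "length_out_of_window")))
  log <- rbind(cur$log,
               data.frame(reason = paste0("pcr_", names(rej)),
                          n = as.integer(rej)),
               data.frame(reason = "amplicons", n = nrow(amplicons)))
  list(amplicons = amplicons,
       lineages = cur$lineages[ok, , drop = FALSE],
       log = log)
}
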