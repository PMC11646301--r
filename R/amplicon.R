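# Read processing chain: merge paired reads, trim primers, quality-filter,
# dereplicate, denoise into ESVs by d=1 single-linkage clustering, remove
# chimeras and numts, and re-map reads onto the final ESVs.

#' Construct an ESV set
#'
#' Container for denoised exact sequence variants with per-sample abundances.
#'
#' @param sequences data frame with columns `esv_id`, `sequence`, `total`.
#' @param abundance integer matrix, ESVs x samples, rownames = `esv_id`.
#' @return object of class `esv_set`.
#' @export
esv_set <- function(sequences, abundance) {
  stopifnot(nrow(sequences) == nrow(abundance),
            all(rowSums(abundance) == sequences$total),
            all(sequences$total >= 1) || nrow(sequences) == 0L,
            !anyDuplicated(sequences$sequence))
  rownames(abundance) <- sequences$esv_id
  structure(list(sequences = sequences, abundance = abundance),
            class = "esv_set")
}

#' @export
print.esv_set <- function(x, ...) {
  cat(sprintf("<esv_set> %d ESVs, %d samples, %d reads\n",
              nrow(x$sequences), ncol(x$abundance), sum(x$abundance)))
  invisible(x)
}

# subset an esv_set by row index
.esv_subset <- function(x, keep) {
  esv_set(x$sequences[keep, , drop = FALSE],
          x$abundance[keep, , drop = FALSE])
}

#' Merge one read pair
#'
#' The reverse read is reverse-complemented, then all non-staggered overlaps
#' of at least `min_overlap` bases are scanned and the one maximising
#' matching positions is taken (ties favour fewer mismatches). The pair is
#' rejected when the best overlap carries more than `max_diffs` mismatches.
#' At agreeing positions the consensus quality is the larger of the two
#' scores; at conflicts the higher-quality base wins and the consensus
#' quality is the absolute score difference.
#'
#' @param seq1,qual1 forward read sequence and Phred+33 quality.
#' @param seq2,qual2 reverse read (as sequenced; reverse-complemented
#'   internally).
#' @param min_overlap minimum overlap length in bases.
#' @param max_diffs maximum nucleotide differences tolerated in the overlap.
#' @return list with `status` (`"ok"`, `"no_overlap"`, `"too_many_diffs"`)
#'   and, on success, `sequence` and `quality` of the merged read.
#' @export
merge_pairs <- function(seq1, qual1, seq2, qual2, min_overlap = 50,
                        max_diffs = 10) {
  a <- charToRaw(toupper(seq1))
  b <- charToRaw(revcomp(toupper(seq2)))
  qa <- .phred(qual1)
  qb <- rev(.phred(qual2))
  L1 <- length(a); L2 <- length(b)
  if (L1 < min_overlap || L2 < min_overlap)
    return(list(status = "no_overlap"))
  best_k <- -1L; best_matches <- -1L; best_mism <- .Machine$integer.max
  for (k in 0:(L1 - min_overlap)) {
    ov <- L1 - k
    if (ov > L2) next                      # staggered: out of scope
    matches <- sum(a[(k + 1L):L1] == b[1:ov])
    mism <- ov - matches
    # most matching positions wins; ties favour the cleaner overlap
    if (matches > best_matches ||
        (matches == best_matches && mism < best_mism)) {
      best_matches <- matches
      best_mism <- mism
      best_k <- k
    }
  }
  if (best_k < 0L) return(list(status = "no_overlap"))
  ov <- L1 - best_k
  mism <- ov - best_matches
  if (mism > max_diffs) return(list(status = "too_many_diffs"))
  # consensus over the overlap
  ia <- (best_k + 1L):L1; ib <- 1:ov
  agree <- a[ia] == b[ib]
  cons <- a[ia]
  consq <- pmax(qa[ia], qb[ib])
  if (any(!agree)) {
    conf <- which(!agree)
    use_b <- qb[ib][conf] > qa[ia][conf]   # tie keeps the forward base
    cons[conf[use_b]] <- b[ib][conf[use_b]]
    consq[conf] <- abs(qa[ia][conf] - qb[ib][conf])
  }
  tail_seq <- if (ov < L2) rawToChar(b[(ov + 1L):L2]) else ""
  merged_seq <- paste0(substr(seq1, 1L, best_k), rawToChar(cons), tail_seq)
  merged_q <- c(qa[seq_len(best_k)], consq,
                if (ov < L2) qb[(ov + 1L):L2] else integer(0))
  list(status = "ok", sequence = toupper(merged_seq),
       quality = intToUtf8(merged_q + 33L))
}

#' Trim linked, 5'-anchored primers from a merged read
#'
#' The forward primer must match at position 0 and the reverse complement of
#' the reverse primer at the 3' end, each within a mismatch budget of
#' `floor(error_rate x primer length)` (degenerate-aware). Reads lacking
#' either site are discarded (linked semantics).
#'
#' @param sequence,quality merged read.
#' @param primers a [primer_set].
#' @param error_rate allowed mismatch fraction per primer.
#' @return list with `status` (`"ok"`, `"no_forward_anchor"`, `"no_reverse"`)
#'   and, on success, the trimmed `sequence` and `quality`.
#' @export
trim_primers <- function(sequence, quality, primers, error_rate = 0.1) {
  fl <- primers$forward$length
  rl <- primers$reverse$length
  L <- nchar(sequence)
  if (L < fl + rl + 1L) return(list(status = "no_forward_anchor"))
  fbudget <- floor(error_rate * fl)
  rbudget <- floor(error_rate * rl)
  if (match_primer(substr(sequence, 1L, fl), primers$forward) > fbudget)
    return(list(status = "no_forward_anchor"))
  rc_rev <- degenerate_primer(primers$reverse$name,
                              revcomp(primers$reverse$bases))
  if (match_primer(substr(sequence, L - rl + 1L, L), rc_rev) > rbudget)
    return(list(status = "no_reverse"))
  list(status = "ok",
       sequence = substr(sequence, fl + 1L, L - rl),
       quality = substr(quality, fl + 1L, L - rl))
}

#' Quality-filter a primer-trimmed read
#'
#' Keeps a read iff its length deviates at most `len_tolerance` bp from the
#' expected insert length, its expected error count is below `max_ee`, and
#' its mean Phred score reaches `min_mean_q`.
#'
#' @param sequence,quality trimmed read.
#' @param expected_len expected insert length in bp.
#' @param len_tolerance allowed length deviation in bp.
#' @param max_ee expected-error ceiling; reads with `EE >= max_ee` are
#'   dropped.
#' @param min_mean_q minimum mean Phred score.
#' @return list with `keep` (logical) and `reason` (`"ok"`, `"length"`,
#'   `"expected_errors"`, `"mean_quality"`).
#' @export
quality_filter <- function(sequence, quality, expected_len,
                           len_tolerance = 10, max_ee = 1.0,
                           min_mean_q = 30) {
  if (abs(nchar(sequence) - expected_len) > len_tolerance)
    return(list(keep = FALSE, reason = "length"))
  q <- .phred(quality)
  if (sum(10^(-q / 10)) >= max_ee)
    return(list(keep = FALSE, reason = "expected_errors"))
  if (mean(q) < min_mean_q)
    return(list(keep = FALSE, reason = "mean_quality"))
  list(keep = TRUE, reason = "ok")
}

#' Dereplicate reads into unique sequences with per-sample abundances
#'
#' Exact-sequence grouping across all samples. Output is sorted by total
#' abundance descending, ties broken by lexicographic sequence order.
#'
#' @param reads_by_sample named list of data frames with a `sequence` column.
#' @return list with `sequences` (character vector), `abundance` (integer
#'   matrix uniques x samples), `total` (integer vector).
#' @export
dereplicate <- function(reads_by_sample) {
  samples <- names(reads_by_sample)
  stopifnot(!is.null(samples), !anyDuplicated(samples))
  all_seqs <- unlist(lapply(reads_by_sample, `[[`, "sequence"),
                     use.names = FALSE)
  if (!length(all_seqs)) {
    ab <- matrix(0L, 0L, length(samples), dimnames = list(NULL, samples))
    return(list(sequences = character(0), abundance = ab, total = integer(0)))
  }
  uniq <- sort(unique(all_seqs))
  ab <- vapply(reads_by_sample, function(df)
    as.integer(table(factor(df$sequence, levels = uniq))),
    integer(length(uniq)))
  ab <- matrix(ab, nrow = length(uniq), dimnames = list(NULL, samples))
  total <- as.integer(rowSums(ab))
  ord <- order(-total, uniq)
  list(sequences = uniq[ord], abundance = ab[ord, , drop = FALSE],
       total = total[ord])
}

#' Denoise unique sequences into ESVs (d = 1 single-linkage swarms)
#'
#' Iterative single-linkage clustering: starting from the most abundant
#' unassigned unique, any unassigned unique at Levenshtein distance <= 1 from
#' a cluster member is attached, growing chains. In fastidious mode, clusters
#' whose total abundance falls below `boundary` are grafted onto a large
#' cluster when any member lies within distance 2 of a large-cluster member
#' (the most abundant qualifying large cluster wins). The ESV representative
#' is the cluster's most abundant member.
#'
#' @param uniques output of [dereplicate()].
#' @param fastidious graft low-abundance clusters across a distance-2 bridge.
#' @param boundary abundance threshold separating small from large clusters.
#' @return list with `esvs` (an [esv_set]) and `membership` (data frame
#'   `sequence`, `esv_id`).
#' @export
denoise_d1 <- function(uniques, fastidious = TRUE, boundary = 3) {
  n <- length(uniques$sequences)
  samples <- colnames(uniques$abundance)
  if (n == 0L) {
    empty <- esv_set(data.frame(esv_id = character(0), sequence = character(0),
                                total = integer(0)),
                     uniques$abundance)
    return(list(esvs = empty,
                membership = data.frame(sequence = character(0),
                                        esv_id = character(0))))
  }
  seqs <- uniques$sequences
  total <- uniques$total
  d <- utils::adist(seqs)
  cluster <- rep(NA_integer_, n)
  ord <- order(-total, seqs)     # input is sorted already; defensive
  cid <- 0L
  for (s in ord) {
    if (!is.na(cluster[s])) next
    cid <- cid + 1L
    cluster[s] <- cid
    frontier <- s
    while (length(frontier)) {
      if (!anyNA(cluster)) break
      hits <- which(is.na(cluster) &
                      apply(d[frontier, , drop = FALSE] <= 1L, 2, any))
      cluster[hits] <- cid
      frontier <- hits
    }
  }
  if (fastidious && cid > 1L) {
    ctot <- vapply(seq_len(cid), function(k) sum(total[cluster == k]),
                   numeric(1))
    small <- which(ctot < boundary)
    large <- which(ctot >= boundary)
    if (length(small) && length(large)) {
      for (k in small[order(-ctot[small], small)]) {
        members <- which(cluster == k)
        best <- NULL; best_tot <- -Inf
        for (g in large) {
          gm <- which(cluster == g)
          if (min(d[members, gm]) <= 2L && ctot[g] > best_tot) {
            best <- g; best_tot <- ctot[g]
          }
        }
        if (!is.null(best)) cluster[members] <- best
      }
    }
  }
  # build ESVs: representative = most abundant member (tie lexicographic)
  ids <- sort(unique(cluster))
  reps <- vapply(ids, function(k) {
    m <- which(cluster == k)
    m[order(-total[m], seqs[m])][1]
  }, integer(1))
  ab <- do.call(rbind, lapply(ids, function(k)
    colSums(uniques$abundance[cluster == k, , drop = FALSE])))
  ab <- matrix(as.integer(ab), nrow = length(ids),
               dimnames = list(NULL, samples))
  tot <- as.integer(rowSums(ab))
  ord2 <- order(-tot, seqs[reps])
  sequences <- data.frame(esv_id = paste0("esv_", seq_along(ids)),
                          sequence = seqs[reps][ord2],
                          total = tot[ord2], stringsAsFactors = FALSE)
  esvs <- esv_set(sequences, ab[ord2, , drop = FALSE])
  # map each cluster id to its representative's esv_id
  rep_seq <- stats::setNames(seqs[reps], ids)
  esv_id_of <- stats::setNames(
    sequences$esv_id[match(rep_seq, sequences$sequence)], ids)
  membership <- data.frame(sequence = seqs,
                           esv_id = unname(esv_id_of[as.character(cluster)]),
                           stringsAsFactors = FALSE)
  list(esvs = esvs, membership = membership)
}

# longest common prefix / suffix length of two raw vectors
.lcp <- function(a, b) {
  m <- min(length(a), length(b))
  if (m == 0L) return(0L)
  neq <- which(a[1:m] != b[1:m])
  if (!length(neq)) m else neq[1] - 1L
}
.lcs <- function(a, b) .lcp(rev(a), rev(b))

#' Detect perfect two-parent chimeras
#'
#' An ESV is flagged as chimeric iff its sequence is exactly a prefix of one
#' parent followed by a suffix of another, where both parents are distinct
#' ESVs each at least `abundance_skew` times more abundant than the query
#' (the de-novo perfect-chimera criterion).
#'
#' @param esvs an [esv_set].
#' @param abundance_skew minimum parent/query abundance ratio.
#' @return list with `flagged` (character vector of chimeric `esv_id`s),
#'   `parents` (data frame `esv_id`, `parent_a`, `parent_b`), and `esvs` (the
#'   input with flagged ESVs removed).
#' @export
detect_chimeras <- function(esvs, abundance_skew = 16) {
  sq <- esvs$sequences
  n <- nrow(sq)
  flagged <- character(0)
  parents <- data.frame(esv_id = character(0), parent_a = character(0),
                        parent_b = character(0), stringsAsFactors = FALSE)
  if (n >= 3L) {
    raws <- lapply(sq$sequence, charToRaw)
    for (i in seq_len(n)) {
      cand <- which(sq$total >= abundance_skew * sq$total[i])
      cand <- setdiff(cand, i)
      if (length(cand) < 2L) next
      L <- length(raws[[i]])
      lcp_i <- vapply(cand, function(j) .lcp(raws[[i]], raws[[j]]), integer(1))
      lcs_i <- vapply(cand, function(j) .lcs(raws[[i]], raws[[j]]), integer(1))
      found <- FALSE
      for (ai in seq_along(cand)) {
        if (found) break
        if (lcp_i[ai] < 1L) next
        for (bi in seq_along(cand)) {
          if (bi == ai || lcs_i[bi] < 1L) next
          # a crossover k in 1..L-1 exists iff the prefix match on parent A
          # and suffix match on parent B together cover the query
          if (min(lcp_i[ai], L - 1L) + min(lcs_i[bi], L - 1L) >= L) {
            flagged <- c(flagged, sq$esv_id[i])
            parents <- rbind(parents, data.frame(
              esv_id = sq$esv_id[i],
              parent_a = sq$esv_id[cand[ai]],
              parent_b = sq$esv_id[cand[bi]], stringsAsFactors = FALSE))
            found <- TRUE
            break
          }
        }
      }
    }
  }
  list(flagged = flagged, parents = parents,
       esvs = .esv_subset(esvs, !(sq$esv_id %in% flagged)))
}

#' Remove putative numts by stop-codon screening
#'
#' Translates every ESV in the configured forward frame under the
#' invertebrate mitochondrial genetic code (translation table 5, in which
#' TAA/TAG are the only stops; AGA/AGG encode serine and TGA tryptophan) and
#' removes sequences containing a stop codon. Coding mitochondrial inserts
#' are stop-free, so in-frame stops indicate nuclear pseudogene copies.
#'
#' @param esvs an [esv_set].
#' @param frame_offset codon phase of the insert (from the [primer_set]).
#' @param all_frames when `TRUE`, an ESV is removed only if all three forward
#'   frames contain a stop (for use when the insert phase is unknown).
#' @return list with `esvs` (retained), `removed` (data frame `esv_id`,
#'   `reason` in `stop_codon`, `too_short_to_translate`).
#' @export
filter_numts <- function(esvs, frame_offset = 0, all_frames = FALSE) {
  code <- Biostrings::getGeneticCode("5")
  has_stop <- function(seq, off) {
    s <- substr(seq, off + 1L, nchar(seq))
    nc <- nchar(s) %/% 3L
    if (nc == 0L) return(NA)
    codons <- substring(s, 3L * (seq_len(nc) - 1L) + 1L, 3L * seq_len(nc))
    any(code[codons] == "*", na.rm = TRUE)
  }
  sq <- esvs$sequences
  verdict <- vapply(sq$sequence, function(s) {
    if (all_frames) {
      st <- vapply(0:2, function(o) has_stop(s, o), logical(1))
      if (all(is.na(st))) return("too_short_to_translate")
      if (all(st, na.rm = TRUE) && !anyNA(st)) "stop_codon" else "ok"
    } else {
      st <- has_stop(s, frame_offset)
      if (is.na(st)) "too_short_to_translate"
      else if (st) "stop_codon" else "ok"
    }
  }, character(1), USE.NAMES = FALSE)
  removed <- data.frame(esv_id = sq$esv_id[verdict != "ok"],
                        reason = verdict[verdict != "ok"],
                        stringsAsFactors = FALSE)
  list(esvs = .esv_subset(esvs, verdict == "ok"), removed = removed)
}

#' Map reads onto the final ESV set
#'
#' Each read is assigned to the ESV with the fewest differences (Levenshtein)
#' if at most `max_diffs`; ties break toward the more abundant ESV, then by
#' lexicographic sequence order. The per-sample abundance table is rebuilt
#' from the mapping; unmapped reads are counted.
#'
#' @param reads_by_sample named list of data frames with a `sequence` column
#'   (the quality-filtered reads).
#' @param esvs an [esv_set] (the final set after chimera/numt filtering).
#' @param max_diffs maximum differences between read and ESV.
#' @return list with `esvs` (the input set with abundances rebuilt from the
#'   mapping, ESVs that attract no read are kept at zero and dropped),
#'   `unmapped` (integer count), `assignments` (data frame `sequence`,
#'   `esv_id`, `NA` for unmapped).
#' @export
map_reads <- function(reads_by_sample, esvs, max_diffs = 1) {
  samples <- names(reads_by_sample)
  sq <- esvs$sequences
  useq <- sort(unique(unlist(lapply(reads_by_sample, `[[`, "sequence"),
                             use.names = FALSE)))
  target <- rep(NA_character_, length(useq))
  exact <- match(useq, sq$sequence)
  target[!is.na(exact)] <- sq$esv_id[exact[!is.na(exact)]]
  todo <- which(is.na(target))
  if (length(todo) && nrow(sq)) {
    dd <- utils::adist(useq[todo], sq$sequence)
    for (r in seq_along(todo)) {
      dmin <- min(dd[r, ])
      if (dmin <= max_diffs) {
        cand <- which(dd[r, ] == dmin)
        cand <- cand[order(-sq$total[cand], sq$sequence[cand])]
        target[todo[r]] <- sq$esv_id[cand[1]]
      }
    }
  }
  ab <- matrix(0L, nrow(sq), length(samples),
               dimnames = list(sq$esv_id, samples))
  unmapped <- 0L
  for (s in samples) {
    t_s <- target[match(reads_by_sample[[s]]$sequence, useq)]
    unmapped <- unmapped + sum(is.na(t_s))
    tab <- table(factor(t_s[!is.na(t_s)], levels = sq$esv_id))
    ab[, s] <- ab[, s] + as.integer(tab)
  }
  tot <- as.integer(rowSums(ab))
  keep <- tot > 0L
  sq_out <- sq[keep, , drop = FALSE]
  sq_out$total <- tot[keep]
  rownames(sq_out) <- NULL
  out <- esv_set(sq_out, ab[keep, , drop = FALSE])
  list(esvs = out, unmapped = unmapped,
       assignments = data.frame(sequence = useq, esv_id = target,
                                stringsAsFactors = FALSE))
}

#' Process paired FASTQ reads into ESVs
#'
#' Runs the full per-sample chain (merge, trim, quality-filter), pools and
#' dereplicates across samples, denoises, removes chimeras and numts, and
#' re-maps the filtered reads onto the final ESVs. Every stage appends a row
#' to the funnel log, whose in/out counts are conserved
#' (`n_in = n_out + rejected`).
#'
#' @param r1_by_sample,r2_by_sample named lists (same names = sample ids) of
#'   data frames with columns `read_id`, `sequence`, `quality`.
#' @param primers a [primer_set].
#' @param config a [pipeline_config()].
#' @return list with `esvs` (final [esv_set] with mapped abundances),
#'   `stage_log` (data frame `stage`, `n_in`, `n_out`, `detail`),
#'   `filtered_reads` (per-sample data frames entering dereplication),
#'   `denoised` (the [esv_set] before chimera/numt removal), `chimeras`,
#'   `numts`, `mapping` (stage outputs).
#' @export
process_reads <- function(r1_by_sample, r2_by_sample, primers,
                          config = pipeline_config()) {
  stopifnot(identical(names(r1_by_sample), names(r2_by_sample)))
  samples <- names(r1_by_sample)
  log <- list()
  add_log <- function(stage, n_in, n_out, detail = "") {
    log[[length(log) + 1L]] <<- data.frame(stage = stage, n_in = n_in,
                                           n_out = n_out, detail = detail,
                                           stringsAsFactors = FALSE)
  }
  filtered <- stats::setNames(vector("list", length(samples)), samples)
  n_in_total <- 0L; n_merged <- 0L; n_trimmed <- 0L; n_filtered <- 0L
  reasons_merge <- c(); reasons_trim <- c(); reasons_filter <- c()
  for (s in samples) {
    r1 <- r1_by_sample[[s]]; r2 <- r2_by_sample[[s]]
    stopifnot(nrow(r1) == nrow(r2))
    n_in_total <- n_in_total + nrow(r1)
    keep_seq <- character(0); keep_qual <- character(0)
    keep_id <- character(0)
    for (i in seq_len(nrow(r1))) {
      m <- merge_pairs(r1$sequence[i], r1$quality[i],
                       r2$sequence[i], r2$quality[i],
                       config$min_overlap, config$max_diffs)
      if (m$status != "ok") {
        reasons_merge <- c(reasons_merge, m$status); next
      }
      n_merged <- n_merged + 1L
      tr <- trim_primers(m$sequence, m$quality, primers, config$error_rate)
      if (tr$status != "ok") {
        reasons_trim <- c(reasons_trim, tr$status); next
      }
      n_trimmed <- n_trimmed + 1L
      qf <- quality_filter(tr$sequence, tr$quality,
                           primers$expected_insert_len,
                           config$length_tolerance, config$max_ee,
                           config$min_mean_q)
      if (!qf$keep) {
        reasons_filter <- c(reasons_filter, qf$reason); next
      }
      n_filtered <- n_filtered + 1L
      keep_id <- c(keep_id, r1$read_id[i])
      keep_seq <- c(keep_seq, tr$sequence)
      keep_qual <- c(keep_qual, tr$quality)
    }
    filtered[[s]] <- data.frame(read_id = keep_id, sequence = keep_seq,
                                quality = keep_qual, stringsAsFactors = FALSE)
  }
  fmt <- function(x) paste(sprintf("%s=%d", names(table(x)), table(x)),
                           collapse = ";")
  add_log("merge", n_in_total, n_merged, fmt(reasons_merge))
  add_log("trim_primers", n_merged, n_trimmed, fmt(reasons_trim))
  add_log("quality_filter", n_trimmed, n_filtered, fmt(reasons_filter))

  uniq <- dereplicate(filtered)
  add_log("dereplicate", n_filtered, length(uniq$sequences), "")
  den <- denoise_d1(uniq, fastidious = config$fastidious,
                    boundary = config$boundary)
  add_log("denoise_d1", length(uniq$sequences), nrow(den$esvs$sequences), "")
  chi <- detect_chimeras(den$esvs, config$abundance_skew)
  add_log("detect_chimeras", nrow(den$esvs$sequences),
          nrow(chi$esvs$sequences),
          fmt(rep("chimera", length(chi$flagged))))
  num <- filter_numts(chi$esvs, primers$reading_frame_offset)
  add_log("filter_numts", nrow(chi$esvs$sequences),
          nrow(num$esvs$sequences), fmt(num$removed$reason))
  mapped <- map_reads(filtered, num$esvs, config$map_max_diffs)
  add_log("map_reads", n_filtered, sum(mapped$esvs$abundance),
          sprintf("unmapped=%d", mapped$unmapped))
  list(esvs = mapped$esvs, stage_log = do.call(rbind, log),
       filtered_reads = filtered, denoised = den$esvs, chimeras = chi,
       numts = num, mapping = mapped)
}
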