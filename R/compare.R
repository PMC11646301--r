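# Assemblage comparison: translate assignments to chitinous-remain
# morphotypes, build presence-absence incidence matrices, run detrended
# correspondence analysis, and compute sharing/proportion reports.

#' Translate taxon detections to chitinous-remain morphotypes
#'
#' Exact `(taxon, rank)` lookup in the crosswalk. A species without a
#' species-level row falls back to its genus row when present; taxa absent at
#' both ranks are dropped and listed (taxa without a described larva have no
#' morphotype). Detections are deduplicated per sample.
#'
#' @param detections data frame with columns `sample`, `taxon`, `rank`, and
#'   (for species-rank rows) `genus` used by the fallback.
#' @param crosswalk data frame with columns `taxon`, `rank`, `morphotype`;
#'   `(taxon, rank)` keys must be unique.
#' @return list with `detections` (data frame `sample`, `morphotype`,
#'   `matched_rank`, deduplicated) and `dropped` (character vector of taxa
#'   with no crosswalk entry).
#' @export
translate_morphotypes <- function(detections, crosswalk) {
  stopifnot(all(c("taxon", "rank", "morphotype") %in% names(crosswalk)),
            all(nzchar(crosswalk$morphotype)))
  key <- paste(crosswalk$taxon, crosswalk$rank, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (taxon, rank) keys in crosswalk")
  lookup <- stats::setNames(crosswalk$morphotype, key)
  out <- list(); dropped <- character(0)
  for (i in seq_len(nrow(detections))) {
    taxon <- detections$taxon[i]; rank <- detections$rank[i]
    k <- paste(taxon, rank, sep = "\r")
    morpho <- lookup[k]; matched <- rank
    if (is.na(morpho) && identical(rank, "species")) {
      genus <- detections$genus[i]
      if (is.null(genus) || is.na(genus))
        genus <- strsplit(taxon, " ", fixed = TRUE)[[1]][1]
      morpho <- lookup[paste(genus, "genus", sep = "\r")]
      matched <- "genus"
    }
    if (is.na(morpho)) {
      dropped <- c(dropped, taxon)
    } else {
      out[[length(out) + 1L]] <- data.frame(
        sample = detections$sample[i], morphotype = unname(morpho),
        matched_rank = matched, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(sample = character(0), morphotype = character(0),
               matched_rank = character(0))
  rownames(res) <- NULL
  list(detections = res, dropped = sort(unique(dropped)))
}

#' Build a presence-absence incidence matrix
#'
#' Entry = 1 iff the count (or read abundance) is positive; all-zero taxon
#' columns are removed. Counts and read abundances from different methods are
#' made comparable by this transform.
#'
#' @param x either a numeric matrix (samples x taxa) of non-negative counts,
#'   or a long data frame with columns `sample`, `taxon` (or `morphotype`)
#'   and optionally `count` (absent = 1).
#' @return binary integer matrix, samples x taxa.
#' @export
build_incidence <- function(x) {
  if (is.data.frame(x)) {
    taxcol <- if ("taxon" %in% names(x)) "taxon" else "morphotype"
    cnt <- if ("count" %in% names(x)) x$count else rep(1, nrow(x))
    samples <- sort(unique(x$sample)); taxa <- sort(unique(x[[taxcol]]))
    m <- matrix(0, length(samples), length(taxa),
                dimnames = list(samples, taxa))
    for (i in seq_len(nrow(x)))
      m[x$sample[i], x[[taxcol]][i]] <- m[x$sample[i], x[[taxcol]][i]] + cnt[i]
    x <- m
  }
  if (any(x < 0)) stop("negative counts")
  out <- matrix(as.integer(x > 0), nrow(x), ncol(x), dimnames = dimnames(x))
  out[, colSums(out) > 0, drop = FALSE]
}

#' Detrended correspondence analysis of an incidence matrix
#'
#' Correspondence analysis by reciprocal averaging with Hill's detrending by
#' segments and nonlinear rescaling to standard-deviation (species-turnover)
#' units, optionally downweighting taxa rarer than a fifth of the most
#' frequent taxon in proportion to their frequency. Computed by
#' `vegan::decorana`; with `detrend = FALSE` the result is plain orthogonal
#' correspondence analysis and the eigenvalues are the CA principal inertias.
#'
#' @param incidence binary matrix (samples x taxa), at least 3 samples and 3
#'   taxa, no empty rows.
#' @param downweight_rare apply Hill's rare-taxon downweighting (`iweigh =
#'   1`).
#' @param segments number of detrending segments.
#' @param rescale apply nonlinear rescaling to SD units.
#' @param detrend detrend axes 2-4 (`FALSE` gives orthogonal CA).
#' @return object of class `dca_result`: `sample_scores`, `taxon_scores` (4
#'   axes each), `eigenvalues`, `axis_lengths` (sample-score ranges, SD units
#'   when rescaled), `call_args`.
#' @export
dca <- function(incidence, downweight_rare = TRUE, segments = 26,
                rescale = TRUE, detrend = TRUE) {
  if (nrow(incidence) < 3L || ncol(incidence) < 3L)
    stop("need at least 3 samples and 3 taxa")
  empty <- rownames(incidence)[rowSums(incidence) == 0]
  if (length(empty))
    stop("empty sample row(s): ", paste(empty, collapse = ", "))
  ord <- vegan::decorana(incidence,
                         iweigh = as.integer(downweight_rare),
                         iresc = if (rescale) 4L else 0L,
                         ira = if (detrend) 0L else 1L,
                         mk = as.integer(segments))
  ss <- vegan::scores(ord, display = "sites", choices = 1:4)
  ts <- vegan::scores(ord, display = "species", choices = 1:4)
  structure(list(
    sample_scores = ss, taxon_scores = ts,
    eigenvalues = unname(ord$evals),
    axis_lengths = apply(ss, 2, function(v) diff(range(v))),
    call_args = list(downweight_rare = downweight_rare, segments = segments,
                     rescale = rescale, detrend = detrend)),
    class = "dca_result")
}

#' @export
print.dca_result <- function(x, ...) {
  cat("<dca_result>\n  eigenvalues:",
      paste(signif(x$eigenvalues, 4), collapse = ", "),
      "\n  axis lengths:",
      paste(signif(x$axis_lengths, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Plot sample scores of a DCA
#'
#' Minimal first-two-axes scores plot.
#'
#' @param x a `dca_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dca_result <- function(x, ...) {
  s <- x$sample_scores
  graphics::plot(s[, 1], s[, 2], xlab = "DCA1", ylab = "DCA2",
                 type = "n", ...)
  graphics::text(s[, 1], s[, 2], labels = rownames(s), cex = 0.8)
  invisible(x)
}

#' Venn region counts of 2 or 3 labelled taxon sets
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return named integer vector of exact region cardinalities; region names
#'   join set labels with `&` (e.g. `"CH"`, `"CH&CHIT"`).
#' @export
venn_counts <- function(sets) {
  if (length(sets) < 2L || length(sets) > 3L)
    stop("need 2 or 3 sets")
  labels <- names(sets)
  if (is.null(labels) || any(!nzchar(labels))) stop("sets must be named")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, ncol = length(sets),
                   dimnames = list(universe, labels))
  pattern <- apply(member, 1, function(r)
    paste(labels[r], collapse = "&"))
  regions <- unlist(lapply(seq_along(labels), function(k)
    utils::combn(labels, k, paste, collapse = "&", simplify = FALSE)),
    use.names = FALSE)
  counts <- stats::setNames(integer(length(regions)), regions)
  tab <- table(pattern)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Report ESVs detected in field-negative controls
#'
#' Lists every control ESV with its read count and database match (or
#' `no_match`), flagging control taxa that also appear in real samples —
#' candidate contamination.
#'
#' @param esvs an [esv_set] containing control and sediment samples.
#' @param assignments data frame from [assign_all()].
#' @param control_samples character vector of control sample ids (columns of
#'   the abundance matrix).
#' @return data frame `esv_id`, `reads_in_controls`, `match` (deepest
#'   assigned taxon or `"no_match"`), `in_real_samples` (logical); zero rows
#'   when controls are clean.
#' @export
control_report <- function(esvs, assignments, control_samples) {
  ab <- esvs$abundance
  miss <- setdiff(control_samples, colnames(ab))
  if (length(miss))
    stop("unknown control samples: ", paste(miss, collapse = ", "))
  ctrl <- ab[, control_samples, drop = FALSE]
  real <- ab[, setdiff(colnames(ab), control_samples), drop = FALSE]
  hit <- which(rowSums(ctrl) > 0)
  if (!length(hit))
    return(data.frame(esv_id = character(0), reads_in_controls = integer(0),
                      match = character(0), in_real_samples = logical(0)))
  ids <- rownames(ab)[hit]
  arow <- assignments[match(ids, assignments$esv_id), , drop = FALSE]
  deepest <- vapply(seq_len(nrow(arow)), function(i) {
    r <- arow$rank[i]
    if (is.na(r) || !isTRUE(arow$assigned[i])) "no_match" else
      as.character(arow[[r]][i])
  }, character(1))
  data.frame(esv_id = ids,
             reads_in_controls = as.integer(rowSums(ctrl)[hit]),
             match = deepest,
             in_real_samples = rowSums(real)[hit] > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}
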