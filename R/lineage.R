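# Ranked-lineage model: a fixed list of seven Linnaean ranks, sanitisation of
# uncertain taxon names, and lowest-common-ancestor computation.

#' The fixed rank list
#'
#' Seven Linnaean ranks, highest first. Every lineage in the package is a
#' named character vector over exactly these ranks; `NA` marks an absent rank
#' and ranks below the deepest present rank are always absent (no internal
#' gaps).
#'
#' @export
TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family",
               "genus", "species")

#' Default uncertainty markers
#'
#' Tokens indicating unreliable taxon names ("sp.", "aff.", "gr.", "var.").
#' @export
UNCERTAINTY_MARKERS <- c("sp.", "aff.", "gr.", "var.")

# normalise whitespace for deterministic name comparison
.norm_name <- function(x) {
  x <- trimws(gsub("[[:space:]]+", " ", x))
  x[!nzchar(x)] <- NA_character_
  x
}

#' Construct a lineage
#'
#' @param ... rank values given by name, e.g. `lineage(kingdom = "Animalia",
#'   ..., genus = "Tanytarsus", species = "Tanytarsus lugens")`. Missing or
#'   `NA` entries mark absent ranks.
#' @return named character vector over [TAX_RANKS].
#' @details The constructor enforces the gap-free invariant: a present rank
#'   requires all higher ranks to be present. If both genus and species are
#'   present, the species must be a binomial whose first token equals the
#'   genus (violations raise a warning, since curated inputs occasionally
#'   break this and are repaired downstream by sanitisation).
#' @export
lineage <- function(...) {
  vals <- list(...)
  bad <- setdiff(names(vals), TAX_RANKS)
  if (length(bad)) stop("unknown ranks: ", paste(bad, collapse = ", "))
  out <- stats::setNames(rep(NA_character_, length(TAX_RANKS)), TAX_RANKS)
  out[names(vals)] <- .norm_name(unlist(vals, use.names = FALSE))
  validate_lineage(out)
  out
}

#' Validate the lineage invariants
#'
#' @param x named character vector over [TAX_RANKS].
#' @return `x`, invisibly; errors on internal rank gaps.
#' @export
validate_lineage <- function(x) {
  if (!identical(names(x), TAX_RANKS))
    stop("lineage must be a character vector named by the seven ranks")
  present <- !is.na(x)
  if (any(present)) {
    deepest <- max(which(present))
    if (!all(present[seq_len(deepest)]))
      stop("lineage has an internal gap: a present rank requires all ",
           "higher ranks to be present")
  }
  if (!is.na(x["species"]) && !is.na(x["genus"])) {
    first_tok <- strsplit(x["species"], " ", fixed = TRUE)[[1]][1]
    if (!identical(unname(first_tok), unname(x["genus"])))
      warning("species '", x["species"], "' does not start with genus '",
              x["genus"], "'")
  }
  invisible(x)
}

#' Deepest present rank of a lineage
#'
#' @param x a lineage.
#' @return rank name, or `NA_character_` for an empty lineage.
#' @export
assignment_rank <- function(x) {
  present <- which(!is.na(x[TAX_RANKS]))
  if (!length(present)) NA_character_ else TAX_RANKS[max(present)]
}

# does a taxon name contain an uncertainty marker? Token-wise,
# case-insensitive, whole-token equality after stripping trailing punctuation
.has_marker <- function(name, markers) {
  if (is.na(name)) return(FALSE)
  toks <- tolower(strsplit(name, "[[:space:]]+")[[1]])
  toks <- sub("[.,;:]+$", "", toks)
  mks <- sub("[.,;:]+$", "", tolower(markers))
  any(toks %in% mks)
}

#' Remove uncertain taxon names from a lineage
#'
#' Names carrying uncertainty wording (e.g. "sp.", "aff.", "gr.", "var.") are
#' untrustworthy; the lineage is truncated to the last marker-free rank. For
#' example a species entry "Cladotanytarsus gr. mancus" is dropped and the
#' lineage retained down to genus "Cladotanytarsus". Matching is token-wise
#' and case-insensitive, requiring whole-token equality (so "sp." never
#' matches "spinosa").
#'
#' @param x a lineage.
#' @param markers character vector of marker tokens; defaults to
#'   [UNCERTAINTY_MARKERS].
#' @return the truncated lineage; idempotent.
#' @export
sanitize_lineage <- function(x, markers = UNCERTAINTY_MARKERS) {
  validate_lineage(x)
  marked <- vapply(x, .has_marker, logical(1), markers = markers)
  if (any(marked)) {
    cut <- min(which(marked))
    x[cut:length(TAX_RANKS)] <- NA_character_
  }
  x
}

#' Lowest common ancestor of a set of lineages
#'
#' The deepest rank-prefix on which all lineages agree exactly (string
#' equality per rank after whitespace normalisation); the empty lineage if
#' they already disagree at the top rank. Used to resolve tied best hits with
#' differing annotations, and to merge dereplicated reference records.
#'
#' @param lineages a non-empty list of lineages, or a data frame with columns
#'   [TAX_RANKS] (one row per lineage).
#' @return a single lineage.
#' @export
lca <- function(lineages) {
  if (is.data.frame(lineages)) {
    lineages <- lapply(seq_len(nrow(lineages)), function(i) {
      v <- stats::setNames(rep(NA_character_, 7L), TAX_RANKS)
      for (r in intersect(TAX_RANKS, names(lineages)))
        v[r] <- as.character(lineages[[r]][i])
      v
    })
  }
  if (!length(lineages)) stop("no lineages to combine (empty hit set)")
  mat <- do.call(rbind, lapply(lineages, function(l) .norm_name(l[TAX_RANKS])))
  out <- stats::setNames(rep(NA_character_, length(TAX_RANKS)), TAX_RANKS)
  for (j in seq_along(TAX_RANKS)) {
    col <- mat[, j]
    if (anyNA(col) || length(unique(col)) != 1L) break
    out[j] <- col[1]
  }
  out
}

#' Read a lineage table
#'
#' Tab-separated, UTF-8, header required, columns `seq_id` plus the seven
#' ranks; empty cells mark absent ranks.
#'
#' @param path file path.
#' @return data frame with columns `seq_id` and [TAX_RANKS] (`NA` = absent).
#' @export
read_lineage_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          na.strings = c("", "NA"), fileEncoding = "UTF-8")
  need <- c("seq_id", TAX_RANKS)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("lineage TSV missing columns: ", paste(miss, collapse = ", "))
  df[need]
}

#' Write a lineage table
#'
#' @param df data frame with columns `seq_id` and [TAX_RANKS].
#' @param path file path.
#' @export
write_lineage_tsv <- function(df, path) {
  out <- df[c("seq_id", TAX_RANKS)]
  out[is.na(out)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# one row of a rank data frame -> lineage vector
.row_lineage <- function(df, i) {
  v <- stats::setNames(rep(NA_character_, 7L), TAX_RANKS)
  for (r in TAX_RANKS) if (r %in% names(df)) v[r] <- as.character(df[[r]][i])
  v
}

# list of lineages -> rank data frame
.lineage_df <- function(lineages, seq_id = NULL) {
  mat <- do.call(rbind, lapply(lineages, function(l) l[TAX_RANKS]))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- TAX_RANKS
  if (!is.null(seq_id)) df <- cbind(seq_id = seq_id, df)
  rownames(df) <- NULL
  df
}
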