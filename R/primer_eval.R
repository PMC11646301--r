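# Amplicon taxonomic-resolution screen: pairwise percent distances among
# aligned reference inserts and the minimum interspecific distance.

#' Pairwise percent distances among aligned inserts
#'
#' Raw p-distance with pairwise deletion: for a pair, distance = 100 x
#' (differing sites) / (compared sites), where sites with a gap (`-`) or `N`
#' in either sequence are excluded. Pairs with zero comparable sites get `NA`
#' and are listed in the `undefined_pairs` attribute.
#'
#' @param aligned named character vector of aligned sequences (equal length,
#'   gaps as `-`).
#' @return symmetric numeric matrix in percent, zero diagonal, labelled by
#'   the input names; attribute `undefined_pairs` is a data frame of pairs
#'   with no comparable sites (zero rows when none).
#' @export
pairwise_pdistance <- function(aligned) {
  n <- length(aligned)
  if (n < 2L) stop("need at least 2 sequences")
  if (length(unique(nchar(aligned))) != 1L)
    stop("sequences must be aligned to equal length")
  labs <- names(aligned)
  if (is.null(labs)) labs <- paste0("seq", seq_len(n))
  m <- do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
  usable <- m != "-" & m != "N"
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  undef <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- usable[i, ] & usable[j, ]
    nc <- sum(comp)
    if (nc == 0L) {
      d[i, j] <- d[j, i] <- NA_real_
      undef[[length(undef) + 1L]] <- data.frame(a = labs[i], b = labs[j])
    } else {
      d[i, j] <- d[j, i] <- 100 * sum(m[i, comp] != m[j, comp]) / nc
    }
  }
  attr(d, "undefined_pairs") <- if (length(undef)) do.call(rbind, undef) else
    data.frame(a = character(0), b = character(0))
  d
}

#' Minimum interspecific distance of an amplicon
#'
#' The smallest pairwise distance between inserts of *different* species; a
#' primer set resolves its target group to species level when this minimum
#' stays above the resolution threshold (8% for the short Chironomidae CO1
#' fragment).
#'
#' @param dmat distance matrix from [pairwise_pdistance()].
#' @param species_of named character vector mapping every matrix label to a
#'   species name.
#' @param threshold resolution threshold in percent; interspecific pairs
#'   below it are flagged.
#' @return list with `min_distance` (percent), `pairs` (data frame `a`, `b`,
#'   `species_a`, `species_b`, `distance`, `below_threshold` for all
#'   interspecific pairs), and `threshold`.
#' @export
min_interspecific_distance <- function(dmat, species_of, threshold = 8) {
  labs <- rownames(dmat)
  miss <- setdiff(labs, names(species_of))
  if (length(miss))
    stop("labels without species mapping: ", paste(miss, collapse = ", "))
  sp <- species_of[labs]
  idx <- which(upper.tri(dmat), arr.ind = TRUE)
  inter <- idx[sp[idx[, 1]] != sp[idx[, 2]], , drop = FALSE]
  if (nrow(inter) == 0L)
    stop("no interspecific pair: all labels map to one species")
  pairs <- data.frame(
    a = labs[inter[, 1]], b = labs[inter[, 2]],
    species_a = unname(sp[inter[, 1]]), species_b = unname(sp[inter[, 2]]),
    distance = dmat[inter], stringsAsFactors = FALSE)
  pairs$below_threshold <- !is.na(pairs$distance) & pairs$distance < threshold
  list(min_distance = min(pairs$distance, na.rm = TRUE), pairs = pairs,
       threshold = threshold)
}
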