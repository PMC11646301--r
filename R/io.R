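# Readers and writers for FASTA, FASTQ (Phred+33) and TSV, including the
# `;size=N` FASTA header dialect used for abundance-annotated ESVs.

#' Read a FASTA file
#'
#' @param path file path.
#' @return data frame with columns `id` (full header line minus `>`),
#'   `sequence` (uppercased), and `size` (abundance parsed from a trailing
#'   `;size=N` header annotation, `NA` when absent).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  data.frame(id = sub(";size=\\d+;?$", "", ids),
             sequence = toupper(as.character(set)),
             size = parse_size_annotation(ids),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Parse `;size=N` abundance annotations from FASTA headers
#'
#' @param ids character vector of header strings.
#' @return integer vector, `NA` where no annotation is present.
#' @export
parse_size_annotation <- function(ids) {
  out <- rep(NA_integer_, length(ids))
  has <- grepl(";size=\\d+", ids)
  out[has] <- as.integer(sub(".*;size=(\\d+).*", "\\1", ids[has]))
  out
}

#' Write a FASTA file
#'
#' @param df data frame with columns `id`, `sequence`, and optionally `size`
#'   (non-`NA` sizes are emitted as `;size=N` header annotations).
#' @param path file path.
#' @export
write_fasta <- function(df, path) {
  ids <- df$id
  if (!is.null(df$size)) {
    has <- !is.na(df$size)
    ids[has] <- paste0(ids[has], ";size=", df$size[has])
  }
  set <- Biostrings::BStringSet(stats::setNames(df$sequence, ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' Plain four-line-record reader with per-record validation: malformed
#' records are reported with their line number and record id.
#'
#' @param path file path.
#' @return data frame with columns `read_id`, `sequence` (uppercased),
#'   `quality` (Phred+33 string).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L)
    return(data.frame(read_id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  if (n %% 4L != 0L) {
    last_id <- lines[4L * (n %/% 4L) + 1L]
    stop("truncated FASTQ record at line ", 4L * (n %/% 4L) + 1L,
         " (record '", sub("^@", "", last_id), "')")
  }
  idx <- seq(1L, n, by = 4L)
  heads <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  quals <- lines[idx + 3L]
  bad <- which(!startsWith(heads, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ record at line ", idx[bad[1]],
         ": expected '@'/'+' markers")
  ids <- sub("^@", "", heads)
  mismatch <- which(nchar(seqs) != nchar(quals))
  if (length(mismatch))
    stop("sequence/quality length mismatch at line ", idx[mismatch[1]],
         " (record '", ids[mismatch[1]], "')")
  data.frame(read_id = ids, sequence = toupper(seqs), quality = quals,
             stringsAsFactors = FALSE)
}

#' Write a FASTQ file (Phred+33)
#'
#' @param df data frame with columns `read_id`, `sequence`, `quality`.
#' @param path file path.
#' @export
write_fastq <- function(df, path) {
  stopifnot(all(nchar(df$sequence) == nchar(df$quality)))
  lines <- as.vector(rbind(paste0("@", df$read_id), df$sequence,
                           "+", df$quality))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write tab-separated tables
#'
#' Thin wrappers fixing the package's TSV conventions (header, UTF-8, no
#' quoting, empty cell = `NA`).
#'
#' @param path file path.
#' @param df data frame.
#' @return `read_tsv` returns a data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, na.strings = c("", "NA"), fileEncoding = "UTF-8",
                    stringsAsFactors = FALSE)
}

#' @rdname read_tsv
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
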