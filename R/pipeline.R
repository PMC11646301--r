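# Pipeline configuration (all stage thresholds with their standard defaults)
# and the end-to-end orchestrator.

#' Pipeline configuration
#'
#' Collects every threshold of the processing chain with its default:
#' merging (minimum overlap 50 bases, at most 10 differences), primer
#' trimming (10% error rate), quality filtering (length tolerance +/- 10 bp,
#' expected errors < 1, mean Phred >= 30), denoising (d = 1, fastidious with
#' boundary 3), chimera removal (abundance skew 16), read mapping (1
#' difference), reference curation (minimum length 200 bp, 1 primer mismatch,
#' +/- 10 bp amplicon window), assignment (minimum identity 90%, species
#' threshold 95%, at most 5000 hits), and ordination (26 segments, rare-taxon
#' downweighting on). Unknown arguments are rejected.
#'
#' @param min_overlap,max_diffs read-merging thresholds.
#' @param error_rate primer-trimming mismatch fraction.
#' @param length_tolerance,max_ee,min_mean_q quality-filter thresholds.
#' @param fastidious,boundary denoising options (`d` is fixed at 1).
#' @param abundance_skew chimera parent/query abundance ratio.
#' @param map_max_diffs read-to-ESV mapping budget.
#' @param min_length,max_mismatch,pcr_length_tolerance reference curation and
#'   in-silico PCR thresholds.
#' @param min_identity,species_threshold,max_hits assignment thresholds.
#' @param dca_segments,downweight_rare ordination options.
#' @param seed integer seed for any stage needing randomness (the processing
#'   stages themselves are deterministic).
#' @return object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(min_overlap = 50, max_diffs = 10,
                            error_rate = 0.1,
                            length_tolerance = 10, max_ee = 1.0,
                            min_mean_q = 30,
                            fastidious = TRUE, boundary = 3,
                            abundance_skew = 16,
                            map_max_diffs = 1,
                            min_length = 200, max_mismatch = 1,
                            pcr_length_tolerance = 10,
                            min_identity = 90, species_threshold = 95,
                            max_hits = 5000,
                            dca_segments = 26, downweight_rare = TRUE,
                            seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$min_overlap >= 1, cfg$max_diffs >= 0,
            cfg$error_rate >= 0, cfg$error_rate <= 1,
            cfg$length_tolerance >= 0, cfg$max_ee > 0,
            cfg$min_mean_q >= 0, cfg$min_mean_q <= 93,
            cfg$boundary >= 1, cfg$abundance_skew >= 1,
            cfg$map_max_diffs >= 0, cfg$min_length >= 1,
            cfg$max_mismatch >= 0, cfg$pcr_length_tolerance >= 0,
            cfg$min_identity >= 0, cfg$min_identity <= 100,
            cfg$species_threshold >= 0, cfg$species_threshold <= 100,
            cfg$max_hits >= 1, cfg$dca_segments >= 10)
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline on paired reads
#'
#' Builds the curated amplicon database, processes the reads into final ESVs,
#' assigns lineages, and (when a crosswalk is supplied) translates detections
#' to morphotypes with an incidence matrix ready for ordination. The stage
#' log records record counts in and out of every step.
#'
#' @param r1_by_sample,r2_by_sample named lists of read data frames
#'   (`read_id`, `sequence`, `quality`).
#' @param references data frame `seq_id`, `sequence` (raw reference set).
#' @param lineages lineage data frame for the references.
#' @param primers a [primer_set].
#' @param crosswalk optional morphotype crosswalk data frame (`taxon`,
#'   `rank`, `morphotype`).
#' @param control_samples optional character vector of field-control sample
#'   ids.
#' @param config a [pipeline_config()].
#' @return object of class `sedchiron_run`: `refdb`, `processing` (from
#'   [process_reads()]), `esvs`, `assignments`, `detections`, `morphotypes`,
#'   `incidence`, `controls`, `stage_log`.
#' @export
run_pipeline <- function(r1_by_sample, r2_by_sample, references, lineages,
                         primers, crosswalk = NULL, control_samples = NULL,
                         config = pipeline_config()) {
  db <- build_refdb(references, lineages, primers,
                    min_length = config$min_length,
                    max_mismatch = config$max_mismatch,
                    length_tolerance = config$pcr_length_tolerance)
  if (nrow(db$amplicons) == 0L)
    stop("reference database empty after curation and in-silico PCR")
  proc <- process_reads(r1_by_sample, r2_by_sample, primers, config)
  assignments <- assign_all(proc$esvs, db,
                            min_identity = config$min_identity,
                            max_hits = config$max_hits,
                            species_threshold = config$species_threshold)
  detections <- .esv_detections(proc$esvs, assignments,
                                exclude = control_samples)
  morphotypes <- NULL; incidence <- NULL
  if (!is.null(crosswalk) && nrow(detections)) {
    morphotypes <- translate_morphotypes(detections, crosswalk)
    if (nrow(morphotypes$detections))
      incidence <- build_incidence(morphotypes$detections)
  }
  controls <- NULL
  if (length(control_samples))
    controls <- control_report(proc$esvs, assignments, control_samples)
  structure(list(refdb = db, processing = proc, esvs = proc$esvs,
                 assignments = assignments, detections = detections,
                 morphotypes = morphotypes, incidence = incidence,
                 controls = controls, stage_log = proc$stage_log,
                 config = config),
            class = "sedchiron_run")
}

# per-sample taxon detections (deepest assigned rank) from an esv_set and
# its assignments; unassigned ESVs are excluded
.esv_detections <- function(esvs, assignments, exclude = NULL) {
  ab <- esvs$abundance
  keep_samples <- setdiff(colnames(ab), exclude)
  rows <- list()
  for (i in seq_len(nrow(assignments))) {
    if (!isTRUE(assignments$assigned[i]) || is.na(assignments$rank[i])) next
    esv <- assignments$esv_id[i]
    present <- keep_samples[ab[esv, keep_samples] > 0]
    if (!length(present)) next
    rows[[length(rows) + 1L]] <- data.frame(
      sample = present,
      taxon = as.character(assignments[[assignments$rank[i]]][i]),
      rank = assignments$rank[i],
      genus = as.character(assignments$genus[i]),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(sample = character(0), taxon = character(0),
               rank = character(0), genus = character(0))
  rownames(out) <- NULL
  out
}

#' @export
print.sedchiron_run <- function(x, ...) {
  cat("<sedchiron_run>\n")
  log <- x$stage_log
  for (i in seq_len(nrow(log)))
    cat(sprintf("  %-16s %6d -> %6d  %s\n", log$stage[i], log$n_in[i],
                log$n_out[i], log$detail[i]))
  n_ass <- sum(x$assignments$assigned)
  cat(sprintf("  ESVs: %d, identified: %d (%s%%)\n",
              nrow(x$esvs$sequences), n_ass,
              format(proportion(n_ass, max(1, nrow(x$esvs$sequences))))))
  invisible(x)
}
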