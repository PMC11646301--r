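# Synthetic-data generator: reference sequences with a guaranteed
# interspecific divergence floor, core/layer assemblages with controllable
# taxon sharing, and paired amplicon reads carrying primer sites,
# quality-driven substitution errors, chimeras, numts and contaminants.

#' Simulation configuration
#'
#' Encodes the study design the generator emulates: three sediment cores with
#' three layers each, two shallow cores sharing most of their taxon pool and
#' a deep core sharing little, short CO1 amplicons whose species inserts
#' diverge by at least 8%, and the artefact classes the read-processing chain
#' must remove (chimeras, stop-codon numts, database-absent contaminants).
#'
#' @param seed integer seed; all randomness derives from it.
#' @param n_species,n_genera,n_families reference-pool sizes (nested).
#' @param insert_len insert length in bp.
#' @param min_interspecific_divergence minimum pairwise insert divergence
#'   between distinct species, as a fraction.
#' @param n_cores,n_layers sampling layout (cores x layers).
#' @param core_pool_size species per core pool.
#' @param shared_fraction_pair target Jaccard similarity of the two
#'   similar (shallow) cores' pools.
#' @param shared_fraction_outgroup target Jaccard similarity between the
#'   distinct (deep) core and each similar core.
#' @param layer_presence_prob probability a core-pool taxon occurs in a given
#'   layer.
#' @param abundance_meanlog,abundance_sdlog log-normal abundance model for
#'   present taxa.
#' @param reads_per_sample read pairs emitted per sample.
#' @param base_quality,dip_quality,dip_rate quality profile: constant Phred
#'   `base_quality` with a fraction `dip_rate` of positions dipping to
#'   `dip_quality`; substitution probability is `10^(-Q/10)`.
#' @param chimera_rate,numt_rate,contaminant_rate per-read artefact rates.
#' @param n_control_reads contaminant-only reads per field-control sample.
#' @param read_len read length of each mate.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_species = 15L, n_genera = 6L, n_families = 2L,
                              insert_len = 139L,
                              min_interspecific_divergence = 0.08,
                              n_cores = 3L, n_layers = 3L,
                              core_pool_size = 9L,
                              shared_fraction_pair = 0.8,
                              shared_fraction_outgroup = 0.3,
                              layer_presence_prob = 0.85,
                              abundance_meanlog = 3, abundance_sdlog = 1,
                              reads_per_sample = 400L,
                              base_quality = 35L, dip_quality = 15L,
                              dip_rate = 0.01,
                              chimera_rate = 0.02, numt_rate = 0.02,
                              contaminant_rate = 0.03,
                              n_control_reads = 15L,
                              read_len = 150L) {
  cfg <- as.list(environment())
  rates <- c(cfg$chimera_rate, cfg$numt_rate, cfg$contaminant_rate,
             cfg$dip_rate, cfg$layer_presence_prob,
             cfg$shared_fraction_pair, cfg$shared_fraction_outgroup)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (!(n_species >= n_genera && n_genera >= n_families && n_families >= 1))
    stop("need n_species >= n_genera >= n_families >= 1")
  if (core_pool_size > n_species)
    stop("core_pool_size exceeds n_species")
  structure(cfg, class = "sim_config")
}

# validate that paired reads of read_len can overlap by >= min_overlap over
# an amplicon of the given length
.check_read_geometry <- function(config, primers, min_overlap = 50) {
  amp_len <- config$insert_len + primers$forward$length +
    primers$reverse$length
  if (2L * config$read_len - amp_len < min_overlap)
    stop("read_len ", config$read_len, " cannot give a ", min_overlap,
         " bp overlap over a ", amp_len, " bp amplicon")
  if (config$read_len > amp_len)
    stop("read_len exceeds amplicon length (staggered reads unsupported)")
  invisible(amp_len)
}

# random stop-free insert under translation table 5 in frame 0
.random_insert <- function(len) {
  code <- Biostrings::getGeneticCode("5")
  codons <- names(code)[code != "*"]
  n_codon <- len %/% 3L
  rest <- len - 3L * n_codon
  paste0(paste(sample(codons, n_codon, replace = TRUE), collapse = ""),
         paste(sample(c("A", "C", "G", "T"), rest, replace = TRUE),
               collapse = ""))
}

.hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

#' Simulate reference records with truth lineages
#'
#' Each species gets one insert; inserts of distinct species are
#' rejection-sampled until every pair differs at a number of sites at least
#' `ceil(min_interspecific_divergence x insert_len)`, so the resolution
#' premise of the primer screen holds by construction (and is re-checked by
#' tests, not assumed). Inserts are stop-free in frame 0 under the
#' invertebrate mitochondrial code. Full records are pad + concrete
#' forward-primer expansion + insert + revcomp(concrete reverse expansion) +
#' pad. Lineages nest species into genera and families under Diptera; the
#' first family is the target family (Chironomidae-like) and receives the
#' bulk of the genera.
#'
#' @param config a [simulation_config()].
#' @param primers a [primer_set].
#' @return list with `records` (`seq_id`, `sequence`), `lineages` (truth,
#'   `seq_id` + ranks), `inserts` (`species`, `insert`).
#' @export
simulate_references <- function(config, primers) {
  set.seed(.stage_seed(config$seed, "references"))
  n <- config$n_species
  need <- ceiling(config$min_interspecific_divergence * config$insert_len)
  if (need > config$insert_len)
    stop("divergence infeasible for insert length")
  inserts <- character(0)
  tries <- 0L
  while (length(inserts) < n) {
    cand <- .random_insert(config$insert_len)
    if (!length(inserts) ||
        min(vapply(inserts, .hamming, integer(1), b = cand)) >= need) {
      inserts <- c(inserts, cand)
    } else {
      tries <- tries + 1L
      if (tries > 1000L * n)
        stop("cannot satisfy divergence constraint for ", n, " species of ",
             config$insert_len, " bp")
    }
  }
  # nested taxonomy
  fam_names <- c("Chironomidae",
                 paste0("Simfamily", seq_len(max(0, config$n_families - 1L))))
  genus_names <- paste0("Genus", LETTERS[seq_len(config$n_genera)])
  # first family gets the majority of genera
  fam_of_genus <- fam_names[pmin(config$n_families,
                                 c(rep(1L, ceiling(config$n_genera / 2)),
                                   seq_len(config$n_genera))[
                                     seq_len(config$n_genera)])]
  genus_of_sp <- genus_names[(seq_len(n) - 1L) %% config$n_genera + 1L]
  species <- paste0(genus_of_sp, " taxon", seq_len(n))
  lineages <- lapply(seq_len(n), function(i)
    lineage(kingdom = "Animalia", phylum = "Arthropoda", class = "Insecta",
            order = "Diptera",
            family = fam_of_genus[match(genus_of_sp[i], genus_names)],
            genus = genus_of_sp[i], species = species[i]))
  pads <- function() paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                           collapse = "")
  records <- vapply(seq_len(n), function(i)
    paste0(pads(), expand_primer(primers$forward), inserts[i],
           revcomp(expand_primer(primers$reverse)), pads()), character(1))
  seq_ids <- sprintf("ref_%02d", seq_len(n))
  list(records = data.frame(seq_id = seq_ids, sequence = records,
                            stringsAsFactors = FALSE),
       lineages = .lineage_df(lineages, seq_id = seq_ids),
       inserts = data.frame(species = species, insert = inserts,
                            stringsAsFactors = FALSE))
}

#' Simulate core/layer assemblages with controlled taxon sharing
#'
#' Core pools are constructed so that cores 1 and 2 share a fraction
#' `shared_fraction_pair` of their taxa (Jaccard) while core 3 shares only
#' `shared_fraction_outgroup` with them — the two-similar-one-distinct
#' topology of shallow versus deep-lake sediment cores. Layers subsample the
#' core pool independently and abundances are log-normal.
#'
#' @param config a [simulation_config()].
#' @param species character vector: the species pool (from
#'   [simulate_references()]).
#' @return list with `assemblage` (data frame `sample`, `core`, `layer`,
#'   `species`, `abundance`) and `core_pools` (list of species vectors).
#' @export
simulate_assemblages <- function(config, species) {
  set.seed(.stage_seed(config$seed, "assemblages"))
  k <- config$core_pool_size
  n_shared <- function(j) round(j * 2 * k / (1 + j))
  if (config$n_cores != 3L)
    stop("the core-sharing design is defined for 3 cores")
  s12 <- n_shared(config$shared_fraction_pair)
  s3 <- n_shared(config$shared_fraction_outgroup)
  need <- s12 + 2L * (k - s12) + (k - s3)
  if (need > length(species))
    stop("shared fractions infeasible for the species pool (need ", need,
         " species, have ", length(species), ")")
  pool <- sample(species)
  shared12 <- pool[seq_len(s12)]
  p1 <- pool[s12 + seq_len(k - s12)]
  p2 <- pool[s12 + (k - s12) + seq_len(k - s12)]
  used <- s12 + 2L * (k - s12)
  core1 <- c(shared12, p1)
  core2 <- c(shared12, p2)
  from12 <- sample(c(shared12, p1, p2), s3)
  core3 <- c(from12, pool[used + seq_len(k - s3)])
  core_pools <- list(core1 = core1, core2 = core2, core3 = core3)
  rows <- list()
  layer_names <- c("top", "middle", "bottom", "layer4", "layer5")
  for (ci in seq_len(config$n_cores)) {
    for (li in seq_len(config$n_layers)) {
      present <- core_pools[[ci]][
        stats::runif(length(core_pools[[ci]])) <= config$layer_presence_prob]
      if (!length(present)) present <- sample(core_pools[[ci]], 1L)
      ab <- stats::rlnorm(length(present), config$abundance_meanlog,
                          config$abundance_sdlog)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sprintf("core%d_%s", ci, layer_names[li]),
        core = paste0("core", ci), layer = layer_names[li],
        species = present, abundance = ab, stringsAsFactors = FALSE)
    }
  }
  list(assemblage = do.call(rbind, rows), core_pools = core_pools)
}

# apply the quality profile: returns list(sequence, quality) with
# substitution errors drawn from the per-base error probability
.seq_with_errors <- function(seq, config) {
  L <- nchar(seq)
  q <- rep(config$base_quality, L)
  dips <- stats::runif(L) < config$dip_rate
  q[dips] <- config$dip_quality
  perr <- 10^(-q / 10)
  err <- stats::runif(L) < perr
  if (any(err)) {
    ch <- .chars(seq)
    for (i in which(err)) {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    }
    seq <- paste(ch, collapse = "")
  }
  list(sequence = seq, quality = intToUtf8(q + 33L))
}

# inject a premature stop codon (TAA) at a random in-frame codon of an
# insert
.inject_stop <- function(insert, frame_offset) {
  n_codon <- (nchar(insert) - frame_offset) %/% 3L
  cpos <- sample(seq_len(max(1L, n_codon - 1L)), 1L)
  at <- frame_offset + 3L * (cpos - 1L)
  paste0(substr(insert, 1L, at), "TAA",
         substr(insert, at + 4L, nchar(insert)))
}

# a contaminant insert far from every reference insert
.contaminant_insert <- function(len, ref_inserts) {
  repeat {
    cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = "")
    sim <- 1 - min(vapply(ref_inserts, .hamming, integer(1), b = cand)) / len
    if (sim < 0.7) return(cand)
  }
}

#' Simulate paired amplicon reads with truth tables
#'
#' For every sample, reads are allocated to present taxa proportionally to
#' abundance; each amplicon is the concrete forward-primer expansion + insert
#' + reverse complement of a reverse expansion. R1 is the first `read_len`
#' bases, R2 the reverse complement of the last `read_len` bases.
#' Substitution errors follow the quality profile. At the configured rates,
#' reads are replaced by two-parent chimeras (uniform breakpoint), numts
#' (premature in-frame stop injected), or database-absent contaminants. Field
#' controls (one per core, contaminant reads only) are appended when
#' `n_control_reads > 0`.
#'
#' @param assemblage output of [simulate_assemblages()]`$assemblage`.
#' @param references output of [simulate_references()].
#' @param config a [simulation_config()].
#' @param primers a [primer_set].
#' @return list with `r1`, `r2` (named lists of per-sample read data frames),
#'   `truth` (data frame `read_id`, `sample`, `origin` in
#'   clean/chimera/numt/contaminant, `species`), `control_samples`.
#' @export
simulate_reads <- function(assemblage, references, config, primers) {
  .check_read_geometry(config, primers)
  set.seed(.stage_seed(config$seed, "reads"))
  insert_of <- stats::setNames(references$inserts$insert,
                               references$inserts$species)
  samples <- unique(assemblage$sample)
  r1 <- r2 <- stats::setNames(vector("list", length(samples)), samples)
  truth <- list()
  make_amplicon <- function(insert)
    paste0(expand_primer(primers$forward), insert,
           revcomp(expand_primer(primers$reverse)))
  emit <- function(amplicon) {
    L <- nchar(amplicon)
    fw <- substr(amplicon, 1L, config$read_len)
    rv <- revcomp(substr(amplicon, L - config$read_len + 1L, L))
    e1 <- .seq_with_errors(fw, config)
    e2 <- .seq_with_errors(rv, config)
    list(r1 = e1, r2 = e2)
  }
  rid <- 0L
  for (s in samples) {
    sub <- assemblage[assemblage$sample == s, , drop = FALSE]
    alloc <- as.vector(stats::rmultinom(1, config$reads_per_sample,
                                        sub$abundance))
    origin_sp <- rep(sub$species, alloc)
    n <- length(origin_sp)
    u <- stats::runif(n)
    origin <- rep("clean", n)
    origin[u < config$chimera_rate] <- "chimera"
    origin[u >= config$chimera_rate &
             u < config$chimera_rate + config$numt_rate] <- "numt"
    origin[u >= config$chimera_rate + config$numt_rate &
             u < config$chimera_rate + config$numt_rate +
               config$contaminant_rate] <- "contaminant"
    ids <- seqs1 <- quals1 <- seqs2 <- quals2 <- inserts <- character(n)
    for (i in seq_len(n)) {
      rid <- rid + 1L
      sp <- origin_sp[i]
      ins <- switch(origin[i],
        clean = insert_of[[sp]],
        numt = .inject_stop(insert_of[[sp]], primers$reading_frame_offset),
        chimera = {
          others <- setdiff(unique(sub$species), sp)
          sp2 <- if (length(others)) sample(others, 1L) else sp
          a <- insert_of[[sp]]; b <- insert_of[[sp2]]
          bp <- sample(seq_len(config$insert_len - 1L), 1L)
          paste0(substr(a, 1L, bp), substr(b, bp + 1L, nchar(b)))
        },
        contaminant = .contaminant_insert(config$insert_len, insert_of))
      rd <- emit(make_amplicon(ins))
      ids[i] <- sprintf("read_%06d", rid)
      inserts[i] <- ins
      seqs1[i] <- rd$r1$sequence; quals1[i] <- rd$r1$quality
      seqs2[i] <- rd$r2$sequence; quals2[i] <- rd$r2$quality
    }
    r1[[s]] <- data.frame(read_id = ids, sequence = seqs1, quality = quals1,
                          stringsAsFactors = FALSE)
    r2[[s]] <- data.frame(read_id = ids, sequence = seqs2, quality = quals2,
                          stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      read_id = ids, sample = s, origin = origin,
      species = ifelse(origin == "contaminant", NA_character_, origin_sp),
      insert = inserts, stringsAsFactors = FALSE)
  }
  control_samples <- character(0)
  if (config$n_control_reads > 0L) {
    for (ci in seq_len(config$n_cores)) {
      s <- sprintf("core%d_control", ci)
      control_samples <- c(control_samples, s)
      n <- config$n_control_reads
      ids <- seqs1 <- quals1 <- seqs2 <- quals2 <- inserts <- character(n)
      for (i in seq_len(n)) {
        rid <- rid + 1L
        ins <- .contaminant_insert(config$insert_len, insert_of)
        rd <- emit(make_amplicon(ins))
        ids[i] <- sprintf("read_%06d", rid)
        inserts[i] <- ins
        seqs1[i] <- rd$r1$sequence; quals1[i] <- rd$r1$quality
        seqs2[i] <- rd$r2$sequence; quals2[i] <- rd$r2$quality
      }
      r1[[s]] <- data.frame(read_id = ids, sequence = seqs1,
                            quality = quals1, stringsAsFactors = FALSE)
      r2[[s]] <- data.frame(read_id = ids, sequence = seqs2,
                            quality = quals2, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        read_id = ids, sample = s, origin = "contaminant",
        species = NA_character_, insert = inserts, stringsAsFactors = FALSE)
    }
  }
  list(r1 = r1, r2 = r2, truth = do.call(rbind, truth),
       control_samples = control_samples)
}

#' Simulate a full dataset
#'
#' References, assemblages and paired reads in one call.
#'
#' @param config a [simulation_config()].
#' @param primers a [primer_set]; defaults to the Chironomidae-specific set.
#' @return list with `references`, `assemblage`, `core_pools`, `reads`
#'   (output of [simulate_reads()]), `config`, `primers`.
#' @export
simulate_dataset <- function(config = simulation_config(),
                             primers = ch_primer_set()) {
  refs <- simulate_references(config, primers)
  asm <- simulate_assemblages(config, refs$inserts$species)
  reads <- simulate_reads(asm$assemblage, refs, config, primers)
  list(references = refs, assemblage = asm$assemblage,
       core_pools = asm$core_pools, reads = reads, config = config,
       primers = primers)
}

#' Write a simulated dataset to disk
#'
#' FASTA references, lineage and truth TSVs, and paired per-sample FASTQ.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(data.frame(id = sim$references$records$seq_id,
                         sequence = sim$references$records$sequence),
              file.path(dir, "references.fasta"))
  write_lineage_tsv(sim$references$lineages,
                    file.path(dir, "lineages.tsv"))
  write_tsv(sim$reads$truth, file.path(dir, "truth.tsv"))
  write_tsv(sim$assemblage, file.path(dir, "assemblage.tsv"))
  for (s in names(sim$reads$r1)) {
    write_fastq(sim$reads$r1[[s]], file.path(dir, paste0(s, "_R1.fastq")))
    write_fastq(sim$reads$r2[[s]], file.path(dir, paste0(s, "_R2.fastq")))
  }
  invisible(dir)
}
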