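# Read processing: merging, trimming, filtering, dereplication, denoising,
# chimera and numt removal, and read-to-ESV mapping.

q_string <- function(n, q = 35) intToUtf8(rep(q + 33L, n))

test_that("perfect overlaps merge to the expected length and consensus", {
  set.seed(41)
  amplicon <- random_dna(240)
  r1 <- substr(amplicon, 1, 150)
  r2 <- revcomp(substr(amplicon, 91, 240))     # 60 nt overlap
  m <- merge_pairs(r1, q_string(150), r2, q_string(150), min_overlap = 50)
  expect_identical(m$status, "ok")
  expect_identical(nchar(m$sequence), 150L + 150L - 60L)
  expect_identical(m$sequence, amplicon)
  expect_identical(nchar(m$quality), nchar(m$sequence))
})

test_that("overlaps below the minimum or above the mismatch budget reject", {
  set.seed(42)
  amplicon <- random_dna(260)
  r1 <- substr(amplicon, 1, 150)
  r2 <- revcomp(substr(amplicon, 121, 260))    # true overlap 30 < 50
  m <- merge_pairs(r1, q_string(150), r2, q_string(140))
  expect_false(m$status == "ok")
  # 11 mismatches inside a 60 nt overlap
  amplicon2 <- random_dna(240)
  tail2 <- substr(amplicon2, 91, 240)
  tail2_mut <- paste0(mutate_seq(substr(tail2, 1, 60), 11),
                      substr(tail2, 61, 150))
  m2 <- merge_pairs(substr(amplicon2, 1, 150), q_string(150),
                    revcomp(tail2_mut), q_string(150))
  expect_identical(m2$status, "too_many_diffs")
  # 10 mismatches still pass
  tail3 <- paste0(mutate_seq(substr(tail2, 1, 60), 10),
                  substr(tail2, 61, 150))
  m3 <- merge_pairs(substr(amplicon2, 1, 150), q_string(150),
                    revcomp(tail3), q_string(150))
  expect_identical(m3$status, "ok")
})

test_that("merge consensus takes the higher-quality base at conflicts", {
  a <- "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT" # 60
  r1 <- a
  r2rc <- a
  substr(r2rc, 10, 10) <- "G"   # conflict at position 10 (r1 has C)
  m <- merge_pairs(r1, q_string(60, 20), revcomp(r2rc), q_string(60, 38),
                   min_overlap = 50)
  expect_identical(m$status, "ok")
  expect_identical(substr(m$sequence, 10, 10), "G")        # higher quality wins
  expect_identical(utf8ToInt(substr(m$quality, 10, 10)) - 33L, 18L) # |38-20|
  expect_identical(utf8ToInt(substr(m$quality, 11, 11)) - 33L, 38L) # max(q)
})

test_that("linked anchored primer trimming returns the bare insert", {
  set.seed(43)
  ch <- ch_primer_set()
  insert <- random_dna(139)
  fwd <- expand_primer(ch$forward)
  rev <- expand_primer(ch$reverse)
  read <- paste0(fwd, insert, revcomp(rev))
  tr <- trim_primers(read, q_string(nchar(read)), ch)
  expect_identical(tr$status, "ok")
  expect_identical(tr$sequence, insert)
  expect_identical(nchar(tr$quality), 139L)
  # forward site at offset 3 violates the anchor
  tr2 <- trim_primers(paste0("AAA", read), q_string(nchar(read) + 3), ch)
  expect_identical(tr2$status, "no_forward_anchor")
  # reverse site absent (linked requirement)
  read3 <- paste0(fwd, insert, random_dna(20))
  tr3 <- trim_primers(read3, q_string(nchar(read3)), ch)
  expect_identical(tr3$status, "no_reverse")
})

test_that("quality filter applies length, expected-error and mean-Q rules", {
  set.seed(44)
  # length deviation beyond 10 bp
  expect_false(quality_filter(random_dna(194), q_string(194, 40),
                              expected_len = 205)$keep)
  # 200 nt at Q40: EE = 200 * 1e-4 = 0.02 < 1 -> kept
  qf <- quality_filter(random_dna(200), q_string(200, 40),
                       expected_len = 205)
  expect_true(qf$keep)
  expect_equal(expected_errors(q_string(200, 40)), 0.02)
  # EE = 1.2 (120 bases at Q20) -> dropped even though mean Q fails later
  qf2 <- quality_filter(random_dna(200),
                        paste0(q_string(120, 20), q_string(80, 93)),
                        expected_len = 205, min_mean_q = 0)
  expect_equal(expected_errors(paste0(q_string(120, 20), q_string(80, 93))),
               1.2, tolerance = 1e-6)
  expect_identical(qf2$reason, "expected_errors")
  # mean quality below 30
  qf3 <- quality_filter(random_dna(200), q_string(200, 29),
                        expected_len = 205, max_ee = 100)
  expect_identical(qf3$reason, "mean_quality")
})

test_that("dereplication tracks per-sample abundances and sorts deterministically", {
  s1 <- data.frame(sequence = c(rep("AAA", 3), rep("CCC", 2)))
  u <- dereplicate(list(s1 = s1))
  expect_identical(u$sequences, c("AAA", "CCC"))
  expect_identical(u$total, c(3L, 2L))
  # same sequence in two samples: abundances add per sample
  u2 <- dereplicate(list(s1 = data.frame(sequence = rep("AAA", 2)),
                         s2 = data.frame(sequence = rep("AAA", 5))))
  expect_identical(unname(u2$abundance[1, ]), c(2L, 5L))
  expect_identical(u2$total, 7L)
  # ties broken lexicographically
  u3 <- dereplicate(list(s1 = data.frame(sequence = c("TTT", "GGG"))))
  expect_identical(u3$sequences, c("GGG", "TTT"))
  # empty input
  u4 <- dereplicate(list(s1 = data.frame(sequence = character(0))))
  expect_identical(length(u4$sequences), 0L)
})

test_that("d=1 denoising links chains and the most abundant member represents", {
  set.seed(45)
  a <- random_dna(60)
  b <- mutate_seq(a, 1)
  res <- denoise_d1(make_uniques(c(a, b), c(100, 5)))
  expect_identical(nrow(res$esvs$sequences), 1L)
  expect_identical(res$esvs$sequences$sequence, a)
  expect_identical(res$esvs$sequences$total, 105L)
  # two uniques at distance 3: unlinkable and ungraftable
  c3 <- mutate_seq(a, 3)
  res2 <- denoise_d1(make_uniques(c(a, c3), c(100, 5)))
  expect_identical(nrow(res2$esvs$sequences), 2L)
  # chain a - b - c with consecutive distances 1 (a-c distance 2)
  cc <- mutate_seq(b, 1)
  while (oracle_levenshtein(cc, a) != 2) cc <- mutate_seq(b, 1)
  res3 <- denoise_d1(make_uniques(c(a, b, cc), c(100, 5, 2)))
  expect_identical(nrow(res3$esvs$sequences), 1L)
  expect_identical(res3$esvs$sequences$total, 107L)
})

test_that("fastidious mode grafts small clusters across a distance-2 bridge", {
  set.seed(46)
  a <- random_dna(60)
  small <- mutate_seq(a, 2)       # distance 2 from the big cluster
  res <- denoise_d1(make_uniques(c(a, small), c(100, 2)),
                    fastidious = TRUE, boundary = 3)
  expect_identical(nrow(res$esvs$sequences), 1L)
  res2 <- denoise_d1(make_uniques(c(a, small), c(100, 2)),
                     fastidious = FALSE)
  expect_identical(nrow(res2$esvs$sequences), 2L)
  # abundance >= boundary: not grafted even in fastidious mode
  res3 <- denoise_d1(make_uniques(c(a, small), c(100, 3)),
                     fastidious = TRUE, boundary = 3)
  expect_identical(nrow(res3$esvs$sequences), 2L)
})

test_that("pre-fastidious denoising equals brute-force d<=1 components", {
  set.seed(47)
  for (rep in 1:15) {
    n <- sample(4:12, 1)
    base <- random_dna(40)
    seqs <- unique(vapply(seq_len(n), function(i)
      mutate_seq(base, sample(0:3, 1)), character(1)))
    totals <- sample(1:50, length(seqs))
    u <- make_uniques(seqs, totals)
    res <- denoise_d1(u, fastidious = FALSE)
    comp <- oracle_components_d1(u$sequences)
    # same partition: cluster count and same-cluster relation
    expect_identical(nrow(res$esvs$sequences), length(unique(comp)))
    mem <- res$membership$esv_id
    for (i in seq_along(comp)) for (j in seq_along(comp))
      expect_identical(mem[i] == mem[j], comp[i] == comp[j])
  }
})

test_that("perfect two-parent chimeras are flagged; parents never are", {
  set.seed(48)
  pa <- random_dna(100)
  pb <- mutate_seq(pa, 12)
  chim <- paste0(substr(pa, 1, 40), substr(pb, 41, 100))
  stopifnot(chim != pa, chim != pb)
  esvs <- make_esvs(c(pa, pb, chim), c(100, 64, 2))
  res <- detect_chimeras(esvs, abundance_skew = 16)
  id_of <- function(s) esvs$sequences$esv_id[esvs$sequences$sequence == s]
  expect_identical(res$flagged, id_of(chim))
  expect_false(id_of(pa) %in% res$flagged)
  expect_false(id_of(pb) %in% res$flagged)
  expect_identical(nrow(res$esvs$sequences), 2L)
  # abundance skew unmet (64/10 < 16): not flagged
  esvs2 <- make_esvs(c(pa, pb, chim), c(100, 64, 10))
  expect_identical(detect_chimeras(esvs2, 16)$flagged, character(0))
  # not reconstructable from any parent pair: not flagged
  other <- mutate_seq(chim, 6)
  esvs3 <- make_esvs(c(pa, pb, other), c(100, 64, 2))
  expect_identical(detect_chimeras(esvs3, 16)$flagged, character(0))
})

test_that("numt filtering removes in-frame stops under translation table 5", {
  # TAA in frame 0 is a stop
  with_stop <- paste0("ATG", "TAA", "GGC")
  # AGA encodes serine in the invertebrate mitochondrial code, not a stop
  with_aga <- paste0("ATG", "AGA", "GGC")
  clean <- paste0("ATG", "GCC", "GGC")
  esvs <- make_esvs(c(with_stop, with_aga, clean), c(5, 4, 3))
  res <- filter_numts(esvs, frame_offset = 0)
  expect_setequal(res$esvs$sequences$sequence, c(with_aga, clean))
  expect_identical(res$removed$reason, "stop_codon")
  # frame offset shifts the codon grid: TAA at offset 1 is no longer in frame
  res1 <- filter_numts(make_esvs(with_stop, 5), frame_offset = 1)
  expect_identical(nrow(res1$removed), 0L)
  # sequence shorter than one codon after the offset
  res2 <- filter_numts(make_esvs("AT", 5), frame_offset = 1)
  expect_identical(res2$removed$reason, "too_short_to_translate")
})

test_that("reads map to the nearest ESV within one difference", {
  set.seed(49)
  e1 <- random_dna(80)
  e2 <- mutate_seq(e1, 10)
  esvs <- make_esvs(c(e1, e2), c(50, 30), sample_name = "sA")
  near <- mutate_seq(e1, 1)
  far <- mutate_seq(e1, 5)
  reads <- list(sA = data.frame(sequence = c(e1, e1, near, far)))
  res <- map_reads(reads, esvs, max_diffs = 1)
  expect_identical(res$unmapped, 1L)
  ab <- res$esvs$abundance
  expect_identical(unname(ab[res$esvs$sequences$sequence == e1, "sA"]), 3L)
  asn <- res$assignments
  expect_true(is.na(asn$esv_id[asn$sequence == far]))
})

test_that("the stage log conserves the read funnel end to end", {
  cfg <- simulation_config(seed = 9, n_species = 6, n_genera = 3,
                           n_families = 2, core_pool_size = 3,
                           reads_per_sample = 40, dip_rate = 0.05)
  pr <- ch_primer_set()
  sim <- simulate_dataset(cfg, pr)
  run <- process_reads(sim$reads$r1, sim$reads$r2, pr)
  log <- run$stage_log
  for (stage in c("merge", "trim_primers", "quality_filter")) {
    row <- log[log$stage == stage, ]
    rejected <- if (nzchar(row$detail))
      sum(as.integer(sub(".*=", "", strsplit(row$detail, ";")[[1]]))) else 0L
    expect_identical(row$n_in - row$n_out, rejected)
  }
  # stage inputs chain: out of one stage = in of the next
  expect_identical(log$n_out[log$stage == "merge"],
                   log$n_in[log$stage == "trim_primers"])
  expect_identical(log$n_out[log$stage == "trim_primers"],
                   log$n_in[log$stage == "quality_filter"])
  expect_identical(log$n_out[log$stage == "quality_filter"],
                   log$n_in[log$stage == "dereplicate"])
})
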