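# Morphotype translation, incidence matrices, DCA, Venn regions and report
# arithmetic.

toy_crosswalk <- data.frame(
  taxon = c("Alpha unus", "Alpha", "Beta", "Sergentia coracina"),
  rank = c("species", "genus", "genus", "species"),
  morphotype = c("Alpha unus-type", "Alpha", "Beta", "Sergentia coracina-type"),
  stringsAsFactors = FALSE)

test_that("crosswalk lookup is exact with genus fallback for species", {
  det <- data.frame(
    sample = c("s1", "s1", "s1", "s2"),
    taxon = c("Alpha unus", "Alpha duo", "Gamma unus", "Beta"),
    rank = c("species", "species", "species", "genus"),
    genus = c("Alpha", "Alpha", "Gamma", NA),
    stringsAsFactors = FALSE)
  res <- translate_morphotypes(det, toy_crosswalk)
  got <- res$detections
  # species-level row hits directly
  expect_identical(got$morphotype[got$sample == "s1" &
                                    got$matched_rank == "species"],
                   "Alpha unus-type")
  # species absent from the table falls back to its genus row
  expect_true("Alpha" %in% got$morphotype[got$sample == "s1"])
  expect_identical(got$matched_rank[got$morphotype == "Alpha"], "genus")
  # absent at both ranks: dropped and reported
  expect_identical(res$dropped, "Gamma unus")
  # genus-rank detection hits the genus row
  expect_identical(got$morphotype[got$sample == "s2"], "Beta")
  # never emits a morphotype absent from the crosswalk
  expect_true(all(got$morphotype %in% toy_crosswalk$morphotype))
})

test_that("translated detections are deduplicated per sample", {
  det <- data.frame(sample = c("s1", "s1"),
                    taxon = c("Alpha unus", "Alpha duo"),
                    rank = c("species", "species"),
                    genus = c("Alpha", "Alpha"), stringsAsFactors = FALSE)
  cw <- data.frame(taxon = "Alpha", rank = "genus", morphotype = "Alpha",
                   stringsAsFactors = FALSE)
  res <- translate_morphotypes(det, cw)
  expect_identical(nrow(res$detections), 1L)
})

test_that("incidence transform binarises counts and drops empty columns", {
  m <- matrix(c(0, 3, 17, 0, 0, 0), nrow = 3,
              dimnames = list(paste0("s", 1:3), c("taxA", "taxB")))
  inc <- build_incidence(m)
  expect_identical(unname(inc[, "taxA"]), c(0L, 1L, 1L))
  expect_false("taxB" %in% colnames(inc))       # all-zero column removed
  expect_identical(build_incidence(inc), inc)    # idempotent
  # long data frame input with read counts
  df <- data.frame(sample = c("s1", "s1", "s2"),
                   taxon = c("taxA", "taxB", "taxA"),
                   count = c(250, 3, 1))
  inc2 <- build_incidence(df)
  expect_identical(sort(colnames(inc2)), c("taxA", "taxB"))
  expect_identical(unname(inc2["s2", ]), c(1L, 0L))
  expect_error(build_incidence(matrix(-1, 3, 3)), "negative")
})

test_that("undetrended, unrescaled DCA eigenvalues equal a power-iteration CA oracle", {
  set.seed(61)
  m <- matrix(rbinom(30, 1, 0.5), 5, 6,
              dimnames = list(paste0("s", 1:5), paste0("t", 1:6)))
  m[rowSums(m) == 0, 1] <- 1
  m <- build_incidence(m)
  res <- dca(m, downweight_rare = FALSE, rescale = FALSE, detrend = FALSE)
  oracle <- oracle_ca_eigenvalues(m, naxes = 4)
  expect_equal(res$eigenvalues, oracle, tolerance = 1e-8)
})

test_that("DCA input validation and duplicate-sample symmetry", {
  m <- matrix(1, 2, 2)
  expect_error(dca(m), "at least 3")
  m2 <- matrix(c(1, 1, 0, 0, 0, 0, 1, 0, 1, 1, 0, 1), 4, 3,
               dimnames = list(paste0("s", 1:4), paste0("t", 1:3)))
  m2["s2", ] <- 0
  expect_error(dca(m2), "s2")
  # identical samples receive identical scores
  set.seed(62)
  m3 <- matrix(rbinom(40, 1, 0.5), 8, 5,
               dimnames = list(paste0("s", 1:8), paste0("t", 1:5)))
  m3[rowSums(m3) == 0, 1] <- 1
  m3["s2", ] <- m3["s1", ]
  m3 <- build_incidence(m3)
  res <- dca(m3)
  expect_equal(unname(res$sample_scores["s1", ]),
               unname(res$sample_scores["s2", ]), tolerance = 1e-10)
})

test_that("DCA axis 1 recovers a simulated unimodal gradient", {
  set.seed(63)
  n_samples <- 20; n_taxa <- 12
  gradient <- seq_len(n_samples)
  optima <- seq(1, n_samples, length.out = n_taxa)
  inc <- outer(gradient, optima, function(g, o) as.integer(abs(g - o) <= 4))
  dimnames(inc) <- list(paste0("s", 1:n_samples), paste0("t", 1:n_taxa))
  inc <- build_incidence(inc)
  res <- dca(inc, downweight_rare = FALSE)
  rho <- suppressWarnings(
    stats::cor(res$sample_scores[, 1], gradient, method = "spearman"))
  expect_gte(abs(rho), 0.95)
})

test_that("venn region counts are exact and sum to the union", {
  v2 <- venn_counts(list(A = c("a", "b"), B = c("b", "c")))
  expect_identical(unname(v2["A&B"]), 1L)
  expect_identical(unname(v2["A"]), 1L)
  expect_identical(unname(v2["B"]), 1L)
  # disjoint sets share nothing
  v0 <- venn_counts(list(A = c("a"), B = c("b")))
  expect_identical(unname(v0["A&B"]), 0L)
  expect_error(venn_counts(list(A = "a")), "2 or 3")
  # 3-set regions match exhaustive membership tabulation
  set.seed(64)
  for (i in 1:10) {
    universe <- letters[1:10]
    sets <- list(X = sample(universe, sample(2:8, 1)),
                 Y = sample(universe, sample(2:8, 1)),
                 Z = sample(universe, sample(2:8, 1)))
    v <- venn_counts(sets)
    expect_identical(sum(v), length(unique(unlist(sets))))
    # brute-force oracle: classify each element by its membership pattern
    for (el in unique(unlist(sets))) {
      pat <- paste(names(sets)[vapply(sets, function(s) el %in% s,
                                      logical(1))], collapse = "&")
      expect_true(v[pat] >= 1L)
    }
    brute <- table(vapply(unique(unlist(sets)), function(el)
      paste(names(sets)[vapply(sets, function(s) el %in% s, logical(1))],
            collapse = "&"), character(1)))
    expect_identical(unname(v[names(brute)]), as.integer(brute))
    expect_true(all(v[setdiff(names(v), names(brute))] == 0L))
  }
})

test_that("proportions use half-up rounding at the requested precision", {
  expect_identical(proportion(1605, 45343, 1), 3.5)
  expect_identical(proportion(26, 83, 0), 31)
  expect_identical(proportion(0, 100, 1), 0)
  # half-up, not banker's
  expect_identical(round_half_up(2.5, 0), 3)
  expect_identical(round_half_up(0.125, 2), 0.13)
  expect_error(proportion(5, 0), "positive")
  expect_error(proportion(-1, 10), "non-negative")
})

test_that("control report lists matches and flags overlap with real samples", {
  set.seed(65)
  seqs <- vapply(1:3, function(i) random_dna(60), character(1))
  ab <- matrix(c(5L, 0L, 0L, 0L,
                 3L, 2L, 0L, 0L,
                 0L, 4L, 1L, 0L), nrow = 3, byrow = TRUE,
               dimnames = list(NULL, c("ctrl1", "s1", "s2", "ctrl2")))
  esvs <- esv_set(data.frame(esv_id = paste0("esv_", 1:3), sequence = seqs,
                             total = as.integer(rowSums(ab))), ab)
  asn <- data.frame(esv_id = paste0("esv_", 1:3),
                    genus = c(NA, "Alpha", "Beta"),
                    species = c(NA, NA, "Beta unus"),
                    rank = c(NA, "genus", "species"),
                    assigned = c(FALSE, TRUE, TRUE),
                    stringsAsFactors = FALSE)
  rep <- control_report(esvs, asn, "ctrl1")
  expect_identical(nrow(rep), 2L)               # esv_3 absent from controls
  expect_identical(rep$match[rep$esv_id == "esv_1"], "no_match")
  expect_identical(rep$match[rep$esv_id == "esv_2"], "Alpha")
  expect_false(rep$in_real_samples[rep$esv_id == "esv_1"])
  expect_true(rep$in_real_samples[rep$esv_id == "esv_2"])
  # clean control: empty table
  rep2 <- control_report(esvs, asn, "ctrl2")
  expect_identical(nrow(rep2), 0L)
  expect_error(control_report(esvs, asn, "nope"), "unknown control")
})
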