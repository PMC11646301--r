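# Independent oracles and small fixture builders used across the suite.

# brute-force rank-prefix LCA: compare rank by rank, stop at first
# disagreement or absence
oracle_lca <- function(lineages) {
  out <- stats::setNames(rep(NA_character_, 7L), TAX_RANKS)
  for (r in TAX_RANKS) {
    vals <- vapply(lineages, function(l) l[[r]], character(1))
    if (anyNA(vals) || length(unique(vals)) != 1L) break
    out[r] <- vals[1]
  }
  out
}

# plain Needleman-Wunsch DP with linear (per-base) gap cost; returns the
# optimal score only
oracle_nw_linear <- function(a, b, match = 2, mismatch = -4, gap = -1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  prev <- gap * (0:m)
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- gap * i
    for (j in seq_len(m)) {
      sub <- prev[j] + if (av[i] == bv[j]) match else mismatch
      cur[j + 1] <- max(sub, prev[j + 1] + gap, cur[j] + gap)
    }
    prev <- cur
  }
  prev[m + 1]
}

# plain DP Levenshtein distance (independent of utils::adist)
oracle_levenshtein <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1)
    cur[1] <- i
    for (j in seq_len(m)) {
      cur[j + 1] <- min(prev[j] + (av[i] != bv[j]), prev[j + 1] + 1L,
                        cur[j] + 1L)
    }
    prev <- cur
  }
  prev[m + 1]
}

# connected components of the distance-<=1 graph over sequences, by
# breadth-first search with the DP Levenshtein oracle
oracle_components_d1 <- function(seqs) {
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- oracle_levenshtein(seqs[i], seqs[j]) <= 1L
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    frontier <- s
    comp[s] <- cid
    while (length(frontier)) {
      nxt <- which(is.na(comp) & apply(adj[frontier, , drop = FALSE], 2, any))
      comp[nxt] <- cid
      frontier <- nxt
    }
  }
  comp
}

# correspondence-analysis eigenvalues by power iteration with deflation on
# the standardised matrix S = D_r^{-1/2} (P - r c^T) D_c^{-1/2}; eigenvalues
# of S S^T are the CA principal inertias
oracle_ca_eigenvalues <- function(M, naxes = 4, iters = 20000) {
  P <- M / sum(M)
  r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  B <- S %*% t(S)
  evals <- numeric(naxes)
  set.seed(42)
  for (k in seq_len(naxes)) {
    v <- stats::rnorm(nrow(B))
    v <- v / sqrt(sum(v^2))
    lam <- 0
    for (it in seq_len(iters)) {
      w <- B %*% v
      nl <- sqrt(sum(w^2))
      if (nl < 1e-300) break
      v_new <- as.vector(w) / nl
      if (max(abs(v_new - v)) < 1e-14 && it > 10) { v <- v_new; lam <- nl; break }
      v <- v_new
      lam <- nl
    }
    evals[k] <- lam
    B <- B - lam * outer(v, v)
  }
  evals
}

# random lineage over small name pools, always gap-free; species binomial
# consistent with genus
random_lineage <- function(depth = sample(0:7, 1)) {
  pools <- list(kingdom = c("Animalia"),
                phylum = c("Arthropoda", "Annelida"),
                class = c("Insecta", "Clitellata"),
                order = c("Diptera", "Trichoptera"),
                family = c("Chironomidae", "Chaoboridae"),
                genus = c("Alpha", "Beta", "Gamma"),
                species = NA)
  vals <- stats::setNames(rep(NA_character_, 7L), TAX_RANKS)
  if (depth >= 1) for (i in seq_len(depth)) {
    r <- TAX_RANKS[i]
    vals[r] <- if (r == "species")
      paste(vals["genus"], sample(c("unus", "duo", "tres"), 1)) else
        sample(pools[[r]], 1)
  }
  do.call(lineage, as.list(vals[!is.na(vals)]))
}

# mutate a sequence with k random substitutions
mutate_seq <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

random_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

# uniques structure (as from dereplicate()) built from sequences + totals in
# a single sample
make_uniques <- function(seqs, totals, sample_name = "s1") {
  ord <- order(-totals, seqs)
  ab <- matrix(as.integer(totals[ord]), ncol = 1,
               dimnames = list(NULL, sample_name))
  list(sequences = seqs[ord], abundance = ab, total = as.integer(totals[ord]))
}

make_esvs <- function(seqs, totals, sample_name = "s1") {
  u <- make_uniques(seqs, totals, sample_name)
  esv_set(data.frame(esv_id = paste0("esv_", seq_along(u$sequences)),
                     sequence = u$sequences, total = u$total,
                     stringsAsFactors = FALSE),
          u$abundance)
}
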