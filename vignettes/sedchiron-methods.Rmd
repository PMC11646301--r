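---
title: "Methods: sedDNA metabarcoding of Chironomidae assemblages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sedDNA metabarcoding of Chironomidae assemblages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedchiron)
```

## The problem

Chironomidae (non-biting midge) larvae are standard bioindicators in
paleolimnology: their chitinised head capsules preserve in lake sediments and
are identified under the microscope to species- or genus-level *morphotypes*.
Sediment DNA (sedDNA) metabarcoding offers an independent route to the same
assemblages: short CO1 amplicons amplified directly from sediment, sequenced,
denoised into exact sequence variants (ESVs), and assigned to taxa against a
curated reference database. `sedchiron` implements that analytical route as a
reusable, testable pipeline, together with the comparison machinery needed to
confront molecular detections with morphotype counts, and a synthetic-data
generator so that every stage can be exercised and validated without any
sequencing data.

## Processing model

The read-processing chain mirrors standard amplicon practice, with every
threshold exposed in `pipeline_config()`:

1. **Merging** (`merge_pairs`). The reverse mate is reverse-complemented and
   all non-staggered overlaps of at least `min_overlap` (50) bases are
   scanned; the overlap maximising matching positions wins, with ties going
   to the overlap with fewer mismatches. More than `max_diffs` (10)
   differences rejects the pair. At agreeing positions the consensus quality
   is the larger Phred score; at conflicts the higher-quality base wins and
   the consensus quality is the absolute score difference, so an equal-quality
   conflict yields quality zero and the expected-error filter downstream
   treats that base as certain error. This simple rule was chosen over
   posterior recomputation; it is conservative, removing most reads whose
   overlap carries a sequencing error.
2. **Primer trimming** (`trim_primers`): linked, 5'-anchored semantics. The
   forward primer must match at position 0 and the reverse complement of the
   reverse primer at the 3' end, each within a mismatch budget of
   `floor(0.1 x primer length)`. Degenerate positions (IUPAC codes, and
   inosine in the CH reverse primer) match at zero cost when the read base is
   in the allowed set.
3. **Quality filtering** (`quality_filter`): insert length within ±10 bp of
   the primer set's expected insert, expected errors
   (`sum(10^(-Q/10))`) below 1, and mean Phred at least 30. The "below Q30"
   rule is interpreted at read level (mean quality) rather than as per-base
   truncation, which would conflict with the expected-error criterion; the
   threshold is configurable.
4. **Dereplication and denoising** (`dereplicate`, `denoise_d1`): exact
   dereplication with per-sample abundances, then single-linkage clustering
   at Levenshtein distance 1 growing from the most abundant unique
   outwards (chain growth), with a fastidious pass grafting clusters of total
   abundance below 3 onto a large cluster across a distance-2 bridge. The
   cluster representative (the ESV) is its most abundant member. No
   within-swarm abundance-gradient splitting is attempted; at d = 1 with
   realistic error rates the single-linkage partition is the object of
   interest.
5. **Chimera removal** (`detect_chimeras`): an ESV is flagged only when its
   sequence is *exactly* a prefix of one parent plus a suffix of another,
   both parents being distinct ESVs at least 16 times more abundant — the
   de-novo perfect-chimera criterion. Three-way chimeras are out of scope.
6. **Numt removal** (`filter_numts`): translation in the configured forward
   frame under the invertebrate mitochondrial code (table 5: TAA/TAG are the
   only stops, AGA/AGG encode serine, TGA tryptophan); any in-frame stop
   removes the ESV as a putative nuclear pseudogene copy. Because the true
   codon phase of an amplicon is a property of the primer design, the frame
   offset lives on the `primer_set`; an all-frames mode (remove only if every
   frame is stopped) is available when the phase is unknown.
7. **Read mapping** (`map_reads`): the quality-filtered reads are re-mapped
   onto the surviving ESVs allowing one difference, ties resolved toward the
   more abundant ESV then lexicographically; the per-sample abundance table
   is rebuilt from this mapping and unmapped reads counted. Mapping is pooled
   across samples and tabulated per sample.

Every stage appends to a funnel log and the in/out counts are conserved —
the suite asserts `n_in = n_out + rejected` at each step.

## Reference database and assignment

`curate_references` filters a raw reference set to a minimum length of
200 bp with no internal Ns (terminal Ns stripped first) and dereplicates
exact duplicates, merging their *sanitised* lineages by lowest common
ancestor. Sanitisation (`sanitize_lineage`) removes taxon names carrying
uncertainty wording — "sp.", "aff.", "gr.", "var." — by truncating the
lineage to the last trustworthy rank; matching requires whole-token equality
so that "sp." never truncates "spinosa". `insilico_pcr` then restricts every
record to the primer-specific insert: a forward site within one mismatch, a
downstream reverse-complemented reverse site, both primers removed, and the
insert length required to fall within ±10 bp of the expected insert. Both
strands are scanned (the plus strand wins if both qualify); the leftmost
forward site with a qualifying nearest reverse site makes the outcome
deterministic.

Assignment (`assign_all`) aligns each ESV globally (Needleman–Wunsch, affine
gaps) against every curated insert, keeps hits at `min_identity` ≥ 90% (at
most 5000), and ranks them by lowest e-value, highest identity, highest bit
score, fewest gap openings, fewest mismatches. All hits tied on the full key
contribute to a lowest-common-ancestor lineage, and species-level
assignments with best identity below 95% are demoted to genus. Choices worth
noting:

* Alignment scoring (+2/−4, gap open −10, extend −1) is a configuration, not
  a claim: for global alignments of near-equal-length sequences the
  e-value/bit-score ordering is monotone in the raw score, so the best-hit
  criteria are computable regardless of the exact constants. Bit scores and
  e-values use Karlin–Altschul with fixed constants (λ = 0.625, K = 0.041)
  recorded in the code.
* Identity excludes terminal-gap columns (usearch-style).
* "Fewest alignment gaps" is read as fewest gap *openings*; total gap
  columns are reported alongside.
* ESVs without any hit stay in all outputs as unassigned — the proportions
  of identified ESVs are part of the reporting.

The CH primer set (CH181F, 22 nt / CH181R, 20 nt) targets a 181 bp fragment
whose insert is 139 bp by arithmetic; the FWH set (fwhF2/fwhR2n) targets
254 bp with a 205 bp insert. Expected insert lengths are configuration values
on the `primer_set` rather than derived quantities, because published
expected lengths occasionally deviate from the arithmetic; the defaults here
are the arithmetic-consistent 139 and 205.

## Comparison with chitinous-remain morphotypes

`translate_morphotypes` maps assigned taxa onto remain morphotypes through an
exact `(taxon, rank)` crosswalk, with a genus fallback for species lacking
their own row (morphotypes are frequently genus-level); taxa absent at both
ranks — species without a described larva — are dropped and listed. Because
read abundances and head-capsule counts are not commensurable, all abundance
data are presence–absence transformed (`build_incidence`) before ordination.
`dca` wraps `vegan::decorana` — detrended correspondence analysis with 26
detrending segments, nonlinear rescaling to standard-deviation units and
Hill's rare-taxon downweighting (`iweigh = 1`) by default. With detrending
and rescaling disabled the result is plain orthogonal correspondence
analysis, which the tests pin to a hand-written power-iteration CA oracle at
1e-8. `venn_counts` and `proportion` (half-up rounding, the convention used
for all reported percentages) provide the sharing and proportion reports.

## The synthetic-data generator

`simulation_config()` encodes the study conditions the generator emulates:

* **Layout**: 3 sediment cores × 3 layers (top/middle/bottom), one sample
  per core–layer, plus one field-negative control per core (15 contaminant
  read pairs each by default, mirroring the few-reads-per-control outcome of
  real field blanks).
* **References**: 15 species in 6 genera and 2 families (the target family
  receives most genera), one 139 bp insert per species, rejection-sampled so
  every interspecific pair differs at ≥ `ceil(0.08 × 139)` = 12 sites. This
  enforces the ≥ 8% interspecific divergence premise under which the short
  fragment resolves species; the tests re-check it rather than assume it.
  Inserts are generated codon-wise stop-free in frame 0 so that genuine
  sequences never trip the numt filter.
* **Assemblages**: per-core species pools of 9 constructed so the two
  shallow cores share a Jaccard fraction of 0.8 while the deep core shares
  0.3 with them — the two-similar-one-distinct topology that the ordination
  must recover. Layers subsample their core pool independently (presence
  probability 0.85) and abundances are log-normal (meanlog 3, sdlog 1).
* **Reads**: 400 pairs per sample, 2 × 150 bp, giving a 119 bp overlap on
  the 181 bp CH amplicon. The quality profile is constant Q35 with 1% of
  positions dipping to Q15; substitution probability is `10^(-Q/10)`
  (substitution-only; indel errors are out of scope). Artefacts are injected
  per read at configurable rates — 2% perfect two-parent chimeras (uniform
  breakpoint), 2% numts (premature in-frame TAA), 3% contaminants (random
  inserts kept below 70% similarity to every reference, hence far below the
  90% search floor). A truth table records every read's origin class and
  insert.

Sample sizes are deliberately desk-scale: 15 species and ~3.6 k read pairs
keep a full run near half a minute while preserving the structure the
statistics need. The generator does **not** emulate PCR amplification bias,
indel sequencing errors, intraspecific haplotype variation, taphonomic DNA
damage, or reference databases with missing species; passing tests therefore
demonstrate the correctness of the pipeline's logic under its stated error
model, not field performance on real sediment extracts.

All randomness derives from a single integer seed; each generator stage
draws a deterministic child seed, so identical configurations reproduce
byte-identical datasets.

## Numerical and design choices

* Edit distance for denoising and mapping is Levenshtein (substitutions and
  single-base indels), computed with `utils::adist`.
* Name comparison in LCA is exact, case-sensitive string equality after
  whitespace normalisation; spelling variants or authority differences are
  treated as distinct names — no synonym resolution is attempted.
* Records annotated only to an intermediate rank (e.g. an ostracod
  identified to order) occupy that rank with deeper ranks absent; the
  seven-rank vector forbids internal gaps.
* Dereplication keys on the exact full-length sequence after uppercasing and
  terminal-N stripping, not on substring containment.
* Sorting everywhere breaks abundance ties lexicographically on the
  sequence, making every stage deterministic given its inputs; the pipeline
  needs no random numbers.
* Degenerate inputs: empty hit lists yield `unassigned` rather than errors;
  an empty reference set after curation aborts the run; ordination refuses
  matrices with fewer than 3 samples or taxa, or with empty sample rows
  (naming the offending sample).
* `proportion` rounds half-up (away from zero), not banker's style, because
  that is the convention the reported percentages follow.

## Worked example

```{r, eval = FALSE}
library(sedchiron)

cfg <- simulation_config(seed = 1)
sim <- simulate_dataset(cfg, ch_primer_set())
run <- run_pipeline(sim$reads$r1, sim$reads$r2,
                    sim$references$records, sim$references$lineages,
                    ch_primer_set(),
                    control_samples = sim$reads$control_samples)
print(run)                     # stage funnel + identified-ESV share
head(run$assignments)
det <- run$detections
ord <- dca(build_incidence(data.frame(sample = det$sample,
                                      taxon = det$taxon)))
plot(ord)
```

## Known limitations

* The chimera model is the perfect two-parent criterion only; imperfect
  chimeras (with additional errors) pass until the error also breaks the
  exact reconstruction.
* Pairwise search is exhaustive (no k-mer prefilter); appropriate at desk
  scale, not for millions of ESVs.
* `pairwise_pdistance` expects pre-aligned inserts. Synthetic inserts are
  generated indel-free at equal length and need no aligner; real inserts of
  unequal length must be aligned externally before the resolution screen.
* The DCA rescaling iteration count follows `decorana`'s published default;
  ordination outputs are deterministic up to axis reflection.
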