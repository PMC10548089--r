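---
title: "Statistical methods behind cnidomir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind cnidomir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnidomir)
```

cnidomir implements the downstream statistics of a miRNA-knockdown
transcriptome study in a cnidarian model: which genes respond to the
knockdown, whether the responding genes are concentrated in the
stinging-cell (cnidocyte) expression program, where they sit among
single-cell cluster markers, which transcripts carry high-complementarity
binding sites for the miRNA, and how strongly the knockdown itself
depresses the mature miRNA as measured by stem-loop qPCR. This vignette
explains each model, its assumptions, the defaults, and the numerical and
design choices that were genuinely open.

## Background filtering and DEG definition

The expression background is built from the raw count matrix alone:
`cpm[g, l] = counts[g, l] * 1e6 / library_total[l]`, and a gene is
*removed* when its CPM falls below `cpm_threshold` (default 1) in at
least `cpm_min_libraries` (default 2) libraries. Three readings of this
rule were possible and are worth making explicit:

* libraries are pooled across conditions (the rule names no per-condition
  grouping); the parameter is configurable for analysts who prefer a
  per-group rule;
* the comparison is strict (`CPM < threshold`), so a threshold of exactly
  0 removes nothing;
* the background is computed independently of the DE tables — whether the
  original analysis filtered before or after intersecting DE methods is
  not documented, and filtering from the count matrix is the only
  self-contained choice.

DEG calling is the two-method intersection rule: a gene is differentially
expressed iff in *every* supplied table the method's adjusted p-value is
strictly below `fdr` (default 0.05) and `|log2FC| >= log2(fc)` (default
`fc = 2`, two-sided — the analysis reports both up- and downregulated
genes), with fold-change signs agreeing across tables. The asymmetric
strict/inclusive pair mirrors the printed thresholds ("FDR < 0.05",
"fold change ≥ 2"). Genes passing both thresholds with discordant signs
are excluded and reported rather than raising an error: intersection
semantics, with an audit trail. Genes missing from either table are never
DEGs, and `NA` adjusted p-values are treated as 1 with a warning. DE
tables may carry either a `log2fc` or a linear `fc` column; the reader
auto-detects which and records the choice.

## Permutation set-overlap enrichment

The enrichment question — do the `n` DEGs overlap a size-`K` gene
catalogue more than chance — is answered by the study's own resampling
scheme: draw `r` lists of `n` genes uniformly from the size-`B`
background and record each list's overlap with the target. Design
decisions:

* **Sampling is without replacement.** Random "lists" of distinct genes
  are the only reading consistent with overlap counts approaching the
  full query size; a with-replacement variant would not be a gene list.
* **The observed query is not injected into the null ensemble**, matching
  the described procedure. Consequently the raw empirical p-value
  `p_raw = #{null >= x} / r` can be exactly zero; the pseudocount
  version `p_pseudo = (#{null >= x} + 1) / (r + 1)` is also reported and
  is the recommended summary, since a true resampling p-value is bounded
  below by `1/(r+1)`.
* **Query and target are intersected with the background first** (with a
  warning and an adjusted `n` for out-of-background query genes): genes
  that cannot be drawn in the null must not count in the observation.
* The null histogram is reported per integer overlap count, unsmoothed.

Because the draws are uniform without replacement, the null is exactly
hypergeometric: mean `nK/B`, upper tail `P(X >= x)` computed in log
space via `phyper`. The closed form is exposed
(`hypergeometric_tail()`, `hypergeometric_mean()`) and serves as the
permanent cross-check of the sampler: the test suite verifies the
sampled null against exhaustive subset enumeration (a lattice counting
DP independent of `dhyper`) for every feasible configuration with
`B <= 25`, and at total-variation distance < 0.02 for `r = 1e5` draws.

The calibration study in the acceptance suite uses `B = 4000`,
`K = 1600`, `n = 500` with `r = 2000` permutations per dataset, 500
null datasets and 200 enriched datasets. The size was chosen from the
discreteness of the statistic, before any test was run: p-values of an
integer-valued statistic deviate from uniformity by roughly the largest
point mass of the null, about `0.4/sd`, so a null standard deviation
near 10 is needed for a Kolmogorov–Smirnov distance below 0.08 to be
attainable at all; the chosen configuration has null SD ≈ 10.2.

## DEGs across single-cell cluster markers

`assign_degs_to_clusters()` consumes a `(gene, cluster)` marker table —
clustering and marker calling themselves are out of scope — and counts
DEGs per cluster plus the share of marker-overlapping DEGs in a focal
cluster set. A gene that is a marker of several clusters contributes to
each cluster's count but only once to the distinct-gene totals; this
keeps the focal fraction a well-defined proportion (the "110 of 168"
style of statement implies distinct-gene counting). When no DEG overlaps
the catalogue the fraction is reported as undefined with an explicit
flag, never silently as 0. Cluster identifiers are opaque labels:
"clusters 1 and 2 are cnidocytes" is configuration.
`cluster_enrichment_test()` reuses the permutation machinery with the
union of focal-cluster markers as the target.

## Target-site scanning

Cnidarian miRNAs bind their targets with plant-like, nearly full
complementarity, so target prediction is a penalty sum over the whole
duplex rather than a seed-match lookup. The expectation score of an
aligned duplex is: Watson–Crick pair 0; G:U wobble `gu_penalty` (0.5);
other mismatch `mismatch_penalty` (1); a gap run costs `gap_open` (2)
for its first column and `gap_extend` (0.5) per additional column; every
penalty at a seed position (miRNA positions `seed_start`–`seed_end`,
default 2–13, counted 5'→3', 1-based) is multiplied by `seed_weight`
(1.5). A site is accepted when its expectation is at most
`max_expectation` (2, inclusive — a site scoring exactly 2.0 is kept),
it has at most `max_seed_mismatches` (2) non-Watson-Crick seed columns
(G:U and gaps count toward this cap), and its paired span is at least
`hsp_size` (19 nt).

The published parameterization fixes the penalties but not the search
algorithm, so the scanner defines its contract precisely — a deliberate
re-specification, not a claim of bit-compatibility with any web service:

* per transcript position, the whole miRNA is aligned against the local
  window by dynamic programming over (miRNA position, gap counts, last
  move, capped seed mismatches), with at most `max_gaps = 2` gap columns
  per duplex and the first and last miRNA positions required to pair
  (no overhanging gaps);
* a bulged *target* base (gap in the miRNA row) is weighted at the
  position of the next miRNA base; a bulged *miRNA* base carries its own
  position — so a bulge between positions 14 and 15 under the default
  seed (2–13) is unweighted;
* the seed-mismatch cap is a DP dimension, so the reported optimum is
  the cheapest *feasible* alignment, not a cheapest alignment that is
  discarded afterwards;
* overlapping candidate placements are resolved greedily by expectation,
  ties to the leftmost start; ties within one placement prefer fewer
  gaps and then the shorter site — all deterministic across runs and
  platforms;
* `T` and `U` are interchangeable on input; alignments print as RNA,
  miRNA 3'→5' over the target 5'→3', with `|` for Watson–Crick and `o`
  for G:U.

The DP kernel is implemented in C++ (Rcpp), as is usual for
per-position sequence scans; the test suite checks it against a
pure-R brute-force enumeration of all ungapped and single-gap
alignments on short transcripts, and re-scores every emitted alignment
through the independent R scorer `score_duplex()`.

## qPCR quantification

`ddct()` is the Livak 2^−ΔΔCt method with its standard conventions
made explicit: technical replicates are averaged before any statistic;
ΔCt = Ct(target) − Ct(reference) per biological replicate; ΔΔCt is
anchored to the *mean* control ΔCt (so the control group averages an RQ
of 1 by construction, to floating tolerance); amplification efficiency
is fixed at 2, with no standard-curve correction. The companion
`two_group_ttest()` defaults to the equal-variance Student variant —
the convention named in the source analyses — with Welch available;
zero-variance degenerate inputs return p = 1 (equal means) or a flagged
p = 0 (different means) instead of failing.

## The synthetic-data generators

Every consumer has a generator whose planted truth is exact by
construction, so pipeline tests compare against certainty rather than
approximations:

* `simulate_universe()` draws negative-binomial counts (mean 100,
  dispersion 0.3 by default, 6 libraries as 3 + 3) identical across
  libraries: the pipeline never re-estimates differential expression, so
  realism beyond the CPM rule would add nothing. A chosen fraction of
  genes is constructed to fail the CPM rule (zero in all but at most one
  library); expressed genes are nudged above the rule where sampling
  noise would break the guarantee, and the truth table is verified
  against `cpm_filter()` before the generator returns.
* `plant_enrichment()` produces target and query sets whose overlap is
  *exactly* the requested value, uniformly random otherwise; infeasible
  requests fail with the feasible range quoted.
* `simulate_marker_table()` assigns each marker to exactly one cluster,
  which makes focal fractions unambiguous; real marker tables may repeat
  genes, and the consumer handles that case by distinct-gene counting.
* `simulate_de_tables()` plants DEGs that pass both thresholds in every
  method with concordant signs (85% down by default, matching a
  knockdown dominated by downregulation), and non-DEGs that fail for a
  randomly chosen reason: non-significant everywhere, sub-threshold fold
  change, or significance in only one method.
* `simulate_transcripts_with_sites()` embeds site classes whose nominal
  expectations follow directly from the penalty table — perfect 0,
  one non-seed G:U 0.5, one seed mismatch 1.5, one-nucleotide bulge
  exactly 2.0 (the acceptance boundary), decoy 4.5 — in random flanks
  that are rejection-sampled until the scanner reports exactly the
  planted sites (capped at 1,000 attempts per transcript, then an
  explicit error, so generation time is bounded and failure is loud).
* `simulate_qpcr()` shifts the treatment target Ct by −log2(effect), so
  zero-noise recovery is exact and noisy recovery has known truth.

What passing tests on these data do *not* show: robustness to
library-size-correlated composition effects (no TMM-style factors are
simulated or applied), to expression-dependent sampling biases in the
enrichment null (the study's null is uniform over the background, and so
is ours), to marker tables with shared genes beyond the distinct-gene
convention, or to qPCR efficiency departing from 2.

## Study-shaped configuration

The acceptance script rebuilds the analysis at the study's printed
dimensions: 944 DEGs against a 2,615-gene catalogue with 268 observed
overlaps, 10,000 permutations, a 2,168-marker catalogue over 12 clusters
with 168 marker-overlapping DEGs of which 110 are focal. Two quantities
are not printed in any source and had to be fixed once: the background
size, set to 22,500 (the closed-form null mean `944 × 2615 / 22500 =
109.7` then matches the reported ~110 overlapping genes per random
list), and the focal-cluster marker count, set to 437 of the 2,168
(`944 × 437 / 22500 = 18.3`, matching the reported cluster-null mean).
Both follow from the closed-form mean, not from tuning against any test
output. Problem sizes elsewhere (500 calibration datasets at
`r = 2000`; 50 scanner seeds at 200-nt transcripts; 100 random
universes) were chosen as the smallest sizes at which the Monte-Carlo
tolerances above are meaningful.

## Known limitations

* Gene identifiers are opaque, case-sensitive strings; reconciling
  different gene-model catalogues is the caller's job via a mapping
  table.
* The scanner reports a single expectation score per site; it does not
  distinguish cleavage from translation-inhibition site geometries, does
  not model conservation across species, degradome support, or RNA
  secondary-structure accessibility.
* `call_degs()` consumes method-provided adjusted p-values; it performs
  no normalization, dispersion estimation, or DE testing of its own
  (`benjamini_hochberg()` exists for synthetic tables only).
* The permutation null is uniform over the background — no
  expression- or length-matched sampling.
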