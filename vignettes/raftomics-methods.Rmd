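---
title: "Methods: DRM/DSF partitioning statistics and the lipid-protein network"
author: "raftomics maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DRM/DSF partitioning statistics and the lipid-protein network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The experimental design the package models

Plasma-membrane proteomes can be split by non-ionic detergent treatment into
a detergent-resistant membrane fraction (DRM, enriched for sterol-dependent
microdomains) and a detergent-soluble fraction (DSF). Together with a
soluble-protein (SP) and an intracellular-membrane (IM) reference fraction,
this yields a 4-fraction x 2-genotype x 3-4-replicate label-free LC-MS
design. The scientific question is which proteins change their DRM/DSF
partitioning when a mutation alters membrane sterol composition, which
lipids change in abundance, and which lipid-protein pairs co-vary.

`raftomics` implements the full inference chain on such data: peptide
evidence → protein abundances → a bootstrap ratio-shift test with a
randomized-data FDR threshold → a co-purification filter → lipid
normalization and differential testing → a significance-filtered bipartite
lipid-protein correlation network.

## Peptide-to-protein quantitation

1. **Presence filter.** A peptide is excluded if it was measured in less
   than 70% of the samples of every fraction; equivalently, it is retained
   if at least one fraction reaches 70% presence. The rule's phrasing is
   ambiguous between "any fraction" and "all fractions"; we default to the
   *any-fraction* reading because fraction-specific proteins (e.g. pure DRM
   residents) are exactly what the downstream analysis needs, and expose
   the strict reading as `scope = "all_fractions"`. Presence is pooled
   across genotypes by default (`per_genotype` switches this).
2. **Total-ion normalization.** Within each sample, intensities are divided
   by the sample's summed intensity, making abundances fractions of total
   ion intensity. This removes injection-amount differences but makes the
   data *compositional* — see the centering note below.
3. **Median scaling and median averaging.** Each peptide profile is divided
   by the median of its quantified values across samples (removing
   peptide-specific ionization efficiency); a protein's abundance per
   sample is then the median across its peptides' scaled values, multiplied
   by the median of the peptide scales so units remain fraction-of-total.
   The two-step scheme is our operational reading of "median scaled and
   median averaged"; it is exactly reproducible by a spreadsheet
   computation, which the test suite exploits as an oracle.

Missing values are never imputed; every downstream statistic resamples or
tests observed values only. Technical injections, when present in the
design, are mean-averaged into biological replicates before any statistics.

## The ratio-shift statistic

For each protein with at least 2 quantified replicates in DRM and DSF for
both genotypes, we build per genotype a bootstrap distribution of
`log2(DRM/DSF)`: each of `n_boot = 1000` draws resamples one DRM and one DSF
replicate independently with replacement. The protein's score is

    score = (median(mut) - median(wt) - m) / s,

where the medians are bootstrap-sample medians, `s` is the pooled
IQR-based spread `sqrt((s_wt^2 + s_mut^2)/2)` with `s_g = IQR_g/1.349`, and
`m` is a cohort centering term (below). The score is zero-centered under
the null, signed (positive = DRM/DSF increased in the mutant), and monotone
in the true log2 shift at fixed noise. The scoring formula itself is this
package's definition — the underlying publication chain describes only
"bootstrapping intensities from ratios" — and it was chosen for robustness
(medians and IQRs tolerate outlier replicates) and for exact zero-centering
under label exchange.

**Cohort centering (`center = TRUE`).** Fraction-of-total normalization is
compositional: if 10% of proteins genuinely quadruple their mutant DRM
intensity, every *other* protein's normalized mutant DRM value deflates,
shifting all apparent ratios. A per-protein permutation null cannot absorb
such a cohort-wide offset. We therefore subtract the across-protein median
of the raw median-differences, identically for the observed data and for
every permutation round. On data without planted shifts the median is ~0
and the correction is a no-op; with planted shifts it restores both
calibration and power (in our simulations, without centering a 10% planted
cohort produced an offset of ≈ −1.5 score units and dozens of spurious
calls).

**Randomized-data threshold.** Null scores are generated by permuting
genotype labels within each fraction's pooled replicate values,
`n_perm = 200` rounds per protein. The default scheme is *balanced*: each
pseudo-genotype draws half its members from each true genotype, so a
genuine shift cancels in the null instead of inflating its tail. The naive
pooled shuffle (`perm = "full"`) is available but is severely conservative
when many proteins carry large true shifts, because near-original
relabelings reproduce the alternative. Balanced permutation slightly
under-represents the most unbalanced null configurations, which can make
calls mildly anti-conservative in heavily shifted cohorts; on a pure null
its calibration is exact within Monte-Carlo tolerance, which the acceptance
suite verifies directly.

Per tail, the threshold is the smallest |t| such that

    (expected null exceedances among candidates) / (observed exceedances) < FDR,

with FDR = 1%. Null exceedances are counted *strictly above* t, so a
permutation that happens to reassemble an observed configuration (an exact
tie with its own candidate) is not evidence against it. No further
multiple-testing correction is applied anywhere in the package; the
original analysis explicitly made the same choice to keep the
co-purification filter stringent, and we adopt it globally.

Zero abundances are raised to a pseudo-floor of half the smallest positive
abundance in the matrix (configurable) so log-ratios stay finite.

## Co-purification filter

A significant DRM/DSF shift is uninterpretable if the protein mostly
resides in the soluble or intracellular-membrane fraction (altered
trafficking rather than altered microdomain residence). A protein is
flagged co-purifying when (a) its highest mean abundance is in SP or IM, or
(b) a one-sided Welch t-test at α = 0.01 finds SP or IM significantly above
the better of DRM/DSF. The two rules come from different parts of the
source description and are OR-combined here; the test is one-sided because
the filter targets *higher* abundance in SP/IM, and Welch because equal
variances across fractions are implausible. Flagged significant proteins
are moved to an excluded list — reported, never silently dropped.

## Lipidomics

Positive- and negative-mode tables are combined first (shared species kept
as distinct mode-tagged rows). Normalization divides every species
(including TAG) by a per-sample denominator summed over a low-variation
reference set: non-TAG species with coefficient of variation strictly below
the median CV of all species. When strictness empties the set (exact CV
ties, e.g. several zero-variance species), the non-strict rule (CV ≤
median) is used with a warning; this fallback is forced by the tie
semantics and reduces to "all non-TAG" when all CVs are equal. "Variation"
is read as CV (`variation = "sd"` switches to standard deviation).
Triacylglycerols are excluded from denominators because storage-lipid
contamination varies independently of membrane composition.

For testing, data are z-scaled per species, shifted by the single global
constant `c = |min(z)| + 1` (recorded in the output), and log2-transformed.
Differential abundance uses Welch t-tests (α = 0.05) on the transformed
values; log2 fold changes are computed on the normalized pre-transform
scale. Class-level analysis applies the same test to per-sample class sums
of normalized values — an interpretation choice; summarizing species-level
tests is the alternative reading. A Benjamini-Hochberg column is emitted
for reference but does not gate the significance call.

Targeted annotation matches retention-time-corrected peaks against a
library at 5 ppm mass and 0.5 min retention-time tolerance. RT correction
is a piecewise-linear map through marker pairs with linear extension of the
boundary segments. Ambiguous matches resolve to the nearest candidate by
ppm, then by RT deviation — the original workflow resolved such ties by
manual chromatogram inspection, which a package cannot reproduce.

## The lipid-protein network

For every *significant* protein and every lipid with a defined log2 fold
change, the combined edge score is `lipid log2FC × protein score`. The edge
null re-pairs the two factor vectors: each round independently shuffles
both vectors (without replacement, preserving the marginals exactly) and
pairs them positionally. Note that recomputing the *full outer product* of
shuffled vectors would be a no-op — the outer-product multiset is invariant
under within-vector shuffles — so positional re-pairing is the only
faithful reading of "randomized sampling" of the two factors. The per-tail
threshold rule is shared with the protein-level calibration, scaling the
null tail proportion to the candidate edge count. The default edge FDR is
1%; the source texts print both "<1%" and "0.01%" in different places, so
the stricter value is one `fdr = 1e-4` away, deliberately not guessed as
"the correct one".

Significant edges form a bipartite igraph graph: protein nodes carry
localization, DRM/DSF direction, group and PTM annotations (defaulting to
"unknown"); lipid nodes carry class and fold-change direction; node degree
counts incident significant edges. Subnetwork extraction keeps edges whose
protein's curated group has significant members in *both* mutants and
splits each mutant's subnetwork by DRM/DSF direction; proteins absent from
the group map become singleton groups.

## The synthetic-data generator

Because the study's raw data are not deposited, the generator *is* the
package's test bed. It emulates:

* log-normal protein baselines (median 1e6 ion-intensity units, sdlog 1)
  and per-peptide ionization efficiencies (sdlog 0.7), constant across
  samples;
* per-protein fraction profiles: membrane proteins place 80% of their mass
  in DRM+DSF with a random split; planted co-purifying proteins place 60%
  in their SP/IM top fraction;
* planted DRM/DSF shifts: the mutant DRM intensity (only) is multiplied by
  `2^(±shift_log2)` — the direction convention follows expressing ratios
  relative to DRM;
* multiplicative log-normal noise at a given CV (default 0.2, a realistic
  label-free replicate CV);
* intensity-dependent dropout: P(missing) is a decreasing logistic in
  log10 intensity (midpoint 4.5, steepness 2), yielding ≈ 20% missingness
  overall — typical of label-free data. The generator reports the
  analytically integrated expected dropout rate and its standard error so
  tests can compare realized against expected;
* lipid tables in two ionization modes with class-typical primary modes,
  ~10% dual-mode species, planted log2 fold changes, and always-present
  TAG species;
* optional lipid-protein *coupling*: planted protein shifts and lipid fold
  changes share a per-replicate latent factor (sd 0.1) drawn from a
  seed-derived stream, so true pairs co-vary and their combined scores are
  detectable.

What the generator does **not** emulate: correlated peptide noise within a
run, retention-time-dependent intensity drift, isotope interference,
protein-inference ambiguity from shared peptides, and non-logistic
(e.g. MNAR-at-random mixtures of) missingness. A green recovery test
therefore establishes that the chain recovers planted structure under the
stated noise model — not that it is robust to every pathology of real
LC-MS data.

Defaults are the stated world of the acceptance suite: 4 replicates, noise
CV 0.2, 10% shifted at |log2| = 2, 15% co-purifying, 5 lipid replicates.
Determinism is end-to-end: one seed reproduces byte-identical tables,
results and manifests.

## Numerical choices and degenerate inputs

* Bootstrap medians/IQRs use type-7 quantiles (R's default).
* Zero bootstrap spread with unequal medians yields a signed infinite
  sentinel score, flagged rather than dropped; infinite scores exceed any
  finite threshold but are never used as threshold candidates.
* Proteins with fewer than 2 quantified replicates in any required
  fraction are marked untestable and excluded from calibration.
* A lipid with zero variance transforms to a flat `log2(c)` profile and is
  flagged.
* Samples with no quantified peptides are dropped with a warning during
  normalization.
* `n_boot = 1000` and `n_perm = 200` balance Monte-Carlo error in the
  threshold (stability under doubling `n_perm` is tested) against runtime;
  the permutation inner loop is implemented in C++ and uses R's RNG, so
  `set.seed()` governs everything.

## Known limitations

* The score is defined at the protein level; bootstrapping peptide-level
  intensities is a possible extension the current design deliberately
  avoids (peptide counts per protein vary, which would entangle score
  scale with coverage).
* Balanced permutation trades a small anti-conservative bias under very
  heavy alternative contamination for non-degenerate power; the pure-null
  calibration is exact within Monte-Carlo tolerance.
* With only 3-4 replicates per cell the bootstrap ratio distribution is
  coarse (at most 16 distinct ratio pairs); scores are meaningful as
  ranking/threshold statistics, not as calibrated effect sizes.
* Class-level lipid tests treat class sums as the unit; a species-level
  summary aggregation would weight species differently.
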