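---
title: "Methods: from a developmental expression atlas to GWAS gene-set enrichment"
author: "atlasEnrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from a developmental expression atlas to GWAS gene-set enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the statistics it implements,
the choices that were genuinely open, and what the validation on synthetic
data does and does not show.

# The scientific setting

A developmental gene expression atlas (dGEA) measures transcript abundance
(TPM) for tens of thousands of genes across many tissues and ordered
developmental stages, with biological replicates per tissue × stage cell.
The working hypothesis is that genomic variants influence complex traits by
modifying gene expression in particular tissues or at particular
developmental windows. The pipeline therefore (1) defines, from the atlas,
gene sets that characterize a tissue or a stage; (2) summarizes how those
genes move through development; and (3) asks whether GWAS association
signal concentrates near those genes.

# Expression processing

All inference operates on `log2(TPM + 0.25)`. The pseudocount puts zeros at
a finite floor of −2 log2 units; TPM is a within-sample relative measure,
so columns of a valid atlas sum to 10^6.

QC filters, in the fixed order genes → samples → tissues:

* genes kept when TPM ≥ 0.1 in at least one sample (the boundary is
  inclusive: removal applies to genes *below* 0.1 everywhere);
* samples removed when *strictly fewer* than 40% of the current genes are
  expressed at TPM ≥ 0.1;
* tissues removed when fewer than 3 samples survive.

The same strictly-below reading is applied consistently to both
thresholds. Cohort-level outlier removal after sample clustering has no
closed-form rule, so it is exposed only as an explicit exclude-list
(`excludeSamples()`), never inferred. Each filter is idempotent, and the
composition is pinned by tests. For sample-level exploration the package
provides the 6000 top-variance genes (SD of TPM, ties broken
lexicographically so output is deterministic) and the 1 − Pearson-r sample
distance.

# Specificity calling

**Tau.** For a per-group profile the index
τ = Σ(1 − xᵢ/max x)/(N − 1) ∈ [0, 1] is invariant to positive rescaling.
`tissueTau()` evaluates it on per-tissue *median* TPM transformed
`log2(x + 1)`: medians resist replicate outliers, and the +1 transform
keeps the profile non-negative so τ stays in range.

**Tissue-specific sets.** One tissue is compared against all others. The
published analyses of this kind fit count models (e.g. edgeR) on raw
counts; this package's inputs are TPM, where a count likelihood is not
available, so the comparison is a two-sided Welch t-test on
`log2(TPM + 0.25)` with the log2 fold change as the difference of group
means. Because the tissue-specific call is *rank-based* — the top 5% of
upregulated genes by FDR — the calling is robust to the exact test family;
what matters is the ordering. The 5% quota uses a ceiling
(101 genes tested → 6 called) and a fixed tie-break chain (FDR, then p,
then descending log2FC, then gene id) so output is deterministic. Whether
the 5% denominator should be all tested genes or only genes expressed in
the target tissue is ambiguous; this package uses all genes tested in the
comparison.

**Stage-specific sets.** Within one tissue, one stage vs the rest, with
*strict* thresholds log2FC > 2 and FDR < 0.05 and at least 3 samples on
each side. Stage labels come from the sample metadata as given: if time
points should be pooled into named stages, that pooling belongs in the
metadata, not in the caller. Multiple testing is Benjamini–Hochberg
throughout.

# Trajectory clustering

Per-stage mean profiles of `log2(TPM + 0.25)` are row-standardized to mean
0 and unit *population* SD (constant rows are dropped and reported — they
have no shape). Fuzzy c-means then minimizes Σ u_ik^m d²(x_i, c_k) by
alternating the membership update u_ik = 1/Σ_j (d_ik/d_ij)^{2/(m−1)} and
the u^m-weighted centroid update, stopping when the objective moves less
than 1e−6. The objective is provably non-increasing under this scheme and
the implementation asserts it each sweep. A point coinciding with a
centroid receives membership 1 there (split over exact ties) — the
standard degenerate rule.

Choices worth recording:

* **m = 2.** Soft-clustering folklore estimates m from the data; the
  canonical default is 2 and it is exposed as a knob.
* **Initialization** draws K data rows under an explicit seed;
  `nstart` seeded restarts keep the best objective. Cluster labels are
  arbitrary across seeds, so all tests compare partitions by adjusted Rand
  index, never by label identity.
* **K selection** scans K and reports the minimum pairwise centroid
  distance. Once K exceeds the number of real trajectory shapes, two
  centroids fall into one cluster and the curve collapses; the suggested K
  (largest K before the steepest drop) is reported, not enforced.
* Distances are Euclidean on the standardized trajectories.

# Co-expression module comparison

Module *detection* (WGCNA-like clustering, ICA/PEER-like factorizations)
is out of scope; assignments are inputs, and may overlap. Two module
catalogues are compared by the Jaccard module-sharing index
|a ∩ b| / |a ∪ b| over all pairs. A module's behaviour over development is
summarized by its eigengene — the first right singular vector of the
gene-standardized log-expression submatrix, signed to correlate
non-negatively with the module's mean profile — and associated with each
stage by the Pearson correlation against the stage's one-hot sample
indicator (point-biserial), p from the t transform of r, BH across all
(module, stage) pairs. Whether such stage heatmaps are built from
eigengenes or module mean profiles is a convention; for a coherent module
the two are nearly identical, and the eigengene is the standard choice.

# GWAS gene-set enrichment

SNPs are assigned to every gene whose ±20 kb window (gene body plus
symmetric flank, strand-agnostic, clamped at position 1, inclusive
1-based interval test) contains them; a gene set's SNPs are the *union*
over its genes, so overlapping windows never double-weight an effect. The
set statistic is T_sum = Σ b², the sum of squared marginal SNP effects.

The null is permutation-based: `nPerm` random SNP subsets of matched size
m_g drawn uniformly without replacement from all GWAS SNPs, and

p = (1 + #\{T_perm ≥ T_obs\}) / (1 + nPerm).

Two deliberate deviations from the literal "proportion greater than
observed": ties count *against* significance (≥, conservative), and the
+1/+1 pseudocount prevents p = 0 — the smallest attainable value is
1/(nPerm + 1). Because the permuted subsets do not depend on effect
values, p is exactly invariant to rescaling all effects by a nonzero
constant; whether b is a raw allele-substitution effect or a standardized
effect is therefore immaterial to inference (asserted by test). A
gene-matched null (`nullMode = "gene"`: random gene sets of matched gene
count, each with its own windows) is provided as an alternative, since the
two nulls differ when genes vary in SNP density. Sets whose windows
contain no SNP are untestable: reported with NA statistics and excluded
from the BH correction.

# The synthetic generator

`simulateAtlas()` emulates the tissue × stage × replicate design: per-gene
log2 baselines ~ Normal(3, 2²); planted tissue-specific genes gain 4 log2
units in one tissue; planted stage-specific genes gain 4 log2 units at one
stage; trajectory genes follow fixed archetype curves (monotone up,
monotone down, single peak, single dip, then raised cosines) scaled to
unit amplitude and cycled in fixed order; Gaussian noise (SD 0.3 by
default) is added; values are exponentiated and each column renormalized
to sum to 10^6. Defaults — 6 tissues, 7 stages, 5 replicates, 1000 genes,
50 specific genes per tissue — are a desk-scale rendition of a real
atlas's design chosen once for the validation suite and not revisited.

The noise model is log-normal on the analysis scale rather than
negative-binomial counts: the downstream statistics consume TPM, and a
log-scale Gaussian keeps every planted effect exact in the units being
tested. Two honest consequences: (i) TPM renormalization slightly shrinks
planted log-fold-changes (a few percent at these sizes, since planted
genes are a minority of the column mass); (ii) real RNA-seq features —
count overdispersion at low expression, library-composition artifacts,
correlated genes, batch effects — are absent, so passing tests demonstrate
the *statistics* are implemented correctly and calibrated under their own
assumptions, not that the pipeline is robust to real-data pathologies.

`simulateGenomeGwas()` tiles genes deterministically (10 kb bodies, 30 kb
gaps, 3 chromosomes by default) so window overlaps are analytically
predictable; SNP positions are uniform over the covered genome and effects
are Normal(0, 0.1²), inflated to a configurable SD inside the windows of a
chosen gene set. The Gaussian variance-inflation planting is a calibration
device, not a claim about any species' genetic architecture; no LD, allele
frequencies or genotypes are modelled, matching the LD-free permutation
null.

# Validation problem sizes

The test suite and `scripts/acceptance.R` run, per seed: calibration of
the permutation test with 500 random 10-gene sets against a null GWAS of
20,000 SNPs over 1000 genes at nPerm = 1000 (the p < 0.05 rate must sit in
the exact 95% binomial interval around 0.05); power with a 50-gene set at
3× effect SD against 20 size-matched decoys over 20 replicate simulations;
exhaustive-enumeration agreement on a 12-SNP, set-size-3 fixture
(C(12,3) = 220 subsets) at nPerm = 200,000; planted-gene recovery and
null-atlas false-call rates for the specificity caller (20 null
replicates); a 1000-profile tau oracle at 1e−12; 4-archetype recovery at
noise SD 0.2 over 10 seeds with the K-selection drop between K = 4 and 5;
an exact window-mapping oracle over 50 genes × 5000 SNPs; and bit-identical
rerun checksums for the full pipeline.

# Known limitations

* The Welch-on-log-TPM test substitutes for count-based DE; with very few
  replicates, count models borrow strength across genes and will be better
  powered on real counts.
* The permutation null ignores LD: in real GWAS, clumped or LD-pruned
  summary statistics are advisable, or an LD-aware method where LD
  reference panels exist.
* Eigengene-based stage association assumes a module is coherent enough
  for one component to summarize it.
* The minimum-centroid-distance heuristic suggests K; in flat or noisy
  data the curve may lack a clean drop, and inspection remains advisable.
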