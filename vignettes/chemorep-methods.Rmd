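---
title: "Methods: chemoreceptor repertoire analysis from bulk RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemoreceptor repertoire analysis from bulk RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemorep)
```

## The scientific problem

Vertebrate olfactory organs express large families of chemosensory
receptor genes — in teleosts the *or*, *taar*, *ora/V1r* and *olfC/V2r*
families — under the one-receptor-one-neuron rule: each mature olfactory
sensory neuron (OSN) expresses a single receptor gene. Tissue-level RNA
abundance of a receptor therefore scales with the number of neurons that
chose it, and a bulk RNA-seq profile of the olfactory mucosa (OM) doubles
as a census of the neuronal repertoire. `chemorep` implements the
analysis chain this idea supports: depth- and length-normalized
expression quantification, classification of genes into high- and
low-expressed classes, family-level repertoire statistics, calibration of
RNA abundance against microscopy counts, cross-species comparison of
ortholog expression, and quantification of the spatial distribution of
labeled cells — all exercised against a synthetic-data generator that
encodes the one-receptor-one-neuron structure with known ground truth.

## Quantification

Fragment counts are transformed to FPKM (fragments per kilobase of
transcript per million fragments):

$$\mathrm{FPKM}_{g,r} = \frac{C_{g,r} \times 10^9}{L_g \times N_r}$$

with $C_{g,r}$ the fragment count of gene $g$ in replicate $r$, $L_g$
the gene length in bp and $N_r$ the per-replicate total. $N_r$ is the
column sum of the supplied count matrix — the total of gene-assigned,
uniquely mapped fragments — so the transform is reproducible from the
count matrix alone. The annotation stores a single `length_bp` per gene
and leaves its derivation (union-exon vs transcript-model length) to the
user, since either convention can be fed in. A useful conservation
identity, asserted in the test suite, is that
$\sum_g \mathrm{FPKM}_{g,r} \cdot L_g = 10^9$ for every replicate.

Per-gene summaries are the arithmetic mean across replicates and the SEM
with the $n-1$ denominator, the appropriate choice at the small
replicate numbers (here $n = 3$ by default) the design targets.

## HE/LE mixture classification

Log10 expression of bulk tissue RNA-seq is bimodal: a low-expressed (LE)
component dominated by transcriptional noise and a high-expressed (HE)
component carrying the functional transcriptome. `fit_em()` fits a
two-component univariate Gaussian mixture by expectation-maximization to
`log10(mean FPKM)` of every gene with at least one fragment count in at
least one replicate (`select_fit_set()`); all-zero genes cannot enter
the fit set, so no pseudocount is needed. Replicate-mean expression is
the default fit target; per-replicate fitting is possible by calling
`fit_em()` on a single column.

Numerical choices:

* **Initialization** is deterministic — the sample is split at its
  median and component moments taken from each half — so the fit is
  reproducible without a random start and invariant to input order.
* **Convergence**: relative log-likelihood change below `tol = 1e-8`,
  capped at `max_iter = 1000`; the log-likelihood trace is stored and is
  non-decreasing by construction of EM.
* **Variance floor**: component sd is clamped at `1e-6` to exclude
  degenerate single-point spikes.
* **Labeling**: the component with the larger mean is HE.

A gene is called HE when its posterior probability of HE membership is
at least 0.25 (inclusive). The deliberately asymmetric threshold favors
sensitivity for the HE class; with well-separated components the HE
fraction recovers the generating mixture weight within a few percentage
points, which the test suite checks at $n = 20000$.

## Repertoire statistics

`family_profiles()` aggregates cumulative FPKM per chemoreceptor family
per replicate, then reports mean ± SEM, each family's share of the
four-family repertoire (gene counts) and of cumulative expression, and
the per-gene average. Reported shares are rounded half-up to one
decimal, matching the conventional presentation.

The equal-expression null — every receptor gene expressed at the same
level — is tested with a Pearson chi-squared statistic. Observed values
are replicate-mean cumulative FPKM used directly as quantities, with
expected values proportional to family gene counts (or uniform within a
family for `per_gene_chi2()`). Because FPKM is not a count, the
statistic scales linearly with the overall FPKM magnitude; this is a
documented property (asserted in the tests), and the statistic and df
are always reported alongside the p-value rather than the p-value alone.

## RNA-to-neuron calibration

`spearman_test()` assesses the correlation between per-receptor mean
FPKM and mean ISH-labeled cells per section. For tie-free samples with
$n \le 9$ (9! = 362880 permutations, sub-second) the two-sided p-value
is exact: the fraction of all rank permutations with $|\rho|$ at least
the observed value. This exact convention reproduces the reference
two-sided p-values at both $n = 7$ (0.00675 for $\Sigma d^2 = 4$) and,
via the $t$-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$, at
$n = 17$ (0.00059 at $\rho = 0.745$). Ties break the exchangeability of
the simple permutation null under average ranks, so tied data always use
the $t$-approximation, with a warning. The two conventions agree
closely in the bulk of the distribution; in the far tail the
$t$-approximation is anti-conservative relative to the exact count,
which the test suite documents as a band (95 of 100 random $n = 9$
datasets within 25% relative, all within 40%).

`fit_calibration()` regresses log10 cells/section on log10 FPKM — both
span orders of magnitude, so a power law is the natural model — and
`predict_cells()` inverts it. `estimate_total_cells()` multiplies mean
cells/section by the section count and floors the result: a lower bound,
since no stereological correction is attempted.

## Cross-species comparison

Ortholog pairs are retained when they are one-to-one, have amino-acid
identity of at least 40% (inclusive), and are expressed in at least 2 of
the pooled tissue-replicate columns across both species. "Expressed" is
read as FPKM strictly above `min_fpkm_expressed = 0`, the weakest
consistent definition; it is a parameter, not a constant. The retained
matrix is transformed as `log10(FPKM + 1)` — the offset keeps zero
expression at zero on the log scale, which is also what makes the
marker-heatmap category bounds (0 < low ≤ 0.63 < moderate ≤ 1.82 <
high) well defined — and each pair's row is z-scored across samples.
Transform-then-standardize order is a package decision; the reverse
order is not meaningful for z-scores of raw FPKM spanning decades.

PCA is the eigen-decomposition of the correlation matrix among samples
(samples as variables, pairs as observations): eigenvalues sum to the
number of samples, per-component variance shares to 100%. Loadings are
sign-fixed so each component's largest-magnitude entry is positive;
sample coordinates are loadings scaled by the square root of their
eigenvalue. On synthetic two-species data generated with a species
divergence larger than the tissue effect, PC1 separates species and PC2
separates tissues, mirroring the counter-intuitive species-first
ordering seen in real zebrafish–mouse comparisons.

Hierarchical clustering uses Euclidean distances with Ward's method.
The default linkage applies the classical Ward criterion
(squared-Euclidean Lance–Williams update, `hclust` method `ward.D` on
squared distances); the unsquared-height convention (`ward.D2`) is a
switch. Node support is the fraction of 100 bootstrap dendrograms —
ortholog pairs resampled with replacement, the only exchangeable unit —
containing the identical leaf set under some node; support of 1 is
reported as ">0.999" following the convention that a finite bootstrap
cannot certify certainty.

## Spatial quantification

Raw per-cell measurements in arbitrary units are normalized to three
relative axes: laminar height `h_rel` (soma-to-basal-border distance
over local epithelium thickness; 0 = most basal, 1 = most apical),
radial position `r_rel` (distance from the lamellar apex over the
radial extent of the section — the exact distal landmark is left to the
measurement protocol and enters only through the `radial_extent`
field), and section depth `z_rel` (section index over section count).
Distributions are summarized as 10-bin histograms on [0, 1]
(right-closed, first bin including 0; bin count configurable — the
reference presentations do not fix one). `enrichment_summary()` adds a
mean, median and an exact two-sided sign test against the uniform
midpoint 0.5; the sign test is an explicit convenience extension beyond
the histogram presentation, flagged as such in its documentation.

## The synthetic-data generator

`generate_synthetic()` emits a count matrix, annotation, ISH counts,
spatial records and a toy two-species ortholog set, with ground truth,
under one coherent model:

1. Per-receptor neuron counts are drawn from a heavy-tailed law —
   exponential by default, echoing the roughly exponential abundance
   distributions seen across receptor repertoires; a Pareto (power-law)
   option is available. Per-family mean neurons per receptor default to
   400 (or), 150 (taar), 140 (ora), 320 (olfC), chosen so that a
   ~300-receptor repertoire yields the order of 10^5 OSNs and so that
   or/olfC neurons are enriched relative to taar/ora after gene-count
   normalization, as in the zebrafish OM.
2. Receptor RNA mass = neurons × per-neuron expression (0.04 mass
   units, log-normal noise of 0.2 dex), putting the four families at a
   fraction of a percent of the transcriptome. Background genes (20000)
   draw log10 mass from a two-component mixture (HE weight 0.77, means
   −1.5 and 1.0, sds 0.6 and 0.9), so roughly three quarters of nonzero
   genes are HE-labeled.
3. Replicate counts are multinomial over mass × length at 25 million
   fragments (about 70% of a typical 36M-read library mapping
   uniquely), with 0.03 dex replicate jitter — giving pairwise replicate
   Spearman correlations near 0.98–0.99. Gene lengths are uniform on
   500–4000 bp.
4. ISH counts per gene are Poisson per section (60 sections, sampling
   fraction 0.01 of the organ's neurons per section, matching
   counts of roughly 0.5–10 cells/section).
5. Spatial records realize configurable apical, central and dorsal
   biases through beta- and exponentially-weighted draws, re-expressed
   as raw measurements so the normalization path is exercised.
6. The ortholog toy set models log10 expression of 400 pairs across 14
   samples (zebrafish OM ×3 and brain ×3; mouse OM ×3, VNO ×3, brain
   ×2) as gene baseline + per-species divergence (sd 1.0) + per-tissue
   effect (sd 0.5) + noise (sd 0.1); species divergence deliberately
   exceeds the tissue effect.

Each output table draws from its own seeded substream, so resizing one
table leaves the others bit-identical at a fixed seed. What the
generator does *not* emulate: mapping artifacts and multi-mapping
(counts are assigned perfectly), gene-correlated library composition,
cross-hybridization in ISH, and section-to-section anatomy. Passing
recovery tests therefore demonstrate that the estimators invert the
generative model they assume — not that real tissue obeys it.

## Problem sizes and degenerate inputs

The default test-scale runs use 20314 genes × 3 replicates at 25M
fragments (seconds per simulation), EM recovery at n = 20000, exact
Spearman enumeration up to n = 9, and 100-replicate bootstraps on
14-sample matrices; the full suite runs in well under a minute. Degenerate
inputs fail loudly and early: all-zero count matrices, zero-variance
mixture input, fewer than 3 correlation pairs, non-positive values on
log scales, zero epithelium thickness, and out-of-range table cells are
all rejected with messages naming the offending gene, cell or row.

## Known limitations

* The chi-squared tests inherit the FPKM scale; their p-values are not
  invariant to re-normalization of expression units.
* The exact Spearman test covers tie-free data only; heavily tied cell
  counts at small n fall back to an approximation that is
  anti-conservative in the far tail.
* The calibration line assumes a single power law across receptors;
  family-specific per-neuron expression differences would bias the
  organ-level inversion.
* Bootstrap node support resamples ortholog pairs; it does not model
  uncertainty in the ortholog assignments themselves.
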