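---
title: "Methods: multicellular program discovery in pooled-donor snRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multicellular program discovery in pooled-donor snRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(villagefactor)
```

## The analysis problem

In a "village" design, post-mortem tissue from roughly twenty donors is
pooled and processed as a single snRNA-seq library. Donors are recovered
computationally: each nucleus carries reads over hundreds of transcribed
SNPs, and the combination of observed alleles identifies its donor of
origin. The design has a second benefit: because most droplet doublets
combine nuclei from two *different* donors, they can be recognised by
their mixed allele content. With donors resolved, expression can be
aggregated per donor and cell type, and latent factor analysis across the
concatenated per-cell-type matrices can reveal *multicellular programs* —
coordinated expression variation spanning neurons and glia whose donor
scores track age and disease status. This package implements that whole
chain at desk scale, together with a seeded synthetic-data generator that
stands in for the controlled-access study data.

## Donor demultiplexing

Per nucleus, the likelihood of donor $d$ is
$\sum_{s} \log P(a_s \mid g_{ds}, \varepsilon)$ over observed alleles
$a_s$, with the linear error-contamination model
$P(\text{alt} \mid g, \varepsilon) = (1-2\varepsilon)\,g/2 + \varepsilon$.
This is exact at homozygous dosages and unbiased at $g = 1$. Doublets are
scored by evaluating every donor pair under a 50/50 mixture (dosage
$(g_1+g_2)/2$); a pair must beat the best singlet by `doublet_margin`
(default 5 nats) to call a doublet, and singlet calls below
`margin_threshold` (default 2 nats) are reported ambiguous. Both
thresholds are conservative, explicit defaults — the underlying assignment
tools do not publish a comparable margin rule. Observation counts are
capped at one read per SNP per nucleus by default, so PCR duplicates do
not masquerade as independent evidence.

For a pool with donor proportions $p$, the expected cross-donor doublet
fraction is $1-\sum_d p_d^2$ — 0.95 for twenty equal donors:

```{r}
expected_cross_donor_fraction(rep(1/20, 20))
```

## Metagene (paralog family) quantification

High-homology paralogs (C4A/C4B being the canonical example) yield reads
that multi-map with low quality, so their UMIs cannot be assigned to a
single gene. The association rule: a UMI belongs to one gene if at least
one of its reads maps uniquely with high quality; otherwise it is
associated with the union of its multi-hit genes. Families are gene sets
that recur as association sets with at least `min_support` UMIs (default
50) and purity at least `min_purity` (default 0.95), where purity is the
fraction of ambiguous UMIs touching any member whose set is exactly the
candidate. The source analysis gives no numeric criterion for
"consistently"; these two thresholds make it explicit and testable.
Ambiguous UMIs that match a family count once to its joint row;
inconsistent ones (strict sub/supersets) go to a discarded bucket rather
than being fractionally allocated, because nothing in the data supports a
proportional split. Total UMIs are conserved by construction, and the
joint counts can be validated against a collapsed single-copy reference,
which our generator reproduces exactly when no uniquely-mapping reads are
planted.

## Normalisation, pseudobulk and donor QC

Counts are variance-stabilised to Pearson residuals
$r = (x-\mu)/\sqrt{\mu + \mu^2/\theta}$ with $\mu_{gc}$ the product of the
cell's depth and the gene's pooled proportion. Per-gene $\theta$ comes
from a pooled method-of-moments estimate regularised by a rolling median
of $\log\theta$ along expression; genes below a $10^{-4}$ pooled
proportion inherit the global median. This captures the regularisation
intent of the standard single-cell normalisation without reproducing its
exact kernel regression. Residuals are clipped at $\pm\sqrt{n_\text{cells}}$.

Pseudobulk matrices sum either raw counts (`raw_sum`, used for expression
ranking and QC) or residuals (`residual_sum`, used for factor analysis)
per donor within each cell type, and the mode is carried on the object so
stages cannot be fed the wrong flavour.

Donor QC uses conformity scores: per cell type, donor columns are scaled
to 100,000 UMIs, genes with at least 10 per 100,000 in at least one donor
are kept, kept rows are merged across types, and each donor's conformity
is the median of its pairwise Pearson correlations (of `log10(x+1)`
values) with all other donors. The `+1` keeps zeros finite; the source
text says only "log10-scaled". Conformity scores are converted to
modified z-scores $M_i = 0.6745\,(x_i-\tilde x)/\mathrm{MAD}$ (unscaled
MAD), and donors are excluded if they have under 1,000 UMIs in any cell
type, $|M|>5$ on expression conformity, or $|M|>15$ on cell-type
proportion conformity. All three thresholds are configurable and default
to those values.

## Latent factor model

Residual pseudobulk per cell type is filtered to the top 50% of genes by
scaled raw expression, gene names get a cell-type suffix
(`ACAP3_astrocyte`), and the blocks are column-bound into one donor ×
(gene, cell type) matrix. Factors are inferred by coordinate-ascent
variational Bayes for the Gaussian factor model
$X \approx S L^\top + E$ with automatic relevance determination:
independent Gamma-prior precisions per factor shrink surplus factors to
zero, and per-feature Gamma noise precisions let features differ in
residual scale. Hyperpriors are broad ($10^{-3}$ for all Gamma shapes and
rates). Iteration stops when the relative change of the evidence lower
bound falls below `tol` ($10^{-6}$) or after `max_iter` (1000)
iterations; the ELBO trace is stored and is non-decreasing, which the
test suite asserts step by step. A truncated-SVD initialisation plus a
seeded $10^{-3}$ jitter makes fits reproducible. `method = "pca"` gives a
deterministic truncated-PCA oracle used in the oracle-equivalence tests.
Features are centered, not variance-scaled, because residual inputs are
already variance-stabilised. Each factor is oriented so its
largest-|loading| feature is positive — a fixed convention replacing the
ad hoc sign flips such analyses otherwise need. The default `k = 10`
matches the headline configuration of the source analysis; because of the
relevance prior, `k` is an upper bound rather than a model choice.

Donor scores are summarised with `quantile_normalize()`
($\Phi^{-1}(\mathrm{rank}/(n+1))$, ties averaged — display only, since
every downstream statistic is rank-based or refit), adjusted for age by
OLS residuals, and tested with Spearman correlation, the two-sided
Wilcoxon rank-sum test, or a joint OLS on age, sex and case status. The
two rank tests enumerate their exact null at small sizes ($n \le 10$ for
Spearman, both groups $\le 8$ for the rank-sum) and otherwise use the
standard $t$ and tie-corrected normal approximations, without continuity
correction; the exact paths are pinned against brute-force enumeration in
the tests.

## Enrichment

Preranked GSEA on gene loadings: hits advance a running sum by
$|m|^p/N_R$ (weight $p = 1$, the conventional default), misses retreat
uniformly, and the enrichment score is the extremal deviation, with exact
ties in magnitude resolved toward the positive extremum. Metric ties keep
stable input order. The null is gene-label permutation (10,000 by
default), NES divides by the mean same-sign null, and FDR uses the
sign-stratified NES-ratio construction of the original method (a BH
alternative is exposed). Leading-edge genes are the members at or before
the positive peak (or at/after the negative one). Set-size limits default
to 10–500, stated explicitly because the source does not restate them.

## Consensus NMF programs

Within one cell type, cells are filtered (fewer than 200 genes or 200
UMIs removed, then genes in fewer than 10 cells), counts are scaled to
unit gene variance (switchable to raw), and for each candidate $k$ the
package runs seeded HALS NMF restarts (default 20; the reference protocol
uses more, but 20 keeps desk-scale runtime while leaving the consensus
stable), L2-normalises all component spectra, drops outlier components
whose mean distance to their nearest third of neighbours exceeds
`outlier_distance` (0.3), clusters the rest with seeded k-means (10
restarts), and takes cluster medians as consensus spectra. Usages are
refit by non-negative least squares and normalised so each cell sums
to 1. Stability is the mean silhouette of the component clustering;
reconstruction error is the relative Frobenius error. The selection
report lists both across `k_values` (default 3–30); the stability
maximum is chosen by default but the full table is returned for manual
selection, which is how such reports are used in practice. Donor-level
program scores are per-donor means of normalised usages times a
per-program orientation (±1), mirroring the convention of sign-flipping
a program so that "more of the program" points the same way across
analyses.

## The synthetic village generator

Every stage above is exercised against `simulate_village()`, which plants
known structure and returns full ground truth:

* **Donors** — ages uniform on 22–97, balanced case/control, genotypes at
  200 independent SNPs with MAF uniform on 0.1–0.5 (linkage is irrelevant
  to the demux likelihood, so independent sites suffice).
* **Counts** — negative binomial ($\theta = 10$, configurable to the
  Poisson limit) around depth × donor-type profile; log-mean carries
  baseline + planted program effects. Default depth 20,000 UMIs per
  nucleus and a Poisson-varying ~40 nuclei per donor per type (scaled by
  unequal cell-type abundances across seven cortical cell types).
* **Programs** — per-donor score = age_slope × (age − mean) + case_shift ×
  case + noise; sparse Gaussian loadings per cell type. Defaults: slope
  −0.02/yr, shift −0.5, score noise at half the structured score sd.
* **Doublets** — a droplet captures a second nucleus from the same
  village with probability `doublet_rate` (5%); doublets mix the two
  donors' expected profiles 50/50 and pool their SNP evidence.
* **Donor heterogeneity** — a lognormal per-donor × gene multiplicative
  effect (sdlog 0.4) shared across cell types models idiosyncratic
  biological variation between individuals.
* **Outliers** — aberrant donors get a much stronger lognormal
  perturbation (sdlog 1.0) on 30% of genes, renormalised so library size
  is unchanged: the expression *pattern* is wrong, not the depth,
  emulating agonal-spectrum profiles.

### Why these defaults

The donor-exclusion statistic is scale-free: modified z-scores divide by
the MAD of the conformity scores, so what matters is not how noisy the
data are but *which source of donor-to-donor heterogeneity dominates and
what shape it has*. In the study's regime, measurement noise is small
compared with symmetric biological donor heterogeneity, which in turn is
dwarfed by genuinely aberrant profiles. The defaults reproduce that
ordering: enough nuclei and depth that cell-yield sampling noise is
subordinate; a donor effect whose realised per-donor magnitude (a mean
over 1000 genes) is nearly Gaussian; planted programs subtle enough that
age-extreme donors are not conformity outliers. Under these conditions
the planted aberrant donors sit at $|M| > 20$ while unperturbed donors
stay below 5 across seeds, and proportion conformity stays far inside
its threshold of 15.

The factor-recovery benchmark (`scenario_factor_recovery()`) is a
deliberately different planting: 180 donors, three cell types, and one
strongly loaded cross-cell-type program (loading sd 0.5 on 20% of genes,
score noise at half the structured sd — signal-to-noise 2 at the score
level). A program subtle enough to leave QC nulls clean is, at 180
donors, below the spectral detection threshold of any unsupervised
factorisation — the singular value bulk is flat and no method could find
it — so the recovery benchmark plants a resolvable factor, and the QC
benchmark keeps the subtle default. This is a real trade-off of the
desk-scale setting, not of the method: at the study's feature and donor
counts both conditions hold simultaneously.

### What the generator does not emulate

Ambient RNA, batch effects between villages, cell-type
misclassification, genotype imputation error, linkage between SNPs,
read-level alignment artefacts and empty droplets are all absent.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated model, not robustness to every artefact of
real data.

## Numerical choices and degenerate inputs

* All-zero genes get zero residuals; zero-variance donors make
  conformity fail loudly rather than silently.
* MAD = 0 is an error in `modified_z()` (the statistic is undefined).
* A nucleus with no SNP observations is `ambiguous` with a
  "no evidence" note, not an exception.
* Exact magnitude ties in the GSEA running sum resolve to the positive
  extremum; metric ties keep input order.
* k-means consensus clustering and all NMF restarts derive their seeds
  from the user seed; identical seeds give identical fits.
* `all_permutations()` enumeration is chunked above $n = 8$ so the exact
  Spearman path stays within memory at $n = 10$.

## Problem sizes

The shipped tests and benchmarks run, per scenario, at: 40 donors ×
7 cell types × ~40 nuclei × 1000 genes (QC); 60–180 donors × 3 cell
types for factor recovery; 20-donor villages with ~10,000 doublets for
the cross-donor fraction; universes up to a few hundred genes for
enrichment; and 60–80 cells × ~40 genes for consensus NMF. These sizes
were chosen so each property is measured with comfortable statistical
margin while a full run stays in the minutes range on one core.

## Known limitations

The demultiplexer fixes the doublet mixture at 50/50 rather than
estimating it; the factor engine assumes a complete donor × feature
matrix (donors missing a cell type are dropped, consistent with the
UMI-minimum exclusion upstream); enrichment FDR at few gene sets is
coarse because the observed-NES denominator is coarse; and consensus-NMF
program identity is only defined up to the clustering, so downstream
interpretation should always start from the stability/error report
rather than a single run.
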