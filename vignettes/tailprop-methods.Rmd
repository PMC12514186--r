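---
title: "Methods: models, estimators and design choices in tailprop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in tailprop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailprop)
```

`tailprop` identifies genes associated with disproportionate elongation of
individual tail vertebrae by intersecting cross-species and intra-species
differential-expression contrasts, and implements the morphometric
measurements that define the phenotype. This vignette is the package's
account of its statistical machinery: the models, the estimators, the
numerical choices, and what the synthetic validation does and does not
establish.

## The count model and its normalizations

Counts are modelled per gene as negative binomial with log link,

$$K_{gj} \sim \mathrm{NB}\!\left(\mu_{gj},\ \alpha_g\right), \qquad
\mu_{gj} = s_j\, e^{o_{gj}}\, q_{g,\mathrm{group}(j)},$$

with variance $\mu + \alpha\mu^2$. Two normalizations enter as known
multipliers rather than estimated coefficients:

* **Size factors** $s_j$ are the median, over genes with no zero count, of
  $K_{gj}/(\prod_{j'} K_{gj'})^{1/m}$. The median-of-ratios form is robust
  to the minority of genes that are differentially expressed, which would
  bias a total-count normalizer. When no gene is zero-free the function
  refuses and offers a positive-count pseudo-reference flag intended for
  sparse toy matrices, not production data. Factors are returned exactly as
  the medians; no rescaling to unit geometric mean is applied, because only
  ratios of factors matter downstream.
* **Gene-length offsets** put the two species' counts on a common scale. At
  equal expression, a transcript annotated with different lengths in the
  two genomes collects proportionally different read counts, which would
  masquerade as interspecies differential expression. The offset
  $o_{gs} = \ln\!\big(L_{gs}/\sqrt{L_{g,\text{mouse}}L_{g,\text{jerboa}}}\big)$
  is centered by the geometric mean of the two lengths so the pair of
  species offsets sums to zero per gene; intra-species contrasts are
  untouched, and a gene whose counts scale exactly with length fits a zero
  interspecies fold change. The offset formulation (rather than pre-scaling
  the counts) keeps the counts integral and the NB likelihood exact; it is
  one of two arithmetically reasonable readings of length normalization for
  cross-species pipelines and is flagged here as the package's choice.

Genes of the one-to-zero orthology class (predicted lost or unannotated in
jerboa, retained because apparent loss can be an assembly artifact) lack a
jerboa length. They stay in intra-species contrasts and are excluded, with
an explicit status flag, from interspecies contrasts.

## Dispersion estimation and why shrinkage is the default

Per-gene dispersions are estimated on a 60-point log-spaced grid
($10^{-8}$ to $30$) of the Cox–Reid adjusted profile likelihood — group
means are profiled out by Newton iterations in the group log-mean, and the
adjustment $-\tfrac12\sum_{\text{groups}}\log\sum_j \mu/(1+\alpha\mu)$
removes most of the downward bias of plain profile ML at small replicate
numbers. The grid argmax is refined by one parabolic interpolation step and
floored at $10^{-8}$.

With 4 replicates per group the gene-wise estimate is still noisy (its
log-scale sampling standard deviation is about
$\sqrt{\psi'(3)} \approx 0.63$), and a Wald test that treats a noisy
dispersion as known is anti-conservative. `estimate_dispersions()`
therefore offers trend shrinkage, and `run_de()` turns it on by default: a
parametric trend $\alpha_{\mathrm{tr}}(\bar\mu) = a_1 + a_0/\bar\mu$ is
fitted across genes by a gamma-family regression (falling back to the
geometric-mean constant when the regression fails), and each gene's
dispersion is re-estimated as the maximum a-posteriori value of the same
grid likelihood under a log-normal prior centered on the trend. The prior
variance is the robust excess of the log-residual spread over the sampling
variance, floored at 0.05 — a deliberately low floor, chosen because the
shrinkage target is exactly right when dispersion is homogeneous and the
escape hatch below protects the heterogeneous case. Genes more than two
prior-plus-sampling standard deviations *above* the trend keep their
gene-wise estimate, so a genuinely overdispersed gene is not forced into
significance. The bare gene-wise estimator remains available
(`shrink = FALSE`) and is what the parameter-recovery tests exercise.

The Wald p-value uses the standard normal reference, matching the named
test's convention; the calibration that a small-sample t correction would
otherwise provide is supplied by the shrinkage above. The package's
testable contract here is false-discovery-rate control of the whole stage,
which the test suite checks over replicate simulations (20 datasets of
2000 genes, 4 vs 4) against the Benjamini–Hochberg target.

An expression filter (at least 10 counts in at least 2 samples of the
contrast) runs before testing; filtered genes carry missing p-values and a
status flag. This is the package's own choice of an "expressed" universe —
it also defines the background for enrichment — since bulk growth-plate
libraries at these depths give essentially no power below it.

## The disproportionality classification

All stages share one significance threshold (`alpha`, default 0.05 on the
BH-adjusted p-value). The regression of TV6 on TV1 interspecies log2 fold
changes is ordinary least squares fitted on exactly the both-significant
set, in a single pass: no outlier-and-refit iteration, because the interval
is defined relative to the bulk relation and a refit would move the goal
while classifying. The 95% prediction interval for a new observation,

$$\hat y_0 \pm t_{n-2}\, s_e \sqrt{1 + \tfrac1n + (x_0-\bar x)^2/S_{xx}},$$

is evaluated at each gene's TV1 fold change; boundary-exact values count as
inside. Genes outside the interval (set B) join the TV6-only genes (set A)
to form the disproportionate set D, and the final candidates are the genes
of D that are also significant intra-jerboa with matching fold-change sign
(the sign convention is fixed so positive always means higher in jerboa
TV6). A zero fold change with a significant adjusted p-value is excluded
with a warning rather than assigned an arbitrary direction. Missing
adjusted p-values count as not significant at every stage.

Degenerate inputs fail loudly: fewer than three both-significant genes, or
zero variance in the x fold changes, abort the fit rather than return a
meaningless interval.

## Enrichment and overlap testing

Term enrichment is the upper-tail hypergeometric test
$P(X \ge k)$ for $X \sim \mathrm{HG}(N, K, n)$ after intersecting query
and terms with the declared universe, BH-adjusted across terms. Terms
smaller than 3 genes or larger than half the universe are skipped by
default (both ends are uninformative; both bounds are arguments). The
overlap test between two gene lists is the one-sided ("greater") Fisher
exact test computed from the same hypergeometric tail — the convention of
gene-overlap testing, with a two-sided option — reporting the sample odds
ratio with a 0.5 continuity correction when a cell is empty. The universe
size for overlap testing is a required argument, not a default, because the
choice (expressed genes versus all orthologs) materially changes the
result and should be visible at the call site.

## Morphometric measurement

The vertebral length measurement interprets the operator's rule — begin at
the midpoint between the first intensity minimum and maximum, end at the
midpoint of the last — as the half-height crossing $(m+M)/2$ of each edge
ramp, with $m$ and $M$ taken over a window spanning the element and its
flanking gaps (per element, not per edge), and linear sub-pixel
interpolation at both crossings. This is the one reading that yields a
well-defined sub-pixel landmark on both edges of a discrete profile.
Lengths are pixels times `voxel * resize` (9 µm × 3 = 27 µm by default).
Element segmentation thresholds at half the profile's range; sub-threshold
dips shorter than 2 pixels do not split an element, and an optional
centered 3-pixel moving average (off by default — the emulated protocol is
manual cursor placement, not filtering) handles noisy scans. Indexing is
1-based with TV1 the first post-sacral element.

Proportions divide by each animal's naso-anal length; weekly change is the
difference of per-timepoint animal means of normalized length between
consecutive timepoints (a per-week rate flag divides by the interval in
weeks — the difference form is the default because the default sampling is
already weekly); the peak vertebra is the argmax of summed change over a
window, with exact ties broken toward the smaller index and flagged.
Calcein rates divide the front distance by the chase duration in days
(distance/2 under the 48-hour protocol). Cell summaries follow the fixed
averaging order sections → specimen → group; the hypertrophic height is
the per-section mean of the three largest cells. Group means are compared
by Welch's unequal-variances t-test with Satterthwaite degrees of freedom;
sex is carried as a label but not stratified on by default.

## What the generator emulates — and what it does not

The generator reproduces the study design: 4 replicates per species ×
vertebra, NB counts with species-specific transcript lengths (mouse
lengths log-normal around 2 kb, jerboa/mouse log-ratio SD 0.3, 2%
one-to-zero), uniform size factors on [0.7, 1.3], and four gene classes
whose group means are parameterized so that the interspecies TV1,
interspecies TV6, and intra-jerboa contrasts all derive from one ground
truth (`intra = delta_vert + lfc_TV6 - lfc_TV1`). The paired fold-change
law is `x ~ N(0, 1.5^2)`, inliers `y = 0 + 0.883 x + N(0, 0.25^2)`,
outlier fraction 0.062 with extra residuals of magnitude
`1.5 + |N(0, 0.5^2)|` and random sign. Only the slope (0.883) and the
replicate count are taken from the emulated biology; the magnitude
distribution of true fold changes is nowhere stated for the real data, so
the remaining constants are declared synthetic calibrations, chosen once
to give a realistic mix of strong and borderline effects, and recorded in
`tailprop_defaults()`.

Phantoms render each ossified diaphysis as a plateau with linear one-pixel
edge ramps whose half-height midpoints sit exactly at the planted
boundaries (element starts are placed on half-integer pixel positions so a
w-pixel element also yields exactly w supra-threshold samples); with zero
noise the measurement stage is exact by construction, which is the point —
it isolates discretization error (≤ 1 effective pixel) from model error.
Growth series interpolate between a birth profile (exponential decay from
TV1, summed tail length = 0.5 × naso-anal) and an adult profile (decay
plus a Gaussian bump centered on TV6, summed length = 1.0 or 1.5 × body)
with a mildly accelerating time course; the shapes were chosen once so the
weekly-change analysis peaks at TV6 with a TV5–TV8 plateau, which is the
emulated observation.

What passing tests therefore establish is that the *pipeline* is correct
and well calibrated under its stated model — not that real cross-species
growth-plate data satisfy that model. Real data bring dispersion
heterogeneity beyond a mean trend, unmodelled batch structure,
misannotated orthologs, and image artifacts (beam hardening, partial
mineralization) that the 1-D phantom deliberately omits; 2-D/3-D
reconstruction, read alignment, and orthology annotation itself are out of
scope and consumed as inputs.

## Seeds, determinism and problem sizes

Every generator is a pure function of its configuration including its
seed. A master seed fans out to named per-stage streams through a fixed
multiplicative hash (`fan_out_seed()`), so stages are individually
reproducible and reordering stages cannot silently change results.
Re-running a pipeline with an identical configuration reproduces
byte-identical outputs, and the run manifest records the configuration
hash, seed fan-out, stage counts and fit parameters.

The shipped validation uses desk-scale problem sizes chosen to estimate
each property to comfortably better than its tolerance: 2000-gene
simulations with 4 + 4 replicates for the DE stage (20 replicates for the
FDR experiment), 5000 training and 5000 held-out pairs for interval
coverage, 6786 pairs for the slope calibration, and full 28/31-element
phantoms. The paper-scale gene lists (17,640 orthologs and the deposited
sequencing data) are an optional replication path, not something the
package asserts about.

## Known limitations

* The Wald test's calibration leans on dispersion shrinkage; with `shrink
  = FALSE` and few replicates it is anti-conservative, as for any
  plug-in-dispersion Wald test.
* No fold-change shrinkage is applied: reported log2 fold changes are
  MLEs, noisy for low-count genes. Downstream classification uses only
  padj and sign, which moderated fold changes would not change, but users
  ranking genes by effect size should be aware.
* Single-pass regression means planted outliers inflate the residual
  standard error and widen the interval slightly; the recovery tests show
  this costs little at realistic outlier fractions.
* Exact invariance of fold changes to rescaling one sample's counts holds
  only approximately: any likelihood-pooled estimator re-weights the
  rescaled sample. The suite checks the exact relative size-factor
  property and bounded fold-change movement instead.
* Gene-name collation is case-insensitive exact matching; alias resolution
  is out of scope.
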