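# tailprop

Cross-species transcriptomics and morphometrics of tail vertebral
proportion.

Mammal tails differ enormously in relative length, and much of that
difference is made vertebra by vertebra: in jerboas the mid-tail vertebrae
elongate disproportionately until the tail reaches 1.5 times body length,
while the homologous mouse vertebrae stay close to body proportion. Finding
the genes associated with that *disproportionate* elongation requires more
than a single differential-expression contrast — a gene that simply differs
between species everywhere is not a candidate for why one vertebra outgrows
its neighbour. `tailprop` implements the intersectional analysis that
isolates such candidates, together with the morphometric computations that
define the phenotype, and a synthetic-data generator with planted ground
truth so every stage can be validated end to end.

## What the package computes

**Differential expression across species.** For gene *g* in sample *j* the
count model is negative binomial with mean

```
mu_gj = s_j * exp(o_gj) * q_g,group(j)
```

where `s_j` is a median-of-ratios size factor, `o_gj = ln(L_gs /
sqrt(L_g,mouse * L_g,jerboa))` is a gene-length offset that puts both
species' counts on a common length scale (orthologous transcripts differ in
length between genomes), and `q` are group means. Per-gene dispersions are
estimated by Cox–Reid adjusted profile likelihood with optional shrinkage
toward a mean–dispersion trend; the Wald statistic `log2(q_num/q_den) / se`
is referred to the standard normal, and p-values are Benjamini–Hochberg
adjusted.

**Disproportionality classification.** With three contrasts — jerboa vs
mouse in TV6, jerboa vs mouse in TV1, and jerboa TV6 vs TV1 — genes are
classified as:

* **A**: significant between species in TV6 but not in TV1;
* **B**: significant in both, but outside the 95% OLS prediction interval
  `yhat ± t * s_e * sqrt(1 + 1/n + (x0 - xbar)^2 / Sxx)` of the TV6-vs-TV1
  log2FC regression (most genes sit near the fitted line and are
  "equivalently" differentially expressed);
* **candidates**: genes in A ∪ B that are also significant intra-jerboa
  (TV6 vs TV1) with the same fold-change sign.

Candidates can then be tested for hypergeometric term enrichment, for
Fisher-exact overlap with external limb-proportion gene lists, and collated
against mutant-phenotype annotations (`table1_candidates()` ships the
collated reference list; *Npr3* is the one gene present in all four
external datasets).

**Morphometrics.** Vertebral lengths are measured from 1-D micro-CT
intensity profiles by the half-height midpoint rule with sub-pixel
interpolation (27 µm effective pixels at the default 9 µm voxel × 3
resize), normalized to naso-anal length, differenced weekly, and scanned
for the peak-growth vertebra. Calcein pulse-chase rates, EdU proliferative
indices, hypertrophic cell heights, and Welch's t comparisons round out the
growth-plate quantities.

## Worked example

```r
library(tailprop)

run <- run_pipeline(pipeline_config(seed = 1, include_morphometrics = FALSE))
run$disprop
#> Disproportionality classification
#>   TV6-only (A): 177 | both-significant pairs: 301 | outside PI (B): 27
#>   D = A union B: 204 | sign-consistent candidates: 158
run$disprop$fit
#> OLS log2FC regression: y = -0.0255 + 0.9068 x (n = 301, R^2 = 0.836)
#> Residual SE 0.7393; 95% prediction interval (t = 1.968)
```

The default simulation plants 2000 genes (4 replicates per species and
vertebra), of which 100 are TV6-only (A-type) and 60 disproportionate
(B-type); comparing the candidate set against the planted truth:

```r
planted <- run$truth$gene_id[run$truth$class %in% c("A_type", "B_type")]
cand <- run$disprop$sets$candidates
length(intersect(cand, planted)) / length(cand)    # precision 0.918
length(intersect(cand, planted)) / length(planted) # recall    0.906
```

158 candidates are called, 145 of them planted: the intersection design
recovers disproportionate genes at ~92% precision and ~91% recall while the
much larger equivalent class (500 genes on the regression line) is
excluded. On the morphometric side:

```r
ph <- simulate_tail_phantom(phantom_config("jerboa"))
head(measure_profile(ph$profile), 3)
#>   vertebra start_px end_px length_um
#> 1 TV1            12     85     1999.
#> 2 TV2            97    165     1851.
#> 3 TV3           177    239     1703.

gs <- simulate_growth_series("jerboa", noise_sd = 0)
tb <- tail_body_ratio(gs)
mean(tb$ratio[tb$timepoint_days == 42])
#> [1] 1.5
```

All 28 jerboa elements are segmented and measured to within one effective
pixel of their planted lengths, and the adult series reproduces the
1.5 tail:body ratio. `plot_lfc_pairs()`, `plot_growth_heatmap()` and
`autoplot()` draw the scatter-with-band and heat-map figures;
`write_report()` assembles a run summary.

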