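# secretofft

Differential secretome analysis and 2D-FFT quantification of cytoskeleton
fiber organization, for experiments in which cultured cells (the motivating
system is the KGN human granulosa-like cell line under FSH / hCG
gonadotropin stimulation) are profiled by label-free proteomics of their
conditioned medium while F-actin remodeling is imaged by fluorescence
microscopy. The package is aimed at proteomics and imaging analysts who
want both tracks as tested, scriptable R functions rather than a chain of
web tools and spreadsheets.

## What it computes

**Secretome track.** Peptide tables are aggregated by top-3 label-free
quantification (protein abundance = mean of the three most intense peptide
precursor areas). Identifications supported by ≥ 2 unique peptides are
split per contrast into common / treatment-exclusive / control-exclusive
sets (Venn partition). Quantified proteins are quantile-normalized, and
log2 fold changes `log2(mean_T / mean_C)` are called UP when
`log2FC > 1.5` and DOWN when `log2FC < −1.5` (strict). Row-standardized
log abundances (`z = (log x − mean)/sd`) feed a hierarchically clustered
heatmap structure, and UP/DOWN lists are tested for pathway
over-representation with the upper-tail hypergeometric test

```
P(X ≥ x),  X ~ Hypergeometric(N = |background|, K = |pathway|, n = |query|)
```

with Benjamini–Hochberg FDR across pathways (GMT input, explicit
background supported).

**Fiber track.** Per 100×100-pixel ROI, the 2D power spectrum (mean
subtraction, Tukey taper) is reduced to an angular mass profile p(θ) over
a 0.02–0.30 cycles/pixel band, and anisotropy is summarized by the second
circular harmonic

```
amplitude = | Σ_k p(θ_k) · exp(2iθ_k) |        ∈ [0, 1]
```

(0 = isotropic meshwork, 1 = perfectly aligned fibers), together with the
dominant fiber axis, the mean fluorescence intensity, and the eccentricity
of the spectral inertia ellipse. Conditions are compared by one-way ANOVA
with Bonferroni post hoc t-tests and medians with bootstrap or
order-statistic confidence intervals.

**Synthetic generators.** Both tracks come with seeded generators — a
peptide-level log-normal secretome simulator with condition effects and
whole-condition dropout, and an oriented-filament image simulator with an
axial von-Mises orientation distribution (κ = 0 isotropic) — so the full
pipeline runs and is tested without any external data.

## Worked example

```r
library(secretofft)

# simulate a 200-protein secretome: one protein secreted 8x more under
# FSH, one 8x less, 5% whole-condition dropout
p <- secretome_sim_params(
  n_proteins = 200,
  effects = list(P0003 = c(FSH = 8), P0004 = c(FSH = 1/8)),
  replicate_cv = 0.05, dropout_rate = 0.05, seed = 31)
res <- run_secretome_pipeline(p, out_dir = "run")

res$venn$FSH
#> venn_partition: 173 common, 14 treatment-only, 13 control-only
subset(res$differential$FSH, call != "NS")
#>   protein    log2fc call
#> 3   P0003  2.878170   UP
#> 4   P0004 -3.010259 DOWN
```

The Venn line is the qualitative result: 14 proteins detected only under
FSH (dropout in the control) and 13 only in the control. The quantitative
track recovers the two spiked effects — log2(8) = 3 up and −3 down —
slightly compressed by quantile normalization (a documented property);
everything else stays `NS`. `run/` now holds the Venn JSON, per-contrast
differential TSVs, the clustergram exports and a run log, all embedding
the configuration hash.

```r
# fiber track: isotropic vs aligned filament images
img0 <- simulate_fiber_image(fiber_sim_params(kappa = 0, seed = 1))
img8 <- simulate_fiber_image(fiber_sim_params(kappa = 8, seed = 1))
rbind(isotropic = colMeans(image_metrics(img0, n = 4)[, 3:5]),
      aligned   = colMeans(image_metrics(img8, n = 4)[, 3:5]))
#>           intensity  amplitude eccentricity
#> isotropic  50.61631 0.05910062    0.4406593
#> aligned    51.08361 0.46654333    0.9495490
image_metrics(img8, n = 4)$orientation
#> [1] 0.054154853 3.137008970 0.001646109 0.011668357
```

Same fluorescence intensity, but the aligned meshwork (κ = 8, mean axis
0 rad) shows an amplitude of 0.47 against the isotropic floor of 0.06, a
strongly elongated spectrum, and per-ROI dominant axes clustered at the
imposed orientation (0 and 3.14 rad are the same axis — orientations are
axial, so summarize them circularly, never with a plain mean).
`run_fiber_pipeline()` wraps this per condition and adds the ANOVA /
Bonferroni comparison.

The bundled reference differential tables from the motivating KGN
gonadotropin study are available via
`reference_differential_table("fsh" | "hcg" | "fsh_hcg")`.

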