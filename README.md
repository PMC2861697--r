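# regspline

Penalized-spline models of how the genomic **position** of transcription
factor binding sites shapes gene expression.

Genome-wide ChIP experiments find tens of thousands of binding sites per
regulator, most of them kilobases away from any promoter, and give little
direct guidance on which ones drive transcription. `regspline` is for
computational biologists who want to ask that question quantitatively from
peak calls, TSS annotations and expression measurements alone. Its core
assumption is that binding events contribute additively to a gene's log
expression, with a contribution that depends smoothly on the site's signed
distance *d* from the transcription start site:

    y_i = const + Σ_j α_j f(d_ij) + ε_i ,    f(d) = Σ_k c_k B_k(d)

The **influence function** *f* is a cubic B-spline curve fitted by
penalized least squares with a discrete second-difference penalty (the
P-spline approach), so the fit is one exact symmetric solve:

    ĉ = argmin_c (1/N) ||y − B c||² + σ cᵀD c ,    D = Δ₂ᵀΔ₂

Around that core the package provides:

* **Genome plumbing** — TSS tables, BED-like binding sites, merging
  per-regulator peak sets into putative regulatory regions (bound by a
  designated coactivator or by ≥ 2 other factors), strand-aware signed
  distances, and site-to-gene association under both multi-gene and
  nearest-gene-only assumptions.
* **Model variants** — uniform weighting (position-blind site counts),
  conservation-weighted influence, per-regulator influence weights fitted
  by alternating least squares, and ChIP-affinity weighting.
* **Conservation scoring** — maximum 100 bp moving-average scores from
  bedGraph/wiggle tracks, and data-driven threshold selection separating
  bound regions from background sequence.
* **Evaluation protocol** — repeated 2:1 train/test splits with held-out
  MSE and correlations, paired model comparisons, permutation controls,
  and bootstrap confidence bands for the influence curve.
* **A synthetic-data generator** — genomes, tissue-specific binding and
  expression with the exact structure the model assumes, so the entire
  pipeline is testable by parameter recovery.

## A worked example

```r
library(regspline)

spec  <- synthetic_spec(n_genes = 500, noise_sd = 0.5)   # study conditions
study <- simulate_study(spec, seed = 7)

profiles <- associate_sites(study$tss, study$sites$tissueA, cutoff = 1e5)
fit <- fit_influence(profiles, study$expression$tissueA, sigma = 1e-3)
summary(fit)
#> influence_fit (position variant): P = 20 basis functions on [-1e+05, 1e+05], sigma = 0.001
#>   n = 500 genes, training MSE = 0.2278
#>   peak influence 0.9399 at 2,500 bp; roughness c'Dc = 1.366; R^2 = 0.970

run_experiment(study$tss, study$sites, study$expression,
               mode = "absolute", variant = "position",
               cutoff = 1e5, n_trials = 20, base_seed = 3, sigma = 1e-3)
#> evaluation_report: mode=absolute, variant=position, cutoff=1e+05, assignment=multi, sigma=0.001, n_basis=20, n_genes=500, conserved_only=FALSE, n_trials=20, base_seed=3
#>   mse                mean   0.5183  sd  0.0512  median   0.5102
#>   pearson            mean   0.7210  sd  0.0333  median   0.7234
#>   spearman           mean   0.6761  sd  0.0368  median   0.6743
```

The fitted curve peaks near the TSS (0.94 at +2.5 kb here, against a
generating curve that peaks at 1.0 at d = 0) and decays towards zero by
±50 kb; `plot(fit)` draws it. The evaluation report shows the model
explaining about half the held-out variance (Pearson ≈ 0.72) at noise
sd 0.5 — the MSE is on standardized-response scale, where predicting the
training mean would score ≈ 1. `predict_differential()`,
`fit_variant_model()`, `fit_regulator_weights()`,
`bootstrap_influence()` and `compare_assignment_modes()` build the
tissue-differential, competing-model and uncertainty analyses on top;
see the vignette in `vignettes/influence-modelling.Rmd` for the model's
assumptions and every design decision.

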