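---
title: "Modelling the positional influence of regulatory binding on expression"
author: "regspline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the positional influence of regulatory binding on expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(regspline)
```

## The model

High-throughput ChIP experiments show that regulatory proteins bind
thousands of genomic sites, most of them far from any promoter, and that
only a subset of those binding events measurably affect transcription.
`regspline` implements a deliberately simple quantitative answer to the
question *which binding events matter*: it assumes that every binding site
contributes additively to a gene's log expression, and that the size of a
site's contribution is a smooth function of its signed distance $d$ from
the gene's transcription start site (TSS):

$$ y_i \;=\; \mathrm{const} + \sum_{j \in \text{sites}(i)} \alpha_j\, f(d_{ij}) + \varepsilon_i . $$

Here $y_i$ is the (centered) log expression of gene $i$, the sum runs over
all binding sites within a distance cutoff of its TSS, $\alpha_j$ is a
positive per-site modifier (1 by default; regulator-identity weights and
ChIP-enrichment weighting fold into it), and $f$ — the **influence
function** — is the object of inference. Upstream distances are negative,
downstream positive, with the sign following the gene's transcription
direction, so $f$ is free to treat upstream and downstream binding
differently.

The kinetic reading is zeroth-order mRNA production whose log rate is
shifted additively by enhancers, with first-order degradation at
equilibrium; the basal production/degradation term is a gene-independent
constant. Because responses are mean-centered before fitting (or generated
without a basal term in simulation), no intercept is fitted. Between two
conditions $a$ and $b$ sharing basal and degradation rates, the same model
predicts the log fold change as the difference of the two influence sums
(`predict_differential()`), which is how tissue-differential expression is
analyzed.

$f$ is represented in a cubic B-spline basis with uniformly spaced knots
over the association window (default $\pm 100$ kb),
$f(d) = \sum_k c_k B_k(d)$, and fitted by penalized least squares with a
discrete second-difference penalty on the coefficients — the standard
P-spline approximation to the integrated squared second derivative:

$$ \hat c = \arg\min_c \; \tfrac1N \lVert y - Bc \rVert^2 + \sigma\, c^\top D c,
   \qquad D = \Delta_2^\top \Delta_2 . $$

The design entry $b_{ik} = \sum_j \alpha_j B_k(d_{ij})$ is precomputed per
gene, so the minimizer is a single exact symmetric solve — there is no
iteration and no stochastic step in the core fit. With $\sigma = 0$ the fit
is ordinary least squares; as $\sigma \to \infty$ the coefficient sequence
is driven into the penalty null space (constants and lines).

## Parameters that matter

* **Association cutoff** (bp, default `1e5`). Sites whose midpoint lies
  within this distance of a TSS (inclusive) enter the gene's profile, and
  the spline domain equals $\pm$cutoff so no site falls outside the basis.
  A named promoter-array analysis restricts to −5.5 kb..+2.5 kb via the
  `cutoff`/`tissues` arguments and an asymmetric basis if desired.
* **Basis size** `n_basis` (default 20 over $\pm 100$ kb, i.e. a knot
  roughly every 12 kb). This is a resolution/variance trade-off: 20
  functions resolve the decade-scale decay the model targets while keeping
  the solve small. Analyses whose *product is the curve itself* (bootstrap
  bands, curve recovery at large N) benefit from a finer basis; the
  bootstrap examples below use `n_basis = 30`, because at $N \ge 1000$ the
  sampling bands are narrow enough that the approximation bias of a coarse
  basis near sharp features of the target would dominate.
* **Regularization** $\sigma$ (default `1e-3`). At the design's natural
  scale the data term dominates for $\sigma \lesssim 10^{-2}$, so the
  default acts mostly as numerical stabilization; `select_sigma()`
  implements the data-driven alternative (grid search on an inner
  train/validation split, candidates $10^{-5}..10^2$), and
  `run_experiment(sigma = "auto")` uses it once per experiment so that all
  trials share one smoothing level.
* **Site position convention**: the interval midpoint,
  $\lfloor(start+end)/2\rfloor$ converted to 1-based coordinates. Peak
  summits are not assumed to be available.
* **Proximal window**: 500 bp centered on the TSS (half-window 250 bp,
  inclusive), used only for descriptive classification.

## Model variants

`fit_variant_model()` exposes the three competing weighting schemes under
one interface: `"position"` (the spline in distance), `"uniform"` (every
binding event counts equally — a single least-squares weight on the site
count), and `"conservation"` (the same spline machinery applied to the
sites' sequence-conservation scores on $[0,1]$ instead of their
positions). Because all three are linear models fitted by the same solver,
held-out comparisons between them isolate the value of the covariate, not
the fitting technology.

**Per-regulator weights.** `fit_regulator_weights()` extends the position
model to $\hat y_i = \sum_j a(\mathrm{regs}_j)\,\alpha_j f(d_{ij})$ where
$a$ averages per-regulator weights $w_r$ over the regulators bound at a
site. The model is bilinear in $(w, c)$, and the product $w \cdot f$ is
only identified up to scale, so one designated reference regulator's
weight is **fixed at 1** and fitting alternates two exact coordinate
steps: solve the penalized system for $c$ with $w$ fixed, then solve least
squares for the non-reference weights with $c$ fixed (clamped to a small
positive floor, with the step accepted only if it does not increase the
objective). Exact coordinate minimization makes the objective trace
provably non-increasing — an invariant the tests assert — which is also
why the reference weight is pinned rather than renormalized after each
round: rescaling $(w/s,\, s\,c)$ leaves predictions unchanged but
multiplies the roughness penalty by $s^2$ and can break monotonicity. The
mean combination rule is the default; `"product"` and `"max"` are
available (the weight step then uses box-constrained BFGS) and are flagged
in the returned object.

**Affinity weighting.** `apply_affinity_weights()` multiplies each site's
$\alpha$ by $(\text{enrichment}/\text{median enrichment})^\gamma$ (median
over the tissue's distinct sites, $\gamma = 1$ by default), upweighting
sites with stronger ChIP enrichment before any fit.

## Conservation scoring

A region's conservation score is the maximum 100 bp moving average of
per-base PhastCons-style scores over windows fully inside the region;
regions shorter than the window use the whole-region mean. Bases not
covered by the track score 0 (missing alignment treated as unconserved).
`select_threshold()` picks the score threshold best separating bound
regions from background sequence by maximizing the sum of the two
correct-classification fractions (equivalent to Youden's J; a KS objective
is available and selects the same maximizer for equally weighted samples),
scanning midpoints of adjacent sorted unique scores and taking the
smallest on ties. "Non-conserved" means *at or below* the threshold.

## Evaluation protocol

`run_experiment()` mirrors the standard protocol for this model class:
restrict to genes bound at the chosen cutoff (and, for differential
analyses, to genes flagged differentially expressed), standardize the
response (mean 0, population sd 1, so a train-mean baseline has held-out
MSE ≈ 1), then repeat over random 2:1 train/test splits of genes,
recording held-out MSE and both Pearson and Spearman correlations. Every
split, permutation and bootstrap draw consumes an explicit seed derived
from one base seed; identical seeds give identical reports.

Paired designs (`compare_variants()`, `compare_assignment_modes()`,
`conserved_only_comparison()`) reuse the same splits in both arms and keep
the same gene set — the bound-gene filter always uses unfiltered
multi-gene association, so e.g. the conserved-only arm scores exactly the
genes the all-sites arm scores, with a gene whose sites are all filtered
out simply predicting the basal level. `permutation_control()` permutes
the standardized response across genes before each trial and reports the
train-mean baseline alongside. `bootstrap_influence()` resamples *genes*
with replacement (the observation unit of the regression; resampling sites
would break the per-gene sums) and returns pointwise empirical quantile
bands for the curve.

One normalization subtlety: evaluation experiments standardize the
response, matching how microarray data are analyzed, but the curve-facing
analyses (`bootstrap_influence()` defaults, parameter-recovery checks) fit
on the response's natural scale. With no intercept in the model, centering
shifts the whole fitted curve by a quantity the spline cannot represent
exactly; on the natural scale of a realizable simulation the fit is
unbiased and directly comparable to the generating curve.

## The synthetic-data generator

`synthetic_spec()`/`simulate_study()` generate data with exactly the
statistical structure the model assumes, so parameter recovery is a
meaningful test of the whole pipeline:

* ~2000 genes on one linear chromosome at ~20 kb mean spacing (uniform
  placement with a 2 kb minimum), random strands — close enough that a
  single site routinely lies within 50–100 kb of several genes;
* a Poisson(3) number of 201 bp sites per gene, at signed distances drawn
  from a mixture of a TSS-proximal normal (sd 5 kb, weight 0.4) and a
  uniform background over $\pm 100$ kb, so most sites are distal;
* two tissues sharing each site with probability 0.5, the rest
  tissue-unique; genes whose site sets differ are flagged differential;
* per-site regulator labels with true weights, conservation scores from a
  low/high beta mixture drawn **independently of influence** (a coupled
  `conservation_only` preset exists for testing the conservation model),
  and log-normal enrichment ratios;
* expression = sum of true influence contributions + Gaussian noise
  (sd 0.5 by default — roughly half the signal's dynamic range, chosen so
  held-out correlations land in the 0.6–0.8 range typical of real
  tissue-pair analyses).

True influence presets: `linear_decay_50kb`
($f(d) = \max(0, 1 - |d|/50000)$, the approximately linear falloff
vanishing by 50 kb), `asymmetric_upstream` (upstream side × 1.2), `flat`,
and `conservation_only`.

What the generator does **not** emulate: peak-calling noise and width
variation, probe-level microarray effects, basal-rate variation between
genes, correlated binding of co-factors, chromatin domain structure, and
any genuine biology of conservation. Passing recovery tests therefore
demonstrates that the estimator and protocol are correct and well
calibrated under the model's own assumptions — not that the model is true
of any particular genome.

## Numerical choices and degenerate inputs

* The penalized system is solved by Cholesky factorization. If
  factorization fails with a zero right-hand side (a design with no active
  features, e.g. every site filtered out), the fit is the zero curve. If
  it fails with $\sigma > 0$ — possible when a degenerate design leaves a
  direction unidentified by both data and penalty, e.g. every site sharing
  one covariate value — the normal equations of the convex objective are
  still consistent and the minimum-norm solution is returned; predictions
  are identical across solutions. An unpenalized ($\sigma = 0$)
  rank-deficient fit is an error advising a positive $\sigma$.
* Nearest-gene ties (equal |distance|) break to the lexicographically
  smallest gene id; association boundaries are inclusive; co-binding
  overlap for regulatory-region definition is ≥ 1 bp intersection.
* Train size is `round(2N/3)`; population (not sample) sd is used for
  standardization; degenerate bootstrap resamples (constant response) are
  skipped and counted.
* The alternating weight fit stops on a relative objective change below
  `tol` or at `max_iter` (flagged, best iterate returned; the trace is
  monotone either way).

## A worked example

```{r example}
spec <- synthetic_spec(n_genes = 500, noise_sd = 0.5)
study <- simulate_study(spec, seed = 7)
profiles <- associate_sites(study$tss, study$sites$tissueA, cutoff = 1e5)
fit <- fit_influence(profiles, study$expression$tissueA, sigma = 1e-3)
summary(fit)
plot(fit)

report <- run_experiment(study$tss, study$sites, study$expression,
                         mode = "absolute", variant = "position",
                         cutoff = 1e5, n_trials = 20, base_seed = 3,
                         sigma = 1e-3)
report
```

The experiment sizes used in the package's own acceptance analyses —
N = 2000 genes for recovery and comparisons, N = 1000 with 200 replicates
for bootstrap bands, 100 trials or replicates per comparison — were chosen
as the smallest sizes at which the quantities of interest (weight errors
≲ 0.1, band coverage, win fractions) are stable across seeds.

## Known limitations

* One TSS per gene id; isoform structure is out of scope.
* The influence function is shared across genes and tissues within a fit;
  gene- or class-specific curves would need stratified fits.
* Conservation and position are never fitted jointly in one surface, and
  regulator interactions at a site are not modelled beyond the weight
  combination rule.
* The affinity-weighting form (power of median-normalized enrichment) is a
  pragmatic choice; other monotone transforms are plausible.
* Bootstrap bands are pointwise, not simultaneous.
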