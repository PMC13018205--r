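---
title: "Modeling variability in agroinfiltration fluorescence assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling variability in agroinfiltration fluorescence assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agrovar)
```

Transient expression by *Agrobacterium* infiltration of *Nicotiana
benthamiana* leaves is fast and convenient, but its quantitative readouts are
noisy at every level of the experiment: cohorts of plants grown and
infiltrated together ("batches", i.e. experimental replicates) differ in both
mean expression and spread; plants within a batch differ; and leaf disks
punched from the same plant differ again. `agrovar` provides a coherent
statistical toolkit around this hierarchy: a disk-level data model with QC
filters, a hierarchical location–scale model that attributes observed
variance to five sources, tools to evaluate ratiometric normalization
schemes, distribution-level reproducibility metrics, and a Monte Carlo power
engine that converts an empirical coefficient-of-variation (CV) distribution
into minimum-plant-number recommendations.

## The location–scale hierarchy

The core model treats the fluorescence $y_{bpd}$ of disk $d$ from plant $p$
in batch $b$ as

$$y_{bpd} = \mu + \alpha_b + \beta_{bp} + \sigma_{bp}\,\varepsilon_{bpd},
\qquad \varepsilon_{bpd} \sim N(0, 1),$$

with mean-level random effects
$\alpha_b \sim N(0, \tau_b^2)$ (batch means) and
$\beta_{bp} \sim N(0, \tau_p^2)$ (plant means within batch), and — the
location–scale part — random effects on the *log standard deviation*:

$$\log \sigma_{bp} = \lambda + u_b + v_{bp}, \qquad
u_b \sim N(0, \omega_b^2), \quad v_{bp} \sim N(0, \omega_p^2).$$

So a batch can be noisy as well as bright, and a plant can be erratic as well
as dim; both phenomena are visible in real disk data and neither is captured
by a mean-only mixed model. Disk noise is Gaussian on the raw fluorescence
scale with a plant-specific SD (raw-scale densities of disk fluorescence are
approximately symmetric within a plant; the heavy upper tail across plants
comes from the lognormal $\sigma_{bp}$), and leaves are treated as
exchangeable within a plant — per-plant quantities always pool both leaves'
disks, and no leaf-level stratum is modeled.

### Variance attribution

The marginal disk variance decomposes as
$V = \tau_b^2 + \tau_p^2 + E[\sigma^2]$ with the lognormal moment identity
$E[\sigma^2] = e^{2\lambda + 2\omega_b^2 + 2\omega_p^2}$. `compute_shares()`
splits $V$ into five percentages, resolving the scale contribution along the
nesting order (batch before plant, mirroring the design):

* batch mean: $\tau_b^2$
* plant mean: $\tau_p^2$
* disk SD (baseline): $e^{2\lambda}$
* batch SD: $e^{2\lambda}(e^{2\omega_b^2} - 1)$ — what batch-level scale
  wobble adds at baseline
* plant SD: $e^{2\lambda + 2\omega_b^2}(e^{2\omega_p^2} - 1)$ — what
  plant-level scale wobble adds on top

The shares are nonnegative and sum to 100 by construction. The attribution
of the scale components is order-dependent; the sequential-ablation Monte
Carlo oracle used in the test suite switches components off in this same
order and agrees with the closed forms to well under a percentage point.

### Fitting

`fit_location_scale()` maximizes the marginal likelihood. The plant-level
mean effect $\beta_{bp}$ integrates analytically (everything stays Gaussian
given $\sigma_{bp}$); the plant-level scale effect $v_{bp}$ is integrated by
a one-dimensional adaptively centred Gauss–Hermite rule (centres and scales
from conjugate-style moment approximations of each plant's posterior, so the
likelihood stays a smooth deterministic function of the parameters); the
batch-level pair $(\alpha_b, u_b)$ by a two-dimensional adaptively centred
Gauss–Hermite product rule. Defaults are 7 nodes per batch-level dimension
and 9 for the plant-level effect; 5/7 give visually identical estimates on
designs of 50 batches × 20 plants and run in roughly half the time.

Numerical choices:

* Optimization by `nlminb` with box constraints (variances $\ge 0$),
  relative tolerance $10^{-8}$, on a response standardized to unit variance
  (estimates are transformed back afterwards).
* A fixed three-point multi-start schedule anchored at method-of-moments
  values (batch-mean variance for $\tau_b^2$, pooled within-batch plant-mean
  variance for $\tau_p^2$, bias-corrected log within-plant SDs for
  $\lambda$, $\omega_b$, $\omega_p$), guarding against local optima in the
  scale parameters while keeping the fit deterministic.
* Boundary estimates are legitimate: variance parameters below $10^{-6}$ of
  the response SD are reported as exact zeros, not errors. A table with no
  within-plant variation at all short-circuits to boundary estimates with
  $\lambda = -\infty$.

## The synthetic-data generator

`generate_hierarchical()` draws from exactly the model above, so it is both
the test bed for the fitter and the source of calibrated inputs for every
other stage. Negative draws are truncated to zero — plate readers report
nonnegative values — and the truncation count is surfaced in the table's
provenance so analyses can confirm it is negligible. The fitter does not
model the truncation; parameter-recovery checks therefore run in regimes
where truncation essentially never fires, and the variance-share oracle
simulates the untruncated model directly.

The default parameters encode the variability structure of an unnormalized
GFP reporter delivered by GV3101, reconstructed from the five-way share
structure of a multi-year longitudinal compilation (batch mean 23.8%, batch
SD 15.6%, plant mean 9.9%, plant SD 28.2%, disk SD 22.3%) together with an
overall raw-fluorescence CV of 0.5 (batch means in such compilations differ
by up to fourfold). Around a grand mean of $\mu = 20000$ a.u. this inverts
to

$$\tau_b = 4879,\quad \tau_p = 3146,\quad e^{\lambda} = 4722,\quad
\omega_b = 0.515,\quad \omega_p = 0.527 .$$

```{r shares-default}
compute_shares(list(
  tau_batch = 4879, tau_plant = 3146, lambda_log_sigma = log(4722),
  omega_batch = 0.515, omega_plant = 0.527
))
```

`generate_dual_channel()` adds a second (red) channel for
reporter/normalizer studies. Batch effects and the plant scale effect are
shared outright between channels; the plant mean effects and the disk-level
noise are correlated with `rho_channels`. The disk-level correlation is
essential: a per-plant CV is computed across the plant's eight disks, so
only co-variation *at the disk level* can make the per-disk ratio quieter
than the raw reporter. (Biologically this is co-variation in tissue amount,
punch position, and delivery efficiency, which move both fluorophores
together.) At `rho_channels = 1` with no disk noise the ratio is exactly
constant; at `rho_channels = 0` the ratio accumulates both channels' noise
and normalization can only hurt.

`co_delivery_config()` is a second named parameterization for controlled
single-session co-delivery comparisons (two replicates of six plants,
identical promoters): moderate mean effects ($\tau_b = 0.12\mu$,
$\tau_p = 0.08\mu$) and within-plant disk CVs around 0.2
($e^{\lambda} = 0.2\mu$, $\omega_b = 0.12$, $\omega_p = 0.15$). The
distinction matters for ratio readouts: a ratio's denominator contributes
second-order noise of order $\mathrm{cv}^4$ that channel correlation cannot
remove, and under the longitudinal parameterization (heavy-tailed plant CVs,
mean effects occasionally pulling a plant's expression toward zero) that
term can swamp the first-order normalization benefit for individual plants.
In the controlled regime the benefit is robustly first-order:

```{r dual-demo}
tab <- apply_qc_filters(generate_dual_channel(co_delivery_config(seed = 850)))
g <- summarize_scheme(tab, "A", "green")
r <- summarize_scheme(tab, "A", "green_over_red")
c(
  green_cv = mean(g$plant_cvs), ratio_cv = mean(r$plant_cvs),
  reduction_pct = 100 * (1 - mean(r$plant_cvs) / mean(g$plant_cvs))
)
```

What the generator does *not* emulate: spatial structure within a leaf,
strain–strain antagonism as a function of inoculum density, leaf-level (T4
vs T5) strata, skewed disk noise, or plate-reader saturation. Tests passing
on synthetic data therefore demonstrate the statistical machinery under the
declared model, not that real assays follow that model in every respect.

## Normalization evaluation

CVs use the $n-1$ sample SD throughout. Per-plant CVs pool all of a plant's
disks regardless of leaf; the pooled-disk CV of a condition is kept as a
separate readout, not a replacement. Ratios are formed per disk and then
summarized — never as a ratio of plant means. Whether a scheme's
reporter/normalizer CVs are significantly below the unnormalized control's
reporter CVs is tested with a one-tailed Welch (unequal-variance) $t$-test
followed by a Bonferroni correction whose family size `m` is explicit
(17 scheme-vs-control comparisons per reporter orientation in the motivating
design; whether the family should span both orientations is a judgment call
the caller makes by setting `m`).

## Reproducibility metrics

`ks_one_sample()` computes the exact supremum distance between a replicate's
ECDF and a step-function reference, checking both one-sided gaps at every
jump of either function; p-values use the asymptotic Kolmogorov series,
adequate at the $n \ge 30$ sizes these comparisons run at (exact small-$n$
p-values are out of scope). The pooled reference conventionally includes the
evaluated replicate's own observations; `leave_one_out = TRUE` switches to
the excluded form. `wasserstein_1d()` integrates the absolute ECDF gap
exactly between breakpoints; `mean_ecdf_difference()` averages the gap over
the union of both samples' jump points by default (a uniform grid is
available via `grid = "uniform"` since the evaluation grid is a genuine
free choice of the metric).

## The power engine

A simulated experiment propagates variability the way a real one does:

1. A batch CV is drawn from the empirical batch-CV distribution by
   generating a uniform percentile and interpolating linearly between order
   statistics (`quantile` type 7). Both conditions of the experiment share
   this batch draw by default (`shared_batch = FALSE` for independent
   draws).
2. Plant CVs scatter around the batch CV as a zero-truncated Normal with the
   pooled within-batch dispersion estimated by `build_cv_distribution()`
   (batches need at least 30 plants to qualify). The alternative of drawing
   each plant's CV directly from the empirical per-plant values is available
   as `plant_sampling = "direct"`.
3. Each plant contributes eight disk values
   $N(m_c, (\mathrm{cv} \cdot m_c)^2)$ around its condition's fixed mean
   expression; condition B's mean is $m(1 + \mathrm{effect}/100)$.
4. The two conditions are compared with a two-tailed pooled-variance
   Student's $t$-test on the per-plant means ($n$ = plants, the reported
   sample-size axis; `unit = "disk"` tests on disks instead, since the
   experimental unit is a design choice the analyst must own).

Power is the fraction of (by default 1000) simulated replicates with
$p < 0.05$; `find_min_n()` searches $n = 2, 3, \dots$ for the smallest count
reaching 95% power, using a fixed per-$n$ seed schedule derived from the
master seed so the returned bracket (power at $n_{\min}$ above target, at
$n_{\min} - 1$ below) is reproducible. `fit_power_curve()` summarizes the
$(\text{effect}, n_{\min})$ points with a least-squares exponential decay
$n_{\min} = a e^{-b\,\mathrm{effect}} + c$ (coefficients constrained so the
curve is nonincreasing), fitted on the $n$-axis; inverting it at a plant
budget gives the smallest detectable effect with that many plants.

```{r power-demo}
long <- generate_hierarchical(generator_config(
  n_batches = 32, plants_per_batch = 30, seed = 2
))
dist <- build_cv_distribution(apply_qc_filters(long), min_plants = 30)
dist
find_min_n(40, dist, n_reps = 400, seed = 3)$n_min
```

The degenerate case (a single CV, zero dispersion) reduces to the textbook
two-sample problem, and the simulated power then matches the closed-form
noncentral-$t$ power formula — the test suite verifies this on a grid of
mild effects (10–20%) where the formula's equal-variance assumption holds to
first order (in the simulated model the SD scales with the condition mean,
so very large effects take the two groups' variances apart and the
closed form stops being the right oracle).

## Problem sizes used by the checks

The test suite exercises the pipeline at deliberately chosen scales:
parameter recovery on 20 simulations of 50 batches × 20 plants × 8 disks
(median relative error of every variance parameter well under 15%);
variance-share ablation on 20 random parameter draws with $10^6$ simulated
disks each (agreement within one percentage point, using standardized
component draws as a variance-reduction device); KS/Wasserstein against
brute-force grid oracles on 100 random cases each; type-I calibration of the
power engine on 2000 null replicates; and the noncentral-$t$ comparison on a
3 × 3 (effect, $n$) grid at 5000 replicates.

## Known limitations

* The fitter ignores the zero-truncation of fluorescence; at parameterizations
  where a nontrivial fraction of draws would be negative, estimates are
  mildly biased. The truncation count in the provenance tells you when to
  worry.
* KS p-values are asymptotic; below $n \approx 30$ they are approximate.
* Variance estimates from heterogeneous longitudinal compilations are
  deliberately conservative inputs for power analysis — a single
  well-controlled experiment will usually do better than the prediction.
* Ratio readouts inherit denominator noise that normalization cannot remove;
  validate a normalization scheme under your own conditions (the package
  makes that validation cheap) rather than assuming it helps.
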