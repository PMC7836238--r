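---
title: "Methods: spatial confidence sets for Cohen's d images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial confidence sets for Cohen's d images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohensdCS)
```

## The problem

A group-level neuroimaging analysis ends, more often than not, with a
thresholded statistic map: voxels where a null hypothesis of no effect could
be rejected. With modern sample sizes that statement carries less and less
information — test statistics grow without bound as N increases, so
eventually *everything* is "significant", including effects far too small to
matter. What a reader actually wants to know is *where the standardized
effect size is large*, and how sure we can be about that region's outline.

`cohensdCS` answers that question for one-sample designs. Given N aligned
subject-level maps $Y_1(s), \dots, Y_N(s)$ modelled as
$Y_i(s) = \mu(s) + \epsilon_i(s)$ with pointwise variance $\sigma^2(s)$, the
target is the excursion set of the Cohen's d field $d(s) = \mu(s)/\sigma(s)$
at a threshold $c$:

$$A_c = \{ s : d(s) \ge c \}.$$

The package produces a nested pair of voxel sets, an **upper confidence set**
$\hat A_c^+$ and a **lower confidence set** $\hat A_c^-$, such that

$$P\left( \hat A_c^+ \subseteq A_c \subseteq \hat A_c^- \right) \ge 1 - \alpha$$

holds simultaneously over the whole domain as N grows. Voxels inside the
upper set can be declared to have effect size above $c$; voxels outside the
lower set to have effect size below $c$; the annulus between them is the
spatial analogue of a confidence interval around the set boundary. A
bias-corrected **point-estimate set** sits between the two as the best guess.

## Why Cohen's d needs special treatment

For the raw mean $\bar Y(s)$ the analogous construction is straightforward:
band the estimate by $k \hat\sigma(s) / \sqrt N$ and calibrate $k$ by
bootstrapping the supremum of the standardized error field along the
estimated set boundary. Three features of the Cohen's d estimator
$\hat d(s) = \bar Y(s)/\hat\sigma(s)$ break that recipe:

1. **Effect-dependent variance.** $\sqrt N (\hat d - d)$ is asymptotically
   normal with variance $1 + d^2/2$: the image gets noisier where the effect
   is stronger. Any valid band must widen accordingly.
2. **Bias.** Under Gaussian errors, $\sqrt N \hat d$ follows a noncentral t
   distribution with $N - 1$ degrees of freedom and noncentrality
   $\sqrt N d$, whose mean is inflated by the factor
   $C_N = \sqrt{(N-1)/2}\,\Gamma(\tfrac{N-2}{2})/\Gamma(\tfrac{N-1}{2})
   \approx (1 - \tfrac{3}{4N-5})^{-1}.$
   All thresholds in the package are therefore applied to $\hat d$ at the
   inflated level $c\,(1-\tfrac{3}{4N-5})^{-1}$ (`corrected_threshold()`),
   which targets the set where the *true* effect exceeds $c$.
3. **Skew.** The noncentral t is right-skewed for $d > 0$, increasingly so
   for small N, which a symmetric band ignores.

A further, subtler problem concerns the bootstrap itself: multiplying the
plain standardized residuals $(Y_i - \bar Y)/\hat\sigma$ by random signs
reproduces the correlation structure of the *mean* field, not of the Cohen's
d field — the two differ whenever $d \ne 0$. The package therefore
bootstraps the first-order (delta-method) expansion of the estimator, the
**Cohen's d residuals**

$$R_i(s) = \frac{Y_i(s) - \bar Y(s)}{\hat\sigma(s)} -
  \frac{\bar Y(s)}{2 \hat\sigma(s)}
  \left( \frac{(Y_i(s) - \bar Y(s))^2}{\hat\sigma^2(s)} - \kappa \right),$$

whose empirical covariance converges to the correct limit
$(\rho + \rho^2 d^2/2) / \sqrt{(1 + d^2/2)(1 + d^2/2)}$ between two points
with error correlation $\rho$. The centering constant $\kappa$ is the
empirical mean of the squared standardized deviations, which makes
$\sum_i R_i(s) = 0$ hold exactly at every voxel for every N — the binding
identity the wild bootstrap relies on (see *Numerical conventions* below).

## The three constructions

All three algorithms share the same skeleton, differing only in how the
residuals are standardized and how the band is drawn:

| | standardization | band half-width |
|---|---|---|
| Algorithm 1 | $\sqrt{1 + \hat d^2/2}$ (limiting sd) | $\tfrac{k}{\sqrt N}\sqrt{1 + \hat d^2/2}$ |
| Algorithm 2 | $\hat\sigma_R(s) = \sqrt{\tfrac1N \sum_i R_i^2(s)}$ (sample sd) | $\tfrac{k}{\sqrt N}\,\hat\sigma_R(s)$ |
| Algorithm 3 | arcsinh-stabilized scale (below) | $\tfrac{k}{\sqrt N}$ on that scale |

**Algorithm 3** transforms the whole problem onto a variance-stabilized
scale before thresholding. Writing $a = (N-1)/(N-3)$ and
$b_*^2 = N (8N^2 - 17N + 11) / ((N-3)(4N-5)^2)$, the finite-sample variance
of the estimator satisfies $N \,\mathrm{Var}(\hat d) \approx a + b_*^2 d^2$,
and the map

$$\zeta(x) = \alpha_* \operatorname{arcsinh}(\beta_* x), \qquad
  \alpha_* = 1/b_*, \quad \beta_* = b_* \sqrt{(N-3)/(N-1)}$$

has derivative $1/\sqrt{a + b_*^2 x^2}$, so $\sqrt N\, \zeta(\hat d)$ has
approximately unit variance regardless of the true effect. A second-order
mean (skewness) correction,
$\tfrac{b_*^2 \tilde c}{2N} \big( a + b_*^2 c^2 \big)^{-1/2}$ with $\tilde c$
the bias-corrected threshold, recenters the transformed threshold; after it,
the transformed deviate is close to standard normal even at N = 60 (the
package's tests verify its 0.9 quantile against $\Phi^{-1}(0.9)$ within 2%,
via `vst_zeta()`). Because $x \mapsto \alpha_* \operatorname{arcsinh}(\beta_* x)$
is strictly monotone, sets built on the transformed scale remain valid
statements about the original Cohen's d field.

The constants deserve one remark. The variance coefficient $b_*^2$ is
derived by substituting the $(1-\tfrac{3}{4N-5})^{-1}$ bias approximation
into the exact noncentral-t variance
$\tfrac{N-1}{N-3}(1 + N d^2) - N d^2 C_N^2$; carried through exactly, the
$d^2$ coefficient is $N(8N^2-17N+11)/(16 (N-3)(N-2)^2)$, while the package's
constants use the algebraically simplified denominator $(N-3)(4N-5)^2$. The
two agree to $O(1/N)$ and both pass the Gaussianity check above; the package
fixes one convention for the constants and uses the $16(N-3)(N-2)^2$ bracket
inside the skew offset, and pins correctness behaviorally through the
quantile test rather than through any single printed form. By construction
$\alpha_* b_* = 1$, which the test suite asserts to machine precision.

## Boundary, bootstrap, and assessment

**Plug-in boundary.** The supremum that calibrates $k$ runs over the
estimated set boundary. The package scans every axis-aligned edge between
in-mask neighbour voxels (4-connectivity in 2D, 6-connectivity in 3D) and
records edges where the decision field crosses the corrected threshold,
with linear interpolation weight $w = (\tau - f_u)/(f_v - f_u)$; a voxel
sitting exactly at the threshold contributes a crossing at weight 0 or 1
(a measure-zero tie, handled deterministically). For algorithms 1–2 the
decision field is $\hat d$; for algorithm 3 the crossings are computed on
the arcsinh scale, where its supremum lives — a monotone transform keeps
the same edge set but moves the weights. Residual values at each boundary
point are linearly interpolated with the same weights.

**Wild t-bootstrap.** Per replicate, N i.i.d. Rademacher signs $r_i^*$
multiply the standardized residuals, and the approximating field at each
boundary point is studentized by the standard deviation $\hat\sigma^*$ of
the signed values at that point — computed with mean-centering and divisor
N−1, matching the package-wide variance convention. The replicate's record
is the supremum of the absolute field over the boundary; the critical value
$k$ is the nearest-rank $(1-\alpha)$ percentile (the $\lceil (1-\alpha) B
\rceil$-th order statistic) of the B records — deterministic and slightly
conservative. Because Rademacher signs square to 1, the per-point sum of
squares is sign-free, and the whole bootstrap collapses to a single
$B \times N$ by $N \times P$ matrix product; B = 5000 replicates on a few
hundred boundary points take well under a second.

If the estimated boundary does not intersect the mask (the estimate never
approaches $c$ — a legitimate outcome under null data or extreme
thresholds), no supremum exists: the package returns both sets equal to the
point-estimate set, flags the result degenerate, and warns, rather than
failing.

**Coverage assessment.** A simulation trial counts as covered when the
lattice nesting $\hat A_c^+ \subseteq A_c \subseteq \hat A_c^-$ holds at
every voxel *and*, at every interpolated crossing of the true boundary
(edges where the true $d$ crosses $c$, weights from the true field), the
interpolated upper-set decision field is non-positive and the lower-set
field non-negative. The sub-voxel check catches violations that sit between
lattice points; its density is tied to the lattice, so signals with longer
boundaries are assessed at relatively sparser points — a known source of
slight upward bias in empirical coverage for such signals.

## The synthetic data generator

`make_signal()` and `make_noise()` reproduce the study conditions the
coverage experiments are defined under:

* **ramp2d** — linear ramp from 0 at the first x-column to 1 at the last
  (inclusive endpoints), constant in y, on 100×100; unsmoothed.
* **circle2d** — a radius-30 disk of magnitude 1 centred in 100×100,
  smoothed with a 3-voxel-FWHM Gaussian; not rescaled after smoothing (the
  wide disk's interior plateau remains at essentially 1).
* **sphere3d_small / sphere3d_large** — radius 5 / 30 spheres in
  100×100×100, smoothed, then rescaled imagewise to maximum 1.
* **multi_sphere3d** — four spheres smoothed and individually peak-rescaled
  so every sphere centre carries magnitude 1, with overlap regions clipped
  back to 1. The radii (4, 6, 8, 10) and centre positions are this
  package's choice; only the construction principle is prescribed.

Noise is white standard-normal noise smoothed with the same 3-voxel-FWHM
kernel, **standardized pointwise to exact unit variance** and multiplied by
the standard-deviation field: either homogeneous (sd 1, so the true d field
equals the signal) or rising linearly from 0.5 to 1.5 along the last axis
(so the variance profile is quadratic). Standardization uses the analytic
per-voxel sd of smoothed white noise — the separable product of
squared-kernel row sums — which handles edge truncation under zero padding
exactly rather than approximately. The kernel is truncated at $4\sigma$
with $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$.

What the generator does *not* emulate: non-Gaussian errors, spatially
varying smoothness, anatomically realistic signal geometry, or missing
data. Passing coverage here demonstrates correctness of the procedure under
its stated assumptions, not robustness beyond them; the
variance-stabilizing transform in particular assumes Gaussianity, while
algorithm 2 estimates its standardization from the data and is expected to
degrade more gracefully.

## Numerical conventions and edge cases

* **Variance divisor.** The sample variance uses divisor N−1 throughout.
  This makes $\sqrt N \hat d$ *exactly* noncentral-t with N−1 degrees of
  freedom and makes $\hat d = t/\sqrt N$ for the usual one-sample t
  statistic. (With divisor N the characterization holds only
  approximately.) Consequently the residual centering constant is the
  empirical mean $(N-1)/N$ rather than 1, preserving the exact mean-zero
  residual identity under either convention.
* **$\hat\sigma_R$ divisor.** The residual sample second moment uses
  divisor N (the residuals are exactly mean-zero by construction).
* **Degenerate voxels.** Voxels with zero sample variance are dropped from
  the mask with a warning by default (real masks contain constant voxels at
  edges); an error mode is available.
* **Point-estimate set.** Defined as $\{\hat d \ge c(1-\tfrac{3}{4N-5})^{-1}\}$
  for every algorithm, so the nesting
  upper ⊆ point estimate ⊆ lower is exact for algorithms 1–2 at any
  $k \ge 0$. For algorithm 3 the band is drawn around the transformed
  threshold including the small skew offset, so nesting of the point
  estimate is guaranteed only when $k/\sqrt N$ exceeds that offset — in
  practice the offset is of order $10^{-3}$ while $k/\sqrt N$ is two orders
  larger, and the suite asserts nesting on every simulated run.
* **Ties and empty results.** Threshold ties at voxels produce
  deterministic weight-0/1 crossings; an empty boundary yields flagged
  degenerate sets (see above); an empty true excursion set makes
  sensitivity undefined (error) while coverage reduces to requiring an
  empty upper set.
* **Non-finite values** in residuals abort with a voxel diagnostic; nothing
  is clipped silently.
* **Determinism.** A single seed drives signal-independent noise draws and
  replicate-major bootstrap signs; every pipeline output, including files
  written by the command-line tool, is bitwise reproducible under a fixed
  seed.

## Problem sizes used for validation

The packaged test suite reproduces the study's qualitative findings at desk
scale: 300 Monte-Carlo trials with B = 500 bootstrap replicates for the
coverage targets (the full study design uses 3000 trials and B = 5000;
empirical coverage is binomial, so 300 trials give a ±3-SE window of about
±0.06 at the 80% level and ±0.034 at 96%), and 200 trials for the
sensitivity bound. Distributional identities are checked with $10^5$–$2
\times 10^5$ single-voxel replications. These counts are the package's
validation design; `sim_config()` defaults to the full-scale study values.

## A worked example

```{r example, eval = FALSE}
library(cohensdCS)

# study-style design: circular effect, homogeneous smoothed noise, N = 120
sig   <- signal_spec("circle2d")
noise <- noise_spec()
grid  <- domain_grid(sig$shape)

set.seed(7)
stack <- make_noise(grid, noise, 120)
stack$data <- stack$data + make_signal(sig)

cs <- compute_confidence_sets(stack, c = 0.8, alpha = 0.05,
                              algorithm = 3, n_boot = 5000, seed = 7)
print(cs)

truth <- truth_set(make_signal(sig), grid, noise, 0.8)
assess_coverage_trial(cs, truth)
upper_cs_sensitivity(cs, truth)
```

A scaled-down coverage experiment (the full harness behind the package's
validation):

```{r harness, eval = FALSE}
res <- run_experiment(
  sim_config(n_trials = 300, n_boot = 500, sample_sizes = c(60, 240),
             levels = c(0.80, 0.95), c = 0.8, algorithms = c(2, 3), seed = 1),
  signal_spec("circle2d"), noise_spec())
res
```

## Known limitations

* One-sample designs only; the general-linear-model extension (standardized
  contrasts) is out of scope.
* Gaussian-error theory; heavy-tailed or skewed subject noise is untested
  territory, especially for algorithm 3.
* A single threshold per bootstrap run; simultaneous multi-threshold sets
  and false-discovery-rate-controlled variants are not provided.
* The interpolation-based coverage assessment is tied to the lattice
  resolution and is slightly optimistic for signals with very long
  boundaries.
* Sensitivity of the upper set is intrinsically low in small samples —
  of order a few percent of the true cluster at N = 60 under these designs —
  which is a property of the inferential goal (simultaneous spatial
  confidence), not an implementation artefact.
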