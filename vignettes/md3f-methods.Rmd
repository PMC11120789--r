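---
title: "Drift estimation from interpoint distances: model, design and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drift estimation from interpoint distances: model, design and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(md3f)
```

## The model

A longitudinal multivariate profile (a microbial composition, an expression
vector) is modelled as a random walk M_s in p dimensions. The displacement
over a finite interval t is Gaussian,

$$X_t = M_{s+t} - M_s \sim N(\alpha t W,\ \Xi_t),$$

with drift magnitude $\alpha \ge 0$, unit drift direction $W$, and a diffusion
covariance $\Xi_t$ that grows linearly with the interval (for the isotropic
walk used in simulation, $\Xi_t = t I$). Because Euclidean distances are
invariant under orthonormal changes of basis, the drift direction can be
rotated onto the first axis without changing any interpoint distance — which
is why an inference based *only* on distances can be basis-free and need not
estimate $W$ at all.

Expanding the quadratic form of the squared displacement and using a Gaussian
approximation for the diffusion part yields the working regression model: the
squared interpoint distance decomposes into a term $\alpha^2 t^2$ from the
drift, a term linear in $t$ from diffusion, and mean-zero noise. Dividing by
$t$,

$$\frac{d^2(M_s, M_{s+t})}{t} = r + \beta\, t + e, \qquad \beta = \alpha^2,$$

so the time-scaled squared distance is **linear in the interval length**, with
an intercept $r$ absorbing the per-unit-time diffusion contribution (equal to
$d$ for a unit-rate isotropic walk in $d$ dimensions). `fit_md3f()` fits this
by ordinary least squares with an intercept and reports the slope, its
two-sided coefficient t-test p-value, and the drift-magnitude estimate
$\hat\alpha = \sqrt{\max(\hat\beta, 0)}$ (a magnitude cannot be negative; the
raw slope is reported alongside).

### Why the time-scaled response is the default

Two readings of the squared-quantities model are possible: regress $d^2$ on
$t^2$ ("literal"), or regress $d^2/t$ on $t$ ("time_scaled"). They differ
materially. Under pure diffusion $d^2$ given $t$ has mean $c\,t$ and variance
growing with $t$; in the literal regression this diffusion term is correlated
with the regressor $t^2$, inflating the slope and the type I error. After
time-scaling, the diffusion contribution moves into the intercept:
conditional on $t$, $d^2/t$ has mean $\alpha^2 t + c$, so the slope is an
unbiased estimate of $\alpha^2$ under both null and alternative, and for the
isotropic pre/post generator the null response $d^2/s \sim \chi^2_d$ is even
independent of the regressor, giving near-exact calibration. `time_scaled` is
therefore the default; `literal` is retained as a flag, and the unsquared
estimator (`model = "linear"`, response $d/\sqrt t$ on $\sqrt t$, slope
estimating $\alpha$ itself) is retained for comparison — the bias grid shows
its dimension-driven bias, which is the reason the squared model is preferred.

### Pairing modes

`build_pairs()` turns a distance matrix plus a (subject, time) design into
regression pairs. The default, `baseline`, pairs each observation with the
subject's first one, measuring intervals from the start of the walk;
`consecutive` and `all_pairs` are available. Within-subject pairs are not
independent; the OLS deliberately ignores this dependence (slopes remain
unbiased since the conditional mean is exact), and per-subject fitting
(`fit_per_subject()`) followed by a group comparison on the per-subject
estimates (`compare_group_drifts()`, pooled-variance Student t-test) is the
supported route for between-group questions.

## Parameters that matter

* **model** (`linear2`/`linear`) and **scaling** (`time_scaled`/`literal`):
  above. Defaults: `linear2`, `time_scaled`.
* **mode** (`baseline`): pairing rule; all modes coincide for two-timepoint
  designs.
* **pseudocount** for the CLR transform: default half the smallest positive
  table entry when zeros are present. Chosen to avoid scale dependence; it is
  a disclosed, overridable convention, and analyses of zero-heavy tables
  should examine sensitivity to it.
* **time_rate** (default 1, per unit study time): rate of the exponential
  interpoint-time distribution in the pre/post simulator. Time-scaled
  calibration and unbiasedness are invariant to it (exercised at rates 0.5
  and 2 in the tests); 1 is the conventional unit-mean choice.
* **level** (default 0.05): nominal significance threshold of the study
  runner.

## The simulator

`simulate_prepost()` generates the two-timepoint design used throughout the
operating-characteristics study: per subject an interval
$s \sim \mathrm{Exp}(\text{rate})$, the pre observation at the origin, and a
displacement $X \sim N(\alpha s W,\ sI)$ with $W = \mathbf 1_d/\sqrt d$ by
default, so each coordinate has mean $\alpha s/\sqrt d$ and the mean
displacement norm is $\alpha s$ exactly. `simulate_trajectory()` generates
multi-step walks with Gaussian increments of mean $\alpha\,dt\,W$ and
covariance $dt\,I$ on a regular grid. Study conditions follow the pre/post
design with exponential unit-rate intervals; the grid presets cross
$n \in \{10, 20, 50, 100\}$, $d \in \{1, 10, 100, 1000\}$ (or 400 in the
`paper-figure2` preset) and $\alpha \in \{0, 0.5, 1, 2, 3\}$.

What the simulator emulates — and what it does not: isotropic, uncorrelated
Gaussian diffusion with no missing values, no compositional closure, no
count noise, and a drift of equal magnitude in every dimension. Passing tests
under this generator demonstrate the statistical properties of the estimator
under its own model; they do not certify behaviour under correlated features,
heavy-tailed noise, or sparse counts, where the distances themselves (e.g.
Aitchison with a pseudocount) carry additional modelling choices.

Seeding: every scenario takes one seed; grid runners derive one seed per
(cell, replicate) from the root seed by a fixed affine map modulo
$2^{31}-1$, so results are deterministic, order-independent and
parallelisable.

## Baseline methods

Five minimum-p procedures are implemented exactly as commonly practised, as
comparison points rather than recommendations: regression of the first
principal coordinate on time (PCo1), the minimum over the first two (PCo2) or
all retained coordinates (PCoA) *without* multiplicity adjustment, and
per-feature screens with Benjamini–Hochberg (uFDR) or Holm (uHolm)
adjustment. Under diffusion the displacement variance grows with the
observation time, so each per-axis regression is heteroscedastic and
anticonservative, and taking minima compounds this; the study runner measures
the resulting over-rejection. The unadjusted minima in PCo2/PCoA are part of
the procedures being evaluated and are deliberately not "corrected".

## Numerical choices

* **PCoA** (`pcoa_embed()`): Gower double-centering of $-\tfrac12 D^2$ and a
  symmetric eigendecomposition. Axes with eigenvalue below
  $\max(n,1)\,\varepsilon\,\lambda_{\max}$ are dropped; dropped
  negative-eigenvalue axes (non-Euclidean dissimilarities) are counted and
  warned about, with no Cailliez/Lingoes correction so that baseline
  behaviour is not silently altered. Each axis is oriented so its
  largest-magnitude coordinate is positive, for reproducible output.
* **Degenerate fits**: a constant response short-circuits to slope 0 with
  p = 1; an exactly collinear (noiseless) fit reports p = 0 for a nonzero
  slope. Zero-variance features in the univariate screen get p = 1 with a
  warning rather than a spurious perfect fit.
* **Negative slopes** are kept as slopes but clipped at zero in the
  drift-magnitude estimate.
* **Duplicate (subject, time) records** error by default; `dedupe = "first"`
  keeps the first occurrence. Subjects with fewer than two timepoints are
  skipped with a warning; per-subject fitting additionally requires three
  pairs (slope, intercept, one residual degree of freedom).
* **Row-sum filtering** applies to the table as given, with no prior
  rescaling — whether to renormalise before filtering is a dataset-level
  decision the tool does not make silently.
* The slope test is **two-sided** by convention, although $\beta = \alpha^2
  \ge 0$ under the model would license a one-sided test.

## Monte-Carlo problem sizes

The shipped tests and the acceptance script use 2000 replicates for
rejection-rate checks (99% binomial band half-width ±0.0126 around 0.05),
500 for bias at a single cell, and 1000 trajectories for drift recovery —
sizes at which the Monte-Carlo bands are tight enough to be informative while
a full run stays in the minutes range on one core. The null-bias check uses
2000 replicates because the slope distribution under exponential leverage is
heavy-tailed and the 3-SE band relies on the central limit theorem. Where a
calibration regression has variance growing with the regressor (the
simulator's moment identity), tests use heteroscedasticity-consistent
(sandwich) standard errors as the Monte-Carlo SE.

## A small end-to-end run

```{r example}
sim <- simulate_prepost(md3f_scenario(n = 40, d = 10, alpha = 1.5, seed = 7))
fit_md3f(prepost_pairs(sim))
```

## Known limitations

* The Gaussian approximation behind the regression is asymptotic in the
  number of dimensions; in univariate data with small samples the squared
  model's type I error can sit slightly above nominal.
* Drift *direction* is out of scope by design, as are mixed-effects pooling
  across subjects, restricted permutation tests, phylogeny-aware distances
  (UniFrac) and missing-value imputation.
* Power falls as dimension grows at fixed drift magnitude, since every extra
  dimension adds diffusion noise but no signal; the grid runner quantifies
  this trade-off for planning.
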