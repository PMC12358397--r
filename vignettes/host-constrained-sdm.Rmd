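---
title: "Host-constrained maximum-entropy habitat modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host-constrained maximum-entropy habitat modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hostSDM models the potential distribution of an obligate parasite in two
dimensions: the parasite's own environmental niche, and the availability of
its host. The motivating system is a desert holoparasite (e.g. *Cistanche
deserticola*, which parasitizes the roots of *Haloxylon ammodendron*), but
every component is generic. This vignette describes the model, the design
choices behind the numerical machinery, and what the synthetic test system
does and does not demonstrate.

## The maximum-entropy model

Presence-background species distribution modelling estimates a probability
distribution over landscape cells. Given expanded features $f(x)$ of the
environmental predictors, the model is the Gibbs density

$$ \mathrm{raw}(x) = \frac{e^{\lambda \cdot f(x)}}{Z}, \qquad
   Z = \sum_{b \in \text{background}} e^{\lambda \cdot f(b)}, $$

the maximum-entropy distribution whose feature expectations are pulled
toward the presence-sample means. `maxent()` maximizes the equivalent
penalized log likelihood

$$ \frac{1}{m}\sum_{\text{presence}} \lambda \cdot f(x)
   \;-\; \log \sum_{\text{background}} e^{\lambda \cdot f(b)}
   \;-\; \sum_j \beta_j |\lambda_j|, $$

which is concave in $\lambda$. The L1 penalty widths $\beta_j$ follow the
reference defaults per feature class, interpolated against the presence
count $m$ and scaled by the feature's background standard deviation and
$1/\sqrt{m}$; the regularization multiplier (RM) scales every $\beta_j$
linearly, so larger RM gives sparser, smoother models.

Feature classes are the conventional five: linear (L), quadratic (Q),
pairwise products (P), forward/reverse hinges (H) and step thresholds (T).
Each raw variable is first scaled to $u = (v - \min)/(\max - \min)$ over
the background and clamped to $[0, 1]$ at projection time (clamp counts
are recorded, not warnings per cell). Hinge and threshold knots sit on a
uniform grid over $[0, 1]$ — 50 per variable per direction by default;
threshold indicators use a strict `>`, so a value exactly at a knot does
not trigger the step.

The "logistic" suitability index in $[0,1]$ is the entropy-based transform
$P = e^H \mathrm{raw} / (1 + e^H \mathrm{raw})$, with $H$ the Shannon
entropy of the fitted background distribution. A null model
($\lambda = 0$) therefore scores $P = 0.5$ everywhere, and $P$ is a
monotone rescaling of the raw density.

### Optimization

The objective is maximized by monotone proximal gradient (gradient step on
the smooth part, soft-thresholding for the L1 term) with a backtracking
line search, the step growing 1.5-fold after each accepted iteration. Two
conditions must hold to stop: the relative objective change falls below
`tol` (default 1e-7), and the KKT subgradient residual falls below 2e-6 —
the second guards against stopping early on a flat stretch of the
objective. Unit tests pin the 1-D fit to an independent golden-section
search of the same objective to within 1e-4. Non-convergence within
`max_iter` (default 10^4) returns the model with `converged = FALSE` and a
warning rather than an error.

Two documented toggles the reference tool leaves implicit: the background
size (default 10^4 cells, or all valid cells when fewer) and whether
presences are also background cells — `sample_background()` samples the
mask uniformly, so presences enter the background only when their cells
are drawn.

## Model tuning and evaluation

`tune_maxent()` evaluates the feature-combination × RM grid (defaults: L,
LQ, LQH, H, LQHP, LQHPT × 0.5–4 by 0.5, i.e. 48 combinations) with a
shared background and train/test split. Model complexity $k$ counts
coefficients with $|\lambda_j| > 10^{-7}$; the likelihood for AICc
standardizes the raw density over *all* valid study cells and evaluates it
at the presences, and $\mathrm{AICc}$ is undefined when $k = 0$ or
$k \ge n - 1$. The selected row has $\Delta\mathrm{AICc} = 0$; ties break
toward smaller $k$, then larger RM, then grid order — a deterministic rule
the underlying criterion does not supply.

Evaluation follows the standard replicate protocol: 10 random 75/25
presence splits (each replicate redraws the background too), test AUC by
the rank-sum (Mann–Whitney) estimator with background as pseudo-absence,
and the cell-wise mean of the replicate logistic layers as the working
suitability surface. "Percent contribution" is implemented as normalized
permutation importance — the mean AUC drop when one variable is permuted
across evaluation cells, floored at zero and normalized to 100 — because
the reference tool's path-dependent attribution is not reproducible from
its description. Jackknife gains refit the model with each variable alone
and withheld and report the regularized training gain
($\tfrac1m\sum\lambda f - \log Z + \log n_{bg}$, zero for the null
model).

Collinearity filtering mirrors contribution-aware practice: variables with
non-positive contribution are dropped, then the pair with the largest
$|r| \ge 0.8$ (Pearson, over jointly valid cells) repeatedly loses its
lower-contribution member. Greedy max-|r|-first order and
input-order tie-breaks make the outcome deterministic.

## The host constraint

The package's distinctive step couples two models. The host is fitted
first; its mean replicate suitability layer $P_{HA}$ then enters the
parasite model twice:

* as a **spatially explicit predictor** appended to the environmental
  stack (the Parasitic Constraint Scenario, PCS), and
* as a **conditional probability transfer** applied to the parasite's
  mean prediction: wherever $P_{HA} < \theta$ the parasite suitability is
  forced to zero; where $P_{HA} \ge \theta$ the model's own response
  stands. The default $\theta = 0.4$ is the medium-or-high suitability
  cut, read as the threshold for effective parasitism.

The transfer is idempotent and guarantees the subset invariant — every
PCS-suitable cell ($P \ge 0.4$) is host-suitable — which the tests assert
unconditionally. The masking is applied to the *mean* replicate layer
(masking before averaging would give the same zero set but different
intermediate values; the order is a documented choice). The Natural
Habitat Scenario (NHS) is the same parasite model on the environmental
predictors alone. Scenario divergence is summarized per suitability class
by the area difference rate

$$ \frac{A_{PCS} - A_{NHS}}{A_{NHS}} \times 100\% , $$

undefined (flagged `NA`) when the reference area is zero. Whether the
(FC, RM) pair should be re-tuned for the PCS model is genuinely open; the
default reuses the supplied settings for both scenarios and `tune = TRUE`
in `run_study()` tunes them independently.

## Classification, change and centroids

Suitability classes use half-open bins at 0.2 / 0.4 / 0.6: unsuitable
$P<0.2$, low $0.2 \le P < 0.4$, medium $0.4 \le P < 0.6$, high
$P \ge 0.6$; the binary suitable map cuts at $P \ge 0.4$. Change maps
code the four binary transitions (0–0 stable unsuitable, 0–1 expansion,
1–0 contraction, 1–1 stable suitable), which partition the valid grid
exactly.

Cell areas are spherical latitude-band slices
$R^2\,\Delta\lambda\,(\sin\varphi_t - \sin\varphi_b)$ on the authalic
radius $R = 6371.0072$ km — closed-form and reproducible, where a GIS
might use planar or ellipsoidal areas (the difference is well below the
rounding of reported figures). Range centroids are suitable-cell centers
averaged with these areas as weights; whether a GIS toolbox weights by
area or counts cells equally is unspecified in common descriptions, so
area-weighting is the documented choice here. Longitude averaging assumes
the region does not span the antimeridian and errors if it does.
Centroid shifts are haversine distances (geosphere, same radius) with the
initial bearing.

## Synthetic landscapes

`generate_env_layers()` builds predictors as Gaussian random fields —
white noise smoothed by a separable Gaussian kernel (`smoothness` = kernel
SD in cells), rescaled linearly to $[0,1]$; inter-layer correlation comes
from mixing a shared latent field with weight $\sqrt{r}$. The canonical
test system (`synthetic_study()`) places unimodal niches
$\eta = b_0 - \sum_i b_i \left((u_i - c_i)/s_i\right)^2$ anchored to each
realized field's mean and SD: anchoring to the field's moments rather
than to fixed values of the rescaled scale keeps the suitable fraction of
the landscape stable across random realizations (min–max rescaling shifts
the value distribution from seed to seed). The host responds to
`env1`/`env2` ($b = 12, 10$, $b_0 = 3$, optimum 0.2 SD above the mean on
`env1`), the parasite to `env2`/`env3` ($b = 10, 10$, $b_0 = 3.5$) masked
by host truth $\ge 0.4$ — so the parasite's truth is genuinely
two-dimensional: environment times host availability. Default sampling:
234 host and 200 parasite presences on a 100 × 100 grid at 2.5
arc-minutes, drawn without replacement with probability proportional to
truth. These sizes keep the full two-scenario study and its five-seed
evaluation within a few minutes on one CPU while leaving presences an
order of magnitude fewer than cells.

What passing the synthetic suite shows: the fitting engine recovers a
known linear+quadratic niche in rank (ρ ≥ 0.9), discriminates presences
from background (mean test AUC ≥ 0.85 in both scenarios across five
seeds), and the constraint machinery enforces its invariants exactly.
What it does not show: robustness to sampling bias, spatially aggregated
survey effort, predictor measurement error, niche shapes outside the
linear+quadratic family, or truly independent test data — real
occurrence data violate all of these, and the AUC of a real study is not
comparable to the synthetic one.

## Numerical choices and degenerate inputs

* Correlations require ≥ 3 jointly valid cells; a zero-variance layer
  yields flagged `NA` correlations, never a silent zero.
* A predictor with zero background range contributes constant features
  and a warning (this arises naturally when a degenerate host layer is
  appended in the PCS stack).
* Presences in nodata cells are excluded from AICc with a warning; rows
  with unparseable coordinates are dropped with a logged count.
* Occurrence thinning keeps the first record per cell in file order;
  cells are half-open ($[w, e) \times (s, n]$) so boundary points map to
  exactly one cell.
* An empty stable-suitable mask or an all-undefined AICc grid is an
  explicit error/warning, not a silent zero.
* All stochastic steps (background draws, splits, replicate seeds, field
  generation, occurrence sampling) derive from explicit integer seeds and
  restore the caller's RNG state.

## Limitations

The engine fits continuous predictors only (no categorical features or
bias grids), one output transform (the entropy-based logistic), and the
single 75/25 replicate protocol rather than spatial block
cross-validation. Areas are spherical, not ellipsoidal. The host
constraint is a hard threshold: it encodes obligate parasitism as
presence/absence of host habitat, not host density or infection dynamics.
Land-use layers must already be co-registered with the analysis grid —
there is no resampling.
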