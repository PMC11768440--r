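---
title: "Methods: dust hazard screening and multivariate structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dust hazard screening and multivariate structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dustrisk)
```

## The exposure model

For an adult in contact with metal-laden dust, the average daily dose of
metal $k$ through each path is

$$\mathrm{ADD}_{k,\mathrm{ing}} = \frac{c_k \, R_\mathrm{ing} \, EF \, ED}{BW \cdot AT} \times 10^{-6}, \qquad
\mathrm{ADD}_{k,\mathrm{inh}} = \frac{c_k \, R_\mathrm{inh} \, EF \, ED}{PEF \cdot BW \cdot AT}, \qquad
\mathrm{ADD}_{k,\mathrm{derm}} = \frac{c_k \, SA \cdot SL \cdot ABS \, EF \, ED}{BW \cdot AT} \times 10^{-6},$$

with $c_k$ in mg/kg and the factors of `exposure_factors()`: ingestion rate
$R_\mathrm{ing}$ = 100 mg/day, inhalation rate $R_\mathrm{inh}$ = 20 m³/day,
body weight 70 kg, exposure frequency 365 day/yr over 24 yr, skin surface
5700 cm², adherence 0.07 mg/cm², dermal absorption 0.001, and particle
emission factor $1.36 \times 10^9$ m³/kg. The averaging time defaults to
$365 \times ED$ days — the non-carcinogenic convention, under which
$EF \cdot ED / AT = 1$ — but remains an explicit field so other averaging
scenarios stay expressible. Quotients $HQ = \mathrm{ADD}/\mathrm{RfD}$ use the
path-specific reference doses of `rfd_table()`; the hazard index sums all
quotients per site. The screening threshold is the strict inequality
$HI > 1$: equality is reported safe. An advisory band boundary (default 0.5)
is echoed in the concordance output for monitoring narratives but never
asserted by any test. Every quantity in the chain is homogeneous of degree 1
in the concentrations, which the tests exploit as an exact invariant.

Dose summaries are emitted in natural units alongside columns scaled by
$10^8$ (a common presentation convention for these small doses); the scale is
explicit in the column names rather than implicit in the values.

## PCA and component selection

PCA is performed on the correlation matrix of column-standardized
concentrations ($n-1$ denominator), because the metals span four orders of
magnitude. Four retention rules are reported side by side rather than fused:

* **Kaiser**: count of eigenvalues strictly greater than 1 (ties excluded).
* **Cumulative variance**: smallest $k$ reaching the configured fraction
  (default 0.80).
* **AIC/BIC minimization** over a profile log-likelihood $L_k$: the Gaussian
  likelihood of the standardized data under a covariance that keeps the top
  $k$ eigencomponents and replaces the discarded eigenvalues by their mean
  (isotropic residual). This is the standard probabilistic-PCA profile
  likelihood, and it is the likelihood for which accepting one more component
  under per-component AIC reduces approximately to an eigenvalue threshold of
  the $\exp(-2/n)$ form.
* **Sequential eigenvalue thresholds**: keep adding component $k+1$ while
  $\lambda_{k+1} > \exp(-2/n)$ (AIC form) or $\lambda_{k+1} > n^{1/n}$ (BIC
  form).

The rules frequently disagree at $n = 14$, which is informative in itself;
the pipeline reports all of them in `pca_selection.json`. Eigenvector signs
are fixed by making each vector's largest-magnitude entry positive; cos2 and
contribution tables follow the usual conventions (variable cos2 =
$\lambda_j e_{vj}^2$, contributions $100\,e_{vj}^2$ summing to 100 per
component).

## Factor analysis

Extraction is maximum likelihood (minimizing
$F = \log|\Sigma| - \log|R| + \mathrm{tr}(R\Sigma^{-1}) - p$ with
$\Sigma = \Lambda\Lambda' + \Psi$), followed by an oblique **oblimin**
rotation implemented with the gradient-projection algorithm (quartimin
criterion, ten seeded random orthogonal starts to avoid local optima; the
identity start is always included and the best criterion value wins).
Oblique rotation is essential here: realistic metal sources are correlated,
and reference solutions for this kind of data show factor correlations
around 0.5.

Per-variable diagnostics follow the oblique conventions: communality
$h^2 = \mathrm{diag}(\Lambda\Phi\Lambda')$, uniqueness $u^2 = 1 - h^2$,
Hoffman complexity $(\sum_f \lambda^2)^2 / \sum_f \lambda^4$ (1 = pure
single-factor variable), SS loadings $\mathrm{diag}(\Lambda'\Lambda\Phi)$.
Fit statistics use the Bartlett-corrected
$\chi^2 = (n - 1 - (2p+5)/6 - 2m/3)\,F_{\min}$ with
$df = ((p-m)^2 - (p+m))/2$, RMSR over off-diagonal residuals, and a TLI
against the independence model. The information criteria driving the default
retention rule are the degrees-of-freedom forms $BIC = \chi^2 - 2\,df$ and
$AIC = \chi^2 + 2\,df$ (their difference is exactly $4\,df$); the
conventional sample-size-penalized $\chi^2 - df\ln n$ is reported under a
separate name for comparison. Uniquenesses below 0.001 (Heywood cases) are
floored and flagged rather than aborting — with $n$ in the teens they are
routine. Factor labels follow extraction order; no semantic meaning attaches
to the ordering.

The retention battery combines parallel analysis (observed eigenvalues
versus the **mean** — not 95th percentile — of eigenvalues from
standard-normal data of the same shape), VSS at complexities 1 and 2 (loading
matrix simplified to its $c$ largest entries per row;
$VSS = 1 - \|R - \Lambda_s\Phi\Lambda_s'\|^2_{\mathrm{off}} /
\|R\|^2_{\mathrm{off}}$, with the $m = 0$ baseline defined as 0), and the
AIC/BIC curves. The pipeline default is the BIC argmin. A consequence of the
mean-comparison choice worth knowing: on pure noise the first observed
eigenvalue exceeds its random mean in roughly half of draws, so parallel
analysis keeps one or two spurious factors in a minority of noise datasets;
the percentile variant would suppress these but is not what this battery
implements.

Because concentration data are strictly positive and right-skewed, the
factor-analysis and clustering recovery analyses in this package operate on
**standardized log-concentrations** — the scale on which a linear factor
model for such data is plausible. Running ML factor analysis on the raw
exponentiated scale visibly degrades model-order selection (the lognormal
warp acts as a structured model violation that information criteria chase
with extra factors).

Regression factor scores use $W = R^{-1}\Lambda\Phi$; score adequacy reports
$R^2 = \mathrm{diag}(\Phi\Lambda'R^{-1}\Lambda\Phi)$, its square root, and
the minimum correlation $2R^2 - 1$.

## t-SNE

The embedding is written from first principles. Conditional affinities
$p_{j|i} \propto \exp(-\|x_i - x_j\|^2 / 2\sigma_i^2)$ are calibrated per
point by bisection on the precision so that the row perplexity $2^{H(P_i)}$
hits the target within $10^{-5}$ bits (default); duplicated points make the
calibration impossible and raise an error naming the pair. The joint
distribution is the canonical symmetrization
$P_{ij} = (p_{j|i} + p_{i|j})/2n$. Low-dimensional similarities use the
Cauchy kernel $q_{ij} \propto (1 + \|y_i - y_j\|^2)^{-1}$, whose heavy tail
counters the crowding problem. The KL objective
$\sum_{i \ne j} P_{ij}\log(P_{ij}/Q_{ij})$ is minimized by plain momentum
gradient descent with the exact gradient
$4\sum_j (P_{ij} - q_{ij})(1 + \|y_i - y_j\|^2)^{-1}(y_i - y_j)$, constant
momentum, and no early exaggeration by default (an exaggeration factor and
duration are exposed but off). Defaults: 2 output dimensions, perplexity 3,
learning rate 50, momentum 0.5, 500 iterations — sized for the ~14-point
surveys this package targets; a 100-iteration quick look is a config change.
Initialization is a seeded standard normal scaled by $10^{-4}$, small enough
for stable affinity matching at these sample sizes.

Numerical note: the momentum dynamics amplify floating-point perturbations
by roughly an order of magnitude every few iterations during the early
expansion phase. Affinities are exactly equivariant to rigid rotations of
the input, and the KL trace of a rotated input matches to ~1e-9 over a
30-iteration horizon, but bitwise trace agreement over hundreds of
iterations should not be expected from mathematically equivalent inputs —
only from identical ones (same data, parameters, seed, which the tests do
assert bit-for-bit).

## Hyperparameter optimization and cluster quality

`optimize_tsne()` tunes (perplexity, learning rate, momentum) over
$[2, n-2] \times [10, 1000] \times [0.5, 0.9]$ with a Gaussian-process
surrogate (anisotropic squared-exponential kernel on inputs rescaled to the
unit cube, hyperparameters by marginal likelihood) and expected improvement
with a $10^{-6}$ jitter, acquisition maximized over a seeded 500-point
candidate set. The initial design is an 8-point maximin Latin hypercube whose
first point is replaced by the default t-SNE configuration, so the incumbent
can never end worse than the default under the same seed policy. Default
budget: 30 evaluations. Each evaluation runs a full t-SNE whose seed derives
deterministically from the master seed and the evaluation index — the
objective is a deterministic function of the parameters, otherwise the
surrogate would fit seed noise at these sample sizes.

Three objectives are offered: final KL divergence (minimized), mean
silhouette of the clustered embedding (maximized; negated internally), and
Sammon error (minimized). A caveat stated rather than hidden: the KL
objective's $P$ changes with perplexity, so KL values at different
perplexities are not strictly commensurable; the optimizer treats the number
as-is, which in practice drives perplexity toward the top of its range
unless the data resist.

Cluster assignment uses seeded k-means (10 restarts); with `k = "auto"` the
count in $\{2, \dots, \min(6, n-2)\}$ maximizing the mean silhouette wins.
Quality metrics: mean pairwise intra-cluster distance per cluster (0 with a
flag for singletons), pooled mean cross-cluster pairwise distance (a
centroid-linkage alternative is available by flag), silhouette
$s_i = (b_i - a_i)/\max(a_i, b_i)$ with singletons scored 0, and the Sammon
error $E = (\sum_{i<j} d^*_{ij})^{-1} \sum_{i<j} (d^*_{ij} -
d_{ij})^2/d^*_{ij}$. Each has an independent brute-force double-loop oracle
in the test suite agreeing to $10^{-10}$.

The concordance report aggregates the hazard index within each cluster,
ranks clusters by mean HI, and cross-tabulates membership against empirical
HI terciles, with boundary ties assigned to the lower band.

## The synthetic generator

`generate_dataset()` draws site factor scores from $N(0, \Phi)$, assembles
log-concentrations as base level + cluster shift + $\Lambda f$ + unique
noise, and exponentiates, guaranteeing positivity and right skew. Defaults
describe a 14-site, 10-metal survey: three source factors in blocks
(Zn–Fe–Cu–Pb, Cr–Mn–Ba, Co–Cd–Ni) with loading 0.8 and a 0.5 correlation
between the first two factors; unique noise SD 0.6 per metal (unit total
log-variance); base levels at order-of-magnitude typical urban values (Fe 75,
Zn 90, Mn 40 … Cd 0.3 mg/kg); and three site clusters shifted by ±0.6 on the
log scale — about the threefold HI spread seen across real surveys of this
kind. A single integer seed drives one generator stream; identical
configurations regenerate bit-identical tables.

What the generator does *not* emulate: spatial autocorrelation, censoring at
detection limits, heteroscedastic measurement error, or any geochemical
mass-balance constraint. Passing recovery tests therefore demonstrate that
the statistical machinery recovers the structure it assumes, not that field
data satisfy those assumptions.

One identifiability fact the tests respect: when strong common factors load
every metal positively, a uniform cluster shift points along the dominant
factor direction, and k-means separability is governed by the *total*
within-cluster variance (communal + unique), not the unique noise alone.
The cluster-recoverability checks therefore use a weak-loading configuration
(0.3) in which within-cluster spread is noise-dominated, and shifts of three
noise SDs then yield adjusted-Rand recovery ≥ 0.9 in 20/20 seeds.

## Problem sizes and seeds

The deterministic seed chain derives stage seeds and per-evaluation seeds
from one master seed through a fixed linear-congruential step, all within
the 32-bit range. The recovery studies in the test suite use the sizes this
package considers informative for its claims: 20 seeds at $n = 300$ for
model-order recovery, 20 seeds at $n = 30$ for cluster recovery, 10 datasets
with a 15-evaluation budget for the optimizer comparisons, and 50 random
instances ($n \le 12$) for the oracle-equivalence checks.

## Known limitations

* Adults only; no child exposure profile, no carcinogenic slope-factor risk,
  no Monte-Carlo uncertainty on the exposure factors.
* Missing concentrations are rejected, never imputed.
* ML factor analysis at $n = 14$ is fragile: Heywood flooring, rotation
  multimodality and wide information-criterion variance are all expected;
  the package reports every retention rule precisely so that no single
  number is over-trusted at that sample size.
* The dense t-SNE and GP implementations are sized for tens of sites, not
  thousands; no tree or FFT acceleration is attempted.
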