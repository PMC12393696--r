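---
title: "Management practices and CBO performance: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Management practices and CBO performance: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgmtperf)
```

## The problem

Community-based organizations (CBOs) deliver HIV services — antiretroviral
therapy (ART), HIV testing (HTS), STI screening, condom outreach — to key
populations under severe resource constraints. A standing question in
health-systems research is how much of the variation in facility
performance (cost efficiency, service volume, outreach quality) is
associated with management capacity, and which management domains matter
most. This package implements that analysis as a reusable pipeline and
pairs it with a synthetic data generator whose ground truth is known, so
that every estimator in the chain can be validated by parameter recovery
rather than by eyeballing.

## The management index

Management is measured by 67 yes/no practice items grouped into six
domains (target setting 7, performance monitoring 18, people management
20, operations management 11, financial management 7, community
engagement 4). Scoring follows the efficient GLS summary-index tradition:

1. Each item is z-scored with the sample (n−1) standard deviation.
   Zero-variance items are dropped and reported; they carry no ranking
   information and imputing them would only dilute the index.
2. Within a domain with standardized item matrix $\tilde X$ and sample
   covariance $\Sigma$, the index weights are
   $w = (1'\Sigma^{-1}1)^{-1}\,\Sigma^{-1}1$, i.e. proportional to the row
   sums of $\Sigma^{-1}$, normalized to sum to one. Highly correlated
   (redundant) items split their weight; items carrying independent signal
   are up-weighted.
3. The six domain scores and one overall score are re-standardized to mean
   0, SD 1, so downstream coefficients read as "per one SD of management".

**Conditioning and the ridge rule.** When $\Sigma$ is near-singular the
inverse is regularized with a ridge $\lambda I$, $\lambda$ starting at
$10^{-6}\times$ the mean diagonal and escalating tenfold until the
condition number falls below $10^{10}$; every such event is recorded in
the score object and the run provenance.

**Why the overall score aggregates domain scores, not all 67 items.** With
45 CBOs the covariance of 67 items has rank at most 44. A minimally-ridged
inverse of that matrix produces essentially arbitrary weights: in our
experiments the resulting overall score correlated only ~0.49 with the
generating latent quality, against ~0.89–0.94 for the GLS combination of
the six domain scores. The all-items mode remains available
(`overall_mode = "items"`) and is tested, but `"domains"` is the default
because the all-items estimator is statistically unsound at this n/p
ratio.

## Contextual adjustment

Each score is regressed on an intercept plus five context covariates
(country indicator, manager bachelor's/postgraduate indicator, years since
opening, staff count, competitor CBOs within a 30-minute radius) by OLS.
Two readings of "adjusted score" exist:

* **residual** — the part of the score orthogonal to context (default);
* **fitted** — the conditional expectation $X\hat\beta$.

The modes decompose the crude score exactly (fitted + residual = crude)
and both are exposed. Residual is the default for an identification
reason discovered during implementation: the fitted-mode domain scores are
six linear combinations of the *same* six-column context design, so any
regression on all six of them together is exactly rank deficient — the
six-dimension model and its Shapley decomposition only exist under the
residual reading. `fit_six_dimension_model()` raises a collinearity error
rather than silently projecting. Re-standardization of adjusted scores is
off by default and recorded when requested.

The crude-vs-adjusted comparison uses the two-sample Kolmogorov–Smirnov
statistic. Both the raw $D=\sup_x|F_1-F_2|\in[0,1]$ and the scaled
$T=\sqrt{n_1n_2/(n_1+n_2)}\,D$ are reported: published "D statistics"
larger than 1 are necessarily the scaled form, and reporting both removes
the ambiguity.

## Mean regressions

Per-outcome models $Y_i=\alpha+\beta\hat u_i+\varepsilon_i$ are fit by
OLS with sandwich covariance
$(X'X)^{-1}X'\mathrm{diag}(w_ie_i^2)X(X'X)^{-1}$. HC1 ($w_i=n/(n-k)$) is
the default on the assumption of a Stata-lineage original analysis; HC0,
HC2, HC3 are selectable. Unit-cost models additionally control for the
matching intervention's service scale, the standard adjustment when
modelling unit costs. Missing outcomes are dropped listwise per model and
counted, reproducing the 89-vs-90 sample-size asymmetry when one ART
record is absent. The overall F reported is the robust Wald test of all
slopes; classical "degrees of freedom" rows are deliberately replaced by
explicitly labelled F statistics and residual df.

Pooling two fiscal years with management measured once per CBO induces
within-CBO dependence; the default mirrors the plain-HC convention of the
original analysis, and this is a known limitation rather than an
oversight (a clustered variant would be the natural sensitivity check).

## Shapley (Shorrocks) decomposition

For the six-dimension model the explained variance is allocated across
domains by
$$\phi_j=\sum_{S\not\ni j}\frac{|S|!\,(p-|S|-1)!}{p!}
 \left[R^2(S\cup\{j\})-R^2(S)\right],$$
computed by exact enumeration of all $2^p$ subsets (centered $R^2$,
results cached per subset). Contributions are order-independent and sum
exactly to the full-model $R^2$; negative (suppression) contributions are
reported as-is. In unit-cost models the scale control enters as a genuine
seventh player whose share is computed but suppressed from the default
display — the only convention under which non-cost columns sum to 100%
while unit-cost columns sum to less than 100% whenever the scale share is
positive. Rank-deficient subset designs contribute the $R^2$ of their
column space, with the degeneracy recorded.

## Quantile regressions and bootstrap inference

$Q_q(Y|\hat u)=\gamma_1+\gamma_2\hat u$ is estimated at
$q\in\{0.25,0.5,0.75,0.95\}$ by exact minimization of the check loss
$\sum_i\rho_q(y_i-x_i'\gamma)$, $\rho_q(u)=u(q-\mathbf 1\{u<0\})$. The
solver (C++/Armadillo) runs IRLS on the smoothed objective as a warm
start, then a simplex descent over interpolating basic solutions:
directional derivatives at the current basis decide the leaving point, a
weighted-median line search finds the entering observation, and the
iteration stops when no one-sided derivative is negative — a global
optimum of the convex piecewise-linear objective, with a deterministic
tie-break. The suite verifies exactness against full enumeration of all
$\binom n p$ interpolating fits.

Standard errors come from (a) the iid kernel-sparsity estimate with the
Hall–Sheather bandwidth and (b) the paired bootstrap. Cross-quantile
equality tests resample rows with replacement, refit all quantiles on the
shared resample (resampling indices are drawn in R so all randomness is
seed-controlled), and refer the full-sample coefficient difference to the
bootstrap SD of replicate differences (normal/Wald by default, percentile
interval optional). The default is 500 repetitions; size calibration is
verified in the suite at B = 200 over 300 datasets. Fits with fewer than
five expected tail observations (e.g. q95 at n = 90, ~4.5 points) are
flagged as fragile rather than refused, and fitted-value crossings across
quantiles are detected and flagged, never rearranged. Reported SEs are
non-negative by construction.

## The synthetic world

The generator states one coherent data-generating process:

* **Latent quality** $z\sim N(0,1)$ per CBO — the single ground truth.
  Management is a CBO trait: one $z$ (and one item draw) is shared by both
  fiscal years, so the panel carries repeated management values.
* **Items**: Bernoulli with $\mathrm{logit}^{-1}(\alpha_j+\lambda z)$,
  intercepts spread over $[-1,1]$, loading $\lambda=1.2$ by default.
* **Context**: country fixed 30/15; manager degree Bernoulli centred at
  0.53; years open and staff log-normal-ish, clipped to the observed 1–16
  and 2–21 ranges; competitors Poisson clipped at 5. Each is mildly tied
  to $z$, so adjustment has something to remove.
* **Outcomes**: linear in $z$ with normal noise. Intercepts sit at the
  observed averages (ART unit cost $847, HTS $68, STI $39; 112 on ART,
  1,888 tests, 2,273 screenings, 275 condoms per person reached). Unit
  costs are location-scale, residual SD
  $\sigma(1+\kappa z)$ with $\kappa=-0.2$: better-managed CBOs have less
  dispersed costs, so the true quantile slope
  $\gamma_2(q)=\beta+\kappa\sigma\Phi^{-1}(q)$ steepens (more negative)
  at high quantiles — the closed form the recovery tests check against.
* **Bookkeeping**: one random CBO-year loses its ART outcomes, forcing
  listwise deletion downstream (n = 89 vs 90).
* Unit costs are floored at $1 and volumes at 0 (integers). Default
  effect/noise scales were chosen so these floors bind for well under 1%
  of draws; the measured slope bias from flooring is an order of magnitude
  below the 0.1·σ embedding tolerance.

**What a green test does not establish.** The generator's outcomes are
symmetric and nearly unbounded, while real cost and volume data are
heavily right-skewed (observed HTS volume ranges 76–9,253 around a mean of
1,888); the generator deliberately understates that skew to keep the
linear model exactly correctly specified. Recovery results therefore
validate the estimators, not the distributional realism of any particular
CBO program. Item independence given $z$ (a single factor) is also an
idealization.

**Recovery-test worlds.** Coverage/size calibration of the robust OLS
machinery regresses outcomes on the *true* latent score, where the
embedded coefficient is exactly the estimand. The end-to-end test (through
estimated scores) uses a stated world chosen a priori from a reliability
analysis: item loading 3 and effect size 0.4 × residual SD, so that
score-measurement attenuation (score–latent correlation ≈ 0.94, hence
~6% coefficient bias) stays a small fraction of the sampling SE at
n = 90. With larger effect sizes the attenuation from any feasible
67-item score would dominate and nominal coverage is unattainable — a
measurement-error fact, not an estimator defect.

## Numerical conventions

* Covariance estimation: sample (n−1) throughout.
* Condition-number threshold $10^{10}$; ridge escalation ×10, recorded.
* Scores standardized with the sample SD; exact replication invariance
  holds up to the common $\sqrt{(2n-2)/(2n-1)}$-type factor this implies.
* QR solver tie-break: on equal check loss, the smaller-norm coefficient
  vector wins; bootstrap resamples of rank-deficient design are skipped
  and counted, with a 10% failure-rate abort.
* All stage seeds derive deterministically from one global seed (kept
  below $2^{31}$); identical configs yield byte-identical CSV output.

## Known limitations

Descriptive associations only — no instrument, no panel identification;
plain HC errors ignore within-CBO dependence across the two years; the
q95 estimates at n = 90 rest on a handful of tail points and are flagged
accordingly; the all-items overall score is retained for comparability
but should not be used at 45 CBOs; the generator's aggregate "total
services" is the sum of the three intervention volumes, treated as
derived rather than primitive.
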