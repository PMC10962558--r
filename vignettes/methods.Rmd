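---
title: "Permutation-based multiplicity corrections for cluster trials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation-based multiplicity corrections for cluster trials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(permcrt)
```

`permcrt` performs randomization inference for cluster randomized trials
with several outcomes: permutation tests built on studentized quasi-score
statistics, family-wise error rate (FWER) corrections (Bonferroni, Holm,
Romano–Wolf stepdown), and simultaneous confidence sets located by a
Robbins–Monro search. This vignette explains the model, the algorithms, the
tunable parameters and their defaults, the numerical choices, and the known
limitations. It states no empirical result beyond what the package's test
suite and `scripts/acceptance.R` themselves compute.

## Model and test statistics

Each outcome is modelled by a univariate generalized linear mixed model
with linear predictor
$\eta_{ict} = \mu_0 + \delta D_{ct} + X'_{ict}\beta + \theta_{ct}$
for individual $i$ in cluster $c$ at period $t$, where $D_{ct}$ indicates
treatment, $\delta$ is the effect of interest, and $\theta_{ct}$ is a
cluster(-period) random effect. Supported families are Gaussian/identity,
Poisson/log, and Bernoulli/logit (`outcome_spec()`). Gaussian models are
fit by maximum likelihood with `lme4::lmer` (REML via a flag), the others
by `lme4::glmer` (Laplace); multi-period designs with autoregressive random
effects fall back to fixed-effects GLMs, with variance components supplied
externally, because mixed-model software for that structure is limited.

The test of $H_0\!: \delta = \delta^*$ uses the quasi-score statistic: per
cluster, the signed sum of generalized residuals
$D^*_c G_c V_c^{-1}(Y_c - \mu_c)$ evaluated at the null, where $D^*$ is
$+1$ in treated cluster-periods and $-1$ otherwise, $G_c$ holds the inverse
mean-derivative weights ($1$, $1/\mu$, or $(\mu(1-\mu))^{-1}$ by link), and
$V_c$ is the within-cluster covariance. The *unweighted* variant replaces
$G_c V_c^{-1}$ by ones. The statistic is the sum of cluster contributions
divided by the root of their sum of squares (studentization), which makes
it scale-free and comparable across outcomes — the property the stepdown
correction and balanced confidence sets rely on.

### Nuisance estimation under the null

Two principles govern the nuisance parameters
$(\mu_0, \beta, \Theta)$:

1. **Frozen across permutations.** Validity of the permutation test
   requires that everything except the treatment-label signs stay fixed
   while allocations are re-drawn. Fits, residuals, $G_c$, $V_c$ and
   $V_c^{-1}$ are computed once per tested null and reused for every
   permutation (`build_cluster_covariance()` inverts each small dense
   $V_c$ once by Cholesky).

2. **Re-estimated per null value.** For each tested $\delta^*$ the
   remaining fixed effects are re-estimated by maximum likelihood with the
   treatment term held at $\delta^*$ (an offset). This matters: plugging
   $\delta^*$ into the *unrestricted* fit's linear predictor leaves the
   observed treatment contrast inside the residual sum of squares, which
   deflates precisely the outcome whose observed statistic is largest and
   makes the max-statistic stepdown severely conservative (roughly half
   the nominal FWER in the two-outcome designs below). With null
   re-estimation the single-outcome test is numerically exact for balanced
   Gaussian designs and the stepdown is nominal. The plug-in behaviour
   remains available as `null_marginal_means(..., refit = FALSE)`.

The null re-fit solves a small weighted least-squares/Fisher-scoring
problem (typically 1–2 columns). Inside the confidence-limit search it is
warm-started from the previous iterate; the solver is cross-checked
against `stats::glm` with an offset in the test suite. Variance components
$\Theta$ are *not* re-estimated per null: the original estimates generate
$V_c^{-1}$ once, reused throughout.

## Permutation engine

The permutation group acts on cluster treatment labels: every allocation
assigns the observed number of treated clusters, and in the baseline-period
design the treated arm's rollout profile (control in period 1, treated in
period 2) moves with the label. `generate_allocations()` enumerates the
full group when it has at most `cap = 20000` elements (then p-values are
exact proportions, the identity allocation included exactly once) and
otherwise samples allocations uniformly *with replacement*, matching the
add-one Monte-Carlo estimator
$\hat p = (1 + \#\{m: |T(a_mX)| \ge |T(X)|\})/(M+1)$, whose floor is
$1/(M+1)$. Ties count toward rejection — the conservative direction.
One-sided tests drop the absolute values. Restricted randomization schemes
are supported by passing an explicit allocation list; there is no
constraint engine.

`M = 1000` is the default for final analyses (the verification harness
uses 500); enumeration is preferable whenever feasible.

## Corrections

`adjust_pvalues()` computes Bonferroni and Holm from the raw permutation
p-values via `stats::p.adjust`. `romano_wolf_stepdown()` orders hypotheses
by decreasing $|T|$ (ties broken by original index — any deterministic
tie-break yields valid stepdown inference) and, at step $r$, compares the
observed statistic with the permutation distribution of
$\max_{j \in K_r} |T_j|$ over the not-yet-rejected set $K_r$; adjusted
p-values are made monotone nondecreasing down the order, and estimated
critical values use the quantile index $\lceil L(1-\alpha)\rceil$ clamped
to $[1, L]$ (the conservative direction of "nearest integer"). With one
hypothesis every method collapses to the raw permutation test.

The familiar ordering $p^{RW} \le p^{Holm} \le p^{Bonf}$ is a population
statement about max-statistics versus union bounds: with finite $M$ it
holds up to Monte-Carlo noise (exactly so under perfect dependence), and
the test suite checks it in that form.

## Confidence sets

The $1-\alpha$ simultaneous confidence set inverts the corrected tests.
For each side, starting from $\hat\delta_j \pm 2\,SE_j$, step $q$ of
`crt_ci()`:

1. treats the current limits as null values, re-fits the null fixed
   effects per outcome (warm-started), and computes observed statistics;
2. draws **one** random allocation and applies the method's single-draw
   stepdown rule (for Romano–Wolf: reject the top hypothesis if the max
   permuted statistic is below its observed statistic, then continue down);
3. updates every limit: down by $s_j\alpha^*/q$ if rejected, up by
   $s_j(1-\alpha^*)/q$ otherwise (mirrored for lower limits), where
   $\alpha^*$ is $\alpha$ for no correction and Romano–Wolf, $\alpha/J$
   for Bonferroni, and $\alpha/(J-r+1)$ along the current order for Holm.
   The paper-specified rule is explicit only for Romano–Wolf; the
   per-hypothesis (Bonferroni) and ordered (Holm) single-draw comparisons
   are our documented interpretation.

Step lengths are $s_j = k(\alpha^*)\,(u_{jq} - \hat\delta_j)$ with
$k = 2 z_{1-\alpha^*}\phi(z_{1-\alpha^*})$ (`step_constant()`; $k(0.05)
\approx 0.339$), refreshed each iteration. If a limit crosses the point
estimate the raw step length turns negative; it is floored at
$0.05\,SE_j$ — the recursion's equilibrium does not depend on the step
constant, so the floor only guards against sign pathologies. The recursion
settles where the single-draw rejection probability is $1-\alpha^*$, i.e.
where the corrected test's p-value equals $\alpha^*$. Upper and lower
searches use independent permutation streams split from the master seed.

**Convergence is the method's weak point.** The $1/q$ decay gives a finite
"travel budget" of order $s\log Q$: a search started far from the true
limit stalls short of it, and a limit lying well outside
$\hat\delta \pm 2SE$ (small enumeration groups, strong corrections, many
outcomes) may need much larger `Q`. The default `Q = 2000` matches the
reference protocol; the applied-scale guidance is 10000, and
`convergence_diagnostic()`/`autoplot()` flag drifting tails (range or
linear drift of the final 20% of the trace above 10% of the interval
width). In the package's own verification runs the searched Romano–Wolf
intervals come out slightly narrow (family-wise coverage a little below
the nominal 95% at `Q` in the 1000–2000 range), which is consistent with
this budget argument; treat reported confidence sets as approximate and
check the traces.

## Synthetic designs

`crt_scenario()`/`simulate_crt()` implement the three verification
designs. Defaults are the reference study conditions and are not meant to
be tuned:

| design | outcomes | key defaults |
|---|---|---|
| 1 | two Gaussian | $\mu_j = 1$, $\sigma_j^2 = 1$, $\tau_j^2 = 0.05$ (ICC 0.05), correlations $\rho$ (individual) and $\pi$ (cluster), 7 clusters/arm × 20 |
| 2 | Poisson + Gaussian | as model 1 with $\pi = 0$; Poisson rate $\exp(\mu + \theta_c)$ |
| 3 | Poisson, Gaussian, Bernoulli | two periods, rollout in period 2, $\mu_j = -1$, $\tau_j = 1$, AR decay $\lambda = 0.7$, period effect 0.5 |

Model 3's cluster-period effects have
$\mathrm{Cov}(\theta_{j,ct}, \theta_{j,ct'}) = \tau_j^2\lambda^{|t-t'|}$
with zero cross-outcome correlation; this covariance (and the period
effect's value, which the analysis model absorbs) is a reconstruction and
both are exposed as parameters. Treated clusters are drawn uniformly over
1:1 splits per replicate; cluster sizes are equal. The generators emulate
the correlation structure and family mix of real multi-outcome trials but
not missingness, informative cluster sizes, or covariate imbalance — so
passing operating-characteristic tests says nothing about those features.

## Verification harness and problem sizes

`run_scenario()` simulates replicates, runs the full pipeline, and scores:
FWER as the proportion of replicates rejecting at least one *true* null;
coverage as simultaneous containment of all true effects; mean interval
widths. The "naive" comparator is the model-based Wald test
$|\hat\delta/SE| > z_{1-\alpha/2}$ with REML standard errors for Gaussian
outcomes (what default mixed-model output reports), uncorrected.

Desk-scale defaults are `n_sims = 1000`, `M = 500`, `Q = 1000` against the
reference protocol's 10000/1000/2000; the acceptance script uses 1000
replicates per design and the test suite 300–400 (with the confidence-set
search run on the 300-replicate batch), sizes chosen so the whole suite
runs in minutes on one CPU. At these scales binomial Monte-Carlo error
dominates: tolerances in the acceptance tests are three binomial standard
errors plus 0.01 for the extra permutation/search randomness.

## Numerical choices and degenerate inputs

* All-zero score contributions return statistic 0 with a warning rather
  than NaN; all-zero Poisson outcomes are a fit error, not a crash.
* $V_c$ inverses use dense Cholesky per cluster (cluster sizes are small);
  a non-positive-definite $V_c$ aborts naming the cluster.
* Zero variance components are legitimate: the generator handles positive
  semi-definite random-effect covariances, and $\tau^2 = 0$ reduces the
  weighted statistic to a rescaled unweighted one.
* lme4 marginal-gradient warnings are recorded on the fit (`converged`)
  but do not trigger the GLM fallback; hard errors do, with a warning.
* Writing data as delimited text rounds doubles at the last bit, which can
  flip exact ties between observed and complement-allocation statistics;
  comparisons against on-disk data should therefore be made against the
  re-read table.

## Limitations

* Only canonical family-link pairs; no survival outcomes, individually
  randomized or crossover designs, or multi-arm trials.
* No small-sample corrections for model-based standard errors — the point
  of permutation inference is to avoid needing them.
* Hochberg, Hommel, Šidák, Westfall–Young, gatekeeping, and
  intersection-union procedures are out of scope.
* The Robbins–Monro search is the original fixed-schedule version; its
  slow travel from distant starting values is inherited by design, and a
  more efficient search variant is deliberately not implemented.
* Weighted-statistic covariances for non-Gaussian families use the
  quasi-likelihood form (family variance on the diagonal plus $\tau^2$
  exchangeable/AR off-diagonals); this is an approximation to the true
  marginal covariance of, e.g., a Poisson-lognormal outcome.
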