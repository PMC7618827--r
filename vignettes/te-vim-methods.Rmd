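---
title: "Methods: treatment-effect variable importance in tevim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: treatment-effect variable importance in tevim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tevim)
```

## The estimand

For i.i.d. observations $Z = (Y, A, X)$ with continuous outcome $Y$, binary
treatment $A \in \{0,1\}$ and covariates $X \in \mathbb{R}^p$, the
conditional average treatment effect (CATE) is
$\tau(x) = E(Y^1 - Y^0 \mid X = x)$, identified under consistency,
conditional exchangeability and positivity as
$\tau(x) = \mu(1,x) - \mu(0,x)$ with $\mu(a,x) = E(Y \mid A=a, X=x)$ and
propensity score $\pi(x) = E(A \mid X = x)$.

The treatment-effect variable importance measure for a covariate subset
$s \subseteq \{1,\dots,p\}$ is

$$\Theta_s \;=\; E[\{\tau(X) - \tau_s(X)\}^2]
  \;=\; \mathrm{var}\{\tau(X)\} - \mathrm{var}\{\tau_s(X)\},$$

where $\tau_s(x) = E(Y^1 - Y^0 \mid X_{-s} = x_{-s})$ conditions only on
the retained covariates. $\Theta_s \ge 0$ is the increase in
individual-treatment-effect prediction MSE when $X_s$ is dropped. For
$s$ equal to the full covariate set, $\tau_s$ is the constant ATE
$\tau_p$ and $\Theta_p = \mathrm{var}\{\tau(X)\}$ is the variance of the
treatment effect (VTE), a global heterogeneity measure. The scaled
importance $\Psi_s = \Theta_s / \Theta_p \in [0,1]$ reads like an $R^2$:
the proportion of effect heterogeneity attributable to $X_s$ beyond
$X_{-s}$. By construction $s' \subseteq s$ implies
$\Theta_{s'} \le \Theta_s \le \Theta_p$ at the population level; sample
estimates need not respect this ordering (or positivity), and the package
reports negative estimates as-is with a flag rather than truncating.

## Estimation

The AIPW pseudo-outcome
$$\varphi(z) = \frac{\{y - \mu(a,x)\}(a - \pi(x))}{\pi(x)\{1-\pi(x)\}}
  + \mu(1,x) - \mu(0,x)$$
satisfies $E\{\varphi(Z) \mid X = x\} = \tau(x)$ and acts like the
unobservable individual effect. The efficient influence curve of
$\Theta_s$ is
$\phi_s(z) = \{\varphi(z)-\tau_s(x)\}^2 - \{\varphi(z)-\tau(x)\}^2 -
\Theta_s$, and setting its sample mean to zero gives the one-step /
estimating-equation estimator implemented in `theta_estimate()`:

$$\hat\Theta_s = n^{-1}\sum_i \hat\phi_{i,s}, \qquad
  \hat\phi_{i,s} = \{\hat\varphi_i - \hat\tau_{s,i}\}^2 -
                   \{\hat\varphi_i - \hat\tau_i\}^2,$$

with variance $n^{-2}\sum_i(\hat\phi_{i,s} - \hat\Theta_s)^2$ and Wald
intervals at the user's level (default 0.95, $z = 1.96$). Replacing
$\hat\tau_{s,i}$ by the scalar AIPW ATE $\hat\tau_p = n^{-1}\sum_i
\hat\varphi_i$ gives $\hat\Theta_p$; this plug-in is deliberate because
$\partial\hat\Theta_p/\partial\hat\tau_p = -2(\hat\tau_p^* - \hat\tau_p)$
vanishes at the AIPW value, so ATE uncertainty is first-order ignorable
(`test-vim.R` checks the perturbation moves $\hat\Theta_p$ by exactly
$\delta^2$). The ratio $\hat\Psi_s = \hat\Theta_s/\hat\Theta_p$ uses the
variance $(n\hat\Theta_p)^{-2}\sum_i(\hat\phi_{i,s} -
\hat\Psi_s\hat\phi_{i,p})^2$.

Under the zero-importance null ($\tau = \tau_s$) the IC degenerates to
zero and Wald inference is unreliable; estimates with
$|\hat\Theta| < 2\,\mathrm{SE}$ carry a `near-null` flag. The package
does not attempt a valid test of the null (split-sample constructions
exist but are out of scope here); the flag is a warning, not a p-value.
Bounded intervals are available through `transformed_ci()`, which applies
the standard delta method on the log scale for $\Theta$ (SE
$\mathrm{se}/\hat\Theta$) and the logit scale for $\Psi$ (SE
$\mathrm{se}/[\hat\Psi(1-\hat\Psi)]$) and back-transforms; estimates
outside the transform's domain yield an `NA` interval with a flag.

### CATE metalearners

Two metalearners produce $\hat\tau$: the **T-learner**
$\hat\mu(1,x)-\hat\mu(0,x)$ (difference of per-arm regressions) and the
**DR-learner** (regression of $\hat\varphi$ on $X$, whose smoothness is
controlled by the final-stage learner rather than by the arm
regressions). Subset CATEs $\hat\tau_s$ are always obtained by the
*projection* metalearner — regressing $\hat\tau(X)$ evaluations on
$X_{-s}$ — because it handles runtime confounding
($Y \not\perp A \mid X_{-s}$) through
$\tau_s(x) = E\{\tau(X) \mid X_{-s}=x_{-s}\}$ and keeps $\hat\tau_s$
approximately mean-compatible with $\hat\tau$. The alternative of
regressing $\hat\varphi$ directly on $X_{-s}$ is legitimate and can be
obtained by passing pseudo-outcome values to `project_cate()`; we did not
make it the default because compatibility of $\hat\tau$ and $\hat\tau_s$
is what the squared-difference estimator consumes.

### Pipelines and cross-fitting

`tevim()` offers four pipelines. `noSS-A`/`noSS-B` fit everything on the
full sample ($K = 1$); they rely on Donsker-type complexity restrictions
and empirically over-estimate TE-VIMs through in-sample optimism.
`SS-A` ($K \ge 2$) cross-fits the T-learner: per fold, nuisances are
trained on the complement and evaluated held-out, and the projection is
trained on the complement's own T-learner evaluations. `SS-B`
($K \ge 3$) cross-fits the DR-learner: nuisances are fit once per
unordered fold pair $\{j,k\}$ (the fit excluding both serves both
directions, giving $K(K-1)/2$ nuisance fits), the fold-$k$ CATE
regression is trained on pseudo-outcomes computed away from fold $k$, and
each row's final pseudo-outcome averages its $K-1$ pair evaluations.
Every prediction carries fold provenance; `check_crossfit()` asserts that
no row was ever scored by a model that saw its fold, and `dr_learner()`
refuses training targets whose provenance touches an evaluation fold.

Folds are assigned by a seeded uniform permutation with sizes differing
by at most one. Assignment is *not* stratified by treatment arm by
default — the algorithms as stated split uniformly — but
`stratify_folds = TRUE` is available for small samples where a fold
might otherwise lose an arm (such a fold raises an error naming it).
All randomness descends from one top-level seed, split deterministically
into a fold seed and per-role, per-fold learner seeds, so identical
configurations reproduce bitwise-identical results for deterministic
learners.

### Tunable parameters

* `clip` ($\epsilon$, default 0.01): fitted propensities are clipped to
  $[\epsilon, 1-\epsilon]$. Asymptotic theory requires
  $\hat\pi \in (\epsilon, 1-\epsilon)$ but gives no operational rule; we
  chose a small fixed bound and surface the clipped fraction as a
  warning so extreme-overlap problems are visible rather than silent.
  Known propensities (e.g. a randomization constant, `propensity = 0.48`)
  bypass fitting and clipping entirely.
* `K`: 1 for the noSS pipelines, default 8 otherwise (10 is typical for
  applied cross-fitting; both are user-overridable).
* `level` (default 0.95) and the learner registry defaults described in
  `?learner_spec`. The spline smoother (`"gam"`, via mgcv) is the
  default for every role; basis dimension `k` and optional
  tensor-product interaction terms are hyperparameters because the right
  flexibility is problem-specific.
* `shapley_cap` (default 15): Shapley mode evaluates all $2^p - 1$
  subsets and is refused above the cap instead of silently sampling.

## Comparison modes and Shapley attributions

`subsets_for_mode()` builds leave-one-out (may under-represent correlated
covariates), keep-one-in (may over-represent them; reported both raw and
as the complement $\Theta_p - \Theta_s$ with an IC-based SE for the
difference), covariate groups, and Shapley mode. The Shapley game is
defined on explained heterogeneity: $v(S) = \Theta_p - \Theta_{S^c}$,
$v(\emptyset) = 0$, $v(\text{full}) = \Theta_p$, with the usual
permutation weights. Attributions are linear in the per-subset
$\hat\Theta$ values, so each attribution's SE comes from the same linear
combination of influence curves, and efficiency
($\sum_j \phi_j = \hat\Theta_p$) holds exactly by construction — the
tests verify efficiency, the dummy axiom and symmetry on analytic games.
This is the standard choice for a "variance explained" game; on benchmark
design 3 it reproduces the analytic per-covariate table (2.375, 4.625,
0.875, 0.125, 0, 0), which sums to $\Theta_p = 8$ as efficiency demands.

## The synthetic benchmark designs

`generate_dgp()` implements three designs chosen to exercise distinct
failure modes, with closed-form truths in `dgp_truth()`:

1. **Design 1** — independent $X_1, X_2 \sim U(-1,1)$, logistic
   assignment $\text{expit}(-0.4X_1 + 0.1X_1X_2)$, nonlinear CATE
   $\tau = X_1^3 + 1.4X_1^2 + 25X_2^2/9$, unit outcome noise. Truths
   follow from uniform moments ($EX^2 = 1/3$, $EX^4 = 1/5$,
   $EX^6 = 1/7$): $\tau_p = 1.393$, $\Theta_p = 1.003$,
   $\Theta_1 = 0.317$, $\Theta_2 = 0.686$.
2. **Design 2** — design 1 with $\tau/10$: identical scaled importances
   in a low-heterogeneity regime where VTE estimates can go negative.
3. **Design 3** — three independent Gaussian pairs with within-pair
   correlation 0.5, $\tau = X_1 + 2X_2 + X_3$, $\Theta_p = 8$, outcome
   noise variance 3, and a propensity depending on $X_5$ which is absent
   from the CATE (runtime confounding). Truths are Gaussian linear
   projections. The noise argument "3" is read as a *variance*
   (consistent with the mean/covariance notation of the multivariate
   normal); reading it as an SD would change only estimator noise, never
   the population truths.

`dgp_truth_mc()` is an independent brute-force oracle: it samples
covariates, evaluates the exact $\tau$, and computes $\tau_s$ by
Gauss–Legendre quadrature over the dropped uniform covariate (designs
1–2) or OLS of $\tau$ on the kept covariates (design 3, where the
conditional mean is exactly linear). The test suite requires the two
routes to agree at Monte-Carlo precision.

These designs emulate smooth heterogeneity, moderate confounding and
correlated covariates. They do **not** emulate discrete or heavy-tailed
covariates, poor overlap, non-additive outcome noise, or
high-dimensional $p$ — passing the simulation tests says nothing about
those regimes, and real analyses should choose learners accordingly.

## The replicate study and its scaled-down defaults

`run_study()` repeats generate–estimate over replicates and aggregates
bias, empirical SD, Wald coverage and the ranking accuracy
$\Pr(\hat\Theta_2 > \hat\Theta_1)$ (designs 1–2), each with Monte-Carlo
SEs; replicate failures are counted and more than 10% aborts the run.
The package's verification suite runs 200 replicates of design 1 at
$n = 2000$ with all four pipelines — SS-A at $K = 8$, SS-B at its
minimal $K = 3$ (its $O(K^2)$ nuisance cost is the single most expensive
component, and the qualitative under-estimation signature is present at
any admissible $K$) — plus 100 replicates at $n = 5000$ for the ranking
check. Learners there are `gam` smoothers with basis dimension $k = 5$
and an $(X_1,X_2)$ tensor interaction for the outcome/CATE roles, and a
logistic GLM with interaction for the propensity (the assignment model
is additive on the logit scale, so this is a fast, correctly specified
choice). The checks are qualitative by design: positive VTE bias for the
single-sample pipelines, negative for the cross-fitted ones, coverage
for $\Theta_1, \Theta_2$ under SS-A within 3 Monte-Carlo SEs of nominal,
and ranking accuracy above 0.9.

## Degenerate inputs and numerical choices

* A subset equal to the full covariate set is never projected; the AIPW
  ATE replaces $\hat\tau_s$ (and `project_cate()` redirects the caller).
  The empty subset needs no estimation: $\Theta_\emptyset = 0$.
* $\hat\Theta_p = 0$ exactly makes $\hat\Psi_s$ an error;
  $\hat\Theta_p < 0$ yields a flagged, still-reported ratio.
* Constant-only heterogeneity (constant learners) gives exact zeros with
  zero SEs rather than numerical noise.
* Pseudo-outcomes refuse propensities at the boundary; clipping is the
  only sanctioned repair and happens upstream of $\varphi$.

## Limitations

Continuous outcomes only; no missing-data handling; no TMLE-style
plug-in construction; no valid test under the zero-importance null; no
sampled approximation for Shapley beyond the cap; bounded interval
estimators are delta-method back-transforms rather than dedicated
one-step constructions on the transformed scale. TE-VIM p-values across
many subsets face multiplicity — the CLI offers a Bonferroni option, and
any covariate flagged as a heterogeneity driver should be confirmed on
independent data.
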