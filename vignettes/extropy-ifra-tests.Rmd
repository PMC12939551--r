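---
title: "Testing exponentiality against IFRA aging with cumulative extropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing exponentiality against IFRA aging with cumulative extropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifratest)
```

## The testing problem

A non-negative lifetime distribution $F$ with survival function
$\bar F = 1 - F$ belongs to the **IFRA** (increasing failure rate average)
class when $-\log \bar F(x) / x$ is increasing, or equivalently when

$$\bar F(bx) \ge \bar F(x)^b, \qquad x > 0,\ 0 < b < 1,$$

with equality exactly at the exponential distribution.  IFRA is the
smallest aging class containing the exponential model that is closed under
the formation of coherent systems, which makes it the natural alternative
class for reliability work: rejecting exponentiality in favour of IFRA is
formal evidence of adverse aging (wear-out), the kind of finding that
drives maintenance scheduling and warranty decisions.  The package tests

$$H_0: F(x) = 1 - e^{-\lambda x} \ (\lambda \text{ unknown})
  \qquad \text{vs.} \qquad H_1: F \text{ is IFRA, not exponential},$$

and, through the dual decision rule, the reverse DFRA direction.

## Deviation measures built from cumulative extropy

Extropy is the dual of Shannon entropy; its *cumulative* variants replace
the density with functions that are easy to estimate nonparametrically.
For a lifetime $X$ the cumulative residual extropy (CREX) and cumulative
past extropy (CPEX) are

$$\mathcal{E}J(X) = -\tfrac12 \int_0^\infty \bar F^2(x)\,dx,
  \qquad
  \bar{\mathcal{E}}J(X) = -\tfrac12 \int_0^\infty (1 - F^2(x))\,dx.$$

Let $X_{1:n}$ be the minimum of $n$ i.i.d. copies (a series system;
survival $\bar F^n$), and let the superscript $b$ denote the
proportional-hazards transform $\bar F \mapsto \bar F^{\,b}$ (for CREX) or
the proportional-reversed-hazards transform $F \mapsto F^{\,b}$ (for
CPEX).  If $F$ is IFRA, then for all $0 < b < 1$

$$\mathcal{E}J(X_{1:n}) \le b\, \mathcal{E}J(X_{1:n}^b),
  \qquad
  \bar{\mathcal{E}}J(X_{1:n}) \le b\, \bar{\mathcal{E}}J(\tilde X_{1:n}^b),$$

with equality exactly under $H_0$.  `weibull_min_extropy()` evaluates both
sides for the Weibull family by direct quadrature, and the test suite
verifies the inequalities numerically over a grid of shapes and $(n, b)$
values.  (The Weibull closed forms that circulate for these quantities
drop factors of 2; the package trusts the defining integrals, e.g. at
shape 1, $\mathcal{E}J(X_{1:1}) = -1/4$, not $-1$.)

The gaps in these inequalities, rewritten by integration by parts, give
two signed *deviation measures*

$$\delta^{(1)}_{n,b} = \int_0^\infty x\, J_1(F(x))\, dF(x), \qquad
  \delta^{(2)}_{n,b} = \int_0^\infty x\, J_2(F(x))\, dF(x),$$

with weight functions on the probability scale

$$J_1(u) = n\left[(1-u)^{2n-1} - b^2 (1-u)^{2nb-1}\right], \qquad
  J_2(u) = n\left[(1-u)^{n-1} - (1-u)^{2n-1}
    - b^2\{(1-u)^{nb-1} - (1-u)^{2nb-1}\}\right].$$

Both measures vanish under $H_0$, are positive for strict IFRA
alternatives and negative for DFRA ones (`population_delta()` computes
them for the built-in families by quadrature).  Two boundary conventions
matter in practice and are frozen here: $0^0 = 1$ at $u = 1$ (needed for
$n = 1, b = 0.5$, where $2nb - 1 = 0$), and a strictly negative exponent
at $u = 1$ is treated as a domain error because it marks a violated
regularity condition ($nb \ge 1/4$ for $J_1$, $nb \ge 1/2$ for $J_2$ —
these are exactly the conditions under which the envelope bounds
$|J_1| \le 2n(1-u)^{2nb-1}$ and $|J_2| \le 2n(1-u)^{nb-1}$ keep the
weights integrable).

## The empirical statistics

Plugging the empirical cdf into the integrals gives L-statistics

$$\hat\delta = \frac1N \sum_{i=1}^N J(u_i)\, X_{i:N},$$

computed by `delta_hat()`, and the scale-invariant versions
$\hat\delta^\star = \hat\delta / \bar X$ (`delta_star()`) that let a single
standard-exponential null calibrate any exponential scale.

**Evaluation grid.** The first statistic evaluates $J_1$ at $u_i = i/N$;
the second evaluates $J_2$ at $u_i = i/(N+1)$.  The shifted grid for the
second family keeps the evaluation points away from $u = 1$, where the
$J_2$ terms with exponents $nb - 1$ are largest in magnitude; the two
grids are asymptotically equivalent, and the package's defaults are the
pair under which the published worked-example values for the four
reference datasets reproduce to all four printed decimals.  Either grid
can be forced via the `grid` argument.  The $J_2$ grouping follows the
parenthesization above ($b^2$ multiplying the whole second difference);
the alternative reading that distributes the $b^2$ over only the first
term produces values that are wrong by an order of magnitude on real
data.

**Variance.** The asymptotic variance of $\sqrt N \hat\delta$ is
estimated by the Jones–Zitikis quadratic form with the Brownian-bridge
kernel $\min(s,t) - st$ on the grid $i/N$ and *adjacent* spacings
$X_{i+1:N} - X_{i:N}$ in both factors (`sigma2_hat()`).  One printed
display of this estimator has $X_{i+1:N} - X_{1:N}$ in the first factor;
the package uses the symmetric adjacent-spacing form, which is the form
that makes the estimator a positive semi-definite quadratic form (hence
non-negative, and zero only for constant samples).

**Decision rules and the standardization constant.** The published
uncensored rule rejects for
$2\sqrt N\, \hat\delta^\star / \hat\sigma > z_{1-\alpha}$.  Two repairs
are applied.  First, $\hat\sigma$ is scale-equivariant while
$\hat\delta^\star$ is scale-free, so the printed ratio is only meaningful
at unit scale (on data with mean 10 it would shrink tenfold); the limit
theorem itself carries an $E(X)$ normalization alongside $\sigma$, and
restoring it amounts to standardizing the *raw* statistic,
$z = c\sqrt N\, \hat\delta / \hat\sigma$, which is scale-invariant and
identical to the printed form at unit scale.  Second, simulation
shows that $\sqrt N\, \hat\delta / \hat\sigma$ is itself
approximately standard normal under the null (mean $\approx -0.1$, sd
$\approx 1.04$ at $N = 200$), so the factor 2 makes the asymptotic rule
anti-conservative.  The package keeps `const = 2` as the documented
default for the asymptotic path but exposes it as an argument, and makes
**Monte Carlo calibration the default decision path** (`extropy_test()`
with `calibration = "montecarlo"`), which sidesteps the constant entirely
and holds the nominal level by construction.  Both p-values are reported.

The DFRA direction uses the mirrored rule (reject for small statistics);
`side = "dfra"` selects it.

## Monte Carlo calibration and the power engine

`critical_values()` draws `reps` standard-exponential samples of size $N$
(scale invariance makes $\lambda = 1$ sufficient), evaluates the chosen
statistic (`ifra_statistic()` wraps the six extropy settings and three
competitors), and returns empirical upper quantiles using type-7
(linear-interpolation) quantiles — the interpolation rule is recorded in
the output because it is not standardized across software.
`empirical_power()` reports the fraction of alternative-model samples
exceeding the critical value.  Critical values are recomputed **per
sample size**: size-correct comparisons at $N = 50$ or $100$ need their
own calibration, and the reference power figures at those sizes are only
reproducible this way.  The calibration statistic is the scale-invariant
$\hat\delta^\star$; the raw $\hat\delta$ is not scale-invariant and
calibrating with it against non-unit-scale alternatives gives meaningless
comparisons.

The alternative families (`lifetime_model()`) are the standard aging
test-bed: linear failure rate $F(x) = 1 - e^{-(x + \theta x^2/2)}$ (with
the closed-form quantile $x = (-1 + \sqrt{1 + 2\theta t})/\theta$,
$t = -\log(1-u)$), Makeham $F(x) = 1 - e^{-x - \theta(x + e^{-x} - 1)}$
(the conventional baseline-rate-1 form, exponential at $\theta = 0$, IFR
for $\theta > 0$; the printed form in some sources drops the grouping),
gamma and Weibull with shape $\theta$.  All sampling is inverse-cdf on
uniforms from the seeded generator, so a seed fully determines every
draw; the Makeham quantile is solved by a safeguarded Newton iteration on
the cumulative hazard (derivative $\ge 1$, so the iteration is globally
stable; any non-converged point falls back to bracketed root finding),
accurate to about $10^{-12}$.  Population deviation measures integrate
$Q(u) J(u)$ over the probability scale rather than $x J(F) f$ over
$(0, \infty)$, which avoids truncating the infinite support and keeps the
endpoint singularity of $J$ integrable and visible to the adaptive rule.

What the simulation design does and does not emulate: it reproduces the
reference study's conditions exactly — i.i.d. complete samples at unit
scale, $N \in \{25, 50, 100\}$, $\theta \in \{1.2, \dots, 3\}$, 10,000
replicates, level 0.05 — and therefore says nothing about serial
dependence, covariate-driven heterogeneity, measurement rounding, or
model misspecification outside these four families.  Passing the
power-reproduction checks shows agreement with the reference Monte Carlo
design, not field performance on real maintenance data.

## Competitor tests

Three classical scale-invariant competitors are included for the same
null, all rejected for large values and all calibrated by the same Monte
Carlo engine:

* **Deshpande's** $J_a$: the U-statistic
  $\frac{1}{N(N-1)}\sum_{i \ne j} \mathbf 1\{X_i > a X_j\}$, with ties
  counted $1/2$.  The half-tie (midrank) convention is the one that
  reproduces the published worked examples on tie-heavy integer data; on
  continuous data it coincides with the strict indicator (both are
  available).  Null mean $1/(1+a)$.
* **Aly's** $t_1(a, c) = N^{-(c+1)} \sum_i (N + i - R_i)^c$ with $R_i$
  the rank of $X_i$ in the combined sample $\{X\} \cup \{aX\}$, $a > 1$.
  Three conventions are frozen by validation against the published
  worked examples: midranks for combined-sample ties, the observation
  index $i$ taken in the *given input order* (the reference analyses
  were computed this way; the value is therefore input-order dependent,
  and a permutation-invariant `order = "sorted"` variant is provided and
  tested), and negative bases $N + i - R_i < 0$ truncated at zero before
  the power is applied.
* **Jammalamadaka's** $T_N$: the average of $\min(1, X_i/X_j)$ over all
  *ordered* pairs $i \ne j$, i.e. $\tfrac12(1 + \text{mean small/large
  ratio})$.  This permutation-invariant form, with range $(1/2, 1]$ and
  null mean $\log 2$, is the convention under which the published values
  reproduce; reading the double sum as restricted to $i < j$ on sorted
  data would bound the statistic by $1/2$, which the published values
  exceed.

## Right-censored data

With right censoring, the empirical cdf is replaced by the Kaplan–Meier
estimator in jump form, $\hat p_i = \frac{\delta_i}{N-i+1}
\prod_{j<i}(1 - \frac{\delta_j}{N-j+1})$ at the ordered observed times
(`kaplan_meier()`; implemented from this product-limit formula directly
and cross-checked in the tests against the survival package).  The
plug-in statistic is
$\hat\delta(\hat F) = \sum_i \hat p_i\, J(\sum_{j \le i} \hat p_j)\,
Z_{i:N}$ (`delta_censored()`), which reduces *exactly* to the uncensored
estimator on the $i/N$ grid when no observation is censored.  The
observed times $Z_{i:N}$ stand in for the unobservable $X_{i:N}$ — a
notational repair of the printed display, since $X$ is not observed under
censoring.

The censored variance (`sigma2_censored()`) discretizes
$$2\int_0^\infty\!\!\int_x^\infty F(x)\bar F(y) J(F(x))J(F(y))
  \Big[\int_0^x \tfrac{dF}{\bar F\,\bar K}\Big]\,dy\,dx$$
over the Kaplan–Meier jump grid: the inner integral as a left-Riemann sum
with $\bar F$ and $\bar K$ evaluated just before each jump (avoiding the
division by zero at the last event), outer terms beyond the identifiable
region ($\hat{\bar F}\bar K = 0$) truncated, and $\bar K$ estimated by
the empirical survival of the *observed* times
$\bar K_N(t) = N^{-1}\sum \mathbf 1\{Z_i > t\}$, as specified in the
source for this variance (note this estimates the survival of $Z$, i.e.
$\bar F \bar K$; it is also the factor a Stute-type variance for
Kaplan–Meier integrals uses, and it is implemented as specified).

**Censored decision rule.** The printed censored rule omits the factor 2
of the uncensored rule while describing itself as analogous to it.  The
two cannot both hold, and the as-printed version is far too conservative
in simulation (null rejection rate $\approx 0.009$ at 20% censoring,
$N = 200$, nominal 0.05), while the unified rule
$2\sqrt N\, \hat\delta(\hat F)/\hat\sigma > z_{1-\alpha}$ lands at
$\approx 0.08$.  The package treats the omission as a typo and uses the
same constant as the uncensored rule (default 2, again exposed as
`const`).  Because the censored variance discretization and the
uncensored Jones–Zitikis form are different estimators, the censored and
uncensored z-statistics on identical (uncensored) data are close but not
algebraically equal; the tests assert proximity, not identity.

## Diagnostics and data

`ttt_transform()` computes the scaled total-time-on-test curve
$(i/N, S_i/S_N)$ with $D_k = (N-k+1)(X_{k:N} - X_{k-1:N})$,
$X_{0:N} := 0$ (the standard convention, which makes $S_N = \sum X_i$
exactly).  Exponential samples hug the unit-square diagonal; concave
curves above it indicate IFR (hence IFRA) aging.  It is a diagnostic, not
a test.

`load_dataset()` ships four classical reliability datasets exactly as
printed in the literature: air-conditioner failure intervals (declared
$n = 27$ but 29 values printed — both facts are surfaced, and the
worked-example statistics reproduce with all 29 values), snubber life
tests ($n = 51$), aquifer thickness ($n = 77$), and leukemia survival
times ($n = 43$, with a final out-of-order value 250 that is likely a
truncation of a larger figure).  Values are stored verbatim and never
corrected; the `notes` field carries the discrepancy flags.  Because the
Aly statistic is input-order dependent, datasets preserve the printed
order.

## Problem sizes, tolerances and reproducibility

The test suite verifies the deterministic worked examples to
$\pm 5 \times 10^{-4}$ (four-decimal rounding), reproduces five reference
power cells at the full 10,000 replicates to $\pm 0.02$ (binomial
standard error $\approx 0.005$ plus critical-value noise), checks the
nominal 5% size of all nine calibrated statistics at
$N \in \{25, 50, 100\}$ with 10,000 calibration and 10,000 fresh
replicates against the band $[0.04, 0.06]$, and checks the censored null
rejection rate at $N = 200$, 20% censoring, 2,000 replicates against
$[0.02, 0.09]$.  Oracle comparisons (Riemann–Stieltjes summation,
brute-force quadratic forms and pairwise enumerations, independent
product-limit computation) are at $10^{-12}$.  Every stochastic function
takes an explicit seed, and all sampling is inverse-cdf, so a seed pins
down the entire simulation stream.

## Known limitations

* The asymptotic calibration inherits the unresolved standardization
  constant; use the Monte Carlo path (the default) for level-accurate
  decisions.
* The censored variance is a plug-in discretization whose agreement with
  the uncensored variance at zero censoring is numerical, not algebraic;
  its test holds its level within a generous band rather than tightly.
* The given-order Aly statistic is not permutation-invariant; for
  simulation work this is immaterial (i.i.d. samples arrive in random
  order), but for data analysis the `sorted` variant may be preferable.
* No bootstrap or permutation calibration, no progressive censoring, and
  no covariate adjustment.

## A worked example

```{r example, eval = FALSE}
ds <- load_dataset(2)                      # 51 snubber lifetimes
plot(ttt_transform(ds$values))             # concave: suggests IFRA aging
res <- extropy_test(ds$values, n = 1, b = 0.5, which = 1,
                    calibration = "montecarlo", reps = 10000, seed = 1)
print(res)
```
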