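---
title: "Modelling daily milk fat percentage with the Wood curve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling daily milk fat percentage with the Wood curve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woodlac)
```

## The model

Milk fat percentage declines from calving, reaches a minimum a few months
into lactation, and rises towards dry-off — the mirror image of the
milk-yield curve. `woodlac` describes a stratum's daily fat percentage with
the minimum-shaped Wood incomplete-gamma function

$$Y(t) = a\,t^{-b}e^{ct},$$

with $t$ the lactation month. The three parameters have direct
interpretations: $a$ (in % units) is the level of the curve (the "lactation
potential" of fat percentage), $b \ge 0$ is the strength of the initial
decline, and $c \ge 0$ (per month) the speed of the late-lactation rise.
On the log scale the model is linear,
$\ln Y = \ln a - b\ln t + ct$, which the package exploits both for exact
starting values and as a test invariant.

For $b, c > 0$ the curve has a unique interior minimum, yielding the three
derived traits reported throughout the dairy literature:

* time to the minimum $T_{\min} = b/c$ (months; also reported in days),
* minimum fat percentage $Y_{\min} = a\,(b/c)^{-b}e^{b}$,
* persistency $\mathrm{Per} = -(b+1)\ln c$, a unitless summary of how the
  trait holds after the extremum (larger when the rise is slow).

When $b = 0$ or $c = 0$ the curve is monotone and has no interior minimum.
`wood_traits()` then returns a flagged degenerate result instead of pushing
the closed forms through: real fits do land on this boundary (very flat
strata can fit $b \approx 0$), and a silent $T_{\min} = 0$ would poison
downstream tables. Persistency is still reported when $c > 0$, since it
remains finite there.

All derived traits are computed from full-precision parameters; the
two-decimal rounding seen in report tables happens only in
`stratum_table()`.

### Months and days

Records are binned into lactation months of 30 days,
$\mathrm{month} = \lceil \mathrm{DIM}/30 \rceil$, with every day past 300
assigned to the eleventh and final month, so the month axis is exactly
1–11. $T_{\min}$ is converted from months to days with a configurable
factor (`days_per_month`, default 30.25). Published tables in this area are
not internally consistent with any single conversion factor, so the choice
is exposed rather than hidden; 30 matches the binning width, 30.25 the
average calendar month.

## Fitting

`wood_fit()` minimises $\sum_i (y_i - a t_i^{-b} e^{c t_i})^2$ by damped
Gauss–Newton (Levenberg–Marquardt-style) iterations with the analytic
Jacobian

$$\partial Y/\partial a = Y/a,\qquad
  \partial Y/\partial b = -Y\ln t,\qquad
  \partial Y/\partial c = Y t.$$

Defaults: damping $\lambda = 10^{-3}$, divided by 10 on an accepted step
and multiplied by 10 on a rejected one; convergence when the relative SSE
decrease of an accepted step falls below $10^{-10}$; at most 200 outer
iterations. Steps that would make $a \le 0$ or drive $b$ or $c$ negative
are rejected and retried at higher damping, so the boundary $b = 0$ or
$c = 0$ is reachable but the parameter space is never left. Accepted
iterations never increase the SSE (a test invariant). Standard errors come
from the asymptotic covariance $\hat\sigma^2 (J^\top J)^{-1}$ with
$\hat\sigma^2 = \mathrm{SSE}/(n-3)$; with exactly three points the fit
interpolates and SEs are undefined (`NA`).

Starting values use the log-linear structure of the model: OLS of $\ln y$
on $(\ln t, t)$ recovers the parameters exactly from noiseless data and is
within a few percent of truth at realistic noise, so the nonlinear fit
starts essentially at the optimum. If the log-linear fit is unavailable
(fewer than three distinct months) a fixed fallback of
$(4.0, 0.2, 0.05)$ — the scale of pooled Holstein fat curves — is used.

The fit is performed on raw test-day records against their integer
lactation month (`fit_on` the records, not monthly means). Monthly-mean
fits are possible by aggregating beforehand; the difference matters only
for the $R^2$ conventions below.

### Goodness of fit and the two $R^2$ conventions

`wood_gof()` reports the residual mean square $\mathrm{SSE}/(n-3)$ and two
coefficients of determination: the corrected convention
$1 - \mathrm{SSE}/\sum(y-\bar y)^2$ and the uncorrected convention
$1 - \mathrm{SSE}/\sum y^2$, which several nonlinear-regression programs
print for models without an intercept. On raw test-day records the
corrected $R^2$ is bounded by the share of variance the month profile
explains — with a test-day noise SD near 0.23 percentage points it sits
around 0.3–0.6 even when the curve is estimated essentially without error —
whereas the uncorrected convention is near 0.99, and corrected $R^2$ on
11 monthly means exceeds 0.96. Published fits in this field report values
above 0.96 next to residual mean squares near 0.054, which cannot arise
from a single convention on raw records; the package therefore computes
both and leaves the choice visible instead of guessing.

## Quality screening and factor classes

`qc_filter()` keeps records with parity 1–5, days in milk 1–305 and fat
1–7%, attributing each rejection to the **first** failing rule in the fixed
order parity → days-in-milk → fat-range, so rejection counts are
deterministic and conserved ($n_\mathrm{input} = n_\mathrm{kept} + \sum
\mathrm{rejected}$). Day 305 itself is kept: the 305-day yield is the
standard trait horizon and the month binning already treats everything past
day 300 as the final month. The filter is idempotent.

`assign_factor_bins()` produces the five factor classes. Boundary
conventions, chosen so each factor partitions its in-range domain:
herd-size classes `<1000 / 1000–2000 / 2001–5000 / >5000` (integer
head-counts make these seamless); calving-interval classes
`300–365 / 366–400 / 401–420 / 421–440 / ≥441` days — an interval of
exactly 441 days goes to the open top class, which is the only reading
that leaves no gap; 305-day-yield classes from 3000 to 13000 kg in the
usual steps with `>13000` as an open top class into which 13001–15000 kg
is folded. Yields below 3000 kg or above 15000 kg and intervals below 300
days have no defined class: such records are flagged out-of-range for that
factor (and counted in the `factor_exclusions` attribute) but never
dropped, since they remain usable for every other factor. Calving seasons
follow the meteorological calendar: March–May spring, June–August summer,
September–November autumn, December–February winter.

## The fixed-effects factor analysis

Fat percentage is analysed with the additive fixed-effects model

$$Y = \mu + F_i + P_j + S_k + D_l + N_m + e,$$

($F$ farm size, $P$ parity, $S$ season, $D$ calving interval, $N$ 305-day
yield; no interactions), fitted by OLS under sum-to-zero contrasts so $\mu$
is the grand least-squares mean. Repeated test days of one cow enter as
independent observations, exactly as the model is written; no cow effect is
included, an assumption the simulator shares (below).

**The parity-1 interval problem.** First-parity cows have no previous
calving and hence no calving interval. Giving them an explicit `"none"`
level does **not** keep the model estimable: the `"none"` indicator
coincides exactly with the parity-1 indicator and the design loses one
degree of freedom. The package resolves this by giving `"none"` a zero
contrast row — its effect is absorbed into the parity-1 coefficient — while
the five real interval levels remain sum-to-zero among themselves. The
model is then full rank, the interval F test compares the five real levels,
and `fat_lsmeans()` flags the `"none"` LSM as non-estimable rather than
extrapolating it. The parity-1 LSM consequently includes the average
`"none"` effect, which is the only self-consistent reading of an additive
model on this design.

Least-squares means are the model prediction at a level with every other
factor averaged with equal weight over its levels; under balance they equal
raw level means (a test anchor). Their SEs come from the variance of the
corresponding coefficient contrast. Per-factor tests are Type-III partial
F tests — the SSE increase from dropping the factor's columns from the full
sum-coded design — which under balance coincide with classical sequential
ANOVA F. The data here are heavily unbalanced, which is precisely when the
Type-III choice matters; the balanced equivalence anchors its correctness.

**Duncan's multiple range test.** For a span of $p$ ordered means the least
significant range is $q_{\gamma_p,\,p,\,\nu}\sqrt{\mathrm{MSE}/n_h}$ with
Duncan's protection level $\gamma_p = (1-\alpha)^{p-1}$, $q$ the
studentized-range quantile (`stats::qtukey`), $\nu$ the residual df and
$n_h$ the harmonic mean of the span's level counts. Testing steps down from
the full span; a span whose range falls short of its least significant
range is declared homogeneous and shields all its sub-spans. Letters mark
the maximal homogeneous spans, so they always form contiguous runs over the
sorted means. The display convention is capital letters at
$\alpha = 0.01$ ("extremely significant" groupings) and lowercase at
$\alpha = 0.05$. The test suite checks the grouping against an independent
exhaustive span-enumeration oracle and for invariance to input order.

## The synthetic herd generator

`simulate_herd()` emulates the structure of a multi-farm DHI fat-percentage
dataset: each cow draws a farm (four farms spanning the size classes, with
three quarters of cows on the largest — the skew typical of regional DHI
populations), a parity from frequencies declining from first to fifth
lactation (0.395, 0.310, 0.173, 0.071, 0.051), a calving season
(autumn-heavy: 0.116/0.134/0.448/0.302) with a calendar date in that
season, a calving interval for parity ≥ 2 (mostly 300–400 days) and a
305-day yield (centred on 9000–13000 kg). Test days run every 30 days from
day 15 in milk through day 305 — the standard monthly DHI cadence. A test
day's fat percentage is the cow's stratum curve (by default the four
season-specific parameter sets of `season_wood_params()`) evaluated at the
test day's lactation month, plus i.i.d. Gaussian noise with SD 0.232
percentage points, the square root of a typical residual mean square of
0.054. Everything is reproducible from one integer seed, and the generating
parameters and traits are returned as ground truth.

What the generator deliberately does **not** emulate: within-cow
correlation across test days (the fixed-effects model assumes independence,
and the simulator matches the model), effects of lactation stage on noise
variance, herd-test-day effects, and any genetic structure. Passing
recovery tests therefore show that the estimation machinery is correct
under the model's own assumptions — not that real herd data satisfy those
assumptions.

Two consequences of taking published season curves as the generating truth
are worth knowing. First, the marginal fat mean implied by those curves
over the test schedule is about 3.68%, a little below the 3.90% a raw
population table shows — the published curve parameters and the published
marginal moments are not mutually consistent at that level, and the
simulator follows the curves. Second, a **null** dataset for calibrating
the factor F tests must satisfy the model it calibrates:
`null_effects_dataset()` therefore defaults to a *flat* shared curve
($a = 3.90$, $b = c = 0$), making records the constant mean plus i.i.d.
noise. Sharing a *curved* profile across strata is also a valid null for
the factor effects, but its common lactation-stage trend sits in the
residual of the five-factor model, inflates the MSE without adding
between-level variance, and makes the F tests markedly conservative
(empirically, type-I error below 0.01 at nominal 0.05). That
misspecification scenario remains available through the `shared_params`
argument; the calibration tests use the model-conformant flat null, where
per-factor type-I error is confirmed to lie within [0.035, 0.065] over
1000 replicates.

## Numerical choices

* Optimizer tolerances as above; the brute-force check
  (`wood_minimum_search()`) uses a 2000-point grid refined by
  golden-section search to $10^{-8}$, and the test suite requires
  closed-form and numerical minima to agree within $10^{-6}$ months over
  randomized parameter draws.
* Duncan quantiles come from `stats::qtukey`; no bespoke root-finding is
  needed.
* Degenerate inputs: all-equal responses leave the corrected $R^2$
  undefined (flagged, not silently 1 or 0); a single-record parity reports
  an `NA` SD; non-converged strata keep their row with traits suppressed.
* Ties in Duncan spans need no special handling: a zero range is always
  below its least significant range.

## Problem sizes in the tests

The test suite runs at desk scale, chosen to keep the full suite under
half a minute while leaving every assertion statistically comfortable:
parameter-recovery property tests use 25–50 random draws; the per-season
recovery experiment simulates 2000 cows (about 20,000 records) per season;
the type-I-error calibration uses 1000 replicates of a 60-cow herd; the
pipeline round-trips use herds of 150–400 cows. The same code runs
unchanged at larger scale.

## Known limitations

* No within-cow covariance modelling (random regression or repeated
  measures); all effects are fixed, as in the model stated above.
* Only the Wood family is implemented; alternative lactation-curve
  families (Wilmink, Ali–Schaeffer, Dijkstra, Nelder) are out of scope.
* LSMs average over observed level combinations of an additive model;
  with empty cells beyond the structural parity-1/interval case,
  non-estimable contrasts are flagged rather than imputed.
* The simulator's factor effects enter only through season-specific curves
  by default; other stratum factors can be configured, but joint
  multi-factor effect surfaces are not simulated.
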