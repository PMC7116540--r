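---
title: "Group sequential designs for two-arm Poisson trials: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group sequential designs for two-arm Poisson trials: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gspois)
```

## The design problem

`gspois` designs two-arm experiments whose outcome is a count accrued over a
fixed observation period: each subject $i$ in arm $j \in \{1,2\}$ at stage
$k$ contributes $X_{ijk} \sim \mathrm{Po}(\lambda_j)$. The trial runs for at
most $K$ stages of $n$ subjects per arm per stage, with the option to stop
early at each analysis to reject or accept

$$H_0:\ \lambda_1 = \lambda_2 \in \Lambda_0,$$

powered against the alternative $\lambda_1 = \lambda_2 + \delta$ with
$\lambda_1 \in \Lambda_1$. Both hypothesis sets are closed intervals rather
than points: in many applications (the packaged example is a sleep-apnea
trial whose endpoint, the apnea–hypopnea index, ranges over $[15, 30]$
events/hour in moderate disease) the plausible control rate is known only up
to a range, and error rates must be controlled at their *maximum* over that
range,

$$\alpha'(n, \mathbf a, \mathbf r) = \max_{\lambda \in \Lambda_0}
  \sum_{k=1}^K R_k(\lambda, \lambda), \qquad
  \beta'(n, \mathbf a, \mathbf r) = \max_{\lambda \in \Lambda_1}
  \sum_{k=1}^K A_k(\lambda, \lambda - \delta),$$

where $R_k$ and $A_k$ are the probabilities of stopping at analysis $k$ to
reject or accept. Stopping uses boundary vectors $\mathbf a, \mathbf r$: at
interim analyses the trial rejects when the test statistic is $\ge r_k$,
accepts when $< a_k$, and continues on $[a_k, r_k)$; the final boundaries
coincide ($a_K = r_K$) so a decision is always reached.

## Two engines

**Exact engine.** The per-stage difference in event totals
$\tilde T_k = Y_{1k} - Y_{2k}$, with $Y_{jk} \sim \mathrm{Po}(n\lambda_j)$,
has a Skellam distribution; its pmf involves the modified Bessel function of
the first kind and is evaluated in log space with exponentially scaled
Bessel functions, so rates as large as $n\lambda \sim 10^4$ cause no
overflow. The cdf uses the classical noncentral-$\chi^2$ relation, with a
tail-truncated summation implemented as an independent cross-check (the two
routes agree to $10^{-10}$ in the tests). The cumulative statistic
$T_{Sk} = \tilde T_1 + \cdots + \tilde T_k$ is *not* Skellam for $k \ge 2$,
and its full pmf is not computable on an infinite support; but its
sub-density restricted to the continuation region,

$$h_k(t) = \sum_{s=a_{k-1}}^{r_{k-1}-1} h_{k-1}(s)\, g(t-s), \qquad
  h_1 = g,$$

is, and it is all that stage-wise stopping probabilities need: stage-$k$
rejection weights $h_{k-1}$ by upper Skellam tails. The recursion is
evaluated vectorized in one pass per design and rate pair, with pmf/cdf
tables cached per $(n, \lambda_1, \lambda_2)$.

**Normal engine.** The Wald statistics
$T_{Wk} = (\hat\lambda_{1k} - \hat\lambda_{2k})\sqrt{\hat{\mathcal I}_k}$
with information $\mathcal I_k = kn/(\lambda_1 + \lambda_2)$ follow,
asymptotically, the canonical joint multivariate normal distribution with
covariance $\sqrt{\mathcal I_{k_1}/\mathcal I_{k_2}}$. On the score scale
$S_k = T_{Wk}\sqrt{\mathcal I_k}$ the increments are independent
$N(\theta\Delta, \Delta)$ with $\Delta = n/(\lambda_1+\lambda_2)$, so the
nested rectangle probabilities are computed by the standard
group-sequential density recursion: the continuation density is propagated
across stages by Gauss–Legendre quadrature (96 nodes per continuation
region, far below $10^{-6}$ absolute error against closed forms). Under the
null the joint law does not depend on the common rate, so type-I quantities
are evaluated at the interval midpoint (a reproducibility convention — any
value gives the same answer, which the tests assert); type-II error is
largest at $\sup \Lambda_1$, where information is smallest, and is
evaluated there directly.

Exact boundaries are integers — real-valued boundaries would introduce
redundant design parameters, since only the integer lattice matters for an
integer statistic — while normal boundaries are real and can be tuned
continuously. This is why normal designs sometimes post slightly smaller
expected sample sizes at the same nominal level, and why their realized
error rates are only approximately controlled, whereas the exact engine's
control is guaranteed.

## Maximizing error rates over an interval

For the exact engine the rate maximizing a stopping probability has no
usable closed form and, empirically, no simple pattern. Every maximal error
rate is therefore located numerically: a 21-point equispaced scan of the
interval (endpoints included) picks the dominant mode, and bounded Brent
refinement in the bracketing subinterval polishes it to an absolute
tolerance of $10^{-6}$ in $\lambda$. A single Brent call without the scan
can silently converge to a minor mode; the scan makes that failure mode
practically impossible at the smoothness scales involved. Degenerate
(point) intervals skip the search.

## Error-spending boundaries and group size

Given spending vectors $\pi_R$ (summing to $\alpha$) and $\pi_A$ (summing
to $\beta$), boundaries are derived stage by stage: $r_k$ is the smallest
boundary whose stage-$k$ rejection probability — maximized over $\Lambda_0$
for the exact engine, evaluated at the fixed null rate for the normal —
stays within $\pi_{Rk}$, then $a_k$ is the largest boundary whose stage-$k$
acceptance probability stays within $\pi_{Ak}$; the final stage uses the
rejection rule only and sets $a_K = r_K$. Within a stage $r_k$ is computed
before $a_k$; the two solves do not feed back into each other ($r_k$
depends only on earlier boundaries, as does $a_k$), so a single pass per
stage suffices. Integer solves bracket the monotone stage-spending function
starting from a normal-approximation guess, bisect under the cheap
grid-only rate maximization, and then verify the candidate under the full
scan-plus-Brent maximization, stepping outward until it passes — by
monotonicity this equals direct bisection under the full maximization at a
fraction of the cost. If an interim continuation region collapses
($a_k \ge r_k$) the plan is infeasible at that $n$; infeasibility is a
value, not an error.

The group size is the smallest $n$ whose derived design attains
$\beta' \le \beta$. The scan over $n$ is linear and upward from 1: attained
power of spending-derived exact designs is not provably monotone in $n$, so
bisection could return a non-minimal $n$. `grid_search()` repeats this over
a set of spending plans and ranks feasible designs by the optimality score

$$w_1\, \mathrm{ESS}(\lambda_{\mathrm{ESS}}, \lambda_{\mathrm{ESS}})
 + w_2\, \mathrm{ESS}(\lambda_{\mathrm{ESS}}, \lambda_{\mathrm{ESS}}-\delta)
 + w_3\, 2Kn, \qquad
 \mathrm{ESS} = 2n \sum_k k (A_k + R_k),$$

with ties broken by smaller maximal sample size, then smaller $n$, then
lexicographically smaller $\pi_R$ (the criterion itself is silent on ties;
a fixed rule keeps reruns identical). The default cap on the $n$-scan is
twice the single-stage group size — deliberately looser than the
$1.5\times$ range of the exhaustive search below, since spending-derived
designs occasionally need slightly larger groups than the optimum.

## The exhaustive two-stage search

For $K = 2$ the package also finds the globally optimal exact design over
an $\epsilon$-bounded box: for each $n$ up to $1.5\, n_{\mathrm{fixed}}$,
$a_*$ is the largest integer whose stage-1 acceptance probability over
$\Lambda_0$ is at most $\epsilon = 10^{-7}$, $r_*$ the smallest integer
whose stage-1 rejection probability over $\Lambda_1$ is at most
$\epsilon$, and the search covers $a_1 \in [a_*, r_*-2]$,
$r_1 \in [a_1+2, r_*]$, $a_2 = r_2 \in [a_1 + a_*, r_1 + r_*]$. Boundaries
outside the box change the design's behaviour by less than $\epsilon$ under
every rate the trial is powered for; shrinking $\epsilon$ can only widen
the box and weakly improve the optimum.

Two structural facts make the search tractable without changing its
answer:

* With $a_2 = r_2$, the two-stage ESS equals
  $2n\,(1 + \Pr(\text{continue past stage 1}))$ — the final boundary never
  enters the score. Candidates $(n, a_1, r_1)$ are therefore enumerated in
  ascending score order (a threshold sweep over score bands), each is
  checked for feasibility — the smallest in-box final boundary with
  $\alpha' \le \alpha$, then $\beta' \le \beta$ — and the first feasible
  candidate is the optimum. Raising the final boundary only lowers power,
  so the minimal-$\alpha'$ choice is also the most favourable for
  feasibility.
* Group sizes that cannot work are excluded wholesale by a randomized
  Neyman–Pearson bound: the most powerful size-$\alpha$ test of a simple
  null against a simple alternative, based on the full two-stage data,
  upper-bounds the power of *every* stopping rule at that $n$. If even
  that bound misses $1 - \beta$, no boundary triple at that $n$ is
  feasible. This prunes roughly the lower third of the $n$ range and
  cannot exclude a feasible design.

Grid-level (21-point) rate maxima act as screens throughout — they are
lower bounds on the true maxima, so a candidate they reject is truly
infeasible — and the few surviving candidates are confirmed under the full
Brent-refined maxima. On the packaged example the search visits roughly
25,000 of the several hundred thousand boxed candidates and finishes in
minutes on one core.

## Monte Carlo validation

`simulate_trial()` and `empirical_error_rates()` draw per-stage totals
$Y_{jk} \sim \mathrm{Po}(n\lambda_j)$ directly — the totals are sufficient
for both engines' statistics, so simulating individual subjects would be a
$100\times$ slower route to the same distribution. The exact statistic is
the running difference of totals; the Wald statistic reduces to
$(C_1 - C_2)/\sqrt{C_1 + C_2}$ in the cumulative totals, and is sent to the
accept branch when no events have occurred at all. Replication is
vectorized and seed-deterministic, with binomial standard errors reported.
The tests validate every exact stage probability against $10^6$-replicate
simulation (3 standard errors) and against exhaustive enumeration of the
truncated joint support ($10^{-9}$) for small designs, and the full
empirical-validation scenario family is exposed through
`validate_design()` at a default of $10^4$ replicates per scenario, a desk
scale chosen so the whole suite runs in minutes; the $10^5$-replicate
setting is one argument away.

What the simulator does *not* emulate: overdispersion, rate heterogeneity
across subjects, delayed outcome accrual, or unequal allocation. Passing
validation therefore says the engines compute the stated model's
probabilities correctly — not that a real trial's counts are Poisson.

## Numerical conventions and edge cases

* Summations over the Skellam support truncate at
  $\pm\max(40\sigma, 50)$ around the mean; the neglected mass is below
  $10^{-300}$.
* Scaled-Bessel underflow in extreme tails maps to a pmf of exactly 0
  rather than an error; the affected masses are below double precision.
* $\lambda_1 = \lambda_2$ needs no special-casing anywhere; the formulas
  remain valid at zero drift.
* Boundary displays round to 2 decimals (normal engine), error rates and
  power to 3, ESS to 1 — display only; internal values are never rounded.
* Spending targets that are unreachable inside a solve's bracket clamp to
  the bracket edge; with conforming plans on realistic problems this
  cannot trigger, and the affected stage simply spends less than its
  budget.

## Worked example

```{r example, eval = FALSE}
prob <- osah_problem()

# exact single-stage reference design: n = 73 per arm, critical value 110
d1 <- find_group_size(spending_plan(0.2, 0.05), prob, engine = "exact")

# near-optimal two-stage design from its spending vectors
d2 <- find_group_size(spending_plan(c(0.14, 0.06), c(0.01, 0.04)), prob,
                      engine = "exact")
operating_characteristics(d2, prob)

# globally optimal two-stage design for the ESS-under-null criterion
d_opt <- exhaustive_search_k2(prob, weights = c(1, 0, 0))

# three-stage near-optimal design, evaluated and simulated
d3 <- gs_design(3, 30, a = c(19, 49, 121), r = c(100, 125, 121))
design_table(list(d3), prob)
validate_design(d3, 15, 15, replicates = 1e4, seed = 1)
```

Run at the packaged example's conditions these reproduce the single-stage
$n = 73$ (ESS 146.0), the two-stage near-optimal ESS-null of 94.6 against
the optimal 92.8, and the three-stage 81.7 — a 44% expected-sample-size
saving under the null relative to the single-stage design, at the cost of
a 23% larger maximal sample size.

## Known limitations

* The exhaustive optimal search is implemented for $K = 2$ only; the
  design space is $2K$-dimensional and brute force beyond two stages buys
  little over the spending search.
* Spending vectors are free parameters, not spending *functions* of
  information time; Lan–DeMets-style shapes are out of scope.
* Allocation is 1:1 with equal observation periods; no inference at
  termination (confidence intervals, p-values) is provided.
* Error-rate maximization over an interval is a one-dimensional numerical
  search per stage; the maximizing rate may differ across stages, which
  can make spending-derived exact designs mildly conservative.
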