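---
title: "Counterfactual and regression Hamilton's rules in assorted groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual and regression Hamilton's rules in assorted groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assorthr)
```

## The model

Individuals are cooperators (C) or defectors (D) and interact in groups of
fixed size $n$.  Fitness depends only on own type and the number $i$ of
cooperators in the group (self included): $\pi_C(i)$ is defined for
$i = 1,\dots,n$ and $\pi_D(i)$ for $i = 0,\dots,n-1$; the two impossible
entries are never represented.  A *population structure* maps the overall
cooperator frequency $p$ to a distribution $f_0(p),\dots,f_n(p)$ over group
compositions, subject to $\sum_i f_i(p) = 1$ and $\sum_i (i/n) f_i(p) = p$.
Because both constraints are linear in $f$, convex mixtures of valid
structures are valid, which the mixture family exploits.

The objects that decide invasion are the *population structure profiles*:
$u_i = \lim_{p \downarrow 0} (i/n) f_i(p)/p$ is the distribution of group
compositions experienced by a rare mutant cooperator, and
$\bar u_i = \lim_{p \uparrow 1} ((n-i)/n) f_i(p)/(1-p)$ its analogue for a
rare defector.  Cooperators invade iff
$\sum_i u_i \pi_C(i) > \pi_D(0)$; defectors invade iff
$\sum_i \bar u_i \pi_D(i) > \pi_C(n)$ (strict inequalities; exact ties are
reported as neutral non-invasion).  At interior $p$ the package uses the
conditional composition distributions $v^C_i = (i/n) f_i(p)/p$ and
$v^D_i = ((n-i)/n) f_i(p)/(1-p)$, whose limits are $u$ and $\bar u$.  The
selection differential $S(p) = \bar\pi_C(p) - \bar\pi_D(p)$ is computed
exactly from these distributions, never by simulation.

Relatedness is $r = P(C|C) - P(C|D)$, the excess probability that a
cooperator's random group mate cooperates relative to a defector's.  At
$p = 0$ this reduces to $\sum_i u_i (i-1)/(n-1)$: the sum formally runs
over all $i$ with the $i = 0$ term forced to zero, which is equivalent to
restricting the summation range because $u$ has no mass at 0 (a focal
cooperator is itself in its group).

## Counterfactual costs and benefits, and where violations live

For a focal cooperator at composition $i$, the counterfactual cost is
$c_i = \pi_D(i-1) - \pi_C(i)$ and the aggregate benefit to its $n-1$
partners is
$b_i = (i-1)[\pi_C(i) - \pi_C(i-1)] + (n-i)[\pi_D(i) - \pi_D(i-1)]$.
`population_cb()` combines these with relatedness into $rb - c$ under one
documented convention:

* **At the boundaries** the relevant switch is that of a focal in the
  *resident* group type — all-defector groups at $p = 0$, all-cooperator
  groups at $p = 1$ — so $c, b$ are the composition-1 (resp. composition-$n$)
  values.  With this convention $rb - c$ agrees to machine precision with
  the endpoint inequality forms computed independently by
  `hamilton_at_endpoint()`,
  $$\textstyle\sum_i u_i \{\pi_C(1) + (i-1)[\pi_D(1)-\pi_D(0)]\}
  \gtrless \pi_D(0),$$
  and its mirror at $p = 1$, for *every* fitness function and profile — a
  dual-route identity the test suite checks on randomized instances.
* **At interior $p$** no single resident group type exists; the package
  averages $c_i, b_i$ over the cooperators' conditional distribution $v^C$.
  This is a genuine design choice (several defensible averaging rules
  exist); it is isolated in one function, and for non-linear fitness its
  $p \to 0$ limit deliberately need not equal the boundary value.  Under
  equal gains from switching all conventions collapse to the same number.

With a linear ("equal gains") fitness function,
$\pi_C(i) = \pi_C(1) + (i-1)[\pi_D(1)-\pi_D(0)]$ and the matching defector
schedule, $rb - c = S(p)$ identically — Hamilton's rule is exact for any
structure.  Violations therefore require non-linearity.  The road map
implemented by `synergy_conditions()` classifies a system by three
conditions: (1) $\pi_C(i) \ge \pi_C(1) + (i-1)[\pi_D(1)-\pi_D(0)]$ for all
$i$; (2) $\pi_D(i) \ge \pi_D(n-1) - (n-i-1)[\pi_C(n)-\pi_C(n-1)]$ for all
$i$; (3) $S(p)$ nondecreasing in $p$.  Equal gains (conditions 1 and 2 with
equality) means no violation is possible anywhere; all three conditions
together mean violations can occur only out of equilibrium, because
selection then moves the population out of any disagreement region; systems
with anti-synergies can instead park a *stable mixed equilibrium* inside a
disagreement region, where $S(p^*) = 0$ but $rb - c \neq 0$.
`violation_map()` reports disagreement intervals and whether a stable state
(interior root, or an endpoint that resists invasion) lies in one; unstable
boundaries are never counted, since a population does not sit at them.

## The regression engine

The regression method defines $-c$ and $b_k$ as OLS partial regression
coefficients of fitness on own cooperativeness and on each relationship
class's aggregated partner cooperativeness, and
$r_k = \mathrm{cov}(x_k, x_{se})/\mathrm{var}(x_{se})$.  Partner traits are
aggregated by class means by default (coefficients then read as the benefit
of a fully cooperative class; sums are available), a choice the underlying
theory leaves open.  Under faithful transmission (fitness = offspring
count, offspring copy the parental trait) the Price equation gives
$\Delta\bar x = \mathrm{cov}(w, x_{se})/\bar w$, and OLS orthogonality turns
this into
$$\Delta\bar x \;=\; \frac{\mathrm{var}(x_{se})}{\bar w}
  \Big(\sum_k r_k b_k - c\Big)$$
for every linear specification.  The proportionality factor
$\mathrm{var}(x_{se})/\bar w$ (population moments) is stored explicitly
rather than silently absorbed: the literature usually writes the relation
as an equality of $\Delta\bar x$ and $rb - c$, but exact bookkeeping
requires the factor, and what holds in full generality is the *sign*
equivalence.  `regression_hr()` reports both the identity residual (zero to
numerical precision for linear specifications — the module's core
theorem-test) and the specification-dependence of the individual $b, c$
values: specifications I (siblings) and II (siblings + cousins) generally
disagree about costs and benefits while both Hamilton's rules hold, so the
regression rule is not uniquely defined, merely unfalsifiable.

Because only non-linear fitness can produce genuine counterfactual
violations, the engine ships two F-tests: `nonlinearity_test()` compares
nested individual-level specifications, and `estimate_pi_from_groups()`
estimates $\hat\pi_C(i), \hat\pi_D(i)$ as saturated cell means and tests
them against the constrained common-slope ("generalized equal gains")
model.  `spurious_violation_sim()` reproduces the sampling mechanism behind
apparent violations in linear analyses: Hamilton's rule evaluated with the
phenotypic relatedness estimator holds in every sample, but substituting an
independent pedigree value can flip the sign of $rb - c$ when samples are
small, at a rate that decays with sample size.

## Synthetic data: what it emulates and what it does not

`simulate_social_population()` generates the observational design an
empirical test would collect: binary traits at frequency 0.5, one sibling
and one cousin class (two partners each) correlated with the focal through
a copy-with-probability-$r$ mechanism ($r_{sib} = 0.5$, $r_{cou} = 0.125$,
the pedigree values), and fitness
$w = 5 - 0.5\,x_{se} + 2\,\bar x_{sib} + 0.5\,\bar x_{cou} + \varepsilon$
with Gaussian noise (sd 1), plus optional interaction/quadratic terms for
power studies.  `simulate_group_records()` draws 50 observations per
(type, composition) cell with measurement noise sd 0.1.  These generators
produce independent records with homoskedastic Gaussian noise and exact
trait inheritance; real data have overlapping generations, class-size
variation, non-Gaussian fitness, and relatedness measured with error, so
passing tests certify the algebra and the statistical calibration of the
engines, not robustness to those complications.  The Price/OLS identity, in
particular, is an algebraic fact about any data set and holds regardless.

## Numerical conventions

* Compositions are stored as dense vectors indexed $0..n$; $\pi_C(0)$ and
  $\pi_D(n)$ do not exist and access to them is an error, never NA.
* Structure validation checks the two consistency constraints and
  non-negativity on an even $p$-grid, tolerance $10^{-9}$ (analytic
  families hold to machine precision).
* Endpoint profiles use closed forms for every built-in family.  Custom
  structures take a numerical one-sided limit: the ratio is evaluated at
  $p = 10^{-3} \cdot 2^{-k}$ with one-step Richardson extrapolation
  ($2g(p/2) - g(p)$ cancels the linear term, since the built-in families
  are polynomial in $p$); convergence is declared when successive
  extrapolants differ by less than $10^{-7}$, and custom structures are
  documented as requiring one-sided differentiability at the endpoints —
  failure raises an error rather than returning a bad profile.
* The `endpoint_profiles` family realizes prescribed $(u, \bar u)$ by
  seeding $f_i = p\,(n/i)\,u_i$ near $p = 0$ (which has exactly the limit
  $u$), fading into the clonal structure before the leftover all-defector
  mass would go negative, mirroring the construction from the $p = 1$ side,
  and gluing the halves with weights $(1-p, p)$ — which preserves both
  constraints and both limits.  Only the endpoint behaviour is pinned down;
  the interior path is arbitrary and flagged in the structure's metadata.
  Whether an arbitrary $(u, \bar u)$ pair is realizable by *some* structure
  is an open question; the package guarantees realizability only for pairs
  built this way.
* `find_equilibria()` scans $S(p)$ on a 1001-point grid, refines sign
  changes by bisection to $|S| < 10^{-10}$, treats grid nodes with
  $|S| \le$ tol as root candidates, merges roots closer than two grid
  steps, and classifies stability from the sign of $S$ on either side.
  Monotonicity (condition 3) is likewise a grid check; non-monotonicity
  between grid points is an accepted, documented risk.  An identically zero
  $S$ raises a degenerate-system warning with no roots reported.
* A state counts as an in-equilibrium violation when $|rb - c| > 10^{-8}$
  at a stable interior root, or when a stable (uninvadable) endpoint has
  $rb - c$ on the wrong side of zero.
* All tolerances live in one `hr_control()` object.

## Problem sizes

The bundled examples are desk-scale by design ($n = 10$ fitness functions
with few-atom profiles, $2$-player games with closed-form dynamics), so
every deterministic quantity is checked against hand-derivable values.  The
randomized suites use 1000 instances for the synergy/no-violation and
Price-identity properties, 4000 replicates for the type-I calibration of
the non-linearity F-test, several hundred for the remaining power and
calibration checks, and sibling-pair samples of 20–320 (plus $10^5$ for the
consistency limit) in the spurious-violation simulation — sizes at which
the Monte-Carlo standard errors quoted in the tests are small compared to
the effects being demonstrated.

## Known limitations

Continuous within-group frequencies (the large-$n$ limit), spatial or
network structure, overlapping generations, multi-allele or continuous
traits, and evolutionary branching are out of scope.  The interior-$p$
counterfactual averaging convention is one defensible choice among several;
conclusions at the invasion boundaries — where the theory pins the
definitions down — do not depend on it, and results quoted at interior
equilibria should be read under that convention.  The regression engine
assumes asexual copy inheritance; transmission bias would add a term to the
Price identity that the reports do not include.
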