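# assorthr

Exact analysis of Hamilton's rule in group-structured populations with
assortative group formation.

## The problem

Hamilton's rule says a social behaviour is selected for when *rb > c* —
relatedness times benefit exceeds cost.  Whether that rule can ever be
*violated* depends entirely on how *b* and *c* are defined:

* Under the **regression method**, −*c* and *b* are partial OLS regression
  coefficients of fitness on own and partners' cooperativeness, and *r* is
  cov(partner trait, own trait)/var(own trait).  In that case the rule is an
  algebraic consequence of the Price equation and **cannot** be violated for
  any linear specification — which also means testing it empirically with a
  linear model is not a meaningful exercise.
* Under the **counterfactual method**, *c* is what a cooperator would gain
  by switching to defection and *b* is the total fitness change its switch
  causes in its n − 1 group mates.  Here violations are possible — but only
  when the fitness function is non-linear in the number of cooperators, and
  observing one *in equilibrium* additionally requires anti-synergies.

`assorthr` implements both definitions exactly, for cooperator/defector
populations interacting in groups of size n.  A **fitness function** gives
π_C(i) and π_D(i), the payoffs of a cooperator/defector in a group with i
cooperators.  A **population structure** is a family f_i(p) of
group-composition distributions indexed by the overall cooperator frequency
p, with Σ f_i = 1 and Σ (i/n) f_i = p.  Its **population structure
profiles**

&nbsp;&nbsp;&nbsp;&nbsp;u_i = lim_{p↓0} (i/n) f_i(p)/p,&nbsp;&nbsp;&nbsp;
ū_i = lim_{p↑1} ((n−i)/n) f_i(p)/(1−p)

are the group-composition distributions a rare mutant cooperator (or
defector) experiences, and together with the fitness function they determine
the direction of selection exactly.  The package computes selection
differentials, relatedness r = P(C|C) − P(C|D), counterfactual and
regression costs/benefits, equilibria and their stability, the three synergy
conditions that preclude in-equilibrium violations, maps of where rb − c
disagrees with selection, and simulations of the small-sample mechanism that
generates *spurious* violations in empirical data.

## Worked example: a violation at a mixed equilibrium

An anti-synergistic 2-player prisoner's dilemma (defecting on a cooperator
pays best) combined with a constant-relatedness structure at r = 0.3:

```r
library(assorthr)
g  <- demo_games()$antisynergy           # piC(1)=1.9, piC(2)=3, piD(0)=2, piD(1)=4.9
st <- make_structure("constant_r_2player", 2, list(r = 0.3))

population_cb(st, g, p = 0)
#> p = 0: r = 0.3, c = 0.1, b = 2.9, rb - c = 0.77

find_equilibria(st, g)
#> Equilibria:
#>   p = 0: unstable (cooperators can invade), rb - c = 0.77
#>   p* = 0.18254 (stable), S = 4.05e-11, rb - c = -0.231
#>   p = 1: unstable (defectors can invade), rb - c = -1.57

synergy_conditions(st, g)
#> System classification:
#>   equal gains: FALSE
#>   synergy conditions: FALSE FALSE FALSE
#>   verdict: in_equilibrium_violations_possible
```

The population settles at a stable mixed equilibrium p\* ≈ 0.183 where the
selection differential S is zero yet inclusive fitness rb − c = −0.231 ≠ 0:
Hamilton's rule (counterfactual version) is violated *at* an equilibrium,
exactly the signature the synergy-condition road map predicts for
anti-synergistic payoffs.  Replacing the game with any equal-gains (linear)
fitness function makes rb − c coincide with S at every p and every
structure — no violation is possible, which `synergy_conditions()` reports
as `no_violation_possible`.

A command-line wrapper with the same operations (`validate`, `profiles`,
`selection`, `hamilton`, `equilibria`, `classify`, `scan`, `regress`,
`estimate-pi`, `simulate-spurious`, `fixtures`) is installed at
`exec/assorthr`.

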