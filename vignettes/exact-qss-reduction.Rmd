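---
title: "Exact quasi-steady-state reduction of multiscale stochastic reaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact quasi-steady-state reduction of multiscale stochastic reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exactqss)
```

## The problem

Stochastic simulation of biochemical reaction networks with disparate
timescales is dominated by the fast reactions: almost every Gillespie event
is a fast binding, unbinding, synthesis or degradation step, while the
biology of interest evolves on the slow timescale.  Because fast species
equilibrate to their stationary conditional distribution long before the
slow state changes, every slow propensity that involves fast species can be
replaced by its stationary conditional expectation given the slow state —
the quasi-steady state (QSS).  The result is a reduced model over slow
variables only, which simulates orders of magnitude faster.

The difficulty is computing that conditional expectation *exactly* when the
fast subnetwork contains nonlinear (bimolecular) reactions: moment equations
of nonlinear networks are generally an infinite hierarchy.  This package
implements the two structural classes for which the hierarchy is not a
problem, and builds the corresponding reduced models:

1. **Feedforward fast subnetworks.**  If fast species split into layers such
   that every reaction of order above one only uses earlier-layer species as
   unchanged catalysts and only produces species of a single later layer,
   then every moment belongs to a *finite* closed linear system
   $\dot x = A x$, found by expanding moment derivatives from the master
   equation and recursing on the new moments that appear.  Stationary
   conditional moments are then a finite exact linear solve.
2. **Complex-balanced fast subnetworks** (weakly reversible, deficiency
   zero — e.g. fast reversible bindings).  The stationary law conditioned on
   the conserved totals is a product of Poisson distributions restricted to
   the conservation class, normalized by the partition function
   $Z(\beta) = \sum_{Ak=\beta}\prod_i \lambda_i^{k_i}/k_i!$, where $\lambda$
   is any complex-balanced equilibrium.  All stationary factorial moments
   are ratios of shifted partition functions,
   $E[\prod_j S_j^{(r_j)} \mid Y{=}\beta] = (\prod_j\lambda_j^{r_j})\,
   Z(\beta - \textstyle\sum_j r_j\alpha_{\cdot j})/Z(\beta)$.

A reduced model built from the exact QSS is called an **EMB** model
(exact-moment based); the baseline that replaces it with a factorized
product of means (feedforward case) or with a deterministic total-QSSA-style
formula (complex-balanced case) is called an **AMB** model
(approximate-moment based).

## Conventions

Propensities are falling-factorial mass action:
$\rho_j(k) = \kappa_j\prod_i k_i(k_i-1)\cdots(k_i-a_{ij}+1)$.  The rate
constant $\kappa_j$ is the constant that multiplies that product; a
binomial-coefficient convention would differ by $\prod_i a_{ij}!$.  We use
the falling-factorial convention because it matches how rate constants are
printed next to explicit propensities such as
$k_f/\Omega\, X_R(X_R-1)$ for a dimerization.

Combined constants like $\alpha_1\Omega$ or $\alpha_3/\Omega$ are stored as
single per-reaction rates; the volume $\Omega$ is model metadata.  The
bundled examples default to $\Omega = 1$; the `omega` argument of
`build_example()` rescales zeroth-order rates by $\Omega$ and bimolecular
rates by $1/\Omega$.

## Exact arithmetic, and why

Every structural and moment computation runs over exact big rationals
(`R/bigq.R`) with polynomial and rational-function layers on top.  This is
not a luxury: the normalized numerator/denominator polynomials of a rational
QSS such as $\langle X_{D_A}\mid X_T\rangle = f(X_T)/g(X_T)$ have
coefficients of order $10^{16}$–$10^{18}$ with alternating signs, and
evaluating them in floating point destroys all significant digits for
moderate $X_T$.  `qss_eval()` therefore always evaluates in rational
arithmetic and converts only the final value.

## The moment engine

`moment_derivative()` expands
$\frac{d}{dt}E[k^u] = \sum_j E[\rho_j(k)\,((k+\gamma_j)^u - k^u)]$
with the propensity first rewritten in the monomial basis (Stirling numbers
of the first kind convert falling factorials), so the derivative of a raw
moment is an exact finite linear combination of raw moments.  Slow species
appearing as catalysts of fast reactions are folded into the rate constants
as symbolic parameters, so conditional moments "given the slow state" come
out as functions of those symbols.

`build_closure()` recurses breadth-first from seed moments until no new
moments appear.  Determinism choices: FIFO queue; within a single
derivative, new moments are enqueued in lexicographic order; the constant
moment $E[k^0]=1$ is always carried as the first system variable with zero
derivative, which keeps systems with zeroth-order reactions
homogeneous-linear.  The default recursion cap is 500 moments; exceeding it
returns a failure report with the unexpanded frontier rather than silently
truncating.  For the repressor module of the negative-feedback example
(species E, F, Q, R, protein count symbolic), seeding with the second moment
of R closes after exactly 24 moments of maximal order 4:

```{r closure}
module <- reaction_network(c("E", "F", "Q", "R"), list(
  rxn(products = c(E = 1), rate = "aE", timescale = "fast"),
  rxn(reactants = c(E = 1), rate = "bE", timescale = "fast"),
  rxn(reactants = c(E = 1), products = c(E = 1, Q = 1), rate = "aQ*XP",
      timescale = "fast"),
  rxn(reactants = c(Q = 1), rate = "bQ", timescale = "fast"),
  rxn(products = c(F = 1), rate = "aF", timescale = "fast"),
  rxn(reactants = c(F = 1), rate = "bF", timescale = "fast"),
  rxn(reactants = c(Q = 1, F = 1), products = c(Q = 1, F = 1, R = 1),
      rate = "aR", timescale = "fast"),
  rxn(reactants = c(R = 1), rate = "bR", timescale = "fast")),
  params = c("aE", "bE", "aQ", "bQ", "aF", "bF", "aR", "bR", "XP"))
sys <- build_closure(list(c(0L, 0L, 0L, 2L)), module)
sys
head(moment_strings(sys))
```

`stationary_moments()` solves $Ax = 0$ with the constant moment normalized
to one, exactly; a singular reduced system (which happens when conservation
laws make the stationary law non-unique) raises a diagnostic with the
nullspace dimension instead of guessing.

**Stationary conditional moments with one free symbol.**  When exactly one
symbol (a slow count, the volume, or a scaling parameter) is left free,
`stationary_conditional()` solves the system exactly at integer values of
the symbol and reconstructs the unique bounded-degree rational function
through those values (Cauchy interpolation over the rationals, with a degree
search and held-out verification points).  Because the stationary solution
of a closed linear system with coefficients affine in the symbol *is* a
rational function of bounded degree, the reconstruction is exact, and every
returned expression is verified against extra sample points before being
reduced by a polynomial gcd.  Identities involving several free rate symbols
at once are verified in the test suite by exact evaluation at random
rational points, which avoids multivariate gcd canonicalization.

## The complex-balance engine

`analyze_structure()` counts complexes, linkage classes (connected
components of the complex graph), the exact rational rank of the
stoichiometry matrix, the deficiency, and strong connectivity of every
linkage class.  `solve_equilibrium()` handles networks made of reversible
reaction pairs — the fast subnetworks this reduction targets — by detailed
balance propagation with free species set to one, and verifies per-complex
balance exactly afterwards.  Any other admissible equilibrium differs by a
factor constant on each conservation class and yields identical conditional
moments (tested).

`partition_function()` enumerates the constrained lattice exactly; the
bundled examples have at most a few hundred lattice points, so bounded
enumeration is both exact and fast, and avoids recursive schemes entirely.
`conditional_mean_rational()` eliminates the species carrying the symbolic
total $n$, writes $n!\,Z$ as a finite sum of falling factorials $n^{(h)}$,
converts to the monomial basis with Stirling numbers, and normalizes the
denominator to constant term one.  The result agrees with
`factorial_moment()` at every feasible integer total, including totals past
all saturation thresholds (tested exactly).

```{r fg}
bind <- reaction_network(c("DA", "R", "DR"), list(
  rxn(c(DA = 1, R = 1), c(DR = 1), rate = 16, timescale = "fast"),
  rxn(c(DR = 1), c(DA = 1, R = 1), rate = 1, timescale = "fast")))
eq <- solve_equilibrium(bind)
cons <- conservation_constraint(conservation_basis(bind), list(10, "XT"))
conditional_mean_rational(c(DA = 1), cons, eq)
```

## Reduction

`split_fast_slow()` takes the reaction timescale tags, defines fast species
as those with nonzero net change under any fast reaction, and computes slow
variables as the integer left nullspace of the fast-restricted stoichiometry
matrix (restricted to combinations touching fast species).  Combinations
conserved by *all* reactions are conserved totals, fixed by the initial
condition; the rest are genuine slow variables (e.g. the total repressor
$T = X_R + X_{D_R}$ of the oscillator).

`build_reduced_model()` rewrites every slow propensity in the slow state:
untouched slow species remain mass-action factors; each fast-species factor
(a falling-factorial monomial, e.g. $X_R(X_R-1)$ for a dimerization) is
replaced by its stationary conditional expectation.  Expressions that depend
on a slow variable are tabulated exactly over `0:reach_cap` (default 400);
a table value that is negative aborts construction, and a simulation whose
slow state leaves the table raises an error rather than clamping.  The cap
default is an engineering choice — roughly an order of magnitude above the
stationary slow totals of the bundled examples — and is exposed because no
general a-priori bound on slow-state reachability exists.

**AMB baselines.**  For feedforward subnetworks the baseline is first-moment
factorization, $\langle X_i X_j\rangle \approx \langle X_i\rangle\langle
X_j\rangle$ and $\langle X^{(2)}\rangle \approx \langle X\rangle(\langle
X\rangle - 1)$.  For complex-balanced subnetworks it is the deterministic
QSS in total variables.  `deterministic_qss_formulas()` returns, by default,
the exact root of the deterministic binding equilibrium (for the oscillator:
discriminant $(X_{D_T}-X_T-c)^2 + 4cX_{D_T}$ with $c = \Omega/K$, which
satisfies $\langle X_{D_A}\rangle = X_{D_T}$ at $X_T = 0$ identically).  A
`variant = "printed"` form with discriminant term $4c$ instead of
$4cX_{D_T}$ is also provided, and the bundled oscillator AMB model uses it
as its comparator: that variant is the form some published
deterministic-reduction baselines actually used, and with the algebraically
exact root as baseline the EMB/AMB period difference is smaller than
Monte-Carlo noise at any reasonable budget — the approximate baseline would
no longer represent what it is meant to represent.  Both variants are
exposed so users can compare.

## Simulation and period analysis

`gillespie_direct()` is a compiled direct-method sampler supporting
falling-factorial mass action plus one tabulated multiplier per reaction
(the rational-QSS propensities of reduced models).  Seeds give bitwise
reproducible paths; ensemble runs use `seed + i` for run $i$.  Recording is
piecewise-constant on a fixed grid (memory bounded); event recording is
optional.

`period_analysis()` splits a uniformly recorded trajectory into contiguous
segments and estimates each segment's period as the lag of the first
autocorrelation local maximum with value at least 0.1 at lag at least 10
samples (both exposed; no published values exist for either threshold, and
the comparisons below are insensitive to them), with quadratic peak
interpolation.  Segments without such a peak are flagged and excluded.  The
dominant discrete-Fourier frequency of the full trace is computed on a
power-of-two truncation.  The autocorrelation estimator is the standard
biased (`stats::acf`) one with per-segment demeaning; no detrending is
applied.

## The bundled examples and what they show

`build_example()` constructs four multiscale networks entirely in code, with
published parameter values as defaults:

* `feedforward` — 4 species, 8 reactions; fast input and intermediate
  ($\epsilon = 0.01$); the exact slow propensity for the output species
  carries a covariance correction that the factorized baseline misses
  (20 $X_2$ vs 16 $X_2$ with the default constants, hence stationary output
  means 80 vs 64).
* `negative_feedback` — 16 reactions; the repressor is produced through the
  fast feedforward module above; the slow dimerization propensity
  $k_{f2}/\Omega\,\langle X_R(X_R-1)\mid X_P\rangle$ comes from the
  24-moment closure.
* `oscillator` — 9 reactions; fast repressor–promoter binding with
  association ratio $K\Omega = 16$ molecules$^{-1}$ and promoter total 10
  ($\epsilon = 0.1$ by default).  The association ratio is exposed
  (`assoc`) because its published rendering is ambiguous; the default is
  the value consistent with the published exact QSS coefficients, which the
  test suite reproduces to six significant figures.
* `decoy` — positive feedback with one promoter site and $N = 10$ decoy
  binding sites (fast competitive bindings); two transcription presets
  (`low`: $\alpha_0 = 4, \alpha_A = 10$; `high`: $\alpha_0 = 8,
  \alpha_A = 20$).

Initial conditions: promoter/gene/decoy species start at their conserved
totals (a gene cannot start at zero copies), the feedforward input starts at
its fast stationary mean (2 molecules), and everything else starts at zero.

These synthetic networks exercise exactly the two structural classes the
method covers, with small copy numbers and clean timescale tags.  They do
not emulate features of real systems such as ambiguous timescale separation,
non-mass-action kinetics, extrinsic noise, or cell division; passing tests
show correctness of the reduction machinery under the stated model classes,
not accuracy of QSS reduction for arbitrary real networks.

## Numerical and design choices

* Exact rational arithmetic throughout the symbolic layer; doubles only in
  simulation, the truncated-CME cross-check, and final outputs.
* Conservation bases by exact rational row reduction, scaled to primitive
  integer vectors, with a bounded search for an all-non-negative basis
  (conserved totals are naturally non-negative); deterministic ordering by
  first nonzero index.
* Closure recursion: FIFO with lexicographic tie-break, cap 500.
* Rational reconstruction: integer sample points from 0 upward, degree
  search in increasing total degree, 4 held-out verification points.
* Truncated-CME oracle: reflecting truncation on a box; direct sparse solve
  up to 5000 states, embedded-jump-chain power iteration above that
  (stopping at successive-difference $10^{-15}$); the reported boundary
  tail mass certifies the box size.
* Simulation problem sizes used in the tests (a package choice to keep the
  default suite fast while leaving Monte-Carlo error well below the
  assertion margins): 2000 runs for reduced-model stationary means, 600
  runs for the full cascade, and a $10^4$-cycle trajectory split into 2000
  segments for oscillator period distributions.

## Known limitations

* Equilibrium solving covers networks of reversible reaction pairs (the
  fast-binding subnetworks this reduction targets); weakly reversible
  deficiency-zero networks with irreversible cycles are detected
  structurally but not solved.
* `conditional_mean_rational()` supports exactly one symbolic conserved
  total, with the carried species entering that total with coefficient one.
* QSS expressions may depend on at most one slow variable; propensities
  depending jointly on several slow counts (beyond mass-action factors of
  untouched slow species) are not tabulated.
* No SBML import, non-mass-action kinetics, tau-leaping, or hybrid
  simulation.
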