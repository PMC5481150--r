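# exactqss

Exact quasi-steady-state (QSS) reduction of multiscale stochastic
biochemical reaction networks.

## What it does, and for whom

Gillespie simulation of a reaction network with fast reversible bindings or
fast signaling cascades spends almost all of its events on the fast
reactions.  On the slow timescale, fast species sit at their stationary
conditional distribution given the slow state, so every slow propensity
involving fast species can be replaced by its stationary conditional
expectation — the QSS — producing a reduced model over slow variables only.
The hard part is deriving that expectation **exactly** when the fast
subnetwork is nonlinear.  This package does so for the two structural
classes where an exact derivation exists, and is aimed at modelers of
stochastic gene-regulatory and signaling networks who want reductions with
controlled (zero) QSS error instead of deterministic Michaelis–Menten-style
surrogates:

* **Feedforward fast subnetworks** — layered cascades whose nonlinear
  reactions use earlier-layer species only as unchanged catalysts.  Every
  moment then lies in a finite closed linear system $\dot{x} = Ax$ obtained
  by expanding master-equation moment derivatives
  $\tfrac{d}{dt}E[k^u] = \sum_j E[\rho_j(k)\,\{(k+\gamma_j)^u - k^u\}]$ and
  recursing; stationary conditional moments come from solving $Ax = 0$
  exactly with slow counts as symbolic parameters.
* **Complex-balanced fast subnetworks** — weakly reversible, deficiency
  zero (e.g. fast reversible bindings).  Conditioned on the conserved
  totals $\beta$, the stationary law is product-form Poisson normalized by
  the partition function $Z(\beta)=\sum_{Ak=\beta}\prod_i
  \lambda_i^{k_i}/k_i!$, and mixed factorial moments are shifted-$Z$
  ratios: $E[\prod_j S_j^{(r_j)}\mid Y{=}\beta] =
  (\prod_j\lambda_j^{r_j})\,Z(\beta-\sum_j r_j\alpha_{\cdot j})/Z(\beta)$.
  With one total left symbolic, the conditional mean becomes a ratio of
  polynomials with exact rational coefficients.

Reduced models built from the exact QSS (**EMB**) and from the usual
approximations (**AMB**: factorized first moments, or deterministic
total-QSSA formulas) can both be constructed and simulated with the
compiled Gillespie sampler, so the accuracy gain of the exact reduction is
directly measurable.  All symbolic work runs over exact big-rational
arithmetic — the normalized QSS polynomials have coefficients of order
$10^{16}$–$10^{18}$ with massive cancellation and are unusable in floating
point.

## Worked example

A genetic oscillator: promoter (total 10 copies) repressed by a fast
reversible binding of repressor R (association ratio 16), with slow
transcription, translation and degradation.

```r
library(exactqss)
osc <- build_example("oscillator")
osc
#> <reaction_network> 5 species, 9 reactions (2 fast), volume = 1
#>   DA -> DA + M   [10, slow]
#>   M -> 0   [1, slow]
#>   ...
#>   DA + R -> DR   [160, fast]
#>   DR -> DA + R   [10, fast]
```

The exact QSS of the active promoter given the slow repressor total
$T = X_R + X_{D_R}$ is a degree-9/degree-10 rational function with exact
rational coefficients:

```r
q <- derive_qss(osc, list(c(DA = 1)), mode = "emb")[["DA^1"]]$qss
q
#> stationary <DA^(1) | DR+R>
#> <qss_rational> (10 + 2.58274e+16*(DR+R) + -7.04208e+16*(DR+R)^2 + ... +
#>   6.87195e+11*(DR+R)^9) / (1 + -3.72234e+17*(DR+R) + ... +
#>   1.09951e+12*(DR+R)^10)
qss_eval(q, c(0, 5, 10, 15))
#> [1] 10.0000000  5.0512481  0.4749808  0.1017674
```

With no repressor the ten promoter copies are all active; by $T = 15$
transcription is essentially shut off.  Substituting the exact QSS into the
slow propensities gives a three-variable reduced model that the compiled
direct-method sampler simulates directly:

```r
emb <- build_reduced_model(osc, "emb")
emb
#> <reduced_model> EMB, variables: M, P, DR+R
#>   M +1: rate 10 * qss(DR+R)
#>   M -1: rate 1 * M^(1)
#>   P +1: rate 1 * M^(1)
#>   P -1: rate 1 * P^(1)
#>   DR+R +1: rate 1 * P^(1)
#>   DR+R -1: rate 1 * qss(DR+R)
#>   DR+R -1: rate 1 * qss(DR+R)

tr <- gillespie_direct(emb, t_end = 60, seed = 1, grid = seq(0, 60, 0.05))
period_analysis(tr, "M", n_segments = 2)
#> <period_stats> M: mean period 7.4301 (sd 2.771) from 2 segments
#>   (0 flagged); dominant spectral period 5.12
```

`autoplot()` methods exist for trajectories, ensemble summaries, period
statistics and rational QSS curves; `tidy()`/`glance()` return tibbles of
coefficients and summary statistics.

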