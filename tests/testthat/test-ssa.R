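# Gillespie direct method, ensemble summaries, period analysis.

test_that("identical seeds give bitwise-identical trajectories", {
  bd <- bd_network()
  t1 <- gillespie_direct(bd, 20, seed = 42, grid = seq(0, 20, 0.1))
  t2 <- gillespie_direct(bd, 20, seed = 42, grid = seq(0, 20, 0.1))
  expect_identical(t1$S, t2$S)
  t3 <- gillespie_direct(bd, 20, seed = 43, grid = seq(0, 20, 0.1))
  expect_false(identical(t1$S, t3$S))
})

test_that("birth-death long-run time average is the stationary mean", {
  bd <- bd_network(200, 1)
  tr <- gillespie_direct(bd, 60, seed = 7, grid = seq(0, 60, 0.05))
  y <- tr$S[tr$time > 5]
  # stationary law is Poisson(200); allow 3 standard errors with a crude
  # effective sample size of one per unit autocorrelation time
  se <- sd(y) / sqrt(55)
  expect_lt(abs(mean(y) - 200), 3 * max(se, sqrt(200 / 55)))
})

test_that("event counts of a pure birth process follow the Poisson law", {
  prod0 <- reaction_network("N", list(rxn(products = c(N = 1), rate = 3)))
  counts <- vapply(1:400, function(i) {
    tr <- gillespie_direct(prod0, 5, seed = 1000 + i, grid = c(0, 5))
    tr$N[2]
  }, numeric(1))
  lam <- 15
  breaks <- c(-Inf, qpois(c(0.2, 0.4, 0.6, 0.8), lam), Inf)
  obs <- table(cut(counts, breaks))
  pr <- diff(ppois(c(-1, qpois(c(0.2, 0.4, 0.6, 0.8), lam), Inf), lam))
  expect_gt(suppressWarnings(chisq.test(obs, p = pr)$p.value), 0.01)
})

test_that("absorbing states return early with constant state and zero spread", {
  dead <- reaction_network("S", list(rxn(reactants = c(S = 1), rate = 1)))
  tr <- gillespie_direct(dead, 10, seed = 1, grid = seq(0, 10, 0.5))
  expect_true(attr(tr, "absorbing"))
  expect_true(all(tr$S == 0))
  es <- ensemble_summary(dead, n_runs = 3, t_end = 5, grid = seq(0, 5, 0.5))
  expect_true(all(es$mean == 0))
  expect_true(all(es$sd == 0))
  expect_error(ensemble_summary(dead, n_runs = 3, t_end = 5, grid = numeric(0)),
               "empty")
})

test_that("stationary birth-death ensembles have Poisson mean-variance", {
  bd <- bd_network(20, 1)
  es <- ensemble_summary(bd, n_runs = 600, t_end = 12, grid = c(0, 10, 12), seed = 5)
  fin <- es[es$time == 12, ]
  expect_equal(fin$mean, 20, tolerance = 0.1)
  expect_equal(fin$sd^2, 20, tolerance = 0.25)
})

test_that("promoter total is conserved at every event of the oscillator", {
  osc <- build_example("oscillator", eps = 0.1)
  tr <- gillespie_direct(osc, 30, seed = 9, grid = seq(0, 30, 0.5),
                         record = "events")
  ev <- attr(tr, "events")
  expect_gt(nrow(ev), 100)
  expect_true(all(ev$DA + ev$DR == 10))
  expect_true(all(diff(ev$time) >= 0))
})

test_that("grid recording is piecewise-constant and never reads future events", {
  bd <- bd_network(5, 0.5)
  grid <- seq(0, 10, 0.25)
  tr <- gillespie_direct(bd, 10, seed = 21, grid = grid, record = "events")
  ev <- attr(tr, "events")
  for (k in c(2L, 11L, 23L, 41L)) {
    last <- which(ev$time <= grid[k])
    expected <- if (length(last) == 0L) bd$species$initial else ev$S[max(last)]
    expect_identical(tr$S[k], as.numeric(expected))
  }
})

test_that("period analysis recovers a known period and flags noise", {
  t <- seq(0, 480, 0.25)
  clean <- tibble::tibble(time = t, y = sin(2 * pi * t / 24))
  ps <- period_analysis(clean, "y", n_segments = 4)
  expect_equal(ps$mean, 24, tolerance = 0.01)
  expect_lt(ps$sd, 0.05)
  expect_equal(ps$n_flagged, 0L)
  expect_equal(ps$dominant_period, 24, tolerance = 0.3)
  set.seed(99)
  noise <- tibble::tibble(time = t, y = rnorm(length(t)))
  pn <- period_analysis(noise, "y", n_segments = 2)
  expect_equal(pn$n_valid, 0L)
  expect_true(is.na(pn$mean))
  expect_error(period_analysis(tibble::tibble(time = c(0, 1, 3), y = 1:3), "y", 1),
               "uniform")
})

test_that("the reduced cascade reproduces its analytic stationary mean", {
  emb <- build_reduced_model(build_example("feedforward"), "emb", reach_cap = 60)
  es <- ensemble_summary(emb, n_runs = 400, t_end = 8, grid = c(0, 8), seed = 2)
  fin <- es[es$time == 8 & es$species == "S4", ]
  expect_lt(abs(fin$mean - 80), 3 * fin$sd / sqrt(400))
})
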