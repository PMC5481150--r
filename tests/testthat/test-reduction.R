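# Timescale splitting, QSS derivation and reduced-model construction.

test_that("fast/slow splits identify the published fast species and slow variables", {
  pf <- split_fast_slow(build_example("feedforward"))
  expect_setequal(pf$fast_species, c("S1", "S3"))
  expect_setequal(pf$slow_species, c("S2", "S4"))
  expect_equal(nrow(pf$slow_variables), 0L)
  po <- split_fast_slow(build_example("oscillator"))
  expect_setequal(po$fast_species, c("DA", "DR", "R"))
  expect_equal(po$slow_variable_names, "DR+R")
  expect_equal(unname(po$conserved_values), 10)
  pd <- split_fast_slow(build_example("decoy"))
  expect_setequal(pd$fast_species, c("P", "G0", "GA", "D", "DP"))
  expect_equal(pd$slow_variable_names, "P+GA+DP")
  expect_setequal(unname(pd$conserved_values), c(1, 10))
  slowonly <- reaction_network("S", list(rxn(products = c(S = 1), rate = 1)))
  expect_error(split_fast_slow(slowonly), "no fast")
})

test_that("slow variables are invariant under every fast reaction", {
  for (nm in c("feedforward", "negative_feedback", "oscillator", "decoy")) {
    net <- build_example(nm)
    p <- split_fast_slow(net)
    G <- stoichiometry_matrix(net)
    for (M in list(p$slow_variables, p$conserved_totals)) {
      if (nrow(M) > 0)
        expect_true(all(M %*% G[, p$fast_reactions] == 0L))
    }
  }
})

test_that("exact and factorized QSS reproduce the cascade's slow propensities", {
  net <- build_example("feedforward")        # eps = 0.01; QSS is eps-free
  qe <- derive_qss(net, mode = "emb")
  qa <- derive_qss(net, mode = "amb")
  expect_identical(qe[["S1^1"]]$kind, "constant")
  expect_identical(qstr(qe[["S1^1"]]$value), "2")
  expect_identical(qstr(qa[["S1^1"]]$value), "2")
  # <X1 X3 | X2> = 10 X2 exactly; factorized approximation gives 8 X2
  expect_equal(qss_coefficients(qe[["S1^1*S3^1"]]$qss, "num"), c(0, 10))
  expect_equal(qss_coefficients(qe[["S1^1*S3^1"]]$qss, "den"), 1)
  expect_equal(qss_coefficients(qa[["S1^1*S3^1"]]$qss, "num"), c(0, 8))
  # with the slow propensity factor alpha4/Omega = 2: 20 X2 vs 16 X2
})

test_that("exact QSS from the moment closure matches the truncated-CME oracle", {
  net <- build_example("negative_feedback", eps = 1)
  q <- derive_qss(net, list(c(R = 2)), mode = "emb")[["R^2"]]
  expect_identical(q$var, "P")
  for (XP in 1L) {
    sub <- reaction_network(c("E", "F", "Q", "R"), list(
      rxn(products = c(E = 1), rate = 1),
      rxn(reactants = c(E = 1), rate = 1),
      rxn(reactants = c(E = 1), products = c(E = 1, Q = 1), rate = XP),
      rxn(reactants = c(Q = 1), rate = 1),
      rxn(products = c(F = 1), rate = 1),
      rxn(reactants = c(F = 1), rate = 1),
      rxn(reactants = c(Q = 1, F = 1), products = c(Q = 1, F = 1, R = 1), rate = 1),
      rxn(reactants = c(R = 1), rate = 1)))
    orc <- cme_stationary(sub, cap = c(E = 13, F = 13, Q = 22, R = 66))
    expect_lt(orc$tail_mass, 1e-10)
    r2 <- orc$moment(c(0, 0, 0, 2)) - orc$moment(c(0, 0, 0, 1))
    expect_equal(qss_eval(q$qss, XP), r2, tolerance = 1e-6)
  }
})

test_that("deterministic QSS formulas satisfy their boundary identities", {
  f <- deterministic_qss_formulas("oscillator_tqssa", list(XDT = 10, c = 1 / 16))
  expect_equal(f(0), 10)                       # exact algebraic identity
  expect_true(all(diff(f(0:50)) < 0))
  fp <- deterministic_qss_formulas("oscillator_tqssa", list(XDT = 10, c = 1 / 16),
                                   variant = "printed")
  expect_lt(fp(0), 10)                         # the printed variant misses it
  g <- deterministic_qss_formulas("decoy")
  expect_equal(g(0), 0)
  expect_equal(g(1e7), 1, tolerance = 1e-5)    # promoter saturation
  expect_error(f(-1), "negative")
  expect_error(g(-1), "negative")
})

test_that("reduced models eliminate fast species and carry correct propensities", {
  net <- build_example("feedforward")
  emb <- build_reduced_model(net, "emb", reach_cap = 60)
  amb <- build_reduced_model(net, "amb", reach_cap = 60)
  expect_setequal(emb$variables$name, c("S2", "S4"))
  expect_false(any(c("S1", "S3") %in% emb$variables$name))
  # S2 production at constant rate alpha2 <X1> = 4
  r_s2 <- emb$reactions[[which(vapply(emb$reactions, function(r)
    r$net[["S2"]] == 1, logical(1)))]]
  expect_equal(r_s2$rate, 4)
  # S4 production: 20 X2 (EMB) vs 16 X2 (AMB), via the tabulated QSS
  pick_s4 <- function(m) m$reactions[[which(vapply(m$reactions, function(r)
    r$net[["S4"]] == 1, logical(1)))]]
  re <- pick_s4(emb); ra <- pick_s4(amb)
  expect_equal(re$rate * re$table[6], 20 * 5)  # at X2 = 5
  expect_equal(ra$rate * ra$table[6], 16 * 5)
  # oscillator EMB: transcription propensity alphaM * f(T)/g(T)
  osc <- build_example("oscillator")
  oemb <- build_reduced_model(osc, "emb", reach_cap = 50)
  expect_setequal(oemb$variables$name, c("M", "P", "DR+R"))
  rm1 <- oemb$reactions[[1]]
  qssDA <- derive_qss(osc, list(c(DA = 1)), "emb")[["DA^1"]]$qss
  expect_equal(rm1$rate * rm1$table[1:6], 10 * qss_eval(qssDA, 0:5))
  # negative feedback EMB: dimerization propensity from the 24-moment closure
  nfb <- build_example("negative_feedback")
  nemb <- build_reduced_model(nfb, "emb", reach_cap = 40)
  expect_setequal(nemb$variables$name, c("G", "GR", "M", "P", "RR"))
  rdim <- nemb$reactions[[which(vapply(nemb$reactions, function(r)
    !is.na(r$table_var) && r$net[["RR"]] == 1, logical(1)))]]
  expect_identical(rdim$table_var, "P")
  expect_equal(rdim$table[1], 0)               # no protein, no dimerization
  expect_true(all(rdim$table >= 0))
})

test_that("simulation errors out when the slow state leaves the tabulated range", {
  osc <- build_example("oscillator")
  tiny <- build_reduced_model(osc, "emb", reach_cap = 5)
  expect_error(gillespie_direct(tiny, t_end = 50, seed = 5), "reach_cap")
})
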