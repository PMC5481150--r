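# Network representation, propensities, conservation laws, model I/O.

test_that("falling-factorial propensities match printed propensity forms", {
  dimer <- reaction_network("R", list(rxn(c(R = 2), c(R = 1), rate = 1)))
  expect_equal(propensity_eval(dimer, c(R = 3)), 6)       # kf2/W * X(X-1)
  expect_equal(propensity_eval(dimer, c(R = 1)), 0)
  prod0 <- reaction_network("S1", list(rxn(products = c(S1 = 1), rate = 200)))
  expect_equal(propensity_eval(prod0, c(S1 = 999)), 200)  # zeroth order
  bim <- reaction_network(c("S1", "S2", "S3"),
    list(rxn(c(S1 = 1, S2 = 1), c(S1 = 1, S2 = 1, S3 = 1), rate = 2)))
  expect_equal(propensity_eval(bim, c(S1 = 2, S2 = 5, S3 = 0)), 20)
  expect_error(propensity_eval(bim, c(S1 = -1, S2 = 5, S3 = 0)), "negative")
})

test_that("propensities are non-negative and invariant under species reordering", {
  set.seed(11)
  net <- build_example("negative_feedback", eps = 0.5)
  sp <- net$species$name
  for (i in 1:20) {
    st <- setNames(sample(0:6, length(sp), TRUE), sp)
    p1 <- propensity_eval(net, st)
    p2 <- propensity_eval(net, st[sample(sp)])  # named lookup reorders
    expect_true(all(p1 >= 0))
    expect_equal(p1, p2)
  }
})

test_that("conservation bases match the known totals of the example subnetworks", {
  b1 <- conservation_basis(binding_network())
  expect_equal(nrow(b1), 2L)
  expect_true(all(apply(b1, 1, function(v) paste(names(v)[v != 0], collapse = "+")) %in%
                  c("DA+DR", "R+DR")))
  b2 <- conservation_basis(double_binding_network())
  nm <- apply(b2, 1, function(v) paste(names(v)[v != 0], collapse = "+"))
  expect_setequal(nm, c("P+GA+DP", "G0+GA", "D+DP"))
  expect_true(all(b2 >= 0))
  bd <- bd_network()
  expect_equal(nrow(conservation_basis(bd)), 0L)
})

test_that("every conservation vector is exactly orthogonal to its stoichiometry columns", {
  for (nm in c("feedforward", "negative_feedback", "oscillator", "decoy")) {
    net <- build_example(nm)
    G <- stoichiometry_matrix(net)
    B <- conservation_basis(net)
    if (nrow(B) > 0) expect_true(all(B %*% G == 0L))
    fast <- which(vapply(net$reactions, function(r) r$timescale == "fast", logical(1)))
    Bf <- conservation_basis(net, fast)
    expect_true(all(Bf %*% G[, fast] == 0L))
  }
})

test_that("JSON model round trip is the identity (numeric and symbolic rates)", {
  net <- build_example("oscillator")
  rt <- model_from_json(model_to_json(net))
  expect_identical(stoichiometry_matrix(net), stoichiometry_matrix(rt))
  expect_identical(net$species$initial, rt$species$initial)
  expect_identical(lapply(net$reactions, `[[`, "rate"),
                   lapply(rt$reactions, `[[`, "rate"))
  sym <- reaction_network("S", list(rxn(products = c(S = 1), rate = "2/eps")),
                          params = "eps")
  rt2 <- model_from_json(model_to_json(sym))
  expect_identical(rt2$reactions[[1]]$rate, "2/eps")
  expect_equal(propensity_eval(rt2, c(S = 0), params = list(eps = 0.01)), 200)
  tmp <- tempfile(fileext = ".json")
  model_to_json(net, tmp)
  expect_identical(stoichiometry_matrix(model_from_json(tmp)),
                   stoichiometry_matrix(net))
})

test_that("malformed model documents raise informative errors", {
  expect_error(model_from_json('{"species": [{"name": "A"}]}'), "reactions")
  expect_error(model_from_json(
    '{"species": [{"name": "A"}],
      "reactions": [{"reactants": {"X9": 1}, "products": {}, "rate": 1}]}'),
    "X9")
  expect_error(model_from_json(
    '{"species": [{"name": "A"}],
      "reactions": [{"reactants": {"A": 1}, "products": {}}]}'),
    "rate")
  expect_error(rxn(reactants = c(A = 1), rate = -2), "positive")
  expect_error(reaction_network(c("A", "A"),
                                list(rxn(reactants = c(A = 1), rate = 1))),
               "unique")
})
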