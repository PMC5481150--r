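# Complex-balance route: structure, equilibria, partition functions,
# factorial moments and the closed-form rational QSS.

test_that("deficiency reports match hand counts", {
  r1 <- analyze_structure(binding_network())
  expect_equal(tidy(r1)$n_complexes, 2L)
  expect_equal(r1$n_linkage_classes, 1L)
  expect_equal(r1$stoich_rank, 1L)
  expect_equal(r1$deficiency, 0L)
  expect_true(r1$weakly_reversible)
  r2 <- analyze_structure(double_binding_network())
  expect_equal(r2$n_complexes, 4L)
  expect_equal(r2$n_linkage_classes, 2L)
  expect_equal(r2$stoich_rank, 2L)
  expect_equal(r2$deficiency, 0L)
  expect_true(r2$weakly_reversible)
  oneway <- reaction_network(c("A", "B"),
    list(rxn(reactants = c(A = 1), products = c(B = 1), rate = 1)))
  expect_false(analyze_structure(oneway)$weakly_reversible)
})

test_that("equilibria satisfy detailed balance with free species at one", {
  eq <- solve_equilibrium(binding_network(16, 1))
  expect_identical(qstr(eq$lambda$DA), "1")
  expect_identical(qstr(eq$lambda$R), "1")
  expect_identical(qstr(eq$lambda$DR), "16")
  # symbolic rates instantiated through params: (kf, kb) = (16/eps, 1/eps)
  bindE <- reaction_network(c("DA", "R", "DR"), list(
    rxn(c(DA = 1, R = 1), c(DR = 1), rate = "16/eps", timescale = "fast"),
    rxn(c(DR = 1), c(DA = 1, R = 1), rate = "1/eps", timescale = "fast")),
    params = "eps")
  eqE <- solve_equilibrium(bindE, params = list(eps = "1/100"))
  expect_identical(qstr(eqE$lambda$DR), "16")
  eq2 <- solve_equilibrium(double_binding_network())
  expect_identical(qstr(eq2$lambda$GA), "20")
  expect_identical(qstr(eq2$lambda$DP), "100")
  expect_identical(qstr(solve_equilibrium(bd_network(3, 4))$lambda$S), "3/4")
  oneway <- reaction_network(c("A", "B"),
    list(rxn(reactants = c(A = 1), products = c(B = 1), rate = 1)))
  expect_error(solve_equilibrium(oneway), "weakly reversible")
})

test_that("partition functions and factorial moments match hand enumeration", {
  eq <- solve_equilibrium(binding_network())
  cons <- conservation_constraint(conservation_basis(binding_network()), c(1, 1))
  expect_equal(partition_function(eq, cons, beta = c(1, 0)), 1)
  expect_equal(partition_function(eq, cons), 17)
  expect_equal(partition_function(eq, cons, beta = c(1, -1)), 0)
  expect_identical(qstr(factorial_moment(c(DA = 1), cons, eq, exact = TRUE)), "1/17")
  cons10 <- conservation_constraint(conservation_basis(binding_network()), c(10, 1))
  expect_identical(qstr(factorial_moment(c(DA = 1), cons10, eq, exact = TRUE)),
                   "1450/161")
  # boundary rule: second factorial moment with a single promoter copy
  cons15 <- conservation_constraint(conservation_basis(binding_network()), c(1, 5))
  expect_equal(factorial_moment(c(DA = 2), cons15, eq), 0)
  expect_error(factorial_moment(c(DA = 1), conservation_constraint(
    conservation_basis(binding_network()), c(0, 0)), eq), NA)
  # conditioning on an infeasible class errors
  A <- conservation_basis(binding_network())
  expect_error(
    factorial_moment(c(DA = 1),
                     conservation_constraint(A[1, , drop = FALSE], 1), eq),
    "unbounded")
})

test_that("factorial moments agree with brute-force enumeration (random networks)", {
  set.seed(15)
  for (i in 1:6) {
    kf <- sample.int(40, 2); kb <- sample.int(9, 2)
    net <- double_binding_network(kf[1], kb[1], kf[2], kb[2])
    eq <- solve_equilibrium(net)
    cons <- conservation_constraint(conservation_basis(net),
                                    c(sample(0:8, 1), sample(1:3, 1), sample(0:4, 1)))
    if (partition_function(eq, cons) == 0) next
    cd <- conditional_distribution(cons, eq)
    exact_p <- attr(cd, "exact")
    total <- Reduce(exactqss:::q_add, exact_p)
    expect_identical(qstr(total), "1")              # normalization, exactly
    for (spn in c("P", "GA", "DP")) {
      direct <- Reduce(exactqss:::q_add, lapply(seq_along(exact_p), function(k)
        exactqss:::q_mul(exact_p[[k]], exactqss:::q_from_int(cd[[spn]][k]))))
      expect_true(exactqss:::q_eq(direct,
        factorial_moment(setNames(1L, spn), cons, eq, exact = TRUE)))
    }
    # a mixed second-order factorial moment against direct enumeration
    direct2 <- Reduce(exactqss:::q_add, lapply(seq_along(exact_p), function(k)
      exactqss:::q_mul(exact_p[[k]],
                       exactqss:::q_from_int(cd$P[k] * (cd$P[k] - 1)))))
    expect_true(exactqss:::q_eq(direct2,
      factorial_moment(c(P = 2), cons, eq, exact = TRUE)))
  }
})

test_that("conditional moments are invariant across admissible equilibria", {
  net <- binding_network()
  cons <- conservation_constraint(conservation_basis(net), c(10, 7))
  eq1 <- solve_equilibrium(net)
  eq2 <- equilibrium(c(DA = 2, R = 3, DR = 96))    # scaled along the class
  expect_true(exactqss:::is_complex_balanced(net, eq2))
  for (spn in c("DA", "R", "DR")) {
    expect_true(exactqss:::q_eq(
      factorial_moment(setNames(1L, spn), cons, eq1, exact = TRUE),
      factorial_moment(setNames(1L, spn), cons, eq2, exact = TRUE)))
  }
})

test_that("partition function slices reproduce the Poisson law of a free species", {
  eq <- equilibrium(c(S = "7/2"))
  consS <- conservation_constraint(matrix(1L, 1, 1, dimnames = list(NULL, "S")), 0)
  zs <- vapply(0:20, function(b) partition_function(eq, consS, beta = b), numeric(1))
  expect_equal(cumsum(zs) * exp(-7 / 2), ppois(0:20, 7 / 2), tolerance = 1e-12)
})

test_that("the closed-form rational QSS equals enumeration at every feasible total", {
  net <- binding_network()
  eq <- solve_equilibrium(net)
  consS <- conservation_constraint(conservation_basis(net), list(10, "XT"))
  qss <- conditional_mean_rational(c(DA = 1), consS, eq)
  expect_identical(qss$var, "XT")
  expect_equal(length(qss$num) - 1L, 9L)
  expect_equal(length(qss$den) - 1L, 10L)
  expect_identical(qstr(qss$den[[1]]), "1")        # normalization g(0) = 1
  for (n in c(0:12, 20, 30, 50)) {
    cz <- conservation_constraint(conservation_basis(net), c(10, n))
    expect_true(exactqss:::q_eq(qss_eval(qss, n, exact = TRUE),
                                factorial_moment(c(DA = 1), cz, eq, exact = TRUE)))
  }
  # decoy: no transcription factors, no active promoter
  dec <- double_binding_network()
  eqd <- solve_equilibrium(dec)
  consD <- conservation_constraint(conservation_basis(dec)[c(2, 3, 1), ],
                                   list(1, 10, "XT"))
  qd <- conditional_mean_rational(c(GA = 1), consD, eqd)
  expect_equal(qss_eval(qd, 0), 0)
  for (n in c(1, 5, 11, 25)) {
    cz <- conservation_constraint(conservation_basis(dec)[c(2, 3, 1), ],
                                  c(1, 10, n))
    expect_true(exactqss:::q_eq(qss_eval(qd, n, exact = TRUE),
                                factorial_moment(c(GA = 1), cz, eqd, exact = TRUE)))
  }
})
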