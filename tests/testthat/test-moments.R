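# Moment machinery: finite differences, master-equation moment derivatives,
# recursive closure, feedforward verification, stationary solving.

test_that("delta expansion matches hand calculations and always cancels k^u", {
  d <- delta_monomial(c(2L, 1L), c(1L, 0L))        # 2 k1 k2 + k2
  terms <- exactqss:::mp_terms(d)
  keys <- vapply(terms, function(t) exactqss:::moment_string(t$nu), character(1))
  expect_setequal(keys, c("11", "01"))
  expect_identical(format(terms[[which(keys == "11")]]$coef), "2")
  expect_length(delta_monomial(c(3L, 2L), c(0L, 0L)), 0L)
  d2 <- exactqss:::mp_terms(delta_monomial(1L, -1L))
  expect_identical(exactqss:::moment_string(d2[[1]]$nu), "0")
  expect_identical(format(d2[[1]]$coef), "-1")
  set.seed(12)
  for (i in 1:30) {
    u <- sample(0:3, 3, TRUE)
    g <- sample(-2:2, 3, TRUE)
    dd <- delta_monomial(u, g)
    expect_false(exactqss:::mp_key(u) %in% names(unclass(dd)))
  }
})

test_that("moment derivatives reproduce hand-derived master-equation terms", {
  bd <- reaction_network("S", list(rxn(products = c(S = 1), rate = "a"),
                                   rxn(reactants = c(S = 1), rate = "b")),
                         params = c("a", "b"))
  md <- exactqss:::mp_terms(moment_derivative(1L, bd))
  keys <- vapply(md, function(t) exactqss:::moment_string(t$nu), character(1))
  expect_setequal(keys, c("0", "1"))
  expect_identical(format(md[[which(keys == "0")]]$coef), "a")
  expect_identical(format(md[[which(keys == "1")]]$coef), "-b")
  # second moment of R in the fast feedforward module: production through
  # Q*F touches 0111 and 0110, degradation touches 0002 and 0001
  d <- exactqss:::mp_terms(moment_derivative(c(0L, 0L, 0L, 2L), ffmodule_network()))
  keys <- vapply(d, function(t) exactqss:::moment_string(t$nu), character(1))
  expect_setequal(keys, c("0110", "0111", "0001", "0002"))
})

test_that("recursive closure terminates with the expected moment sets", {
  bd <- bd_network(2, 1)
  sys <- build_closure(list(1L), bd)
  expect_identical(moment_strings(sys), "1")
  expect_identical(moment_strings(sys, include_constant = TRUE), c("0", "1"))
  sm <- stationary_moments(sys)
  expect_identical(qstr(sm[["1"]]), "2")
  # the published 24-moment closure of the fast feedforward module
  sys24 <- build_closure(list(c(0L, 0L, 0L, 2L)), ffmodule_network())
  ms <- moment_strings(sys24)
  published <- c("0002", "0001", "0110", "0111", "0010", "0011", "0220",
                 "1100", "1101", "0020", "0100", "0101", "0120", "0210",
                 "1000", "1001", "1200", "1210", "0200", "1010", "1110",
                 "2200", "2000", "2100")
  expect_length(ms, 24L)
  expect_setequal(ms, published)
  expect_identical(max(vapply(sys24$moments, sum, integer(1))), 4L)
  expect_error(build_closure(list(1L), bd, max_moments = 0L), "positive")
  # cap exceeded -> failure report, not an error
  fail <- build_closure(list(c(0L, 0L, 0L, 2L)), ffmodule_network(),
                        max_moments = 5L)
  expect_s3_class(fail, "closure_failure")
  expect_gt(length(fail$frontier), 0L)
})

test_that("closure succeeds from any seed for purely linear networks", {
  set.seed(13)
  for (i in 1:10) {
    nsp <- sample(2:3, 1)
    sp <- paste0("Z", seq_len(nsp))
    rxns <- list(rxn(products = setNames(1L, sp[1]), rate = 1))
    for (j in 1:4) {
      from <- sample(nsp, 1)
      to <- sample(nsp, 1)
      rxns[[length(rxns) + 1L]] <- if (from == to)
        rxn(reactants = setNames(1L, sp[from]), rate = 1)
      else rxn(reactants = setNames(1L, sp[from]),
               products = setNames(1L, sp[to]), rate = 1)
    }
    net <- reaction_network(sp, rxns)
    seed <- sample(0:2, nsp, TRUE)
    if (all(seed == 0L)) seed[1] <- 1L
    sys <- build_closure(list(seed), net)
    expect_s3_class(sys, "moment_system")
  }
})

test_that("feedforward verification accepts the layered cascades and rejects binding", {
  expect_true(check_feedforward(build_example("feedforward"))$feedforward)
  expect_true(check_feedforward(ffmodule_network())$feedforward)
  # explicit layer witness for the module: E,F | Q | R
  man <- check_feedforward(ffmodule_network(),
                           layers = c(E = 1, F = 1, Q = 2, R = 3))
  expect_true(man$feedforward)
  cb <- check_feedforward(binding_network())
  expect_false(cb$feedforward)
  expect_match(cb$violation, "reactants")
})

test_that("stationary conditional moments match the closed-form fast-pair results", {
  # <X1> = a1/b1 and <X1 X3> = a1^2 a3 X2 / (b1^2 b3) + a1 a3 X2/(b1 (b1+b3)),
  # in combined-rate form, at random exact parameter points
  net <- fastpair_network()
  sys <- build_closure(list(c(1L, 1L)), net)
  set.seed(14)
  for (i in 1:6) {
    v <- lapply(setNames(sample.int(6, 5, TRUE), c("a1", "b1", "a3", "b3", "X2")),
                exactqss:::q_from_int)
    sm <- stationary_moments(sys, v)
    m1 <- exactqss:::q_div(v$a1, v$b1)
    expect_true(exactqss:::q_eq(sm[["10"]], m1))
    e2 <- exactqss:::q_add(
      exactqss:::q_div(exactqss:::q_mul(exactqss:::q_mul(m1, m1),
                                        exactqss:::q_mul(v$a3, v$X2)), v$b3),
      exactqss:::q_div(exactqss:::q_mul(m1, exactqss:::q_mul(v$a3, v$X2)),
                       exactqss:::q_add(v$b1, v$b3)))
    expect_true(exactqss:::q_eq(sm[["11"]], e2))
  }
})

test_that("singular stationary systems report the nullspace dimension", {
  conv <- reaction_network(c("A", "B"), list(
    rxn(reactants = c(A = 1), products = c(B = 1), rate = 1),
    rxn(reactants = c(B = 1), products = c(A = 1), rate = 2)))
  sys <- build_closure(list(c(1L, 0L)), conv)
  expect_error(stationary_moments(sys), "nullspace dimension 1")
})

test_that("stationary moments agree with the truncated-CME oracle", {
  # fast pair at X2 = 3 (combined rates of the cascade example, eps = 1)
  net <- fastpair_network()
  pars <- list(a1 = 2, b1 = 1, a3 = 2, b3 = 1, X2 = 3)
  sys <- build_closure(list(c(1L, 1L), c(2L, 0L)), net)
  sm <- stationary_moments(sys, pars, as_numeric = TRUE)
  orc <- cme_stationary(
    reaction_network(c("S1", "S3"), list(
      rxn(products = c(S1 = 1), rate = 2),
      rxn(reactants = c(S1 = 1), rate = 1),
      rxn(reactants = c(S1 = 1), products = c(S1 = 1, S3 = 1), rate = 6),
      rxn(reactants = c(S3 = 1), rate = 1))),
    cap = c(S1 = 20, S3 = 130))
  expect_lt(orc$tail_mass, 1e-10)
  for (key in names(sm)) {
    u <- as.integer(strsplit(key, "")[[1]])
    expect_equal(sm[[key]], orc$moment(u), tolerance = 1e-6)
  }
})
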