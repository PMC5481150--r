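# Multivariate polynomial / rational-function layer and exact rational
# reconstruction.

rand_poly <- function(vars, max_terms = 4L) {
  nt <- sample.int(max_terms, 1)
  ex <- matrix(sample(0:3, nt * length(vars), TRUE), nt, length(vars))
  cf <- lapply(seq_len(nt), function(i)
    exactqss:::q_from_frac(sample(-9:9, 1), sample.int(5, 1)))
  keep <- !vapply(cf, exactqss:::q_is_zero, logical(1))
  if (!any(keep)) return(exactqss:::qp_zero())
  exactqss:::qp_make(vars, ex[keep, , drop = FALSE], cf[keep])
}

test_that("polynomial arithmetic is a commutative ring (random cases)", {
  set.seed(7)
  pt <- list(x = qn(3), y = qn("-2/3"), z = qn("5/7"))
  for (i in 1:25) {
    a <- rand_poly(c("x", "y")); b <- rand_poly(c("y", "z")); c <- rand_poly("x")
    lhs <- exactqss:::qp_mul(a, exactqss:::qp_add(b, c))
    rhs <- exactqss:::qp_add(exactqss:::qp_mul(a, b), exactqss:::qp_mul(a, c))
    expect_true(exactqss:::qp_equal(lhs, rhs))
    expect_true(exactqss:::q_eq(
      exactqss:::qp_eval(exactqss:::qp_mul(a, b), pt),
      exactqss:::q_mul(exactqss:::qp_eval(a, pt), exactqss:::qp_eval(b, pt))))
  }
})

test_that("partial substitution then evaluation equals direct evaluation", {
  set.seed(8)
  pt <- list(x = qn("7/2"), y = qn(-4), z = qn("1/3"))
  for (i in 1:20) {
    p <- rand_poly(c("x", "y", "z"), 5L)
    q <- exactqss:::qp_subs(p, list(y = pt$y))
    expect_true(exactqss:::q_eq(exactqss:::qp_eval(q, pt), exactqss:::qp_eval(p, pt)))
  }
})

test_that("rate expressions parse to exact rational functions", {
  f <- exactqss:::parse_qexpr("a1^2*a3/(b1^2*b3) + a1*a3/(b1*(b1+b3)*W)",
                              c("a1", "a3", "b1", "b3", "W"))
  v <- list(a1 = qn(2), a3 = qn(2), b1 = qn(1), b3 = qn(1), W = qn(1))
  expect_identical(qstr(exactqss:::qrf_eval(f, v)), "10")
  expect_error(exactqss:::parse_qexpr("a + q9", params = "a"), "undeclared")
  expect_identical(qstr(exactqss:::qrf_eval(exactqss:::parse_qexpr("2/0.5"))), "4")
})

test_that("univariate division, gcd and derivative behave algebraically", {
  set.seed(9)
  upl <- function(v) lapply(v, exactqss:::q_parse)
  for (i in 1:20) {
    a <- upl(sample(-5:5, sample(2:6, 1), TRUE))
    b <- upl(sample(-5:5, sample(1:4, 1), TRUE))
    a <- exactqss:::up_trim(a); b <- exactqss:::up_trim(b)
    if (length(b) == 0L) next
    dm <- exactqss:::up_divrem(a, b)
    back <- exactqss:::up_add(exactqss:::up_mul(dm$q, b), dm$r)
    expect_equal(exactqss:::up_deg(exactqss:::up_add(
      back, exactqss:::up_scale(a, qn(-1)))), -1L)
    g <- exactqss:::up_gcd(exactqss:::up_mul(a, b), b)
    if (length(exactqss:::up_trim(a)) > 0L)
      expect_identical(exactqss:::up_deg(exactqss:::up_divrem(b, g)$r), -1L)
  }
  d <- exactqss:::up_deriv(upl(c(5, 0, 3)))     # d/dx (5 + 3x^2) = 6x
  expect_identical(qstr(d[[2]]), "6")
})

test_that("rational reconstruction recovers random rational functions exactly", {
  set.seed(10)
  for (i in 1:8) {
    dp <- sample(0:3, 1); dq <- sample(0:3, 1)
    p <- lapply(sample(-6:6, dp + 1, TRUE), exactqss:::q_parse)
    q <- c(lapply(sample(-6:6, dq, TRUE), exactqss:::q_parse), list(qn(1)))
    if (exactqss:::q_is_zero(p[[length(p)]])) p[[length(p)]] <- qn(1)
    fn <- function(x) {
      den <- exactqss:::up_eval(q, x)
      if (exactqss:::q_is_zero(den)) stop("pole")
      exactqss:::q_div(exactqss:::up_eval(p, x), den)
    }
    rc <- reconstruct_rational(fn, max_total = 8)
    for (x in c(23, 57, 101)) {
      expect_true(exactqss:::q_eq(
        exactqss:::q_div(exactqss:::up_eval(rc$num, qn(x)),
                         exactqss:::up_eval(rc$den, qn(x))),
        fn(qn(x))))
    }
  }
})
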