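# Exact big-rational arithmetic layer.

test_that("big-integer ring operations agree with machine arithmetic on small operands", {
  set.seed(101)
  for (i in 1:200) {
    a <- sample.int(2^25, 1) - 2^24
    b <- sample.int(2^25, 1) - 2^24
    A <- exactqss:::bi_from_num(a)
    B <- exactqss:::bi_from_num(b)
    expect_identical(exactqss:::bi_to_num(exactqss:::bi_add(A, B)), a + b)
    expect_identical(exactqss:::bi_to_num(exactqss:::bi_mul(A, B)), a * b)
    if (b != 0) {
      dm <- exactqss:::bi_divmod(A, B)
      expect_identical(exactqss:::bi_to_num(dm$q), trunc(a / b))
      expect_identical(exactqss:::bi_to_num(dm$r), a - trunc(a / b) * b)
    }
  }
})

test_that("division identity a = q*b + r holds for random 60-digit integers", {
  set.seed(202)
  rand_digits <- function(n) paste(c(sample(1:9, 1), sample(0:9, n - 1, TRUE)),
                                   collapse = "")
  for (i in 1:40) {
    a <- exactqss:::bi_from_str(rand_digits(sample(25:60, 1)))
    b <- exactqss:::bi_from_str(rand_digits(sample(5:30, 1)))
    dm <- exactqss:::bi_divmod(a, b)
    back <- exactqss:::bi_add(exactqss:::bi_mul(dm$q, b), dm$r)
    expect_identical(exactqss:::bi_to_str(back), exactqss:::bi_to_str(a))
    expect_lt(exactqss:::bi_cmp(exactqss:::bi_abs(dm$r), exactqss:::bi_abs(b)), 1L)
    g <- exactqss:::bi_gcd(a, b)
    expect_identical(exactqss:::bi_to_str(exactqss:::bi_divmod(a, g)$r), "0")
    expect_identical(exactqss:::bi_to_str(exactqss:::bi_divmod(b, g)$r), "0")
  }
})

test_that("rational parsing and field operations are exact", {
  expect_identical(qstr(exactqss:::q_add(qn("1/3"), qn("1/6"))), "1/2")
  expect_identical(qstr(qn("0.8")), "4/5")
  expect_identical(qstr(qn("2.5e3")), "2500")
  expect_identical(qstr(qn(-16)), "-16")
  expect_identical(qstr(exactqss:::q_div(qn("2/3"), qn("4/9"))), "3/2")
  expect_identical(qstr(exactqss:::q_pow_int(qn("2/3"), -2)), "9/4")
  # a/b + c/d recombined exactly
  set.seed(33)
  for (i in 1:50) {
    v <- sample.int(50, 4)
    lhs <- exactqss:::q_add(exactqss:::q_from_frac(v[1], v[2]),
                            exactqss:::q_from_frac(v[3], v[4]))
    rhs <- exactqss:::q_from_frac(v[1] * v[4] + v[3] * v[2], v[2] * v[4])
    expect_true(exactqss:::q_eq(lhs, rhs))
  }
})

test_that("Stirling numbers of the first kind satisfy the classical identities", {
  S1 <- exactqss:::stirling1_table(8)
  for (n in 2:8) {
    row <- S1[[n + 1L]]
    total <- Reduce(exactqss:::q_add, row)
    expect_true(exactqss:::q_is_zero(total))             # sum_k s(n,k) = 0
    abs_total <- Reduce(exactqss:::q_add, lapply(row, exactqss:::q_abs))
    expect_identical(exactqss:::q_to_num(abs_total), factorial(n))
  }
  # x^(3) = x^3 - 3x^2 + 2x
  expect_identical(qstr(S1[[4]][[3]]), "-3")
  expect_identical(qstr(S1[[4]][[2]]), "2")
})
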