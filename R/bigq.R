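# Exact big-integer / big-rational arithmetic.
#
# Partition functions and the normalized rational QSS polynomials involve
# coefficients far beyond 2^53 with massive alternating-sign cancellation, so
# every moment/partition-function computation in this package runs over exact
# rationals.  Integers are stored little-endian in base 1e7 double digits;
# all intermediate digit products stay below 2^53.

BI_BASE <- 1e7

bi_zero <- function() list(s = 0L, d = numeric(0))

bi_norm <- function(s, d) {
  n <- length(d)
  while (n > 0L && d[n] == 0) n <- n - 1L
  if (n == 0L) return(list(s = 0L, d = numeric(0)))
  list(s = as.integer(s), d = d[seq_len(n)])
}

# x: integer-valued double with |x| < 2^53
bi_from_num <- function(x) {
  if (is.na(x) || x != trunc(x) || abs(x) >= 2^53)
    stop("bi_from_num: not an exactly representable integer: ", x)
  s <- if (x > 0) 1L else if (x < 0) -1L else 0L
  x <- abs(x)
  d <- numeric(0)
  while (x > 0) {
    d <- c(d, x %% BI_BASE)
    x <- (x - x %% BI_BASE) / BI_BASE
  }
  bi_norm(s, d)
}

bi_from_str <- function(str) {
  str <- trimws(str)
  s <- 1L
  if (startsWith(str, "-")) { s <- -1L; str <- substring(str, 2L) }
  else if (startsWith(str, "+")) str <- substring(str, 2L)
  if (!grepl("^[0-9]+$", str)) stop("bi_from_str: bad integer literal: ", str)
  str <- sub("^0+(?=.)", "", str, perl = TRUE)
  if (str == "0") return(bi_zero())
  nd <- ceiling(nchar(str) / 7)
  d <- numeric(nd)
  for (i in seq_len(nd)) {
    hi <- nchar(str) - (i - 1L) * 7L
    lo <- max(1L, hi - 6L)
    d[i] <- as.numeric(substr(str, lo, hi))
  }
  bi_norm(s, d)
}

bi_is_zero <- function(a) a$s == 0L
bi_neg <- function(a) if (a$s == 0L) a else list(s = -a$s, d = a$d)
bi_abs <- function(a) if (a$s < 0L) list(s = 1L, d = a$d) else a

# magnitude comparison: -1, 0, 1
mag_cmp <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la != lb) return(if (la < lb) -1L else 1L)
  for (i in rev(seq_len(la))) {
    if (a[i] != b[i]) return(if (a[i] < b[i]) -1L else 1L)
  }
  0L
}

mag_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  r <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    v <- r[i] + carry
    carry <- if (v >= BI_BASE) 1 else 0
    r[i] <- v - carry * BI_BASE
  }
  if (carry > 0) r <- c(r, carry)
  r
}

# requires mag(a) >= mag(b)
mag_sub <- function(a, b) {
  n <- length(a)
  b <- c(b, numeric(n - length(b)))
  r <- a - b
  for (i in seq_len(n)) {
    if (r[i] < 0) {
      r[i] <- r[i] + BI_BASE
      r[i + 1L] <- r[i + 1L] - 1
    }
  }
  ln <- n
  while (ln > 0L && r[ln] == 0) ln <- ln - 1L
  r[seq_len(ln)]
}

mag_mul <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la == 0L || lb == 0L) return(numeric(0))
  r <- numeric(la + lb)
  for (i in seq_len(la)) {
    ai <- a[i]
    if (ai == 0) next
    carry <- 0
    # digit products <= (1e7-1)^2 ~ 1e14; + existing digit + carry stays < 2^53
    for (j in seq_len(lb)) {
      v <- r[i + j - 1L] + ai * b[j] + carry
      carry <- floor(v / BI_BASE)
      r[i + j - 1L] <- v - carry * BI_BASE
    }
    k <- i + lb
    while (carry > 0) {
      v <- r[k] + carry
      carry <- floor(v / BI_BASE)
      r[k] <- v - carry * BI_BASE
      k <- k + 1L
    }
  }
  ln <- length(r)
  while (ln > 0L && r[ln] == 0) ln <- ln - 1L
  r[seq_len(ln)]
}

# divide magnitude by single digit b (0 < b < BI_BASE); returns list(q, r)
mag_divmod_small <- function(a, b) {
  n <- length(a)
  q <- numeric(n)
  r <- 0
  for (i in rev(seq_len(n))) {
    cur <- r * BI_BASE + a[i]       # < 1e14 + 1e7, exact in double
    q[i] <- floor(cur / b)
    r <- cur - q[i] * b
  }
  ln <- n
  while (ln > 0L && q[ln] == 0) ln <- ln - 1L
  list(q = q[seq_len(ln)], r = r)
}

# log-magnitude of a digit vector, exact enough to estimate quotient digits
mag_log <- function(x) {
  l <- length(x)
  if (l == 0L) return(-Inf)
  v <- x[l]
  if (l >= 2L) v <- v * BI_BASE + x[l - 1L]
  if (l >= 3L) v <- v * BI_BASE + x[l - 2L]
  log(v) + (l - min(l, 3L)) * log(BI_BASE)
}

# schoolbook long division; digit estimate by log ratio, corrected exactly.
# returns list(q, r) of magnitudes
mag_divmod <- function(a, b) {
  if (length(b) == 0L) stop("division by zero")
  cc <- mag_cmp(a, b)
  if (cc < 0L) return(list(q = numeric(0), r = a))
  if (length(b) == 1L) {
    dm <- mag_divmod_small(a, b[1L])
    return(list(q = dm$q, r = if (dm$r == 0) numeric(0) else dm$r))
  }
  la <- length(a)
  q <- numeric(la)
  r <- numeric(0)
  lb <- mag_log(b)
  for (i in rev(seq_len(la))) {
    # r <- r * BASE + a[i]
    r <- if (length(r) == 0L) {
      if (a[i] == 0) numeric(0) else a[i]
    } else c(a[i], r)
    if (mag_cmp(r, b) < 0L) { q[i] <- 0; next }
    qd <- floor(exp(mag_log(r) - lb) + 0.5)
    qd <- max(1, min(qd, BI_BASE - 1))
    while (qd > 0 && mag_cmp(mag_mul(b, qd), r) > 0L) qd <- qd - 1
    while (qd < BI_BASE - 1 && mag_cmp(mag_mul(b, qd + 1), r) <= 0L) qd <- qd + 1
    q[i] <- qd
    if (qd > 0) {
      r <- mag_sub(r, mag_mul(b, qd))
    }
  }
  lq <- la
  while (lq > 0L && q[lq] == 0) lq <- lq - 1L
  list(q = q[seq_len(lq)], r = r)
}

bi_add <- function(a, b) {
  if (a$s == 0L) return(b)
  if (b$s == 0L) return(a)
  if (a$s == b$s) return(bi_norm(a$s, mag_add(a$d, b$d)))
  cc <- mag_cmp(a$d, b$d)
  if (cc == 0L) return(bi_zero())
  if (cc > 0L) bi_norm(a$s, mag_sub(a$d, b$d)) else bi_norm(b$s, mag_sub(b$d, a$d))
}

bi_sub <- function(a, b) bi_add(a, bi_neg(b))

bi_mul <- function(a, b) {
  if (a$s == 0L || b$s == 0L) return(bi_zero())
  bi_norm(a$s * b$s, mag_mul(a$d, b$d))
}

# truncated toward zero
bi_divmod <- function(a, b) {
  if (bi_is_zero(b)) stop("division by zero")
  dm <- mag_divmod(a$d, b$d)
  list(q = bi_norm(a$s * b$s, dm$q), r = bi_norm(a$s, dm$r))
}

bi_cmp <- function(a, b) {
  if (a$s != b$s) return(if (a$s < b$s) -1L else 1L)
  if (a$s == 0L) return(0L)
  a$s * mag_cmp(a$d, b$d)
}

bi_gcd <- function(a, b) {
  a <- bi_abs(a); b <- bi_abs(b)
  while (!bi_is_zero(b)) {
    r <- bi_divmod(a, b)$r
    a <- b
    b <- r
  }
  if (bi_is_zero(a)) bi_from_num(1) else a
}

bi_to_num <- function(a) {
  if (a$s == 0L) return(0)
  v <- 0
  for (i in rev(seq_along(a$d))) v <- v * BI_BASE + a$d[i]
  a$s * v
}

bi_to_str <- function(a) {
  if (a$s == 0L) return("0")
  n <- length(a$d)
  parts <- vapply(rev(a$d), function(x) formatC(x, width = 7, flag = "0", format = "d"),
                  character(1))
  parts[1L] <- sub("^0+", "", parts[1L])
  paste0(if (a$s < 0L) "-" else "", paste(parts, collapse = ""))
}

bi_pow <- function(a, n) {
  if (n < 0) stop("negative power")
  r <- bi_from_num(1)
  while (n > 0) {
    if (n %% 2 == 1) r <- bi_mul(r, a)
    a <- bi_mul(a, a)
    n <- n %/% 2
  }
  r
}

## ---- rationals -------------------------------------------------------------

# rational: list(n = bigint, d = bigint > 0), always reduced
q_make <- function(n, d) {
  if (bi_is_zero(d)) stop("rational with zero denominator")
  if (bi_is_zero(n)) return(structure(list(n = bi_zero(), d = bi_from_num(1)), class = "bigq"))
  s <- n$s * d$s
  n <- bi_abs(n); d <- bi_abs(d)
  g <- bi_gcd(n, d)
  if (!(length(g$d) == 1L && g$d[1L] == 1)) {
    n <- bi_divmod(n, g)$q
    d <- bi_divmod(d, g)$q
  }
  n$s <- as.integer(s)
  structure(list(n = n, d = d), class = "bigq")
}

q_from_int <- function(x) q_make(bi_from_num(x), bi_from_num(1))

q_from_frac <- function(a, b) q_make(bi_from_num(a), bi_from_num(b))

# exact rational from a double or a string like "-3/4", "16", "0.8", "2.5e3"
q_parse <- function(x) {
  if (inherits(x, "bigq")) return(x)
  if (is.numeric(x)) {
    if (x == trunc(x) && abs(x) < 2^53) return(q_from_int(x))
    x <- format(x, digits = 15, scientific = FALSE)
  }
  x <- trimws(as.character(x))
  if (grepl("/", x, fixed = TRUE)) {
    parts <- strsplit(x, "/", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("q_parse: bad rational literal: ", x)
    return(q_make(bi_from_str(parts[1L]), bi_from_str(parts[2L])))
  }
  m <- regmatches(x, regexec("^([+-]?)([0-9]*)\\.?([0-9]*)[eE]?([+-]?[0-9]+)?$", x))[[1L]]
  if (length(m) == 0L || (m[3L] == "" && m[4L] == ""))
    stop("q_parse: bad numeric literal: ", x)
  sgn <- if (m[2L] == "-") "-" else ""
  digits <- paste0(m[3L], m[4L])
  expo <- (if (m[5L] == "") 0L else as.integer(m[5L])) - nchar(m[4L])
  num <- bi_from_str(paste0(sgn, digits))
  if (expo >= 0L) {
    q_make(bi_mul(num, bi_pow(bi_from_num(10), expo)), bi_from_num(1))
  } else {
    q_make(num, bi_pow(bi_from_num(10), -expo))
  }
}

q_zero <- function() q_from_int(0)
q_one <- function() q_from_int(1)
q_is_zero <- function(a) bi_is_zero(a$n)
q_sign <- function(a) a$n$s
q_neg <- function(a) structure(list(n = bi_neg(a$n), d = a$d), class = "bigq")
q_abs <- function(a) structure(list(n = bi_abs(a$n), d = a$d), class = "bigq")

q_add <- function(a, b) q_make(bi_add(bi_mul(a$n, b$d), bi_mul(b$n, a$d)), bi_mul(a$d, b$d))
q_sub <- function(a, b) q_add(a, q_neg(b))
q_mul <- function(a, b) q_make(bi_mul(a$n, b$n), bi_mul(a$d, b$d))
q_div <- function(a, b) {
  if (q_is_zero(b)) stop("rational division by zero")
  q_make(bi_mul(a$n, b$d), bi_mul(a$d, b$n))
}
q_inv <- function(a) q_div(q_one(), a)

q_cmp <- function(a, b) bi_cmp(bi_mul(a$n, b$d), bi_mul(b$n, a$d))
q_eq <- function(a, b) q_cmp(a, b) == 0L

q_pow_int <- function(a, n) {
  if (n < 0) return(q_inv(q_pow_int(a, -n)))
  r <- q_one()
  while (n > 0) {
    if (n %% 2 == 1) r <- q_mul(r, a)
    a <- q_mul(a, a)
    n <- n %/% 2
  }
  r
}

q_to_num <- function(a) {
  v <- bi_to_num(a$n) / bi_to_num(a$d)
  if (is.finite(v)) return(v)
  # fall back through scaled division for very large magnitudes
  dm <- bi_divmod(a$n, a$d)
  bi_to_num(dm$q) + bi_to_num(dm$r) / bi_to_num(a$d)
}

q_to_str <- function(a) {
  if (length(a$d$d) == 1L && a$d$d[1L] == 1) return(bi_to_str(a$n))
  paste0(bi_to_str(a$n), "/", bi_to_str(a$d))
}

#' @export
format.bigq <- function(x, ...) q_to_str(x)

#' @export
print.bigq <- function(x, ...) {
  cat("<bigq> ", q_to_str(x), "\n", sep = "")
  invisible(x)
}

q_factorial <- function(n) {
  r <- bi_from_num(1)
  if (n >= 2) for (i in 2:n) r <- bi_mul(r, bi_from_num(i))
  q_make(r, bi_from_num(1))
}

# signed Stirling numbers of the first kind, s(n, k), as a dense table
# up to order nmax: falling factorial x^(n) = sum_k s(n,k) x^k
stirling1_table <- function(nmax) {
  tab <- vector("list", nmax + 1L)
  tab[[1L]] <- list(q_one())                       # s(0,0) = 1
  if (nmax >= 1L) {
    for (n in seq_len(nmax)) {
      prev <- tab[[n]]
      row <- vector("list", n + 1L)
      row[[1L]] <- q_zero()
      for (k in seq_len(n)) {
        a <- if (k <= length(prev) && k >= 1L) prev[[k]] else q_zero()      # s(n-1, k-1)
        b <- if (k + 1L <= length(prev)) prev[[k + 1L]] else q_zero()       # s(n-1, k)
        row[[k + 1L]] <- q_sub(a, q_mul(q_from_int(n - 1), b))
      }
      # row indices: [k+1] holds s(n, k)
      row[[1L]] <- q_zero()
      tab[[n + 1L]] <- row
    }
  }
  tab
}
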