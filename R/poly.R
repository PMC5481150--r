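# Multivariate polynomials and rational functions over exact rationals.
#
# Coefficients of moment equations are polynomials in rate constants, the
# volume and designated slow-species counts; stationary conditional moments
# are rational functions of one conserved total.  Terms are kept in a
# canonical sorted order so symbolic objects compare and print predictably.

## ---- multivariate polynomials ---------------------------------------------

qp_make <- function(vars, expts, coefs) {
  stopifnot(is.character(vars), is.matrix(expts) || length(coefs) == 0L)
  if (length(coefs) == 0L)
    return(structure(list(vars = character(0),
                          expts = matrix(0L, 0L, 0L), coefs = list()),
                     class = "qpoly"))
  # drop variables that never appear
  if (length(vars) > 0L) {
    used <- colSums(expts) > 0L
    vars <- vars[used]
    expts <- expts[, used, drop = FALSE]
  }
  # sort variables alphabetically
  if (length(vars) > 1L) {
    o <- order(vars)
    vars <- vars[o]
    expts <- expts[, o, drop = FALSE]
  }
  # combine duplicate terms
  keys <- if (ncol(expts) == 0L) rep("c", nrow(expts))
          else paste0("e", apply(expts, 1L, paste, collapse = ","))
  env <- new.env(parent = emptyenv())
  for (i in seq_along(coefs)) {
    k <- keys[i]
    cur <- if (exists(k, envir = env, inherits = FALSE)) get(k, envir = env) else NULL
    assign(k, if (is.null(cur)) coefs[[i]] else q_add(cur, coefs[[i]]), envir = env)
  }
  uk <- unique(keys)
  keep_coefs <- list(); keep_rows <- integer(0)
  for (k in uk) {
    v <- get(k, envir = env)
    if (!q_is_zero(v)) {
      keep_coefs[[length(keep_coefs) + 1L]] <- v
      keep_rows <- c(keep_rows, match(k, keys))
    }
  }
  if (length(keep_coefs) == 0L)
    return(structure(list(vars = character(0),
                          expts = matrix(0L, 0L, 0L), coefs = list()),
                     class = "qpoly"))
  expts <- expts[keep_rows, , drop = FALSE]
  # canonical term order: total degree, then lexicographic on exponents
  ord <- do.call(order, c(list(rowSums(expts)),
                          lapply(seq_len(ncol(expts)), function(j) expts[, j])))
  structure(list(vars = vars, expts = expts[ord, , drop = FALSE],
                 coefs = keep_coefs[ord]), class = "qpoly")
}

qp_zero <- function() qp_make(character(0), matrix(0L, 0L, 0L), list())

qp_const <- function(q) {
  if (!inherits(q, "bigq")) q <- q_parse(q)
  if (q_is_zero(q)) return(qp_zero())
  qp_make(character(0), matrix(0L, 1L, 0L), list(q))
}

qp_var <- function(name, power = 1L) {
  qp_make(name, matrix(as.integer(power), 1L, 1L), list(q_one()))
}

qp_is_zero <- function(p) length(p$coefs) == 0L

qp_is_const <- function(p) length(p$vars) == 0L

qp_const_value <- function(p) {
  if (qp_is_zero(p)) return(q_zero())
  stopifnot(qp_is_const(p))
  p$coefs[[1L]]
}

# extend p's exponent matrix to a variable superset
qp_extend <- function(p, vars) {
  ex <- matrix(0L, nrow(p$expts), length(vars))
  if (length(p$vars) > 0L) ex[, match(p$vars, vars)] <- p$expts
  ex
}

qp_add <- function(a, b) {
  vars <- sort(union(a$vars, b$vars))
  qp_make(vars, rbind(qp_extend(a, vars), qp_extend(b, vars)),
          c(a$coefs, b$coefs))
}

qp_neg <- function(p) {
  p$coefs <- lapply(p$coefs, q_neg)
  p
}

qp_sub <- function(a, b) qp_add(a, qp_neg(b))

qp_scale <- function(p, q) {
  if (!inherits(q, "bigq")) q <- q_parse(q)
  if (q_is_zero(q) || qp_is_zero(p)) return(qp_zero())
  p$coefs <- lapply(p$coefs, q_mul, b = q)
  p
}

qp_mul <- function(a, b) {
  if (qp_is_zero(a) || qp_is_zero(b)) return(qp_zero())
  vars <- sort(union(a$vars, b$vars))
  ea <- qp_extend(a, vars); eb <- qp_extend(b, vars)
  na <- nrow(ea); nb <- nrow(eb)
  ex <- matrix(0L, na * nb, length(vars))
  cf <- vector("list", na * nb)
  k <- 0L
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      k <- k + 1L
      ex[k, ] <- ea[i, ] + eb[j, ]
      cf[[k]] <- q_mul(a$coefs[[i]], b$coefs[[j]])
    }
  }
  qp_make(vars, ex, cf)
}

qp_pow <- function(p, n) {
  stopifnot(n >= 0)
  r <- qp_const(q_one())
  while (n > 0) {
    if (n %% 2 == 1) r <- qp_mul(r, p)
    p <- qp_mul(p, p)
    n <- n %/% 2
  }
  r
}

# substitute a subset of variables with bigq values (or other polynomials)
qp_subs <- function(p, assign) {
  if (qp_is_zero(p) || length(assign) == 0L) return(p)
  out <- qp_zero()
  hit <- intersect(p$vars, names(assign))
  if (length(hit) == 0L) return(p)
  for (i in seq_along(p$coefs)) {
    term <- qp_const(p$coefs[[i]])
    for (j in seq_along(p$vars)) {
      e <- p$expts[i, j]
      if (e == 0L) next
      v <- p$vars[j]
      if (v %in% hit) {
        val <- assign[[v]]
        fac <- if (inherits(val, "qpoly")) qp_pow(val, e)
               else qp_const(q_pow_int(q_parse(val), e))
        term <- qp_mul(term, fac)
      } else {
        term <- qp_mul(term, qp_var(v, e))
      }
    }
    out <- qp_add(out, term)
  }
  out
}

# full evaluation to a bigq; every variable must be assigned
qp_eval <- function(p, assign = list()) {
  missing <- setdiff(p$vars, names(assign))
  if (length(missing) > 0L)
    stop("qp_eval: unassigned variables: ", paste(missing, collapse = ", "))
  tot <- q_zero()
  for (i in seq_along(p$coefs)) {
    v <- p$coefs[[i]]
    for (j in seq_along(p$vars)) {
      e <- p$expts[i, j]
      if (e > 0L) v <- q_mul(v, q_pow_int(q_parse(assign[[p$vars[j]]]), e))
    }
    tot <- q_add(tot, v)
  }
  tot
}

qp_deg <- function(p, var = NULL) {
  if (qp_is_zero(p)) return(-Inf)
  if (is.null(var)) return(max(rowSums(p$expts), 0L))
  j <- match(var, p$vars)
  if (is.na(j)) return(0L)
  max(p$expts[, j])
}

qp_equal <- function(a, b) qp_is_zero(qp_sub(a, b))

qp_to_str <- function(p) {
  if (qp_is_zero(p)) return("0")
  terms <- character(length(p$coefs))
  for (i in seq_along(p$coefs)) {
    mono <- character(0)
    for (j in seq_along(p$vars)) {
      e <- p$expts[i, j]
      if (e == 1L) mono <- c(mono, p$vars[j])
      else if (e > 1L) mono <- c(mono, paste0(p$vars[j], "^", e))
    }
    cstr <- q_to_str(p$coefs[[i]])
    terms[i] <- if (length(mono) == 0L) cstr
                else if (cstr == "1") paste(mono, collapse = "*")
                else if (cstr == "-1") paste0("-", paste(mono, collapse = "*"))
                else paste(c(cstr, mono), collapse = "*")
  }
  out <- terms[1L]
  for (t in terms[-1L]) {
    out <- if (startsWith(t, "-")) paste0(out, " - ", substring(t, 2L))
           else paste0(out, " + ", t)
  }
  out
}

#' @export
format.qpoly <- function(x, ...) qp_to_str(x)

#' @export
print.qpoly <- function(x, ...) {
  cat("<qpoly> ", qp_to_str(x), "\n", sep = "")
  invisible(x)
}

## ---- dense univariate helpers (lists of bigq, ascending powers) ------------

up_trim <- function(cf) {
  n <- length(cf)
  while (n > 0L && q_is_zero(cf[[n]])) n <- n - 1L
  cf[seq_len(n)]
}

up_deg <- function(cf) length(up_trim(cf)) - 1L

up_add <- function(a, b) {
  n <- max(length(a), length(b))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    x <- if (i <= length(a)) a[[i]] else q_zero()
    y <- if (i <= length(b)) b[[i]] else q_zero()
    out[[i]] <- q_add(x, y)
  }
  up_trim(out)
}

up_scale <- function(a, q) up_trim(lapply(a, q_mul, b = q))

up_mul <- function(a, b) {
  a <- up_trim(a); b <- up_trim(b)
  if (length(a) == 0L || length(b) == 0L) return(list())
  out <- rep(list(q_zero()), length(a) + length(b) - 1L)
  for (i in seq_along(a)) for (j in seq_along(b))
    out[[i + j - 1L]] <- q_add(out[[i + j - 1L]], q_mul(a[[i]], b[[j]]))
  out
}

up_eval <- function(cf, x) {
  if (!inherits(x, "bigq")) x <- q_parse(x)
  acc <- q_zero()
  for (i in rev(seq_along(cf))) acc <- q_add(q_mul(acc, x), cf[[i]])
  acc
}

# polynomial division over the rationals; returns list(q, r)
up_divrem <- function(a, b) {
  a <- up_trim(a); b <- up_trim(b)
  if (length(b) == 0L) stop("polynomial division by zero")
  q <- list()
  while (length(a) >= length(b) && length(a) > 0L) {
    k <- length(a) - length(b)            # shift
    c <- q_div(a[[length(a)]], b[[length(b)]])
    term <- c(rep(list(q_zero()), k), list(c))
    q <- up_add(q, term)
    a <- up_trim(up_add(a, up_scale(up_mul(term, b), q_from_int(-1))))
  }
  list(q = q, r = a)
}

up_gcd <- function(a, b) {
  a <- up_trim(a); b <- up_trim(b)
  while (length(b) > 0L) {
    r <- up_divrem(a, b)$r
    a <- b
    b <- r
  }
  if (length(a) == 0L) return(list(q_one()))
  up_scale(a, q_inv(a[[length(a)]]))      # monic
}

up_deriv <- function(a) {
  a <- up_trim(a)
  if (length(a) <= 1L) return(list())
  out <- vector("list", length(a) - 1L)
  for (i in 2:length(a)) out[[i - 1L]] <- q_mul(a[[i]], q_from_int(i - 1L))
  out
}

# dense univariate view of a qpoly in `var` (all other vars must be absent)
qp_uni_coeffs <- function(p, var) {
  extra <- setdiff(p$vars, var)
  if (length(extra) > 0L)
    stop("polynomial is not univariate in ", var, " (also contains: ",
         paste(extra, collapse = ", "), ")")
  if (qp_is_zero(p)) return(list())
  d <- qp_deg(p, var)
  out <- rep(list(q_zero()), d + 1L)
  j <- match(var, p$vars)
  for (i in seq_along(p$coefs)) {
    e <- if (is.na(j)) 0L else p$expts[i, j]
    out[[e + 1L]] <- q_add(out[[e + 1L]], p$coefs[[i]])
  }
  up_trim(out)
}

qp_from_uni <- function(cf, var) {
  cf <- up_trim(cf)
  if (length(cf) == 0L) return(qp_zero())
  qp_make(var, matrix(seq_along(cf) - 1L, ncol = 1L), cf)
}

## ---- rational functions ----------------------------------------------------

qrf_make <- function(num, den = qp_const(q_one())) {
  if (qp_is_zero(den)) stop("rational function with zero denominator")
  if (qp_is_zero(num)) den <- qp_const(q_one())
  # reduce when both parts are constant or share one variable
  onevar <- union(num$vars, den$vars)
  if (length(onevar) == 0L) {
    if (!qp_is_zero(num)) {
      v <- q_div(qp_const_value(num), qp_const_value(den))
      return(structure(list(num = qp_const(v), den = qp_const(q_one())),
                       class = "qratf"))
    }
  } else if (length(onevar) == 1L) {
    v <- onevar
    cn <- qp_uni_coeffs(num, v); cd <- qp_uni_coeffs(den, v)
    g <- up_gcd(cn, cd)
    if (up_deg(g) > 0L) {
      cn <- up_divrem(cn, g)$q
      cd <- up_divrem(cd, g)$q
    }
    # normalize: denominator constant term 1 when nonzero, else monic
    nz <- if (!q_is_zero(cd[[1L]])) cd[[1L]] else cd[[length(cd)]]
    cn <- up_scale(cn, q_inv(nz)); cd <- up_scale(cd, q_inv(nz))
    num <- qp_from_uni(cn, v); den <- qp_from_uni(cd, v)
  }
  structure(list(num = num, den = den), class = "qratf")
}

qrf_const <- function(q) qrf_make(qp_const(q))
qrf_var <- function(name) qrf_make(qp_var(name))
qrf_is_zero <- function(f) qp_is_zero(f$num)

qrf_add <- function(a, b) {
  qrf_make(qp_add(qp_mul(a$num, b$den), qp_mul(b$num, a$den)),
           qp_mul(a$den, b$den))
}
qrf_neg <- function(a) { a$num <- qp_neg(a$num); a }
qrf_sub <- function(a, b) qrf_add(a, qrf_neg(b))
qrf_mul <- function(a, b) qrf_make(qp_mul(a$num, b$num), qp_mul(a$den, b$den))
qrf_div <- function(a, b) {
  if (qrf_is_zero(b)) stop("rational function division by zero")
  qrf_make(qp_mul(a$num, b$den), qp_mul(a$den, b$num))
}
qrf_scale <- function(a, q) { a$num <- qp_scale(a$num, q); a }

qrf_eval <- function(f, assign = list()) {
  d <- qp_eval(f$den, assign)
  if (q_is_zero(d)) stop("qrf_eval: denominator vanishes at the given point")
  q_div(qp_eval(f$num, assign), d)
}

qrf_subs <- function(f, assign) qrf_make(qp_subs(f$num, assign), qp_subs(f$den, assign))

qrf_vars <- function(f) union(f$num$vars, f$den$vars)

# exact equality of rational functions as such
qrf_equal <- function(a, b) {
  qp_is_zero(qp_sub(qp_mul(a$num, b$den), qp_mul(b$num, a$den)))
}

#' @export
format.qratf <- function(x, ...) {
  if (qp_is_const(x$den) && q_eq(qp_const_value(x$den), q_one()))
    return(qp_to_str(x$num))
  paste0("(", qp_to_str(x$num), ") / (", qp_to_str(x$den), ")")
}

#' @export
print.qratf <- function(x, ...) {
  cat("<qratf> ", format(x), "\n", sep = "")
  invisible(x)
}

## ---- expression parsing -----------------------------------------------------

# Parse an arithmetic expression over declared parameter names into an exact
# rational function (used for symbolic rate constants in model files).
parse_qexpr <- function(text, params = NULL) {
  e <- tryCatch(str2lang(as.character(text)),
                error = function(err) stop("cannot parse expression: ", text))
  walk <- function(node) {
    if (is.numeric(node)) return(qrf_const(q_parse(node)))
    if (is.symbol(node)) {
      nm <- as.character(node)
      if (!is.null(params) && !(nm %in% params))
        stop("undeclared parameter in expression: ", nm)
      return(qrf_var(nm))
    }
    if (is.call(node)) {
      op <- as.character(node[[1L]])
      if (op == "(") return(walk(node[[2L]]))
      if (length(node) == 2L && op == "-") return(qrf_neg(walk(node[[2L]])))
      if (length(node) == 2L && op == "+") return(walk(node[[2L]]))
      a <- walk(node[[2L]]); b <- walk(node[[3L]])
      return(switch(op,
        "+" = qrf_add(a, b),
        "-" = qrf_sub(a, b),
        "*" = qrf_mul(a, b),
        "/" = qrf_div(a, b),
        "^" = {
          if (!qp_is_const(b$num) || !qp_is_const(b$den))
            stop("only numeric exponents are supported")
          n <- q_to_num(qrf_eval(b))
          if (n != trunc(n)) stop("only integer exponents are supported")
          r <- qrf_const(q_one())
          base <- if (n >= 0) a else qrf_div(qrf_const(q_one()), a)
          for (i in seq_len(abs(n))) r <- qrf_mul(r, base)
          r
        },
        stop("unsupported operator in rate expression: ", op)))
    }
    stop("unsupported construct in rate expression")
  }
  walk(e)
}

## ---- exact dense linear algebra ---------------------------------------------

# Solve A x = b over the rationals; A is a list of rows (lists of bigq).
# Returns the solution (list of bigq) or NULL if A is singular.
q_solve <- function(A, b) {
  n <- length(A)
  if (n == 0L) return(list())
  M <- lapply(seq_len(n), function(i) c(A[[i]], b[i]))
  for (col in seq_len(n)) {
    piv <- 0L
    for (r in col:n) if (!q_is_zero(M[[r]][[col]])) { piv <- r; break }
    if (piv == 0L) return(NULL)
    if (piv != col) { tmp <- M[[col]]; M[[col]] <- M[[piv]]; M[[piv]] <- tmp }
    pv <- M[[col]][[col]]
    M[[col]] <- lapply(M[[col]], q_div, b = pv)
    for (r in seq_len(n)) {
      if (r == col) next
      f <- M[[r]][[col]]
      if (q_is_zero(f)) next
      M[[r]] <- mapply(function(x, y) q_sub(x, q_mul(f, y)),
                       M[[r]], M[[col]], SIMPLIFY = FALSE)
    }
  }
  lapply(seq_len(n), function(i) M[[i]][[n + 1L]])
}

# Exact nullspace dimension of a square rational matrix (list-of-rows)
q_null_dim <- function(A) {
  n <- length(A)
  if (n == 0L) return(0L)
  m <- length(A[[1L]])
  M <- A
  rank <- 0L
  row <- 1L
  for (col in seq_len(m)) {
    piv <- 0L
    if (row > n) break
    for (r in row:n) if (!q_is_zero(M[[r]][[col]])) { piv <- r; break }
    if (piv == 0L) next
    if (piv != row) { tmp <- M[[row]]; M[[row]] <- M[[piv]]; M[[piv]] <- tmp }
    pv <- M[[row]][[col]]
    M[[row]] <- lapply(M[[row]], q_div, b = pv)
    for (r in seq_len(n)) {
      if (r == row) next
      f <- M[[r]][[col]]
      if (q_is_zero(f)) next
      M[[r]] <- mapply(function(x, y) q_sub(x, q_mul(f, y)),
                       M[[r]], M[[row]], SIMPLIFY = FALSE)
    }
    rank <- rank + 1L
    row <- row + 1L
  }
  m - rank
}

## ---- exact rational-function reconstruction ---------------------------------

#' Reconstruct a univariate rational function from exact evaluations
#'
#' Cauchy interpolation over the rationals: `fn` is evaluated exactly at
#' integer points, the unique rational function of bounded total degree
#' through the samples is found by an exact linear solve (searching
#' numerator/denominator degree splits in increasing total degree), and the
#' candidate is verified on held-out points before being reduced by the
#' polynomial gcd.  The denominator is normalized to constant term one (or
#' monic when that vanishes).
#'
#' @param fn function taking a `bigq` and returning a `bigq` (it may error
#'   at poles; such points are skipped).
#' @param max_total maximum numerator-plus-denominator degree searched.
#' @param n_verify number of held-out verification points.
#' @param start first integer sample point.
#' @return list with `num` and `den`, ascending-power `bigq` coefficient
#'   lists.
#' @export
reconstruct_rational <- function(fn, max_total = 16L, n_verify = 4L, start = 0L) {
  samples_x <- list(); samples_v <- list()
  next_x <- start
  get_samples <- function(k) {
    while (length(samples_x) < k) {
      x <- q_from_int(next_x)
      next_x <<- next_x + 1L
      v <- tryCatch(fn(x), error = function(e) NULL)
      if (is.null(v)) next
      samples_x[[length(samples_x) + 1L]] <<- x
      samples_v[[length(samples_v) + 1L]] <<- v
    }
  }
  for (total in 0:max_total) {
    for (dq in 0:total) {
      dp <- total - dq
      n_unk <- dp + 1L + dq                  # p_0..p_dp, q_0..q_{dq-1}; q_dq = 1
      get_samples(n_unk + n_verify)
      xs <- samples_x[seq_len(n_unk)]
      vs <- samples_v[seq_len(n_unk)]
      A <- vector("list", n_unk); bvec <- vector("list", n_unk)
      ok_build <- TRUE
      for (i in seq_len(n_unk)) {
        x <- xs[[i]]; v <- vs[[i]]
        row <- vector("list", n_unk)
        xp <- q_one()
        for (j in 0:dp) { row[[j + 1L]] <- xp; xp <- q_mul(xp, x) }
        xp <- q_one()
        for (j in seq_len(dq)) {
          row[[dp + 1L + j]] <- q_neg(q_mul(v, xp))
          xp <- q_mul(xp, x)
        }
        A[[i]] <- row
        bvec[[i]] <- q_mul(v, q_pow_int(x, dq))
      }
      if (!ok_build) next
      sol <- q_solve(A, bvec)
      if (is.null(sol)) next
      p <- sol[seq_len(dp + 1L)]
      q <- c(if (dq > 0L) sol[dp + 1L + seq_len(dq)] else list(), list(q_one()))
      p <- up_trim(p); q <- up_trim(q)
      if (length(q) == 0L) next
      # verify on held-out points
      ver <- samples_x[n_unk + seq_len(n_verify)]
      verv <- samples_v[n_unk + seq_len(n_verify)]
      good <- TRUE
      for (i in seq_len(n_verify)) {
        qd <- up_eval(q, ver[[i]])
        if (q_is_zero(qd)) { good <- FALSE; break }
        if (!q_eq(q_div(up_eval(p, ver[[i]]), qd), verv[[i]])) { good <- FALSE; break }
      }
      if (!good) next
      # reduce and normalize
      g <- up_gcd(p, q)
      if (up_deg(g) > 0L) { p <- up_divrem(p, g)$q; q <- up_divrem(q, g)$q }
      nz <- if (length(q) > 0L && !q_is_zero(q[[1L]])) q[[1L]] else q[[length(q)]]
      p <- up_scale(p, q_inv(nz)); q <- up_scale(q, q_inv(nz))
      return(list(num = p, den = q))
    }
  }
  stop("reconstruct_rational: no rational function of total degree <= ",
       max_total, " fits the evaluations")
}
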