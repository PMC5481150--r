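# Exact rational quasi-steady-state expressions in one symbolic slow total.

#' Exact rational QSS expression
#'
#' A stationary conditional expectation expressed as a ratio of polynomials
#' in one symbolic conserved total (e.g. \eqn{\langle X_{D_A} | X_T\rangle =
#' f(X_T)/g(X_T)}), with exact rational coefficients.  The denominator is
#' normalized so its constant term is one (or, if that vanishes, monic).
#' Evaluation is exact: the printed decimal coefficients of such functions
#' suffer catastrophic cancellation in floating point, so values are always
#' computed over the rationals and only converted at the end.
#'
#' @param num,den coefficient vectors (ascending powers), as `bigq` lists or
#'   numerics.
#' @param var name of the symbolic total.
#' @param description free-text label.
#' @return an object of class `qss_rational`.
#' @export
qss_rational <- function(num, den, var = "n", description = "") {
  tolist <- function(v) {
    if (is.numeric(v)) v <- lapply(v, q_parse)
    up_trim(v)
  }
  num <- tolist(num); den <- tolist(den)
  if (length(den) == 0L) stop("zero denominator")
  structure(list(num = num, den = den, var = var, description = description),
            class = "qss_rational")
}

#' Evaluate an exact rational QSS expression
#'
#' @param qss a [qss_rational].
#' @param n value(s) of the symbolic total (integers or `bigq`).
#' @param exact return `bigq` (single value) instead of doubles.
#' @return numeric vector, or a `bigq` when `exact = TRUE`.
#' @export
qss_eval <- function(qss, n, exact = FALSE) {
  one <- function(x) {
    xq <- if (inherits(x, "bigq")) x else q_parse(x)
    d <- up_eval(qss$den, xq)
    if (q_is_zero(d)) stop("denominator vanishes at ", format(xq))
    q_div(up_eval(qss$num, xq), d)
  }
  if (exact) {
    stopifnot(length(n) == 1L)
    return(one(n))
  }
  vapply(n, function(x) q_to_num(one(x)), numeric(1))
}

#' Polynomial coefficients of a rational QSS
#'
#' @param qss a [qss_rational].
#' @param part `"num"` or `"den"`.
#' @param exact return `bigq` list instead of doubles.
#' @return numeric vector of ascending-power coefficients.
#' @export
qss_coefficients <- function(qss, part = c("num", "den"), exact = FALSE) {
  part <- match.arg(part)
  cf <- qss[[part]]
  if (exact) cf else vapply(cf, q_to_num, numeric(1))
}

#' @export
print.qss_rational <- function(x, ...) {
  v <- if (grepl("[^A-Za-z0-9._]", x$var)) paste0("(", x$var, ")") else x$var
  fmt <- function(cf) {
    s <- vapply(seq_along(cf), function(i) {
      c <- q_to_num(cf[[i]])
      if (c == 0) return(NA_character_)
      pow <- if (i == 1L) "" else if (i == 2L) paste0("*", v)
             else paste0("*", v, "^", i - 1L)
      paste0(format(c, digits = 6), pow)
    }, character(1))
    paste(stats::na.omit(s), collapse = " + ")
  }
  if (nzchar(x$description)) cat(x$description, "\n")
  cat("<qss_rational> (", fmt(x$num), ") / (", fmt(x$den), ")\n", sep = "")
  invisible(x)
}

#' @rdname qss_rational
#' @param x a `qss_rational`.
#' @param ... unused.
#' @export
tidy.qss_rational <- function(x, ...) {
  part <- function(cf, lbl) tibble::tibble(
    part = lbl, degree = seq_along(cf) - 1L,
    coefficient = vapply(cf, q_to_num, numeric(1)),
    exact = vapply(cf, q_to_str, character(1)))
  dplyr::bind_rows(part(x$num, "numerator"), part(x$den, "denominator"))
}

#' @rdname qss_rational
#' @export
glance.qss_rational <- function(x, ...) {
  tibble::tibble(variable = x$var,
                 degree_num = length(x$num) - 1L,
                 degree_den = length(x$den) - 1L,
                 value_at_0 = qss_eval(x, 0))
}

#' Plot an exact rational QSS over a range of the conserved total
#'
#' @param object a [qss_rational].
#' @param from,to integer range of the total.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.qss_rational <- function(object, from = 0L, to = 30L, ...) {
  n <- seq.int(from, to)
  df <- tibble::tibble(n = n, value = qss_eval(object, n))
  ggplot2::ggplot(df, ggplot2::aes(x = n, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = object$var, y = "conditional expectation",
                  title = object$description)
}

#' Difference of two rational QSS expressions in the same variable
#'
#' @param a,b [qss_rational] objects sharing the same variable.
#' @return a [qss_rational] for `a - b`, reduced by their polynomial gcd.
#' @export
qss_sub <- function(a, b) {
  stopifnot(identical(a$var, b$var))
  num <- up_add(up_mul(a$num, b$den), up_scale(up_mul(b$num, a$den), q_from_int(-1)))
  den <- up_mul(a$den, b$den)
  num <- up_trim(num)
  if (length(num) == 0L) return(qss_rational(list(q_zero()), list(q_one()), var = a$var))
  g <- up_gcd(num, den)
  if (up_deg(g) > 0L) { num <- up_divrem(num, g)$q; den <- up_divrem(den, g)$q }
  nz <- if (!q_is_zero(den[[1L]])) den[[1L]] else den[[length(den)]]
  qss_rational(up_scale(num, q_inv(nz)), up_scale(den, q_inv(nz)), var = a$var,
               description = "difference")
}

#' Limit of a rational QSS as its variable tends to infinity
#'
#' @param qss a [qss_rational].
#' @param exact return a `bigq` (only for finite limits).
#' @return 0 when the numerator degree is smaller than the denominator
#'   degree, the ratio of leading coefficients when equal, and `Inf`/`-Inf`
#'   otherwise.
#' @export
qss_limit_inf <- function(qss, exact = FALSE) {
  dn <- length(up_trim(qss$num)) - 1L
  dd <- length(up_trim(qss$den)) - 1L
  if (dn < 0L) return(if (exact) q_zero() else 0)
  if (dn < dd) return(if (exact) q_zero() else 0)
  if (dn == dd) {
    v <- q_div(qss$num[[dn + 1L]], qss$den[[dd + 1L]])
    return(if (exact) v else q_to_num(v))
  }
  s <- q_sign(qss$num[[dn + 1L]]) * q_sign(qss$den[[dd + 1L]])
  if (exact) stop("limit is infinite")
  if (s > 0) Inf else -Inf
}
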