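# Symbolic moment machinery: chemical-master-equation moment derivatives,
# recursive linear-closure detection, feedforward verification and exact
# stationary (conditional) moment solving.
#
# A moment index u over the network's species ordering denotes the raw moment
# E[k^u] = E[k_1^{u_1} ... k_n^{u_n}].  The time derivative of E[k^u] follows
# from the master equation as
#   d/dt E[k^u] = sum_j E[ rho_j(k) * ((k + gamma_j)^u - k^u) ],
# and, with mass-action propensities expanded into monomials, the right-hand
# side is a finite linear combination of other raw moments.  For feedforward
# networks the recursion closes on a finite moment set.

## ---- moment polynomials -----------------------------------------------------

mp_zero <- function() structure(list(), class = "moment_poly")

mp_key <- function(nu) paste(nu, collapse = ",")

mp_add_term <- function(mp, nu, coef) {
  k <- mp_key(nu)
  cur <- mp[[k]]
  if (is.null(cur)) {
    mp[[k]] <- list(nu = as.integer(nu), coef = coef)
  } else {
    s <- qrf_add(cur$coef, coef)
    if (qrf_is_zero(s)) mp[[k]] <- NULL else mp[[k]]$coef <- s
  }
  mp
}

mp_terms <- function(mp) unclass(mp)

moment_string <- function(nu) {
  if (all(nu < 10L)) paste(nu, collapse = "") else paste(nu, collapse = ",")
}

#' @export
print.moment_poly <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<moment_poly> 0\n")
    return(invisible(x))
  }
  for (t in unclass(x)) {
    cat("  [", moment_string(t$nu), "] * (", format(t$coef), ")\n", sep = "")
  }
  invisible(x)
}

#' Finite-difference expansion of a monomial
#'
#' Expands \eqn{(k+\gamma)^u - k^u} as a polynomial in \eqn{k} with integer
#' coefficients.  The input monomial \eqn{k^u} always cancels exactly, which
#' is what makes moment derivatives expressible through strictly "smaller"
#' moment directions.
#'
#' @param u non-negative integer exponent vector.
#' @param gamma integer net-change vector of the same length.
#' @return a `moment_poly`: a set of exponent vectors with exact coefficients.
#' @examples
#' delta_monomial(c(2, 1), c(1, 0))  # 2*k1*k2 + k2
#' @export
delta_monomial <- function(u, gamma) {
  stopifnot(length(u) == length(gamma), all(u >= 0))
  # expand prod_i (k_i + g_i)^{u_i} by binomials, then subtract k^u
  terms <- list(list(nu = integer(0), coef = q_one()))
  for (i in seq_along(u)) {
    new <- list()
    for (t in terms) {
      if (u[i] == 0L) {
        new[[length(new) + 1L]] <- list(nu = c(t$nu, 0L), coef = t$coef)
        next
      }
      for (c in 0:u[i]) {
        coef <- q_mul(t$coef,
                      q_mul(q_from_int(choose(u[i], c)),
                            q_pow_int(q_from_int(gamma[i]), u[i] - c)))
        if (q_is_zero(coef)) next
        new[[length(new) + 1L]] <- list(nu = c(t$nu, as.integer(c)), coef = coef)
      }
    }
    terms <- new
  }
  mp <- mp_zero()
  for (t in terms) mp <- mp_add_term(mp, t$nu, qrf_const(t$coef))
  mp_add_term(mp, u, qrf_const(q_from_int(-1)))
}

#' Moment derivative from the master equation
#'
#' Computes \eqn{\frac{d}{dt} E[k^u]} for a mass-action network as an exact
#' linear combination of raw moments.  Propensities are first expanded from
#' falling factorials into monomials; symbolic rate constants (including
#' designated slow-species counts folded into rates) are carried through as
#' exact rational-function coefficients.
#'
#' @param u moment index: non-negative integer vector, one entry per species
#'   of `network` (in network species order).
#' @param network a [reaction_network()].
#' @return a `moment_poly` mapping moment indices to coefficients.
#' @export
moment_derivative <- function(u, network) {
  sp <- network$species$name
  stopifnot(length(u) == length(sp))
  G <- stoichiometry_matrix(network)
  A <- reactant_matrix(network)
  s1max <- max(c(A, 1L))
  S1 <- stirling1_table(s1max)
  out <- mp_zero()
  for (j in seq_along(network$reactions)) {
    gamma <- G[, j]
    if (all(gamma == 0L)) next
    dl <- delta_monomial(u, gamma)
    if (length(dl) == 0L) next
    rate <- rxn_rate_qrf(network$reactions[[j]], network)
    # expand the falling-factorial propensity into monomials k^c
    idx <- which(A[, j] > 0L)
    monos <- list(list(c = integer(length(sp)), coef = q_one()))
    for (i in idx) {
      a <- A[i, j]
      new <- list()
      for (m in monos) {
        for (cc in seq_len(a)) {        # s(a, 0) = 0 for a >= 1
          s <- S1[[a + 1L]][[cc + 1L]]
          if (q_is_zero(s)) next
          c2 <- m$c; c2[i] <- cc
          new[[length(new) + 1L]] <- list(c = c2, coef = q_mul(m$coef, s))
        }
      }
      monos <- new
    }
    for (m in monos) {
      kap <- qrf_scale(rate, m$coef)
      for (t in mp_terms(dl)) {
        out <- mp_add_term(out, t$nu + m$c, qrf_mul(t$coef, kap))
      }
    }
  }
  out
}

## ---- closure ----------------------------------------------------------------

#' Recursive linear moment closure
#'
#' Starting from seed moment indices, repeatedly applies
#' [moment_derivative()] to every newly appearing moment until no new moments
#' appear (breadth-first, FIFO; new moments from a single derivative are
#' enqueued in lexicographic order so the output is deterministic).  The
#' constant moment \eqn{E[k^0] = 1} is carried as the first system variable
#' with derivative zero, which keeps systems with zeroth-order reactions
#' homogeneous-linear, \eqn{\dot x = A x}.
#'
#' @param seeds list of moment index vectors (or a single vector).
#' @param network a [reaction_network()].
#' @param max_moments recursion cap; exceeding it returns a closure-failure
#'   report (class `closure_failure`) listing the unexpanded frontier.
#' @return a `moment_system`: ordered moment list (constant first), the exact
#'   coefficient matrix rows, and the species ordering; or a
#'   `closure_failure`.
#' @examples
#' bd <- reaction_network("S", list(
#'   rxn(products = c(S = 1), rate = 2),
#'   rxn(reactants = c(S = 1), rate = 1)
#' ))
#' sys <- build_closure(list(c(1L)), bd)
#' moment_strings(sys)
#' @export
build_closure <- function(seeds, network, max_moments = 500L) {
  if (!is.list(seeds)) seeds <- list(seeds)
  if (length(seeds) == 0L) stop("seeds must be non-empty")
  if (max_moments <= 0L) stop("max_moments must be a positive integer")
  n <- nrow(network$species)
  zero <- integer(n)
  seen <- new.env(parent = emptyenv())
  order_keys <- character(0)
  moments <- list()
  push <- function(nu) {
    k <- mp_key(nu)
    if (exists(k, envir = seen, inherits = FALSE)) return(FALSE)
    assign(k, TRUE, envir = seen)
    moments[[length(moments) + 1L]] <<- as.integer(nu)
    order_keys <<- c(order_keys, k)
    TRUE
  }
  push(zero)                              # constant moment, always first
  for (s in seeds) {
    stopifnot(length(s) == n, all(s >= 0))
    push(s)
  }
  derivs <- list()
  derivs[[mp_key(zero)]] <- mp_zero()
  queue <- moments[-1L]
  while (length(queue) > 0L) {
    u <- queue[[1L]]
    queue <- queue[-1L]
    d <- moment_derivative(u, network)
    derivs[[mp_key(u)]] <- d
    new_nus <- lapply(mp_terms(d), `[[`, "nu")
    if (length(new_nus) > 0L) {
      # lexicographic enqueue order within one derivative
      keys <- vapply(new_nus, function(x) paste(sprintf("%03d", x), collapse = ""),
                     character(1))
      for (i in order(keys)) {
        if (push(new_nus[[i]])) queue[[length(queue) + 1L]] <- new_nus[[i]]
      }
    }
    if (length(moments) - 1L > max_moments) {
      return(structure(list(n_found = length(moments) - 1L,
                            max_moments = max_moments,
                            frontier = queue),
                       class = "closure_failure"))
    }
  }
  # assemble rows in moment order
  key_index <- stats::setNames(seq_along(order_keys), order_keys)
  rows <- lapply(moments, function(u) {
    d <- derivs[[mp_key(u)]]
    row <- rep(list(qrf_const(q_zero())), length(moments))
    for (t in mp_terms(d)) row[[key_index[[mp_key(t$nu)]]]] <- t$coef
    row
  })
  structure(list(species = network$species$name, moments = moments,
                 rows = rows, seeds = seeds),
            class = "moment_system")
}

#' Moment strings of a closed system
#'
#' Digit-string labels in declared species order (e.g. `"0002"` is the second
#' moment of the fourth species), excluding the constant moment by default.
#'
#' @param system a `moment_system` from [build_closure()].
#' @param include_constant also list the constant moment.
#' @return character vector.
#' @export
moment_strings <- function(system, include_constant = FALSE) {
  out <- vapply(system$moments, moment_string, character(1))
  if (!include_constant) out <- out[-1L]
  out
}

#' @export
print.moment_system <- function(x, ...) {
  cat("<moment_system> ", length(x$moments) - 1L,
      " moments (+ constant) over species ",
      paste(x$species, collapse = ","),
      "; max order ", max(vapply(x$moments, sum, integer(1))), "\n", sep = "")
  invisible(x)
}

#' @export
print.closure_failure <- function(x, ...) {
  cat("<closure_failure> moment recursion exceeded max_moments = ",
      x$max_moments, " (", x$n_found, " found, frontier ",
      length(x$frontier), ")\n", sep = "")
  invisible(x)
}

## ---- feedforward verification ------------------------------------------------

#' Check the feedforward (layered catalysis) property
#'
#' A network is feedforward if its species can be partitioned into layers
#' such that every reaction of order greater than one (i) leaves all its
#' reactants unchanged (pure catalysis: products contain the reactants with
#' equal stoichiometry), and (ii) only produces species in a single layer
#' strictly later than all reactant layers.  Such networks admit a finite
#' linear moment closure for every moment.
#'
#' @param network a [reaction_network()].
#' @param layers `"auto"` (search for a valid assignment via the
#'   catalyst-to-product dependency graph) or a named integer vector.
#' @return list with `feedforward` (logical) and either `layers` (a witness
#'   assignment) or `violation` (a message naming the offending reaction or
#'   cycle).
#' @export
check_feedforward <- function(network, layers = "auto") {
  sp <- network$species$name
  G <- stoichiometry_matrix(network)
  A <- reactant_matrix(network)
  nonlinear <- which(colSums(A) > 1L)
  # catalysis condition: reactants of nonlinear reactions are unchanged
  for (j in nonlinear) {
    touched <- sp[A[, j] > 0L & G[, j] != 0L]
    if (length(touched) > 0L) {
      return(list(feedforward = FALSE,
                  violation = paste0("reaction ", j,
                                     " consumes/changes its reactants (",
                                     paste(touched, collapse = ", "), ")")))
    }
  }
  if (identical(layers, "auto")) {
    lay <- stats::setNames(rep(1L, length(sp)), sp)
    for (iter in seq_len(length(sp) + 1L)) {
      changed <- FALSE
      for (j in nonlinear) {
        rs <- which(A[, j] > 0L)
        ps <- which(G[, j] != 0L)
        need <- max(lay[rs]) + 1L
        for (p in ps) if (lay[p] < need) { lay[p] <- need; changed <- TRUE }
      }
      if (!changed) break
      if (iter > length(sp)) {
        return(list(feedforward = FALSE,
                    violation = "cyclic dependency among nonlinear reactions"))
      }
    }
    layers <- lay
  } else {
    if (is.null(names(layers)) || !all(sp %in% names(layers)))
      stop("layers must be a named vector covering every species, or \"auto\"")
    layers <- layers[sp]
  }
  for (j in nonlinear) {
    rs <- which(A[, j] > 0L)
    ps <- which(G[, j] != 0L)
    pls <- unique(layers[ps])
    if (length(pls) != 1L || max(layers[rs]) >= pls) {
      return(list(feedforward = FALSE,
                  violation = paste0("reaction ", j,
                                     " does not respect a layered ordering")))
    }
  }
  list(feedforward = TRUE, layers = layers)
}

## ---- stationary solving -------------------------------------------------------

instantiate_rows <- function(system, assign = list()) {
  lapply(system$rows, function(row) lapply(row, function(f) {
    v <- qrf_subs(f, assign)
    miss <- qrf_vars(v)
    if (length(miss) > 0L)
      stop("stationary solve: unassigned symbols: ", paste(miss, collapse = ", "))
    qrf_eval(v)
  }))
}

#' Exact stationary moments of a closed linear moment system
#'
#' Solves \eqn{A x = 0} with the normalization that the constant moment
#' equals one.  All symbolic coefficients must be instantiated through
#' `assign`; the solve is carried out in exact rational arithmetic.
#'
#' @param system a `moment_system` from [build_closure()].
#' @param assign named list of exact values (numbers, strings like `"2/3"`,
#'   or `bigq`) for every symbol appearing in the coefficients.
#' @param as_numeric return doubles instead of exact `bigq` values.
#' @return named list (moment string -> value), constant moment omitted.
#' @export
stationary_moments <- function(system, assign = list(), as_numeric = FALSE) {
  rowsq <- instantiate_rows(system, assign)
  n <- length(system$moments)
  if (n == 1L) return(stats::setNames(list(), character(0)))
  idx <- 2:n
  A <- lapply(idx, function(i) rowsq[[i]][idx])
  b <- lapply(idx, function(i) q_neg(rowsq[[i]][[1L]]))
  x <- q_solve(A, b)
  if (is.null(x)) {
    nd <- q_null_dim(A)
    stop("stationary moment system is singular: the reduced linear system ",
         "(constant moment removed) has nullspace dimension ", nd,
         "; the stationary conditional moments are not unique")
  }
  nm <- vapply(system$moments[idx], moment_string, character(1))
  if (as_numeric) stats::setNames(lapply(x, q_to_num), nm)
  else stats::setNames(x, nm)
}

#' Stationary conditional moment as an exact rational function
#'
#' Leaves exactly one symbol free (typically a slow-species count) and
#' derives the stationary value of one target moment as an exact rational
#' function of that symbol.  The moment system is solved exactly at integer
#' values of the free symbol and the unique rational function of bounded
#' degree through those values is reconstructed and verified on held-out
#' points (Cauchy interpolation over the rationals).
#'
#' @param system a `moment_system`.
#' @param moment target moment index vector or digit string (default: the
#'   first seed).
#' @param symbol name of the free symbol.
#' @param assign named list instantiating all other symbols.
#' @param max_total maximum numerator plus denominator degree searched.
#' @return a [qss_rational] in `symbol`.
#' @export
stationary_conditional <- function(system, moment = NULL, symbol,
                                   assign = list(), max_total = 16L) {
  if (is.null(moment)) moment <- system$seeds[[1L]]
  key <- if (is.character(moment)) moment else moment_string(moment)
  fn <- function(x) {
    a2 <- assign
    a2[[symbol]] <- x
    sm <- stationary_moments(system, a2)
    v <- sm[[key]]
    if (is.null(v)) stop("moment ", key, " not in system")
    v
  }
  rc <- reconstruct_rational(fn, max_total = max_total)
  qss_rational(rc$num, rc$den, var = symbol,
               description = paste0("stationary <", key, "> as a function of ",
                                    symbol))
}
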