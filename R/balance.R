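# Complex-balanced fast subnetworks: structural analysis (complexes, weak
# reversibility, deficiency), complex-balanced equilibria, conservation-
# constrained partition functions and exact stationary factorial moments.
#
# For a weakly reversible deficiency-zero mass-action network the stationary
# law of the master equation restricted to a conservation class is a product
# of independent Poissons with parameters lambda (any complex-balanced
# equilibrium), conditioned on the conserved totals; all stationary moments
# reduce to ratios of the partition function
#   Z(beta) = sum_{k : A k = beta} prod_i lambda_i^{k_i} / k_i! .

complex_key <- function(v) {
  v <- v[v > 0]
  if (length(v) == 0L) return("0")
  v <- v[order(names(v))]
  paste(paste0(v, "*", names(v)), collapse = "+")
}

#' Structural analysis: complexes, linkage classes, deficiency
#'
#' Extracts the distinct complexes (reactant and product sides), builds the
#' directed reaction graph on complexes, and reports: the number of complexes
#' \eqn{n_c}, the number of linkage classes \eqn{\ell} (connected components),
#' the stoichiometric rank \eqn{r} (exact rational rank of \eqn{\Gamma}), the
#' deficiency \eqn{\delta = n_c - \ell - r}, and weak reversibility (every
#' linkage class strongly connected).  Weak reversibility together with
#' deficiency zero guarantees a complex-balanced equilibrium for every choice
#' of rate constants.
#'
#' @param network a [reaction_network()].
#' @param reactions optional reaction subset (indices), e.g. the fast ones.
#' @return an object of class `deficiency_report`.
#' @export
analyze_structure <- function(network, reactions = NULL) {
  rxns <- if (is.null(reactions)) seq_along(network$reactions) else reactions
  cx <- list(); cx_keys <- character(0)
  get_cx <- function(v) {
    k <- complex_key(v)
    i <- match(k, cx_keys)
    if (is.na(i)) {
      cx[[length(cx) + 1L]] <<- v
      cx_keys <<- c(cx_keys, k)
      i <- length(cx)
    }
    i
  }
  edges <- matrix(0L, 0L, 2L)
  for (j in rxns) {
    r <- network$reactions[[j]]
    edges <- rbind(edges, c(get_cx(r$reactants), get_cx(r$products)))
  }
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  n_c <- length(cx)
  weak <- igraph::components(g, mode = "weak")
  ell <- weak$no
  wr <- TRUE
  strong <- igraph::components(g, mode = "strong")
  # weak reversibility: each weak component is a single strong component
  for (comp in seq_len(ell)) {
    verts <- which(weak$membership == comp)
    if (length(unique(strong$membership[verts])) > 1L) { wr <- FALSE; break }
  }
  G <- stoichiometry_matrix(network)[, rxns, drop = FALSE]
  r <- length(q_rref(G)$pivots)
  structure(list(n_complexes = n_c, n_linkage_classes = ell,
                 stoich_rank = r, deficiency = n_c - ell - r,
                 weakly_reversible = wr,
                 complexes = cx, complex_keys = cx_keys, edges = edges),
            class = "deficiency_report")
}

#' @export
print.deficiency_report <- function(x, ...) {
  cat("<deficiency_report> complexes: ", x$n_complexes,
      ", linkage classes: ", x$n_linkage_classes,
      ", rank: ", x$stoich_rank,
      ", deficiency: ", x$deficiency,
      ", weakly reversible: ", x$weakly_reversible, "\n", sep = "")
  invisible(x)
}

#' @rdname analyze_structure
#' @param x a `deficiency_report`.
#' @param ... unused.
#' @export
tidy.deficiency_report <- function(x, ...) {
  tibble::tibble(n_complexes = x$n_complexes,
                 n_linkage_classes = x$n_linkage_classes,
                 stoich_rank = x$stoich_rank,
                 deficiency = x$deficiency,
                 weakly_reversible = x$weakly_reversible)
}

## ---- equilibria --------------------------------------------------------------

#' A positive equilibrium of the deterministic rate equations
#'
#' @param lambda named vector/list of strictly positive values (numerics,
#'   strings, or `bigq`), one per species.
#' @return an object of class `equilibrium`.
#' @export
equilibrium <- function(lambda) {
  vals <- lapply(lambda, q_parse)
  if (any(!vapply(vals, function(q) q_sign(q) > 0L, logical(1))))
    stop("equilibrium values must be strictly positive")
  structure(list(lambda = vals), class = "equilibrium")
}

#' @export
print.equilibrium <- function(x, ...) {
  cat("<equilibrium> ",
      paste(names(x$lambda), vapply(x$lambda, q_to_str, character(1)),
            sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Solve for a complex-balanced equilibrium
#'
#' Requires the (sub)network to be weakly reversible with deficiency zero.
#' For networks made of reversible reaction pairs, detailed balance of each
#' pair suffices: free species are set to 1 and bound species are propagated
#' through the pair equations \eqn{\kappa_f \prod \lambda^a = \kappa_b \prod
#' \lambda^b}, giving the simplest positive equilibrium.  The result is
#' verified against per-complex balance exactly; different admissible
#' equilibria differ only by factors constant on each conservation class and
#' give identical conditional moments.
#'
#' @param network a [reaction_network()].
#' @param reactions optional reaction subset (indices).
#' @param params named values for symbolic rate parameters.
#' @return an [equilibrium()].
#' @export
solve_equilibrium <- function(network, reactions = NULL, params = list()) {
  rxns <- if (is.null(reactions)) seq_along(network$reactions) else reactions
  rep_ <- analyze_structure(network, rxns)
  if (!rep_$weakly_reversible)
    stop("unsupported network: not weakly reversible, no complex-balanced ",
         "equilibrium is guaranteed")
  if (rep_$deficiency != 0L)
    stop("unsupported network: deficiency is ", rep_$deficiency,
         " (nonzero), no complex-balanced equilibrium is guaranteed")
  sp <- network$species$name
  # pair up reversible reactions
  sig <- function(r) paste(complex_key(r$reactants), complex_key(r$products), sep = ">")
  rev_sig <- function(r) paste(complex_key(r$products), complex_key(r$reactants), sep = ">")
  sigs <- vapply(rxns, function(j) sig(network$reactions[[j]]), character(1))
  pairs <- list(); used <- logical(length(rxns))
  for (i in seq_along(rxns)) {
    if (used[i]) next
    r <- network$reactions[[rxns[i]]]
    k <- match(rev_sig(r), sigs)
    if (is.na(k) || used[k])
      stop("unsupported network: reaction ", rxns[i],
           " has no reverse partner; equilibrium solving handles reversible pairs")
    used[i] <- used[k] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(rxns[i], rxns[k])
  }
  qvals <- lapply(params, q_parse)
  ratec <- function(j) qrf_eval(qrf_subs(rxn_rate_qrf(network$reactions[[j]], network),
                                         qvals))
  lam <- stats::setNames(vector("list", length(sp)), sp)
  # exponent vector per pair: b - a; rhs = kf / kb
  eqs <- lapply(pairs, function(p) {
    rf <- network$reactions[[p[1L]]]
    expo <- stats::setNames(integer(length(sp)), sp)
    expo[names(rf$products)] <- expo[names(rf$products)] + rf$products
    expo[names(rf$reactants)] <- expo[names(rf$reactants)] - rf$reactants
    list(expo = expo, rhs = q_div(ratec(p[1L]), ratec(p[2L])))
  })
  solved <- function(nm) !is.null(lam[[nm]])
  repeat {
    progress <- FALSE
    for (e in eqs) {
      unk <- names(e$expo)[e$expo != 0L & !vapply(names(e$expo), solved, logical(1))]
      if (length(unk) != 1L || abs(e$expo[[unk]]) != 1L) next
      acc <- e$rhs
      for (nm in names(e$expo)) {
        if (nm == unk || e$expo[[nm]] == 0L) next
        acc <- q_mul(acc, q_pow_int(lam[[nm]], -e$expo[[nm]]))
      }
      lam[[unk]] <- if (e$expo[[unk]] == 1L) acc else q_inv(acc)
      progress <- TRUE
    }
    if (all(vapply(sp, solved, logical(1)))) break
    if (!progress) {
      nm <- sp[!vapply(sp, solved, logical(1))][1L]
      lam[[nm]] <- q_one()                 # simplest point: free species at 1
    }
  }
  eq <- equilibrium(lam)
  if (!is_complex_balanced(network, eq, rxns, params))
    stop("unsupported network: the propagated detailed-balance point does not ",
         "satisfy complex balance")
  eq
}

# exact per-complex balance check of the deterministic mass-action rates
is_complex_balanced <- function(network, eq, reactions = NULL, params = list()) {
  rxns <- if (is.null(reactions)) seq_along(network$reactions) else reactions
  qvals <- lapply(params, q_parse)
  flux <- function(j) {
    r <- network$reactions[[j]]
    f <- qrf_eval(qrf_subs(rxn_rate_qrf(r, network), qvals))
    for (nm in names(r$reactants))
      f <- q_mul(f, q_pow_int(eq$lambda[[nm]], r$reactants[[nm]]))
    f
  }
  keys <- unique(unlist(lapply(rxns, function(j) {
    r <- network$reactions[[j]]
    c(complex_key(r$reactants), complex_key(r$products))
  })))
  for (k in keys) {
    outfl <- q_zero(); infl <- q_zero()
    for (j in rxns) {
      r <- network$reactions[[j]]
      if (complex_key(r$reactants) == k) outfl <- q_add(outfl, flux(j))
      if (complex_key(r$products) == k) infl <- q_add(infl, flux(j))
    }
    if (!q_eq(outfl, infl)) return(FALSE)
  }
  TRUE
}

## ---- conservation constraints and partition functions ------------------------

#' Conservation constraints for a fast subnetwork
#'
#' Rows of `A` are integer conservation vectors of the (fast) network and
#' `beta` their conserved totals.  Exactly one entry of `beta` may be a
#' character name, declaring that total symbolic (used by
#' [conditional_mean_rational()]).
#'
#' @param A integer matrix (rows = laws, columns = species) with non-negative
#'   entries and species column names.
#' @param beta vector/list of non-negative integer totals; one entry may be a
#'   character symbol name.
#' @return an object of class `conservation_constraint`.
#' @export
conservation_constraint <- function(A, beta) {
  stopifnot(is.matrix(A), !is.null(colnames(A)), nrow(A) == length(beta))
  if (any(A < 0L)) stop("constraint rows must be non-negative conservation vectors")
  beta <- as.list(beta)
  sym <- vapply(beta, is.character, logical(1))
  if (sum(sym) > 1L) stop("at most one total may be symbolic")
  for (b in beta[!sym]) {
    if (b < 0 || b != trunc(b)) stop("numeric totals must be non-negative integers")
  }
  structure(list(A = A, beta = beta, symbolic = which(sym)),
            class = "conservation_constraint")
}

# enumerate {k >= 0 : A k = beta} for numeric beta; returns integer matrix
# (rows = states).  Every species must be bounded by some constraint row.
enumerate_lattice <- function(A, beta) {
  sp <- colnames(A)
  n <- length(sp)
  unbounded <- vapply(seq_len(n), function(i) all(A[, i] == 0L), logical(1))
  if (any(unbounded))
    stop("constrained lattice is unbounded: species ",
         paste(sp[unbounded], collapse = ", "),
         " appear in no constraint")
  states <- matrix(0L, 0L, n, dimnames = list(NULL, sp))
  k <- integer(n)
  recur <- function(i, rem) {
    if (i > n) {
      if (all(rem == 0L)) states <<- rbind(states, k)
      return(invisible())
    }
    col <- A[, i]
    cap <- if (any(col > 0L)) min(rem[col > 0L] %/% col[col > 0L]) else 0L
    for (v in 0:cap) {
      k[i] <<- v
      recur(i + 1L, rem - v * col)
    }
    k[i] <<- 0L
  }
  recur(1L, as.integer(beta))
  rownames(states) <- NULL
  states
}

#' Exact partition function of a constrained product-Poisson law
#'
#' \eqn{Z(\beta) = \sum_{k : A k = \beta} \prod_i \lambda_i^{k_i}/k_i!},
#' computed by exact bounded enumeration over the constrained lattice in
#' rational arithmetic.  Returns 0 for infeasible totals.
#'
#' @param eq an [equilibrium()].
#' @param cons a [conservation_constraint()] with numeric totals (or supply
#'   `beta` to override).
#' @param beta optional numeric totals replacing `cons$beta`.
#' @param exact return a `bigq` instead of a double.
#' @return the partition function value.
#' @export
partition_function <- function(eq, cons, beta = NULL, exact = FALSE) {
  b <- if (is.null(beta)) cons$beta else as.list(beta)
  if (any(vapply(b, is.character, logical(1))))
    stop("partition_function needs numeric totals")
  b <- vapply(b, as.numeric, numeric(1))
  z <- q_zero()
  if (all(b >= 0)) {
    states <- enumerate_lattice(cons$A, b)
    sp <- colnames(cons$A)
    for (i in seq_len(nrow(states))) {
      w <- q_one()
      for (s in seq_along(sp)) {
        ki <- states[i, s]
        if (ki > 0L)
          w <- q_div(q_mul(w, q_pow_int(eq$lambda[[sp[s]]], ki)), q_factorial(ki))
      }
      z <- q_add(z, w)
    }
  }
  if (exact) z else q_to_num(z)
}

#' Exact stationary factorial moments under conservation constraints
#'
#' For the conditioned product-Poisson stationary law, the mixed factorial
#' moment of multi-index \eqn{r} is
#' \deqn{E\Big[\prod_j S_j^{(r_j)} \,\Big|\, Y = \beta\Big] =
#'   \Big(\prod_j \lambda_j^{r_j}\Big)
#'   \frac{Z(\beta - \sum_j r_j \alpha_{\cdot j})}{Z(\beta)},}
#' where \eqn{S^{(r)} = S(S-1)\cdots(S-r+1)} and \eqn{\alpha_{\cdot j}} is
#' species \eqn{j}'s column of the constraint matrix; the value is zero when
#' any shifted total is negative or infeasible.
#'
#' @param r named non-negative integer vector of factorial powers (e.g.
#'   `c(DA = 1)` for a conditional mean, `c(R = 2)` for
#'   \eqn{E[R(R-1)\mid Y]}).
#' @param cons a [conservation_constraint()] with numeric totals.
#' @param eq an [equilibrium()].
#' @param exact return a `bigq`.
#' @return the conditional factorial moment.
#' @export
factorial_moment <- function(r, cons, eq, exact = FALSE) {
  sp <- colnames(cons$A)
  stopifnot(all(names(r) %in% sp), all(r >= 0))
  z0 <- partition_function(eq, cons, exact = TRUE)
  if (q_is_zero(z0))
    stop("conditioning on an empty event: Z(beta) = 0 for these totals")
  b <- vapply(cons$beta, as.numeric, numeric(1))
  shift <- b
  for (nm in names(r)) shift <- shift - r[[nm]] * cons$A[, nm]
  if (any(shift < 0)) {
    out <- q_zero()
  } else {
    zs <- partition_function(eq, cons, beta = shift, exact = TRUE)
    pre <- q_one()
    for (nm in names(r)) pre <- q_mul(pre, q_pow_int(eq$lambda[[nm]], r[[nm]]))
    out <- q_div(q_mul(pre, zs), z0)
  }
  if (exact) out else q_to_num(out)
}

#' Enumerated conditional stationary distribution
#'
#' Direct enumeration of the conditioned product-Poisson law: every state of
#' the constrained lattice with its exact probability.  Serves as a
#' brute-force cross-check of [factorial_moment()].
#'
#' @param cons a [conservation_constraint()] with numeric totals.
#' @param eq an [equilibrium()].
#' @return tibble with one row per state and a `prob` column (doubles; exact
#'   probabilities available via attribute `"exact"`).
#' @export
conditional_distribution <- function(cons, eq) {
  b <- vapply(cons$beta, as.numeric, numeric(1))
  states <- enumerate_lattice(cons$A, b)
  sp <- colnames(cons$A)
  ws <- vector("list", nrow(states))
  tot <- q_zero()
  for (i in seq_len(nrow(states))) {
    w <- q_one()
    for (s in seq_along(sp)) {
      ki <- states[i, s]
      if (ki > 0L)
        w <- q_div(q_mul(w, q_pow_int(eq$lambda[[sp[s]]], ki)), q_factorial(ki))
    }
    ws[[i]] <- w
    tot <- q_add(tot, w)
  }
  if (q_is_zero(tot)) stop("empty conditional distribution")
  probs <- lapply(ws, q_div, b = tot)
  out <- tibble::as_tibble(as.data.frame(states))
  out$prob <- vapply(probs, q_to_num, numeric(1))
  attr(out, "exact") <- probs
  out
}

## ---- closed-form rational QSS in one symbolic total ---------------------------

#' Exact conditional moment as a rational function of one conserved total
#'
#' With exactly one symbolic total \eqn{n}, expresses the conditional
#' factorial moment of `r` as a ratio of polynomials in \eqn{n} with exact
#' rational coefficients.  The species carrying \eqn{n} (coefficient one in
#' the symbolic row, absent from all numeric rows) is eliminated; the finite
#' lattice of the remaining species is enumerated, \eqn{n! \, Z} becomes a
#' finite sum of falling factorials \eqn{n^{(h)}}, which is converted to the
#' monomial basis through Stirling numbers of the first kind; the denominator
#' is normalized to constant term one.  The result agrees with
#' [factorial_moment()] at every feasible integer total.
#'
#' @param r named factorial-power multi-index (see [factorial_moment()]).
#' @param cons a [conservation_constraint()] with exactly one symbolic total.
#' @param eq an [equilibrium()].
#' @return a [qss_rational] in the symbolic total.
#' @export
conditional_mean_rational <- function(r, cons, eq) {
  if (length(cons$symbolic) != 1L)
    stop("exactly one total must be symbolic")
  qrow <- cons$symbolic
  var <- cons$beta[[qrow]]
  A <- cons$A
  sp <- colnames(A)
  # the species carrying n: coefficient 1 in the symbolic row, 0 elsewhere
  carrier <- which(A[qrow, ] == 1L &
                   colSums(A[-qrow, , drop = FALSE] != 0L) == 0L)
  if (length(carrier) == 0L)
    stop("unsupported structure: no species appears only in the symbolic ",
         "total with coefficient one")
  carrier <- carrier[1L]
  others <- setdiff(seq_along(sp), carrier)
  A_num <- A[-qrow, others, drop = FALSE]
  b_num <- vapply(cons$beta[-qrow], as.numeric, numeric(1))
  lam_c <- eq$lambda[[sp[carrier]]]

  # (n! * Z(beta with symbolic entry n - shift) / lambda_c^n) as falling
  # factorial coefficients: index h -> coefficient of n^(h)
  z_ff <- function(shift, bnum) {
    states <- enumerate_lattice(A_num, bnum)
    ff <- list()
    for (i in seq_len(nrow(states))) {
      off <- shift + sum(A[qrow, others] * states[i, ])
      w <- q_pow_int(lam_c, -off)          # lambda_c^{n-off} / lambda_c^n
      for (s in seq_along(others)) {
        ki <- states[i, s]
        if (ki > 0L)
          w <- q_div(q_mul(w, q_pow_int(eq$lambda[[sp[others[s]]]], ki)),
                     q_factorial(ki))
      }
      key <- as.character(off)
      ff[[key]] <- if (is.null(ff[[key]])) w else q_add(ff[[key]], w)
    }
    ff
  }
  ff_to_poly <- function(ff) {
    if (length(ff) == 0L) return(list(q_zero()))
    hmax <- max(as.integer(names(ff)))
    S1 <- stirling1_table(hmax)
    out <- rep(list(q_zero()), hmax + 1L)
    for (key in names(ff)) {
      h <- as.integer(key)
      for (i in 0:h) {
        s <- S1[[h + 1L]][[i + 1L]]
        if (!q_is_zero(s)) out[[i + 1L]] <- q_add(out[[i + 1L]], q_mul(ff[[key]], s))
      }
    }
    up_trim(out)
  }

  stopifnot(all(names(r) %in% sp), all(r >= 0))
  shift_rows <- rep(0, nrow(A))
  for (nm in names(r)) shift_rows <- shift_rows + r[[nm]] * A[, nm]
  b_shift <- b_num - shift_rows[-qrow]
  pre <- q_one()
  for (nm in names(r)) pre <- q_mul(pre, q_pow_int(eq$lambda[[nm]], r[[nm]]))

  den <- ff_to_poly(z_ff(0L, b_num))
  num <- if (any(b_shift < 0)) list(q_zero())
         else up_scale(ff_to_poly(z_ff(as.integer(shift_rows[qrow]), b_shift)), pre)
  nz <- if (!q_is_zero(den[[1L]])) den[[1L]] else den[[length(den)]]
  num <- up_scale(num, q_inv(nz))
  den <- up_scale(den, q_inv(nz))
  qss_rational(num, den, var = var,
               description = paste0("stationary <", paste0(names(r), "^(", r, ")",
                                                           collapse = " "),
                                    " | ", var, ">"))
}
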