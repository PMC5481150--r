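# Truncated chemical-master-equation stationary distribution.
#
# Independent numerical route to stationary moments on a finite box: used to
# validate the symbolic moment machinery and the partition-function formulas
# on small networks (the CME itself is otherwise never solved).

#' Stationary distribution of the truncated CME
#'
#' Builds the generator of the master equation restricted to the box
#' \eqn{0 \le k_i \le \mathrm{cap}_i} (transitions leaving the box are
#' dropped) and solves for its stationary distribution with a sparse linear
#' solve.  The returned tail mass (largest total probability on any boundary
#' face) indicates whether the box was large enough.
#'
#' @param network a [reaction_network()].
#' @param cap named (or species-ordered) vector of per-species caps.
#' @param params named values for symbolic rate parameters.
#' @return list with `states` (integer matrix), `p` (stationary
#'   probabilities), `tail_mass`, and `moment(u)`, a function returning the
#'   raw moment \eqn{E[k^u]} for an exponent vector `u`.
#' @export
cme_stationary <- function(network, cap, params = list()) {
  sp <- network$species$name
  if (!is.null(names(cap))) cap <- cap[sp]
  stopifnot(length(cap) == length(sp), all(cap >= 1))
  dims <- as.integer(cap) + 1L
  n_states <- prod(dims)
  if (n_states > 7e5) stop("truncated state space too large: ", n_states)
  states <- as.matrix(do.call(expand.grid, lapply(dims, function(d) 0:(d - 1L))))
  colnames(states) <- sp
  strides <- cumprod(c(1L, dims[-length(dims)]))
  idx_of <- function(M) as.integer(1L + M %*% strides)
  G <- stoichiometry_matrix(network)
  A <- reactant_matrix(network)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diag_acc <- numeric(n_states)
  for (j in seq_along(network$reactions)) {
    rate <- rxn_rate_numeric(network$reactions[[j]], network, params)
    prop <- rep(rate, n_states)
    for (i in seq_along(sp)) {
      if (A[i, j] > 0L) prop <- prop * falling_factorial(states[, i], A[i, j])
    }
    tgt <- sweep(states, 2L, -G[, j])
    ok <- prop > 0 & rowSums(tgt < 0L) == 0L &
      rowSums(sweep(tgt, 2L, cap, ">")) == 0L
    if (!any(ok)) next
    from <- which(ok)
    to <- idx_of(tgt[ok, , drop = FALSE])
    ii <- c(ii, to); jj <- c(jj, from); vv <- c(vv, prop[ok])
    diag_acc[from] <- diag_acc[from] + prop[ok]
  }
  # generator Q: Q[to, from] = rate, Q[from, from] -= total outflow
  Q <- Matrix::sparseMatrix(i = c(ii, seq_len(n_states)),
                            j = c(jj, seq_len(n_states)),
                            x = c(vv, -diag_acc),
                            dims = c(n_states, n_states))
  if (n_states <= 5000L) {
    # replace one balance equation with the normalization
    M <- rbind(Q[-n_states, , drop = FALSE],
               Matrix::sparseMatrix(i = rep(1L, n_states), j = seq_len(n_states),
                                    x = rep(1, n_states),
                                    dims = c(1L, n_states)))
    b <- c(rep(0, n_states - 1L), 1)
    p <- as.numeric(Matrix::solve(M, b))
  } else {
    # power iteration on the embedded jump chain (direct sparse
    # factorization fills in badly on higher-dimensional lattices):
    # phi = P_jump^T phi with P_jump[from, to] = rate/outflow(from), then
    # pi propto phi / outflow
    # Gauss-Seidel sweeps on pi_i d_i = sum_j pi_j q_{j -> i}; direct sparse
    # factorization fills in badly on higher-dimensional lattices
    o <- order(ii)
    ptr <- c(0L, cumsum(tabulate(ii, n_states)))
    gs <- cme_gauss_seidel(as.integer(ptr), as.integer(jj[o] - 1L), vv[o],
                           diag_acc, 5000L, 1e-16)
    if (gs$delta > 1e-13)
      warning("stationary Gauss-Seidel did not fully converge (delta = ",
              gs$delta, ")")
    p <- gs$p
  }
  p[p < 0 & p > -1e-12] <- 0
  tail_mass <- max(vapply(seq_along(sp), function(i)
    sum(p[states[, i] == cap[i]]), numeric(1)))
  list(states = states, p = p, tail_mass = tail_mass,
       moment = function(u) {
         stopifnot(length(u) == length(sp))
         m <- p
         for (i in seq_along(sp)) if (u[i] > 0) m <- m * states[, i]^u[i]
         sum(m)
       })
}
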