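# Reaction-network representation, propensities, conservation laws, model I/O.

#' Create a mass-action reaction network
#'
#' A reaction network holds an ordered species list, an ordered reaction list
#' with stochastic mass-action rate constants (numeric or symbolic expressions
#' over declared parameters), per-reaction timescale tags (`"fast"`/`"slow"`),
#' and a system volume.  Rate constants are the constants multiplying the
#' falling-factorial product in the propensity, i.e. the propensity of a
#' reaction with reactant multiplicities \eqn{a_{ij}} at state \eqn{k} is
#' \deqn{\rho_j(k) = \kappa_j \prod_i k_i (k_i - 1) \cdots (k_i - a_{ij} + 1).}
#' (Some texts define mass-action propensities with binomial coefficients
#' \eqn{\binom{k_i}{a_{ij}}}; the two conventions differ by
#' \eqn{\prod_i a_{ij}!}.  The falling-factorial convention used here matches
#' how rate constants are usually printed next to explicit propensities such
#' as \eqn{k_f/\Omega \, X(X-1)} for a dimerization.)
#'
#' @param species character vector of species names, or a data frame with
#'   columns `name` and (optionally) `initial`.
#' @param reactions list of reactions created by [rxn()].
#' @param volume system volume \eqn{\Omega} (numeric, default 1).  Kept as
#'   metadata; combined constants such as \eqn{\alpha_1 \Omega} should be
#'   stored as single per-reaction rates.
#' @param params character vector of parameter names allowed in symbolic rates.
#' @return an object of class `reaction_network`.
#' @seealso [rxn()], [propensity_eval()], [conservation_basis()],
#'   [stoichiometry_matrix()], [model_to_json()]
#' @examples
#' bd <- reaction_network(
#'   species = "S",
#'   reactions = list(
#'     rxn(products = c(S = 1), rate = 200),
#'     rxn(reactants = c(S = 1), rate = 1)
#'   )
#' )
#' propensity_eval(bd, c(S = 5))
#' @export
reaction_network <- function(species, reactions, volume = 1, params = character(0)) {
  if (is.character(species)) {
    species <- tibble::tibble(name = species, initial = 0)
  } else {
    species <- tibble::as_tibble(species)
    if (!"initial" %in% names(species)) species$initial <- 0
  }
  stopifnot(is.character(species$name))
  if (anyDuplicated(species$name))
    stop("species names must be unique")
  if (any(species$initial < 0 | species$initial != trunc(species$initial)))
    stop("initial counts must be non-negative integers")
  if (!is.list(reactions) || length(reactions) == 0L)
    stop("a reaction network needs at least one reaction")
  for (i in seq_along(reactions)) {
    r <- reactions[[i]]
    if (!inherits(r, "rxn")) stop("reactions must be built with rxn()")
    refs <- union(names(r$reactants), names(r$products))
    bad <- setdiff(refs, species$name)
    if (length(bad) > 0L)
      stop("reaction ", i, " references undeclared species: ",
           paste(bad, collapse = ", "))
  }
  structure(list(species = species, reactions = reactions,
                 volume = volume, params = params),
            class = "reaction_network")
}

#' Define a single reaction
#'
#' @param reactants,products named non-negative integer vectors mapping
#'   species names to stoichiometric multiplicities; either may be empty
#'   (zeroth-order production / pure degradation).
#' @param rate positive number, or a character expression over the network's
#'   declared parameters (e.g. `"2/eps"`).
#' @param timescale `"slow"` (default) or `"fast"`.
#' @return an object of class `rxn`.
#' @export
rxn <- function(reactants = integer(0), products = integer(0), rate,
                timescale = c("slow", "fast")) {
  timescale <- match.arg(timescale)
  clean <- function(x) {
    if (length(x) == 0L) return(integer(0))
    if (is.null(names(x)) || any(names(x) == ""))
      stop("reactants/products must be named vectors")
    if (any(x < 0 | x != trunc(x))) stop("stoichiometries must be non-negative integers")
    x <- x[x > 0]
    storage.mode(x) <- "integer"
    x
  }
  reactants <- clean(reactants); products <- clean(products)
  if (length(reactants) == 0L && length(products) == 0L)
    stop("a reaction needs at least one reactant or product")
  if (is.numeric(rate)) {
    if (!is.finite(rate) || rate <= 0) stop("numeric rates must be strictly positive")
  } else if (!is.character(rate)) {
    stop("rate must be numeric or a character expression")
  }
  structure(list(reactants = reactants, products = products,
                 rate = rate, timescale = timescale),
            class = "rxn")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", nrow(x$species), " species, ",
      length(x$reactions), " reactions (",
      sum(vapply(x$reactions, function(r) r$timescale == "fast", logical(1))),
      " fast), volume = ", format(x$volume), "\n", sep = "")
  for (r in x$reactions) {
    side <- function(s) if (length(s) == 0L) "0"
      else paste(ifelse(s > 1L, paste0(s, " ", names(s)), names(s)), collapse = " + ")
    cat(sprintf("  %s -> %s   [%s, %s]\n", side(r$reactants), side(r$products),
                format(r$rate), r$timescale))
  }
  invisible(x)
}

#' Stoichiometry matrix
#'
#' One row per species, one column per reaction; entries are net changes
#' (product minus reactant multiplicity).
#'
#' @param network a [reaction_network()].
#' @return integer matrix with species names as row names.
#' @export
stoichiometry_matrix <- function(network) {
  sp <- network$species$name
  G <- matrix(0L, length(sp), length(network$reactions),
              dimnames = list(sp, NULL))
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    G[names(r$reactants), j] <- G[names(r$reactants), j] - r$reactants
    G[names(r$products), j] <- G[names(r$products), j] + r$products
  }
  G
}

reactant_matrix <- function(network) {
  sp <- network$species$name
  A <- matrix(0L, length(sp), length(network$reactions),
              dimnames = list(sp, NULL))
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    A[names(r$reactants), j] <- r$reactants
  }
  A
}

falling_factorial <- function(k, a) {
  out <- rep(1, length(k))
  for (l in seq_len(max(a, 0L)) - 1L) out <- out * pmax(k - l, 0)
  ifelse(k >= a, out, 0)
}

#' Evaluate mass-action propensities
#'
#' Falling-factorial mass action: the propensity of reaction \eqn{j} at state
#' \eqn{k} is \eqn{\kappa_j \prod_i k_i^{(a_{ij})}} where
#' \eqn{k^{(a)} = k(k-1)\cdots(k-a+1)}; it is zero whenever any reactant count
#' is below its required multiplicity, and a zeroth-order reaction returns its
#' rate constant.
#'
#' @param network a [reaction_network()] with numeric rates (or supply
#'   `params` to instantiate symbolic ones).
#' @param state named (or network-ordered) vector of non-negative counts.
#' @param params named list/vector of numeric values for symbolic parameters.
#' @return numeric vector of propensities, one per reaction.
#' @export
propensity_eval <- function(network, state, params = list()) {
  sp <- network$species$name
  if (!is.null(names(state))) state <- state[sp]
  if (length(state) != length(sp) || any(is.na(state)))
    stop("state must supply one count per species")
  if (any(state < 0)) stop("invalid state: negative counts")
  vapply(network$reactions, function(r) {
    rate <- rxn_rate_numeric(r, network, params)
    p <- rate
    for (s in names(r$reactants)) p <- p * falling_factorial(state[[s]], r$reactants[[s]])
    unname(p)
  }, numeric(1))
}

rxn_rate_numeric <- function(r, network, params = list()) {
  if (is.numeric(r$rate)) return(r$rate)
  vals <- lapply(params, q_parse)
  q_to_num(qrf_eval(parse_qexpr(r$rate, union(network$params, names(params))), vals))
}

rxn_rate_qrf <- function(r, network) {
  if (is.numeric(r$rate)) return(qrf_const(q_parse(r$rate)))
  parse_qexpr(r$rate, network$params)
}

## ---- conservation laws ------------------------------------------------------

# exact RREF over the rationals of a small integer matrix; returns list with
# the reduced rows (lists of bigq) and pivot column indices
q_rref <- function(M) {
  n <- nrow(M); m <- ncol(M)
  rows <- lapply(seq_len(n), function(i) lapply(M[i, ], q_from_int))
  pivots <- integer(0)
  r <- 1L
  for (c in seq_len(m)) {
    if (r > n) break
    piv <- 0L
    for (i in r:n) if (!q_is_zero(rows[[i]][[c]])) { piv <- i; break }
    if (piv == 0L) next
    if (piv != r) { tmp <- rows[[r]]; rows[[r]] <- rows[[piv]]; rows[[piv]] <- tmp }
    pv <- rows[[r]][[c]]
    rows[[r]] <- lapply(rows[[r]], q_div, b = pv)
    for (i in seq_len(n)) {
      if (i == r) next
      f <- rows[[i]][[c]]
      if (q_is_zero(f)) next
      rows[[i]] <- mapply(function(x, y) q_sub(x, q_mul(f, y)),
                          rows[[i]], rows[[r]], SIMPLIFY = FALSE)
    }
    pivots <- c(pivots, c)
    r <- r + 1L
  }
  list(rows = rows, pivots = pivots)
}

# scale a rational vector to the smallest-magnitude integer vector with
# positive first nonzero entry
q_vec_primitive <- function(v) {
  dens <- vapply(v, function(q) bi_to_num(q$d), numeric(1))
  l <- 1
  for (d in dens) l <- l * d / gcd_num(l, d)
  ints <- vapply(v, function(q) q_to_num(q) * l, numeric(1))
  ints <- round(ints)
  g <- 0
  for (x in ints) g <- gcd_num(g, abs(x))
  if (g > 0) ints <- ints / g
  fn <- which(ints != 0)[1L]
  if (!is.na(fn) && ints[fn] < 0) ints <- -ints
  as.integer(ints)
}

gcd_num <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

#' Conservation laws of a reaction network
#'
#' Computes an integer basis of the left nullspace of the stoichiometry
#' matrix, i.e. all independent linear combinations \eqn{v^\top X} of species
#' counts that are invariant under every (selected) reaction.  Basis vectors
#' are scaled to smallest-magnitude integers; when a basis of non-negative
#' vectors exists among small integer combinations, one is returned
#' (conserved totals such as \eqn{D_A + D_R} are naturally non-negative).
#'
#' @param network a [reaction_network()].
#' @param reactions optional integer vector restricting to a reaction subset
#'   (e.g. only fast reactions).
#' @return integer matrix, one conservation vector per row, species as
#'   columns; zero rows when the left nullspace is trivial.
#' @export
conservation_basis <- function(network, reactions = NULL) {
  G <- stoichiometry_matrix(network)
  if (!is.null(reactions)) G <- G[, reactions, drop = FALSE]
  sp <- rownames(G)
  n <- nrow(G)
  rr <- q_rref(t(G))                              # kernel of G^T x = 0
  piv <- rr$pivots
  free <- setdiff(seq_len(n), piv)
  basis <- matrix(0L, 0L, n, dimnames = list(NULL, sp))
  for (f in free) {
    v <- rep(list(q_zero()), n)
    v[[f]] <- q_one()
    for (i in seq_along(piv)) v[[piv[i]]] <- q_neg(rr$rows[[i]][[f]])
    basis <- rbind(basis, q_vec_primitive(v))
  }
  if (nrow(basis) == 0L) return(basis)
  basis <- nonneg_basis(basis)
  # deterministic ordering by first nonzero index, then lexicographic
  first_nz <- apply(basis, 1L, function(v) which(v != 0)[1L])
  o <- do.call(order, c(list(first_nz), lapply(seq_len(n), function(j) basis[, j])))
  basis <- basis[o, , drop = FALSE]
  rownames(basis) <- NULL
  colnames(basis) <- sp
  basis
}

# search small integer combinations for an all-non-negative basis
nonneg_basis <- function(basis) {
  k <- nrow(basis)
  if (all(basis >= 0L) || k > 5L) return(basis)
  rng <- -3:3
  combos <- as.matrix(do.call(expand.grid, rep(list(rng), k)))
  cands <- matrix(0L, 0L, ncol(basis))
  for (i in seq_len(nrow(combos))) {
    v <- drop(combos[i, ] %*% basis)
    if (all(v >= 0L) && any(v != 0L)) {
      v <- v %/% max(1L, Reduce(gcd_num, abs(v[v != 0L])))
      cands <- rbind(cands, as.integer(v))
    }
  }
  if (nrow(cands) == 0L) return(basis)
  cands <- unique(cands)
  o <- do.call(order, c(list(rowSums(abs(cands))),
                        lapply(seq_len(ncol(cands)), function(j) cands[, j])))
  cands <- cands[o, , drop = FALSE]
  chosen <- matrix(0L, 0L, ncol(basis))
  for (i in seq_len(nrow(cands))) {
    trial <- rbind(chosen, cands[i, ])
    if (qr(trial)$rank == nrow(trial)) chosen <- trial
    if (nrow(chosen) == k) break
  }
  if (nrow(chosen) == k) chosen else basis
}

## ---- model I/O --------------------------------------------------------------

#' Serialize a reaction network to JSON
#'
#' The document layout is
#' `{"species": [{"name", "initial"}...], "volume", "parameters",`
#' `"reactions": [{"reactants": {name: int}, "products": {...},`
#' `"rate": number|string, "timescale": "fast"|"slow"}...]}`.
#' Symbolic rates are preserved textually, so a write/read round trip is the
#' identity.
#'
#' @param network a [reaction_network()].
#' @param path optional file path; when `NULL` the JSON text is returned.
#' @return the JSON text, invisibly when written to a file.
#' @export
model_to_json <- function(network, path = NULL) {
  doc <- list(
    species = lapply(seq_len(nrow(network$species)), function(i)
      list(name = network$species$name[i],
           initial = as.integer(network$species$initial[i]))),
    volume = network$volume,
    parameters = as.list(network$params),
    reactions = lapply(network$reactions, function(r)
      list(reactants = as.list(r$reactants), products = as.list(r$products),
           rate = r$rate, timescale = r$timescale))
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a reaction network from JSON
#'
#' @param x a file path or a JSON string in the schema of [model_to_json()].
#' @return a [reaction_network()].
#' @export
model_from_json <- function(x) {
  txt <- if (length(x) == 1L && !grepl("\\{", x) && file.exists(x))
    paste(readLines(x), collapse = "\n") else paste(x, collapse = "\n")
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  for (field in c("species", "reactions")) {
    if (is.null(doc[[field]]))
      stop("model document is missing required field: '", field, "'")
  }
  species <- tibble::tibble(
    name = vapply(doc$species, function(s) {
      if (is.null(s$name)) stop("species entry missing required field: 'name'")
      s$name
    }, character(1)),
    initial = vapply(doc$species, function(s)
      if (is.null(s$initial)) 0 else as.numeric(s$initial), numeric(1))
  )
  reactions <- lapply(seq_along(doc$reactions), function(j) {
    r <- doc$reactions[[j]]
    if (is.null(r$rate)) stop("reaction ", j, " missing required field: 'rate'")
    tovec <- function(m) {
      if (is.null(m) || length(m) == 0L) return(integer(0))
      v <- vapply(m, as.integer, integer(1))
      names(v) <- names(m)
      v
    }
    rate <- if (is.character(r$rate)) r$rate else as.numeric(r$rate)
    rxn(reactants = tovec(r$reactants), products = tovec(r$products),
        rate = rate,
        timescale = if (is.null(r$timescale)) "slow" else r$timescale)
  })
  reaction_network(
    species = species, reactions = reactions,
    volume = if (is.null(doc$volume)) 1 else as.numeric(doc$volume),
    params = vapply(doc$parameters %||% list(), as.character, character(1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
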