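# Timescale separation and model reduction: split a multiscale network into
# fast and slow parts, derive exact (EMB) or approximate (AMB) QSS for the
# fast monomials that appear in slow propensities, and emit a reduced model
# over slow variables only.

#' Split a network into fast and slow parts
#'
#' Fast species are those with nonzero net change in any fast-tagged
#' reaction.  Slow variables are integer combinations of species invariant
#' under every fast reaction that involve at least one fast species (the left
#' nullspace of the fast-restricted stoichiometry matrix); combinations
#' conserved by *every* reaction are reported separately as conserved totals.
#' Untouched slow species carry over unchanged.
#'
#' @param network a [reaction_network()] with fast/slow tags.
#' @return an object of class `timescale_partition`.
#' @export
split_fast_slow <- function(network) {
  ts <- vapply(network$reactions, function(r) r$timescale, character(1))
  fast_rxns <- which(ts == "fast")
  if (length(fast_rxns) == 0L)
    stop("nothing to reduce: the network has no fast-tagged reactions")
  slow_rxns <- which(ts == "slow")
  G <- stoichiometry_matrix(network)
  sp <- network$species$name
  fast_species <- sp[rowSums(G[, fast_rxns, drop = FALSE] != 0L) > 0L]
  slow_species <- setdiff(sp, fast_species)
  basis <- conservation_basis(network, fast_rxns)
  keep <- apply(basis, 1L, function(v) any(v[fast_species] != 0L))
  basis <- basis[keep, , drop = FALSE]
  slow_vars <- matrix(0L, 0L, length(sp), dimnames = list(NULL, sp))
  conserved <- matrix(0L, 0L, length(sp), dimnames = list(NULL, sp))
  for (i in seq_len(nrow(basis))) {
    v <- basis[i, ]
    if (all(drop(v %*% G) == 0L)) conserved <- rbind(conserved, v)
    else slow_vars <- rbind(slow_vars, v)
  }
  var_name <- function(v) paste(names(v)[v != 0L], collapse = "+")
  structure(list(
    fast_reactions = fast_rxns, slow_reactions = slow_rxns,
    fast_species = fast_species, slow_species = slow_species,
    slow_variables = slow_vars,
    slow_variable_names = unname(apply(slow_vars, 1L, var_name)),
    conserved_totals = conserved,
    conserved_values = drop(conserved %*% network$species$initial)
  ), class = "timescale_partition")
}

#' @export
print.timescale_partition <- function(x, ...) {
  cat("<timescale_partition>\n")
  cat("  fast species: ", paste(x$fast_species, collapse = ", "), "\n", sep = "")
  cat("  slow species: ", paste(x$slow_species, collapse = ", "), "\n", sep = "")
  if (nrow(x$slow_variables) > 0L)
    cat("  slow variables: ", paste(x$slow_variable_names, collapse = "; "),
        "\n", sep = "")
  if (nrow(x$conserved_totals) > 0L) {
    nm <- apply(x$conserved_totals, 1L,
                function(v) paste(names(v)[v != 0L], collapse = "+"))
    cat("  conserved totals: ",
        paste(paste0(nm, " = ", x$conserved_values), collapse = "; "),
        "\n", sep = "")
  }
  invisible(x)
}

# Fast subnetwork for moment analysis: fast species only, fast reactions
# only, slow reactant counts folded into symbolic rate factors (a slow
# catalyst of multiplicity a contributes the falling factorial
# X(X-1)...(X-a+1) as a symbolic expression).
fast_subnetwork <- function(network, partition, symbolic_slow = TRUE) {
  fs <- partition$fast_species
  rxns <- lapply(partition$fast_reactions, function(j) {
    r <- network$reactions[[j]]
    re <- r$reactants[names(r$reactants) %in% fs]
    pr <- r$products[names(r$products) %in% fs]
    rate <- r$rate
    slow_re <- r$reactants[!(names(r$reactants) %in% fs)]
    if (length(slow_re) > 0L) {
      if (!symbolic_slow)
        stop("fast reaction ", j, " involves slow reactants")
      ffs <- unlist(lapply(names(slow_re), function(s) {
        vapply(seq_len(slow_re[[s]]) - 1L, function(l)
          if (l == 0L) s else paste0("(", s, "-", l, ")"), character(1))
      }))
      rate <- paste(c(if (is.numeric(rate)) format(rate, digits = 17) else
                        paste0("(", rate, ")"), ffs), collapse = "*")
    }
    rxn(reactants = re, products = pr, rate = rate, timescale = "fast")
  })
  init <- network$species$initial[match(fs, network$species$name)]
  reaction_network(tibble::tibble(name = fs, initial = init), rxns,
                   volume = network$volume,
                   params = union(network$params,
                                  setdiff(network$species$name, fs)))
}

## ---- QSS derivation ----------------------------------------------------------

# decompose a falling-factorial monomial over `species` into raw moments:
# returns list of list(nu = exponent vector, coef = bigq)
ff_monomial_to_raw <- function(a, species) {
  amax <- max(c(a, 1L))
  S1 <- stirling1_table(amax)
  terms <- list(list(nu = integer(length(species)), coef = q_one()))
  for (i in seq_along(species)) {
    ai <- if (species[i] %in% names(a)) a[[species[i]]] else 0L
    if (ai == 0L) next
    new <- list()
    for (t in terms) {
      for (cc in seq_len(ai)) {
        s <- S1[[ai + 1L]][[cc + 1L]]
        if (q_is_zero(s)) next
        nu <- t$nu; nu[i] <- cc
        new[[length(new) + 1L]] <- list(nu = nu, coef = q_mul(t$coef, s))
      }
    }
    terms <- new
  }
  terms
}

#' Derive quasi-steady-state expressions for fast monomials
#'
#' For each requested monomial over fast species (reactant multiplicities of
#' a slow propensity, interpreted as falling factorials), derives its
#' stationary conditional expectation given the slow state.  Exact mode
#' (`"emb"`) dispatches on the structure of the fast subnetwork: a
#' feedforward subnetwork goes through the linear moment closure
#' ([build_closure()] / [stationary_conditional()]); a weakly reversible
#' deficiency-zero subnetwork goes through the conservation-constrained
#' partition function ([conditional_mean_rational()]).  Approximate mode
#' (`"amb"`) factorizes products of first moments (the moment-closure
#' assumption \eqn{\langle X_i X_j\rangle = \langle X_i\rangle\langle
#' X_j\rangle}) for feedforward subnetworks; for complex-balanced
#' subnetworks the caller supplies deterministic QSS functions (see
#' [deterministic_qss_formulas()]).
#'
#' @param network a [reaction_network()] with fast/slow tags.
#' @param monomials list of named integer vectors over fast species; `NULL`
#'   derives every fast monomial appearing in a slow propensity.
#' @param mode `"emb"` (exact) or `"amb"` (approximate).
#' @param params named values instantiating symbolic rate parameters.
#' @param max_total degree cap for rational reconstruction.
#' @return named list (monomial string -> `qss_expression`), each with fields
#'   `kind` (`"constant"`/`"rational"`), `value` (bigq, constants only),
#'   `qss` ([qss_rational], rational only) and `var`.
#' @export
derive_qss <- function(network, monomials = NULL, mode = c("emb", "amb"),
                       params = list(), max_total = 16L) {
  mode <- match.arg(mode)
  part <- split_fast_slow(network)
  if (is.null(monomials)) monomials <- needed_fast_monomials(network, part)
  if (length(monomials) == 0L) return(list())
  sub <- fast_subnetwork(network, part)
  ffc <- check_feedforward(sub)
  route <- if (ffc$feedforward) "feedforward" else {
    subcb <- fast_subnetwork(network, part, symbolic_slow = FALSE)
    rep_ <- analyze_structure(subcb)
    if (rep_$weakly_reversible && rep_$deficiency == 0L) "complex_balanced"
    else stop("unsupported fast subnetwork: neither feedforward (",
              ffc$violation, ") nor complex balanced (deficiency ",
              rep_$deficiency, ", weakly reversible: ",
              rep_$weakly_reversible, ")")
  }
  out <- list()
  for (a in monomials) {
    a <- a[a > 0L]
    key <- paste0(names(a), "^", a, collapse = "*")
    out[[key]] <- switch(route,
      feedforward = qss_feedforward(sub, a, mode, params, max_total),
      complex_balanced = qss_complex_balanced(network, part, a, mode, params))
    out[[key]]$monomial <- a
  }
  out
}

qss_expression <- function(kind, var = NA_character_, value = NULL, qss = NULL) {
  structure(list(kind = kind, var = var, value = value, qss = qss),
            class = "qss_expression")
}

#' @export
print.qss_expression <- function(x, ...) {
  if (x$kind == "constant") {
    cat("<qss_expression> constant ", q_to_str(x$value),
        " = ", q_to_num(x$value), "\n", sep = "")
  } else {
    print(x$qss)
  }
  invisible(x)
}

# evaluate a qss_expression at an integer slow count (exact)
qss_expression_eval <- function(expr, n) {
  if (expr$kind == "constant") return(expr$value)
  qss_eval(expr$qss, n, exact = TRUE)
}

qss_feedforward <- function(sub, a, mode, params, max_total) {
  fs <- sub$species$name
  stopifnot(all(names(a) %in% fs))
  assign <- lapply(params, q_parse)
  if (mode == "emb") {
    terms <- ff_monomial_to_raw(a, fs)
    seeds <- lapply(terms, `[[`, "nu")
    sys <- build_closure(seeds, sub)
    if (inherits(sys, "closure_failure"))
      stop("moment closure did not terminate within the cap")
    free <- setdiff(unique(unlist(lapply(sys$rows, function(row)
      unlist(lapply(row, qrf_vars))))), names(assign))
    value_at <- function(extra) {
      sm <- stationary_moments(sys, c(assign, extra))
      tot <- q_zero()
      for (t in terms)
        tot <- q_add(tot, q_mul(t$coef, sm[[moment_string(t$nu)]]))
      tot
    }
    if (length(free) == 0L)
      return(qss_expression("constant", value = value_at(list())))
    if (length(free) > 1L)
      stop("QSS depends on more than one slow symbol: ",
           paste(free, collapse = ", "))
    rc <- reconstruct_rational(function(x) value_at(stats::setNames(list(x), free)),
                               max_total = max_total)
    return(qss_expression("rational", var = free,
                          qss = qss_rational(rc$num, rc$den, var = free,
                                             description = paste0("exact <",
                                               paste0(names(a), "^(", a, ")", collapse = " "),
                                               " | ", free, ">"))))
  }
  # AMB: product of first moments, <X^(a)> ~ prod_l (<X> - l)
  means <- list()
  free_all <- character(0)
  for (s in names(a)) {
    seed <- integer(length(fs)); seed[match(s, fs)] <- 1L
    sys <- build_closure(list(seed), sub)
    free <- setdiff(unique(unlist(lapply(sys$rows, function(row)
      unlist(lapply(row, qrf_vars))))), names(assign))
    free_all <- union(free_all, free)
    means[[s]] <- list(sys = sys, key = moment_string(seed))
  }
  value_at <- function(extra) {
    tot <- q_one()
    for (s in names(a)) {
      sm <- stationary_moments(means[[s]]$sys, c(assign, extra))
      m <- sm[[means[[s]]$key]]
      for (l in seq_len(a[[s]]) - 1L)
        tot <- q_mul(tot, q_sub(m, q_from_int(l)))
    }
    tot
  }
  if (length(free_all) == 0L)
    return(qss_expression("constant", value = value_at(list())))
  if (length(free_all) > 1L)
    stop("QSS depends on more than one slow symbol: ",
         paste(free_all, collapse = ", "))
  rc <- reconstruct_rational(function(x)
    value_at(stats::setNames(list(x), free_all)), max_total = max_total)
  qss_expression("rational", var = free_all,
                 qss = qss_rational(rc$num, rc$den, var = free_all,
                                    description = paste0("approximate <",
                                      paste0(names(a), "^(", a, ")", collapse = " "),
                                      " | ", free_all, ">")))
}

qss_complex_balanced <- function(network, part, a, mode, params) {
  if (mode != "emb")
    stop("approximate QSS for complex-balanced subnetworks uses the ",
         "deterministic formulas; see deterministic_qss_formulas()")
  subcb <- fast_subnetwork(network, part, symbolic_slow = FALSE)
  eq <- solve_equilibrium(subcb, params = params)
  basis <- conservation_basis(subcb)
  if (nrow(basis) == 0L)
    stop("complex-balanced fast subnetwork has no conservation laws; ",
         "the constrained lattice is unbounded")
  fs <- subcb$species$name
  G <- stoichiometry_matrix(network)[fs, , drop = FALSE]
  beta <- vector("list", nrow(basis))
  for (i in seq_len(nrow(basis))) {
    v <- basis[i, ]
    if (all(drop(v %*% G) == 0L)) {
      beta[[i]] <- sum(v * network$species$initial[match(fs, network$species$name)])
    } else {
      j <- which(apply(part$slow_variables[, fs, drop = FALSE], 1L,
                       function(w) all(w == v)))
      nm <- if (length(j) == 1L) part$slow_variable_names[j]
            else paste(fs[v != 0L], collapse = "+")
      beta[[i]] <- nm
    }
  }
  n_sym <- sum(vapply(beta, is.character, logical(1)))
  cons <- conservation_constraint(basis, beta)
  if (n_sym == 0L)
    return(qss_expression("constant",
                          value = factorial_moment(a, cons, eq, exact = TRUE)))
  if (n_sym > 1L)
    stop("more than one slow total enters the fast conservation laws")
  qss_expression("rational", var = beta[[cons$symbolic]],
                 qss = conditional_mean_rational(a, cons, eq))
}

# fast monomials appearing in slow propensities
needed_fast_monomials <- function(network, part) {
  out <- list(); keys <- character(0)
  for (j in part$slow_reactions) {
    r <- network$reactions[[j]]
    a <- r$reactants[names(r$reactants) %in% part$fast_species]
    if (length(a) == 0L) next
    k <- paste0(names(a), "^", a, collapse = "*")
    if (!(k %in% keys)) {
      keys <- c(keys, k)
      out[[length(out) + 1L]] <- a
    }
  }
  out
}

## ---- deterministic QSS formulas ----------------------------------------------

#' Deterministic (total-QSSA style) QSS formulas
#'
#' Closed-form deterministic quasi-steady-states used by the approximate
#' (AMB) reduced models of the complex-balanced examples.
#'
#' For the genetic oscillator (`"oscillator_tqssa"`), the active-promoter
#' total-QSSA with total promoter \eqn{X_{D_T}}, slow total \eqn{X_T} and
#' dissociation count \eqn{c = \Omega/K}:
#' \deqn{\langle X_{D_A}\rangle \approx \tfrac12\Big(X_{D_T} - X_T - c +
#'   \sqrt{(X_{D_T} - X_T - c)^2 + 4 c X_{D_T}}\Big).}
#' (The discriminant carries the factor \eqn{X_{D_T}}; this is the standard
#' total-QSSA root, the form that satisfies the exact identity
#' \eqn{\langle X_{D_A}\rangle = X_{D_T}} at \eqn{X_T = 0}.)
#'
#' For the decoy model (`"decoy"`), with \eqn{A = X_T - K_D/\Omega - N} and
#' \eqn{S = \sqrt{A^2 + 4 K_D X_T/\Omega}}:
#' \deqn{\langle X_{G_A}\rangle \approx \frac{A + S}{2 K_A/\Omega + A + S}.}
#'
#' The `"printed"` oscillator variant replaces the discriminant term
#' \eqn{4 c X_{D_T}} with the bare \eqn{4c}.  It is not the algebraic
#' total-QSSA root (and misses the \eqn{X_T = 0} identity slightly), but it
#' is the form some deterministic-reduction baselines use in practice, and
#' the bundled oscillator AMB model adopts it as its comparator.
#'
#' @param example `"oscillator_tqssa"` or `"decoy"`.
#' @param params named list: oscillator needs `XDT` (total promoter) and `c`
#'   (dissociation count \eqn{\Omega/K}); decoy needs `KA`, `KD`
#'   (dissociation counts \eqn{K_A/\Omega}, \eqn{K_D/\Omega}) and `N`.
#' @param variant `"corrected"` (the exact deterministic equilibrium root,
#'   default) or `"printed"` (oscillator only, see above).
#' @return a function of the slow total \eqn{X_T} returning the approximate
#'   conditional mean; errors on negative slow counts.
#' @export
deterministic_qss_formulas <- function(example = c("oscillator_tqssa", "decoy"),
                                       params = list(),
                                       variant = c("corrected", "printed")) {
  example <- match.arg(example)
  variant <- match.arg(variant)
  if (example == "oscillator_tqssa") {
    XDT <- params$XDT %||% 10
    cc <- params$c %||% (1 / 16)
    disc <- if (variant == "printed") 4 * cc else 4 * cc * XDT
    return(function(XT) {
      if (any(XT < 0)) stop("negative slow counts")
      A <- XDT - XT - cc
      (A + sqrt(A^2 + disc)) / 2
    })
  }
  KA <- params$KA %||% (100 / 2000)
  KD <- params$KD %||% (100 / 10000)
  N <- params$N %||% 10
  function(XT) {
    if (any(XT < 0)) stop("negative slow counts")
    A <- XT - KD - N
    S <- sqrt(A^2 + 4 * KD * XT)
    (A + S) / (2 * KA + A + S)
  }
}

## ---- reduced model -----------------------------------------------------------

#' Build a reduced model over slow variables
#'
#' Every slow reaction's propensity is rewritten in the slow state: factors
#' from untouched slow species stay mass-action; fast-species factors are
#' replaced by their stationary conditional expectations (exact for
#' `mode = "emb"`, approximate for `mode = "amb"`).  Conditional expectations
#' that depend on a slow variable are tabulated exactly over
#' `0:reach_cap`; simulation errors out if the slow state leaves the table
#' (values are never clamped), and a QSS value that is negative at a
#' reachable slow state aborts construction.
#'
#' @param network a [reaction_network()] with fast/slow tags.
#' @param mode `"emb"` or `"amb"`.
#' @param params named values for symbolic rate parameters.
#' @param reach_cap tabulation range for slow-variable dependent
#'   propensities.
#' @param amb_qss for complex-balanced fast subnetworks in `"amb"` mode:
#'   named list (fast species -> function of the slow total) of
#'   deterministic QSS values; defaults are provided for the bundled
#'   examples via their `example` attribute.
#' @return an object of class `reduced_model`, simulable by
#'   [gillespie_direct()].
#' @export
build_reduced_model <- function(network, mode = c("emb", "amb"), params = list(),
                                reach_cap = 400L, amb_qss = NULL) {
  mode <- match.arg(mode)
  part <- split_fast_slow(network)
  sp <- network$species$name
  vars <- c(part$slow_species, part$slow_variable_names)
  v_init <- c(network$species$initial[match(part$slow_species, sp)],
              if (nrow(part$slow_variables) > 0L)
                drop(part$slow_variables %*% network$species$initial) else numeric(0))
  # net change of each slow reaction on the reduced variables
  G <- stoichiometry_matrix(network)
  net_of <- function(j) {
    g <- G[, j]
    c(g[match(part$slow_species, sp)],
      if (nrow(part$slow_variables) > 0L) drop(part$slow_variables %*% g)
      else numeric(0))
  }
  # QSS expressions for needed monomials
  mono <- needed_fast_monomials(network, part)
  qss <- NULL
  route_cb <- FALSE
  if (length(mono) > 0L) {
    sub <- fast_subnetwork(network, part)
    if (check_feedforward(sub)$feedforward) {
      qss <- derive_qss(network, mono, mode = mode, params = params)
    } else {
      route_cb <- TRUE
      if (mode == "emb") {
        qss <- derive_qss(network, mono, mode = "emb", params = params)
      } else {
        if (is.null(amb_qss)) amb_qss <- default_amb_qss(network, part, params)
        if (is.null(amb_qss))
          stop("mode = \"amb\" with a complex-balanced fast subnetwork needs ",
               "deterministic QSS functions (amb_qss)")
      }
    }
  }
  reactions <- list()
  for (j in part$slow_reactions) {
    r <- network$reactions[[j]]
    net <- net_of(j)
    if (all(net == 0L) ) next
    rate <- rxn_rate_numeric(r, network, params)
    re_slow <- r$reactants[names(r$reactants) %in% part$slow_species]
    a <- r$reactants[names(r$reactants) %in% part$fast_species]
    tab <- NULL; tab_var <- NA_character_
    if (length(a) > 0L) {
      if (route_cb && mode == "amb") {
        if (length(a) != 1L || a[[1L]] != 1L)
          stop("deterministic AMB tables are defined for first-order fast factors")
        svar <- part$slow_variable_names[1L]
        fn <- amb_qss[[names(a)]]
        if (is.null(fn)) stop("no deterministic QSS supplied for ", names(a))
        tab <- fn(0:reach_cap)
        tab[tab < 0 & tab > -1e-9] <- 0
        if (any(tab < 0))
          stop("approximate QSS for ", names(a),
               " is negative at a reachable slow state")
        tab_var <- svar
      } else {
        key <- paste0(names(a), "^", a, collapse = "*")
        ex <- qss[[key]]
        if (ex$kind == "constant") {
          if (q_sign(ex$value) < 0L)
            stop("QSS for ", key, " is negative")
          rate <- rate * q_to_num(ex$value)
        } else {
          vals_q <- lapply(0:reach_cap, function(n) qss_expression_eval(ex, n))
          if (any(vapply(vals_q, q_sign, integer(1)) < 0L))
            stop("QSS for ", key, " is negative at a reachable slow state ",
                 "(within 0:", reach_cap, ")")
          tab <- vapply(vals_q, q_to_num, numeric(1))
          tab_var <- ex$var
        }
      }
    }
    if (!is.na(tab_var) && !(tab_var %in% vars))
      stop("QSS variable ", tab_var, " is not a reduced-model variable")
    reactions[[length(reactions) + 1L]] <- list(
      net = stats::setNames(net, vars),
      reactants = re_slow, rate = rate,
      table_var = tab_var, table = tab, source = j)
  }
  structure(list(variables = tibble::tibble(name = vars, initial = v_init),
                 reactions = reactions, mode = toupper(mode),
                 partition = part, reach_cap = reach_cap),
            class = "reduced_model")
}

# deterministic AMB QSS defaults for the bundled complex-balanced examples
default_amb_qss <- function(network, part, params) {
  ex <- attr(network, "example")
  if (is.null(ex)) return(NULL)
  if (ex == "oscillator") {
    XDT <- sum(network$species$initial[match(c("DA", "DR"), network$species$name)])
    kf <- rxn_rate_numeric(network$reactions[[8L]], network, params)
    kb <- rxn_rate_numeric(network$reactions[[9L]], network, params)
    f <- deterministic_qss_formulas("oscillator_tqssa",
                                    list(XDT = XDT, c = kb / kf),
                                    variant = "printed")
    list(DA = f,
         DR = function(XT) XDT - f(XT),
         R = function(XT) pmax(XT - (XDT - f(XT)), 0))
  } else if (ex == "decoy") {
    kfA <- rxn_rate_numeric(network$reactions[[3L]], network, params)
    kbA <- rxn_rate_numeric(network$reactions[[4L]], network, params)
    kfD <- rxn_rate_numeric(network$reactions[[5L]], network, params)
    kbD <- rxn_rate_numeric(network$reactions[[6L]], network, params)
    N <- sum(network$species$initial[match(c("D", "DP"), network$species$name)])
    g <- deterministic_qss_formulas("decoy",
                                    list(KA = kbA / kfA, KD = kbD / kfD, N = N))
    # free transcription factor from the gene-site detailed balance, bound
    # decoys from the decoy-site detailed balance
    p_free <- function(XT) {
      ga <- g(XT)
      (kbA / kfA) * ga / pmax(1 - ga, 1e-12)
    }
    list(GA = g,
         G0 = function(XT) 1 - g(XT),
         P = p_free,
         DP = function(XT) {
           p <- p_free(XT)
           N * p / (kbD / kfD + p)
         })
  } else NULL
}

#' @export
print.reduced_model <- function(x, ...) {
  cat("<reduced_model> ", x$mode, ", variables: ",
      paste(x$variables$name, collapse = ", "), "\n", sep = "")
  for (r in x$reactions) {
    chg <- r$net[r$net != 0L]
    cat(sprintf("  %s: rate %g%s%s\n",
                paste(paste0(names(chg), ifelse(chg > 0, " +", " "), chg),
                      collapse = ", "),
                r$rate,
                if (length(r$reactants) > 0L)
                  paste0(" * ", paste0(names(r$reactants), "^(",
                                       r$reactants, ")", collapse = "*")) else "",
                if (!is.na(r$table_var))
                  paste0(" * qss(", r$table_var, ")") else ""))
  }
  invisible(x)
}

#' @rdname build_reduced_model
#' @param x a `reduced_model`.
#' @param ... unused.
#' @export
tidy.reduced_model <- function(x, ...) {
  tibble::tibble(
    reaction = seq_along(x$reactions),
    net = vapply(x$reactions, function(r) {
      chg <- r$net[r$net != 0L]
      paste(paste0(names(chg), ifelse(chg > 0, "+", ""), chg), collapse = ", ")
    }, character(1)),
    rate = vapply(x$reactions, function(r) r$rate, numeric(1)),
    mass_action = vapply(x$reactions, function(r)
      if (length(r$reactants) == 0L) "" else
        paste0(names(r$reactants), "^(", r$reactants, ")", collapse = "*"),
      character(1)),
    qss_table = vapply(x$reactions, function(r)
      if (is.na(r$table_var)) "" else r$table_var, character(1)))
}
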