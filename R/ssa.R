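# Stochastic simulation: Gillespie direct method (compiled core), ensemble
# summaries and oscillation period analysis.

model_matrices <- function(model, params = list()) {
  if (inherits(model, "reaction_network")) {
    sp <- model$species$name
    nr <- length(model$reactions)
    Re <- matrix(0L, nr, length(sp))
    Ne <- matrix(0L, nr, length(sp))
    rate <- numeric(nr)
    for (j in seq_len(nr)) {
      r <- model$reactions[[j]]
      Re[j, match(names(r$reactants), sp)] <- r$reactants
      Ne[j, ] <- -Re[j, ]
      Ne[j, match(names(r$products), sp)] <-
        Ne[j, match(names(r$products), sp)] + r$products
      rate[j] <- rxn_rate_numeric(r, model, params)
    }
    list(vars = sp, init = as.integer(model$species$initial),
         reactants = Re, net = Ne, rate = rate,
         table_var = integer(nr), tables = vector("list", nr))
  } else if (inherits(model, "reduced_model")) {
    vars <- model$variables$name
    nr <- length(model$reactions)
    Re <- matrix(0L, nr, length(vars))
    Ne <- matrix(0L, nr, length(vars))
    rate <- numeric(nr)
    tv <- integer(nr)
    tabs <- vector("list", nr)
    for (j in seq_len(nr)) {
      r <- model$reactions[[j]]
      if (length(r$reactants) > 0L)
        Re[j, match(names(r$reactants), vars)] <- r$reactants
      Ne[j, ] <- as.integer(r$net[vars])
      rate[j] <- r$rate
      if (!is.na(r$table_var)) {
        tv[j] <- match(r$table_var, vars)
        tabs[[j]] <- r$table
      }
    }
    list(vars = vars, init = as.integer(round(model$variables$initial)),
         reactants = Re, net = Ne, rate = rate, table_var = tv, tables = tabs)
  } else {
    stop("model must be a reaction_network or a reduced_model")
  }
}

#' Simulate one exact sample path (Gillespie direct method)
#'
#' Generates a statistically exact trajectory of the chemical master
#' equation for a full [reaction_network()] or a [build_reduced_model()]
#' output (whose rational-QSS propensities are tabulated).  The path is
#' recorded piecewise-constantly on a fixed time grid; identical seeds give
#' bitwise-identical trajectories.
#'
#' @param model a [reaction_network()] (numeric rates after `params`) or a
#'   `reduced_model`.
#' @param t_end end time.
#' @param seed integer seed (`set.seed`); `NULL` continues the current RNG
#'   stream.
#' @param grid recording times (default: 201 equispaced points).
#' @param params named values for symbolic rate parameters.
#' @param record `"grid"` or `"events"` (also keeps every post-event state,
#'   up to `max_events`).
#' @param max_events event budget; exceeding it truncates the run and flags
#'   the trajectory.
#' @return a tibble of class `ssa_trajectory` (`time` plus one column per
#'   variable) with attributes `seed`, `n_events`, `absorbing`, `truncated`
#'   and (optionally) `events`.
#' @export
gillespie_direct <- function(model, t_end, seed = NULL, grid = NULL,
                             params = list(), record = c("grid", "events"),
                             max_events = 5e8) {
  record <- match.arg(record)
  mm <- model_matrices(model, params)
  if (is.null(grid)) grid <- seq(0, t_end, length.out = 201L)
  stopifnot(!is.unsorted(grid), all(grid >= 0), all(grid <= t_end))
  if (!is.null(seed)) set.seed(seed)
  res <- ssa_direct_cpp(mm$init, mm$reactants, mm$net, mm$rate,
                        mm$table_var, mm$tables, as.numeric(grid),
                        t_end, max_events, record == "events")
  if (res$status == 2L)
    stop("slow state left the tabulated QSS range during simulation ",
         "(state: ", paste(mm$vars, res$final_state, sep = "=", collapse = ", "),
         "); increase reach_cap")
  if (res$status == 3L)
    stop("negative propensity encountered (state: ",
         paste(mm$vars, res$final_state, sep = "=", collapse = ", "), ")")
  out <- tibble::as_tibble(as.data.frame(res$states))
  names(out) <- mm$vars
  out <- dplyr::bind_cols(tibble::tibble(time = as.numeric(grid)), out)
  class(out) <- c("ssa_trajectory", class(out))
  attr(out, "seed") <- seed
  attr(out, "n_events") <- res$n_events
  attr(out, "absorbing") <- res$status == 1L
  attr(out, "truncated") <- res$truncated
  attr(out, "final_state") <- stats::setNames(res$final_state, mm$vars)
  if (record == "events") {
    ev <- tibble::as_tibble(as.data.frame(res$event_states))
    names(ev) <- mm$vars
    attr(out, "events") <- dplyr::bind_cols(
      tibble::tibble(time = res$event_times), ev)
  }
  out
}

#' Ensemble mean and standard deviation over independent runs
#'
#' Runs `n_runs` independent simulations (seeds `seed + 1, ..., seed +
#' n_runs`) and accumulates the per-grid-point mean and standard deviation
#' of every variable (Welford accumulation; trajectories are
#' piecewise-constant interpolated on the grid by the simulator).
#'
#' @inheritParams gillespie_direct
#' @param n_runs number of independent runs (at least 2).
#' @param seed base seed; run `i` uses `seed + i`.
#' @return a tibble of class `ensemble_summary` with columns `time`,
#'   `species`, `mean`, `sd`.
#' @export
ensemble_summary <- function(model, n_runs, t_end, grid = NULL, seed = 1L,
                             params = list(), max_events = 5e8) {
  stopifnot(n_runs >= 2L)
  if (is.null(grid)) grid <- seq(0, t_end, length.out = 201L)
  if (length(grid) == 0L) stop("empty recording grid")
  mm <- model_matrices(model, params)
  ng <- length(grid)
  nv <- length(mm$vars)
  mean_acc <- matrix(0, ng, nv)
  m2_acc <- matrix(0, ng, nv)
  for (i in seq_len(n_runs)) {
    set.seed(seed + i)
    res <- ssa_direct_cpp(mm$init, mm$reactants, mm$net, mm$rate,
                          mm$table_var, mm$tables, as.numeric(grid),
                          max(grid), max_events, FALSE)
    if (res$status >= 2L) stop("simulation failure in run ", i)
    d <- res$states - mean_acc
    mean_acc <- mean_acc + d / i
    m2_acc <- m2_acc + d * (res$states - mean_acc)
  }
  sd_mat <- sqrt(m2_acc / (n_runs - 1L))
  out <- tibble::tibble(
    time = rep(as.numeric(grid), nv),
    species = rep(mm$vars, each = ng),
    mean = as.vector(mean_acc),
    sd = as.vector(sd_mat))
  class(out) <- c("ensemble_summary", class(out))
  attr(out, "n_runs") <- n_runs
  attr(out, "seed") <- seed
  out
}

#' Oscillation period statistics from a trajectory
#'
#' Splits a uniformly recorded trajectory into `n_segments` contiguous
#' segments, estimates each segment's period as the lag of the first
#' prominent positive autocorrelation peak (local maximum with value at
#' least `prominence`, at lag at least `min_lag` samples; quadratic
#' interpolation around the peak), and reports the mean and standard
#' deviation over segments.  Segments without such a peak are flagged and
#' excluded.  The dominant discrete-Fourier frequency of the full trace is
#' also reported.
#'
#' @param traj an `ssa_trajectory` (or any tibble with a `time` column).
#' @param species variable name to analyze.
#' @param n_segments number of segments.
#' @param min_lag minimum peak lag in samples.
#' @param prominence autocorrelation threshold for a peak.
#' @return an object of class `period_stats`.
#' @export
period_analysis <- function(traj, species, n_segments, min_lag = 10L,
                            prominence = 0.1) {
  stopifnot(species %in% names(traj), "time" %in% names(traj))
  tt <- traj$time
  dt <- diff(tt)
  if (length(dt) < 3L || diff(range(dt)) > 1e-8 * max(dt))
    stop("period analysis needs a uniform recording grid")
  dt <- dt[1L]
  y <- traj[[species]]
  n <- length(y)
  if (n_segments < 1L || n %/% n_segments < 4L * min_lag)
    stop("trajectory too short for ", n_segments, " segments")
  # dominant Fourier frequency of the full (demeaned) trace; truncated to a
  # power-of-two length so the transform stays O(n log n)
  n2 <- 2^floor(log2(n))
  yc <- y[seq_len(n2)] - mean(y[seq_len(n2)])
  pw <- Mod(stats::fft(yc))^2
  half <- 2:(n2 %/% 2)
  kdom <- half[which.max(pw[half])] - 1L
  dom_freq <- kdom / (n2 * dt)
  seg_len <- n %/% n_segments
  periods <- rep(NA_real_, n_segments)
  for (s in seq_len(n_segments)) {
    ys <- y[((s - 1L) * seg_len + 1L):(s * seg_len)]
    if (stats::sd(ys) == 0) next
    ac <- stats::acf(ys, lag.max = seg_len - 2L, plot = FALSE,
                     demean = TRUE)$acf[, 1L, 1L]
    lags <- seq_along(ac) - 1L
    for (k in seq(max(min_lag, 2L) + 1L, length(ac) - 1L)) {
      if (ac[k] >= ac[k - 1L] && ac[k] >= ac[k + 1L] && ac[k] >= prominence) {
        # quadratic refinement of the peak position
        denom <- ac[k - 1L] - 2 * ac[k] + ac[k + 1L]
        shift <- if (denom < 0) 0.5 * (ac[k - 1L] - ac[k + 1L]) / denom else 0
        periods[s] <- (lags[k] + shift) * dt
        break
      }
    }
  }
  ok <- !is.na(periods)
  structure(list(
    periods = tibble::tibble(segment = seq_len(n_segments),
                             period = periods, valid = ok),
    mean = if (any(ok)) mean(periods[ok]) else NA_real_,
    sd = if (sum(ok) > 1L) stats::sd(periods[ok]) else NA_real_,
    n_valid = sum(ok), n_flagged = sum(!ok),
    dominant_freq = dom_freq,
    dominant_period = 1 / dom_freq,
    species = species, dt = dt, segment_length = seg_len
  ), class = "period_stats")
}

#' @export
print.period_stats <- function(x, ...) {
  cat("<period_stats> ", x$species, ": mean period ", format(x$mean, digits = 5),
      " (sd ", format(x$sd, digits = 4), ") from ", x$n_valid,
      " segments (", x$n_flagged, " flagged); dominant spectral period ",
      format(x$dominant_period, digits = 5), "\n", sep = "")
  invisible(x)
}

#' @rdname period_analysis
#' @param x a `period_stats`.
#' @param ... unused.
#' @export
tidy.period_stats <- function(x, ...) x$periods

#' @rdname period_analysis
#' @export
glance.period_stats <- function(x, ...) {
  tibble::tibble(mean_period = x$mean, sd_period = x$sd,
                 n_valid = x$n_valid, n_flagged = x$n_flagged,
                 dominant_period = x$dominant_period,
                 dominant_freq = x$dominant_freq)
}

## ---- plotting ----------------------------------------------------------------

#' Plot a simulated trajectory
#'
#' @param object an `ssa_trajectory`.
#' @param species variables to show (default: all).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ssa_trajectory <- function(object, species = NULL, ...) {
  vars <- setdiff(names(object), "time")
  if (!is.null(species)) vars <- intersect(vars, species)
  df <- dplyr::bind_rows(lapply(vars, function(v)
    tibble::tibble(time = object$time, species = v, count = object[[v]])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$count,
                                   color = .data$species)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time", y = "copy number")
}

#' Plot an ensemble mean with a +/- one standard deviation ribbon
#'
#' @param object an `ensemble_summary`.
#' @param species variables to show (default: all).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ensemble_summary <- function(object, species = NULL, ...) {
  df <- object
  if (!is.null(species)) df <- dplyr::filter(df, .data$species %in% !!species)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mean,
                                   color = .data$species, fill = .data$species)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "copy number (mean ± sd)")
}

#' Histogram of per-segment period estimates
#'
#' @param object a `period_stats`.
#' @param binwidth histogram bin width.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.period_stats <- function(object, binwidth = NULL, ...) {
  df <- dplyr::filter(object$periods, .data$valid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period)) +
    ggplot2::geom_histogram(binwidth = binwidth, bins = 30) +
    ggplot2::geom_vline(xintercept = object$mean, linetype = 2) +
    ggplot2::labs(x = "period", y = "segments")
}
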