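#' Simulation configuration
#'
#' @param n_runs number of replicate stochastic runs averaged together.
#' @param duration simulated time in ms.
#' @param threshold maximum allowed cumulative per-step transition
#'   probability; sets the time step through [choose_dt()].  Default 0.7.
#' @param seed integer seed; each replicate run gets its own deterministic
#'   substream.
#' @param record_dt approximate spacing (ms) of recorded trace points; the
#'   actual spacing is an integer multiple of the time step.
#' @param avg_frac fraction of the trace (from the end) averaged when a
#'   steady-state force is requested.  Default 0.25 (the final quarter).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_runs = 400, duration = 7500, threshold = 0.7,
                       seed = 1, record_dt = 5, avg_frac = 0.25) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  if (duration <= 0) stop("duration must be > 0")
  if (avg_frac <= 0 || avg_frac > 1) stop("avg_frac must lie in (0, 1]")
  structure(list(n_runs = as.integer(n_runs), duration = duration,
                 threshold = threshold, seed = seed, record_dt = record_dt,
                 avg_frac = avg_frac), class = "sim_config")
}

#' Automatic time-step selection
#'
#' The time step is chosen so that the cumulative per-step transition
#' probability of any regulatory unit never exceeds `threshold`, for any
#' state and any combination of nearest-neighbor states, evaluated at the
#' largest calcium concentration the simulation will see:
#' dt = threshold / max total exit rate.
#'
#' @param params a [tm_params()] object.
#' @param ca_max largest calcium concentration (uM) of the protocol.
#' @param threshold maximum cumulative transition probability per step.
#' @return Time step in ms.
#' @export
choose_dt <- function(params, ca_max, threshold = 0.7) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  ctx <- neighbor_contexts()
  max_rate <- 0
  for (k in seq_len(nrow(ctx))) {
    Q <- ru_rate_table(ctx$X[k], ctx$Y[k], params, ca_max)
    diag(Q) <- 0
    max_rate <- max(max_rate, rowSums(Q))
  }
  if (max_rate <= 0)
    stop("degenerate model: all transition rates are zero")
  threshold / max_rate
}

# flattened ca-independent rate array over the 9 neighbor contexts,
# ctx-major ((X,Y) with X outer), then from-state, then to-state
horiz_rate_array <- function(params) {
  arr <- numeric(9 * 36)
  for (xi in 1:3) for (yi in 1:3) {
    Q <- ru_rate_table(TM_LEVELS[xi], TM_LEVELS[yi], params, ca = 0)
    diag(Q) <- 0
    c0 <- (xi - 1L) * 3L + (yi - 1L)
    # row-major per (from, to)
    arr[c0 * 36 + rep((0:5) * 6, each = 6) + rep(1:6, times = 6)] <-
      as.numeric(t(Q))
  }
  arr
}

ca_on_array <- function(params) {
  m <- matrix(0, 6, 6)
  m[1, 2] <- m[3, 4] <- m[5, 6] <- params$k_Ca_on
  as.numeric(t(m))  # row-major (from, to)
}

#' Run the stochastic filament simulation
#'
#' Simulates `n_live` regulatory units in series, flanked by two dummy
#' units permanently fixed in the blocked, calcium-free state, under either
#' a constant calcium concentration or a calcium transient.  All live units
#' start in the blocked calcium-free state.  Replicate runs are averaged
#' into a single trajectory; force is the fraction of live units in an
#' M (open, crossbridge-bound) state.
#'
#' @param params a [tm_params()] object.
#' @param ca either a single calcium concentration in uM, or a
#'   [calcium_transient()] object for twitch simulations.
#' @param config a [sim_config()] object.
#' @param n_live number of live regulatory units (default 24).
#' @param reset_at optional time (ms) at which every open unit is instantly
#'   returned to the closed state (the slack-restretch maneuver of the ktr
#'   protocol).
#' @return A `filament_trajectory` object: recorded times (ms), mean force
#'   and its standard error across runs, mean six-state occupancy, and the
#'   per-run steady-window force means used by [steady_force()].
#' @export
simulate_filament <- function(params, ca, config = sim_config(),
                              n_live = 24, reset_at = NULL) {
  validate_params(params)
  stopifnot(inherits(config, "sim_config"))
  transient <- inherits(ca, "calcium_transient")
  if (transient) {
    if (max(ca$times) < config$duration)
      stop("calcium transient (", max(ca$times), " ms) is shorter than the ",
           "simulation duration (", config$duration, " ms)")
    ca_max <- max(ca$ca)
  } else {
    if (!is.numeric(ca) || length(ca) != 1L || ca < 0)
      stop("ca must be a single non-negative concentration or a ",
           "calcium_transient")
    ca_max <- ca
  }
  dt <- choose_dt(params, ca_max, config$threshold)
  if (config$duration < dt)
    stop("duration is shorter than one time step (", signif(dt, 4), " ms)")
  record_every <- max(1L, as.integer(round(config$record_dt / dt)))
  rec_dt <- record_every * dt
  n_bins <- max(1L, as.integer(ceiling(config$duration / rec_dt)))
  times <- (0:n_bins) * rec_dt
  ca_bins <- if (transient) {
    mid <- (times[-1] + times[-length(times)]) / 2
    stats::approx(ca$times, ca$ca, xout = mid, rule = 2)$y
  } else {
    rep(ca, n_bins)
  }
  reset_rec <- -1L
  if (!is.null(reset_at)) {
    reset_rec <- as.integer(round(reset_at / rec_dt))
    if (reset_rec < 1L || reset_rec > n_bins)
      stop("reset_at must fall inside the simulated interval")
  }
  avg_start <- as.integer(floor((1 - config$avg_frac) * n_bins)) + 1L
  res <- engine_run(as.integer(n_live), horiz_rate_array(params),
                    ca_on_array(params), dt, record_every, ca_bins,
                    config$n_runs, as.numeric(config$seed), reset_rec,
                    avg_start)
  occupancy <- res$occupancy
  colnames(occupancy) <- RU_STATES
  structure(list(times = times, force = res$force,
                 force_sem = res$force_sem, occupancy = occupancy,
                 run_means = res$run_means, n_live = as.integer(n_live),
                 n_runs = config$n_runs, dt = dt, record_dt = rec_dt,
                 seed = config$seed, params = params,
                 ca = if (transient) ca else NULL,
                 ca_const = if (transient) NA_real_ else ca,
                 reset_at = if (reset_rec > 0) reset_rec * rec_dt else NULL,
                 avg_start_time = times[avg_start + 1L]),
            class = "filament_trajectory")
}

#' @method print filament_trajectory
#' @export
print.filament_trajectory <- function(x, ...) {
  cat(sprintf("Filament trajectory: %d live RUs, %d runs, %.0f ms (dt = %.4g ms)\n",
              x$n_live, x$n_runs, max(x$times), x$dt))
  if (!is.na(x$ca_const))
    cat(sprintf("  constant [Ca] = %.4g uM (pCa %.2f)\n", x$ca_const,
                6 - log10(x$ca_const)))
  else
    cat("  calcium-transient driven\n")
  if (!is.null(x$reset_at))
    cat(sprintf("  M->C reset at %.0f ms\n", x$reset_at))
  n <- length(x$force)
  cat(sprintf("  final force = %.4f +/- %.4f\n", x$force[n], x$force_sem[n]))
  invisible(x)
}

#' @export
plot.filament_trajectory <- function(x, ...) {
  graphics::plot(x$times, x$force, type = "l", xlab = "time (ms)",
                 ylab = "force (M-state fraction)", ...)
  graphics::lines(x$times, x$force + 2 * x$force_sem, lty = 3)
  graphics::lines(x$times, pmax(0, x$force - 2 * x$force_sem), lty = 3)
  invisible(x)
}

#' Single synchronous Monte Carlo step (reference implementation)
#'
#' Plain-R synchronous update used as a small-scale reference for the
#' compiled engine: every live unit independently transitions with
#' probability rate*dt per allowed move, all using the pre-step
#' configuration; a single uniform draw per unit is partitioned among the
#' moves, the remainder meaning "stay".
#'
#' @param states integer vector of state indices (1..6, ordering B0, B1,
#'   C0, C1, M0, M1) of length n_live + 2 including the two boundary dummy
#'   units, which must be and remain in state 1 (B0).
#' @param params a [tm_params()] object.
#' @param ca calcium concentration (uM).
#' @param dt time step (ms); must keep every cumulative transition
#'   probability <= 1.
#' @return Updated state vector.
#' @export
step_filament <- function(states, params, ca, dt) {
  n <- length(states)
  if (n < 3) stop("states must include two boundary units")
  if (states[1] != 1L || states[n] != 1L)
    stop("boundary units must be in state B0")
  tabs <- vector("list", 9L)
  for (xi in 1:3) for (yi in 1:3) {
    Q <- ru_rate_table(TM_LEVELS[xi], TM_LEVELS[yi], params, ca)
    diag(Q) <- 0
    tabs[[(xi - 1L) * 3L + yi]] <- Q
  }
  out <- states
  u <- stats::runif(n - 2L)
  for (i in 2:(n - 1L)) {
    xl <- TM_OF_STATE[states[i - 1L]]
    yr <- TM_OF_STATE[states[i + 1L]]
    p <- tabs[[(xl - 1L) * 3L + yr]][states[i], ] * dt
    tot <- sum(p)
    if (tot > 1) stop("time-step violation: cumulative probability ", tot)
    cum <- cumsum(p)
    hit <- which(u[i - 1L] <= cum)
    if (length(hit)) out[i] <- hit[1L]
  }
  out
}
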