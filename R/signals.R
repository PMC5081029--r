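#' Calcium transient container
#'
#' @param times time grid in ms, strictly increasing.
#' @param ca calcium concentration in uM, non-negative, same length.
#' @return An object of class `calcium_transient`.
#' @export
calcium_transient <- function(times, ca) {
  if (length(times) != length(ca) || length(times) < 2)
    stop("times and ca must be equal-length vectors (>= 2 points)")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(ca < 0)) stop("ca must be non-negative everywhere")
  structure(list(times = as.numeric(times), ca = as.numeric(ca)),
            class = "calcium_transient")
}

#' @method print calcium_transient
#' @export
print.calcium_transient <- function(x, ...) {
  cat(sprintf(
    "Calcium transient: %d points over %.0f ms, %.3g-%.3g uM (peak at %.0f ms)\n",
    length(x$times), max(x$times) - min(x$times), min(x$ca), max(x$ca),
    x$times[which.max(x$ca)]))
  invisible(x)
}

#' @export
plot.calcium_transient <- function(x, ...) {
  graphics::plot(x$times, x$ca, type = "l", xlab = "time (ms)",
                 ylab = "[Ca] (uM)", ...)
  invisible(x)
}

#' Synthetic intracellular calcium transient
#'
#' Generates a physiologically shaped stand-in for a measured intracellular
#' calcium transient: a double-exponential pulse
#' ca(t) = ca_diastolic + A (exp(-t/tau_decay) - exp(-t/tau_rise)) riding on
#' the diastolic level.  The rise time constant is solved so that the
#' maximum falls exactly at `t_peak`, and the amplitude A is scaled so the
#' maximum equals `ca_peak`.  This is a stand-in, not a digitized
#' experimental record; mutant-versus-wild-type twitch comparisons are made
#' under one identical transient, which is all they require.
#'
#' @param ca_diastolic resting calcium (uM), default 0.1.
#' @param ca_peak peak calcium (uM), default 1.0; must be >= `ca_diastolic`.
#' @param t_peak time of the peak (ms), default 30; must be smaller than
#'   `tau_decay`.
#' @param tau_decay decay time constant (ms), default 150.
#' @param duration length of the trace (ms), default 1000.
#' @param dt sample spacing (ms), default 1.
#' @return A [calcium_transient()].
#' @export
make_transient <- function(ca_diastolic = 0.1, ca_peak = 1.0, t_peak = 30,
                           tau_decay = 150, duration = 1000, dt = 1) {
  if (ca_peak < ca_diastolic || ca_diastolic < 0)
    stop("need ca_peak >= ca_diastolic >= 0")
  if (t_peak <= 0 || t_peak >= duration)
    stop("t_peak must lie inside (0, duration)")
  times <- seq(0, duration, by = dt)
  if (ca_peak == ca_diastolic)
    return(calcium_transient(times, rep(ca_diastolic, length(times))))
  if (t_peak >= tau_decay)
    stop("unsatisfiable transient spec: t_peak must be < tau_decay for a ",
         "double-exponential pulse")
  # peak location of exp(-t/td) - exp(-t/tr) is log(td/tr)*tr*td/(td-tr)
  peak_time <- function(tr) log(tau_decay / tr) * tr * tau_decay /
    (tau_decay - tr)
  tr <- stats::uniroot(function(tr) peak_time(tr) - t_peak,
                       lower = tau_decay * 1e-8,
                       upper = tau_decay * (1 - 1e-8), tol = 1e-12)$root
  shape <- function(t) exp(-t / tau_decay) - exp(-t / tr)
  A <- (ca_peak - ca_diastolic) / shape(t_peak)
  calcium_transient(times, ca_diastolic + A * pmax(0, shape(times)))
}
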