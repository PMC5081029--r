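#' Convert between pCa and micromolar calcium concentration
#'
#' pCa is -log10 of the molar concentration; concentrations in this package
#' are carried in uM (matching the units of the calcium association rate),
#' so ca = 10^(6 - pCa).
#'
#' @param pca pCa value(s).
#' @param ca concentration(s) in uM.
#' @return Concentration in uM, or pCa.
#' @export
pca_to_ca <- function(pca) 10^(6 - pca)

#' @rdname pca_to_ca
#' @export
ca_to_pca <- function(ca) 6 - log10(ca)

new_force_pca_curve <- function(pca, force, sem, params, n_runs) {
  structure(list(pca = as.numeric(pca), force = as.numeric(force),
                 force_sem = as.numeric(sem), params_used = params,
                 n_runs = n_runs),
            class = "force_pca_curve")
}

#' Steady-state force at one calcium concentration
#'
#' Runs the filament to steady state at a constant calcium concentration
#' and averages the final portion of each replicate trace (by default the
#' final quarter of a 7500 ms activation).  The returned standard error is
#' the between-run SEM of the window means.  A drift check compares the two
#' halves of the averaging window and warns when the trace has visibly not
#' settled.
#'
#' @param pca pCa of the activating solution (between 4 and 9).
#' @param params a [tm_params()] object.
#' @param config a [sim_config()] object.
#' @param n_live number of live regulatory units.
#' @return List with `force`, `sem`, `n_runs` and the underlying
#'   `trajectory`.
#' @export
steady_force <- function(pca, params, config = sim_config(), n_live = 24) {
  if (pca < 4 || pca > 9) stop("pca must lie in [4, 9]")
  traj <- simulate_filament(params, pca_to_ca(pca), config, n_live = n_live)
  drift_check(traj)
  m <- traj$run_means
  list(force = mean(m),
       sem = if (length(m) > 1) stats::sd(m) / sqrt(length(m)) else NA_real_,
       n_runs = length(m), trajectory = traj)
}

drift_check <- function(traj) {
  sel <- traj$times >= traj$avg_start_time
  f <- traj$force[sel]; s <- traj$force_sem[sel]
  n <- length(f)
  if (n < 8 || all(is.na(s))) return(invisible(FALSE))
  h1 <- mean(f[seq_len(n %/% 2)])
  h2 <- mean(f[(n %/% 2 + 1):n])
  tol <- 3 * mean(s)  # conservative: time samples are autocorrelated
  drifted <- abs(h2 - h1) > max(tol, 1e-3)
  if (drifted)
    warning("steady-state window may not have converged: halves differ by ",
            signif(abs(h2 - h1), 3))
  invisible(drifted)
}

#' Steady-state force-pCa curve
#'
#' Computes [steady_force()] on a grid of pCa values.  Each grid point uses
#' its own deterministic seed substream derived from `config$seed`.
#'
#' @param pca_grid numeric vector of pCa values (>= 2 points).
#' @param params a [tm_params()] object.
#' @param config a [sim_config()] object.
#' @param n_live number of live regulatory units.
#' @param normalize if `TRUE`, scale the curve to its own maximum
#'   (relative force).
#' @return A `force_pca_curve` object.
#' @export
force_pca_curve <- function(pca_grid, params, config = sim_config(),
                            n_live = 24, normalize = FALSE) {
  if (length(pca_grid) < 2) stop("pca_grid needs at least two points")
  res <- lapply(seq_along(pca_grid), function(i) {
    cfg <- config
    cfg$seed <- config$seed + 1000 * i
    steady_force(pca_grid[i], params, cfg, n_live = n_live)[c("force", "sem")]
  })
  force <- vapply(res, `[[`, numeric(1), "force")
  sem <- vapply(res, `[[`, numeric(1), "sem")
  if (normalize) {
    fmax <- max(force)
    if (fmax <= 0) stop("cannot normalize an all-zero curve")
    force <- force / fmax
    sem <- sem / fmax
  }
  new_force_pca_curve(pca_grid, force, sem, params, config$n_runs)
}

#' @method print force_pca_curve
#' @export
print.force_pca_curve <- function(x, ...) {
  cat(sprintf("Force-pCa curve (%d points%s)\n", length(x$pca),
              if (is.na(x$n_runs)) ", exact" else
                sprintf(", %d runs/point", x$n_runs)))
  df <- data.frame(pCa = x$pca, force = signif(x$force, 4),
                   sem = signif(x$force_sem, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.force_pca_curve <- function(x, ...) {
  graphics::plot(x$pca, x$force, xlim = rev(range(x$pca)), xlab = "pCa",
                 ylab = "force", pch = 16, ...)
  graphics::arrows(x$pca, x$force - x$force_sem, x$pca,
                   x$force + x$force_sem, angle = 90, code = 3,
                   length = 0.02)
  invisible(x)
}

#' @export
as.data.frame.force_pca_curve <- function(x, ...) {
  data.frame(pca = x$pca, force = x$force, force_sem = x$force_sem)
}

#' Rate of force redevelopment (ktr) protocol
#'
#' Reproduces the slack-restretch maneuver in silico: the filament is run
#' to steady force (default 7500 ms), every open unit is instantaneously
#' returned to the closed state (M0 -> C0, M1 -> C1), and the recovery of
#' mean force to its steady level is fitted with a monoexponential
#' F(t) = F_ss (1 - exp(-ktr t)) starting at the reset instant.
#'
#' @param pca pCa of the activating solution.
#' @param params a [tm_params()] object.
#' @param config a [sim_config()] object; `config$duration` is the
#'   pre-reset interval.
#' @param n_live number of live regulatory units.
#' @param post_duration recovery interval simulated after the reset (ms).
#' @return An object of class `ktr_result`: `ktr` (ms^-1), `F_ss`,
#'   `fit_residual` (RMSE of the fit) and the full `trace`.
#' @export
ktr_protocol <- function(pca, params, config = sim_config(), n_live = 24,
                         post_duration = 2500) {
  pre <- config$duration
  cfg <- config
  cfg$duration <- pre + post_duration
  traj <- simulate_filament(params, pca_to_ca(pca), cfg, n_live = n_live,
                            reset_at = pre)
  t_reset <- traj$reset_at
  sel <- traj$times >= t_reset
  tt <- traj$times[sel] - t_reset
  ff <- traj$force[sel]
  if (max(ff) < 1e-3)
    stop("protocol error: no measurable force recovery (steady force ~ 0)")
  fss0 <- mean(ff[tt > 0.75 * max(tt)])
  i63 <- which(ff >= 0.632 * fss0)[1]
  k0 <- if (!is.na(i63) && tt[i63] > 0) 1 / tt[i63] else 1 / max(tt)
  fit <- minpack.lm::nlsLM(ff ~ fss * (1 - exp(-k * tt)),
                           start = list(fss = fss0, k = k0),
                           lower = c(0, 1e-8),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  out <- list(ktr = unname(co["k"]), F_ss = unname(co["fss"]),
              fit_residual = sqrt(mean(stats::resid(fit)^2)),
              pca = pca, trace = traj)
  class(out) <- "ktr_result"
  out
}

#' @method print ktr_result
#' @export
print.ktr_result <- function(x, ...) {
  cat(sprintf("ktr protocol at pCa %.2f: ktr = %.4g ms^-1 (= %.3g s^-1), F_ss = %.4f, fit RMSE = %.2g\n",
              x$pca, x$ktr, 1000 * x$ktr, x$F_ss, x$fit_residual))
  invisible(x)
}

#' Calcium-transient-driven twitch simulation
#'
#' Drives the filament with a time-varying calcium concentration.  A
#' constant diastolic-calcium pad is prepended so that the filament reaches
#' its diastolic steady state before the transient begins; reported times
#' are shifted so the transient onset is t = 0 (the pad occupies negative
#' times), which is what [twitch_metrics()] expects.
#'
#' @param ca_transient a [calcium_transient()]; its first sample is taken
#'   as the diastolic level for the pad.
#' @param params a [tm_params()] object.
#' @param config a [sim_config()] object (duration is taken from the
#'   transient, not from `config`).
#' @param n_live number of live regulatory units.
#' @param pad equilibration time at diastolic calcium before onset (ms).
#' @return A `filament_trajectory` whose times run from `-pad` to the end
#'   of the transient.
#' @export
twitch <- function(ca_transient, params, config = sim_config(),
                   n_live = 24, pad = 500) {
  stopifnot(inherits(ca_transient, "calcium_transient"))
  dia <- ca_transient$ca[1]
  times <- c(0, pad * 0.999, pad + ca_transient$times)
  ca <- c(dia, dia, ca_transient$ca)
  padded <- calcium_transient(times, ca)
  cfg <- config
  cfg$duration <- max(times)
  if (is.null(config$record_dt) || config$record_dt > 2) cfg$record_dt <- 1
  traj <- simulate_filament(params, padded, cfg, n_live = n_live)
  traj$times <- traj$times - pad
  traj$onset <- 0
  traj$pad <- pad
  traj
}
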