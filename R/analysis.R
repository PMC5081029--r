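#' Hill fit of a force-pCa curve, with asymmetric half-curve coefficients
#'
#' Fits F = F_max ca^n / (ca^n + ca50^n) by nonlinear least squares
#' (parameterized in pCa for conditioning: F = F_max / (1 + 10^(n (pCa -
#' pCa50)))).  After the global fit, separate Hill coefficients are fitted
#' to the points below and above half-maximal force with `F_max` and
#' `pCa50` held at their global values, quantifying the asymmetry of the
#' activation curve.
#'
#' When `offset = TRUE` a calcium-independent baseline force F_0 is added
#' to the model (F = F_0 + (F_max - F_0) ca^n / (ca^n + ca50^n)); this is
#' the appropriate form for absolute-tension curves of preparations with
#' constitutive (calcium-free) activation, as in reconstituted-myocardium
#' datasets that report baseline tension.
#'
#' @param curve a `force_pca_curve`, or any list/data.frame with elements
#'   `pca` and `force`.
#' @param offset fit a calcium-independent baseline force as well
#'   (default `FALSE`).
#' @return An object of class `hill_fit` with elements `n_H`, `pCa50`,
#'   `F_max`, `F_0` (0 unless `offset`), `n_H_lower`, `n_H_upper`,
#'   standard errors (`se`), `residual` (fit RMSE) and the data.
#' @examples
#' pca <- seq(6.5, 4.8, by = -0.1)
#' f <- 1 / (1 + 10^(4 * (pca - 5.7)))
#' coef(fit_hill(list(pca = pca, force = f)))
#' @export
fit_hill <- function(curve, offset = FALSE) {
  pca <- curve$pca
  force <- curve$force
  if (length(pca) < 5)
    stop("fit-domain error: need at least 5 points for a Hill fit")
  if (any(!is.finite(pca)) || any(!is.finite(force)))
    stop("non-finite values in curve")
  fmax0 <- max(force)
  if (fmax0 <= 0) stop("fit-domain error: curve has no positive force")
  half0 <- (fmax0 + if (offset) min(force) else 0) / 2
  if (min(force) > half0 || max(force) < half0)
    stop("fit-domain error: curve does not cross half-maximal force")
  pca50_0 <- pca[which.min(abs(force - half0))]
  if (offset) {
    fit <- minpack.lm::nlsLM(
      force ~ f0 + (fmax - f0) / (1 + 10^(n * (pca - pca50))),
      start = list(f0 = min(force), fmax = fmax0, n = 2, pca50 = pca50_0),
      lower = c(0, 1e-12, 0.05, min(pca)),
      upper = c(Inf, Inf, 50, max(pca)),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    fit <- minpack.lm::nlsLM(
      force ~ fmax / (1 + 10^(n * (pca - pca50))),
      start = list(fmax = fmax0, n = 2, pca50 = pca50_0),
      lower = c(1e-12, 0.05, min(pca)), upper = c(Inf, 50, max(pca)),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  co <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  fmax <- unname(co["fmax"]); pca50 <- unname(co["pca50"])
  f0 <- if (offset) unname(co["f0"]) else 0
  half <- f0 + (fmax - f0) / 2

  half_fit <- function(sel) {
    if (sum(sel) < 2) return(c(n = NA_real_, se = NA_real_))
    p <- pca[sel]; f <- force[sel]
    hf <- try(minpack.lm::nlsLM(
      f ~ f0 + (fmax - f0) / (1 + 10^(n * (p - pca50))),
      start = list(n = unname(co["n"])), lower = 0.05, upper = 50,
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (inherits(hf, "try-error")) return(c(n = NA_real_, se = NA_real_))
    c(n = unname(stats::coef(hf)["n"]),
      se = unname(summary(hf)$coefficients["n", "Std. Error"]))
  }
  lower <- half_fit(force <= half)   # low-force limb (high pCa side)
  upper <- half_fit(force > half)

  out <- list(n_H = unname(co["n"]), pCa50 = pca50, F_max = fmax, F_0 = f0,
              n_H_lower = unname(lower["n"]), n_H_upper = unname(upper["n"]),
              se = c(n_H = unname(se["n"]), pCa50 = unname(se["pca50"]),
                     F_max = unname(se["fmax"]),
                     n_H_lower = unname(lower["se"]),
                     n_H_upper = unname(upper["se"])),
              residual = sqrt(mean(stats::resid(fit)^2)),
              data = data.frame(pca = pca, force = force),
              fit = fit)
  class(out) <- "hill_fit"
  out
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(n_H = object$n_H, pCa50 = object$pCa50, F_max = object$F_max,
    n_H_lower = object$n_H_lower, n_H_upper = object$n_H_upper)
}

#' @method print hill_fit
#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill fit of force-pCa curve\n")
  cat(sprintf("  n_H   = %.3f (SE %.3f)   pCa50 = %.3f (SE %.3f)   F_max = %.4f\n",
              x$n_H, x$se[["n_H"]], x$pCa50, x$se[["pCa50"]], x$F_max))
  cat(sprintf("  half-curve coefficients: lower %.3f, upper %.3f (fit RMSE %.3g)\n",
              x$n_H_lower, x$n_H_upper, x$residual))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, pca = object$data$pca, ...) {
  object$F_max / (1 + 10^(object$n_H * (pca - object$pCa50)))
}

#' @export
plot.hill_fit <- function(x, ...) {
  graphics::plot(x$data$pca, x$data$force, xlim = rev(range(x$data$pca)),
                 xlab = "pCa", ylab = "force", pch = 16, ...)
  grid <- seq(max(x$data$pca), min(x$data$pca), length.out = 200)
  graphics::lines(grid, predict(x, grid))
  invisible(x)
}

#' Kinetic and mechanical metrics of a simulated twitch
#'
#' @param traj a `filament_trajectory` from [twitch()], or any list with
#'   `times` and `force`; the transient onset is time 0, with any
#'   pre-onset pad at negative times.
#' @param onset onset time (default 0).
#' @return An object of class `twitch_metrics`: `peak_force`,
#'   `diastolic_force`, `diastolic_fraction`, `ttp` (time to peak, ms),
#'   `rt50` (time from peak to 50% relaxation, ms; `NA` with a warning if
#'   the trace never relaxes that far) and `tension_time_integral`
#'   (force x ms, trapezoidal, from onset to the end of the record).
#' @export
twitch_metrics <- function(traj, onset = 0) {
  t <- traj$times
  f <- traj$force
  if (length(t) < 3 || length(t) != length(f))
    stop("need a trace with matching times and force")
  if (max(f) - min(f) < .Machine$double.eps^0.5)
    stop("metric error: constant trace has no twitch")
  pre <- t < onset
  dia <- if (any(pre)) mean(f[pre & t >= onset - (onset - min(t)) / 2])
         else f[1]
  post_t <- t[t >= onset]; post_f <- f[t >= onset]
  ipk <- which.max(post_f)
  peak <- post_f[ipk]
  ttp <- post_t[ipk] - onset
  if (peak <= dia) stop("metric error: no peak above the diastolic level")
  half <- dia + 0.5 * (peak - dia)
  rt50 <- NA_real_
  after <- seq_along(post_t) > ipk
  cross <- which(after & post_f <= half)
  if (length(cross)) {
    j <- cross[1]
    # linear interpolation between the bracketing samples
    t1 <- post_t[j - 1]; t2 <- post_t[j]
    f1 <- post_f[j - 1]; f2 <- post_f[j]
    tc <- if (f1 == f2) t2 else t1 + (f1 - half) / (f1 - f2) * (t2 - t1)
    rt50 <- tc - post_t[ipk]
  } else {
    warning("trace never relaxes to 50%; rt50 is NA")
  }
  n <- length(post_t)
  tti <- sum(diff(post_t) * (post_f[-1] + post_f[-n]) / 2)
  out <- list(peak_force = peak, diastolic_force = dia,
              diastolic_fraction = dia / peak, ttp = ttp, rt50 = rt50,
              tension_time_integral = tti)
  class(out) <- "twitch_metrics"
  out
}

#' @method print twitch_metrics
#' @export
print.twitch_metrics <- function(x, ...) {
  cat(sprintf(
    "Twitch metrics: peak %.4f, diastolic %.4f (fraction %.3f)\n  TTP %.1f ms, RT50 %.1f ms, TTI %.2f force*ms\n",
    x$peak_force, x$diastolic_force, x$diastolic_fraction, x$ttp, x$rt50,
    x$tension_time_integral))
  invisible(x)
}

#' Root-mean-square error between a model curve and a data table
#'
#' Interpolates the model curve onto the data's pCa points (linear in pCa)
#' and returns the RMSE of the force differences.  Forces are compared on
#' the scale supplied: absolute tensions when the data are absolute (as in
#' reconstituted-myocardium datasets that report calcium-free baseline
#' tension), normalized otherwise.
#'
#' @param model_curve a `force_pca_curve` (or list with `pca`, `force`).
#' @param data a data.frame with columns `pca` and `force`.
#' @return RMSE (same units as force).
#' @export
rmse_curve <- function(model_curve, data) {
  if (!all(c("pca", "force") %in% names(data)))
    stop("data must have columns 'pca' and 'force'")
  rng <- range(model_curve$pca)
  if (min(data$pca) > rng[2] || max(data$pca) < rng[1])
    stop("data pCa range is disjoint from the model curve")
  m <- stats::approx(model_curve$pca, model_curve$force, xout = data$pca,
                     rule = 2)$y
  sqrt(mean((m - data$force)^2))
}
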