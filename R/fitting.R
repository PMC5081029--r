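#' Constrained particle swarm optimization
#'
#' Minimal, deterministic particle swarm minimizer with reflecting bounds:
#' a particle that would leave the box is placed back inside at the
#' reflected position with its velocity component reversed, so bound-
#' violating candidates are never evaluated.
#'
#' @param fn objective function of a numeric vector.
#' @param lower,upper finite bound vectors.
#' @param control list: `swarm` (default 30), `maxit` (default 100),
#'   `seed` (default 1), inertia `w` (0.7298) and acceleration `c1`, `c2`
#'   (1.496 each).
#' @return List with `par`, `value`, `trace` (best value per iteration)
#'   and `n_eval`.
#' @export
pso_optim <- function(fn, lower, upper,
                      control = list()) {
  ctl <- utils::modifyList(list(swarm = 30L, maxit = 100L, seed = 1L,
                                w = 0.7298, c1 = 1.496, c2 = 1.496),
                           control)
  d <- length(lower)
  if (length(upper) != d || any(!is.finite(c(lower, upper))) ||
      any(upper <= lower))
    stop("bounds must be finite with upper > lower")
  set.seed(ctl$seed)
  ns <- ctl$swarm
  span <- upper - lower
  X <- matrix(stats::runif(ns * d), ns, d) * rep(span, each = ns) +
    rep(lower, each = ns)
  V <- (matrix(stats::runif(ns * d), ns, d) - 0.5) *
    rep(span, each = ns) * 0.5
  reflect <- function(x, v) {
    for (j in seq_len(d)) {
      if (x[j] < lower[j]) { x[j] <- min(upper[j], 2 * lower[j] - x[j]); v[j] <- -v[j] }
      if (x[j] > upper[j]) { x[j] <- max(lower[j], 2 * upper[j] - x[j]); v[j] <- -v[j] }
      x[j] <- min(max(x[j], lower[j]), upper[j])
    }
    list(x = x, v = v)
  }
  pbest <- X
  pval <- apply(X, 1, fn)
  n_eval <- ns
  g <- which.min(pval)
  gbest <- X[g, ]; gval <- pval[g]
  trace <- numeric(ctl$maxit)
  for (it in seq_len(ctl$maxit)) {
    r1 <- matrix(stats::runif(ns * d), ns, d)
    r2 <- matrix(stats::runif(ns * d), ns, d)
    V <- ctl$w * V + ctl$c1 * r1 * (pbest - X) +
      ctl$c2 * r2 * (matrix(gbest, ns, d, byrow = TRUE) - X)
    X <- X + V
    for (i in seq_len(ns)) {
      rf <- reflect(X[i, ], V[i, ])
      X[i, ] <- rf$x; V[i, ] <- rf$v
      v <- fn(X[i, ])
      n_eval <- n_eval + 1L
      if (v < pval[i]) { pval[i] <- v; pbest[i, ] <- X[i, ] }
      if (v < gval) { gval <- v; gbest <- X[i, ] }
    }
    trace[it] <- gval
  }
  list(par = gbest, value = gval, trace = trace, n_eval = n_eval)
}

# replace named free parameters in a tm_params object, revalidating
set_free_params <- function(base, free, values) {
  p <- unclass(base)
  p[free] <- as.list(values)
  class(p) <- "tm_params"
  validate_params(p)
  p
}

#' Fit model parameters to a force-pCa dataset
#'
#' Global optimization (particle swarm, reflecting bounds) of a named
#' subset of model parameters against a steady-state force-pCa data table.
#' The objective is the RMSE between the simulated curve on the data's pCa
#' grid and the data forces.  With `engine = "exact"` the curve comes from
#' the master-equation stationary solution of a short filament (cheap,
#' noise-free, useful for parameter-recovery studies); with
#' `engine = "mc"` it comes from the full stochastic filament with a fixed
#' engine seed, making the objective deterministic.
#'
#' @param data data.frame with columns `pca` and `force`.
#' @param base_params a [tm_params()] object supplying all fixed
#'   parameters.
#' @param free character vector naming the free parameters (among
#'   `gamma`, `K_BC`, `k_BC_ref`, `f_ref`, `delta`, `lam`, `k_Ca_on`,
#'   `k_Ca_off`).
#' @param lower,upper bound vectors, one entry per free parameter.
#' @param engine `"exact"` or `"mc"`.
#' @param n_live filament size for the chosen engine.
#' @param config a [sim_config()] (MC engine only).
#' @param control optimizer control list, see [pso_optim()].
#' @return List with `params` (best-fit [tm_params()]), `value` (RMSE),
#'   `free`, `trace` and `n_eval`.
#' @export
fit_parameters <- function(data, base_params, free, lower, upper,
                           engine = c("exact", "mc"), n_live = 3,
                           config = sim_config(n_runs = 50, duration = 3000),
                           control = list()) {
  engine <- match.arg(engine)
  if (length(free) < 1) stop("free parameter set must be non-empty")
  if (length(lower) != length(free) || length(upper) != length(free))
    stop("bounds must match the free parameter set")
  objective <- function(x) {
    p <- try(set_free_params(base_params, free, x), silent = TRUE)
    if (inherits(p, "try-error")) return(1e6)
    curve <- if (engine == "exact") {
      exact_force_pca(data$pca, p, n_live = n_live)
    } else {
      force_pca_curve(data$pca, p, config, n_live = n_live)
    }
    rmse_curve(curve, data)
  }
  opt <- pso_optim(objective, lower, upper, control)
  list(params = set_free_params(base_params, free, opt$par),
       value = opt$value, free = opt$par, trace = opt$trace,
       n_eval = opt$n_eval)
}

#' Grid-search error surface over K_BC and duty-cycle scales
#'
#' Characterizes a tropomyosin mutation whose stiffness change is known a
#' priori: the baseline stiffness is scaled by `stiffness_scale`, then the
#' blocked-closed equilibrium constant and the crossbridge duty cycle are
#' varied over multiplicative grids and the RMSE between the simulated
#' force-pCa curve and the mutant dataset is computed at every grid point.
#'
#' @param baseline wild-type [tm_params()].
#' @param stiffness_scale multiplicative factor applied to gamma before the
#'   sweep (e.g. 0.60 for a 40% stiffness reduction).
#' @param data mutant data.frame with columns `pca` and `force`.
#' @param kbc_scales,delta_scales multiplicative grids (defaults
#'   0.70-1.30 in steps of 0.05).
#' @param engine,n_live,config as in [fit_parameters()].
#' @return An object of class `error_surface`: the RMSE matrix (rows =
#'   `kbc_scales`, columns = `delta_scales`), the argmin scales, and the
#'   fraction of grid cells within 5% of the minimum RMSE (a shallowness
#'   diagnostic of the valley around the optimum).
#' @export
grid_search_kbc_delta <- function(baseline, stiffness_scale, data,
                                  kbc_scales = seq(0.70, 1.30, by = 0.05),
                                  delta_scales = seq(0.70, 1.30, by = 0.05),
                                  engine = c("mc", "exact"), n_live = 24,
                                  config = sim_config()) {
  engine <- match.arg(engine)
  if (!length(kbc_scales) || !length(delta_scales))
    stop("scale grids must be non-empty")
  rmse <- matrix(NA_real_, length(kbc_scales), length(delta_scales),
                 dimnames = list(kbc = signif(kbc_scales, 4),
                                 delta = signif(delta_scales, 4)))
  for (i in seq_along(kbc_scales)) {
    for (j in seq_along(delta_scales)) {
      sc <- mutation_scenario(stiffness_scale, kbc_scales[i],
                              delta_scales[j])
      p <- try(apply_mutation(baseline, sc), silent = TRUE)
      if (inherits(p, "try-error")) next  # e.g. delta scaled past 1
      curve <- if (engine == "exact") {
        exact_force_pca(data$pca, p, n_live = n_live)
      } else {
        force_pca_curve(data$pca, p, config, n_live = n_live)
      }
      rmse[i, j] <- rmse_curve(curve, data)
    }
  }
  amin <- which(rmse == min(rmse, na.rm = TRUE), arr.ind = TRUE)[1, ]
  out <- list(kbc_scales = kbc_scales, delta_scales = delta_scales,
              rmse = rmse,
              argmin = c(kbc_scale = kbc_scales[amin[1]],
                         delta_scale = delta_scales[amin[2]]),
              min_rmse = min(rmse, na.rm = TRUE),
              shallow_fraction = mean(rmse <= 1.05 *
                                        min(rmse, na.rm = TRUE),
                                      na.rm = TRUE),
              stiffness_scale = stiffness_scale)
  class(out) <- "error_surface"
  out
}

#' @method print error_surface
#' @export
print.error_surface <- function(x, ...) {
  cat(sprintf("RMSE surface over K_BC x delta scales (stiffness x %g)\n",
              x$stiffness_scale))
  cat(sprintf("  argmin: K_BC x %g, delta x %g (RMSE %.4g)\n",
              x$argmin[["kbc_scale"]], x$argmin[["delta_scale"]],
              x$min_rmse))
  cat(sprintf("  %.0f%% of grid cells lie within 5%% of the minimum\n",
              100 * x$shallow_fraction))
  invisible(x)
}

#' @export
plot.error_surface <- function(x, ...) {
  graphics::image(x$kbc_scales, x$delta_scales, x$rmse,
                  xlab = "K_BC scale", ylab = "duty-cycle scale",
                  main = "RMSE", ...)
  graphics::points(x$argmin[["kbc_scale"]], x$argmin[["delta_scale"]],
                   pch = 4, cex = 2)
  invisible(x)
}

#' @export
as.data.frame.error_surface <- function(x, ...) {
  data.frame(kbc_scale = rep(x$kbc_scales, times = length(x$delta_scales)),
             delta_scale = rep(x$delta_scales, each = length(x$kbc_scales)),
             rmse = as.vector(x$rmse))
}
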