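# Exact continuous-time master equation over the full 6^N configuration
# space of a short filament with fixed B0 boundary units.  Used as an
# independent oracle for the Monte Carlo engine; never for the production
# 24-unit filament.

# enumerate configurations as integers 0..6^n-1, RU i state = digit i (base 6)
config_states <- function(idx, n_live) {
  s <- integer(n_live)
  for (i in seq_len(n_live)) {
    s[i] <- idx %% 6L
    idx <- idx %/% 6L
  }
  s + 1L  # 1-based state index into RU_STATES
}

#' Build the exact generator of a small filament
#'
#' Constructs the 6^n x 6^n continuous-time generator over all
#' configurations of `n_live` regulatory units flanked by permanently
#' blocked, calcium-free boundary units.  A transition connects two
#' configurations only when exactly one RU changes by one allowed move; its
#' rate comes from [ru_rate_table()] evaluated with that RU's neighbor
#' context in the source configuration.
#'
#' @param n_live number of live regulatory units (<= 6; the state space is
#'   6^n).
#' @param params a [tm_params()] object.
#' @param ca calcium concentration (uM).
#' @return An object of class `lattice_generator`: list with `Q` (dense
#'   matrix for n <= 4, a sparse `Matrix` beyond), `n_live`, `params`, `ca`.
#' @export
build_generator <- function(n_live, params, ca) {
  validate_params(params)
  if (n_live < 1 || n_live > 6)
    stop("n_live must be between 1 and 6 (state space grows as 6^n)")
  n_live <- as.integer(n_live)
  nconf <- 6L^n_live
  # 6x6 single-RU rate tables for all 9 contexts
  tabs <- vector("list", 9L)
  for (xi in 1:3) for (yi in 1:3)
    tabs[[(xi - 1L) * 3L + yi]] <-
      ru_rate_table(TM_LEVELS[xi], TM_LEVELS[yi], params, ca)
  dense <- n_live <= 4L
  if (dense) {
    Q <- matrix(0, nconf, nconf)
  } else {
    cap <- nconf * n_live * 5L
    ii <- integer(cap); jj <- integer(cap); vv <- numeric(cap)
    ntrip <- 0L
  }
  pow6 <- 6L^(seq_len(n_live) - 1L)
  for (cfg in 0:(nconf - 1L)) {
    s <- config_states(cfg, n_live)
    tm <- TM_OF_STATE[s]
    for (i in seq_len(n_live)) {
      xl <- if (i == 1L) 1L else tm[i - 1L]          # boundary is B
      yr <- if (i == n_live) 1L else tm[i + 1L]
      tab <- tabs[[(xl - 1L) * 3L + yr]]
      from <- s[i]
      for (to in 1:6) {
        rate <- tab[from, to]
        if (to == from || rate <= 0) next
        cfg2 <- cfg + (to - from) * pow6[i]
        if (dense) {
          Q[cfg + 1L, cfg2 + 1L] <- Q[cfg + 1L, cfg2 + 1L] + rate
        } else {
          ntrip <- ntrip + 1L
          ii[ntrip] <- cfg + 1L; jj[ntrip] <- cfg2 + 1L; vv[ntrip] <- rate
        }
      }
    }
  }
  if (!dense) {
    keep <- seq_len(ntrip)
    Q <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = vv[keep],
                              dims = c(nconf, nconf))
  }
  diag(Q) <- 0
  diag(Q) <- -Matrix::rowSums(Q)
  out <- list(Q = Q, n_live = n_live, params = params, ca = ca)
  class(out) <- "lattice_generator"
  out
}

#' Stationary distribution of a lattice generator
#'
#' Solves pi Q = 0 with sum(pi) = 1 by replacing one equation of the
#' transposed system with the normalization constraint.  When some
#' configurations are unreachable (e.g. `lam = 0` leaves calcium-free
#' closed/open states without inflow) their stationary mass is zero and the
#' solve still returns the unique distribution on the recurrent class.
#'
#' @param gen a [build_generator()] result.
#' @return Numeric probability vector over all 6^n configurations.
#' @export
stationary_distribution <- function(gen) {
  stopifnot(inherits(gen, "lattice_generator"))
  n <- nrow(gen$Q)
  A <- Matrix::t(gen$Q)
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  pi <- as.numeric(Matrix::solve(A, b))
  pi[pi < 0 & pi > -1e-12] <- 0
  if (any(pi < 0))
    stop("stationary solve produced negative probabilities; ",
         "generator may be reducible in an unexpected way")
  pi / sum(pi)
}

#' Transient solution of the master equation
#'
#' @param gen a [build_generator()] result.
#' @param p0 initial probability vector over configurations.
#' @param t time (ms), >= 0.
#' @return Probability vector at time `t`: p0 expm(Q t).
#' @export
transient_distribution <- function(gen, p0, t) {
  stopifnot(inherits(gen, "lattice_generator"))
  if (t < 0) stop("t must be >= 0")
  if (length(p0) != nrow(gen$Q) || abs(sum(p0) - 1) > 1e-8)
    stop("p0 must be a probability vector over all configurations")
  if (t == 0) return(p0)
  E <- Matrix::expm(Matrix::Matrix(t * gen$Q))
  as.numeric(Matrix::t(E) %*% p0)
}

#' Expected force (M-state fraction) under a configuration distribution
#'
#' @param gen a [build_generator()] result.
#' @param p probability vector over configurations (defaults to the
#'   stationary distribution).
#' @return Expected fraction of live RUs in M0 or M1.
#' @export
expected_force <- function(gen, p = stationary_distribution(gen)) {
  stopifnot(inherits(gen, "lattice_generator"))
  nconf <- nrow(gen$Q)
  mfrac <- vapply(0:(nconf - 1L), function(cfg) {
    s <- config_states(cfg, gen$n_live)
    mean(TM_OF_STATE[s] == 3L)
  }, numeric(1))
  sum(p * mfrac)
}

# index (0-based config code) of the all-B0 configuration
all_b0_config <- function(n_live) 0L

# initial distribution concentrated on all-B0
initial_b0_distribution <- function(gen) {
  p0 <- numeric(nrow(gen$Q))
  p0[all_b0_config(gen$n_live) + 1L] <- 1
  p0
}

#' Exact steady-state force-pCa curve for a small filament
#'
#' Convenience wrapper: builds the generator and stationary distribution at
#' each pCa and returns the expected M-fraction.  Exact (no sampling error);
#' feasible only for `n_live <= 6`.
#'
#' @param pca_grid numeric vector of pCa values.
#' @param params a [tm_params()] object.
#' @param n_live number of live RUs (default 1).
#' @return A `force_pca_curve` object with zero SEM.
#' @export
exact_force_pca <- function(pca_grid, params, n_live = 1) {
  force <- vapply(pca_grid, function(pca) {
    gen <- build_generator(n_live, params, pca_to_ca(pca))
    expected_force(gen)
  }, numeric(1))
  new_force_pca_curve(pca_grid, force, rep(0, length(pca_grid)), params,
                      n_runs = NA_integer_)
}
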