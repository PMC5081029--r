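# State bookkeeping used across the package.
# Six RU states, ordered B0, B1, C0, C1, M0, M1 (0 = Ca-free, 1 = Ca-bound).
# The tropomyosin level of a state collapses calcium occupancy: B, C or M.
RU_STATES <- c("B0", "B1", "C0", "C1", "M0", "M1")
TM_LEVELS <- c("B", "C", "M")
TM_OF_STATE <- c(1L, 1L, 2L, 2L, 3L, 3L)  # index into TM_LEVELS

tm_level_index <- function(x) {
  i <- match(x, TM_LEVELS)
  if (anyNA(i)) stop("neighbor state must be one of 'B', 'C', 'M'")
  i
}

well_angle <- function(angles, level_idx) {
  c(angles$phi_B, angles$phi_C, angles$phi_M)[level_idx]
}

#' Tropomyosin chain distortion energy
#'
#' Potential energy stored in the effective torsion spring linking two
#' adjacent tropomyosins whose azimuthal angles differ:
#' U = gamma (phi_a - phi_b)^2 / 2.
#'
#' @param phi_a,phi_b azimuthal angles in radians.
#' @param gamma chain stiffness (kJ mol^-1 rad^-2), >= 0.
#' @return Energy in kJ/mol.
#' @examples
#' distortion_energy(25 * pi / 180, 0, 68)  # ~6.47 kJ/mol
#' @export
distortion_energy <- function(phi_a, phi_b, gamma) {
  if (any(gamma < 0)) stop("gamma must be >= 0")
  0.5 * gamma * (phi_a - phi_b)^2
}

# barrier angle for a tropomyosin move; the barrier is shared by the two
# directions of a transition (phi_BC = phi_CB, phi_CM = phi_MC)
barrier_angle <- function(angles, transition) {
  switch(transition,
         BC = , CB = angles$phi_BC,
         CM = , MC = angles$phi_CM,
         stop("transition must be one of 'BC', 'CB', 'CM', 'MC'"))
}

from_level <- function(transition)
  switch(transition, BC = 1L, CB = 2L, CM = 2L, MC = 3L)

#' Neighbor-dependent scaling of a tropomyosin transition rate
#'
#' Nearest neighbors alter the activation energy of a tropomyosin move in
#' two ways: chain distortion raises the energy well of the current state
#' (lowering the barrier) and raises the transition-state energy at the
#' barrier angle (raising the barrier).  The net multiplicative factor on
#' the reference rate is
#' exp(-(dU_barrier,X - dU_well,X + dU_barrier,Y - dU_well,Y) / RT),
#' where X and Y are the tropomyosin levels of the left and right neighbor.
#'
#' Calcium occupancy of the neighbors is irrelevant: the strain energy
#' depends only on their tropomyosin position.
#'
#' @param transition one of `"BC"`, `"CB"`, `"CM"`, `"MC"` (direct B-M moves
#'   are prohibited).
#' @param X,Y tropomyosin level of the left / right neighbor: `"B"`, `"C"`
#'   or `"M"`.
#' @param params a [tm_params()] object.
#' @return Dimensionless positive scale factor (1 when `gamma = 0`).
#' @examples
#' p <- param_set("set1_skinned")
#' rate_scale("BC", "B", "B", p)  # ~0.285: blocked neighbors retard B -> C
#' rate_scale("BC", "C", "C", p)  # ~43.3: closed neighbors accelerate it
#' @export
rate_scale <- function(transition, X, Y, params) {
  validate_params(params)
  a <- params$angles
  z <- well_angle(a, from_level(transition))
  zb <- barrier_angle(a, transition)
  g <- params$gamma
  de <- 0
  for (n in c(X, Y)) {
    phi_n <- well_angle(a, tm_level_index(n))
    de <- de + distortion_energy(zb, phi_n, g) - distortion_energy(z, phi_n, g)
  }
  exp(-de / params$RT)
}

#' Transition-rate generator for a single regulatory unit
#'
#' Builds the 6x6 continuous-time generator of one regulatory unit given the
#' tropomyosin levels of its two neighbors and a fixed calcium
#' concentration.  Rows/columns are ordered B0, B1, C0, C1, M0, M1.
#'
#' Horizontal (tropomyosin) rates are the reference rates scaled by
#' [rate_scale()]; the calcium-free B0 -> C0 move is additionally multiplied
#' by `lam`.  Vertical rates are `k_Ca_on * ca` for all calcium-binding
#' moves, `k_Ca_off` for B1 -> B0, and `lam * k_Ca_off` for C1 -> C0 and
#' M1 -> M0 (the latter scaling enforces microscopic reversibility around
#' every calcium/tropomyosin cycle).  Direct B-M moves are zero.
#'
#' @param X,Y tropomyosin level of the left / right neighbor (`"B"`, `"C"`,
#'   `"M"`).
#' @param params a [tm_params()] object.
#' @param ca calcium concentration in uM, >= 0.
#' @return A 6x6 matrix with non-negative off-diagonal rates (ms^-1) and
#'   diagonal entries equal to minus the row sums (a proper generator).
#' @export
ru_rate_table <- function(X, Y, params, ca) {
  validate_params(params)
  if (!is.numeric(ca) || length(ca) != 1L || !is.finite(ca) || ca < 0)
    stop("ca must be a single non-negative concentration (uM)")
  r <- derive_rates(params)
  Q <- matrix(0, 6, 6, dimnames = list(RU_STATES, RU_STATES))
  s_BC <- rate_scale("BC", X, Y, params)
  s_CB <- rate_scale("CB", X, Y, params)
  s_CM <- rate_scale("CM", X, Y, params)
  s_MC <- rate_scale("MC", X, Y, params)
  # tropomyosin moves, calcium-free row
  Q["B0", "C0"] <- params$lam * r[["k_BC_ref"]] * s_BC
  Q["C0", "B0"] <- r[["k_CB_ref"]] * s_CB
  Q["C0", "M0"] <- r[["f_ref"]] * s_CM
  Q["M0", "C0"] <- r[["g_ref"]] * s_MC
  # tropomyosin moves, calcium-bound row
  Q["B1", "C1"] <- r[["k_BC_ref"]] * s_BC
  Q["C1", "B1"] <- r[["k_CB_ref"]] * s_CB
  Q["C1", "M1"] <- r[["f_ref"]] * s_CM
  Q["M1", "C1"] <- r[["g_ref"]] * s_MC
  # calcium binding / unbinding (independent of neighbor context)
  Q["B0", "B1"] <- Q["C0", "C1"] <- Q["M0", "M1"] <- r[["k_Ca_on"]] * ca
  Q["B1", "B0"] <- r[["k_Ca_off"]]
  Q["C1", "C0"] <- params$lam * r[["k_Ca_off"]]
  Q["M1", "M0"] <- params$lam * r[["k_Ca_off"]]
  diag(Q) <- -rowSums(Q)
  Q
}

# All nine neighbor contexts as a data.frame (X = left, Y = right)
neighbor_contexts <- function()
  expand.grid(X = TM_LEVELS, Y = TM_LEVELS, KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)

#' Static equilibrium of an elastically jointed cantilevered chain
#'
#' Validation utility for the quadratic energy-angle law underlying the
#' torsion-spring representation of the tropomyosin chain.  A chain of
#' `n_joints` rigid segments (unit length) is cantilevered at one end; each
#' joint (including the clamped base) carries a torsional spring of
#' stiffness `joint_stiffness` resisting the angle change between adjacent
#' segments.  A point load `tip_load` acts at the free tip, orthogonal to
#' the undeformed chain axis.  The equilibrium configuration minimizes total
#' potential energy (elastic energy minus work of the load).
#'
#' In the small-deflection regime the stored elastic energy is proportional
#' to the square of the azimuthal angle subtended at the tip, which is what
#' justifies representing inter-RU coupling with a single linear spring.
#'
#' @param n_joints number of segments/joints (>= 1).
#' @param joint_stiffness torsional stiffness per joint (energy per rad^2).
#' @param tip_load transverse load at the free end (energy per unit length).
#' @return List with `energy` (stored elastic energy), `tip_angle` (tangent
#'   angle of the last segment, radians) and `angles` (all segment angles).
#' @export
jointed_chain_energy <- function(n_joints, joint_stiffness, tip_load) {
  if (n_joints < 1) stop("n_joints must be >= 1")
  if (joint_stiffness <= 0) stop("joint_stiffness must be > 0")
  n <- as.integer(n_joints)
  k <- joint_stiffness
  elastic <- function(theta) 0.5 * k * sum(diff(c(0, theta))^2)
  potential <- function(theta) elastic(theta) - tip_load * sum(sin(theta))
  grad <- function(theta) {
    d <- diff(c(0, theta))
    ge <- k * (d - c(d[-1], 0))
    ge - tip_load * cos(theta)
  }
  fit <- stats::optim(rep(0, n), potential, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  theta <- fit$par
  if (max(abs(theta)) > pi / 2 - 1e-6 || fit$convergence != 0)
    stop("jointed-chain solve failed to converge (load too large for the ",
         "small-deflection regime)")
  list(energy = elastic(theta), tip_angle = theta[n], angles = theta)
}
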