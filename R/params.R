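#' Tropomyosin azimuthal angles
#'
#' Azimuthal positions (in degrees) of tropomyosin on actin for the blocked
#' (B), closed (C) and myosin-bound open (M) regulatory states, taken from
#' structural measurements, together with the barrier angles used for
#' transition-state energies.  The barrier between two wells sits exactly
#' halfway between their angles, so the B-C barrier defaults to 12.5 degrees
#' and the C-M barrier to 30 degrees.
#'
#' Angles are stored internally in radians; the constructor takes degrees
#' because that is how structural data are reported.
#'
#' @param phi_B,phi_C,phi_M well angles in degrees for the B, C and M states.
#' @return An object of class `tm_angles`: a list with elements `phi_B`,
#'   `phi_C`, `phi_M`, `phi_BC`, `phi_CM`, all in radians.
#' @examples
#' a <- tm_angles()
#' a$phi_C / pi * 180  # 25 degrees
#' @export
tm_angles <- function(phi_B = 0, phi_C = 25, phi_M = 35) {
  if (!(phi_B < phi_C && phi_C < phi_M))
    stop("angles must satisfy phi_B < phi_C < phi_M")
  deg <- c(phi_B = phi_B, phi_C = phi_C, phi_M = phi_M)
  rad <- deg * pi / 180
  out <- list(
    phi_B  = unname(rad["phi_B"]),
    phi_C  = unname(rad["phi_C"]),
    phi_M  = unname(rad["phi_M"]),
    phi_BC = unname((rad["phi_B"] + rad["phi_C"]) / 2),
    phi_CM = unname((rad["phi_C"] + rad["phi_M"]) / 2)
  )
  class(out) <- "tm_angles"
  out
}

#' Model parameters for the six-state regulatory-unit model
#'
#' Collects every kinetic and energetic constant of the model.  Rates are in
#' ms^-1, the calcium association rate in uM^-1 ms^-1, the chain stiffness
#' `gamma` in kJ mol^-1 rad^-2 and the thermal energy `RT` in kJ mol^-1.
#'
#' The closed-to-blocked rate and the myosin detachment rate are not free:
#' they follow from the blocked-closed equilibrium constant `K_BC`
#' (k_CB_ref = k_BC_ref / K_BC) and from the crossbridge duty cycle `delta`
#' (g_ref = f_ref * (1 - delta) / delta), the duty cycle being the fraction
#' f/(f+g) of time spent in the force-generating M state under reference
#' (strain-free) conditions.
#'
#' @param gamma effective tropomyosin chain torsional stiffness
#'   (kJ mol^-1 rad^-2).
#' @param K_BC blocked-closed equilibrium constant (dimensionless, > 0).
#' @param k_BC_ref reference blocked-to-closed rate (ms^-1).
#' @param f_ref reference closed-to-open (crossbridge attachment) rate
#'   (ms^-1).
#' @param delta crossbridge duty cycle, in (0, 1).
#' @param lam dimensionless factor (>= 0) coupling troponin calcium occupancy
#'   to tropomyosin movement: the B0 -> C0 rate and the C1 -> C0 / M1 -> M0
#'   calcium dissociation rates are multiplied by `lam`.  `lam = 0` makes
#'   calcium binding obligatory for leaving the blocked state.
#' @param k_Ca_on second-order calcium association rate (uM^-1 ms^-1).
#' @param k_Ca_off calcium dissociation rate (ms^-1).
#' @param RT thermal energy (kJ mol^-1); default 2.577 corresponds to 310 K.
#' @param angles a [tm_angles()] object.
#' @param label optional free-text label.
#' @return An object of class `tm_params`.
#' @seealso [derive_rates()], [apply_mutation()], [param_set()]
#' @examples
#' p <- tm_params(gamma = 68, K_BC = 0.898, k_BC_ref = 1.83,
#'                f_ref = 0.0058, delta = 0.4754, lam = 0,
#'                k_Ca_on = 0.125, k_Ca_off = 0.58)
#' derive_rates(p)
#' @export
tm_params <- function(gamma, K_BC, k_BC_ref, f_ref, delta, lam,
                      k_Ca_on, k_Ca_off, RT = 2.577, angles = tm_angles(),
                      label = "") {
  p <- list(gamma = gamma, K_BC = K_BC, k_BC_ref = k_BC_ref, f_ref = f_ref,
            delta = delta, lam = lam, k_Ca_on = k_Ca_on, k_Ca_off = k_Ca_off,
            RT = RT, angles = angles, label = label)
  class(p) <- "tm_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "tm_params"))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("gamma", "K_BC", "k_BC_ref", "f_ref", "delta", "lam",
              "k_Ca_on", "k_Ca_off", "RT"))
    if (!num1(p[[f]])) stop("parameter '", f, "' must be a finite number")
  if (p$gamma < 0) stop("gamma must be >= 0")
  if (p$K_BC <= 0) stop("K_BC must be > 0")
  if (p$delta <= 0 || p$delta >= 1) stop("delta must lie in (0, 1)")
  if (p$lam < 0) stop("lam must be >= 0")
  if (p$RT <= 0) stop("RT must be > 0")
  for (f in c("k_BC_ref", "f_ref", "k_Ca_on", "k_Ca_off"))
    if (p[[f]] < 0) stop(f, " must be >= 0")
  if (!inherits(p$angles, "tm_angles")) stop("angles must be a tm_angles object")
  invisible(p)
}

#' @method print tm_params
#' @export
print.tm_params <- function(x, ...) {
  cat("Six-state regulatory-unit model parameters",
      if (nzchar(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  r <- derive_rates(x)
  cat(sprintf("  gamma    = %-8.4g kJ/mol/rad^2    K_BC     = %.4g\n",
              x$gamma, x$K_BC))
  cat(sprintf("  k_BC_ref = %-8.4g ms^-1           k_CB_ref = %.4g ms^-1\n",
              r[["k_BC_ref"]], r[["k_CB_ref"]]))
  cat(sprintf("  f_ref    = %-8.4g ms^-1           g_ref    = %.4g ms^-1  (delta = %.4g)\n",
              r[["f_ref"]], r[["g_ref"]], x$delta))
  cat(sprintf("  k_Ca_on  = %-8.4g uM^-1 ms^-1     k_Ca_off = %.4g ms^-1\n",
              x$k_Ca_on, x$k_Ca_off))
  cat(sprintf("  lambda   = %-8.4g                 RT       = %.4g kJ/mol\n",
              x$lam, x$RT))
  ang <- x$angles
  cat(sprintf("  angles (deg): B = %g, C = %g, M = %g (barriers %g, %g)\n",
              ang$phi_B * 180 / pi, ang$phi_C * 180 / pi, ang$phi_M * 180 / pi,
              ang$phi_BC * 180 / pi, ang$phi_CM * 180 / pi))
  invisible(x)
}

#' Reference kinetic rates derived from a parameter set
#'
#' Expands the (K_BC, delta) parameterization into the full table of
#' strain-free reference rates.  The closed-to-blocked rate is
#' k_BC_ref / K_BC and the myosin detachment rate is
#' f_ref (1 - delta) / delta.
#'
#' @param params a [tm_params()] object.
#' @return Named numeric vector with elements `k_BC_ref`, `k_CB_ref`,
#'   `f_ref`, `g_ref`, `k_Ca_on`, `k_Ca_off`.
#' @export
derive_rates <- function(params) {
  validate_params(params)
  c(k_BC_ref = params$k_BC_ref,
    k_CB_ref = params$k_BC_ref / params$K_BC,
    f_ref    = params$f_ref,
    g_ref    = params$f_ref * (1 - params$delta) / params$delta,
    k_Ca_on  = params$k_Ca_on,
    k_Ca_off = params$k_Ca_off)
}

#' Mutation scenarios as multiplicative parameter changes
#'
#' A tropomyosin mutation is represented by multiplicative factors on the
#' chain stiffness, the blocked-closed equilibrium constant and the
#' crossbridge duty cycle.  `mutation_scenario()` builds an arbitrary
#' scenario; `scenario_E180G()` and `scenario_D175N()` return the two
#' HCM-linked scenarios used throughout: E180G is a 25% stiffness decrease
#' with a 10% K_BC increase and 15% duty-cycle increase, D175N a 40%
#' stiffness decrease with a 15% K_BC decrease.
#'
#' @param gamma_scale,K_BC_scale,delta_scale positive multiplicative factors.
#' @param label free-text label.
#' @return An object of class `mutation_scenario`.
#' @export
mutation_scenario <- function(gamma_scale = 1, K_BC_scale = 1,
                              delta_scale = 1, label = "") {
  if (any(c(gamma_scale, K_BC_scale, delta_scale) <= 0))
    stop("scenario factors must be > 0")
  s <- list(gamma_scale = gamma_scale, K_BC_scale = K_BC_scale,
            delta_scale = delta_scale, label = label)
  class(s) <- "mutation_scenario"
  s
}

#' @rdname mutation_scenario
#' @export
scenario_E180G <- function()
  mutation_scenario(0.75, 1.10, 1.15, label = "E180G")

#' @rdname mutation_scenario
#' @export
scenario_D175N <- function()
  mutation_scenario(0.60, 0.85, 1.00, label = "D175N")

#' @method print mutation_scenario
#' @export
print.mutation_scenario <- function(x, ...) {
  cat(sprintf("Mutation scenario%s: gamma x %g, K_BC x %g, delta x %g\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              x$gamma_scale, x$K_BC_scale, x$delta_scale))
  invisible(x)
}

#' Apply a mutation scenario to a parameter set
#'
#' Multiplies gamma, K_BC and delta by the scenario factors, leaving every
#' other field unchanged.  Derived rates (k_CB_ref, g_ref) change implicitly
#' through [derive_rates()].
#'
#' @param params a [tm_params()] object.
#' @param scenario a [mutation_scenario()] object.
#' @return A new `tm_params` object.
#' @export
apply_mutation <- function(params, scenario) {
  validate_params(params)
  stopifnot(inherits(scenario, "mutation_scenario"))
  new_delta <- params$delta * scenario$delta_scale
  if (new_delta >= 1)
    stop("scenario drives duty cycle delta to ", signif(new_delta, 4),
         " >= 1")
  tm_params(gamma = params$gamma * scenario$gamma_scale,
            K_BC = params$K_BC * scenario$K_BC_scale,
            k_BC_ref = params$k_BC_ref,
            f_ref = params$f_ref,
            delta = new_delta,
            lam = params$lam,
            k_Ca_on = params$k_Ca_on,
            k_Ca_off = params$k_Ca_off,
            RT = params$RT,
            angles = params$angles,
            label = if (nzchar(scenario$label))
              paste0(params$label, if (nzchar(params$label)) " + ",
                     scenario$label) else params$label)
}

#' Packaged parameter sets
#'
#' Returns one of the packaged parameter sets, read from the YAML
#' configuration files shipped under `extdata/params`.  Sets 1-3 are
#' wild-type fits (skinned rat trabeculae, reconstituted bovine myocardium,
#' intact rat trabeculae); the mutant variants carry the E180G and D175N
#' changes expressed through the blocked-to-closed reference rate, as in the
#' published parameter table.
#'
#' @param name one of `"set1_skinned"`, `"set2_reconstituted"`,
#'   `"set2_E180G"`, `"set2_D175N"`, `"set3_intact"`, `"set4_intact_E180G"`,
#'   `"set5_intact_D175N"`.
#' @return A [tm_params()] object.
#' @export
param_set <- function(name = c("set1_skinned", "set2_reconstituted",
                               "set2_E180G", "set2_D175N", "set3_intact",
                               "set4_intact_E180G", "set5_intact_D175N")) {
  name <- match.arg(name)
  path <- system.file("extdata", "params", paste0(name, ".yaml"),
                      package = "tmcoop", mustWork = TRUE)
  load_params(path)
}
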