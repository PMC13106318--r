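#' Sheet-normal stretch under incompressible biaxial deformation
#'
#' For an incompressible material stretched along the fiber and sheet axes
#' with traction-free sheet-normal faces, the sheet-normal stretch follows
#' from volume preservation: `lambda_n = 1 / (lambda_f * lambda_s)`.
#'
#' @param lambda_f Fiber-direction stretch (> 0). Vectorized.
#' @param lambda_s Sheet-direction stretch (> 0). Vectorized.
#' @return Sheet-normal stretch.
#' @export
sheet_normal_stretch <- function(lambda_f, lambda_s) {
  if (any(lambda_f <= 0) || any(lambda_s <= 0))
    stop("stretches must be > 0")
  1 / (lambda_f * lambda_s)
}

#' Kinematic state for axis-aligned incompressible biaxial stretch
#'
#' Assembles the deviatoric invariants of the deformation in which the
#' principal stretch axes coincide with the fiber/sheet/sheet-normal frame
#' and no shear is applied: `J = 1`, `I1_bar = lf^2 + ls^2 + ln^2`,
#' `I4f = lf^2`, `I4s = ls^2`, `I8fs = 0`.
#'
#' @inheritParams sheet_normal_stretch
#' @return An object of class `kinematic_state` (a list with fields
#'   `lambda_f`, `lambda_s`, `lambda_n`, `J`, `I1_bar`, `I4f`, `I4s`, `I8fs`).
#' @export
kinematics_from_biaxial <- function(lambda_f, lambda_s) {
  lambda_n <- sheet_normal_stretch(lambda_f, lambda_s)
  structure(list(
    lambda_f = lambda_f, lambda_s = lambda_s, lambda_n = lambda_n, J = 1,
    I1_bar = lambda_f^2 + lambda_s^2 + lambda_n^2,
    I4f = lambda_f^2, I4s = lambda_s^2, I8fs = 0
  ), class = "kinematic_state")
}

#' Strain-energy density breakdown
#'
#' Evaluates each additive term of the passive strain energy at a kinematic
#' state: isotropic matrix, fiber and sheet reinforcement (tension-only: the
#' anisotropic terms contribute only when the corresponding `I4 > 1`),
#' fiber-sheet coupling, and the volumetric penalty
#' `psi_vol = (1/D) * ((J^2 - 1)/2 - log(J))`.
#'
#' @param params A [passive_params()] object.
#' @param state A [kinematics_from_biaxial()] state (or any list with the same
#'   fields).
#' @return A list of class `energy_breakdown` with components `psi_iso`,
#'   `psi_fiber`, `psi_sheet`, `psi_coupling`, `psi_vol`, `psi_total` (MPa).
#' @export
strain_energy <- function(params, state) {
  stopifnot(inherits(params, "passive_params"))
  i4f <- pmax(state$I4f, 1)   # tension-only reinforcement
  i4s <- pmax(state$I4s, 1)
  psi_iso <- params$a / (2 * params$b) * (exp(params$b * (state$I1_bar - 3)) - 1)
  psi_fiber <- params$a_f / (2 * params$b_f) *
    (exp(params$b_f * (i4f - 1)^2) - 1)
  psi_sheet <- params$a_s / (2 * params$b_s) *
    (exp(params$b_s * (i4s - 1)^2) - 1)
  psi_coupling <- params$a_fs / (2 * params$b_fs) *
    (exp(params$b_fs * state$I8fs^2) - 1)
  psi_vol <- 1 / params$D * ((state$J^2 - 1) / 2 - log(state$J))
  out <- list(psi_iso = psi_iso, psi_fiber = psi_fiber, psi_sheet = psi_sheet,
              psi_coupling = psi_coupling, psi_vol = psi_vol)
  out$psi_total <- with(out, psi_iso + psi_fiber + psi_sheet + psi_coupling + psi_vol)
  structure(out, class = "energy_breakdown")
}

#' Closed-form Cauchy stresses under biaxial stretch
#'
#' Analytical fiber- and sheet-direction Cauchy stresses of the passive law
#' under homogeneous, axis-aligned, incompressible biaxial stretch, with the
#' incompressibility pressure eliminated through the traction-free
#' sheet-normal faces:
#' \deqn{\sigma_{ff} = a e^{b(I_1-3)}(\lambda_f^2-\lambda_n^2) +
#'   2 a_f (I_{4f}-1) e^{b_f (I_{4f}-1)^2} \lambda_f^2}
#' and symmetrically for the sheet direction. The anisotropic terms are
#' tension-only (active for `I4 > 1`).
#'
#' @param params A [passive_params()] object.
#' @inheritParams sheet_normal_stretch
#' @return A list of class `stress_pair` with numeric fields `sigma_ff` and
#'   `sigma_ss` (MPa), vectorized over the stretches.
#' @export
cauchy_biaxial <- function(params, lambda_f, lambda_s) {
  stopifnot(inherits(params, "passive_params"))
  st <- kinematics_from_biaxial(lambda_f, lambda_s)
  iso <- params$a * exp(params$b * (st$I1_bar - 3))
  e4f <- pmax(st$I4f - 1, 0)
  e4s <- pmax(st$I4s - 1, 0)
  sigma_ff <- iso * (st$lambda_f^2 - st$lambda_n^2) +
    2 * params$a_f * e4f * exp(params$b_f * e4f^2) * st$lambda_f^2
  sigma_ss <- iso * (st$lambda_s^2 - st$lambda_n^2) +
    2 * params$a_s * e4s * exp(params$b_s * e4s^2) * st$lambda_s^2
  structure(list(sigma_ff = sigma_ff, sigma_ss = sigma_ss),
            class = "stress_pair")
}

#' Finite-difference stress oracle
#'
#' Brute-force check of the closed-form biaxial stresses: the incompressible
#' strain energy is evaluated with the constraint
#' `lambda_n = 1/(lambda_f*lambda_s)` substituted, and the Cauchy stresses
#' are obtained as central differences with respect to the log-stretches.
#' Differentiating the constrained energy in log-stretch automatically
#' subtracts the reaction pressure of the traction-free direction, so the
#' result agrees with [cauchy_biaxial()] to O(h^2).
#'
#' @param params A [passive_params()] object.
#' @inheritParams sheet_normal_stretch
#' @param h Log-stretch perturbation (> 0), default `1e-6`.
#' @return A `stress_pair` list (MPa).
#' @export
numeric_stress_oracle <- function(params, lambda_f, lambda_s, h = 1e-6) {
  stopifnot(inherits(params, "passive_params"))
  if (h <= 0) stop("perturbation h must be > 0")
  psi_hat <- function(lf, ls) {
    strain_energy(params, kinematics_from_biaxial(lf, ls))$psi_total
  }
  d_log <- function(f, x, y) (f(x * exp(h), y) - f(x * exp(-h), y)) / (2 * h)
  sigma_ff <- d_log(psi_hat, lambda_f, lambda_s)
  sigma_ss <- d_log(function(ls, lf) psi_hat(lf, ls), lambda_s, lambda_f)
  structure(list(sigma_ff = sigma_ff, sigma_ss = sigma_ss),
            class = "stress_pair")
}
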