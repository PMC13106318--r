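#' Sarcomere length from fiber strain
#'
#' Current sarcomere length implied by the fiber-direction Green-Lagrange
#' strain: `L = L_r * sqrt(2*E_ff + 1)`.
#'
#' @param E_ff Fiber Green-Lagrange strain (dimensionless). Vectorized.
#' @param L_r Unloaded sarcomere length (um).
#' @return Sarcomere length (um).
#' @export
sarcomere_length <- function(E_ff, L_r) {
  if (any(2 * E_ff + 1 <= 0))
    stop("non-physical compression: 2*E_ff + 1 must be > 0")
  L_r * sqrt(2 * E_ff + 1)
}

#' Length-dependent half-maximal calcium concentration
#'
#' The calcium concentration at which half-maximal tension develops,
#' `ECa50 = Ca0_max / sqrt(exp(B*(L - L_0)) - 1)`, with lengths converted
#' to millimetres (the unit of `B`) internally. ECa50 decreases as the
#' sarcomere lengthens beyond `L_0`, which encodes the Frank-Starling
#' increase in calcium sensitivity. At or below the activation threshold
#' (`L <= L_0`) no finite half-maximal concentration exists and `Inf` is
#' returned, so downstream active stress is zero.
#'
#' @param E_ff Fiber Green-Lagrange strain. Vectorized.
#' @param params An [active_params()] object.
#' @return ECa50 in the units of `Ca0` (Inf below the activation threshold).
#' @export
eca50 <- function(E_ff, params) {
  stopifnot(inherits(params, "active_params"))
  L <- sarcomere_length(E_ff, params$L_r)
  arg <- exp(params$B * um_to_mm(L - params$L_0)) - 1
  out <- rep(Inf, length(arg))
  ok <- arg > 0
  out[ok] <- params$Ca0_max / sqrt(arg[ok])
  out
}

#' Length-dependent relaxation duration
#'
#' Duration of the relaxation phase as an affine function of sarcomere
#' length, `t_r = m*L + b_relax`, with `L` converted to millimetres.
#'
#' @param L Sarcomere length (um). Vectorized.
#' @param params An [active_params()] object.
#' @return Relaxation duration (s).
#' @export
relaxation_duration <- function(L, params) {
  stopifnot(inherits(params, "active_params"))
  if (any(L <= 0)) stop("sarcomere length must be > 0")
  t_r <- params$m * um_to_mm(L) + params$b_relax
  if (any(t_r <= 0))
    stop("relaxation duration t_r must be positive; check m, b_relax, and L")
  t_r
}

#' Activation phase of the twitch waveform
#'
#' Piecewise phase angle of the `1 - cos` activation waveform:
#' `pi*t/t0` during the rise (`0 <= t < t0`), `pi*(t - t0 + t_r)/t_r`
#' during relaxation (`t0 <= t < t0 + t_r`), and 0 afterwards. The phase is
#' continuous at `t0` (both branches give `pi`) and the left limit at
#' `t0 + t_r` is `2*pi`, so `1 - cos` closes to zero continuously. The
#' relaxation duration is evaluated at the current sarcomere length
#' `L(E_ff)`, i.e. the length dependence is time-varying.
#'
#' @param t Time since activation (s, >= 0). Vectorized.
#' @param E_ff Fiber Green-Lagrange strain (scalar or same length as `t`).
#' @param params An [active_params()] object.
#' @return Phase angle in radians, in `[0, 2*pi)`.
#' @export
activation_phase <- function(t, E_ff, params) {
  stopifnot(inherits(params, "active_params"))
  if (any(t < 0)) stop("time must be >= 0")
  n <- max(length(t), length(E_ff))
  t <- rep_len(t, n); E_ff <- rep_len(E_ff, n)
  t_r <- relaxation_duration(sarcomere_length(E_ff, params$L_r), params)
  omega <- numeric(n)
  rise <- t < params$t0
  relax <- !rise & t < params$t0 + t_r
  omega[rise] <- pi * t[rise] / params$t0
  omega[relax] <- pi * (t[relax] - params$t0 + t_r[relax]) / t_r[relax]
  omega
}

#' Active fiber stress of the time-varying-elastance law
#'
#' `sigma_af = (T_max/2) * Ca0^2 / (Ca0^2 + ECa50(E_ff)^2) * (1 - cos(omega))`.
#' Below the activation threshold (`L <= L_0`) the stress is defined as 0,
#' so organ-level sweeps remain well-posed. The stress is bounded by `T_max`.
#'
#' @inheritParams activation_phase
#' @return Active fiber Cauchy stress (MPa).
#' @export
active_fiber_stress <- function(t, E_ff, params) {
  stopifnot(inherits(params, "active_params"))
  ec <- eca50(E_ff, params)
  ca_frac <- ifelse(is.finite(ec), params$Ca0^2 / (params$Ca0^2 + ec^2), 0)
  omega <- activation_phase(t, E_ff, params)
  params$T_max / 2 * ca_frac * (1 - cos(omega))
}

#' Peak isometric active stress
#'
#' Closed-form peak of the isometric twitch (`E_ff = 0`, `omega = pi`):
#' `T_max * Ca0^2 / (Ca0^2 + ECa50(0)^2)`. Because `ECa50(0)` depends on the
#' sarcomere lengths only through `L_r - L_0`, the peak is an exact function
#' of the sarcomere length difference (SLD).
#'
#' @param params An [active_params()] object.
#' @return Peak isometric stress (MPa).
#' @export
peak_isometric_stress <- function(params) {
  stopifnot(inherits(params, "active_params"))
  ec <- eca50(0, params)
  if (!is.finite(ec)) return(0)
  params$T_max * params$Ca0^2 / (params$Ca0^2 + ec^2)
}

#' Duration of contraction
#'
#' Time from activation until the isometric active stress returns to zero:
#' `DOC = t0 + t_r(L_r)`. Affine and strictly increasing in `L_r`, and
#' independent of `L_0`.
#'
#' @param params An [active_params()] object.
#' @return Duration of contraction (s).
#' @export
duration_of_contraction <- function(params) {
  stopifnot(inherits(params, "active_params"))
  params$t0 + relaxation_duration(params$L_r, params)
}

#' Model-based sarcomere length-tension curve
#'
#' Peak isometric tension as a function of sarcomere length:
#' `T_max * Ca0^2 / (Ca0^2 + ECa50(L)^2)`, zero at or below `L_0`.
#' Lowering `L_0` shifts the curve leftward, raising the tension available
#' at every length.
#'
#' @param L_grid Sarcomere lengths (um, > 0).
#' @param params An [active_params()] object.
#' @return A data.frame with columns `L_um` and `peak_tension_MPa`.
#' @export
length_tension_curve <- function(L_grid, params) {
  stopifnot(inherits(params, "active_params"))
  if (any(L_grid <= 0)) stop("lengths must be > 0")
  arg <- exp(params$B * um_to_mm(L_grid - params$L_0)) - 1
  tension <- numeric(length(L_grid))
  ok <- arg > 0
  ec2 <- params$Ca0_max^2 / arg[ok]
  tension[ok] <- params$T_max * params$Ca0^2 / (params$Ca0^2 + ec2)
  data.frame(L_um = L_grid, peak_tension_MPa = tension)
}
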