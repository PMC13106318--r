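#' Passive biaxial verification report
#'
#' Reproduces the unit-cube passive verification: for each prescribed stretch
#' the closed-form Cauchy stresses ([cauchy_biaxial()]) are compared against
#' the finite-difference energy oracle ([numeric_stress_oracle()]) in both an
#' equibiaxial case (`lambda_f = lambda_s = lambda`) and a fiber-only case
#' (`lambda_f = lambda`, `lambda_s = 1`). A single reduced-integration
#' hexahedron under homogeneous deformation is mathematically the point-wise
#' constitutive response, so the oracle plays the role of the independent
#' numerical solution.
#'
#' @param params A [passive_params()] object.
#' @param stretch_list Stretches to test, in (1, 1.3]; default
#'   `c(1.10, 1.20, 1.30)`.
#' @param tol_rel Relative tolerance for PASS (default `1e-5`).
#' @param tol_abs Absolute error floor (MPa) below which a row passes
#'   regardless of relative error (default `1e-9`).
#' @return A data.frame of class `verification_report` with one row per
#'   (case, stretch, stress component): columns `case`, `lambda_f`,
#'   `lambda_s`, `component`, `analytic`, `numeric`, `abs_err`, `rel_err`,
#'   `pass`, and an attribute `status` equal to `"PASS"` or `"FAIL"`.
#' @export
passive_biaxial_report <- function(params, stretch_list = c(1.10, 1.20, 1.30),
                                   tol_rel = 1e-5, tol_abs = 1e-9) {
  stopifnot(inherits(params, "passive_params"))
  if (any(stretch_list <= 0)) stop("stretches must be > 0")
  rows <- list()
  for (lam in stretch_list) {
    for (case in c("equibiaxial", "fiber-only")) {
      lf <- lam
      ls <- if (case == "equibiaxial") lam else 1.0
      ana <- cauchy_biaxial(params, lf, ls)
      num <- numeric_stress_oracle(params, lf, ls)
      for (comp in c("sigma_ff", "sigma_ss")) {
        a <- ana[[comp]]; n <- num[[comp]]
        abs_err <- abs(a - n)
        rel_err <- if (abs(a) > 0) abs_err / abs(a) else abs_err
        rows[[length(rows) + 1L]] <- data.frame(
          case = case, lambda_f = lf, lambda_s = ls, component = comp,
          analytic = a, numeric = n, abs_err = abs_err, rel_err = rel_err,
          pass = abs_err <= tol_abs || rel_err <= tol_rel,
          stringsAsFactors = FALSE)
      }
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case = character(), lambda_f = numeric(), lambda_s = numeric(),
               component = character(), analytic = numeric(),
               numeric = numeric(), abs_err = numeric(), rel_err = numeric(),
               pass = logical(), stringsAsFactors = FALSE)
  attr(report, "status") <- if (all(report$pass)) "PASS" else "FAIL"
  class(report) <- c("verification_report", "data.frame")
  report
}

#' Sampled isometric twitch
#'
#' Samples the active fiber stress of a fully constrained twitch
#' (`E_ff = 0`, all faces fixed) on a uniform time grid and summarizes its
#' peak and duration. Mirrors the unit-cube active benchmark in which the
#' element is activated at `t = 0` and observed over a window long enough to
#' contain the full contraction.
#'
#' @param params An [active_params()] object.
#' @param t_end End of the sampling window (s), default 0.7.
#' @param dt Grid step (s, > 0), default `1e-4`.
#' @return An object of class `twitch_trace`: a list with `times`, `stresses`
#'   (MPa), `peak_stress`, `peak_time`, and `duration_of_contraction` (the
#'   first grid time at and after which the stress stays zero). If the window
#'   ends before the stress returns to zero a warning is issued and the
#'   duration is truncated at `t_end`.
#' @export
isometric_twitch <- function(params, t_end = 0.7, dt = 1e-4) {
  stopifnot(inherits(params, "active_params"))
  if (dt <= 0) stop("dt must be > 0")
  doc <- duration_of_contraction(params)
  if (t_end < doc)
    warning("t_end (", t_end, " s) is shorter than the duration of ",
            "contraction (", round(doc, 4), " s); duration is truncated")
  times <- seq(0, t_end, by = dt)
  stresses <- active_fiber_stress(times, 0, params)
  i_peak <- which.max(stresses)
  zero_after <- stresses == 0 & times > times[i_peak]
  doc_sampled <- if (any(zero_after)) times[which(zero_after)[1L]] else t_end
  structure(list(times = times, stresses = stresses,
                 peak_stress = stresses[i_peak], peak_time = times[i_peak],
                 duration_of_contraction = doc_sampled, dt = dt),
            class = "twitch_trace")
}

#' @export
print.verification_report <- function(x, ...) {
  cat("Passive biaxial verification:", attr(x, "status"), "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
print.twitch_trace <- function(x, ...) {
  cat(sprintf("Isometric twitch: peak %.5f MPa at t = %.4f s, DOC = %.4f s (dt = %g s)\n",
              x$peak_stress, x$peak_time, x$duration_of_contraction, x$dt))
  invisible(x)
}
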