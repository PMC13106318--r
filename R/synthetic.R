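#' Synthetic scenario metric table with linear parameter dependence
#'
#' Generates EDV/ESV per scenario as
#' `baseline + slope * (parameter - baseline parameter) + Gaussian noise`,
#' the generative structure that the series-wise linear sensitivity analysis
#' assumes. The regressor is the series' own parameter (`L_r` for the S0 and
#' constant-SLD series, `L_0` for the S1 series). SV/LVEF/CO are derived via
#' [cardiac_metrics()], so the generated table is a valid input to every
#' analysis stage.
#'
#' @param true_slopes Named list with elements `EDV` and `ESV`, each a named
#'   vector of slopes (mL/um) for series `S0`, `S1`, `S2`.
#' @param baseline_metrics Named vector/list with `EDV` and `ESV` baseline
#'   values (mL).
#' @param scenario_table Scenario design, default [build_scenario_table()].
#' @param noise_sd Gaussian noise SD (mL), applied to EDV and ESV.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @param on_negative `"error"` (default) or `"resample"`: policy when a
#'   generated volume is non-positive or ESV >= EDV.
#' @return A data.frame with columns `id`, `EDV_mL`, `ESV_mL`.
#' @export
synth_metric_table <- function(true_slopes, baseline_metrics,
                               scenario_table = build_scenario_table(),
                               noise_sd = 0, seed = 1L,
                               on_negative = c("error", "resample")) {
  on_negative <- match.arg(on_negative)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  base_p <- c(S0 = 1.85, S1 = 1.58, S2 = 1.85)
  param_col <- c(S0 = "Lr_um", S1 = "L0_um", S2 = "Lr_um")
  gen <- function() {
    edv <- esv <- numeric(nrow(scenario_table))
    for (i in seq_len(nrow(scenario_table))) {
      ser <- scenario_table$series[i]
      dp <- scenario_table[[param_col[[ser]]]][i] - base_p[[ser]]
      edv[i] <- baseline_metrics[["EDV"]] + true_slopes[["EDV"]][[ser]] * dp +
        stats::rnorm(1, 0, noise_sd)
      esv[i] <- baseline_metrics[["ESV"]] + true_slopes[["ESV"]][[ser]] * dp +
        stats::rnorm(1, 0, noise_sd)
    }
    data.frame(id = scenario_table$id, EDV_mL = edv, ESV_mL = esv,
               stringsAsFactors = FALSE)
  }
  tab <- gen()
  tries <- 0L
  while (any(tab$ESV_mL <= 0 | tab$ESV_mL >= tab$EDV_mL)) {
    if (on_negative == "error" || tries >= 100L)
      stop("generated volumes violate EDV > ESV > 0; lower noise_sd")
    tab <- gen()
    tries <- tries + 1L
  }
  tab
}

#' Noisy isometric peak-stress measurements
#'
#' Draws `n` replicates of the closed-form peak isometric stress with
#' additive Gaussian noise, truncated at zero (negative draws are set to 0,
#' emulating a force transducer floor).
#'
#' @param params An [active_params()] object.
#' @param noise_sd Noise SD (MPa).
#' @param n Number of replicates (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of length `n` (MPa).
#' @export
synth_twitch_measurements <- function(params, noise_sd = 0, n = 1L, seed = 1L) {
  stopifnot(inherits(params, "active_params"))
  if (n < 1) stop("n must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  pmax(0, peak_isometric_stress(params) + stats::rnorm(n, 0, noise_sd))
}

#' Recover the sarcomere length difference from peak-stress measurements
#'
#' Inverts the closed-form peak isometric stress for the sarcomere length
#' difference: from `sigma = T_max Ca0^2 / (Ca0^2 + ECa50^2)` and
#' `ECa50 = Ca0_max / sqrt(exp(B * SLD) - 1)`,
#' \deqn{SLD = \frac{1}{B}\,\log\!\left(1 +
#'   \frac{Ca_{0,max}^2}{Ca_0^2\,(T_{max}/\sigma - 1)}\right),}
#' converted back to micrometres. Each admissible measurement is inverted and
#' the estimates averaged; the estimator is exact for noiseless input and
#' consistent as noise shrinks. Measurements outside `(0, T_max)` are
#' rejected.
#'
#' @param peak_measurements Peak stresses (MPa), in `(0, T_max)`.
#' @param params An [active_params()] object supplying all parameters except
#'   the length difference.
#' @return A list with `sld_um` (the averaged estimate), `per_measurement`
#'   (individual inversions), and `n_used`.
#' @export
recover_sld <- function(peak_measurements, params) {
  stopifnot(inherits(params, "active_params"))
  ok <- peak_measurements > 0 & peak_measurements < params$T_max
  if (!any(ok)) stop("no measurement lies in (0, T_max)")
  sig <- peak_measurements[ok]
  sld_mm <- log(1 + params$Ca0_max^2 /
                  (params$Ca0^2 * (params$T_max / sig - 1))) / params$B
  est <- sld_mm * 1e3   # mm -> um
  list(sld_um = mean(est), per_measurement = est, n_used = sum(ok))
}

#' Synthetic regional average-peak-strain records
#'
#' Generates per region/direction average peak strain values as
#' `mu + shift(scenario) + Gaussian noise` around user-supplied reference
#' means and SDs, the structure assumed by the strain-type deviation scoring
#' ([aps_deviation()]).
#'
#' @param reference A data.frame with columns `region`, `mu`, `sigma`
#'   (`sigma > 0`).
#' @param scenario_shifts Named numeric vector: additive shift (strain units)
#'   per scenario id, applied to every region.
#' @param noise_sd Gaussian noise SD (strain units).
#' @param seed Integer seed.
#' @return A data.frame with columns `id`, `region`, `aps`, `mu`, `sigma`,
#'   and `score` (the per-record deviation).
#' @export
synth_aps_records <- function(reference, scenario_shifts, noise_sd = 0,
                              seed = 1L) {
  if (!all(c("region", "mu", "sigma") %in% names(reference)))
    stop("reference must have columns region, mu, sigma")
  if (any(reference$sigma <= 0)) stop("reference sigma must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  out <- do.call(rbind, lapply(names(scenario_shifts), function(id) {
    aps <- reference$mu + scenario_shifts[[id]] +
      stats::rnorm(nrow(reference), 0, noise_sd)
    data.frame(id = id, region = reference$region, aps = aps,
               mu = reference$mu, sigma = reference$sigma,
               stringsAsFactors = FALSE)
  }))
  out$score <- aps_deviation(out$aps, out$mu, out$sigma)
  out
}

#' Summed APS deviation score and ranking
#'
#' Sums the per-record strain deviation scores of [synth_aps_records()] per
#' scenario and ranks scenarios by the total (descending, ties broken by id).
#'
#' @param aps_records Output of [synth_aps_records()].
#' @return A data.frame with columns `id`, `total`, ordered by rank.
#' @export
rank_aps_scores <- function(aps_records) {
  tot <- stats::aggregate(score ~ id, data = aps_records, FUN = sum)
  names(tot)[names(tot) == "score"] <- "total"
  rank_scenarios(tot)
}
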