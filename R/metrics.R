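#' Cardiac-function metrics from end-diastolic and end-systolic volumes
#'
#' Stroke volume `SV = EDV - ESV` (mL), ejection fraction
#' `LVEF = 100 * SV / EDV` (%), and cardiac output `CO = SV * HR / 1000`
#' (L/min). The default heart rate of 60 beats/min corresponds to a 1-s cycle.
#'
#' @param EDV End-diastolic volume (mL). Vectorized.
#' @param ESV End-systolic volume (mL). Vectorized.
#' @param HR Heart rate (beats/min), default 60.
#' @return A data.frame with columns `EDV`, `ESV`, `SV`, `LVEF`, `CO`, `HR`,
#'   at full precision.
#' @export
cardiac_metrics <- function(EDV, ESV, HR = 60) {
  if (HR <= 0) stop("heart rate must be > 0")
  if (any(ESV < 0) || any(ESV >= EDV))
    stop("volumes must satisfy EDV > ESV >= 0")
  SV <- EDV - ESV
  data.frame(EDV = EDV, ESV = ESV, SV = SV, LVEF = 100 * SV / EDV,
             CO = SV * HR / 1000, HR = HR)
}

#' Percent change relative to a baseline
#'
#' `100 * (value - baseline) / baseline`. Use [round_half_away()] with
#' `digits = 2` to reproduce the two-decimal table convention.
#'
#' @param value New value(s).
#' @param baseline Baseline value (non-zero).
#' @return Percent change, full precision.
#' @export
percent_change <- function(value, baseline) {
  if (any(baseline == 0)) stop("baseline must be non-zero")
  100 * (value - baseline) / baseline
}

#' Round half away from zero
#'
#' Decimal rounding in which ties go away from zero (the convention of the
#' reported tables), unlike base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Formatted cardiac-function report with percent changes
#'
#' Builds the display table of the scenario study: per scenario, EDV/ESV as
#' given, `SV = EDV - ESV`, LVEF and CO rounded to 3 decimals, and percent
#' changes relative to the baseline scenario rounded to 2 decimals.
#' Percent changes are computed from the values as displayed (the 3-decimal
#' columns), matching the convention of clinical reporting tables; internal
#' analyses ([cardiac_metrics()]) keep full precision.
#'
#' @param metric_table A data.frame with columns `id`, `EDV_mL`, `ESV_mL`
#'   (e.g. from [read_metric_table()] or [scenario_response_table()]).
#' @param baseline_id Scenario used as reference, default `"S00"`.
#' @param HR Heart rate (beats/min), default 60.
#' @return A data.frame with columns `id`, `EDV_mL`, `ESV_mL`, `SV_mL`,
#'   `LVEF_pct`, `CO_Lmin` and percent-change columns `EDV_chg`, `ESV_chg`,
#'   `SV_chg`, `LVEF_chg`, `CO_chg` (baseline row has `NA` changes).
#' @export
metric_report <- function(metric_table, baseline_id = "S00", HR = 60) {
  need <- c("id", "EDV_mL", "ESV_mL")
  if (!all(need %in% names(metric_table)))
    stop("metric_table must have columns ", paste(need, collapse = ", "))
  if (!baseline_id %in% metric_table$id)
    stop("baseline scenario '", baseline_id, "' not in table")
  m <- cardiac_metrics(metric_table$EDV_mL, metric_table$ESV_mL, HR)
  out <- data.frame(id = metric_table$id,
                    EDV_mL = m$EDV, ESV_mL = m$ESV, SV_mL = m$SV,
                    LVEF_pct = round_half_away(m$LVEF, 3),
                    CO_Lmin = round_half_away(m$CO, 3),
                    stringsAsFactors = FALSE)
  base <- out[out$id == baseline_id, ]
  chg <- function(col) round_half_away(percent_change(out[[col]], base[[col]]), 2)
  out$EDV_chg <- chg("EDV_mL"); out$ESV_chg <- chg("ESV_mL")
  out$SV_chg <- chg("SV_mL"); out$LVEF_chg <- chg("LVEF_pct")
  out$CO_chg <- chg("CO_Lmin")
  out[out$id == baseline_id,
      c("EDV_chg", "ESV_chg", "SV_chg", "LVEF_chg", "CO_chg")] <- NA
  out
}

#' Ordinary least-squares sensitivity with normalization
#'
#' Regresses a cardiac metric on a sarcomere-length parameter and reports
#' the slope `dY/dp`, the coefficient of determination, and the normalized
#' sensitivity `S* = (p_base / Y_base) * dY/dp`. For a zero-variance
#' response the slope, `S*` and `R^2` are all defined as 0.
#'
#' @param p_values Parameter values (um); at least 3 distinct values.
#' @param Y_values Metric values, same length.
#' @param p_base Baseline parameter value.
#' @param Y_base Baseline metric value (non-zero).
#' @param label Optional segment/series label carried into the result.
#' @return A one-row data.frame of class `sensitivity_result` with columns
#'   `label`, `slope`, `S_star`, `R2`, `p_base`, `Y_base`, `n`.
#' @export
ols_sensitivity <- function(p_values, Y_values, p_base, Y_base,
                            label = NA_character_) {
  if (length(p_values) != length(Y_values))
    stop("p_values and Y_values must have equal length")
  if (length(p_values) < 3) stop("at least 3 points are required")
  if (length(unique(p_values)) < 2) stop("degenerate parameter spread")
  if (Y_base == 0) stop("Y_base must be non-zero")
  if (stats::var(Y_values) == 0) {
    slope <- 0; r2 <- 0
  } else {
    fit <- stats::lm(Y_values ~ p_values)
    slope <- unname(stats::coef(fit)[2L])
    # R^2 computed directly (summary.lm warns on exact fits)
    r2 <- 1 - sum(stats::residuals(fit)^2) /
      sum((Y_values - mean(Y_values))^2)
  }
  structure(data.frame(label = label, slope = slope,
                       S_star = p_base / Y_base * slope, R2 = r2,
                       p_base = p_base, Y_base = Y_base,
                       n = length(p_values), stringsAsFactors = FALSE),
            class = c("sensitivity_result", "data.frame"))
}

# Series and piecewise-segment definitions of the scenario design.
series_defs <- function() {
  list(
    Lr   = list(ids = c("S01", "S02", "S00", "S03", "S04"), param = "Lr_um",
                p_base = 1.85),
    L0   = list(ids = c("S11", "S12", "S00", "S13", "S14"), param = "L0_um",
                p_base = 1.58),
    diag = list(ids = c("S21", "S22", "S00", "S23", "S24"), param = "Lr_um",
                p_base = 1.85)
  )
}

#' Piecewise segment definitions around the baseline
#'
#' The four three-scenario segments of the piecewise sensitivity analysis:
#' below- and above-baseline `L_0` segments (regressor `L_0`), and below- and
#' above-baseline constant-SLD segments (regressor `L_r` along the diagonal
#' path where `L_r` and `L_0` increase together).
#'
#' @return A named list of segment definitions (`ids`, `param`, `p_base`).
#' @export
segment_defs <- function() {
  list(
    `S11-S12-S00` = list(ids = c("S11", "S12", "S00"), param = "L0_um",
                         p_base = 1.58),
    `S00-S13-S14` = list(ids = c("S00", "S13", "S14"), param = "L0_um",
                         p_base = 1.58),
    `S21-S22-S00` = list(ids = c("S21", "S22", "S00"), param = "Lr_um",
                         p_base = 1.85),
    `S00-S23-S24` = list(ids = c("S00", "S23", "S24"), param = "Lr_um",
                         p_base = 1.85)
  )
}

# Join a metric table with the scenario parameters and compute full-precision
# derived metrics.
metrics_with_params <- function(metric_table,
                                scenario_table = build_scenario_table(),
                                HR = 60) {
  tab <- merge(metric_table, scenario_table, by = "id", sort = FALSE)
  cbind(tab[, c("id", "Lr_um", "L0_um", "SLD_um")],
        cardiac_metrics(tab$EDV_mL, tab$ESV_mL, HR))
}

#' Global series sensitivity analysis
#'
#' OLS sensitivity of every cardiac metric (EDV, ESV, SV, LVEF, CO) over each
#' five-scenario series: the `L_r` series, the `L_0` series, and the
#' constant-SLD diagonal series (regressor `L_r`). Baselines are the control
#' scenario's parameter and metric values.
#'
#' @inheritParams metric_report
#' @param scenario_table Scenario design, default [build_scenario_table()].
#' @return A data.frame with one row per (series, metric): columns `series`,
#'   `metric`, `slope`, `S_star`, `R2`, `p_base`, `Y_base`, `n`.
#' @export
global_sensitivity <- function(metric_table,
                               scenario_table = build_scenario_table(),
                               HR = 60) {
  full <- metrics_with_params(metric_table, scenario_table, HR)
  run_sensitivity(full, series_defs())
}

#' Piecewise sensitivity analysis around the baseline
#'
#' OLS sensitivity of every cardiac metric over each three-scenario segment
#' of [segment_defs()].
#'
#' @inheritParams global_sensitivity
#' @param segments Segment definitions, default [segment_defs()].
#' @return A data.frame with one row per (segment, metric), columns as in
#'   [global_sensitivity()] with `series` replaced by `segment`.
#' @export
piecewise_sensitivity <- function(metric_table,
                                  scenario_table = build_scenario_table(),
                                  segments = segment_defs(), HR = 60) {
  full <- metrics_with_params(metric_table, scenario_table, HR)
  out <- run_sensitivity(full, segments)
  names(out)[names(out) == "series"] <- "segment"
  out
}

run_sensitivity <- function(full, defs) {
  metrics <- c("EDV", "ESV", "SV", "LVEF", "CO")
  base <- full[full$id == "S00", ]
  if (nrow(base) != 1L) stop("control scenario S00 missing from table")
  rows <- list()
  for (nm in names(defs)) {
    d <- defs[[nm]]
    missing_ids <- setdiff(d$ids, full$id)
    if (length(missing_ids))
      stop("scenario(s) missing from metric table: ",
           paste(missing_ids, collapse = ", "))
    sub <- full[match(d$ids, full$id), ]
    for (met in metrics) {
      r <- ols_sensitivity(sub[[d$param]], sub[[met]],
                           p_base = d$p_base, Y_base = base[[met]],
                           label = nm)
      rows[[length(rows) + 1L]] <- data.frame(
        series = nm, metric = met, slope = r$slope, S_star = r$S_star,
        R2 = r$R2, p_base = r$p_base, Y_base = r$Y_base, n = r$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Deviation score against a mean +/- SD reference
#'
#' Strain-type deviation: `max(0, |x - mu|/sigma - 1)`; zero whenever the
#' value lies within one standard deviation of the reference mean.
#'
#' @param x Observed value(s).
#' @param mu Reference mean.
#' @param sigma Reference standard deviation (> 0).
#' @return Non-negative score, vectorized over `x`.
#' @export
aps_deviation <- function(x, mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  pmax(0, abs(x - mu) / sigma - 1)
}

#' Deviation score against a normal range
#'
#' Range-type deviation: `max(0, (L - x)/(U - L)) + max(0, (x - U)/(U - L))`;
#' zero inside `[L, U]`, and the distance outside the range normalized by the
#' range width. Invariant under affine re-uniting of the metric together with
#' its bounds.
#'
#' @param x Observed value(s).
#' @param L Lower bound of the normal range.
#' @param U Upper bound (`U > L`).
#' @return Non-negative score, vectorized over `x`.
#' @export
range_deviation <- function(x, L, U) {
  if (any(U <= L)) stop("normal range must satisfy U > L")
  pmax(0, (L - x) / (U - L)) + pmax(0, (x - U) / (U - L))
}

#' Cardiac-function deviation scores per scenario
#'
#' Computes the range-type deviation of each displayed metric (EDV, ESV, SV,
#' LVEF at 3 decimals, CO at 3 decimals) against its normal range, and their
#' sum per scenario.
#'
#' @inheritParams metric_report
#' @param ranges A data.frame with columns `metric` (`EDV`, `ESV`, `SV`,
#'   `LVEF`, `CO`), `lower`, `upper`, e.g. from [load_normal_ranges()].
#' @return A data.frame with columns `id`, `EDV`, `ESV`, `SV`, `LVEF`, `CO`
#'   (per-metric scores) and `total`.
#' @export
deviation_scores <- function(metric_table, ranges = load_normal_ranges(),
                             HR = 60) {
  m <- cardiac_metrics(metric_table$EDV_mL, metric_table$ESV_mL, HR)
  vals <- data.frame(EDV = m$EDV, ESV = m$ESV, SV = m$SV,
                     LVEF = round_half_away(m$LVEF, 3),
                     CO = round_half_away(m$CO, 3))
  out <- data.frame(id = metric_table$id, stringsAsFactors = FALSE)
  for (met in c("EDV", "ESV", "SV", "LVEF", "CO")) {
    r <- ranges[ranges$metric == met, ]
    if (nrow(r) != 1L) stop("missing normal range for metric ", met)
    out[[met]] <- range_deviation(vals[[met]], r$lower, r$upper)
  }
  out$total <- rowSums(out[, c("EDV", "ESV", "SV", "LVEF", "CO")])
  out
}

#' Rank scenarios by total deviation score
#'
#' Orders scenarios by descending total score; ties are broken
#' lexicographically by scenario id.
#'
#' @param score_table A data.frame with columns `id` and `total`
#'   (e.g. from [deviation_scores()]).
#' @return The table reordered, most deviating scenario first.
#' @export
rank_scenarios <- function(score_table) {
  stopifnot(all(c("id", "total") %in% names(score_table)))
  score_table[order(-score_table$total, score_table$id), , drop = FALSE]
}

#' Strain measure conversions
#'
#' `nominal_strain()` is the fractional length change `e = lambda - 1`;
#' `green_to_nominal()` converts a Green-Lagrange strain to the nominal
#' measure, `e = sqrt(2E + 1) - 1`. The two are consistent under
#' `E = (lambda^2 - 1)/2`.
#'
#' @param lambda Stretch ratio (> 0).
#' @return Nominal (engineering) strain.
#' @export
nominal_strain <- function(lambda) {
  if (any(lambda <= 0)) stop("stretch must be > 0")
  lambda - 1
}

#' @rdname nominal_strain
#' @param E Green-Lagrange strain with `2E + 1 > 0`.
#' @export
green_to_nominal <- function(E) {
  if (any(2 * E + 1 <= 0)) stop("2E + 1 must be > 0")
  sqrt(2 * E + 1) - 1
}
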