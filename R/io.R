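#' Read a cardiac-metric table from CSV
#'
#' Reads a table with header `id, EDV_mL, ESV_mL` and optionally `SV_mL`,
#' `LVEF_pct`, `CO_Lmin`. Derived columns are recomputed from EDV/ESV and
#' cross-checked against any provided ones to a tolerance of 0.001 in the
#' metric's unit; an inconsistency is a validation error naming the cell.
#' Unicode minus signs (U+2212) are normalized on read.
#'
#' @param path Path to a CSV file.
#' @param HR Heart rate used for the CO cross-check (beats/min), default 60.
#' @param tol Cross-check tolerance, default 0.001.
#' @return A data.frame with columns `id`, `EDV_mL`, `ESV_mL` (plus any
#'   additional columns present in the file, validated).
#' @export
read_metric_table <- function(path, HR = 60, tol = 1e-3) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!length(txt)) stop("empty metric table: ", path)
  txt <- gsub("−", "-", txt)
  tab <- utils::read.csv(text = paste(txt, collapse = "\n"),
                         stringsAsFactors = FALSE)
  need <- c("id", "EDV_mL", "ESV_mL")
  if (!all(need %in% names(tab)))
    stop("metric table must have columns ", paste(need, collapse = ", "))
  if (!nrow(tab)) stop("metric table has no rows: ", path)
  m <- cardiac_metrics(tab$EDV_mL, tab$ESV_mL, HR)
  checks <- list(SV_mL = m$SV, LVEF_pct = m$LVEF, CO_Lmin = m$CO)
  for (col in names(checks)) {
    if (!col %in% names(tab)) next
    bad <- which(abs(tab[[col]] - checks[[col]]) > tol)
    if (length(bad))
      stop("column ", col, " inconsistent with EDV/ESV at row(s) ",
           paste(tab$id[bad], collapse = ", "))
  }
  tab
}

#' Write a cardiac-metric table to CSV
#'
#' Full-precision, lossless counterpart of [read_metric_table()] (values are
#' written with 15 significant digits).
#'
#' @param tab A data.frame with at least `id`, `EDV_mL`, `ESV_mL`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(tab, path) {
  num <- vapply(tab, is.numeric, logical(1L))
  out <- tab
  out[num] <- lapply(tab[num], function(x) format(x, digits = 15, trim = TRUE,
                                                  scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged cardiac-function metrics of the 13 scenarios
#'
#' The end-diastolic and end-systolic volumes (with their derived SV, LVEF,
#' CO) reported for the 13 sarcomere-length scenarios of the Living Heart
#' Model study. These in-study values are the canonical input to the
#' sensitivity and deviation analytics.
#'
#' @return A validated data.frame (see [read_metric_table()]).
#' @export
load_reference_metrics <- function() {
  read_metric_table(system.file("extdata", "cardiac_function_metrics.csv",
                                package = "sarcomech", mustWork = TRUE))
}

#' Packaged normal ranges of the cardiac-function metrics
#'
#' Literature normal ranges: EDV 102-202 mL, ESV 24-92 mL, SV 57-150 mL,
#' LVEF 50-65 %, CO 4-8 L/min.
#'
#' @return A data.frame with columns `metric`, `lower`, `upper`.
#' @export
load_normal_ranges <- function() {
  utils::read.csv(system.file("extdata", "normal_ranges.csv",
                              package = "sarcomech", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Reported percent changes of the scenario study
#'
#' The percent-change cells of the reported cardiac-function table (two
#' decimals, relative to S00), shipped for verification of the
#' [metric_report()] reproduction.
#'
#' @return A data.frame with columns `id`, `EDV_chg`, `ESV_chg`, `SV_chg`,
#'   `LVEF_chg`, `CO_chg`.
#' @export
load_reported_changes <- function() {
  tab <- utils::read.csv(system.file("extdata", "reported_percent_changes.csv",
                                     package = "sarcomech", mustWork = TRUE),
                         stringsAsFactors = FALSE)
  tab
}

#' Write a twitch trace to CSV
#'
#' @param trace A [isometric_twitch()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_twitch_trace <- function(trace, path) {
  stopifnot(inherits(trace, "twitch_trace"))
  utils::write.csv(data.frame(t = trace$times, sigma_af = trace$stresses),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
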