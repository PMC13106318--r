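#' Passive Holzapfel-Ogden parameter set
#'
#' Constructs the parameter set of the orthotropic hyperelastic strain-energy
#' law for passive myocardium: an isotropic exponential matrix term, tensile
#' fiber and sheet reinforcement terms, a fiber-sheet coupling term, and a
#' volumetric penalty. Defaults are the left-heart verification values.
#'
#' @param a Isotropic modulus (MPa).
#' @param b Isotropic exponent (dimensionless).
#' @param a_f Fiber modulus (MPa).
#' @param b_f Fiber exponent (dimensionless).
#' @param a_s Sheet modulus (MPa).
#' @param b_s Sheet exponent (dimensionless).
#' @param a_fs Fiber-sheet coupling modulus (MPa). The coupling term only
#'   contributes under shear (I8fs != 0); it is zero in all axis-aligned
#'   deformations, and no verification value is published, so the default is 0.
#' @param b_fs Coupling exponent (dimensionless).
#' @param D Volumetric compliance (1/MPa). Only used when a compressible
#'   evaluation is requested; the analytical biaxial path assumes J = 1.
#' @return An object of class `passive_params`.
#' @examples
#' pp <- passive_params()
#' cauchy_biaxial(pp, 1.1, 1.0)
#' @export
passive_params <- function(a = 0.004, b = 8.0, a_f = 0.005, b_f = 5.0,
                           a_s = 0.002, b_s = 2.0, a_fs = 0, b_fs = 1.0,
                           D = 1e-3) {
  p <- list(a = a, b = b, a_f = a_f, b_f = b_f, a_s = a_s, b_s = b_s,
            a_fs = a_fs, b_fs = b_fs, D = D)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("passive parameter '", nm, "' must be a finite scalar")
  }
  if (any(c(a, a_f, a_s, a_fs) < 0)) stop("passive moduli must be >= 0")
  if (any(c(b, b_f, b_s, b_fs) <= 0)) stop("passive exponents must be > 0")
  if (D <= 0) stop("volumetric compliance D must be > 0")
  structure(p, class = "passive_params")
}

#' Active time-varying-elastance parameter set
#'
#' Parameters of the active fiber-stress law in which tension is the product
#' of a length-dependent calcium-sensitivity factor and a cosine activation
#' waveform. Sarcomere lengths are given in micrometres at the interface; the
#' constants `B` (1/mm) and `m` (s/mm) act on lengths in millimetres, and the
#' conversion is handled internally.
#'
#' @param T_max Maximum isometric tension (MPa).
#' @param Ca0 Peak intracellular calcium (arbitrary concentration units).
#' @param Ca0_max Maximum calcium concentration (same units as `Ca0`).
#' @param B Calcium-sensitivity exponent (1/mm).
#' @param t0 Time to peak tension (s).
#' @param m Slope of the length-dependent relaxation duration (s/mm).
#' @param b_relax Intercept of the relaxation duration (s). Named `b_relax`
#'   to avoid colliding with the passive isotropic exponent `b`.
#' @param L_r Unloaded (reference) sarcomere length (um).
#' @param L_0 Sarcomere length at which no active tension develops (um).
#' @return An object of class `active_params`.
#' @examples
#' ap <- active_params()
#' peak_isometric_stress(ap)
#' duration_of_contraction(ap)
#' @export
active_params <- function(T_max = 0.1, Ca0 = 4.35, Ca0_max = 4.35, B = 4750,
                          t0 = 0.1, m = 1048.9, b_relax = -1.429,
                          L_r = 1.85, L_0 = 1.58) {
  p <- list(T_max = T_max, Ca0 = Ca0, Ca0_max = Ca0_max, B = B, t0 = t0,
            m = m, b_relax = b_relax, L_r = L_r, L_0 = L_0)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("active parameter '", nm, "' must be a finite scalar")
  }
  if (T_max <= 0) stop("T_max must be > 0")
  if (t0 <= 0) stop("t0 must be > 0")
  if (L_0 <= 0 || L_r <= L_0) stop("sarcomere lengths must satisfy L_r > L_0 > 0")
  if (m * um_to_mm(L_r) + b_relax <= 0)
    stop("relaxation duration t_r(L_r) must be positive")
  structure(p, class = "active_params")
}

# micrometre -> millimetre, the internal length unit of B and m
um_to_mm <- function(L_um) L_um * 1e-3

#' Read parameter sets from a key-value configuration file
#'
#' Parses a flat, commented `key = value` document with `[section]` headers
#' (sections `passive`, `active`, `surrogate`). Unknown keys are rejected.
#' The packaged default configuration (`system.file("extdata",
#' "default_params.cfg", package = "sarcomech")`) mirrors the constructor
#' defaults.
#'
#' @param path Path to the configuration file.
#' @return A named list with elements `passive` ([passive_params()]),
#'   `active` ([active_params()]), and `surrogate` ([surrogate_params()]),
#'   for the sections present in the file.
#' @export
read_params_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- NA_character_
  vals <- list()
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      vals[[section]] <- list()
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) stop("malformed config line: '", ln, "'")
    if (is.na(section)) stop("config key outside any [section]: '", ln, "'")
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L])
    val <- suppressWarnings(as.numeric(trimws(paste(kv[-1L], collapse = "="))))
    if (is.na(val)) stop("non-numeric value for key '", key, "'")
    vals[[section]][[key]] <- val
  }
  constructors <- list(passive = passive_params, active = active_params,
                       surrogate = surrogate_params)
  out <- list()
  for (sec in names(vals)) {
    ctor <- constructors[[sec]]
    if (is.null(ctor)) stop("unknown config section [", sec, "]")
    known <- names(formals(ctor))
    bad <- setdiff(names(vals[[sec]]), known)
    if (length(bad)) stop("unknown key(s) in [", sec, "]: ",
                          paste(bad, collapse = ", "))
    out[[sec]] <- do.call(ctor, vals[[sec]])
  }
  out
}

#' Packaged default parameter configuration
#'
#' Convenience loader for the configuration file shipped with the package,
#' containing the verification passive set, the default active set, and the
#' frozen calibration of the 0D surrogate.
#'
#' @return See [read_params_config()].
#' @export
default_params <- function() {
  read_params_config(system.file("extdata", "default_params.cfg",
                                 package = "sarcomech", mustWork = TRUE))
}
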