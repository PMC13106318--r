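#' Parameters of the reduced closed-loop left-heart surrogate
#'
#' A 0D lumped model used to explore organ-level phenotypes of the sarcomere
#' length scenarios directionally: a thick-walled spherical left ventricle
#' driven by the active and passive myocardial laws, a passive elastance left
#' atrium, ideal-diode mitral and aortic valves with small forward
#' resistances, and arterial/venous compliance compartments closed through a
#' peripheral resistance. Defaults are a frozen calibration under which the
#' baseline scenario lands inside the normal ranges of the cardiac-function
#' metrics; the study's absolute reported volumes are not fitting targets.
#'
#' @param V_wall LV wall volume (mL).
#' @param V_ref Unloaded LV cavity volume (mL); the midwall stretch is 1 at
#'   this volume.
#' @param E_la Left-atrial elastance (mmHg/mL).
#' @param V_la0 Left-atrial unstressed volume (mL).
#' @param C_art Arterial compliance (mL/mmHg).
#' @param V_art0 Arterial unstressed volume (mL).
#' @param C_ven Venous compliance (mL/mmHg).
#' @param V_ven0 Venous unstressed volume (mL).
#' @param R_mit Mitral valve forward resistance (mmHg s/mL).
#' @param R_ao Aortic valve forward resistance (mmHg s/mL).
#' @param R_p Peripheral (systemic) resistance (mmHg s/mL).
#' @param R_ven Venous-return resistance into the atrium (mmHg s/mL).
#' @param total_volume Total blood volume in the loop (mL).
#' @param cycle_length Cardiac cycle length (s), default 1.0.
#' @param beat_duration Nominal systolic (beat) window (s), must not exceed
#'   the cycle length; the active twitch itself runs for its own duration of
#'   contraction from beat onset.
#' @param preload_time Passive filling time before the first beat (s).
#' @return An object of class `surrogate_params`.
#' @export
surrogate_params <- function(V_wall = 140, V_ref = 100,
                             E_la = 0.18, V_la0 = 5,
                             C_art = 1.3, V_art0 = 350,
                             C_ven = 60, V_ven0 = 900,
                             R_mit = 0.025, R_ao = 0.012,
                             R_p = 1.05, R_ven = 0.035,
                             total_volume = 2400,
                             cycle_length = 1.0, beat_duration = 0.5,
                             preload_time = 0.3) {
  p <- as.list(environment())
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0)
      stop("surrogate parameter '", nm, "' must be a positive finite scalar")
  }
  if (beat_duration > cycle_length)
    stop("beat_duration must not exceed cycle_length")
  structure(p, class = "surrogate_params")
}

# mmHg per MPa
MMHG_PER_MPA <- 7500.617

# Midwall fiber stretch of the thick-walled spherical LV at cavity volume V.
lv_midwall_stretch <- function(V, params) {
  k <- 3 / (4 * pi)
  r_in <- (k * V)^(1 / 3)
  r_out <- (k * (V + params$V_wall))^(1 / 3)
  r_ref <- ((k * params$V_ref)^(1 / 3) + (k * (params$V_ref + params$V_wall))^(1 / 3)) / 2
  list(r_in = r_in, r_out = r_out, lambda = (r_in + r_out) / 2 / r_ref)
}

#' Left-ventricular pressure from cavity volume
#'
#' Thick-walled-sphere (Laplace-type) mapping from cavity volume and time in
#' the beat to LV pressure. The midwall fiber stretch is
#' `lambda = r_mid / r_mid,ref`; the fiber Green-Lagrange strain is
#' `E_ff = (lambda^2 - 1)/2`; the wall tangential stress is the active fiber
#' stress plus the mean in-plane passive stress of the equibiaxial state
#' `(lambda, lambda)`; and `P = 2 * sigma * log(r_out/r_in)`, converted from
#' MPa to mmHg. At volumes below the unloaded volume the isotropic passive
#' term is compressive, giving the diastolic suction of elastic recoil.
#'
#' @param V Cavity volume (mL, > 0). Vectorized.
#' @param t_in_beat Time since beat onset (s); use a value beyond the
#'   duration of contraction (e.g. `Inf`) for a passive state.
#' @param active An [active_params()] object (the scenario's).
#' @param passive A [passive_params()] object.
#' @param params A [surrogate_params()] object.
#' @return LV pressure (mmHg).
#' @export
lv_pressure_from_volume <- function(V, t_in_beat, active, passive, params) {
  stopifnot(inherits(params, "surrogate_params"))
  if (any(V <= 0)) stop("cavity volume must be > 0")
  g <- lv_midwall_stretch(V, params)
  E_ff <- (g$lambda^2 - 1) / 2
  sig_a <- if (is.finite(t_in_beat))
    active_fiber_stress(t_in_beat, E_ff, active) else 0
  sp <- cauchy_biaxial(passive, g$lambda, g$lambda)
  sig_p <- (sp$sigma_ff + sp$sigma_ss) / 2
  2 * (sig_a + sig_p) * log(g$r_out / g$r_in) * MMHG_PER_MPA
}

# Fast closure evaluating the LV pressure; inlines the constitutive laws so
# the fixed-step integrator avoids per-step S3 dispatch. Must agree with
# lv_pressure_from_volume (tested).
make_lv_pressure <- function(active, passive, params) {
  k <- 3 / (4 * pi)
  V_wall <- params$V_wall
  r_ref <- ((k * params$V_ref)^(1 / 3) +
              (k * (params$V_ref + V_wall))^(1 / 3)) / 2
  a <- passive$a; b <- passive$b
  a_f <- passive$a_f; b_f <- passive$b_f
  a_s <- passive$a_s; b_s <- passive$b_s
  T_max <- active$T_max; Ca0sq <- active$Ca0^2; Ca0max <- active$Ca0_max
  B_um <- active$B * 1e-3            # per um
  m_um <- active$m * 1e-3            # s per um
  b_relax <- active$b_relax; t0 <- active$t0
  L_r <- active$L_r; L_0 <- active$L_0
  function(V, t_beat) {
    r_in <- (k * V)^(1 / 3)
    r_out <- (k * (V + V_wall))^(1 / 3)
    lam <- (r_in + r_out) / 2 / r_ref
    lam2 <- lam^2
    lamn2 <- 1 / lam2^2
    # passive: mean in-plane equibiaxial stress, tension-only reinforcement
    iso <- a * exp(b * (2 * lam2 + lamn2 - 3)) * (lam2 - lamn2)
    e4 <- max(lam2 - 1, 0)
    sig_p <- iso + (a_f * exp(b_f * e4^2) + a_s * exp(b_s * e4^2)) * e4 * lam2
    # active twitch at the current length
    sig_a <- 0
    L <- L_r * lam
    dL <- L - L_0
    if (dL > 0 && t_beat >= 0) {
      t_r <- m_um * L + b_relax
      if (t_beat < t0) {
        omega <- pi * t_beat / t0
      } else if (t_r > 0 && t_beat < t0 + t_r) {
        omega <- pi * (t_beat - t0 + t_r) / t_r
      } else {
        omega <- 0
      }
      if (omega > 0) {
        ec2 <- Ca0max^2 / (exp(B_um * dL) - 1)
        sig_a <- T_max / 2 * Ca0sq / (Ca0sq + ec2) * (1 - cos(omega))
      }
    }
    2 * (sig_a + sig_p) * log(r_out / r_in) * MMHG_PER_MPA
  }
}

#' Run the closed-loop surrogate for several cardiac cycles
#'
#' Integrates the four-compartment loop (LV, LA, arterial, venous) with a
#' fixed-step explicit scheme and ideal-diode valves. The run starts with a
#' passive preload fill of `preload_time` seconds, after which the active
#' twitch is triggered at the onset of every cycle. Total blood volume is
#' conserved exactly by construction of the flow updates; the realized
#' per-cycle deviation is recorded.
#'
#' @param params A [surrogate_params()] object.
#' @param active An [active_params()] object (the scenario's lengths).
#' @param passive A [passive_params()] object.
#' @param n_cycles Number of cardiac cycles (>= 1), default 5.
#' @param dt Time step (s), default `1e-4`.
#' @param record_every Store the state every this many steps (default 10,
#'   i.e. a 1-ms output grid for the default `dt`).
#' @return An object of class `beat_series`: a list with `trace` (data.frame
#'   `time`, `P_LV`, `P_LA`, `P_art`, `P_ven`, `V_LV`, `V_LA`, `V_art`,
#'   `V_ven`), `cycles` (data.frame `cycle`, `EDV`, `ESV`, `SV`,
#'   `max_volume_drift`), and the inputs.
#' @export
run_cycles <- function(params = surrogate_params(), active = active_params(),
                       passive = passive_params(), n_cycles = 5, dt = 1e-4,
                       record_every = 10L) {
  stopifnot(inherits(params, "surrogate_params"),
            inherits(active, "active_params"),
            inherits(passive, "passive_params"))
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (dt <= 0) stop("dt must be > 0")
  plv <- make_lv_pressure(active, passive, params)

  # initial allocation: LV at its unloaded volume, atrium mildly filled,
  # remainder split between the arterial and venous reservoirs at equal
  # pressure; the preload phase then redistributes passively.
  V_lv <- params$V_ref
  V_la <- params$V_la0 + 8 / params$E_la
  rest <- params$total_volume - V_lv - V_la
  stressed <- rest - params$V_art0 - params$V_ven0
  if (stressed <= 0) stop("total_volume too small for the unstressed volumes")
  p_eq <- stressed / (params$C_art + params$C_ven)
  V_art <- params$V_art0 + p_eq * params$C_art
  V_ven <- params$V_ven0 + p_eq * params$C_ven

  n_pre <- round(params$preload_time / dt)
  n_cyc <- round(params$cycle_length / dt)
  n_tot <- n_pre + n_cycles * n_cyc
  n_rec <- floor(n_tot / record_every) + 1L
  rec <- matrix(NA_real_, n_rec, 9L)
  colnames(rec) <- c("time", "P_LV", "P_LA", "P_art", "P_ven",
                     "V_LV", "V_LA", "V_art", "V_ven")
  cyc <- data.frame(cycle = seq_len(n_cycles), EDV = NA_real_, ESV = NA_real_,
                    SV = NA_real_, max_volume_drift = NA_real_)
  total0 <- V_lv + V_la + V_art + V_ven
  i_rec <- 0L
  cur_cycle <- 0L
  esv <- Inf
  drift <- 0
  for (step in 0:(n_tot - 1L)) {
    t <- step * dt
    if (step >= n_pre) {
      in_cycle <- step - n_pre
      cycle_idx <- in_cycle %/% n_cyc + 1L
      t_beat <- (in_cycle %% n_cyc) * dt
      if (cycle_idx != cur_cycle) {      # beat onset: close out previous cycle
        if (cur_cycle >= 1L) {
          cyc$ESV[cur_cycle] <- esv
          cyc$SV[cur_cycle] <- cyc$EDV[cur_cycle] - esv
          cyc$max_volume_drift[cur_cycle] <- drift
        }
        cur_cycle <- cycle_idx
        cyc$EDV[cur_cycle] <- V_lv
        esv <- V_lv
        drift <- 0
      }
    } else {
      t_beat <- -1                        # passive preload
    }
    P_lv <- plv(V_lv, t_beat)
    P_la <- params$E_la * (V_la - params$V_la0)
    P_art <- (V_art - params$V_art0) / params$C_art
    P_ven <- (V_ven - params$V_ven0) / params$C_ven
    if (!is.finite(P_lv) || !is.finite(P_la))
      stop("integration diverged at t = ", signif(t, 6), " s (V_LV = ",
           signif(V_lv, 6), " mL)")
    if (step %% record_every == 0L) {
      i_rec <- i_rec + 1L
      rec[i_rec, ] <- c(t, P_lv, P_la, P_art, P_ven, V_lv, V_la, V_art, V_ven)
    }
    q_mit <- if (P_la > P_lv) (P_la - P_lv) / params$R_mit else 0
    q_ao <- if (P_lv > P_art) (P_lv - P_art) / params$R_ao else 0
    q_per <- (P_art - P_ven) / params$R_p
    q_ret <- (P_ven - P_la) / params$R_ven
    V_lv <- V_lv + dt * (q_mit - q_ao)
    V_la <- V_la + dt * (q_ret - q_mit)
    V_art <- V_art + dt * (q_ao - q_per)
    V_ven <- V_ven + dt * (q_per - q_ret)
    if (V_lv <= 0 || V_la <= 0 || V_art <= 0 || V_ven <= 0)
      stop("integration produced a non-positive compartment volume at t = ",
           signif(t, 6), " s")
    if (V_lv < esv) esv <- V_lv
    d <- abs(V_lv + V_la + V_art + V_ven - total0)
    if (d > drift) drift <- d
  }
  if (cur_cycle >= 1L) {
    cyc$ESV[cur_cycle] <- esv
    cyc$SV[cur_cycle] <- cyc$EDV[cur_cycle] - esv
    cyc$max_volume_drift[cur_cycle] <- drift
  }
  structure(list(trace = as.data.frame(rec[seq_len(i_rec), , drop = FALSE]),
                 cycles = cyc, total_volume = total0, dt = dt,
                 params = params, active = active, passive = passive),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  last <- x$cycles[nrow(x$cycles), ]
  cat(sprintf("Closed-loop surrogate: %d cycle(s), dt = %g s\n",
              nrow(x$cycles), x$dt))
  cat(sprintf("Final cycle: EDV = %.1f mL, ESV = %.1f mL, SV = %.1f mL\n",
              last$EDV, last$ESV, last$SV))
  invisible(x)
}

#' Organ-level scenario response table
#'
#' Runs the closed-loop surrogate for each scenario and reports the
#' final-cycle end-diastolic and end-systolic volumes, ready for
#' [metric_report()], [global_sensitivity()] and [deviation_scores()].
#'
#' @param scenario_table Scenario design, default [build_scenario_table()].
#' @param params A [surrogate_params()] object.
#' @param active_defaults Base [active_params()]; each scenario overrides the
#'   two sarcomere lengths.
#' @param passive A [passive_params()] object.
#' @param n_cycles Cycles per scenario, default 5.
#' @param dt Time step (s), default `1e-4`.
#' @return A data.frame with columns `id`, `EDV_mL`, `ESV_mL` plus
#'   `max_volume_drift` (mL, worst per-run conservation error).
#' @export
scenario_response_table <- function(scenario_table = build_scenario_table(),
                                    params = surrogate_params(),
                                    active_defaults = active_params(),
                                    passive = passive_params(),
                                    n_cycles = 5, dt = 1e-4) {
  rows <- lapply(seq_len(nrow(scenario_table)), function(i) {
    ap <- scenario_active_params(scenario_table[i, ], active_defaults)
    bs <- run_cycles(params, ap, passive, n_cycles = n_cycles, dt = dt,
                     record_every = 50L)
    last <- bs$cycles[nrow(bs$cycles), ]
    data.frame(id = scenario_table$id[i], EDV_mL = last$EDV,
               ESV_mL = last$ESV, max_volume_drift = last$max_volume_drift,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
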