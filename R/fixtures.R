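#' Tuning specification for the cardiogenic-shock baseline
#'
#' Target bounds of the shock criteria, the knobs the tuner may move and
#' their limits. The internal targets sit inside the bounds so that
#' cross-talk between knobs (volume raises systolic pressure, resistance
#' lowers it) does not push a previously satisfied bound back out.
#'
#' @param sbp_bound Systolic (max) aortic pressure bound, mmHg (`<`).
#' @param svri_bound SVRi bound, dyn s cm^-5 m^2 (`<`).
#' @param pcwp_bound Wedge pressure bound, mmHg (`>`).
#' @param ci_bound Cardiac index bound, L/min/m^2 (`<`).
#' @param sbp_target,svri_target,pcwp_target,ci_target Internal aiming
#'   points inside the bounds.
#' @param ees_scale_min Lower limit of the ventricular elastance scale.
#' @param volume_max Upper limit of total blood volume, mL.
#' @param r_scale_range Limits of the systemic bed resistance scale.
#' @param max_iterations Maximum number of full tuning passes (>= 10 knob
#'   evaluations are always allowed inside one pass).
#' @param bisect_iter Bisection steps per knob.
#' @return An object of class `tuning_spec`.
#' @export
tuning_spec <- function(sbp_bound = 90, svri_bound = 1800, pcwp_bound = 15,
                        ci_bound = 2.2,
                        sbp_target = 84, svri_target = 1580,
                        pcwp_target = 17, ci_target = 2.0,
                        ees_scale_min = 0.05, volume_max = 7500,
                        r_scale_range = c(0.25, 2), max_iterations = 4,
                        bisect_iter = 8) {
  structure(list(sbp_bound = sbp_bound, svri_bound = svri_bound,
                 pcwp_bound = pcwp_bound, ci_bound = ci_bound,
                 sbp_target = sbp_target, svri_target = svri_target,
                 pcwp_target = pcwp_target, ci_target = ci_target,
                 ees_scale_min = ees_scale_min, volume_max = volume_max,
                 r_scale_range = r_scale_range,
                 max_iterations = max_iterations, bisect_iter = bisect_iter),
            class = "tuning_spec")
}

#' Apply the shock phenotype to a base patient
#'
#' The declared components of the shock model: ventricular end-systolic
#' elastance scale (the right ventricle is depressed by the square root of
#' the left ventricular scale — biventricular but left-dominant failure),
#' total blood volume, a common scale on the systemic microvascular bed
#' resistances, a fixed diastolic stiffening of the failing left ventricle
#' (EDPVR exponent multiplied by `diastolic_scale`; acute ischaemic failure
#' raises passive stiffness, and without it the congestion criteria can
#' only be met by a ventricle too weak to eject against support), and the
#' shock heart rate of 90 bpm. Everything else is untouched. The tuner
#' moves only the first three; the stiffening and heart rate are fixed
#' phenotype constants.
#'
#' @param base A [patient_params()] object.
#' @param ees_scale LV elastance scale in (0, 1].
#' @param volume Total blood volume, mL.
#' @param r_scale Systemic bed resistance scale.
#' @param diastolic_scale LV EDPVR exponent multiplier (>= 1).
#' @param heart_rate Heart rate of the tuned patient, bpm.
#' @return A modified [patient_params()] object with `meta$knobs` recording
#'   the applied values.
#' @export
apply_shock_knobs <- function(base, ees_scale = 1, volume = NULL,
                              r_scale = 1, diastolic_scale = 1.6,
                              heart_rate = 90) {
  p <- base
  if (is.null(volume)) volume <- base$blood_volume
  p$heart_rate <- heart_rate
  p$blood_volume <- volume
  p$chambers$lv$Ees <- base$chambers$lv$Ees * ees_scale
  p$chambers$rv$Ees <- base$chambers$rv$Ees * sqrt(ees_scale)
  p$chambers$lv$B <- base$chambers$lv$B * diastolic_scale
  bed <- p$links$role == "bed"
  p$links$R[bed] <- base$links$R[bed] * r_scale
  p$meta$knobs <- list(ees_scale = ees_scale, volume = volume,
                       r_scale = r_scale, diastolic_scale = diastolic_scale,
                       heart_rate = heart_rate)
  p
}

# the four shock criteria of one converged, unsupported run
shock_criteria <- function(patient, sim) {
  beat <- run_to_steady_state(patient, device_config(), sim)
  h <- haemodynamic_report(beat)
  c(sbp = h$aop_max, svri = h$svri, pcwp = h$pcwp, ci = h$ci)
}

#' Deterministic cardiogenic-shock patient
#'
#' Tunes the healthy reference patient into a cardiogenic-shock baseline
#' satisfying all four criteria simultaneously on a converged simulation:
#' systolic aortic pressure < 90 mmHg, SVRi < 1800 dyn s cm^-5 m^2,
#' PCWP > 15 mmHg and cardiac index < 2.2 L/min/m^2. The tuner is a fixed
#' sequence of monotone bisections, one knob at a time (elastance scale
#' down until the pressure and index targets are met, volume up until the
#' wedge target is met, bed resistance until the SVRi target is met),
#' re-checking all bounds after each pass. No randomness is involved: the
#' same inputs always give byte-identical parameters.
#'
#' @param spec A [tuning_spec()].
#' @param base The patient to degrade (default [make_healthy_patient()]).
#' @param init Optional named list of starting knob values (`ees_scale`,
#'   `volume`, `r_scale`) — the bounds are recovered from perturbed starts.
#' @param sim Simulation settings used during tuning (a slightly relaxed
#'   configuration keeps the tuner fast; the returned patient is verified
#'   against `verify_sim`).
#' @param verify_sim Simulation settings of the final verification run.
#' @param verbose Print knob trajectory.
#' @return A [patient_params()] object with `meta$knobs` and
#'   `meta$criteria` (the verified criterion values).
#' @export
make_cs_patient <- function(spec = tuning_spec(), base = make_healthy_patient(),
                            init = list(), sim = simulation_config(
                              ss_tol = 2e-3, max_beats = 40, sample_hz = 100,
                              min_beats = 4),
                            verify_sim = simulation_config(),
                            verbose = FALSE) {
  es <- if (is.null(init$ees_scale)) 1 else init$ees_scale
  vol <- if (is.null(init$volume)) base$blood_volume else init$volume
  rs <- if (is.null(init$r_scale)) 1 else init$r_scale
  eval_knobs <- function(es, vol, rs) {
    shock_criteria(apply_shock_knobs(base, es, vol, rs), sim)
  }
  say <- function(...) if (verbose) message(sprintf(...))

  for (pass in seq_len(spec$max_iterations)) {
    m <- eval_knobs(es, vol, rs)
    say("pass %d start: es=%.3f vol=%.0f rs=%.3f | SBP=%.1f SVRi=%.0f PCWP=%.1f CI=%.2f",
        pass, es, vol, rs, m["sbp"], m["svri"], m["pcwp"], m["ci"])

    # 1. contractility: lower Ees scale until SBP and CI targets are met
    if (m[["sbp"]] > spec$sbp_target || m[["ci"]] > spec$ci_target) {
      lo <- spec$ees_scale_min; hi <- es; best <- NA_real_
      m_lo <- eval_knobs(lo, vol, rs)
      if (m_lo[["sbp"]] > spec$sbp_target || m_lo[["ci"]] > spec$ci_target)
        stop("shock bounds unreachable: SBP/CI targets not met even at the ",
             "elastance floor (SBP=", round(m_lo[["sbp"]], 1),
             ", CI=", round(m_lo[["ci"]], 2), ")", call. = FALSE)
      best <- lo
      for (i in seq_len(spec$bisect_iter)) {
        mid <- (lo + hi) / 2
        mm <- eval_knobs(mid, vol, rs)
        if (mm[["sbp"]] <= spec$sbp_target && mm[["ci"]] <= spec$ci_target) {
          best <- mid; lo <- mid
        } else hi <- mid
      }
      es <- best
      m <- eval_knobs(es, vol, rs)
      say("  es -> %.4f (SBP=%.1f CI=%.2f)", es, m["sbp"], m["ci"])
    }

    # 2. volume: raise until the wedge target is met
    if (m[["pcwp"]] < spec$pcwp_target) {
      lo <- vol; hi <- spec$volume_max; best <- NA_real_
      m_hi <- eval_knobs(es, hi, rs)
      if (m_hi[["pcwp"]] < spec$pcwp_target)
        stop("shock bounds unreachable: PCWP stays at ",
             round(m_hi[["pcwp"]], 1), " mmHg at the volume ceiling",
             call. = FALSE)
      best <- hi
      for (i in seq_len(spec$bisect_iter)) {
        mid <- (lo + hi) / 2
        mm <- eval_knobs(es, mid, rs)
        if (mm[["pcwp"]] >= spec$pcwp_target) { best <- mid; hi <- mid }
        else lo <- mid
      }
      vol <- best
      m <- eval_knobs(es, vol, rs)
      say("  vol -> %.0f (PCWP=%.1f)", vol, m["pcwp"])
    }

    # 3. systemic bed resistance: meet the SVRi target
    if (m[["svri"]] > spec$svri_target) {
      lo <- spec$r_scale_range[1]; hi <- rs; best <- NA_real_
      m_lo <- eval_knobs(es, vol, lo)
      if (m_lo[["svri"]] > spec$svri_target)
        stop("shock bounds unreachable: SVRi stays at ",
             round(m_lo[["svri"]]), " at the resistance floor", call. = FALSE)
      best <- lo
      for (i in seq_len(spec$bisect_iter)) {
        mid <- (lo + hi) / 2
        mm <- eval_knobs(es, vol, mid)
        if (mm[["svri"]] <= spec$svri_target) { best <- mid; lo <- mid }
        else hi <- mid
      }
      rs <- best
      say("  rs -> %.4f", rs)
    }

    patient <- apply_shock_knobs(base, es, vol, rs)
    crit <- shock_criteria(patient, verify_sim)
    say("pass %d verify: SBP=%.1f SVRi=%.0f PCWP=%.1f CI=%.2f",
        pass, crit["sbp"], crit["svri"], crit["pcwp"], crit["ci"])
    ok <- crit[["sbp"]] < spec$sbp_bound && crit[["svri"]] < spec$svri_bound &&
      crit[["pcwp"]] > spec$pcwp_bound && crit[["ci"]] < spec$ci_bound
    if (ok) {
      patient$meta$criteria <- as.list(crit)
      patient$meta$tuning_passes <- pass
      return(patient)
    }
  }
  stop("shock tuner did not satisfy all bounds within ",
       spec$max_iterations, " passes; final values: ",
       paste(sprintf("%s=%.2f", names(crit), crit), collapse = ", "),
       call. = FALSE)
}
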