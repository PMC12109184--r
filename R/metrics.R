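#' Min / time-weighted mean / max of a sampled signal
#'
#' The mean is the trapezoidal time average on the (possibly non-uniform)
#' grid.
#'
#' @param x Signal samples spanning exactly one beat (>= 2 samples).
#' @param t Sample times, s (strictly increasing).
#' @return Named vector `c(min, mean, max)`.
#' @export
cycle_stats <- function(x, t) {
  if (length(x) < 2 || length(x) != length(t))
    stop("need >= 2 samples with matching time grid", call. = FALSE)
  dt <- diff(t)
  m <- sum((x[-1] + x[-length(x)]) / 2 * dt) / (t[length(t)] - t[1])
  c(min = refine_extremum(x, which.min(x), lower = TRUE),
    mean = m,
    max = refine_extremum(x, which.max(x), lower = FALSE))
}

# parabolic refinement of a sampled extremum: smooth extrema lose O(dt^2)
# to sampling, which a vertex fit recovers. Kink-type extrema (valve
# opening corners) have strongly asymmetric side slopes and a parabola
# overshoots there, so refinement is skipped for them.
refine_extremum <- function(x, i, lower) {
  if (i == 1 || i == length(x)) return(x[i])
  s1 <- x[i] - x[i - 1]
  s2 <- x[i + 1] - x[i]
  asym <- min(abs(s1), abs(s2)) / max(abs(s1), abs(s2), 1e-300)
  d <- x[i - 1] - 2 * x[i] + x[i + 1]
  if (asym < 0.2 || (lower && d <= 1e-12) || (!lower && d >= -1e-12))
    return(x[i])
  x[i] - 0.125 * (x[i - 1] - x[i + 1])^2 / d
}

shoelace <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Area of a pressure-volume loop
#'
#' Shoelace (Green's theorem) area of the closed `(V, P)` polygon; the
#' absolute value is reported. The loop must close: first and last samples
#' must agree within `tol` times the signal range.
#'
#' @param P Pressure samples, mmHg.
#' @param V Volume samples, mL.
#' @param tol Relative closure tolerance (default 0.05).
#' @return Area in mmHg mL (>= 0).
#' @export
loop_area <- function(P, V, tol = 0.05) {
  if (length(P) < 3) stop("need at least 3 samples", call. = FALSE)
  rp <- diff(range(P)); rv <- diff(range(V))
  if (rp == 0 && rv == 0) return(0)
  gap_p <- abs(P[1] - P[length(P)])
  gap_v <- abs(V[1] - V[length(V)])
  if (gap_p > tol * max(rp, 1e-12) || gap_v > tol * max(rv, 1e-12))
    stop("open loop: first and last samples differ beyond tolerance",
         call. = FALSE)
  abs(shoelace(V, P))
}

# intersection parameter of segments p1->p2 and p3->p4, or NULL
seg_intersect <- function(x1, y1, x2, y2, x3, y3, x4, y4) {
  d <- (x2 - x1) * (y4 - y3) - (y2 - y1) * (x4 - x3)
  if (abs(d) < 1e-14) return(NULL)
  s <- ((x3 - x1) * (y4 - y3) - (y3 - y1) * (x4 - x3)) / d
  u <- ((x3 - x1) * (y2 - y1) - (y3 - y1) * (x2 - x1)) / d
  if (s <= 1e-9 || s >= 1 - 1e-9 || u <= 1e-9 || u >= 1 - 1e-9) return(NULL)
  list(s = s, u = u)
}

#' Total area of a possibly self-intersecting loop
#'
#' Atrial pressure-volume loops are typically figure-eight shaped, so the
#' signed shoelace area cancels between sub-loops. This splits the polygon
#' at its self-intersections (recursively, first intersection found) and
#' sums the absolute areas of the sub-loops.
#'
#' @param P,V Loop samples.
#' @param depth Internal recursion guard.
#' @return Total enclosed area in mmHg mL.
#' @export
loop_area_split <- function(P, V, depth = 0) {
  n <- length(P)
  if (n < 3) return(0)
  if (depth < 6) {
    for (i in seq_len(n - 2)) {
      jmax <- if (i == 1) n - 1 else n
      js <- seq(i + 2, jmax)
      for (j in js) {
        jn <- if (j == n) 1 else j + 1
        hit <- seg_intersect(V[i], P[i], V[i + 1], P[i + 1],
                             V[j], P[j], V[jn], P[jn])
        if (!is.null(hit)) {
          xi <- V[i] + hit$s * (V[i + 1] - V[i])
          yi <- P[i] + hit$s * (P[i + 1] - P[i])
          idx1 <- (i + 1):j
          v1 <- c(xi, V[idx1]); p1 <- c(yi, P[idx1])
          idx2 <- if (jn == 1) 1:i else c(jn:n, 1:i)
          v2 <- c(xi, V[idx2]); p2 <- c(yi, P[idx2])
          return(loop_area_split(p1, v1, depth + 1) +
                   loop_area_split(p2, v2, depth + 1))
        }
      }
    }
  }
  abs(shoelace(V, P))
}

#' Elastic potential energy at end-systole
#'
#' Area between the ESPVR and the EDPVR to the left of the end-systolic
#' point: `PE = Ees d^2 / 2 - A ((exp(B d) - 1)/B - d)` with
#' `d = V_es - V0`. Clamped to zero (with a warning) for `V_es < V0`.
#'
#' @param v_es End-systolic volume, mL.
#' @param p A [chamber_params()] object.
#' @return Potential energy in mmHg mL (>= 0).
#' @export
potential_energy <- function(v_es, p) {
  d <- v_es - p$V0
  if (d < 0) {
    warning("end-systolic volume below V0; potential energy clamped to 0")
    return(0)
  }
  edpvr_int <- if (p$B > 0) p$A * (expm1(p$B * d) / p$B - d) else 0
  max(p$Ees * d^2 / 2 - edpvr_int, 0)
}

#' Effective arterial elastance
#'
#' `Ea = P_es / SV`: end-systolic ventricular pressure over stroke volume,
#' the standard lumped measure of the arterial load seen by the ventricle.
#'
#' @param p_es End-systolic ventricular pressure, mmHg.
#' @param sv Stroke volume, mL (> 0).
#' @return Ea in mmHg/mL.
#' @export
arterial_elastance <- function(p_es, sv) {
  if (sv <= 0) stop("no ejection: stroke volume must be > 0", call. = FALSE)
  p_es / sv
}

#' Systemic vascular resistance index
#'
#' Clinical convention `SVRi = 79.9 (MAP - CVP) / CI` in
#' dyn s cm^-5 m^2 (79.9 converts mmHg min/L to dyn s cm^-5).
#'
#' @param map Mean arterial pressure, mmHg.
#' @param cvp Central venous pressure, mmHg.
#' @param co Cardiac output, L/min (> 0).
#' @param bsa Body surface area, m^2 (> 0).
#' @return SVRi in dyn s cm^-5 m^2.
#' @export
svri <- function(map, cvp, co, bsa) {
  if (co <= 0) stop("cardiac output must be > 0", call. = FALSE)
  if (bsa <= 0) stop("`bsa` must be > 0", call. = FALSE)
  79.9 * (map - cvp) / (co / bsa)
}

#' Coronary perfusion index
#'
#' The clinical index (aortic diastolic pressure minus left ventricular
#' end-diastolic pressure) over the coronary vascular resistance. The
#' simulated mean coronary branch flow is reported separately in
#' [haemodynamic_report()].
#'
#' @param aop_dia Aortic diastolic pressure, mmHg.
#' @param lvedp LV end-diastolic pressure, mmHg.
#' @param r_cor Coronary vascular resistance, mmHg s/mL.
#' @return Index flow in mL/s.
#' @export
coronary_flow_index <- function(aop_dia, lvedp, r_cor) {
  (aop_dia - lvedp) / r_cor
}

#' Pulmonary capillary wedge pressure of a beat
#'
#' Time-weighted mean pressure of the pulmonary venous node over the beat
#' (the model's surrogate of left atrial filling pressure).
#'
#' @param beat A `beat_series`.
#' @return PCWP in mmHg.
#' @export
pcwp <- function(beat) {
  unname(cycle_stats(beat$P_pulmonary_veins, beat$t)["mean"])
}

#' Percentage change against the pathological baseline
#'
#' @param assisted Value under support.
#' @param pathological Baseline value (non-zero).
#' @return Signed percentage `100 (assisted - pathological)/pathological`.
#' @export
percentage_change <- function(assisted, pathological) {
  if (any(pathological == 0))
    stop("baseline value is zero; percentage change undefined", call. = FALSE)
  100 * (assisted - pathological) / pathological
}

#' Haemodynamic metric suite of a converged beat
#'
#' Min/mean/max of left atrial, aortic, pulmonary arterial and left
#' ventricular pressures; wedge pressure; chamber end-systolic/diastolic
#' volumes; native cardiac output (LV stroke volume times heart rate),
#' pump flow and total flow; cardiac index; SVRi; mean coronary and
#' cerebral branch flows and the coronary perfusion index. All report-level
#' unit conversions (mL/s to L/min, x79.9) happen here.
#'
#' @param beat A `beat_series` from [run_to_steady_state()].
#' @return One-row data frame of metrics.
#' @export
haemodynamic_report <- function(beat) {
  patient <- attr(beat, "patient")
  lm <- attr(beat, "landmarks")
  t <- beat$t
  lap <- cycle_stats(beat$P_la, t)
  aop <- cycle_stats(beat$P_ascending_aorta, t)
  pap <- cycle_stats(beat$P_pulmonary_artery, t)
  lvp <- cycle_stats(beat$P_lv, t)
  rap <- cycle_stats(beat$P_ra, t)
  sv <- lm$edv_lv - lm$esv_lv
  co <- sv * patient$heart_rate / 1000
  q_pump <- cycle_stats(beat$q_pump, t)[["mean"]] * 60 / 1000
  total <- co + q_pump
  ci <- co / patient$bsa
  links <- patient$links
  r_cor <- sum(links$R[links$role == "coronary"])
  lvedp <- beat$P_lv[which.max(beat$V_lv)]
  data.frame(
    lap_min = lap[["min"]], lap_mean = lap[["mean"]], lap_max = lap[["max"]],
    aop_min = aop[["min"]], aop_mean = aop[["mean"]], aop_max = aop[["max"]],
    pap_min = pap[["min"]], pap_mean = pap[["mean"]], pap_max = pap[["max"]],
    lvp_min = lvp[["min"]], lvp_mean = lvp[["mean"]], lvp_max = lvp[["max"]],
    pcwp = pcwp(beat),
    lvesv = lm$esv_lv, lvedv = lm$edv_lv,
    rvesv = lm$esv_rv, rvedv = lm$edv_rv,
    laesv = min(beat$V_la), laedv = max(beat$V_la),
    co = co, pump_flow = q_pump, total_flow = total, ci = ci,
    svri = svri(aop[["mean"]], rap[["mean"]], co, patient$bsa),
    cbf = cycle_stats(beat$q_coronary_in, t)[["mean"]] * 60,
    cbf_index = coronary_flow_index(aop[["min"]], lvedp, r_cor) * 60,
    cerebral_flow = cycle_stats(beat$q_arch_to_upper, t)[["mean"]] * 60
  )
}

#' Energetic metric suite of a converged beat
#'
#' Ventricular external work (PV-loop areas), elastic potential energies,
#' pressure-volume areas (`PVA = EW + PE` by construction), atrial loop
#' areas (self-intersection aware), effective arterial elastances of both
#' sides and the ventricular-arterial coupling ratios `Ea/Ees`.
#'
#' @param beat A `beat_series` from [run_to_steady_state()].
#' @return One-row data frame of metrics.
#' @export
energetic_report <- function(beat) {
  patient <- attr(beat, "patient")
  lm <- attr(beat, "landmarks")
  lvew <- loop_area(beat$P_lv, beat$V_lv)
  rvew <- loop_area(beat$P_rv, beat$V_rv)
  lvpe <- potential_energy(lm$esv_lv, patient$chambers$lv)
  rvpe <- potential_energy(lm$esv_rv, patient$chambers$rv)
  pes_lv <- beat$P_lv[which.min(beat$V_lv)]
  pes_rv <- beat$P_rv[which.min(beat$V_rv)]
  ea_sys <- arterial_elastance(pes_lv, lm$edv_lv - lm$esv_lv)
  ea_pul <- arterial_elastance(pes_rv, lm$edv_rv - lm$esv_rv)
  data.frame(
    lvew = lvew, rvew = rvew,
    lvpe = lvpe, rvpe = rvpe,
    lvpva = lvew + lvpe, rvpva = rvew + rvpe,
    la_pvla = loop_area_split(beat$P_la, beat$V_la),
    ra_pvla = loop_area_split(beat$P_ra, beat$V_ra),
    ea_sys = ea_sys, ea_pul = ea_pul,
    ea_over_ees_lv = ea_sys / patient$chambers$lv$Ees,
    ea_over_ees_rv = ea_pul / patient$chambers$rv$Ees
  )
}

#' Names of all study metrics
#'
#' The frozen column schema of the study report tables.
#' @return Character vector.
#' @export
metric_names <- function() {
  c("lap_min", "lap_mean", "lap_max", "aop_min", "aop_mean", "aop_max",
    "pap_min", "pap_mean", "pap_max", "lvp_min", "lvp_mean", "lvp_max",
    "pcwp", "lvesv", "lvedv", "rvesv", "rvedv", "laesv", "laedv",
    "co", "pump_flow", "total_flow", "ci", "svri", "cbf", "cbf_index",
    "cerebral_flow",
    "lvew", "rvew", "lvpe", "rvpe", "lvpva", "rvpva", "la_pvla", "ra_pvla",
    "ea_sys", "ea_pul", "ea_over_ees_lv", "ea_over_ees_rv")
}
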