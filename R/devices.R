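#' Centrifugal pump head curve
#'
#' Similarity-law head characteristic `dP = k1 w^2 - k2 Q w - k3 Q^2` with
#' `w` the rotational speed in rpm, `Q` the pump flow in mL/s and `dP` the
#' pressure head in mmHg. At `w = 0` the head is non-positive for all
#' `Q >= 0`.
#'
#' @param k1 Shut-off head coefficient, mmHg/rpm^2 (> 0).
#' @param k2 Cross-term coefficient, mmHg s/(mL rpm) (>= 0).
#' @param k3 Flow-loss coefficient, mmHg s^2/mL^2 (>= 0).
#' @return An object of class `pump_characteristic`.
#' @export
pump_characteristic <- function(k1 = 2.5e-5, k2 = 2e-4, k3 = 0.035) {
  if (k1 <= 0) stop("`k1` must be > 0", call. = FALSE)
  if (k2 < 0 || k3 < 0) stop("`k2` and `k3` must be >= 0", call. = FALSE)
  structure(list(k1 = k1, k2 = k2, k3 = k3), class = "pump_characteristic")
}

#' Pump head at a given flow and speed
#'
#' @param Q Pump flow, mL/s (vectorised).
#' @param rpm Rotational speed, rpm.
#' @param char A [pump_characteristic()].
#' @return Head in mmHg.
#' @export
pump_head <- function(Q, rpm, char) {
  char$k1 * rpm^2 - char$k2 * Q * rpm - char$k3 * Q^2
}

#' Equilibrium pump flow against a pressure difference
#'
#' Solves `head(Q, w) = dp + R Q` for the operating flow: the positive root
#' of `k3 Q^2 + (k2 w + R) Q + (dp - k1 w^2) = 0`. With the backflow valve
#' enabled the flow is clamped at zero (the valve blocks retrograde flow
#' when the head cannot overcome the pressure difference).
#'
#' @param dp Pressure difference return minus drainage site, mmHg.
#' @param rpm Rotational speed, rpm.
#' @param char A [pump_characteristic()].
#' @param r_cannula Total cannula resistance, mmHg s/mL.
#' @param backflow_valve Clamp negative flows to zero (default `TRUE`).
#' @return Flow in mL/s.
#' @export
pump_equilibrium_flow <- function(dp, rpm, char, r_cannula = 0,
                                  backflow_valve = TRUE) {
  b <- char$k2 * rpm + r_cannula
  c0 <- dp - char$k1 * rpm^2
  q <- if (char$k3 > 0) {
    disc <- b^2 - 4 * char$k3 * c0
    (-b + sqrt(pmax(disc, 0))) / (2 * char$k3)
  } else {
    -c0 / b
  }
  if (backflow_valve) pmax(q, 0) else q
}

#' VA ECMO configuration
#'
#' Drainage/return sites, rotational speed, cannula impedance and pump
#' characteristic of the extracorporeal circuit. Central cannulation drains
#' the right atrium and returns to an aortic node; peripheral cannulation
#' drains the femoral vein and returns to a femoral or thoracic arterial
#' node. Both return sites are overridable. The oxygenator is represented
#' only as part of the cannula resistance.
#'
#' @param mode `"off"`, `"central"` or `"peripheral"`.
#' @param rpm Pump speed in rpm.
#' @param drain_node,return_node Node names; defaults by mode (central:
#'   `ra` -> `ascending_aorta`; peripheral: `femoral_vein` ->
#'   `femoral_artery`).
#' @param cannula_resistance Total drainage+return cannula resistance,
#'   mmHg s/mL; default 0.35 (central) / 0.55 (peripheral).
#' @param cannula_inertance Circuit inertance, mmHg s^2/mL.
#' @param priming_volume Extracorporeal circuit volume, mL.
#' @param backflow_valve Block retrograde circuit flow (default `TRUE`).
#' @param characteristic A [pump_characteristic()].
#' @return An object of class `ecmo_config`.
#' @export
ecmo_config <- function(mode = c("off", "central", "peripheral"), rpm = 0,
                        drain_node = NULL, return_node = NULL,
                        cannula_resistance = NULL,
                        cannula_inertance = 0.01,
                        priming_volume = 350,
                        backflow_valve = TRUE,
                        characteristic = pump_characteristic()) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    off = list(drain = NA_character_, ret = NA_character_, r = 0),
    central = list(drain = "ra", ret = "ascending_aorta", r = 0.35),
    peripheral = list(drain = "femoral_vein", ret = "femoral_artery", r = 0.55)
  )
  structure(
    list(mode = mode, rpm = rpm,
         drain_node = if (is.null(drain_node)) defaults$drain else drain_node,
         return_node = if (is.null(return_node)) defaults$ret else return_node,
         cannula_resistance = if (is.null(cannula_resistance)) defaults$r
                              else cannula_resistance,
         cannula_inertance = cannula_inertance,
         priming_volume = if (mode == "off") 0 else priming_volume,
         backflow_valve = backflow_valve,
         characteristic = characteristic),
    class = "ecmo_config"
  )
}

#' Rate of change of the ECMO circuit flow
#'
#' Momentum balance of the cannula flow:
#' `L dQ/dt = head(Q, w) - (P_return - P_drain) - R Q`. With zero cannula
#' inertance the algebraic operating point ([pump_equilibrium_flow()]) is
#' returned instead. With the backflow valve on, retrograde flow is blocked
#' by a steep smooth resistance so `Q >= 0` up to a negligible leak.
#'
#' @param p_drain,p_return Pressures at the drainage and return sites, mmHg.
#' @param cfg An [ecmo_config()] (mode must not be `"off"`).
#' @param Q Current circuit flow, mL/s.
#' @return `dQ/dt` in mL/s^2, or the algebraic flow when
#'   `cannula_inertance = 0` (marked by attribute `algebraic = TRUE`).
#' @export
pump_operating_flow <- function(p_drain, p_return, cfg, Q = 0) {
  if (cfg$mode == "off") stop("ECMO mode is off", call. = FALSE)
  dp <- p_return - p_drain
  if (cfg$cannula_inertance <= 0) {
    q <- pump_equilibrium_flow(dp, cfg$rpm, cfg$characteristic,
                               cfg$cannula_resistance, cfg$backflow_valve)
    return(structure(q, algebraic = TRUE))
  }
  r_block <- if (cfg$backflow_valve) 300 * stats::plogis(-Q / 0.05) else 0
  (pump_head(Q, cfg$rpm, cfg$characteristic) - dp -
     (cfg$cannula_resistance + r_block) * Q) / cfg$cannula_inertance
}

#' IABP configuration
#'
#' Pneumatic balloon drive: a high-pressure source inflates the balloon
#' through the gas delivery resistance during diastole and a vacuum source
#' empties it during systole. The balloon sits at the descending thoracic
#' aorta and acts on the blood as a flow source equal to the rate of change
#' of the gas volume.
#'
#' @param drive_pressure Inflation source pressure, mmHg (> 0).
#' @param vacuum_pressure Deflation source pressure, mmHg (< 0).
#' @param gas_resistance Gas delivery resistance, mmHg s/mL.
#' @param balloon_volume Maximum balloon gas volume, mL (0-60].
#' @param balloon_node Attachment node name.
#' @param inflation_start Cycle fraction at which inflation starts on the
#'   first beat, before any valve landmark exists (default 0.35); from the
#'   second beat on, inflation is triggered at aortic valve closure.
#' @param deflation_start First-beat deflation cycle fraction (default 0.95).
#' @param deflation_lead Lead time of deflation before systole onset, s.
#' @param enabled Logical.
#' @return An object of class `iabp_config`.
#' @export
iabp_config <- function(drive_pressure = 260, vacuum_pressure = -10,
                        gas_resistance = 0.25, balloon_volume = 40,
                        balloon_node = "descending_thoracic_aorta",
                        inflation_start = 0.35, deflation_start = 0.95,
                        deflation_lead = 0, enabled = TRUE) {
  if (enabled) {
    if (!(drive_pressure > 0 && vacuum_pressure < 0))
      stop("require drive pressure > 0 > vacuum pressure", call. = FALSE)
    if (balloon_volume <= 0 || balloon_volume > 60)
      stop("balloon volume must lie in (0, 60] mL", call. = FALSE)
    if (gas_resistance <= 0)
      stop("gas resistance must be > 0", call. = FALSE)
  }
  structure(
    list(drive_pressure = drive_pressure, vacuum_pressure = vacuum_pressure,
         gas_resistance = gas_resistance, balloon_volume = balloon_volume,
         balloon_node = balloon_node, inflation_start = inflation_start,
         deflation_start = deflation_start, deflation_lead = deflation_lead,
         enabled = enabled),
    class = "iabp_config"
  )
}

#' Balloon drive phase at a point in the cycle
#'
#' Counterpulsation timing: inflation begins at aortic valve closure,
#' deflation at systole onset minus the configured lead. Before landmarks
#' exist (first beat) the configured fixed cycle fractions are used. The
#' returned phase distinguishes the transient (`"inflating"`/`"deflating"`)
#' from the saturated (`"inflated"`/`"deflated"`) states using the current
#' gas volume.
#'
#' @param t Time, s.
#' @param period Cardiac period, s.
#' @param cfg An [iabp_config()].
#' @param landmarks Optional list with `t_avc` (aortic valve closure, s,
#'   within the cycle) and `t_systole_onset` (s).
#' @param gas_volume Current balloon gas volume, mL (default 0).
#' @return One of `"inflating"`, `"inflated"`, `"deflating"`, `"deflated"`.
#' @export
iabp_trigger <- function(t, period, cfg, landmarks = NULL, gas_volume = 0) {
  if (!cfg$enabled) return("deflated")
  w <- iabp_windows(period, cfg, landmarks)
  phi <- (t %% period) / period
  in_inflation <- if (w$infl < w$defl) phi >= w$infl & phi < w$defl
                  else phi >= w$infl | phi < w$defl
  if (in_inflation) {
    if (gas_volume >= cfg$balloon_volume) "inflated" else "inflating"
  } else {
    if (gas_volume <= 0) "deflated" else "deflating"
  }
}

# inflation/deflation window start fractions for one beat
iabp_windows <- function(period, cfg, landmarks = NULL) {
  if (is.null(landmarks) || is.null(landmarks$t_avc) || is.na(landmarks$t_avc)) {
    list(infl = cfg$inflation_start, defl = cfg$deflation_start)
  } else {
    onset <- if (is.null(landmarks$t_systole_onset)) 0 else landmarks$t_systole_onset
    infl <- (landmarks$t_avc %% period) / period
    defl <- ((onset - cfg$deflation_lead) %% period) / period
    if (defl == 0) defl <- 1          # deflate at the turn of the cycle
    list(infl = infl, defl = defl)
  }
}

#' Gas flow into the balloon
#'
#' Ohmic gas transport from the drive (inflation) or vacuum (deflation)
#' source through the gas delivery resistance, clipped so the gas volume
#' stays within `[0, balloon_volume]`.
#'
#' @param phase Phase string from [iabp_trigger()].
#' @param p_balloon Pressure surrounding the balloon (local aortic
#'   pressure), mmHg.
#' @param gas_volume Current gas volume, mL.
#' @param cfg An [iabp_config()].
#' @return Gas flow in mL/s (positive = inflating).
#' @export
iabp_gas_flow <- function(phase, p_balloon, gas_volume, cfg) {
  if (!cfg$enabled) return(0)
  switch(phase,
    inflating = ,
    inflated = {
      if (gas_volume >= cfg$balloon_volume) 0
      else (cfg$drive_pressure - p_balloon) / cfg$gas_resistance
    },
    deflating = ,
    deflated = {
      if (gas_volume <= 0) 0
      else (cfg$vacuum_pressure - p_balloon) / cfg$gas_resistance
    },
    0
  )
}

#' Blood flow displaced by the balloon
#'
#' The balloon acts on the blood as a flow source equal to the rate of
#' change of its gas volume: positive into the aortic node while inflating
#' (diastolic augmentation), negative while deflating (systolic unloading).
#' Over one periodic cycle the displaced volume integrates to zero.
#'
#' @param gas_rate `d(gas volume)/dt`, mL/s.
#' @return Blood flow injected at the balloon node, mL/s.
#' @export
balloon_blood_displacement <- function(gas_rate) {
  gas_rate
}

#' Device configuration bundle
#'
#' @param ecmo An [ecmo_config()].
#' @param iabp An [iabp_config()].
#' @return An object of class `device_config`.
#' @export
device_config <- function(ecmo = ecmo_config("off"),
                          iabp = iabp_config(enabled = FALSE)) {
  stopifnot(inherits(ecmo, "ecmo_config"), inherits(iabp, "iabp_config"))
  structure(list(ecmo = ecmo, iabp = iabp), class = "device_config")
}
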