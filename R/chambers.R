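#' Activation timing of a heart chamber
#'
#' Describes when and for how long a chamber contracts within the cardiac
#' cycle. The activation waveform itself is produced by
#' [activation_fraction()].
#'
#' @param period Cardiac period T in seconds.
#' @param onset_frac Fraction of the cycle (in `[0, 1)`) at which systole
#'   starts. Ventricular systole conventionally starts at 0; atrial systole
#'   precedes it by the atrio-ventricular delay.
#' @param systolic_duration Duration of systole Ts in seconds; must satisfy
#'   `0 < Ts < T`.
#' @param peak_frac Position of the activation peak within systole as a
#'   fraction of `systolic_duration` (default 0.5, i.e. a symmetric
#'   raised cosine).
#' @return An object of class `activation_timing`.
#' @export
activation_timing <- function(period, onset_frac = 0, systolic_duration,
                              peak_frac = 0.5) {
  if (!is.numeric(period) || period <= 0)
    stop("`period` must be a positive number", call. = FALSE)
  if (systolic_duration <= 0 || systolic_duration >= period)
    stop("invalid timing: systolic duration must satisfy 0 < Ts < T",
         call. = FALSE)
  if (onset_frac < 0 || onset_frac >= 1)
    stop("`onset_frac` must lie in [0, 1)", call. = FALSE)
  if (peak_frac <= 0 || peak_frac >= 1)
    stop("`peak_frac` must lie in (0, 1)", call. = FALSE)
  structure(
    list(period = period, onset_frac = onset_frac,
         systolic_duration = systolic_duration, peak_frac = peak_frac),
    class = "activation_timing"
  )
}

#' Normalised activation waveform
#'
#' Piecewise raised-cosine activation: zero outside systole, rising from 0 at
#' systole onset to exactly 1 at the peak time `tp = peak_frac * Ts`, and
#' falling back to 0 at the end of systole. With the default
#' `peak_frac = 0.5` this is the single raised cosine
#' `a(s) = (1 - cos(2*pi*s/Ts)) / 2` for `s` in `[0, Ts]`. The waveform is
#' periodic with period T and continuous everywhere.
#'
#' @param t Time in seconds (vectorised); any non-negative values.
#' @param timing An [activation_timing()] object.
#' @return Activation fraction(s) in `[0, 1]`.
#' @export
activation_fraction <- function(t, timing) {
  stopifnot(inherits(timing, "activation_timing"))
  Ts <- timing$systolic_duration
  tp <- timing$peak_frac * Ts
  s <- (t - timing$onset_frac * timing$period) %% timing$period
  a <- numeric(length(s))
  rise <- s < tp
  fall <- !rise & s <= Ts
  a[rise] <- 0.5 * (1 - cos(pi * s[rise] / tp))
  a[fall] <- 0.5 * (1 + cos(pi * (s[fall] - tp) / (Ts - tp)))
  a
}

#' Chamber mechanical parameters
#'
#' Time-varying elastance description of one chamber: a linear end-systolic
#' pressure-volume relation (ESPVR) with slope `Ees` anchored at the
#' unstressed volume `V0`, and an exponential end-diastolic relation (EDPVR)
#' `Ped(V) = A * (exp(B * (V - V0)) - 1)`, also zero at `V0`.
#'
#' @param Ees End-systolic elastance, mmHg/mL (> 0).
#' @param V0 Unstressed volume, mL (>= 0).
#' @param A EDPVR stiffness coefficient, mmHg (>= 0).
#' @param B EDPVR exponent, 1/mL (>= 0).
#' @param timing Optional [activation_timing()] attached to the chamber.
#' @param label Optional chamber name.
#' @return An object of class `chamber_params`.
#' @export
chamber_params <- function(Ees, V0, A, B, timing = NULL, label = NULL) {
  if (Ees <= 0) stop("`Ees` must be > 0", call. = FALSE)
  if (V0 < 0 || A < 0 || B < 0)
    stop("`V0`, `A` and `B` must be non-negative", call. = FALSE)
  structure(list(Ees = Ees, V0 = V0, A = A, B = B, timing = timing,
                 label = label),
            class = "chamber_params")
}

#' Instantaneous chamber pressure
#'
#' Activation-weighted blend of the two limiting pressure-volume relations:
#' `P(V, a) = a * Ees * (V - V0) + (1 - a) * A * (exp(B * (V - V0)) - 1)`.
#' At `a = 1` this is the ESPVR, at `a = 0` the EDPVR; the blend is linear in
#' the activation for fixed volume.
#'
#' @param V Chamber volume, mL (vectorised).
#' @param a Activation fraction in `[0, 1]` (vectorised, recycled).
#' @param p A [chamber_params()] object.
#' @return Pressure in mmHg. Negative transients are physically admissible
#'   (diastolic suction below `V0`).
#' @export
chamber_pressure <- function(V, a, p) {
  stopifnot(inherits(p, "chamber_params"))
  d <- V - p$V0
  a * p$Ees * d + (1 - a) * p$A * expm1(p$B * d)
}

#' Interventricular septal coupling parameters
#'
#' Pressure-superposition coupling between the ventricular free walls: the
#' left ventricular pressure is raised in proportion to right ventricular
#' distension beyond a reference volume (and symmetrically). Zero coupling
#' reduces each ventricle to an independent chamber.
#'
#' @param k_lv Coupling of RV volume into LV pressure, mmHg/mL (>= 0).
#' @param k_rv Coupling of LV volume into RV pressure, mmHg/mL (>= 0).
#' @param vref_lv,vref_rv Reference volumes (mL) about which the coupling
#'   terms are centred.
#' @return An object of class `septum_params`.
#' @export
septum_params <- function(k_lv = 0.02, k_rv = 0.02,
                          vref_lv = 60, vref_rv = 60) {
  if (k_lv < 0 || k_rv < 0)
    stop("septal coupling coefficients must be >= 0", call. = FALSE)
  structure(list(k_lv = k_lv, k_rv = k_rv,
                 vref_lv = vref_lv, vref_rv = vref_rv),
            class = "septum_params")
}

#' Septally coupled ventricular pressures
#'
#' `Plv = Plv_free(Vlv, a_lv) + k_lv * (Vrv - vref_rv)` and symmetrically for
#' the right ventricle. With zero coupling this returns exactly the
#' uncoupled [chamber_pressure()] values.
#'
#' @param Vlv,Vrv Ventricular volumes, mL.
#' @param a_lv,a_rv Activation fractions.
#' @param lv,rv [chamber_params()] for each ventricle.
#' @param s A [septum_params()] object.
#' @return Named numeric vector `c(Plv = ..., Prv = ...)` in mmHg.
#' @export
septal_pressures <- function(Vlv, Vrv, a_lv, a_rv, lv, rv, s) {
  stopifnot(inherits(s, "septum_params"))
  c(Plv = chamber_pressure(Vlv, a_lv, lv) + s$k_lv * (Vrv - s$vref_rv),
    Prv = chamber_pressure(Vrv, a_rv, rv) + s$k_rv * (Vlv - s$vref_lv))
}

#' Valve parameters
#'
#' Ideal diode-resistor valve: zero flow against the gradient, Ohmic flow
#' `(P_up - P_down)/R` when open. An optional smooth regularisation of the
#' corner (softplus of the stated width, in mmHg) keeps the right-hand side
#' differentiable for stiff integration. No regurgitation is modelled.
#'
#' @param resistance Forward resistance, mmHg s/mL (> 0).
#' @param width Regularisation width in mmHg (default 0 = sharp diode).
#' @return An object of class `valve_params`.
#' @export
valve_params <- function(resistance, width = 0) {
  if (resistance <= 0) stop("valve resistance must be > 0", call. = FALSE)
  if (width < 0) stop("`width` must be >= 0", call. = FALSE)
  structure(list(resistance = resistance, width = width),
            class = "valve_params")
}

# numerically stable softplus: width * log(1 + exp(x/width))
softplus <- function(x, width) {
  z <- x / width
  out <- numeric(length(z))
  hi <- z > 30
  mid <- !hi & z > -30
  out[hi] <- x[hi]
  out[mid] <- width * log1p(exp(z[mid]))
  out
}

#' Valve flow
#'
#' @param p_up,p_down Upstream and downstream pressures, mmHg (vectorised).
#' @param v A [valve_params()] object.
#' @return Flow in mL/s; never negative, continuous and monotone
#'   non-decreasing in the pressure gradient.
#' @export
valve_flow <- function(p_up, p_down, v) {
  stopifnot(inherits(v, "valve_params"))
  dp <- p_up - p_down
  if (v$width > 0) softplus(dp, v$width) / v$resistance
  else pmax(dp, 0) / v$resistance
}
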