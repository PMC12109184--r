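---
title: "Closed-loop haemodynamics with VA-ECMO and IABP: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop haemodynamics with VA-ECMO and IABP: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and intent

`cardioloop` is a zero-dimensional (lumped-parameter) simulator of the adult
circulation built to study one question quantitatively: how do central and
peripheral veno-arterial extracorporeal membrane oxygenation (VA ECMO), with
and without intra-aortic balloon counterpulsation (IABP), redistribute
pressures, volumes, flows and ventricular energetics in cardiogenic shock?
The package provides the model, a deterministic shock-patient tuner, the
full haemodynamic/energetic metric suite, and a pipeline that runs the
13-condition support matrix and reports percentage changes against the
unsupported pathological baseline.

Everything is deterministic: identical configurations produce identical
beat series, metric tables and CSV exports.

## The cardiac model

Each of the four chambers is a modified time-varying elastance. Chamber
pressure is an activation-weighted blend of the two limiting
pressure-volume relations,

$$P(V, t) = a(t)\, E_{es}(V - V_0) \;+\; \bigl(1 - a(t)\bigr)\,
A\left(e^{B (V - V_0)} - 1\right),$$

with `Ees` the end-systolic elastance (slope of the ESPVR), `V0` the common
volume intercept, and an exponential end-diastolic relation (EDPVR) with
stiffness `A` (mmHg) and exponent `B` (1/mL). Both limbs are anchored at
zero pressure at `V0`; pressures below `V0` are admissible transients
(diastolic suction).

The activation `a(t)` is a piecewise raised cosine: zero outside systole,
rising from 0 at systole onset to exactly 1 at the peak time
`t_p = peak_frac * Ts` and returning to 0 at the end of systole `Ts`. With
the default `peak_frac = 0.5` this is the single raised cosine
`a(s) = (1 - cos(2*pi*s/Ts))/2`. Ventricular systole lasts
`0.35*sqrt(T)` s and atrial systole `0.17*sqrt(T)` s; atrial activation
precedes ventricular activation by an atrio-ventricular delay of 0.16 s at
T = 0.857 s, scaled linearly with the period. These timing rules are
standard square-root rate corrections; none of them is a fitted quantity.

Ventricular interdependence is a pressure-superposition septal coupling:
`P_lv = P_lv,free + k_sept (V_rv - V_rv,ref)` and symmetrically, with a
small default `k_sept = 0.02` mmHg/mL. Setting the coupling to zero
reduces each ventricle exactly to an independent chamber, which keeps the
term testable in isolation.

Valves are ideal diodes with a series resistance and no regurgitation. For
stiff integration the corner is smoothed by a softplus of width 0.1 mmHg;
the smoothing admits a parasitic conductance only within a fraction of a
mmHg of the closing point, far below the gradients at which the valves
operate. Tests that need exact zero flows (equilibrium states) set the
width to zero.

## The vascular network

The closed loop follows the classic systemic topology: left ventricle,
ascending aorta, aortic arch, descending thoracic aorta (carrying the
thoracic resistance and the balloon attachment), thoracic/abdominal aorta,
and five parallel beds — upper limbs and head (the cerebral flow tap),
renal-hepatic, splanchnic, abdominal, and lower limbs with explicit
femoral artery and femoral vein nodes. Venous return collects through the
superior and inferior venae cavae into the right atrium; the pulmonary
circulation (pulmonary artery, microvascular bed, pulmonary veins) closes
the loop into the left atrium. A coronary branch runs from the aortic root
through an RC compartment into the right atrium.

Each segment is an RLC element: `L dQ/dt = P_in - P_out - R Q` where
inertance is present (proximal aorta, pulmonary artery), the algebraic
`Q = (P_in - P_out)/R` otherwise, and `C dP/dt = Q_in - Q_out` at every
compliant node. Flows are positive in the direction of normal circulation
and device flows positive into the arterial system, so the sign of every
percentage change is unambiguous. External (intrathoracic) pressure is a
constant zero; respiratory coupling is deliberately out of scope.

All parameter values live in one packaged file,
`inst/extdata/healthy_patient.yaml`. They are stand-ins assembled from
standard lumped-parameter practice — commercial cardiovascular simulators
do not publish their patient parameterisations, so no reference set exists
— and are calibrated once so that the simulated healthy subject lands in a
documented sanity band (cardiac output 4.5–6 L/min, mean aortic pressure
85–100 mmHg at 70 bpm). Two deliberately "anatomically generous" choices
deserve mention because they are load-bearing for device physics rather
than baseline haemodynamics:

* the venous inflow resistances into the right atrium (0.10–0.11
  mmHg·s/mL) let a central drainage cannula pull the right atrium below
  the caval pressure and thereby starve the right ventricle at high pump
  speed; with looser coupling the cannula drains the entire venous pool
  and central support fails to decongest the lungs;
* the femoral-vein-to-cava resistance (0.60 mmHg·s/mL) represents the
  iliofemoral drainage path with an indwelling cannula partially
  obstructing the vessel; it localises peripheral suction at the femoral
  vein so that peripheral support congests rather than unloads the right
  heart.

## Support devices

**VA ECMO.** The centrifugal pump follows the similarity-law head curve
`dP = k1 w^2 - k2 Q w - k3 Q^2` (`w` in rpm, `Q` in mL/s, `dP` in mmHg)
with defaults `k1 = 2.5e-5`, `k2 = 2e-4`, `k3 = 0.035`, calibrated once so
that the shock fixture receives roughly 2–5 L/min across 3000–4000 rpm —
the clinically familiar range. The circuit flow is a state with cannula
inertance: `L_c dQ/dt = head(Q, w) - (P_return - P_drain) - R_c Q`. A
backflow valve is modelled as a narrow reverse-only resistance
(`300 * plogis(-Q/0.05)` mmHg·s/mL), which blocks retrograde flow while
adding a negligible drop (< 2 mmHg) to forward operation. Central
cannulation drains the right atrium and returns to the ascending aorta;
peripheral cannulation drains the femoral vein and returns to the femoral
artery. Clinical practice varies — central return is sometimes placed at
the descending aorta and peripheral return reaches the thoracic aorta with
long cannulae — so drainage and return sites are plain configuration
fields validated against the topology; the defaults above are this
package's choice. The oxygenator appears only as part of the cannula
resistance.

**IABP.** The balloon at the descending thoracic aorta is driven
pneumatically: gas flows from a 260 mmHg drive source during diastole and
to a −10 mmHg vacuum source during systole, through a gas delivery
resistance of 0.25 mmHg·s/mL, clipped so the gas volume stays within
[0, 40] mL. The blood sees a flow source equal to `+d(gas volume)/dt` at
the balloon node: positive (diastolic augmentation) while inflating,
negative (systolic unloading) while deflating. Inflation triggers at the
aortic valve closure detected on the previous beat; deflation at systole
onset (configurable lead). On the first beat, before landmarks exist,
fixed cycle fractions (0.35 and 0.95 of the cycle) bootstrap the timing.
The drive windows are smoothed over ~8 ms so the right-hand side stays
continuous for the adaptive stiff integrator.

## Numerics

The global system (chamber volumes, node pressures, inertant flows, pump
flow, balloon gas volume — 24 states for the default topology) is
integrated beat by beat with `deSolve::lsoda` at `rtol = 1e-6`,
`atol = 1e-5`. A run is declared periodic when every monitored scalar
(left/right stroke volume, LV end-diastolic volume, mean aortic, pulmonary
arterial and pulmonary venous pressures) changes by less than `1e-3`
(relative) from one beat to the next; the default cap is 60 beats and
typical runs converge in 10–30. The returned beat is sampled at 200 Hz.
Sampled extrema of reported pressures are refined by a parabolic fit
through the three samples around the discrete extremum, which removes the
O(dt²) sampling bias from quantities such as systolic aortic pressure.

Volume conservation is structural — every flow leaves one compartment and
enters another — so total blood volume (chambers + segments + circuit
priming − balloon gas displacement) is conserved to solver tolerance; the
test suite bounds the drift below 0.5% over 20 beats and it is typically
orders of magnitude smaller.

## The cardiogenic-shock fixture

The pathological baseline is produced from the healthy reference by a
deterministic tuner targeting the standard shock criteria: systolic blood
pressure < 90 mmHg, SVRi < 1800 dyn·s·cm⁻⁵·m², wedge pressure > 15 mmHg
and cardiac index < 2.2 L/min/m². The shock phenotype has five declared
components: the LV end-systolic elastance scale (tuned), total blood
volume (tuned), a common scale on the systemic bed resistances (tuned), a
fixed RV elastance scale (square root of the LV scale — biventricular but
left-dominant failure) and a fixed diastolic stiffening of the failing LV
(EDPVR exponent × 1.6). Heart rate is fixed at 90 bpm (typical shock
tachycardia) and body surface area at 1.8 m².

The diastolic stiffening deserves its rationale: with the healthy EDPVR,
the only way to satisfy wedge > 15 mmHg together with CI < 2.2 L/min/m² is
an end-systolic elastance so low that the left ventricle stops ejecting
once the retrograde ECMO jet raises aortic pressure — the aortic valve
then stays closed, pulmonary blood is trapped, and the model cannot
reproduce the qualitative behaviour the support study is about. Acute
ischaemic failure raises passive chamber stiffness, and a modest fixed
stiffening resolves the degeneracy while leaving the tuner with the three
haemodynamic knobs.

The tuner itself is a fixed sequence of monotone bisections (elastance
scale down until the pressure and index targets are met; volume up until
the wedge target is met; bed resistance until the SVRi target is met),
re-verifying all four bounds after each pass, with internal targets placed
inside the bounds so knob cross-talk cannot un-satisfy a previously met
criterion. There is no randomness: the tuner recovers the bounds from
perturbed starting knobs, and two runs from identical inputs are
byte-identical. The tuned fixture ships as
`inst/extdata/cs_patient_synthetic.yaml` (regenerated by
`tools/make_fixtures.R`); the `synthetic` in the name is deliberate — it
stands in for an unpublished reference parameterisation.

## Metrics

From the converged beat the package reports min/mean/max left atrial,
aortic, left ventricular and pulmonary arterial pressures (trapezoidal
time averages); wedge pressure as the mean pulmonary venous node pressure;
end-systolic/diastolic volumes of both ventricles and the left atrium
(volume extrema); native cardiac output (LV stroke volume × heart rate),
pump flow and total flow; cardiac index CO/BSA; SVRi in the clinical
convention `79.9 (MAP − CVP)/CI` (the alternative reading "SVR divided by
BSA" contradicts the customary unit dyn·s·cm⁻⁵·m², so the clinical
convention is implemented); the simulated mean coronary branch flow plus
the clinical perfusion index `(AoP_dia − LVEDP)/R_cor` (both exposed,
labelled); and the mean flow of the upper-limbs-and-head branch as
cerebral flow.

Energetics follow the pressure-volume-area framework: external work `EW`
is the shoelace area of the ventricular PV loop; potential energy `PE` is
the area between the ESPVR and EDPVR left of end-systole,
`Ees d²/2 − A((e^{Bd}−1)/B − d)` with `d = V_es − V0`; and
`PVA = EW + PE` holds exactly by construction. Atrial loops are typically
figure-eight shaped, so their area is computed by splitting the polygon at
self-intersections and summing absolute sub-loop areas — a convention this
package defines explicitly because none is standard. Effective arterial
elastance is `Ea = P_es/SV` per side, and ventricular-arterial coupling is
reported as `Ea/Ees` against the (scaled) chamber elastance. Unit
conversions (mL/s → L/min, ×79.9) happen only at the report boundary.

## The study pipeline

`run_matrix()` enumerates the 13 conditions — the pathological baseline
plus {central, peripheral} × {3000, 3500, 4000 rpm} × {IABP off, on at
260/−10 mmHg} — and `run_study()` executes them against one baseline,
assembling absolute metrics and signed percentage changes
`100 (assisted − baseline)/baseline`. `directional_checks()` evaluates the
qualitative expectations of this support physiology (central support
unloads the right heart and lungs while loading the LV; peripheral support
congests both ventricles and raises wedge and pulmonary pressures;
coronary and total flow grow with pump speed; counterpulsation raises mean
aortic pressure at every matched condition) and reports each with its
observed signed percentage. Reports export to two CSVs plus a JSON summary
with a configuration hash; exports round-trip numerically.

Problem sizes were chosen for desk-scale reproducibility: the tuner needs
roughly forty short steady-state runs and the full matrix thirteen, each a
10–30 beat integration; the complete pipeline runs in minutes on one CPU.

## What the synthetic fixtures do and do not show

The generator emulates the *study conditions*: a guideline-defined shock
state and the support matrix applied to it. It does not emulate
patient-specific waveforms, autonomic reflexes (no baroreflex — percentage
changes are pure mechanics), respiratory pressure swings, gas exchange, or
the wall-shear/haemolysis physics of real cannulae. Passing the
directional suite therefore shows that the implemented mechanics reproduce
the qualitative redistribution this class of models predicts — not that
any individual patient's numbers would match. Quantitative percentage
changes depend on the stand-in parameterisation and are expected to differ
from any particular published figure; the four shock-criterion bounds are
the only numeric anchors, and they are met by construction of the tuner
with margin determined by the physics, not by fitting.

## Known limitations

* No regurgitant valves, no stenoses; valve smoothing admits sub-mmHg
  leak conductance near the closing point.
* No baroreflex or metabolic autoregulation; regional beds are fixed
  resistances, so flow redistribution under support is purely mechanical.
* The balloon displaces volume at a single node; it has no axial extent,
  so it cannot occlude the aorta or generate the "de-clamping" wave
  effects of a real device.
* Atrial loop-area conventions differ between groups; comparisons of
  PVLA magnitudes across tools should use the definition stated above.
* The linear ESPVR makes stroke volume strongly Starling-sensitive; the
  shock fixture's fixed diastolic stiffening compensates within the range
  of the study, but extreme volume loading outside the tuner bounds will
  exaggerate output.
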