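---
title: "A closed-loop lumped-parameter model of graded head-up tilt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop lumped-parameter model of graded head-up tilt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiotilt)
```

## The problem

Passive head-up tilt (HUT) shifts blood toward the dependent body under
gravity. Central venous pressure and ventricular filling fall, stroke volume
drops, and the arterial and cardiopulmonary baroreflexes plus local vascular
autoregulation act to keep arterial pressure nearly constant while heart
rate rises. `cardiotilt` implements a closed-loop 0-D (lumped-parameter)
model of this response for healthy subjects and for a simulated congestive
heart-failure (NYHA class III) state, together with the parameter-estimation
machinery needed to fit its reflex constants to tilt-table measurements.

## Model structure

**Heart.** Four chambers, each obeying an activation-blended
pressure-volume law
\[
P(V, t) = e(t)\,E_{es}(V - V_0) + \bigl(1 - e(t)\bigr)\,
P_0\bigl(e^{\lambda (V - V_0)} - 1\bigr) + P_{ext},
\]
linear end-systolic (ESPVR) and exponential end-diastolic (EDPVR)
relationships. The activation \(e(t)\) is a raised-cosine lobe occupying a
fixed fraction (default 0.48) of the beat: it peaks at 1, is exactly zero
through diastole, and its broad top lets even a weak ventricle complete
ejection. The atria use the same law with their own lobe, peaking 0.16 of a
beat before ventricular onset. The ventricles share the interventricular
septum: its displacement volume solves the transseptal pressure balance (a
Newton iteration to a 1e-10 mmHg residual) so that left-sided loading bulges
the septum rightward and vice versa. The ventricles and myocardium are
enclosed by the pericardial sac, a passive exponential pressure-volume law;
the atria sit outside the sac. This placement matters: during tilt the sac
unloads as the ventricles shrink, letting central luminal pressures fall
deeply while ventricular transmural filling is partly preserved; in heart
failure the dilated ventricles engage the sac, which raises filling
pressures at little volume cost and assists systolic pressure generation.
The four heart valves are resistances in series with inertances; flow is a
state variable, a valve closes when its flow decelerates through zero and
re-opens only under a positive gradient.

**Circulation.** Six parallel systemic branches (cerebral, upper body,
coronary, splanchnic, renal, lower body), each an arterial/peripheral plus a
venous compartment, joined at the large-artery node and the thoracic veins;
the pulmonary loop is a three-compartment series (arteries, capillaries,
veins). Each compartment stores volume according to its transmural pressure
\((V - V_u)/C\); flow nodes are heart-referenced, i.e. the node pressure is
the transmural pressure minus the hydrostatic column
\(\rho g h \sin\alpha\) of the compartment's distance \(h\) from the
hydrostatic indifference point at heart level (1 mmHg = 133.322 Pa,
\(\rho\) = 1060 kg/m^3). With this convention supine (\(\alpha = 0\)) is
exactly independent of the \(h\) values, and tilting pools blood below the
heart and drains compartments above it, as it must. Venous compartments
above the heart stiffen by a factor 10 when their transmural pressure goes
negative (vessel collapse); without this the cerebral and upper-body
drainage overshoots grossly. The lower-body venous compartment uses the
arctangent capacity law
\[
P = \frac{2(V_{max} - V_u)}{\pi C_0}
    \tan\!\Bigl(\frac{\pi (V - V_u)}{2 (V_{max} - V_u)}\Bigr),
\]
whose local compliance is \(C_0\) at the unstressed volume and vanishes as
the volume approaches \(V_{max}\) (700 mL): at high tilt angles the leg
veins stiffen and transmural pressure, not volume, absorbs the gravitational
load. Venous valves (ideal diodes) prevent retrograde flow out of every
systemic venous compartment. Baseline resistances compose to 1.06 mmHg·s/mL
systemic and 0.13 pulmonary; systemic compliance totals ~115 mL/mmHg.

**Reflexes.** The arterial baroreceptors sense the large-artery pressure
minus a 16-cm carotid column scaled by \(\sin\alpha\), filtered through a
pole-zero linear block and a bounded sigmoid. Efferent sympathetic activity
decays exponentially with afferent firing, vagal activity rises
sigmoidally. Four effector arms respond to the log-transformed sympathetic
drive through first-order dynamics with transport delays: the four
controlled peripheral resistances, the four venous unstressed volumes
(venous tone), the two ventricular contractilities, and the heart period
(which also takes the vagal activity, and is sampled once per beat at beat
onset). Effector statics are expressed relative to calibrated supine
baselines: value \(= \sigma_0 (1 + g\,(x - x_{ref})/k_D)\), where
\(x_{ref}\) is the supine mean drive and \(k_D\) the desensitization
factor. The cardiopulmonary (low-pressure) reflex is a bounded linear
deviation of low-pass-filtered central venous pressure from its set-point,
wired to the peripheral resistances only. The lower-body resistance is
additionally scaled by a myogenic factor linear in the local arterial
transmural pressure deviation, calibrated so its tilt-induced relative rise
is twice the upper-body rise.

## Numerical scheme

The full system (21 volumes, 4 valve flows, 13 reflex/effector states) is
integrated by a fixed-step classical Runge-Kutta scheme, default step
0.5 ms, output resampled at 200 Hz. Valves are handled by zero-crossing
clamping: a closed valve's flow state is pinned at zero until its pressure
gradient turns positive; |Q| below 1e-9 mL/s counts as closed. Transport
delays are exact ring buffers (a benefit of the fixed step). A fixed step
was chosen over an adaptive stiff solver because the pulsatile right-hand
side is evaluated millions of times per run and the step-halving check
below replaces adaptive error control: halving the step changes all
beat-averaged outputs by well under 0.1%. Total blood volume is conserved
to ~1e-13 relative over minutes of simulated time.

Steady state is declared when two consecutive 5-beat windows of
beat-averaged arterial pressure and cardiac output agree to 0.1%; reported
values average the trailing 12 beats (about 15 s, mirroring typical
experimental averaging windows). Each tilt angle settles for at least 120 s
before the test, after a 60 s supine cold-start absorption; tilt
transitions are 2-s linear ramps in \(\sin\alpha\) (the model targets
steady state, so the ramp shape is immaterial, but discontinuities hurt the
integrator). At the calibrated gains and the published 2-s sympathetic
latency the closed loop exhibits slow Mayer-type pressure oscillations;
since transient fidelity is outside the model's scope, the default
latencies are shortened (0.5 s sympathetic, 0.2 s vagal), which damps the
oscillation without affecting the steady-state operating points.

## Parameters and calibration

Chamber, septum, pericardium and valve constants start from the published
minimal heart model this model family builds on; afferent/efferent
constants from the published short-term regulation models. Neither source
fixes every number for this configuration, so the bundle was calibrated in
two documented stages (see `scripts/calibrate.R`): unstressed volumes are
back-computed so the supine equilibrium reproduces the regional volume and
flow distribution of the six districts at the target pressures, and the
effector reference drives are set to the realized supine mean drives (beat
rectification makes the mean drive differ slightly from the static
set-point value; making the reference explicit decouples the supine
operating point from the gain magnitudes). Gains were then tuned against
the healthy tilt response: arterial pressure change ~+4 mmHg and under
5 mmHg variation across angles, heart rate ~+21%, stroke volume ~-36%,
cardiac output ~-24% at 80 degrees, thoracic volume reduction inside the
26-30% band, lower-body pooling ~+25%, lower-body flow ~-53%, and the 2:1
lower/upper resistance-rise ratio.

Two deliberate deviations from commonly quoted constants are worth
flagging. First, the afferent zero time constant is 1.0 s (not ~6 s): the
larger value amplifies the arterial pulse roughly three-fold through the
lead-lag block and saturates the firing sigmoid within every beat,
destroying mean-pressure sensitivity in this implementation. Second, total
pulmonary compliance is 14 mL/mmHg rather than the often-assumed 32: with
32, the heart-failure scenario's fixed +600 mL volume increase cannot
congest the left side to a mean left-atrial pressure of ~24 mmHg — the
required volume would be roughly twice the budget. The smaller pulmonary
venous compliance resolves this while the healthy thoracic depletion is
carried by the heart chambers and pulmonary arteries.

With the defaults, the healthy supine state settles at MAP ~86 mmHg, HR
~68 bpm, SV ~68 mL, CO ~4.7 L/min; the LV end-diastolic volume settles
near 100 mL, on the low side of published supine values — a consequence of
the relatively stiff EDPVR needed for the heart-failure congestion (below).

## Scenarios and hypothesis toggles

`scenario_heart_failure()` applies the published NYHA-III modifier set: LV
contractility x0.2, RV x0.6, pulmonary resistance x1.4, baseline systemic
resistance x1.25, +600 mL blood volume, and effector desensitization
factor 10. Desensitization divides the sympathetic static gains; the vagal
arm of the heart-period effector keeps its full gain (vagal withdrawal is
not a sympathetic effector characteristic), which is what raises the
resting heart-failure heart rate while leaving the desensitized-only
single-factor scenario exactly at healthy supine values. The resulting
state reproduces the congested left side (mean left-atrial pressure
~25 mmHg, pulmonary arterial pressure ~33 mmHg) and the blunted tilt
response (all percentage changes smaller in magnitude than healthy). Known
limitation: arterial pressure (~70 mmHg) and cardiac output (~2.8 L/min)
fall below published heart-failure ranges — with the six fixed modifiers, a
+600 mL budget, and compliances consistent with the healthy tilt response,
the left-atrial pressure target and the output targets cannot be met
simultaneously; reproducing all of them would need roughly 1000 mL of
congestion volume. The package resolves the conflict in favour of the
filling-pressure target, and the corresponding acceptance test documents
the miss.

`perturb_single_factor()` applies exactly one modifier (the LV diastolic
stiffness column uses x2 on the LV EDPVR coefficient — the source tables do
not print the multiplier). `hypothesis_toggles()` switches off the
cardiopulmonary reflex (gain 0), the myogenic response (constant 0), or
freezes the pericardial pressure at the scenario's supine mean
(`freeze_pericardium()`), and can multiply the four efferent resistance
gains by a common factor (`retune_resistance_gains()` calibrates the factor
that matches the CP-intact resistances at supine and maximal tilt).

## Parameter estimation

`synth_measurements()` emulates a 13-subject tilt-table dataset: supine
absolutes of MAP, HR, SV and CO plus per-angle changes, with independent
Gaussian noise, deterministic per seed. The objective is the weighted sum
of squared residuals; default weights are inverse squared variable scales
so mmHg, bpm, mL, L/min and percentage-point residuals are commensurate
(the source material does not state its weights). Fitting is bounded
Levenberg-Marquardt over multiplicative factors, with the two physiologic
constraints (thoracic reduction in 26-30%; lower/upper resistance-rise
ratio 2) available as quadratic penalties and always checked post-fit. The
finite-difference Jacobian uses a relative step of 1e-2: beat-count
quantisation in the periodic-orbit averages makes smaller steps
noise-dominated, which is also why the nominal 1e-4 step suggested by
gradient-based-optimization folklore is not used here. Sensitivity
screening perturbs each parameter +10% and reports
\(S = ((J - J_0)/J_0)/0.1\); covariance-guided subset reduction iteratively
removes the free parameter with the largest absolute pairwise correlation
at the optimum, stopping when the objective degrades by more than 10% or no
pair is correlated above 0.5.

The test-suite and acceptance problem sizes are deliberately reduced:
estimation checks run on the angle grid {0, 40, 80} with 40 s settling per
angle and a 1-ms step, where noise-free recovery from 20%-perturbed starts
returns the generating factors to well under 1%.

## What the synthetic data do and do not show

The generator reproduces the structure of the experimental dataset —
subject count, angle grid, variable set, independent Gaussian noise — but
not its physiology: real subjects differ in their parameters (the generator
uses one truth for all subjects), real noise is not independent across
angles, and real tilt data contain transients, breathing and measurement
artefacts that the steady-state model excludes by design. Passing the
recovery tests therefore demonstrates identifiability and correctness of
the estimation machinery under the model's own assumptions, not field
performance on clinical recordings.

## Known limitations

* Transient response in the first ~30 s after tilt is out of scope (no
  venous viscoelasticity; shortened reflex latencies).
* The cardiopulmonary reflex is a simplified bounded-linear pathway wired
  to the resistances only; no respiratory or hormonal control.
* Heart-failure arterial pressure and cardiac output under-shoot published
  ranges (see above).
* The supine LV end-diastolic volume is low relative to published means;
  stroke volume, output and pressures are nevertheless within tolerance.
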