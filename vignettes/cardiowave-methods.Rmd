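---
title: "The cardiowave model and estimation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cardiowave model and estimation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(cardiowave)
```

## The model

cardiowave simulates systemic arterial blood pressure with a four-compartment
lumped-parameter model: an aortic **exit region** (`e`), the **arterial
tree** (`a`), the **venous pool** (`v`) and the **left ventricle** (`LV`).
Each vascular compartment stores blood volume in a linear compliance,
\(V = V_0 + C\,p\), and compartments exchange volume through Poiseuille-type
resistances, \(Q = \Delta p / R\). Conservation of blood volume in each
compartment gives four coupled ODEs:

\[
\begin{aligned}
C_e \dot p_e &= \frac{p_{LV}-p_e}{R_e(t)} - \frac{p_e-p_a}{R_a} + f(t) \\
C_a \dot p_a &= \frac{p_e-p_a}{R_a} - \frac{p_a-p_v}{R_{LV}} \\
C_v \dot p_v &= \frac{p_a-p_v}{R_{LV}} - \frac{p_v-p_{LV}}{R_v(t)} \\
\frac{d}{dt}\!\left(\frac{p_{LV}}{E_{LV}(t)}\right)
  &= \frac{p_v-p_{LV}}{R_v(t)} - \frac{p_{LV}-p_e}{R_e(t)} - f(t)
\end{aligned}
\]

The resistance placement follows the physiology and the printed magnitudes:
`R_LV` (~0.3–1.2 s·mmHg/ml) is the systemic peripheral resistance between
arteries and veins — it sets both the diastolic decay time
\(\tau \approx (C_e + C_a) R_{LV}\) and a cardiac output of ~4–7 L/min — while
the two small resistances `R_e0` and `R_v0` (~0.005–0.016) are the open
aortic and mitral valves. Placing the small resistance on the periphery
would give a diastolic decay time of ~10 ms and litres-per-second flows,
so no other assignment is viable.

### The pump

The ventricle is driven by a prescribed time-varying elastance
\(E_{LV}(t) = E_d + a(t)\,(E_s(t) - E_d)\). The activation
\(a(t) = \sin^2\!\big(\psi/(2\phi)\big)\) rises from 0 to 1 and back over the
systolic fraction \(\phi\) (default 1/3) of each beat and is zero in
diastole; \(\psi\) is the cardiac phase since the start of the beat. Because
the heart rate is modulated by respiration,
\(\omega(t) = \omega_0 + c_3 \sin(\omega_0 t / c_2)\), beats are delimited by
the *accumulated* phase
\(\Phi(t) = \int_0^t \omega(s)\,ds
 = \omega_0 t - \frac{c_3 c_2}{\omega_0}\big(\cos(\omega_0 t/c_2) - 1\big)\):
a new beat starts at every multiple of \(2\pi\). This closed form makes the
beat grid exact and reproducible — the alternative (re-reading \(\omega\) at
each beat start) would let rounding decide beat boundaries. The systolic
amplitude is modulated on the same respiratory time scale,
\(E_s(t) = E_{s0} + c_1 \sin(\omega_0 t / c_2)\); `c2` is the number of
heart beats per breath (typically 4–7 in ventilated patients).

### Valves and the dicrotic notch

The aortic valve is a soft exponential diode,
\(R_e = R_{e0}\,[1 + \varepsilon_1 e^{-A_1 (p_{LV}-p_e)}]\), capped at the
maximum resistance `R_eM`. With the conventional
\(\varepsilon_1 = 10^{-5}\), \(A_1 \approx 0.4\text{–}0.5\) /mmHg the
resistance only doubles once the reverse gradient reaches
\(\ln(1/\varepsilon_1)/A_1 \approx 23\text{–}28\) mmHg and reaches the cap
near 47 mmHg, so the valve is deliberately leaky over a wide band of reverse
gradients — `A1` is therefore a genuinely influential shape parameter (it
ranks in the top half of the sensitivity table) and not a mere numerical
device. The mitral valve is a Heaviside switch: `R_v0` while
\(p_v \ge p_{LV}\) (equality counts as open, which avoids chattering on a
zero-measure set), `R_eM` otherwise.

Valve closure launches the dicrotic-notch mechanism: each downward crossing
of \(p_{LV} - p_e\) through zero is an event \(t_n\), and blood rebounding
off the closing valve re-enters the exit region as a Gaussian flux pulse
\(f(t) = c_4 \exp\big(-c_5 (t - t_n - c_6 \Delta t)^2 / \Delta t^2\big)\),
subtracted from the ventricle so no volume is created. The closure delay
\(\Delta t\) is held at `dt0` by default (`dt_mode = "fixed"`; the
per-patient parameter sets ship fitted `dt0` values), or measured each cycle
as the interval from \(t_n\) to the moment \(R_e\) first exceeds
\(2 R_{e0}\) (`dt_mode = "adaptive"`). By default every pulse whose Gaussian still
overlaps the present remains active (`f_mode = "sum"`). This matters
because the fitted closure delays sit within 1% of a full heart period, so
with \(c_6 \ge 1\) a pulse peaks one or more beats *after* the event that
launched it — truncating pulses at the next event (`f_mode = "latest"`)
would erase the notch of any patient with \(c_6 > 1\) entirely, including
the large-notch fixture whose pulse fires 3.5 beats late.

### State variable and conservation

The integrated ventricular state is the volume-like
\(U_{LV} = p_{LV}/E_{LV}(t)\), not \(p_{LV}\): this removes the \(\dot E\)
term from the equations and makes the total stored volume
\(C_e p_e + C_a p_a + C_v p_v + U_{LV}\) an exact invariant of the
right-hand side (the fluxes telescope around the loop and \(f\) cancels
between the exit and ventricular equations). Conservation is therefore a
sharp correctness probe: over a 30-s run the simulator keeps the relative
drift near 1e-14, and the test suite requires < 1e-6.

## Numerics

The system is integrated with a stiff-capable adaptive solver
(`deSolve::lsodar`, compiled right-hand side, `rtol = atol = 1e-8`) with
root-finding for the valve-closure events. Two numerical guards matter:

* **Exponent clamping.** The valve exponent is clamped at 700 before
  exponentiation; beyond that the cap `R_eM` dominates anyway.
* **Hysteresis in event detection.** The soft valve admits a regime in
  which \(p_{LV}\) hovers within solver noise of \(p_e\) for a sizeable
  fraction of diastole. A naive root-restart loop then detects thousands of
  crossings per beat. After an accepted closure (classified by the true
  \(d(p_{LV}-p_e)/dt\) computed from the right-hand side), the root function
  is re-armed only once \(p_{LV} - p_e\) has risen through +2 mmHg, i.e.
  the valve has genuinely reopened. The 2-mmHg threshold is far below any
  systolic forward gradient and far above the hovering noise.

Simulated traces are sampled at 100 Hz by default — a typical bedside
monitor rate that resolves the notch.

A deliberately passive configuration (elastance pinned at \(E_d\), no notch
pulse) must relax to the compliance-weighted mean of the initial pressures,
\(p^\* = \frac{C_e p_{e0} + C_a p_{a0} + C_v p_{v0} + U_0}
{C_e + C_a + C_v + 1/E_d}\); the suite checks this closed form to 1e-8.

## Sensitivity analysis

`sensitivity_table()` ranks parameters by how much a relative perturbation
changes the arterial output: each parameter is scaled to \((1\pm q)\) times
nominal, the model is run at both values, and the score is the \(L_2\)
distance between the two arterial traces over a 20-beat window placed after
10 settling beats. Approximately dependent parameters are perturbed as a
group (\(C_v = 1/E_d\), \(C_a = C_e = 1/E_{s0}\), \(R_{v0} = R_{e0}\),
\(p_{e0} = p_{LV0} = p_{a0}\)): scaling one member scales its proportional
partners by the same factor and reciprocal partners by the inverse, so the
nominal values are preserved while the relation's shape is honoured —
applying the reciprocal relation literally to the nominal values would be a
−67% jump, not a perturbation. Each group is reported once, by its
largest-score member, giving 19 independent directions.

The nominal configuration uses the literature constants with initial
pressures \(p_{a0} = p_{e0} = p_{LV0} = 35\), \(p_{v0} = 10\) mmHg, and the
*adaptive* closure-delay mode, under which `dt0` seeds only the first cycle;
its influence has decayed by the comparison window and it duly ranks last
with a score that is zero at any reasonable printed precision. The diastolic
elastance group (\(E_d\), \(C_v\)) ranks first at every perturbation size:
it controls both the ventricle's diastolic stiffness and the largest volume
reservoir. Scores grow with \(q\) for every direction except `c2`, the
beats-per-breath: perturbing the respiratory period makes the two traces
drift in and out of phase across the fixed window, so its score aliases
rather than grows.

## Parameter estimation

`fit_cardio()` runs four stages, each consuming the previous stage's
parameters. All comparisons happen on a window that starts after 10 beats
(clear of the initial transient) and spans three respiratory cycles,
clipped to the recording's extent.

**Initial guesses** (`init_guesses()`). The arterial compliance comes from
the stroke-volume/pulse-pressure ratio \(C_a = SV/(P_{sys}-P_{dia})\) with
an assumed 70 ml stroke volume (not observable from pressure alone;
configurable). Then \(C_e = C_a\), \(C_v = 20 C_a\), and the elastances are
tied reciprocally. The mean angular rate \(\omega_0\) is measured from the
signal's systolic upstrokes — the mean-level crossings on the steepest part
of the waveform, interpolated to sub-sample accuracy. This precision matters:
the fitting windows span 15+ seconds, so even a 0.3% rate error de-phases
the model from the recording by a good fraction of a beat and corrupts the
\(L_2\) objective; upstroke timing brings the error down to ~1e-4 where
diastolic minima (which sit on a flat valley) cannot. `c2` comes from the
dominant low-frequency component (2–15 beats/cycle, detrended) of the
per-beat systolic series, `p_a0` is the first diastolic value,
`p_v0 = p_a0/3`, `p_e0 = p_LV0 = p_a0`, `dt0 = 0.1 T`, and `c1` is scaled
to the measured relative systolic variation (clamped to 0.2–2% of
\(E_{s0}\)) so the pump stays positive-definite at every later iterate.

**Stage 1** is gradient descent with step \(\alpha = 0.001\) on the
five-vector \(\Theta = (C_v, p_{a0}, C_a, R_{LV}, A_1)\), each update also
moving the five tied dependents (ten values in all). Gradients are central
finite differences at \(\pm 10\%\) of each coordinate. At every step the
descent attacks whichever moment error is currently worse in normalised
terms — \(|\mu - \hat\mu|/\hat\mu\) or \(|\sigma - \hat\sigma|/\hat\sigma\)
— and stops when both fall below 0.02. The objective is the moment
*distance* itself (the absolute error), so the descent approaches the
target from either side. On noise-free synthetic targets this converges in
well under ~30 iterations; non-convergence is reported, not raised, and the
pipeline continues from the best iterate.

**Stages 2–3** refine with Nelder–Mead on the windowed \(L_2\) distance
\(\delta_2 = (\int (p_a - \hat p_a)^2 dt)^{1/2}\): stage 2 over the same
five-vector with ties re-applied at every evaluation, stage 3 over all
scalars except the measured \(\omega_0\), \(\phi\), `c2` and the numerical
device \(\varepsilon_1\), with the ties released. The search runs in log
space, which keeps every parameter positive without ad-hoc clipping.
Budgets are 200 evaluations per free parameter with a 1e-4 relative
objective tolerance. Stage 3's initial simplex uses 3% steps (stage 2 the
conventional 10%): it is a local refinement of an already-close start, and
wide exploratory steps slide along the objective's sloppy directions —
directions in parameter space that barely change the waveform — ending with
a marginally better \(\delta_2\) but physically meaningless parameters.

**Stage 4** is an automated stand-in for refining the notch "by hand": a
cyclic ±1% coordinate search over \((c_4, c_5, c_6, c_1)\), accepting a move
only if it reduces the \(L_2\) distance restricted to ±0.15 T around the
detected notch (the first interior minimum after the systolic peak of the
median beat) — the global \(\delta_2\) under-weights the notch because the
notch occupies a small fraction of the beat. If neither signal has a
detectable notch the stage reports itself skipped.

The pipeline is deterministic: the only randomness anywhere is the noise
optionally added by the pseudo-patient generator, under a user seed.

### What recovery experiments do and do not show

On noise-free pseudo-patients the pipeline reliably recovers what the
waveform actually constrains — the initial arterial pressure \(p_{a0}\)
(which sets the conserved total blood volume) comes back within ~10%, and
the moment statistics are matched to within a few percent. Most individual
constants, however (\(E_d\), \(E_{s0}\), \(A_1\), \(R_{LV}\)), sit along
sloppy directions: stage 3 routinely reduces \(\delta_2\) to a fraction of
its value at the generating truth while moving them tens of percent.
This is a property of the model/objective pair, not of the optimiser — with
the soft aortic valve the diastolic limb carries little independent
information about \(A_1\) and \(R_{LV}\), and \(E_{s0}\) trades off against
the compliances. Recovery results should therefore be read per-parameter,
not as a blanket statement about all 21 constants.

## The pseudo-patient generator

`generate_pseudo_patient()` turns any parameter set into a synthetic
arterial recording: the forward model's arterial trace plus i.i.d. Gaussian
measurement noise of chosen standard deviation. The packaged fixtures
(three fitted ICU patients plus the literature nominal set) span
85–135 mmHg systolic, 70–101 bpm, absent-to-large notches, and 4–7 beats
per breath, with respiratory modulation of both rate and amplitude. What
the generator does **not** emulate: catheter artefacts (damping, flush
transients, quantisation), baseline wander, arrhythmic beats, or
measurement dropouts. Tests that pass on pseudo-patients therefore validate
the algorithms' internal consistency, not their robustness to clinical
artefacts.

## Problem sizes

The shipped tests and the acceptance script use 30-s simulations at 100 Hz
for waveform summaries, a 20-beat window for sensitivity, three respiratory
cycles for fitting objectives, and one full pipeline run on a noise-free
pseudo-patient; these sizes give settled statistics (25+ beats, 5+
respiratory cycles) while keeping any single check in the minutes range.

## Known limitations

* No pulmonary circulation, no baroreflex or nervous control, no blood
  volume change: total volume is exactly conserved, so haemorrhage-like
  states can only be represented through the initial pressures.
* The soft exponential aortic valve passes substantial retrograde flow at
  reverse gradients below ~45 mmHg; parameter regimes with a soft systolic
  elastance can settle into a regurgitant steady state in which diastolic
  arterial pressure relaxes toward venous pressure.
* \(\phi\) and \(\omega_0\) are measured from the signal, never fitted;
  recordings whose rate drifts over the fitting window will de-phase.
* The notch detector assumes a single dominant secondary minimum per beat.
```
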