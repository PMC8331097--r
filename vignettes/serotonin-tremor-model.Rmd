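---
title: "Modelling serotonin-dopamine interplay and parkinsonian tremor with serotrem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling serotonin-dopamine interplay and parkinsonian tremor with serotrem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

serotrem simulates a system-level hypothesis about resting tremor in
Parkinson's disease: that one tremor phenotype arises not from the
dopaminergic lesion alone but from the interplay between the serotonergic
raphe system and the basal-ganglia-thalamo-cortical loop. This vignette
documents the model, every numerical and design choice that is not forced
by the mathematics, and what the simulated experiments can and cannot show.

## The circuit model

Eight state variables evolve under coupled first-order equations: firing
rates (Hz) of primary motor cortex (`M1`), thalamus (`Thal`), dorsal raphe
nucleus (`DRN`), substantia nigra pars compacta (`SNc`) and the striatal
populations of the direct and indirect basal-ganglia pathways (`DP`, `IP`),
plus striatal concentrations (nM) of serotonin (`fiveHT`) and dopamine
(`DA`). Each equation is linear -- a weighted sum of inputs minus a decay
term -- with two exceptions:

* dopamine release is the *product* of serotonin concentration and SNc
  activity (`G * fiveHT * SNc`), which is the pivot of the serotonergic
  compensation mechanism: when SNc degenerates, rising serotonin can
  partially restore the product;
* the indirect pathway carries a sinusoidal drive
  `alphaIP * sin(fIP * t) / max(DA, 1e-3)`, a lumped stand-in for the
  pallido-subthalamic oscillator. Dividing by dopamine makes dopamine
  inhibitory on the oscillation, which is what lets a lesion convert a
  quiet oscillator into overt tremor.

The division in the oscillatory term deserves a note: the term could also
be read as a multiplication by `DA`. We implement the division because it
is the only reading consistent with the direction of every reported effect
(dopamine loss amplifies the oscillation; raising dopamine through
treatment suppresses it). A multiplicative reading would make tremor
*shrink* after a lesion. The `max(DA, 1e-3 nM)` guard keeps the term
bounded if a trajectory drives dopamine to zero; the floor is three orders
of magnitude below the physiological operating point, so it is inert in
ordinary simulations.

Decay coefficients are applied exactly as multiplicative rates
(`- tau_X * X`), matching the equations as written; no unit conversion is
applied to them. State variables are not clamped at zero by default --
the equations do not require it, and clamping would mask instabilities --
but `clamp = TRUE` is available.

### Integration

The circuit is integrated with a fixed-step explicit Euler scheme at
`dt = 0.1` s, the step at which the model and all its reported behaviours
were defined; a classical RK4 scheme is available behind
`method = "rk4"` and the test suite exercises both. Intervention
schedules (timed multiplicative parameter changes representing lesions and
drug doses) are applied by multiplying the named coefficient immediately
before the step at the scheduled time; multipliers compose on the current
value, so "-20% then -30% of baseline" is expressed as steps of 0.8 and
0.7/0.8. Interventions are snapped to the step grid.

An integration is declared failed when the summed magnitude of the state
exceeds 1e8 or becomes non-finite; single simulations raise an error
naming the time and variable, cohort runs record the failure and continue
with the remaining subjects.

### Steady states

`steady_state()` integrates the model and averages over trailing 10 s
windows; convergence is declared when successive windowed means agree to a
relative tolerance of 0.01. The window averages out the indirect-pathway
oscillation (period about 1 s), and the tolerance is set deliberately
above the wobble that a sinusoid leaves in a 10 s mean when the window
does not hold an integer number of cycles (about 0.5% of the IP level at
the calibrated frequency); a tighter tolerance would never trigger for any
oscillating parameterisation. Relative change is measured with an absolute
floor of 1e-8 so that states decaying to zero register as converged.

## Calibration

The literature seed vector (`default_parameters()`) is, under these
equations, not a consistent operating point: plugging it in leaves
fixed-point residuals in several equations, and -- more importantly -- it
is dynamically unstable, because the residuals let dopamine dip below the
denominator guard, after which the amplified oscillation diverges. The
package therefore treats that vector strictly as the *seed* of a
calibration, and ships `calibrated_parameters()`, the output of
`calibrate_circuit()` at its defaults (GA seed 1), as the simulator
default.

The calibration is a generational genetic algorithm (population 30, 300
generations) over all 24 coefficients with box bounds at 0.2-5 times the
seed. Three objective components are measured per candidate by simulating
150 s from the reference state:

* `meanAPE` -- mean absolute percentage error of the eight simulated
  steady states against the reference values (minimised);
* `meanPhys` -- the cycle-based amplitude of the detrended dopamine series
  over the final 50 s of the healthy run (minimised: a healthy subject
  should not oscillate);
* `meanPark` -- the same amplitude under a reference dopaminergic lesion
  (`tauSNc` +25%, `alphaIP` +11%) applied from the start (rewarded: a
  lesioned model should oscillate).

The aggregate objective is
`(1*(1 - meanAPE) + 1*(1 - meanPhys) + 0.5*min(meanPark, 1)) / 2.5`.
The parkinsonian term is weighted *below* the physiological term on
purpose: the lesion multiplies the oscillation amplitude by a factor
greater than one, so with equal weights any parameter move that inflates
the oscillation everywhere is net-rewarded, and unconstrained runs drift
the oscillator frequency far from its published value to exploit this.
With the 1:1:0.5 weighting the optimiser keeps healthy oscillation small
while still preferring candidates whose lesioned oscillation is larger.

Because eight steady-state targets cannot identify 24 coefficients, the
optimum is a manifold; which point on it the GA returns would otherwise be
arbitrary. A proximity regulariser, `0.2 * mean(|log(p / seed)|)`
subtracted from the objective, resolves the redundancy toward the
published operating point: directions the data cannot identify stay at
their seed values, while identifiable directions move as far as the error
term demands (the penalty for the few percent they need is negligible
against the error reduction). This matters scientifically: the
dose-response of dopamine to raphe damage depends on exactly these
unidentifiable directions, and with the regulariser the calibrated model
reproduces the reported dose-response levels within a few percent.

GA operators: tournament selection (size 3), per-gene BLX-0.5 blend
crossover, per-gene lognormal mutation with probability 0.2 whose spread
anneals from 0.10 by a factor 0.98 per generation, single-individual
elitism, bounds enforced by clipping. The annealing is the one place we
departed from the plainest textbook choice (fixed-spread Gaussian
mutation): a fixed spread of a few percent of the search range cannot
refine below roughly `meanAPE = 0.07`, while the annealed lognormal
reaches `meanAPE` of a few 1e-4 within the same 9 000 evaluations.
Divergent candidates receive worst-case fitness and are counted, not
raised. The whole run is deterministic given the configuration seed.

## The two-link arm and the tremor readout

The arm is a planar, gravity-free two-link rigid body (task space is a
horizontal plane) with canonical human constants: upper arm 0.30 m /
1.9 kg, forearm-plus-hand 0.35 m / 1.1 kg, mid-link centres of mass and
literature moments of inertia, all swappable through `arm_parameters()`.
Exact values scale tremor amplitude smoothly and change no ordering.
Shoulder angle is measured from the +x axis, limits -60 to 150 degrees.
The elbow angle is the *interior* angle between upper arm and forearm,
limits 0 to 180 degrees with 180 = fully extended -- the anatomical
convention. This choice is substantive: with the alternative (flexion)
convention the commanded posture sits near a folded configuration whose
endpoint lever is a few centimetres, and simulated tremor amplitudes come
out several-fold below the reported meters; with the interior convention
the arm operates near extension and all five reported amplitudes are
reproduced within about 20%.

A proportional-derivative controller converts desired angles into torques
(`T = Kp (A_des - A_cur) - Kd * velocity`; stiffness 20/10 Nm/rad,
damping 1.5/1.0 Nm s/rad for shoulder/elbow), a lumped model of muscular
visco-elasticity. Dynamics are integrated with RK4 at `dt = 0.01` s; the
PD feedback is re-evaluated at every RK4 stage. Joint limits clamp the
angle and zero the offending velocity. The arm starts at rest at
shoulder 0, elbow 0.

The single M1 firing-rate trace drives both joints through an affine map.
The map's default anchor sends a *silent* cortex (0 Hz -- the natural
floor of a firing rate, which every equation decays to without input) to
the joint minima and the experiment-wide M1 maximum to the joint maxima.
An alternative anchor (`anchor = "range"`) stretches the observed
min-to-max excursion over the full anatomical range instead; because
quasi-steady M1 fluctuations are small against its mean, that choice
produces an effective gain several times larger and tremor amplitudes
5-10x the reported values, so the zero anchor is the default. Absolute
amplitudes in meters inherit the uncertainty of this under-determined
mapping; orderings across conditions do not. The M1 command is resampled
from the circuit grid (0.1 s) to the arm grid (0.01 s) by zero-order hold
(linear interpolation behind a flag).

Tremor is quantified per time window: endpoint positions are centred on
the window mean, projected onto the principal axis of their spread (making
the metric translation-invariant and orientation-free), and the amplitude
is half the mean per-cycle peak-to-peak excursion, cycles delimited by
upward zero crossings. For a pure sinusoid this is exactly the sinusoid
amplitude. Fewer than two cycles yields 0 with a `no_cycles` flag.

## Cohort experiments

A cohort (default 20 subjects) perturbs every coefficient and every
initial-state value with additive Gaussian noise of SD equal to the value
times a per-subject scale, evenly spaced from 0.01 (subject 1) to 0.02
(subject n); the even spacing honours the stated endpoints (the
alternative fixed step of 0.0005 cannot reach the upper endpoint at
subject 20). Draws violating positivity are resampled. Subject draws are
deterministic given the master seed and subject index.

Three presets reproduce the in-silico experiments:

* **snc-lesion**: `tauSNc` +25% and `alphaIP` +11% at 75 s; windows
  HEALTH/LESION. Probes the compensation chain: SNc and dopamine fall,
  the raphe disinhibits (via reduced cortical drive), serotonin rises, and
  dopamine partially recovers.
* **drn-damage**: one 300 s run per damage level (`tauDRN` x1.4, x1.6,
  x1.8 at 75 s) plus a healthy run. The per-condition dopamine level
  (`da_mean`) is the mean over the condition's *full run*. We verified
  that this -- and not a post-onset quasi-steady mean -- is the reading
  under which a reference-consistent parameter vector reproduces the
  reported condition levels (2.723/2.435/2.313/2.204 nM) within a few
  percent; the quasi-steady level is also reported (`da_steady`).
* **ssri**: a strong lesion at 75 s (`tauSNc` +70%, `alphaIP` +333%),
  then three serotonin-reuptake-blocker doses at 125/175/225 s bringing
  `tau5HT` to 80/70/60% of baseline (dose steps are baseline-relative).
  Five windows tile the 300 s run at 75/125/175/225 s.

In windowed scenarios, every condition window drops its first 10 s before
averaging dopamine or measuring tremor: this removes the intervention
transient, and for the first window it also removes the arm's initial
reach from rest, which would otherwise dominate the healthy-window
amplitude. Summary tables report cohort means and SDs per condition; the
per-subject table (via `tidy()`) is what a repeated-measures analysis
would consume -- hypothesis testing itself is left to standard statistics
routines and is not re-implemented here.

What the generator emulates: between-subject parametric variability around
one operating point, sufficient for reproducibility and ordering claims.
What it does not: measurement noise, within-subject drift, receptor-level
pharmacology, heterogeneous disease progression. Passing cohort tests
therefore shows that the circuit mechanism is robust to small parametric
spread -- not that it captures clinical population variance. Cohort means
of nonlinear readouts also sit slightly (about 2-3%) below the noise-free
values because the readouts are curved in the parameters; this bias is a
property of the noise model, not an estimator defect.

## Problem sizes and runtime choices

The shipped defaults are the experiment sizes themselves: 300 s horizons
at `dt = 0.1` (circuit) and 0.01 (arm), 20-subject cohorts, GA budget
30 x 300. The test suite runs the full GA twice (calibration quality and
synthetic-parameter recovery) and the full cohorts once; unit tests use
3-5 subject cohorts and shorter horizons where only mechanics are being
checked.

## Known limitations

* Absolute tremor amplitudes depend on the under-determined M1-to-angle
  mapping and the arm constants; they are reproducible and correctly
  ordered, but their scale carries the mapping choice.
* The oscillation objectives (`meanPhys`, `meanPark`) have no published
  formula; our cycle-based dopamine amplitude is one defensible reading,
  and their reported numeric values are not reproduction targets.
* The calibrated vector is one point on the optimum manifold, selected by
  the proximity regulariser; scientific claims should rest on the
  behaviours the tests pin down (steady states, dose-response direction
  and level, tremor ordering), not on individual coefficient values.
* The circuit is a lumped firing-rate model: no spiking dynamics, no
  spatial structure, no receptor subtypes.
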