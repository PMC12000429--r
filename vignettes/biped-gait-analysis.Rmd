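---
title: "Gait events, transition impulses and energetics on a planar spring-tendon biped"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait events, transition impulses and energetics on a planar spring-tendon biped}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bipedgait)
```

## The scientific problem

A planar bipedal robot with actuated hips and knees and passive,
spring-loaded ankles walks on a treadmill. The ankle is driven only by two
spring-tendons over 13 mm pulleys: a monoarticular one emulating the
soleus (SOL, 4500 N/m) and a biarticular one emulating the gastrocnemius
(GAS, 1400 N/m) that also spans the knee. During stance the ankle
dorsiflexes and loads the tendons; knee flexion at the end of stance
releases them, catapulting the leg into swing. The package analyses how
the *way knee flexion is initiated* — actively commanded by the knee motor
(AKFI) versus emerging passively when the knee motor torque is switched
off mid-stance (PKFI) — changes the timing of the gait events around
push-off and, through them, the distribution of momentum between the
trailing leg (TL), the remaining body (RB, the other leg plus trunk), and
the whole-body centre of mass (CoM) during the step-to-step transition.

The pipeline covers five stages, each usable on its own:

1. **Preprocessing** (`resample_uniform()`, `lowpass_zero_phase()`,
   `detect_touchdowns()`, `segment_cycles()`): non-uniformly sampled
   encoder logs are linearly interpolated to 1000 Hz, filtered with
   zero-phase Butterworth low-passes realised in second-order sections,
   segmented at touch-downs of the reference foot and ensemble-averaged on
   a common percent-gait-cycle (%GC) grid.
2. **Event detection** (`extract_events()`): the five kinematic events —
   start of knee flexion (SKF), start of hip flexion (SHF), start of ankle
   plantarflexion (SAPF), leading-leg touch-down (LLTD) and toe-off (TO) —
   from angle gradients thresholded at 1 rad/s.
3. **Kinetics** (`momentum_series()`, `transition_impulses()`): planar
   forward kinematics of the 7-segment body, segment momenta
   `p_i = m_i v_i`, the TL/RB/CoM partition, the transition window from
   the vertical CoM-velocity minimum to the second subsequent peak, and
   the momentum changes (impulses) across it.
4. **Energetics** (`ankle_power()`, `knee_gas_power()`, `motor_power()`,
   `cost_of_transport()`): spring-tendon joint powers, electrical motor
   power `P = I U`, mean net positive power, and the cost of transport
   `COT = E / (m g v)` with its percentage of a same-mass natural runner.
5. **Statistics** (`wilcoxon_signed_rank()`, `compare_experiments()`):
   paired Wilcoxon signed-rank tests over the twelve standard measures,
   pairing the 120 cycles of each condition by index.

Because the hardware's raw recordings are not bundled, the package ships a
first-class synthetic generator (`simulate_gait()`) that emulates their
statistical structure with known ground truth; every stage is validated
against it.

## Conventions

All computation is in SI units; degrees appear only at I/O boundaries.
Ankle angles are dorsiflexion-positive with the swing plateau at −22°,
knee flexion-positive with extension at 0, hip flexion-positive. The
hardware's drawing does not print signed zero directions, so this is a
package convention, chosen to be consistent with the −22° plantarflexion
swing plateau and the slack-length calibration at (−22°, 0°); it is
recorded in the header of every log the package writes. A gait cycle runs
from one touch-down of the reference foot to the next on the half-open
scale [0, 100) %GC, so an event exactly at the next touch-down belongs to
the next cycle.

## What the synthetic generator emulates

`simulate_gait()` draws a per-cycle **event schedule** around the
condition means (AKFI: SKF 39.00, SAPF 46.25, LLTD 48 %GC; PKFI: SKF
43.67, SAPF 48.77, LLTD 47 %GC; SHF 4 %GC apart between conditions; TO is
a package default) with 0.3 %GC Gaussian jitter per event — emulating the
robot's sub-0.4 %GC event repeatability — and 1 s cycles with 2 ms period
jitter. From the schedule it synthesizes piecewise cosine-blended curves:

* **Ankle**: constant at −22° in swing; a short touch-down transient
  (0.8 %GC, ~1°) whose *start* defines the cycle start (the detector's
  "angle starts to change") and whose *end* defines LLTD on the
  contralateral side (the detector's "last above-threshold gradient");
  a slow dorsiflexion whose gradient grows towards the SAPF peak, kept
  below ~0.9 rad/s so it never trips the 1 rad/s event threshold; a
  push-off descent whose gradient is steepest at toe-off; and a small
  (~0.9°) rebound below the plateau at TO so the angle minimum is a sharp
  V that survives zero-phase filtering.
* **Knee**: holds its 8° offset through stance, rises by 55° from SKF
  with a quarter-sine profile (angular velocity maximal at onset, which
  makes the SKF gradient crossing crisp) and returns before the next
  touch-down.
* **Hip**: extends at constant angular rate through stance — a stance leg
  rotates at a steady rate as the trunk passes over the planted foot —
  with cosine blends at both ends; flexion engages at SHF above 1 rad/s
  and keeps accelerating to a mid-swing velocity peak, as in walking, so
  the trailing leg is still gaining forward momentum inside the
  transition window.
* **Trunk**: the vertical velocity is a sum of event-locked
  raised-cosine lobes — a descent that deepens with the time between knee
  flexion onset and the collision (the trunk falls once the stance knee
  buckles), then two similar-height redirection peaks after LLTD and TO;
  the forward speed drops at each collision and recovers linearly until
  the next one, with the drop reduced in proportion to the push-off time
  occurring *before* touch-down (preemptive push-off cancels part of the
  collision loss). This reproduces, rather than postulates, the published
  ordinal findings: with PKFI the trailing leg gains more horizontal
  momentum inside the window (its swing starts later, so more of the
  acceleration falls inside), the remaining body loses more (no
  preemptive push-off to offset the collision), and the CoM momentum
  magnitude grows more (the vertical minimum is shallower).
* **Currents**: raised-cosine effort bumps (hip: early stance and swing
  drive; knee: early stance and flexion drive) on small baselines, with
  the knee channel gated to zero from 35 %GC to cycle end in PKFI. The
  bump areas were chosen once so that the mean net positive power at 24 V
  lands at a COT near 0.56 (AKFI) and 0.52 (PKFI) for the 2.1 kg robot at
  0.44 m/s.

The **sensor model** then resamples onto jittered ~600 Hz timestamps
(±15 % spacing), quantises angles to the encoder resolutions (5000 CPR at
hip/knee, 4096 CPR at ankle and four-bar), and adds white measurement
noise (0.5 mrad angles, 0.2 mm slider, 10 mA currents).

What the generator does *not* emulate — and hence what passing tests do
not show about real data: contact dynamics and ground-reaction forces,
structural left-right asymmetries, slow drifts (belt speed, temperature),
heel-compliance transients beyond the single touch-down burst, and any
coupling of the controller to the mechanics. Event-detection accuracy on
hardware logs can therefore be worse than the loop-closure numbers below,
which is why every threshold is configurable.

## Numerical choices

* **Filtering**: the per-sensor filter table of the hardware is not
  published; defaults are order 2 with 50 Hz cutoffs for angle/position
  channels and 10 Hz for currents, applied forward-backward (squared
  magnitude response, zero phase). The 50 Hz angle cutoff is deliberate:
  the event detectors threshold the angle *gradient*, and the zero-phase
  smear of a 20 Hz filter (~25 ms) would blur threshold crossings by over
  2 %GC, far beyond the hardware's event repeatability, while encoder
  noise at 50 Hz contributes only ~0.05 rad/s of gradient noise against
  the 1 rad/s thresholds. Edge handling is even-reflection padding of six
  characteristic lengths, after which the start-up transient is below
  1e-9.
* **Gradients** are central differences (one-sided at edges) everywhere —
  events, CoM velocities, powers — so all stages share one convention.
* **Crossings and ties**: a threshold crossing is the first strict
  inequality; tied extrema resolve to the earliest sample.
* **Transition window**: the minimum is the global minimum of vertical
  CoM velocity within 30–80 %GC; peaks after it are accepted by a
  hysteresis rule with a prominence floor of 10 % of the post-minimum
  range, and the second accepted peak closes the window. For peak picking
  only, the per-cycle vertical velocity is additionally smoothed at 15 Hz
  (zero-phase), because encoder noise surviving the 50 Hz channel filters
  otherwise spawns spurious prominence peaks; impulses are always
  evaluated on the unsmoothed momenta.
* **Spring powers**: tendon extensions are measured relative to the slack
  calibration pose (ankle −22°, knee 0°, slack lengths 0 m), since the
  printed slack setting would otherwise contradict zero force at
  calibration. The unclamped expressions are the default (they are the
  exact differential of the stored elastic energy when the knee is
  frozen, and integrate to zero over closed loops); `clamp_slack = TRUE`
  floors each tendon force at zero, since a physical tendon cannot push.
* **Net positive power**: channels are summed first, idle power
  subtracted, and the *sum* clipped at zero — clipping per channel would
  give a different (larger) number on mixed-sign inputs. The driver idle
  power is not published and defaults to 0 W; COT values on hardware-like
  data require setting it explicitly. The natural-runner reference
  COT is an input constant (1.36 for 2.1 kg); the allometric formula
  behind it is not implemented.
* **Kinetic energy** of a multi-segment part defaults to the aggregate
  form `|p|^2 / (2 m)`, which tracks the part's CoM velocity vector; the
  per-segment sum is available via `form = "segment_sum"`.
* **Wilcoxon**: exact enumeration over all `2^n` sign assignments for
  n ≤ 12 non-zero differences, continuity- and tie-corrected normal
  approximation beyond; zero differences are discarded by default
  (classic test), with Pratt-style splitting available. No
  multiple-testing correction is applied, matching per-measure reporting
  at p < 0.001; the report footer says so.
* **Four-bar geometry**: the rod lengths are not published; the trunk's
  vertical position is `r_fourbar * sin(fourbar_angle)` with
  `r_fourbar = 0.2` m, configurable. Segment mass fractions are likewise
  not published; the defaults (trunk 0.58, thigh 0.10, shank 0.07, foot
  0.04 each) are a plausible distal-light distribution over 2.1 kg, and
  all bundled checks are either mass-free or synthetic-relative.

## Design decisions that were genuinely open

* **Ground-truth semantics of touch-down.** The cycle start is defined by
  "the angle starts to change" (first above-threshold gradient) while
  LLTD is "the last above-threshold gradient before TO". These are two
  different operationalisations of the same physical contact. The
  generator therefore records the transient's *start* as the scheduled
  cycle start and its *end* as the scheduled LLTD, so each detector is
  validated against the time its own definition identifies.
* **SAPF search window.** Whether the original analysis searched the
  whole cycle or a stance window is unstated; the package searches
  10–90 %GC by default (configurable) to avoid touch-down transients.
* **Sign of the SAPF-LLTD interval.** The package reports
  `delta_SAPF_LLTD = t_SAPF - t_LLTD`: negative when push-off starts
  before the collision (AKFI, ≈ −1.8 %GC), positive when after (PKFI,
  ≈ +1.8 %GC). Published tables sometimes print the interval with the
  opposite sign ("time from SAPF to LLTD"); only the convention differs.
* **Leading-leg alignment.** LLTD is detected on the contralateral ankle
  channel on the same absolute clock as the trailing cycle (no
  re-segmentation), matching the hardware's half-cycle phase shift.
* **PKFI knee-torque window.** The zero-torque command starts at 35 %GC
  (40 %GC in the PKFI40 variant) and lasts to the end of the cycle; in
  the generator this gates the knee current channel and, through the
  schedule, delays SKF. The ~20 %GC shift between the observed touch-down
  and the start of the controller-defined cycle is kept as a single
  configurable constant (`cpg_phase_offset`, default 0.20) in the
  synthesis section of the configuration.

## Problem sizes and validation

The bundled validation runs the full pipeline on 120-cycle records (the
standard experiment length) for both conditions, noiseless and with the
default sensor model — about 120 000 samples per channel after 1000 Hz
resampling per run. On these, the generator-detector loop closes with a
mean absolute recovery error ≤ 0.35 %GC per event (well inside the
0.5 %GC noiseless and 1.0 %GC noisy bounds the tests assert), per-event
SDs ≤ 0.33 %GC against the injected 0.3 %GC, all four published ordinal
impulse findings reproduce with margins, and the recovered COT percentages
round to 41 % (AKFI) and 38 % (PKFI). Unit tests use 3-10 cycle records;
the statistical null calibration uses 1000 replicates at n = 20.

## Known limitations

* The analysis is strictly planar and kinematic: no ground-reaction
  forces, inverse dynamics, angular momentum, or 3-D stabilisation.
* Toe-joint dynamics are ignored (each foot is one segment); the toe
  spring constant is stored but unused.
* The PD current control is metadata only; no torque-level simulation.
* Mass-dependent absolute momenta depend on the unpublished segment mass
  fractions; cross-condition *differences* are robust to them, absolute
  values are not.
* `diff_percent` is undefined for a zero reference mean and is reported
  as `NA` in that case.
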