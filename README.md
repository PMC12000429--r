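# bipedgait

Gait-event, momentum and energetics analysis for a planar bipedal robot
with actuated hips and knees and passive, spring-tendon loaded ankles.

## The problem

In spring-legged walking, the ankle acts as a catapult: monoarticular
(soleus-like, SOL) and biarticular (gastrocnemius-like, GAS) spring-tendons
load gradually during stance dorsiflexion and release rapidly at push-off,
with knee flexion acting as the release trigger. `bipedgait` implements the
complete measurement chain needed to study how the *initiation* of that
knee flexion — actively commanded (AKFI) versus emerging passively once the
knee motor torque is switched off mid-stance (PKFI) — shifts the timing of
the gait events around push-off and redistributes momentum between the
trailing leg (TL), the remaining body (RB: leading leg + trunk) and the
whole-body centre of mass (CoM) during the step-to-step transition.

The package is for robotics/biomechanics researchers who have (or want to
emulate) multichannel robot sensor logs: joint encoder angles for both
legs, the trunk guide position, and per-motor currents, sampled
non-uniformly around 600 Hz.

## What it computes

- **Preprocessing**: linear resampling to 1000 Hz, zero-phase Butterworth
  low-pass filtering (second-order sections, forward-backward),
  touch-down segmentation from the swing ankle plateau, ensemble
  averaging on a percent-gait-cycle grid.
- **Gait events** (per cycle, in %GC): start of knee flexion
  `t_SKF`, start of hip flexion `t_SHF`, start of ankle plantarflexion
  `t_SAPF` (the stance dorsiflexion maximum), leading-leg touch-down
  `t_LLTD` (last ankle-gradient crossing above 1 rad/s before toe-off)
  and toe-off `t_TO`, plus `delta_SAPF_LLTD = t_SAPF - t_LLTD`.
- **Kinetics**: planar forward kinematics of the 7-segment body, segment
  momenta `p_i = m_i v_i`, the TL/RB/CoM partition
  (`p_CoM = p_TL + p_RB` holds at machine precision), the step-to-step
  transition window from the vertical CoM-velocity minimum `vmin` to the
  second subsequent peak `vmax`, momentum changes (impulses) `Δp_x`,
  `Δp_y` and `Δ|p|` across it, and the CoM velocity redirection angle.
- **Energetics**: spring-tendon ankle power
  `P_A = ω_A (k_SOL r_SOL (α_A r_SOL - l_SOL,slack) + k_GAS r_GAS ((α_A - α_K) r_GAS - l_GAS,slack))`
  (SOL-only branch when the GAS tendon disengages), the GAS contribution
  to knee power, electrical motor power `P = I·U`, mean net positive
  power, cost of transport `COT = E_en/(m g v)` and its percentage of a
  same-mass natural runner (`COT_nr = 1.36` at 2.1 kg).
- **Statistics**: paired Wilcoxon signed-rank tests (exact enumeration
  for n ≤ 12, tie/continuity-corrected normal approximation beyond) over
  the twelve standard measures, with
  `Diff% = (mean_PKFI - mean_AKFI)/mean_AKFI · 100`.
- **Synthetic data**: a first-class generator (`simulate_gait()`) that
  emulates the robot logs' statistical structure — 1 Hz cycles, jittered
  ~600 Hz sampling, encoder quantisation, condition-dependent event
  schedules with 0.3 %GC repeatability, the −22° swing ankle plateau —
  with bit-reproducible ground truth for every event.

## Worked example

```r
library(bipedgait)

# simulate both conditions (40 gait cycles, default sensor model)
akfi <- simulate_gait("AKFI", n_cycles = 40, seed = 7)
pkfi <- simulate_gait("PKFI", n_cycles = 40, seed = 7)

# run the full analysis pipeline on each log
an_a <- analyze_gait(akfi$log, n_keep = 40)
an_p <- analyze_gait(pkfi$log, n_keep = 40)

an_a$events
#> <gait_events> 40 cycles (0 excluded)
#>             event  mean    sd
#> 1           t_SKF 38.79 0.308
#> 2           t_SHF 41.88 0.270
#> 3          t_SAPF 46.25 0.271
#> 4          t_LLTD 48.07 0.232
#> 5            t_TO 62.16 0.342
#> 6 delta_SAPF_LLTD -1.82 0.328

an_a$energy
#> <energy_summary> E_en 5.035 W at v 0.440 m/s -> COT 0.555 (41% of a natural runner)
an_p$energy
#> <energy_summary> E_en 4.672 W at v 0.441 m/s -> COT 0.515 (38% of a natural runner)

# paired comparison of the twelve standard measures
compare_gait_analyses(an_a, an_p)
#> <comparison_report> AKFI vs PKFI (alpha = 0.001)
#>            measure   unit   mean_A   sd_A   mean_B  sd_B diff_percent  p_value
#> 1            t_SKF    %GC 38.79000 0.3100 43.46000 0.310        12.05 2.40e-08
#> 2           t_SAPF    %GC 46.25000 0.2700 48.76000 0.260         5.43 7.40e-09
#> 3  delta_SAPF_LLTD    %GC -1.82300 0.3300  1.68200 0.320      -192.32 1.51e-08
#> 4          dmag_TL kg m/s  0.16920 0.0094  0.34420 0.025       103.44 3.71e-08
#> 5          dp_TL_x kg m/s  0.16950 0.0099  0.33930 0.024       100.23 3.71e-08
#> ...
```

Reading the output: in the active condition the ankle starts to
plantarflex at 46.25 %GC, about 1.8 %GC *before* the leading leg touches
down (`delta_SAPF_LLTD < 0`, preemptive push-off); in the passive
condition knee flexion starts ~4.7 %GC later and push-off begins ~1.7 %GC
*after* touch-down, the interval flips sign, and the trailing leg's
horizontal impulse over the transition roughly doubles while the
remaining body decelerates more — the event-timing cascade redirects
push-off energy into the swing leg. The cost of transport barely moves
(41 % → 38 % of a natural runner), showing the overall gait is robust to
how knee flexion is initiated.

Logs round-trip through a plain delimited format with provenance
comments (`write_gait_log()`/`read_gait_log()`), configurations through
YAML (`read_gait_config()`), and reports through CSV/JSON
(`render_report()`). A small command-line front end for the common
simulate/analyze/compare cycle ships in `inst/scripts/gait-cli.R`.

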