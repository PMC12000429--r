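# Example analysis configuration. Any subset of the sections may be given;
# unspecified entries keep the package defaults (see default_config()).
# Units: SI (m, N/m, kg, s, Hz, rad); angles in the config that represent
# hardware datasheet values must already be converted.

morphology:
  k_SOL: 4500          # N/m
  k_GAS: 1400          # N/m
  total_mass: 2.1      # kg

control:
  mode: AKFI

filtering:
  rate: 1000           # Hz, uniform resampling rate
  order: 2
  cutoff_angles: 50    # Hz, angle and position channels
  cutoff_currents: 10  # Hz

synthesis:
  n_cycles: 120
  mean_forward_speed: 0.44   # m/s
  event_jitter_sd: 0.3       # %GC
  sampling_rate_nominal: 600 # Hz
  sampling_jitter: 0.15
  cpg_phase_offset: 0.20     # observed GC lag behind the controller cycle

analysis:
  n_keep: 120
  trailing_side: L
  gradient_threshold: 1      # rad/s, LLTD/SHF/SKF detectors
  stance_window: [10, 90]    # %GC, SAPF search
  transition_search: [30, 80]
  prominence_frac: 0.1
  idle_power: 0              # W per motor driver
  cot_nr: 1.36               # natural-runner COT at 2.1 kg
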