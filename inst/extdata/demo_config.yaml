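# Demo configuration: 6-cell synthetic cohort, 2 cells per class with
# contrasting sub-class parameters.  Phase convention: 0 deg = trough.
seed: 20140
fs: 1250
behavior:
  run_duration: 60
  rest_duration: 250
  speed_threshold: 1
background:
  noise_exponent: 1
  noise_scale: 0.05
theta:
  freq: 8
  amplitude: 0.15
epsilon:
  freq: 110
  amplitude: 0.03
  carrier: theta
  preferred_carrier_phase: 270
  modulation_depth: 1
ripples:
  n_events: 40
  freq_range: [100, 180]
  duration_range: [0.05, 0.12]
  amplitude_sd: 9        # planted envelope peak, detector SD units
  min_separation: 1.0
detection:
  high_threshold: 5
  edge_threshold: 2
  min_duration: 0.015
  merge_gap: 0.01
surrogates:
  mode: spike_shuffle
  n_surrogates: 999
cells:
  - id: bc_classic
    sub_class: C-BC
    rate_run: 28
    theta_pref: 310
    theta_kappa: 0.6
    rate_rest: 8
    event_pref: 55
    event_kappa: 2.5
    event_gain: 8
    doublet_prob: 0.1
  - id: bc_horizontal
    sub_class: H-BC
    rate_run: 28
    theta_pref: 310
    theta_kappa: 0.6
    rate_rest: 10
    event_pref: 55
    event_kappa: 2.5
    event_gain: 14
    doublet_prob: 0.8
  - id: bistrat_classic
    sub_class: C-Bistrat
    rate_run: 34
    theta_pref: 0
    theta_kappa: 0.35
    rate_rest: 6
    event_pref: 126
    event_kappa: 2.5
    event_gain: 4
    doublet_prob: 0.0
  - id: bistrat_oriens
    sub_class: O-Bistrat
    rate_run: 34
    theta_pref: 0
    theta_kappa: 0.35
    rate_rest: 6
    event_pref: 126
    event_kappa: 2.5
    event_gain: 9
    doublet_prob: 0.0
  - id: aac_classic
    sub_class: C-AAC
    rate_run: 27
    theta_pref: 251
    theta_kappa: 1.0
    rate_rest: 6
    event_pref: 0
    event_kappa: 0
    event_gain: 1
    doublet_prob: 0.0
  - id: aac_external
    sub_class: E-AAC
    rate_run: 27
    theta_pref: 251
    theta_kappa: 1.0
    rate_rest: 5
    event_pref: 120
    event_kappa: 2.0
    event_gain: 4
    doublet_prob: 0.0
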