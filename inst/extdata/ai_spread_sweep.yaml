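experiment: ai_spread_sweep
grid:
  n_rows: 40
  n_cols: 40
  pixel_um: 50.0
  nose_um:
  - 250.0
  - 1000.0
  vf_scale_m: 2.5
  vf_deg_per_pixel: 0.6
wave:
  b: 0.35
  q: 2.4
  n_theta: 1
  tau_iei_frames: 60
  t_frame_s: 0.5
  t_wave_s: 1.0
  tau_on_s: 0.0
  tau_off_s: 1.0
  r: 1.0
  gamma: 0.0
  sigma_ai_um: 50.0
  rho_rule: scale
  noise_mode: background
  max_frames: 400
learn:
  eta: 0.01
  t_trial_frames: ~
  w0: 0.1
  r_radius_um: 175.0
  n_waves: 2000
  plasticity_noise_sd: 0.0
  update_dropout_p: 0.0
  conserve_total: no
off_delays_s:
- 0.0
- 0.5
- 1.0
- 1.5
- 2.0
- 2.5
- 3.0
- 3.5
bias_targets:
- 0.0
- 0.25
- 0.5
- 0.75
- 1.0
ai_spreads_um:
- 5.0
- 25.0
- 50.0
- 150.0
- 250.0
- 350.0
- 500.0
- 600.0
- 750.0
- 1000.0
- 1500.0
- 2000.0
- 3000.0
noise_fractions:
- 0.0
- 0.1
- 0.2
- 0.3
- 0.4
- 0.5
- 0.6
- 0.7
- 0.8
- 0.9
- 1.0
n_seeds: 5
n_waves: 500
seed: 1
output_dir: ~
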