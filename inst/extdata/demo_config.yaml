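# Demo run: one meandering synthetic front and a warm-preferring fishery.
seed: 42
date: "2019-10-15"
domain:
  lon: [150.0, 155.0]
  lat: [38.0, 43.0]
  res: 0.05
front:
  delta_T: 2.0        # degC cross-front contrast
  width_km: 10
  T_cold: 12
  meander_amplitude_km: 40
  meander_wavelength_km: 250
  noise_sd: 0.1       # degC observation noise
fishery:
  n_records: 1500
  mu_pref: 14.0       # degC thermal optimum (warm-side saturation)
  sigma_pref: 0.8
detection:
  window_px: 32
  theta_crit: 0.70
  min_length_px: 15
zones:
  mode: relative
  threshold_frac: 0.5
  max_extent_km: 100
randomization:
  window_deg: 2
  R: 100
thermal:
  bin_width: 0.5
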