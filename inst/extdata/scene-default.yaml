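field_w_px: 1376
field_h_px: 1038
pixel_size_nm: 102.33
n_timepoints: 16
t_start_h: 8.0
t_step_h: 4.0
fields_per_timepoint: 20
nuclei_mean: 23.6
nuclei_sd: 9.1
pb_diameter_mean_nm: 476.0
pb_diameter_sd_nm: 60.0
count_program:
  mesor: 240.0
  amplitude: 55.0
  period_h: 24.0
  phase_h: 6.5
intensity_program:
  mesor: 85.0
  amplitude: 5.0
  period_h: 24.0
  phase_h: 6.5
area_program:
  mesor: 17.0
  amplitude: 1.0
  period_h: 24.0
  phase_h: 6.5
coloc_fraction: 0.6
cell_area_fraction: 0.85
background_cell: 12.0
background_free: 2.0
poisson_gain: 1.0
read_noise_sd: 2.0
rng_seed: 1
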