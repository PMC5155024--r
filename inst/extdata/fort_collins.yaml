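# Reference run: industrial flat-panel array at a high-plains site (40 N),
# 5x f/2 medium, daily harvest at the fitted dilution fraction.
# Clearness calendar and dilution are fitted values (see package docs);
# omitted keys fall back to the documented defaults.
site:
  latitude_deg: 40
  solar_constant_pfd: 2500
  clearness: [0.80, 0.787, 0.75, 0.70, 0.65, 0.613, 0.60, 0.613, 0.65, 0.70, 0.75, 0.787]
geometry:
  width_m: 0.05
  height_m: 0.28
  length_m: 17.3
  separation_m: 0.15
  n_panels: 1
operation:
  harvest_interval_d: 1
  nut_n: 61.6
  nut_p: 5.5
  sim_days: 365
integrator:
  dt_min: 11.25
  method: euler
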