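# Example simulation config for the `simulate` command.
# A small two-line plate: one media-only well, one monoculture well per
# line and one mixed well, imaged on days 0 and 4.
seed: 11
days: [0, 4]
n0_per_field: 30
fields_per_well: 2
channels: [em1, em2, yfp]
image:
  size: [256, 256]
  vignette_amplitude: 0.15
  baseline_background: 10
  per_well_offset_sd: 1.5
  read_noise_sd: 2
  debris_rate: 4
lines:
  - label: mCherry_NLS_mCherry
    ratio_mean: 0.560
    ratio_sd: 0.025
    growth_per_day: 1.155
    reporter_response: {vehicle: 40, DHT: 200}
  - label: mPlum_NLS_mPlum
    ratio_mean: 1.067
    ratio_sd: 0.045
    growth_per_day: 1.12
    reporter_response: {vehicle: 40, DHT: 45}
treatment_effects:
  DHT:
    mCherry_NLS_mCherry: 1.3
layout:
  - {well_id: A01, role: background}
  - {well_id: B02, role: sample, mixture: mCherry_NLS_mCherry, treatment: vehicle}
  - {well_id: B03, role: sample, mixture: mPlum_NLS_mPlum, treatment: vehicle}
  - {well_id: C02, role: sample, mixture: mCherry_NLS_mCherry|mPlum_NLS_mPlum, treatment: DHT}
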