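# Phosphorus-MRSI-like Alzheimer cohort: 62 subjects, one multi-channel
# sample per subject (four single-voxel brain ROIs stacked as channels).
P: 256
n_channels: 4
channel_names: [ACC, RSC, HL, HR]
seed: 1
ppm_range: [10.0, -20.0]
peaks:
  - {name: Pi, center_bin: 90, width_bins: 3, base_amplitude: 0.5}
  - {name: PCr, center_bin: 120, width_bins: 3, base_amplitude: 1.0}
  - {name: gATP, center_bin: 160, width_bins: 4, base_amplitude: 0.55}
  - {name: aATP, center_bin: 180, width_bins: 4, base_amplitude: 0.6}
  - {name: bATP, center_bin: 210, width_bins: 5, base_amplitude: 0.5}
class_effects:
  control: {PCr: 1.0, Pi: 1.0}
  AD: {PCr: 0.8, Pi: 1.2}
n_patients_per_class:
  control: 31
  AD: 31
voxels_per_patient:
  control: 1
  AD: 1
patient_effect_sd: 0.2
noise_sd: 0.03
image_shape: [8, 8]
contrasts: [T1]
image_class_effect:
  control: 0.0
  AD: 0.15
image_noise_sd: 1.0
image_baseline: 0.0
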