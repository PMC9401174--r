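# Proton-MRSI-like brain tumor cohort: 29 subjects, six tissue classes,
# fewer voxels per patient for higher glioma grades, four MRI contrasts.
P: 512
n_channels: 1
seed: 1
ppm_range: [4.3, 0.5]
peaks:
  - {name: Cho, center_bin: 150, width_bins: 4, base_amplitude: 1.0}
  - {name: Cr, center_bin: 180, width_bins: 4, base_amplitude: 0.9}
  - {name: NAA, center_bin: 260, width_bins: 5, base_amplitude: 1.2}
  - {name: Lac, center_bin: 380, width_bins: 6, base_amplitude: 0.3}
class_effects:
  grade_II: {Cho: 1.2, Cr: 0.9, NAA: 0.8, Lac: 1.5}
  grade_III: {Cho: 1.5, Cr: 0.8, NAA: 0.6, Lac: 2.5}
  grade_IV: {Cho: 1.8, Cr: 0.7, NAA: 0.4, Lac: 4.0}
  meningioma: {Cho: 2.0, Cr: 0.6, NAA: 0.3, Lac: 1.2}
  csf: {Cho: 0.15, Cr: 0.15, NAA: 0.15, Lac: 0.3}
  normal: {Cho: 1.0, Cr: 1.0, NAA: 1.0, Lac: 1.0}
n_patients_per_class:
  grade_II: 5
  grade_III: 5
  grade_IV: 5
  meningioma: 5
  csf: 5
  normal: 4
voxels_per_patient:
  grade_II: 18
  grade_III: 14
  grade_IV: 10
  meningioma: 27
  csf: 27
  normal: 27
patient_effect_sd: 0.25
noise_sd: 0.03
image_shape: [8, 8]
contrasts: [T1, T2, PD, Gd]
image_class_effect:
  grade_II: 0.10
  grade_III: 0.20
  grade_IV: 0.35
  meningioma: 0.25
  csf: -0.30
  normal: 0.0
image_noise_sd: 1.0
image_baseline: 0.0
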