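# Acquisition / reconstruction-surrogate presets.
#
# sensitivity_kappa maps concentration x voxel volume x time to the expected
# detected (reconstructed-equivalent) counts per voxel: lambda = C[kBq/mL] *
# V[mL] * kappa * t[s]. It is calibrated so that, under the default study
# conditions (soft-tissue phantom, 3.30-mm grid, TOF system PSF 3.6 mm, 4-mm
# post filter), the 9.7-mm sphere CNR at 60 s lies near the Rose threshold.
time_grid_s: [30, 60, 90, 120, 150, 180, 210, 240, 270, 300]
reference_time_s: 600
resolution_time_s: 1800
sensitivity_kappa: 0.32
iteration_noise_scale: 1.0
filter_fwhm_mm: 4
psf_fwhm_mm:
  tof: 3.6
  tof_psf: 2.9
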