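# Bone-lung tumour phantom: three non-radioactive density tubes (lung cork
# surrogate at -800 HU, two K2HPO4 bone surrogates at 500 and 1000 HU) inside
# the warm torso. Each tube holds an 8.5-mm and a 19.4-mm hot sphere at
# 15 kBq/mL. Densities carry labels and an optional noise multiplier only.
name: bone_lung
body:
  semi_axis_x_mm: 150
  semi_axis_y_mm: 100
  length_mm: 180
background_kbq_ml: 3
tubes:
  - {label: "lung_-800HU", center_x_mm: -70, center_y_mm: 0, diameter_mm: 40,
     length_mm: 160, density_hu: -800, activity_kbq_ml: 0, noise_scale: 1.0}
  - {label: "bone_500HU",  center_x_mm: 0,   center_y_mm: 0, diameter_mm: 40,
     length_mm: 160, density_hu: 500,  activity_kbq_ml: 0, noise_scale: 1.0}
  - {label: "bone_1000HU", center_x_mm: 70,  center_y_mm: 0, diameter_mm: 40,
     length_mm: 160, density_hu: 1000, activity_kbq_ml: 0, noise_scale: 1.0}
tube_spheres:
  - {diameter_mm: 8.5,  z_mm: 35,  activity_kbq_ml: 15}
  - {diameter_mm: 19.4, z_mm: -35, activity_kbq_ml: 15}
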