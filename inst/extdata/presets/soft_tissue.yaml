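# Soft-tissue tumour phantom: six hot spheres in a warm torso background.
# Sphere diameters 6.5-28.0 mm at 15 kBq/mL, background 3 kBq/mL (SBR 5:1),
# sphere centers on a 57.2-mm ring in the central transaxial plane.
name: soft_tissue
body:
  semi_axis_x_mm: 150
  semi_axis_y_mm: 100
  length_mm: 180
background_kbq_ml: 3
sphere_ring_radius_mm: 57.2
inserts:
  - {label: "6.5mm",  diameter_mm: 6.5,  activity_kbq_ml: 15, angle_deg: 210}
  - {label: "9.7mm",  diameter_mm: 9.7,  activity_kbq_ml: 15, angle_deg: 270}
  - {label: "12.6mm", diameter_mm: 12.6, activity_kbq_ml: 15, angle_deg: 330}
  - {label: "15.1mm", diameter_mm: 15.1, activity_kbq_ml: 15, angle_deg: 30}
  - {label: "22.2mm", diameter_mm: 22.2, activity_kbq_ml: 15, angle_deg: 90}
  - {label: "28.0mm", diameter_mm: 28.0, activity_kbq_ml: 15, angle_deg: 150}
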