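# Resolution phantom: two 0.5-mm inner-diameter line sources parallel to the
# scanner axis at 10-mm and 100-mm transaxial offset, filled at 7.1 MBq/mL
# (7100 kBq/mL); phantom cavity filled with non-radioactive water.
name: resolution
body:
  semi_axis_x_mm: 150
  semi_axis_y_mm: 100
  length_mm: 180
background_kbq_ml: 0
line_length_mm: 180
lines:
  - {transaxial_offset_mm: 10,  inner_diameter_mm: 0.5, activity_kbq_ml: 7100}
  - {transaxial_offset_mm: 100, inner_diameter_mm: 0.5, activity_kbq_ml: 7100}
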