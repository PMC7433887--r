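# Example configuration for a simulated tankyrase-inhibitor-style screen.
acquisition:
  n_z_planes: 25
  z_step: 10
  pixel_size: 1.7
  frame_shape: [192, 192]
phenotype:
  n_organoids: 5
  organoid_radius_mean: 40
  organoid_radius_sd: 6
  lumen_fraction: 0.5
  nuclei_per_organoid_mean: 12
plate:
  n_doses: 9
  dilution_factor: 3.162
  top_dose: 3160
  n_replicates: 8
  n_control_wells: 8
  control_label: DMSO
compounds:
  - name: C1
    ec50: 2
    hill: 1
  - name: C2
    ec50: 36
    hill: 1
  - name: C3
    ec50: 319
    hill: 1
segmentation:
  min_area: 250
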