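# Example analysis configuration for a time-resolved dissolution scan
voxel_size_um: 2.75
frame_interval_s: 6.0
spacer_threshold: auto     # number | "auto" | "none"
crop_diameter_voxels: 2016
opening_radius: 0          # voxels; 0 = no morphological opening
rho_mg_cm3: 2165           # crystal density (NaCl)
surface_estimator: coarea  # "faces" | "coarea"
tracking:
  growth_tolerance: 0.05
  jump_volume_fraction: 0.5
  sphericity_jump: 0.3
  min_track_length: 4
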