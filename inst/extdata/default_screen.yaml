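# Default synthetic-screen configuration (schema version 1).
# Two cell lines (HeLa, HPFC) x six treatments (control, EDL21, Pt-ttpy,
# 360A, Phen-DC3, cisplatin); 2 wells/group x 4 fields/well x ~30
# cells/field, so every group yields >= 200 quantified cells.
schema_version: 1
seed: 1
plate:
  wells_per_group: 2
  fields_per_well: 4
  cells_per_field: 30
geometry:
  image_size: 512
  background_level: 100.0
  poisson_gain: 1.0
  read_noise_sd: 2.0
segmentation:
  smooth_sigma: 2.0
  min_area: 50
  max_distance: 20
  tophat_radius: 4
features:
  enabled: true
coupling:
  control: control
  cor_scale: log
stats:
  values:
    - mmp_mito_corrected
    - ros_corrected
    - mtros_mito_corrected
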