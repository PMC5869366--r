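seed: 1.0
landscape:
  n_rows: 128
  n_cols: 128
  cell: 100.0
  x0: 0.0
  y0: 0.0
  elev_range:
  - 1650.0
  - 2900.0
  elev_mean: 2075.0
  elev_sd: 250.0
  elev_autocorr_m: 1200.0
  n_water: 10
  veg_autocorr_m: 800.0
  n_veg_classes: 5
truth:
  intercept: 0.0
  sigma_b: 0.5
  terms:
  - var: elev
    type: hump
    coef: 2.0
    optimum: 2075.0
    width: 150.0
  - var: slope
    type: hump
    coef: 1.0
    optimum: 18.0
    width: 10.0
  - var: dist_water
    type: threshold
    coef: 2.0
    breakpoint: 1000.0
    width: 150.0
  - var: cos_aspect
    type: linear
    coef: 0.3
    center: 1.0
    scale: 0.7
  interactions:
  - vars:
    - slope
    - elev
    coef: 0.75
    centers:
    - 12.0
    - 2075.0
    scales:
    - 5.0
    - 250.0
    bounded: yes
  class_effects:
    sagebrush: 0.0
    pinyon_juniper: -1.0
    mahogany: 0.5
    grassland: -0.5
    desert_scrub: 0.3
telemetry:
  n_individuals: 15.0
  fixes_per_individual: 120.0
  season: summer
design:
  isopleth_level: 0.999
  buffer_m: 1000.0
  ratio: 1.0
  cor_threshold: 0.65
glmm:
  interactions:
  - - slope
    - elev
  - - slope
    - dist_water
  - - elev
    - dist_water
  all_subsets: no
forest:
  ntree: 500
  fraction: 0.25
  mtry: 3
  alpha: 1.0
  min_node: 20
cv:
  do_cv: yes
  cv_ntree: 80.0
out_dir: ~
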