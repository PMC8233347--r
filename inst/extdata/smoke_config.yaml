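seed: 1
grid:
  extent:
  - -10.0
  - -8.4
  - -36.0
  - -34.4
  resolution: 0.08
  coastline:
    type: band
covariates: []
truth:
  occurrence:
    alpha_occ: 0.5
    beta_occ:
      SST: 1.2
    alpha_cond: 2.0
    beta_cond:
      SST: 0.5
    sigma2_cond: 0.3
    matern_occ:
      sigma: 0.8
      range: 0.4
      nu: 1.0
    matern_cond:
      sigma: 0.5
      range: 0.4
      nu: 1.0
  cover:
    alpha_occ: 0.8
    beta_occ:
      SST: 1.0
    alpha_cond: 2.5
    beta_cond:
      SST: 0.6
    sigma2_cond: 0.3
    matern_occ:
      sigma: 0.8
      range: 0.4
      nu: 1.0
    matern_cond:
      sigma: 0.5
      range: 0.4
      nu: 1.0
  bleaching:
    alpha_occ: -0.5
    beta_occ:
      SST: 1.5
    alpha_cond: 2.0
    beta_cond:
      SST: 0.8
    sigma2_cond: 0.4
    matern_occ:
      sigma: 0.8
      range: 0.4
      nu: 1.0
    matern_cond:
      sigma: 0.5
      range: 0.4
      nu: 1.0
observations:
  n_sites: 150
  records_per_site: 1
screening:
  gvif_threshold: 3.0
  corr_threshold: 0.7
models:
  candidates: retained
  max_candidates: 4
  n_draws: 600
  selection_draws: 300
  hyper_method: grid
  spatial: last
scenarios:
  mid_century:
    SST: 1.0
    SSS: 1.0
  end_century:
    SST: 3.0
    SSS: 1.5
classification:
  mode: auto
  fixed:
  - 0.21
  - 0.78
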