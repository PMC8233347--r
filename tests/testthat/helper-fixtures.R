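# Small in-code fixtures shared across test files.

small_grid <- function(all_sea = TRUE, n = 15) {
  side <- n * 0.08
  make_grid(c(0, side, 0, side), resolution = 0.08,
            coastline = if (all_sea) list(type = "all_sea")
            else list(type = "band"))
}

std_stack_fixture <- function(grid = small_grid(), seed = 42) {
  standardize_stack(simulate_covariates(grid, seed = seed))
}

# a stack with two controllable raw layers on an all-sea grid, for
# correlation/GVIF oracles
toy_stack <- function(grid, layers) cov_stack(grid, layers)

# sites covering every sea cell (for screening tests)
all_cell_sites <- function(grid) {
  cells <- grid_cells(grid)
  structure(data.frame(site_id = paste0("s", cells$cell),
                       lat = cells$lat, lon = cells$lon,
                       response_kind = "occurrence",
                       y = 1L, z = 1,
                       lat_idx = cells$lat_idx, lon_idx = cells$lon_idx),
            class = c("obs_set", "data.frame"))
}

# deterministic layer matrix from a vector of sea-cell values
layer_from <- function(grid, values) {
  m <- matrix(NA_real_, grid$n_lat, grid$n_lon)
  m[grid$mask] <- values
  m
}

quick_truth <- function(beta_occ = c(SST = 1.2),
                        matern_occ = matern_params(0.6, 0.4)) {
  model_truth(alpha_occ = 0, beta_occ = beta_occ,
              alpha_cond = 1, beta_cond = c(SST = -0.5),
              sigma2_cond = 0.25, matern_occ = matern_occ,
              matern_cond = matern_params(0.4, 0.4))
}
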