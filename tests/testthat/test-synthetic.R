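test_that("simulated SST spans the configured range with a latitudinal
           trend shared across seeds", {
  g <- small_grid(n = 20)
  st <- simulate_covariates(g, seed = 5)
  sst <- st$layers$SST[g$mask]
  # trend spans exactly [21, 28]; noise sd is 0.4, so 4 sd of slack
  expect_gte(min(sst), 21 - 1.6)
  expect_lte(max(sst), 28 + 1.6)
  # zero noise: strictly monotone in latitude along any column
  st0 <- simulate_covariates(g, seed = 5,
                             spec = list(SST = list(noise_sd = 0)))
  col <- st0$layers$SST[, 3]
  expect_true(all(diff(col) > 0))
  # two seeds share the trend (zero-noise layer) and differ in noise
  a <- simulate_covariates(g, seed = 1)
  b <- simulate_covariates(g, seed = 2)
  expect_false(identical(a$layers$SST, b$layers$SST))
  expect_identical(
    simulate_covariates(g, seed = 1, spec = list(SST = list(noise_sd = 0)))$layers$SST,
    simulate_covariates(g, seed = 2, spec = list(SST = list(noise_sd = 0)))$layers$SST)
  expect_error(simulate_covariates(g, spec = list(mystery = list(noise_sd = 1))),
               "unknown covariate")
})

test_that("default stack includes all emulated layers, NA exactly on land", {
  g <- make_grid(c(0, 1.2, 0, 1.2), 0.08, list(type = "band"))
  st <- simulate_covariates(g, seed = 2)
  expect_setequal(names(st$layers),
                  c("SST", "SSS", "KD", "pH", "O2", "PP", "bathymetry",
                    "rugosity"))
  expect_true(all(st$layers$bathymetry[g$mask] < 0))
  for (nm in names(st$layers)) {
    expect_true(all(is.na(st$layers[[nm]][!g$mask])), info = nm)
    expect_true(all(!is.na(st$layers[[nm]][g$mask])), info = nm)
  }
})

test_that("observation generator honours degenerate truths", {
  g <- small_grid(n = 10)
  st <- std_stack_fixture(g)
  # saturated logit: all presences
  tr <- model_truth(alpha_occ = 20, beta_occ = c(SST = 0),
                    matern_occ = matern_params(0, 1),
                    matern_cond = matern_params(0, 1),
                    sigma2_cond = 1e-8, alpha_cond = 0,
                    beta_cond = c(SST = 0))
  obs <- simulate_observations(g, st, tr, n_sites = 50, seed = 1)
  expect_true(all(obs$y == 1))
  # degenerate lognormal: z ~= exp(0) = 1
  expect_true(all(abs(obs$z - 1) < 1e-3))
  expect_error(simulate_observations(g, st, tr, n_sites = 1e6, seed = 1),
               "exceeds")
})

test_that("presence rate matches an intercept-only binomial oracle at
           n = 5000", {
  g <- make_grid(c(0, 6, 0, 6), 0.08, list(type = "all_sea"))
  # betas are zero here, so noise-free gradient layers suffice (and avoid
  # factorising a 5625-cell covariance seven times)
  nn <- function() list(noise_sd = 0)
  st <- simulate_covariates(g, seed = 8, include_rugosity = FALSE,
                            spec = list(SST = nn(), SSS = nn(), KD = nn(),
                                        pH = nn(), O2 = nn(), PP = nn(),
                                        bathymetry = nn()))
  tr <- model_truth(alpha_occ = 0, beta_occ = c(SST = 0),
                    beta_cond = c(SST = 0),
                    matern_occ = matern_params(0, 1),
                    matern_cond = matern_params(0, 1))
  obs <- simulate_observations(g, st, tr, n_sites = 5000, seed = 31)
  se <- sqrt(0.25 / 5000)
  expect_lt(abs(mean(obs$y) - 0.5), 3 * se)
  # conditional log-mean and log-variance match the truth within 3 SE
  lz <- log(obs$z[obs$y == 1]); n1 <- length(lz)
  expect_lt(abs(mean(lz) - tr$alpha_cond), 3 * sqrt(tr$sigma2_cond / n1))
  expect_lt(abs(stats::var(lz) - tr$sigma2_cond),
            3 * tr$sigma2_cond * sqrt(2 / (n1 - 1)))
})

test_that("observations are reproducible and respect the obs_set contract", {
  g <- small_grid(n = 10)
  st <- std_stack_fixture(g)
  tr <- quick_truth()
  o1 <- simulate_observations(g, st, tr, 60, seed = 4)
  o2 <- simulate_observations(g, st, tr, 60, seed = 4)
  expect_identical(o1, o2)
  expect_true(all(o1$y %in% 0:1))
  expect_true(all(is.na(o1$z[o1$y == 0])))
  expect_true(all(o1$z[o1$y == 1] > 0))
  expect_true(all(g$mask[cbind(o1$lat_idx, o1$lon_idx)]))
  # pooled assemblage records share sites
  o3 <- simulate_observations(g, st, tr, 30, seed = 4, records_per_site = 3)
  expect_equal(nrow(o3), 90)
  expect_equal(length(unique(paste(o3$lat, o3$lon))), 30)
})

test_that("future scenarios shift exactly SST and SSS", {
  g <- small_grid(n = 8)
  st <- simulate_covariates(g, seed = 3)
  mid <- make_future_covariates(st, "mid_century")
  endc <- make_future_covariates(st, "end_century")
  expect_equal(mid$layers$SST, st$layers$SST + 1)
  expect_equal(mid$layers$SSS, st$layers$SSS + 1)
  expect_equal(endc$layers$SST, st$layers$SST + 3)
  expect_equal(endc$layers$SSS, st$layers$SSS + 1.5)
  for (nm in setdiff(names(st$layers), c("SST", "SSS")))
    expect_identical(endc$layers[[nm]], st$layers[[nm]])
  # uniform 25 degC raster becomes uniform 28 degC by end-century
  u <- cov_stack(g, list(SST = layer_from(g, rep(25, n_sea(g))),
                         SSS = layer_from(g, rep(35, n_sea(g)))))
  expect_equal(unique(make_future_covariates(u, "end_century")$layers$SST[g$mask]),
               28)
  # zero-delta override is the identity
  z <- make_future_covariates(st, "mid_century", deltas = c(SST = 0, SSS = 0))
  expect_equal(z$layers, st$layers)
  bad <- cov_stack(g, list(SST = layer_from(g, rep(25, n_sea(g)))))
  expect_error(make_future_covariates(bad, "mid_century"), "SSS")
})
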