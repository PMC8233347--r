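# Model-fitting contracts at small n (heavier recovery studies live in the
# acceptance suite).

test_that("intercept-only occurrence fit recovers a 50% presence rate", {
  g <- small_grid(n = 21)
  st <- std_stack_fixture(g)
  cells <- grid_cells(g)[1:400, ]
  obs <- structure(data.frame(site_id = paste0("s", 1:400),
                              lat = cells$lat, lon = cells$lon,
                              response_kind = "occurrence",
                              y = rep(0:1, 200), z = NA_real_,
                              lat_idx = cells$lat_idx,
                              lon_idx = cells$lon_idx),
                   class = c("obs_set", "data.frame"))
  fit <- fit_occurrence(obs, st, character(), spatial = FALSE,
                        n_draws = 600, seed = 2)
  pi_hat <- mean(stats::plogis(fit$draws$alpha))
  expect_gt(pi_hat, 0.45); expect_lt(pi_hat, 0.55)
})

test_that("separation and missing covariates are rejected", {
  g <- small_grid(n = 8)
  st <- std_stack_fixture(g)
  tr <- model_truth(alpha_occ = 20, beta_occ = c(SST = 0),
                    matern_occ = matern_params(0, 1),
                    matern_cond = matern_params(0, 1))
  obs <- simulate_observations(g, st, tr, 30, seed = 1)
  expect_error(fit_occurrence(obs, st, "SST"), "separation")
})

test_that("constant conditional data pin the intercept and shrink sigma2", {
  g <- small_grid(n = 10)
  st <- std_stack_fixture(g)
  cells <- grid_cells(g)[1:60, ]
  obs <- structure(data.frame(site_id = paste0("s", 1:60),
                              lat = cells$lat, lon = cells$lon,
                              response_kind = "cover",
                              y = 1L, z = exp(2),
                              lat_idx = cells$lat_idx,
                              lon_idx = cells$lon_idx),
                   class = c("obs_set", "data.frame"))
  attr(obs, "response_kind") <- "cover"
  fit <- fit_conditional_lognormal(obs, st, character(), spatial = FALSE,
                                   n_draws = 500, seed = 3)
  s <- fit$summaries
  expect_lt(abs(s$mean[s$parameter == "(Intercept)"] - 2), 0.05)
  expect_lt(s$mean[s$parameter == "sigma2"], 0.02)
  # z <= 0 and n < 10 guards
  bad <- obs; bad$z[1] <- 0
  expect_error(fit_conditional_lognormal(bad, st), "positive")
  expect_error(fit_conditional_lognormal(obs[1:5, ], st), "at least 10")
})

test_that("doubling z shifts the conditional intercept by log 2 and leaves
           beta and sigma2 unchanged", {
  g <- small_grid(n = 12)
  st <- std_stack_fixture(g)
  tr <- quick_truth()
  obs <- simulate_observations(g, st, tr, 120, seed = 9)
  f1 <- fit_conditional_lognormal(obs, st, "SST", spatial = FALSE,
                                  n_draws = 800, seed = 4)
  obs2 <- obs; obs2$z <- obs2$z * 2
  f2 <- fit_conditional_lognormal(obs2, st, "SST", spatial = FALSE,
                                  n_draws = 800, seed = 4)
  g1 <- f1$summaries; g2 <- f2$summaries
  expect_lt(abs((g2$mean[1] - g1$mean[1]) - log(2)), 0.05)
  expect_lt(abs(g2$mean[2] - g1$mean[2]), 0.05)
  expect_lt(abs(g2$mean[3] - g1$mean[3]), 0.05)
})

test_that("the two hurdle components are independent and combine by the
           closed-form mean", {
  g <- small_grid(n = 12)
  st <- std_stack_fixture(g)
  tr <- quick_truth(matern_occ = matern_params(0.4, 0.4))
  obs <- simulate_observations(g, st, tr, 120, seed = 10)
  h <- fit_hurdle(obs, st, "SST", "SST", spatial = FALSE, n_draws = 300,
                  seed = 6)
  # refitting the occurrence side never changes the conditional posterior
  occ2 <- fit_occurrence(obs, st, "SST", spatial = FALSE, n_draws = 300,
                         seed = 99)
  h2 <- fit_conditional_lognormal(obs, st, "SST", spatial = FALSE,
                                  n_draws = 300,
                                  seed = child_seed(6, "cond"))
  expect_identical(h$conditional$draws, h2$draws)
  expect_equal(hurdle_mean(0.5, 0, 0), 0.5)
  expect_equal(hurdle_mean(0, 3, 1), 0)
  # Monte-Carlo hurdle draws match pi * exp(mu + s2/2)
  set.seed(11)
  n <- 10000; pi <- 0.6; mu <- 0.4; s2 <- 0.3
  draws <- rbinom(n, 1, pi) * rlnorm(n, mu, sqrt(s2))
  expect_lt(abs(mean(draws) - hurdle_mean(pi, mu, s2)),
            3 * sd(draws) / sqrt(n))
})

test_that("pointwise log-likelihoods match closed forms and are finite", {
  g <- small_grid(n = 12)
  st <- std_stack_fixture(g)
  tr <- quick_truth(matern_occ = matern_params(0.4, 0.4))
  obs <- simulate_observations(g, st, tr, 100, seed = 12)
  fit <- fit_occurrence(obs, st, "SST", spatial = FALSE, n_draws = 200,
                        seed = 7)
  ll <- pointwise_loglik(fit, obs)
  expect_equal(dim(ll), c(100, 200))
  expect_true(all(is.finite(ll)) && all(ll <= 0))
  # agreement with direct Bernoulli log-density draw by draw
  eta <- as.matrix(fit$draws$eta)
  ref <- dbinom(obs$y, 1, stats::plogis(eta), log = TRUE)
  expect_equal(ll, ref, tolerance = 1e-10)
  # conditional fit: lognormal density including the Jacobian
  fc <- fit_conditional_lognormal(obs, st, "SST", spatial = FALSE,
                                  n_draws = 150, seed = 8)
  llc <- pointwise_loglik(fc)
  z <- obs$z[obs$y == 1]
  refc <- sapply(seq_len(150), function(s)
    stats::dlnorm(z, fc$draws$eta[, s], sqrt(fc$draws$sigma2[s]), log = TRUE))
  expect_equal(llc, refc, tolerance = 1e-10)
  expect_error(pointwise_loglik(fit, obs[1:10, ]), "misaligned")
})

test_that("fits are reproducible under a fixed seed and respond to priors
           only weakly when well identified", {
  g <- small_grid(n = 14)
  st <- std_stack_fixture(g)
  tr <- quick_truth(matern_occ = matern_params(0.4, 0.4))
  obs <- simulate_observations(g, st, tr, 196, seed = 13)
  f1 <- fit_occurrence(obs, st, "SST", spatial = FALSE, n_draws = 400,
                       seed = 5)
  f2 <- fit_occurrence(obs, st, "SST", spatial = FALSE, n_draws = 400,
                       seed = 5)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_occurrence(obs, st, "SST", spatial = FALSE, n_draws = 400,
                       seed = 5, prior_var = 10000)
  expect_lt(abs(f3$summaries$mean[2] - f1$summaries$mean[2]), 0.05)
})
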