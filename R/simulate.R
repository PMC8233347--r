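## Synthetic environmental stacks and reef survey observations.
## These generators define the study conditions every downstream stage is
## exercised under: spatially autocorrelated covariate rasters, latent Matern
## fields per response, Bernoulli-logit occurrence, conditional lognormal
## percent cover / percent bleached, and climate-scenario covariate shifts.

#' Construct a covariate stack
#'
#' @param grid a `reef_grid`
#' @param layers named list of `n_lat x n_lon` matrices (NA on land)
#' @param scenario scenario label, default "current"
#' @return object of class `cov_stack`
#' @export
cov_stack <- function(grid, layers, scenario = "current") {
  stopifnot(inherits(grid, "reef_grid"), is.list(layers),
            !is.null(names(layers)))
  for (nm in names(layers)) {
    if (!all(dim(layers[[nm]]) == c(grid$n_lat, grid$n_lon)))
      stop("layer `", nm, "` does not match the grid dimensions")
  }
  structure(list(grid = grid, layers = layers, scenario = scenario,
                 scaling = NULL),
            class = "cov_stack")
}

#' @export
print.cov_stack <- function(x, ...) {
  cat(sprintf("cov_stack [%s]: %s\n", x$scenario,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

# Default synthetic layers. Trend directions and noise levels are chosen so
# that distinct environmental drivers stay statistically distinguishable:
# SST (and the weak-trend pH/O2) run along latitude, salinity/productivity
# cross-shelf along longitude, bathymetry and turbidity along oblique
# axes, and each layer carries Matern noise at a substantial fraction of
# its gradient. Typical pairwise |r| then sits around 0.4-0.65, so
# collinearity screening is exercised without routinely discarding the
# scenario drivers (SST, SSS).
default_covariate_spec <- function() {
  list(
    SST        = list(range = c(21, 28),     axis = "lat", decreasing = FALSE,
                      noise_sd = 0.4,  noise_range = 0.5, nu = 1),
    SSS        = list(range = c(33, 37),     axis = "lon", decreasing = FALSE,
                      noise_sd = 0.7,  noise_range = 0.5, nu = 1),
    KD         = list(range = c(0.05, 0.30), axis = 135, decreasing = FALSE,
                      noise_sd = 0.06, noise_range = 0.4, nu = 1),
    pH         = list(range = c(8.00, 8.10), axis = "lat", decreasing = FALSE,
                      noise_sd = 0.04, noise_range = 0.6, nu = 1),
    O2         = list(range = c(4.5, 6.0),   axis = "lat", decreasing = TRUE,
                      noise_sd = 0.5,  noise_range = 0.5, nu = 1),
    PP         = list(range = c(0.006, 0.014), axis = "lon", decreasing = FALSE,
                      noise_sd = 0.006, noise_range = 0.4, nu = 1),
    bathymetry = list(range = c(-80, -5),    axis = 45, decreasing = TRUE,
                      noise_sd = 7,    noise_range = 0.4, nu = 1)
  )
}

# deterministic trend component of one covariate layer (matrix over the
# grid); `axis` is "lat" (0 degrees), "lon" (90) or a numeric gradient
# direction in degrees mixing the two
covariate_trend <- function(grid, def) {
  lo <- def$range[1]; hi <- def$range[2]
  theta <- if (identical(def$axis, "lat")) 0
  else if (identical(def$axis, "lon")) 90
  else if (is.numeric(def$axis)) def$axis
  else stop("unknown trend axis: ", def$axis)
  lat01 <- (grid$lat_centers - grid$lat_min) /
    max(grid$lat_max - grid$lat_min, 1e-12)
  lon01 <- (grid$lon_centers - grid$lon_min) /
    max(grid$lon_max - grid$lon_min, 1e-12)
  th <- theta * pi / 180
  mix <- outer(cos(th) * lat01, sin(th) * lon01, "+")
  rng <- range(mix)
  t01 <- if (diff(rng) < 1e-12) mix * 0 else (mix - rng[1]) / diff(rng)
  if (isTRUE(def$decreasing)) t01 <- 1 - t01
  lo + (hi - lo) * t01
}

#' Simulate a stack of spatially autocorrelated environmental covariates
#'
#' Each layer is a smooth monotone gradient (in latitude or longitude) plus a
#' seeded Matern noise field over sea cells. The default layers emulate
#' annual-mean marine rasters: SST spanning 21 to 28 degC along latitude,
#' SSS, light attenuation KD, pH, dissolved O2, net primary productivity PP,
#' and a negative-depth bathymetry; seabed rugosity is derived from the
#' simulated bathymetry via [derive_rugosity()] and appended.
#'
#' The gradient component depends only on the grid and spec, so two seeds
#' share the identical trend and differ only in the noise fields.
#'
#' @param grid a `reef_grid`
#' @param seed integer seed
#' @param spec named list of per-covariate definitions overriding or adding to
#'   the defaults. Each definition needs `range` (trend endpoints; equal
#'   endpoints give a flat, pure-noise layer), `axis` ("lat", "lon", or a
#'   gradient direction in degrees mixing the two),
#'   optional `decreasing`, `noise_sd`, `noise_range` (degrees), `nu`. Names
#'   outside the default set must come with a complete definition, otherwise
#'   they error.
#' @param include_rugosity derive and append a rugosity layer (default TRUE)
#' @return a `cov_stack` with land cells set to NA
#' @export
simulate_covariates <- function(grid, seed = 1L, spec = list(),
                                include_rugosity = TRUE) {
  stopifnot(inherits(grid, "reef_grid"))
  defs <- default_covariate_spec()
  for (nm in names(spec)) {
    if (nm %in% names(defs)) {
      defs[[nm]] <- utils::modifyList(defs[[nm]], spec[[nm]])
    } else {
      need <- c("range", "axis", "noise_sd", "noise_range")
      if (!all(need %in% names(spec[[nm]])))
        stop("unknown covariate `", nm,
             "`: supply a full definition (range, axis, noise_sd, noise_range)")
      defs[[nm]] <- utils::modifyList(list(decreasing = FALSE, nu = 1),
                                      spec[[nm]])
    }
  }
  # keep defaults plus any extras, in stable order
  layers <- list()
  k <- 0L
  for (nm in names(defs)) {
    k <- k + 1L
    def <- defs[[nm]]
    tr <- covariate_trend(grid, def)
    noise <- 0
    if (def$noise_sd > 0) {
      f <- simulate_matern_field(
        grid, matern_params(def$noise_sd, def$noise_range, def$nu %||% 1),
        seed = child_seed(seed, paste0("cov_", nm)), n_draws = 1L)
      noise <- embed_sea(grid, f[, 1])
      noise[is.na(noise)] <- 0
    }
    m <- tr + noise
    m[!grid$mask] <- NA_real_
    layers[[nm]] <- m
  }
  if (include_rugosity && "bathymetry" %in% names(layers))
    layers$rugosity <- derive_rugosity_matrix(layers$bathymetry,
                                              grid$resolution)
  cov_stack(grid, layers, scenario = "current")
}

#' True model parameters for the synthetic observation generator
#'
#' Holds the generating intercepts, coefficient vectors (keyed by covariate
#' name, on the scale of the stack handed to [simulate_observations()]),
#' lognormal variance and Matern hyperparameters of the occurrence and
#' conditional latent fields.
#'
#' @param alpha_occ,alpha_cond intercepts of the occurrence logit and the
#'   conditional log-mean
#' @param beta_occ,beta_cond named numeric vectors of covariate coefficients
#' @param sigma2_cond lognormal variance (> 0)
#' @param matern_occ,matern_cond [matern_params()] of the two latent fields
#' @return object of class `model_truth`
#' @export
model_truth <- function(alpha_occ = 0, beta_occ = c(SST = 1),
                        alpha_cond = 1, beta_cond = c(SST = -0.5),
                        sigma2_cond = 0.25,
                        matern_occ = matern_params(0.8, 0.4),
                        matern_cond = matern_params(0.5, 0.4)) {
  if (sigma2_cond <= 0) stop("sigma2_cond must be positive")
  if (length(beta_occ) && is.null(names(beta_occ)))
    stop("beta_occ must be named by covariate")
  if (length(beta_cond) && is.null(names(beta_cond)))
    stop("beta_cond must be named by covariate")
  structure(list(alpha_occ = alpha_occ, beta_occ = beta_occ,
                 alpha_cond = alpha_cond, beta_cond = beta_cond,
                 sigma2_cond = sigma2_cond,
                 matern_occ = matern_occ, matern_cond = matern_cond),
            class = "model_truth")
}

# covariate matrix at given sea-cell rows of grid_cells(grid)
extract_covariates <- function(stack, cells, names) {
  if (length(names) == 0)
    return(matrix(0, nrow(cells), 0))
  missing <- setdiff(names, names(stack$layers))
  if (length(missing))
    stop("covariates not in stack: ", paste(missing, collapse = ", "))
  X <- sapply(names, function(nm)
    stack$layers[[nm]][cbind(cells$lat_idx, cells$lon_idx)])
  X <- matrix(X, nrow = nrow(cells),
              dimnames = list(NULL, names))
  X
}

#' Simulate reef survey observations from known truth
#'
#' Samples `n_sites` distinct sea cells, draws presence
#' `y ~ Bernoulli(plogis(alpha_occ + X beta_occ + W_occ))` and, where
#' `y = 1`, a conditional percent value
#' `z ~ Lognormal(alpha_cond + X beta_cond + W_cond, sigma2_cond)` on the
#' natural-log scale. `z` is a percent in (0, 100]: draws above 100 are
#' capped at 100 and counted in the `capped` attribute.
#'
#' Truth coefficients apply to the covariate values as stored in `stack`
#' (standardize the stack first if per-SD effects are wanted).
#'
#' @param grid a `reef_grid`
#' @param stack a `cov_stack` containing every covariate named in `truth`
#' @param truth a [model_truth()]
#' @param n_sites number of distinct sites (must not exceed the sea-cell
#'   count)
#' @param seed integer seed
#' @param response_kind "occurrence", "cover" or "bleaching" (label only)
#' @param records_per_site emulate multiple pooled assemblage records per
#'   site: each site contributes this many independent (y, z) rows sharing
#'   the site's covariates and latent field values
#' @return data.frame of class `obs_set` with columns `site_id, lat, lon,
#'   response_kind, y, z` plus hidden cell indices; attributes `capped`
#'   (number of z draws capped at 100) and `response_kind`
#' @export
simulate_observations <- function(grid, stack, truth, n_sites, seed = 1L,
                                  response_kind = c("cover", "occurrence",
                                                    "bleaching"),
                                  records_per_site = 1L) {
  stopifnot(inherits(grid, "reef_grid"), inherits(stack, "cov_stack"),
            inherits(truth, "model_truth"))
  response_kind <- match.arg(response_kind)
  if (n_sites < 1) stop("n_sites must be >= 1")
  cells <- grid_cells(grid)
  if (n_sites > nrow(cells))
    stop("n_sites exceeds the number of sea cells (", nrow(cells), ")")

  covs <- union(names(truth$beta_occ), names(truth$beta_cond))
  W_occ_full <- simulate_matern_field(grid, truth$matern_occ,
                                      seed = child_seed(seed, "W_occ"))[, 1]
  W_cond_full <- simulate_matern_field(grid, truth$matern_cond,
                                       seed = child_seed(seed, "W_cond"))[, 1]

  local_seed(seed, {
    pick <- sample.int(nrow(cells), n_sites)
    sites <- cells[pick, , drop = FALSE]
    X <- extract_covariates(stack, sites, covs)
    eta_occ <- truth$alpha_occ + drop(X[, names(truth$beta_occ), drop = FALSE] %*%
                                        truth$beta_occ) + W_occ_full[pick]
    eta_cond <- truth$alpha_cond + drop(X[, names(truth$beta_cond), drop = FALSE] %*%
                                          truth$beta_cond) + W_cond_full[pick]
    rep_idx <- rep(seq_len(n_sites), each = records_per_site)
    n_rec <- length(rep_idx)
    y <- stats::rbinom(n_rec, 1, stats::plogis(eta_occ[rep_idx]))
    z <- rep(NA_real_, n_rec)
    pres <- which(y == 1)
    capped <- 0L
    if (length(pres)) {
      zd <- stats::rlnorm(length(pres), meanlog = eta_cond[rep_idx[pres]],
                          sdlog = sqrt(truth$sigma2_cond))
      capped <- sum(zd > 100)
      if (capped > 0) {
        warning(capped, " conditional draws exceeded 100% and were capped")
        zd <- pmin(zd, 100)
      }
      z[pres] <- zd
    }
    out <- data.frame(
      site_id = sprintf("s%04d_r%d", rep_idx, sequence(rep(records_per_site,
                                                           n_sites))),
      lat = sites$lat[rep_idx], lon = sites$lon[rep_idx],
      response_kind = response_kind, y = y, z = z,
      lat_idx = sites$lat_idx[rep_idx], lon_idx = sites$lon_idx[rep_idx],
      stringsAsFactors = FALSE)
    attr(out, "capped") <- capped
    attr(out, "response_kind") <- response_kind
    class(out) <- c("obs_set", "data.frame")
    out
  })
}

#' Shift a covariate stack to a future climate scenario
#'
#' Applies the scenario's SST and SSS increments and leaves every other layer
#' bit-identical (future projections of the remaining variables are treated
#' as unavailable, so they are held constant). Default increments follow
#' RCP8.5 expectations: +1 degC / +1 PSU by mid-century (2040-2050) and
#' +3 degC / +1.5 PSU by end-century (2090-2100).
#'
#' @param stack a `cov_stack` containing `SST` and `SSS`
#' @param scenario "mid_century" or "end_century"
#' @param deltas optional named numeric overrides `c(SST = ..., SSS = ...)`
#' @return a new `cov_stack` labelled with the scenario
#' @export
make_future_covariates <- function(stack,
                                   scenario = c("mid_century", "end_century"),
                                   deltas = NULL) {
  stopifnot(inherits(stack, "cov_stack"))
  scenario <- match.arg(scenario)
  if (!all(c("SST", "SSS") %in% names(stack$layers)))
    stop("stack must contain SST and SSS layers")
  if (is.null(deltas))
    deltas <- switch(scenario,
                     mid_century = c(SST = 1,  SSS = 1),
                     end_century = c(SST = 3,  SSS = 1.5))
  out <- stack
  out$scenario <- scenario
  for (nm in names(deltas)) {
    if (!nm %in% names(out$layers))
      stop("delta for `", nm, "` but layer is missing")
    out$layers[[nm]] <- out$layers[[nm]] + deltas[[nm]]
  }
  out
}
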