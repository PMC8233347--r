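## Projection of fitted models onto the full grid, under current and
## future covariate stacks, and scenario delta maps.

# GP conditional-mean (kriging) interpolation weights from fitted nodes to
# target coordinates: a linear operator on posterior field draws, exact at
# the nodes.
krige_weights <- function(fit, coords) {
  params <- matern_params(1, fit$hypers$range, fit$hypers$nu)
  R_nn <- matern_correlation(
    pairwise_dist(fit$node_coords, method = fit$distance), params)
  R_cn <- matern_correlation(
    pairwise_dist(coords, fit$node_coords, method = fit$distance), params)
  R_cn %*% solve(R_nn + diag(1e-8, nrow(R_nn)))
}

# per-cell draw matrix of the linear predictor for one posterior_fit
cell_eta_draws <- function(fit, stack, cells) {
  X <- extract_covariates(stack, cells,
                          fit$covariate_names %||% character())
  if (anyNA(X)) stop("missing covariate value at one or more grid cells")
  S <- length(fit$draws$alpha)
  eta <- matrix(rep(fit$draws$alpha, each = nrow(cells)), nrow(cells), S)
  if (length(fit$covariate_names))
    eta <- eta + X %*% t(fit$draws$beta)
  if (fit$spatial) {
    A <- krige_weights(fit, as.matrix(cells[, c("lat", "lon")]))
    eta <- eta + A %*% fit$draws$W
  }
  eta
}

# extrapolation flag: any covariate outside the fitted per-variable range
extrapolation_mask <- function(fit, stack, cells) {
  covs <- fit$covariate_names %||% character()
  if (!length(covs)) return(rep(FALSE, nrow(cells)))
  Xc <- extract_covariates(stack, cells, covs)
  out <- rep(FALSE, nrow(cells))
  for (j in seq_along(covs)) {
    r <- range(fit$X[, covs[j]])
    out <- out | Xc[, j] < r[1] | Xc[, j] > r[2]
  }
  out
}

new_surface <- function(grid, scenario, response_kind, values, sd,
                        extrapolated) {
  structure(list(grid = grid, scenario = scenario,
                 response_kind = response_kind,
                 values = embed_sea(grid, values),
                 sd = embed_sea(grid, sd),
                 extrapolated = embed_sea(grid, as.numeric(extrapolated))),
            class = "prob_surface")
}

#' Project a fitted model onto the grid as a probability/cover surface
#'
#' Per-cell posterior predictive mean through the fitted link: the mean over
#' posterior draws of `plogis(eta)` for occurrence fits, of the conditional
#' mean `exp(eta + sigma2/2)` for conditional lognormal fits, and of the
#' hurdle expectation `pi * exp(mu + sigma2/2)` for hurdle fits (draws of
#' the two components paired by index). The latent spatial field is carried
#' to unsampled cells by linear (GP conditional-mean) interpolation of the
#' posterior field draws from the fitted nodes, which is exact at the nodes.
#' Cells whose covariates fall outside the fitted covariate range are
#' flagged in the `extrapolated` companion mask (projection proceeds).
#'
#' The stack must be on the same standardization as the fitting stack (its
#' `scaling` is checked when both are present).
#'
#' @param fit a `posterior_fit` or `hurdle_fit`
#' @param stack covariate `cov_stack` for the scenario to project
#' @param grid target `reef_grid` (defaults to the stack's grid)
#' @return a `prob_surface`: per-cell `values`, posterior `sd` and
#'   `extrapolated` mask matrices (NA on land), with the stack's scenario
#'   label
#' @export
predict_surface <- function(fit, stack, grid = stack$grid) {
  stopifnot(inherits(stack, "cov_stack"))
  if (!all(dim(stack$layers[[1]]) == c(grid$n_lat, grid$n_lon)))
    stop("grid and stack dimensions do not match")
  check_scaling <- function(f) {
    if (!is.null(f$scaling) && !is.null(stack$scaling) &&
        !isTRUE(all.equal(f$scaling, stack$scaling)))
      stop("stack standardization differs from the fitting stack")
  }
  cells <- grid_cells(grid)
  if (inherits(fit, "hurdle_fit")) {
    check_scaling(fit$occurrence); check_scaling(fit$conditional)
    pi_d <- stats::plogis(cell_eta_draws(fit$occurrence, stack, cells))
    mu_d <- cell_eta_draws(fit$conditional, stack, cells)
    S <- min(ncol(pi_d), ncol(mu_d))
    s2 <- fit$conditional$draws$sigma2[seq_len(S)]
    vals_d <- pi_d[, seq_len(S)] *
      exp(mu_d[, seq_len(S)] + rep(s2, each = nrow(cells)) / 2)
    ex <- extrapolation_mask(fit$occurrence, stack, cells) |
      extrapolation_mask(fit$conditional, stack, cells)
    rk <- fit$response_kind
  } else if (inherits(fit, "posterior_fit")) {
    check_scaling(fit)
    eta <- cell_eta_draws(fit, stack, cells)
    vals_d <- if (fit$likelihood == "bernoulli") stats::plogis(eta) else
      exp(eta + rep(fit$draws$sigma2, each = nrow(cells)) / 2)
    ex <- extrapolation_mask(fit, stack, cells)
    rk <- fit$response_kind %||% fit$likelihood
  } else stop("`fit` must be a posterior_fit or hurdle_fit")
  new_surface(grid, stack$scenario, rk,
              values = rowMeans(vals_d),
              sd = apply(vals_d, 1, stats::sd),
              extrapolated = ex)
}

#' Project one fit under current and future covariate stacks
#'
#' One surface per scenario from the same fit: no refitting, identical
#' posterior draws, and the latent spatial field held fixed across
#' scenarios, so scenario differences are driven by the covariate shifts
#' alone.
#'
#' @param fit a `posterior_fit` or `hurdle_fit`
#' @param current_stack the fitting-period stack
#' @param future_stacks named list of future stacks (built by
#'   [make_future_covariates()] and standardized with the current scaling)
#' @return named list of `prob_surface` (current first)
#' @export
predict_scenarios <- function(fit, current_stack, future_stacks = list()) {
  out <- list(current = predict_surface(fit, current_stack))
  for (nm in names(future_stacks))
    out[[nm]] <- predict_surface(fit, future_stacks[[nm]])
  out
}

#' Scenario delta map (future minus current)
#'
#' @param future,current `prob_surface`s on the same grid and response
#' @return object of class `delta_surface` with cell-wise differences (NA on
#'   land)
#' @export
delta_map <- function(future, current) {
  stopifnot(inherits(future, "prob_surface"), inherits(current, "prob_surface"))
  if (!isTRUE(all.equal(future$grid[c("n_lat", "n_lon", "resolution")],
                        current$grid[c("n_lat", "n_lon", "resolution")])) ||
      !identical(future$grid$mask, current$grid$mask))
    stop("surfaces are on different grids")
  if (!identical(future$response_kind, current$response_kind))
    stop("surfaces have different response kinds")
  structure(list(grid = future$grid,
                 pair = c(future = future$scenario,
                          current = current$scenario),
                 response_kind = future$response_kind,
                 values = future$values - current$values),
            class = "delta_surface")
}

#' @export
print.prob_surface <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("prob_surface [%s, %s]: %d sea cells, mean %.3f, range %.3f..%.3f\n",
              x$response_kind, x$scenario, length(v), mean(v), min(v), max(v)))
  invisible(x)
}
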