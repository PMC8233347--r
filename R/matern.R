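#' Matern hyperparameters for a latent spatial field
#'
#' @param sigma marginal standard deviation of the field (> 0; 0 is allowed
#'   as the degenerate no-field limit in the simulator)
#' @param range practical range: the distance (same units as the coordinates,
#'   decimal degrees for planar distance) at which the correlation has
#'   dropped to about 0.14 under the `sqrt(8 nu) / range` scaling convention
#' @param nu smoothness (> 0); default 1
#' @return object of class `matern_params`
#' @export
matern_params <- function(sigma, range, nu = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0 || !is.finite(sigma))
    stop("`sigma` must be a single non-negative number")
  if (!is.numeric(range) || length(range) != 1 || range <= 0)
    stop("`range` must be a single positive number")
  if (!is.numeric(nu) || length(nu) != 1 || nu <= 0)
    stop("`nu` must be a single positive number")
  structure(list(sigma = sigma, range = range, nu = nu),
            class = "matern_params")
}

#' Matern correlation function
#'
#' Correlation at distance `d` for a Matern field with smoothness `nu` and
#' practical range `range`, using the scaling `kappa = sqrt(8 nu) / range`
#' (so the correlation is about 0.14 at `d = range`). For `nu = 0.5` this
#' reduces to `exp(-2 d / range)`.
#'
#' @param d non-negative distance(s)
#' @param params a [matern_params()] object
#' @return correlation value(s) in (0, 1]
#' @export
matern_correlation <- function(d, params) {
  stopifnot(inherits(params, "matern_params"))
  if (any(d < 0)) stop("distances must be non-negative")
  kappa <- sqrt(8 * params$nu) / params$range
  x <- kappa * d
  out <- numeric(length(x))
  zero <- x < 1e-12
  out[zero] <- 1
  if (any(!zero)) {
    xx <- x[!zero]
    nu <- params$nu
    out[!zero] <- 2^(1 - nu) / gamma(nu) * xx^nu * besselK(xx, nu)
  }
  dim(out) <- dim(d)
  out
}

# Matern covariance matrix between coordinate sets (lat, lon matrices)
matern_cov <- function(a, b = a, params, distance = "planar") {
  d <- pairwise_dist(a, b, method = distance)
  params$sigma^2 * matern_correlation(d, params)
}

#' Simulate zero-mean Matern Gaussian fields on the sea cells of a grid
#'
#' Draws from a multivariate normal with Matern covariance between sea-cell
#' centers, by dense Cholesky factorisation (the contract is the covariance,
#' not the factorisation; dense is exact at the desk scales this package
#' targets). Distances are planar in decimal degrees by default, appropriate
#' for a narrow coastal strip; great-circle (km) is available, in which case
#' `range` must be in km.
#'
#' @param grid a `reef_grid` with at least 2 sea cells
#' @param params [matern_params()]; `sigma = 0` returns identically zero
#'   fields
#' @param seed integer seed; fixed seed gives bit-identical draws
#' @param n_draws number of independent replicate fields
#' @param distance "planar" or "greatcircle"
#' @return matrix `n_sea x n_draws` of field values (a vector if
#'   `n_draws = 1` and `drop = TRUE` semantics are wanted, use `[ , 1]`)
#' @export
simulate_matern_field <- function(grid, params, seed = 1L, n_draws = 1L,
                                  distance = c("planar", "greatcircle")) {
  stopifnot(inherits(grid, "reef_grid"))
  distance <- match.arg(distance)
  cells <- grid_cells(grid)
  m <- nrow(cells)
  if (m < 2) stop("grid must have at least 2 sea cells")
  if (params$sigma == 0)
    return(matrix(0, m, n_draws))
  coords <- as.matrix(cells[, c("lat", "lon")])
  S <- matern_cov(coords, params = params, distance = distance)
  L <- chol(S + diag(1e-10 * params$sigma^2, m))
  local_seed(seed, {
    z <- matrix(stats::rnorm(m * n_draws), m, n_draws)
    crossprod(L, z)
  })
}
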