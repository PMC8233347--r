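## Covariate preparation: rugosity from bathymetry, regridding,
## standardization, cover rescaling, and collinearity screening
## (Pearson correlation + generalized variance inflation factors).

# Horn 3x3 slope on a value matrix; edge cells reuse the nearest available
# neighbour (replicate padding). Returns slope in degrees.
derive_rugosity_matrix <- function(m, cell_size) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) stop("bathymetry raster must be at least 3x3 cells")
  if (all(is.na(m))) stop("bathymetry raster is all missing")
  # replicate-pad, NA-aware: missing neighbours fall back to the center value
  pad <- matrix(NA_real_, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  pad[1, ] <- pad[2, ]; pad[nr + 2, ] <- pad[nr + 1, ]
  pad[, 1] <- pad[, 2]; pad[, nc + 2] <- pad[, nc + 1]
  get <- function(di, dj) {
    v <- pad[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
    v[is.na(v)] <- m[is.na(v)]  # fall back to center where neighbour missing
    v
  }
  zN <- get(-1, 0); zS <- get(1, 0); zE <- get(0, 1); zW <- get(0, -1)
  zNE <- get(-1, 1); zNW <- get(-1, -1); zSE <- get(1, 1); zSW <- get(1, -1)
  gx <- ((zNE + 2 * zE + zSE) - (zNW + 2 * zW + zSW)) / (8 * cell_size)
  gy <- ((zSW + 2 * zS + zSE) - (zNW + 2 * zN + zNE)) / (8 * cell_size)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  slope[is.na(m)] <- NA_real_
  slope
}

#' Derive seabed rugosity (slope) from bathymetry
#'
#' Per-cell slope of the bathymetry surface from the 3x3 neighbourhood
#' (Horn's method), reported in degrees; edge cells reuse the available
#' neighbours by replicate padding, and missing neighbours fall back to the
#' center value. Gradients are taken per coordinate unit of the grid
#' (decimal degrees), matching how terrain functions treat projected cells.
#'
#' @param bathymetry an `n_lat x n_lon` matrix of (negative) depths, or a
#'   `cov_stack` whose `bathymetry` layer is used
#' @param cell_size cell side in the gradient units (taken from the stack's
#'   grid when a stack is given)
#' @return matrix of non-negative slopes in degrees (NA where bathymetry is
#'   NA)
#' @export
derive_rugosity <- function(bathymetry, cell_size = NULL) {
  if (inherits(bathymetry, "cov_stack")) {
    if (!"bathymetry" %in% names(bathymetry$layers))
      stop("stack has no bathymetry layer")
    return(derive_rugosity_matrix(bathymetry$layers$bathymetry,
                                  bathymetry$grid$resolution))
  }
  if (is.null(cell_size) || cell_size <= 0)
    stop("`cell_size` must be a positive number")
  derive_rugosity_matrix(as.matrix(bathymetry), cell_size)
}

#' Aggregate a raster to a coarser resolution by block means
#'
#' Missing-aware block-mean aggregation (the mean of the non-missing source
#' cells in each target block). The target resolution must be an integer
#' multiple of the source resolution: refining, or non-nesting ratios, would
#' invent detail and error out.
#'
#' @param values source matrix
#' @param source_resolution,target_resolution cell sides in degrees
#' @return aggregated matrix of block means
#' @export
regrid <- function(values, source_resolution, target_resolution) {
  values <- as.matrix(values)
  if (target_resolution < source_resolution - 1e-12)
    stop("target resolution is finer than the source; refuse to invent detail")
  f <- target_resolution / source_resolution
  if (abs(f - round(f)) > 1e-8)
    stop("target resolution must be an integer multiple of the source")
  f <- as.integer(round(f))
  if (f == 1L) return(values)
  nr <- ceiling(nrow(values) / f); nc <- ceiling(ncol(values) / f)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    ri <- ((i - 1L) * f + 1L):min(i * f, nrow(values))
    for (j in seq_len(nc)) {
      cj <- ((j - 1L) * f + 1L):min(j * f, ncol(values))
      block <- values[ri, cj]
      if (any(!is.na(block))) out[i, j] <- mean(block, na.rm = TRUE)
    }
  }
  out
}

#' Standardize every layer of a covariate stack to z-scores over sea cells
#'
#' Records the per-layer means and standard deviations so that future-
#' scenario stacks can be standardized with the *current* parameters,
#' keeping scenario shifts interpretable (a +3 degC shift stays visible as
#' +3/sd).
#'
#' @param stack a `cov_stack`
#' @param scaling optional scaling to reuse (the `$scaling` of a previously
#'   standardized stack): data.frame with `variable`, `mean`, `sd`
#' @return a `cov_stack` with standardized layers and `$scaling` filled in
#' @export
standardize_stack <- function(stack, scaling = NULL) {
  stopifnot(inherits(stack, "cov_stack"))
  grid <- stack$grid
  if (is.null(scaling)) {
    scaling <- data.frame(variable = names(stack$layers),
                          mean = NA_real_, sd = NA_real_,
                          stringsAsFactors = FALSE)
    for (k in seq_along(stack$layers)) {
      v <- sea_values(grid, stack$layers[[k]])
      v <- v[!is.na(v)]
      if (length(v) < 2)
        stop("layer `", names(stack$layers)[k],
             "` has fewer than 2 non-missing sea values")
      s <- stats::sd(v)
      if (!is.finite(s) || s < 1e-12)
        stop("layer `", names(stack$layers)[k],
             "` has zero variance; cannot standardize")
      scaling$mean[k] <- mean(v); scaling$sd[k] <- s
    }
  } else {
    missing <- setdiff(names(stack$layers), scaling$variable)
    if (length(missing))
      stop("scaling has no parameters for: ", paste(missing, collapse = ", "))
  }
  out <- stack
  for (nm in names(out$layers)) {
    row <- match(nm, scaling$variable)
    out$layers[[nm]] <- (out$layers[[nm]] - scaling$mean[row]) / scaling$sd[row]
  }
  out$scaling <- scaling
  out
}

#' Rescale a species' share of coral to percent of total benthos
#'
#' Converts a species' fraction of the coral assemblage into percent cover
#' of the whole benthos, given the total coral cover of the area.
#'
#' @param species_fraction_of_coral proportion in [0, 1]
#' @param total_coral_cover percent in [0, 100]
#' @return percent cover of total benthos
#' @export
rescale_cover <- function(species_fraction_of_coral, total_coral_cover) {
  if (any(species_fraction_of_coral < 0 | species_fraction_of_coral > 1,
          na.rm = TRUE))
    stop("species_fraction_of_coral must be in [0, 1]")
  if (any(total_coral_cover < 0 | total_coral_cover > 100, na.rm = TRUE))
    stop("total_coral_cover must be in [0, 100]")
  species_fraction_of_coral * total_coral_cover
}

# covariate matrix at observation sites (complete rows only when requested)
site_design <- function(stack, sites, variables = names(stack$layers)) {
  cells <- data.frame(lat_idx = sites$lat_idx, lon_idx = sites$lon_idx)
  extract_covariates(stack, cells, variables)
}

#' Pairwise Pearson correlation of covariates at observation sites
#'
#' @param stack a `cov_stack`
#' @param sites an `obs_set` (or any data.frame with `lat_idx`, `lon_idx`)
#' @param variables covariate names, default all layers
#' @return symmetric correlation matrix with unit diagonal
#' @export
pearson_matrix <- function(stack, sites, variables = names(stack$layers)) {
  X <- site_design(stack, sites, variables)
  ok <- stats::complete.cases(X)
  if (sum(ok) < 3) stop("need at least 3 sites with complete covariate values")
  stats::cor(X[ok, , drop = FALSE])
}

#' Generalized variance inflation factors at observation sites
#'
#' For each variable, GVIF from projecting the variable on the others in
#' correlation space; for 1-df continuous variables this equals the
#' classical VIF
#' `1/(1 - R^2)` from regressing the variable on the others. The
#' df-corrected value `GVIF^(1/(2 df))` is reported alongside for
#' comparability across terms. Perfect collinearity yields `Inf`, not an
#' error.
#'
#' @inheritParams pearson_matrix
#' @return data.frame with `variable`, `df`, `gvif`, `gvif_corrected`
#' @export
gvif <- function(stack, sites, variables = names(stack$layers)) {
  if (length(variables) < 2) stop("need at least 2 variables for GVIF")
  R <- pearson_matrix(stack, sites, variables)
  gvif_from_cor(R)
}

# GVIF table from a correlation matrix (all terms 1 df). Per-variable
# R^2 from projecting the variable on the others via a pseudoinverse, so a
# collinear pair elsewhere in the set does not contaminate an uninvolved
# variable, and perfect collinearity of the variable itself gives Inf.
gvif_from_cor <- function(R) {
  p <- ncol(R)
  out <- data.frame(variable = colnames(R), df = 1L,
                    gvif = NA_real_, gvif_corrected = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    Ro <- R[-j, -j, drop = FALSE]
    r <- R[-j, j]
    sv <- svd(Ro)
    keep <- sv$d > 1e-10 * sv$d[1]
    coef <- sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], r)) / sv$d[keep])
    r2 <- min(max(sum(r * coef), 0), 1)
    g <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    out$gvif[j] <- g
    out$gvif_corrected[j] <- sqrt(g)
  }
  out
}

#' Stepwise collinearity screening of covariates
#'
#' Iteratively removes the single worst offender until the retained set has
#' maximum df-corrected GVIF at or below `gvif_threshold` and maximum
#' absolute pairwise Pearson correlation at or below `corr_threshold`. At
#' each step the variable with the highest corrected GVIF above threshold is
#' removed first (ties broken alphabetically); if none, the member of the
#' highest-|r| offending pair with the larger mean |r| to all other
#' variables is removed. Everything is recomputed after each removal and a
#' full audit trail is returned.
#'
#' @inheritParams pearson_matrix
#' @param gvif_threshold maximum acceptable corrected GVIF (default 3)
#' @param corr_threshold maximum acceptable |Pearson r| (default 0.70)
#' @param order "gvif_first" (default) or "corr_first": which criterion is
#'   checked for offenders first at each step
#' @return object of class `screening_report`: `correlation_matrix`,
#'   `gvif_table` (of the retained set), `removed` (data.frame variable,
#'   reason, value, step), `retained`, thresholds
#' @export
screen_covariates <- function(stack, sites, variables = names(stack$layers),
                              gvif_threshold = 3, corr_threshold = 0.70,
                              order = c("gvif_first", "corr_first")) {
  order <- match.arg(order)
  if (length(variables) < 2) stop("need at least 2 candidate variables")
  current <- variables  # input order preserved; ties break alphabetically
  removed <- data.frame(variable = character(), reason = character(),
                        value = numeric(), step = integer(),
                        stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    step <- step + 1L
    if (length(current) < 2) break
    R <- pearson_matrix(stack, sites, current)
    gt <- gvif_from_cor(R)
    absR <- abs(R); diag(absR) <- 0

    gvif_offender <- function() {
      worst <- max(gt$gvif_corrected)
      if (worst > gvif_threshold) {
        cand <- gt$variable[gt$gvif_corrected == worst]
        list(var = sort(cand)[1], reason = "gvif", value = worst)
      } else NULL
    }
    corr_offender <- function() {
      worst <- max(absR)
      if (worst > corr_threshold) {
        ij <- which(absR == worst, arr.ind = TRUE)[1, ]
        pair <- colnames(R)[ij]
        mean_abs <- colSums(absR[, pair, drop = FALSE]) / (nrow(R) - 1)
        pick <- pair[order(-mean_abs, pair)][1]
        list(var = pick, reason = "correlation", value = worst)
      } else NULL
    }
    off <- if (order == "gvif_first") {
      gvif_offender() %||% corr_offender()
    } else {
      corr_offender() %||% gvif_offender()
    }
    if (is.null(off)) break
    removed <- rbind(removed, data.frame(
      variable = off$var, reason = off$reason, value = off$value,
      step = step, stringsAsFactors = FALSE))
    current <- setdiff(current, off$var)
  }
  R_final <- if (length(current) >= 2)
    pearson_matrix(stack, sites, current)
  else matrix(1, length(current), length(current),
              dimnames = list(current, current))
  gt_final <- if (length(current) >= 2) gvif_from_cor(R_final) else
    data.frame(variable = current, df = 1L, gvif = 1, gvif_corrected = 1,
               stringsAsFactors = FALSE)
  structure(list(correlation_matrix = R_final, gvif_table = gt_final,
                 removed = removed, retained = current,
                 gvif_threshold = gvif_threshold,
                 corr_threshold = corr_threshold),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("screening_report: retained", length(x$retained), "of",
      length(x$retained) + nrow(x$removed), "variables\n")
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$removed)) {
    for (i in seq_len(nrow(x$removed)))
      cat(sprintf("  removed %s (%s = %.3f, step %d)\n",
                  x$removed$variable[i], x$removed$reason[i],
                  x$removed$value[i], x$removed$step[i]))
  }
  invisible(x)
}
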