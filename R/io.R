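## Plain-text I/O: observation tables and long-format raster CSVs.

#' Write / read observation sets as CSV
#'
#' Schema: `site_id,lat,lon,response_kind,y,z` with `y` in {0,1} and `z`
#' positive exactly where `y = 1` (empty otherwise).
#'
#' @param obs an `obs_set`
#' @param path file path
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(obs[, c("site_id", "lat", "lon", "response_kind",
                           "y", "z")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @param grid optional `reef_grid`: sites are snapped to cells and must lie
#'   on sea cells
#' @return an `obs_set`
#' @export
read_observations <- function(path, grid = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "lat", "lon", "response_kind", "y", "z")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("malformed observation CSV, missing column(s): ",
         paste(missing, collapse = ", "))
  if (!all(df$y %in% c(0, 1))) stop("column `y` must be 0 or 1")
  if (any(df$y == 1 & (is.na(df$z) | df$z <= 0)))
    stop("column `z` must be positive where y = 1")
  if (any(df$y == 0 & !is.na(df$z)))
    stop("column `z` must be empty where y = 0")
  if (!is.null(grid)) {
    idx <- snap_to_cell(grid, df$lat, df$lon)
    if (!all(grid$mask[idx]))
      stop("some sites fall on land cells of the grid")
    df$lat_idx <- idx[, "lat_idx"]; df$lon_idx <- idx[, "lon_idx"]
  }
  attr(df, "response_kind") <- df$response_kind[1]
  class(df) <- c("obs_set", "data.frame")
  df
}

#' Write / read covariate stacks as long-format CSV rasters
#'
#' One row per sea cell and layer: `lat,lon,name,value`.
#'
#' @param stack a `cov_stack`
#' @param path file path
#' @export
write_stack_csv <- function(stack, path) {
  cells <- grid_cells(stack$grid)
  rows <- lapply(names(stack$layers), function(nm)
    data.frame(lat = cells$lat, lon = cells$lon, name = nm,
               value = stack$layers[[nm]][cbind(cells$lat_idx,
                                                cells$lon_idx)],
               stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_stack_csv
#' @param grid the `reef_grid` the raster must match
#' @param scenario scenario label for the rebuilt stack
#' @return a `cov_stack`
#' @export
read_stack_csv <- function(path, grid, scenario = "current") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lat", "lon", "name", "value")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("malformed raster CSV, missing column(s): ",
         paste(missing, collapse = ", "))
  idx <- snap_to_cell(grid, df$lat, df$lon)
  off <- abs(grid$lat_centers[idx[, 1]] - df$lat) > grid$resolution / 2 + 1e-9 |
    abs(grid$lon_centers[idx[, 2]] - df$lon) > grid$resolution / 2 + 1e-9
  if (any(off))
    stop("raster coordinates do not match the configured grid")
  layers <- list()
  for (nm in unique(df$name)) {
    m <- matrix(NA_real_, grid$n_lat, grid$n_lon)
    sel <- df$name == nm
    m[idx[sel, , drop = FALSE]] <- df$value[sel]
    layers[[nm]] <- m
  }
  cov_stack(grid, layers, scenario = scenario)
}

#' Write a projected surface as CSV
#'
#' One row per sea cell: `lat,lon,value,sd,extrapolated` (probability or
#' vulnerability surfaces; `sd`/`extrapolated` columns included when
#' available).
#'
#' @param surface a `prob_surface` or `vuln_surface`
#' @param path file path
#' @export
write_surface <- function(surface, path) {
  g <- surface$grid
  cells <- grid_cells(g)
  ij <- cbind(cells$lat_idx, cells$lon_idx)
  df <- data.frame(lat = cells$lat, lon = cells$lon,
                   value = surface$values[ij])
  if (!is.null(surface$sd)) df$sd <- surface$sd[ij]
  if (!is.null(surface$extrapolated))
    df$extrapolated <- surface$extrapolated[ij]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
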