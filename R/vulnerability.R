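## Bleaching-vulnerability framework: max-standardize the occurrence, cover
## and bleaching surfaces, overlap (multiply) them, classify by quartile
## thresholds of the current projection, and compare scenarios by area
## change and kernel density estimates.

#' Max-standardize a surface to [0, 1]
#'
#' Cell-wise division by the surface maximum over sea cells, so surfaces on
#' different scales contribute without disproportional weight to the
#' overlap. Scale-invariant: multiplying the input by any c > 0 leaves the
#' output unchanged.
#'
#' @param surface a `prob_surface`
#' @return the surface with values (and sd) divided by the max; attribute
#'   `max_standardized` set
#' @export
max_standardize <- function(surface) {
  stopifnot(inherits(surface, "prob_surface"))
  mx <- max(surface$values, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0)
    stop("surface maximum must be positive to max-standardize")
  surface$values <- surface$values / mx
  surface$sd <- surface$sd / mx
  attr(surface, "max_standardized") <- TRUE
  surface
}

#' Overlap three max-standardized surfaces into a vulnerability surface
#'
#' Cell-wise product of the (max-standardized) occurrence, cover and
#' bleaching projections; the result varies between 0 and 1, higher meaning
#' more vulnerable. Inputs must be on the same grid and scenario and already
#' max-standardized (max exactly 1 over sea cells).
#'
#' @param occ,cover,bleach `prob_surface`s from [max_standardize()]
#' @return object of class `vuln_surface`
#' @export
overlap_surfaces <- function(occ, cover, bleach) {
  surfaces <- list(occ, cover, bleach)
  g <- occ$grid
  for (s in surfaces) {
    stopifnot(inherits(s, "prob_surface"))
    if (!identical(s$grid$mask, g$mask) ||
        !isTRUE(all.equal(s$grid$resolution, g$resolution)))
      stop("surfaces are on different grids")
    if (!identical(s$scenario, occ$scenario))
      stop("surfaces are from different scenarios")
    mx <- max(s$values, na.rm = TRUE)
    if (abs(mx - 1) > 1e-8)
      stop("input surface is not max-standardized (max = ",
           format(mx), "); call max_standardize() first")
  }
  structure(list(grid = g, scenario = occ$scenario,
                 values = occ$values * cover$values * bleach$values,
                 components = c(occ$response_kind, cover$response_kind,
                                bleach$response_kind)),
            class = "vuln_surface")
}

#' Quartile classification thresholds of a vulnerability surface
#'
#' Lower and upper quartiles (25th and 75th percentiles, linear-interpolation
#' convention, `stats::quantile` type 7) of the current-scenario cell
#' values. The published fixed bounds (0.21, 0.78) are available as an
#' override for reproducing the original classification.
#'
#' @param vuln a `vuln_surface` with at least 4 sea cells
#' @param mode "auto" (compute quartiles) or "fixed" (return `fixed`)
#' @param fixed thresholds returned verbatim in fixed mode
#' @return numeric `c(q_low, q_high)`
#' @export
quartile_thresholds <- function(vuln, mode = c("auto", "fixed"),
                                fixed = c(0.21, 0.78)) {
  mode <- match.arg(mode)
  if (mode == "fixed") return(c(q_low = fixed[1], q_high = fixed[2]))
  v <- vuln$values[!is.na(vuln$values)]
  if (length(v) < 4) stop("need at least 4 sea cells for quartiles")
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  c(q_low = q[1], q_high = q[2])
}

#' Classify a vulnerability surface into low / intermediate / hotspot
#'
#' Half-open classes close the gaps the printed bounds would leave:
#' low = [0, q_low), intermediate = [q_low, q_high), hotspot = [q_high, 1].
#'
#' @param vuln a `vuln_surface`
#' @param thresholds `c(q_low, q_high)` with q_low <= q_high (typically from
#'   [quartile_thresholds()] of the *current* scenario, reused for futures)
#' @return list of class `vuln_classes`: `class_map` (character matrix, NA
#'   on land), `area` data.frame (class, cells, pct), `thresholds`,
#'   `scenario`
#' @export
classify_vulnerability <- function(vuln, thresholds) {
  stopifnot(inherits(vuln, "vuln_surface"))
  if (thresholds[1] > thresholds[2])
    stop("inverted thresholds: q_low must be <= q_high")
  v <- vuln$values
  cls <- matrix(NA_character_, nrow(v), ncol(v))
  sea <- !is.na(v)
  cls[sea] <- ifelse(v[sea] < thresholds[1], "low",
                     ifelse(v[sea] < thresholds[2], "intermediate",
                            "hotspot"))
  lev <- c("low", "intermediate", "hotspot")
  counts <- vapply(lev, function(l) sum(cls == l, na.rm = TRUE), 0L)
  area <- data.frame(class = lev, cells = as.integer(counts),
                     pct = 100 * counts / sum(counts),
                     stringsAsFactors = FALSE)
  structure(list(class_map = cls, area = area,
                 thresholds = c(q_low = unname(thresholds[1]),
                                q_high = unname(thresholds[2])),
                 scenario = vuln$scenario),
            class = "vuln_classes")
}

#' Percent change of class areas between scenarios
#'
#' `100 * (future - current) / current` per class; classification of both
#' scenarios must use the current scenario's thresholds (held fixed) for the
#' change to be meaningful. A class with zero current area is reported with
#' `undefined = TRUE` rather than erroring.
#'
#' @param current,future `vuln_classes` objects
#' @return data.frame with `class`, `current_pct`, `future_pct`,
#'   `pct_change`, `undefined`
#' @export
class_area_change <- function(current, future) {
  stopifnot(inherits(current, "vuln_classes"), inherits(future, "vuln_classes"))
  if (!identical(dim(current$class_map), dim(future$class_map)))
    stop("class maps are on different grids")
  cur <- current$area; fut <- future$area
  undef <- cur$cells == 0
  chg <- ifelse(undef, NA_real_,
                100 * (fut$cells - cur$cells) / cur$cells)
  data.frame(class = cur$class, current_pct = cur$pct, future_pct = fut$pct,
             pct_change = chg, undefined = undef, stringsAsFactors = FALSE)
}

#' Kernel density comparison of surfaces across scenarios
#'
#' Gaussian-kernel density of the sea-cell values of each surface, evaluated
#' on a common lattice, with the percent change of the distribution mean
#' (and, when thresholds are supplied, of the mass in each vulnerability
#' class) relative to the first surface.
#'
#' @param surfaces named list of `vuln_surface` or `prob_surface` on one grid
#' @param bw bandwidth rule or value passed to [stats::density()]
#' @param n_eval evaluation lattice size
#' @param thresholds optional `c(q_low, q_high)` for class-mass summaries
#' @return list of class `kde_comparison`: `lattice`, `densities` (matrix,
#'   one column per scenario), `summary` data.frame
#' @export
kde_compare <- function(surfaces, bw = "nrd0", n_eval = 512,
                        thresholds = NULL) {
  if (length(surfaces) < 2) stop("need at least 2 surfaces to compare")
  if (is.null(names(surfaces)))
    names(surfaces) <- vapply(surfaces, function(s) s$scenario, "")
  vals <- lapply(surfaces, function(s) {
    v <- s$values[!is.na(s$values)]
    if (!length(v)) stop("empty surface")
    v
  })
  bws <- vapply(vals, function(v)
    if (is.character(bw)) stats::bw.nrd0(v) else bw, 0)
  lo <- min(unlist(vals)) - 3 * max(bws)
  hi <- max(unlist(vals)) + 3 * max(bws)
  dens <- sapply(seq_along(vals), function(i)
    stats::density(vals[[i]], bw = bws[i], from = lo, to = hi,
                   n = n_eval)$y)
  colnames(dens) <- names(surfaces)
  lattice <- seq(lo, hi, length.out = n_eval)
  means <- vapply(vals, mean, 0)
  summary <- data.frame(scenario = names(surfaces), mean = means,
                        mean_pct_change = 100 * (means - means[1]) /
                          means[1],
                        stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(thresholds)) {
    for (cl in c("low", "intermediate", "hotspot")) {
      mass <- vapply(vals, function(v) switch(cl,
        low = mean(v < thresholds[1]),
        intermediate = mean(v >= thresholds[1] & v < thresholds[2]),
        hotspot = mean(v >= thresholds[2])), 0)
      summary[[paste0(cl, "_mass")]] <- mass
      summary[[paste0(cl, "_mass_pct_change")]] <-
        ifelse(mass[1] > 0, 100 * (mass - mass[1]) / mass[1], NA_real_)
    }
  }
  structure(list(lattice = lattice, densities = dens, summary = summary),
            class = "kde_comparison")
}
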