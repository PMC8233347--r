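mk_surface <- function(grid, values, scenario = "current",
                       kind = "occurrence") {
  structure(list(grid = grid, scenario = scenario, response_kind = kind,
                 values = layer_from(grid, values),
                 sd = layer_from(grid, rep(0, length(values))),
                 extrapolated = layer_from(grid, rep(0, length(values)))),
            class = "prob_surface")
}

test_that("max-standardization divides by the sea-cell maximum and is
           scale-invariant", {
  g <- make_grid(c(0, 0.16, 0, 0.24), 0.08, list(type = "all_sea"))
  s <- mk_surface(g, c(0.2, 0.4, 0.8, 0.1, 0.3, 0.5))
  m <- max_standardize(s)
  expect_equal(sort(m$values[g$mask]), c(0.125, 0.25, 0.375, 0.5, 0.625, 1))
  expect_equal(max(m$values, na.rm = TRUE), 1)
  s2 <- s; s2$values <- s$values * 7.3
  expect_equal(max_standardize(s2)$values, m$values, tolerance = 1e-12)
  s0 <- s; s0$values[] <- 0
  expect_error(max_standardize(s0), "positive")
})

test_that("overlap is the cell-wise product with annihilation and
           monotonicity", {
  g <- make_grid(c(0, 0.16, 0, 0.16), 0.08, list(type = "all_sea"))
  one <- max_standardize(mk_surface(g, rep(1, 4)))
  half <- max_standardize(mk_surface(g, c(0.5, 0.5, 0.5, 1), kind = "cover"))
  zero <- max_standardize(mk_surface(g, c(0, 1, 0.5, 1), kind = "bleaching"))
  v <- overlap_surfaces(one, half, zero)
  expect_equal(v$values[g$mask], c(0, 0.5, 0.25, 1))
  # (1,1,1) -> 1 and zero annihilates
  expect_equal(v$values[g$mask][1], 0)
  expect_equal(v$values[g$mask][4], 1)
  # un-standardized input rejected
  raw <- mk_surface(g, c(0.2, 0.3, 0.1, 0.4))
  expect_error(overlap_surfaces(one, half, raw), "max-standardized")
  # monotone non-decreasing in each input
  half_up <- half; half_up$values <- pmin(half$values + 0.1, 1)
  half_up <- max_standardize(half_up)
  v2 <- overlap_surfaces(one, half_up, zero)
  expect_true(all(v2$values[g$mask] >= v$values[g$mask] - 1e-12))
})

test_that("quartile thresholds use the linear-interpolation convention with
           a verbatim fixed override", {
  g <- make_grid(c(0, 0.16, 0, 0.16), 0.08, list(type = "all_sea"))
  v <- structure(list(grid = g, scenario = "current",
                      values = layer_from(g, c(0.1, 0.2, 0.3, 0.4))),
                 class = "vuln_surface")
  thr <- quartile_thresholds(v)
  expect_equal(unname(thr), c(0.175, 0.325))
  const <- v; const$values <- layer_from(g, rep(0.4, 4))
  expect_equal(unname(quartile_thresholds(const)), c(0.4, 0.4))
  expect_equal(unname(quartile_thresholds(v, mode = "fixed")), c(0.21, 0.78))
})

test_that("classification respects the published bounds and counts areas", {
  g <- make_grid(c(0, 0.16, 0, 0.16), 0.08, list(type = "all_sea"))
  v <- structure(list(grid = g, scenario = "current",
                      values = layer_from(g, c(0.1, 0.3, 0.5, 0.9))),
                 class = "vuln_surface")
  cl <- classify_vulnerability(v, c(0.21, 0.78))
  expect_equal(cl$area$pct, c(25, 50, 25))
  expect_equal(sum(cl$area$pct), 100, tolerance = 1e-9)
  # 0.80 is a hotspot, 0.10 is low under the published thresholds
  expect_equal(cl$class_map[g$mask][c(1, 4)], c("low", "hotspot"))
  expect_error(classify_vulnerability(v, c(0.8, 0.2)), "inverted")
  # class percentages are invariant to cell ordering
  v2 <- v; v2$values <- layer_from(g, c(0.9, 0.5, 0.3, 0.1))
  expect_equal(classify_vulnerability(v2, c(0.21, 0.78))$area$pct,
               cl$area$pct)
})

test_that("class area change mirrors the halving construction and conserves
           total area", {
  g <- make_grid(c(0, 0.16, 0, 0.64), 0.08, list(type = "all_sea"))
  cur_vals <- c(rep(0.1, 4), rep(0.5, 10), rep(0.9, 2))
  fut_vals <- c(rep(0.1, 2), rep(0.5, 12), rep(0.9, 2))
  mk <- function(vals, sc) structure(
    list(grid = g, scenario = sc, values = layer_from(g, vals)),
    class = "vuln_surface")
  thr <- c(0.21, 0.78)
  cur <- classify_vulnerability(mk(cur_vals, "current"), thr)
  fut <- classify_vulnerability(mk(fut_vals, "end_century"), thr)
  chg <- class_area_change(cur, fut)
  expect_equal(chg$pct_change[chg$class == "low"], -50)
  expect_equal(sum(cur$area$cells), sum(fut$area$cells))
  # identical reports give 0% everywhere
  same <- class_area_change(cur, cur)
  expect_equal(same$pct_change, c(0, 0, 0))
  # zero current area flagged, not crashed
  cur0 <- classify_vulnerability(mk(rep(0.5, 16), "current"), thr)
  chg0 <- class_area_change(cur0, fut)
  expect_true(chg0$undefined[chg0$class == "low"])
  expect_true(is.na(chg0$pct_change[chg0$class == "low"]))
})

test_that("kernel densities integrate to one and shift with the surface", {
  g <- make_grid(c(0, 0.8, 0, 0.8), 0.08, list(type = "all_sea"))
  set.seed(5)
  vals <- runif(n_sea(g), 0.1, 0.6)
  mk <- function(v, sc) structure(
    list(grid = g, scenario = sc, values = layer_from(g, v)),
    class = "vuln_surface")
  cmp <- kde_compare(list(current = mk(vals, "current"),
                          future = mk(vals + 0.1, "future")))
  dx <- diff(cmp$lattice[1:2])
  for (j in 1:2)
    expect_lt(abs(sum(cmp$densities[, j]) * dx - 1), 1e-3)
  # identical surfaces: zero change
  cmp0 <- kde_compare(list(a = mk(vals, "a"), b = mk(vals, "b")))
  expect_equal(cmp0$summary$mean_pct_change, c(0, 0))
  # +0.1 shift moves the mode by one lattice step at most
  mode_at <- function(j) cmp$lattice[which.max(cmp$densities[, j])]
  expect_lt(abs((mode_at(2) - mode_at(1)) - 0.1), dx + 1e-9)
})
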