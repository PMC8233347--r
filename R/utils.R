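## internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv())
    else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a reproducible child seed from a parent seed and a stage label,
# kept well below 2^31.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1009 + h %% 100000) %% 2000000000)
}

#' Pairwise distances between coordinate rows
#'
#' Distances between points given as (lat, lon) pairs, either planar in
#' decimal degrees (default; adequate for narrow coastal domains) or
#' great-circle (haversine, km).
#'
#' @param a,b matrices with columns lat, lon (b defaults to a)
#' @param method "planar" (degrees) or "greatcircle" (km)
#' @return matrix of distances, nrow(a) x nrow(b)
#' @keywords internal
pairwise_dist <- function(a, b = a, method = c("planar", "greatcircle")) {
  method <- match.arg(method)
  a <- as.matrix(a); b <- as.matrix(b)
  if (method == "planar") {
    dlat <- outer(a[, 1], b[, 1], "-")
    dlon <- outer(a[, 2], b[, 2], "-")
    sqrt(dlat^2 + dlon^2)
  } else {
    rad <- pi / 180
    la1 <- a[, 1] * rad; lo1 <- a[, 2] * rad
    la2 <- b[, 1] * rad; lo2 <- b[, 2] * rad
    dlat <- outer(la1, la2, "-")
    dlon <- outer(lo1, lo2, "-")
    h <- sin(dlat / 2)^2 + outer(cos(la1), cos(la2)) * sin(dlon / 2)^2
    h[h > 1] <- 1
    2 * 6371 * asin(sqrt(h))
  }
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
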