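## Bayesian hierarchical spatial model fitting.
##
## Latent Gaussian formulation: eta = alpha + X beta + W(site), with
## Normal(0, prior_var) priors on the fixed effects and a zero-mean Matern
## Gaussian field W over the site cells. The field is whitened
## (W = sigma_w * t(chol(R)) %*% wtilde, wtilde ~ N(0, I)) so the joint
## latent vector u = (alpha, beta, wtilde) always has a diagonal prior
## precision. Inference: Newton mode-finding + Laplace approximation for the
## latents; Matern hyperparameters by MAP-II (marginal-likelihood
## optimisation under weak lognormal hyperpriors); for the lognormal
## observation variance, deterministic 1-D grid integration so sigma^2
## carries posterior uncertainty. Posterior draws are taken from the
## Gaussian (mixture) approximation.

log1pexp <- function(x) {
  out <- x
  lo <- x <= 35
  out[lo] <- log1p(exp(x[lo]))
  out
}

# build the latent design: list(M, P_diag, p, n_nodes, L_R)
build_design <- function(X, node_index, R_chol, sigma_w, prior_var) {
  n <- length(node_index)
  Mf <- cbind(`(Intercept)` = rep(1, n), X)
  if (is.null(R_chol)) {
    list(M = Mf, P_diag = rep(1 / prior_var, ncol(Mf)), p = ncol(X),
         n_nodes = 0L)
  } else {
    Lt <- t(R_chol)                       # n_nodes x n_nodes, lower
    Msp <- sigma_w * Lt[node_index, , drop = FALSE]
    list(M = cbind(Mf, Msp),
         P_diag = c(rep(1 / prior_var, ncol(Mf)), rep(1, ncol(Lt))),
         p = ncol(X), n_nodes = ncol(Lt))
  }
}

# Newton mode + Laplace evidence for Bernoulli-logit likelihood
laplace_bernoulli <- function(y, design, u0 = NULL, maxit = 60, tol = 1e-7) {
  M <- design$M; Pd <- design$P_diag
  m <- ncol(M)
  u <- if (is.null(u0) || length(u0) != m) numeric(m) else u0
  eta <- drop(M %*% u)
  obj <- function(u, eta) sum(y * eta - log1pexp(eta)) - 0.5 * sum(Pd * u^2)
  f <- obj(u, eta)
  converged <- FALSE
  LH <- NULL
  for (it in seq_len(maxit)) {
    p <- stats::plogis(eta)
    g <- drop(crossprod(M, y - p)) - Pd * u
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    d <- pmax(p * (1 - p), 1e-10)
    Mw <- M * sqrt(d)
    H <- crossprod(Mw)
    diag(H) <- diag(H) + Pd
    LH <- chol(H)
    step <- backsolve(LH, forwardsolve(t(LH), g))
    s <- 1
    repeat {
      u_new <- u + s * step
      eta_new <- drop(M %*% u_new)
      f_new <- obj(u_new, eta_new)
      if (f_new >= f - 1e-12 || s < 1e-4) break
      s <- s / 2
    }
    if (abs(f_new - f) < 1e-10 * (abs(f) + 1)) {
      u <- u_new; eta <- eta_new; f <- f_new; converged <- TRUE; break
    }
    u <- u_new; eta <- eta_new; f <- f_new
  }
  # Hessian at the mode
  p <- stats::plogis(eta)
  d <- pmax(p * (1 - p), 1e-10)
  Mw <- M * sqrt(d)
  H <- crossprod(Mw)
  diag(H) <- diag(H) + Pd
  LH <- chol(H)
  ll <- sum(y * eta - log1pexp(eta))
  logZ <- ll - 0.5 * sum(Pd * u^2) - sum(log(diag(LH))) +
    0.5 * sum(log(Pd))
  list(u = u, eta = eta, LH = LH, logZ = logZ, converged = converged)
}

# exact Gaussian posterior + evidence for Normal likelihood with variance s2
laplace_gaussian <- function(t, design, s2) {
  M <- design$M; Pd <- design$P_diag
  H <- crossprod(M) / s2
  diag(H) <- diag(H) + Pd
  LH <- chol(H)
  b <- drop(crossprod(M, t)) / s2
  u <- backsolve(LH, forwardsolve(t(LH), b))
  eta <- drop(M %*% u)
  ll <- sum(stats::dnorm(t, eta, sqrt(s2), log = TRUE))
  logZ <- ll - 0.5 * sum(Pd * u^2) - sum(log(diag(LH))) + 0.5 * sum(log(Pd))
  list(u = u, eta = eta, LH = LH, logZ = logZ, converged = TRUE)
}

# draws from N(u_hat, H^-1) given chol(H); returns m x S
draw_latents <- function(u, LH, S) {
  m <- length(u)
  z <- matrix(stats::rnorm(m * S), m, S)
  u + backsolve(LH, z)
}

# weak lognormal hyperpriors on (sigma_w, range, sigma_obs)
hyper_logprior <- function(lsw = NULL, lrg = NULL, lso = NULL, lrg0 = 0) {
  lp <- 0
  if (!is.null(lsw)) lp <- lp + stats::dnorm(lsw, 0, 1.5, log = TRUE)
  if (!is.null(lrg)) lp <- lp + stats::dnorm(lrg, lrg0, 1.0, log = TRUE)
  if (!is.null(lso)) lp <- lp + stats::dnorm(lso, 0, 1.5, log = TRUE)
  lp
}

# shared fitting core for both likelihoods
fit_latent_gaussian <- function(y, X, sites, likelihood = c("bernoulli",
                                                            "gaussian"),
                                spatial = TRUE, prior_var = 100,
                                n_draws = 800, seed = 1L,
                                hyper_method = c("optim", "grid"),
                                nu = 1, distance = "planar") {
  likelihood <- match.arg(likelihood)
  hyper_method <- match.arg(hyper_method)
  n <- length(y)

  # spatial nodes = distinct site cells (pooled records share a node)
  key <- paste(sites$lat_idx, sites$lon_idx)
  node_key <- unique(key)
  node_index <- match(key, node_key)
  first <- match(node_key, key)
  node_coords <- cbind(lat = sites$lat[first], lon = sites$lon[first])
  n_nodes <- nrow(node_coords)

  domain_diag <- if (n_nodes > 1)
    max(pairwise_dist(node_coords, method = distance)) else 1
  lrg0 <- log(max(0.3 * domain_diag, 1e-6))

  R_chol_for <- function(range) {
    R <- matern_correlation(pairwise_dist(node_coords, method = distance),
                            matern_params(1, range, nu))
    chol(R + diag(1e-8, n_nodes))
  }

  lik_fit <- function(design, s2, u0) {
    if (likelihood == "bernoulli") laplace_bernoulli(y, design, u0 = u0)
    else laplace_gaussian(y, design, s2)
  }

  warm <- new.env(parent = emptyenv()); warm$u <- NULL
  eval_theta <- function(lsw, lrg, lso) {
    sw <- exp(lsw %||% 0); rg <- exp(lrg %||% 0); s2 <- exp(2 * (lso %||% 0))
    R_chol <- if (spatial) R_chol_for(rg) else NULL
    design <- build_design(X, node_index, R_chol, sw, prior_var)
    res <- lik_fit(design, s2, warm$u)
    warm$u <- res$u
    list(lp = res$logZ + hyper_logprior(if (spatial) lsw, if (spatial) lrg,
                                        if (likelihood == "gaussian") lso,
                                        lrg0 = lrg0),
         res = res, design = design, R_chol = R_chol,
         sw = sw, rg = rg, s2 = s2)
  }

  # ---- hyperparameter MAP ----
  opt_ok <- TRUE
  init <- c(lsw = 0, lrg = lrg0,
            lso = if (likelihood == "gaussian")
              log(max(stats::sd(y) / sqrt(2), 1e-3)) else NA)
  if (spatial) {
    if (hyper_method == "grid") {
      lsws <- init["lsw"] + log(c(0.3, 1, 3))
      lrgs <- init["lrg"] + log(c(0.5, 1, 2))
      lsos <- if (likelihood == "gaussian")
        init["lso"] + log(c(0.5, 1, 2)) else NA
      best <- NULL
      for (a in lsws) for (b in lrgs) for (cc in lsos) {
        cand <- eval_theta(a, b, if (is.na(cc)) NULL else cc)
        cand$theta <- c(a, b, cc)
        if (is.null(best) || cand$lp > best$lp) best <- cand
      }
      theta_map <- best$theta
    } else {
      par0 <- if (likelihood == "gaussian")
        init[c("lsw", "lrg", "lso")] else init[c("lsw", "lrg")]
      negf <- function(th) {
        e <- tryCatch(
          eval_theta(th[1], th[2], if (length(th) > 2) th[3] else NULL),
          error = function(e) NULL)
        if (is.null(e) || !is.finite(e$lp)) 1e10 else -e$lp
      }
      o <- stats::optim(par0, negf, method = "Nelder-Mead",
                        control = list(maxit = 100, reltol = 1e-3))
      opt_ok <- o$convergence %in% c(0L, 1L)
      theta_map <- c(o$par, if (length(o$par) == 2) NA)
    }
  } else if (likelihood == "gaussian") {
    negf <- function(lso) -eval_theta(NULL, NULL, lso)$lp
    o <- stats::optimize(negf, init["lso"] + c(-4, 4))
    theta_map <- c(NA, NA, o$minimum)
  } else {
    theta_map <- c(NA, NA, NA)
  }

  map <- eval_theta(if (spatial) theta_map[1] else NULL,
                    if (spatial) theta_map[2] else NULL,
                    if (likelihood == "gaussian") theta_map[3] else NULL)

  p <- ncol(X)
  split_u <- function(u_draws, design, R_chol, sw) {
    alpha <- u_draws[1, ]
    beta <- if (p > 0) t(u_draws[2:(p + 1), , drop = FALSE]) else
      matrix(0, ncol(u_draws), 0)
    colnames(beta) <- colnames(X)
    W <- if (spatial)
      sw * crossprod(R_chol, u_draws[(p + 2):nrow(u_draws), , drop = FALSE])
    else matrix(0, n_nodes, ncol(u_draws))
    list(alpha = alpha, beta = beta, W = W,
         eta = design$M %*% u_draws)
  }

  draws <- local_seed(child_seed(seed, "draws"), {
    if (likelihood == "gaussian") {
      # grid integration over log sigma_obs around the MAP, with the grid
      # width matched to the local curvature of the log-evidence
      ev_at <- function(l) eval_theta(if (spatial) theta_map[1] else NULL,
                                      if (spatial) theta_map[2] else NULL, l)
      d <- 0.05
      curv <- -(ev_at(theta_map[3] + d)$lp - 2 * map$lp +
                  ev_at(theta_map[3] - d)$lp) / d^2
      sd_lso <- min(max(1 / sqrt(max(curv, 1e-4)), 1e-3), 1)
      lso_grid <- theta_map[3] + seq(-4, 4, length.out = 15) * sd_lso
      evals <- lapply(lso_grid, ev_at)
      lps <- vapply(evals, function(e) e$lp, 0)
      w <- exp(lps - max(lps)); w <- w / sum(w)
      alloc <- floor(w * n_draws)
      rem <- n_draws - sum(alloc)
      if (rem > 0) {
        extra <- order(w * n_draws - alloc, decreasing = TRUE)[seq_len(rem)]
        alloc[extra] <- alloc[extra] + 1L
      }
      parts <- list(); s2d <- numeric(0)
      for (gidx in which(alloc > 0)) {
        e <- evals[[gidx]]
        ud <- draw_latents(e$res$u, e$res$LH, alloc[gidx])
        parts[[length(parts) + 1]] <- split_u(ud, e$design, e$R_chol, e$sw)
        s2d <- c(s2d, rep(e$s2, alloc[gidx]))
      }
      out <- list(
        alpha = unlist(lapply(parts, `[[`, "alpha")),
        beta = do.call(rbind, lapply(parts, `[[`, "beta")),
        W = do.call(cbind, lapply(parts, `[[`, "W")),
        eta = do.call(cbind, lapply(parts, `[[`, "eta")),
        sigma2 = s2d)
      out
    } else {
      ud <- draw_latents(map$res$u, map$res$LH, n_draws)
      c(split_u(ud, map$design, map$R_chol, map$sw), list(sigma2 = NULL))
    }
  })

  qs <- function(x) c(mean = mean(x), sd = stats::sd(x),
                      q2.5 = unname(stats::quantile(x, 0.025)),
                      q97.5 = unname(stats::quantile(x, 0.975)))
  summ <- rbind(`(Intercept)` = qs(draws$alpha))
  if (p > 0)
    summ <- rbind(summ, t(apply(draws$beta, 2, qs)))
  if (!is.null(draws$sigma2))
    summ <- rbind(summ, sigma2 = qs(draws$sigma2))
  summaries <- data.frame(parameter = rownames(summ), summ,
                          row.names = NULL, stringsAsFactors = FALSE)

  structure(list(
    likelihood = likelihood, covariate_names = colnames(X),
    spatial = spatial, prior_var = prior_var, nu = nu, distance = distance,
    y = y, X = X, sites = sites,
    node_coords = node_coords, node_index = node_index,
    hypers = list(sigma_w = if (spatial) map$sw else 0,
                  range = if (spatial) map$rg else NA_real_,
                  nu = nu,
                  sigma2_map = if (likelihood == "gaussian") map$s2 else NULL),
    draws = draws, summaries = summaries,
    logZ = map$lp, converged = isTRUE(map$res$converged) && opt_ok,
    n_obs = n, n_draws = n_draws, seed = seed), class = "posterior_fit")
}

#' Fit the Bernoulli-logit occurrence model
#'
#' `Y_i ~ Bernoulli(pi_i)` with
#' `logit(pi_i) = alpha + X_i beta + W_i`, vague Normal(0, `prior_var`)
#' priors on the fixed effects (default variance 100) and, when
#' `spatial = TRUE`, a Matern Gaussian field W over the distinct site cells.
#'
#' @param obs an `obs_set` with both presences and absences
#' @param stack a `cov_stack` (standardized stacks recommended) providing
#'   the covariates
#' @param covariates character vector of covariate names (possibly empty)
#' @param spatial include the spatial random effect
#' @param prior_var prior variance of intercept and coefficients
#' @param n_draws posterior draws retained
#' @param seed integer seed for the posterior draws
#' @param hyper_method "optim" (Nelder-Mead MAP-II, default) or "grid"
#'   (coarse deterministic grid; faster, used inside model selection)
#' @param nu Matern smoothness
#' @param distance "planar" or "greatcircle"
#' @return a `posterior_fit`
#' @export
fit_occurrence <- function(obs, stack, covariates = character(),
                           spatial = TRUE, prior_var = 100, n_draws = 800,
                           seed = 1L, hyper_method = "optim", nu = 1,
                           distance = "planar") {
  y <- obs$y
  if (all(y == 0) || all(y == 1))
    stop("all responses are ", y[1],
         ": occurrence model is non-identifiable (separation)")
  X <- site_design(stack, obs, covariates)
  if (anyNA(X)) stop("missing covariate value at one or more sites")
  fit <- fit_latent_gaussian(y, X, obs, "bernoulli", spatial, prior_var,
                             n_draws, seed, hyper_method, nu, distance)
  fit$response_kind <- "occurrence"
  fit$scaling <- stack$scaling
  if (!fit$converged) warning("occurrence fit did not fully converge")
  fit
}

#' Fit the conditional lognormal cover/bleaching model
#'
#' For presence records only: `Z_i ~ Lognormal(mu_i, sigma^2)` on the
#' natural-log scale with `log(mu_i) = alpha + X_i beta + W_i`; fitted as a
#' Normal model on `log z`. The observation variance sigma^2 is integrated
#' over a deterministic likelihood grid so its posterior uncertainty is
#' carried into the draws.
#'
#' @param obs an `obs_set`; only rows with `y == 1` are used and at least 10
#'   are required, all with `z > 0`
#' @inheritParams fit_occurrence
#' @return a `posterior_fit` with `sigma2` draws and summaries
#' @export
fit_conditional_lognormal <- function(obs, stack, covariates = character(),
                                      spatial = TRUE, prior_var = 100,
                                      n_draws = 800, seed = 1L,
                                      hyper_method = "optim", nu = 1,
                                      distance = "planar") {
  sub <- obs[obs$y == 1, , drop = FALSE]
  if (nrow(sub) < 10)
    stop("need at least 10 conditional (presence) records, got ", nrow(sub))
  if (any(is.na(sub$z)) || any(sub$z <= 0))
    stop("all conditional z values must be positive")
  X <- site_design(stack, sub, covariates)
  if (anyNA(X)) stop("missing covariate value at one or more sites")
  fit <- fit_latent_gaussian(log(sub$z), X, sub, "gaussian", spatial,
                             prior_var, n_draws, seed, hyper_method, nu,
                             distance)
  fit$response_kind <- attr(obs, "response_kind") %||% "cover"
  fit$scaling <- stack$scaling
  fit$z <- sub$z
  if (!fit$converged) warning("conditional fit did not fully converge")
  fit
}

#' Fit the two-step hurdle model (occurrence x conditional abundance)
#'
#' The occurrence and conditional components are fitted independently (the
#' two-step construction): refitting one never changes the other. The
#' unconditional expected cover is `pi_i * exp(mu_i + sigma^2/2)`.
#'
#' @inheritParams fit_occurrence
#' @param covariates_occ,covariates_cond covariate names per component
#' @return object of class `hurdle_fit` with elements `occurrence` and
#'   `conditional`
#' @export
fit_hurdle <- function(obs, stack, covariates_occ = character(),
                       covariates_cond = covariates_occ, spatial = TRUE,
                       prior_var = 100, n_draws = 800, seed = 1L,
                       hyper_method = "optim", nu = 1, distance = "planar") {
  occ <- fit_occurrence(obs, stack, covariates_occ, spatial, prior_var,
                        n_draws, child_seed(seed, "occ"), hyper_method, nu,
                        distance)
  cond <- fit_conditional_lognormal(obs, stack, covariates_cond, spatial,
                                    prior_var, n_draws,
                                    child_seed(seed, "cond"), hyper_method,
                                    nu, distance)
  structure(list(occurrence = occ, conditional = cond,
                 response_kind = attr(obs, "response_kind") %||% "cover"),
            class = "hurdle_fit")
}

#' Unconditional hurdle mean
#'
#' Closed-form expectation of a hurdle (Bernoulli x lognormal) response:
#' `pi * exp(mu + sigma2 / 2)`.
#'
#' @param pi occurrence probability
#' @param mu lognormal log-scale mean
#' @param sigma2 lognormal log-scale variance
#' @export
hurdle_mean <- function(pi, mu, sigma2) pi * exp(mu + sigma2 / 2)

#' Pointwise log-likelihood matrix of a fit
#'
#' Log-likelihood of each observation under each retained posterior draw;
#' the n_obs x n_draws input to [waic()] and [lcpo()]. For conditional fits
#' the lognormal density of `z` (including the Jacobian) is used.
#'
#' @param fit a `posterior_fit`
#' @param obs optional `obs_set` to check alignment against the data stored
#'   in the fit (must contain the same records in the same order)
#' @return matrix n_obs x n_draws of finite log-densities
#' @export
pointwise_loglik <- function(fit, obs = NULL) {
  stopifnot(inherits(fit, "posterior_fit"))
  eta <- as.matrix(fit$draws$eta)
  if (!is.null(obs)) {
    ref <- if (fit$likelihood == "bernoulli") obs$y else obs$z[obs$y == 1]
    if (length(ref) != fit$n_obs)
      stop("observation set is misaligned with the fit (",
           length(ref), " vs ", fit$n_obs, " records)")
    if (fit$likelihood == "bernoulli" && any(ref != fit$y))
      stop("observation set is misaligned with the fit (responses differ)")
  }
  if (fit$likelihood == "bernoulli") {
    y <- fit$y
    ll <- -log1pexp(ifelse(y == 1, -1, 1) * eta)
  } else {
    sd_s <- sqrt(fit$draws$sigma2)
    t <- fit$y                    # log z
    ll <- stats::dnorm(t, eta, rep(sd_s, each = nrow(eta)), log = TRUE) -
      t                           # lognormal Jacobian: -log z
  }
  if (!all(is.finite(ll))) stop("non-finite pointwise log-likelihoods")
  ll
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("posterior_fit [%s, %s]: n = %d, draws = %d%s\n",
              x$response_kind %||% x$likelihood, x$likelihood, x$n_obs,
              length(x$draws$alpha),
              if (x$spatial) sprintf(", Matern(sigma=%.2f, range=%.2f)",
                                     x$hypers$sigma_w, x$hypers$range)
              else ", no spatial effect"))
  print(x$summaries, digits = 3)
  invisible(x)
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat("hurdle_fit:", x$response_kind, "\n-- occurrence component --\n")
  print(x$occurrence)
  cat("-- conditional component --\n")
  print(x$conditional)
  invisible(x)
}
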