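## Model comparison and forward covariate selection by WAIC and LCPO.

#' Watanabe-Akaike information criterion from a pointwise log-likelihood
#' matrix
#'
#' `elpd_i = log mean_d exp(ll_id)`, `p_waic_i = var_d(ll_id)`,
#' `waic = -2 sum_i (elpd_i - p_waic_i)`. Lower is better.
#'
#' @param ll matrix n_obs x n_draws of pointwise log-likelihoods
#' @return list with `waic`, `p_waic`, `elpd`
#' @export
waic <- function(ll) {
  ll <- as.matrix(ll)
  S <- ncol(ll)
  if (S < 2) stop("need at least 2 posterior draws (variance undefined)")
  lpd <- apply(ll, 1, log_sum_exp) - log(S)
  p <- apply(ll, 1, stats::var)
  list(waic = -2 * sum(lpd - p), p_waic = sum(p), elpd = sum(lpd - p))
}

#' Mean logarithmic score of the conditional predictive ordinate (LCPO)
#'
#' `CPO_i` is the harmonic mean over draws of the likelihood of observation
#' i (the importance-sampling estimate of its leave-one-out predictive
#' density); `LCPO = -(1/n) sum_i log CPO_i`. Values closer to 0 indicate
#' better predictive quality; for discrete likelihoods LCPO >= 0.
#'
#' @param ll matrix n_obs x n_draws of pointwise log-likelihoods
#' @return list with `lcpo`, per-observation `log_cpo`, and `n_unstable`
#'   (observations whose CPO estimate was non-finite, flagged not dropped)
#' @export
lcpo <- function(ll) {
  ll <- as.matrix(ll)
  S <- ncol(ll)
  if (S < 2) stop("need at least 2 posterior draws")
  log_cpo <- -(apply(-ll, 1, log_sum_exp) - log(S))
  bad <- !is.finite(log_cpo)
  list(lcpo = -mean(log_cpo[!bad]), log_cpo = log_cpo,
       n_unstable = sum(bad))
}

# fit one candidate spec and score it
fit_and_score <- function(obs, stack, covs, spatial, response_kind,
                          inference) {
  fitter <- if (response_kind == "occurrence") fit_occurrence else
    fit_conditional_lognormal
  fit <- fitter(obs, stack, covariates = covs, spatial = spatial,
                prior_var = inference$prior_var %||% 100,
                n_draws = inference$n_draws %||% 400,
                seed = inference$seed %||% 1L,
                hyper_method = inference$hyper_method %||% "grid",
                nu = inference$nu %||% 1,
                distance = inference$distance %||% "planar")
  ll <- pointwise_loglik(fit)
  w <- waic(ll); l <- lcpo(ll)
  list(fit = fit, waic = w$waic, p_waic = w$p_waic, lcpo = l$lcpo)
}

# rank-sum winner among scored specs; ties broken by WAIC
combined_best <- function(waics, lcpos) {
  rs <- rank(waics, ties.method = "average") +
    rank(lcpos, ties.method = "average")
  cands <- which(rs == min(rs))
  cands[which.min(waics[cands])]
}

#' Forward covariate selection by WAIC and LCPO
#'
#' Starts from the null model (intercept only, no spatial effect) and
#' greedily adds, one at a time, the candidate covariate that most improves
#' the combined criterion (sum of within-comparison ranks of WAIC and LCPO;
#' ties broken by WAIC); after no covariate improves, the spatial effect is
#' offered as a final addition (default order; `spatial = "never"` disables
#' it). Stops when no addition improves. An exhaustive mode evaluating all
#' covariate subsets (x spatial on/off) is available for up to 5 candidates.
#'
#' @param obs an `obs_set`
#' @param stack a `cov_stack`
#' @param candidates character vector of candidate covariates (typically the
#'   screening-retained set); empty is allowed and returns the null model
#' @param response_kind "occurrence", "cover" or "bleaching" (defaults to
#'   the observation set's kind); conditional kinds are fitted on the
#'   presence subset
#' @param inference list of inference options passed to the fitters:
#'   `n_draws` (default 400), `seed`, `hyper_method` (default "grid"),
#'   `prior_var`, `nu`, `distance`
#' @param spatial "last" (default: offered after covariate search) or
#'   "never"
#' @param exhaustive evaluate every subset instead of greedy search
#'   (requires <= 5 candidates)
#' @return object of class `selection_trace`: `steps` data.frame (one row
#'   per evaluated spec: covariates, spatial, waic, p_waic, lcpo, accepted),
#'   `best` (list with `covariates`, `spatial`), `best_fit`
#' @export
forward_select <- function(obs, stack, candidates,
                           response_kind = attr(obs, "response_kind"),
                           inference = list(), spatial = c("last", "never"),
                           exhaustive = FALSE) {
  spatial <- match.arg(spatial)
  response_kind <- response_kind %||% "occurrence"
  candidates <- unique(candidates)
  steps <- data.frame(step = integer(), covariates = character(),
                      spatial = logical(), waic = numeric(),
                      p_waic = numeric(), lcpo = numeric(),
                      accepted = logical(), stringsAsFactors = FALSE)
  scored <- list()
  score <- function(covs, sp, step) {
    key <- paste(paste(sort(covs), collapse = "+"), sp)
    if (is.null(scored[[key]])) {
      inf2 <- inference
      inf2$seed <- child_seed(inference$seed %||% 1L, key)
      scored[[key]] <<- fit_and_score(obs, stack, covs, sp, response_kind,
                                      inf2)
    }
    s <- scored[[key]]
    steps <<- rbind(steps, data.frame(
      step = step, covariates = paste(sort(covs), collapse = "+"),
      spatial = sp, waic = s$waic, p_waic = s$p_waic, lcpo = s$lcpo,
      accepted = FALSE, stringsAsFactors = FALSE))
    s
  }

  if (exhaustive) {
    if (length(candidates) > 5)
      stop("exhaustive mode supports at most 5 candidates")
    subsets <- unlist(lapply(0:length(candidates), function(k)
      utils::combn(candidates, k, simplify = FALSE)), recursive = FALSE)
    specs <- list()
    for (ss in subsets) {
      specs[[length(specs) + 1]] <- list(covs = ss, sp = FALSE)
      if (spatial == "last")
        specs[[length(specs) + 1]] <- list(covs = ss, sp = TRUE)
    }
    for (i in seq_along(specs))
      score(specs[[i]]$covs, specs[[i]]$sp, step = i)
    b <- combined_best(steps$waic, steps$lcpo)
  } else if (length(candidates) == 0) {
    score(character(), FALSE, 0L)
    b <- 1L
  } else {
    incumbent <- list(covs = character(), sp = FALSE)
    step <- 0L
    s0 <- score(incumbent$covs, incumbent$sp, step)
    inc_row <- nrow(steps)
    remaining <- candidates
    repeat {
      step <- step + 1L
      trial_rows <- integer()
      for (cv in remaining) {
        score(c(incumbent$covs, cv), incumbent$sp, step)
        trial_rows <- c(trial_rows, nrow(steps))
      }
      if (spatial == "last" && !incumbent$sp && length(remaining) == 0) {
        score(incumbent$covs, TRUE, step)
        trial_rows <- c(trial_rows, nrow(steps))
      }
      if (!length(trial_rows)) break
      cmp <- c(inc_row, trial_rows)
      b_local <- cmp[combined_best(steps$waic[cmp], steps$lcpo[cmp])]
      if (b_local == inc_row) {
        # no covariate improves; offer the spatial effect if not yet tried
        if (spatial == "last" && !incumbent$sp && length(remaining) > 0) {
          remaining <- character()
          next
        }
        break
      }
      inc_row <- b_local
      added <- setdiff(
        strsplit(steps$covariates[b_local], "+", fixed = TRUE)[[1]],
        incumbent$covs)
      if (steps$spatial[b_local] && !incumbent$sp) {
        incumbent$sp <- TRUE
      } else {
        incumbent$covs <- c(incumbent$covs, added)
        remaining <- setdiff(remaining, added)
      }
      if (!length(remaining) && (incumbent$sp || spatial == "never")) break
    }
    b <- inc_row
  }
  steps$accepted[b] <- TRUE
  best_covs <- strsplit(steps$covariates[b], "+", fixed = TRUE)[[1]]
  best_covs <- best_covs[nzchar(best_covs)]
  best_key <- paste(paste(sort(best_covs), collapse = "+"), steps$spatial[b])
  structure(list(steps = steps,
                 best = list(covariates = best_covs,
                             spatial = steps$spatial[b]),
                 best_fit = scored[[best_key]]$fit),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("selection_trace:", nrow(x$steps), "specs evaluated; best = {",
      paste(x$best$covariates, collapse = ", "), "}",
      if (x$best$spatial) "+ spatial" else "", "\n")
  print(x$steps, digits = 4)
  invisible(x)
}
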