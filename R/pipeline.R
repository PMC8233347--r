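## End-to-end pipeline: simulate -> screen -> select -> fit -> project ->
## vulnerability -> report, from a single structured config.

pipeline_keys <- c("seed", "grid", "covariates", "truth", "observations",
                   "screening", "models", "scenarios", "classification")

#' Default pipeline configuration
#'
#' A compact coastal-strip setup: 20 x 20 grid at 0.08 degrees, 150 sites
#' per response, SST-driven truth on the standardized covariate scale, the
#' two RCP8.5 scenario shifts, and automatic quartile classification.
#'
#' @return nested named list accepted by [run_pipeline()]
#' @export
default_config <- function() {
  list(
    seed = 1L,
    grid = list(extent = c(-10.0, -8.4, -36.0, -34.4), resolution = 0.08,
                coastline = list(type = "band")),
    covariates = list(),
    truth = list(
      occurrence = list(alpha_occ = 0.5, beta_occ = list(SST = 1.2),
                        alpha_cond = 2.0, beta_cond = list(SST = 0.5),
                        sigma2_cond = 0.3,
                        matern_occ = list(sigma = 0.8, range = 0.4, nu = 1),
                        matern_cond = list(sigma = 0.5, range = 0.4, nu = 1)),
      cover = list(alpha_occ = 0.8, beta_occ = list(SST = 1.0),
                   alpha_cond = 2.5, beta_cond = list(SST = 0.6),
                   sigma2_cond = 0.3,
                   matern_occ = list(sigma = 0.8, range = 0.4, nu = 1),
                   matern_cond = list(sigma = 0.5, range = 0.4, nu = 1)),
      bleaching = list(alpha_occ = -0.5, beta_occ = list(SST = 1.5),
                       alpha_cond = 2.0, beta_cond = list(SST = 0.8),
                       sigma2_cond = 0.4,
                       matern_occ = list(sigma = 0.8, range = 0.4, nu = 1),
                       matern_cond = list(sigma = 0.5, range = 0.4, nu = 1))),
    observations = list(n_sites = 150L, records_per_site = 1L),
    screening = list(gvif_threshold = 3, corr_threshold = 0.70),
    models = list(candidates = "retained", max_candidates = 4L,
                  n_draws = 600L, selection_draws = 300L,
                  hyper_method = "grid", spatial = "last"),
    scenarios = list(mid_century = list(SST = 1, SSS = 1),
                     end_century = list(SST = 3, SSS = 1.5)),
    classification = list(mode = "auto", fixed = c(0.21, 0.78))
  )
}

#' Read and validate a pipeline config
#'
#' @param path YAML file
#' @return validated config list
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config a config list
#' @export
validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a named list")
  unknown <- setdiff(names(config), pipeline_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$seed))
    stop("config key `seed` is required")
  base <- default_config()
  merged <- utils::modifyList(base, config)
  if (!is.numeric(merged$seed)) stop("`seed` must be an integer")
  for (k in c("occurrence", "cover", "bleaching"))
    if (is.null(merged$truth[[k]]))
      stop("config key `truth$", k, "` is required")
  merged$seed <- as.integer(merged$seed)
  merged
}

truth_from_config <- function(tr) {
  model_truth(
    alpha_occ = tr$alpha_occ, beta_occ = unlist(tr$beta_occ),
    alpha_cond = tr$alpha_cond, beta_cond = unlist(tr$beta_cond),
    sigma2_cond = tr$sigma2_cond,
    matern_occ = matern_params(tr$matern_occ$sigma, tr$matern_occ$range,
                               tr$matern_occ$nu %||% 1),
    matern_cond = matern_params(tr$matern_cond$sigma, tr$matern_cond$range,
                                tr$matern_cond$nu %||% 1))
}

#' Run the full vulnerability pipeline from a config
#'
#' Simulates grid, covariate stacks and observations, screens covariates,
#' selects and fits the occurrence, cover and bleaching models, projects
#' them under the current and two future scenarios, builds the
#' vulnerability surfaces, classifies them against the current-scenario
#' thresholds, and writes every artifact (plus a checksum manifest) under
#' `out_dir`. Rerunning with an identical config and seed reproduces
#' bit-identical numerical outputs.
#'
#' @param config a config list (see [default_config()]) or path to a YAML
#'   file
#' @param out_dir output directory (created; stages write into
#'   covariates/, screening/, fits/, selection/, surfaces/, vulnerability/,
#'   logs/)
#' @param quiet suppress progress messages
#' @return invisibly, a list with the in-memory artifacts (grid, stacks,
#'   screening, traces, fits, surfaces, vulnerability, manifest path)
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  seed <- config$seed
  dirs <- file.path(out_dir, c("covariates", "screening", "fits",
                               "selection", "surfaces", "vulnerability",
                               "logs"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  notes <- list()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(log_lines, file.path(out_dir, "logs", "pipeline.log"))
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## -- simulate ----------------------------------------------------------
  sim <- stage("simulate", {
    grid <- make_grid(config$grid$extent, config$grid$resolution %||% 0.08,
                      config$grid$coastline %||% list(type = "band"),
                      seed = seed)
    raw <- simulate_covariates(grid, seed = child_seed(seed, "covariates"),
                               spec = config$covariates %||% list())
    std <- standardize_stack(raw)
    futures_raw <- lapply(names(config$scenarios), function(sc)
      make_future_covariates(raw, sc,
                             deltas = unlist(config$scenarios[[sc]])))
    names(futures_raw) <- names(config$scenarios)
    futures <- lapply(futures_raw, standardize_stack, scaling = std$scaling)
    obs <- list()
    for (rk in c("occurrence", "cover", "bleaching")) {
      truth <- truth_from_config(config$truth[[rk]])
      obs[[rk]] <- withCallingHandlers(
        simulate_observations(grid, std, truth,
                              n_sites = config$observations$n_sites,
                              seed = child_seed(seed, paste0("obs_", rk)),
                              response_kind = rk,
                              records_per_site =
                                config$observations$records_per_site %||% 1L),
        warning = function(w) {
          notes[[paste0("capped_", rk)]] <<- conditionMessage(w)
          invokeRestart("muffleWarning")
        })
    }
    say("simulate: grid %dx%d (%d sea cells), %d sites per response",
        grid$n_lat, grid$n_lon, n_sea(grid), config$observations$n_sites)
    write_stack_csv(raw, file.path(out_dir, "covariates",
                                   "stack_current.csv"))
    for (nm in names(futures_raw))
      write_stack_csv(futures_raw[[nm]],
                      file.path(out_dir, "covariates",
                                paste0("stack_", nm, ".csv")))
    for (rk in names(obs))
      write_observations(obs[[rk]], file.path(out_dir, "covariates",
                                              paste0("obs_", rk, ".csv")))
    list(grid = grid, std = std, futures = futures, obs = obs)
  })

  ## -- screen ------------------------------------------------------------
  screening <- stage("screen", {
    rep <- screen_covariates(sim$std, sim$obs$occurrence,
                             gvif_threshold =
                               config$screening$gvif_threshold %||% 3,
                             corr_threshold =
                               config$screening$corr_threshold %||% 0.70)
    say("screen: retained {%s}", paste(rep$retained, collapse = ", "))
    utils::write.csv(rep$gvif_table,
                     file.path(out_dir, "screening", "gvif.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(rep$correlation_matrix),
                     file.path(out_dir, "screening", "correlation.csv"))
    audit <- utils::capture.output(print(rep))
    writeLines(audit, file.path(out_dir, "screening", "audit.txt"))
    rep
  })

  ## -- select + fit ------------------------------------------------------
  models <- stage("select_fit", {
    cands <- screening$retained
    if (!identical(config$models$candidates, "retained"))
      cands <- intersect(unlist(config$models$candidates), cands)
    cands <- utils::head(cands, config$models$max_candidates %||% 4L)
    out <- list()
    for (rk in c("occurrence", "cover", "bleaching")) {
      inf <- list(n_draws = config$models$selection_draws %||% 300L,
                  seed = child_seed(seed, paste0("select_", rk)),
                  hyper_method = config$models$hyper_method %||% "grid")
      trace <- forward_select(sim$obs[[rk]], sim$std, cands,
                              response_kind = rk, inference = inf,
                              spatial = config$models$spatial %||% "last")
      best <- trace$best
      fit_seed <- child_seed(seed, paste0("fit_", rk))
      nd <- config$models$n_draws %||% 600L
      hm <- config$models$hyper_method %||% "grid"
      fit <- if (rk == "occurrence") {
        fit_occurrence(sim$obs[[rk]], sim$std, best$covariates,
                       spatial = best$spatial, n_draws = nd,
                       seed = fit_seed, hyper_method = hm)
      } else {
        fit_hurdle(sim$obs[[rk]], sim$std, best$covariates, best$covariates,
                   spatial = best$spatial, n_draws = nd, seed = fit_seed,
                   hyper_method = hm)
      }
      conv <- if (inherits(fit, "hurdle_fit"))
        fit$occurrence$converged && fit$conditional$converged
      else fit$converged
      notes[[paste0("converged_", rk)]] <- conv
      say("select_fit [%s]: best {%s}%s", rk,
          paste(best$covariates, collapse = ", "),
          if (best$spatial) " + spatial" else "")
      utils::write.csv(trace$steps,
                       file.path(out_dir, "selection",
                                 paste0("trace_", rk, ".csv")),
                       row.names = FALSE)
      summ <- if (inherits(fit, "hurdle_fit"))
        rbind(cbind(component = "occurrence", fit$occurrence$summaries),
              cbind(component = "conditional", fit$conditional$summaries))
      else cbind(component = "occurrence", fit$summaries)
      utils::write.csv(summ, file.path(out_dir, "fits",
                                       paste0("summary_", rk, ".csv")),
                       row.names = FALSE)
      out[[rk]] <- list(trace = trace, fit = fit)
    }
    out
  })

  ## -- predict -----------------------------------------------------------
  surfaces <- stage("predict", {
    out <- list()
    for (rk in c("occurrence", "cover", "bleaching")) {
      fit <- models[[rk]]$fit
      # the bleaching vulnerability input is the probability that bleaching
      # occurs: use the occurrence component of its hurdle
      f <- if (rk == "bleaching" && inherits(fit, "hurdle_fit"))
        fit$occurrence else fit
      surfs <- predict_scenarios(f, sim$std, sim$futures)
      for (sc in names(surfs)) {
        surfs[[sc]]$response_kind <- rk
        write_surface(surfs[[sc]],
                      file.path(out_dir, "surfaces",
                                paste0(rk, "_", sc, ".csv")))
        nex <- sum(surfs[[sc]]$extrapolated, na.rm = TRUE)
        if (nex > 0)
          notes[[paste0("extrapolated_", rk, "_", sc)]] <- nex
      }
      for (sc in setdiff(names(surfs), "current")) {
        d <- delta_map(surfs[[sc]], surfs$current)
        write_surface(d, file.path(out_dir, "surfaces",
                                   paste0(rk, "_delta_", sc, ".csv")))
      }
      out[[rk]] <- surfs
      say("predict [%s]: %d scenarios", rk, length(surfs))
    }
    out
  })

  ## -- vulnerability -----------------------------------------------------
  vulnerability <- stage("vulnerability", {
    scen <- names(surfaces$occurrence)
    vulns <- lapply(scen, function(sc)
      overlap_surfaces(max_standardize(surfaces$occurrence[[sc]]),
                       max_standardize(surfaces$cover[[sc]]),
                       max_standardize(surfaces$bleaching[[sc]])))
    names(vulns) <- scen
    thr <- quartile_thresholds(vulns$current,
                               mode = config$classification$mode %||% "auto",
                               fixed = unlist(config$classification$fixed %||%
                                                c(0.21, 0.78)))
    classes <- lapply(vulns, classify_vulnerability, thresholds = thr)
    changes <- lapply(setdiff(scen, "current"), function(sc)
      class_area_change(classes$current, classes[[sc]]))
    names(changes) <- setdiff(scen, "current")
    kde <- kde_compare(vulns, thresholds = thr)
    say("vulnerability: thresholds (%.3f, %.3f); current areas %s",
        thr[1], thr[2],
        paste(sprintf("%s %.1f%%", classes$current$area$class,
                      classes$current$area$pct), collapse = ", "))
    for (sc in scen)
      write_surface(vulns[[sc]],
                    file.path(out_dir, "vulnerability",
                              paste0("vulnerability_", sc, ".csv")))
    area <- do.call(rbind, lapply(scen, function(sc)
      cbind(scenario = sc, classes[[sc]]$area)))
    utils::write.csv(area, file.path(out_dir, "vulnerability",
                                     "area_report.csv"), row.names = FALSE)
    chg <- do.call(rbind, lapply(names(changes), function(sc)
      cbind(scenario = sc, changes[[sc]])))
    utils::write.csv(chg, file.path(out_dir, "vulnerability",
                                    "area_change.csv"), row.names = FALSE)
    utils::write.csv(kde$summary, file.path(out_dir, "vulnerability",
                                            "kde_summary.csv"),
                     row.names = FALSE)
    list(surfaces = vulns, thresholds = thr, classes = classes,
         changes = changes, kde = kde)
  })

  ## -- manifest ----------------------------------------------------------
  manifest_path <- stage("manifest", {
    cfg_path <- file.path(out_dir, "logs", "config.yaml")
    yaml::write_yaml(config, cfg_path)
    writeLines(log_lines, file.path(out_dir, "logs", "pipeline.log"))
    files <- sort(setdiff(
      list.files(out_dir, recursive = TRUE),
      file.path("logs", "manifest.yaml")))
    sums <- tools::md5sum(file.path(out_dir, files))
    manifest <- list(
      package_version = as.character(utils::packageVersion("reefvuln")),
      seed = seed,
      config_md5 = unname(tools::md5sum(cfg_path)),
      warnings = notes,
      files = stats::setNames(as.list(unname(sums)), files))
    mp <- file.path(out_dir, "logs", "manifest.yaml")
    yaml::write_yaml(manifest, mp)
    mp
  })

  invisible(list(grid = sim$grid, stack = sim$std, futures = sim$futures,
                 observations = sim$obs, screening = screening,
                 models = models, surfaces = surfaces,
                 vulnerability = vulnerability, manifest = manifest_path))
}
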