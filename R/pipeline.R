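#' Pipeline configuration
#'
#' Bundles every stage's configuration under a single master seed. Stage
#' seeds are derived with [child_seed()] so each stage is reproducible in
#' isolation.
#'
#' @param sim a [simulation_config()].
#' @param fatigue a [fatigue_model()].
#' @param criteria a [selection_criteria()].
#' @param bootstrap_grid data.frame with columns `n_resamples`,
#'   `noise_fraction`, `include_demographics` defining the validation grid;
#'   defaults to the 100/300-sample x 10\%/30\%-noise grid with and without
#'   demographics.
#' @param n_bootstrap_repeats Monte-Carlo repeats per grid cell.
#' @param target_name dependent variable (default the composite index).
#' @param write_sessions write per-session signal bundles to disk (large;
#'   default FALSE keeps only derived tables).
#' @param make_figures emit correlation-heatmap and dendrogram figures.
#' @param master_seed integer master seed (overrides `sim$master_seed`).
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            fatigue = fatigue_model(),
                            criteria = selection_criteria(),
                            bootstrap_grid = default_bootstrap_grid(),
                            n_bootstrap_repeats = 200,
                            target_name = "total_performance",
                            write_sessions = FALSE,
                            make_figures = FALSE,
                            master_seed = sim$master_seed) {
  sim$master_seed <- as.integer(master_seed)
  structure(list(sim = sim, fatigue = fatigue, criteria = criteria,
                 bootstrap_grid = bootstrap_grid,
                 n_bootstrap_repeats = n_bootstrap_repeats,
                 target_name = target_name,
                 write_sessions = write_sessions,
                 make_figures = make_figures,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Default bootstrap validation grid
#'
#' Original-size fit plus 100- and 300-sample bootstraps at 10\% and 30\%
#' proportional Gaussian noise, each with and without sex/age covariates.
#'
#' @return data.frame with columns `n_resamples`, `noise_fraction`,
#'   `include_demographics`.
#' @export
default_bootstrap_grid <- function() {
  base <- expand.grid(n_resamples = c(100L, 300L),
                      noise_fraction = c(0.10, 0.30),
                      include_demographics = c(FALSE, TRUE))
  rbind(data.frame(n_resamples = NA_integer_, noise_fraction = 0,
                   include_demographics = c(FALSE, TRUE)),
        base)
}

log_stage <- function(log, stage, ...) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage, sprintf(...))
  message(line)
  c(log, line)
}

#' Run the full simulate-extract-metrics-model-validate pipeline
#'
#' Generates a cohort with muscle parameters, synthesizes all six sessions
#' per participant, extracts the 27 performance metrics, screens and fits
#' regression models for the composite strength target (full survivor set
#' and squat-only ablation), and runs the bootstrap-with-noise validation
#' grid. All tabular outputs are written as CSV under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list (class `"pipeline_bundle"`): `cohort`,
#'   `metrics`, `selection`, `models`, `bootstrap`, `standardizer`, `log`,
#'   `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = "results") {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  sim <- config$sim

  # stage 1: cohort + muscle parameters + composite target
  log <- log_stage(log, "cohort", "n = %d, seed = %d", sim$n_participants,
                   child_seed(sim$master_seed, "cohort"))
  cohort <- generate_muscle_parameters(generate_cohort(sim), sim)
  cohort <- weight_normalize(cohort)
  std <- fit_standardizer(cohort)
  cohort$total_performance <- total_performance(cohort, std)
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  write_standardizer(std, file.path(out_dir, "standardizer.csv"))

  # stage 2 + 3: sessions and metric extraction
  log <- log_stage(log, "sessions", "generating %d x 6 sessions",
                   sim$n_participants)
  protocols <- all_protocols()
  sessions <- list()
  for (i in seq_len(nrow(cohort))) {
    prof <- cohort[i, ]
    sessions[[prof$id]] <- lapply(protocols, function(pr)
      generate_session(prof, pr, config$fatigue, sim))
    if (config$write_sessions) {
      sdir <- file.path(out_dir, "sessions")
      dir.create(sdir, showWarnings = FALSE)
      for (s in sessions[[prof$id]])
        write_session(s, file.path(sdir, sprintf("%s_%s_%s.csv", prof$id,
                                                 s$protocol$exercise,
                                                 s$protocol$condition)))
    }
  }
  metrics <- build_metric_table(sessions, mains_freq = sim$mains_freq)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  log <- log_stage(log, "metrics", "%d rows x %d metric columns",
                   nrow(metrics), ncol(metrics) - 1L)

  # stage 4: screening + models
  tab <- merge(metrics, cohort[, c("id", "sex", "age",
                                   "vj", "rm_le_lc_weight",
                                   "iso_le_lc_weight",
                                   config$target_name)], by = "id")
  sel <- select_variables(tab, config$target_name, config$criteria,
                          candidates = intersect(metric_names(), names(tab)))
  utils::write.csv(sel$audit, file.path(out_dir, "selection_audit.csv"),
                   row.names = FALSE)
  log <- log_stage(log, "selection", "%d predictors retained: %s",
                   length(sel$selected),
                   paste(sel$selected, collapse = ", "))
  models <- list()
  fit_or_log <- function(name, predictors) {
    if (!length(predictors)) {
      log <<- log_stage(log, "model", "%s: no admissible predictors", name)
      return(NULL)
    }
    m <- tryCatch(fit_ols(tab, config$target_name, predictors),
                  error = function(e) {
                    log <<- log_stage(log, "model", "%s: %s", name,
                                      conditionMessage(e))
                    NULL
                  })
    if (!is.null(m))
      log <<- log_stage(log, "model", "%s: R = %.3f, adj R2 = %.3f", name,
                        m$r, m$adj_r2)
    m
  }
  models$all_metrics <- fit_or_log("all_metrics", sel$selected)
  squat_sel <- grep("^Squat_IS_Max$", sel$selected, value = TRUE)
  if (!length(squat_sel)) squat_sel <- "Squat_IS_Max"
  models$squat_only <- fit_or_log("squat_only", squat_sel)
  models <- Filter(Negate(is.null), models)
  if (length(models)) {
    coefs <- do.call(rbind, lapply(names(models), function(nm)
      cbind(model = nm, models[[nm]]$coefficients)))
    utils::write.csv(coefs, file.path(out_dir, "model_coefficients.csv"),
                     row.names = FALSE)
    summ <- lapply(models, function(m)
      m[c("r", "r2", "adj_r2", "f2", "power", "p_overall", "n",
          "predictors")])
    jsonlite::write_json(summ, file.path(out_dir, "model_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  # stage 5: bootstrap validation grid
  boot <- NULL
  if (length(models)) {
    grid <- config$bootstrap_grid
    rows <- list()
    for (nm in names(models)) {
      for (g in seq_len(nrow(grid))) {
        spec <- bootstrap_spec(
          n_resamples = grid$n_resamples[g],
          noise_fraction = grid$noise_fraction[g],
          n_repeats = config$n_bootstrap_repeats,
          include_demographics = grid$include_demographics[g],
          resample = !is.na(grid$n_resamples[g]) ||
            grid$noise_fraction[g] > 0,
          seed = child_seed(config$master_seed,
                            sprintf("boot_%s_%d", nm, g)))
        bv <- bootstrap_validate(tab, models[[nm]]$predictors, spec, std)
        rows[[length(rows) + 1L]] <- data.frame(
          model = nm, n_resamples = grid$n_resamples[g],
          noise_fraction = grid$noise_fraction[g],
          demographics = grid$include_demographics[g],
          mean_r = bv$mean_r, sd_r = bv$sd_r,
          mean_adj_r2 = bv$mean_adj_r2, sd_adj_r2 = bv$sd_adj_r2)
      }
    }
    boot <- do.call(rbind, rows)
    utils::write.csv(boot, file.path(out_dir, "bootstrap.csv"),
                     row.names = FALSE)
    log <- log_stage(log, "validate", "%d grid cells x %d repeats",
                     nrow(boot), config$n_bootstrap_repeats)
  }

  # optional figures
  if (config$make_figures) {
    r <- correlation_matrix(tab[intersect(metric_names(), names(tab))])
    ok <- rowSums(is.na(r)) < nrow(r) - 1
    r <- r[ok, ok]
    grDevices::png(file.path(out_dir, "correlation_heatmap.png"),
                   900, 900)
    stats::heatmap(abs(r), symm = TRUE, col = grDevices::hcl.colors(64),
                   margins = c(10, 10))
    grDevices::dev.off()
    cl <- cluster_metrics(r, config$criteria)
    if (!is.null(cl$hclust)) {
      grDevices::png(file.path(out_dir, "metric_dendrogram.png"), 900, 600)
      graphics::plot(cl$hclust, xlab = "", sub = "",
                     main = "Metric clustering on 1 - |r|")
      grDevices::dev.off()
    }
  }

  writeLines(log, file.path(out_dir, "pipeline.log"))
  bundle <- structure(list(cohort = cohort, metrics = metrics,
                           selection = sel, models = models,
                           bootstrap = boot, standardizer = std, log = log,
                           paths = list(out_dir = out_dir)),
                      class = "pipeline_bundle")
  invisible(bundle)
}

#' Render a human-readable pipeline report
#'
#' Plain-text tables mirroring the layout results in this literature are
#' reported in: cohort summary, metric summary, one coefficient block per
#' fitted model, and the bootstrap grid. Missing artifacts are listed as
#' absent rather than failing.
#'
#' @param bundle a `pipeline_bundle` from [run_pipeline()].
#' @param path optional file to write the report to.
#' @return the report lines, invisibly (visibly printed when `path` is
#'   `NULL`).
#' @export
render_report <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  out <- c("== Strength-estimation pipeline report ==", "")
  if (!is.null(bundle$cohort)) {
    out <- c(out, sprintf("Cohort: n = %d (%d male / %d female)",
                          nrow(bundle$cohort),
                          sum(bundle$cohort$sex == "male"),
                          sum(bundle$cohort$sex == "female")),
             sprintf("  weight %.1f +/- %.1f kg, age %.1f +/- %.1f y",
                     mean(bundle$cohort$weight), stats::sd(bundle$cohort$weight),
                     mean(bundle$cohort$age), stats::sd(bundle$cohort$age)),
             "")
  } else out <- c(out, "Cohort: absent", "")
  if (!is.null(bundle$metrics)) {
    filled <- colSums(!is.na(bundle$metrics[-1]))
    out <- c(out, sprintf("Metrics: %d participants x %d metrics (%d cells filled)",
                          nrow(bundle$metrics), ncol(bundle$metrics) - 1,
                          sum(filled)), "")
  } else out <- c(out, "Metrics: absent", "")
  if (length(bundle$models)) {
    for (nm in names(bundle$models)) {
      m <- bundle$models[[nm]]
      out <- c(out, sprintf("-- Model: %s (n = %d) --", nm, m$n),
               utils::capture.output(print(format(m$coefficients, digits = 3),
                                           row.names = FALSE)),
               sprintf("R = %.3f (adj R2 = %.3f)  f2 = %.2f  power = %.3f",
                       m$r, m$adj_r2, m$f2, m$power), "")
    }
  } else out <- c(out, "Models: no admissible predictors", "")
  if (!is.null(bundle$bootstrap)) {
    out <- c(out, "-- Bootstrap validation (mean R, mean adj R2) --",
             utils::capture.output(print(format(bundle$bootstrap, digits = 3),
                                         row.names = FALSE)), "")
  } else out <- c(out, "Bootstrap: absent", "")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
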