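#!/usr/bin/env Rscript
# Stage 3: screen the 27 metrics and fit the strength-estimation models.
#
# Screening: (1) Shapiro-Wilk normality on each metric, (2) residual
# normality + Breusch-Pagan homoscedasticity of each single-predictor fit
# against the composite index, (3) hierarchical clustering on 1 - |r| cut
# at |r| = 0.7, keeping one representative per cluster. Then fits the
# multivariable model on the survivors and the squat-only reduction, and
# reports B, SE, beta, R, adjusted R^2, Cohen's f2 and post-hoc power.

suppressMessages(library(exostrength))

cohort <- utils::read.csv("results/cohort.csv", stringsAsFactors = FALSE)
metrics <- utils::read.csv("results/metrics.csv", check.names = FALSE,
                           stringsAsFactors = FALSE)
tab <- merge(metrics, cohort[, c("id", "sex", "age", "vj",
                                 "rm_le_lc_weight", "iso_le_lc_weight",
                                 "total_performance")], by = "id")

sel <- select_variables(tab, "total_performance",
                        candidates = intersect(metric_names(), names(tab)))
utils::write.csv(sel$audit, "results/selection_audit.csv",
                 row.names = FALSE)
cat("Screening retained", length(sel$selected), "predictors:\n  ",
    paste(sel$selected, collapse = ", "), "\n\n")

models <- list(all_metrics = fit_ols(tab, "total_performance",
                                     sel$selected),
               squat_only = fit_ols(tab, "total_performance",
                                    "Squat_IS_Max"))
for (nm in names(models)) {
  cat("--", nm, "--\n")
  print(models[[nm]])
  cat("\n")
}

coefs <- do.call(rbind, lapply(names(models), function(nm)
  cbind(model = nm, models[[nm]]$coefficients)))
utils::write.csv(coefs, "results/model_coefficients.csv", row.names = FALSE)
summ <- lapply(models, function(m)
  m[c("r", "r2", "adj_r2", "f2", "power", "p_overall", "n", "predictors")])
jsonlite::write_json(summ, "results/model_summary.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("Coefficients and summaries written under results/\n")
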