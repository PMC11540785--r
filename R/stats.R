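#' Selection criteria for the variable-screening pipeline
#'
#' @param normality_alpha Shapiro-Wilk significance level for predictors
#'   (default 0.05; a predictor must NOT reject normality to survive).
#' @param residual_alpha significance level for residual normality and
#'   homoscedasticity checks (default 0.05).
#' @param linearity_threshold absolute-correlation bound between retained
#'   predictors (default 0.7): within a cluster of metrics correlated above
#'   it, only one representative is kept.
#' @param cluster_linkage agglomeration method on the 1 - |r| distance.
#' @return list of class `"selection_criteria"`.
#' @export
selection_criteria <- function(normality_alpha = 0.05,
                               residual_alpha = 0.05,
                               linearity_threshold = 0.7,
                               cluster_linkage = c("average", "complete",
                                                   "single")) {
  cluster_linkage <- match.arg(cluster_linkage)
  if (normality_alpha <= 0 || normality_alpha >= 1 ||
      residual_alpha <= 0 || residual_alpha >= 1)
    stop("selection_criteria: alphas must lie in (0, 1)")
  if (linearity_threshold <= 0 || linearity_threshold > 1)
    stop("selection_criteria: linearity_threshold must lie in (0, 1]")
  structure(list(normality_alpha = normality_alpha,
                 residual_alpha = residual_alpha,
                 linearity_threshold = linearity_threshold,
                 cluster_linkage = cluster_linkage),
            class = "selection_criteria")
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] returning the W statistic
#' and p-value, with explicit guards on sample size and degeneracy.
#'
#' @param values numeric sample, 3 <= n <= 5000, non-constant.
#' @return list `w`, `p_value`.
#' @export
normality_test <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 5000)
    stop("normality_test: sample size must lie in [3, 5000]")
  if (stats::sd(values) == 0)
    stop("normality_test: constant sample")
  ht <- stats::shapiro.test(values)
  list(w = unname(ht$statistic), p_value = ht$p.value)
}

#' Pairwise-complete Pearson correlation matrix
#'
#' @param table data.frame; non-numeric columns are dropped.
#' @param min_pairs minimum complete pairs per cell (default 3); cells with
#'   fewer become `NA` with a warning.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(table, min_pairs = 3) {
  num <- table[vapply(table, is.numeric, logical(1))]
  m <- as.matrix(num)
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  ok <- !is.na(m)
  pairs <- crossprod(ok)
  short <- pairs < min_pairs
  if (any(short & upper.tri(short))) {
    warning("correlation_matrix: some cells have fewer than ", min_pairs,
            " complete pairs; set to NA")
    r[short] <- NA_real_
  }
  diag(r) <- 1
  r
}

#' Hierarchically cluster metrics by absolute correlation
#'
#' Agglomerative clustering on the dissimilarity d = 1 - |r|, cut at
#' d = 1 - linearity_threshold so that metrics correlated above the
#' threshold share a flat cluster.
#'
#' @param corr correlation matrix (complete on the selected columns).
#' @param criteria a [selection_criteria()].
#' @return list: `hclust` (the tree; `NULL` for a single metric),
#'   `clusters` (named integer cluster labels), `order` (leaf order).
#' @export
cluster_metrics <- function(corr, criteria = selection_criteria()) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (nrow(corr) == 1L) {
    cl <- stats::setNames(1L, rownames(corr))
    return(list(hclust = NULL, clusters = cl, order = 1L))
  }
  d <- stats::as.dist(1 - abs(corr))
  hc <- stats::hclust(d, method = criteria$cluster_linkage)
  h <- 1 - criteria$linearity_threshold
  clusters <- stats::cutree(hc, h = h)
  list(hclust = hc, clusters = clusters, order = hc$order)
}

#' Residual diagnostics for a fitted linear model
#'
#' Shapiro-Wilk on the residuals (normality) and the Breusch-Pagan test
#' (homoscedasticity); a formal, reproducible stand-in for the visual
#' residual/QQ-plot inspection such screening is usually done by.
#'
#' @param model a fitted [stats::lm()] model.
#' @return list `shapiro_p`, `bp_p`.
#' @export
residual_diagnostics <- function(model) {
  stopifnot(inherits(model, "lm"))
  res <- stats::residuals(model)
  if (length(res) < 3 || stats::sd(res) < 1e-10 * max(1, stats::sd(model$model[[1]])))
    stop("residual_diagnostics: degenerate residuals")
  list(shapiro_p = stats::shapiro.test(res)$p.value,
       bp_p = lmtest::bptest(model)$p.value[[1]])
}

#' Statistically screened variable selection
#'
#' The three-stage screen applied to candidate predictors of a strength
#' target: (1) drop metrics whose own distribution rejects normality at
#' `normality_alpha`; (2) drop metrics whose single-predictor regression on
#' the target fails residual normality or homoscedasticity at
#' `residual_alpha`; (3) cluster the survivors on 1 - |r| at the linearity
#' threshold and keep one representative per cluster - the metric with the
#' highest absolute correlation with the target (alphabetical tie-break).
#' Every exclusion is recorded with its reason.
#'
#' @param table data.frame holding the target and candidate columns.
#' @param target_name dependent-variable column name.
#' @param criteria a [selection_criteria()].
#' @param candidates candidate columns (default: all numeric columns other
#'   than the target).
#' @return list: `selected` (character), `audit` (data.frame `metric`,
#'   `stage`, `action`, `detail`).
#' @export
select_variables <- function(table, target_name,
                             criteria = selection_criteria(),
                             candidates = NULL) {
  stopifnot(is.data.frame(table), target_name %in% names(table))
  if (is.null(candidates))
    candidates <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                          target_name)
  audit <- list()
  note <- function(metric, stage, action, detail)
    audit[[length(audit) + 1L]] <<- data.frame(
      metric = metric, stage = stage, action = action, detail = detail,
      stringsAsFactors = FALSE)

  y <- table[[target_name]]

  # stage 1: marginal normality
  surv <- character(0)
  for (v in candidates) {
    x <- table[[v]]
    p <- tryCatch(normality_test(x)$p_value, error = function(e) NA_real_)
    if (is.na(p)) {
      note(v, "normality", "drop", "test not computable")
    } else if (p <= criteria$normality_alpha) {
      note(v, "normality", "drop", sprintf("Shapiro-Wilk p = %.4g", p))
    } else {
      note(v, "normality", "keep", sprintf("Shapiro-Wilk p = %.4g", p))
      surv <- c(surv, v)
    }
  }

  # stage 2: single-predictor residual diagnostics against the target
  surv2 <- character(0)
  for (v in surv) {
    ok <- stats::complete.cases(table[, c(target_name, v)])
    fit <- stats::lm(stats::reformulate(v, target_name), data = table[ok, ])
    dg <- tryCatch(residual_diagnostics(fit), error = function(e) NULL)
    if (is.null(dg)) {
      note(v, "residuals", "drop", "degenerate residuals")
    } else if (dg$shapiro_p <= criteria$residual_alpha) {
      note(v, "residuals", "drop",
           sprintf("residual Shapiro-Wilk p = %.4g", dg$shapiro_p))
    } else if (dg$bp_p <= criteria$residual_alpha) {
      note(v, "residuals", "drop",
           sprintf("Breusch-Pagan p = %.4g", dg$bp_p))
    } else {
      note(v, "residuals", "keep",
           sprintf("Shapiro p = %.3g, BP p = %.3g", dg$shapiro_p, dg$bp_p))
      surv2 <- c(surv2, v)
    }
  }

  # stage 3: multicollinearity pruning via clustering
  selected <- character(0)
  if (length(surv2) == 1L) {
    selected <- surv2
    note(surv2, "clustering", "keep", "single survivor")
  } else if (length(surv2) > 1L) {
    r <- correlation_matrix(table[surv2])
    cl <- cluster_metrics(r, criteria)$clusters
    tc <- vapply(surv2, function(v) {
      ok <- stats::complete.cases(table[, c(target_name, v)])
      abs(stats::cor(table[[v]][ok], y[ok]))
    }, numeric(1))
    for (g in sort(unique(cl))) {
      members <- names(cl)[cl == g]
      best <- members[order(-tc[members], members)][1]
      selected <- c(selected, best)
      note(best, "clustering", "keep",
           sprintf("cluster %d representative, |r| with target = %.3f",
                   g, tc[best]))
      for (m in setdiff(members, best))
        note(m, "clustering", "drop",
             sprintf("cluster %d, represented by %s", g, best))
    }
  }
  list(selected = sort(selected), audit = do.call(rbind, audit))
}

#' Cohen's f-squared effect size
#'
#' @param r2 coefficient of determination (0 <= r2 < 1).
#' @return f2 = r2 / (1 - r2).
#' @export
cohens_f2 <- function(r2) {
  if (any(r2 < 0 | r2 >= 1)) stop("cohens_f2: r2 must lie in [0, 1)")
  r2 / (1 - r2)
}

#' Post-hoc power of the overall F test
#'
#' Power of the regression F test under the noncentral F distribution with
#' numerator df u = number of predictors, denominator df v = n - u - 1 and
#' noncentrality lambda = f2 * n.
#'
#' @param f2 Cohen's effect size (>= 0).
#' @param n sample size.
#' @param n_predictors number of predictors u.
#' @param alpha test size (default 0.05).
#' @return power in [alpha, 1].
#' @export
posthoc_power <- function(f2, n, n_predictors, alpha = 0.05) {
  stopifnot(f2 >= 0, n_predictors >= 1)
  u <- n_predictors
  v <- n - u - 1
  if (v < 1) stop("posthoc_power: n must exceed n_predictors + 1")
  crit <- stats::qf(1 - alpha, u, v)
  stats::pf(crit, u, v, ncp = f2 * n, lower.tail = FALSE)
}

#' Fit a multivariable OLS strength model
#'
#' Ordinary least squares of the target on the given predictors (listwise
#' deletion), reported the way regression tables in this literature are:
#' unstandardized coefficients B with standard errors, standardized
#' coefficients beta (B scaled by sd(x)/sd(y)), multiple R, adjusted R^2,
#' Cohen's f2 and the post-hoc power of the overall F test.
#'
#' @param table data.frame with target and predictor columns.
#' @param target_name dependent-variable column.
#' @param predictors character vector of predictor columns.
#' @param alpha test size used for the power computation.
#' @return list of class `"strength_model"`: `coefficients` (data.frame
#'   `term`, `b`, `se`, `beta`, `p_value`), `r`, `r2`, `adj_r2`, `f2`,
#'   `power`, `p_overall`, `n`, `target`, `predictors`, `fit` (the lm).
#' @export
fit_ols <- function(table, target_name, predictors, alpha = 0.05) {
  stopifnot(is.data.frame(table), target_name %in% names(table),
            length(predictors) >= 1, all(predictors %in% names(table)))
  use <- stats::complete.cases(table[, c(target_name, predictors)])
  dat <- table[use, c(target_name, predictors), drop = FALSE]
  n <- nrow(dat)
  p <- length(predictors)
  if (n <= p + 1)
    stop("fit_ols: need more than n_predictors + 1 complete observations")
  qrX <- qr(as.matrix(cbind(1, dat[predictors])))
  if (qrX$rank < p + 1) {
    cols <- c("(Intercept)", predictors)
    bad <- setdiff(cols[qrX$pivot[seq.int(qrX$rank + 1, p + 1)]],
                   "(Intercept)")
    stop("fit_ols: rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(stats::reformulate(predictors, target_name), data = dat)
  sm <- summary(fit)
  co <- stats::coef(sm)
  sdy <- stats::sd(dat[[target_name]])
  beta <- vapply(predictors, function(v)
    co[v, "Estimate"] * stats::sd(dat[[v]]) / sdy, numeric(1))
  r2 <- sm$r.squared
  fstat <- sm$fstatistic
  p_overall <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  f2 <- cohens_f2(min(r2, 1 - 1e-15))
  structure(list(
    coefficients = data.frame(
      term = rownames(co),
      b = co[, "Estimate"],
      se = co[, "Std. Error"],
      beta = c(NA_real_, beta)[match(rownames(co),
                                     c("(Intercept)", predictors))],
      p_value = co[, "Pr(>|t|)"],
      row.names = NULL, stringsAsFactors = FALSE),
    r = sqrt(r2), r2 = r2, adj_r2 = sm$adj.r.squared,
    f2 = f2,
    power = posthoc_power(f2, n, p, alpha),
    p_overall = unname(p_overall),
    n = n, target = target_name, predictors = predictors,
    fit = fit
  ), class = "strength_model")
}

#' @export
print.strength_model <- function(x, digits = 3, ...) {
  cat(sprintf("<strength_model> %s ~ %s  (n = %d)\n", x$target,
              paste(x$predictors, collapse = " + "), x$n))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  cat(sprintf("R = %.3f, adj R2 = %.3f, f2 = %.2f, power = %.3f, overall p = %.3g\n",
              x$r, x$adj_r2, x$f2, x$power, x$p_overall))
  invisible(x)
}

#' Bootstrap specification for the robustness validation
#'
#' @param n_resamples bootstrap sample size per repeat (e.g. 100, 300);
#'   `NA` keeps the original n.
#' @param noise_fraction additive Gaussian noise SD as a fraction of each
#'   column's original SD (e.g. 0.10, 0.30).
#' @param n_repeats Monte-Carlo repetitions (default 200).
#' @param include_demographics add sex (male 1 / female 0) and age as extra
#'   predictors.
#' @param resample resample rows with replacement (TRUE) or keep the
#'   original rows (FALSE, for the identity configuration).
#' @param seed RNG seed.
#' @return list of class `"bootstrap_spec"`.
#' @export
bootstrap_spec <- function(n_resamples = NA_integer_, noise_fraction = 0,
                           n_repeats = 200, include_demographics = FALSE,
                           resample = TRUE, seed = 1L) {
  if (!is.na(noise_fraction) && (noise_fraction < 0 || noise_fraction >= 1))
    stop("bootstrap_spec: noise_fraction must lie in [0, 1)")
  structure(list(n_resamples = n_resamples, noise_fraction = noise_fraction,
                 n_repeats = n_repeats,
                 include_demographics = include_demographics,
                 resample = resample, seed = as.integer(seed)),
            class = "bootstrap_spec")
}

#' Bootstrap-with-noise validation of a strength model
#'
#' For each repeat: resample participants with replacement to
#' `n_resamples`; add independent Gaussian noise with SD equal to
#' `noise_fraction` times the original column SD to every predictor and to
#' every raw component of the dependent composite; recompute the composite
#' with the frozen standardizer (the reference cohort's means and SDs);
#' refit the model; record R and adjusted R^2. Optionally augments the
#' predictors with sex (male 1 / female 0) and age.
#'
#' @param table data.frame holding predictors, the composite components
#'   (`components`), and - when demographics are requested - `sex`
#'   (`"male"`/`"female"` or 0/1) and `age`.
#' @param predictors character vector of predictor columns.
#' @param spec a [bootstrap_spec()].
#' @param std frozen [fit_standardizer()] from the original cohort
#'   (required on the composite route).
#' @param components columns of the raw dependent components (default the
#'   three composite inputs). Pass `NULL` together with `target` to
#'   validate a model whose dependent variable is an ordinary column:
#'   noise is then added to the target itself rather than to composite
#'   components.
#' @param target dependent-variable column, used only when
#'   `components = NULL`.
#' @return list: `mean_r`, `sd_r`, `mean_adj_r2`, `sd_adj_r2`,
#'   `n_repeats`, `spec`, `per_repeat` (data.frame of R / adj R^2).
#' @export
bootstrap_validate <- function(table, predictors, spec, std = NULL,
                               components = c("vj", "rm_le_lc_weight",
                                              "iso_le_lc_weight"),
                               target = NULL) {
  stopifnot(inherits(spec, "bootstrap_spec"),
            all(predictors %in% names(table)))
  if (is.null(components)) {
    if (is.null(target) || !target %in% names(table))
      stop("bootstrap_validate: need a 'target' column when components = NULL")
  } else {
    stopifnot(inherits(std, "cohort_standardizer"),
              all(components %in% names(table)))
  }
  n0 <- nrow(table)
  nres <- if (is.na(spec$n_resamples)) n0 else spec$n_resamples
  preds <- predictors
  tab <- table
  if (spec$include_demographics) {
    stopifnot(all(c("sex", "age") %in% names(table)))
    tab$sex01 <- if (is.numeric(table$sex)) table$sex
      else as.numeric(table$sex == "male")
    preds <- c(preds, "sex01", "age")
  }
  noisy_cols <- c(preds, if (is.null(components)) target else components)
  sds <- vapply(noisy_cols, function(v) stats::sd(tab[[v]]), numeric(1))
  if (spec$noise_fraction > 0 && any(sds == 0))
    stop("bootstrap_validate: zero-SD column '",
         noisy_cols[which(sds == 0)[1]], "' cannot receive proportional noise")
  res <- withr_seed(spec$seed, {
    out <- matrix(NA_real_, spec$n_repeats, 2)
    for (b in seq_len(spec$n_repeats)) {
      idx <- if (spec$resample) sample.int(n0, nres, replace = TRUE)
        else seq_len(n0)
      d <- tab[idx, , drop = FALSE]
      if (spec$noise_fraction > 0)
        for (v in noisy_cols)
          d[[v]] <- d[[v]] +
            stats::rnorm(nrow(d), 0, spec$noise_fraction * sds[[v]])
      d$.target <- if (is.null(components)) d[[target]]
        else total_performance(d, std)
      fit <- fit_ols(d, ".target", preds)
      out[b, ] <- c(fit$r, fit$adj_r2)
    }
    out
  })
  list(mean_r = mean(res[, 1]), sd_r = stats::sd(res[, 1]),
       mean_adj_r2 = mean(res[, 2]), sd_adj_r2 = stats::sd(res[, 2]),
       n_repeats = spec$n_repeats, spec = spec,
       per_repeat = data.frame(r = res[, 1], adj_r2 = res[, 2]))
}
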