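#' Fill weight-normalized muscle-parameter columns
#'
#' Adds the six weight ratios used as strength indicators: the 1RM and
#' isometric leg-extension/leg-curl values, singly and summed, divided by
#' body weight. Expressing strength per kilogram of body weight makes
#' participants of different size comparable.
#'
#' @param params data.frame with columns `vj`, `rm_le`, `rm_lc`, `iso_le`,
#'   `iso_lc`, `weight` (one row per participant).
#' @return `params` with columns `rm_le_weight`, `rm_lc_weight`,
#'   `rm_le_lc_weight`, `iso_le_weight`, `iso_lc_weight`,
#'   `iso_le_lc_weight` appended.
#' @export
weight_normalize <- function(params) {
  need <- c("rm_le", "rm_lc", "iso_le", "iso_lc", "weight")
  stopifnot(is.data.frame(params), all(need %in% names(params)))
  if (any(params$weight <= 0))
    stop("weight_normalize: body weight must be positive")
  params$rm_le_weight <- params$rm_le / params$weight
  params$rm_lc_weight <- params$rm_lc / params$weight
  params$rm_le_lc_weight <- (params$rm_le + params$rm_lc) / params$weight
  params$iso_le_weight <- params$iso_le / params$weight
  params$iso_lc_weight <- params$iso_lc / params$weight
  params$iso_le_lc_weight <- (params$iso_le + params$iso_lc) / params$weight
  params
}

#' Fit a cohort standardizer
#'
#' Stores the sample mean and SD (denominator n - 1) of each variable that
#' enters the composite strength index, so z-scores can later be computed
#' against a frozen reference cohort (as the bootstrap validation
#' requires).
#'
#' @param params data.frame of (weight-normalized) muscle parameters.
#' @param variables columns to standardize; defaults to the three composite
#'   components.
#' @return list of class `"cohort_standardizer"`: `moments` (data.frame
#'   `variable`, `mean`, `sd`), `source` (`"fitted"` or `"frozen"`).
#' @export
fit_standardizer <- function(params,
                             variables = c("vj", "rm_le_lc_weight",
                                           "iso_le_lc_weight")) {
  stopifnot(is.data.frame(params), nrow(params) >= 2,
            all(variables %in% names(params)))
  mom <- data.frame(variable = variables,
                    mean = vapply(variables,
                                  function(v) mean(params[[v]]), numeric(1)),
                    sd = vapply(variables,
                                function(v) stats::sd(params[[v]]),
                                numeric(1)),
                    stringsAsFactors = FALSE)
  zero <- mom$variable[mom$sd == 0 | !is.finite(mom$sd)]
  if (length(zero))
    stop("fit_standardizer: zero or undefined SD for variable '",
         zero[1], "'")
  structure(list(moments = mom, source = "fitted"),
            class = "cohort_standardizer")
}

# z-score one variable against a standardizer
standardize_value <- function(x, std, variable) {
  m <- std$moments[std$moments$variable == variable, ]
  if (nrow(m) != 1L)
    stop("standardizer has no moments for variable '", variable, "'")
  (x - m$mean) / m$sd
}

#' Composite strength index (z-score sum)
#'
#' Sum of the cohort z-scores of vertical jump, weight-normalized 1RM sum
#' and weight-normalized isometric sum: one dimensionless number per
#' participant summarizing baseline lower-limb strength.
#'
#' @param params data.frame with columns `vj`, `rm_le_lc_weight`,
#'   `iso_le_lc_weight` (see [weight_normalize()]).
#' @param std a [fit_standardizer()] result (fitted on this cohort or
#'   frozen from a reference cohort).
#' @return numeric vector of z-sums.
#' @export
total_performance <- function(params, std) {
  stopifnot(inherits(std, "cohort_standardizer"))
  standardize_value(params$vj, std, "vj") +
    standardize_value(params$rm_le_lc_weight, std, "rm_le_lc_weight") +
    standardize_value(params$iso_le_lc_weight, std, "iso_le_lc_weight")
}

#' Write / read a standardizer as plain text
#'
#' @param std a `cohort_standardizer`.
#' @param path CSV path (`variable,mean,sd`).
#' @return `path` (write) or the standardizer (read), with
#'   `source = "frozen"`.
#' @export
write_standardizer <- function(std, path) {
  stopifnot(inherits(std, "cohort_standardizer"))
  utils::write.csv(std$moments, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_standardizer
#' @export
read_standardizer <- function(path) {
  mom <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("variable", "mean", "sd") %in% names(mom)))
  structure(list(moments = mom, source = "frozen"),
            class = "cohort_standardizer")
}
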