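#' Generate a cohort of participant profiles
#'
#' Draws participant demographics and a standard-normal latent strength
#' value per participant. Latent strength is the single factor behind both
#' the muscle parameters and the free-pace exercise speed, which is what
#' gives the downstream regression something real to recover.
#'
#' @param config a [simulation_config()].
#' @return data.frame with one row per participant: `id`, `latent_strength`,
#'   `weight` (kg), `height` (cm), `age` (years), `sex` ("male"/"female"),
#'   `seed` (per-participant child seed).
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_participants
  withr_seed(child_seed(config$master_seed, "cohort"), {
    data.frame(
      id = sprintf("P%03d", seq_len(n)),
      latent_strength = stats::rnorm(n),
      weight = stats::rnorm(n, config$weight_mean, config$weight_sd),
      height = stats::rnorm(n, config$height_mean, config$height_sd),
      age = stats::rnorm(n, config$age_mean, config$age_sd),
      sex = ifelse(stats::runif(n) < config$male_prob, "male", "female"),
      seed = vapply(seq_len(n),
                    function(i) child_seed(config$master_seed,
                                           paste0("participant", i)),
                    integer(1)),
      stringsAsFactors = FALSE
    )
  })
}

# run code under a temporary RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate raw muscle parameters for a cohort
#'
#' Each raw parameter (vertical jump, 1RM leg extension/curl, isometric leg
#' extension/curl) is `intercept + loading * latent_strength + noise`.
#' Draws that come out non-positive are rejection-resampled up to 100 times,
#' then clipped at 1\% of the configured intercept, which preserves the
#' configured moments almost everywhere.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param config a [simulation_config()].
#' @return the cohort with columns `vj` (cm), `rm_le`, `rm_lc` (kg),
#'   `iso_le`, `iso_lc` (N) appended.
#' @export
generate_muscle_parameters <- function(cohort, config = simulation_config()) {
  stopifnot(is.data.frame(cohort), "latent_strength" %in% names(cohort))
  load <- config$muscle_param_loadings
  if (any(load$intercept <= 0))
    stop("generate_muscle_parameters: non-positive intercept for '",
         load$parameter[load$intercept <= 0][1],
         "' makes positivity unreachable")
  n <- nrow(cohort)
  out <- cohort
  withr_seed(child_seed(config$master_seed, "muscle_parameters"), {
    for (k in seq_len(nrow(load))) {
      p <- load[k, ]
      mu <- p$intercept + p$loading * cohort$latent_strength
      x <- mu + stats::rnorm(n, 0, p$noise_sd)
      for (tries in seq_len(100)) {
        bad <- which(x <= 0)
        if (!length(bad)) break
        x[bad] <- mu[bad] + stats::rnorm(length(bad), 0, p$noise_sd)
      }
      x[x <= 0] <- 0.01 * p$intercept
      out[[p$parameter]] <- x
    }
  })
  out
}

#' Planted free-pace squat initial speed for a cohort
#'
#' Applies the configured strength-to-speed mapping: speed in reps per 10 s
#' equals `intercept + slope * latent_strength + N(0, noise_sd)`. This is
#' the pace the session generator plants for the max-effort squat; other
#' exercises scale it by `config$pace_scale`.
#'
#' @param cohort data.frame with a `latent_strength` column.
#' @param config a [simulation_config()].
#' @return numeric vector of speeds, reps per 10 s, floored at 1.
#' @export
planted_initial_speed <- function(cohort, config = simulation_config()) {
  sts <- config$strength_to_speed
  vapply(seq_len(nrow(cohort)), function(i) {
    withr_seed(child_seed(cohort$seed[i], "pace"), {
      sp <- sts$intercept + sts$slope * cohort$latent_strength[i] +
        stats::rnorm(1, 0, sts$noise_sd)
      max(sp, 1)
    })
  }, numeric(1))
}
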