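# Synthetic rating observers.
#
# Emulates a viscosity rating experiment: each observer rates each stimulus on
# the 1..16 scale. Ratings are the true step passed through a scene-specific
# response distortion (gain, additive bias and a compressive/expansive
# exponent, giving scene-dependent accuracy), plus a per-observer bias and
# trial noise. Defaults are calibrated so that the physical step explains
# roughly two thirds of the variance in mean ratings and an individual
# observer deviates from the mean observer by about 12% of the scale.

#' Construct an observer model
#'
#' @param n_observers number of observers (default 16).
#' @param scene_gain_sd SD of per-scene multiplicative gain around 1.
#' @param scene_bias_sd SD of per-scene additive bias (rating units).
#' @param scene_gamma_sd SD of the log of the per-scene compression exponent.
#' @param observer_bias_sd SD of each observer's constant bias (rating units).
#' @param trial_noise_sd SD of independent trial noise (rating units).
#' @return an `observer_model` list.
#' @export
observer_model <- function(n_observers = 16L, scene_gain_sd = 0.3,
                           scene_bias_sd = 2.4, scene_gamma_sd = 0.45,
                           observer_bias_sd = 1.0, trial_noise_sd = 2.1) {
  if (n_observers < 1) stop("invalid observer model: need at least one observer")
  pars <- list(
    n_observers = as.integer(n_observers),
    scene_gain_sd = scene_gain_sd, scene_bias_sd = scene_bias_sd,
    scene_gamma_sd = scene_gamma_sd, observer_bias_sd = observer_bias_sd,
    trial_noise_sd = trial_noise_sd
  )
  if (any(!is.finite(unlist(pars)))) stop("observer model parameters must be finite")
  structure(pars, class = "observer_model")
}

#' Simulate observer ratings for a stimulus design
#'
#' Draws scene distortion parameters, observer biases and trial noise from a
#' seeded stream, and produces one rating per observer per stimulus, clipped
#' to the rating scale. With all noise and bias SDs zero the mean rating is
#' exactly the true viscosity step (identity observers).
#'
#' @param design a `stimulus_design`.
#' @param scale the [viscosity_scale()].
#' @param model an [observer_model()].
#' @param seed integer seed.
#' @return a list with `ratings` (data frame: observer_id, stimulus_id,
#'   scene_class, viscosity_step, scene_variation, optical_variation, rating)
#'   and `mean_rating` (per-stimulus mean across observers, aligned with
#'   `design`).
#' @export
simulate_observers <- function(design, scale = viscosity_scale(),
                               model = observer_model(), seed = 1L) {
  stopifnot(nrow(design) > 0)
  n_obs <- model$n_observers
  r <- rng_stream(derive_seed(seed, 7001L))
  scenes <- sort(unique(design$scene_class))
  gain <- pmax(0.25, 1 + r$norm(length(scenes), 0, model$scene_gain_sd))
  bias <- r$norm(length(scenes), 0, model$scene_bias_sd)
  gamma <- exp(r$norm(length(scenes), 0, model$scene_gamma_sd))
  names(gain) <- names(bias) <- names(gamma) <- scenes
  obias <- r$norm(n_obs, 0, model$observer_bias_sd)

  si <- as.character(design$scene_class)
  u <- (design$viscosity_step - 1) / (scale$n_steps - 1)
  f <- 1 + (scale$n_steps - 1) * u^gamma[si] # scene response curve
  centre <- (1 + scale$n_steps) / 2
  base <- centre + gain[si] * (f - centre) + bias[si]

  n_stim <- nrow(design)
  ratings <- matrix(base, n_stim, n_obs) +
    matrix(obias, n_stim, n_obs, byrow = TRUE) +
    matrix(r$norm(n_stim * n_obs, 0, model$trial_noise_sd), n_stim, n_obs)
  ratings <- clamp(ratings, 1, scale$n_steps)

  df <- data.frame(
    observer_id = rep(seq_len(n_obs), each = n_stim),
    stimulus_id = rep(design$stimulus_id, n_obs),
    scene_class = rep(design$scene_class, n_obs),
    viscosity_step = rep(design$viscosity_step, n_obs),
    scene_variation = rep(design$scene_variation, n_obs),
    optical_variation = rep(design$optical_variation, n_obs),
    rating = as.numeric(ratings)
  )
  list(ratings = df, mean_rating = rowMeans(ratings))
}

#' Write ratings as a delimited table
#' @param ratings the `ratings` data frame from [simulate_observers()].
#' @param path output TSV path.
#' @export
write_ratings <- function(ratings, path) {
  utils::write.table(ratings, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Variance in mean ratings explained by the physical step
#'
#' Simple linear regression R-squared of the (variation-averaged) mean rating
#' on the viscosity step.
#'
#' @param mean_rating per-stimulus mean rating (already variation-averaged or
#'   not; averaging is the caller's choice).
#' @param step per-stimulus physical viscosity step.
#' @return R-squared in `[0, 1]`.
#' @export
rating_variance_explained <- function(mean_rating, step) {
  stopifnot(length(mean_rating) == length(step))
  summary(stats::lm(mean_rating ~ step))$r.squared
}

#' Average values across scene variations
#'
#' Collapses a per-stimulus vector to (scene, viscosity step) cell means,
#' the convention used when reporting behavioural comparisons.
#'
#' @param x per-stimulus values aligned with `design`.
#' @param design the `stimulus_design`.
#' @return a data frame with `scene_class`, `viscosity_step`, `value`.
#' @export
average_variations <- function(x, design) {
  stopifnot(length(x) == nrow(design))
  ag <- stats::aggregate(
    list(value = x),
    by = list(scene_class = design$scene_class,
              viscosity_step = design$viscosity_step),
    FUN = mean
  )
  ag[order(ag$scene_class, ag$viscosity_step), , drop = FALSE]
}
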