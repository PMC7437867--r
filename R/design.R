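# Factorial stimulus design and the log-spaced viscosity scale.

#' Log-spaced dynamic viscosity scale
#'
#' The generative viscosity parameter takes `n_steps` values logarithmically
#' spaced between `min_visc` and `max_visc` (dynamic viscosity in Pa.s,
#' roughly the range from water to molasses). Training and rating labels use
#' the linear step index `1..n_steps`.
#'
#' @param n_steps number of steps (default 16).
#' @param min_visc viscosity at step 1, in Pa.s.
#' @param max_visc viscosity at step `n_steps`, in Pa.s.
#' @return an object of class `viscosity_scale`.
#' @export
#' @examples
#' sc <- viscosity_scale()
#' viscosity_value(1, sc)   # 0.001
#' viscosity_value(16, sc)  # 10
viscosity_scale <- function(n_steps = 16L, min_visc = 0.001, max_visc = 10) {
  stopifnot(n_steps >= 2, min_visc > 0, max_visc > min_visc)
  structure(
    list(n_steps = as.integer(n_steps), min_visc = min_visc, max_visc = max_visc),
    class = "viscosity_scale"
  )
}

#' @export
print.viscosity_scale <- function(x, ...) {
  cat(sprintf(
    "Viscosity scale: %d log-spaced steps, %.4g to %.4g Pa.s\n",
    x$n_steps, x$min_visc, x$max_visc
  ))
  invisible(x)
}

#' Dynamic viscosity at a scale step
#'
#' @param step integer step(s) in `1..n_steps`.
#' @param scale a [viscosity_scale()].
#' @return dynamic viscosity in Pa.s.
#' @export
viscosity_value <- function(step, scale = viscosity_scale()) {
  if (any(step < 1 | step > scale$n_steps) || any(step != round(step))) {
    stop("`step` must be an integer in 1..", scale$n_steps)
  }
  ratio <- scale$max_visc / scale$min_visc
  scale$min_visc * ratio^((step - 1) / (scale$n_steps - 1))
}

#' Enumerate the factorial stimulus design
#'
#' Builds the full crossing of scene class, viscosity step, scene variation
#' (randomised simulation parameters: emitter position/velocity, geometry) and
#' optical variation (palette, background luminance, rendering noise). The
#' ordering is scene-major: optical variation varies fastest, then scene
#' variation, then viscosity step, then scene class. One scene variation of a
#' scene at a given viscosity is one "unique simulation"; optical variations
#' re-render the same simulation.
#'
#' @param n_scenes number of scene classes (default 10).
#' @param n_viscosities number of viscosity steps (default 16).
#' @param n_scene_variations simulation variations per cell (default 125).
#' @param n_optical_variations render variations per simulation (default 5).
#' @param global_seed integer seed from which per-stimulus seeds are derived.
#' @return a `stimulus_design` data frame with one row per clip and columns
#'   `stimulus_id`, `scene_class`, `viscosity_step`, `scene_variation`,
#'   `optical_variation`, `seed`; attributes `n_specs`, `n_unique_simulations`
#'   and `n_frames` summarise the design.
#' @export
#' @examples
#' d <- make_design(10, 16, 5, 1)
#' nrow(d)  # 800, the rated experimental set
make_design <- function(n_scenes = 10L, n_viscosities = 16L,
                        n_scene_variations = 125L, n_optical_variations = 5L,
                        global_seed = 1L) {
  counts <- c(n_scenes, n_viscosities, n_scene_variations, n_optical_variations)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("invalid design: all counts must be positive integers")
  }
  d <- expand.grid(
    optical_variation = seq_len(n_optical_variations),
    scene_variation = seq_len(n_scene_variations),
    viscosity_step = seq_len(n_viscosities),
    scene_class = seq_len(n_scenes),
    KEEP.OUT.ATTRS = FALSE
  )[, c("scene_class", "viscosity_step", "scene_variation", "optical_variation")]
  d$seed <- mapply(
    derive_seed,
    d$scene_class, d$viscosity_step, d$scene_variation, d$optical_variation,
    MoreArgs = list(seed = global_seed)
  )
  d <- cbind(stimulus_id = seq_len(nrow(d)), d)
  attr(d, "n_specs") <- prod(counts)
  attr(d, "n_unique_simulations") <- prod(counts[1:3])
  attr(d, "n_frames") <- prod(counts) * 20
  attr(d, "global_seed") <- as.integer(global_seed)
  class(d) <- c("stimulus_design", "data.frame")
  d
}

#' @export
print.stimulus_design <- function(x, ...) {
  cat(sprintf(
    "Stimulus design: %d clips (%d unique simulations, %d frames)\n",
    attr(x, "n_specs"), attr(x, "n_unique_simulations"), attr(x, "n_frames")
  ))
  print.data.frame(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
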