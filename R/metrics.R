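# The predictor registry and the batch driver computing all eighteen
# predictors for a stimulus set: fifteen image-computable metrics plus three
# high-level predictors (physical viscosity, perceived viscosity, scene).

#' The predictor registry
#'
#' Names, categories and per-stimulus shapes of the eighteen predictors for
#' 20-frame 64 x 64 input. Shapes fixed by convention (flow stacks, spectra,
#' GIST) are exact; bank-dependent dimensionalities (motion energy, SIFT,
#' texture) follow from the default bank configuration.
#'
#' @return a data frame with `name`, `category` and `shape`.
#' @export
metric_registry <- function() {
  data.frame(
    name = c("of_speed", "of_gradient", "of_speed_hist", "of_gradient_hist",
             "power_spectrum", "contrast", "gradient",
             "s_hsv", "l_lab", "a_lab", "b_lab",
             "motion_energy", "sift", "gist", "texture",
             "viscosity", "perceived", "scene"),
    category = c("motion", "motion", "motion", "motion",
                 "spatial", "spatial", "spatial",
                 "lightness/colour", "lightness/colour", "lightness/colour",
                 "lightness/colour",
                 "multi-feature", "multi-feature", "multi-feature", "multi-feature",
                 "high-level", "high-level", "high-level"),
    shape = c("32x32x19", "32x32x19", "Bx19", "Bx19",
              "33x20", "64x64x20", "64x64x20",
              "64x64x20", "64x64x20", "64x64x20", "64x64x20",
              "128x20", "2048x20", "512x20", "119x20",
              "1", "1", "1"),
    stringsAsFactors = FALSE
  )
}

#' High-level predictors for a design
#'
#' The physical viscosity step, the perceived viscosity (mean rating), and
#' the scene class of each stimulus. Viscosity and perceived live on the
#' linear 1..16 label scale and are compared by Euclidean (absolute)
#' distance; scene is compared by the binary same/different-class map.
#'
#' @param design a `stimulus_design`.
#' @param mean_rating per-stimulus mean rating aligned with `design`.
#' @return a list of three single-column feature matrices, tagged with their
#'   distance conventions.
#' @export
high_level <- function(design, mean_rating) {
  if (length(mean_rating) != nrow(design)) {
    stop("coverage error: mean ratings do not cover the design")
  }
  v <- matrix(as.numeric(design$viscosity_step), ncol = 1)
  p <- matrix(as.numeric(mean_rating), ncol = 1)
  s <- matrix(as.numeric(design$scene_class), ncol = 1)
  attr(v, "distance") <- "euclidean_always"
  attr(p, "distance") <- "euclidean_always"
  attr(s, "distance") <- "binary"
  list(viscosity = v, perceived = p, scene = s)
}

#' Compute all predictors for a clip set
#'
#' Runs every registered image metric on each clip (flattening the
#' per-stimulus arrays to feature vectors) and appends the high-level
#' predictors. Flow histograms use a set-level shared Freedman-Diaconis bin
#' count, so they are computed in a second pass.
#'
#' @param cs a `clipset`.
#' @param mean_rating per-stimulus mean ratings (for the perceived
#'   predictor); omit to skip the high-level predictors.
#' @param mask flow mask.
#' @param metrics character vector of metric names (default all).
#' @param progress print progress dots.
#' @return a named list of feature matrices (stimuli x dims), ordered as the
#'   registry; attribute `bins` holds the shared histogram bins.
#' @export
compute_metrics <- function(cs, mean_rating = NULL, mask = scene_mask(),
                            metrics = metric_registry()$name,
                            progress = FALSE) {
  n <- length(cs)
  image_names <- setdiff(metrics, c("viscosity", "perceived", "scene"))
  need_flow <- any(c("of_speed", "of_gradient", "of_speed_hist",
                     "of_gradient_hist") %in% metrics)
  flows <- if (need_flow) vector("list", n) else NULL
  grads <- if (need_flow) vector("list", n) else NULL
  feats <- list()
  add <- function(name, i, v) {
    if (is.null(feats[[name]])) feats[[name]] <<- matrix(0, n, length(v))
    feats[[name]][i, ] <<- v
  }
  for (i in seq_len(n)) {
    clip <- get_clip(cs, i)
    if (need_flow) {
      fl <- optical_flow(clip, mask)
      flows[[i]] <- fl
      grads[[i]] <- flow_gradient(fl)
      if ("of_speed" %in% metrics) add("of_speed", i, as.numeric(fl))
      if ("of_gradient" %in% metrics) add("of_gradient", i, as.numeric(grads[[i]]))
    }
    if ("power_spectrum" %in% metrics) add("power_spectrum", i, as.numeric(power_spectrum(clip)))
    if ("contrast" %in% metrics) add("contrast", i, as.numeric(local_contrast(clip)))
    if ("gradient" %in% metrics) add("gradient", i, as.numeric(image_gradient(clip)))
    if (any(c("s_hsv", "l_lab", "a_lab", "b_lab") %in% metrics)) {
      cc <- colour_channels(clip)
      for (nm in intersect(c("s_hsv", "l_lab", "a_lab", "b_lab"), metrics)) {
        add(nm, i, as.numeric(cc[[nm]]))
      }
    }
    if ("motion_energy" %in% metrics) add("motion_energy", i, as.numeric(motion_energy(clip)))
    if ("sift" %in% metrics) add("sift", i, as.numeric(sift_dense(clip)))
    if ("gist" %in% metrics) add("gist", i, as.numeric(gist(clip)))
    if ("texture" %in% metrics) add("texture", i, as.numeric(ps_texture(clip)))
    if (progress && i %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  bins <- NULL
  if ("of_speed_hist" %in% metrics) {
    bins <- shared_flow_bins(flows)
    feats[["of_speed_hist"]] <- t(vapply(flows, function(fl) as.numeric(flow_hist(fl, bins)),
                                         numeric(bins$n_bins * 19)))
  }
  if ("of_gradient_hist" %in% metrics) {
    gbins <- shared_flow_bins(grads)
    feats[["of_gradient_hist"]] <- t(vapply(grads, function(fl) as.numeric(flow_hist(fl, gbins)),
                                            numeric(gbins$n_bins * 19)))
  }
  if (!is.null(mean_rating) && any(c("viscosity", "perceived", "scene") %in% metrics)) {
    hl <- high_level(cs$design, mean_rating)
    for (nm in intersect(c("viscosity", "perceived", "scene"), metrics)) {
      feats[[nm]] <- hl[[nm]]
    }
  }
  ord <- intersect(metric_registry()$name, names(feats))
  feats <- feats[ord]
  attr(feats, "bins") <- bins
  feats
}
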