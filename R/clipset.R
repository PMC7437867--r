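# Compact clip container and the canonical reference set.

CLIP_DIM <- c(20L, 64L, 64L, 3L)

#' Simulate every clip of a design into a compact clip set
#'
#' Renders each row of a [make_design()] data frame and stores the frames
#' 8-bit quantised (as rendered images would be), one clip per column. This
#' keeps even thousands of clips in a few hundred megabytes while round
#' tripping values in `[0, 1]` to within 1/510.
#'
#' @param design a `stimulus_design`.
#' @param templates scene templates.
#' @param scale viscosity scale.
#' @param canonical_optics passed to [simulate_movie()].
#' @param progress print a dot every 200 clips.
#' @return a `clipset`: list with `data` (raw matrix, one column per clip)
#'   and `design`.
#' @export
simulate_clipset <- function(design, templates = scene_templates(),
                             scale = viscosity_scale(),
                             canonical_optics = FALSE, progress = FALSE) {
  n <- nrow(design)
  data <- matrix(as.raw(0), prod(CLIP_DIM), n)
  for (i in seq_len(n)) {
    cl <- simulate_movie(design[i, ], templates, scale,
                         canonical_optics = canonical_optics)
    data[, i] <- as.raw(round(as.numeric(cl) * 255))
    if (progress && i %% 200 == 0) cat(".")
  }
  if (progress) cat("\n")
  structure(list(data = data, design = design), class = "clipset")
}

#' Number of clips in a clip set
#' @param x a `clipset`.
#' @param ... unused.
#' @export
length.clipset <- function(x) ncol(x$data)

#' Extract one clip from a clip set
#' @param cs a `clipset`.
#' @param i clip index.
#' @return a `movie_clip` array (20 x 64 x 64 x 3, values in `[0,1]`).
#' @export
get_clip <- function(cs, i) {
  stopifnot(inherits(cs, "clipset"), i >= 1, i <= ncol(cs$data))
  structure(array(as.integer(cs$data[, i]) / 255, CLIP_DIM), class = "movie_clip")
}

#' @export
print.clipset <- function(x, ...) {
  cat(sprintf("Clip set: %d clips of %d x %d x %d x %d (8-bit stored)\n",
              ncol(x$data), CLIP_DIM[1], CLIP_DIM[2], CLIP_DIM[3], CLIP_DIM[4]))
  invisible(x)
}

# Batch of clips as a double matrix (pixels x n).
clipset_batch <- function(cs, idx) {
  matrix(as.integer(cs$data[, idx, drop = FALSE]), nrow = nrow(cs$data)) / 255
}

#' Generate the controlled reference stimulus set
#'
#' One clip per scene class and viscosity step with every nuisance parameter
#' (emitter jitter, geometry size, palette, background luminance, rendering
#' noise) held at fixed canonical values, so that only scene and viscosity
#' vary. With the default 10 x 16 design this yields 160 clips.
#'
#' @param scale viscosity scale.
#' @param templates scene templates.
#' @param global_seed design seed.
#' @return a `clipset` of `n_scenes * n_steps` clips.
#' @export
make_reference_set <- function(scale = viscosity_scale(),
                               templates = scene_templates(),
                               global_seed = 1L) {
  design <- make_design(length(templates), scale$n_steps, 1L, 1L,
                        global_seed = global_seed)
  simulate_clipset(design, templates, scale, canonical_optics = TRUE)
}

#' Export a clip's frames as lossless PNG images
#'
#' @param clip a `movie_clip`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return the written file paths, invisibly.
#' @export
write_frames_png <- function(clip, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(dim(clip)[1])
  for (f in seq_len(dim(clip)[1])) {
    img <- aperm(array(clip[f, , , ], dim(clip)[2:4]), c(1, 2, 3))
    paths[f] <- file.path(dir, sprintf("%s_%02d.png", prefix, f))
    png::writePNG(img, paths[f])
  }
  invisible(paths)
}
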