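# Scene templates: ten liquid-interaction classes for the procedural generator.
#
# Each template describes how liquid particles are emitted and forced in a
# 2-D side view of a one-box scene (a light container sitting at the bottom of
# the frame), plus a scene-specific static backdrop so that classes are
# visually distinct. All other dynamics (gravity, viscosity-dependent damping
# and cohesion, wall collisions) are shared and live in the simulator.

#' Default scene templates
#'
#' Ten liquid-interaction classes: pouring, rain, stirring, dipping, spraying,
#' splashing, dripping, a side jet, a sheet fall and a fountain. Each template
#' fixes the emitter schedule and the backdrop; scene variations randomise
#' emitter position/velocity and geometry size within template-specific ranges.
#'
#' @return a named list of 10 templates (class `scene_template` each).
#' @export
scene_templates <- function() {
  tpl <- list(
    list(id = 1L, name = "pour",     kind = "stream",
         emit_pos = c(10, 8), emit_vel = c(1.4, 0.3), emit_rate = 1.0,
         emit_window = c(1, 120), max_p = 40L),
    list(id = 2L, name = "rain",     kind = "rain",
         emit_pos = c(32, 2), emit_vel = c(0, 0.5), emit_rate = 1.4,
         emit_window = c(1, 120), radius_mult = 1.0, max_p = 16L),
    list(id = 3L, name = "stir",     kind = "stir",
         emit_pos = c(32, 48), emit_vel = c(0, 0), emit_rate = 0,
         emit_window = c(0, 0), n_init = 55, stir_omega = 0.07),
    list(id = 4L, name = "dip",      kind = "dipdrain",
         emit_pos = c(32, 24), emit_vel = c(0, 1.2), emit_rate = 4.5,
         emit_window = c(1, 120), n_init = 25, dip_width = 9, radius_mult = 1.3,
         max_p = 50L),
    list(id = 5L, name = "spray",    kind = "spray",
         emit_pos = c(14, 26), emit_vel = c(2.2, -0.6), emit_rate = 1.0,
         emit_window = c(1, 120), spread = 0.7),
    list(id = 6L, name = "twinpour", kind = "twin",
         emit_pos = c(32, 8), emit_vel = c(0.1, 0.6), emit_rate = 1.5,
         emit_window = c(1, 120), n_init = 15, twin_offset = 12),
    list(id = 7L, name = "drip",     kind = "drip",
         emit_pos = c(40, 6), emit_vel = c(0, 0.2), emit_rate = 6,
         emit_window = c(1, 120), drip_period = 9, max_p = 34L),
    list(id = 8L, name = "jet",      kind = "stream",
         emit_pos = c(10, 24), emit_vel = c(2.8, -0.2), emit_rate = 4.0,
         emit_window = c(1, 120), max_p = 70L),
    list(id = 9L, name = "sheetfall", kind = "sheet",
         emit_pos = c(32, 20), emit_vel = c(0.3, 0.4), emit_rate = 1.2,
         emit_window = c(1, 120), sheet_halfwidth = 12, max_p = 42L),
    list(id = 10L, name = "fountain", kind = "fountain",
         emit_pos = c(32, 50), emit_vel = c(0, -3.5), emit_rate = 6.5,
         emit_window = c(1, 120), spread = 0.5, max_p = 70L)
  )
  lapply(tpl, function(t) {
    t$n_init <- t$n_init %||% 0L
    structure(t, class = "scene_template")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flow-evaluation mask for a scene
#'
#' A fixed central region covering the container interior, where liquid motion
#' occurs; optical flow speeds outside the mask are zeroed before analysis.
#'
#' @param scene_class integer scene class (1..10); the mask is shared across
#'   templates since the container geometry is common.
#' @return a 64 x 64 logical matrix.
#' @export
scene_mask <- function(scene_class = 1L) {
  m <- matrix(FALSE, 64, 64)
  m[6:58, 4:60] <- TRUE
  m
}

# Scene-specific static backdrop (64 x 64 x 3). `pal` is the optical palette
# (list with bg_col, accent_col, bg_lum). The shapes below only serve to make
# classes visually separable, in the way distinct scene geometry does.
scene_backdrop <- function(template, pal, geom_size = 1) {
  h <- w <- 64
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  s <- template$id
  # per-scene gradient direction
  ang <- (s - 1) * pi / 5
  g <- ((cos(ang) * xx + sin(ang) * yy) - 32) / 64
  base <- clamp(pal$bg_lum + 0.25 * g, 0, 1)
  img <- array(0, c(h, w, 3))
  for (k in 1:3) img[, , k] <- base * pal$bg_col[k]
  # scene-identifying accents: s ellipses along a scene-specific arc
  set_px <- function(maskm, col, gain = 1) {
    for (k in 1:3) {
      ch <- img[, , k]
      ch[maskm] <- clamp((1 - gain) * ch[maskm] + gain * col[k], 0, 1)
      img[, , k] <<- ch
    }
  }
  n_acc <- 1 + (s - 1) %% 4
  for (j in seq_len(n_acc)) {
    cx <- 8 + ((s * 13 + j * 17) %% 48)
    cy <- 4 + ((s * 7 + j * 11) %% 24)
    rx <- (3 + (s + j) %% 4) * geom_size
    ry <- (2 + (s + 2 * j) %% 3) * geom_size
    mm <- ((xx - cx) / rx)^2 + ((yy - cy) / ry)^2 <= 1
    set_px(mm, pal$accent_col, gain = 0.85)
  }
  # sheetfall ledge
  if (template$kind == "sheet") {
    mm <- yy >= 18 & yy <= 20 & xx >= (32 - template$sheet_halfwidth - 4) &
      xx <= (32 + template$sheet_halfwidth + 4)
    set_px(mm, c(0.55, 0.5, 0.45))
  }
  # the light container: floor and side walls near the frame border
  wallcol <- c(0.93, 0.93, 0.9)
  mm <- (yy >= 59 & yy <= 61) | (xx <= 3 & yy >= 30) | (xx >= 61 & yy >= 30)
  set_px(mm, wallcol)
  img
}

# Optical palette for an optical-variation seed: liquid colour, backdrop
# colour, accent colour, background luminance and rendering-noise level.
optical_palette <- function(opt_seed) {
  r <- rng_stream(opt_seed)
  hue <- r$unif(1)
  bg_lum <- 0.4 + 0.3 * r$unif(1)
  # keep a minimum luminance gap between liquid and backdrop so the liquid
  # is always visible against its background
  lv <- bg_lum + sign(r$unif(1) - 0.5) * (0.22 + 0.15 * r$unif(1))
  lv <- clamp(lv, 0.12, 0.95)
  liquid <- hsv_to_rgb(hue, 0.35 + 0.5 * r$unif(1), lv)
  bg_col <- hsv_to_rgb(r$unif(1), 0.08 + 0.25 * r$unif(1), 1)
  accent <- hsv_to_rgb(r$unif(1), 0.5 + 0.4 * r$unif(1), 0.5 + 0.4 * r$unif(1))
  list(
    liquid_col = liquid,
    bg_col = bg_col,
    accent_col = accent,
    bg_lum = bg_lum,
    noise_sd = 0.0012 + 0.0006 * r$unif(1)
  )
}

# Small deterministic RNG stream helper: isolates use of R's RNG so that
# generator calls never disturb the caller's random state.
rng_stream <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    st
  })
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- f()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  }
  list(
    unif = function(n = 1, min = 0, max = 1) with_state(function() stats::runif(n, min, max)),
    norm = function(n = 1, mean = 0, sd = 1) with_state(function() stats::rnorm(n, mean, sd)),
    int = function(n, k) with_state(function() sample.int(k, n, replace = TRUE))
  )
}

hsv_to_rgb <- function(h, s, v) {
  as.numeric(grDevices::col2rgb(grDevices::hsv(h %% 1, s, v))) / 255
}
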