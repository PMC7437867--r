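# Procedural pseudo-liquid movie generator.
#
# A 2-D particle/metaball stand-in for a fluid simulation: particles are
# emitted per scene template, integrated for 120 internal steps under gravity,
# viscosity-dependent velocity damping and cohesion, and wall collisions; the
# final 20 steps are rendered as 64 x 64 colour frames (nominally 30 fps).
# The viscosity step maps monotonically onto damping, cohesion and blob
# radius, so motion statistics decrease and cohesion increases with viscosity.

# Monotone viscosity -> dynamics mapping. The viscosity step sets a geometric
# ladder of terminal fall speeds (3.5 px/frame for the runniest liquid down to
# ~0.12 px/frame for the thickest); per-frame velocity retention is chosen so
# that gravity balances damping exactly at that speed. Cohesion and blob
# radius grow with viscosity (thicker liquids hang together).
viscosity_dynamics <- function(step, n_steps = 16) {
  u <- (step - 1) / (n_steps - 1)
  grav <- 0.12
  vt <- 1.3 * (0.12 / 1.3)^u
  list(
    retention = vt / (vt + grav),
    cohesion = 0.005 + 0.015 * u,
    radius = 2.5 + 1.2 * u,
    emit_scale = sqrt(vt / 1.3)
  )
}

#' Simulate one movie clip
#'
#' Generates the 20-frame 64 x 64 RGB clip for one cell of the factorial
#' design. The clip is cut from the end of a longer internal simulation
#' (default 120 steps), mirroring a rendering pipeline that discards the
#' transient onset. Identical spec and seed reproduce the clip bit-exactly.
#'
#' @param spec a one-row slice of a [make_design()] data frame, or a list with
#'   fields `scene_class`, `viscosity_step`, `scene_variation`,
#'   `optical_variation`, `seed`.
#' @param templates scene templates, see [scene_templates()].
#' @param scale the [viscosity_scale()] in force (its `n_steps` bounds the
#'   step index).
#' @param n_sim_steps internal simulation length (default 120; the last 20
#'   are rendered).
#' @param canonical_optics if `TRUE`, palette, luminance and noise are held at
#'   fixed canonical values (used by the reference set).
#' @return a `movie_clip`: numeric array `20 x 64 x 64 x 3` with values in
#'   `[0, 1]`.
#' @export
simulate_movie <- function(spec, templates = scene_templates(),
                           scale = viscosity_scale(), n_sim_steps = 120L,
                           canonical_optics = FALSE) {
  sc <- as.integer(spec$scene_class)
  if (sc < 1 || sc > length(templates)) stop("unknown scene class: ", sc)
  step <- as.integer(spec$viscosity_step)
  if (step < 1 || step > scale$n_steps) stop("viscosity step out of range")
  tpl <- templates[[sc]]
  dyn <- viscosity_dynamics(step, scale$n_steps)

  # scene-variation stream: emitter/geometry randomisation (viscosity-independent)
  svar_seed <- derive_seed(spec$seed, 101L, sc, spec$scene_variation)
  rs <- rng_stream(svar_seed)
  jitter_pos <- rs$unif(2, -1, 1) * c(6, 3)
  vel_mult <- 0.9 + 0.2 * rs$unif(1)
  geom_size <- 0.8 + 0.4 * rs$unif(1)
  vol_mult <- 0.9 + 0.2 * rs$unif(1)

  # optical stream: palette must not depend on the viscosity step
  if (canonical_optics) {
    pal <- list(
      liquid_col = c(0.30, 0.45, 0.80), bg_col = c(0.95, 0.93, 0.90),
      accent_col = c(0.65, 0.40, 0.30), bg_lum = 0.55, noise_sd = 0
    )
  } else {
    opt_seed <- derive_seed(spec$seed, 202L, sc, spec$scene_variation, spec$optical_variation)
    pal <- optical_palette(opt_seed)
  }
  # per-clip stream: emission jitter and rendering noise (full tuple)
  rc <- rng_stream(derive_seed(spec$seed, 303L, sc, step,
                               spec$scene_variation, spec$optical_variation))

  traj <- simulate_particles(tpl, dyn, n_sim_steps,
    jitter_pos = if (canonical_optics) c(0, 0) else jitter_pos,
    vel_mult = if (canonical_optics) 1 else vel_mult,
    vol_mult = if (canonical_optics) 1 else vol_mult,
    rng = rc
  )
  render_frames(traj, tpl, pal, dyn,
    geom_size = if (canonical_optics) 1 else geom_size,
    n_frames = 20L, rng = rc
  )
}

# Particle integration. Emission is sustained through the whole simulation so
# the rendered tail still shows viscosity-dependent motion, and particles fade
# in at birth and fade out when culled (no abrupt field changes). Returns, for
# each rendered step, the particle positions and render weights.
simulate_particles <- function(tpl, dyn, n_sim_steps, jitter_pos, vel_mult,
                               vol_mult, rng, n_frames = 20L) {
  max_p <- as.integer(tpl$max_p %||% 60L)
  pos <- matrix(numeric(0), 0, 2)
  vel <- matrix(numeric(0), 0, 2)
  fade <- numeric(0) # render weight in [0,1]
  rad <- numeric(0) # per-particle radius multiplier (stream texture)
  dying <- logical(0)
  is_blob <- logical(0) # splash blob currently in flight
  e0 <- tpl$emit_pos + jitter_pos
  pulse_phase <- rng$unif(1, 0, 2 * pi)
  grav <- 0.12
  floor_y <- 58
  out <- vector("list", n_frames)
  wts <- vector("list", n_frames)
  rds <- vector("list", n_frames)
  dip_y <- rep(NA_real_, n_frames)

  init_n <- round(tpl$n_init * vol_mult)
  if (init_n > 0) {
    # resting pool / blob initial condition
    px <- e0[1] + rng$unif(init_n, -9, 9)
    py <- e0[2] + rng$unif(init_n, -4, 4)
    pos <- cbind(px, py)
    vel <- matrix(0, init_n, 2)
    if (tpl$kind == "splash") {
      # only the resting pool; the blob is released near the rendered window
      npool <- round(tpl$n_pool * vol_mult)
      pos <- cbind(32 + rng$unif(npool, -20, 20), floor_y - rng$unif(npool, 0, 3))
      vel <- matrix(0, nrow(pos), 2)
    }
    fade <- rep(1, nrow(pos))
    rad <- 0.85 + 0.3 * rng$unif(nrow(pos))
    dying <- rep(FALSE, nrow(pos))
    is_blob <- rep(FALSE, nrow(pos))
  }

  emit_v0 <- tpl$emit_vel * vel_mult * dyn$emit_scale
  for (t in seq_len(n_sim_steps)) {
    # emission schedule
    n_new <- 0
    if (tpl$emit_rate > 0 && t >= tpl$emit_window[1] && t <= tpl$emit_window[2]) {
      rate <- tpl$emit_rate
      if (tpl$kind == "drip") {
        n_new <- if (t %% tpl$drip_period == 0) round(rate) else 0
      } else {
        # pulsed emission: travelling density waves give streams visible
        # texture (a perfectly steady stream would look static)
        rate <- rate * (0.55 + 0.9 * (0.5 + 0.5 * sin(2 * pi * t / 7 + pulse_phase)))
        n_new <- floor(rate) + (rng$unif(1) < (rate %% 1))
      }
    }
    if (tpl$kind == "splash" && t %% tpl$splash_period == 8 &&
        !any(is_blob)) { # one blob in flight at a time
      nb <- round(tpl$n_init * vol_mult)
      pos <- rbind(pos, cbind(32 + rng$unif(nb, -4, 4), tpl$emit_pos[2] + rng$unif(nb, -3, 3)))
      vel <- rbind(vel, cbind(rng$norm(nb, 0, 0.05),
                              rep(tpl$emit_vel[2] * dyn$emit_scale, nb)))
      fade <- c(fade, rep(1, nb))
      rad <- c(rad, 0.85 + 0.3 * rng$unif(nb))
      dying <- c(dying, rep(FALSE, nb))
      is_blob <- c(is_blob, rep(TRUE, nb))
    }
    if (n_new > 0) {
      if (tpl$kind == "rain") {
        nx <- rng$unif(n_new, 6, 58)
        ny <- rep(2, n_new)
      } else if (tpl$kind == "twin") {
        side <- sign(rng$unif(n_new) - 0.5)
        nx <- e0[1] + side * tpl$twin_offset + rng$unif(n_new, -1.5, 1.5)
        ny <- e0[2] + rng$unif(n_new, -1.5, 1.5)
      } else if (tpl$kind == "sheet") {
        nx <- e0[1] + rng$unif(n_new, -tpl$sheet_halfwidth, tpl$sheet_halfwidth)
        ny <- rep(e0[2], n_new)
      } else if (tpl$kind == "dipdrain") {
        nx <- e0[1] + rng$unif(n_new, -tpl$dip_width / 2, tpl$dip_width / 2)
        ny <- e0[2] + rng$unif(n_new, -1, 1)
      } else {
        nx <- e0[1] + rng$unif(n_new, -1.5, 1.5)
        ny <- e0[2] + rng$unif(n_new, -1.5, 1.5)
      }
      nv <- matrix(rep(emit_v0, each = n_new), n_new, 2)
      if (tpl$kind %in% c("spray", "fountain")) {
        ang <- rng$unif(n_new, -tpl$spread, tpl$spread)
        sp <- sqrt(sum(emit_v0^2)) * (0.7 + 0.6 * rng$unif(n_new))
        base_ang <- atan2(emit_v0[2], emit_v0[1])
        nv <- cbind(sp * cos(base_ang + ang), sp * sin(base_ang + ang))
      } else {
        nv <- nv + matrix(rng$norm(2 * n_new, 0, 0.08), n_new, 2)
      }
      pos <- rbind(pos, cbind(nx, ny))
      vel <- rbind(vel, nv)
      fade <- c(fade, rep(0, n_new))
      rad <- c(rad, 0.85 + 0.3 * rng$unif(n_new))
      dying <- c(dying, rep(FALSE, n_new))
      is_blob <- c(is_blob, rep(FALSE, n_new))
    }
    # cull: mark the oldest surplus particles as dying (gradual drainage)
    alive <- sum(!dying)
    if (alive > max_p) {
      surplus <- which(!dying)[seq_len(alive - max_p)]
      dying[surplus] <- TRUE
    }
    fade[!dying] <- pmin(1, fade[!dying] + 1 / 6)
    fade[dying] <- fade[dying] - 1 / 16
    keep <- fade > 0
    if (!all(keep)) {
      pos <- pos[keep, , drop = FALSE]
      vel <- vel[keep, , drop = FALSE]
      fade <- fade[keep]
      rad <- rad[keep]
      dying <- dying[keep]
      is_blob <- is_blob[keep]
    }
    if (any(is_blob)) is_blob[is_blob & pos[, 2] > 52] <- FALSE # landed
    n <- nrow(pos)
    if (n > 0) {
      vel[, 2] <- vel[, 2] + grav
      # steady rotational stirring forcing
      if (tpl$kind == "stir") {
        omega <- tpl$stir_omega
        dx <- pos[, 1] - 32
        dy <- pos[, 2] - 50
        vel[, 1] <- vel[, 1] - omega * dy * 0.12
        vel[, 2] <- vel[, 2] + omega * dx * 0.12
      }
      # cohesion toward the local (neighbourhood) centre of mass; a global
      # pull would drag separated clusters through space toward each other
      if (n > 1) {
        dx <- outer(pos[, 1], pos[, 1], "-")
        dy <- outer(pos[, 2], pos[, 2], "-")
        nb <- (dx * dx + dy * dy) < 100 # neighbours within 10 px
        cnt <- rowSums(nb)
        cmx <- (nb %*% pos[, 1]) / cnt
        cmy <- (nb %*% pos[, 2]) / cnt
        vel <- vel + dyn$cohesion * cbind(cmx - pos[, 1], cmy - pos[, 2])
      }
      # viscosity damping
      vel <- vel * dyn$retention
      # speed clamp (numerical guard; also keeps flow in the trackable range)
      sp <- sqrt(rowSums(vel^2))
      f <- pmin(1, 2.5 / pmax(sp, 1e-9))
      vel <- vel * f
      pos <- pos + vel
      # wall and floor collisions (restitution shrinks with viscosity)
      rest <- 0.25 * dyn$retention
      blo <- pos[, 2] > floor_y
      vel[blo, 2] <- -abs(vel[blo, 2]) * rest
      pos[blo, 2] <- floor_y - (pos[blo, 2] - floor_y) * 0.5
      bl <- pos[, 1] < 3
      vel[bl, 1] <- abs(vel[bl, 1]) * rest
      pos[bl, 1] <- 3 + (3 - pos[bl, 1]) * 0.5
      br <- pos[, 1] > 61
      vel[br, 1] <- -abs(vel[br, 1]) * rest
      pos[br, 1] <- 61 - (pos[br, 1] - 61) * 0.5
      bt <- pos[, 2] < -12
      pos[bt, 2] <- -12
      vel[bt, 2] <- pmax(vel[bt, 2], 0)
    }
    fidx <- t - (n_sim_steps - n_frames)
    if (fidx >= 1) {
      out[[fidx]] <- pos
      wts[[fidx]] <- fade
      rds[[fidx]] <- rad
    }
  }
  list(frames = out, weights = wts, radii = rds, dip_y = dip_y,
       rod_x = if (tpl$kind == "dipdrain") e0[1] else NA_real_)
}

# Metaball rendering of particle frames over the scene backdrop.
render_frames <- function(traj, tpl, pal, dyn, geom_size, n_frames, rng) {
  bg <- scene_backdrop(tpl, pal, geom_size)
  clip <- array(0, c(n_frames, 64, 64, 3))
  sdv <- dyn$radius / 1.6 * (tpl$radius_mult %||% 1)
  hw <- ceiling(3 * sdv) # truncated splat window half-width
  for (f in seq_len(n_frames)) {
    pos <- traj$frames[[f]]
    wt <- traj$weights[[f]]
    rd <- traj$radii[[f]]
    field <- matrix(0, 64, 64)
    if (!is.null(pos) && nrow(pos) > 0) {
      for (i in seq_len(nrow(pos))) {
        si <- sdv * rd[i]
        x0 <- max(1, floor(pos[i, 1]) - hw)
        x1 <- min(64, ceiling(pos[i, 1]) + hw)
        y0 <- max(1, floor(pos[i, 2]) - hw)
        y1 <- min(64, ceiling(pos[i, 2]) + hw)
        if (x1 < x0 || y1 < y0) next
        xs <- x0:x1
        ys <- y0:y1
        dxe <- exp(-((xs - pos[i, 1])^2) / (2 * si^2))
        dye <- exp(-((ys - pos[i, 2])^2) / (2 * si^2))
        field[ys, xs] <- field[ys, xs] + wt[i] * outer(dye, dxe)
      }
    }
    alpha <- 1 - exp(-1.3 * field)
    shade <- 0.72 + 0.28 * tanh(field - 0.8)
    fr <- bg
    for (k in 1:3) {
      fr[, , k] <- fr[, , k] * (1 - alpha) + alpha * pal$liquid_col[k] * shade
    }
    if (is.finite(traj$rod_x)) {
      # the withdrawn dipper: a static rod the liquid drains off
      x0 <- max(1, round(traj$rod_x - tpl$dip_width / 2))
      x1 <- min(64, round(traj$rod_x + tpl$dip_width / 2))
      for (k in 1:3) fr[6:30, x0:x1, k] <- c(0.25, 0.25, 0.3)[k]
    }
    if (pal$noise_sd > 0) {
      fr <- fr + array(rng$norm(64 * 64 * 3, 0, pal$noise_sd), c(64, 64, 3))
    }
    clip[f, , , ] <- clamp(fr, 0, 1)
  }
  structure(clip, class = "movie_clip")
}

#' @export
print.movie_clip <- function(x, ...) {
  cat(sprintf("Movie clip: %d frames, %d x %d px, %d channels, values in [%.3f, %.3f]\n",
              dim(x)[1], dim(x)[2], dim(x)[3], dim(x)[4], min(x), max(x)))
  invisible(x)
}
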