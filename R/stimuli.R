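#' Stimulus sequences on a hexagonal lattice
#'
#' A stimulus is a time-by-column matrix of luminance values in `[0, 1]`
#' together with the frame interval and the lattice the columns live on.
#' Luminance 0.5 is "grey" (the background of all protocols).
#'
#' @param frames Numeric matrix, time (rows) by lattice column (columns).
#' @param frame_dt Frame interval, ms.
#' @param lattice The [hex_lattice()] the columns are ordered by.
#' @param meta Optional list of protocol metadata.
#' @return An object of class `"stimulus_sequence"`.
#' @export
stimulus_sequence <- function(frames, frame_dt, lattice, meta = list()) {
  stopifnot(inherits(lattice, "hex_lattice"), frame_dt > 0)
  frames <- as.matrix(frames)
  if (ncol(frames) != lattice$n)
    stop("frame width (", ncol(frames), ") does not match lattice size (",
         lattice$n, ")")
  structure(list(frames = frames, frame_dt = frame_dt, lattice = lattice,
                 meta = meta),
            class = "stimulus_sequence")
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat(sprintf("<stimulus_sequence> %d frames x %d columns, %g ms/frame\n",
              nrow(x$frames), ncol(x$frames), x$frame_dt))
  invisible(x)
}

#' Duration spanned by a frame sequence
#'
#' @param n_frames Number of frames.
#' @param rate_hz Frame rate in Hz.
#' @return Duration in ms. 19 frames at the 24 Hz film rate span 792 ms
#'   (rounded to the millisecond).
#' @export
sequence_duration_ms <- function(n_frames, rate_hz) {
  n_frames * 1000 / rate_hz
}

#' Render Cartesian video onto the fly eye
#'
#' Places the lattice columns in pixel space (centred on the frame,
#' `spacing` pixels between neighbouring columns) and reads each column's
#' luminance as the greyscale mean of the `kernel x kernel` pixel box around
#' its position. The standard calibration is 13 pixels spacing with a 13 x 13
#' mean box.
#'
#' @param video Numeric array `height x width x frames` (or a single matrix)
#'   of greyscale values in `[0, 1]`.
#' @param lattice A [hex_lattice()].
#' @param frame_dt Frame interval of the video, ms.
#' @param spacing Pixel distance between neighbouring columns.
#' @param kernel Side length of the averaging box, pixels (odd).
#' @return A [stimulus_sequence()].
#' @export
render_fly_eye <- function(video, lattice, frame_dt, spacing = 13, kernel = 13) {
  if (is.matrix(video)) video <- array(video, c(dim(video), 1L))
  stopifnot(length(dim(video)) == 3L, kernel %% 2 == 1)
  h <- dim(video)[1L]; w <- dim(video)[2L]; nf <- dim(video)[3L]
  xy <- hex_to_cartesian(lattice$u, lattice$v, spacing)
  # image rows grow downwards; centre the array on the frame
  px <- round((w + 1) / 2 + xy[, 1L])
  py <- round((h + 1) / 2 - xy[, 2L])
  half <- (kernel - 1) / 2
  if (any(px - half < 1 | px + half > w | py - half < 1 | py + half > h))
    stop("hexagonal array (plus averaging box) exceeds the frame bounds")
  frames <- matrix(NA_real_, nf, lattice$n)
  for (f in seq_len(nf)) {
    im <- video[, , f]
    for (c in seq_len(lattice$n)) {
      frames[f, c] <- mean(im[(py[c] - half):(py[c] + half),
                              (px[c] - half):(px[c] + half)])
    }
  }
  stimulus_sequence(pmin(pmax(frames, 0), 1), frame_dt, lattice,
                    meta = list(protocol = "fly_eye", spacing = spacing,
                                kernel = kernel))
}

#' Circular flash protocol
#'
#' One second of grey followed by a one-second ON (`intensity = 1`) or OFF
#' (`intensity = 0`) disc of the given column radius on a grey background,
#' sampled at a 5 ms step. Used to probe contrast preference (flash response
#' index).
#'
#' @param lattice A [hex_lattice()].
#' @param intensity Flash luminance (0 or 1; 0.5 reproduces plain grey).
#' @param radius Disc radius in columns (default 6, i.e. 127 columns).
#' @param warmup,flash Durations, ms.
#' @param dt Frame interval, ms.
#' @return A [stimulus_sequence()].
#' @export
circular_flash <- function(lattice, intensity, radius = 6, warmup = 1000,
                           flash = 1000, dt = 5) {
  if (radius > lattice$radius) stop("flash radius exceeds lattice radius")
  n_warm <- round(warmup / dt); n_flash <- round(flash / dt)
  inside <- hex_distance(lattice$u, lattice$v) <= radius
  frames <- matrix(0.5, n_warm + n_flash, lattice$n)
  frames[(n_warm + 1):(n_warm + n_flash), inside] <- intensity
  stimulus_sequence(frames, dt, lattice,
                    meta = list(protocol = "circular_flash",
                                intensity = intensity, radius = radius))
}

#' Moving-edge protocol
#'
#' A half-plane edge of the given intensity advances over a grey background
#' along direction `theta` (degrees, counter-clockwise from the +x lattice
#' axis) at `speed` degrees of visual angle per second. The edge front moves
#' from `-extent` to `+extent` visual degrees; columns are `column_pitch`
#' degrees apart (single-column angular radius 5.8 degrees). The standard
#' direction set is 0 to 330 in steps of 30; the standard speeds are
#' 13.92, 27.84, 56.26, 75.4, 110.2, 145 deg/s.
#'
#' @param lattice A [hex_lattice()].
#' @param theta Motion direction, degrees.
#' @param speed Angular speed, degrees/s.
#' @param intensity Edge luminance (1 = ON, 0 = OFF).
#' @param extent Half-range of the edge front, visual degrees.
#' @param column_pitch Angular distance between neighbouring columns, degrees.
#' @param dt Frame interval, ms.
#' @return A [stimulus_sequence()].
#' @export
moving_edge <- function(lattice, theta, speed, intensity, extent = 13.5,
                        column_pitch = 5.8, dt = 5) {
  stopifnot(speed > 0)
  xy <- hex_to_cartesian(lattice$u, lattice$v, column_pitch)
  th <- theta * pi / 180
  proj <- xy[, 1L] * cos(th) + xy[, 2L] * sin(th)
  duration <- 2 * extent / speed * 1000    # ms
  n_frames <- ceiling(duration / dt)
  frames <- matrix(0.5, n_frames, lattice$n)
  for (f in seq_len(n_frames)) {
    pos <- -extent + speed * (f * dt) / 1000
    frames[f, proj <= pos] <- intensity
  }
  stimulus_sequence(frames, dt, lattice,
                    meta = list(protocol = "moving_edge", theta = theta,
                                speed = speed, intensity = intensity))
}

#' Standard moving-edge directions (degrees)
#' @export
edge_directions <- function() seq(0, 330, by = 30)

#' Standard moving-edge speeds (degrees/s)
#' @export
edge_speeds <- function() c(13.92, 27.84, 56.26, 75.4, 110.2, 145.0)

#' Single-ommatidium flash protocol
#'
#' Only the target column deviates from grey: 2 s of grey, then a flash of
#' the given intensity and duration, then 5 s of grey. Flash durations of
#' 5, 20, 50, 100, 200 and 300 ms are the standard set; receptive fields use
#' the 20 ms flash.
#'
#' @param lattice A [hex_lattice()].
#' @param u,v Axial coordinates of the target column.
#' @param intensity Flash luminance (1 = ON, 0 = OFF).
#' @param duration Flash duration, ms.
#' @param pre,post Grey durations before/after the flash, ms.
#' @param dt Frame interval, ms.
#' @return A [stimulus_sequence()].
#' @export
ommatidium_flash <- function(lattice, u, v, intensity, duration = 20,
                             pre = 2000, post = 5000, dt = 5) {
  target <- hex_index(lattice, u, v)
  if (is.na(target)) stop("target column (", u, ", ", v, ") is outside the lattice")
  n_pre <- round(pre / dt); n_on <- round(duration / dt); n_post <- round(post / dt)
  frames <- matrix(0.5, n_pre + n_on + n_post, lattice$n)
  if (n_on > 0) frames[(n_pre + 1):(n_pre + n_on), target] <- intensity
  stimulus_sequence(frames, dt, lattice,
                    meta = list(protocol = "ommatidium_flash", u = u, v = v,
                                intensity = intensity, duration = duration))
}

#' Augmentation configuration
#'
#' Training-time augmentation: random flips across one of the three principal
#' lattice axes and random rotation about the six-fold axis; element-wise
#' Gaussian pixel noise (standard deviation `noise_sd`) clamped at 0; and a
#' contrast/brightness jitter `X' = c (X - 0.5) + 0.5 + c b` with
#' `log c ~ N(0, contrast_var)` and `b ~ N(0, brightness_var)`.
#'
#' @param noise_sd Pixel-noise standard deviation (default 0.08).
#' @param contrast_var Variance of `log c` (default 0.04).
#' @param brightness_var Variance of `b` (default 0.01).
#' @param flip,rotate Logical: apply the geometric components?
#' @return A list of class `"augmentation_config"`.
#' @export
augmentation_config <- function(noise_sd = 0.08, contrast_var = 0.04,
                                brightness_var = 0.01, flip = TRUE,
                                rotate = TRUE) {
  stopifnot(noise_sd >= 0, contrast_var >= 0, brightness_var >= 0)
  structure(list(noise_sd = noise_sd, contrast_var = contrast_var,
                 brightness_var = brightness_var, flip = flip, rotate = rotate),
            class = "augmentation_config")
}

# column permutation realizing a lattice symmetry: entry c gives the source
# column whose value moves to column c
symmetry_permutation <- function(lattice, k = 0L, axis = NA) {
  u <- lattice$u; v <- lattice$v
  # invert: rotation by -k, then (self-inverse) flip
  src <- hex_rotate(u, v, -k)
  if (!is.na(axis)) src <- hex_flip(src$u, src$v, axis)
  hex_index(lattice, src$u, src$v)
}

#' Augment a stimulus sequence
#'
#' Applies, in order: a random lattice symmetry (rotation, optionally a
#' flip), pixel noise clamped at 0, and the contrast/brightness jitter.
#' Deterministic under `seed`. The sampled geometric transform is attached as
#' attribute `"transform"` (`k`, `axis`) so that paired targets (e.g. optic
#' flow) can be transformed consistently via [transform_flow()].
#'
#' @param stim A [stimulus_sequence()].
#' @param cfg An [augmentation_config()].
#' @param seed Integer RNG seed.
#' @return The augmented [stimulus_sequence()].
#' @export
augment_stimulus <- function(stim, cfg = augmentation_config(), seed = 1L) {
  stopifnot(inherits(stim, "stimulus_sequence"),
            inherits(cfg, "augmentation_config"))
  withr::with_seed(seed, {
    k <- if (cfg$rotate) sample(0:5, 1L) else 0L
    axis <- if (cfg$flip && stats::runif(1) < 0.5) sample(0:2, 1L) else NA
    X <- stim$frames
    if (k != 0L || !is.na(axis)) {
      perm <- symmetry_permutation(stim$lattice, k, axis)
      X <- X[, perm, drop = FALSE]
    }
    if (cfg$noise_sd > 0)
      X <- pmax(X + matrix(stats::rnorm(length(X), 0, cfg$noise_sd), nrow(X)), 0)
    cc <- exp(stats::rnorm(1, 0, sqrt(cfg$contrast_var)))
    b <- stats::rnorm(1, 0, sqrt(cfg$brightness_var))
    X <- cc * (X - 0.5) + 0.5 + cc * b
    out <- stimulus_sequence(X, stim$frame_dt, stim$lattice, meta = stim$meta)
    attr(out, "transform") <- list(k = k, axis = axis, contrast = cc, brightness = b)
    out
  })
}

#' Transform flow vectors under a lattice symmetry
#'
#' Rotates/reflects per-column 2-D flow targets consistently with the column
#' permutation applied by [augment_stimulus()]: vectors are rotated by
#' `k * 60` degrees after an optional reflection across principal axis
#' `axis`, and the columns are permuted by the same symmetry.
#'
#' @param flow Array `time x 2 x columns`.
#' @param lattice The [hex_lattice()].
#' @param k Rotation steps (0..5).
#' @param axis Flip axis (0, 1, 2) or `NA` for none.
#' @return The transformed flow array.
#' @export
transform_flow <- function(flow, lattice, k = 0L, axis = NA) {
  stopifnot(length(dim(flow)) == 3L, dim(flow)[2L] == 2L)
  perm <- symmetry_permutation(lattice, k, axis)
  out <- flow[, , perm, drop = FALSE]
  M <- diag(2)
  if (!is.na(axis)) {                    # reflection across line at angle axis*60
    a <- axis * pi / 3
    M <- matrix(c(cos(2 * a), sin(2 * a), sin(2 * a), -cos(2 * a)), 2, 2) %*% M
  }
  th <- k * pi / 3
  M <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) %*% M
  for (n in seq_len(dim(out)[1L]))
    out[n, , ] <- M %*% out[n, , ]
  out
}
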