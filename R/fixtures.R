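#' Toy connectome with a designed motion-detector motif
#'
#' Builds a four-type connectome whose detector cell is direction selective
#' by construction, mirroring the elementary fly motion-detector logic of
#' fast central excitation paired with slower, spatially offset inhibition:
#' a photoreceptor type `R1` (full coverage) drives a fast excitatory relay
#' `FastE` and a slow inhibitory relay `SlowI` in the same column; the
#' detector `Det` receives `FastE` input from its own column and `SlowI`
#' input from the column displaced by one step along the +x lattice axis.
#' Motion along +x (direction 0 degrees) reaches the detector's excitatory
#' centre before the inhibitory flank, so the delayed inhibition arrives too
#' late to cancel the excitatory transient; motion along 180 degrees is
#' suppressed. `mirror = TRUE` places the flank on the opposite side,
#' flipping the preferred direction by 180 degrees.
#'
#' @param radius Lattice radius for the coverage tables (default 6).
#' @param delay_ratio Ratio of the slow to the fast relay time constant
#'   (must exceed 1; default 4).
#' @param mirror Mirror the inhibitory flank (flips the preferred direction).
#' @param inhibition If `FALSE`, the inhibitory relay is disconnected from
#'   the detector (ablation control: the detector loses its selectivity).
#' @param seed Unused; the fixture is fully deterministic. Kept so all
#'   fixture generators share one signature.
#' @return List with `spec` (a [connectome_spec()]), `params` (a
#'   `"dmn_params"` set operating in the positive, linear regime), and
#'   `meta` (ground-truth `preferred_direction` in degrees, the `detector`
#'   type, and the designed `symmetric_types`).
#' @export
make_motion_motif <- function(radius = 6, delay_ratio = 4, mirror = FALSE,
                              inhibition = TRUE, seed = 1L) {
  if (delay_ratio <= 1) stop("'delay_ratio' must exceed 1")
  lat <- hex_lattice(radius)
  tn <- c("R1", "FastE", "SlowI", "Det")
  coverage <- data.frame(type = rep(tn, each = lat$n),
                         u = rep(lat$u, length(tn)),
                         v = rep(lat$v, length(tn)))
  # offset of the inhibitory flank: SlowI source column at +x of the detector
  flank_du <- if (mirror) 1L else -1L     # du = u_post - u_pre
  filters <- data.frame(
    pre_type = c("R1", "R1", "FastE", "SlowI"),
    post_type = c("FastE", "SlowI", "Det", "Det"),
    du = c(0L, 0L, 0L, flank_du),
    dv = 0L,
    count = 1,
    stringsAsFactors = FALSE)
  signs <- data.frame(
    pre_type = filters$pre_type, post_type = filters$post_type,
    sign = c(1, 1, 1, -1))
  if (!inhibition) {
    keep <- !(filters$pre_type == "SlowI" & filters$post_type == "Det")
    filters <- filters[keep, ]
    signs <- signs[keep, ]
  }
  spec <- connectome_spec(data.frame(name = tn), coverage, filters, signs,
                          input_types = "R1")
  tau_fast <- 15
  tau <- stats::setNames(c(10, tau_fast, delay_ratio * tau_fast, tau_fast), tn)
  v_rest <- stats::setNames(c(0, 0, 0, 0.5), tn)
  alpha <- rep(1, nrow(spec$pairs))
  params <- structure(list(tau = tau, v_rest = v_rest, alpha = alpha),
                      class = "dmn_params")
  list(spec = spec, params = params,
       meta = list(preferred_direction = if (mirror) 180 else 0,
                   detector = "Det", symmetric_types = c("FastE", "SlowI"),
                   input_type = "R1"))
}

#' Drifting-pattern optic-flow dataset
#'
#' Generates rigidly drifting smooth luminance patterns on a hexagonal
#' lattice with analytically exact flow targets: each sequence is a random
#' sum of sinusoidal plaids translated at a constant velocity, and the flow
#' target equals that velocity at every column and frame, expressed in the
#' standard optic-flow convention of displacement per frame (column units,
#' Cartesian components). Sequences are whole scenes; train/validation
#' splits never share a scene.
#'
#' @param n_sequences Number of sequences (at least 1).
#' @param radius Lattice radius (default 6).
#' @param speeds Range of drift speeds to sample, columns/s; a scalar pins
#'   the speed (0 gives static scenes with zero flow).
#' @param n_frames Frames per sequence (default 19).
#' @param frame_dt Frame interval, ms (default 20, i.e. 50 Hz).
#' @param val_fraction Fraction of sequences held out for validation.
#' @param seed Integer RNG seed; the dataset is a pure function of it.
#' @return List of class `"drifting_dataset"`: `sequences` (each with
#'   `frames` time-by-column in `[0, 1]`, `flow` time x 2 x column in
#'   columns/frame, and `velocity` in columns/s), `train`, `val` (index
#'   vectors), `lattice`, `frame_dt`.
#' @export
make_drifting_dataset <- function(n_sequences, radius = 6, speeds = c(2, 8),
                                  n_frames = 19, frame_dt = 20,
                                  val_fraction = 0.25, seed = 1L) {
  if (n_sequences < 1) stop("'n_sequences' must be at least 1")
  lat <- hex_lattice(radius)
  xy <- hex_to_cartesian(lat$u, lat$v)
  withr::with_seed(seed, {
    sequences <- lapply(seq_len(n_sequences), function(s) {
      speed <- if (length(speeds) == 1L) speeds else stats::runif(1, speeds[1L], speeds[2L])
      ang <- stats::runif(1, 0, 2 * pi)
      vel <- speed * c(cos(ang), sin(ang))          # columns / s
      # random plaid: 3 sinusoidal components, wavelengths 2-6 columns
      nc <- 3L
      wl <- stats::runif(nc, 2, 6)
      ka <- stats::runif(nc, 0, 2 * pi)
      ph <- stats::runif(nc, 0, 2 * pi)
      am <- stats::runif(nc, 0.05, 0.15)
      frames <- matrix(0.5, n_frames, lat$n)
      flow <- array(0, c(n_frames, 2L, lat$n))
      for (n in seq_len(n_frames)) {
        t_s <- (n - 1L) * frame_dt / 1000
        p <- cbind(xy[, 1L] - vel[1L] * t_s, xy[, 2L] - vel[2L] * t_s)
        lum <- 0.5
        for (m in seq_len(nc)) {
          k <- (2 * pi / wl[m]) * c(cos(ka[m]), sin(ka[m]))
          lum <- lum + am[m] * sin(p %*% k + ph[m])
        }
        frames[n, ] <- pmin(pmax(lum, 0), 1)
        flow[n, 1L, ] <- vel[1L] * frame_dt / 1000   # columns per frame
        flow[n, 2L, ] <- vel[2L] * frame_dt / 1000
      }
      list(frames = frames, flow = flow, velocity = vel)
    })
    n_val <- max(if (n_sequences > 1L) 1L else 0L,
                 floor(val_fraction * n_sequences))
    val <- if (n_val > 0L) sort(sample.int(n_sequences, n_val)) else integer(0)
    structure(list(sequences = sequences,
                   train = setdiff(seq_len(n_sequences), val), val = val,
                   lattice = lat, frame_dt = frame_dt),
              class = "drifting_dataset")
  })
}

# smooth a matrix with a small separable Gaussian kernel (clamped edges)
gaussian_smooth <- function(m, sd = 1.5, half = 3L) {
  k <- stats::dnorm(seq.int(-half, half), sd = sd)
  k <- k / sum(k)
  sm1 <- function(x) {            # smooth columns of x
    n <- nrow(x)
    out <- 0 * x
    for (j in seq.int(-half, half)) {
      idx <- pmin(pmax(seq_len(n) + j, 1L), n)
      out <- out + k[j + half + 1L] * x[idx, , drop = FALSE]
    }
    out
  }
  t(sm1(t(sm1(m))))
}

#' Synthetic ten-class digit-style classification task
#'
#' A stand-in for a handwritten-digit task that needs no download: ten fixed
#' sparse "stroke" templates (the positive part of a smooth random field,
#' normalized to peak 1, so most of the background is exactly zero as in
#' handwritten-digit images), translated by a random per-sample integer
#' shift of up to `max_shift` pixels (emulating the within-class variability
#' of handwriting) plus i.i.d. Gaussian pixel noise, clipped to the
#' luminance range `[0, 1]` so images can be fed to rectified units
#' unchanged. With zero noise and no jitter a nearest-template classifier is
#' perfect; at the default corruption a dense network baseline exceeds 90%
#' held-out accuracy. Class balance is exact.
#'
#' @param n_train,n_test Numbers of training and test images (multiples of
#'   10, at least 100).
#' @param noise_sd Pixel noise standard deviation (default 0.3).
#' @param max_shift Maximal per-sample translation, pixels (default 2).
#' @param side Image side length (default 28).
#' @param seed Integer RNG seed.
#' @return List of class `"digit_task"`: `x_train`, `x_test` (images in
#'   rows), `y_train`, `y_test` (labels 0-9), `templates` (10 x pixels).
#' @export
make_digit_task <- function(n_train, n_test, noise_sd = 0.3, max_shift = 2L,
                            side = 28L, seed = 1L) {
  if (n_train %% 10 != 0 || n_test %% 10 != 0 || n_train < 100 || n_test < 100)
    stop("'n_train' and 'n_test' must be multiples of 10, at least 100")
  withr::with_seed(seed, {
    d <- side * side
    raw_templates <- t(vapply(1:10, function(k) {
      m <- rectify(gaussian_smooth(matrix(stats::rnorm(d), side, side)))
      as.numeric(m / max(m))
    }, numeric(d)))
    to_lum <- function(x) pmin(pmax(x, 0), 1)
    shift_img <- function(v, dx, dy) {
      m <- matrix(v, side, side)
      out <- matrix(0, side, side)
      rs <- seq_len(side) - dy; cs <- seq_len(side) - dx
      ok_r <- rs >= 1 & rs <= side; ok_c <- cs >= 1 & cs <= side
      out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
      as.numeric(out)
    }
    make_split <- function(n) {
      y <- rep(0:9, each = n / 10L)
      x <- raw_templates[y + 1L, , drop = FALSE]
      if (max_shift > 0) {
        dx <- sample.int(2L * max_shift + 1L, n, replace = TRUE) - max_shift - 1L
        dy <- sample.int(2L * max_shift + 1L, n, replace = TRUE) - max_shift - 1L
        for (i in seq_len(n)) x[i, ] <- shift_img(x[i, ], dx[i], dy[i])
      }
      x <- to_lum(x + matrix(stats::rnorm(n * d, 0, noise_sd), n, d))
      perm <- sample.int(n)
      list(x = x[perm, , drop = FALSE], y = y[perm])
    }
    tr <- make_split(n_train)
    te <- make_split(n_test)
    structure(list(x_train = tr$x, y_train = tr$y,
                   x_test = te$x, y_test = te$y,
                   templates = to_lum(raw_templates)),
              class = "digit_task")
  })
}
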