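#' Central cells of an assembled network
#'
#' The tuning statistics are computed on the cell of each type sitting in the
#' central column (the origin of the lattice), the model analogue of a
#' recorded neuron.
#'
#' @param net An [tile_network()] result.
#' @param types Character vector of types (default: all types with a central
#'   cell).
#' @return Data frame with columns `type` and `id`.
#' @export
central_cells <- function(net, types = NULL) {
  nn <- net$neurons
  ctr <- nn[nn$u == 0L & nn$v == 0L, , drop = FALSE]
  if (!is.null(types)) ctr <- ctr[ctr$type %in% types, , drop = FALSE]
  data.frame(type = ctr$type, id = ctr$id, stringsAsFactors = FALSE)
}

#' Flash response index
#'
#' Contrast preference from circular-flash responses: with the non-negative
#' peak activity `r_peak(I) = max_n V[n](I) + |min over n and both I of V|`,
#' `FRI = (r_peak(1) - r_peak(0)) / (r_peak(1) + r_peak(0))`. Positive values
#' indicate ON-preferring (depolarizes more to light increments), negative
#' OFF-preferring. If both peaks are zero the index is undefined and `NA` is
#' returned with attribute `"undefined"` set.
#'
#' @param trace_on,trace_off Numeric vectors (or time-by-cell matrices) of
#'   voltage responses of the same cell(s) to the ON and OFF flash protocol.
#' @return Numeric FRI value(s) in `[-1, 1]`, `NA` where undefined.
#' @export
flash_response_index <- function(trace_on, trace_off) {
  trace_on <- as.matrix(trace_on); trace_off <- as.matrix(trace_off)
  stopifnot(ncol(trace_on) == ncol(trace_off))
  offset <- abs(pmin(apply(trace_on, 2L, min), apply(trace_off, 2L, min), 0))
  r1 <- apply(trace_on, 2L, max) + offset
  r0 <- apply(trace_off, 2L, max) + offset
  undef <- (r1 + r0) == 0
  out <- ifelse(undef, NA_real_, (r1 - r0) / (r1 + r0))
  attr(out, "undefined") <- undef
  out
}

#' Run the circular-flash protocol and compute FRIs
#'
#' Simulates ON and OFF circular flashes (grey steady-state initialization,
#' 1 s grey then 1 s flash, radius 6 columns, 5 ms step) and returns the FRI
#' of each type's central cell.
#'
#' @param net,params Assembled network and parameter set.
#' @param types Types to report (default: all with a central cell).
#' @param radius Flash radius, columns.
#' @param dt Integration step, ms.
#' @return Data frame with `type`, `fri`.
#' @export
fri_protocol <- function(net, params, types = NULL, radius = 6, dt = 5) {
  ctr <- central_cells(net, types)
  compiled <- compile_network(net, params)
  init <- steady_state(net, params, duration = 500, dt = dt, compiled = compiled)
  tr <- lapply(c(on = 1, off = 0), function(I) {
    stim <- circular_flash(net$lattice, I, radius = radius, dt = dt)
    simulate_network(net, params, stim, dt = dt, record = ctr$id,
                     init = init, compiled = compiled)$V
  })
  fri <- flash_response_index(tr$on, tr$off)
  data.frame(type = ctr$type, fri = as.numeric(fri), stringsAsFactors = FALSE)
}

#' Peak responses to moving edges
#'
#' Simulates the moving-edge protocol over directions, speeds and intensities
#' and records the rectified peak voltage (`max_n f(V[n])`) of each requested
#' cell. This is the input to the DSI and to the permutation null.
#'
#' @param net,params Assembled network and parameter set.
#' @param ids Neuron ids to record (e.g. from [central_cells()]).
#' @param directions Motion directions, degrees.
#' @param speeds Angular speeds, degrees/s.
#' @param intensities Edge intensities.
#' @param dt Integration step, ms.
#' @param ... Passed to [moving_edge()].
#' @return Numeric array `cell x direction x speed x intensity` with dimnames.
#' @export
moving_edge_peaks <- function(net, params, ids,
                              directions = edge_directions(),
                              speeds = edge_speeds(),
                              intensities = c(0, 1), dt = 5, ...) {
  compiled <- compile_network(net, params)
  init <- steady_state(net, params, duration = 1000, dt = dt, compiled = compiled)
  out <- array(NA_real_,
               c(length(ids), length(directions), length(speeds), length(intensities)),
               dimnames = list(NULL, directions, speeds, intensities))
  for (ii in seq_along(intensities)) for (si in seq_along(speeds))
    for (di in seq_along(directions)) {
      stim <- moving_edge(net$lattice, directions[di], speeds[si],
                          intensities[ii], dt = dt, ...)
      tr <- simulate_network(net, params, stim, dt = dt, record = ids,
                             init = init, compiled = compiled)
      out[, di, si, ii] <- apply(rectify(tr$V), 2L, max)
    }
  out
}

#' Direction selectivity index
#'
#' For one cell, from rectified peak responses `r(I, S, theta)` to edges
#' moving in directions `Theta`: per intensity,
#' `DSI(I) = (1/|S|) sum_S |sum_theta r(I,S,theta) exp(i theta)| /
#' max_{I'} |sum_theta r(I',S,theta)|`. The vector sum cancels for
#' direction-symmetric tuning and reaches 1 for a response concentrated at a
#' single direction of the dominant intensity. Speeds at which the
#' denominator vanishes are skipped (with a warning) and the speed average is
#' taken over the remaining speeds.
#'
#' @param peaks Numeric array `direction x speed x intensity` of rectified
#'   peak responses (e.g. one cell's slice of [moving_edge_peaks()]).
#' @param directions Motion directions, degrees (default: dimnames).
#' @return Named numeric vector, one DSI per intensity.
#' @export
dsi <- function(peaks, directions = NULL) {
  stopifnot(length(dim(peaks)) == 3L)
  if (is.null(directions)) directions <- as.numeric(dimnames(peaks)[[1L]])
  stopifnot(length(directions) == dim(peaks)[1L])
  ph <- exp(1i * directions * pi / 180)
  n_speed <- dim(peaks)[2L]; n_int <- dim(peaks)[3L]
  vs <- matrix(NA_real_, n_speed, n_int)    # |vector sum| per speed, intensity
  tot <- matrix(NA_real_, n_speed, n_int)   # |plain sum|
  for (s in seq_len(n_speed)) for (i in seq_len(n_int)) {
    r <- peaks[, s, i]
    vs[s, i] <- Mod(sum(r * ph))
    tot[s, i] <- Mod(sum(r))
  }
  denom <- apply(tot, 1L, max)
  ok <- denom > 0
  if (!any(ok)) {
    warning("all speeds have zero total response; DSI undefined")
    return(stats::setNames(rep(NA_real_, n_int), dimnames(peaks)[[3L]]))
  }
  if (!all(ok)) warning(sum(!ok), " speed(s) with zero total response skipped")
  out <- colSums(vs[ok, , drop = FALSE] / denom[ok]) / sum(ok)
  stats::setNames(out, dimnames(peaks)[[3L]])
}

#' Preferred direction from moving-edge peaks
#'
#' The argument (degrees, in `[0, 360)`) of the complex vector sum of peak
#' responses over directions, evaluated at the speed and intensity with the
#' largest vector-sum magnitude.
#'
#' @param peaks Array `direction x speed x intensity`.
#' @param directions Directions in degrees (default: dimnames).
#' @return Preferred direction in degrees, `NA` if all responses vanish.
#' @export
preferred_direction <- function(peaks, directions = NULL) {
  stopifnot(length(dim(peaks)) == 3L)
  if (is.null(directions)) directions <- as.numeric(dimnames(peaks)[[1L]])
  ph <- exp(1i * directions * pi / 180)
  best <- NULL; best_mod <- -Inf
  for (s in seq_len(dim(peaks)[2L])) for (i in seq_len(dim(peaks)[3L])) {
    z <- sum(peaks[, s, i] * ph)
    if (Mod(z) > best_mod) { best_mod <- Mod(z); best <- z }
  }
  if (best_mod <= 0) return(NA_real_)
  (Arg(best) * 180 / pi) %% 360
}

#' Permutation null for direction selectivity
#'
#' Builds the null distribution of apparent selectivity for cell types with
#' direction-symmetric inputs: for each symmetric cell's condition
#' (intensity, speed), the statistic
#' `d* = |sum_theta r(theta*) exp(i theta)| / |sum_theta r(theta)|` is
#' sampled under `n_perm` independent permutations `theta*` of the direction
#' labels. The selectivity threshold is the 99% quantile of the pooled
#' samples.
#'
#' @param peaks_list List of `direction x speed x intensity` peak arrays, one
#'   per symmetric cell (pool across models by concatenating lists).
#' @param n_perm Number of permutations per condition (default 100).
#' @param prob Quantile defining the threshold (default 0.99).
#' @param seed Integer RNG seed.
#' @return List with the pooled `samples` and the `threshold`.
#' @export
permutation_null <- function(peaks_list, n_perm = 100, prob = 0.99, seed = 1L) {
  if (length(peaks_list) == 0L) stop("'peaks_list' must contain at least one cell")
  if (is.array(peaks_list)) peaks_list <- list(peaks_list)
  withr::with_seed(seed, {
    samples <- numeric(0)
    for (pk in peaks_list) {
      stopifnot(length(dim(pk)) == 3L)
      directions <- as.numeric(dimnames(pk)[[1L]])
      ph <- exp(1i * directions * pi / 180)
      for (s in seq_len(dim(pk)[2L])) for (i in seq_len(dim(pk)[3L])) {
        r <- pk[, s, i]
        tot <- Mod(sum(r))
        if (tot == 0) next
        d <- vapply(seq_len(n_perm), function(p)
          Mod(sum(r[sample.int(length(r))] * ph)) / tot, numeric(1))
        samples <- c(samples, d)
      }
    }
    list(samples = samples,
         threshold = unname(stats::quantile(samples, prob)))
  })
}

#' Classify a cell type as direction selective across an ensemble
#'
#' One-sided binomial test on the number of models in which the type's DSI
#' exceeds the permutation-null threshold, against the null that exceedances
#' occur with probability `p0 = 0.1`. The type counts as direction selective
#' if `p < alpha`.
#'
#' @param dsi_values Numeric vector, the type's DSI in each model.
#' @param threshold Selectivity threshold (from [permutation_null()]).
#' @param p0 Null exceedance probability (default 0.1).
#' @param alpha Significance level (default 0.05).
#' @return List with `selective` (logical), `p_value`, `n_exceed`, `n_models`.
#' @export
classify_direction_selective <- function(dsi_values, threshold, p0 = 0.1,
                                         alpha = 0.05) {
  k <- sum(dsi_values > threshold, na.rm = TRUE)
  n <- sum(!is.na(dsi_values))
  p <- stats::binom.test(k, n, p = p0, alternative = "greater")$p.value
  list(selective = p < alpha, p_value = p, n_exceed = k, n_models = n)
}

#' Receptive fields from single-ommatidium flash responses
#'
#' The spatio-temporal receptive field (STRF) is the baseline-subtracted
#' response of the central cell to a flash at each ommatidium offset:
#' `STRF[n](u, v) = V[n](J(u, v)) - V[0](J(u, v))`, so `STRF` at the first
#' sample is exactly zero. The spatial receptive field (SRF) is the STRF
#' sliced at the time of the extremum of the central-offset response; the
#' temporal receptive field (TRF) is the central-offset time course.
#'
#' @param traces Numeric matrix time-by-offset of the central cell's voltage
#'   (each column: response to a flash at one offset; first row: baseline).
#' @param offsets Data frame with `u`, `v` per trace column; must contain the
#'   central offset `(0, 0)`.
#' @return List of class `"receptive_field"` with `strf` (matrix), `srf`
#'   (vector over offsets), `trf` (vector over time), `peak_step`, `offsets`.
#' @export
receptive_fields <- function(traces, offsets) {
  traces <- as.matrix(traces)
  stopifnot(nrow(offsets) == ncol(traces))
  ctr <- which(offsets$u == 0L & offsets$v == 0L)
  if (length(ctr) != 1L) stop("'offsets' must contain the central offset once")
  strf <- sweep(traces, 2L, traces[1L, ], "-")
  peak_step <- which.max(abs(strf[, ctr]))
  structure(list(strf = strf, srf = strf[peak_step, ],
                 trf = strf[, ctr], peak_step = peak_step, offsets = offsets),
            class = "receptive_field")
}

#' Run the single-ommatidium flash protocol for one cell type
#'
#' Flashes each column within `window` hex steps of the centre in turn and
#' records the central cell of `type`, assembling the input to
#' [receptive_fields()].
#'
#' @param net,params Assembled network and parameter set.
#' @param type Cell type whose central cell is recorded.
#' @param intensity Flash intensity (1 = ON, 0 = OFF).
#' @param window Offset radius in columns (default 2).
#' @param duration Flash duration, ms (default 20).
#' @param pre,post Grey periods, ms (protocol defaults 2000 / 5000).
#' @param dt Integration step, ms.
#' @return A `"receptive_field"` object.
#' @export
strf_protocol <- function(net, params, type, intensity = 1, window = 2,
                          duration = 20, pre = 2000, post = 5000, dt = 5) {
  ctr <- central_cells(net, type)
  if (nrow(ctr) != 1L) stop("no central cell of type '", type, "'")
  compiled <- compile_network(net, params)
  init <- steady_state(net, params, duration = 2000, dt = dt, compiled = compiled)
  lat <- net$lattice
  keep <- hex_distance(lat$u, lat$v) <= window
  offsets <- data.frame(u = lat$u[keep], v = lat$v[keep])
  traces <- NULL
  for (k in seq_len(nrow(offsets))) {
    stim <- ommatidium_flash(lat, offsets$u[k], offsets$v[k], intensity,
                             duration = duration, pre = pre, post = post, dt = dt)
    tr <- simulate_network(net, params, stim, dt = dt, record = ctr$id,
                           init = init, compiled = compiled)
    if (is.null(traces))
      traces <- matrix(NA_real_, nrow(tr$V) + 1L, nrow(offsets))
    traces[, k] <- c(init[ctr$id + 0L], tr$V[, 1L])
  }
  receptive_fields(traces, offsets)
}

#' Normalize responses for cross-model averaging
#'
#' Threshold-linear networks have arbitrary voltage units, so before
#' averaging responses across models each cell's responses are divided by the
#' root mean square of its responses to a bank of naturalistic sequences.
#' Models whose normalizer vanishes are flagged excluded (`NA` output,
#' attribute `"excluded"`), not an error.
#'
#' @param x Numeric vector/matrix of responses to normalize.
#' @param r_nat Numeric vector/matrix, the cell's responses to the
#'   naturalistic stimulus bank.
#' @return `x` divided by `rms(r_nat)`, with attribute `"excluded"`.
#' @export
normalize_response <- function(x, r_nat) {
  rms <- sqrt(mean(r_nat^2))
  if (rms == 0) {
    out <- x * NA_real_
    attr(out, "excluded") <- TRUE
  } else {
    out <- x / rms
    attr(out, "excluded") <- FALSE
  }
  out
}

#' Correlation between motion-tuning curves
#'
#' Pearson correlation between a model's direction-tuning curve and a
#' reference curve, maximized over the probed speeds (robust to a shifted
#' preferred speed). Speeds with fewer than 3 directions or zero variance are
#' treated as missing.
#'
#' @param model_curve Matrix `direction x speed` of model responses.
#' @param reference Numeric vector over the same directions.
#' @return Maximum correlation across speeds, `NA` if no speed admits one.
#' @export
tuning_correlation <- function(model_curve, reference) {
  model_curve <- as.matrix(model_curve)
  stopifnot(nrow(model_curve) == length(reference))
  cors <- apply(model_curve, 2L, function(x) {
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(reference) == 0)
      return(NA_real_)
    stats::cor(x, reference)
  })
  if (all(is.na(cors))) NA_real_ else max(cors, na.rm = TRUE)
}

#' Select ensemble models by tuning criteria
#'
#' Keeps the models whose tuning matches the reference for every target type:
#' correct contrast-preference sign (FRI), DSI above the selectivity
#' threshold, and preferred direction within the acceptance angle of the
#' reference direction.
#'
#' @param stats_df Data frame with columns `model`, `type`, `fri`, `dsi`,
#'   `pref_dir` (degrees).
#' @param criteria Data frame with columns `type`, `fri_sign` (+1/-1), and
#'   `pref_dir` (reference direction, degrees, or `NA` to skip the direction
#'   criterion for that type).
#' @param dsi_threshold Selectivity threshold.
#' @param acceptance_angle Maximal angular distance to the reference
#'   direction, degrees (default 45).
#' @return Vector of model identifiers passing all criteria.
#' @export
select_models <- function(stats_df, criteria, dsi_threshold,
                          acceptance_angle = 45) {
  ang_dist <- function(a, b) {
    d <- abs((a - b) %% 360)
    pmin(d, 360 - d)
  }
  models <- unique(stats_df$model)
  keep <- vapply(models, function(m) {
    sub <- stats_df[stats_df$model == m, , drop = FALSE]
    for (k in seq_len(nrow(criteria))) {
      row <- sub[sub$type == criteria$type[k], , drop = FALSE]
      if (nrow(row) != 1L) return(FALSE)
      if (is.na(row$fri) || sign(row$fri) != criteria$fri_sign[k]) return(FALSE)
      if (is.na(row$dsi) || row$dsi <= dsi_threshold) return(FALSE)
      if (!is.na(criteria$pref_dir[k])) {
        if (is.na(row$pref_dir) ||
            ang_dist(row$pref_dir, criteria$pref_dir[k]) > acceptance_angle)
          return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  models[keep]
}
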