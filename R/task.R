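#' Optic-flow training loss
#'
#' L2 norm of the residual between target and predicted flow fields,
#' `L = ||Y - Yhat||` (square root of the sum of squared element
#' differences). Zero iff the fields are equal, and positively homogeneous in
#' the residual.
#'
#' @param Y,Yhat Numeric arrays of identical shape (time x 2 x column).
#' @return Non-negative scalar.
#' @export
flow_loss <- function(Y, Yhat) {
  if (!identical(dim(Y), dim(Yhat))) stop("flow field shapes differ")
  sqrt(sum((Y - Yhat)^2))
}

#' Average end-point error
#'
#' The standard optic-flow metric: the mean over time steps and columns of
#' the Euclidean norm of the per-column 2-D flow residual.
#'
#' @param Y,Yhat Flow arrays `time x 2 x column`.
#' @return Non-negative scalar.
#' @export
epe <- function(Y, Yhat) {
  if (!identical(dim(Y), dim(Yhat))) stop("flow field shapes differ")
  d <- Y - Yhat
  mean(sqrt(d[, 1L, , drop = FALSE]^2 + d[, 2L, , drop = FALSE]^2))
}

#' Activity regularizer on time-averaged responses
#'
#' Encourages every cell type's time-averaged central-column response `vbar`
#' to sit near a target activity `a` (arbitrary units): quadratic penalty
#' `gamma (vbar - a)^2` below the target (pushing silent cells up) and a much
#' weaker `delta (vbar - a)^2` above it (discouraging runaway activity),
#' averaged over batch and cell types and scaled by `lambda`.
#'
#' @param vbar Numeric matrix `batch x types` (or vector) of time-averaged
#'   central-column responses.
#' @param a Target activity (default 5, a.u.).
#' @param gamma Weight below the target (default 1).
#' @param delta Weight above the target (default 0.01).
#' @param lambda Overall scale (default 0.1).
#' @return Non-negative scalar.
#' @export
activity_regularizer <- function(vbar, a = 5, gamma = 1, delta = 0.01,
                                 lambda = 0.1) {
  vbar <- as.matrix(vbar)
  w <- ifelse(vbar <= a, gamma, delta)
  lambda / length(vbar) * sum(w * (vbar - a)^2)
}

# map (column, decoder type) -> neuron id (NA where the type has no cell)
decoder_input_map <- function(net, decoder_types) {
  C <- net$lattice$n
  m <- matrix(NA_integer_, C, length(decoder_types))
  for (d in seq_along(decoder_types)) {
    nn <- net$neurons[net$neurons$type == decoder_types[d], , drop = FALSE]
    m[nn$column, d] <- nn$id
  }
  m
}

# forward Euler pass storing the full state history.
# Returns V: (N+1) x n matrix (row 1 = initial state).
dmn_forward <- function(compiled, frames, dt, init) {
  n_steps <- nrow(frames)
  V <- matrix(NA_real_, n_steps + 1L, compiled$n)
  V[1L, ] <- init
  e <- numeric(compiled$n)
  a <- dt / pmax(compiled$tau, dt)
  for (s in seq_len(n_steps)) {
    e[compiled$input_ids] <- frames[s, compiled$input_cols]
    v <- V[s, ]
    drive <- -v + as.numeric(compiled$W %*% rectify(v)) + compiled$v_rest + e
    V[s + 1L, ] <- v + a * drive
    if (!all(is.finite(V[s + 1L, ])))
      stop(sprintf("numerical divergence at step %d (t = %g ms)", s, s * dt))
  }
  V
}

# backpropagation through time for the threshold-linear dynamics.
# g_loss: (N x n) per-step loss gradients with respect to V[n] (n = 1..N).
# Returns gradients for alpha (per pair), v_rest and tau (per type), and
# optionally the gradient with respect to the external input frames.
dmn_backward <- function(net, compiled, params, V, g_loss, dt,
                         want_input_grad = FALSE) {
  n_steps <- nrow(g_loss)
  cn <- net$connections
  tn <- net$spec$types$name
  type_idx <- match(net$neurons$type, tn)
  tau_eff <- pmax(compiled$tau, dt)
  a <- dt / tau_eff
  clamped <- compiled$tau < dt
  sigmaN <- net$spec$pairs$sign[cn$pair] * cn$count
  Wt <- Matrix::t(compiled$W)
  d_alpha <- numeric(nrow(net$spec$pairs))
  d_vrest_n <- numeric(compiled$n)
  d_tau_n <- numeric(compiled$n)
  de <- if (want_input_grad) matrix(0, n_steps, compiled$n)
  g <- g_loss[n_steps, ]
  for (s in seq.int(n_steps, 1L)) {
    if (s < n_steps) g <- g + g_loss[s, ]
    gA <- g * a
    d_vrest_n <- d_vrest_n + gA
    if (want_input_grad) de[s, ] <- gA
    fV <- rectify(V[s, ])
    cg <- gA[cn$post] * sigmaN * fV[cn$pre]
    if (length(cg)) {
      acc <- rowsum(cg, cn$pair)
      d_alpha[as.integer(rownames(acc))] <-
        d_alpha[as.integer(rownames(acc))] + acc[, 1L]
    }
    drive <- (V[s + 1L, ] - V[s, ]) / a
    d_tau_n <- d_tau_n + ifelse(clamped, 0, g * drive * (-dt / tau_eff^2))
    # adjoint one step back
    g <- g * (1 - a) + (V[s, ] > 0) * as.numeric(Wt %*% gA)
  }
  d_vrest <- rowsum(d_vrest_n, type_idx)
  d_tau <- rowsum(d_tau_n, type_idx)
  tv <- numeric(length(tn)); tv[as.integer(rownames(d_vrest))] <- d_vrest[, 1L]
  tt <- numeric(length(tn)); tt[as.integer(rownames(d_tau))] <- d_tau[, 1L]
  list(alpha = d_alpha,
       v_rest = stats::setNames(tv, tn),
       tau = stats::setNames(tt, tn),
       input = de)
}

#' Predict optic flow for a stimulus
#'
#' Runs the network from its grey steady state over the frames and decodes
#' per-frame flow from the rectified voltages of the decoder input types.
#'
#' @param net,params Assembled network and parameter set.
#' @param decoder A [flow_decoder()].
#' @param frames Stimulus matrix `time x column` (values in `[0, 1]`).
#' @param decoder_types Character vector of decoder input types.
#' @param dt Integration step, ms (one step per frame).
#' @return Flow array `time x 2 x column`.
#' @export
predict_flow <- function(net, params, decoder, frames, decoder_types, dt = 20) {
  compiled <- compile_network(net, params)
  init <- steady_state(net, params, duration = 500, dt = dt, compiled = compiled)
  V <- dmn_forward(compiled, frames, dt, init)
  dmap <- decoder_input_map(net, decoder_types)
  act <- activity_from_history(V, dmap)
  decode_flow(decoder, act, net$lattice)
}

# rectified activity array time x D x C from a state history (dropping the
# initial-state row); NA map entries give silent channels
activity_from_history <- function(V, dmap) {
  N <- nrow(V) - 1L
  act <- array(0, c(N, ncol(dmap), nrow(dmap)))
  for (d in seq_len(ncol(dmap))) {
    ok <- !is.na(dmap[, d])
    act[, d, ok] <- rectify(V[-1L, dmap[ok, d], drop = FALSE])
  }
  act
}

#' Mean validation end-point error
#'
#' @param net,params,decoder Model components.
#' @param dataset A [make_drifting_dataset()] (or compatible) dataset.
#' @param indices Sequence indices to evaluate (default: the validation
#'   split).
#' @param decoder_types Decoder input types (default: all non-photoreceptor
#'   types).
#' @param dt Integration step, ms.
#' @return Mean [epe()] across the sequences.
#' @export
validate_epe <- function(net, params, decoder, dataset,
                         indices = dataset$val,
                         decoder_types = setdiff(net$spec$types$name,
                                                 net$spec$input_types),
                         dt = dataset$frame_dt) {
  errs <- vapply(indices, function(i) {
    sq <- dataset$sequences[[i]]
    epe(sq$flow, predict_flow(net, params, decoder, sq$frames, decoder_types, dt))
  }, numeric(1))
  mean(errs)
}

#' Training configuration for the optic-flow task
#'
#' Defaults follow the reference optimization recipe: adaptive-moment SGD
#' with `beta1 = 0.9`, `beta2 = 0.999`, learning rate stepped down from
#' 5e-5 to 5e-6 in ten stages, batches of four 19-frame sequences at a 20 ms
#' integration step (50 Hz).
#'
#' @param iterations Number of optimization iterations.
#' @param batch Sequences per iteration.
#' @param lr,lr_end Initial and final learning rates.
#' @param beta1,beta2 Moment decay rates.
#' @param dt Integration step, ms (must equal the dataset frame interval).
#' @param dropout Decoder dropout probability during training.
#' @param augment An [augmentation_config()], or `NULL` for none.
#' @param freeze_network If `TRUE`, only the decoder is trained (the
#'   frozen-network control).
#' @param tau_lr_mult Learning-rate multiplier for the time constants, which
#'   are optimized in log space (their natural scale, tens of ms, differs by
#'   orders of magnitude from the unitless synapse scales; without the
#'   reparametrization they are effectively frozen at short training
#'   budgets).
#' @param val_every Validation period, iterations.
#' @param seed Integer RNG seed.
#' @return List of class `"train_config"`.
#' @export
train_config <- function(iterations = 200L, batch = 4L, lr = 5e-5,
                         lr_end = 5e-6, beta1 = 0.9, beta2 = 0.999, dt = 20,
                         dropout = 0.5, augment = NULL,
                         freeze_network = FALSE, tau_lr_mult = 10,
                         val_every = 50L, seed = 1L) {
  structure(list(iterations = iterations, batch = batch, lr = lr,
                 lr_end = lr_end, beta1 = beta1, beta2 = beta2, dt = dt,
                 dropout = dropout, augment = augment,
                 freeze_network = freeze_network, tau_lr_mult = tau_lr_mult,
                 val_every = val_every, seed = seed),
            class = "train_config")
}

lr_schedule <- function(cfg, it) {
  stage <- floor((it - 1L) / ceiling(cfg$iterations / 10))
  cfg$lr * (cfg$lr_end / cfg$lr)^(stage / 9)
}

#' Train the network and decoder on optic flow
#'
#' Joint gradient-based optimization of the biophysical parameters (unitary
#' synapse strengths `alpha`, per-type resting potentials and time constants)
#' and the decoder, by backpropagation through time through the Euler
#' integration of the threshold-linear dynamics. After every step `alpha` is
#' clamped non-negative and the time constants are clamped at the integration
#' step (projected gradient descent). The grey-screen initial state is
#' recomputed every iteration from the current parameters. Deterministic
#' under the configuration seed.
#'
#' @param net An [tile_network()] result.
#' @param params Initial parameters (e.g. [init_parameters()]).
#' @param decoder A [flow_decoder()] (initialized).
#' @param dataset A [make_drifting_dataset()]-style dataset.
#' @param cfg A [train_config()].
#' @param decoder_types Decoder input types (default: all non-photoreceptor
#'   types).
#' @return List with trained `params`, `decoder`, a `history` data frame of
#'   training losses, and `val_epe` (data frame of validation errors over
#'   iterations).
#' @export
train_optic_flow <- function(net, params, decoder, dataset, cfg = train_config(),
                             decoder_types = setdiff(net$spec$types$name,
                                                     net$spec$input_types)) {
  stopifnot(inherits(cfg, "train_config"))
  if (!isTRUE(all.equal(cfg$dt, dataset$frame_dt)))
    stop("training requires dt equal to the dataset frame interval")
  dmap <- decoder_input_map(net, decoder_types)
  rpos <- raster_positions(net$lattice)
  tn <- net$spec$types$name
  dyn_par <- list(alpha = params$alpha, v_rest = params$v_rest)
  tau_par <- list(ltau = log(params$tau))
  dec_par <- decoder$par
  st_dyn <- adam_init(dyn_par)
  st_tau <- adam_init(tau_par)
  st_dec <- adam_init(dec_par)
  history <- numeric(cfg$iterations)
  val_rows <- list()
  P <- decoder$G^2
  for (it in seq_len(cfg$iterations)) {
    params$alpha <- dyn_par$alpha
    params$v_rest <- dyn_par$v_rest
    params$tau <- pmax(exp(tau_par$ltau), cfg$dt)
    decoder$par <- dec_par
    compiled <- compile_network(net, params)
    init <- steady_state(net, params, duration = 500, dt = cfg$dt,
                         compiled = compiled)
    g_dyn <- lapply(dyn_par, function(p) 0 * p)
    g_tau <- lapply(tau_par, function(p) 0 * p)
    g_dec <- lapply(dec_par, function(p) 0 * p)
    batch_loss <- 0
    picks <- withr::with_seed(cfg$seed * 1000L + it,
                              sample(dataset$train, cfg$batch, replace = TRUE))
    for (b in seq_len(cfg$batch)) {
      sq <- dataset$sequences[[picks[b]]]
      frames <- sq$frames
      flow <- sq$flow
      if (!is.null(cfg$augment)) {
        stim <- stimulus_sequence(frames, cfg$dt, net$lattice)
        aug <- augment_stimulus(stim, cfg$augment,
                                seed = cfg$seed * 100000L + it * 10L + b)
        tf <- attr(aug, "transform")
        frames <- aug$frames
        flow <- transform_flow(flow, net$lattice, tf$k, tf$axis)
      }
      V <- dmn_forward(compiled, frames, cfg$dt, init)
      act <- activity_from_history(V, dmap)
      N <- nrow(frames)
      mask <- if (cfg$dropout > 0)
        withr::with_seed(cfg$seed * 7919L + it * 100L + b,
          matrix(stats::rbinom(N * P * decoder$channels, 1L, 1 - cfg$dropout) /
                   (1 - cfg$dropout), N * P, decoder$channels))
      fw <- decoder_seq_forward(decoder, act, rpos, train = TRUE,
                                drop_mask = mask, keep = TRUE)
      decoder <- decoder_update_bn(decoder, fw$mu, fw$va)
      Yhat <- fw$pred
      L <- flow_loss(flow, Yhat)
      batch_loss <- batch_loss + L
      if (L == 0) next
      dY <- (Yhat - flow) / L
      bw <- decoder_seq_backward(decoder, fw, dY, rpos, drop_mask = mask)
      for (nm in names(g_dec)) g_dec[[nm]] <- g_dec[[nm]] + bw$grads[[nm]]
      # route activity gradients to neurons (rectifier gate)
      g_loss <- matrix(0, N, compiled$n)
      for (d in seq_len(ncol(dmap))) {
        ok <- !is.na(dmap[, d])
        ids <- dmap[ok, d]
        g_loss[, ids] <- g_loss[, ids] +
          bw$dact[, ok, d] * (V[-1L, ids, drop = FALSE] > 0)
      }
      if (!cfg$freeze_network) {
        gb <- dmn_backward(net, compiled, params, V, g_loss, cfg$dt)
        g_dyn$alpha <- g_dyn$alpha + gb$alpha
        g_dyn$v_rest <- g_dyn$v_rest + gb$v_rest
        g_tau$ltau <- g_tau$ltau + gb$tau * params$tau  # chain rule to log tau
      }
    }
    history[it] <- batch_loss / cfg$batch
    lr <- lr_schedule(cfg, it)
    if (!cfg$freeze_network) {
      g_dyn <- lapply(g_dyn, function(g) g / cfg$batch)
      upd <- adam_step(dyn_par, g_dyn, st_dyn, lr, cfg$beta1, cfg$beta2)
      dyn_par <- upd$par
      st_dyn <- upd$state
      dyn_par$alpha <- pmax(dyn_par$alpha, 0)
      upd <- adam_step(tau_par, list(ltau = g_tau$ltau / cfg$batch), st_tau,
                       lr * cfg$tau_lr_mult, cfg$beta1, cfg$beta2)
      tau_par <- upd$par
      st_tau <- upd$state
    }
    g_dec <- lapply(g_dec, function(g) g / cfg$batch)
    upd <- adam_step(dec_par, g_dec, st_dec, lr, cfg$beta1, cfg$beta2)
    dec_par <- upd$par
    st_dec <- upd$state
    if (it %% cfg$val_every == 0L || it == cfg$iterations) {
      params$alpha <- dyn_par$alpha
      params$v_rest <- dyn_par$v_rest
      params$tau <- pmax(exp(tau_par$ltau), cfg$dt)
      decoder$par <- dec_par
      val_rows[[length(val_rows) + 1L]] <-
        data.frame(iteration = it,
                   epe = validate_epe(net, params, decoder, dataset,
                                      decoder_types = decoder_types,
                                      dt = cfg$dt))
    }
  }
  params$alpha <- dyn_par$alpha
  params$v_rest <- dyn_par$v_rest
  params$tau <- pmax(exp(tau_par$ltau), cfg$dt)
  decoder$par <- dec_par
  list(params = params, decoder = decoder,
       history = data.frame(iteration = seq_len(cfg$iterations), loss = history),
       val_epe = do.call(rbind, val_rows))
}

#' Optimize resting potentials against the activity regularizer
#'
#' A separate tuning phase using plain stochastic gradient descent (no
#' momentum) on the shared resting potentials only, minimizing
#' [activity_regularizer()] of the time-averaged central-column responses to
#' the dataset's sequences. Encourages non-silent, non-exploding activity in
#' every cell type.
#'
#' @param net,params Assembled network and parameters.
#' @param dataset Dataset providing stimulus sequences.
#' @param iterations SGD iterations.
#' @param lr Learning rate.
#' @param batch Sequences per iteration.
#' @param dt Integration step, ms.
#' @param a,gamma,delta,lambda Regularizer constants (see
#'   [activity_regularizer()]).
#' @param seed Integer RNG seed.
#' @return List with updated `params` and the regularizer `history`.
#' @export
optimize_resting_potentials <- function(net, params, dataset, iterations = 20L,
                                        lr = 1e-2, batch = 2L,
                                        dt = dataset$frame_dt, a = 5,
                                        gamma = 1, delta = 0.01, lambda = 0.1,
                                        seed = 1L) {
  ctr <- central_cells(net)
  tn <- net$spec$types$name
  history <- numeric(iterations)
  for (it in seq_len(iterations)) {
    compiled <- compile_network(net, params)
    init <- steady_state(net, params, duration = 500, dt = dt,
                         compiled = compiled)
    picks <- withr::with_seed(seed * 131L + it,
                              sample(dataset$train, batch, replace = TRUE))
    grad <- stats::setNames(numeric(length(tn)), tn)
    rtot <- 0
    for (b in picks) {
      frames <- dataset$sequences[[b]]$frames
      V <- dmn_forward(compiled, frames, dt, init)
      N <- nrow(frames)
      vbar <- colMeans(V[-1L, ctr$id, drop = FALSE])
      w <- ifelse(vbar <= a, gamma, delta)
      rtot <- rtot + lambda / (batch * length(vbar)) * sum(w * (vbar - a)^2)
      dvbar <- lambda / (batch * length(vbar)) * 2 * w * (vbar - a)
      g_loss <- matrix(0, N, compiled$n)
      g_loss[, ctr$id] <- matrix(dvbar / N, N, length(dvbar), byrow = TRUE)
      gb <- dmn_backward(net, compiled, params, V, g_loss, dt)
      grad <- grad + gb$v_rest
    }
    params$v_rest <- params$v_rest - lr * grad
    history[it] <- rtot
  }
  list(params = params, history = history)
}
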