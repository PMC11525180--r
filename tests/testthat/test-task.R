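test_that("losses and EPE match brute-force evaluation", {
  set.seed(21)
  Y <- array(rnorm(10 * 2 * 7), c(10, 2, 7))
  Yhat <- array(rnorm(10 * 2 * 7), c(10, 2, 7))
  expect_equal(flow_loss(Y, Y), 0)
  expect_equal(flow_loss(Y, Yhat), sqrt(sum((Y - Yhat)^2)))
  # homogeneity: doubling the residual doubles the loss
  expect_equal(flow_loss(Y, Y + 2 * (Yhat - Y)), 2 * flow_loss(Y, Yhat))
  expect_equal(epe(Y, Y), 0)
  # constant residual (3, 4) everywhere: EPE is 5
  Y2 <- Yhat
  Y2[, 1, ] <- Yhat[, 1, ] + 3
  Y2[, 2, ] <- Yhat[, 2, ] + 4
  expect_equal(epe(Y2, Yhat), 5)
  # brute-force per-element oracle
  acc <- 0
  for (n in 1:10) for (c in 1:7)
    acc <- acc + sqrt((Y[n, 1, c] - Yhat[n, 1, c])^2 + (Y[n, 2, c] - Yhat[n, 2, c])^2)
  expect_equal(epe(Y, Yhat), acc / 70)
  expect_error(epe(Y, Yhat[1:5, , ]), "shapes differ")
})

test_that("activity regularizer is piecewise quadratic and continuous", {
  expect_equal(activity_regularizer(5), 0)                 # at the target
  expect_equal(activity_regularizer(4), 0.1 * 1 * 1)       # below: gamma branch
  expect_equal(activity_regularizer(7), 0.1 * 0.01 * 4)    # above: delta branch
  # continuity at the target
  eps <- 1e-8
  expect_equal(activity_regularizer(5 - eps), activity_regularizer(5 + eps),
               tolerance = 1e-12)
  # averaged over batch and types
  vbar <- matrix(c(4, 5, 6, 5), 2, 2)
  expect_equal(activity_regularizer(vbar),
               0.1 / 4 * (1 * 1 + 0.01 * 1))
  # gradient sign pushes vbar towards the target from both sides
  num_grad <- function(v) (activity_regularizer(v + 1e-6) -
                             activity_regularizer(v - 1e-6)) / 2e-6
  expect_lt(num_grad(3), 0)
  expect_gt(num_grad(8), 0)
})

test_that("the decoder is per-frame pure with no temporal structure", {
  lat <- hex_lattice(2)
  dec <- flow_decoder(3, 2)
  # break the symmetric initialization so outputs vary across frames
  set.seed(31)
  dec$par$W1 <- dec$par$W1 + array(rnorm(length(dec$par$W1), 0, 0.05),
                                   dim(dec$par$W1))
  act <- array(abs(rnorm(6 * 3 * lat$n)), c(6, 3, lat$n))
  out <- decode_flow(dec, act, lat)
  # all-zero activity: constant output field set by the biases
  z <- decode_flow(dec, 0 * act, lat)
  for (n in 2:6) expect_equal(z[n, , ], z[1, , ])
  # permuting input frames permutes output frames identically; in
  # particular reversing a sequence cannot be told apart frame-by-frame
  perm <- c(4, 1, 6, 2, 5, 3)
  out_p <- decode_flow(dec, act[perm, , , drop = FALSE], lat)
  expect_equal(out_p, out[perm, , , drop = FALSE])
  rev <- 6:1
  expect_equal(decode_flow(dec, act[rev, , , drop = FALSE], lat),
               out[rev, , , drop = FALSE])
})

test_that("decoder and dynamics gradients agree with finite differences", {
  fx <- make_motion_motif(radius = 1)
  net <- tile_network(fx$spec, hex_lattice(1))
  params <- fx$params
  dt <- 20
  ds <- make_drifting_dataset(1, radius = 1, n_frames = 6, seed = 13)
  frames <- ds$sequences[[1]]$frames
  flow <- ds$sequences[[1]]$flow
  dtypes <- c("FastE", "SlowI", "Det")
  dec <- flow_decoder(3, 1)
  set.seed(17)
  dec$par$W1 <- dec$par$W1 + array(rnorm(length(dec$par$W1), 0, 0.05),
                                   dim(dec$par$W1))
  dec$par$W2 <- dec$par$W2 + array(rnorm(length(dec$par$W2), 0, 0.05),
                                   dim(dec$par$W2))
  dmap <- hexdmn:::decoder_input_map(net, dtypes)
  rpos <- hexdmn:::raster_positions(net$lattice)
  compiled <- compile_network(net, params)
  init <- steady_state(net, params, duration = 500, dt = dt,
                       compiled = compiled)
  loss_of <- function(params, dec) {
    cm <- compile_network(net, params)
    V <- hexdmn:::dmn_forward(cm, frames, dt, init)
    act <- hexdmn:::activity_from_history(V, dmap)
    fw <- hexdmn:::decoder_seq_forward(dec, act, rpos, train = TRUE)
    flow_loss(flow, fw$pred)
  }
  # analytic gradients (training-mode normalization, as in the optimizer)
  V <- hexdmn:::dmn_forward(compiled, frames, dt, init)
  act <- hexdmn:::activity_from_history(V, dmap)
  N <- nrow(frames)
  fw <- hexdmn:::decoder_seq_forward(dec, act, rpos, train = TRUE, keep = TRUE)
  Yhat <- fw$pred
  L <- flow_loss(flow, Yhat)
  dY <- (Yhat - flow) / L
  bw <- hexdmn:::decoder_seq_backward(dec, fw, dY, rpos)
  g_dec <- bw$grads
  g_loss <- matrix(0, N, compiled$n)
  for (d in seq_len(ncol(dmap))) {
    ok <- !is.na(dmap[, d]); ids <- dmap[ok, d]
    g_loss[, ids] <- g_loss[, ids] +
      bw$dact[, ok, d] * (V[-1, ids, drop = FALSE] > 0)
  }
  gb <- hexdmn:::dmn_backward(net, compiled, params, V, g_loss, dt)
  eps <- 1e-6
  fd <- function(mutate) {
    p1 <- mutate(eps); p2 <- mutate(-eps)
    (loss_of(p1$params, p1$dec) - loss_of(p2$params, p2$dec)) / (2 * eps)
  }
  for (k in seq_along(params$alpha)) {
    g_fd <- fd(function(e) {
      p <- params; p$alpha[k] <- p$alpha[k] + e; list(params = p, dec = dec)
    })
    expect_equal(gb$alpha[k], g_fd, tolerance = 1e-5)
  }
  # unclamped time constant (SlowI: 60 ms > dt) has a nonzero exact gradient
  g_fd <- fd(function(e) {
    p <- params; p$tau["SlowI"] <- p$tau["SlowI"] + e; list(params = p, dec = dec)
  })
  expect_equal(unname(gb$tau["SlowI"]), g_fd, tolerance = 1e-4)
  expect_true(abs(g_fd) > 0)
  # clamped time constant (tau < dt) has zero gradient
  expect_equal(unname(gb$tau["R1"]), 0)
  for (k in seq_along(params$v_rest)) {
    g_fd <- fd(function(e) {
      p <- params; p$v_rest[k] <- p$v_rest[k] + e; list(params = p, dec = dec)
    })
    expect_equal(unname(gb$v_rest[k]), g_fd, tolerance = 1e-5)
  }
  for (probe in list(c("W1", 7), c("b1", 3), c("gamma", 2), c("beta", 5),
                     c("W2", 40), c("b2", 1))) {
    nm <- probe[1]; k <- as.integer(probe[2])
    g_fd <- fd(function(e) {
      d <- dec; d$par[[nm]][k] <- d$par[[nm]][k] + e; list(params = params, dec = d)
    })
    expect_equal(g_dec[[nm]][k], g_fd, tolerance = 1e-4)
  }
})

test_that("training is reproducible and clamps hold at every checkpoint", {
  fx <- make_motion_motif(radius = 1)
  net <- tile_network(fx$spec, hex_lattice(1))
  ds <- make_drifting_dataset(3, radius = 1, n_frames = 8, seed = 2)
  dtypes <- c("FastE", "SlowI", "Det")
  dec <- flow_decoder(3, 1)
  params <- init_parameters(fx$spec, seed = 4)
  cfg <- train_config(iterations = 6, lr = 1e-3, val_every = 3, seed = 11)
  t1 <- train_optic_flow(net, params, dec, ds, cfg, decoder_types = dtypes)
  t2 <- train_optic_flow(net, params, dec, ds, cfg, decoder_types = dtypes)
  expect_equal(t1$history, t2$history)
  expect_equal(t1$params$alpha, t2$params$alpha)
  expect_true(all(t1$params$alpha >= 0))
  expect_true(all(t1$params$tau >= cfg$dt))
  # loss moves under training
  expect_false(identical(t1$history$loss[1], t1$history$loss[6]))
})

test_that("resting-potential tuning reduces the activity regularizer", {
  fx <- make_motion_motif(radius = 1)
  net <- tile_network(fx$spec, hex_lattice(1))
  ds <- make_drifting_dataset(2, radius = 1, n_frames = 8, seed = 6)
  params <- init_parameters(fx$spec, seed = 4)
  out <- optimize_resting_potentials(net, params, ds, iterations = 8,
                                     lr = 0.5, batch = 1, seed = 3)
  expect_lt(tail(out$history, 1), out$history[1])
})
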