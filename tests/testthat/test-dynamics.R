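test_that("rectification is threshold-linear at zero", {
  expect_identical(rectify(c(2.5, -1, 0)), c(2.5, 0, 0))
})

test_that("an isolated neuron relaxes exponentially to its fixed point", {
  spec <- toy_two_type_spec(du = 0L, dv = 0L, radius = 0L)
  net <- tile_network(spec, hex_lattice(0))
  params <- toy_params(spec, tau = 20, v_rest = 0.3, alpha = 0)
  compiled <- compile_network(net, params)
  # V = V_rest with no input is a fixed point
  V <- compiled$v_rest
  for (s in 1:10) V <- neural_step(V, compiled, e = 0, dt = 1)
  expect_equal(V, compiled$v_rest)
  # constant input: value at t = tau within integrator tolerance of
  # V_rest + e (1 - 1/e)
  e_in <- grey_input(compiled, 1)          # photoreceptor gets e = 1
  V <- compiled$v_rest
  dt <- 0.1
  for (s in seq_len(round(20 / dt))) V <- neural_step(V, compiled, e_in, dt)
  id <- compiled$input_ids[1L]
  expect_equal(V[id], 0.3 + 1 * (1 - exp(-1)), tolerance = 1e-2)
  # long run approaches V_rest + e
  for (s in seq_len(3000)) V <- neural_step(V, compiled, e_in, dt)
  expect_equal(V[id], 1.3, tolerance = 1e-6)
})

test_that("a two-neuron chain reaches its closed-form fixed point", {
  spec <- toy_two_type_spec(du = 0L, dv = 0L, radius = 0L, count = 2, sign = 1)
  net <- tile_network(spec, hex_lattice(0))
  params <- toy_params(spec, tau = 20, v_rest = 0.2, alpha = 0.4)  # w = 0.8
  compiled <- compile_network(net, params)
  e_in <- grey_input(compiled, 0.6)
  V <- compiled$v_rest
  for (s in seq_len(5000)) V <- neural_step(V, compiled, e_in, dt = 5)
  pre <- V[compiled$input_ids[1L]]
  post_id <- setdiff(net$neurons$id, compiled$input_ids)
  expect_equal(pre, 0.8, tolerance = 1e-8)           # V_rest + e
  expect_equal(V[post_id], 0.2 + 0.8 * rectify(pre), tolerance = 1e-8)
  # fixed-point identity V = W f(V) + V_rest + e
  resid <- -V + as.numeric(compiled$W %*% rectify(V)) + compiled$v_rest + e_in
  expect_equal(max(abs(resid)), 0, tolerance = 1e-8)
})

test_that("sparse evaluation equals the per-connection loop exactly", {
  fx <- make_motion_motif(radius = 3)
  net <- tile_network(fx$spec, hex_lattice(3))
  compiled <- compile_network(net, fx$params)
  w <- connection_weights(net, fx$params)
  set.seed(99)
  for (rep in 1:5) {
    V <- rnorm(compiled$n)
    expect_equal(as.numeric(compiled$W %*% rectify(V)),
                 hexdmn:::naive_synaptic_input(net, w, V))
  }
})

test_that("time constants are clamped at the integration step", {
  spec <- toy_two_type_spec(du = 0L, dv = 0L, radius = 0L)
  net <- tile_network(spec, hex_lattice(0))
  params <- toy_params(spec, tau = 1, v_rest = 0, alpha = 0)  # tau < dt
  compiled <- compile_network(net, params)
  V <- compiled$v_rest
  # with tau clamped to dt the update is exactly V <- V_rest + e
  V2 <- neural_step(V, compiled, grey_input(compiled, 0.7), dt = 5)
  expect_equal(V2[compiled$input_ids[1L]], 0.7)
})

test_that("steady state converges, is deterministic and flags divergence", {
  fx <- make_motion_motif(radius = 2)
  net <- tile_network(fx$spec, hex_lattice(2))
  s1 <- steady_state(net, fx$params, duration = 1500, dt = 5)
  s2 <- steady_state(net, fx$params, duration = 3000, dt = 5)
  expect_identical(s1, steady_state(net, fx$params, duration = 1500, dt = 5))
  expect_equal(s1, s2, tolerance = 1e-6)   # doubling duration changes little
  # no-connection network: photoreceptors at V_rest + e, others at V_rest
  spec <- toy_two_type_spec(radius = 0L)
  spec$filters <- spec$filters[0, ]
  net0 <- tile_network(spec, hex_lattice(0))
  p0 <- toy_params(spec, v_rest = 0.1)
  st <- steady_state(net0, p0, luminance = 0.5, duration = 2000, dt = 5)
  compiled <- compile_network(net0, p0)
  expect_equal(st[compiled$input_ids], 0.6, tolerance = 1e-9)
  expect_equal(st[setdiff(net0$neurons$id, compiled$input_ids)], 0.1,
               tolerance = 1e-9)
  # runaway positive feedback aborts with diagnostics
  bad_spec <- connectome_spec(
    data.frame(name = "A"),
    data.frame(type = "A", u = 0L, v = 0L),
    data.frame(pre_type = "A", post_type = "A", du = 0L, dv = 0L, count = 1e6),
    data.frame(pre_type = "A", post_type = "A", sign = 1),
    input_types = "A")
  bad_net <- tile_network(bad_spec, hex_lattice(0))
  bad_par <- toy_params(bad_spec, v_rest = 1, alpha = 1e6)
  expect_error(steady_state(bad_net, bad_par, duration = 5000, dt = 5),
               "divergence at warm-up step")
})

test_that("simulation resamples stimuli and reports aligned traces", {
  fx <- make_motion_motif(radius = 2)
  net <- tile_network(fx$spec, hex_lattice(2))
  stim <- circular_flash(net$lattice, 1, radius = 1, warmup = 100,
                         flash = 100, dt = 10)
  tr <- simulate_network(net, fx$params, stim, dt = 5,
                         record = central_cells(net)$id)
  expect_identical(nrow(tr$V), 40L)      # 200 ms at 5 ms step
  expect_identical(ncol(tr$V), 4L)
  # zero-weight network: trace constant at the warm-up state
  p0 <- fx$params; p0$alpha[] <- 0
  tr0 <- simulate_network(net, p0, circular_flash(net$lattice, 0.5, radius = 1,
                                                  warmup = 50, flash = 50, dt = 5),
                          dt = 5, record = central_cells(net)$id)
  expect_equal(max(abs(sweep(tr0$V, 2L, tr0$V[1L, ]))), 0, tolerance = 1e-9)
  # lattice mismatch rejected
  stim_big <- circular_flash(hex_lattice(3), 1, radius = 1, dt = 5)
  expect_error(simulate_network(net, fx$params, stim_big), "lattice")
})

test_that("Euler integration converges at first order in the step size", {
  fx <- make_motion_motif(radius = 1)
  net <- tile_network(fx$spec, hex_lattice(1))
  mk <- function(dt) {
    stim <- circular_flash(net$lattice, 1, radius = 1, warmup = 100,
                           flash = 200, dt = dt)
    init <- steady_state(net, fx$params, duration = 1000, dt = 1)
    simulate_network(net, fx$params, stim, dt = dt, init = init,
                     record = central_cells(net)$id)
  }
  t5 <- mk(5); t2.5 <- mk(2.5); t1.25 <- mk(1.25)
  # compare states at common times against the dt/4 reference
  sub <- function(tr, k) tr$V[seq(k, nrow(tr$V), by = k), , drop = FALSE]
  err5 <- max(abs(sub(t5, 1) - sub(t1.25, 4)))
  err2.5 <- max(abs(sub(t2.5, 2) - sub(t1.25, 4)[seq_len(nrow(sub(t2.5, 2))), ]))
  expect_gt(err5, 0)
  # halving dt roughly halves the error (first order); allow generous slack
  expect_lt(err2.5, 0.75 * err5)
})

test_that("the rectified-linear system is linear while voltages stay positive", {
  # relay chain biased into the positive regime: superposition holds
  spec <- toy_two_type_spec(du = 1L, dv = 0L, radius = 2L, count = 1, sign = 1)
  net <- tile_network(spec, hex_lattice(2))
  params <- toy_params(spec, tau = 20, v_rest = 1, alpha = 0.5)
  lat <- net$lattice
  base <- matrix(0.5, 40, lat$n)
  s1 <- base; s1[11:20, 3] <- 0.9
  s2 <- base; s2[16:30, 8] <- 0.8
  a <- 0.6; b <- 0.3
  mix <- a * s1 + b * s2
  run <- function(frames) {
    stim <- stimulus_sequence(frames, 5, lat)
    init <- rep(0, nrow(net$neurons))  # start at 0 so responses superpose
    compiled <- compile_network(net, params)
    V <- hexdmn:::dmn_forward(compiled, frames, 5, init)
    V
  }
  Vmix <- run(mix); V1 <- run(s1); V2 <- run(s2); V0 <- run(0 * base)
  # affine superposition: resp(a s1 + b s2) - resp(0) relates linearly when
  # every voltage stays >= 0 along all four trajectories
  expect_true(min(V1, V2, Vmix, V0) >= 0)
  lhs <- Vmix - V0
  rhs <- a * (V1 - V0) + b * (V2 - V0)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})
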