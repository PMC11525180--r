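test_that("flash response index follows its defining formula", {
  # constructed traces with known peaks: r1 = 3, r0 = 1 (no negative part)
  on <- c(0, 1, 3, 2); off <- c(0, 1, 0.5, 0.2)
  expect_equal(as.numeric(flash_response_index(on, off)), (3 - 1) / (3 + 1))
  expect_equal(as.numeric(flash_response_index(on, on)), 0)
  # shared negative excursion enters both peaks via the global minimum
  on2 <- c(-2, 4); off2 <- c(0, 1)
  r1 <- 4 + 2; r0 <- 1 + 2
  expect_equal(as.numeric(flash_response_index(on2, off2)), (r1 - r0) / (r1 + r0))
  # both peaks zero: undefined, flagged
  z <- flash_response_index(c(0, 0), c(0, 0))
  expect_true(is.na(z))
  expect_true(attr(z, "undefined"))
})

test_that("an ON-rectifying relay has positive FRI for any positive gain", {
  for (alpha in c(0.3, 1, 3)) {
    spec <- toy_two_type_spec(du = 0L, dv = 0L, radius = 2L)
    net <- tile_network(spec, hex_lattice(2))
    params <- toy_params(spec, tau = 20, v_rest = 0, alpha = alpha)
    fri <- fri_protocol(net, params, types = "B", radius = 2)
    expect_gt(fri$fri, 0)
  }
})

test_that("DSI matches the brute-force complex-sum formula", {
  th <- edge_directions()
  # response at exactly one direction of the dominant intensity: DSI 1
  pk <- array(0, c(12, 2, 2), dimnames = list(th, c(10, 20), c(0, 1)))
  pk[4, , 2] <- 5
  d <- dsi(pk)
  expect_equal(unname(d["1"]), 1)
  expect_equal(unname(d["0"]), 0)
  # equal response at all directions cancels
  pk_flat <- array(1, c(12, 1, 1), dimnames = list(th, "10", "1"))
  expect_equal(unname(dsi(pk_flat)), 0)
  # two equal responses 180 degrees apart cancel
  pk2 <- array(0, c(12, 1, 1), dimnames = list(th, "10", "1"))
  pk2[c(1, 7), , ] <- 3
  expect_equal(unname(dsi(pk2)), 0)
  # cosine tuning: closed form against an independent evaluation
  set.seed(4)
  for (rep in 1:5) {
    th0 <- runif(1, 0, 360)
    r <- 1 + cos((th - th0) * pi / 180)
    pk3 <- array(r, c(12, 3, 2), dimnames = list(th, c(1, 2, 3), c(0, 1)))
    pk3[, , 1] <- pk3[, , 1] * 0.5
    # oracle: direct formula evaluation with explicit loops
    oracle <- 0
    for (s in 1:3) {
      vs <- abs(sum(r * exp(1i * th * pi / 180)))
      denom <- max(abs(sum(r * 0.5)), abs(sum(r)))
      oracle <- oracle + vs / denom
    }
    oracle <- oracle / 3
    expect_equal(unname(dsi(pk3)["1"]), oracle)
    # invariance to a global rotation of all directions
    sh <- sample(12, 1)
    pk_rot <- pk3[c(seq(sh, 12), seq_len(sh - 1)), , , drop = FALSE]
    dimnames(pk_rot)[[1]] <- th
    expect_equal(unname(dsi(pk_rot)["1"]), unname(dsi(pk3)["1"]))
  }
  # preferred direction recovers the tuning peak at the best speed
  r <- 1 + cos((th - 90) * pi / 180)
  pk4 <- array(r, c(12, 1, 1), dimnames = list(th, "1", "1"))
  expect_equal(preferred_direction(pk4), 90)
})

test_that("permutation null pools d* samples and takes the 99% quantile", {
  th <- edge_directions()
  # constant peaks: every d* equals |sum exp(i theta)| / 12 = 0
  pk <- array(2, c(12, 2, 2), dimnames = list(th, c(1, 2), c(0, 1)))
  null <- permutation_null(list(pk), n_perm = 50, seed = 3)
  expect_equal(max(abs(null$samples)), 0, tolerance = 1e-12)
  expect_equal(null$threshold, 0, tolerance = 1e-12)
  # reproducible under seed; samples bounded in [0, 1]
  set.seed(8)
  pk2 <- array(runif(12 * 2 * 2), c(12, 2, 2), dimnames = list(th, c(1, 2), c(0, 1)))
  n1 <- permutation_null(list(pk2), seed = 5)
  n2 <- permutation_null(list(pk2), seed = 5)
  expect_identical(n1$threshold, n2$threshold)
  expect_true(all(n1$samples >= 0 & n1$samples <= 1 + 1e-12))
  expect_identical(length(n1$samples), 400L)  # 4 conditions x 100 permutations
  expect_error(permutation_null(list()), "at least one")
})

test_that("binomial classification of selectivity uses the exact tail", {
  r0 <- classify_direction_selective(rep(0, 50), threshold = 0.3)
  expect_false(r0$selective)
  r50 <- classify_direction_selective(rep(1, 50), threshold = 0.3)
  expect_true(r50$selective)
  expect_equal(r50$p_value, 0.1^50)
  # 10 of 50 exceed: closed-form upper tail at p0 = 0.1
  vals <- c(rep(1, 10), rep(0, 40))
  r10 <- classify_direction_selective(vals, threshold = 0.5)
  tail <- sum(dbinom(10:50, 50, 0.1))
  expect_equal(r10$p_value, tail)
  expect_true(r10$selective)
})

test_that("receptive fields are baseline-subtracted with the right slices", {
  offsets <- data.frame(u = c(0L, 1L, -1L), v = c(0L, 0L, 1L))
  traces <- cbind(c(1, 1, 4, 2), c(0.5, 0.5, 0.5, 1.5), c(2, 2, 2, 2))
  rf <- receptive_fields(traces, offsets)
  expect_equal(rf$strf[1, ], c(0, 0, 0))          # zero at the first sample
  expect_identical(rf$peak_step, 3L)              # central extremum at step 3
  expect_equal(rf$srf, c(3, 0, 0))
  expect_equal(rf$trf, c(0, 0, 3, 1))
  # zero-weight network: STRF vanishes for a non-photoreceptor cell
  fx <- make_motion_motif(radius = 2)
  p0 <- fx$params; p0$alpha[] <- 0
  net <- tile_network(fx$spec, hex_lattice(2))
  rf0 <- strf_protocol(net, p0, "Det", window = 1, pre = 100, post = 100)
  expect_equal(max(abs(rf0$strf)), 0, tolerance = 1e-9)
})

test_that("linear-regime STRF amplitude scales with flash contrast", {
  spec <- toy_two_type_spec(du = 0L, dv = 0L, radius = 1L)
  net <- tile_network(spec, hex_lattice(1))
  params <- toy_params(spec, tau = 20, v_rest = 1, alpha = 0.5)
  run <- function(I) {
    ctr <- central_cells(net, "B")
    stim <- ommatidium_flash(net$lattice, 0L, 0L, I, duration = 100,
                             pre = 200, post = 200, dt = 5)
    tr <- simulate_network(net, params, stim, dt = 5, record = ctr$id,
                           init = steady_state(net, params, duration = 2000, dt = 5))
    tr$V[, 1] - tr$V[1, 1]
  }
  # excursion +0.5 vs +0.25 above grey: amplitude doubles in the linear regime
  big <- run(1); small <- run(0.75)
  expect_equal(max(abs(big)), 2 * max(abs(small)), tolerance = 1e-6)
})

test_that("response normalization is scale invariant and flags zero RMS", {
  r_nat <- c(1, 2, 2, 3)
  tr <- c(2, 4)
  n1 <- normalize_response(tr, r_nat)
  expect_false(attr(n1, "excluded"))
  # a model with all responses scaled by 10 normalizes identically
  n10 <- normalize_response(10 * tr, 10 * r_nat)
  expect_equal(as.numeric(n10), as.numeric(n1))
  # trace equal to its own normalizer has unit RMS afterwards
  self <- normalize_response(r_nat, r_nat)
  expect_equal(sqrt(mean(self^2)), 1)
  # cross-model average of two scaled copies equals either normalized copy
  avg <- (as.numeric(n1) + as.numeric(n10)) / 2
  expect_equal(avg, as.numeric(n1))
  z <- normalize_response(tr, c(0, 0))
  expect_true(attr(z, "excluded"))
  expect_true(all(is.na(z)))
})

test_that("tuning correlation takes the maximum over speeds", {
  set.seed(12)
  ref <- rnorm(12)
  curve <- cbind(rnorm(12), ref, -ref)
  expect_equal(tuning_correlation(curve, ref), 1)
  expect_equal(tuning_correlation(cbind(-ref, -ref + rnorm(12, 0, 1e-8)), ref),
               -1, tolerance = 1e-4)
  # oracle: max over per-speed correlations
  curve2 <- matrix(rnorm(12 * 6), 12, 6)
  oracle <- max(apply(curve2, 2, cor, y = ref))
  expect_equal(tuning_correlation(curve2, ref), oracle)
  # constant speeds are skipped, not zero
  expect_equal(tuning_correlation(cbind(rep(1, 12), ref), ref), 1)
})

test_that("model selection applies sign, threshold and acceptance angle", {
  crit <- data.frame(type = "Det", fri_sign = 1, pref_dir = 0)
  mk <- function(model, fri, dsi, pd)
    data.frame(model = model, type = "Det", fri = fri, dsi = dsi, pref_dir = pd)
  stats_df <- rbind(
    mk("good", 0.4, 0.5, 40),     # 40 degrees off: inside the 45-degree cone
    mk("wide", 0.4, 0.5, 50),     # 50 degrees off: outside
    mk("flip", -0.4, 0.5, 10),    # wrong contrast sign
    mk("weak", 0.4, 0.1, 10))     # below the DSI threshold
  sel <- select_models(stats_df, crit, dsi_threshold = 0.3)
  expect_identical(sel, "good")
  expect_identical(length(select_models(stats_df[0, ], crit, 0.3)), 0L)
  # wrap-around distance: 350 degrees is 10 degrees from 0
  expect_identical(select_models(mk("wrap", 0.4, 0.5, 350), crit, 0.3), "wrap")
})
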