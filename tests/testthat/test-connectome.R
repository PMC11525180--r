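test_that("connectome tables round-trip through CSV with validation", {
  spec <- make_motion_motif(radius = 2)$spec
  dir <- withr::local_tempdir()
  write_connectome(spec, dir)
  spec2 <- read_connectome(dir, input_types = "R1")
  expect_identical(spec2$types$name, spec$types$name)
  expect_equal(spec2$filters$count, spec$filters$count)
  expect_identical(spec2$pairs$sign, spec$pairs$sign)
  # empty filter table loads cleanly
  lat <- hex_lattice(1)
  empty <- connectome_spec(
    data.frame(name = "A"),
    data.frame(type = "A", u = lat$u, v = lat$v),
    data.frame(pre_type = character(0), post_type = character(0),
               du = integer(0), dv = integer(0), count = numeric(0)),
    data.frame(pre_type = character(0), post_type = character(0),
               sign = numeric(0)),
    input_types = character(0))
  expect_identical(nrow(empty$filters), 0L)
  net <- tile_network(empty, lat)
  expect_identical(nrow(net$connections), 0L)
})

test_that("schema violations are rejected with the offending row", {
  types <- data.frame(name = c("A", "B"))
  cov <- data.frame(type = c("A", "B"), u = 0L, v = 0L)
  sgn <- data.frame(pre_type = "A", post_type = "B", sign = 1)
  fil <- data.frame(pre_type = "A", post_type = "B", du = 0L, dv = 0L, count = 2)
  expect_silent(connectome_spec(types, cov, fil, sgn))
  bad_type <- fil; bad_type$pre_type <- "Z"
  expect_error(connectome_spec(types, cov, bad_type, sgn), "row 1.*'Z'")
  dup <- rbind(fil, fil)
  expect_error(connectome_spec(types, cov, dup, sgn), "duplicate filter entry at row 2")
  expect_error(connectome_spec(types, cov, fil,
                               data.frame(pre_type = "B", post_type = "A", sign = 1)),
               "no sign entry")
  neg <- fil; neg$count <- -1
  expect_error(connectome_spec(types, cov, neg, sgn), "non-positive synapse count")
  expect_error(connectome_spec(types, cov, fil, transform(sgn, sign = 2)),
               "outside")
})

test_that("tiling instantiates the translation-invariant filter exactly", {
  # 2 types, full coverage, one filter at (1,0), radius 1: 14 neurons and
  # one connection per (pre, post) column pair at offset (1,0) inside the
  # hexagon -- 4 such pairs by direct enumeration: pre in
  # {(0,0),(-1,0),(-1,1),(0,-1)} keeps pre+(1,0) inside the radius-1 ring
  spec <- toy_two_type_spec(du = 1L, dv = 0L, radius = 1L)
  net <- tile_network(spec, hex_lattice(1))
  expect_identical(nrow(net$neurons), 14L)
  expect_identical(nrow(net$connections), 4L)
  # every connection offset matches its filter entry
  nn <- net$neurons
  for (k in seq_len(nrow(net$connections))) {
    pre <- nn[nn$id == net$connections$pre[k], ]
    post <- nn[nn$id == net$connections$post[k], ]
    f <- spec$filters[net$connections$filter[k], ]
    expect_identical(post$u - pre$u, f$du)
    expect_identical(post$v - pre$v, f$dv)
    expect_identical(pre$type, f$pre_type)
    expect_identical(post$type, f$post_type)
  }
  # single self-filter at the origin of a radius-0 lattice
  lat0 <- hex_lattice(0)
  self_spec <- connectome_spec(
    data.frame(name = "A"),
    data.frame(type = "A", u = 0L, v = 0L),
    data.frame(pre_type = "A", post_type = "A", du = 0L, dv = 0L, count = 1),
    data.frame(pre_type = "A", post_type = "A", sign = 1),
    input_types = character(0))
  net0 <- tile_network(self_spec, lat0)
  expect_identical(nrow(net0$neurons), 1L)
  expect_identical(nrow(net0$connections), 1L)
})

test_that("tile connection counts equal the brute-force pair enumeration", {
  for (case in list(list(du = 1L, dv = 0L, r = 2L), list(du = -1L, dv = 2L, r = 3L),
                    list(du = 0L, dv = 0L, r = 2L))) {
    spec <- toy_two_type_spec(du = case$du, dv = case$dv, radius = case$r)
    net <- tile_network(spec, hex_lattice(case$r))
    expect_identical(nrow(net$connections), brute_force_connections(spec, net))
  }
  # richer motif connectome, radius 3
  fx <- make_motion_motif(radius = 3)
  net <- tile_network(fx$spec, hex_lattice(3))
  expect_identical(nrow(net$connections), brute_force_connections(fx$spec, net))
})

test_that("tiling is translation-equivariant on partial coverage", {
  lat <- hex_lattice(3)
  base_cov <- data.frame(type = "A", u = c(0L, 1L, 0L), v = c(0L, 0L, 1L))
  shift <- function(cov, du, dv) transform(cov, u = u + du, v = v + dv)
  mk <- function(cov) {
    spec <- connectome_spec(
      data.frame(name = "A"), cov,
      data.frame(pre_type = "A", post_type = "A", du = 1L, dv = 0L, count = 1),
      data.frame(pre_type = "A", post_type = "A", sign = 1),
      input_types = character(0))
    tile_network(spec, lat)
  }
  n0 <- mk(base_cov)
  n1 <- mk(shift(base_cov, -1L, 1L))
  expect_identical(nrow(n0$neurons), nrow(n1$neurons))
  expect_setequal(paste(n0$neurons$u - 1L, n0$neurons$v + 1L),
                  paste(n1$neurons$u, n1$neurons$v))
  expect_identical(nrow(n0$connections), nrow(n1$connections))
})

test_that("synaptic weights scale exactly with synapse count", {
  expect_identical(synaptic_weight(5, 1, 0.1) / synaptic_weight(10, 1, 0.1), 0.5)
  expect_identical(synaptic_weight(7, -1, 0), 0)
  expect_equal(synaptic_weight(3, -1, 0.01), -0.03)
  expect_error(synaptic_weight(3, 1, -0.1), "non-negative")
})

test_that("parameter initialization follows the stated distributions", {
  lat <- hex_lattice(1)
  cov <- data.frame(type = rep(c("A", "B"), each = lat$n),
                    u = rep(lat$u, 2), v = rep(lat$v, 2))
  spec <- connectome_spec(
    data.frame(name = c("A", "B")), cov,
    data.frame(pre_type = "A", post_type = "B", du = c(0L, 1L), dv = 0L,
               count = c(2, 4)),
    data.frame(pre_type = "A", post_type = "B", sign = 1),
    input_types = character(0))
  p <- init_parameters(spec, seed = 11)
  expect_equal(unname(p$tau), c(50, 50))
  expect_equal(p$alpha, 0.01 / 3)   # mean count (2 + 4)/2 = 3
  expect_identical(p, init_parameters(spec, seed = 11))
  expect_false(identical(p$v_rest, init_parameters(spec, seed = 12)$v_rest))
  # resting potentials sample the stated Gaussian
  many <- replicate(400, init_parameters(spec, seed = sample.int(1e6, 1))$v_rest[1])
  expect_equal(mean(many), 0.5, tolerance = 0.05)
  expect_equal(stats::var(many), 0.05, tolerance = 0.3)
})

test_that("free-parameter counts match the sharing-scheme formulas", {
  expect_identical(count_parameters("unconstrained", T = 65, C = 721), 2196421955)
  expect_identical(count_parameters("type_convolutional", T = 65, C = 721), 3046355)
  expect_identical(count_parameters("filter_window", T = 65, F = 5), 384605)
  expect_identical(count_parameters("connectome_sparse", T = 65, Q = 604), 734)
  expect_identical(count_parameters("unconstrained", T = 1, C = 1), 3)
  expect_error(count_parameters("bogus", T = 2), "unknown scheme")
})

test_that("scheme parameter buffers expose the right trainable counts", {
  fx <- make_motion_motif(radius = 2)
  spec <- fx$spec
  Q <- nrow(spec$pairs); Tt <- nrow(spec$types)
  full <- build_scheme_parameters(spec, "full", seed = 3)
  expect_equal(full$n_trainable, Q + 2 * Tt)
  expect_equal(full$n_trainable,
               count_parameters("connectome_sparse", T = Tt, Q = Q))
  ls <- build_scheme_parameters(spec, "learn_signs", seed = 3)
  expect_false(any(ls$buffers$count$trainable))
  expect_true(all(ls$buffers$sign$trainable))
  expect_true(all(ls$buffers$sign$init %in% c(-1, 1)))
  lc <- build_scheme_parameters(spec, "learn_counts", seed = 3)
  expect_true(all(lc$buffers$m$init >= 0))
  expect_identical(nrow(lc$buffers$m), nrow(spec$filters))
  la <- build_scheme_parameters(spec, "learn_all", seed = 3)
  # window |du|,|dv|,|du+dv| < 3 covers 19 offsets per connected pair
  expect_identical(nrow(la$buffers$w), 19L * Q)
  expect_identical(build_scheme_parameters(spec, "learn_all", seed = 3),
                   build_scheme_parameters(spec, "learn_all", seed = 3))
  expect_false(identical(la$buffers$w$init,
                         build_scheme_parameters(spec, "learn_all", seed = 4)$buffers$w$init))
  expect_error(build_scheme_parameters(spec, "bogus"), "unknown scheme")
})
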