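# Shared toy builders used across test files.

# two-type connectome with full coverage and a single filter at offset
# (du, dv); used for analytically tractable assembly and dynamics checks
toy_two_type_spec <- function(du = 1L, dv = 0L, radius = 1L, count = 1,
                              sign = 1) {
  lat <- hex_lattice(radius)
  coverage <- data.frame(type = rep(c("R1", "B"), each = lat$n),
                         u = rep(lat$u, 2L), v = rep(lat$v, 2L))
  connectome_spec(
    types = data.frame(name = c("R1", "B")),
    coverage = coverage,
    filters = data.frame(pre_type = "R1", post_type = "B", du = du, dv = dv,
                         count = count),
    signs = data.frame(pre_type = "R1", post_type = "B", sign = sign),
    input_types = "R1")
}

toy_params <- function(spec, tau = 20, v_rest = 0, alpha = 1) {
  tn <- spec$types$name
  structure(list(tau = stats::setNames(rep(tau, length(tn)), tn),
                 v_rest = stats::setNames(rep(v_rest, length(tn)), tn),
                 alpha = rep(alpha, max(1L, nrow(spec$pairs)))),
            class = "dmn_params")
}

# brute-force connection enumeration: double loop over all neuron pairs
# testing filter membership
brute_force_connections <- function(spec, net) {
  nn <- net$neurons
  hits <- 0L
  for (i in seq_len(nrow(nn))) for (j in seq_len(nrow(nn))) {
    post <- nn[i, ]; pre <- nn[j, ]
    match <- spec$filters$pre_type == pre$type &
      spec$filters$post_type == post$type &
      spec$filters$du == post$u - pre$u &
      spec$filters$dv == post$v - pre$v
    hits <- hits + sum(match)
  }
  hits
}
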