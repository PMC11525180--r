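#' Threshold-linear rectifier
#'
#' Graded synaptic release is modelled as a threshold-linear function of the
#' presynaptic voltage, `f(V) = max(V, 0)`, approximating nonlinear
#' voltage-gated neurotransmitter release. The threshold is fixed at 0.
#'
#' @param v Numeric vector of voltages.
#' @return Rectified voltages.
#' @export
rectify <- function(v) pmax(v, 0)

#' Compile an assembled network into simulation buffers
#'
#' Turns the connection list into a sparse weight matrix (rows = postsynaptic
#' neuron, columns = presynaptic neuron) plus per-neuron time constants,
#' resting potentials and the external-input map. This is the scatter/gather
#' compilation: the per-connection weight `alpha * sign * count` is gathered
#' from the shared parameter buffers via the connection's pair and filter
#' indices, and summed synaptic input is one sparse matrix-vector product.
#'
#' @param net An [tile_network()] result.
#' @param params A [init_parameters()] result (or a list with `tau`, `v_rest`
#'   per type and `alpha` per pair).
#' @return List with sparse matrix `W`, numeric `tau`, `v_rest` (per neuron),
#'   integer `input_ids` and `input_cols` (photoreceptor neurons and their
#'   lattice columns), and `n`.
#' @export
compile_network <- function(net, params) {
  stopifnot(inherits(net, "assembled_network"))
  n <- nrow(net$neurons)
  cn <- net$connections
  w <- connection_weights(net, params)
  W <- Matrix::sparseMatrix(i = cn$post, j = cn$pre, x = w, dims = c(n, n))
  tt <- net$neurons$type
  tau <- unname(params$tau[tt])
  v_rest <- unname(params$v_rest[tt])
  is_input <- tt %in% net$spec$input_types
  list(W = W, tau = tau, v_rest = v_rest,
       input_ids = net$neurons$id[is_input],
       input_cols = net$neurons$column[is_input], n = n)
}

#' Per-connection synaptic weights
#'
#' @param net An [tile_network()] result.
#' @param params Parameter set with `alpha` per pair.
#' @return Numeric vector, one weight per connection row.
#' @export
connection_weights <- function(net, params) {
  cn <- net$connections
  alpha <- params$alpha[cn$pair]
  if (any(alpha < 0, na.rm = TRUE)) stop("'alpha' must be non-negative")
  sgn <- net$spec$pairs$sign[cn$pair]
  synaptic_weight(cn$count, sgn, alpha)
}

# reference evaluation of summed synaptic input by an explicit loop over
# connections; used as an oracle against the sparse product
naive_synaptic_input <- function(net, weights, V) {
  out <- numeric(nrow(net$neurons))
  cn <- net$connections
  fV <- rectify(V)
  for (k in seq_len(nrow(cn)))
    out[cn$post[k]] <- out[cn$post[k]] + weights[k] * fV[cn$pre[k]]
  out
}

#' One Euler step of the voltage dynamics
#'
#' Advances `tau dV/dt = -V + W f(V) + V_rest + e` by one step of length `dt`:
#' `V <- V + (dt / max(tau, dt)) * (-V + W f(V) + V_rest + e)`. Time constants
#' are clamped at the integration step so the update never overshoots the
#' leak.
#'
#' @param V Numeric state vector (one voltage per neuron).
#' @param compiled A [compile_network()] result.
#' @param e External input per neuron (numeric vector or scalar 0); nonzero
#'   only for photoreceptors in the standard protocols.
#' @param dt Positive integration step, ms.
#' @return The next state vector.
#' @export
neural_step <- function(V, compiled, e = 0, dt = 5) {
  if (dt <= 0) stop("'dt' must be positive")
  if (length(V) != compiled$n) stop("state length does not match network size")
  if (!(length(e) %in% c(1L, compiled$n))) stop("input length does not match network size")
  tau_eff <- pmax(compiled$tau, dt)
  drive <- -V + as.numeric(compiled$W %*% rectify(V)) + compiled$v_rest + e
  V + (dt / tau_eff) * drive
}

# external-input vector for a uniform luminance on all photoreceptors
grey_input <- function(compiled, luminance = 0.5) {
  e <- numeric(compiled$n)
  e[compiled$input_ids] <- luminance
  e
}

#' Relax the network to its grey-screen steady state
#'
#' Simulates constant uniform luminance input from the resting state
#' (`V = V_rest`, the fixed point of the unconnected system). Every stimulus
#' protocol initializes from this state.
#'
#' @param net An [tile_network()] result.
#' @param params Parameter set.
#' @param luminance Grey level (default 0.5).
#' @param duration Warm-up duration, ms.
#' @param dt Integration step, ms.
#' @param compiled Optional pre-compiled buffers (skips recompilation).
#' @return Numeric state vector after the warm-up.
#' @export
steady_state <- function(net, params, luminance = 0.5, duration = 500, dt = 5,
                         compiled = NULL) {
  if (duration < 0) stop("'duration' must be non-negative")
  if (is.null(compiled)) compiled <- compile_network(net, params)
  V <- compiled$v_rest
  e <- grey_input(compiled, luminance)
  n_steps <- ceiling(duration / dt)
  for (s in seq_len(n_steps)) {
    V <- neural_step(V, compiled, e, dt)
    if (!all(is.finite(V)))
      stop(sprintf("numerical divergence at warm-up step %d (t = %g ms)", s, s * dt))
  }
  V
}

#' Simulate the network response to a stimulus sequence
#'
#' The stimulus is resampled to the integration rate by zero-order hold and
#' its per-column luminance is added as external input current to the
#' photoreceptor neurons of the matching column. The trace of the recorded
#' neurons is returned on a stimulus-aligned time base.
#'
#' @param net An [tile_network()] result.
#' @param params Parameter set.
#' @param stimulus A `stimulus_sequence` (see [stimulus_sequence()]); its
#'   lattice must match the network's.
#' @param dt Integration step, ms (default: the stimulus frame interval).
#' @param record Integer neuron ids to record (default: all neurons).
#' @param init Initial state vector (default: grey-screen [steady_state()]
#'   with 500 ms warm-up at the same `dt`).
#' @param compiled Optional pre-compiled buffers.
#' @return An object of class `"response_trace"`: list with matrix `V`
#'   (time x recorded neuron), `times` (ms, end of each step), `dt`,
#'   `neurons` (recorded ids) and `stimulus` metadata.
#' @export
simulate_network <- function(net, params, stimulus, dt = stimulus$frame_dt,
                             record = NULL, init = NULL, compiled = NULL) {
  stopifnot(inherits(stimulus, "stimulus_sequence"))
  if (is.null(compiled)) compiled <- compile_network(net, params)
  if (!identical(stimulus$lattice$n, net$lattice$n) ||
      !identical(stimulus$lattice$radius, net$lattice$radius))
    stop("stimulus lattice does not match network lattice")
  if (is.null(record)) record <- net$neurons$id
  if (is.null(init))
    init <- steady_state(net, params, duration = 500, dt = dt, compiled = compiled)
  frames <- stimulus$frames
  duration <- nrow(frames) * stimulus$frame_dt
  n_steps <- ceiling(duration / dt)
  V <- init
  out <- matrix(NA_real_, n_steps, length(record))
  e <- numeric(compiled$n)
  for (s in seq_len(n_steps)) {
    k <- min(nrow(frames), ceiling(s * dt / stimulus$frame_dt))
    e[compiled$input_ids] <- frames[k, compiled$input_cols]
    V <- neural_step(V, compiled, e, dt)
    if (!all(is.finite(V)))
      stop(sprintf("numerical divergence at step %d (t = %g ms)", s, s * dt))
    out[s, ] <- V[record]
  }
  structure(list(V = out, times = seq_len(n_steps) * dt, dt = dt,
                 neurons = record,
                 stimulus = stimulus$meta),
            class = "response_trace")
}

#' @export
print.response_trace <- function(x, ...) {
  cat(sprintf("<response_trace> %d steps x %d neurons, dt = %g ms\n",
              nrow(x$V), ncol(x$V), x$dt))
  invisible(x)
}
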