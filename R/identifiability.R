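# Identifiability simulation: can a network refit under connectome
# constraints recover the responses of the ground-truth network that
# generated the connectome? Ground truths are sparse Dale's-law feedforward
# rectifier networks trained on a ten-class image task and sparsified by
# iterative magnitude (lottery-ticket) pruning; "measured" connectomes expose
# the adjacency and presynaptic signs (and optionally noisy weight
# magnitudes), and simulated networks are refit from scratch under those
# constraints.

#' Create a Dale's-law feedforward rectifier network
#'
#' Units follow `V_i = sum_j sigma_j c_ij m_ij f(V_j) + V_i^rest` with
#' `f = max(., 0)`: every presynaptic unit (input pixels and hidden units)
#' carries one sign used by all of its outgoing synapses (Dale's law),
#' synapse magnitudes `m_ij >= 0`, and a binary adjacency `c_ij`. The readout
#' layer maps the last hidden layer to the 10 class logits under the same
#' sign constraint.
#'
#' @param d_in Input dimension.
#' @param hidden Hidden-layer width (default 128).
#' @param n_hidden Number of hidden layers (default 6).
#' @param d_out Output classes (default 10).
#' @param seed Integer RNG seed (magnitudes and signs).
#' @return Object of class `"dale_net"`: lists `m` (pre x post magnitude
#'   matrices), `mask` (adjacency), `v_rest` (per layer), `signs` (one sign
#'   per unit of each presynaptic layer), `sizes`.
#' @export
dale_network <- function(d_in, hidden = 128L, n_hidden = 6L, d_out = 10L,
                         seed = 1L) {
  sizes <- c(d_in, rep(hidden, n_hidden), d_out)
  withr::with_seed(seed, {
    L <- length(sizes) - 1L
    m <- mask <- v_rest <- vector("list", L)
    signs <- lapply(sizes[-length(sizes)], function(n)
      sample(c(-1, 1), n, replace = TRUE))
    for (l in seq_len(L)) {
      m[[l]] <- matrix(abs(stats::rnorm(sizes[l] * sizes[l + 1L],
                                        0, sqrt(2 / sizes[l]))),
                       sizes[l], sizes[l + 1L])
      mask[[l]] <- matrix(1, sizes[l], sizes[l + 1L])
      # small positive resting potentials keep units in the active regime at
      # initialization (balanced +/- inputs would otherwise silence deep
      # layers and block all gradient flow)
      v_rest[[l]] <- rep(0.1, sizes[l + 1L])
    }
    structure(list(m = m, mask = mask, v_rest = v_rest, signs = signs,
                   sizes = sizes),
              class = "dale_net")
  })
}

#' Calibrate resting potentials on a probe batch
#'
#' Sign-constrained networks have a layer-wide common mode at initialization
#' (all magnitudes are non-negative, so every unit is coupled to the signed
#' input sum), which can silence entire layers. This sets each unit's resting
#' potential so that its median pre-activation over the probe batch equals a
#' small positive `target`, layer by layer, leaving roughly half of the
#' responses in the active regime. Resting potentials remain free parameters
#' afterwards.
#'
#' @param net A [dale_network()].
#' @param x Probe images (rows).
#' @param target Median voltage after calibration (default 0.1).
#' @return The calibrated network.
#' @export
dale_calibrate <- function(net, x, target = 0.1) {
  a <- x
  L <- length(net$m)
  for (l in seq_len(L)) {
    W <- net$signs[[l]] * net$mask[[l]] * net$m[[l]]
    drive <- rectify(a) %*% W
    net$v_rest[[l]] <- target - apply(drive, 2L, stats::median)
    a <- sweep(drive, 2L, net$v_rest[[l]], "+")
  }
  net
}

# forward pass; returns per-layer voltages (before rectification) and logits
dale_forward <- function(net, x) {
  a <- x                       # inputs are non-negative luminances
  L <- length(net$m)
  volts <- vector("list", L - 1L)
  for (l in seq_len(L)) {
    W <- net$signs[[l]] * net$mask[[l]] * net$m[[l]]
    v <- sweep(rectify(a) %*% W, 2L, net$v_rest[[l]], "+")
    if (l < L) {
      volts[[l]] <- v
      a <- v
    } else {
      logits <- v
    }
  }
  list(volts = volts, logits = logits)
}

#' Classification accuracy of a Dale network
#' @param net A [dale_network()].
#' @param x,y Images (rows) and integer labels 0-9.
#' @return Fraction correct.
#' @export
dale_accuracy <- function(net, x, y) {
  logits <- dale_forward(net, x)$logits
  mean(max.col(logits, ties.method = "first") - 1L == y)
}

# softmax cross-entropy loss and gradient w.r.t. logits
softmax_ce <- function(logits, y) {
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = g / n)
}

# backward pass: gradients for magnitudes and resting potentials
dale_backward <- function(net, x, fw, dlogits) {
  L <- length(net$m)
  acts <- c(list(x), lapply(fw$volts, rectify))   # presynaptic activities
  gm <- vector("list", L)
  gv <- vector("list", L)
  d <- dlogits
  for (l in seq.int(L, 1L)) {
    W <- net$signs[[l]] * net$mask[[l]] * net$m[[l]]
    gW <- crossprod(rectify(acts[[l]]), d)
    gm[[l]] <- net$signs[[l]] * net$mask[[l]] * gW
    gv[[l]] <- colSums(d)
    if (l > 1L) {
      da <- d %*% t(W)
      d <- da * (fw$volts[[l - 1L]] > 0)
    }
  }
  list(m = gm, v_rest = gv)
}

#' Train a Dale network by projected adaptive-moment descent
#'
#' Minimizes the softmax cross-entropy with the max-variant adaptive-moment
#' optimizer (learning rate 0.001, batch 500, learning-rate decay 0.5 per
#' epoch); magnitudes are clamped at zero after every step so Dale's law and
#' non-negativity hold throughout. Optionally adds a squared-distance penalty
#' pulling the magnitudes towards a measured reference (`m_ref`), weighted
#' `l2_weight` times the task objective.
#'
#' @param net A [dale_network()].
#' @param x,y Training images and labels.
#' @param epochs Training epochs.
#' @param lr Initial learning rate.
#' @param batch Minibatch size.
#' @param decay Learning-rate decay factor per epoch.
#' @param m_ref Optional list of reference magnitude matrices.
#' @param l2_weight Weight of the reference penalty (default 10).
#' @param seed Integer RNG seed (shuffling).
#' @return The trained network (masks, signs unchanged).
#' @export
train_dale <- function(net, x, y, epochs = 4L, lr = 0.001, batch = 500L,
                       decay = 0.5, m_ref = NULL, l2_weight = 10, seed = 1L) {
  par <- list()
  for (l in seq_along(net$m)) {
    par[[paste0("m", l)]] <- net$m[[l]]
    par[[paste0("v", l)]] <- net$v_rest[[l]]
  }
  state <- adam_init(par)
  n <- nrow(x)
  it <- 0L
  for (ep in seq_len(epochs)) {
    lr_ep <- lr * decay^(ep - 1L)
    ord <- withr::with_seed(seed * 613L + ep, sample.int(n))
    for (start in seq(1L, n, by = batch)) {
      it <- it + 1L
      rows <- ord[start:min(start + batch - 1L, n)]
      fw <- dale_forward(net, x[rows, , drop = FALSE])
      sc <- softmax_ce(fw$logits, y[rows])
      gb <- dale_backward(net, x[rows, , drop = FALSE], fw, sc$grad)
      grads <- list()
      for (l in seq_along(net$m)) {
        g <- gb$m[[l]]
        if (!is.null(m_ref))
          g <- g + l2_weight * 2 * (net$m[[l]] - m_ref[[l]]) * net$mask[[l]] /
            length(rows)
        grads[[paste0("m", l)]] <- g
        grads[[paste0("v", l)]] <- gb$v_rest[[l]]
      }
      upd <- adam_step(par, grads, state, lr_ep, amsgrad = TRUE)
      par <- upd$par
      state <- upd$state
      for (l in seq_along(net$m)) {
        net$m[[l]] <- pmax(par[[paste0("m", l)]], 0)
        par[[paste0("m", l)]] <- net$m[[l]]
        net$v_rest[[l]] <- par[[paste0("v", l)]]
      }
    }
  }
  net
}

# fraction of surviving prunable weights (readout excluded)
dale_connectivity <- function(net) {
  pr <- seq_len(length(net$mask) - 1L)
  sum(vapply(net$mask[pr], sum, numeric(1))) /
    sum(vapply(net$mask[pr], length, numeric(1))) * 100
}

#' Sparsify a trained network by iterative magnitude pruning
#'
#' Lottery-ticket-style local pruning: in each round the smallest-magnitude
#' `prune_frac` of the surviving weights of every prunable layer (input and
#' hidden-to-hidden; the 10-way readout is never pruned) are removed, and the
#' network is retrained from the pruned state. Rounds continue until the
#' surviving connectivity is at or below `target_pct`. Pruning only removes
#' connections (masks are non-increasing).
#'
#' @param net A trained [dale_network()].
#' @param x,y Training data for the retraining rounds.
#' @param target_pct Target connectivity percentage (0-100].
#' @param prune_frac Fraction of surviving weights removed per round.
#' @param retrain_epochs Epochs of retraining per round.
#' @param seed Integer RNG seed.
#' @param ... Passed to [train_dale()] for the retraining rounds.
#' @return The pruned, retrained network with a `pruning` history attribute.
#' @export
lottery_prune <- function(net, x, y, target_pct, prune_frac = 0.2,
                          retrain_epochs = 2L, seed = 1L, ...) {
  if (target_pct <= 0 || target_pct > 100) stop("'target_pct' must be in (0, 100]")
  hist <- data.frame(round = 0L, connectivity = dale_connectivity(net),
                     accuracy = NA_real_)
  round <- 0L
  while (dale_connectivity(net) > target_pct) {
    round <- round + 1L
    for (l in seq_len(length(net$mask) - 1L)) {
      alive <- which(net$mask[[l]] > 0)
      n_drop <- floor(prune_frac * length(alive))
      if (n_drop < 1L) next
      mags <- net$m[[l]][alive]
      drop <- alive[order(mags)[seq_len(n_drop)]]
      net$mask[[l]][drop] <- 0
      net$m[[l]][drop] <- 0
    }
    net <- train_dale(net, x, y, epochs = retrain_epochs,
                      seed = seed + round, ...)
    hist <- rbind(hist, data.frame(round = round,
                                   connectivity = dale_connectivity(net),
                                   accuracy = NA_real_))
  }
  attr(net, "pruning") <- hist
  net
}

#' Train a sparse ground-truth connectome network
#'
#' Dense training followed by [lottery_prune()] down to the target
#' connectivity. If the pruned network's held-out accuracy falls below
#' `accuracy_floor` times the dense accuracy, the best effort is returned
#' with a warning.
#'
#' @param task A [make_digit_task()] dataset.
#' @param target_pct Target connectivity percentage.
#' @param hidden,n_hidden Network size (defaults 128 and 6).
#' @param epochs Dense-training epochs.
#' @param retrain_epochs Retraining epochs per pruning round.
#' @param accuracy_floor Minimal acceptable accuracy relative to dense.
#' @param seed Integer RNG seed.
#' @return The pruned `"dale_net"` with attributes `pruning` and
#'   `accuracies` (`dense`, `pruned`).
#' @export
train_ground_truth <- function(task, target_pct, hidden = 128L, n_hidden = 6L,
                               epochs = 4L, retrain_epochs = 2L,
                               accuracy_floor = 0.9, seed = 1L, ...) {
  net <- dale_network(ncol(task$x_train), hidden, n_hidden, seed = seed)
  net <- dale_calibrate(net, task$x_train)
  net <- train_dale(net, task$x_train, task$y_train, epochs = epochs,
                    seed = seed, ...)
  dense_acc <- dale_accuracy(net, task$x_test, task$y_test)
  net <- lottery_prune(net, task$x_train, task$y_train, target_pct,
                       retrain_epochs = retrain_epochs, seed = seed, ...)
  pruned_acc <- dale_accuracy(net, task$x_test, task$y_test)
  if (pruned_acc < accuracy_floor * dense_acc)
    warning(sprintf("pruned accuracy %.3f below floor (%.3f of dense %.3f)",
                    pruned_acc, accuracy_floor, dense_acc))
  attr(net, "accuracies") <- c(dense = dense_acc, pruned = pruned_acc)
  net
}

#' Simulate a connectome measurement of a ground-truth network
#'
#' Copies the adjacency and the presynaptic signs. In the `"with_strength"`
#' regime the measurement additionally reports noisy magnitudes
#' `m~ = m * eps` with `eps ~ Uniform(1 - sigma, 1 + sigma)` i.i.d. per
#' connection (`sigma = 0.5` for the main results; `sigma >= 1` would allow
#' non-positive strengths and is rejected).
#'
#' @param net The ground-truth [dale_network()].
#' @param sigma Multiplicative measurement-noise half-width, in `[0, 1)`.
#' @param regime `"connectivity_only"` or `"with_strength"`.
#' @param seed Integer RNG seed.
#' @return Object of class `"measured_connectome"`: `mask`, `signs`,
#'   `sizes`, and `m_tilde` (only in the with-strength regime).
#' @export
measure_connectome <- function(net, sigma = 0.5,
                               regime = c("connectivity_only", "with_strength"),
                               seed = 1L) {
  regime <- match.arg(regime)
  if (sigma < 0 || sigma >= 1)
    stop("'sigma' must be in [0, 1): larger noise allows non-positive strengths")
  out <- list(mask = net$mask, signs = net$signs, sizes = net$sizes,
              regime = regime)
  if (regime == "with_strength") {
    out$m_tilde <- withr::with_seed(seed, lapply(net$m, function(M)
      M * matrix(stats::runif(length(M), 1 - sigma, 1 + sigma),
                 nrow(M), ncol(M))))
  }
  structure(out, class = "measured_connectome")
}

#' Fit a simulated network to a measured connectome
#'
#' Builds a network with the measured adjacency and signs frozen, and
#' task-optimizes the free parameters: magnitudes and resting potentials. In
#' the `"connectivity_only"` regime magnitudes start random; in the
#' `"with_strength"` regime they start at the measured `m~` and a squared
#' distance to `m~`, weighted ten times the task objective, keeps them close
#' to the measurement. Masked-out connections stay exactly zero.
#'
#' @param measured A [measure_connectome()] result.
#' @param task A [make_digit_task()] dataset.
#' @param epochs Training epochs.
#' @param seed Integer RNG seed.
#' @param ... Passed to [train_dale()].
#' @return The fitted `"dale_net"`.
#' @export
fit_simulated <- function(measured, task, epochs = 4L, seed = 1L, ...) {
  stopifnot(inherits(measured, "measured_connectome"))
  sizes <- measured$sizes
  net <- dale_network(sizes[1L], sizes[2L], length(sizes) - 2L,
                      sizes[length(sizes)], seed = seed + 7777L)
  net$mask <- measured$mask
  net$signs <- measured$signs
  net$m <- lapply(seq_along(net$m), function(l) net$m[[l]] * net$mask[[l]])
  if (measured$regime == "with_strength") {
    net$m <- measured$m_tilde
    net <- dale_calibrate(net, task$x_train)
    train_dale(net, task$x_train, task$y_train, epochs = epochs,
               m_ref = measured$m_tilde, l2_weight = 10, seed = seed, ...)
  } else {
    net <- dale_calibrate(net, task$x_train)
    train_dale(net, task$x_train, task$y_train, epochs = epochs, seed = seed, ...)
  }
}

#' Response similarity between ground-truth and simulated networks
#'
#' Pearson correlation of the rectified voltages of corresponding neurons
#' over a stimulus set, for up to `n_per_layer` randomly sampled neurons in
#' each hidden layer; the summary is the median over all sampled neurons of
#' all hidden layers. Neurons with constant response in either network are
#' excluded (their count is reported).
#'
#' @param gt,sim Two [dale_network()]s with matching architecture.
#' @param stimuli Stimulus matrix (images in rows), e.g. the task test set.
#' @param n_per_layer Neurons sampled per hidden layer (default 100).
#' @param seed Integer RNG seed for the sampling.
#' @return List with `median`, `per_layer` medians, `correlations` and
#'   `n_excluded`.
#' @export
network_similarity <- function(gt, sim, stimuli, n_per_layer = 100L, seed = 1L) {
  stopifnot(identical(gt$sizes, sim$sizes))
  fg <- dale_forward(gt, stimuli)$volts
  fs <- dale_forward(sim, stimuli)$volts
  n_layers <- length(fg)
  per_layer <- numeric(n_layers)
  cors <- list()
  excluded <- 0L
  idx <- withr::with_seed(seed, lapply(seq_len(n_layers), function(l)
    sample.int(ncol(fg[[l]]), min(n_per_layer, ncol(fg[[l]])))))
  for (l in seq_len(n_layers)) {
    rg <- rectify(fg[[l]][, idx[[l]], drop = FALSE])
    rs <- rectify(fs[[l]][, idx[[l]], drop = FALSE])
    cc <- vapply(seq_along(idx[[l]]), function(j) {
      if (stats::sd(rg[, j]) == 0 || stats::sd(rs[, j]) == 0) return(NA_real_)
      stats::cor(rg[, j], rs[, j])
    }, numeric(1))
    excluded <- excluded + sum(is.na(cc))
    cors[[l]] <- cc
    per_layer[l] <- stats::median(cc, na.rm = TRUE)
  }
  all_c <- unlist(cors)
  list(median = stats::median(all_c, na.rm = TRUE), per_layer = per_layer,
       correlations = cors, n_excluded = excluded)
}

#' Run the sparsity-identifiability experiment
#'
#' For each connectivity density, trains `n_pairs` ground-truth networks,
#' simulates connectome measurements in one or both regimes, refits simulated
#' networks, and scores ground-truth/simulation response similarity on the
#' task test set. The headline comparison is the median similarity per
#' (density, regime) across pairs.
#'
#' @param task A [make_digit_task()] dataset.
#' @param connectivities Connectivity percentages (default 10, 40, 80).
#' @param regimes Regimes to run (default both).
#' @param n_pairs Ground-truth/simulation pairs per density.
#' @param hidden,n_hidden Network size.
#' @param epochs,retrain_epochs,fit_epochs Training budgets.
#' @param sigma Measurement-noise half-width for the with-strength regime.
#' @param n_per_layer Neurons sampled per layer for the similarity.
#' @param seed Integer RNG seed.
#' @param ... Further optimizer settings (`batch`, `decay`, `lr`) passed to
#'   [train_dale()].
#' @return List with `results` (one row per pair) and `summary` (median
#'   similarity per density and regime).
#' @export
identifiability_experiment <- function(task, connectivities = c(10, 40, 80),
                                       regimes = c("connectivity_only",
                                                   "with_strength"),
                                       n_pairs = 3L, hidden = 128L,
                                       n_hidden = 6L, epochs = 4L,
                                       retrain_epochs = 2L, fit_epochs = 4L,
                                       sigma = 0.5, n_per_layer = 100L,
                                       seed = 1L, ...) {
  rows <- list()
  for (ci in seq_along(connectivities)) for (p in seq_len(n_pairs)) {
    gt_seed <- seed + 100L * ci + p
    gt <- train_ground_truth(task, connectivities[ci], hidden = hidden,
                             n_hidden = n_hidden, epochs = epochs,
                             retrain_epochs = retrain_epochs, seed = gt_seed, ...)
    for (rg in regimes) {
      meas <- measure_connectome(gt, sigma = sigma, regime = rg,
                                 seed = gt_seed + 31L)
      sim <- fit_simulated(meas, task, epochs = fit_epochs,
                           seed = gt_seed + 57L, ...)
      sm <- network_similarity(gt, sim, task$x_test, n_per_layer = n_per_layer,
                               seed = gt_seed + 91L)
      rows[[length(rows) + 1L]] <-
        data.frame(connectivity = connectivities[ci], regime = rg, pair = p,
                   similarity = sm$median,
                   gt_accuracy = attr(gt, "accuracies")[["pruned"]],
                   sim_accuracy = dale_accuracy(sim, task$x_test, task$y_test))
    }
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(similarity ~ connectivity + regime, results,
                              stats::median)
  list(results = results, summary = summary)
}
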