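# Optic-flow decoding head: a small feedforward convolutional network with no
# temporal structure. Rectified voltages of the decoder cell types are
# scattered from the hexagonal lattice onto a square grid (axial raster:
# pixel (u + r + 1, v + r + 1), injective for any lattice of radius r),
# passed through a 5x5 convolution to 8 channels, batch normalization,
# softplus and dropout, then a second 5x5 convolution to 3 channels. The
# first two output channels, gathered back at the lattice pixels and divided
# by a softplus of the third (shared-normalization) channel, are the flow
# prediction. During training, normalization statistics are taken over all
# frames and grid positions of the processed sequence (and folded into
# running averages); at evaluation the running averages are used, so the
# decoder maps each frame independently. Forward and reverse passes are
# written out explicitly; feature maps are (frame-position x channel)
# matrices.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_grad <- function(x) 1 / (1 + exp(-x))

# fast column-wise arithmetic on small matrices (sweep is too slow here)
addc <- function(x, v) x + v[col(x)]
subc <- function(x, v) x - v[col(x)]
mulc <- function(x, v) x * v[col(x)]
divc <- function(x, v) x / v[col(x)]

# gather index for a k x k convolution on a G x G grid with zero padding,
# in im2col form: `flat[p + (o-1) P]` is the input position feeding output
# position p at filter offset o, with G*G + 1 denoting the zero pad row
conv_index <- function(G, k) {
  half <- (k - 1L) %/% 2L
  pos <- expand.grid(row = seq_len(G), col = seq_len(G))
  flat <- integer(0)
  for (dc in seq.int(-half, half)) for (dr in seq.int(-half, half)) {
    r <- pos$row + dr
    c <- pos$col + dc
    ok <- r >= 1L & r <= G & c >= 1L & c <= G
    flat <- c(flat, ifelse(ok, (c - 1L) * G + r, G * G + 1L))
  }
  P <- G * G
  keep <- flat <= P
  scatter <- Matrix::sparseMatrix(i = flat[keep], j = which(keep), x = 1,
                                  dims = c(P, length(flat)))
  list(flat = flat, P = P, k2 = k * k, scatter = scatter)
}

# one gather + one matrix product per frame: columns of the patch matrix are
# ordered offset-fastest, matching the flattening of the (k2, Cin, Cout)
# kernel
conv_patches <- function(X, idx) {
  Cin <- ncol(X)
  Xcol <- rbind(X, 0)[idx$flat, , drop = FALSE]
  dim(Xcol) <- c(idx$P, idx$k2 * Cin)
  Xcol
}

conv_forward <- function(Xcol, W, b) {
  W2d <- W
  dim(W2d) <- c(dim(W)[1L] * dim(W)[2L], dim(W)[3L])
  addc(Xcol %*% W2d, b)
}

conv_backward <- function(dY, Xcol, W, idx, n_frames) {
  Cin <- dim(W)[2L]
  W2d <- W
  dim(W2d) <- c(idx$k2 * Cin, dim(W)[3L])
  dW <- crossprod(Xcol, dY)
  dim(dW) <- dim(W)
  dXcol <- dY %*% t(W2d)
  # scatter patch gradients back to grid positions, frame by frame
  dX <- matrix(NA_real_, n_frames * idx$P, Cin)
  for (n in seq_len(n_frames)) {
    rows <- (n - 1L) * idx$P + seq_len(idx$P)
    block <- dXcol[rows, , drop = FALSE]
    dim(block) <- c(idx$P * idx$k2, Cin)
    dX[rows, ] <- as.matrix(idx$scatter %*% block)
  }
  list(dW = dW, db = colSums(dY), dX = dX)
}

#' Decoder configuration and initialization
#'
#' @param d_in Number of input cell types (feature maps).
#' @param radius Lattice radius the decoder operates on.
#' @param channels Hidden channels (default 8).
#' @param kernel Convolution kernel side (default 5).
#' @param dropout Dropout probability on the hidden layer (default 0.5).
#' @param init Homogeneous initial filter value (default 0.001).
#' @return List of class `"flow_decoder"` with parameter arrays, the
#'   normalization running statistics, and layout.
#' @export
flow_decoder <- function(d_in, radius, channels = 8L, kernel = 5L,
                         dropout = 0.5, init = 0.001) {
  G <- 2L * radius + 1L
  par <- list(
    W1 = array(init, c(kernel * kernel, d_in, channels)),
    b1 = numeric(channels),
    gamma = rep(1, channels),
    beta = numeric(channels),
    W2 = array(init, c(kernel * kernel, channels, 3L)),
    b2 = numeric(3L))
  structure(list(par = par, d_in = d_in, radius = radius, G = G,
                 channels = channels, kernel = kernel, dropout = dropout,
                 bn_mean = numeric(channels), bn_var = rep(1, channels),
                 bn_momentum = 0.1,
                 idx = conv_index(G, kernel)),
            class = "flow_decoder")
}

# lattice columns -> raster positions on the G x G grid
raster_positions <- function(lattice) {
  r <- lattice$radius
  G <- 2L * r + 1L
  (lattice$v + r) * G + (lattice$u + r + 1L)
}

bn_eps <- 1e-5

# whole-sequence decoder forward; act: N x D x C activity array.
# train = TRUE uses (and reports) batch statistics over all frames and grid
# positions; train = FALSE uses the stored running statistics, making the
# map per-frame pure. Returns predictions (N x 2 x C) and, when keep = TRUE,
# the intermediates for the reverse pass.
decoder_seq_forward <- function(decoder, act, rpos, train = FALSE,
                                drop_mask = NULL, keep = FALSE) {
  N <- dim(act)[1L]
  P <- decoder$idx$P
  p <- decoder$par
  X1 <- matrix(NA_real_, N * P, decoder$idx$k2 * decoder$d_in)
  X <- matrix(0, P, decoder$d_in)
  for (n in seq_len(N)) {
    X[] <- 0
    X[rpos, ] <- t(matrix(act[n, , ], dim(act)[2L], dim(act)[3L]))
    X1[(n - 1L) * P + seq_len(P), ] <- conv_patches(X, decoder$idx)
  }
  Z1 <- conv_forward(X1, p$W1, p$b1)
  if (train) {
    mu <- colMeans(Z1)
    xc <- subc(Z1, mu)
    va <- colMeans(xc^2)
  } else {
    mu <- decoder$bn_mean
    va <- decoder$bn_var
    xc <- subc(Z1, mu)
  }
  xhat <- divc(xc, sqrt(va + bn_eps))
  H <- addc(mulc(xhat, p$gamma), p$beta)
  S <- softplus(H)
  Dd <- if (is.null(drop_mask)) S else S * drop_mask
  X2 <- matrix(NA_real_, N * P, decoder$idx$k2 * decoder$channels)
  for (n in seq_len(N)) {
    rows <- (n - 1L) * P + seq_len(P)
    X2[rows, ] <- conv_patches(Dd[rows, , drop = FALSE], decoder$idx)
  }
  Y <- conv_forward(X2, p$W2, p$b2)
  pred <- array(NA_real_, c(N, 2L, length(rpos)))
  ys <- array(NA_real_, c(N, length(rpos), 3L))
  for (n in seq_len(N)) {
    y <- Y[(n - 1L) * P + rpos, , drop = FALSE]
    ys[n, , ] <- y
    pred[n, , ] <- t(y[, 1:2] / softplus(y[, 3L]))
  }
  out <- list(pred = pred, mu = mu, va = va)
  if (keep) {
    out <- c(out, list(X1 = X1, Z1 = Z1, xhat = xhat, H = H, X2 = X2,
                       ys = ys, train = train, N = N))
  }
  out
}

# reverse pass over a whole sequence; dpred: N x 2 x C. Returns parameter
# gradients and the gradient with respect to the activities (N x C x D).
decoder_seq_backward <- function(decoder, fw, dpred, rpos, drop_mask = NULL) {
  p <- decoder$par
  P <- decoder$idx$P
  N <- fw$N
  C <- length(rpos)
  dY <- matrix(0, N * P, 3L)
  for (n in seq_len(N)) {
    y <- matrix(fw$ys[n, , ], C, 3L)
    denom <- softplus(y[, 3L])
    dp <- matrix(dpred[n, , ], 2L, C)
    dy <- cbind(dp[1L, ] / denom, dp[2L, ] / denom,
                -(dp[1L, ] * y[, 1L] + dp[2L, ] * y[, 2L]) / denom^2 *
                  softplus_grad(y[, 3L]))
    dY[(n - 1L) * P + rpos, ] <- dy
  }
  bw2 <- conv_backward(dY, fw$X2, p$W2, decoder$idx, N)
  dDd <- bw2$dX
  dS <- if (is.null(drop_mask)) dDd else dDd * drop_mask
  dH <- dS * softplus_grad(fw$H)
  dgamma <- colSums(dH * fw$xhat)
  dbeta <- colSums(dH)
  dxhat <- mulc(dH, p$gamma)
  sd_ <- sqrt(fw$va + bn_eps)
  if (fw$train) {
    # gradients flow through the batch statistics
    xc <- mulc(fw$xhat, sd_)
    dvar <- colSums(dxhat * xc) * (-0.5) / sd_^3
    dmu <- -colSums(dxhat) / sd_
    n <- nrow(fw$Z1)
    dZ1 <- addc(divc(dxhat, sd_) + mulc(xc, 2 * dvar / n), dmu / n)
  } else {
    dZ1 <- divc(dxhat, sd_)
  }
  bw1 <- conv_backward(dZ1, fw$X1, p$W1, decoder$idx, N)
  dact <- array(NA_real_, c(N, C, decoder$d_in))
  for (n in seq_len(N))
    dact[n, , ] <- bw1$dX[(n - 1L) * P + rpos, , drop = FALSE]
  list(grads = list(W1 = bw1$dW, b1 = bw1$db, gamma = dgamma, beta = dbeta,
                    W2 = bw2$dW, b2 = bw2$db),
       dact = dact)
}

# fold a sequence's batch statistics into the decoder's running averages
decoder_update_bn <- function(decoder, mu, va) {
  m <- decoder$bn_momentum
  decoder$bn_mean <- (1 - m) * decoder$bn_mean + m * mu
  decoder$bn_var <- (1 - m) * decoder$bn_var + m * va
  decoder
}

#' Decode optic flow from neural activity
#'
#' Applies the decoder to a (time x type x column) array of rectified
#' voltages in evaluation mode: normalization uses the stored running
#' statistics and dropout is off, so the decoder is purely feedforward and
#' per-frame — it has no temporal structure, and any motion information must
#' already be present in the network dynamics feeding it.
#'
#' @param decoder A [flow_decoder()].
#' @param activity Numeric array `time x d_in x columns` of rectified
#'   voltages of the decoder input types.
#' @param lattice The [hex_lattice()] the columns are ordered by.
#' @return Flow prediction, array `time x 2 x columns`.
#' @export
decode_flow <- function(decoder, activity, lattice) {
  stopifnot(inherits(decoder, "flow_decoder"),
            length(dim(activity)) == 3L,
            dim(activity)[2L] == decoder$d_in,
            dim(activity)[3L] == lattice$n,
            lattice$radius == decoder$radius)
  rpos <- raster_positions(lattice)
  decoder_seq_forward(decoder, activity, rpos, train = FALSE)$pred
}
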