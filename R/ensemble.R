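# Ensemble-level analyses: models trained from different seeds under the same
# connectome and task constraints are compared by embedding their normalized
# central-column responses in 2-D, fitting Gaussian mixtures (2-5 components,
# Bayesian information criterion selection), and ranking by task error.

# deterministic 2-D principal-component embedding; sign of each component is
# fixed by its largest-magnitude loading so the embedding does not depend on
# numerical sign conventions
pca_embed <- function(x, seed = 1L) {
  x <- as.matrix(x)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = 2L)
  rot <- p$rotation
  for (j in seq_len(ncol(rot))) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) rot[, j] <- -rot[, j]
  }
  emb <- scale(x, center = p$center, scale = FALSE) %*% rot
  if (ncol(emb) < 2L) emb <- cbind(emb, 0)
  unname(emb[, 1:2, drop = FALSE])
}

#' Cluster ensemble models by their response predictions
#'
#' Embeds each model's (normalized, concatenated) response vector into two
#' dimensions and fits Gaussian mixtures with 2 to 5 components, keeping the
#' component count that minimizes the Bayesian information criterion.
#' Component labels are returned up to permutation. The embedding is a
#' pluggable contract: any deterministic-under-seed function
#' `function(x, seed)` returning one 2-D point per model; the default is a
#' principal-component projection.
#'
#' @param responses Numeric matrix, models x response features (normalize per
#'   model first, e.g. with [normalize_response()]).
#' @param seed Integer seed passed to the embedding.
#' @param k_range Candidate component counts (default 2:5); candidates
#'   exceeding the number of models are skipped.
#' @param embed Embedding function (default [pca_embed]).
#' @return List of class `"cluster_report"`: `embedding` (models x 2), `k`
#'   (chosen components), `classification` (cluster label per model), `bic`
#'   (criterion per candidate k, smaller is better), `model` (covariance
#'   model name).
#' @export
cluster_models <- function(responses, seed = 1L, k_range = 2:5,
                           embed = pca_embed) {
  responses <- as.matrix(responses)
  n <- nrow(responses)
  if (n < 2L) stop("need at least 2 models to cluster")
  k_range <- k_range[k_range <= n]
  if (!length(k_range)) stop("all candidate component counts exceed the ensemble size")
  emb <- embed(responses, seed)
  fit <- withr::with_seed(seed,
    mclust::Mclust(emb, G = k_range, verbose = FALSE))
  if (is.null(fit)) stop("mixture fitting failed for all candidate k")
  # mclust maximizes 2*loglik - npar*log(n); report the standard (minimized) BIC
  bics <- -apply(fit$BIC, 1L, max, na.rm = TRUE)
  structure(list(embedding = emb, k = fit$G,
                 classification = as.integer(fit$classification),
                 bic = stats::setNames(bics, rownames(fit$BIC)),
                 model = fit$modelName),
            class = "cluster_report")
}

#' Per-cluster mean task error
#'
#' @param report A [cluster_models()] report.
#' @param task_error Numeric vector of per-model task errors (same model
#'   order as the clustered response matrix).
#' @return Data frame with `cluster`, `n`, `mean_error`, sorted by error.
#' @export
cluster_task_errors <- function(report, task_error) {
  stopifnot(length(task_error) == length(report$classification))
  agg <- stats::aggregate(task_error,
                          by = list(cluster = report$classification), FUN = mean)
  out <- data.frame(cluster = agg$cluster,
                    n = as.integer(table(report$classification)[as.character(agg$cluster)]),
                    mean_error = agg$x)
  out[order(out$mean_error), ]
}

#' Rank ensemble models by validation task error
#'
#' Computes the mean end-point error of each model on the validation split
#' and returns the models in ascending order (best first). Lower task error
#' correlates with more realistic tuning, so this ranking is the basis for
#' selecting models for mechanistic analysis.
#'
#' @param models List of models, each a list with elements `params` and
#'   `decoder` (sharing `net`).
#' @param net The assembled network.
#' @param dataset Validation dataset.
#' @param ... Passed to [validate_epe()].
#' @return Data frame with `model` (index into `models`) and `epe`,
#'   ascending.
#' @export
rank_by_task_error <- function(models, net, dataset, ...) {
  errs <- vapply(models, function(m)
    validate_epe(net, m$params, m$decoder, dataset, ...), numeric(1))
  out <- data.frame(model = seq_along(models), epe = errs)
  out[order(out$epe), ]
}

#' Maximally excitatory naturalistic stimulus
#'
#' Screens a dataset of stimulus sequences for the one that elicits the
#' strongest response (maximum over time of the voltage) in the central cell
#' of a given type. The result depends only on the set of sequences, not
#' their order (ties resolve to the first).
#'
#' @param net,params Assembled network and parameters.
#' @param dataset A dataset with `sequences` (each with `frames`) and
#'   `frame_dt`, e.g. [make_drifting_dataset()].
#' @param type Cell type whose central cell is probed.
#' @param dt Integration step, ms.
#' @return List with `index` (best sequence), `response` (its peak voltage)
#'   and `responses` (peak voltage per sequence).
#' @export
naturalistic_mes <- function(net, params, dataset, type, dt = dataset$frame_dt) {
  if (!length(dataset$sequences)) stop("empty stimulus dataset")
  ctr <- central_cells(net, type)
  if (nrow(ctr) != 1L) stop("no central cell of type '", type, "'")
  compiled <- compile_network(net, params)
  init <- steady_state(net, params, duration = 500, dt = dt, compiled = compiled)
  responses <- vapply(dataset$sequences, function(sq) {
    V <- dmn_forward(compiled, sq$frames, dt, init)
    max(V[-1L, ctr$id])
  }, numeric(1))
  list(index = which.max(responses), response = max(responses),
       responses = responses)
}

#' Regularize a maximally excitatory stimulus
#'
#' Starting from a (naturalistic) stimulus `X*`, minimizes
#' `L(X') = sum_n (V_c(X*)[n] - V_c(X')[n])^2 + (1/C) sum_{n,c} (X'[n,c] - 0.5)^2`
#' by projected gradient descent on the stimulus: the first term preserves
#' the central cell's response, the second pushes columns outside the cell's
#' receptive field towards grey. Steps are accepted only if they do not
#' increase the objective (backtracking line search), so the objective is
#' non-increasing across accepted steps; stimulus values are kept in
#' `[0, 1]`.
#'
#' @param net,params Assembled network and parameters.
#' @param type Cell type whose central response is preserved.
#' @param x_star Stimulus matrix `time x column` (the reference `X*`).
#' @param iterations Maximum accepted steps.
#' @param lr Initial step size.
#' @param grey_weight Weight of the grey prior (default 1; set 0 to recover
#'   `X' = X*` as the global minimizer).
#' @param dt Integration step, ms.
#' @return List with `stimulus` (the regularized `X'`), `objective` (per
#'   accepted step) and `reference` response trace.
#' @export
regularized_mes <- function(net, params, type, x_star, iterations = 30L,
                            lr = 0.5, grey_weight = 1, dt = 20) {
  ctr <- central_cells(net, type)
  if (nrow(ctr) != 1L) stop("no central cell of type '", type, "'")
  compiled <- compile_network(net, params)
  init <- steady_state(net, params, duration = 500, dt = dt, compiled = compiled)
  C <- ncol(x_star)
  v_ref <- dmn_forward(compiled, x_star, dt, init)[-1L, ctr$id]
  objective <- function(X, V = NULL) {
    if (is.null(V)) V <- dmn_forward(compiled, X, dt, init)
    vc <- V[-1L, ctr$id]
    sum((v_ref - vc)^2) + grey_weight / C * sum((X - 0.5)^2)
  }
  X <- x_star
  obj <- objective(X)
  hist <- obj
  for (it in seq_len(iterations)) {
    V <- dmn_forward(compiled, X, dt, init)
    vc <- V[-1L, ctr$id]
    g_loss <- matrix(0, nrow(X), compiled$n)
    g_loss[, ctr$id] <- -2 * (v_ref - vc)
    gb <- dmn_backward(net, compiled, params, V, g_loss, dt,
                       want_input_grad = TRUE)
    gX <- matrix(0, nrow(X), C)
    # photoreceptor input gradients, summed per column across input types
    agg <- rowsum(t(gb$input[, compiled$input_ids, drop = FALSE]),
                  compiled$input_cols)
    gX[, as.integer(rownames(agg))] <- t(agg)
    gX <- gX + grey_weight / C * 2 * (X - 0.5)
    accepted <- FALSE
    step <- lr
    for (tries in 1:8) {
      Xn <- pmin(pmax(X - step * gX, 0), 1)
      on <- objective(Xn)
      if (on <= obj) {
        X <- Xn; obj <- on; accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    hist <- c(hist, obj)
  }
  list(stimulus = X, objective = hist, reference = v_ref)
}
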