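#' Connectome specification
#'
#' A connectome is consumed as three plain tables: a per-type column coverage
#' table (which lattice columns hold a cell of each type), a filter table of
#' per-offset average synapse counts between cell types, and a sign table
#' giving the polarity (+1 depolarizing, -1 hyperpolarizing) of each connected
#' type pair. Filters are translation invariant: the synapse count between two
#' cells depends only on their types and the axial offset
#' `(du, dv) = (u_post - u_pre, v_post - v_pre)` between their columns.
#'
#' @param types Data frame with columns `name` and optionally `compartment_of`
#'   (parent type for electrotonically compartmentalized cells such as the two
#'   CT1 terminals, which are modelled as distinct entries).
#' @param coverage Data frame with columns `type`, `u`, `v`: one row per
#'   (type, column) holding a cell.
#' @param filters Data frame with columns `pre_type`, `post_type`, `du`, `dv`,
#'   `count` (positive real average synapse count).
#' @param signs Data frame with columns `pre_type`, `post_type`, `sign`
#'   (+1 or -1); every type pair appearing in `filters` must have a sign. The
#'   sign may differ across postsynaptic types of the same presynaptic type
#'   (as for R8 outputs).
#' @param input_types Character vector of cell types that receive external
#'   visual input. Defaults to all type names matching `^R[0-9]`, the
#'   photoreceptor naming convention.
#' @return An object of class `"connectome_spec"`, with a derived `pairs`
#'   table (one row per connected, signed type pair; `pair` ids index it) and
#'   a `pair` column added to `filters`.
#' @export
connectome_spec <- function(types, coverage, filters, signs, input_types = NULL) {
  types <- as.data.frame(types)
  coverage <- as.data.frame(coverage)
  filters <- as.data.frame(filters)
  signs <- as.data.frame(signs)
  if (!"name" %in% names(types)) stop("'types' needs a 'name' column")
  if (!"compartment_of" %in% names(types)) types$compartment_of <- NA_character_
  types$name <- as.character(types$name)
  if (anyDuplicated(types$name))
    stop("duplicate type name: ", types$name[duplicated(types$name)][1L])
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(sprintf("%s is missing column(s): %s", what,
                                   paste(miss, collapse = ", ")))
  }
  need(coverage, c("type", "u", "v"), "'coverage'")
  need(filters, c("pre_type", "post_type", "du", "dv", "count"), "'filters'")
  need(signs, c("pre_type", "post_type", "sign"), "'signs'")

  check_types <- function(x, what) {
    bad <- which(!(x %in% types$name))
    if (length(bad))
      stop(sprintf("%s row %d names undeclared type '%s'", what, bad[1L], x[bad[1L]]))
  }
  check_types(as.character(coverage$type), "'coverage'")
  check_types(as.character(filters$pre_type), "'filters' (pre_type)")
  check_types(as.character(filters$post_type), "'filters' (post_type)")
  check_types(as.character(signs$pre_type), "'signs' (pre_type)")
  check_types(as.character(signs$post_type), "'signs' (post_type)")
  if (nrow(filters)) {
    key <- paste(filters$pre_type, filters$post_type, filters$du, filters$dv)
    if (anyDuplicated(key))
      stop("duplicate filter entry at row ", which(duplicated(key))[1L])
    if (any(filters$count <= 0))
      stop("non-positive synapse count at 'filters' row ",
           which(filters$count <= 0)[1L])
  }
  signs$sign <- as.numeric(signs$sign)
  if (nrow(signs) && !all(signs$sign %in% c(-1, 1)))
    stop("'signs' row ", which(!(signs$sign %in% c(-1, 1)))[1L],
         " has sign outside {-1, +1}")
  skey <- paste(signs$pre_type, signs$post_type)
  if (anyDuplicated(skey))
    stop("duplicate sign entry at row ", which(duplicated(skey))[1L])
  fkey <- paste(filters$pre_type, filters$post_type)
  miss <- which(!(fkey %in% skey))
  if (length(miss))
    stop(sprintf("'filters' row %d (%s -> %s) has no sign entry", miss[1L],
                 filters$pre_type[miss[1L]], filters$post_type[miss[1L]]))
  cov_miss <- which(!(types$name %in% coverage$type))
  if (length(cov_miss))
    stop("type '", types$name[cov_miss[1L]], "' has empty coverage")

  # signed, connected type pairs in deterministic order of first appearance
  upairs <- unique(fkey)
  pairs <- data.frame(
    pre_type = sub(" .*$", "", upairs),
    post_type = sub("^[^ ]* ", "", upairs),
    stringsAsFactors = FALSE
  )
  pairs$sign <- signs$sign[match(upairs, skey)]
  filters$pair <- match(fkey, upairs)
  if (is.null(input_types)) input_types <- grep("^R[0-9]", types$name, value = TRUE)
  stopifnot(all(input_types %in% types$name))
  structure(list(types = types, coverage = coverage, filters = filters,
                 signs = signs, pairs = pairs, input_types = input_types),
            class = "connectome_spec")
}

#' @export
print.connectome_spec <- function(x, ...) {
  cat(sprintf("<connectome_spec> %d types, %d signed type pairs, %d filter entries\n",
              nrow(x$types), nrow(x$pairs), nrow(x$filters)))
  invisible(x)
}

#' Read a connectome from CSV tables
#'
#' Expects `filter_table.csv` (`pre_type`, `post_type`, `du`, `dv`, `count`),
#' `sign_table.csv` (`pre_type`, `post_type`, `sign`) and `coverage_table.csv`
#' (`type`, `u`, `v`), UTF-8 with a header row. Types are declared implicitly
#' by the coverage table (first-appearance order); an optional
#' `type_table.csv` (`name`, `compartment_of`) overrides the declaration.
#'
#' @param dir Directory containing the tables, or `NULL` to pass paths.
#' @param filter_table,sign_table,coverage_table,type_table Individual paths
#'   (override `dir`).
#' @param ... Passed to [connectome_spec()] (e.g. `input_types`).
#' @return A validated [connectome_spec()].
#' @export
read_connectome <- function(dir = NULL,
                            filter_table = file.path(dir, "filter_table.csv"),
                            sign_table = file.path(dir, "sign_table.csv"),
                            coverage_table = file.path(dir, "coverage_table.csv"),
                            type_table = if (!is.null(dir)) file.path(dir, "type_table.csv"),
                            ...) {
  rd <- function(p) utils::read.csv(p, stringsAsFactors = FALSE)
  filters <- rd(filter_table)
  signs <- rd(sign_table)
  coverage <- rd(coverage_table)
  if (!is.null(type_table) && file.exists(type_table)) {
    types <- rd(type_table)
  } else {
    types <- data.frame(name = unique(as.character(coverage$type)),
                        stringsAsFactors = FALSE)
  }
  connectome_spec(types, coverage, filters, signs, ...)
}

#' Write a connectome's tables to CSV
#' @param spec A [connectome_spec()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_connectome <- function(spec, dir) {
  stopifnot(inherits(spec, "connectome_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(spec$filters[c("pre_type", "post_type", "du", "dv", "count")],
                   file.path(dir, "filter_table.csv"), row.names = FALSE)
  utils::write.csv(spec$signs, file.path(dir, "sign_table.csv"), row.names = FALSE)
  utils::write.csv(spec$coverage, file.path(dir, "coverage_table.csv"), row.names = FALSE)
  utils::write.csv(spec$types, file.path(dir, "type_table.csv"), row.names = FALSE)
  invisible(dir)
}

#' Tile a connectome across a hexagonal lattice
#'
#' Instantiates one neuron per (type, covered column within the lattice) and
#' one connection per filter entry per column pair with both endpoints
#' instantiated. Connections whose presynaptic column falls outside the
#' lattice are dropped (truncation at the boundary, no wrap-around). Neuron
#' ids are dense and deterministic: types in declaration order, columns in
#' canonical lattice order.
#'
#' @param spec A [connectome_spec()].
#' @param lattice A [hex_lattice()].
#' @return An object of class `"assembled_network"`: list with `neurons`
#'   (data frame `id`, `type`, `u`, `v`, `column` = lattice position),
#'   `connections` (data frame `pre`, `post`, `filter` = row into
#'   `spec$filters`, plus cached `count`, `pair`), the `lattice` and `spec`.
#' @export
tile_network <- function(spec, lattice) {
  stopifnot(inherits(spec, "connectome_spec"), inherits(lattice, "hex_lattice"))
  tn <- spec$types$name
  neuron_list <- vector("list", length(tn))
  # per-type map from lattice position -> neuron id
  pos2id <- vector("list", length(tn))
  names(pos2id) <- tn
  next_id <- 0L
  for (ti in seq_along(tn)) {
    cov <- spec$coverage[spec$coverage$type == tn[ti], , drop = FALSE]
    pos <- hex_index(lattice, cov$u, cov$v)
    pos <- sort(pos[!is.na(pos)])
    ids <- if (length(pos)) next_id + seq_along(pos) else integer(0)
    next_id <- next_id + length(pos)
    neuron_list[[ti]] <- data.frame(
      id = ids, type = rep(tn[ti], length(pos)),
      u = lattice$u[pos], v = lattice$v[pos], column = pos,
      stringsAsFactors = FALSE)
    m <- rep(NA_integer_, lattice$n)
    m[pos] <- ids
    pos2id[[ti]] <- m
  }
  neurons <- do.call(rbind, neuron_list)
  rownames(neurons) <- NULL

  conn_list <- vector("list", nrow(spec$filters))
  for (fi in seq_len(nrow(spec$filters))) {
    f <- spec$filters[fi, ]
    post <- neuron_list[[match(f$post_type, tn)]]
    if (!nrow(post)) next
    pre_map <- pos2id[[f$pre_type]]
    pre_pos <- hex_index(lattice, post$u - f$du, post$v - f$dv)
    pre_id <- ifelse(is.na(pre_pos), NA_integer_, pre_map[pre_pos])
    ok <- !is.na(pre_id)
    if (!any(ok)) next
    conn_list[[fi]] <- data.frame(pre = pre_id[ok], post = post$id[ok],
                                  filter = fi, count = f$count, pair = f$pair)
  }
  connections <- do.call(rbind, conn_list)
  if (is.null(connections))
    connections <- data.frame(pre = integer(0), post = integer(0),
                              filter = integer(0), count = numeric(0),
                              pair = integer(0))
  rownames(connections) <- NULL
  structure(list(neurons = neurons, connections = connections,
                 lattice = lattice, spec = spec),
            class = "assembled_network")
}

#' @export
print.assembled_network <- function(x, ...) {
  cat(sprintf("<assembled_network> %d neurons, %d connections (radius-%d lattice)\n",
              nrow(x$neurons), nrow(x$connections), x$lattice$radius))
  invisible(x)
}

#' Synaptic weight from a filter entry
#'
#' The weight of a connection is `w = alpha * sign * count`: the average
#' synapse count scaled by the non-negative unitary synapse strength of its
#' type pair and signed by the pair's polarity. Within one type pair, weights
#' are therefore exactly proportional to synapse counts (five synapses are
#' half as strong as ten).
#'
#' @param count Positive synapse count(s).
#' @param sign Polarity, +1 or -1 (vectorized).
#' @param alpha Non-negative unitary synapse strength (vectorized).
#' @return Numeric weight(s).
#' @export
synaptic_weight <- function(count, sign, alpha) {
  if (any(alpha < 0)) stop("'alpha' must be non-negative")
  alpha * sign * count
}

#' Initialize the free biophysical parameters
#'
#' Per-type membrane time constants start at 50 ms; per-type resting
#' potentials are drawn from a Gaussian with mean 0.5 and variance 0.05
#' (arbitrary units); per type-pair unitary synapse strengths start at
#' `0.01 / <N>`, where `<N>` is the mean synapse count over that pair's filter
#' offsets. Identical seeds yield identical parameter sets.
#'
#' @param spec A [connectome_spec()].
#' @param seed Integer RNG seed.
#' @return An object of class `"dmn_params"`: list with named numeric vectors
#'   `tau` (ms, per type), `v_rest` (a.u., per type) and `alpha` (per signed
#'   type pair, in `spec$pairs` order).
#' @export
init_parameters <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "connectome_spec"))
  tn <- spec$types$name
  tau <- stats::setNames(rep(50, length(tn)), tn)
  v_rest <- withr::with_seed(seed,
    stats::setNames(stats::rnorm(length(tn), mean = 0.5, sd = sqrt(0.05)), tn))
  mean_count <- tapply(spec$filters$count, spec$filters$pair, mean)
  alpha <- rep(NA_real_, nrow(spec$pairs))
  alpha[as.integer(names(mean_count))] <- 0.01 / as.numeric(mean_count)
  structure(list(tau = tau, v_rest = v_rest, alpha = alpha), class = "dmn_params")
}

#' Free-parameter counts under different sharing assumptions
#'
#' Counts the trainable scalars of a recurrent threshold-linear model of `T`
#' cell types on `C` columns under progressively stronger structural
#' assumptions: `"unconstrained"` (every cell-to-cell weight free):
#' `(TC)^2 + 2TC`; `"type_convolutional"` (filters, time constants and resting
#' potentials shared within a type, filters span the whole lattice):
#' `T^2 C + 2T`; `"filter_window"` (filters restricted to a hex window of
#' radius `F`, covering `P = 3F(F+1) + 1` input columns): `T^2 P + 2T`;
#' `"connectome_sparse"` (only the `Q` measured type pairs connected, one
#' unitary strength each): `Q + 2T`.
#'
#' @param scheme One of `"unconstrained"`, `"type_convolutional"`,
#'   `"filter_window"`, `"connectome_sparse"`.
#' @param T Number of cell types.
#' @param C Number of columns (lattice size).
#' @param F Filter window radius in columns (for `"filter_window"`).
#' @param Q Number of connected type pairs (for `"connectome_sparse"`).
#' @return The integer parameter count (as numeric; counts can exceed the
#'   32-bit integer range).
#' @examples
#' count_parameters("connectome_sparse", T = 65, Q = 604) # 734
#' @export
count_parameters <- function(scheme, T, C = NULL, F = NULL, Q = NULL) {
  stopifnot(T > 0)
  switch(scheme,
    unconstrained = {
      stopifnot(!is.null(C), C > 0)
      (T * C)^2 + 2 * (T * C)
    },
    type_convolutional = {
      stopifnot(!is.null(C), C > 0)
      T^2 * C + 2 * T
    },
    filter_window = {
      stopifnot(!is.null(F), F > 0)
      P <- 3 * F * (F + 1) + 1
      T^2 * P + 2 * T
    },
    connectome_sparse = {
      stopifnot(!is.null(Q), Q > 0)
      Q + 2 * T
    },
    stop("unknown scheme '", scheme, "'")
  )
}

# offsets of the hex window |du|,|dv|,|du+dv| < w (w = 3: 19 offsets)
hex_window_offsets <- function(w = 3L) {
  g <- expand.grid(du = seq.int(-(w - 1L), w - 1L), dv = seq.int(-(w - 1L), w - 1L))
  g[abs(g$du + g$dv) < w, , drop = FALSE]
}

#' Lay out trainable parameter buffers for a constraint scheme
#'
#' Builds the per-scheme parameter buffers used in the constraint-ablation
#' experiments, with trainable/frozen masks and random initialization where a
#' quantity is learned rather than measured. Learned magnitudes `m` and signed
#' weights `w` are initialized from a Gaussian with variance `2 / n_in`
#' (`n_in` = number of incoming single-cell connections of the postsynaptic
#' type), magnitudes taken non-negative; learned signs are +1/-1 with equal
#' probability. Schemes that learn single-cell connectivity span all offsets
#' with `|du|, |dv|, |du+dv| < 3` (19 columns).
#'
#' Schemes: `"full"` (measured counts and signs; learn per-pair `alpha`),
#' `"learn_counts"` (adjacency and signs known; learn non-negative per-offset
#' magnitudes), `"learn_cell_conn"` (type connectivity and signs known; learn
#' magnitudes over the 3-column window), `"learn_signs"` (counts known; learn
#' per-pair `alpha` and presynaptic-type signs), `"learn_weights"` (adjacency
#' known; learn signed per-offset weights), `"learn_all"` (type connectivity
#' only; learn signed weights over the window).
#'
#' @param spec A [connectome_spec()].
#' @param scheme Scheme name, see Details.
#' @param seed Integer RNG seed.
#' @return List with the scheme name, a `buffers` list of data frames (each
#'   with an `init` value and a `trainable` flag per scalar), and the total
#'   trainable count `n_trainable`.
#' @export
build_scheme_parameters <- function(spec, scheme, seed = 1L) {
  stopifnot(inherits(spec, "connectome_spec"))
  schemes <- c("full", "learn_counts", "learn_cell_conn", "learn_signs",
               "learn_weights", "learn_all")
  if (!scheme %in% schemes) stop("unknown scheme '", scheme, "'")
  tn <- spec$types$name
  p0 <- init_parameters(spec, seed)
  cellular <- data.frame(name = rep(tn, 2L),
                         param = rep(c("tau", "v_rest"), each = length(tn)),
                         init = c(p0$tau, p0$v_rest), trainable = TRUE)
  # fan-in per postsynaptic type: number of incoming filter entries
  n_in <- stats::setNames(pmax(1L, as.integer(
    table(factor(spec$filters$post_type, levels = tn)))), tn)
  fil <- spec$filters
  pr <- spec$pairs
  win <- hex_window_offsets(3L)
  pair_window <- data.frame(pair = rep(seq_len(nrow(pr)), each = nrow(win)),
                            du = rep(win$du, nrow(pr)), dv = rep(win$dv, nrow(pr)))

  rand_mag <- function(post_types, seed, non_negative) {
    withr::with_seed(seed, {
      x <- stats::rnorm(length(post_types), 0, sqrt(2 / n_in[post_types]))
      if (non_negative) abs(x) else x
    })
  }
  buffers <- switch(scheme,
    full = list(
      alpha = data.frame(pair = seq_len(nrow(pr)), init = p0$alpha, trainable = TRUE),
      sign = data.frame(pair = seq_len(nrow(pr)), init = pr$sign, trainable = FALSE),
      count = data.frame(filter = seq_len(nrow(fil)), init = fil$count, trainable = FALSE)),
    learn_counts = list(
      m = data.frame(pair = fil$pair, du = fil$du, dv = fil$dv,
                     init = rand_mag(fil$post_type, seed, TRUE), trainable = TRUE),
      sign = data.frame(pair = seq_len(nrow(pr)), init = pr$sign, trainable = FALSE)),
    learn_cell_conn = list(
      m = data.frame(pair_window,
                     init = rand_mag(pr$post_type[pair_window$pair], seed, TRUE),
                     trainable = TRUE),
      sign = data.frame(pair = seq_len(nrow(pr)), init = pr$sign, trainable = FALSE)),
    learn_signs = list(
      alpha = data.frame(pair = seq_len(nrow(pr)), init = p0$alpha, trainable = TRUE),
      sign = data.frame(pre_type = tn,
                        init = withr::with_seed(seed + 1L,
                          sample(c(-1, 1), length(tn), replace = TRUE)),
                        trainable = TRUE),
      count = data.frame(filter = seq_len(nrow(fil)), init = fil$count, trainable = FALSE)),
    learn_weights = list(
      w = data.frame(pair = fil$pair, du = fil$du, dv = fil$dv,
                     init = rand_mag(fil$post_type, seed, FALSE), trainable = TRUE)),
    learn_all = list(
      w = data.frame(pair_window,
                     init = rand_mag(pr$post_type[pair_window$pair], seed, FALSE),
                     trainable = TRUE))
  )
  n_trainable <- nrow(cellular) +
    sum(vapply(buffers, function(b) sum(b$trainable), numeric(1)))
  list(scheme = scheme, cellular = cellular, buffers = buffers,
       n_trainable = n_trainable)
}
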