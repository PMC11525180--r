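#' Save a model to a plain-text JSON container
#'
#' Serializes the connectome tables, lattice radius and biophysical
#' parameters at full floating-point precision. The network itself is not
#' stored: tiling is deterministic, so [load_model()] reassembles an
#' identical network from the tables.
#'
#' @param net An [tile_network()] result.
#' @param params A parameter set.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(net, params, path) {
  stopifnot(inherits(net, "assembled_network"))
  spec <- net$spec
  # doubles are stored as 17-significant-digit strings, which round-trip to
  # the identical IEEE value
  enc <- function(x) stats::setNames(sprintf("%.17g", x), names(x))
  filters <- spec$filters[c("pre_type", "post_type", "du", "dv")]
  filters$count <- enc(spec$filters$count)
  obj <- list(
    container = "hexdmn_model", version = 1L,
    radius = net$lattice$radius,
    types = spec$types,
    coverage = spec$coverage,
    filters = filters,
    signs = spec$signs,
    input_types = spec$input_types,
    params = list(tau = as.list(enc(params$tau)),
                  v_rest = as.list(enc(params$v_rest)),
                  alpha = enc(params$alpha)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path File path.
#' @return List with `net` (reassembled [tile_network()]) and `params`.
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("not a readable model container: ", conditionMessage(e)))
  if (!identical(obj$container, "hexdmn_model"))
    stop("not a hexdmn model container")
  if (!identical(as.integer(obj$version), 1L))
    stop("unsupported model container version: ", obj$version)
  dec <- function(x) {
    out <- as.numeric(unlist(x))
    names(out) <- names(unlist(x))
    out
  }
  filters <- obj$filters
  filters$count <- as.numeric(filters$count)
  spec <- connectome_spec(obj$types, obj$coverage, filters, obj$signs,
                          input_types = obj$input_types)
  params <- structure(
    list(tau = dec(obj$params$tau),
         v_rest = dec(obj$params$v_rest),
         alpha = unname(dec(obj$params$alpha))),
    class = "dmn_params")
  net <- tile_network(spec, hex_lattice(obj$radius))
  list(net = net, params = params)
}

#' Write a response trace to CSV
#'
#' Long format: `time_ms`, `neuron`, `voltage`.
#'
#' @param trace A `"response_trace"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "response_trace"))
  df <- data.frame(time_ms = rep(trace$times, times = ncol(trace$V)),
                   neuron = rep(trace$neurons, each = nrow(trace$V)),
                   voltage = as.numeric(trace$V))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
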