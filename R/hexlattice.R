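#' Hexagonal retinotopic lattices
#'
#' The optic lobe is organized in a crystalline hexagonal lattice of columns,
#' one per ommatidium. We represent column positions in axial coordinates
#' `(u, v)` with the third cube coordinate implicit as `-(u + v)`. A lattice of
#' radius `r` ("2r + 1 columns across", point to point) contains all
#' coordinates with `max(|u|, |v|, |u + v|) <= r`, i.e. `3 r (r + 1) + 1`
#' columns. Coordinates are enumerated deterministically, ring by ring from the
#' origin and counter-clockwise within each ring starting from the `(d, 0)`
#' coordinate, so that buffer layouts and serializations are reproducible.
#'
#' The Cartesian embedding is "pointy-top": `x = s (u + v/2)`,
#' `y = s (sqrt(3)/2) v`, so the `(1, 0)` lattice axis points along +x and
#' direction angles are measured counter-clockwise from +x. All six nearest
#' neighbours of a column lie at Euclidean distance `s` (the column spacing).
#'
#' @param radius Non-negative integer lattice radius.
#' @return `hex_lattice()` returns an object of class `"hex_lattice"`: a list
#'   with integer vectors `u`, `v` (one entry per column, in the canonical
#'   order), the `radius` and the column count `n`.
#' @examples
#' lat <- hex_lattice(2)
#' lat$n                      # 3 * 2 * 3 + 1 = 19
#' hex_distance(lat$u, lat$v) # ring index of each column
#' @export
hex_lattice <- function(radius) {
  if (length(radius) != 1L || is.na(radius) || radius < 0 || radius != floor(radius))
    stop("'radius' must be a single non-negative integer")
  radius <- as.integer(radius)
  g <- expand.grid(u = seq.int(-radius, radius), v = seq.int(-radius, radius))
  keep <- hex_distance(g$u, g$v) <= radius
  u <- as.integer(g$u[keep]); v <- as.integer(g$v[keep])
  d <- hex_distance(u, v)
  xy <- hex_to_cartesian(u, v)
  ang <- atan2(xy[, 2L], xy[, 1L])
  ang <- ifelse(ang < -1e-9, ang + 2 * pi, pmax(ang, 0))
  ord <- order(d, ang)
  structure(list(radius = radius, u = u[ord], v = v[ord],
                 n = length(u)),
            class = "hex_lattice")
}

#' @export
print.hex_lattice <- function(x, ...) {
  cat(sprintf("<hex_lattice> radius %d, %d columns\n", x$radius, x$n))
  invisible(x)
}

#' Hex distance from the origin
#'
#' Ring index of an axial coordinate: `max(|u|, |v|, |u + v|)`, equal to the
#' minimal number of nearest-neighbour steps from the origin.
#'
#' @param u,v Integer axial coordinates (vectorized).
#' @return Integer vector of distances.
#' @export
hex_distance <- function(u, v) {
  pmax(abs(u), abs(v), abs(u + v))
}

#' Look up column positions in a lattice
#'
#' @param lattice A [hex_lattice()].
#' @param u,v Axial coordinates (vectorized).
#' @return Integer positions into the lattice ordering, `NA` for coordinates
#'   outside the lattice.
#' @export
hex_index <- function(lattice, u, v) {
  stopifnot(inherits(lattice, "hex_lattice"))
  match(paste(u, v), paste(lattice$u, lattice$v))
}

#' Rotate axial coordinates about the six-fold axis
#'
#' Rotation by `k` times 60 degrees counter-clockwise: one step maps
#' `(u, v) -> (-v, u + v)`. Rotation by `k = 6` is the identity and the origin
#' is a fixed point; on any lattice the map is a permutation of columns.
#'
#' @param u,v Integer axial coordinates (vectorized).
#' @param k Integer number of 60-degree steps (any sign).
#' @return A list with rotated integer vectors `u` and `v`.
#' @export
hex_rotate <- function(u, v, k) {
  if (length(k) != 1L || is.na(k) || k != floor(k))
    stop("'k' must be a single integer")
  k <- ((as.integer(k) %% 6L) + 6L) %% 6L
  u <- as.integer(u); v <- as.integer(v)
  if (k > 0L) for (i in seq_len(k)) {
    tmp <- -v
    v <- u + v
    u <- tmp
  }
  list(u = u, v = v)
}

#' Reflect axial coordinates across a principal lattice axis
#'
#' Axis 0 is the line through the origin and `(1, 0)` (the +x axis of the
#' Cartesian embedding); axes 1 and 2 are the same line rotated by 60 and 120
#' degrees. Each flip is an involution and permutes the columns of any lattice.
#'
#' @param u,v Integer axial coordinates (vectorized).
#' @param axis Axis index, one of 0, 1, 2.
#' @return A list with reflected integer vectors `u` and `v`.
#' @export
hex_flip <- function(u, v, axis) {
  if (length(axis) != 1L || is.na(axis) || !(axis %in% 0:2))
    stop("'axis' must be 0, 1 or 2")
  axis <- as.integer(axis)
  # conjugate the base reflection (u, v) -> (u + v, -v) by a rotation
  r <- hex_rotate(u, v, -axis)
  f <- list(u = r$u + r$v, v = -r$v)
  hex_rotate(f$u, f$v, axis)
}

#' Map axial coordinates to Cartesian points
#'
#' Pointy-top embedding with nearest-neighbour spacing `spacing`:
#' `x = s (u + v/2)`, `y = s sqrt(3)/2 v`.
#'
#' @param u,v Axial coordinates (vectorized).
#' @param spacing Positive Euclidean distance between neighbouring columns.
#' @return A two-column numeric matrix of `(x, y)` points.
#' @export
hex_to_cartesian <- function(u, v, spacing = 1) {
  if (length(spacing) != 1L || is.na(spacing) || spacing <= 0)
    stop("'spacing' must be a single positive number")
  cbind(x = spacing * (u + v / 2), y = spacing * (sqrt(3) / 2) * v)
}
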