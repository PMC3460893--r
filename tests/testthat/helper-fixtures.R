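# shared fixture builders; everything is generated in code at test time

sq_ring <- function(x0, y0, s) {
  list(x = c(x0, x0 + s, x0 + s, x0), y = c(y0, y0, y0 + s, y0 + s))
}

# layer of axis-aligned squares from a data frame of (x0, y0, side)
square_layer <- function(x0, y0, side, id = NULL, ...) {
  n <- length(x0)
  vector_layer(tibble::tibble(
    id = id %||% paste0("f", seq_len(n)),
    geometry = lapply(seq_len(n), function(i) list(sq_ring(x0[i], y0[i], side[i]))),
    ...
  ))
}

rect_layer <- function(xmin, ymin, xmax, ymax, id = NULL, ...) {
  n <- length(xmin)
  vector_layer(tibble::tibble(
    id = id %||% paste0("r", seq_len(n)),
    geometry = lapply(seq_len(n), function(i) {
      rect_geom(xmin[i], ymin[i], xmax[i], ymax[i])
    }),
    ...
  ))
}

`%||%` <- rlang::`%||%`

# star-shaped simple polygon around a centre: random radii at sorted angles
random_simple_polygon <- function(n_vertices = 12, centre = c(0, 0), r_range = c(0.5, 2)) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  rad <- stats::runif(n_vertices, r_range[1], r_range[2])
  polygon_geom(centre[1] + rad * cos(ang), centre[2] + rad * sin(ang))
}

# likely-invalid polygon: shuffle the vertex order of a simple polygon
random_invalid_polygon <- function(n_vertices = 8) {
  g <- random_simple_polygon(n_vertices)
  ord <- sample(seq_along(g[[1]]$x))
  polygon_geom(g[[1]]$x[ord], g[[1]]$y[ord])
}

# independent Monte-Carlo area oracle: rejection sampling over the bbox with
# sp::point.in.polygon (even-odd parity across rings; not polyclip)
mc_area <- function(g, n = 1e5) {
  bb <- c(min(vapply(g, function(r) min(r$x), 0)), min(vapply(g, function(r) min(r$y), 0)),
          max(vapply(g, function(r) max(r$x), 0)), max(vapply(g, function(r) max(r$y), 0)))
  px <- stats::runif(n, bb[1], bb[3])
  py <- stats::runif(n, bb[2], bb[4])
  crossings <- rep(0L, n)
  for (r in g) {
    crossings <- crossings + as.integer(sp::point.in.polygon(px, py, r$x, r$y) > 0)
  }
  inside <- crossings %% 2L == 1L
  box <- (bb[3] - bb[1]) * (bb[4] - bb[2])
  p <- mean(inside)
  list(area = box * p, se = box * sqrt(p * (1 - p) / n))
}
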