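#' Polygon geometries
#'
#' A geometry is a multipolygon stored as a list of rings; each ring is a
#' `list(x =, y =)` pair of equal-length numeric vectors of planar coordinates
#' in kilometres, implicitly closed. Exterior rings are counter-clockwise
#' (positive shoelace area), holes clockwise, the convention enforced by
#' [make_valid()]. All overlay arithmetic snaps to a fixed integer grid with
#' 1e-10 km resolution so results from different calls are mutually consistent.
#'
#' @param x,y numeric vectors of vertex coordinates (at least 3 vertices),
#'   without a repeated closing vertex.
#' @return A geometry (list of rings).
#' @export
#' @examples
#' g <- polygon_geom(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' planar_area(g)
polygon_geom <- function(x, y) {
  g <- list(list(x = as.numeric(x), y = as.numeric(y)))
  .check_polygonal(g)
  g
}

#' @rdname polygon_geom
#' @param xmin,ymin,xmax,ymax rectangle extent in km.
#' @export
rect_geom <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  polygon_geom(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

# fast unchecked rectangle constructor for generator-internal use
.rect <- function(x1, y1, x2, y2) {
  list(list(x = c(x1, x2, x2, x1), y = c(y1, y1, y2, y2)))
}

# structural check: a list of >=3-vertex rings with finite coordinates
.check_polygonal <- function(g) {
  ok <- is.list(g) && length(g) > 0 && all(vapply(g, function(r) {
    is.list(r) && is.numeric(r$x) && is.numeric(r$y) &&
      length(r$x) == length(r$y) && length(r$x) >= 3 &&
      all(is.finite(r$x)) && all(is.finite(r$y))
  }, logical(1)))
  if (!ok) .stop_geometry("unsupported geometry: expected polygonal rings (lists with numeric x, y of length >= 3)")
  invisible(g)
}

.is_empty_geom <- function(g) length(g) == 0

.ring_signed_area <- function(r) {
  x <- r$x; y <- r$y
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

# net signed area of a multipolygon (holes subtract); assumes validity
.geom_area <- function(g) {
  if (.is_empty_geom(g)) return(0)
  a <- 0
  for (r in g) {
    x <- r$x; y <- r$y
    a <- a + sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  }
  0.5 * a
}

.geom_bbox <- function(g) {
  xs <- unlist(lapply(g, `[[`, "x"), use.names = FALSE)
  ys <- unlist(lapply(g, `[[`, "y"), use.names = FALSE)
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

#' Repair a polygonal geometry
#'
#' Resolves self-intersections (bow-ties), duplicate vertices and inconsistent
#' ring orientation, returning a valid multipolygon whose area is the even-odd
#' interpretation of the input. Runs at load time and after every overlay step.
#' Idempotent: repairing a valid geometry leaves its area unchanged.
#'
#' @param g a geometry (list of rings).
#' @return A valid geometry; empty list if the input collapses to zero area.
#' @export
#' @examples
#' bowtie <- polygon_geom(c(0, 1, 1, 0), c(0, 1, 0, 1))
#' planar_area(make_valid(bowtie)) # 0.5: two opposing triangles
make_valid <- function(g) {
  .check_polygonal(g)
  out <- polyclip::polysimplify(g, filltype = "evenodd",
                                x0 = .pa_grid$x0, y0 = .pa_grid$y0, eps = .pa_grid$eps)
  .drop_slivers(out)
}

# drop rings whose net contribution is below the sliver threshold;
# keeps holes (negative rings) paired with retained outers
.drop_slivers <- function(g) {
  if (length(g) == 0) return(list())
  a <- vapply(g, .ring_signed_area, numeric(1))
  g <- g[abs(a) >= .pa_sliver]
  if (length(g) == 0 || .geom_area(g) < .pa_sliver) return(list())
  g
}

# validity probe: a geometry is valid when its nonzero-fill resimplification
# preserves the signed area (catches self-intersections and flipped outers)
.is_valid_geom <- function(g) {
  s <- tryCatch(
    polyclip::polysimplify(g, filltype = "nonzero",
                           x0 = .pa_grid$x0, y0 = .pa_grid$y0, eps = .pa_grid$eps),
    error = function(e) NULL
  )
  if (is.null(s)) return(FALSE)
  a0 <- .geom_area(g)
  a1 <- .geom_area(s)
  abs(a1 - a0) <= max(1e-9, 1e-9 * abs(a0))
}

#' Planar polygon area
#'
#' Shoelace area of a valid multipolygon in km^2; holes subtract. Additive over
#' disjoint parts and invariant under rigid motions.
#'
#' @param g a geometry.
#' @param validate if `TRUE` (default), verify validity first and error with
#'   advice to run [make_valid()]; set `FALSE` for geometries produced by the
#'   package's own overlay operations, which are valid by construction.
#' @return Non-negative area (km^2).
#' @export
planar_area <- function(g, validate = TRUE) {
  if (.is_empty_geom(g)) return(0)
  .check_polygonal(g)
  if (validate && !.is_valid_geom(g)) {
    .stop_geometry("invalid geometry (self-intersection or flipped ring): repair with make_valid() first")
  }
  .geom_area(g)
}

#' Area-weighted polygon centroid
#'
#' Geometric centroid of the whole multipolygon (holes subtract); for a
#' disconnected multipolygon the centroid may lie outside every part.
#'
#' @inheritParams planar_area
#' @return Numeric vector `c(x, y)` in km.
#' @export
planar_centroid <- function(g, validate = TRUE) {
  .check_polygonal(g)
  if (validate && !.is_valid_geom(g)) {
    .stop_geometry("invalid geometry: repair with make_valid() first")
  }
  a <- .geom_area(g)
  if (abs(a) < .pa_sliver) .stop_geometry("zero-area geometry has no centroid")
  cx <- 0; cy <- 0
  for (r in g) {
    x <- r$x; y <- r$y
    x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
    cr <- x * y2 - x2 * y
    cx <- cx + sum((x + x2) * cr)
    cy <- cy + sum((y + y2) * cr)
  }
  c(x = cx / (6 * a), y = cy / (6 * a))
}

# vectorised point-in-multipolygon; boundary counts as inside.
# px, py numeric vectors; returns logical.
.points_in_geom <- function(px, py, g) {
  if (.is_empty_geom(g) || length(px) == 0) return(rep(FALSE, length(px)))
  P <- list(x = px, y = py)
  inside <- integer(length(px))
  boundary <- logical(length(px))
  for (r in g) {
    code <- polyclip::pointinpolygon(P, r)
    boundary <- boundary | code == -1L
    s <- if (.ring_signed_area(r) >= 0) 1L else -1L
    inside <- inside + s * (code == 1L)
  }
  boundary | inside > 0L
}
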