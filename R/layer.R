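#' Vector layers
#'
#' A vector layer is a tibble with one row per feature: a character `id`
#' column (unique), a `geometry` list-column of multipolygons (see
#' [polygon_geom()]), and any number of attribute columns (e.g.
#' `acquisition_date`, `tenure`, `state_name`). A `crs_tag` attribute records
#' the planar frame: `"planar-km"` for synthetic/projected data already in km,
#' or `"albers-na-km"` for data projected with [albers_project()]. Layers in
#' different frames refuse to combine.
#'
#' @param data a data frame with `id` and `geometry` columns.
#' @param crs planar frame tag.
#' @param repair if `TRUE`, run [make_valid()] on every geometry.
#' @return A `vector_layer` tibble.
#' @export
#' @examples
#' vector_layer(tibble::tibble(
#'   id = "a", geometry = list(rect_geom(0, 0, 1, 1))
#' ))
vector_layer <- function(data, crs = "planar-km", repair = FALSE) {
  data <- as_tibble(data)
  if (!all(c("id", "geometry") %in% names(data))) {
    .stop_data("a vector layer needs 'id' and 'geometry' columns")
  }
  data$id <- as.character(data$id)
  if (anyDuplicated(data$id)) .stop_data("feature ids must be unique within a layer")
  if (!is.list(data$geometry)) .stop_data("'geometry' must be a list-column of polygon geometries")
  if (repair) data$geometry <- lapply(data$geometry, make_valid)
  new_vector_layer(data, crs)
}

new_vector_layer <- function(data, crs) {
  stopifnot(is.character(crs), length(crs) == 1)
  structure(as_tibble(data),
            crs_tag = crs,
            class = c("vector_layer", class(as_tibble(data))))
}

#' @rdname vector_layer
#' @param x object to coerce or test.
#' @export
as_vector_layer <- function(x, crs = crs_tag(x) %||% "planar-km") {
  vector_layer(as_tibble(x), crs = crs)
}

#' @rdname vector_layer
#' @export
is_vector_layer <- function(x) inherits(x, "vector_layer")

#' @rdname vector_layer
#' @export
crs_tag <- function(x) attr(x, "crs_tag", exact = TRUE)

#' @export
print.vector_layer <- function(x, ...) {
  cat("# A vector layer: ", nrow(x), " feature(s), frame '", crs_tag(x), "'\n", sep = "")
  NextMethod()
}

# rebuild layer metadata after dplyr-style manipulation of the underlying tibble
.relayer <- function(data, template) {
  new_vector_layer(as_tibble(data), crs_tag(template) %||% "planar-km")
}

.check_same_frame <- function(a, b) {
  ta <- crs_tag(a); tb <- crs_tag(b)
  if (!identical(ta, tb)) {
    .stop_data(sprintf("coordinate frames differ: '%s' vs '%s'", ta, tb))
  }
  invisible(TRUE)
}

#' Per-feature and total layer areas
#'
#' `feature_areas()` returns the planar area of every feature;
#' `layer_area()` the area of the layer's set-union (overlaps counted once).
#'
#' @param layer a `vector_layer`.
#' @return `feature_areas()`: numeric vector (km^2); `layer_area()`: scalar.
#' @export
feature_areas <- function(layer) {
  vapply(layer$geometry, .geom_area, numeric(1))
}

#' @rdname feature_areas
#' @export
layer_area <- function(layer) {
  if (nrow(layer) == 0) return(0)
  .geom_area(.union_geoms(layer$geometry))
}

#' Test points against a layer
#'
#' `TRUE` where the point is inside or on the boundary of any feature.
#'
#' @param px,py numeric vectors of point coordinates (km).
#' @param layer a `vector_layer`.
#' @return Logical vector.
#' @export
point_in_layer <- function(px, py, layer) {
  stopifnot(length(px) == length(py))
  hit <- rep(FALSE, length(px))
  for (g in layer$geometry) {
    todo <- which(!hit)
    if (length(todo) == 0) break
    bb <- .geom_bbox(g)
    cand <- todo[px[todo] >= bb["xmin"] & px[todo] <= bb["xmax"] &
                 py[todo] >= bb["ymin"] & py[todo] <= bb["ymax"]]
    if (length(cand)) hit[cand] <- .points_in_geom(px[cand], py[cand], g)
  }
  hit
}
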