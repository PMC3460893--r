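# ---- union machinery -------------------------------------------------------
#
# polyclip (Clipper) calls are limited to a few thousand rings per call by R's
# protection stack, so set-unions of large layers are computed by recursive
# bbox bisection: features straddling the split line are clipped into both
# halves, each half is unioned independently, and the resulting "pieces" have
# pairwise-disjoint interiors (areas add exactly; every call shares one
# integer grid). A dissolve therefore returns one feature per piece: the
# "minimal set" form of a dissolve rather than always a single feature.

.pc2 <- function(A, B, op) {
  polyclip::polyclip(A, B, op,
                     fillA = "nonzero", fillB = "nonzero",
                     x0 = .pa_grid$x0, y0 = .pa_grid$y0, eps = .pa_grid$eps)
}

.n_rings <- function(geoms) sum(lengths(geoms))

.has_holes <- function(geoms) {
  any(vapply(geoms, function(g) any(vapply(g, .ring_signed_area, numeric(1)) < 0),
             logical(1)))
}

# union a small set (<= .pa_chunk rings) of valid geometries into one geometry
.union_small <- function(geoms, holes = .has_holes(geoms)) {
  geoms <- geoms[lengths(geoms) > 0]
  if (length(geoms) == 0) return(list())
  if (length(geoms) == 1) return(geoms[[1]])
  if (!holes) {
    rings <- unlist(geoms, recursive = FALSE)
    return(.pc2(rings[-1], rings[1], "union"))
  }
  # holes must stay with their exterior: merge feature by feature (binary tree)
  while (length(geoms) > 1) {
    k <- length(geoms)
    merged <- vector("list", ceiling(k / 2))
    for (i in seq_along(merged)) {
      a <- geoms[[2 * i - 1]]
      merged[[i]] <- if (2 * i <= k) .pc2(a, geoms[[2 * i]], "union") else a
    }
    geoms <- merged
  }
  geoms[[1]]
}

# union an arbitrary set of geometries -> list of disjoint-interior pieces.
# bbs (bbox matrix) and holes (any negative ring?) are computed once at entry
# and carried down the recursion.
.union_pieces <- function(geoms, depth = 0L, bbs = NULL, holes = NULL) {
  keep <- lengths(geoms) > 0
  if (!all(keep)) {
    geoms <- geoms[keep]
    if (!is.null(bbs)) bbs <- bbs[keep, , drop = FALSE]
  }
  if (length(geoms) == 0) return(list())
  if (is.null(holes)) holes <- .has_holes(geoms)
  if (.n_rings(geoms) <= .pa_chunk) {
    u <- .union_small(geoms, holes)
    u <- .drop_slivers(u)
    return(if (length(u)) list(u) else list())
  }
  if (depth > 48L) .stop_geometry("dissolve: geometry too complex to partition")
  if (is.null(bbs)) bbs <- t(vapply(geoms, .geom_bbox, numeric(4)))
  wide <- (max(bbs[, "xmax"]) - min(bbs[, "xmin"])) >=
          (max(bbs[, "ymax"]) - min(bbs[, "ymin"]))
  lo <- if (wide) bbs[, "xmin"] else bbs[, "ymin"]
  hi <- if (wide) bbs[, "xmax"] else bbs[, "ymax"]
  mid <- stats::median((lo + hi) / 2)
  left_of <- hi <= mid
  right_of <- lo >= mid
  straddle <- !(left_of | right_of)
  pad <- 1 + max(abs(c(bbs))) # half-plane rectangles safely covering the data
  half <- function(side) {
    if (wide) {
      if (side == "lo") rect_geom(min(bbs[, "xmin"]) - pad, min(bbs[, "ymin"]) - pad, mid, max(bbs[, "ymax"]) + pad)
      else rect_geom(mid, min(bbs[, "ymin"]) - pad, max(bbs[, "xmax"]) + pad, max(bbs[, "ymax"]) + pad)
    } else {
      if (side == "lo") rect_geom(min(bbs[, "xmin"]) - pad, min(bbs[, "ymin"]) - pad, max(bbs[, "xmax"]) + pad, mid)
      else rect_geom(min(bbs[, "xmin"]) - pad, mid, max(bbs[, "xmax"]) + pad, max(bbs[, "ymax"]) + pad)
    }
  }
  if (all(straddle) || all(left_of) || all(right_of)) {
    # no usable spatial split (e.g. heavily overlapping large features):
    # fall back to halving the feature list and merging the two unions
    k <- length(geoms)
    a <- .union_pieces(geoms[seq_len(k %/% 2)], depth + 1L, holes = holes)
    b <- .union_pieces(geoms[(k %/% 2 + 1):k], depth + 1L, holes = holes)
    return(.union_pieces(c(a, b), depth + 1L))
  }
  clip_to <- function(g, rect) .pc2(g, rect, "intersection")
  lo_cut <- lapply(geoms[straddle], clip_to, rect = half("lo"))
  hi_cut <- lapply(geoms[straddle], clip_to, rect = half("hi"))
  cut_bbs <- function(cut) {
    t(vapply(cut, function(g) if (length(g)) .geom_bbox(g) else rep(NA_real_, 4),
             numeric(4)))
  }
  lo_geoms <- c(geoms[left_of], lo_cut)
  hi_geoms <- c(geoms[right_of], hi_cut)
  lo_bbs <- rbind(bbs[left_of, , drop = FALSE], cut_bbs(lo_cut))
  hi_bbs <- rbind(bbs[right_of, , drop = FALSE], cut_bbs(hi_cut))
  c(.union_pieces(lo_geoms, depth + 1L, lo_bbs, holes),
    .union_pieces(hi_geoms, depth + 1L, hi_bbs, holes))
}

# single-geometry union of a whole layer (rings of all disjoint pieces)
.union_geoms <- function(geoms) {
  unlist(.union_pieces(geoms), recursive = FALSE) %||% list()
}

# greedy batching of pieces so each polyclip call stays under the ring budget
.batch_pieces <- function(pieces) {
  if (length(pieces) == 0) return(list())
  n <- lengths(pieces)
  batch <- integer(length(pieces))
  b <- 1L; acc <- 0L
  for (i in seq_along(pieces)) {
    if (acc + n[i] > .pa_chunk && acc > 0L) { b <- b + 1L; acc <- 0L }
    batch[i] <- b
    acc <- acc + n[i]
  }
  lapply(split(pieces, batch), function(ps) unlist(ps, recursive = FALSE))
}

# positional bboxes: c(xmin, ymin, xmax, ymax)
.bbox_disjoint <- function(a, b) {
  a[[3]] < b[[1]] || b[[3]] < a[[1]] || a[[4]] < b[[2]] || b[[4]] < a[[2]]
}

# intersection of two piece-lists -> list of disjoint-interior pieces
.intersect_pieces <- function(ap, bp) {
  A <- .batch_pieces(ap); B <- .batch_pieces(bp)
  if (length(A) == 0 || length(B) == 0) return(list())
  abb <- lapply(A, .geom_bbox); bbb <- lapply(B, .geom_bbox)
  out <- list()
  for (i in seq_along(A)) {
    for (j in seq_along(B)) {
      if (.bbox_disjoint(abb[[i]], bbb[[j]])) next
      r <- .drop_slivers(.pc2(A[[i]], B[[j]], "intersection"))
      if (length(r)) out[[length(out) + 1L]] <- r
    }
  }
  out
}

.pieces_area <- function(pieces) {
  if (length(pieces) == 0) return(0)
  sum(vapply(pieces, .geom_area, numeric(1)))
}

.pieces_layer <- function(pieces, crs, prefix = "piece") {
  new_vector_layer(
    tibble(id = if (length(pieces)) paste0(prefix, "-", seq_along(pieces)) else character(),
           geometry = pieces),
    crs
  )
}

# ---- public overlay verbs --------------------------------------------------

#' Dissolve a layer into its set-union
#'
#' Merges all features so overlapping and duplicated parcels are counted once
#' in area calculations. The result is one feature, or for large layers a
#' minimal set of features with pairwise-disjoint interiors whose areas add up
#' to the union area exactly.
#'
#' @param layer a `vector_layer` of valid geometries.
#' @return A `vector_layer` of the union.
#' @export
#' @examples
#' two <- vector_layer(tibble::tibble(
#'   id = c("a", "b"),
#'   geometry = list(rect_geom(0, 0, 1, 1), rect_geom(0, 0, 1, 1))
#' ))
#' layer_area(dissolve_layer(two)) # 1, not 2
dissolve_layer <- function(layer) {
  pieces <- .union_pieces(layer$geometry)
  out <- .pieces_layer(pieces, crs_tag(layer), "dissolved")
  attr(out, "dissolved") <- TRUE
  out
}

#' Clip a layer to a boundary
#'
#' Restricts every feature to the union of the boundary layer (e.g. state
#' boundaries, eliminating marine and international slivers). Attributes are
#' preserved; features that fall entirely outside are dropped.
#'
#' @param layer,boundary `vector_layer`s in the same planar frame.
#' @return The clipped `vector_layer`.
#' @export
clip_layer <- function(layer, boundary) {
  .check_same_frame(layer, boundary)
  bp <- if (isTRUE(attr(boundary, "dissolved"))) boundary$geometry else .union_pieces(boundary$geometry)
  bp <- bp[lengths(bp) > 0]
  if (length(bp) == 0 || nrow(layer) == 0) {
    return(.relayer(layer[0, ], layer))
  }
  batches <- .batch_pieces(bp)
  bbb <- lapply(batches, .geom_bbox)
  rect <- if (length(batches) == 1) .as_rect(batches[[1]]) else NULL
  gb_all <- vapply(layer$geometry, .geom_bbox, numeric(4))
  keep <- logical(nrow(layer))
  newg <- layer$geometry
  # features wholly inside a rectangular boundary pass through untouched
  easy <- if (is.null(rect)) rep(FALSE, nrow(layer)) else {
    gb_all[1, ] >= rect[1] & gb_all[2, ] >= rect[2] &
      gb_all[3, ] <= rect[3] & gb_all[4, ] <= rect[4]
  }
  keep[easy] <- TRUE
  for (i in which(!easy)) {
    g <- layer$geometry[[i]]
    if (length(g) == 0) next
    gb <- gb_all[, i]
    acc <- list()
    for (j in seq_along(batches)) {
      if (.bbox_disjoint(gb, bbb[[j]])) next
      acc <- c(acc, .pc2(g, batches[[j]], "intersection"))
    }
    acc <- .drop_slivers(acc)
    if (length(acc)) { newg[[i]] <- acc; keep[i] <- TRUE }
  }
  out <- layer[keep, , drop = FALSE]
  out$geometry <- newg[keep]
  .relayer(out, layer)
}

.union_geoms_of_layer <- function(layer) {
  unlist(layer$geometry, recursive = FALSE) %||% list()
}

# axis-aligned rectangle detection (single 4-vertex ring)
.as_rect <- function(g) {
  if (length(g) != 1 || length(g[[1]]$x) != 4) return(NULL)
  x <- sort(unique(g[[1]]$x)); y <- sort(unique(g[[1]]$y))
  if (length(x) != 2 || length(y) != 2) return(NULL)
  c(x[1], y[1], x[2], y[2])
}

#' Overlay intersection of two layers
#'
#' `intersect_layers()` returns the regions common to both layers (each layer
#' is dissolved first so overlaps within a layer are not double-counted);
#' `intersect_area()` returns just the total overlap area in km^2.
#'
#' @param a,b `vector_layer`s in the same planar frame.
#' @return `intersect_layers()`: a `vector_layer`; `intersect_area()`: scalar.
#' @export
intersect_layers <- function(a, b) {
  .check_same_frame(a, b)
  ap <- if (isTRUE(attr(a, "dissolved"))) a$geometry else .union_pieces(a$geometry)
  bp <- if (isTRUE(attr(b, "dissolved"))) b$geometry else .union_pieces(b$geometry)
  pieces <- .intersect_pieces(ap, bp)
  out <- .pieces_layer(pieces, crs_tag(a), "overlap")
  attr(out, "dissolved") <- TRUE
  out
}

#' @rdname intersect_layers
#' @export
intersect_area <- function(a, b) {
  layer_sum <- intersect_layers(a, b)
  .pieces_area(layer_sum$geometry)
}

#' Overlay difference of two layers
#'
#' `difference_layers()` returns the part of `a` outside `b` (both dissolved
#' first); together with [intersect_layers()] it satisfies the conservation
#' identity `area(a - b) + area(a ∩ b) = area(a)`. `difference_area()` returns
#' just the area.
#'
#' @param a,b `vector_layer`s in the same planar frame.
#' @return `difference_layers()`: a `vector_layer`; `difference_area()`: scalar.
#' @export
difference_layers <- function(a, b) {
  .check_same_frame(a, b)
  ap <- if (isTRUE(attr(a, "dissolved"))) a$geometry else .union_pieces(a$geometry)
  bp <- if (isTRUE(attr(b, "dissolved"))) b$geometry else .union_pieces(b$geometry)
  A <- .batch_pieces(ap)
  B <- .batch_pieces(bp)
  pieces <- list()
  for (i in seq_along(A)) {
    r <- A[[i]]
    for (j in seq_along(B)) {
      if (length(r) == 0) break
      r <- .pc2(r, B[[j]], "minus")
    }
    r <- .drop_slivers(r)
    if (length(r)) pieces[[length(pieces) + 1L]] <- r
  }
  out <- .pieces_layer(pieces, crs_tag(a), "difference")
  attr(out, "dissolved") <- TRUE
  out
}

#' @rdname difference_layers
#' @export
difference_area <- function(a, b) {
  .pieces_area(difference_layers(a, b)$geometry)
}
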