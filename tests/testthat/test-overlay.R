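test_that("clip restricts features to the boundary and preserves attributes", {
  boundary <- rect_layer(0, 0, 10, 10)
  lay <- square_layer(c(1, 9.5, 20), c(1, 9.5, 20), c(1, 1, 1),
                      tenure = c("fee", "easement", "fee"))

  out <- clip_layer(lay, boundary)
  expect_equal(nrow(out), 2) # the disjoint square is dropped
  expect_equal(feature_areas(out), c(1, 0.25), tolerance = 1e-9)
  expect_equal(out$tenure, c("fee", "easement"))

  inside <- clip_layer(square_layer(2, 2, 1), boundary)
  expect_equal(feature_areas(inside), 1)

  none <- clip_layer(square_layer(50, 50, 1), boundary)
  expect_equal(nrow(none), 0)

  other <- vector_layer(tibble::tibble(id = "x", geometry = list(rect_geom(0, 0, 1, 1))),
                        crs = "albers-na-km")
  expect_error(clip_layer(lay, other), class = "prioralign_data_error")
})

test_that("dissolve collapses duplicates and counts overlap once", {
  expect_equal(layer_area(square_layer(c(0, 0), c(0, 0), c(1, 1))), 1.0, tolerance = 1e-9)
  expect_equal(layer_area(square_layer(c(0, 5), c(0, 0), c(1, 1))), 2.0, tolerance = 1e-9)
  # half-overlapping unit squares: inclusion-exclusion gives 1.5
  expect_equal(layer_area(square_layer(c(0, 0.5), c(0, 0), c(1, 1))), 1.5, tolerance = 1e-9)
})

test_that("dissolve is idempotent and order-independent", {
  set.seed(21)
  lay <- square_layer(runif(60, 0, 10), runif(60, 0, 10), runif(60, 0.3, 2))
  d1 <- dissolve_layer(lay)
  a1 <- sum(feature_areas(d1))
  expect_equal(sum(feature_areas(dissolve_layer(d1))), a1, tolerance = 1e-9)
  shuffled <- vector_layer(lay[sample(nrow(lay)), ])
  expect_equal(layer_area(shuffled) / a1, 1, tolerance = 1e-9)
})

test_that("dissolve keeps holes", {
  donut <- make_valid(list(sq_ring(0, 0, 10),
                           list(x = rev(c(3, 7, 7, 3)), y = rev(c(3, 3, 7, 7)))))
  lay <- vector_layer(tibble::tibble(id = c("d", "plug"),
                                     geometry = list(donut, rect_geom(4, 4, 6, 6))))
  expect_equal(layer_area(lay), 100 - 16 + 4, tolerance = 1e-9)
})

test_that("intersection is bounded, symmetric, and exact on rectangles", {
  a <- rect_layer(0, 0, 1, 1)
  expect_equal(intersect_area(a, a), 1.0, tolerance = 1e-9)
  expect_equal(intersect_area(a, rect_layer(5, 5, 6, 6)), 0)
  expect_equal(intersect_area(a, rect_layer(0.5, 0, 1.5, 1)), 0.5, tolerance = 1e-9)

  set.seed(33)
  for (i in 1:10) {
    A <- rect_layer(runif(1, 0, 5), runif(1, 0, 5), runif(1, 5, 9), runif(1, 5, 9))
    B <- rect_layer(runif(1, 0, 5), runif(1, 0, 5), runif(1, 5, 9), runif(1, 5, 9))
    ab <- intersect_area(A, B)
    expect_equal(ab, intersect_area(B, A), tolerance = 1e-12)
    expect_lte(ab, min(layer_area(A), layer_area(B)) + 1e-9)
    expect_gte(ab, 0)
  }
})

test_that("overlay conserves area: A = (A and B) + (A minus B)", {
  set.seed(44)
  for (i in 1:8) {
    A <- square_layer(runif(15, 0, 8), runif(15, 0, 8), runif(15, 0.5, 3))
    B <- square_layer(runif(6, 0, 8), runif(6, 0, 8), runif(6, 1, 4))
    lhs <- intersect_area(A, B) + difference_area(A, B)
    expect_equal(lhs / layer_area(A), 1, tolerance = 1e-9)
  }
})

test_that("intersect_area agrees with a Monte-Carlo point-sampling oracle", {
  set.seed(55)
  for (i in 1:3) {
    A <- vector_layer(tibble::tibble(
      id = "a", geometry = list(random_simple_polygon(10, centre = c(0, 0)))))
    B <- vector_layer(tibble::tibble(
      id = "b", geometry = list(random_simple_polygon(10, centre = c(0.8, 0)))))
    got <- intersect_area(A, B)
    # oracle: sample in A's bbox, keep points in both polygons
    g1 <- A$geometry[[1]][[1]]; g2 <- B$geometry[[1]][[1]]
    n <- 2e5
    bb <- c(min(g1$x), min(g1$y), max(g1$x), max(g1$y))
    px <- runif(n, bb[1], bb[3]); py <- runif(n, bb[2], bb[4])
    inboth <- sp::point.in.polygon(px, py, g1$x, g1$y) > 0 &
      sp::point.in.polygon(px, py, g2$x, g2$y) > 0
    p <- mean(inboth)
    box <- (bb[3] - bb[1]) * (bb[4] - bb[2])
    se <- box * sqrt(p * (1 - p) / n)
    expect_lt(abs(got - box * p), 3 * se + 1e-9)
  }
})

test_that("areas and proportions are invariant under joint rigid motions", {
  set.seed(66)
  lands <- square_layer(runif(25, 0, 10), runif(25, 0, 10), runif(25, 0.3, 1.5))
  pri <- rect_layer(c(1, 6), c(1, 5), c(5, 9), c(4, 9))
  a0 <- layer_area(lands); o0 <- intersect_area(lands, pri)

  th <- 0.7; dx <- 31.2; dy <- -14.9
  move <- function(lay) {
    g <- lapply(lay$geometry, function(gg) lapply(gg, function(r) {
      list(x = cos(th) * r$x - sin(th) * r$y + dx,
           y = sin(th) * r$x + cos(th) * r$y + dy)
    }))
    vector_layer(tibble::tibble(id = lay$id, geometry = g))
  }
  a1 <- layer_area(move(lands)); o1 <- intersect_area(move(lands), move(pri))
  expect_equal(a1 / a0, 1, tolerance = 1e-9)
  expect_equal(o1 / o0, 1, tolerance = 1e-9)
  expect_equal((o1 / a1) / (o0 / a0), 1, tolerance = 1e-9)
})

test_that("tiled union of a large layer keeps exact areas", {
  # 80x90 grid of disjoint squares exceeds the per-call ring budget and forces
  # the bbox-bisection path; union area must equal the sum of parts
  xy <- expand.grid(x = seq(0, 79) * 1.0, y = seq(0, 89) * 1.0)
  lay <- square_layer(xy$x, xy$y, rep(0.9, nrow(xy)))
  d <- dissolve_layer(lay)
  expect_gt(nrow(d), 1) # really did tile
  expect_equal(sum(feature_areas(d)) / (nrow(xy) * 0.81), 1, tolerance = 1e-9)

  # overlapping pairs across the whole extent still collapse correctly
  lay2 <- square_layer(c(xy$x, xy$x + 0.2), c(xy$y, xy$y), rep(0.4, 2 * nrow(xy)))
  # each pair unions to area 0.4 * (0.4 + 0.2) = 0.24; pairs stay disjoint
  expect_equal(layer_area(lay2) / (nrow(xy) * 0.24), 1, tolerance = 1e-9)
})
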