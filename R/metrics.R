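#' Science influence score
#'
#' The excess of observed alignment over chance alignment, normalised by its
#' maximum: `(p_tnc - p_s) / (1 - p_s)`, where `p_tnc` is the fraction of
#' acquired land area lying inside priority areas and `p_s` the fraction of
#' the region designated as priority (the alignment expected if acquisitions
#' ignored the priority areas). A score of 0 means chance-level alignment, 1
#' means every acquisition was inside a priority area, and 0.5 means half the
#' portfolio behaves as if priority-driven and half as if placed blindly.
#' Scores below 0 (alignment worse than chance) are returned as-is.
#'
#' @param p_tnc alignment proportion(s) in \[0, 1\].
#' @param p_s priority coverage proportion(s) in \[0, 1).
#' @return Numeric score(s) in `[-p_s/(1-p_s), 1]`.
#' @export
#' @examples
#' science_influence_score(0.805, 0.364) # 0.693...
#' science_influence_score(0.5, 0.5)     # 0: chance level
science_influence_score <- function(p_tnc, p_s) {
  if (any(!is.finite(p_tnc) | p_tnc < 0 | p_tnc > 1, na.rm = TRUE)) {
    .stop_metric("p_tnc must be in [0, 1]")
  }
  if (any(!is.finite(p_s) | p_s < 0 | p_s > 1, na.rm = TRUE)) {
    .stop_metric("p_s must be in [0, 1)")
  }
  if (any(p_s == 1, na.rm = TRUE)) {
    .stop_metric("score undefined: region fully covered by priorities (p_s = 1)")
  }
  (p_tnc - p_s) / (1 - p_s)
}

#' Alignment summary from raw areas
#'
#' Derives the alignment proportion, the coverage proportion and the science
#' influence score from the four overlay areas. With no acquired land the
#' alignment and score are undefined and reported as `NA` (missing, not zero).
#'
#' @param a_o overlap area between acquisitions and priority areas (km^2).
#' @param a_tnc total acquired area (km^2).
#' @param a_p total priority-area extent (km^2).
#' @param a_s total region area (km^2), positive.
#' @param region,stratum optional labels carried into the output row.
#' @return A one-row tibble: labels, the four areas, `p_tnc`, `p_s`, `score`.
#' @export
#' @examples
#' summarize_alignment(50, 100, 25, 100) # score 1/3
summarize_alignment <- function(a_o, a_tnc, a_p, a_s,
                                region = NA_character_, stratum = NA_character_) {
  stopifnot(length(a_o) == 1, length(a_tnc) == 1, length(a_p) == 1, length(a_s) == 1)
  if (a_s <= 0) .stop_metric("region area a_s must be positive")
  tol <- 1e-6 * max(1, a_tnc, a_p)
  if (a_o < -tol || a_o > a_tnc + tol) .stop_metric("need 0 <= a_o <= a_tnc")
  if (a_p < -tol || a_p > a_s + tol) .stop_metric("need 0 <= a_p <= a_s")
  p_s <- a_p / a_s
  if (a_tnc <= 0) {
    p_tnc <- NA_real_; score <- NA_real_
  } else {
    p_tnc <- min(1, max(0, a_o / a_tnc))
    score <- science_influence_score(p_tnc, p_s)
  }
  tibble(region = region, stratum = stratum,
         a_o = a_o, a_tnc = a_tnc, a_p = a_p, a_s = a_s,
         p_tnc = p_tnc, p_s = p_s, score = score)
}

#' Centroid chi-square goodness-of-fit test
#'
#' Tests whether the number of land records whose geometric centroid falls
#' inside a priority area departs from the count expected under the
#' area-proportional null (expected inside = `p_null * n_total`). Uses the
#' two-cell Pearson statistic with 1 degree of freedom and no continuity
#' correction; the p-value is the upper tail of the chi-square distribution.
#'
#' @param n_in records with centroid inside a priority area.
#' @param n_total total records tested.
#' @param p_null probability a record falls inside under the null, usually the
#'   priority fraction of the region's area; strictly between 0 and 1.
#' @return A `centroid_test` object (see [tidy()] / [glance()] methods).
#' @export
#' @examples
#' centroid_chi_square(8, 10, 0.5) # chi2 = 3.6
centroid_chi_square <- function(n_in, n_total, p_null) {
  stopifnot(length(n_in) == 1, length(n_total) == 1, length(p_null) == 1)
  if (!(p_null > 0 && p_null < 1)) .stop_metric("p_null must lie strictly between 0 and 1")
  if (n_total <= 0) .stop_metric("n_total must be positive")
  if (n_in < 0 || n_in > n_total) .stop_metric("need 0 <= n_in <= n_total")
  n_out <- n_total - n_in
  expected_in <- p_null * n_total
  expected_out <- (1 - p_null) * n_total
  chi2 <- (n_in - expected_in)^2 / expected_in +
          (n_out - expected_out)^2 / expected_out
  small <- min(expected_in, expected_out) < 5
  if (small) warn("an expected cell count is below 5; chi-square approximation is weak")
  structure(
    list(n_in = n_in, n_out = n_out, n_total = n_total,
         p_null = p_null, expected_in = expected_in, expected_out = expected_out,
         chi2 = chi2, df = 1L,
         p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
         small_expected = small),
    class = "centroid_test"
  )
}

#' @export
print.centroid_test <- function(x, ...) {
  cat("Centroid chi-square test against the area-fraction null\n")
  cat(sprintf("  observed in/out: %d / %d (n = %d)\n", x$n_in, x$n_out, x$n_total))
  cat(sprintf("  expected in/out: %.1f / %.1f (p_null = %.4f)\n",
              x$expected_in, x$expected_out, x$p_null))
  cat(sprintf("  X-squared = %.4g, df = %d, p-value %s\n",
              x$chi2, x$df,
              if (x$p_value < 1e-4) "< 0.0001" else sprintf("= %.4g", x$p_value)))
  if (x$small_expected) cat("  warning: an expected cell is below 5\n")
  invisible(x)
}

#' @method tidy centroid_test
#' @export
tidy.centroid_test <- function(x, ...) {
  tibble(cell = c("inside", "outside"),
         observed = c(x$n_in, x$n_out),
         expected = c(x$expected_in, x$expected_out))
}

#' @method glance centroid_test
#' @export
glance.centroid_test <- function(x, ...) {
  tibble(n_in = x$n_in, n_out = x$n_out, n_total = x$n_total,
         p_null = x$p_null, statistic = x$chi2, df = x$df,
         p_value = x$p_value, small_expected = x$small_expected)
}

#' Count record centroids inside priority areas
#'
#' Works on per-record (pre-dissolve) geometries because each record
#' corresponds to one acquisition event. Zero-area records cannot yield a
#' centroid and are excluded with a warning.
#'
#' @param lands per-record `vector_layer` of acquisitions.
#' @param priorities `vector_layer` of priority areas.
#' @return One-row tibble with `n_in`, `n_out`, `n_excluded`.
#' @export
count_centroids_in_priorities <- function(lands, priorities) {
  .check_same_frame(lands, priorities)
  areas <- feature_areas(lands)
  ok <- areas >= .pa_sliver
  if (any(!ok)) {
    warn(sprintf("%d zero-area record(s) excluded from the centroid test", sum(!ok)))
  }
  g <- lands$geometry[ok]
  if (length(g) == 0) return(tibble(n_in = 0L, n_out = 0L, n_excluded = sum(!ok)))
  cents <- vapply(g, planar_centroid, numeric(2), validate = FALSE)
  pri <- if (isTRUE(attr(priorities, "dissolved"))) priorities else dissolve_layer(priorities)
  inside <- point_in_layer(cents[1, ], cents[2, ], pri)
  tibble(n_in = sum(inside), n_out = sum(!inside), n_excluded = sum(!ok))
}
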