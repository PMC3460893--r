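#' Run the full alignment assessment
#'
#' Reproduces the standard overlay workflow: repair/clip the acquisitions and
#' priority areas to the jurisdiction boundaries, build the analysis strata
#' (all records, acquisition-date periods, easements and fee-simple holdings),
#' dissolve each stratum, intersect it with the priority areas, and summarise
#' alignment nationally per stratum and per state for the all-records stratum.
#' The centroid chi-square test runs on the per-record (undissolved)
#' geometries, with the null probability taken from the priority fraction of
#' the clipped region area.
#'
#' Records with unknown tenure stay in the all-records and period strata;
#' dissolving happens after subsetting, so parcels shared between strata count
#' fully within each stratum.
#'
#' @param lands per-record `vector_layer` of acquisitions with optional
#'   `acquisition_date` and `tenure` columns.
#' @param priorities `vector_layer` of priority areas.
#' @param states `vector_layer` of jurisdiction boundaries; a `state_name`
#'   column (or the `id`) labels the per-state table.
#' @param periods period definitions, see [default_periods()].
#' @param strata which stratum families to compute.
#' @param centroid_test compute the centroid chi-square test?
#' @param per_state compute the per-state table for the all-records stratum?
#' @param date_col,tenure_col,date_format attribute mapping for `lands`.
#' @return An `alignment_report`: list with `by_stratum` and `by_state`
#'   tibbles, `centroid_test`, and a `meta` list of record counts.
#' @export
run_assessment <- function(lands, priorities, states,
                           periods = default_periods(),
                           strata = c("all", "period", "tenure"),
                           centroid_test = TRUE,
                           per_state = TRUE,
                           date_col = "acquisition_date",
                           tenure_col = "tenure",
                           date_format = "%Y-%m-%d") {
  .check_same_frame(lands, priorities)
  .check_same_frame(lands, states)
  strata <- match.arg(strata, several.ok = TRUE)
  if (nrow(states) == 0) .stop_data("states layer has no features")
  if (nrow(priorities) == 0) {
    .stop_data("priorities layer has no features: all scores would be undefined")
  }

  states_d <- dissolve_layer(states)
  a_s <- .pieces_area(states_d$geometry)
  lands_c <- clip_layer(lands, states_d)
  pri_d <- dissolve_layer(clip_layer(priorities, states_d))
  a_p <- .pieces_area(pri_d$geometry)

  empty_lands <- nrow(lands_c) == 0
  if (empty_lands) warn("no land records after clipping to the region")

  stratum_layers <- list()
  if ("all" %in% strata) stratum_layers[["all"]] <- lands_c
  if ("period" %in% strata && nrow(lands_c) > 0 && date_col %in% names(lands_c)) {
    stratum_layers <- c(stratum_layers,
                        stratify_by_date(lands_c, periods, date_col, date_format))
    und <- is.na(.parse_dates(lands_c[[date_col]], date_format, warn_bad = FALSE))
    stratum_layers[["undated"]] <- .relayer(lands_c[und, , drop = FALSE], lands_c)
  }
  if ("tenure" %in% strata && nrow(lands_c) > 0 && tenure_col %in% names(lands_c)) {
    ten <- stratify_by_tenure(lands_c, tenure_col)
    stratum_layers[["easement"]] <- ten$easement
    stratum_layers[["fee"]] <- ten$fee
  }

  all_d <- NULL
  by_stratum <- dplyr::bind_rows(lapply(names(stratum_layers), function(nm) {
    lay <- stratum_layers[[nm]]
    d <- dissolve_layer(lay)
    if (nm == "all") all_d <<- d
    a_tnc <- .pieces_area(d$geometry)
    a_o <- .pieces_area(.intersect_pieces(d$geometry, pri_d$geometry))
    summarize_alignment(a_o, a_tnc, a_p, a_s, region = "national", stratum = nm)
  }))

  by_state <- NULL
  if (per_state && "all" %in% strata) {
    by_state <- per_state_summary(all_d %||% lands_c, pri_d, states)
  }

  ct <- NULL
  if (centroid_test && !empty_lands) {
    counts <- count_centroids_in_priorities(lands_c, pri_d)
    n_tot <- counts$n_in + counts$n_out
    if (n_tot > 0 && a_p > 0 && a_p < a_s) {
      ct <- centroid_chi_square(counts$n_in, n_tot, p_null = a_p / a_s)
    }
  }

  n_undated <- if (date_col %in% names(lands)) sum(is.na(lands[[date_col]])) else NA_integer_
  structure(
    list(by_stratum = by_stratum, by_state = by_state, centroid_test = ct,
         meta = list(n_records = nrow(lands), n_records_clipped = nrow(lands_c),
                     n_undated = n_undated, a_s = a_s, a_p = a_p,
                     empty_lands = empty_lands,
                     periods = periods, strata = strata)),
    class = "alignment_report"
  )
}

#' Per-state alignment summaries
#'
#' Computes the four overlay areas and the science influence score within each
#' state polygon. States with no acquired land report `NA` alignment and score
#' (missing, not zero).
#'
#' @param lands acquisitions `vector_layer`, already clipped to the states.
#' @param priorities priority-area `vector_layer`, already clipped.
#' @param states `vector_layer` of state polygons; labelled by its
#'   `state_name` column if present, else by `id`.
#' @return A tibble with one row per state (see [summarize_alignment()]).
#' @export
per_state_summary <- function(lands, priorities, states) {
  .check_same_frame(lands, priorities)
  .check_same_frame(lands, states)
  lands_d <- if (isTRUE(attr(lands, "dissolved"))) lands else dissolve_layer(lands)
  pri_d <- if (isTRUE(attr(priorities, "dissolved"))) priorities else dissolve_layer(priorities)
  labels <- if ("state_name" %in% names(states)) states$state_name else states$id
  rows <- lapply(seq_len(nrow(states)), function(i) {
    st <- .relayer(states[i, , drop = FALSE], states)
    attr(st, "dissolved") <- TRUE # a single state polygon is its own union
    a_s <- .geom_area(st$geometry[[1]])
    lands_s <- clip_layer(lands_d, st)
    pri_s <- clip_layer(pri_d, st)
    a_tnc <- sum(feature_areas(lands_s))
    a_p <- sum(feature_areas(pri_s))
    a_o <- .pieces_area(.intersect_pieces(lands_s$geometry, pri_s$geometry))
    summarize_alignment(a_o, a_tnc, a_p, a_s, region = labels[i], stratum = "all")
  })
  dplyr::bind_rows(rows)
}

#' @export
print.alignment_report <- function(x, ...) {
  cat("Alignment assessment report\n")
  cat(sprintf("  region area %.1f km^2, priority coverage %.1f%%\n",
              x$meta$a_s, 100 * x$meta$a_p / x$meta$a_s))
  cat(sprintf("  %d record(s); %s undated\n", x$meta$n_records,
              ifelse(is.na(x$meta$n_undated), "?", x$meta$n_undated)))
  cat("\nBy stratum:\n")
  print(x$by_stratum)
  if (!is.null(x$centroid_test)) { cat("\n"); print(x$centroid_test) }
  invisible(x)
}

#' Tidy an alignment report
#'
#' `tidy()` returns the per-stratum (default) or per-state summary table;
#' `glance()` a one-row national overview including the centroid test.
#'
#' @param x an `alignment_report`.
#' @param table `"stratum"` or `"state"`.
#' @param ... unused.
#' @method tidy alignment_report
#' @export
tidy.alignment_report <- function(x, table = c("stratum", "state"), ...) {
  table <- match.arg(table)
  if (table == "stratum") x$by_stratum else x$by_state
}

#' @rdname tidy.alignment_report
#' @method glance alignment_report
#' @export
glance.alignment_report <- function(x, ...) {
  nat <- x$by_stratum[x$by_stratum$stratum == "all", , drop = FALSE]
  if (nrow(nat) == 0) nat <- x$by_stratum[1, , drop = FALSE]
  out <- tibble(a_tnc = nat$a_tnc, a_o = nat$a_o, p_tnc = nat$p_tnc,
                p_s = nat$p_s, score = nat$score)
  if (!is.null(x$centroid_test)) {
    out$chi2 <- x$centroid_test$chi2
    out$chi2_p_value <- x$centroid_test$p_value
  }
  out
}
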