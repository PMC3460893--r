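#' Configure a synthetic landscape
#'
#' Bundles every knob of the synthetic landscape and acquisition process: a
#' row/grid of square states, rectangular priority patches covering a
#' configured fraction of each state, and square parcels placed by a mixture
#' process — with probability `influence` a parcel is sited wholly inside a
#' priority patch, otherwise its centre is uniform over the state. Under this
#' process the expected alignment proportion is
#' `influence + (1 - influence) * coverage` (small-parcel limit), so the
#' science influence score recovers `influence` — the generative reading of a
#' score of 50% as "half of the portfolio placed blind, half always inside
#' priorities".
#'
#' @param n_states number of square states (tiled in a near-square grid).
#' @param state_size side length of each state (km).
#' @param coverage priority fraction of each state's area, in \[0, 1); scalar
#'   or one value per state.
#' @param priority_blocks rectangular priority patches per state.
#' @param n_parcels number of acquisition records to generate.
#' @param influence mixture weight s in \[0, 1\]: probability a parcel is
#'   placed priority-driven.
#' @param s_easement,s_fee optional tenure-specific influence overriding
#'   `influence` for that tenure class.
#' @param parcel_side_log_mean,parcel_side_log_sd lognormal parameters of the
#'   parcel side length (km).
#' @param undated_fraction probability a record carries no acquisition date.
#' @param period_weights three non-negative weights for the pre-2000,
#'   2000-2005 and 2006-extraction periods (dated records only).
#' @param tenure_weights two non-negative weights for easement / fee records.
#' @param date_min,extraction_date calendar range of acquisition dates.
#' @param seed integer seed; every generator stage derives its own sub-stream
#'   from it, so e.g. adding parcels does not perturb the state geometry.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_states = 2,
                              state_size = 700,
                              coverage = 0.364,
                              priority_blocks = 8,
                              n_parcels = 5000,
                              influence = 0.6,
                              s_easement = NULL,
                              s_fee = NULL,
                              parcel_side_log_mean = log(0.2),
                              parcel_side_log_sd = 0.6,
                              undated_fraction = 0.57,
                              period_weights = c(0.48, 0.28, 0.24),
                              tenure_weights = c(0.78, 0.22),
                              date_min = "1951-01-01",
                              extraction_date = "2011-07-20",
                              seed = 1L) {
  cfg <- list(n_states = as.integer(n_states), state_size = state_size,
              coverage = coverage, priority_blocks = as.integer(priority_blocks),
              n_parcels = as.integer(n_parcels), influence = influence,
              s_easement = s_easement, s_fee = s_fee,
              parcel_side_log_mean = parcel_side_log_mean,
              parcel_side_log_sd = parcel_side_log_sd,
              undated_fraction = undated_fraction,
              period_weights = period_weights, tenure_weights = tenure_weights,
              date_min = as.Date(date_min),
              extraction_date = as.Date(extraction_date),
              seed = as.integer(seed))
  .validate_sim_config(cfg)
  structure(cfg, class = "simulation_config")
}

.validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) .stop_config(msg)
  chk(cfg$n_states >= 1, "n_states must be >= 1")
  chk(cfg$state_size > 0, "state_size must be positive")
  cov <- rep_len(cfg$coverage, cfg$n_states)
  chk(all(cov >= 0 & cov < 1), "coverage must lie in [0, 1) for every state")
  chk(cfg$priority_blocks >= 1, "priority_blocks must be >= 1")
  chk(cfg$n_parcels >= 0, "n_parcels must be >= 0")
  for (f in c("influence", "s_easement", "s_fee")) {
    v <- cfg[[f]]
    if (!is.null(v)) chk(is.numeric(v) && v >= 0 && v <= 1, sprintf("%s must lie in [0, 1]", f))
  }
  chk(cfg$undated_fraction >= 0 && cfg$undated_fraction <= 1,
      "undated_fraction must lie in [0, 1]")
  chk(cfg$parcel_side_log_sd >= 0, "parcel_side_log_sd must be >= 0")
  chk(length(cfg$period_weights) == 3 && all(cfg$period_weights >= 0) &&
        sum(cfg$period_weights) > 0, "period_weights: three non-negative weights")
  chk(length(cfg$tenure_weights) == 2 && all(cfg$tenure_weights >= 0) &&
        sum(cfg$tenure_weights) > 0, "tenure_weights: two non-negative weights")
  chk(cfg$date_min < cfg$extraction_date, "date_min must precede extraction_date")
  invisible(cfg)
}

#' Generate the synthetic state boundaries
#'
#' Non-overlapping square states tiled in a near-square grid, each carrying a
#' `state_name`.
#'
#' @param cfg a [simulation_config()].
#' @return A `vector_layer` of `n_states` squares.
#' @export
generate_states <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n_states; S <- cfg$state_size
  ncol <- ceiling(sqrt(n))
  ix <- (seq_len(n) - 1) %% ncol
  iy <- (seq_len(n) - 1) %/% ncol
  nm <- sprintf("state_%02d", seq_len(n))
  vector_layer(tibble(
    id = nm,
    geometry = lapply(seq_len(n), function(i) {
      .rect(ix[i] * S, iy[i] * S, (ix[i] + 1) * S, (iy[i] + 1) * S)
    }),
    state_name = nm
  ))
}

#' Generate priority patches with exact coverage
#'
#' Places `priority_blocks` disjoint rectangles inside each state whose total
#' area equals the configured coverage fraction analytically (equal-area
#' blocks with random aspect ratios). Blocks are assigned to distinct cells of
#' a grid and jittered uniformly within their cell, so placement is
#' seeded-random yet disjoint by construction at any feasible coverage.
#'
#' @param states layer from [generate_states()].
#' @param cfg a [simulation_config()].
#' @return A `vector_layer` of priority rectangles with a `state_name` column.
#' @export
generate_priorities <- function(states, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  .set_substream(cfg$seed, 2L)
  S <- cfg$state_size
  cov <- rep_len(cfg$coverage, cfg$n_states)
  k <- cfg$priority_blocks
  rows <- list()
  # blocks live in distinct cells of a g x g grid with random in-cell jitter:
  # seeded-random placement that is disjoint by construction and terminates at
  # any feasible coverage (free rejection sampling stalls above ~40% coverage)
  g <- ceiling(sqrt(k))
  cs <- S / g
  for (i in seq_len(cfg$n_states)) {
    if (cov[i] <= 0) next
    org <- .geom_bbox(states$geometry[[i]])
    a_blk <- cov[i] * S^2 / k
    if (a_blk > (0.98 * cs)^2) {
      .stop_config(sprintf(
        "cannot fit %d disjoint priority blocks at coverage %.2f: use fewer (larger) blocks",
        k, cov[i]))
    }
    cells <- sample.int(g^2, k) - 1L
    for (j in seq_len(k)) {
      # aspect ratio constrained so the block stays inside its cell
      r_lo <- max(0.5, a_blk / (0.98 * cs)^2)
      r_hi <- min(2, (0.98 * cs)^2 / a_blk)
      r <- runif(1, r_lo, r_hi)
      w <- sqrt(a_blk * r); h <- a_blk / w
      cx0 <- (cells[j] %% g) * cs
      cy0 <- (cells[j] %/% g) * cs
      x0 <- cx0 + runif(1, 0, cs - w)
      y0 <- cy0 + runif(1, 0, cs - h)
      rows[[length(rows) + 1L]] <- tibble(
        id = sprintf("prio_%s_%02d", states$id[i], j),
        geometry = list(.rect(org[["xmin"]] + x0, org[["ymin"]] + y0,
                              org[["xmin"]] + x0 + w, org[["ymin"]] + y0 + h)),
        state_name = states$id[i]
      )
    }
  }
  if (length(rows) == 0) {
    return(vector_layer(tibble(id = character(), geometry = list(),
                               state_name = character())))
  }
  vector_layer(dplyr::bind_rows(rows))
}

#' Generate acquisition parcels by the mixture process
#'
#' For each record: a state is drawn proportional to area, tenure and
#' (possibly missing) acquisition date are drawn from the configured weights,
#' the square parcel's side comes from the lognormal size distribution, and
#' with probability s (tenure-specific if configured) the parcel is placed
#' wholly inside a priority patch of its state, otherwise its centre is
#' uniform over the state and the parcel is clipped to the state boundary.
#'
#' @param states,priorities layers from the companion generators.
#' @param cfg a [simulation_config()].
#' @return A per-record `vector_layer` with `acquisition_date`, `tenure`,
#'   `state_name` and `placement` columns; `placement` records the ground-truth
#'   arm of the mixture ("priority" or "chance") for validation studies.
#' @export
generate_parcels <- function(states, priorities, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n_parcels
  empty <- tibble(id = character(), geometry = list(),
                  acquisition_date = as.Date(character()),
                  tenure = character(), state_name = character())
  if (n == 0) {
    warn("n_parcels = 0: returning an empty land layer")
    return(vector_layer(empty))
  }

  # patch bookkeeping per state
  patches <- NULL
  if (nrow(priorities) > 0) {
    pm <- t(vapply(priorities$geometry, function(g) .as_rect(g), numeric(4)))
    patches <- tibble(state_name = priorities$state_name,
                      xmin = pm[, 1], ymin = pm[, 2], xmax = pm[, 3], ymax = pm[, 4])
    patches$w <- patches$xmax - patches$xmin
    patches$h <- patches$ymax - patches$ymin
    patches$area <- patches$w * patches$h
  }

  s_any <- max(cfg$influence, cfg$s_easement %||% 0, cfg$s_fee %||% 0)
  min_side <- if (!is.null(patches) && nrow(patches) > 0) min(patches$w, patches$h) else Inf
  if (s_any > 0) {
    if (is.infinite(min_side)) {
      .stop_config("influence > 0 requires priority patches (coverage > 0)")
    }
    q99 <- stats::qlnorm(0.99, cfg$parcel_side_log_mean, cfg$parcel_side_log_sd)
    if (q99 > min_side / 4) {
      .stop_config(sprintf(
        "parcel sizes too large for the priority patches (99th-percentile side %.2f km > min patch side/4 = %.2f km): shrink parcels or enlarge patches",
        q99, min_side / 4))
    }
  }

  .set_substream(cfg$seed, 3L)
  sb <- t(vapply(states$geometry, .geom_bbox, numeric(4)))
  st_area <- feature_areas(states)
  st_idx <- sample.int(nrow(states), n, replace = TRUE, prob = st_area)
  tenure <- sample(c("easement", "fee"), n, replace = TRUE,
                   prob = cfg$tenure_weights / sum(cfg$tenure_weights))
  undated <- runif(n) < cfg$undated_fraction
  periods <- default_periods(cfg$date_min, cfg$extraction_date)
  per_idx <- sample.int(3L, n, replace = TRUE,
                        prob = cfg$period_weights / sum(cfg$period_weights))
  date_frac <- runif(n)
  dates <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  span <- as.integer(periods$end - periods$start)
  dated <- !undated
  dates[dated] <- periods$start[per_idx[dated]] +
    floor(date_frac[dated] * span[per_idx[dated]])

  side <- rlnorm(n, cfg$parcel_side_log_mean, cfg$parcel_side_log_sd)
  if (is.finite(min_side)) side <- pmin(side, 0.999 * min_side)
  side <- pmin(side, 0.999 * cfg$state_size)

  s_parcel <- rep(cfg$influence, n)
  if (!is.null(cfg$s_easement)) s_parcel[tenure == "easement"] <- cfg$s_easement
  if (!is.null(cfg$s_fee)) s_parcel[tenure == "fee"] <- cfg$s_fee
  driven <- runif(n) < s_parcel

  cx <- numeric(n); cy <- numeric(n)
  # chance-driven: centre uniform over the parcel's state
  ch <- which(!driven)
  if (length(ch)) {
    cx[ch] <- sb[st_idx[ch], 1] + runif(length(ch)) * cfg$state_size
    cy[ch] <- sb[st_idx[ch], 2] + runif(length(ch)) * cfg$state_size
  }
  # priority-driven: uniform inside a patch (area-weighted), shrunk by side/2
  dr <- which(driven)
  if (length(dr)) {
    for (s_i in unique(st_idx[dr])) {
      sel <- dr[st_idx[dr] == s_i]
      ps <- patches[patches$state_name == states$id[s_i], , drop = FALSE]
      if (nrow(ps) == 0) .stop_config(sprintf("state %s has no priority patches for influence-driven placement", states$id[s_i]))
      pj <- sample.int(nrow(ps), length(sel), replace = TRUE, prob = ps$area)
      hx <- side[sel] / 2
      cx[sel] <- ps$xmin[pj] + hx + runif(length(sel)) * (ps$w[pj] - side[sel])
      cy[sel] <- ps$ymin[pj] + hx + runif(length(sel)) * (ps$h[pj] - side[sel])
    }
  }

  # build squares; chance parcels are clipped to their (rectangular) state
  x1 <- cx - side / 2; x2 <- cx + side / 2
  y1 <- cy - side / 2; y2 <- cy + side / 2
  x1 <- pmax(x1, sb[st_idx, 1]); y1 <- pmax(y1, sb[st_idx, 2])
  x2 <- pmin(x2, sb[st_idx, 3]); y2 <- pmin(y2, sb[st_idx, 4])

  geoms <- vector("list", n)
  for (i in seq_len(n)) geoms[[i]] <- .rect(x1[i], y1[i], x2[i], y2[i])
  vector_layer(tibble(
    id = sprintf("parcel_%06d", seq_len(n)),
    geometry = geoms,
    acquisition_date = dates,
    tenure = tenure,
    state_name = states$id[st_idx],
    placement = ifelse(driven, "priority", "chance")
  ))
}

#' Generate a complete synthetic landscape
#'
#' @param cfg a [simulation_config()].
#' @return List with `states`, `priorities`, `lands` layers and the `config`.
#' @export
#' @examples
#' ls <- simulate_landscape(simulation_config(n_parcels = 100, seed = 7))
#' layer_area(ls$priorities) / layer_area(ls$states)
simulate_landscape <- function(cfg) {
  states <- generate_states(cfg)
  priorities <- generate_priorities(states, cfg)
  lands <- generate_parcels(states, priorities, cfg)
  structure(list(states = states, priorities = priorities, lands = lands,
                 config = cfg),
            class = "landscape")
}

#' Expected alignment under the mixture process
#'
#' Closed-form small-parcel expectation of the alignment proportion:
#' `s + (1 - s) * p_s`. It is the inverse of the score formula, so
#' `science_influence_score(expected_alignment(s, p), p)` returns `s`.
#'
#' @param s influence parameter(s) in \[0, 1\].
#' @param p_s priority coverage(s) in \[0, 1\].
#' @return Numeric expected alignment proportion(s).
#' @export
expected_alignment <- function(s, p_s) {
  stopifnot(all(s >= 0 & s <= 1), all(p_s >= 0 & p_s <= 1))
  s + (1 - s) * p_s
}
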