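#' Albers equal-area conic projection
#'
#' Forward-projects geographic coordinates (degrees) to planar km on an
#' authalic sphere, using the standard North-America parameterisation
#' (standard parallels 29.5 and 45.5, origin 23N 96W). Equal-area projection
#' is what makes planar polygon areas meaningful.
#'
#' @param lon,lat numeric vectors, degrees.
#' @param lon0,lat0 projection origin (degrees).
#' @param lat1,lat2 standard parallels (degrees).
#' @param radius authalic Earth radius (km).
#' @return List with `x`, `y` in km.
#' @export
#' @examples
#' albers_project(-96, 23) # origin maps to (0, 0)
albers_project <- function(lon, lat, lon0 = -96, lat0 = 23,
                           lat1 = 29.5, lat2 = 45.5, radius = 6371.0072) {
  d2r <- pi / 180
  phi <- lat * d2r; lam <- lon * d2r
  phi0 <- lat0 * d2r; phi1 <- lat1 * d2r; phi2 <- lat2 * d2r; lam0 <- lon0 * d2r
  n <- (sin(phi1) + sin(phi2)) / 2
  C <- cos(phi1)^2 + 2 * n * sin(phi1)
  rho <- radius * sqrt(pmax(0, C - 2 * n * sin(phi))) / n
  rho0 <- radius * sqrt(pmax(0, C - 2 * n * sin(phi0))) / n
  theta <- n * (lam - lam0)
  list(x = rho * sin(theta), y = rho0 - rho * cos(theta))
}

.supported_formats <- c(".geojson", ".json")

#' Read a vector polygon layer
#'
#' Reads a GeoJSON FeatureCollection of polygons/multipolygons, repairs every
#' geometry with [make_valid()] (dropping features that collapse to zero
#' area, with a warning), applies the attribute mapping, and — for geographic
#' input — projects to the Albers equal-area frame in km.
#'
#' Only GeoJSON is supported in this build; `.shp` / `.gpkg` inputs raise an
#' error naming the supported formats.
#'
#' @param path input file.
#' @param crs `"planar-km"` if coordinates are already planar km (the default
#'   for layers this package writes; honoured from the file's `crs_tag`
#'   member when present), or `"wgs84"` to project lon/lat with
#'   [albers_project()].
#' @param date_field,tenure_field optional property names mapped onto
#'   `acquisition_date` / `tenure` columns.
#' @param tenure_map named character vector translating raw tenure values to
#'   `"easement"`, `"fee"` or `"unknown"`.
#' @param date_format date parsing format for the date field.
#' @return A `vector_layer`.
#' @export
read_layer <- function(path, crs = NULL,
                       date_field = NULL, tenure_field = NULL,
                       tenure_map = c(easement = "easement", fee = "fee",
                                      unknown = "unknown"),
                       date_format = "%Y-%m-%d") {
  if (!file.exists(path)) .stop_data(sprintf("file not found: %s", path))
  ext <- tolower(sub(".*(\\.[A-Za-z0-9]+)$", "\\1", path))
  if (!ext %in% .supported_formats) {
    .stop_data(sprintf("unsupported format '%s'; supported formats: %s",
                       ext, paste(.supported_formats, collapse = ", ")))
  }
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(js$type, "FeatureCollection")) {
    .stop_data("expected a GeoJSON FeatureCollection")
  }
  crs <- crs %||% js$crs_tag %||% "wgs84"

  feats <- js$features
  n <- length(feats)
  ids <- character(n); geoms <- vector("list", n); props <- vector("list", n)
  for (i in seq_len(n)) {
    f <- feats[[i]]
    geoms[[i]] <- .geojson_to_geom(f$geometry)
    props[[i]] <- f$properties %||% list()
    ids[i] <- as.character(f$id %||% props[[i]]$id %||% i)
  }

  if (identical(crs, "wgs84")) {
    geoms <- lapply(geoms, function(g) lapply(g, function(r) {
      p <- albers_project(r$x, r$y)
      list(x = p$x, y = p$y)
    }))
    crs_out <- "albers-na-km"
  } else if (crs %in% c("planar-km", "albers-na-km")) {
    crs_out <- crs
  } else {
    .stop_data(sprintf("unknown crs '%s'; use 'planar-km' or 'wgs84'", crs))
  }

  pre <- vapply(geoms, .geom_area, numeric(1))
  geoms <- lapply(geoms, make_valid)
  repaired <- sum(vapply(seq_len(n), function(i) {
    abs(.geom_area(geoms[[i]]) - pre[i]) > 1e-9 * max(1, abs(pre[i]))
  }, logical(1)))
  if (repaired > 0) warn(sprintf("%d geometr%s required repair on load",
                                 repaired, ifelse(repaired == 1, "y", "ies")))
  keep <- lengths(geoms) > 0
  if (any(!keep)) warn(sprintf("%d zero-area feature(s) dropped on load", sum(!keep)))

  tb <- tibble(id = ids[keep], geometry = geoms[keep])
  pk <- props[keep]
  prop_names <- unique(unlist(lapply(pk, names)))
  for (nm in setdiff(prop_names, c("id"))) {
    v <- vapply(pk, function(p) {
      x <- p[[nm]]
      if (is.null(x)) NA_character_ else as.character(x)
    }, character(1))
    tb[[nm]] <- v
  }
  if (!is.null(date_field)) {
    if (!date_field %in% names(tb)) {
      .stop_data(sprintf("declared date field '%s' missing from layer properties", date_field))
    }
    tb$acquisition_date <- as.Date(tb[[date_field]], format = date_format)
    bad <- !is.na(tb[[date_field]]) & nzchar(tb[[date_field]]) & is.na(tb$acquisition_date)
    if (any(bad)) warn(sprintf("%d unparseable date(s) treated as undated", sum(bad)))
  }
  if (!is.null(tenure_field)) {
    if (!tenure_field %in% names(tb)) {
      .stop_data(sprintf("declared tenure field '%s' missing from layer properties", tenure_field))
    }
    raw <- tb[[tenure_field]]
    mapped <- unname(tenure_map[raw])
    mapped[is.na(raw) | !raw %in% names(tenure_map)] <- "unknown"
    tb$tenure <- mapped
  }
  vector_layer(tb, crs = crs_out)
}

.geojson_to_geom <- function(geom) {
  if (is.null(geom)) .stop_data("feature without geometry")
  ring_of <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    # drop the GeoJSON closing vertex
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    list(x = m[, 1], y = m[, 2])
  }
  polys <- switch(geom$type,
    Polygon = list(geom$coordinates),
    MultiPolygon = geom$coordinates,
    .stop_data(sprintf("unsupported geometry type '%s' (polygons only)", geom$type))
  )
  rings <- list()
  for (poly in polys) {
    for (j in seq_along(poly)) {
      r <- ring_of(poly[[j]])
      a <- .ring_signed_area(r)
      # GeoJSON: first ring exterior, rest holes; normalise orientation
      want_pos <- j == 1
      if ((a > 0) != want_pos) r <- list(x = rev(r$x), y = rev(r$y))
      rings[[length(rings) + 1L]] <- r
    }
  }
  rings
}

#' Write a layer as GeoJSON
#'
#' Serialises the layer as a GeoJSON FeatureCollection with a `crs_tag`
#' member recording the planar frame. Output is deterministic for identical
#' layers.
#'
#' @param layer a `vector_layer`.
#' @param path output path (`.geojson` or `.json`).
#' @return `path`, invisibly.
#' @export
write_layer <- function(layer, path) {
  attr_cols <- setdiff(names(layer), c("id", "geometry"))
  feats <- lapply(seq_len(nrow(layer)), function(i) {
    g <- layer$geometry[[i]]
    polys <- .geom_to_geojson(g)
    props <- lapply(layer[i, attr_cols, drop = FALSE], function(v) {
      x <- v[[1]]
      if (inherits(x, "Date")) x <- format(x, "%Y-%m-%d")
      if (length(x) == 1 && is.na(x)) NULL else x
    })
    list(type = "Feature", id = layer$id[i],
         properties = props, geometry = polys)
  })
  out <- list(type = "FeatureCollection", crs_tag = crs_tag(layer),
              features = feats)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}

# group rings into GeoJSON polygons: each positive ring starts a polygon,
# each negative ring becomes a hole of the containing positive ring
.geom_to_geojson <- function(g) {
  if (length(g) == 0) {
    return(list(type = "MultiPolygon", coordinates = list()))
  }
  signs <- vapply(g, .ring_signed_area, numeric(1)) >= 0
  # internal orientation (exterior CCW, holes CW) already matches GeoJSON
  close_ring <- function(r) {
    m <- cbind(r$x, r$y)
    m <- rbind(m, m[1, ])
    lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
  }
  outers <- which(signs)
  polys <- vector("list", length(outers))
  for (k in seq_along(outers)) {
    o <- outers[k]
    ob <- .geom_bbox(g[o])
    rings <- list(close_ring(g[[o]]))
    holes <- which(!signs)
    for (h in holes) {
      hb <- .geom_bbox(g[h])
      if (hb["xmin"] >= ob["xmin"] && hb["xmax"] <= ob["xmax"] &&
          hb["ymin"] >= ob["ymin"] && hb["ymax"] <= ob["ymax"] &&
          .points_in_geom(g[[h]]$x[1], g[[h]]$y[1], g[o])) {
        rings[[length(rings) + 1L]] <- close_ring(g[[h]])
      }
    }
    polys[[k]] <- rings
  }
  list(type = "MultiPolygon", coordinates = polys)
}

#' Write report tables and manifest
#'
#' Renders an [run_assessment()] report the way gap-analysis results are
#' usually tabulated: `by_period.csv` and `by_tenure.csv` (stratum, land
#' acquired km^2, % of acquisition area inside priorities, score),
#' `by_state.csv` (adding % of state area inside priorities),
#' `centroid_test.json`, and a `manifest.json` with a configuration hash and
#' software version. Percentages are rounded half-away-from-zero at the
#' configured precision; missing values render as `NA`, not 0.
#'
#' @param report an `alignment_report`.
#' @param out_dir output directory (created if needed).
#' @param digits decimal places for percentage columns.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, out_dir, digits = 1) {
  stopifnot(inherits(report, "alignment_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    .stop_data(sprintf("output directory not writable: %s", out_dir))
  }
  pct <- function(x) round_half_up(100 * x, digits)
  render <- function(tb) {
    tibble(stratum = tb$stratum,
           land_acquired_km2 = round_half_up(tb$a_tnc, digits),
           pct_acquisition_in_priority = pct(tb$p_tnc),
           science_influence_score = pct(tb$score))
  }
  bs <- report$by_stratum
  files <- character(0)

  per_tab <- render(bs[bs$stratum %in% c("all", report$meta$periods$label, "undated"), , drop = FALSE])
  f <- file.path(out_dir, "by_period.csv")
  readr::write_csv(per_tab, f, na = "NA"); files <- c(files, f)

  ten_tab <- render(bs[bs$stratum %in% c("easement", "fee"), , drop = FALSE])
  f <- file.path(out_dir, "by_tenure.csv")
  readr::write_csv(ten_tab, f, na = "NA"); files <- c(files, f)

  if (!is.null(report$by_state)) {
    st <- report$by_state
    st_tab <- tibble(state = st$region,
                     land_acquired_km2 = round_half_up(st$a_tnc, digits),
                     pct_acquisition_in_priority = pct(st$p_tnc),
                     pct_state_in_priority = pct(st$p_s),
                     science_influence_score = pct(st$score))
    f <- file.path(out_dir, "by_state.csv")
    readr::write_csv(st_tab, f, na = "NA"); files <- c(files, f)
  }

  if (!is.null(report$centroid_test)) {
    f <- file.path(out_dir, "centroid_test.json")
    jsonlite::write_json(unclass(report$centroid_test), f,
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }

  manifest <- list(
    package = "prioralign",
    version = as.character(packageVersion("prioralign")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    meta = report$meta[c("n_records", "n_records_clipped", "n_undated", "a_s", "a_p")],
    config_hash = rlang::hash(report$meta)
  )
  f <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}

#' Read a run configuration
#'
#' Loads the YAML configuration driving the command-line `assess` run: layer
#' paths, attribute mapping, period definitions and output options.
#'
#' @param path YAML file.
#' @return A validated named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) .stop_config(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  cfg$date_format <- cfg$date_format %||% "%Y-%m-%d"
  cfg$crs <- cfg$crs %||% "planar-km"
  cfg$digits <- cfg$digits %||% 1
  cfg$extraction_date <- cfg$extraction_date %||% "2011-07-20"
  cfg$date_min <- cfg$date_min %||% "1951-01-01"
  if (!is.null(cfg$periods)) {
    cfg$periods <- dplyr::bind_rows(lapply(cfg$periods, function(p) {
      period_definition(p$label, p$start, p$end)
    }))
  } else {
    cfg$periods <- default_periods(cfg$date_min, cfg$extraction_date)
  }
  if (!is.null(cfg$tenure_map)) cfg$tenure_map <- unlist(cfg$tenure_map)
  structure(cfg, class = "run_config")
}
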