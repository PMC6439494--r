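# County-level crop-cover maps: loading, validation, and harmonization of
# historic census values onto a reference (modern) county layout.

#' Construct a county/era map
#'
#' Container for county polygons plus per-era crop-cover proportions. One
#' object can hold several census eras over the same polygon layout;
#' proportions are stored as `proportions[[era]][county_id]`.
#'
#' @param county_id character vector of unique county identifiers
#' @param rings list (per county) of lists of polygon ring matrices
#'   (multi-part counties have several rings, assumed disjoint)
#' @param proportions named list: era label -> named numeric vector of
#'   potato-cover proportions in `[0, 1]`
#' @return object of class `county_era_map`
#' @export
county_era_map <- function(county_id, rings, proportions = list()) {
  stopifnot(is.character(county_id), length(county_id) == length(rings))
  if (anyDuplicated(county_id)) stop("duplicate county_id values", call. = FALSE)
  rings <- lapply(rings, function(r) if (is.matrix(r)) list(r) else r)
  all_xy <- do.call(rbind, unlist(rings, recursive = FALSE))
  check_planar_coords(all_xy, "county polygons")
  rings <- lapply(rings, function(parts) lapply(parts, repair_ring))
  areas <- vapply(rings, function(parts) sum(vapply(parts, polygon_area, 0)), 0)
  if (any(areas <= 0)) {
    stop("zero-area county polygon: ",
         paste(county_id[areas <= 0], collapse = ", "), call. = FALSE)
  }
  names(rings) <- county_id
  names(areas) <- county_id
  for (era in names(proportions)) {
    p <- proportions[[era]]
    if (!all(names(p) %in% county_id)) {
      stop("era ", era, ": proportions reference unknown counties", call. = FALSE)
    }
    if (any(p < 0 | p > 1)) {
      stop("era ", era, ": proportions outside [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(county_id = county_id, rings = rings, areas = areas,
         proportions = proportions),
    class = "county_era_map"
  )
}

# repair: drop closing vertex; warn + keep if self-intersecting (areas then
# come from the grid fallback rather than exact clipping)
repair_ring <- function(ring) {
  ring <- drop_closing_vertex(as.matrix(ring))
  storage.mode(ring) <- "double"
  if (ring_self_intersects(ring)) {
    warning("self-intersecting county ring retained; intersection areas for ",
            "this county use the grid fallback", call. = FALSE)
  }
  ring
}

#' @exportS3Method base::print
print.county_era_map <- function(x, ...) {
  cat("<county_era_map>", length(x$county_id), "counties; eras:",
      if (length(x$proportions)) paste(names(x$proportions), collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Read county polygons from a GeoJSON FeatureCollection
#'
#' Features must be Polygon or MultiPolygon geometries carrying a
#' `county_id` property; coordinates must be planar meters. Interior rings
#' (holes) are not supported and raise an error.
#'
#' @param path GeoJSON file
#' @return named list of per-county ring lists
#' @export
read_county_polygons <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  out <- list()
  for (f in gj$features) {
    id <- f$properties$county_id
    if (is.null(id)) stop("feature without county_id property", call. = FALSE)
    geom <- f$geometry
    ring_of <- function(coords) {
      # coerce to double: JSON integers would overflow in area products
      do.call(rbind, lapply(coords, function(pt) {
        c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))
      }))
    }
    parts <- switch(
      geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type ", geom$type, " for county ", id, call. = FALSE)
    )
    rings <- lapply(parts, function(poly) {
      if (length(poly) > 1) {
        stop("county ", id, ": polygon holes are not supported", call. = FALSE)
      }
      ring_of(poly[[1]])
    })
    out[[as.character(id)]] <- rings
  }
  out
}

#' Load a census table onto county polygons
#'
#' Reads a CSV with columns `county_id, year, potato_area, county_area`
#' (areas in the same unit), selects the rows for `era`, converts to
#' proportions `p = potato_area / county_area`, and attaches them to the
#' polygon layout. Counties present in the polygon file but absent from the
#' census get `p = 0` with a warning.
#'
#' @param csv_path census CSV
#' @param polygons_path GeoJSON county polygons
#' @param era census year to extract (must appear in the `year` column)
#' @return a [county_era_map()] with one era
#' @export
load_census <- function(csv_path, polygons_path, era) {
  cen <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("county_id", "year", "potato_area", "county_area")
  if (!all(need %in% names(cen))) {
    stop("census CSV lacks required columns: ",
         paste(setdiff(need, names(cen)), collapse = ", "), call. = FALSE)
  }
  cen <- cen[cen$year == era, , drop = FALSE]
  if (!nrow(cen)) stop("no census rows for era ", era, call. = FALSE)
  if (any(!is.finite(cen$potato_area)) || any(cen$potato_area < 0)) {
    stop("negative or non-finite potato_area", call. = FALSE)
  }
  if (any(cen$county_area <= 0)) stop("non-positive county_area", call. = FALSE)
  bad <- cen$potato_area > cen$county_area
  if (any(bad)) {
    stop("potato_area exceeds county_area for: ",
         paste(cen$county_id[bad], collapse = ", "), call. = FALSE)
  }
  rings <- read_county_polygons(polygons_path)
  ids <- names(rings)
  unknown <- setdiff(cen$county_id, ids)
  if (length(unknown)) {
    warning("census rows without polygons dropped: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    cen <- cen[cen$county_id %in% ids, , drop = FALSE]
  }
  p <- stats::setNames(rep(0, length(ids)), ids)
  p[cen$county_id] <- cen$potato_area / cen$county_area
  absent <- setdiff(ids, cen$county_id)
  if (length(absent)) {
    warning("counties missing from census assigned p = 0: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  props <- stats::setNames(list(p), as.character(era))
  county_era_map(ids, rings, props)
}

county_intersection_area <- function(map_a, id_a, map_b, id_b) {
  total <- 0
  for (ra in map_a$rings[[id_a]]) {
    for (rb in map_b$rings[[id_b]]) {
      total <- total + ring_intersection_area(ra, rb)
    }
  }
  total
}

#' Harmonize historic county values onto a reference county layout
#'
#' Areal interpolation of per-county crop-cover proportions from a historic
#' county layout onto a reference layout. The default `"printed"` mode
#' computes, for each reference county R,
#' \deqn{\sum_i a_i p_i, \quad a_i = \mathrm{area}(i \cap R)/\mathrm{area}(i),}
#' the sum over historic counties i intersecting R of the product of the
#' historic proportion and the fraction of the historic county overlapping
#' R. This quantity is not a proper area-weighted mean (merging two fully
#' covered historic counties yields \eqn{p_1 + p_2}); values above 1 are
#' reported as-is and logged. The `"weighted"` mode instead computes
#' \eqn{\sum_i \mathrm{area}(i \cap R) p_i / \mathrm{area}(R)}, a true areal
#' mean clipped to `[0, 1]`.
#'
#' @param historic,reference [county_era_map()] objects in one planar
#'   projection
#' @param era era label present in `historic$proportions`
#' @param mode `"printed"` (default) or `"weighted"`
#' @return named numeric vector over reference county ids, with attributes
#'   `mode` and `era`
#' @export
harmonize <- function(historic, reference, era, mode = c("printed", "weighted")) {
  mode <- match.arg(mode)
  era <- as.character(era)
  stopifnot(inherits(historic, "county_era_map"), inherits(reference, "county_era_map"))
  if (!era %in% names(historic$proportions)) {
    stop("era ", era, " absent from historic map", call. = FALSE)
  }
  p <- historic$proportions[[era]]
  p_full <- stats::setNames(rep(0, length(historic$county_id)), historic$county_id)
  p_full[names(p)] <- p
  out <- stats::setNames(rep(0, length(reference$county_id)), reference$county_id)
  hbox <- lapply(historic$county_id, function(id) {
    xy <- do.call(rbind, historic$rings[[id]])
    c(range(xy[, 1]), range(xy[, 2]))
  })
  names(hbox) <- historic$county_id
  for (rid in reference$county_id) {
    rxy <- do.call(rbind, reference$rings[[rid]])
    rb <- c(range(rxy[, 1]), range(rxy[, 2]))
    acc <- 0
    for (hid in historic$county_id) {
      hb <- hbox[[hid]]
      if (hb[2] <= rb[1] || rb[2] <= hb[1] || hb[4] <= rb[3] || rb[4] <= hb[3]) next
      ov <- county_intersection_area(historic, hid, reference, rid)
      if (ov <= 0) next
      acc <- acc + switch(mode,
        printed = (ov / historic$areas[[hid]]) * p_full[[hid]],
        weighted = ov * p_full[[hid]]
      )
    }
    out[[rid]] <- if (mode == "weighted") acc / reference$areas[[rid]] else acc
  }
  if (mode == "printed" && any(out > 1)) {
    message("harmonize: ", sum(out > 1),
            " reference counties exceed proportion 1 in printed mode")
  }
  if (mode == "weighted") out <- pmax(pmin(out, 1), 0)
  attr(out, "mode") <- mode
  attr(out, "era") <- era
  out
}

#' Total potato area per era over a set of counties
#'
#' For each map (one or more eras each), sums `p * county_area` over the
#' requested counties: the map-based analogue of a statewide census total.
#'
#' @param maps list of [county_era_map()] objects
#' @param region_county_ids counties to total over (must exist in each map)
#' @return data.frame with columns `era`, `total_potato_area`
#' @export
potato_timeseries <- function(maps, region_county_ids) {
  region_county_ids <- as.character(region_county_ids)
  if (!length(region_county_ids)) {
    return(data.frame(era = character(0), total_potato_area = numeric(0)))
  }
  rows <- list()
  for (m in maps) {
    unknown <- setdiff(region_county_ids, m$county_id)
    if (length(unknown)) {
      stop("unknown county ids in region set: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (era in names(m$proportions)) {
      p <- stats::setNames(rep(0, length(m$county_id)), m$county_id)
      p[names(m$proportions[[era]])] <- m$proportions[[era]]
      tot <- sum(p[region_county_ids] * m$areas[region_county_ids])
      rows[[length(rows) + 1L]] <- data.frame(
        era = era, total_potato_area = tot, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(era = character(0), total_potato_area = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Write a harmonized table as CSV
#'
#' @param values output of [harmonize()]
#' @param path output CSV path
#' @export
write_harmonized_csv <- function(values, path) {
  df <- data.frame(
    reference_county_id = names(values),
    era = attr(values, "era"),
    value = as.numeric(values),
    mode = attr(values, "mode"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
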