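# Landscape resistance to transmission (LRT) along straight-line transects
# between sampling sites, and the pairwise site-by-site matrices consumed by
# the allele-frequency covariance model.

#' Construct/validate a sites table
#'
#' @param df data.frame with columns `site_id`, `x`, `y`,
#'   `population_label` (planar meters)
#' @return validated data.frame of class `site_samples`
#' @export
site_samples <- function(df) {
  need <- c("site_id", "x", "y", "population_label")
  if (!all(need %in% names(df))) {
    stop("sites table lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  df$site_id <- as.character(df$site_id)
  df$population_label <- as.character(df$population_label)
  if (anyDuplicated(df$site_id)) stop("duplicate site_id values", call. = FALSE)
  check_planar_coords(cbind(df$x, df$y), "site coordinates")
  class(df) <- c("site_samples", "data.frame")
  df
}

#' Read a sites CSV (site_id, x, y, population_label)
#' @param path CSV file
#' @export
read_sites_csv <- function(path) {
  site_samples(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Decompose the straight line between two sites into county segments
#'
#' The transect from `a` to `b` is cut at every crossing of a county
#' boundary; each elementary piece is attributed to the county containing
#' its midpoint. Pieces covered by no county get `county_id` `NA`. A piece
#' lying exactly on a shared boundary is assigned to the county with the
#' lexicographically smaller id (deterministic tie-break, logged).
#'
#' @param a,b rows of a [site_samples()] table (or any list with `x`, `y`)
#' @param map a [county_era_map()]
#' @return object of class `path_segments`: data.frame (`county_id`,
#'   `length`) with attribute `total_length`
#' @export
segment_path <- function(a, b, map) {
  pa <- c(a$x, a$y); pb <- c(b$x, b$y)
  if (all(pa == pb)) stop("degenerate path: identical sites", call. = FALSE)
  total <- sqrt(sum((pb - pa)^2))
  ts <- c(0, 1)
  for (id in map$county_id) {
    for (ring in map$rings[[id]]) {
      ts <- c(ts, segment_ring_ts(pa, pb, ring))
    }
  }
  ts <- sort(unique(ts))
  mids_t <- (ts[-1] + ts[-length(ts)]) / 2
  mx <- pa[1] + mids_t * (pb[1] - pa[1])
  my <- pa[2] + mids_t * (pb[2] - pa[2])
  owner <- rep(NA_character_, length(mids_t))
  interior_hits <- vector("list", length(mids_t))
  boundary_hits <- vector("list", length(mids_t))
  for (id in map$county_id) {
    for (ring in map$rings[[id]]) {
      onb <- points_on_ring(mx, my, ring)
      inr <- points_in_ring(mx, my, ring)
      for (k in which(inr & !onb)) interior_hits[[k]] <- c(interior_hits[[k]], id)
      for (k in which(onb)) boundary_hits[[k]] <- c(boundary_hits[[k]], id)
    }
  }
  tie_logged <- FALSE
  for (k in seq_along(mids_t)) {
    hits <- interior_hits[[k]]
    if (!length(hits)) hits <- boundary_hits[[k]]
    if (length(hits) >= 1L) {
      if (length(hits) > 1L && !tie_logged) {
        message("segment_path: boundary-coincident piece assigned to ",
                "lexicographically smaller county id")
        tie_logged <- TRUE
      }
      owner[k] <- sort(unique(hits))[1L]
    }
  }
  len <- diff(ts) * total
  keep <- len > 1e-12 * total
  owner <- owner[keep]; len <- len[keep]
  # merge consecutive pieces with the same owner (NA = outside any county)
  if (length(owner) > 1L) {
    key <- ifelse(is.na(owner), "\r<none>", owner)
    same <- c(FALSE, key[-1] == key[-length(key)])
    grp <- cumsum(!same)
    len <- as.numeric(tapply(len, grp, sum))
    owner <- owner[!same]
  }
  out <- data.frame(county_id = owner, length = len, stringsAsFactors = FALSE)
  attr(out, "total_length") <- total
  class(out) <- c("path_segments", "data.frame")
  out
}

#' Landscape resistance to transmission between two sites
#'
#' Computes `LRT = 1 / sum_i(Z_i * L_i / L_T)` over the counties crossed by
#' the straight line between the sites, where `Z_i` is the county's
#' potato-cover proportion for `era`, `L_i` the transect length inside the
#' county, and `L_T` the total transect length. Transect pieces covered by
#' no county take `Z = 0` (resistance due to absence of the host crop). If
#' the whole transect crosses zero cover the denominator vanishes and the
#' resistance is `+Inf` (logged): sites separated by large extents without
#' potato are maximally disconnected.
#'
#' @inheritParams segment_path
#' @param era era label present in `map$proportions`
#' @return nonnegative scalar, possibly `Inf`
#' @export
lrt_pair <- function(a, b, map, era) {
  era <- as.character(era)
  if (!era %in% names(map$proportions)) {
    stop("era ", era, " absent from map", call. = FALSE)
  }
  segs <- segment_path(a, b, map)
  p <- map$proportions[[era]]
  z <- ifelse(is.na(segs$county_id), 0,
              ifelse(segs$county_id %in% names(p), p[segs$county_id], 0))
  denom <- sum(z * segs$length) / attr(segs, "total_length")
  if (denom <= 0) {
    message("lrt_pair: no potato cover along transect ",
            a$site_id %||% "?", " - ", b$site_id %||% "?", "; LRT = Inf")
    return(Inf)
  }
  1 / denom
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Pairwise matrix container
#'
#' A symmetric numeric matrix over sites with a role label
#' (`"distance"`, `"resistance:<era>"`, `"fst"`) and a standardization flag.
#'
#' @param values symmetric matrix with site ids as dimnames
#' @param label role label
#' @param standardized logical
#' @return object of class `pairwise_matrix`
#' @export
pairwise_matrix <- function(values, label, standardized = FALSE) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values))) stop("pairwise matrix needs site ids as dimnames", call. = FALSE)
  fin <- is.finite(values)
  if (any(abs(values[fin] - t(values)[fin]) > 1e-8 * max(abs(values[fin]), 1))) {
    stop("pairwise matrix not symmetric", call. = FALSE)
  }
  structure(values, label = label, standardized = standardized,
            class = c("pairwise_matrix", class(values)))
}

#' Upper off-diagonal of a pairwise matrix, vectorized
#' @param m matrix
#' @return numeric vector (column-major upper triangle)
#' @export
upper_values <- function(m) m[upper.tri(m)]

standardize_pairwise <- function(m, label) {
  off <- upper_values(m)
  fin <- off[is.finite(off)]
  s <- stats::sd(fin)
  # guard against effectively-constant matrices (float noise only)
  if (!is.finite(s) || s <= 1e-12 * max(abs(fin), 1e-300)) {
    stop(label, ": zero standard deviation over pairs; use standardize = FALSE",
         call. = FALSE)
  }
  d <- diag(m)
  m <- m / s
  diag(m) <- d
  m
}

#' Pairwise landscape-resistance matrix for one era
#'
#' Symmetric matrix of [lrt_pair()] values over all site pairs. With
#' `standardize = TRUE` every off-diagonal entry is divided by the standard
#' deviation of the off-diagonal upper triangle (the diagonal stays 0).
#' Infinite resistances propagate and trigger a warning; see
#' [finite_resistance()] for the policy applied before model fitting.
#'
#' @param sites [site_samples()] table
#' @param map [county_era_map()]
#' @param era era label
#' @param standardize divide by SD of off-diagonal pairs (requires >= 3
#'   sites and positive SD)
#' @return [pairwise_matrix()] labelled `resistance:<era>`
#' @export
lrt_matrix <- function(sites, map, era, standardize = FALSE) {
  n <- nrow(sites)
  if (standardize && n < 3) stop("standardization needs >= 3 sites", call. = FALSE)
  m <- matrix(0, n, n, dimnames = list(sites$site_id, sites$site_id))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      v <- lrt_pair(sites[i, ], sites[j, ], map, era)
      m[i, j] <- v; m[j, i] <- v
    }
  }
  if (any(!is.finite(upper_values(m)))) {
    warning("lrt_matrix: infinite resistance for ",
            sum(!is.finite(upper_values(m))), " site pairs", call. = FALSE)
  }
  if (standardize) m <- standardize_pairwise(m, paste0("resistance:", era))
  pairwise_matrix(m, paste0("resistance:", era), standardized = standardize)
}

#' Pairwise Euclidean distance matrix over sites
#'
#' @inheritParams lrt_matrix
#' @return [pairwise_matrix()] labelled `distance`
#' @export
geographic_distance_matrix <- function(sites, standardize = FALSE) {
  if (nrow(sites) < 2) stop("need >= 2 sites", call. = FALSE)
  m <- as.matrix(stats::dist(cbind(sites$x, sites$y)))
  dimnames(m) <- list(sites$site_id, sites$site_id)
  if (any(upper_values(m) == 0)) {
    message("geographic_distance_matrix: duplicate coordinates (distance 0)")
  }
  if (standardize) m <- standardize_pairwise(m, "distance")
  pairwise_matrix(m, "distance", standardized = standardize)
}

#' Replace infinite resistances by a finite cap
#'
#' Model-layer policy for transects with zero crop cover: `Inf` entries are
#' replaced by `factor` times the largest finite entry, with a prominent
#' warning. Apply before standardization.
#'
#' @param m [pairwise_matrix()]
#' @param factor multiple of the maximum finite entry (default 10)
#' @export
finite_resistance <- function(m, factor = 10) {
  off <- upper_values(m)
  if (all(is.finite(off))) return(m)
  cap <- max(off[is.finite(off)]) * factor
  if (!length(off[is.finite(off)])) stop("all resistances infinite", call. = FALSE)
  warning("finite_resistance: replacing ", sum(!is.finite(off)),
          " infinite entries by max finite x ", factor, call. = FALSE)
  v <- unclass(m)
  v[!is.finite(v)] <- cap
  pairwise_matrix(v, attr(m, "label"), attr(m, "standardized"))
}

#' Write a pairwise matrix as square CSV with site-id header row/column
#' @param m [pairwise_matrix()]
#' @param path output path
#' @export
write_pairwise_csv <- function(m, path) {
  df <- data.frame(site_id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read a square pairwise CSV written by [write_pairwise_csv()]
#' @param path CSV path
#' @param label role label for the matrix
#' @param standardized logical flag carried on the result
#' @export
read_pairwise_csv <- function(path, label, standardized = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(ids, colnames(df)[-1])
  storage.mode(m) <- "double"
  pairwise_matrix(m, label, standardized)
}
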