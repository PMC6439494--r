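# Synthetic landscapes, census histories, sites and genotypes with the
# statistical structure the analysis assumes: county grids with per-era
# crop cover, allele frequencies whose covariance decays with a weighted
# sum of distance and landscape resistance, and beta-binomial genotype
# sampling with missing calls.

#' Specification for a synthetic study system
#'
#' Defaults emulate the sampling design the pipeline targets: a region of
#' rectangular counties tens of kilometers across, 8 populations of 12
#' diploid individuals sampled at distinct sites, and thousands of
#' biallelic SNPs whose between-population frequency covariance decays
#' with geographic distance and era-specific landscape resistance.
#'
#' @param grid_rows,grid_cols county grid dimensions
#' @param county_size county edge length in meters (default 30 km)
#' @param eras character vector of era labels
#' @param cover per-era list of cover models; each element is a list with
#'   `model` one of `"uniform"` (field `p`), `"gradient"` (`p_min`,
#'   `p_max`, along `axis = "col"` or `"row"`), or `"patch"` (`p_in`,
#'   `p_out`, and `cols` and/or `rows` giving the patch block)
#' @param n_sites sampling sites (one population per site)
#' @param inds_per_pop diploid individuals per population (default 12)
#' @param n_loci biallelic SNP loci (default 2000)
#' @param alpha0 true inverse-scale of the frequency covariance
#' @param alphaD true effect size of standardized geographic distance
#' @param alphaE true effect sizes of standardized resistance, one per era
#' @param alpha2 true shape exponent
#' @param dispersion beta-binomial concentration per population (scalar
#'   recycled)
#' @param missing_rate fraction of genotype calls set missing
#' @param seed integer seed fixing all randomness
#' @return object of class `simulation_spec`
#' @export
simulation_spec <- function(grid_rows = 4L, grid_cols = 4L,
                            county_size = 30000, eras = "2012",
                            cover = NULL, n_sites = 8L, inds_per_pop = 12L,
                            n_loci = 2000L, alpha0 = 20, alphaD = 0.05,
                            alphaE = 0.5, alpha2 = 1, dispersion = 100,
                            missing_rate = 0.02, seed = 1L) {
  eras <- as.character(eras)
  if (is.null(cover)) {
    cover <- stats::setNames(
      replicate(length(eras),
                list(model = "gradient", p_min = 0.02, p_max = 0.5),
                simplify = FALSE),
      eras)
  }
  stopifnot(length(cover) == length(eras),
            n_sites <= grid_rows * grid_cols,
            n_loci >= 1, inds_per_pop >= 1,
            missing_rate >= 0, missing_rate < 1,
            alpha0 > 0, alphaD >= 0, all(alphaE >= 0))
  alphaE <- rep_len(alphaE, length(eras))
  structure(list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    county_size = county_size, eras = eras, cover = cover,
    n_sites = as.integer(n_sites), inds_per_pop = as.integer(inds_per_pop),
    n_loci = as.integer(n_loci), alpha0 = alpha0, alphaD = alphaD,
    alphaE = alphaE, alpha2 = alpha2, dispersion = dispersion,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "simulation_spec")
}

cover_proportions <- function(spec, era) {
  cm <- spec$cover[[era]]
  nr <- spec$grid_rows; nc <- spec$grid_cols
  ids <- county_grid_ids(nr, nc)
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  p <- switch(
    cm$model,
    uniform = rep(cm$p, nr * nc),
    gradient = {
      along <- if (identical(cm$axis, "row")) rows else cols
      m <- max(along)
      if (m == 1) rep((cm$p_min + cm$p_max) / 2, nr * nc) else
        cm$p_min + (along - 1) / (m - 1) * (cm$p_max - cm$p_min)
    },
    patch = {
      hit <- rep(TRUE, nr * nc)
      if (!is.null(cm$cols)) hit <- hit & cols %in% cm$cols
      if (!is.null(cm$rows)) hit <- hit & rows %in% cm$rows
      ifelse(hit, cm$p_in, cm$p_out)
    },
    stop("unknown cover model: ", cm$model, call. = FALSE)
  )
  stats::setNames(p, ids)
}

county_grid_ids <- function(nr, nc) {
  idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  sprintf("C%02d%02d", idx$row, idx$col)
}

#' Generate a county-grid landscape with sites
#'
#' Rectangular counties on a grid (so transect segment lengths have closed
#' forms), per-era potato proportions from the spec's cover models, and
#' `n_sites` sites placed in the interiors of distinct counties (off-center
#' so no transect lies exactly on a shared boundary). Deterministic under
#' the spec seed. The grid origin is offset from (0, 0) so coordinates
#' cannot be mistaken for longitude/latitude.
#'
#' @param spec [simulation_spec()]
#' @return list with `map` (a [county_era_map()] holding every era) and
#'   `sites` (a [site_samples()] table; `population_label` equals
#'   `site_id`)
#' @export
make_landscape <- function(spec) {
  nr <- spec$grid_rows; nc <- spec$grid_cols; cs <- spec$county_size
  origin <- c(1e6, 1e6)  # planar offset; keeps |x|,|y| out of lon/lat range
  idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  ids <- county_grid_ids(nr, nc)
  rings <- lapply(seq_len(nrow(idx)), function(i) {
    x0 <- origin[1] + (idx$col[i] - 1) * cs
    y0 <- origin[2] + (idx$row[i] - 1) * cs
    list(rbind(c(x0, y0), c(x0 + cs, y0), c(x0 + cs, y0 + cs), c(x0, y0 + cs)))
  })
  props <- stats::setNames(lapply(spec$eras, function(e) cover_proportions(spec, e)),
                           spec$eras)
  map <- county_era_map(ids, rings, props)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  chosen <- sample(seq_along(ids), spec$n_sites)
  offx <- stats::runif(spec$n_sites, 0.25, 0.75)
  offy <- stats::runif(spec$n_sites, 0.25, 0.75)
  sites <- data.frame(
    site_id = sprintf("S%02d", seq_len(spec$n_sites)),
    x = origin[1] + (idx$col[chosen] - 1 + offx) * cs,
    y = origin[2] + (idx$row[chosen] - 1 + offy) * cs,
    population_label = sprintf("S%02d", seq_len(spec$n_sites)),
    stringsAsFactors = FALSE
  )
  list(map = map, sites = site_samples(sites))
}

#' Standardized distance and resistance inputs for a landscape
#'
#' Convenience wrapper: computes the standardized geographic-distance
#' matrix and one standardized resistance matrix per era (infinite
#' resistances capped first).
#'
#' @param landscape result of [make_landscape()]
#' @return list with `D` and `E_list` (named by era)
#' @export
make_pairwise_inputs <- function(landscape) {
  D <- geographic_distance_matrix(landscape$sites, standardize = TRUE)
  E_list <- lapply(names(landscape$map$proportions), function(era) {
    m <- lrt_matrix(landscape$sites, landscape$map, era, standardize = FALSE)
    m <- finite_resistance(m)
    v <- standardize_pairwise(unclass(m), paste0("resistance:", era))
    pairwise_matrix(v, paste0("resistance:", era), standardized = TRUE)
  })
  names(E_list) <- names(landscape$map$proportions)
  list(D = D, E_list = E_list)
}

#' Simulate latent allele frequencies under the covariance model
#'
#' Per locus: ancestral frequency `mu_l ~ Uniform(0.05, 0.95)`, then the
#' population frequency vector is multivariate normal with mean `mu_l` and
#' covariance `mu_l (1 - mu_l) Omega` built from the spec's true effect
#' sizes, truncated to `[0, 1]` by rejection (up to 100 tries, then
#' clipping, logged).
#'
#' @param spec [simulation_spec()]
#' @param D standardized distance matrix
#' @param E_list standardized resistance matrices, one per era
#' @return populations x loci matrix of latent frequencies with attribute
#'   `mu`
#' @export
simulate_frequencies <- function(spec, D, E_list) {
  omega <- build_covariance(D, E_list, spec$alpha0, spec$alphaD,
                            spec$alphaE, spec$alpha2)
  K <- nrow(omega)
  ch <- chol(omega)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed + 1L)
  mu <- stats::runif(spec$n_loci, 0.05, 0.95)
  freqs <- matrix(0, K, spec$n_loci,
                  dimnames = list(rownames(unclass(D)), NULL))
  clipped <- 0L
  for (l in seq_len(spec$n_loci)) {
    sdev <- sqrt(mu[l] * (1 - mu[l]))
    ok <- FALSE
    for (try in seq_len(100L)) {
      z <- mu[l] + sdev * drop(crossprod(ch, stats::rnorm(K)))
      if (all(z >= 0 & z <= 1)) { ok <- TRUE; break }
    }
    if (!ok) { z <- pmin(1, pmax(0, z)); clipped <- clipped + 1L }
    freqs[, l] <- z
  }
  if (clipped > 0) {
    message("simulate_frequencies: clipped ", clipped,
            " loci after 100 rejection tries")
  }
  attr(freqs, "mu") <- mu
  freqs
}

#' Sample diploid genotypes around latent frequencies
#'
#' Per individual and locus the genotype is binomial(2, p*) with
#' `p* ~ Beta(f theta, (1 - f) theta)` (population dispersion `theta`);
#' missing calls are injected completely at random at the spec's
#' `missing_rate`. Allele counts are tallied from the non-missing calls.
#'
#' @param freqs populations x loci latent frequencies (from
#'   [simulate_frequencies()])
#' @param spec [simulation_spec()]
#' @return list with `genotypes` (a [genotype_matrix()]) and `counts`
#'   (an [allele_counts()] table)
#' @export
sample_genotypes <- function(freqs, spec) {
  stopifnot(all(freqs >= 0 & freqs <= 1))
  pops <- rownames(freqs)
  K <- nrow(freqs); L <- ncol(freqs); n <- spec$inds_per_pop
  theta <- rep_len(spec$dispersion, K)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed + 2L)
  calls <- matrix(NA_integer_, K * n, L)
  rownames(calls) <- paste0(rep(pops, each = n), "_",
                            rep(seq_len(n), times = K))
  colnames(calls) <- sprintf("L%05d", seq_len(L))
  pop_of <- rep(pops, each = n)
  for (j in seq_len(K)) {
    f <- freqs[j, ]
    a <- f * theta[j]; b <- (1 - f) * theta[j]
    rows <- which(pop_of == pops[j])
    mid <- f > 0 & f < 1
    for (i in rows) {
      pstar <- f  # fixed loci stay fixed
      if (any(mid)) pstar[mid] <- stats::rbeta(sum(mid), a[mid], b[mid])
      calls[i, ] <- stats::rbinom(L, 2L, pstar)
    }
  }
  if (spec$missing_rate > 0) {
    drop_mask <- stats::runif(length(calls)) < spec$missing_rate
    calls[drop_mask] <- NA_integer_
  }
  g <- genotype_matrix(calls, pop_of)
  list(genotypes = g, counts = allele_counts(g))
}
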