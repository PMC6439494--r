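# Programmatic fixtures: toy county maps and small genotype matrices.

rect_ring <- function(x0, y0, w, h) {
  rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h), c(x0, y0 + h))
}

# grid of rectangular counties with random potato proportions
toy_grid_map <- function(nr, nc, size = 1000, origin = c(5e5, 5e5),
                         era = "2012", p = NULL) {
  ids <- sprintf("C%02d", seq_len(nr * nc))
  idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  rings <- lapply(seq_len(nr * nc), function(i) {
    rect_ring(origin[1] + (idx$col[i] - 1) * size,
              origin[2] + (idx$row[i] - 1) * size, size, size)
  })
  if (is.null(p)) p <- stats::runif(nr * nc, 0.05, 0.9)
  county_era_map(ids, rings, stats::setNames(list(stats::setNames(p, ids)), era))
}

toy_site <- function(id, x, y) {
  list(site_id = id, x = x, y = y, population_label = id)
}

# irregular (non-grid) rectangle layout for harmonization split/merge tests:
# a historic strip of `k` columns against a reference strip cut at random
# positions over the same extent
toy_split_maps <- function(width = 4000, height = 1000, k_hist = 3,
                           k_ref = 2, era = "1910") {
  origin <- c(6e5, 6e5)
  # cuts jittered around an even partition, keeping every piece wide
  even_cuts <- function(k) {
    if (k == 1) return(c(0, 1) * width)
    inner <- seq_len(k - 1) / k + stats::runif(k - 1, -0.4 / k, 0.4 / k)
    c(0, inner, 1) * width
  }
  cuts_h <- even_cuts(k_hist)
  cuts_r <- even_cuts(k_ref)
  mk <- function(cuts, prefix, p) {
    ids <- sprintf("%s%02d", prefix, seq_len(length(cuts) - 1))
    rings <- lapply(seq_len(length(cuts) - 1), function(i) {
      rect_ring(origin[1] + cuts[i], origin[2], cuts[i + 1] - cuts[i], height)
    })
    props <- if (is.null(p)) NULL else
      stats::setNames(list(stats::setNames(p, ids)), era)
    county_era_map(ids, rings, props %||% list())
  }
  hist_p <- stats::runif(k_hist, 0, 0.8)
  list(historic = mk(cuts_h, "H", hist_p), reference = mk(cuts_r, "R", NULL),
       cuts_h = cuts_h, cuts_r = cuts_r, hist_p = hist_p,
       origin = origin, height = height)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# small genotype matrix with two populations and given calls
toy_genotypes <- function(calls_a, calls_b) {
  calls <- rbind(calls_a, calls_b)
  rownames(calls) <- c(paste0("A_", seq_len(nrow(calls_a))),
                       paste0("B_", seq_len(nrow(calls_b))))
  colnames(calls) <- paste0("L", seq_len(ncol(calls)))
  genotype_matrix(calls, rep(c("A", "B"), c(nrow(calls_a), nrow(calls_b))))
}

# random two-population genotype fixture (no missing data)
random_two_pop <- function(n_per_pop, n_loci, fst_like = 0.1) {
  anc <- stats::runif(n_loci, 0.1, 0.9)
  conc <- (1 - fst_like) / fst_like
  pa <- stats::rbeta(n_loci, anc * conc, (1 - anc) * conc)
  pb <- stats::rbeta(n_loci, anc * conc, (1 - anc) * conc)
  ca <- sapply(seq_len(n_loci), function(l) stats::rbinom(n_per_pop, 2, pa[l]))
  cb <- sapply(seq_len(n_loci), function(l) stats::rbinom(n_per_pop, 2, pb[l]))
  toy_genotypes(ca, cb)
}
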