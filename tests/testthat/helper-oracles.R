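# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route than the package (rasterization instead of
# clipping, Monte-Carlo classification instead of interval arithmetic,
# ANOVA sums of squares instead of moment formulas, explicit pair counting
# instead of closed forms, numerical integration instead of gamma-function
# identities).

# point-in-polygon via mgcv::in.out (C implementation, independent of the
# package's ray caster)
oracle_pip <- function(xs, ys, ring) {
  bnd <- rbind(ring, ring[1, , drop = FALSE])
  mgcv::in.out(bnd, cbind(xs, ys))
}

# intersection area of two rings by rasterization over the bbox overlap
oracle_intersection_area <- function(p, q, cell = 1) {
  lo <- pmax(apply(p, 2, min), apply(q, 2, min))
  hi <- pmin(apply(p, 2, max), apply(q, 2, max))
  if (any(hi <= lo)) return(0)
  xs <- seq(lo[1] + cell / 2, hi[1], by = cell)
  ys <- seq(lo[2] + cell / 2, hi[2], by = cell)
  if (!length(xs) || !length(ys)) return(0)
  pts <- expand.grid(x = xs, y = ys)
  inside <- oracle_pip(pts$x, pts$y, p) & oracle_pip(pts$x, pts$y, q)
  sum(inside) * cell^2
}

# segment lengths per county by classifying many points along the transect
oracle_segment_lengths <- function(a, b, map, n_pts = 1e5) {
  tt <- (seq_len(n_pts) - 0.5) / n_pts
  xs <- a$x + tt * (b$x - a$x)
  ys <- a$y + tt * (b$y - a$y)
  total <- sqrt((b$x - a$x)^2 + (b$y - a$y)^2)
  owner <- rep(NA_character_, n_pts)
  for (id in map$county_id) {
    for (ring in map$rings[[id]]) {
      hit <- oracle_pip(xs, ys, ring)
      take <- hit & (is.na(owner) | owner > id)  # lexicographic tie-break
      owner[take] <- id
    }
  }
  tab <- table(owner, useNA = "ifany")
  stats::setNames(as.numeric(tab) / n_pts * total, names(tab))
}

# LRT between two sites via the Monte-Carlo segmentation oracle
oracle_lrt <- function(a, b, map, era, n_pts = 1e5) {
  lens <- oracle_segment_lengths(a, b, map, n_pts)
  p <- map$proportions[[as.character(era)]]
  z <- ifelse(is.na(names(lens)) | !(names(lens) %in% names(p)), 0, p[names(lens)])
  total <- sqrt((b$x - a$x)^2 + (b$y - a$y)^2)
  denom <- sum(z * lens) / total
  if (denom <= 0) Inf else 1 / denom
}

# exact transect length inside an axis-aligned rectangle (slab clipping):
# closed form for the rectangular-county toy maps
oracle_rect_segment_length <- function(a, b, rect) {
  # rect = c(x0, x1, y0, y1)
  dx <- b$x - a$x; dy <- b$y - a$y
  t0 <- 0; t1 <- 1
  for (dim in 1:2) {
    d <- if (dim == 1) dx else dy
    o <- if (dim == 1) a$x else a$y
    lo <- rect[2 * dim - 1]; hi <- rect[2 * dim]
    if (d == 0) {
      if (o < lo || o > hi) return(0)
    } else {
      ta <- (lo - o) / d; tb <- (hi - o) / d
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  max(0, t1 - t0) * sqrt(dx^2 + dy^2)
}

# closed-form LRT on a rectangular-county map
oracle_rect_lrt <- function(a, b, map, era) {
  total <- sqrt((b$x - a$x)^2 + (b$y - a$y)^2)
  p <- map$proportions[[as.character(era)]]
  acc <- 0
  for (id in map$county_id) {
    ring <- map$rings[[id]][[1]]
    rect <- c(range(ring[, 1]), range(ring[, 2]))
    len <- oracle_rect_segment_length(a, b, rect)
    z <- if (id %in% names(p)) p[[id]] else 0
    acc <- acc + z * len
  }
  denom <- acc / total
  if (denom <= 0) Inf else 1 / denom
}

# Weir-Cockerham two-deme FST via the nested ANOVA sums-of-squares route:
# gene copies nested in individuals nested in populations.
oracle_fst_anova <- function(calls_a, calls_b) {
  num <- 0; den <- 0
  for (l in seq_len(ncol(calls_a))) {
    ga <- calls_a[, l]; gb <- calls_b[, l]
    ga <- ga[!is.na(ga)]; gb <- gb[!is.na(gb)]
    n1 <- length(ga); n2 <- length(gb)
    if (n1 < 1 || n2 < 1 || (n1 + n2) < 3) next
    p1 <- sum(ga) / (2 * n1); p2 <- sum(gb) / (2 * n2)
    if ((p1 == 0 && p2 == 0) || (p1 == 1 && p2 == 1)) next
    # expand each individual into its two allele copies (0/1); within an
    # individual a het contributes one copy of each allele
    copies <- function(g) {
      t(vapply(g, function(x) switch(as.character(x),
                                     `0` = c(0, 0), `1` = c(0, 1), `2` = c(1, 1)),
               numeric(2)))
    }
    ca <- copies(ga); cb <- copies(gb)
    pop <- rep(1:2, c(n1, n2))
    ind <- seq_len(n1 + n2)
    y <- rbind(ca, cb)
    ybar <- mean(y)
    ind_means <- rowMeans(y)
    pop_means <- tapply(ind_means * 2, pop, sum) / (2 * tabulate(pop))
    n_i <- tabulate(pop)
    # sums of squares at the three levels
    ss_pop <- sum(2 * n_i * (pop_means - ybar)^2)
    ss_ind <- sum(2 * (ind_means - pop_means[pop])^2)
    ss_gen <- sum((y - ind_means)^2)
    r <- 2
    nbar <- mean(n_i)
    nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
    ms_pop <- ss_pop / (r - 1)
    ms_ind <- ss_ind / (sum(n_i) - r)
    ms_gen <- ss_gen / sum(n_i)
    s2_a <- (ms_pop - ms_ind) / (2 * nc)
    s2_b <- (ms_ind - ms_gen) / 2
    s2_c <- ms_gen
    num <- num + s2_a
    den <- den + s2_a + s2_b + s2_c
  }
  num / den
}

# nucleotide diversity as the literal average mismatch over all pairs of
# sampled allele copies, per locus, summed and divided by total sites
oracle_pi_pairwise <- function(calls, total_sites) {
  acc <- 0
  for (l in seq_len(ncol(calls))) {
    g <- calls[, l]; g <- g[!is.na(g)]
    copies <- unlist(lapply(g, function(x) switch(as.character(x),
                                                  `0` = c(0, 0), `1` = c(0, 1),
                                                  `2` = c(1, 1))))
    m <- length(copies)
    if (m < 2) next
    mism <- 0; npair <- 0
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        mism <- mism + (copies[i] != copies[j])
        npair <- npair + 1
      }
    }
    acc <- acc + mism / npair
  }
  acc / total_sites
}

# beta-binomial mass by numerical integration of binomial x beta; the
# substitution u = pbeta(p; a, b) removes the endpoint singularities of
# small-concentration betas
oracle_bb_quadrature <- function(k, n, f, theta) {
  a <- f * theta; b <- (1 - f) * theta
  f_int <- function(u) stats::dbinom(k, n, stats::qbeta(u, a, b))
  log(stats::integrate(f_int, 0, 1, rel.tol = 1e-12,
                       subdivisions = 2000L)$value)
}

# compact letter display through multcomp (independent CLD implementation)
oracle_cld <- function(groups, alpha = 0.05) {
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 0L)))
  )
  fit <- stats::aov(value ~ group, data = df)
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Tukey"))
  multcomp::cld(glht, level = alpha)$mcletters$Letters
}

# letters partition equivalence: same grouping structure up to letter names
same_partition <- function(letters_a, letters_b) {
  labs <- names(letters_a)
  share_a <- outer(labs, labs, Vectorize(function(i, j) {
    any(strsplit(letters_a[[i]], "")[[1]] %in% strsplit(letters_a[[j]], "")[[1]])
  }))
  share_b <- outer(labs, labs, Vectorize(function(i, j) {
    any(strsplit(letters_b[[i]], "")[[1]] %in% strsplit(letters_b[[j]], "")[[1]])
  }))
  identical(share_a, share_b)
}
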