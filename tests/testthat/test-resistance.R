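test_that("segment_path decomposes simple transects exactly", {
  m <- toy_grid_map(1, 2, size = 1000, p = c(0.2, 0.4))
  origin <- c(5e5, 5e5)
  # fully inside one county
  a <- toy_site("a", origin[1] + 100, origin[2] + 500)
  b <- toy_site("b", origin[1] + 900, origin[2] + 500)
  segs <- segment_path(a, b, m)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$county_id, "C01")
  expect_equal(segs$length, 800)
  # crossing the shared boundary at the midpoint
  c2 <- toy_site("c", origin[1] + 1900, origin[2] + 500)
  segs2 <- segment_path(a, c2, m)
  expect_equal(segs2$length, c(900, 900))
  expect_equal(segs2$county_id, c("C01", "C02"))
  expect_equal(sum(segs2$length), attr(segs2, "total_length"))
  expect_error(segment_path(a, a, m), "degenerate")
})

test_that("gaps outside county coverage appear as NA segments", {
  m <- toy_grid_map(1, 1, size = 1000, p = 0.5)
  origin <- c(5e5, 5e5)
  a <- toy_site("a", origin[1] - 500, origin[2] + 500)
  b <- toy_site("b", origin[1] + 500, origin[2] + 500)
  segs <- segment_path(a, b, m)
  expect_equal(segs$county_id, c(NA, "C01"))
  expect_equal(segs$length, c(500, 500))
})

test_that("segment lengths match the Monte-Carlo classification oracle", {
  skip_if_not_installed("mgcv")
  set.seed(21)
  m <- toy_grid_map(3, 3, size = 700)
  origin <- c(5e5, 5e5)
  a <- toy_site("a", origin[1] + 130, origin[2] + 215)
  b <- toy_site("b", origin[1] + 1980, origin[2] + 1730)
  segs <- segment_path(a, b, m)
  want <- oracle_segment_lengths(a, b, m)
  got <- stats::setNames(segs$length, segs$county_id)
  got <- tapply(segs$length, segs$county_id, sum)
  for (id in names(got)) {
    expect_lt(abs(got[[id]] - want[[id]]) / attr(segs, "total_length"), 0.001)
  }
})

test_that("lrt_pair evaluates the inverse cover-weighted mean", {
  origin <- c(5e5, 5e5)
  m1 <- toy_grid_map(1, 1, size = 1000, p = 0.25)
  a <- toy_site("a", origin[1] + 100, origin[2] + 500)
  b <- toy_site("b", origin[1] + 900, origin[2] + 500)
  expect_equal(lrt_pair(a, b, m1, 2012), 4.0)
  mfull <- toy_grid_map(1, 1, size = 1000, p = 1)
  expect_equal(lrt_pair(a, b, mfull, 2012), 1.0)
  # two equal-length segments with Z 0.2 and 0.4 -> 1/0.3
  m2 <- toy_grid_map(1, 2, size = 1000, p = c(0.2, 0.4))
  c2 <- toy_site("c", origin[1] + 1900, origin[2] + 500)
  expect_equal(lrt_pair(a, c2, m2, 2012), 1 / 0.3, tolerance = 1e-12)
  # zero cover -> infinite resistance, logged
  m0 <- toy_grid_map(1, 1, size = 1000, p = 0)
  expect_message(v <- lrt_pair(a, b, m0, 2012), "Inf")
  expect_identical(v, Inf)
  expect_error(lrt_pair(a, b, m1, 1860), "era")
})

test_that("lrt invariants: floor at 1, monotonicity, symmetry, scale invariance", {
  set.seed(22)
  for (rep in 1:5) {
    m <- toy_grid_map(2, 3, size = runif(1, 500, 2000))
    origin <- c(5e5, 5e5)
    a <- toy_site("a", origin[1] + runif(1, 50, 900), origin[2] + runif(1, 50, 900))
    b <- toy_site("b", origin[1] + runif(1, 1100, 2800), origin[2] + runif(1, 1000, 1900))
    v <- lrt_pair(a, b, m, 2012)
    expect_gte(v, 1)
    expect_equal(lrt_pair(b, a, m, 2012), v)
    # raising one county's cover never increases resistance
    m2 <- m
    m2$proportions[["2012"]]["C03"] <-
      min(1, m$proportions[["2012"]]["C03"] + 0.3)
    expect_lte(lrt_pair(a, b, m2, 2012), v + 1e-12)
  }
  # uniform coordinate scaling leaves LRT unchanged
  m <- toy_grid_map(1, 2, size = 1000, p = c(0.2, 0.7))
  origin <- c(5e5, 5e5)
  a <- toy_site("a", origin[1] + 100, origin[2] + 300)
  b <- toy_site("b", origin[1] + 1800, origin[2] + 700)
  v1 <- lrt_pair(a, b, m, 2012)
  scale_map <- m
  for (id in scale_map$county_id) {
    scale_map$rings[[id]] <- lapply(scale_map$rings[[id]], function(r) r * 3)
  }
  scale_map <- county_era_map(scale_map$county_id, scale_map$rings,
                              scale_map$proportions)
  a3 <- toy_site("a", a$x * 3, a$y * 3); b3 <- toy_site("b", b$x * 3, b$y * 3)
  expect_equal(lrt_pair(a3, b3, scale_map, 2012), v1, tolerance = 1e-9)
})

test_that("lrt_matrix standardizes to unit SD and flags degenerate inputs", {
  set.seed(23)
  m <- toy_grid_map(2, 2, size = 1000)
  ls <- make_landscape(simulation_spec(grid_rows = 2, grid_cols = 2,
                                       county_size = 1000, n_sites = 4,
                                       seed = 5))
  mat <- lrt_matrix(ls$sites, ls$map, "2012", standardize = TRUE)
  expect_equal(stats::sd(upper_values(mat)), 1, tolerance = 1e-12)
  expect_true(isSymmetric(unclass(mat)))
  # uniform cover -> all pairwise LRT equal -> zero SD -> error
  uni <- simulation_spec(grid_rows = 2, grid_cols = 2, county_size = 1000,
                         n_sites = 4,
                         cover = list(`2012` = list(model = "uniform", p = 0.3)),
                         seed = 5)
  lsu <- make_landscape(uni)
  expect_error(lrt_matrix(lsu$sites, lsu$map, "2012", standardize = TRUE),
               "standard deviation")
})

test_that("lrt_matrix agrees with the closed-form rectangle oracle", {
  set.seed(24)
  ls <- make_landscape(simulation_spec(grid_rows = 3, grid_cols = 3,
                                       county_size = 900, n_sites = 4, seed = 9))
  mat <- lrt_matrix(ls$sites, ls$map, "2012")
  s <- ls$sites
  for (i in 1:3) {
    for (j in (i + 1):4) {
      want <- oracle_rect_lrt(s[i, ], s[j, ], ls$map, "2012")
      expect_lt(abs(mat[i, j] - want) / want, 0.005)
    }
  }
})

test_that("geographic distances are Euclidean and permutation-consistent", {
  sites <- site_samples(data.frame(
    site_id = c("a", "b", "c"), x = c(5e5, 5e5 + 3, 5e5 + 10),
    y = c(5e5, 5e5 + 4, 5e5), population_label = c("a", "b", "c")))
  d <- geographic_distance_matrix(sites)
  expect_equal(d["a", "b"], 5)
  perm <- sites[c(3, 1, 2), ]
  d2 <- geographic_distance_matrix(site_samples(perm))
  expect_equal(sort(upper_values(d2)), sort(upper_values(d)))
  # brute-force double loop
  set.seed(25)
  rnd <- site_samples(data.frame(
    site_id = paste0("s", 1:5), x = 5e5 + runif(5, 0, 1e4),
    y = 5e5 + runif(5, 0, 1e4), population_label = paste0("s", 1:5)))
  dm <- geographic_distance_matrix(rnd)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(dm[i, j],
                 sqrt((rnd$x[i] - rnd$x[j])^2 + (rnd$y[i] - rnd$y[j])^2))
  }
})

test_that("infinite resistances propagate with a warning and can be capped", {
  # two sites share a zero-cover county: their transect has no potato
  m <- toy_grid_map(1, 2, size = 1000, p = c(0, 0.9))
  origin <- c(5e5, 5e5)
  sites <- site_samples(data.frame(
    site_id = c("s1", "s2", "s3"),
    x = origin[1] + c(200, 800, 1500), y = origin[2] + 500,
    population_label = c("s1", "s2", "s3")))
  expect_warning(mat <- lrt_matrix(sites, m, 2012), "infinite")
  expect_true(any(!is.finite(upper_values(mat))))
  expect_warning(fin <- finite_resistance(mat), "replacing")
  expect_true(all(is.finite(upper_values(fin))))
  expect_equal(max(upper_values(fin)),
               10 * max(upper_values(mat)[is.finite(upper_values(mat))]))
})

test_that("pairwise matrices round-trip through square CSV", {
  set.seed(26)
  ls <- make_landscape(simulation_spec(n_sites = 5, seed = 3))
  d <- geographic_distance_matrix(ls$sites, standardize = TRUE)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "d.csv")
  write_pairwise_csv(d, path)
  back <- read_pairwise_csv(path, "distance", standardized = TRUE)
  expect_equal(unclass(back), unclass(d), tolerance = 1e-12, ignore_attr = TRUE)
})
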