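mk_sym <- function(v, ids) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- v
  m <- m + t(m)
  m
}

test_that("residual regression recovers constructed coefficients", {
  set.seed(71)
  ids <- paste0("s", 1:9)
  npair <- choose(9, 2)
  xd <- rnorm(npair); xr <- rnorm(npair)
  xr <- residuals(lm(xr ~ xd))  # orthogonalize
  # fst exactly linear in distance, resistance irrelevant
  fst1 <- mk_sym(0.01 + 0.002 * xd, ids)
  rr1 <- residual_regression(pairwise_matrix(fst1, "fst"),
                             pairwise_matrix(mk_sym(xd, ids), "distance", TRUE),
                             pairwise_matrix(mk_sym(xr, ids), "resistance:e", TRUE))
  expect_equal(rr1$distance$slope, 0.002, tolerance = 1e-10)
  expect_lt(abs(rr1$resistance$slope), 1e-10)
  expect_gt(rr1$resistance$p_value, 0.05)
  # fst = distance + 0.5 * resistance with orthogonal predictors
  fst2 <- mk_sym(xd + 0.5 * xr, ids)
  rr2 <- residual_regression(pairwise_matrix(fst2, "fst"),
                             pairwise_matrix(mk_sym(xd, ids), "distance", TRUE),
                             pairwise_matrix(mk_sym(xr, ids), "resistance:e", TRUE))
  expect_equal(rr2$resistance$slope, 0.5, tolerance = 1e-10)
  # stage-2 slope equals the partial coefficient from bivariate OLS when
  # predictors are orthogonal
  biv <- coef(lm(mk_sym(xd + 0.5 * xr, ids)[upper.tri(fst2)] ~ xd + xr))
  expect_equal(rr2$resistance$slope, unname(biv["xr"]), tolerance = 1e-10)
})

test_that("residual regression is invariant to a common site permutation", {
  set.seed(72)
  ids <- paste0("s", 1:7)
  fst <- mk_sym(runif(21, 0, 0.05), ids)
  d <- mk_sym(runif(21, 0.5, 2), ids)
  e <- mk_sym(runif(21, 0.5, 2), ids)
  rr <- residual_regression(pairwise_matrix(fst, "fst"),
                            pairwise_matrix(d, "distance", TRUE),
                            pairwise_matrix(e, "resistance:x", TRUE))
  perm <- sample(7)
  pm <- function(m, lab, st = FALSE) pairwise_matrix(m[perm, perm], lab, st)
  rr2 <- residual_regression(pm(fst, "fst"), pm(d, "distance", TRUE),
                             pm(e, "resistance:x", TRUE))
  expect_equal(rr2$resistance$slope, rr$resistance$slope, tolerance = 1e-12)
  expect_equal(rr2$resistance$r_squared, rr$resistance$r_squared,
               tolerance = 1e-12)
  expect_error(
    residual_regression(pairwise_matrix(fst, "fst"),
                        pairwise_matrix(mk_sym(rep(1, 21), ids), "distance"),
                        pairwise_matrix(e, "resistance:x")),
    "constant")
})

test_that("regression invariants: residuals centered, n recorded", {
  set.seed(73)
  x <- rnorm(30); y <- 2 * x + rnorm(30)
  res <- resistgen:::ols(y, x, "test")
  expect_lt(abs(mean(res$residuals)), 1e-10 * sd(res$residuals))
  expect_equal(res$n, 30)
})

test_that("anova_tukey separates obvious groups and respects ties", {
  same <- anova_tukey(list(A = c(1, 1.01, 0.99), B = c(1, 1.02, 0.98)))
  expect_equal(unname(same$letters["A"]), unname(same$letters["B"]))
  far <- anova_tukey(list(A = rnorm(5, 0, 0.1), B = rnorm(5, 100, 0.1)))
  expect_false(unname(far$letters["A"]) == unname(far$letters["B"]))
  expect_error(anova_tukey(list(A = 1:3)), ">= 2 groups")
  expect_error(anova_tukey(list(A = 1:3, B = 2)), ">= 2 values")
})

test_that("HSD letters reproduce an independent implementation", {
  skip_if_not_installed("multcomp")
  set.seed(74)
  agree <- 0
  for (rep in 1:60) {
    k <- sample(3:5, 1)
    means <- runif(k, 0, 6)
    groups <- lapply(means, function(m) rnorm(sample(4:8, 1), m, 1))
    names(groups) <- LETTERS[seq_len(k)]
    mine <- anova_tukey(groups)$letters
    ref <- oracle_cld(groups)
    agree <- agree + same_partition(mine, ref[names(mine)])
  }
  # multcomp adjusts slightly differently (glht vs studentized range), so a
  # rare borderline case may differ; require near-perfect agreement
  expect_gte(agree, 57)
})

test_that("three-group power simulation isolates the shifted group", {
  set.seed(75)
  hits <- 0
  for (rep in 1:100) {
    groups <- list(g1 = rnorm(6, 0, 1), g2 = rnorm(6, 0, 1), g3 = rnorm(6, 5, 1))
    lt <- anova_tukey(groups)$letters
    solo <- !any(grepl(lt[["g3"]], lt[c("g1", "g2")], fixed = TRUE))
    hits <- hits + solo
  }
  expect_gte(hits, 95)
})

test_that("diversity regressions recover known slopes", {
  set.seed(76)
  cover <- runif(9, 0, 0.6)
  pi_vals <- 0.008 - 0.005 * cover
  dr <- diversity_regression(setNames(pi_vals, paste0("s", 1:9)),
                             setNames(cover, paste0("s", 1:9)), "1860")
  expect_equal(dr$slope, -0.005, tolerance = 1e-10)
  expect_equal(attr(dr, "era"), "1860")
  expect_error(diversity_regression(pi_vals, rep(0.3, 9)), "constant")
})

test_that("fst_vs_diversity uses pair-averaged diversity as predictor", {
  ids <- paste0("s", 1:6)
  pi_vals <- setNames(seq(0.002, 0.012, length.out = 6), ids)
  pred <- outer(pi_vals, pi_vals, "+") / 2
  fst <- pairwise_matrix(mk_sym(0.05 - 2 * pred[upper.tri(pred)], ids), "fst")
  fd <- fst_vs_diversity(fst, pi_vals)
  expect_equal(fd$slope, -2, tolerance = 1e-10)
  expect_lt(fd$slope, 0)
  expect_error(fst_vs_diversity(fst, setNames(rep(0.005, 6), ids)), "constant")
})
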