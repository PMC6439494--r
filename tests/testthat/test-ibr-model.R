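mk_pair_mats <- function(K, seed = 1) {
  set.seed(seed)
  xy <- cbind(runif(K, 0, 100), runif(K, 0, 100))
  D <- as.matrix(dist(xy))
  dimnames(D) <- list(paste0("P", 1:K), paste0("P", 1:K))
  D <- D / sd(D[upper.tri(D)])
  E <- D[sample(K), sample(K)]
  dimnames(E) <- dimnames(D)
  E <- abs(E + matrix(runif(K * K), K, K)); E <- (E + t(E)) / 2; diag(E) <- 0
  E <- E / sd(E[upper.tri(E)])
  list(D = D, E = E)
}

test_that("build_covariance has the stated closed form and monotonicity", {
  m <- mk_pair_mats(5)
  # zero effects: constant covariance 1/alpha0
  om0 <- build_covariance(m$D, list(m$E), alpha0 = 4, alphaD = 0, alphaE = 0)
  expect_true(all(abs(om0 - 1 / 4) < 1e-9 + diag(5)))  # jitter may touch diag
  # alphaD * D = ln 2 at one pair -> off-diagonal 0.5
  D <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  D[1, 2] <- D[2, 1] <- log(2)
  om <- build_covariance(D, list(), alpha0 = 1, alphaD = 1, alphaE = numeric(0))
  expect_equal(om[1, 2], 0.5, tolerance = 1e-12)
  # increasing alphaE weakly decreases every off-diagonal entry
  om1 <- build_covariance(m$D, list(m$E), 2, 0.3, 0.2)
  om2 <- build_covariance(m$D, list(m$E), 2, 0.3, 0.8)
  off <- upper.tri(om1)
  expect_true(all(om2[off] <= om1[off] + 1e-12))
})

test_that("bb_loglik equals the binomial-beta quadrature and normalizes", {
  # quadrature comparison where the mass is large enough for reliable
  # numerical integration (deep tails are covered by the normalization
  # identity below)
  cases <- expand.grid(k = c(0, 3, 11, 24), n = 24,
                       f = c(0.1, 0.5, 0.93), theta = c(2, 40, 300))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      got <- bb_loglik(k, n, f, theta)
      if (got > -25) {
        expect_equal(got, oracle_bb_quadrature(k, n, f, theta),
                     tolerance = 1e-6)
      }
    })
  }
  # the mass function sums to one exactly, including the extreme tails
  for (f in c(0.05, 0.4, 0.9)) {
    for (theta in c(1.5, 30, 500)) {
      expect_equal(sum(exp(bb_loglik(0:24, 24, f, theta))), 1,
                   tolerance = 1e-12)
    }
  }
  expect_equal(bb_loglik(0, 0, 0.5, 10), 0)
})

test_that("log_posterior is finite, penalizes misfit, ignores empty loci", {
  m <- mk_pair_mats(4, seed = 2)
  K <- 4; L <- 6
  alt <- matrix(c(rep(0L, 12), rep(8L, 12)), K, L)
  an <- matrix(8L, K, L)
  counts <- structure(list(alt = alt, an = an), class = "allele_count_table")
  om <- build_covariance(m$D, list(m$E), 10, 0.1, 0.1)
  f <- matrix(0.5, K, L); mu <- rep(0.5, L); th <- rep(50, K)
  base <- log_posterior(counts, om, f, mu, th)
  expect_true(is.finite(base))
  # extreme counts under a concentrated beta at 0.5 are unlikely: moving the
  # latent toward the data raises the posterior
  f2 <- f; f2[, 1] <- 0.05
  expect_gt(log_posterior(counts, om, f2, mu, th), base)
  # an empty locus (allele_number 0) leaves the value unchanged
  counts2 <- structure(list(alt = cbind(alt, 0L), an = cbind(an, 0L)),
                       class = "allele_count_table")
  f3 <- cbind(f, 0.5); mu3 <- c(mu, 0.5)
  expect_equal(log_posterior(counts2, om, f3, mu3, th), base)
  # out-of-support latents give -Inf, never NaN
  fbad <- f; fbad[1, 1] <- 0
  expect_identical(log_posterior(counts, om, fbad, mu, th), -Inf)
})

test_that("chains are deterministic under seed and distinct across ids", {
  sc <- suppressMessages(simulate_scenario("ibr_strong", seed = 2, n_loci = 60))
  cfg <- ibr_config(n_steps = 3000, n_chains = 1, seed = 42,
                    covariate_labels = "2012")
  a <- suppressWarnings(run_chain(sc$counts, sc$inputs$D, sc$inputs$E_list, cfg, 1))
  b <- suppressWarnings(run_chain(sc$counts, sc$inputs$D, sc$inputs$E_list, cfg, 1))
  expect_identical(a$trace, b$trace)
  c2 <- suppressWarnings(run_chain(sc$counts, sc$inputs$D, sc$inputs$E_list, cfg, 2))
  expect_false(identical(a$trace, c2$trace))
})

test_that("collinear distance and resistance trigger the identifiability warning", {
  m <- mk_pair_mats(6, seed = 3)
  E_col <- m$D * 1.7
  counts <- structure(list(
    alt = matrix(3L, 6, 10, dimnames = list(rownames(m$D), NULL)),
    an = matrix(8L, 6, 10, dimnames = list(rownames(m$D), NULL))),
    class = "allele_count_table")
  cfg <- ibr_config(n_steps = 200, n_chains = 1, covariate_labels = "e")
  expect_warning(
    suppressMessages(run_chain(
      counts, pairwise_matrix(m$D, "distance", TRUE),
      list(pairwise_matrix(E_col, "resistance:e", TRUE)), cfg, 1)),
    "collinear")
})

test_that("gelman_rubin matches its defining formula and flags degeneracy", {
  # identical chains: B = 0 so psrf = sqrt((n-1)/n) <= 1
  x <- rnorm(100)
  gr_same <- gelman_rubin(list(x, x))
  expect_lt(gr_same$psrf, 1)
  # far-separated tight chains blow up
  gr_far <- gelman_rubin(list(rnorm(50, 0, 0.01), rnorm(50, 100, 0.01)))
  expect_gt(gr_far$psrf, 100)
  # hand evaluation of the formula on a tiny case
  c1 <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  c2 <- c(2, 3, 4, 5, 6, 7, 8, 9, 10, 12)
  W <- mean(c(var(c1), var(c2)))
  B <- 10 * var(c(mean(c1), mean(c2)))
  expect_equal(gelman_rubin(list(c1, c2))$psrf,
               sqrt(((9 / 10) * W + B / 10) / W), tolerance = 1e-12)
  expect_warning(gelman_rubin(list(rep(1, 20), rep(1, 20))), "undefined")
})

test_that("gelman_rubin on iid chains sits near one", {
  set.seed(61)
  chains <- lapply(1:4, function(i) rnorm(1000))
  gr <- gelman_rubin(chains)
  expect_gte(gr$psrf, 0.99)
  expect_lte(gr$psrf, 1.05)
})

test_that("effect_summary aggregates per-chain ratios with HSD letters", {
  mk_post <- function(ratio_sets) {
    chains <- lapply(seq_len(nrow(ratio_sets[[1]])), function(i) {
      tr <- do.call(cbind, lapply(ratio_sets, function(m) m[i, ]))
      colnames(tr) <- paste0("alphaE:", names(ratio_sets))
      tr <- cbind(log_post = 0, alpha0 = 1, alphaD = 1, tr, alpha2 = 1)
      structure(list(trace = tr, chain_id = i), class = "ibr_chain")
    })
    structure(list(chains = chains, covariate_labels = names(ratio_sets)),
              class = "ibr_posterior")
  }
  # three chains whose retained-window alphaE medians are 1, 2, 3 (alphaD = 1)
  sets <- list(e1 = rbind(rep(1, 40), rep(2, 40), rep(3, 40)))
  es <- effect_summary(mk_post(sets))
  expect_equal(es$mean_ratio, 2)
  expect_equal(es$se, sd(c(1, 2, 3)) / sqrt(3), tolerance = 1e-12)
  expect_equal(es$hsd_group, "a")
  # constant chains: SE 0
  sets2 <- list(e1 = rbind(rep(2, 40), rep(2, 40), rep(2, 40)))
  es2 <- effect_summary(mk_post(sets2))
  expect_equal(es2$mean_ratio, 2)
  expect_equal(es2$se, 0)
  # output ordering follows the requested label order
  sets3 <- list(x = matrix(4 + rnorm(120, 0, 1e-3), 3, 40),
                y = matrix(9 + rnorm(120, 0, 1e-3), 3, 40))
  es3 <- effect_summary(mk_post(sets3), era_labels = c("y", "x"))
  expect_equal(es3$era, c("y", "x"))
  expect_gt(es3$mean_ratio[1], es3$mean_ratio[2])
  expect_false(es3$hsd_group[1] == es3$hsd_group[2])
  expect_error(effect_summary(structure(list(chains = list(1)),
                                        class = "ibr_posterior")),
               ">= 2 chains")
})

test_that("acceptance rates are reported and mostly inside the target band", {
  sc <- suppressMessages(simulate_scenario("ibr_strong", seed = 3, n_loci = 80))
  cfg <- ibr_config(n_steps = 6000, n_chains = 1, covariate_labels = "2012")
  ch <- suppressWarnings(run_chain(sc$counts, sc$inputs$D, sc$inputs$E_list, cfg, 1))
  expect_true(all(ch$acceptance[c("alpha0", "freq")] >= 0 &
                  ch$acceptance[c("alpha0", "freq")] <= 1, na.rm = TRUE))
  expect_true(is.na(ch$acceptance["alpha2"]))  # fixed by default
})
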