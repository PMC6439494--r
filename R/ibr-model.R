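# Bayesian beta-binomial isolation-by-resistance model: covariance
# construction and likelihood pieces. The sampler itself is compiled
# (src/ibr_mcmc.cpp); the R functions here define the model and serve as
# the reference implementation for its components.
#
# Model. For locus l with ancestral frequency mu_l, the vector of latent
# population frequencies f_l is multivariate normal with mean mu_l and
# covariance mu_l (1 - mu_l) * Omega, truncated to [0, 1]^K. Omega has
# off-diagonal entries (1/alpha0) exp(-(alphaD D_ij + sum_k alphaE_k
# E_k,ij)^alpha2) and diagonal 1/alpha0: allele-frequency covariance decays
# with a weighted sum of geographic distance and per-era landscape
# resistance. Observed alternate-allele counts are beta-binomial around f_l
# with per-population dispersion theta_j. Priors are bounded log-uniform on
# alpha0, alphaD, alphaE_k and theta_j; alpha2 is fixed at 1 by default.

#' Parametric allele-frequency covariance matrix
#'
#' `Omega[i, j] = (1/alpha0) * exp(-(alphaD * D[i,j] + sum_k alphaE[k] *
#' E[[k]][i,j])^alpha2)` off the diagonal and `1/alpha0` on it. If the
#' smallest eigenvalue falls below `1e-10` a diagonal jitter is added
#' (logged) so downstream factorizations succeed.
#'
#' @param D pairwise geographic-distance matrix (standardized)
#' @param E_list list of pairwise resistance matrices (standardized), one
#'   per covariate/era; may be empty
#' @param alpha0 inverse-scale parameter (> 0)
#' @param alphaD effect size of geographic distance (>= 0)
#' @param alphaE numeric vector of resistance effect sizes, one per
#'   element of `E_list`
#' @param alpha2 shape exponent in (0, 2], default 1
#' @return positive-(semi)definite covariance matrix
#' @export
build_covariance <- function(D, E_list, alpha0, alphaD, alphaE, alpha2 = 1) {
  stopifnot(alpha0 > 0, alphaD >= 0, alpha2 > 0, alpha2 <= 2,
            length(alphaE) == length(E_list), all(alphaE >= 0))
  D <- unclass(D)
  if (!all(is.finite(D))) stop("non-finite distance matrix", call. = FALSE)
  lin <- alphaD * D
  for (k in seq_along(E_list)) {
    Ek <- unclass(E_list[[k]])
    if (!all(is.finite(Ek))) stop("non-finite resistance matrix", call. = FALSE)
    lin <- lin + alphaE[k] * Ek
  }
  diag(lin) <- 0
  omega <- exp(-lin^alpha2) / alpha0
  diag(omega) <- 1 / alpha0
  ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 1e-10) {
    message("build_covariance: jitter added (min eigenvalue ", signif(ev, 3), ")")
    omega <- omega + diag(max(1e-10 - ev, 1e-10), nrow(omega))
  }
  omega
}

#' Beta-binomial log likelihood of an allele count
#'
#' Log probability of `k` alternate alleles among `n` sampled copies when
#' the sampling probability is beta-distributed with mean `f` and
#' concentration `theta` (shape parameters `f * theta`, `(1 - f) * theta`).
#' Vectorized over all arguments; `n = 0` contributes 0.
#'
#' @param k alternate-allele count
#' @param n alleles sampled
#' @param f latent frequency in (0, 1)
#' @param theta dispersion (concentration) > 0; larger is closer to
#'   binomial
#' @export
bb_loglik <- function(k, n, f, theta) {
  stopifnot(all(k >= 0), all(k <= n), all(theta > 0))
  a <- f * theta
  b <- (1 - f) * theta
  out <- lchoose(n, k) + lgamma(k + a) + lgamma(n - k + b) - lgamma(n + theta) -
    lgamma(a) - lgamma(b) + lgamma(theta)
  out[n == 0] <- 0
  out
}

#' Joint log posterior of the allele-frequency covariance model
#'
#' Evaluates, up to the flat-prior constant, the joint log density of the
#' latent frequencies and observed counts: the (untruncated) multivariate
#' normal term per locus plus the beta-binomial observation term. Loci with
#' no sampled alleles in any population are dropped (they carry no latent
#' frequency). Used as the reference for the compiled sampler and directly
#' for diagnostics; returns `-Inf` outside the support rather than `NaN`.
#'
#' @param counts [allele_counts()] table (populations x loci)
#' @param omega covariance matrix from [build_covariance()], populations in
#'   the same order as `counts`
#' @param freqs latent frequencies, populations x loci, in (0, 1)
#' @param mu per-locus ancestral frequencies in (0, 1)
#' @param dispersion per-population beta-binomial concentrations
#' @return scalar log posterior (finite for valid parameters)
#' @export
log_posterior <- function(counts, omega, freqs, mu, dispersion) {
  alt <- counts$alt; an <- counts$an
  keep <- colSums(an) > 0
  alt <- alt[, keep, drop = FALSE]; an <- an[, keep, drop = FALSE]
  freqs <- freqs[, keep, drop = FALSE]; mu <- mu[keep]
  K <- nrow(alt); L <- ncol(alt)
  if (any(freqs <= 0 | freqs >= 1) || any(mu <= 0 | mu >= 1)) return(-Inf)
  ch <- tryCatch(chol(omega), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  P <- chol2inv(ch)
  s <- mu * (1 - mu)
  d <- freqs - matrix(mu, K, L, byrow = TRUE)
  quad <- colSums(d * (P %*% d)) / s
  mvn <- -0.5 * (L * K * log(2 * pi) + L * logdet + K * sum(log(s)) + sum(quad))
  bb <- sum(bb_loglik(alt, an, freqs, matrix(dispersion, K, L)))
  if (!is.finite(bb)) return(-Inf)
  mvn + bb
}
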