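# Pairwise FST between two populations: Weir & Cockerham (1984) two-deme
# moment estimator, ratio of averages across loci. This is the standard
# two-population reading of the Weir-Hill variance-components family used
# by landscape-genetic software.

#' Per-locus Weir-Cockerham variance components for two demes
#'
#' Given per-deme sample sizes (diploid individuals successfully genotyped),
#' alternate-allele frequencies, and observed heterozygote proportions,
#' returns the `a` (among-population), `b` (among-individual within
#' population) and `c` (within-individual) components per locus.
#'
#' @param n1,n2 individuals genotyped per deme (vectors over loci)
#' @param p1,p2 alternate-allele frequencies per deme
#' @param h1,h2 observed heterozygote proportions per deme
#' @return list of vectors `a`, `b`, `c`
#' @keywords internal
wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Pairwise multilocus FST between two populations
#'
#' Weir-Cockerham two-deme moment estimator with sample-size correction,
#' combined across loci as a ratio of averages: `sum(a) / sum(a + b + c)`.
#' Loci monomorphic across both demes, or with fewer than one genotyped
#' individual in either deme, contribute nothing. The estimate can be
#' slightly negative when true differentiation is near zero.
#'
#' @param g [genotype_matrix()]
#' @param pop_a,pop_b population labels (each with >= 2 individuals)
#' @return scalar FST estimate
#' @export
pairwise_fst <- function(g, pop_a, pop_b) {
  ga <- subset_populations(g, pop_a)
  gb <- subset_populations(g, pop_b)
  if (nrow(ga$calls) < 2 || nrow(gb$calls) < 2) {
    stop("both populations need >= 2 individuals", call. = FALSE)
  }
  n1 <- colSums(!is.na(ga$calls)); n2 <- colSums(!is.na(gb$calls))
  ok <- n1 >= 1 & n2 >= 1 & (n1 + n2) >= 3  # nbar > 1 required by the correction
  alt1 <- colSums(ga$calls, na.rm = TRUE); alt2 <- colSums(gb$calls, na.rm = TRUE)
  p1 <- alt1 / (2 * n1); p2 <- alt2 / (2 * n2)
  poly <- ok & !((p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1))
  if (!any(poly)) stop("no polymorphic loci between ", pop_a, " and ", pop_b,
                       call. = FALSE)
  h1 <- colSums(ga$calls == 1L, na.rm = TRUE) / n1
  h2 <- colSums(gb$calls == 1L, na.rm = TRUE) / n2
  comp <- wc_components(n1[poly], n2[poly], p1[poly], p2[poly], h1[poly], h2[poly])
  num <- sum(comp$a)
  den <- sum(comp$a + comp$b + comp$c)
  if (den == 0) stop("degenerate FST denominator", call. = FALSE)
  num / den
}

#' Pairwise FST matrix over all populations
#'
#' @param g [genotype_matrix()]
#' @param site_order optional ordering of population labels for the matrix
#' @return [pairwise_matrix()] labelled `fst`
#' @export
fst_matrix <- function(g, site_order = NULL) {
  pops <- site_order %||% sort(unique(g$populations))
  n <- length(pops)
  m <- matrix(0, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      v <- pairwise_fst(g, pops[i], pops[j])
      m[i, j] <- v; m[j, i] <- v
    }
  }
  pairwise_matrix(m, "fst")
}
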