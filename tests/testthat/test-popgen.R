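test_that("genotype codes are validated and mapped from VCF and CSV", {
  expect_error(genotype_matrix(matrix(3L, 1, 1), "A"), "codes")
  g <- toy_genotypes(matrix(c(0L, 1L, 2L, NA), 2, 2),
                     matrix(c(2L, 2L, 0L, 0L), 2, 2))
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "g.vcf"); csv <- file.path(dir, "g.csv")
  write_vcf(g, vcf); write_genotypes_csv(g, csv)
  gv <- load_genotypes(vcf, "vcf")
  gc <- load_genotypes(csv, "csv")
  expect_equal(unname(gv$calls), unname(g$calls))
  expect_equal(gv$populations, g$populations)
  expect_equal(unname(gc$calls), unname(g$calls))
  expect_equal(gc$populations, g$populations)
})

test_that("synthetic VCF round-trips losslessly through the loader", {
  sc <- suppressMessages(simulate_scenario("null", seed = 4, n_loci = 40))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sim.vcf")
  write_vcf(sc$genotypes, path)
  back <- load_genotypes(path, "vcf")
  expect_equal(unname(back$calls), unname(sc$genotypes$calls))
  expect_equal(back$populations, sc$genotypes$populations)
})

test_that("MAF filter folds frequencies and drops monomorphic loci", {
  # 50 individuals -> 100 alleles; construct exact frequencies
  mk_locus <- function(nalt) c(rep(2L, nalt %/% 2), rep(1L, nalt %% 2),
                               rep(0L, 50 - nalt %/% 2 - nalt %% 2))
  calls <- cbind(
    maf04 = mk_locus(4),    # alt freq 0.04 -> removed
    maf96 = 2L - mk_locus(4), # alt freq 0.96 -> minor 0.04 -> removed
    mono = rep(0L, 50),     # monomorphic -> removed
    keep = mk_locus(10)     # alt freq 0.10 -> retained
  )
  g <- genotype_matrix(calls, rep(c("A", "B"), 25))
  out <- filter_maf(g, 0.05)
  expect_equal(colnames(out$calls), "keep")
})

test_that("missingness filter retains the boundary locus", {
  calls <- cbind(
    m31 = c(rep(NA_integer_, 31), rep(1L, 69)),
    m30 = c(rep(NA_integer_, 30), rep(1L, 70)),
    full = rep(1L, 100)
  )
  g <- genotype_matrix(calls, rep("A", 100))
  out <- filter_missing(g, 0.30)
  expect_equal(colnames(out$calls), c("m30", "full"))
})

test_that("filters commute when imputation is not interleaved", {
  set.seed(31)
  g <- random_two_pop(20, 60)
  calls <- g$calls
  calls[sample(length(calls), 200)] <- NA_integer_
  g <- genotype_matrix(calls, g$populations)
  a <- filter_missing(filter_maf(g), threshold = 0.2)
  b <- filter_maf(filter_missing(g, threshold = 0.2))
  expect_equal(colnames(a$calls), colnames(b$calls))
})

test_that("modal imputation fills by scope with deterministic ties", {
  calls <- rbind(c(0L, 1L), c(0L, 1L), c(1L, 0L), c(NA, NA))
  colnames(calls) <- c("L1", "L2")
  g <- genotype_matrix(calls, c("A", "A", "B", "B"))
  # population scope: the missing B individual takes B's modes (1, 0)
  gp <- impute_mode(g, "population")
  expect_equal(unname(gp$calls[4, ]), c(1L, 0L))
  # global scope: modes over everyone (0 and 1)
  gg <- impute_mode(g, "global")
  expect_equal(unname(gg$calls[4, ]), c(0L, 1L))
  expect_false(anyNA(gp$calls))
  # tie breaks toward the smaller code
  tie <- genotype_matrix(rbind(c(0L), c(2L), c(NA)), rep("A", 3))
  expect_equal(unname(impute_mode(tie, "global")$calls[3, 1]), 0L)
  # no-missing input is untouched
  expect_equal(impute_mode(gp, "population")$calls, gp$calls)
  # all-missing locus errors
  allna <- genotype_matrix(matrix(NA_integer_, 2, 1), c("A", "A"))
  expect_error(impute_mode(allna), "no observed")
})

test_that("nucleotide diversity matches its closed form and oracle", {
  # monomorphic population
  mono <- genotype_matrix(matrix(0L, 4, 3), rep("A", 4))
  expect_equal(nucleotide_diversity(mono, "A", 3), 0)
  # one heterozygous individual, one locus: two alleles differ -> pi = 1
  het <- genotype_matrix(matrix(1L, 1, 1), "A")
  expect_warning(v <- nucleotide_diversity(het, "A", 1), regexp = NA)
  expect_equal(v, 1.0)
  # pairwise-mismatch oracle on a small fixture with missing calls
  set.seed(32)
  calls <- matrix(sample(c(0L, 1L, 2L, NA), 50, TRUE, prob = c(.4, .3, .2, .1)),
                  5, 10)
  g <- genotype_matrix(calls, rep("A", 5))
  expect_equal(suppressWarnings(nucleotide_diversity(g, "A", 12)),
               oracle_pi_pairwise(calls, 12), tolerance = 1e-10)
  expect_error(nucleotide_diversity(g, "A", 5), "total_sites")
})

test_that("observed heterozygosity counts heterozygous calls per site", {
  homo <- genotype_matrix(matrix(c(0L, 2L), 2, 4), rep("A", 2))
  expect_equal(observed_heterozygosity(homo, "A", 4), 0)
  allhet <- genotype_matrix(matrix(1L, 3, 4), rep("A", 3))
  expect_equal(observed_heterozygosity(allhet, "A", 4), 1)
  mixed <- genotype_matrix(rbind(c(1L, 0L), c(1L, 1L)), rep("A", 2))
  # locus fractions 1 and 0.5 over total_sites 4
  expect_equal(observed_heterozygosity(mixed, "A", 4), 1.5 / 4)
})

test_that("pi, heterozygosity and folded SFS are invariant to allele relabeling", {
  set.seed(33)
  g <- random_two_pop(10, 30)
  swapped <- genotype_matrix(2L - g$calls, g$populations)
  expect_equal(nucleotide_diversity(g, "A", 40),
               nucleotide_diversity(swapped, "A", 40))
  expect_equal(observed_heterozygosity(g, "A", 40),
               observed_heterozygosity(swapped, "A", 40))
  expect_equal(folded_sfs(g, "A")$bins, folded_sfs(swapped, "A")$bins)
})

test_that("folded SFS folds counts above n and conserves loci", {
  # 12 diploids -> 2n = 24
  calls <- matrix(0L, 12, 3)
  calls[1:2, 1] <- c(2L, 1L)       # alt count 3
  calls[, 2] <- 2L; calls[1:2, 2] <- c(0L, 1L)  # alt count 21 -> folds to 3
  colnames(calls) <- c("a", "b", "c")
  g <- genotype_matrix(calls, rep("P", 12))
  sfs <- folded_sfs(g, "P")
  expect_equal(unname(sfs$bins["3"]), 2L)
  expect_equal(unname(sfs$bins["0"]), 1L)
  expect_equal(sum(sfs$bins), 3L)
  expect_equal(sfs$n_alleles, 24)
  # unequal allele numbers direct the user to imputation
  calls[1, 1] <- NA
  g2 <- genotype_matrix(calls, rep("P", 12))
  expect_error(folded_sfs(g2, "P"), "impute")
})
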