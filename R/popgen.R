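# Genotype-matrix ingestion, SNP filters, modal imputation, and summary
# population-genetic statistics (nucleotide diversity, heterozygosity,
# folded site frequency spectrum). Pairwise FST lives in fst.R.

#' Construct a genotype matrix
#'
#' Diploid calls coded as copies of the designated alternate allele:
#' 0, 1, 2, or `NA` for missing.
#'
#' @param calls integer matrix, individuals x loci, entries in
#'   `{0, 1, 2, NA}`; rownames are individual ids, colnames locus ids
#' @param populations character vector of population labels, one per row
#' @return object of class `genotype_matrix`
#' @export
genotype_matrix <- function(calls, populations) {
  stopifnot(is.matrix(calls), length(populations) == nrow(calls))
  ok <- is.na(calls) | calls %in% c(0, 1, 2)
  if (!all(ok)) {
    stop("genotype codes outside {0, 1, 2, NA}: e.g. ",
         calls[which(!ok)[1]], call. = FALSE)
  }
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) rownames(calls) <- paste0("ind", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) colnames(calls) <- paste0("locus", seq_len(ncol(calls)))
  populations <- as.character(populations)
  if (any(!nzchar(populations)) || anyNA(populations)) {
    stop("empty population labels", call. = FALSE)
  }
  structure(list(calls = calls, populations = populations),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix>", nrow(x$calls), "individuals x", ncol(x$calls),
      "loci;", length(unique(x$populations)), "populations;",
      sum(is.na(x$calls)), "missing calls\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Load genotypes from VCF or CSV
#'
#' VCF: biallelic SNP records only (multiallelic records are skipped with a
#' logged count); the GT field is mapped to 0/1/2/NA. Population labels are
#' taken from `populations` (a named vector keyed by sample id) or, by
#' default, from the sample-id prefix before the first underscore.
#' CSV: one row per individual, first two columns `individual_id` and
#' `population_label`, remaining columns loci with entries 0/1/2/NA.
#'
#' @param path input file
#' @param format `"vcf"` or `"csv"`
#' @param populations optional named character vector sample id -> label
#' @return [genotype_matrix()]
#' @export
load_genotypes <- function(path, format = c("vcf", "csv"), populations = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (ncol(df) < 3 || !all(c("individual_id", "population_label") %in% names(df)[1:2])) {
      stop("genotype CSV must start with individual_id, population_label", call. = FALSE)
    }
    calls <- as.matrix(df[, -(1:2), drop = FALSE])
    storage.mode(calls) <- "integer"
    rownames(calls) <- df$individual_id
    return(genotype_matrix(calls, df$population_label))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) stop("no parsable VCF records in ", path, call. = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (any(!bi)) {
    message("load_genotypes: skipping ", sum(!bi), " multiallelic records")
    v <- v[bi, ]
  }
  if (nrow(v@fix) == 0) stop("no biallelic records in ", path, call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_copies <- function(s) {
    if (is.na(s)) return(NA_integer_)
    al <- strsplit(s, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(as.integer(al) != 0L)
  }
  loci <- if (!is.null(rownames(gt))) rownames(gt) else
    paste0(v@fix[, "CHROM"], ":", v@fix[, "POS"])
  calls <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                  dimnames = list(colnames(gt), loci))
  for (i in seq_len(nrow(gt))) {
    calls[, i] <- vapply(gt[i, ], alt_copies, 0L)
  }
  samples <- rownames(calls)
  pops <- if (!is.null(populations)) {
    if (!all(samples %in% names(populations))) {
      stop("populations vector lacks labels for some samples", call. = FALSE)
    }
    unname(populations[samples])
  } else {
    sub("_.*$", "", samples)
  }
  genotype_matrix(calls, pops)
}

pooled_alt_freq <- function(g) {
  alt <- colSums(g$calls, na.rm = TRUE)
  an <- 2 * colSums(!is.na(g$calls))
  ifelse(an > 0, alt / an, NA_real_)
}

#' Filter loci by minor allele frequency
#'
#' MAF is computed over all non-missing calls pooled across populations;
#' loci with MAF below `threshold` are dropped (monomorphic loci always
#' drop for `threshold > 0`).
#'
#' @param g [genotype_matrix()]
#' @param threshold minimum minor allele frequency retained (default 0.05)
#' @export
filter_maf <- function(g, threshold = 0.05) {
  stopifnot(threshold >= 0, threshold <= 0.5)
  p <- pooled_alt_freq(g)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= threshold
  if (!any(keep)) message("filter_maf: no loci retained")
  subset_loci(g, keep)
}

#' Filter loci by missing-genotype fraction
#'
#' Retains loci whose fraction of missing calls (over all individuals) is
#' at most `threshold`; the boundary value is retained.
#'
#' @param g [genotype_matrix()]
#' @param threshold maximum missing fraction (default 0.30)
#' @export
filter_missing <- function(g, threshold = 0.30) {
  stopifnot(threshold > 0, threshold <= 1)
  miss <- colMeans(is.na(g$calls))
  subset_loci(g, miss <= threshold)
}

subset_loci <- function(g, keep) {
  genotype_matrix(g$calls[, keep, drop = FALSE], g$populations)
}

#' Subset individuals by population label
#' @param g [genotype_matrix()]
#' @param pops labels to keep
#' @export
subset_populations <- function(g, pops) {
  keep <- g$populations %in% pops
  if (!any(keep)) stop("no individuals in populations: ",
                       paste(pops, collapse = ", "), call. = FALSE)
  genotype_matrix(g$calls[keep, , drop = FALSE], g$populations[keep])
}

modal_code <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_integer_)
  tab <- tabulate(x + 1L, nbins = 3L)
  # ties break toward the smaller code
  which.max(tab) - 1L
}

#' Replace missing genotypes by the modal genotype
#'
#' Deterministic single-marker imputation: each missing call becomes the
#' most frequent observed genotype at that locus, within the individual's
#' population (`scope = "population"`, default) or over all individuals
#' (`scope = "global"`). Ties break toward the smaller code. A locus with
#' no observed calls within a population falls back to the global mode; a
#' locus with no observed calls at all is an error.
#'
#' @param g [genotype_matrix()]
#' @param scope `"population"` or `"global"`
#' @export
impute_mode <- function(g, scope = c("population", "global")) {
  scope <- match.arg(scope)
  calls <- g$calls
  if (!anyNA(calls)) return(g)
  global_mode <- apply(calls, 2, modal_code)
  if (anyNA(global_mode)) {
    stop("loci with no observed genotypes: ",
         paste(colnames(calls)[is.na(global_mode)], collapse = ", "), call. = FALSE)
  }
  if (scope == "global") {
    for (l in which(colSums(is.na(calls)) > 0)) {
      calls[is.na(calls[, l]), l] <- global_mode[l]
    }
  } else {
    for (pop in unique(g$populations)) {
      rows <- g$populations == pop
      sub <- calls[rows, , drop = FALSE]
      need <- which(colSums(is.na(sub)) > 0)
      for (l in need) {
        m <- modal_code(sub[, l])
        if (is.na(m)) m <- global_mode[l]
        sub[is.na(sub[, l]), l] <- m
      }
      calls[rows, ] <- sub
    }
  }
  genotype_matrix(calls, g$populations)
}

#' Per-population allele counts
#'
#' @param g [genotype_matrix()]
#' @return object of class `allele_count_table`: list with matrices `alt`
#'   (alternate-allele counts) and `an` (alleles successfully genotyped),
#'   populations x loci
#' @export
allele_counts <- function(g) {
  pops <- sort(unique(g$populations))
  alt <- matrix(0L, length(pops), ncol(g$calls),
                dimnames = list(pops, colnames(g$calls)))
  an <- alt
  for (p in pops) {
    rows <- g$populations == p
    alt[p, ] <- colSums(g$calls[rows, , drop = FALSE], na.rm = TRUE)
    an[p, ] <- 2L * colSums(!is.na(g$calls[rows, , drop = FALSE]))
  }
  structure(list(alt = alt, an = an), class = "allele_count_table")
}

#' Nucleotide diversity within a population
#'
#' Per-site average of the unbiased per-locus heterozygosity
#' `2 p (1 - p) 2n / (2n - 1)` (the mean pairwise difference among the 2n
#' sampled allele copies), divided by the total number of genotyped sites
#' including monomorphic ones. Loci with fewer than two sampled allele
#' copies are skipped with a warning.
#'
#' @param g [genotype_matrix()]
#' @param pop population label
#' @param total_sites denominator: all genotyped sites, monomorphic
#'   included (must be >= number of loci)
#' @export
nucleotide_diversity <- function(g, pop, total_sites) {
  gs <- subset_populations(g, pop)
  if (total_sites < ncol(gs$calls)) {
    stop("total_sites smaller than the number of loci", call. = FALSE)
  }
  alt <- colSums(gs$calls, na.rm = TRUE)
  an <- 2 * colSums(!is.na(gs$calls))
  usable <- an >= 2
  if (any(!usable)) {
    warning("skipping ", sum(!usable), " loci with < 2 sampled alleles", call. = FALSE)
  }
  p <- alt[usable] / an[usable]
  sum(2 * p * (1 - p) * an[usable] / (an[usable] - 1)) / total_sites
}

#' Observed heterozygosity within a population
#'
#' Fraction of heterozygous calls per locus (among genotyped individuals),
#' summed over loci and divided by `total_sites`.
#'
#' @inheritParams nucleotide_diversity
#' @export
observed_heterozygosity <- function(g, pop, total_sites) {
  gs <- subset_populations(g, pop)
  if (total_sites < ncol(gs$calls)) {
    stop("total_sites smaller than the number of loci", call. = FALSE)
  }
  het <- colSums(gs$calls == 1L, na.rm = TRUE)
  n <- colSums(!is.na(gs$calls))
  usable <- n > 0
  sum(het[usable] / n[usable]) / total_sites
}

#' Folded site frequency spectrum for one population
#'
#' Histogram of per-locus minor-allele counts `min(alt, 2n - alt)`.
#' Requires a uniform number of sampled alleles across loci (impute first).
#'
#' @param g [genotype_matrix()]
#' @param pop population label
#' @return object of class `folded_sfs`: list with `population`,
#'   `n_alleles` (2n), and `bins` (named counts for k = 0..n)
#' @export
folded_sfs <- function(g, pop) {
  gs <- subset_populations(g, pop)
  an <- 2 * colSums(!is.na(gs$calls))
  if (length(unique(an)) != 1L) {
    stop("unequal allele numbers across loci; impute missing genotypes first",
         call. = FALSE)
  }
  m <- unname(an[1])
  alt <- colSums(gs$calls, na.rm = TRUE)
  minor <- pmin(alt, m - alt)
  half <- m %/% 2
  bins <- vapply(0:half, function(k) sum(minor == k), 0L)
  names(bins) <- 0:half
  structure(list(population = pop, n_alleles = m, bins = bins),
            class = "folded_sfs")
}
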