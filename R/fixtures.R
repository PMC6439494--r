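# Canned simulation scenarios written to disk as the plain-text formats
# the pipeline consumes (GeoJSON + CSV + VCF + manifest JSON).

#' Write county polygons as a GeoJSON FeatureCollection
#'
#' @param map [county_era_map()]
#' @param path output file
#' @export
write_county_geojson <- function(map, path) {
  features <- lapply(map$county_id, function(id) {
    rings <- lapply(map$rings[[id]], function(r) {
      r <- rbind(r, r[1, , drop = FALSE])  # close the ring
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    list(
      type = "Feature",
      properties = list(county_id = id),
      geometry = list(
        type = "MultiPolygon",
        coordinates = lapply(rings, function(r) list(r))
      )
    )
  })
  gj <- list(type = "FeatureCollection", features = features)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Write per-era census CSVs for a map
#'
#' One CSV per era with columns `county_id, year, potato_area,
#' county_area` consistent with the map's proportions.
#'
#' @param map [county_era_map()]
#' @param dir output directory
#' @return named character vector of paths (by era)
#' @export
write_census_csvs <- function(map, dir) {
  out <- character(0)
  for (era in names(map$proportions)) {
    p <- stats::setNames(rep(0, length(map$county_id)), map$county_id)
    p[names(map$proportions[[era]])] <- map$proportions[[era]]
    df <- data.frame(
      county_id = map$county_id,
      year = as.integer(era),
      potato_area = unname(p * map$areas),
      county_area = unname(map$areas),
      stringsAsFactors = FALSE
    )
    path <- file.path(dir, paste0("census_", era, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    out[era] <- path
  }
  out
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' One biallelic SNP record per locus (placeholder chromosome/positions,
#' REF=A ALT=T), GT-only FORMAT, missing calls as `./.`.
#'
#' @param g [genotype_matrix()]
#' @param path output file
#' @export
write_vcf <- function(g, path) {
  calls <- g$calls
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=resistgen-synthetic",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(calls)), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(calls)), function(l) {
    gts <- ifelse(is.na(calls[, l]), "./.", gt_code[calls[, l] + 1L])
    paste(c("1", l, colnames(calls)[l], "A", "T", ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a genotype matrix as CSV
#'
#' Rows are individuals; the first two columns are `individual_id` and
#' `population_label`, the rest one column per locus (0/1/2, empty for
#' missing).
#'
#' @param g [genotype_matrix()]
#' @param path output file
#' @export
write_genotypes_csv <- function(g, path) {
  df <- data.frame(individual_id = rownames(g$calls),
                   population_label = g$populations,
                   g$calls, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

fixture_spec <- function(name, seed, n_loci) {
  switch(
    name,
    null = simulation_spec(
      eras = "2012",
      cover = list(`2012` = list(model = "gradient", p_min = 0.02, p_max = 0.5)),
      alphaD = 0.05, alphaE = 0, n_loci = n_loci, seed = seed),
    ibr_strong = simulation_spec(
      eras = "2012",
      cover = list(`2012` = list(model = "gradient", p_min = 0.02, p_max = 0.5)),
      alphaD = 0.05, alphaE = 0.5, n_loci = n_loci, seed = seed),
    era_contrast = simulation_spec(
      eras = c("1860", "1910", "2012"),
      cover = list(
        `1860` = list(model = "gradient", p_min = 0.4, p_max = 0.05, axis = "row"),
        `1910` = list(model = "patch", p_in = 0.45, p_out = 0.05,
                      rows = c(1L, 2L), cols = c(3L, 4L)),
        `2012` = list(model = "gradient", p_min = 0.02, p_max = 0.5, axis = "col")
      ),
      alphaD = 0.05, alphaE = c(0, 0, 0.5), n_loci = n_loci, seed = seed),
    stop("unknown fixture name: ", name, call. = FALSE)
  )
}

#' Generate a canned scenario in memory
#'
#' Three scenarios share one landscape layout and differ in the true
#' effect sizes: `null` (no landscape effect, `alphaE = 0`),
#' `ibr_strong` (one era, true `alphaE/alphaD = 10`), and `era_contrast`
#' (three eras with distinct cover maps; genotypes generated from the
#' third era's resistance only).
#'
#' @param name one of `"null"`, `"ibr_strong"`, `"era_contrast"`
#' @param seed integer seed
#' @param n_loci loci to simulate (default 500)
#' @return list: `spec`, `landscape`, `inputs` (D, E_list), `freqs`,
#'   `genotypes`, `counts`
#' @export
simulate_scenario <- function(name, seed = 1L, n_loci = 500L) {
  spec <- fixture_spec(name, seed, n_loci)
  landscape <- make_landscape(spec)
  inputs <- make_pairwise_inputs(landscape)
  # frequencies respond only to eras with nonzero true alphaE
  freqs <- simulate_frequencies(spec, inputs$D, inputs$E_list)
  gen <- sample_genotypes(freqs, spec)
  list(spec = spec, landscape = landscape, inputs = inputs, freqs = freqs,
       genotypes = gen$genotypes, counts = gen$counts)
}

#' Write a canned scenario to disk
#'
#' Writes `counties.geojson`, per-era `census_<era>.csv`, `sites.csv`,
#' `genotypes.vcf`, `genotypes.csv` and `manifest.json` (seed and true
#' parameters) under `dir`. Byte-stable for a fixed seed.
#'
#' @inheritParams simulate_scenario
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest as a list
#' @export
make_fixture <- function(name, dir, seed = 1L, n_loci = 500L) {
  sc <- simulate_scenario(name, seed = seed, n_loci = n_loci)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_county_geojson(sc$landscape$map, file.path(dir, "counties.geojson"))
  write_census_csvs(sc$landscape$map, dir)
  utils::write.csv(as.data.frame(sc$landscape$sites),
                   file.path(dir, "sites.csv"), row.names = FALSE)
  write_vcf(sc$genotypes, file.path(dir, "genotypes.vcf"))
  write_genotypes_csv(sc$genotypes, file.path(dir, "genotypes.csv"))
  manifest <- list(
    fixture = name, seed = seed, n_loci = n_loci,
    eras = sc$spec$eras,
    true_parameters = list(alpha0 = sc$spec$alpha0, alphaD = sc$spec$alphaD,
                           alphaE = sc$spec$alphaE, alpha2 = sc$spec$alpha2,
                           dispersion = sc$spec$dispersion),
    n_sites = sc$spec$n_sites, inds_per_pop = sc$spec$inds_per_pop,
    missing_rate = sc$spec$missing_rate
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  invisible(manifest)
}
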