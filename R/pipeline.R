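# Configuration-driven orchestration: landcover -> resistance -> popgen ->
# covariance model -> association battery, with a run manifest and plain
# ISO-timestamped logs.

#' Build/validate a pipeline configuration
#'
#' Accepts a YAML path or a list. Required fields: `eras` (character),
#' `polygons` (GeoJSON path, or named list per era), `census` (named list
#' era -> CSV), `sites` (CSV), `genotypes` (VCF or CSV path), `outdir`.
#' Optional: `genotype_format` ("vcf"/"csv", default from extension),
#' `reference_polygons` (defaults to the last era's polygons),
#' `harmonize_mode` ("printed"/"weighted"), `maf_threshold` (0.05),
#' `missing_threshold` (0.30), `impute_scope` ("population"),
#' `total_sites` (defaults to the post-filter locus count), `seed`,
#' `per_era_models` (TRUE), and `ibr` (a list of [ibr_config()]
#' arguments).
#'
#' @param config list or YAML file path
#' @return validated config list of class `pipeline_config`
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("eras", "polygons", "census", "sites", "genotypes", "outdir")
  missing_fields <- setdiff(need, names(config))
  if (length(missing_fields)) {
    stop("pipeline config lacks fields: ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  config$eras <- as.character(config$eras)
  if (!length(config$eras)) stop("eras must be nonempty", call. = FALSE)
  if (is.character(config$polygons) && length(config$polygons) == 1) {
    config$polygons <- stats::setNames(
      as.list(rep(config$polygons, length(config$eras))), config$eras)
  }
  config$reference_polygons <- config$reference_polygons %||%
    config$polygons[[config$eras[length(config$eras)]]]
  config$harmonize_mode <- config$harmonize_mode %||% "printed"
  config$maf_threshold <- config$maf_threshold %||% 0.05
  config$missing_threshold <- config$missing_threshold %||% 0.30
  config$impute_scope <- config$impute_scope %||% "population"
  config$seed <- as.integer(config$seed %||% 1L)
  config$per_era_models <- config$per_era_models %||% TRUE
  config$genotype_format <- config$genotype_format %||%
    (if (grepl("\\.vcf$", config$genotypes)) "vcf" else "csv")
  for (era in config$eras) {
    if (is.null(config$census[[era]])) {
      stop("no census file for era ", era, call. = FALSE)
    }
  }
  paths <- c(unlist(config$polygons), unlist(config$census),
             config$sites, config$genotypes, config$reference_polygons)
  absent <- paths[!file.exists(paths)]
  if (length(absent)) {
    stop("missing input files: ", paste(unique(absent), collapse = ", "),
         call. = FALSE)
  }
  class(config) <- c("pipeline_config", "list")
  config
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
  writeLines(msg, con)
  flush(con)
}

#' Locate the county containing each site
#'
#' @param map [county_era_map()]
#' @param sites [site_samples()] table
#' @return named character vector site_id -> county_id (NA when outside
#'   every county)
#' @export
site_county <- function(map, sites) {
  out <- stats::setNames(rep(NA_character_, nrow(sites)), sites$site_id)
  for (id in map$county_id) {
    for (ring in map$rings[[id]]) {
      hit <- points_in_ring(sites$x, sites$y, ring)
      out[hit & is.na(out)] <- id
    }
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes, in order: census loading and harmonization per era;
#' standardized distance and per-era resistance matrices; SNP filters,
#' modal imputation, pairwise FST, diversity, heterozygosity and folded
#' spectra; the all-era covariance model (plus per-era models when
#' configured) with effect summaries and HSD letters; and the residual and
#' diversity regressions. Every artifact lands in `outdir` together with a
#' `manifest.json` (input hashes, seed, package version, stage status) and
#' a timestamped `run.log`. A failing stage aborts with the stage name
#' after writing a partial manifest.
#'
#' @param config [pipeline_config()] input (list or YAML path)
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(outdir, "run.log"), open = "wt")
  on.exit(close(logcon), add = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("resistgen")),
    seed = config$seed,
    inputs = lapply(
      stats::setNames(nm = unique(c(unlist(config$polygons),
                                    unlist(config$census), config$sites,
                                    config$genotypes))),
      function(p) unname(tools::md5sum(p))),
    stages = list(), outputs = character(0)
  )
  flush_manifest <- function() {
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               file.path(outdir, "manifest.json"))
  }
  stage <- function(name, expr) {
    log_line(logcon, "stage ", name, " start")
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- "failed"
      log_line(logcon, "stage ", name, " FAILED: ", conditionMessage(e))
      flush_manifest()
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- "ok"
    log_line(logcon, "stage ", name, " done")
    res
  }
  emit <- function(name) {
    manifest$outputs <<- c(manifest$outputs, name)
    file.path(outdir, name)
  }

  lc <- stage("landcover", {
    reference <- load_census(config$census[[config$eras[length(config$eras)]]],
                             config$reference_polygons,
                             config$eras[length(config$eras)])
    maps <- list(); harmonized <- list()
    for (era in config$eras) {
      m <- load_census(config$census[[era]], config$polygons[[era]], era)
      h <- harmonize(m, reference, era, mode = config$harmonize_mode)
      write_harmonized_csv(h, emit(paste0("harmonized_", era, ".csv")))
      maps[[era]] <- m; harmonized[[era]] <- h
    }
    list(reference = reference, maps = maps, harmonized = harmonized)
  })

  rs <- stage("resistance", {
    sites <- read_sites_csv(config$sites)
    D <- geographic_distance_matrix(sites, standardize = TRUE)
    write_pairwise_csv(D, emit("distance_standardized.csv"))
    E_list <- list()
    for (era in config$eras) {
      raw <- lrt_matrix(sites, lc$maps[[era]], era, standardize = FALSE)
      raw <- finite_resistance(raw)
      std <- pairwise_matrix(
        standardize_pairwise(unclass(raw), paste0("resistance:", era)),
        paste0("resistance:", era), standardized = TRUE)
      write_pairwise_csv(std, emit(paste0("resistance_", era, ".csv")))
      E_list[[era]] <- std
    }
    list(sites = sites, D = D, E_list = E_list)
  })

  pg <- stage("popgen", {
    g <- load_genotypes(config$genotypes, config$genotype_format)
    g <- filter_maf(g, config$maf_threshold)
    g <- filter_missing(g, config$missing_threshold)
    g <- impute_mode(g, config$impute_scope)
    total_sites <- config$total_sites %||% ncol(g$calls)
    pops <- sort(unique(g$populations))
    fst <- fst_matrix(g, site_order = rs$sites$site_id)
    write_pairwise_csv(fst, emit("fst.csv"))
    pi <- vapply(pops, function(p) nucleotide_diversity(g, p, total_sites), 0)
    het <- vapply(pops, function(p) observed_heterozygosity(g, p, total_sites), 0)
    utils::write.csv(
      data.frame(population = pops, nucleotide_diversity = pi,
                 observed_heterozygosity = het, row.names = NULL),
      emit("diversity.csv"), row.names = FALSE)
    for (p in pops) {
      sfs <- folded_sfs(g, p)
      utils::write.csv(
        data.frame(minor_allele_count = as.integer(names(sfs$bins)),
                   n_loci = as.integer(sfs$bins)),
        emit(paste0("sfs_", p, ".csv")), row.names = FALSE)
    }
    list(g = g, counts = allele_counts(g), pi = pi, het = het,
         total_sites = total_sites)
  })

  ibr <- stage("ibr", {
    ibr_args <- config$ibr %||% list()
    ibr_args$seed <- ibr_args$seed %||% config$seed
    ibr_args$covariate_labels <- config$eras
    cfg_all <- do.call(ibr_config, ibr_args)
    post_all <- run_ibr(pg$counts, rs$D, rs$E_list, cfg_all)
    write_traces_csv(post_all, emit("traces_all_eras.csv"))
    summ <- effect_summary(post_all)
    utils::write.csv(as.data.frame(summ), emit("effect_summary.csv"),
                     row.names = FALSE)
    per_era <- list()
    if (isTRUE(config$per_era_models) && length(config$eras) > 1) {
      for (era in config$eras) {
        ibr_args$covariate_labels <- era
        cfg_era <- do.call(ibr_config, ibr_args)
        per_era[[era]] <- run_ibr(pg$counts, rs$D, rs$E_list[era], cfg_era)
        write_traces_csv(per_era[[era]], emit(paste0("traces_", era, ".csv")))
      }
    }
    list(all = post_all, per_era = per_era, summary = summ)
  })

  stage("association", {
    fst <- fst_matrix(pg$g, site_order = rs$sites$site_id)
    rows <- list()
    for (era in config$eras) {
      rr <- residual_regression(fst, rs$D, rs$E_list[[era]])
      rows[[era]] <- data.frame(
        analysis = c("fst_vs_distance", paste0("residual_vs_resistance_", era)),
        slope = c(rr$distance$slope, rr$resistance$slope),
        r_squared = c(rr$distance$r_squared, rr$resistance$r_squared),
        p_value = c(rr$distance$p_value, rr$resistance$p_value))
    }
    counties <- site_county(lc$reference, rs$sites)
    div_rows <- list()
    for (era in config$eras) {
      cover <- lc$harmonized[[era]][counties]
      names(cover) <- rs$sites$site_id
      pi_by_site <- pg$pi[rs$sites$population_label]
      names(pi_by_site) <- rs$sites$site_id
      dr <- tryCatch(diversity_regression(pi_by_site, cover, era),
                     error = function(e) NULL)
      if (!is.null(dr)) {
        div_rows[[era]] <- data.frame(
          analysis = paste0("diversity_vs_cover_", era),
          slope = dr$slope, r_squared = dr$r_squared, p_value = dr$p_value)
      }
    }
    fd <- fst_vs_diversity(fst,
                           stats::setNames(pg$pi[rs$sites$population_label],
                                           rs$sites$site_id))
    tab <- do.call(rbind, c(rows, div_rows, list(data.frame(
      analysis = "fst_vs_diversity", slope = fd$slope,
      r_squared = fd$r_squared, p_value = fd$p_value))))
    utils::write.csv(tab, emit("regressions.csv"), row.names = FALSE)
    tab
  })

  flush_manifest()
  log_line(logcon, "run complete")
  invisible(manifest)
}
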