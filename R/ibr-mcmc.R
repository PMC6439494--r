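# MCMC driver for the allele-frequency covariance model: configuration,
# chain execution, convergence diagnostics, and effect-size summaries.

#' Configuration for the covariance-model sampler
#'
#' Desk-scale defaults: 4 chains of 50,000 steps with the first 20%
#' used as a discarded tuning window (proposal scales adapted toward the
#' `target_acceptance` band, then frozen) and the remainder thinned by 10.
#' Larger runs (more chains, millions of steps) are a matter of changing
#' these fields.
#'
#' @param n_steps steps per chain (tuning window included)
#' @param n_chains independent chains
#' @param thin keep every `thin`-th post-tuning step
#' @param seed integer seed; chain `i` uses an RNG stream derived from
#'   `seed` and `i`
#' @param covariate_labels labels for the resistance covariates (e.g. era
#'   names); length must match the number of resistance matrices
#' @param alpha2 covariance shape exponent in (0, 2]
#' @param estimate_alpha2 sample `alpha2` instead of fixing it
#' @param proposal_scales named list of initial random-walk scales:
#'   `alpha` (log-scale hyperparameters), `alpha2`, `theta` (log
#'   dispersions), `freq` (latent frequencies); adapted during tuning
#' @param mu_concentration concentration of the beta independence proposal
#'   for ancestral frequencies
#' @param target_acceptance acceptance-rate band checked after tuning
#' @param tune_frac fraction of the chain used as the tuning window
#' @param latent_updates single-site latent frequency updates attempted
#'   per step (random-walk)
#' @param joint_updates locus-wise joint latent updates per step
#'   (independence proposals from the Gaussian approximation to the full
#'   conditional; these dominate latent mixing)
#' @param mu_updates ancestral-frequency updates attempted per step
#' @param theta_prob probability of a dispersion update per step
#' @param asis_prob probability per step of an interweaving move (a
#'   covariance-parameter proposal holding the whitened latent field
#'   fixed); inexpensive insurance against the degenerate
#'   independence mode
#' @param warm_sweeps full joint-update sweeps over all loci before the
#'   chain proper, bringing the latent field to its conditional posterior
#'   under the initial hyperparameters
#' @return object of class `ibr_config`
#' @export
ibr_config <- function(n_steps = 50000L, n_chains = 4L, thin = 10L, seed = 1L,
                       covariate_labels = NULL, alpha2 = 1,
                       estimate_alpha2 = FALSE,
                       proposal_scales = list(alpha = 0.5, alpha2 = 0.1,
                                              theta = 0.5, freq = 0.05),
                       mu_concentration = 20, target_acceptance = c(0.2, 0.7),
                       tune_frac = 0.2, latent_updates = 30L,
                       joint_updates = 12L, mu_updates = 20L,
                       theta_prob = 0.15, asis_prob = 0.05,
                       warm_sweeps = 50L) {
  stopifnot(n_steps >= 1, n_chains >= 1, thin >= 1, alpha2 > 0, alpha2 <= 2,
            tune_frac >= 0, tune_frac < 1,
            all(unlist(proposal_scales) > 0))
  structure(list(
    n_steps = as.integer(n_steps), n_chains = as.integer(n_chains),
    thin = as.integer(thin), seed = as.integer(seed),
    covariate_labels = covariate_labels, alpha2 = alpha2,
    estimate_alpha2 = estimate_alpha2, proposal_scales = proposal_scales,
    mu_concentration = mu_concentration,
    target_acceptance = target_acceptance, tune_frac = tune_frac,
    latent_updates = as.integer(latent_updates),
    joint_updates = as.integer(joint_updates),
    mu_updates = as.integer(mu_updates), theta_prob = theta_prob,
    asis_prob = asis_prob, warm_sweeps = as.integer(warm_sweeps)
  ), class = "ibr_config")
}

prep_ibr_inputs <- function(counts, D, E_list, config) {
  stopifnot(inherits(counts, "allele_count_table"))
  pops <- rownames(counts$alt)
  if (!identical(rownames(unclass(D)), pops)) {
    stop("distance matrix and count table disagree on population order",
         call. = FALSE)
  }
  E_list <- lapply(E_list, function(e) {
    if (any(!is.finite(unclass(e)))) e <- finite_resistance(e)
    if (!identical(rownames(unclass(e)), pops)) {
      stop("resistance matrix and count table disagree on population order",
           call. = FALSE)
    }
    e
  })
  dv <- upper_values(unclass(D))
  for (e in E_list) {
    r <- stats::cor(dv, upper_values(unclass(e)))
    if (is.finite(r) && abs(r) > 0.99) {
      warning("distance and resistance are nearly collinear (|r| = ",
              signif(abs(r), 3), "); the effect-size ratio is unstable",
              call. = FALSE)
    }
  }
  keep <- colSums(counts$an) > 0
  if (!all(keep)) {
    message("dropping ", sum(!keep), " loci with no sampled alleles")
    counts <- structure(list(alt = counts$alt[, keep, drop = FALSE],
                             an = counts$an[, keep, drop = FALSE]),
                        class = "allele_count_table")
  }
  list(counts = counts, D = D, E_list = E_list)
}

ibr_init_values <- function(counts, D, E_list) {
  # moment-flavored starting points; the tuning window does the rest.
  # Effect sizes start so the total linear predictor is ~1 at the average
  # pair (initial correlation ~ exp(-1)), split evenly across covariates.
  K <- nrow(counts$alt)
  p <- (counts$alt + 0.5) / (counts$an + 1)
  mu <- colMeans(p)
  sl <- pmax(mu * (1 - mu), 1e-4)
  nv <- mean(apply(p, 2, stats::var) / sl)
  alpha0 <- 1 / max(nv, 1e-4)
  preds <- c(list(unclass(D)), lapply(E_list, unclass))
  a_init <- vapply(preds, function(m) {
    1 / (length(preds) * max(mean(upper_values(m)), 1e-6))
  }, 0)
  c(log(alpha0), log(a_init), rep(log(20), K))
}

#' Run one chain of the covariance-model sampler
#'
#' @param counts [allele_counts()] table (populations x loci)
#' @param D standardized pairwise distance matrix
#' @param E_list list of standardized pairwise resistance matrices (one
#'   per covariate); infinite entries are capped via [finite_resistance()]
#' @param config [ibr_config()]
#' @param chain_id integer chain index (drives the RNG stream)
#' @return object of class `ibr_chain`: `trace` (matrix of retained
#'   samples: log posterior, alpha0, alphaD, alphaE per covariate, alpha2,
#'   per-population dispersions), `acceptance`, `scales`, `config`,
#'   `chain_id`
#' @export
run_chain <- function(counts, D, E_list, config, chain_id = 1L) {
  inp <- prep_ibr_inputs(counts, D, E_list, config)
  counts <- inp$counts; D <- inp$D; E_list <- inp$E_list
  nE <- length(E_list)
  labels <- config$covariate_labels %||% paste0("E", seq_len(nE))
  if (length(labels) != nE) stop("covariate_labels length mismatch", call. = FALSE)
  init <- ibr_init_values(counts, D, E_list)
  sc <- config$proposal_scales
  scales <- c(rep(sc$alpha, 2 + nE), sc$alpha2, sc$theta, sc$freq, 1,
              sc$alpha)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed((config$seed * 1000003L + chain_id * 7919L) %% .Machine$integer.max)
  res <- ibr_mcmc_cpp(
    counts$alt, counts$an, unclass(D),
    lapply(E_list, unclass), config$n_steps, config$thin,
    config$alpha2, config$estimate_alpha2, init, scales,
    config$mu_concentration, config$tune_frac, config$latent_updates,
    config$mu_updates, config$theta_prob, 200L, config$joint_updates,
    config$asis_prob, config$warm_sweeps
  )
  pops <- rownames(counts$alt)
  cols <- c("log_post", "alpha0", "alphaD", paste0("alphaE:", labels),
            "alpha2", paste0("theta:", pops))
  trace <- res$trace[seq_len(res$n_kept), , drop = FALSE]
  colnames(trace) <- cols
  accept <- stats::setNames(
    res$acceptance,
    c("alpha0", "alphaD", paste0("alphaE:", labels), "alpha2", "theta",
      "freq", "latent_joint", "interweave"))
  lo <- config$target_acceptance[1]; hi <- config$target_acceptance[2]
  checked <- accept[c("alpha0", "alphaD", paste0("alphaE:", labels), "freq")]
  out_of_band <- checked[!is.na(checked) & (checked < lo | checked > hi)]
  if (length(out_of_band)) {
    warning("chain ", chain_id, ": acceptance outside [", lo, ", ", hi,
            "] after tuning for ",
            paste(names(out_of_band), collapse = ", "), call. = FALSE)
  }
  structure(list(trace = trace, acceptance = accept, scales = res$scales,
                 jitter_count = res$jitter_count, config = config,
                 chain_id = chain_id, covariate_labels = labels),
            class = "ibr_chain")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Run several independent chains
#'
#' @inheritParams run_chain
#' @return object of class `ibr_posterior`: list of [run_chain()] results
#'   plus the config
#' @export
run_ibr <- function(counts, D, E_list, config) {
  chains <- lapply(seq_len(config$n_chains), function(i) {
    run_chain(counts, D, E_list, config, chain_id = i)
  })
  structure(list(chains = chains, config = config,
                 covariate_labels = chains[[1]]$covariate_labels),
            class = "ibr_posterior")
}

#' @exportS3Method base::print
print.ibr_posterior <- function(x, ...) {
  cat("<ibr_posterior>", length(x$chains), "chains x",
      nrow(x$chains[[1]]$trace), "retained samples; covariates:",
      paste(x$covariate_labels, collapse = ", "), "\n")
  invisible(x)
}

retained_window <- function(trace) {
  n <- nrow(trace)
  trace[seq(floor(n / 2) + 1L, n), , drop = FALSE]
}

#' Per-chain effect-size ratios alphaE/alphaD
#'
#' For each chain and covariate, the posterior median of the sampled
#' ratio `alphaE/alphaD` over the retained window (second half of the
#' stored trace). The median is used as the per-chain location estimate
#' because under the bounded log-uniform priors both effect sizes have
#' heavy-tailed posteriors, and a within-chain mean would be dominated by
#' brief excursions; the median is stable and scale-equivariant.
#'
#' @param posterior [run_ibr()] result
#' @return matrix chains x covariates
#' @export
chain_ratios <- function(posterior) {
  labels <- posterior$covariate_labels
  out <- sapply(labels, function(lab) {
    vapply(posterior$chains, function(ch) {
      tr <- retained_window(ch$trace)
      stats::median(tr[, paste0("alphaE:", lab)] / tr[, "alphaD"])
    }, 0)
  })
  matrix(out, nrow = length(posterior$chains),
         dimnames = list(NULL, labels))
}

#' Gelman-Rubin potential scale reduction factor
#'
#' For each parameter, compares within-chain variance `W` to the
#' between-chain variance `B` of the chain means:
#' `psrf = sqrt(((n - 1)/n * W + B/n) / W)` for chains of length `n`.
#' Values near 1 indicate that the chains have mixed. The upper 95% bound
#' replaces `B` by its sampling quantile (an F quantile on the
#' between/within ratio).
#'
#' @param chains list of equal-length numeric vectors (one parameter), or
#'   list of matrices with identical column names (several parameters)
#' @return data.frame with `parameter`, `psrf`, `upper`
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains[[1]])) {
    params <- colnames(chains[[1]])
    out <- do.call(rbind, lapply(params, function(p) {
      gelman_rubin(lapply(chains, function(m) m[, p]))
    }))
    out$parameter <- params
    return(out)
  }
  m <- length(chains)
  stopifnot(m >= 2)
  n <- unique(vapply(chains, length, 0L))
  if (length(n) != 1 || n < 10) stop("chains must share length >= 10", call. = FALSE)
  means <- vapply(chains, mean, 0)
  vars <- vapply(chains, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) {
    warning("zero within-chain variance; psrf undefined", call. = FALSE)
    return(data.frame(parameter = NA_character_, psrf = NA_real_,
                      upper = NA_real_))
  }
  psrf <- sqrt(((n - 1) / n * W + B / n) / W)
  w_df <- 2 * W^2 / (stats::var(vars) / m)
  upper <- if (is.finite(w_df) && w_df > 0) {
    sqrt((n - 1) / n + stats::qf(0.975, m - 1, w_df) * (B / n) / W)
  } else {
    psrf
  }
  data.frame(parameter = NA_character_, psrf = psrf, upper = upper)
}

#' Effect-size summary across chains
#'
#' Per covariate (era): mean and standard error of the per-chain
#' alphaE/alphaD estimates from [chain_ratios()], plus Tukey HSD group
#' letters from [anova_tukey()] when there are at least two covariates.
#' The ANOVA and HSD comparisons are computed on the log of the per-chain
#' ratios (a ratio-scale quantity; the log stabilizes the across-chain
#' variance), while the reported means and standard errors stay on the
#' natural scale.
#'
#' @param posterior [run_ibr()] result (needs >= 2 chains)
#' @param era_labels optional relabeling/ordering of the covariates
#' @return object of class `effect_summary`: data.frame with `era`,
#'   `mean_ratio`, `se`, `hsd_group`, plus attributes `anova_F`,
#'   `anova_p`
#' @export
effect_summary <- function(posterior, era_labels = NULL) {
  if (length(posterior$chains) < 2) {
    stop("need >= 2 chains for a standard error", call. = FALSE)
  }
  ratios <- chain_ratios(posterior)
  labels <- era_labels %||% colnames(ratios)
  if (!all(labels %in% colnames(ratios))) stop("unknown era labels", call. = FALSE)
  ratios <- ratios[, labels, drop = FALSE]
  mean_ratio <- colMeans(ratios)
  se <- apply(ratios, 2, stats::sd) / sqrt(nrow(ratios))
  if (ncol(ratios) >= 2) {
    groups <- lapply(seq_len(ncol(ratios)), function(i) log(ratios[, i]))
    names(groups) <- labels
    hsd <- anova_tukey(groups)
    letters <- hsd$letters[labels]
    aF <- hsd$F_statistic; ap <- hsd$p_value
  } else {
    letters <- stats::setNames("a", labels)
    aF <- NA_real_; ap <- NA_real_
  }
  out <- data.frame(era = labels, mean_ratio = unname(mean_ratio),
                    se = unname(se), hsd_group = unname(letters),
                    stringsAsFactors = FALSE)
  attr(out, "anova_F") <- aF
  attr(out, "anova_p") <- ap
  class(out) <- c("effect_summary", "data.frame")
  out
}

#' Random-walk Metropolis draws from a standard normal target
#'
#' Thin wrapper over the compiled kernel used by the model sampler, with
#' the likelihood replaced by a standard-normal density; exists so the
#' kernel's stationary distribution is directly checkable.
#'
#' @param n_draws retained draws
#' @param thin steps between retained draws
#' @param scale proposal standard deviation
#' @param init starting value
#' @export
mcmc_normal_draws <- function(n_draws, thin = 1L, scale = 2.4, init = 0) {
  rw_normal_chain_cpp(as.integer(n_draws), as.integer(thin), scale, init)
}

#' Write chain traces as CSV (one row per retained step)
#' @param posterior [run_ibr()] result
#' @param path output CSV
#' @export
write_traces_csv <- function(posterior, path) {
  rows <- do.call(rbind, lapply(posterior$chains, function(ch) {
    data.frame(chain = ch$chain_id, step = seq_len(nrow(ch$trace)),
               ch$trace, check.names = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}
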