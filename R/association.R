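# Downstream statistical battery: residual regression of FST on landscape
# resistance after geographic distance, one-way ANOVA + Tukey HSD over
# effect-size ratios, and the diversity regressions.

regression_result <- function(fit, n) {
  sm <- summary(fit)
  co <- stats::coef(sm)
  structure(list(
    slope = co[2, 1], intercept = co[1, 1],
    r_squared = sm$r.squared, p_value = co[2, 4],
    residuals = unname(stats::residuals(fit)), n = n
  ), class = "regression_result")
}

#' @exportS3Method base::print
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> slope %.4g, intercept %.4g, R^2 %.3f, p %.3g, n %d\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

ols <- function(y, x, what) {
  if (length(unique(x)) < 2) stop(what, ": constant predictor", call. = FALSE)
  if (length(y) < 3) stop(what, ": need >= 3 observations", call. = FALSE)
  regression_result(stats::lm(y ~ x), length(y))
}

#' Residual regression of FST on resistance after distance
#'
#' Stage 1: ordinary least squares of vectorized pairwise FST (upper
#' triangle) on the vectorized distance matrix. Stage 2: OLS of the
#' stage-1 residuals on the vectorized resistance matrix. Matrices must
#' share site ordering; pass standardized distance/resistance matrices for
#' comparability of slopes. Plain OLS over pairwise entries is used
#' deliberately (pairs are not independent; see the methods vignette);
#' `permutations > 0` adds a Mantel-style permutation p-value for the
#' stage-2 slope.
#'
#' @param fst,dist,resist [pairwise_matrix()] objects with identical site
#'   ordering
#' @param permutations optional count of site-label permutations for a
#'   permutation p-value (default 0 = off)
#' @return list with elements `distance` and `resistance` (both
#'   [regression_result] objects); the latter gains `p_permutation` when
#'   requested
#' @export
residual_regression <- function(fst, dist, resist, permutations = 0L) {
  ids <- rownames(unclass(fst))
  if (!identical(ids, rownames(unclass(dist))) ||
      !identical(ids, rownames(unclass(resist)))) {
    stop("matrices disagree on site ordering", call. = FALSE)
  }
  y <- upper_values(unclass(fst))
  xd <- upper_values(unclass(dist))
  xr <- upper_values(unclass(resist))
  stage1 <- ols(y, xd, "fst ~ distance")
  stage2 <- ols(stage1$residuals, xr, "residuals ~ resistance")
  if (permutations > 0) {
    n <- length(ids)
    obs <- stage2$slope
    hits <- 0L
    for (b in seq_len(permutations)) {
      perm <- sample.int(n)
      m <- unclass(resist)[perm, perm]
      sl <- stats::coef(stats::lm(stage1$residuals ~ upper_values(m)))[2]
      if (abs(sl) >= abs(obs)) hits <- hits + 1L
    }
    stage2$p_permutation <- (hits + 1) / (permutations + 1)
  }
  list(distance = stage1, resistance = stage2)
}

#' One-way ANOVA with Tukey HSD letters
#'
#' Fits a one-way ANOVA across the groups, runs Tukey's honest significant
#' differences at level `alpha` (Tukey-Kramer for unequal sizes), and
#' derives a compact letter display by insert-and-absorb: groups sharing a
#' letter are not significantly different.
#'
#' @param groups named list: group label -> numeric vector (>= 2 groups,
#'   each >= 2 values)
#' @param alpha familywise error level (default 0.05)
#' @return object of class `hsd_result`: `means`, `letters` (named),
#'   `F_statistic`, `p_value`, `alpha`, `tukey` (the [stats::TukeyHSD()]
#'   table)
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 0L) < 2)) {
    stop("every group needs >= 2 values", call. = FALSE)
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 0L)),
                   levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = df)
  sm <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  means <- vapply(groups, mean, 0)
  # significant pairs: Tukey adjusted p below alpha
  labs <- names(groups)
  sig <- matrix(FALSE, length(labs), length(labs), dimnames = list(labs, labs))
  for (rn in rownames(tk)) {
    pair <- strsplit(rn, "-", fixed = TRUE)[[1]]
    if (tk[rn, "p adj"] < alpha) {
      sig[pair[1], pair[2]] <- TRUE
      sig[pair[2], pair[1]] <- TRUE
    }
  }
  letters <- compact_letters(means, sig)
  structure(list(means = means, letters = letters,
                 F_statistic = sm[["F value"]][1],
                 p_value = sm[["Pr(>F)"]][1], alpha = alpha, tukey = tk),
            class = "hsd_result")
}

# Insert-and-absorb compact letter display. `sig` is a symmetric logical
# matrix of significant differences; treatments sharing a letter must be
# pairwise non-significant. Letters are assigned scanning means downward.
compact_letters <- function(means, sig) {
  labs <- names(sort(means, decreasing = TRUE))
  sets <- list(labs)
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      if (i >= j || !sig[labs[i], labs[j]]) next
      for (k in rev(seq_along(sets))) {
        s <- sets[[k]]
        if (all(c(labs[i], labs[j]) %in% s)) {
          sets[[k]] <- NULL
          cand <- list(setdiff(s, labs[i]), setdiff(s, labs[j]))
          for (cs in cand) {
            absorbed <- any(vapply(sets, function(o) all(cs %in% o), TRUE))
            if (!absorbed && length(cs)) sets[[length(sets) + 1L]] <- cs
          }
        }
      }
    }
  }
  # order letter sets by the best (largest) mean they contain
  best <- vapply(sets, function(s) max(means[s]), 0)
  sets <- sets[order(-best)]
  out <- stats::setNames(rep("", length(means)), names(means))
  for (k in seq_along(sets)) {
    for (lab in sets[[k]]) out[lab] <- paste0(out[lab], letters[k])
  }
  out
}

#' @exportS3Method base::print
print.hsd_result <- function(x, ...) {
  cat("<hsd_result> F =", signif(x$F_statistic, 4), ", p =",
      signif(x$p_value, 4), "\n")
  print(data.frame(mean = x$means, letter = x$letters))
  invisible(x)
}

#' Regression of per-site nucleotide diversity on crop-cover proportion
#'
#' @param pi named numeric vector of per-site nucleotide diversity
#' @param potato_prop named numeric vector of per-site cover proportions
#'   (same sites)
#' @param era_label label attached to the result
#' @return [regression_result] with attribute `era`
#' @export
diversity_regression <- function(pi, potato_prop, era_label = NULL) {
  if (!is.null(names(pi)) && !is.null(names(potato_prop))) {
    potato_prop <- potato_prop[names(pi)]
  }
  res <- ols(as.numeric(pi), as.numeric(potato_prop), "diversity ~ cover")
  attr(res, "era") <- era_label
  res
}

#' Regression of pairwise FST on average nucleotide diversity
#'
#' The predictor for pair (i, j) is the mean of the two per-site diversity
#' values, `(pi_i + pi_j) / 2`.
#'
#' @param fst [pairwise_matrix()] labelled fst
#' @param pi named numeric vector of per-site diversity in matching order
#' @return [regression_result]
#' @export
fst_vs_diversity <- function(fst, pi) {
  ids <- rownames(unclass(fst))
  if (!is.null(names(pi))) {
    if (!all(ids %in% names(pi))) stop("pi lacks values for some sites", call. = FALSE)
    pi <- pi[ids]
  }
  n <- length(ids)
  pred <- outer(pi, pi, "+") / 2
  ols(upper_values(unclass(fst)), pred[upper.tri(pred)], "fst ~ diversity")
}
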