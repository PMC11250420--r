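# Leave-one-out IVW slopes for all J variants in O(J) via sufficient sums.
loo_slopes <- function(bx, by, se_out) {
  w <- 1 / se_out^2
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

# Observed PRESSO residual sum of squares and its per-variant terms:
# each variant's outcome effect is compared with the prediction of the
# model fitted without it, weighted by its outcome variance.
presso_rss_terms <- function(bx, by, se_out) {
  theta_loo <- loo_slopes(bx, by, se_out)
  (by - theta_loo * bx)^2 / se_out^2
}

# Simulated per-variant RSS terms, vectorised over n_sim replicates.
# Returns an n_sim x J matrix. Expected outcome effects come from the
# observed leave-one-out slopes; both effect vectors are re-drawn with
# their reported standard errors, and the statistic is recomputed
# identically (leave-one-out slopes on the simulated data).
presso_sim_terms <- function(bx, by, se_exp, se_out, n_sim) {
  J <- length(bx)
  theta_loo <- loo_slopes(bx, by, se_out)
  mu_out <- theta_loo * bx
  bx_star <- matrix(rnorm(n_sim * J, rep(bx, each = n_sim),
                          rep(se_exp, each = n_sim)), n_sim, J)
  by_star <- matrix(rnorm(n_sim * J, rep(mu_out, each = n_sim),
                          rep(se_out, each = n_sim)), n_sim, J)
  w <- matrix(1 / se_out^2, n_sim, J, byrow = TRUE)
  sxy <- rowSums(w * bx_star * by_star)
  sxx <- rowSums(w * bx_star^2)
  theta_star <- (sxy - w * bx_star * by_star) / (sxx - w * bx_star^2)
  (by_star - theta_star * bx_star)^2 / (matrix(se_out, n_sim, J, byrow = TRUE))^2
}

#' MR-PRESSO global, outlier and distortion tests
#'
#' Detects horizontal pleiotropy as excess residual dispersion around the
#' leave-one-out IVW fit. The **global test** compares the observed residual
#' sum of squares with its Monte-Carlo null distribution, obtained by
#' redrawing exposure and outcome effects from normal distributions with the
#' reported standard errors and expected outcome effects given by the
#' leave-one-out slopes; the empirical p-value is
#' `(1 + #\{RSS* >= RSS_obs\}) / (n_sim + 1)`, so it is floored at
#' `1/(n_sim + 1)`. When the global test is significant, the **outlier
#' test** compares each variant's observed weighted squared residual with
#' its own simulated distribution and flags variants whose Bonferroni-
#' adjusted empirical p falls below `sig_level`. The **distortion test**
#' then asks whether removing the flagged variants changes the causal
#' estimate more than removing as many randomly chosen variants would.
#'
#' @param pairs harmonized pairs tibble (>= 4 rows; see [harmonize()]).
#' @param n_sim Monte-Carlo replicates for the global and outlier nulls.
#' @param n_boot resamples for the distortion-test null.
#' @param seed integer seed; all output is a pure function of
#'   (`pairs`, `n_sim`, `n_boot`, `seed`).
#' @param sig_level significance threshold for the global test gate and the
#'   Bonferroni-adjusted outlier calls.
#' @param model IVW model used for the corrected estimate.
#' @return object of class `mr_presso`: list with `rss_obs`, `global_p`,
#'   `n_sim`, `per_snp_p` (named, Bonferroni-adjusted), `outliers`,
#'   `distortion_p`, `distortion_stat`, `corrected` (IVW `mr_result` on the
#'   non-outlier set, present only when outliers were found), `seed`.
#' @export
mr_presso <- function(pairs, n_sim = 1000, n_boot = 1000, seed,
                      sig_level = 0.05,
                      model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  pairs <- check_pairs(pairs, 4, "MR-PRESSO")
  if (missing(seed)) stop_usage("MR-PRESSO requires an explicit seed")
  rsids <- if ("rsid" %in% names(pairs)) pairs$rsid else as.character(seq_len(nrow(pairs)))
  J <- nrow(pairs)
  bx <- pairs$beta_exp; by <- pairs$beta_out
  se_exp <- pairs$se_exp; se_out <- pairs$se_out

  seeds <- derive_seeds(seed, 2)
  obs_terms <- presso_rss_terms(bx, by, se_out)
  rss_obs <- sum(obs_terms)
  sim_terms <- with_seed(seeds[1], presso_sim_terms(bx, by, se_exp, se_out, n_sim))
  rss_sim <- rowSums(sim_terms)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  per_snp_p <- rep(NA_real_, J)
  outliers <- character()
  distortion_p <- NULL
  distortion_stat <- NULL
  corrected <- NULL
  if (global_p < sig_level) {
    raw_p <- vapply(seq_len(J), function(j) {
      (1 + sum(sim_terms[, j] >= obs_terms[j])) / (n_sim + 1)
    }, numeric(1))
    per_snp_p <- pmin(1, raw_p * J)
    outliers <- rsids[per_snp_p < sig_level]
    if (length(outliers) > 0 && length(outliers) < J - 1) {
      dist <- presso_distortion(pairs, outliers, n_boot = n_boot,
                                seed = seeds[2], model = model)
      distortion_p <- dist$distortion_p
      distortion_stat <- dist$distortion_stat
      corrected <- dist$corrected
    }
  }
  structure(
    list(rss_obs = rss_obs, global_p = global_p, n_sim = n_sim,
         per_snp_p = setNames(per_snp_p, rsids), outliers = outliers,
         distortion_p = distortion_p, distortion_stat = distortion_stat,
         corrected = corrected, seed = seed, nsnp = J),
    class = "mr_presso"
  )
}

#' MR-PRESSO global test only
#'
#' Convenience wrapper returning just the observed residual sum of squares
#' and the global empirical p-value; see [mr_presso()] for the scheme.
#'
#' @inheritParams mr_presso
#' @return tibble with `rss_obs`, `global_p`, `n_sim`.
#' @export
presso_global <- function(pairs, n_sim = 1000, seed) {
  pairs <- check_pairs(pairs, 4, "MR-PRESSO")
  if (missing(seed)) stop_usage("MR-PRESSO requires an explicit seed")
  seeds <- derive_seeds(seed, 2)
  obs <- presso_rss_terms(pairs$beta_exp, pairs$beta_out, pairs$se_out)
  rss_obs <- sum(obs)
  sim <- with_seed(seeds[1], presso_sim_terms(
    pairs$beta_exp, pairs$beta_out, pairs$se_exp, pairs$se_out, n_sim
  ))
  tibble(rss_obs = rss_obs,
         global_p = (1 + sum(rowSums(sim) >= rss_obs)) / (n_sim + 1),
         n_sim = as.integer(n_sim))
}

#' MR-PRESSO per-variant outlier test only
#'
#' Per-variant empirical p-values (Bonferroni-adjusted) and the resulting
#' outlier calls; see [mr_presso()]. Intended to be run after a significant
#' global test.
#'
#' @inheritParams mr_presso
#' @return list with `per_snp_p` (named numeric) and `outliers` (character).
#' @export
presso_outlier <- function(pairs, n_sim = 1000, seed, sig_level = 0.05) {
  pairs <- check_pairs(pairs, 4, "MR-PRESSO")
  if (missing(seed)) stop_usage("MR-PRESSO requires an explicit seed")
  rsids <- if ("rsid" %in% names(pairs)) pairs$rsid else as.character(seq_len(nrow(pairs)))
  seeds <- derive_seeds(seed, 2)
  obs <- presso_rss_terms(pairs$beta_exp, pairs$beta_out, pairs$se_out)
  sim <- with_seed(seeds[1], presso_sim_terms(
    pairs$beta_exp, pairs$beta_out, pairs$se_exp, pairs$se_out, n_sim
  ))
  J <- nrow(pairs)
  raw_p <- vapply(seq_len(J), function(j) {
    (1 + sum(sim[, j] >= obs[j])) / (n_sim + 1)
  }, numeric(1))
  adj <- pmin(1, raw_p * J)
  list(per_snp_p = setNames(adj, rsids), outliers = rsids[adj < sig_level])
}

#' MR-PRESSO distortion test
#'
#' Compares the relative change in the IVW estimate after removing the
#' flagged outliers, `(theta_all - theta_corrected) / |theta_corrected|`,
#' with the distribution of the same statistic when an equally sized random
#' subset of variants is removed instead (seeded resampling of the outlier
#' assignment). A small two-sided p-value means the flagged variants distort
#' the estimate more than random removal would.
#'
#' @inheritParams mr_presso
#' @param outliers character vector of outlier rsids (non-empty, and fewer
#'   than `nsnp - 1` so the corrected fit keeps >= 2 variants).
#' @return list with `distortion_stat`, `distortion_p` and `corrected`
#'   (IVW `mr_result` on the non-outlier variants).
#' @export
presso_distortion <- function(pairs, outliers, n_boot = 1000, seed,
                              model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  pairs <- check_pairs(pairs, 4, "distortion test")
  if (missing(seed)) stop_usage("distortion test requires an explicit seed")
  if (length(outliers) == 0) stop_usage("distortion test requires a non-empty outlier set")
  rsids <- if ("rsid" %in% names(pairs)) pairs$rsid else as.character(seq_len(nrow(pairs)))
  is_out <- rsids %in% outliers
  if (sum(!is_out) < 2) stop_data("too few non-outlier variants to re-estimate")
  theta_all <- ivw_closed_form(pairs$beta_exp, pairs$beta_out, pairs$se_out)$estimate
  keep <- pairs[!is_out, ]
  corrected <- mr_ivw(keep, model = model)
  stat_obs <- (theta_all - corrected$estimate) / abs(corrected$estimate)
  J <- nrow(pairs)
  k <- sum(is_out)
  stat_null <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      drop <- sample.int(J, k)
      sub <- pairs[-drop, ]
      th <- ivw_closed_form(sub$beta_exp, sub$beta_out, sub$se_out)$estimate
      (theta_all - th) / abs(th)
    }, numeric(1))
  })
  p <- (1 + sum(abs(stat_null) >= abs(stat_obs))) / (n_boot + 1)
  list(distortion_stat = stat_obs, distortion_p = p, corrected = corrected)
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO on %d instruments (n_sim = %d, seed = %s)\n",
              x$nsnp, x$n_sim, format(x$seed)))
  cat(sprintf("  RSS_obs = %.4g, global p = %.4g\n", x$rss_obs, x$global_p))
  if (length(x$outliers) > 0) {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
    if (!is.null(x$distortion_p)) {
      cat(sprintf("  distortion stat = %.4g (p = %.4g)\n",
                  x$distortion_stat, x$distortion_p))
    }
    if (!is.null(x$corrected)) {
      cat(sprintf("  corrected IVW = %.4g (se %.4g)\n",
                  x$corrected$estimate, x$corrected$se))
    }
  } else {
    cat("  no outliers flagged\n")
  }
  invisible(x)
}

#' Run MR-PRESSO and re-estimate after outlier removal
#'
#' Orchestrates the study's sensitivity workflow: run [mr_presso()]; when
#' outliers are flagged, rerun the full estimator battery ([mr_analysis()])
#' on the reduced instrument set and report both passes. Estimators whose
#' minimum instrument count is no longer met on the reduced set are skipped
#' with a logged reason (see `$pass2$skipped`).
#'
#' @inheritParams mr_presso
#' @inheritParams mr_analysis
#' @return list with `presso` (`mr_presso` object), `pass1`
#'   (`mr_analysis` on all instruments), and `pass2` (`mr_analysis` on the
#'   non-outlier instruments; `NULL` when no outliers were flagged).
#' @export
run_presso_and_refit <- function(pairs, n_sim = 1000, n_boot = 1000, seed,
                                 sig_level = 0.05,
                                 model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  pairs <- check_pairs(pairs, 4, "MR-PRESSO")
  if (missing(seed)) stop_usage("MR-PRESSO requires an explicit seed")
  seeds <- derive_seeds(seed, 3)
  pass1 <- mr_analysis(pairs, model = model, seed = seeds[1])
  presso <- mr_presso(pairs, n_sim = n_sim, n_boot = n_boot, seed = seeds[2],
                      sig_level = sig_level, model = model)
  pass2 <- NULL
  if (length(presso$outliers) > 0) {
    rsids <- if ("rsid" %in% names(pairs)) pairs$rsid else as.character(seq_len(nrow(pairs)))
    keep <- pairs[!(rsids %in% presso$outliers), ]
    if (nrow(keep) >= 1) {
      pass2 <- mr_analysis(keep, model = model, seed = seeds[3])
    }
  }
  list(presso = presso, pass1 = pass1, pass2 = pass2)
}
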