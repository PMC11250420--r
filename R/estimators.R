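check_pairs <- function(pairs, min_n, what) {
  pairs <- as_tibble(pairs)
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  missing_cols <- setdiff(need, names(pairs))
  if (length(missing_cols) > 0) {
    stop_usage(paste0("harmonized pairs lack column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  if (nrow(pairs) < min_n) {
    stop_usage(sprintf("%s requires at least %d instrument(s), got %d",
                       what, min_n, nrow(pairs)))
  }
  pairs
}

new_mr_result <- function(method, nsnp, estimate, se, pvalue, level = 0.95,
                          df = NULL) {
  ci <- if (is.null(df)) qnorm(1 - (1 - level) / 2) else qt(1 - (1 - level) / 2, df)
  lo <- estimate - ci * se
  hi <- estimate + ci * se
  out <- tibble(
    method = method, nsnp = as.integer(nsnp),
    estimate = estimate, se = se, ci_low = lo, ci_high = hi, pvalue = pvalue,
    or = exp(estimate), or_ci_low = exp(lo), or_ci_high = exp(hi)
  )
  class(out) <- c("mr_result", class(out))
  out
}

#' Wald ratio causal estimate for a single variant
#'
#' Ratio estimate `beta_out / beta_exp` with first-order standard error
#' `se_out / |beta_exp|` and a two-sided normal p-value. The building block
#' of the multi-variant estimators.
#'
#' @param pairs one-row harmonized pair (see [harmonize()]).
#' @param level confidence level for the reported interval.
#' @return one-row `mr_result` tibble: `method`, `nsnp`, `estimate` (log
#'   odds per exposure unit), `se`, `ci_low`, `ci_high`, `pvalue`, and the
#'   exponentiated `or`, `or_ci_low`, `or_ci_high`.
#' @export
mr_wald_ratio <- function(pairs, level = 0.95) {
  pairs <- check_pairs(pairs, 1, "wald_ratio")
  if (nrow(pairs) != 1) stop_usage("wald_ratio takes exactly one pair")
  if (pairs$beta_exp == 0) stop_usage("wald_ratio undefined for beta_exp = 0")
  est <- pairs$beta_out / pairs$beta_exp
  se <- pairs$se_out / abs(pairs$beta_exp)
  p <- 2 * pnorm(-abs(est / se))
  new_mr_result("wald_ratio", 1L, est, se, p, level)
}

# Closed-form IVW slope and fixed-effects SE; shared by several callers.
ivw_closed_form <- function(bx, by, se_out) {
  w <- 1 / se_out^2
  sxx <- sum(w * bx^2)
  est <- sum(w * bx * by) / sxx
  list(estimate = est, se_fixed = sqrt(1 / sxx),
       q = sum(w * (by - est * bx)^2))
}

#' Inverse-variance weighted causal estimate
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/se_out^2` — the inverse-variance weighted
#' combination of per-variant Wald ratios, the primary estimator of
#' two-sample MR. The default multiplicative random-effects model inflates
#' the fixed-effects standard error by `max(1, sqrt(Q/(J-1)))`, so it never
#' reports less uncertainty than the fixed-effects model; p-values are
#' two-sided normal.
#'
#' @param pairs harmonized pairs tibble (>= 1 row).
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @inheritParams mr_wald_ratio
#' @return one-row `mr_result` tibble.
#' @export
mr_ivw <- function(pairs, model = c("multiplicative_random", "fixed"),
                   level = 0.95) {
  model <- match.arg(model)
  pairs <- check_pairs(pairs, 1, "ivw")
  fit <- ivw_closed_form(pairs$beta_exp, pairs$beta_out, pairs$se_out)
  J <- nrow(pairs)
  se <- fit$se_fixed
  if (model == "multiplicative_random" && J >= 2) {
    se <- se * max(1, sqrt(fit$q / (J - 1)))
  }
  p <- 2 * pnorm(-abs(fit$estimate / se))
  new_mr_result("ivw", J, fit$estimate, se, p, level)
}

#' MR-Egger regression: causal slope and pleiotropy intercept
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' unconstrained intercept, weights `1/se_out^2`, after orienting every
#' pair so its exposure effect is non-negative (required for the intercept
#' to be interpretable). The intercept estimates the average directional
#' pleiotropy; the slope is a causal estimate robust to it under the InSIDE
#' assumption. Both standard errors are inflated by the residual scale
#' `max(1, sqrt(RSS/(J-2)))`; p-values are two-sided t with `J - 2` degrees
#' of freedom.
#'
#' @inheritParams mr_ivw
#' @return list with `slope` (one-row `mr_result`), `intercept` (one-row
#'   tibble with `intercept`, `se`, `pvalue`) and `heterogeneity` (the
#'   regression's weighted residual sum of squares referred to chi-squared
#'   with `J - 2` degrees of freedom).
#' @export
mr_egger <- function(pairs, level = 0.95) {
  pairs <- check_pairs(pairs, 3, "MR-Egger")
  sgn <- ifelse(pairs$beta_exp < 0, -1, 1)
  bx <- sgn * pairs$beta_exp
  by <- sgn * pairs$beta_out
  w <- 1 / pairs$se_out^2
  J <- nrow(pairs)

  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  sxx <- sum(w * bx^2); sxy <- sum(w * bx * by)
  det <- sw * sxx - swx^2
  if (det <= 0) stop_data("MR-Egger design is singular (no spread in beta_exp)")
  slope <- (sw * sxy - swx * swy) / det
  intercept <- (sxx * swy - swx * sxy) / det
  resid <- by - intercept - slope * bx
  rss <- sum(w * resid^2)
  scale <- max(1, sqrt(rss / (J - 2)))
  se_slope <- sqrt(sw / det) * scale
  se_int <- sqrt(sxx / det) * scale
  p_slope <- 2 * pt(-abs(slope / se_slope), df = J - 2)
  p_int <- 2 * pt(-abs(intercept / se_int), df = J - 2)
  list(
    slope = new_mr_result("egger", J, slope, se_slope, p_slope, level, df = J - 2),
    intercept = tibble(intercept = intercept, se = se_int, pvalue = p_int,
                       nsnp = J),
    heterogeneity = tibble(method = "egger", Q = rss, df = J - 2L,
                           pvalue = pchisq(rss, J - 2, lower.tail = FALSE))
  )
}

weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  # Standardised cumulative weight at each ordered ratio; the estimate is
  # the linear interpolation of the ratio at cumulative weight 0.5.
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  below <- max(which(s < 0.5))
  r[below] + (r[below + 1] - r[below]) * (0.5 - s[below]) / (s[below + 1] - s[below])
}

#' Weighted median causal estimate
#'
#' The weighted median of per-variant Wald ratios, with weights proportional
#' to the inverse first-order ratio variance `(beta_exp/se_out)^2`.
#' Consistent when valid instruments carry more than half of the weight,
#' even if up to half are pleiotropic. The standard error comes from a
#' seeded parametric bootstrap: exposure and outcome effects are resampled
#' from normal distributions centred on the observed effects with the
#' reported standard errors, and the estimator is recomputed on each
#' resample. The p-value is two-sided normal.
#'
#' @inheritParams mr_ivw
#' @param n_boot bootstrap resamples for the standard error.
#' @param seed integer seed for the bootstrap (required for reproducibility).
#' @return one-row `mr_result` tibble.
#' @export
mr_weighted_median <- function(pairs, n_boot = 1000, seed, level = 0.95) {
  pairs <- check_pairs(pairs, 3, "weighted median")
  if (missing(seed)) stop_usage("weighted median requires an explicit seed")
  ratios <- pairs$beta_out / pairs$beta_exp
  weights <- (pairs$beta_exp / pairs$se_out)^2
  est <- weighted_median_point(ratios, weights)
  J <- nrow(pairs)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(J, pairs$beta_exp, pairs$se_exp)
      by <- rnorm(J, pairs$beta_out, pairs$se_out)
      ok <- bx != 0
      weighted_median_point(by[ok] / bx[ok], (bx[ok] / pairs$se_out[ok])^2)
    }, numeric(1))
  })
  se <- sd(boot)
  p <- 2 * pnorm(-abs(est / se))
  new_mr_result("weighted_median", J, est, se, p, level)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (ratio_j - estimate)^2` with `w_j = (beta_exp_j/se_out_j)^2`
#' over per-variant Wald ratios, referred to a chi-squared distribution with
#' `J - 1` degrees of freedom (or `J - 2` when the estimate comes from
#' MR-Egger). A p-value above 0.05 is conventionally read as no significant
#' heterogeneity.
#'
#' @inheritParams mr_ivw
#' @param estimate causal estimate to measure dispersion around; defaults to
#'   the IVW estimate of `pairs`.
#' @param method context label; `"egger"` uses `J - 2` degrees of freedom.
#' @return one-row tibble with `method`, `Q`, `df`, `pvalue`.
#' @export
mr_cochran_q <- function(pairs, estimate = NULL, method = c("ivw", "egger")) {
  method <- match.arg(method)
  pairs <- check_pairs(pairs, 2, "Cochran's Q")
  if (is.null(estimate)) {
    estimate <- ivw_closed_form(pairs$beta_exp, pairs$beta_out, pairs$se_out)$estimate
  }
  w <- (pairs$beta_exp / pairs$se_out)^2
  ratios <- pairs$beta_out / pairs$beta_exp
  q <- sum(w * (ratios - estimate)^2)
  df <- nrow(pairs) - if (method == "egger") 2L else 1L
  tibble(method = method, Q = q, df = as.integer(df),
         pvalue = pchisq(q, df, lower.tail = FALSE))
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the IVW causal effect with each variant omitted in turn, to
#' reveal single variants that drive the pooled association.
#'
#' @inheritParams mr_ivw
#' @return tibble with one row per omitted variant: `omitted_rsid` plus the
#'   `mr_result` columns of the IVW fit on the remaining variants.
#' @export
mr_leave_one_out <- function(pairs, model = c("multiplicative_random", "fixed"),
                             level = 0.95) {
  model <- match.arg(model)
  pairs <- check_pairs(pairs, 2, "leave-one-out")
  rsids <- if ("rsid" %in% names(pairs)) pairs$rsid else as.character(seq_len(nrow(pairs)))
  purrr::map_dfr(seq_len(nrow(pairs)), function(j) {
    fit <- mr_ivw(pairs[-j, ], model = model, level = level)
    dplyr::bind_cols(tibble(omitted_rsid = rsids[j]), fit)
  })
}

#' Convert a log-odds estimate to an odds ratio with confidence interval
#'
#' @param estimate log-odds causal estimate.
#' @param se its standard error.
#' @param level confidence level in (0, 1).
#' @return tibble with `or`, `or_ci_low`, `or_ci_high`.
#' @export
to_odds_ratio <- function(estimate, se, level = 0.95) {
  if (any(level <= 0 | level >= 1)) stop_usage("level must lie in (0, 1)")
  z <- qnorm(1 - (1 - level) / 2)
  tibble(or = exp(estimate), or_ci_low = exp(estimate - z * se),
         or_ci_high = exp(estimate + z * se))
}

#' Run the full estimator battery on a harmonized instrument set
#'
#' Computes IVW (primary), MR-Egger slope and intercept, weighted median,
#' Cochran's Q (IVW and Egger contexts) and leave-one-out in one call.
#' Estimators whose minimum instrument count is not met are skipped with a
#' note rather than failing the whole analysis.
#'
#' @inheritParams mr_weighted_median
#' @inheritParams mr_ivw
#' @return object of class `mr_analysis`: list with elements `results`
#'   (tibble of estimator rows), `heterogeneity`, `pleiotropy`,
#'   `leave_one_out`, `nsnp`, `skipped`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
mr_analysis <- function(pairs, model = c("multiplicative_random", "fixed"),
                        n_boot = 1000, seed = 1L, level = 0.95) {
  model <- match.arg(model)
  pairs <- check_pairs(pairs, 1, "MR analysis")
  J <- nrow(pairs)
  skipped <- character()
  results <- if (J == 1) {
    mr_wald_ratio(pairs, level = level)
  } else {
    mr_ivw(pairs, model = model, level = level)
  }
  het <- NULL; pleio <- NULL; loo <- NULL
  if (J >= 3) {
    egger <- mr_egger(pairs, level = level)
    wm <- mr_weighted_median(pairs, n_boot = n_boot, seed = seed, level = level)
    results <- dplyr::bind_rows(results, egger$slope, wm)
    pleio <- egger$intercept
  } else if (J >= 1) {
    skipped <- c(skipped, "egger: needs >= 3 instruments",
                 "weighted_median: needs >= 3 instruments")
  }
  if (J >= 2) {
    het <- mr_cochran_q(pairs, method = "ivw")
    if (J >= 3) het <- dplyr::bind_rows(het, egger$heterogeneity)
    loo <- mr_leave_one_out(pairs, model = model, level = level)
  } else {
    skipped <- c(skipped, "cochran_q, leave_one_out: need >= 2 instruments")
  }
  structure(
    list(results = results, heterogeneity = het, pleiotropy = pleio,
         leave_one_out = loo, nsnp = J, skipped = skipped, level = level),
    class = "mr_analysis"
  )
}

#' @export
print.mr_analysis <- function(x, ...) {
  cat(sprintf("MR analysis on %d instrument(s)\n", x$nsnp))
  print(as.data.frame(x$results), row.names = FALSE, digits = 4)
  if (!is.null(x$heterogeneity)) {
    cat("Heterogeneity:\n")
    print(as.data.frame(x$heterogeneity), row.names = FALSE, digits = 4)
  }
  if (!is.null(x$pleiotropy)) {
    cat(sprintf("Egger intercept: %.4g (se %.4g, p = %.3g)\n",
                x$pleiotropy$intercept, x$pleiotropy$se, x$pleiotropy$pvalue))
  }
  if (length(x$skipped) > 0) cat("Skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}
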