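#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an MR analysis into a one-row-per-estimator tibble
#'
#' @param x an `mr_analysis` from [mr_analysis()].
#' @param ... unused.
#' @return tibble with method, nsnp, estimate, se, CI, p and OR columns.
#' @export
tidy.mr_analysis <- function(x, ...) as_tibble(x$results)

#' @rdname tidy.mr_analysis
#' @export
glance.mr_analysis <- function(x, ...) {
  ivw <- x$results[x$results$method %in% c("ivw", "wald_ratio"), ][1, ]
  tibble(
    nsnp = x$nsnp,
    estimate_ivw = ivw$estimate, se_ivw = ivw$se, pvalue_ivw = ivw$pvalue,
    or_ivw = ivw$or,
    q_ivw = if (is.null(x$heterogeneity)) NA_real_ else x$heterogeneity$Q[x$heterogeneity$method == "ivw"],
    q_pvalue_ivw = if (is.null(x$heterogeneity)) NA_real_ else x$heterogeneity$pvalue[x$heterogeneity$method == "ivw"],
    egger_intercept = if (is.null(x$pleiotropy)) NA_real_ else x$pleiotropy$intercept,
    egger_intercept_pvalue = if (is.null(x$pleiotropy)) NA_real_ else x$pleiotropy$pvalue
  )
}

#' Tidy an MR-PRESSO result
#'
#' @param x an `mr_presso` from [mr_presso()].
#' @param ... unused.
#' @return tibble with one row per variant: Bonferroni-adjusted outlier p
#'   and outlier flag.
#' @export
tidy.mr_presso <- function(x, ...) {
  tibble(
    rsid = names(x$per_snp_p),
    outlier_pvalue = unname(x$per_snp_p),
    is_outlier = names(x$per_snp_p) %in% x$outliers
  )
}

#' @rdname tidy.mr_presso
#' @export
glance.mr_presso <- function(x, ...) {
  tibble(
    nsnp = x$nsnp, rss_obs = x$rss_obs, global_p = x$global_p,
    n_sim = x$n_sim, n_outliers = length(x$outliers),
    distortion_p = x$distortion_p %||% NA_real_,
    corrected_estimate = if (is.null(x$corrected)) NA_real_ else x$corrected$estimate
  )
}

#' Tidy a study report into the long results table
#'
#' @param x an `mr_study` from [run_study()].
#' @param ... unused.
#' @return tibble with one row per exposure x outcome x method (x pass).
#' @export
tidy.mr_study <- function(x, ...) study_results_table(x)

#' @rdname tidy.mr_study
#' @export
glance.mr_study <- function(x, ...) {
  res <- study_results_table(x)
  ok <- res[is.na(res$failure) & res$pass == 1L & res$method %in% c("ivw", "wald_ratio"), ]
  tibble(
    n_pairs = length(x$pairs),
    n_failed = sum(!vapply(x$pairs, function(p) is.null(p$error), logical(1))),
    n_significant_ivw = sum(ok$pvalue < 0.05, na.rm = TRUE)
  )
}
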