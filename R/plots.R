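#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbarh
#'   geom_vline geom_errorbar labs theme_minimal facet_grid scale_x_log10
#' @export
ggplot2::autoplot

#' Forest plot of MR estimates
#'
#' Odds ratios with confidence intervals per method, one panel per
#' exposure x outcome pair for study objects.
#'
#' @param object an `mr_analysis` or `mr_study`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mr_analysis <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$or, y = .data$method)) +
    geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$or_ci_low, xmax = .data$or_ci_high),
                   height = 0.2) +
    geom_point(size = 2) +
    scale_x_log10() +
    labs(x = "Odds ratio (95% CI, log scale)", y = NULL) +
    theme_minimal()
}

#' @rdname autoplot.mr_analysis
#' @export
autoplot.mr_study <- function(object, ...) {
  df <- tidy(object)
  df <- df[is.na(df$failure) & df$pass == 1L, ]
  ggplot(df, aes(x = .data$or, y = .data$method)) +
    geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$or_ci_low, xmax = .data$or_ci_high),
                   height = 0.2) +
    geom_point(size = 2) +
    scale_x_log10() +
    facet_grid(outcome ~ exposure) +
    labs(x = "Odds ratio (95% CI, log scale)", y = NULL) +
    theme_minimal()
}

#' Leave-one-out plot
#'
#' IVW estimate (with CI) after omitting each variant in turn; a variant
#' whose omission moves the estimate across the null flags a driving SNP.
#'
#' @param loo leave-one-out tibble from [mr_leave_one_out()].
#' @return a ggplot object.
#' @export
plot_leave_one_out <- function(loo) {
  ggplot(loo, aes(x = .data$estimate, y = .data$omitted_rsid)) +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2) +
    geom_point(size = 1.5) +
    labs(x = "IVW estimate omitting variant (log odds)", y = "Omitted variant") +
    theme_minimal()
}

#' Scatter plot of harmonized effects with fitted MR slopes
#'
#' Exposure versus outcome effects with the IVW (through the origin) and
#' MR-Egger (free intercept) fits overlaid.
#'
#' @param pairs harmonized pairs tibble.
#' @return a ggplot object.
#' @export
plot_mr_scatter <- function(pairs) {
  pairs <- check_pairs(pairs, 1, "scatter plot")
  ivw <- mr_ivw(pairs)
  p <- ggplot(pairs, aes(x = .data$beta_exp, y = .data$beta_out)) +
    geom_errorbar(aes(ymin = .data$beta_out - .data$se_out,
                      ymax = .data$beta_out + .data$se_out),
                  width = 0, colour = "grey70") +
    geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = ivw$estimate,
                         colour = "steelblue") +
    labs(x = "Effect on exposure", y = "Effect on outcome") +
    theme_minimal()
  if (nrow(pairs) >= 3) {
    egger <- mr_egger(pairs)
    p <- p + ggplot2::geom_abline(intercept = egger$intercept$intercept,
                                  slope = egger$slope$estimate,
                                  colour = "firebrick", linetype = "dotdash")
  }
  p
}
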