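resolve_sumstats <- function(x, what) {
  if (inherits(x, "sumstats")) return(x)
  if (is.character(x) && length(x) == 1) {
    return(read_sumstats(x, trait = what))
  }
  if (is.list(x) && !is.null(x$path)) {
    return(read_sumstats(x$path, dialect = x$dialect %||% "canonical",
                         trait = x$trait %||% what,
                         genome_build = x$genome_build %||% "GRCh37",
                         ancestry = x$ancestry %||% "EUR"))
  }
  stop_config(paste0("cannot interpret ", what, " as summary statistics"))
}

#' Assemble a full drug-target MR study configuration
#'
#' A study is a grid of exposures x outcomes. Each exposure carries its own
#' selection design: cis mode with a [gene_region()] (the drug-target
#' proxy), or genome-wide mode with `excluded_regions` masking the target
#' loci (the trait-level analysis). Outcomes flagged as positive controls
#' (for a glucose-lowering target, type 2 diabetes) are marked in the
#' report so instrument validity can be read off first.
#'
#' @param exposures named list; each element a list with `sumstats` (a
#'   `sumstats` tibble or file path), `config` (a [selection_config()]),
#'   and either `region` (a [gene_region()], cis mode) or nothing
#'   (genome-wide mode, regions taken from `config$excluded_regions`).
#' @param outcomes named list; each element a `sumstats` tibble, a file
#'   path, or a list with `path`/`dialect`.
#' @param ld labelled LD r-squared matrix, or path readable by
#'   [read_ld_matrix()].
#' @param estimator options list: `model`, `n_boot`, `level`.
#' @param presso options list: `run` (logical), `n_sim`, `n_boot`,
#'   `sig_level`, `min_nsnp`.
#' @param sign_convention `"lowering"` reports effects per unit *decrease*
#'   of the exposure (the drug direction for an inhibitor of a
#'   trait-raising target); `"raising"` reports the native GWAS direction.
#' @param harmonize_mode passed to [harmonize()].
#' @param positive_controls character vector of outcome names flagged as
#'   positive controls.
#' @param seed master integer seed for the study.
#' @return a `study_config` list.
#' @export
study_config <- function(exposures, outcomes, ld,
                         estimator = list(), presso = list(),
                         sign_convention = c("lowering", "raising"),
                         harmonize_mode = c("conservative", "permissive"),
                         positive_controls = character(), seed = 1L) {
  sign_convention <- match.arg(sign_convention)
  harmonize_mode <- match.arg(harmonize_mode)
  if (is.null(names(exposures)) || anyDuplicated(names(exposures)) ||
      is.null(names(outcomes)) || anyDuplicated(names(outcomes))) {
    stop_config("exposures and outcomes must be uniquely named lists")
  }
  estimator <- modifyList(
    list(model = "multiplicative_random", n_boot = 1000, level = 0.95), estimator
  )
  presso <- modifyList(
    list(run = TRUE, n_sim = 1000, n_boot = 1000, sig_level = 0.05,
         min_nsnp = 4), presso
  )
  structure(
    list(exposures = exposures, outcomes = outcomes, ld = ld,
         estimator = estimator, presso = presso,
         sign_convention = sign_convention, harmonize_mode = harmonize_mode,
         positive_controls = positive_controls, seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Reorient MR results to the chosen exposure direction
#'
#' MR estimates are computed natively per unit *increase* of the exposure.
#' An inhibitor of a trait-raising target acts in the lowering direction,
#' so reported odds ratios are conventionally flipped: estimates and CI
#' bounds are negated (and swapped) on the log scale, which reciprocates
#' the odds ratios. Applying the convention twice restores the input.
#'
#' @param results `mr_result` tibble (one or more rows).
#' @param direction `"lowering"` (flip) or `"raising"` (identity).
#' @return the reoriented results tibble.
#' @export
apply_sign_convention <- function(results, direction = c("lowering", "raising")) {
  direction <- match.arg(direction)
  if (direction == "raising") return(results)
  dplyr::mutate(
    results,
    estimate = -.data$estimate,
    ci_low_new = -.data$ci_high, ci_high_new = -.data$ci_low,
    ci_low = .data$ci_low_new, ci_high = .data$ci_high_new,
    or = exp(.data$estimate),
    or_ci_low = exp(.data$ci_low), or_ci_high = exp(.data$ci_high)
  ) |>
    dplyr::select(-"ci_low_new", -"ci_high_new")
}

run_one_pair <- function(exp_name, exp_spec, out_name, outcome, ld, cfg, seed) {
  exposure <- resolve_sumstats(exp_spec$sumstats, exp_name)
  sel_cfg <- exp_spec$config %||% selection_config()
  instruments <- if (!is.null(exp_spec$region)) {
    select_cis_instruments(exposure, exp_spec$region, outcome, ld, sel_cfg,
                           exposure = exp_name)
  } else {
    select_genome_wide(exposure, outcome, ld, sel_cfg, exposure = exp_name)
  }
  pairs <- harmonize(instruments, outcome, mode = cfg$harmonize_mode)
  seeds <- derive_seeds(seed, 2)
  analysis <- mr_analysis(
    pairs, model = cfg$estimator$model, n_boot = cfg$estimator$n_boot,
    seed = seeds[1], level = cfg$estimator$level
  )
  presso <- NULL; pass2 <- NULL
  if (isTRUE(cfg$presso$run) && nrow(pairs) >= cfg$presso$min_nsnp) {
    pr <- run_presso_and_refit(
      pairs, n_sim = cfg$presso$n_sim, n_boot = cfg$presso$n_boot,
      seed = seeds[2], sig_level = cfg$presso$sig_level,
      model = cfg$estimator$model
    )
    presso <- pr$presso
    pass2 <- pr$pass2
  }
  list(
    exposure = exp_name, outcome = out_name,
    positive_control = out_name %in% cfg$positive_controls,
    instruments = instruments, harmonized = pairs,
    analysis = analysis, presso = presso, pass2 = pass2,
    error = NULL
  )
}

#' Run the full study grid
#'
#' For every configured exposure x outcome pair: select instruments,
#' harmonize, run the estimator battery and sensitivity tests, run
#' MR-PRESSO and (when outliers are flagged) the post-removal second pass.
#' A failure in one pair (for example, no surviving instruments for one
#' outcome) is recorded as a structured entry and never aborts the rest of
#' the grid. Deterministic given the config and its seed.
#'
#' @param config a [study_config()].
#' @return object of class `mr_study`: list with one entry per pair plus
#'   the config. Use [generics::tidy()] for the results table,
#'   [study_sensitivity()], [study_presso()], [study_leave_one_out()] for
#'   the companion tables, and [render_report()] to write all of them.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  ld <- if (is.character(config$ld)) read_ld_matrix(config$ld) else validate_ld_matrix(config$ld)
  outcomes <- purrr::imap(config$outcomes, resolve_sumstats)
  grid <- tidyr::expand_grid(
    exposure = names(config$exposures), outcome = names(outcomes)
  )
  pair_seeds <- derive_seeds(config$seed, nrow(grid))
  entries <- purrr::map(seq_len(nrow(grid)), function(i) {
    e <- grid$exposure[i]; o <- grid$outcome[i]
    tryCatch(
      run_one_pair(e, config$exposures[[e]], o, outcomes[[o]], ld, config,
                   pair_seeds[i]),
      error = function(err) {
        warn(sprintf("pair %s x %s failed: %s", e, o, conditionMessage(err)))
        list(exposure = e, outcome = o,
             positive_control = o %in% config$positive_controls,
             instruments = NULL, harmonized = NULL, analysis = NULL,
             presso = NULL, pass2 = NULL, error = conditionMessage(err))
      }
    )
  })
  structure(list(pairs = entries, config = config), class = "mr_study")
}

study_results_table <- function(study) {
  purrr::map_dfr(study$pairs, function(p) {
    if (is.null(p$analysis)) {
      return(tibble(
        exposure = p$exposure, outcome = p$outcome,
        positive_control = p$positive_control, pass = NA_integer_,
        method = NA_character_, nsnp = NA_integer_, estimate = NA_real_,
        se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        pvalue = NA_real_, or = NA_real_, or_ci_low = NA_real_,
        or_ci_high = NA_real_, failure = p$error
      ))
    }
    one_pass <- function(analysis, pass) {
      res <- apply_sign_convention(analysis$results,
                                   study$config$sign_convention)
      dplyr::bind_cols(
        tibble(exposure = p$exposure, outcome = p$outcome,
               positive_control = p$positive_control, pass = pass),
        res, tibble(failure = NA_character_)
      )
    }
    out <- one_pass(p$analysis, 1L)
    if (!is.null(p$pass2)) out <- dplyr::bind_rows(out, one_pass(p$pass2, 2L))
    out
  })
}

#' Companion tables of a study report
#'
#' `study_sensitivity()` gathers Cochran's Q and Egger-intercept rows,
#' `study_presso()` the MR-PRESSO global/outlier/distortion summary, and
#' `study_leave_one_out()` the per-omitted-variant IVW table, each keyed by
#' exposure and outcome (and pass, where a post-outlier second pass ran).
#'
#' @param study an `mr_study` from [run_study()].
#' @return a tibble.
#' @export
study_sensitivity <- function(study) {
  purrr::map_dfr(study$pairs, function(p) {
    if (is.null(p$analysis)) return(tibble())
    rows <- tibble()
    collect <- function(analysis, pass) {
      out <- tibble()
      if (!is.null(analysis$heterogeneity)) {
        het <- analysis$heterogeneity
        out <- dplyr::bind_rows(out, tibble(
          test = "cochran_q", context = het$method, statistic = het$Q,
          df = het$df, pvalue = het$pvalue
        ))
      }
      if (!is.null(analysis$pleiotropy)) {
        out <- dplyr::bind_rows(out, tibble(
          test = "egger_intercept", context = "egger",
          statistic = analysis$pleiotropy$intercept,
          df = NA_integer_, pvalue = analysis$pleiotropy$pvalue
        ))
      }
      if (nrow(out) > 0) {
        out <- dplyr::bind_cols(
          tibble(exposure = p$exposure, outcome = p$outcome, pass = pass)[rep(1, nrow(out)), ],
          out
        )
      }
      out
    }
    rows <- collect(p$analysis, 1L)
    if (!is.null(p$pass2)) rows <- dplyr::bind_rows(rows, collect(p$pass2, 2L))
    rows
  })
}

#' @rdname study_sensitivity
#' @export
study_presso <- function(study) {
  purrr::map_dfr(study$pairs, function(p) {
    if (is.null(p$presso)) return(tibble())
    tibble(
      exposure = p$exposure, outcome = p$outcome,
      rss_obs = p$presso$rss_obs, global_p = p$presso$global_p,
      n_sim = p$presso$n_sim,
      outliers = paste(p$presso$outliers, collapse = ","),
      distortion_p = p$presso$distortion_p %||% NA_real_,
      corrected_estimate = if (is.null(p$presso$corrected)) NA_real_ else p$presso$corrected$estimate,
      corrected_se = if (is.null(p$presso$corrected)) NA_real_ else p$presso$corrected$se
    )
  })
}

#' @rdname study_sensitivity
#' @export
study_leave_one_out <- function(study) {
  purrr::map_dfr(study$pairs, function(p) {
    if (is.null(p$analysis) || is.null(p$analysis$leave_one_out)) return(tibble())
    loo <- apply_sign_convention(p$analysis$leave_one_out,
                                 study$config$sign_convention)
    dplyr::bind_cols(
      tibble(exposure = p$exposure, outcome = p$outcome)[rep(1, nrow(loo)), ],
      loo
    )
  })
}

#' @export
print.mr_study <- function(x, ...) {
  cat(sprintf("MR study: %d exposure(s) x %d outcome(s), seed %d\n",
              length(x$config$exposures), length(x$config$outcomes),
              x$config$seed))
  print(study_results_table(x), n = Inf)
  invisible(x)
}

#' Write the study report tables
#'
#' Writes `results.tsv` (estimates on both log-odds and odds-ratio scales,
#' under the configured sign convention), `sensitivity.tsv` (Cochran's Q
#' and Egger intercept), `presso.tsv`, `leave_one_out.tsv`,
#' `instruments.tsv` (per-variant instrument report with variance explained
#' and F), `harmonization.tsv` (per-variant actions) and `run_info.tsv`
#' (package version, seed, sign convention, thresholds).
#'
#' @param study an `mr_study` from [run_study()].
#' @param outdir output directory, created if absent.
#' @return character vector of written file paths, invisibly.
#' @export
render_report <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop_data(paste0("cannot create output directory ", outdir))
  paths <- c(
    results = file.path(outdir, "results.tsv"),
    sensitivity = file.path(outdir, "sensitivity.tsv"),
    presso = file.path(outdir, "presso.tsv"),
    leave_one_out = file.path(outdir, "leave_one_out.tsv"),
    instruments = file.path(outdir, "instruments.tsv"),
    harmonization = file.path(outdir, "harmonization.tsv"),
    run_info = file.path(outdir, "run_info.tsv")
  )
  readr::write_tsv(study_results_table(study), paths["results"], progress = FALSE)
  readr::write_tsv(study_sensitivity(study), paths["sensitivity"], progress = FALSE)
  readr::write_tsv(study_presso(study), paths["presso"], progress = FALSE)
  readr::write_tsv(study_leave_one_out(study), paths["leave_one_out"], progress = FALSE)
  inst <- purrr::map_dfr(study$pairs, function(p) {
    if (is.null(p$instruments)) return(tibble())
    dplyr::bind_cols(
      tibble(exposure = p$exposure, outcome = p$outcome)[rep(1, nrow(p$instruments)), ],
      as_tibble(p$instruments)
    )
  })
  readr::write_tsv(inst, paths["instruments"], progress = FALSE)
  harm <- purrr::map_dfr(study$pairs, function(p) {
    if (is.null(p$harmonized)) return(tibble())
    log <- harmonization_log(p$harmonized)
    dplyr::bind_cols(
      tibble(exposure = p$exposure, outcome = p$outcome)[rep(1, nrow(log)), ],
      log
    )
  })
  readr::write_tsv(harm, paths["harmonization"], progress = FALSE)
  cfg <- study$config
  info <- tibble(
    key = c("package_version", "seed", "sign_convention", "harmonize_mode",
            "ivw_model", "presso_n_sim", "presso_sig_level"),
    value = c(as.character(utils::packageVersion("targetmr")),
              as.character(cfg$seed), cfg$sign_convention, cfg$harmonize_mode,
              cfg$estimator$model, as.character(cfg$presso$n_sim),
              as.character(cfg$presso$sig_level))
  )
  readr::write_tsv(info, paths["run_info"], progress = FALSE)
  invisible(paths)
}
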