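DNA_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

complement_allele <- function(x) {
  vapply(strsplit(x, ""), function(ch) {
    paste(rev(DNA_COMPLEMENT[ch]), collapse = "")
  }, character(1))
}

is_palindromic <- function(a1, a2) {
  nchar(a1) == 1 & nchar(a2) == 1 & complement_allele(a1) == a2
}

#' Harmonize one exposure/outcome variant pair onto a shared effect allele
#'
#' Aligns the outcome association to the exposure's effect allele. Identical
#' allele pairs pass unchanged; swapped alleles flip the outcome effect sign
#' and complement the outcome frequency; strand-complement alleles are
#' relabelled to the exposure strand first. Palindromic variants (A/T, C/G)
#' carry no strand information in their alleles: in `conservative` mode the
#' orientation is inferred from allele frequencies when both lie outside the
#' ambiguity band `[0.42, 0.58]`, otherwise the pair is dropped as
#' ambiguous; `permissive` mode assumes both studies report the same strand.
#' Indel or multi-allelic records and irreconcilable allele pairs are
#' dropped as incompatible.
#'
#' @param exp,out single-row data frames (or lists) with fields `rsid`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue` for the
#'   exposure and outcome association of the same variant.
#' @param mode `"conservative"` (default) or `"permissive"`.
#' @param ambiguity_band frequency band within which a palindromic variant's
#'   orientation is considered undecidable in conservative mode.
#' @return one-row tibble with `rsid`, `beta_exp`, `se_exp`, `beta_out`,
#'   `se_out`, `eaf_exp`, `eaf_out`, `pvalue_out`, `palindromic` and
#'   `action` (`none`, `flip`, `strand_flip`, `dropped_ambiguous`,
#'   `dropped_incompatible`).
#' @export
harmonize_pair <- function(exp, out, mode = c("conservative", "permissive"),
                           ambiguity_band = c(0.42, 0.58)) {
  mode <- match.arg(mode)
  if (!identical(as.character(exp$rsid), as.character(out$rsid))) {
    stop_usage("harmonize_pair requires matching rsids")
  }
  ea_x <- toupper(exp$effect_allele); oa_x <- toupper(exp$other_allele)
  ea_y <- toupper(out$effect_allele); oa_y <- toupper(out$other_allele)

  res <- function(action, beta_out = out$beta, eaf_out = out$eaf,
                  palindromic = FALSE) {
    tibble(
      rsid = as.character(exp$rsid),
      beta_exp = exp$beta, se_exp = exp$se,
      beta_out = beta_out, se_out = out$se,
      eaf_exp = exp$eaf, eaf_out = eaf_out,
      pvalue_out = out$pvalue,
      palindromic = palindromic, action = action
    )
  }

  multi <- nchar(ea_x) > 1 || nchar(oa_x) > 1 || nchar(ea_y) > 1 || nchar(oa_y) > 1
  if (multi) return(res("dropped_incompatible"))

  pal <- is_palindromic(ea_x, oa_x)
  if (pal) {
    # Alleles cannot distinguish strand for palindromic variants; a strand
    # flip looks identical to no flip, and a swap looks identical to a
    # strand-flipped swap. Use frequency concordance instead.
    same_labels <- (ea_y == ea_x && oa_y == oa_x)
    swapped_labels <- (ea_y == oa_x && oa_y == ea_x)
    if (!same_labels && !swapped_labels) return(res("dropped_incompatible"))
    beta_y <- if (same_labels) out$beta else -out$beta
    eaf_y <- if (same_labels) out$eaf else 1 - out$eaf
    if (mode == "permissive") {
      return(res(if (same_labels) "none" else "flip", beta_y, eaf_y,
                 palindromic = TRUE))
    }
    if (is.na(exp$eaf) || is.na(eaf_y)) {
      return(res("dropped_ambiguous", palindromic = TRUE))
    }
    in_band <- function(f) f >= ambiguity_band[1] & f <= ambiguity_band[2]
    if (in_band(exp$eaf) || in_band(eaf_y)) {
      return(res("dropped_ambiguous", palindromic = TRUE))
    }
    concordant <- (exp$eaf < 0.5) == (eaf_y < 0.5)
    if (concordant) {
      return(res(if (same_labels) "none" else "flip", beta_y, eaf_y,
                 palindromic = TRUE))
    }
    # Frequencies disagree: the outcome is on the opposite strand, which for
    # a palindromic variant means the labelled effect allele is really the
    # exposure's other allele.
    return(res("flip", -beta_y, 1 - eaf_y, palindromic = TRUE))
  }

  if (ea_y == ea_x && oa_y == oa_x) return(res("none"))
  if (ea_y == oa_x && oa_y == ea_x) {
    return(res("flip", -out$beta, if (is.na(out$eaf)) NA_real_ else 1 - out$eaf))
  }
  cea <- complement_allele(ea_y); coa <- complement_allele(oa_y)
  if (cea == ea_x && coa == oa_x) {
    return(res("strand_flip"))
  }
  if (cea == oa_x && coa == ea_x) {
    return(res("flip", -out$beta, if (is.na(out$eaf)) NA_real_ else 1 - out$eaf))
  }
  res("dropped_incompatible")
}

#' Harmonize an instrument set against an outcome GWAS
#'
#' Looks up each instrument in the outcome dataset, aligns outcome effects
#' onto the exposure effect allele with [harmonize_pair()], and returns the
#' surviving pairs in instrument order. Instruments missing from the outcome
#' or dropped during alignment are recorded in the harmonization log
#' (`harmonization_log()` on the result).
#'
#' @param instruments an `mr_instruments` tibble (or any sumstats-shaped
#'   tibble) for the exposure.
#' @param outcome a `sumstats` tibble for the outcome.
#' @inheritParams harmonize_pair
#' @return tibble of surviving harmonized pairs (class `mr_harmonized`),
#'   with the full per-variant action log as attribute `"log"`.
#' @export
harmonize <- function(instruments, outcome, mode = c("conservative", "permissive"),
                      ambiguity_band = c(0.42, 0.58)) {
  mode <- match.arg(mode)
  instruments <- as_tibble(instruments)
  if (nrow(instruments) == 0) stop_usage("no instruments to harmonize")
  out_idx <- match(instruments$rsid, outcome$rsid)
  rows <- purrr::map(seq_len(nrow(instruments)), function(i) {
    if (is.na(out_idx[i])) {
      return(tibble(
        rsid = instruments$rsid[i], beta_exp = NA_real_, se_exp = NA_real_,
        beta_out = NA_real_, se_out = NA_real_, eaf_exp = NA_real_,
        eaf_out = NA_real_, pvalue_out = NA_real_, palindromic = NA,
        action = "dropped_missing_outcome"
      ))
    }
    harmonize_pair(instruments[i, ], as_tibble(outcome)[out_idx[i], ],
                   mode = mode, ambiguity_band = ambiguity_band)
  })
  log <- dplyr::bind_rows(rows)
  kept <- dplyr::filter(log, !startsWith(.data$action, "dropped"))
  if (nrow(kept) == 0) {
    stop_data("no valid instruments: all pairs dropped during harmonization")
  }
  n_drop <- nrow(log) - nrow(kept)
  if (n_drop > 0) {
    inform(sprintf("harmonization dropped %d of %d pair(s)", n_drop, nrow(log)))
  }
  attr(kept, "log") <- log
  attr(kept, "mode") <- mode
  class(kept) <- unique(c("mr_harmonized", class(kept)))
  kept
}

#' @rdname harmonize
#' @param x result of [harmonize()].
#' @export
harmonization_log <- function(x) attr(x, "log")
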