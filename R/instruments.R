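#' Define a gene region for cis-instrument selection
#'
#' A cis window is the gene body extended by `flank_kb` kilobases on each
#' side; variants inside the closed interval
#' `[start - flank_kb*1000, end + flank_kb*1000]` on the matching chromosome
#' are cis candidates. Coordinates are build-specific; the packaged region
#' file (see [load_gene_regions()]) carries both GRCh37 and GRCh38 entries.
#'
#' @param gene gene symbol, e.g. `"SLC5A2"`.
#' @param chrom chromosome label.
#' @param start,end gene body coordinates in base pairs, `start < end`.
#' @param flank_kb flanking distance in kilobases (>= 0).
#' @param genome_build `"GRCh37"` or `"GRCh38"`.
#' @return a `gene_region` list.
#' @export
gene_region <- function(gene, chrom, start, end, flank_kb = 500,
                        genome_build = c("GRCh37", "GRCh38")) {
  genome_build <- match.arg(genome_build)
  if (!is_scalar_number(start) || !is_scalar_number(end) || start >= end) {
    stop_config("gene region requires start < end")
  }
  if (!is_scalar_number(flank_kb) || flank_kb < 0) {
    stop_config("flank_kb must be a non-negative number")
  }
  structure(
    list(gene = gene, chrom = as.character(chrom), start = start, end = end,
         flank_kb = flank_kb, genome_build = genome_build),
    class = "gene_region"
  )
}

#' Load gene-region definitions from a YAML config
#'
#' Reads a list of gene regions (gene, chrom, start, end, flank_kb, build)
#' from a YAML file. The packaged default carries SLC5A1 (SGLT1) with a
#' 500 kb flank and SLC5A2 (SGLT2) with a 1000 kb flank in both genome
#' builds; edit or replace the file to analyse other targets.
#'
#' @param path YAML file; defaults to the packaged region config.
#' @param genome_build build to select entries for.
#' @return named list of `gene_region` objects.
#' @export
load_gene_regions <- function(path = system.file("extdata", "gene_regions.yaml",
                                                 package = "targetmr"),
                              genome_build = c("GRCh37", "GRCh38")) {
  genome_build <- match.arg(genome_build)
  spec <- yaml::read_yaml(path)
  regions <- purrr::keep(spec$regions, ~ .x$genome_build == genome_build)
  if (length(regions) == 0) {
    stop_config(paste0("no regions for build ", genome_build, " in ", path))
  }
  out <- purrr::map(regions, ~ gene_region(
    gene = .x$gene, chrom = .x$chrom, start = .x$start, end = .x$end,
    flank_kb = .x$flank_kb, genome_build = .x$genome_build
  ))
  setNames(out, purrr::map_chr(out, "gene"))
}

#' Instrument-selection configuration
#'
#' Bundles the filters applied when building an instrument set. Defaults
#' follow the drug-target cis design: candidate significance `p_threshold`,
#' greedy LD clumping that removes a variant only when both its r-squared
#' with a better variant exceeds `clump_r2` and their distance is within
#' `clump_window_kb`, then exclusion of variants with minor-allele frequency
#' below `maf_min`, instrument F statistic below `f_min`, absence from the
#' outcome GWAS, or outcome association p below `outcome_p_exclude`.
#' Genome-wide mode additionally removes variants inside `excluded_regions`
#' and typically uses the much stricter clumping (10,000 kb, r-squared
#' 0.001) appropriate when variants are drawn from the whole genome.
#'
#' @param mode `"cis"` or `"genome_wide"`.
#' @param p_threshold candidate association p-value threshold.
#' @param clump_r2 LD r-squared above which correlated variants are clumped.
#' @param clump_window_kb distance gate for clumping, kilobases.
#' @param maf_min minimum minor-allele frequency (exclude if MAF < this).
#' @param f_min minimum per-SNP F statistic (exclude if F < this).
#' @param outcome_p_exclude exclude instruments with outcome p below this.
#' @param excluded_regions list of [gene_region()]s to mask (genome-wide mode).
#' @return a `selection_config` list.
#' @export
selection_config <- function(mode = c("cis", "genome_wide"),
                             p_threshold = 5e-8,
                             clump_r2 = 0.3,
                             clump_window_kb = 100,
                             maf_min = 0.01,
                             f_min = 10,
                             outcome_p_exclude = 5e-5,
                             excluded_regions = list()) {
  mode <- match.arg(mode)
  if (mode == "genome_wide" && missing(clump_r2)) clump_r2 <- 0.001
  if (mode == "genome_wide" && missing(clump_window_kb)) clump_window_kb <- 10000
  if (!is_scalar_number(p_threshold) || p_threshold <= 0 || p_threshold >= 1) {
    stop_config("p_threshold must lie in (0, 1)")
  }
  if (!is_scalar_number(clump_r2) || clump_r2 <= 0 || clump_r2 > 1) {
    stop_config("clump_r2 must lie in (0, 1]")
  }
  stopifnot(clump_window_kb > 0, maf_min >= 0, f_min >= 0, outcome_p_exclude >= 0)
  structure(
    list(mode = mode, p_threshold = p_threshold, clump_r2 = clump_r2,
         clump_window_kb = clump_window_kb, maf_min = maf_min, f_min = f_min,
         outcome_p_exclude = outcome_p_exclude,
         excluded_regions = excluded_regions),
    class = "selection_config"
  )
}

#' Per-SNP variance explained in the exposure
#'
#' Proportion of exposure variance explained by one variant, computed from
#' the effect-allele frequency, effect size, standard error and sample size:
#' `(2 eaf (1-eaf) beta^2) / (2 eaf (1-eaf) beta^2 + 2 eaf (1-eaf) N se^2)`,
#' which simplifies to `beta^2 / (beta^2 + N se^2)`.
#'
#' @param eaf effect-allele frequency, strictly inside (0, 1).
#' @param beta per-allele effect estimate.
#' @param se standard error of `beta` (> 0).
#' @param n GWAS sample size (> 2).
#' @return variance explained, in \[0, 1). Vectorised.
#' @export
snp_variance_explained <- function(eaf, beta, se, n) {
  if (any(eaf <= 0 | eaf >= 1, na.rm = TRUE)) {
    stop_usage("eaf must lie strictly inside (0, 1)")
  }
  if (any(se <= 0, na.rm = TRUE)) stop_usage("se must be positive")
  if (any(n <= 2, na.rm = TRUE)) stop_usage("n must exceed 2")
  num <- 2 * eaf * (1 - eaf) * beta^2
  num / (num + 2 * eaf * (1 - eaf) * n * se^2)
}

#' Per-SNP instrument F statistic
#'
#' Instrument-strength F statistic `F = r2 (N - 2) / (1 - r2)`; values below
#' 10 conventionally flag weak instruments.
#'
#' @param r2 variance explained, in \[0, 1).
#' @param n sample size (> 2).
#' @return F statistic (>= 0). Vectorised.
#' @export
snp_f_statistic <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1, na.rm = TRUE)) stop_usage("r2 must lie in [0, 1)")
  if (any(n <= 2, na.rm = TRUE)) stop_usage("n must exceed 2")
  r2 * (n - 2) / (1 - r2)
}

#' Select cis candidate variants around a gene
#'
#' Keeps variants on the region's chromosome whose position falls in the
#' closed window `[start - flank, end + flank]` and whose association
#' p-value is below `p_threshold`.
#'
#' @param dataset a `sumstats` tibble (exposure GWAS).
#' @param region a [gene_region()]; its build must match the dataset's.
#' @param p_threshold association p-value cutoff (keep if p < threshold).
#' @return tibble of candidate records.
#' @export
select_cis_candidates <- function(dataset, region, p_threshold = 5e-8) {
  build <- attr(dataset, "genome_build")
  if (!is.null(build) && !identical(build, region$genome_build)) {
    stop_config(sprintf(
      "genome build mismatch: dataset is %s, region %s is %s",
      build, region$gene, region$genome_build
    ))
  }
  lo <- region$start - region$flank_kb * 1000
  hi <- region$end + region$flank_kb * 1000
  dplyr::filter(
    as_tibble(dataset),
    .data$chrom == region$chrom, .data$pos >= lo, .data$pos <= hi,
    .data$pvalue < p_threshold
  )
}

# r2 lookup tolerant of SNPs absent from the reference LD matrix: unknown
# pairs are treated as unlinked (r2 = 0), once per call with a warning.
ld_r2_lookup <- function(rsids, ld) {
  J <- length(rsids)
  m <- matrix(0, J, J, dimnames = list(rsids, rsids))
  diag(m) <- 1
  present <- rsids %in% rownames(ld)
  if (any(!present)) {
    warn(sprintf(
      "%d candidate SNP(s) absent from LD matrix; treating their r2 as 0",
      sum(!present)
    ))
  }
  if (any(present)) {
    idx <- rsids[present]
    m[present, present] <- ld[idx, idx]
  }
  m
}

#' Greedy LD clumping of candidate variants
#'
#' Repeatedly retains the remaining variant with the smallest p-value and
#' discards every remaining variant that is both correlated with it
#' (r-squared > `r2_thresh`) and within `window_kb` kilobases of it. Ties in
#' p-value are broken by smaller position, then lexicographic rsid, so
#' output is deterministic and order-invariant. Variant pairs missing from
#' the LD matrix are treated as unlinked with a warning.
#'
#' @param candidates tibble of candidate records (needs `rsid`, `chrom`,
#'   `pos`, `pvalue`).
#' @param ld labelled r-squared matrix (see [read_ld_matrix()]).
#' @param r2_thresh r-squared above which a pair counts as linked.
#' @param window_kb distance gate in kilobases.
#' @return tibble of retained records, sorted by chromosome and position.
#' @export
clump_snps <- function(candidates, ld, r2_thresh = 0.3, window_kb = 100) {
  candidates <- as_tibble(candidates)
  if (nrow(candidates) == 0) return(candidates)
  ord <- order(candidates$pvalue, candidates$pos, candidates$rsid)
  work <- candidates[ord, ]
  r2 <- ld_r2_lookup(work$rsid, ld)
  keep <- rep(NA, nrow(work))  # NA = undecided
  for (i in seq_len(nrow(work))) {
    if (!is.na(keep[i])) next
    keep[i] <- TRUE
    later <- which(is.na(keep))
    if (length(later) == 0) break
    same_chr <- work$chrom[later] == work$chrom[i]
    near <- abs(work$pos[later] - work$pos[i]) <= window_kb * 1000
    linked <- r2[later, i] > r2_thresh
    keep[later[same_chr & near & linked]] <- FALSE
  }
  out <- work[which(keep), ]
  dplyr::arrange(out, .data$chrom, .data$pos)
}

annotate_strength <- function(snps) {
  dplyr::mutate(
    snps,
    r2 = snp_variance_explained(.data$eaf, .data$beta, .data$se, .data$n),
    f = snp_f_statistic(.data$r2, .data$n)
  )
}

new_instrument_set <- function(snps, exposure, provenance) {
  attr(snps, "exposure") <- exposure
  attr(snps, "provenance") <- provenance
  class(snps) <- unique(c("mr_instruments", class(snps)))
  snps
}

#' @export
print.mr_instruments <- function(x, ...) {
  cat(sprintf("# MR instrument set for %s: %d SNP(s)\n",
              attr(x, "exposure") %||% "exposure", nrow(x)))
  prov <- attr(x, "provenance")
  if (!is.null(prov)) {
    cat("# filter chain: ",
        paste(sprintf("%s %d->%d", prov$step, prov$n_before, prov$n_after),
              collapse = "; "), "\n", sep = "")
  }
  NextMethod()
}

#' Filter-chain provenance of an instrument set
#'
#' @param x an `mr_instruments` tibble.
#' @return tibble with columns `step`, `n_before`, `n_after`.
#' @export
instrument_provenance <- function(x) attr(x, "provenance")

#' Apply MAF, instrument-strength and outcome-overlap exclusions
#'
#' Applies, in order: minor-allele frequency `MAF = min(eaf, 1 - eaf)` at
#' least `maf_min`; F statistic at least `f_min`; presence of the rsid in
#' the outcome GWAS; outcome association p-value at least
#' `outcome_p_exclude` (a variant strongly associated with the outcome is
#' excluded as a likely exclusion-restriction violation). Each step's
#' before/after counts are logged in the returned set's provenance.
#'
#' @param candidates tibble of cis-filtered, clumped candidates.
#' @param outcome a `sumstats` tibble for the outcome GWAS.
#' @param config a [selection_config()].
#' @param exposure exposure label for the instrument set.
#' @param provenance optional provenance tibble accumulated upstream.
#' @return an `mr_instruments` tibble with `r2` and `f` columns.
#' @export
apply_exclusions <- function(candidates, outcome, config, exposure = "exposure",
                             provenance = NULL) {
  prov <- provenance %||% tibble(step = character(), n_before = integer(),
                                 n_after = integer())
  snps <- annotate_strength(as_tibble(candidates))
  log_step <- function(step, before, after) {
    prov <<- dplyr::bind_rows(prov, tibble(
      step = step, n_before = as.integer(before), n_after = as.integer(after)
    ))
  }
  check_empty <- function(snps, step) {
    if (nrow(snps) == 0) {
      stop_data(paste0("no valid instruments: filter '", step,
                       "' removed the final candidate"))
    }
    snps
  }

  n0 <- nrow(snps)
  snps <- dplyr::filter(snps, pmin(.data$eaf, 1 - .data$eaf) >= config$maf_min)
  log_step("maf", n0, nrow(snps)); snps <- check_empty(snps, "maf")

  n0 <- nrow(snps)
  snps <- dplyr::filter(snps, .data$f >= config$f_min)
  log_step("f_statistic", n0, nrow(snps)); snps <- check_empty(snps, "f_statistic")

  n0 <- nrow(snps)
  snps <- dplyr::filter(snps, .data$rsid %in% outcome$rsid)
  log_step("outcome_presence", n0, nrow(snps))
  snps <- check_empty(snps, "outcome_presence")

  n0 <- nrow(snps)
  out_p <- setNames(outcome$pvalue, outcome$rsid)
  snps <- dplyr::filter(snps, out_p[.data$rsid] >= config$outcome_p_exclude)
  log_step("outcome_pvalue", n0, nrow(snps))
  snps <- check_empty(snps, "outcome_pvalue")

  new_instrument_set(snps, exposure, prov)
}

#' Build a cis drug-target instrument set
#'
#' Full cis selection chain: window + significance filter, LD clumping, then
#' [apply_exclusions()].
#'
#' @inheritParams select_cis_candidates
#' @inheritParams apply_exclusions
#' @param ld labelled r-squared matrix.
#' @return an `mr_instruments` tibble.
#' @export
select_cis_instruments <- function(dataset, region, outcome, ld, config,
                                   exposure = region$gene) {
  n0 <- nrow(dataset)
  cand <- select_cis_candidates(dataset, region, config$p_threshold)
  prov <- tibble(step = "cis_window_and_p", n_before = as.integer(n0),
                 n_after = as.integer(nrow(cand)))
  if (nrow(cand) == 0) {
    stop_data("no valid instruments: filter 'cis_window_and_p' removed the final candidate")
  }
  n0 <- nrow(cand)
  cand <- clump_snps(cand, ld, config$clump_r2, config$clump_window_kb)
  prov <- dplyr::bind_rows(prov, tibble(
    step = "ld_clump", n_before = as.integer(n0), n_after = as.integer(nrow(cand))
  ))
  apply_exclusions(cand, outcome, config, exposure = exposure, provenance = prov)
}

#' Build a genome-wide instrument set with target regions masked
#'
#' Genome-wide significance filter, removal of variants inside any excluded
#' region (closed windows, as in cis selection), stringent LD clumping, then
#' [apply_exclusions()]. Used for the trait-level analysis where the
#' exposure is instrumented by variants independent of the drug-target loci.
#'
#' @inheritParams select_cis_instruments
#' @return an `mr_instruments` tibble.
#' @export
select_genome_wide <- function(dataset, outcome, ld, config,
                               exposure = attr(dataset, "trait") %||% "exposure") {
  if (length(config$excluded_regions) == 0) {
    stop_config("genome-wide selection requires excluded_regions in the config")
  }
  n0 <- nrow(dataset)
  cand <- dplyr::filter(as_tibble(dataset), .data$pvalue < config$p_threshold)
  prov <- tibble(step = "genome_wide_p", n_before = as.integer(n0),
                 n_after = as.integer(nrow(cand)))
  n0 <- nrow(cand)
  in_region <- rep(FALSE, nrow(cand))
  for (reg in config$excluded_regions) {
    lo <- reg$start - reg$flank_kb * 1000
    hi <- reg$end + reg$flank_kb * 1000
    in_region <- in_region |
      (cand$chrom == reg$chrom & cand$pos >= lo & cand$pos <= hi)
  }
  cand <- cand[!in_region, ]
  prov <- dplyr::bind_rows(prov, tibble(
    step = "region_exclusion", n_before = as.integer(n0),
    n_after = as.integer(nrow(cand))
  ))
  if (nrow(cand) == 0) {
    stop_data("no valid instruments: filter 'region_exclusion' removed the final candidate")
  }
  n0 <- nrow(cand)
  cand <- clump_snps(cand, ld, config$clump_r2, config$clump_window_kb)
  prov <- dplyr::bind_rows(prov, tibble(
    step = "ld_clump", n_before = as.integer(n0), n_after = as.integer(nrow(cand))
  ))
  apply_exclusions(cand, outcome, config, exposure = exposure, provenance = prov)
}
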