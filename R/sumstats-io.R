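#' Column dialects for GWAS summary-statistics files
#'
#' Public GWAS resources name the same nine semantic columns differently.
#' A dialect is a named character vector mapping the canonical internal names
#' (`rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#' `se`, `pvalue`, `n`) to the column headers found in the file. Presets are
#' provided for the IEU OpenGWAS export format, FinnGen release files and
#' GWAS Catalog harmonised files; `"canonical"` is the package's own format
#' (SNP, CHR, BP, EA, NEA, EAF, BETA, SE, P, N).
#'
#' @param name one of `"canonical"`, `"ieu"`, `"finngen"`, `"gwas_catalog"`.
#' @return named character vector usable as the `dialect` argument of
#'   [read_sumstats()].
#' @examples
#' sumstats_dialect("finngen")
#' @export
sumstats_dialect <- function(name = c("canonical", "ieu", "finngen", "gwas_catalog")) {
  name <- match.arg(name)
  switch(name,
    canonical = c(
      rsid = "SNP", chrom = "CHR", pos = "BP", effect_allele = "EA",
      other_allele = "NEA", eaf = "EAF", beta = "BETA", se = "SE",
      pvalue = "P", n = "N"
    ),
    ieu = c(
      rsid = "SNP", chrom = "chr", pos = "position", effect_allele = "ea",
      other_allele = "nea", eaf = "eaf", beta = "beta", se = "se",
      pvalue = "p", n = "n"
    ),
    finngen = c(
      rsid = "rsids", chrom = "#chrom", pos = "pos", effect_allele = "alt",
      other_allele = "ref", eaf = "af_alt", beta = "beta", se = "sebeta",
      pvalue = "pval", n = "n"
    ),
    gwas_catalog = c(
      rsid = "variant_id", chrom = "chromosome", pos = "base_pair_location",
      effect_allele = "effect_allele", other_allele = "other_allele",
      eaf = "effect_allele_frequency", beta = "beta", se = "standard_error",
      pvalue = "p_value", n = "n"
    )
  )
}

sumstats_cols <- c(
  "rsid", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pvalue", "n"
)

#' Construct a validated summary-statistics table
#'
#' Coerces a data frame to the package's internal summary-statistics form:
#' a tibble with columns `rsid`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`, carrying `trait`,
#' `genome_build` and `ancestry` as attributes. Rows violating the record
#' invariants (se <= 0, eaf outside \[0,1\], pvalue outside (0,1\], pos <= 0,
#' identical alleles, non-finite beta) are dropped with a warning; `eaf` may
#' be `NA` (some outcome GWAS omit frequencies). Duplicate rsids are an error
#' since records are keyed by rsid.
#'
#' @param x data frame with the ten canonical columns.
#' @param trait trait label.
#' @param genome_build `"GRCh37"` or `"GRCh38"`.
#' @param ancestry ancestry label.
#' @return a `sumstats` tibble.
#' @export
as_sumstats <- function(x, trait = "trait", genome_build = c("GRCh37", "GRCh38"),
                        ancestry = "EUR") {
  genome_build <- match.arg(genome_build)
  missing_cols <- setdiff(sumstats_cols, names(x))
  if (length(missing_cols) > 0) {
    stop_config(paste0(
      "missing required summary-statistics column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  out <- as_tibble(x)[sumstats_cols]
  out <- dplyr::mutate(
    out,
    rsid = as.character(.data$rsid),
    chrom = as.character(.data$chrom),
    pos = suppressWarnings(as.integer(.data$pos)),
    effect_allele = toupper(as.character(.data$effect_allele)),
    other_allele = toupper(as.character(.data$other_allele)),
    dplyr::across(c("eaf", "beta", "se", "pvalue"), ~ suppressWarnings(as.numeric(.x))),
    n = suppressWarnings(as.numeric(.data$n))
  )
  ok <- !is.na(out$rsid) & !is.na(out$chrom) &
    !is.na(out$pos) & out$pos > 0 &
    !is.na(out$effect_allele) & !is.na(out$other_allele) &
    grepl("^[ACGT]+$", out$effect_allele) & grepl("^[ACGT]+$", out$other_allele) &
    out$effect_allele != out$other_allele &
    (is.na(out$eaf) | (out$eaf >= 0 & out$eaf <= 1)) &
    is.finite(out$beta) &
    !is.na(out$se) & out$se > 0 &
    !is.na(out$pvalue) & out$pvalue > 0 & out$pvalue <= 1 &
    !is.na(out$n) & out$n > 0
  if (any(!ok)) {
    warn(sprintf("dropped %d row(s) failing summary-statistics invariants", sum(!ok)))
    out <- out[ok, ]
  }
  if (nrow(out) == 0) stop_data("no valid summary-statistics records")
  if (anyDuplicated(out$rsid) > 0) {
    stop_data("duplicate rsid(s) in summary statistics; records must be keyed by rsid")
  }
  attr(out, "trait") <- trait
  attr(out, "genome_build") <- genome_build
  attr(out, "ancestry") <- ancestry
  class(out) <- c("sumstats", class(out))
  out
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf(
    "# GWAS summary statistics: %s (%s, %s), %d SNPs\n",
    attr(x, "trait"), attr(x, "genome_build"), attr(x, "ancestry"), nrow(x)
  ))
  NextMethod()
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- or comma-delimited file with a header row, renames columns
#' according to `dialect`, validates records and returns a `sumstats` tibble.
#' Delimiter is sniffed from the header line.
#'
#' @param path file path.
#' @param dialect named character vector mapping canonical names to file
#'   headers (see [sumstats_dialect()]), or a preset name.
#' @inheritParams as_sumstats
#' @return a `sumstats` tibble.
#' @seealso [write_sumstats()]
#' @export
read_sumstats <- function(path, dialect = "canonical", trait = "trait",
                          genome_build = c("GRCh37", "GRCh38"), ancestry = "EUR") {
  if (!file.exists(path)) stop_config(paste0("file not found: ", path))
  if (is.character(dialect) && length(dialect) == 1 && is.null(names(dialect))) {
    dialect <- sumstats_dialect(dialect)
  }
  missing_map <- setdiff(sumstats_cols, names(dialect))
  if (length(missing_map) > 0) {
    stop_config(paste0(
      "dialect does not map required column(s): ",
      paste(missing_map, collapse = ", ")
    ))
  }
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  missing_file <- setdiff(unname(dialect[sumstats_cols]), names(raw))
  if (length(missing_file) > 0) {
    stop_config(paste0(
      "file lacks column(s) named by dialect: ",
      paste(missing_file, collapse = ", ")
    ))
  }
  df <- setNames(raw[unname(dialect[sumstats_cols])], sumstats_cols)
  as_sumstats(df, trait = trait, genome_build = match.arg(genome_build),
              ancestry = ancestry)
}

#' Write summary statistics in the canonical delimited format
#'
#' Writes a `sumstats` tibble as tab-delimited text with the canonical
#' header (SNP, CHR, BP, EA, NEA, EAF, BETA, SE, P, N). Reading the file back
#' with [read_sumstats()] recovers the dataset.
#'
#' @param dataset a `sumstats` tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(dataset, path) {
  if (!is.data.frame(dataset) || nrow(dataset) == 0) {
    stop_usage("refusing to write an empty summary-statistics dataset")
  }
  canon <- sumstats_dialect("canonical")
  out <- setNames(as_tibble(dataset)[sumstats_cols], unname(canon[sumstats_cols]))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a labelled LD r-squared matrix
#'
#' Reads a delimited square matrix of pairwise r-squared values with rsID row
#' and column labels, validating symmetry (tolerance 1e-8), a unit diagonal
#' and entries in \[0, 1\].
#'
#' @param path file path (tab-delimited; first column holds row labels).
#' @return numeric matrix with rsID dimnames.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stop_config(paste0("file not found: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(raw[[1]])
  validate_ld_matrix(m)
}

#' @rdname read_ld_matrix
#' @param ld labelled square matrix to validate or write.
#' @export
validate_ld_matrix <- function(ld) {
  if (!is.matrix(ld) || nrow(ld) != ncol(ld)) stop_data("LD matrix must be square")
  if (is.null(rownames(ld)) || is.null(colnames(ld)) ||
      !identical(rownames(ld), colnames(ld))) {
    stop_data("LD matrix must carry identical rsID row and column labels")
  }
  if (any(!is.finite(ld)) || any(ld < 0) || any(ld > 1)) {
    stop_data("LD r-squared entries must lie in [0, 1]")
  }
  if (max(abs(ld - t(ld))) > 1e-8) stop_data("LD matrix is not symmetric")
  if (max(abs(diag(ld) - 1)) > 1e-8) stop_data("LD matrix diagonal must be 1")
  ld
}

#' @rdname read_ld_matrix
#' @export
write_ld_matrix <- function(ld, path) {
  ld <- validate_ld_matrix(ld)
  out <- tibble::tibble(rsid = rownames(ld))
  out <- dplyr::bind_cols(out, as_tibble(ld))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
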