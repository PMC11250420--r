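test_that("variance explained matches the direct arithmetic and its algebraic simplification", {
  expect_equal(snp_variance_explained(0.4, 0, 0.01, 1000), 0)
  expect_gt(snp_variance_explained(0.4, 0.02, 1e-9, 1000), 0.999)

  # direct arithmetic oracle, written out term by term
  eaf <- 0.3; beta <- 0.02; se <- 0.003; n <- 344182
  num <- 2 * eaf * (1 - eaf) * beta^2
  den <- num + 2 * eaf * (1 - eaf) * n * se^2
  expect_equal(snp_variance_explained(eaf, beta, se, n), num / den,
               tolerance = 1e-14)

  # algebraic simplification beta^2/(beta^2 + N se^2) agrees on random inputs
  set.seed(11)
  for (i in 1:50) {
    eaf <- runif(1, 0.01, 0.99); beta <- rnorm(1, 0, 0.05)
    se <- runif(1, 1e-4, 0.05); n <- sample(1000:500000, 1)
    expect_equal(snp_variance_explained(eaf, beta, se, n),
                 beta^2 / (beta^2 + n * se^2), tolerance = 1e-12)
  }
  expect_error(snp_variance_explained(0, 0.1, 0.01, 100),
               class = "targetmr_usage_error")
})

test_that("F statistic follows r2(n-2)/(1-r2) and is monotone", {
  expect_equal(snp_f_statistic(0, 1000), 0)
  expect_equal(snp_f_statistic(0.5, 4), 2)
  r2 <- snp_variance_explained(0.3, 0.02, 0.003, 344182)
  expect_equal(snp_f_statistic(r2, 344182), r2 * (344182 - 2) / (1 - r2),
               tolerance = 1e-12)
  expect_true(all(diff(snp_f_statistic(seq(0, 0.9, 0.1), 1000)) > 0))
  expect_error(snp_f_statistic(1, 1000), class = "targetmr_usage_error")
})

test_that("cis window is closed, chromosome-matched and p-filtered", {
  region <- gene_region("SLC5A2", "16", 31494323, 31502089, flank_kb = 1000)
  lo <- region$start - 1000 * 1000
  d <- make_sumstats(4, chrom = "16", start = lo, step = 1)
  dd <- tibble::as_tibble(d)
  dd$pos[2] <- lo - 1L                   # just outside
  dd$chrom[3] <- "22"                    # wrong chromosome, tiny p
  dd$pvalue[3] <- 1e-300
  dd$pvalue[4] <- 1e-6                   # above threshold
  d2 <- as_sumstats(dd)
  out <- select_cis_candidates(d2, region, p_threshold = 5e-8)
  expect_equal(out$rsid, "rs1")          # boundary SNP retained, others excluded

  wrong_build <- as_sumstats(dd, genome_build = "GRCh38")
  expect_error(select_cis_candidates(wrong_build, region, 5e-8),
               class = "targetmr_config_error")
})

test_that("cis candidate scan equals an exhaustive per-row oracle on 50 SNPs", {
  region <- gene_region("SLC5A1", "22", 32439248, 32509016, flank_kb = 500)
  set.seed(3)
  n <- 50
  raw <- tibble::tibble(
    rsid = sprintf("rs%03d", 1:n),
    chrom = sample(c("22", "16"), n, replace = TRUE),
    pos = as.integer(runif(n, 31.5e6, 33.5e6)),
    effect_allele = "A", other_allele = "G",
    eaf = runif(n, 0.05, 0.95), beta = rnorm(n, 0, 0.02),
    se = runif(n, 0.002, 0.01), pvalue = 10^runif(n, -12, -3), n = 344182
  )
  d <- as_sumstats(raw)
  got <- select_cis_candidates(d, region, 5e-7)
  keep <- vapply(seq_len(nrow(d)), function(i) {
    d$chrom[i] == "22" &&
      d$pos[i] >= 32439248 - 5e5 && d$pos[i] <= 32509016 + 5e5 &&
      d$pvalue[i] < 5e-7
  }, logical(1))
  expect_setequal(got$rsid, d$rsid[keep])
  expect_gt(nrow(got), 0)
})

test_that("clumping keeps the best of a linked close pair and respects the distance gate", {
  d <- make_sumstats(2, start = 31e6, step = 50e3)
  dd <- tibble::as_tibble(d)
  dd$pvalue <- c(1e-10, 1e-8)
  ld <- matrix(c(1, 1, 1, 1), 2, dimnames = list(dd$rsid, dd$rsid))
  out <- clump_snps(dd, ld, r2_thresh = 0.3, window_kb = 100)
  expect_equal(out$rsid, "rs1")

  far <- dd; far$pos[2] <- far$pos[1] + 500000L
  ld2 <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(far$rsid, far$rsid))
  out2 <- clump_snps(far, ld2, r2_thresh = 0.3, window_kb = 100)
  expect_equal(nrow(out2), 2)
})

test_that("clumping equals the brute-force greedy oracle on random instances", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 6
    cand <- tibble::tibble(
      rsid = sprintf("rs%d", 1:n), chrom = "1",
      pos = sort(as.integer(runif(n, 1e6, 1.4e6))),
      pvalue = 10^runif(n, -12, -6)
    )
    a <- matrix(runif(n * n), n)
    r2 <- (a + t(a)) / 2; diag(r2) <- 1
    dimnames(r2) <- list(cand$rsid, cand$rsid)
    got <- clump_snps(cand, r2, r2_thresh = 0.3, window_kb = 100)
    want <- oracle_clump(cand, r2, 0.3, 100)
    expect_identical(got$rsid, want$rsid)
  }
})

test_that("clumping is idempotent and order-invariant", {
  set.seed(5)
  n <- 10
  cand <- tibble::tibble(
    rsid = sprintf("rs%d", 1:n), chrom = "1",
    pos = sort(as.integer(runif(n, 1e6, 1.6e6))),
    pvalue = 10^runif(n, -12, -6)
  )
  a <- matrix(runif(n * n), n); r2 <- (a + t(a)) / 2; diag(r2) <- 1
  dimnames(r2) <- list(cand$rsid, cand$rsid)
  once <- clump_snps(cand, r2, 0.3, 100)
  twice <- clump_snps(once, r2, 0.3, 100)
  expect_identical(once$rsid, twice$rsid)
  shuffled <- clump_snps(cand[sample(n), ], r2, 0.3, 100)
  expect_identical(once$rsid, shuffled$rsid)
})

test_that("SNPs absent from the LD matrix clump as unlinked, with a warning", {
  d <- tibble::as_tibble(make_sumstats(3, step = 10e3))
  d$pvalue <- c(1e-10, 1e-9, 1e-8)
  ld <- matrix(1, 1, 1, dimnames = list("rs1", "rs1"))
  expect_warning(out <- clump_snps(d, ld, 0.3, 100), "absent from LD matrix")
  expect_equal(nrow(out), 3)
})

test_that("exclusion chain applies MAF, F, presence and outcome-p rules in order", {
  cand <- tibble::as_tibble(make_sumstats(5, pvalue = 1e-10))
  cand$eaf[1] <- 0.995                     # MAF 0.005 < 0.01
  cand$beta[2] <- 1e-4                     # weak: F < 10
  cand$se[2] <- 0.05
  out_d <- make_sumstats(5, beta = 0.001, se = 0.01, pvalue = 0.5,
                         trait = "outcome")
  out_t <- tibble::as_tibble(out_d)
  out_t <- out_t[out_t$rsid != "rs3", ]    # rs3 missing from outcome
  out_t$pvalue[out_t$rsid == "rs4"] <- 1e-6  # outcome p < 5e-5
  outcome <- as_sumstats(out_t, trait = "outcome")
  cfg <- selection_config(p_threshold = 5e-8)
  inst <- apply_exclusions(cand, outcome, cfg, exposure = "test")
  expect_equal(inst$rsid, "rs5")
  prov <- instrument_provenance(inst)
  expect_equal(prov$step, c("maf", "f_statistic", "outcome_presence", "outcome_pvalue"))
  expect_true(all(prov$n_after <= prov$n_before))
  expect_true(all(inst$f >= 10))
})

test_that("exclusions match an exhaustive rule-check oracle on planted violations", {
  set.seed(9)
  n <- 10
  cand <- tibble::as_tibble(make_sumstats(n, pvalue = 1e-10))
  cand$eaf <- runif(n, 0.05, 0.95)
  cand$eaf[3] <- 0.002
  cand$beta <- rnorm(n, 0.03, 0.005)
  cand$beta[5] <- 1e-5
  out_t <- tibble::as_tibble(make_sumstats(n, beta = 0.001, pvalue = 0.3,
                                           trait = "outcome"))
  out_t$pvalue[7] <- 1e-7
  out_t <- out_t[-9, ]
  outcome <- as_sumstats(out_t, trait = "outcome")
  cfg <- selection_config(p_threshold = 5e-8)
  inst <- apply_exclusions(cand, outcome, cfg, exposure = "test")
  survive <- vapply(seq_len(n), function(i) {
    maf <- min(cand$eaf[i], 1 - cand$eaf[i])
    r2 <- cand$beta[i]^2 / (cand$beta[i]^2 + cand$n[i] * cand$se[i]^2)
    f <- r2 * (cand$n[i] - 2) / (1 - r2)
    idx <- match(cand$rsid[i], outcome$rsid)
    maf >= 0.01 && f >= 10 && !is.na(idx) && outcome$pvalue[idx] >= 5e-5
  }, logical(1))
  expect_setequal(inst$rsid, cand$rsid[survive])
})

test_that("an emptied instrument set names the filter that emptied it", {
  cand <- tibble::as_tibble(make_sumstats(2))
  cand$eaf <- 0.001
  outcome <- make_sumstats(2, beta = 0.001, pvalue = 0.5, trait = "outcome")
  expect_error(
    apply_exclusions(cand, outcome, selection_config()),
    "no valid instruments.*maf"
  )
})

test_that("genome-wide selection masks excluded regions and equals a brute-force oracle", {
  set.seed(21)
  n <- 40
  raw <- tibble::tibble(
    rsid = sprintf("rs%03d", 1:n),
    chrom = sample(c("16", "22"), n, replace = TRUE),
    pos = as.integer(runif(n, 30e6, 34e6)),
    effect_allele = "A", other_allele = "G",
    eaf = runif(n, 0.05, 0.95), beta = rnorm(n, 0, 0.04),
    se = runif(n, 0.002, 0.006), pvalue = 10^runif(n, -60, -4), n = 344182
  )
  d <- as_sumstats(raw)
  regions <- list(
    gene_region("SLC5A1", "22", 32439248, 32509016, flank_kb = 500),
    gene_region("SLC5A2", "16", 31494323, 31502089, flank_kb = 1000)
  )
  cfg <- selection_config(mode = "genome_wide", p_threshold = 5e-8,
                          clump_r2 = 0.001, clump_window_kb = 10000,
                          excluded_regions = regions)
  outcome <- as_sumstats(dplyr::mutate(raw, beta = 0.001, pvalue = 0.5),
                         trait = "outcome")
  ld <- simulate_ld_block(raw$rsid, block_size = 1, rho = 0)
  inst <- select_genome_wide(d, outcome, ld, cfg)

  # brute-force restatement: p filter, region mask, strict-distance clump
  keep <- raw$pvalue < 5e-8
  for (reg in regions) {
    lo <- reg$start - reg$flank_kb * 1000; hi <- reg$end + reg$flank_kb * 1000
    keep <- keep & !(raw$chrom == reg$chrom & raw$pos >= lo & raw$pos <= hi)
  }
  cand <- raw[keep, ]
  want <- oracle_clump(as.data.frame(cand), ld, 0.001, 10000)
  # then MAF/F/outcome rules (all pass by construction except weak betas)
  ok <- vapply(seq_len(nrow(want)), function(i) {
    r2 <- want$beta[i]^2 / (want$beta[i]^2 + want$n[i] * want$se[i]^2)
    f <- r2 * (want$n[i] - 2) / (1 - r2)
    min(want$eaf[i], 1 - want$eaf[i]) >= 0.01 && f >= 10
  }, logical(1))
  expect_setequal(inst$rsid, want$rsid[ok])
  expect_error(
    select_genome_wide(d, outcome, ld, selection_config(mode = "genome_wide")),
    class = "targetmr_config_error"
  )
})

test_that("packaged gene regions load for both builds with the study flanks", {
  for (build in c("GRCh37", "GRCh38")) {
    regs <- load_gene_regions(genome_build = build)
    expect_setequal(names(regs), c("SLC5A1", "SLC5A2"))
    expect_equal(regs$SLC5A1$flank_kb, 500)
    expect_equal(regs$SLC5A2$flank_kb, 1000)
  }
})
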