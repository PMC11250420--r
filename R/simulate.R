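#' Configuration for the two-sample summary-statistics generator
#'
#' Describes a synthetic two-sample MR study. Per variant `j`, a minor
#' allele frequency is drawn uniformly from `maf_range` and a true exposure
#' effect `gamma_j ~ Normal(0, gamma_sd^2)`. Summary-level sampling error
#' uses the standard single-variant approximation
#' `se = 1/sqrt(2 maf (1-maf) n)` for a unit-variance trait, in each sample
#' separately. The true outcome effect is `theta * gamma_j + alpha_j`, where
#' the pleiotropic effect `alpha_j` is 0 (`none`), `Normal(0, sigma_alpha^2)`
#' (`balanced`), or `Normal(mu_alpha, sigma_alpha^2)` (`directional`);
#' variants listed in `outlier_idx` get a fixed large pleiotropic effect
#' instead, emulating single-variant exclusion-restriction violations.
#' Directional pleiotropy is oriented relative to the exposure-raising
#' allele (its sign follows `sign(gamma_j)`), matching how two-sample MR
#' conventions orient instruments before an Egger fit; balanced pleiotropy
#' is symmetric so orientation does not matter.
#' Outcome effects are on the log-odds scale throughout; no individual-level
#' case-control data are simulated.
#'
#' @param n_snps number of variants J.
#' @param theta true causal effect (log-odds per exposure unit).
#' @param n_exp,n_out exposure and outcome GWAS sample sizes. For a binary
#'   outcome `n_out` plays the role of the effective sample size
#'   `4 v (1-v) n` at case fraction `v`, since outcome effects are
#'   simulated directly on the log-odds scale.
#' @param maf_range interval within (0, 0.5] for minor-allele frequencies.
#' @param gamma_sd SD of true per-variant exposure effects (normal regime).
#' @param gamma_dist `"normal"` draws `gamma_j ~ Normal(0, gamma_sd^2)` — the
#'   unselected genetic architecture; `"selected"` draws magnitudes
#'   uniformly from `gamma_range` with random signs, emulating an
#'   instrument set that has already passed a strength screen (an F filter
#'   leaves no near-zero effects).
#' @param gamma_range magnitude range for the selected regime.
#' @param pleiotropy `"none"`, `"balanced"` or `"directional"`.
#' @param mu_alpha mean pleiotropic effect (directional regime).
#' @param sigma_alpha SD of pleiotropic effects (balanced/directional).
#' @param pleiotropy_frac fraction of variants carrying pleiotropy in the
#'   balanced/directional regimes (the rest are valid instruments).
#' @param outlier_idx integer indices of planted outlier variants.
#' @param outlier_alpha pleiotropic effect given to each planted outlier;
#'   recycled. The default, `NULL`, sets each outlier's effect to 10 times
#'   its outcome standard error.
#' @param palindromic_rate fraction of variants assigned A/T or C/G allele
#'   pairs (exercises harmonization).
#' @param eaf_noise_sd SD of noise added to outcome-study frequencies.
#' @param ld_blocks optional list `list(block_size =, rho =)` describing
#'   block LD for [simulate_ld_block()].
#' @param chrom,region_start,region_span where to place the variants
#'   (uniformly in `[region_start, region_start + region_span]`).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_snps = 15, theta = 0, n_exp = 344182, n_out = 50000,
                       maf_range = c(0.05, 0.5), gamma_sd = 0.025,
                       gamma_dist = c("normal", "selected"),
                       gamma_range = c(0.02, 0.06),
                       pleiotropy = c("none", "balanced", "directional"),
                       mu_alpha = 0, sigma_alpha = 0.01, pleiotropy_frac = 1,
                       outlier_idx = integer(), outlier_alpha = NULL,
                       palindromic_rate = 0.1, eaf_noise_sd = 0,
                       ld_blocks = NULL, chrom = "16",
                       region_start = 30000000L, region_span = 2000000L) {
  pleiotropy <- match.arg(pleiotropy)
  gamma_dist <- match.arg(gamma_dist)
  stopifnot(n_snps >= 1, gamma_sd >= 0, sigma_alpha >= 0,
            gamma_range[1] >= 0, gamma_range[1] <= gamma_range[2],
            maf_range[1] > 0, maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
            pleiotropy_frac >= 0, pleiotropy_frac <= 1)
  if (length(outlier_idx) > 0 && (any(outlier_idx < 1) || any(outlier_idx > n_snps))) {
    stop_config("outlier_idx out of range")
  }
  structure(
    list(n_snps = as.integer(n_snps), theta = theta, n_exp = n_exp, n_out = n_out,
         maf_range = maf_range, gamma_sd = gamma_sd, gamma_dist = gamma_dist,
         gamma_range = gamma_range, pleiotropy = pleiotropy,
         mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
         pleiotropy_frac = pleiotropy_frac,
         outlier_idx = as.integer(outlier_idx), outlier_alpha = outlier_alpha,
         palindromic_rate = palindromic_rate, eaf_noise_sd = eaf_noise_sd,
         ld_blocks = ld_blocks, chrom = as.character(chrom),
         region_start = region_start, region_span = region_span),
    class = "sim_config"
  )
}

ALLELE_PAIRS <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
PALINDROMIC_PAIRS <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulate two-sample GWAS summary statistics with known ground truth
#'
#' Draws exposure and outcome summary datasets from the generative model in
#' [sim_config()], plus the simulation truth (true per-variant exposure
#' effects, pleiotropic effects, causal effect, outlier indices). Identical
#' seed and config give byte-identical output.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `exposure` and `outcome` (`sumstats` tibbles) and
#'   `truth` (list: `gamma`, `alpha`, `theta`, `outlier_idx`, `maf`).
#' @export
simulate_two_sample <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed)) stop_usage("simulate_two_sample requires an explicit seed")
  J <- config$n_snps
  with_seed(seed, {
    maf <- runif(J, config$maf_range[1], config$maf_range[2])
    pos <- sort(sample.int(config$region_span, J)) + config$region_start
    rsid <- sprintf("rs%07d", sample.int(9999999L, J))
    pal <- runif(J) < config$palindromic_rate
    pair_idx <- sample.int(4L, J, replace = TRUE)
    alleles <- t(vapply(seq_len(J), function(j) {
      if (pal[j]) unlist(PALINDROMIC_PAIRS[pair_idx[j]]) else unlist(ALLELE_PAIRS[pair_idx[j]])
    }, character(2)))

    gamma <- if (config$gamma_dist == "selected") {
      sample(c(-1, 1), J, replace = TRUE) *
        runif(J, config$gamma_range[1], config$gamma_range[2])
    } else {
      rnorm(J, 0, config$gamma_sd)
    }
    alpha <- rep(0, J)
    if (config$pleiotropy != "none") {
      # exactly round(frac * J) carriers, so a sub-half nominal fraction
      # cannot drift above half of the instruments in any one replicate
      carrier <- rep(FALSE, J)
      carrier[sample.int(J, round(config$pleiotropy_frac * J))] <- TRUE
      if (config$pleiotropy == "directional") {
        # oriented to the exposure-raising allele of each variant
        orient <- ifelse(gamma[carrier] < 0, -1, 1)
        alpha[carrier] <- orient * rnorm(sum(carrier), config$mu_alpha,
                                         config$sigma_alpha)
      } else {
        alpha[carrier] <- rnorm(sum(carrier), 0, config$sigma_alpha)
      }
    }
    se_out <- 1 / sqrt(2 * maf * (1 - maf) * config$n_out)
    if (length(config$outlier_idx) > 0) {
      oa <- config$outlier_alpha %||% (10 * se_out[config$outlier_idx])
      alpha[config$outlier_idx] <- rep(oa, length.out = length(config$outlier_idx))
    }
    se_exp <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exp)
    beta_exp <- rnorm(J, gamma, se_exp)
    beta_out <- rnorm(J, config$theta * gamma + alpha, se_out)
    eaf_out <- maf + if (config$eaf_noise_sd > 0) rnorm(J, 0, config$eaf_noise_sd) else 0
    eaf_out <- pmin(pmax(eaf_out, 1e-4), 1 - 1e-4)

    mk <- function(beta, se, eaf, n, trait) {
      as_sumstats(tibble(
        rsid = rsid, chrom = config$chrom, pos = pos,
        effect_allele = alleles[, 1], other_allele = alleles[, 2],
        eaf = eaf, beta = beta, se = se,
        pvalue = pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin),
        n = n
      ), trait = trait, genome_build = "GRCh37", ancestry = "EUR")
    }
    list(
      exposure = mk(beta_exp, se_exp, maf, config$n_exp, "synthetic_exposure"),
      outcome = mk(beta_out, se_out, eaf_out, config$n_out, "synthetic_outcome"),
      truth = list(gamma = gamma,
                   # pleiotropic effects reported in the exposure-raising
                   # frame, where "directional" has mean mu_alpha
                   alpha = ifelse(gamma < 0, -alpha, alpha),
                   theta = config$theta,
                   outlier_idx = config$outlier_idx, maf = maf, rsid = rsid)
    )
  })
}

#' Pair up a simulated two-sample study for direct estimation
#'
#' The generator emits exposure and outcome effects that are already aligned
#' on the same effect allele, so estimator-level studies can skip selection
#' and harmonization and work on the paired effects directly. Joins the two
#' datasets by rsid in exposure order.
#'
#' @param sim result of [simulate_two_sample()].
#' @return harmonized-pairs tibble (`rsid`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`, `eaf_exp`, `eaf_out`).
#' @export
pairs_from_sim <- function(sim) {
  i <- match(sim$exposure$rsid, sim$outcome$rsid)
  tibble(
    rsid = sim$exposure$rsid,
    beta_exp = sim$exposure$beta, se_exp = sim$exposure$se,
    beta_out = sim$outcome$beta[i], se_out = sim$outcome$se[i],
    eaf_exp = sim$exposure$eaf, eaf_out = sim$outcome$eaf[i]
  )
}

#' Simulate a block-structured LD r-squared matrix
#'
#' Builds a block-diagonal matrix where within a block of consecutive
#' variants the r-squared between variants `i` and `j` is `rho^|i-j|`, and
#' variants in different blocks are unlinked. With `rho = 0` this is the
#' identity matrix.
#'
#' @param rsids variant identifiers, in order.
#' @param block_size number of consecutive variants per block.
#' @param rho within-block correlation decay base, in `[0, 1)`.
#' @return labelled r-squared matrix passing [validate_ld_matrix()].
#' @export
simulate_ld_block <- function(rsids, block_size = 5, rho = 0.8) {
  if (!is_scalar_number(rho) || rho < 0 || rho >= 1) {
    stop_usage("rho must lie in [0, 1)")
  }
  J <- length(rsids)
  m <- matrix(0, J, J, dimnames = list(rsids, rsids))
  blocks <- split(seq_len(J), (seq_len(J) - 1) %/% block_size)
  for (b in blocks) {
    d <- abs(outer(seq_along(b), seq_along(b), "-"))
    m[b, b] <- rho^d
  }
  validate_ld_matrix(m)
}

#' Named simulation scenario presets
#'
#' Documented study regimes used throughout the test battery. All presets
#' except `weak_instruments` emulate a *post-selection* instrument set: per-
#' variant exposure effects are drawn from the selected-magnitude regime
#' (see [sim_config()]), since an instrument set that passed an F screen
#' contains no near-null effects:
#' \describe{
#'   \item{null}{no causal effect, 15 strong clean instruments.}
#'   \item{causal_clean}{theta = 0.5 with 18 strong valid instruments — the
#'     scale of a well-powered drug-target instrument set.}
#'   \item{directional_pleiotropy}{theta = 0.5 with 40% of instruments
#'     carrying directional pleiotropy (mean 0.02) — under half the weight
#'     invalid, the weighted median's home regime.}
#'   \item{single_outlier}{theta = 0.5, 10 instruments, one with a
#'     pleiotropic effect 10 times its outcome standard error — the
#'     single-outlier situation MR-PRESSO targets.}
#'   \item{weak_instruments}{small true exposure effects and a small
#'     exposure sample, so most variants fail the F >= 10 screen.}
#'   \item{drug_target_cis}{protective causal effect (theta = -0.5) with 12
#'     cis instruments in one LD region — the drug-target analysis scale
#'     (real sets ran 8–18 variants).}
#' }
#'
#' @param name preset name.
#' @return a [sim_config()].
#' @export
scenario_preset <- function(name = c("null", "causal_clean",
                                     "directional_pleiotropy", "single_outlier",
                                     "weak_instruments", "drug_target_cis")) {
  name <- match.arg(name)
  switch(name,
    null = sim_config(n_snps = 15, theta = 0, gamma_dist = "selected"),
    causal_clean = sim_config(n_snps = 18, theta = 0.5, gamma_dist = "selected"),
    directional_pleiotropy = sim_config(
      n_snps = 18, theta = 0.5, gamma_dist = "selected",
      pleiotropy = "directional", mu_alpha = 0.02, sigma_alpha = 0.005,
      pleiotropy_frac = 0.4
    ),
    single_outlier = sim_config(
      n_snps = 10, theta = 0.5, gamma_dist = "selected", outlier_idx = 7L
    ),
    weak_instruments = sim_config(
      n_snps = 15, theta = 0.5, gamma_sd = 0.004, n_exp = 20000
    ),
    drug_target_cis = sim_config(
      n_snps = 12, theta = -0.5, gamma_dist = "selected",
      ld_blocks = list(block_size = 4, rho = 0.5), palindromic_rate = 0.15
    )
  )
}
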