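# Shared fixtures, built in code. All randomness is seeded per call site.

# A small deterministic sumstats tibble with hand-set fields.
make_sumstats <- function(n = 5, chrom = "16", start = 31e6, step = 50e3,
                          pvalue = 1e-10, eaf = 0.3, beta = 0.02, se = 0.003,
                          nsamp = 344182, trait = "hba1c") {
  as_sumstats(tibble::tibble(
    rsid = sprintf("rs%d", seq_len(n)),
    chrom = chrom,
    pos = as.integer(start + step * (seq_len(n) - 1)),
    effect_allele = rep(c("A", "C", "G", "T"), length.out = n),
    other_allele = rep(c("G", "T", "A", "C"), length.out = n),
    eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = nsamp
  ), trait = trait)
}

# Harmonized-pairs tibble straight from numbers.
make_pairs <- function(beta_exp, beta_out, se_exp = 0.01, se_out = 0.01,
                       rsid = sprintf("rs%d", seq_along(beta_exp))) {
  tibble::tibble(
    rsid = rsid,
    beta_exp = beta_exp, se_exp = rep_len(se_exp, length(beta_exp)),
    beta_out = beta_out, se_out = rep_len(se_out, length(beta_exp)),
    eaf_exp = 0.3, eaf_out = 0.3
  )
}

# Independent brute-force greedy clumping oracle: literal restatement of the
# rule, no shared code with clump_snps().
oracle_clump <- function(cand, r2mat, r2_thresh, window_kb) {
  cand <- cand[order(cand$pvalue, cand$pos, cand$rsid), ]
  kept <- cand[0, ]
  while (nrow(cand) > 0) {
    top <- cand[1, ]
    kept <- rbind(kept, top)
    cand <- cand[-1, , drop = FALSE]
    if (nrow(cand) == 0) break
    drop <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      r2 <- if (top$rsid %in% rownames(r2mat) && cand$rsid[i] %in% rownames(r2mat)) {
        r2mat[top$rsid, cand$rsid[i]]
      } else 0
      drop[i] <- cand$chrom[i] == top$chrom &&
        r2 > r2_thresh &&
        abs(cand$pos[i] - top$pos) <= window_kb * 1000
    }
    cand <- cand[!drop, , drop = FALSE]
  }
  kept[order(kept$chrom, kept$pos), ]
}

# Independent weighted-median oracle: explicit cumulative-weight walk.
oracle_weighted_median <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(r[1])
  for (k in seq_along(cum)[-1]) {
    if (cum[k] >= 0.5) {
      return(r[k - 1] + (r[k] - r[k - 1]) * (0.5 - cum[k - 1]) / (cum[k] - cum[k - 1]))
    }
  }
  r[length(r)]
}
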