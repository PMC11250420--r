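test_that("wald ratio follows the delta-method arithmetic", {
  p <- make_pairs(0.1, 0.05, se_out = 0.02)
  w <- mr_wald_ratio(p)
  expect_equal(w$estimate, 0.5)
  expect_equal(w$se, 0.2)
  null <- mr_wald_ratio(make_pairs(0.1, 0))
  expect_equal(null$estimate, 0)
  expect_equal(null$or, 1)

  set.seed(2)
  for (i in 1:20) {
    bx <- rnorm(1, 0.05, 0.02); by <- rnorm(1, 0, 0.03); so <- runif(1, 0.005, 0.05)
    if (bx == 0) next
    got <- mr_wald_ratio(make_pairs(bx, by, se_out = so))
    expect_equal(got$estimate, by / bx, tolerance = 1e-12)
    expect_equal(got$se, so / abs(bx), tolerance = 1e-12)
    expect_equal(got$pvalue, 2 * pnorm(-abs((by / bx) / (so / abs(bx)))),
                 tolerance = 1e-12)
  }
  expect_error(mr_wald_ratio(make_pairs(0, 0.1)), class = "targetmr_usage_error")
})

test_that("IVW equals the closed-form sums and the weighted-lm oracle", {
  set.seed(12)
  for (i in 1:10) {
    J <- 5
    p <- make_pairs(rnorm(J, 0.05, 0.02), rnorm(J, 0.02, 0.03),
                    se_out = runif(J, 0.005, 0.05))
    got <- mr_ivw(p, model = "fixed")
    w <- 1 / p$se_out^2
    expect_equal(got$estimate,
                 sum(w * p$beta_exp * p$beta_out) / sum(w * p$beta_exp^2),
                 tolerance = 1e-10)
    # independent oracle: weighted regression through the origin via lm
    fit <- lm(beta_out ~ 0 + beta_exp, data = p, weights = w)
    expect_equal(got$estimate, unname(coef(fit)), tolerance = 1e-10)
    expect_equal(got$se, sqrt(1 / sum(w * p$beta_exp^2)), tolerance = 1e-10)
  }
})

test_that("single-pair IVW reduces to the Wald ratio", {
  p <- make_pairs(0.08, 0.03, se_out = 0.015)
  ivw <- mr_ivw(p)
  wald <- mr_wald_ratio(p)
  expect_equal(ivw$estimate, wald$estimate)
  expect_equal(ivw$se, wald$se)
})

test_that("exactly collinear pairs give the line's slope, zero Q and equal fixed/random SEs", {
  p <- make_pairs(c(0.02, 0.05, 0.08, 0.1), c(0.02, 0.05, 0.08, 0.1) * 0.7)
  fixed <- mr_ivw(p, model = "fixed")
  random <- mr_ivw(p, model = "multiplicative_random")
  expect_equal(fixed$estimate, 0.7, tolerance = 1e-12)
  expect_equal(fixed$se, random$se)
  q <- mr_cochran_q(p)
  expect_equal(q$Q, 0, tolerance = 1e-18)
  expect_equal(q$pvalue, 1)
})

test_that("random-effects IVW never reports a smaller SE than fixed", {
  set.seed(14)
  for (i in 1:20) {
    J <- sample(3:12, 1)
    p <- make_pairs(rnorm(J, 0.05, 0.02), rnorm(J, 0.02, 0.05),
                    se_out = runif(J, 0.005, 0.05))
    expect_gte(mr_ivw(p)$se, mr_ivw(p, model = "fixed")$se)
  }
})

test_that("Egger slope, intercept and SEs equal the weighted-lm oracle", {
  set.seed(15)
  for (i in 1:10) {
    J <- 8
    bx <- abs(rnorm(J, 0.06, 0.02))
    by <- 0.01 + 0.4 * bx + rnorm(J, 0, 0.01)
    p <- make_pairs(bx, by, se_out = runif(J, 0.005, 0.03))
    got <- mr_egger(p)
    w <- 1 / p$se_out^2
    fit <- lm(by ~ bx, weights = w)
    expect_equal(got$slope$estimate, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(got$intercept$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
    # lm's SEs use the residual scale without the floor at 1; rescale
    sm <- summary(fit)
    scale_lm <- sm$sigma
    scale_pkg <- max(1, scale_lm)
    expect_equal(got$slope$se, sm$coefficients[2, 2] / scale_lm * scale_pkg,
                 tolerance = 1e-8)
    expect_equal(got$intercept$se, sm$coefficients[1, 2] / scale_lm * scale_pkg,
                 tolerance = 1e-8)
  }
})

test_that("exact linear pairs give Egger intercept a, slope b, zero residual heterogeneity", {
  bx <- c(0.02, 0.04, 0.07, 0.09, 0.12)
  p <- make_pairs(bx, 0.01 + 0.5 * bx)
  got <- mr_egger(p)
  expect_equal(got$slope$estimate, 0.5, tolerance = 1e-10)
  expect_equal(got$intercept$intercept, 0.01, tolerance = 1e-10)
  expect_equal(got$heterogeneity$Q, 0, tolerance = 1e-16)
})

test_that("Egger is invariant to negating any one pair's effect directions", {
  set.seed(16)
  J <- 8
  p <- make_pairs(rnorm(J, 0.05, 0.03), rnorm(J, 0.03, 0.02))
  base <- mr_egger(p)
  for (j in c(1, 4, 8)) {
    q <- p
    q$beta_exp[j] <- -q$beta_exp[j]
    q$beta_out[j] <- -q$beta_out[j]
    got <- mr_egger(q)
    expect_equal(got$slope$estimate, base$slope$estimate, tolerance = 1e-12)
    expect_equal(got$intercept$intercept, base$intercept$intercept,
                 tolerance = 1e-12)
  }
  expect_error(mr_egger(make_pairs(c(0.1, 0.2), c(0.1, 0.2))),
               class = "targetmr_usage_error")
})

test_that("weighted median interpolates the 0.5 weight crossing", {
  # equal weights, ratios {0.2, 0.5, 0.9}: plain median
  p <- make_pairs(c(0.1, 0.1, 0.1), c(0.02, 0.05, 0.09))
  got <- mr_weighted_median(p, n_boot = 200, seed = 1)
  expect_equal(got$estimate, 0.5, tolerance = 1e-12)

  # identical ratios: estimate equals the ratio regardless of weights
  p2 <- make_pairs(c(0.02, 0.1, 0.3), c(0.02, 0.1, 0.3) * 0.4,
                   se_out = c(0.01, 0.02, 0.05))
  expect_equal(mr_weighted_median(p2, n_boot = 200, seed = 1)$estimate, 0.4,
               tolerance = 1e-12)

  # unequal weights: matches the independent cumulative-weight oracle
  set.seed(17)
  for (i in 1:10) {
    J <- 7
    p3 <- make_pairs(rnorm(J, 0.08, 0.02), rnorm(J, 0.04, 0.03),
                     se_out = runif(J, 0.005, 0.05))
    got <- mr_weighted_median(p3, n_boot = 100, seed = 2)
    want <- oracle_weighted_median(p3$beta_out / p3$beta_exp,
                                   (p3$beta_exp / p3$se_out)^2)
    expect_equal(got$estimate, want, tolerance = 1e-12)
  }
  expect_error(mr_weighted_median(p, n_boot = 10),
               class = "targetmr_usage_error")  # missing seed
})

test_that("weighted median bootstrap SE is reproducible under a fixed seed", {
  set.seed(18)
  p <- make_pairs(rnorm(6, 0.07, 0.02), rnorm(6, 0.035, 0.02))
  a <- mr_weighted_median(p, n_boot = 300, seed = 99)
  b <- mr_weighted_median(p, n_boot = 300, seed = 99)
  expect_identical(a$se, b$se)
})

test_that("Cochran's Q follows the summation formula and its scaling law", {
  set.seed(19)
  J <- 6
  p <- make_pairs(rnorm(J, 0.06, 0.02), rnorm(J, 0.05, 0.04),
                  se_out = runif(J, 0.01, 0.04))
  est <- mr_ivw(p, model = "fixed")$estimate
  got <- mr_cochran_q(p, estimate = est)
  want <- sum((p$beta_exp / p$se_out)^2 * (p$beta_out / p$beta_exp - est)^2)
  expect_equal(got$Q, want, tolerance = 1e-10)
  expect_equal(got$df, J - 1L)
  expect_equal(got$pvalue, pchisq(want, J - 1, lower.tail = FALSE))

  # doubling every outcome SE quarters Q (at the same reference estimate)
  p2 <- p; p2$se_out <- 2 * p$se_out
  expect_equal(mr_cochran_q(p2, estimate = est)$Q, got$Q / 4, tolerance = 1e-10)
})

test_that("leave-one-out matches per-subset IVW and flags a planted outlier", {
  p <- make_pairs(c(0.1, 0.2), c(0.05, 0.1))
  loo <- mr_leave_one_out(p)
  expect_equal(nrow(loo), 2)
  expect_equal(loo$estimate[loo$omitted_rsid == "rs1"],
               mr_wald_ratio(p[2, ])$estimate)
  expect_equal(loo$estimate[loo$omitted_rsid == "rs2"],
               mr_wald_ratio(p[1, ])$estimate)

  # homogeneous pairs: every omission gives the common slope
  hom <- make_pairs(seq(0.02, 0.1, length.out = 5),
                    seq(0.02, 0.1, length.out = 5) * 0.3)
  loo_hom <- mr_leave_one_out(hom)
  expect_true(all(abs(loo_hom$estimate - 0.3) < 1e-12))

  # planted outlier: omitting it moves the estimate closest to truth
  sim <- simulate_two_sample(scenario_preset("single_outlier"), seed = 77)
  pairs <- pairs_from_sim(sim)
  loo2 <- mr_leave_one_out(pairs)
  errs <- abs(loo2$estimate - sim$truth$theta)
  outlier_rsid <- sim$truth$rsid[sim$truth$outlier_idx]
  expect_equal(loo2$omitted_rsid[which.min(errs)], outlier_rsid)
})

test_that("odds-ratio conversion exponentiates the normal interval", {
  z <- to_odds_ratio(0, 0.1)
  expect_equal(z$or, 1)
  expect_equal(z$or_ci_low * z$or_ci_high, 1, tolerance = 1e-12)
  expect_equal(to_odds_ratio(log(2), 0)$or, 2)
  got <- to_odds_ratio(-0.755, 0.18, 0.95)
  q <- qnorm(0.975)
  expect_equal(got$or, exp(-0.755), tolerance = 1e-12)
  expect_equal(got$or_ci_low, exp(-0.755 - q * 0.18), tolerance = 1e-12)
  expect_equal(got$or_ci_high, exp(-0.755 + q * 0.18), tolerance = 1e-12)
  expect_error(to_odds_ratio(0, 1, level = 1), class = "targetmr_usage_error")
})

test_that("all estimators are invariant to the ordering of input pairs", {
  set.seed(23)
  J <- 9
  p <- make_pairs(rnorm(J, 0.06, 0.02), rnorm(J, 0.03, 0.03),
                  se_out = runif(J, 0.01, 0.04))
  perm <- p[sample(J), ]
  expect_equal(mr_ivw(perm)$estimate, mr_ivw(p)$estimate, tolerance = 1e-12)
  expect_equal(mr_egger(perm)$slope$estimate, mr_egger(p)$slope$estimate,
               tolerance = 1e-12)
  expect_equal(
    mr_weighted_median(perm, n_boot = 50, seed = 4)$estimate,
    mr_weighted_median(p, n_boot = 50, seed = 4)$estimate,
    tolerance = 1e-12
  )
  expect_equal(mr_cochran_q(perm)$Q, mr_cochran_q(p)$Q, tolerance = 1e-12)
})

test_that("weighted median resists directional contamination better than IVW", {
  # With 40% of instruments carrying one-sided pleiotropy, the weighted
  # median's finite-noise bias is bounded by the valid-ratio spread at the
  # shifted weight crossing, while IVW absorbs the full contaminated weight.
  closer <- 0; n_rep <- 100
  for (s in seq_len(n_rep)) {
    sim <- simulate_two_sample(scenario_preset("directional_pleiotropy"),
                               seed = 7000 + s)
    p <- pairs_from_sim(sim)
    wm <- mr_weighted_median(p, n_boot = 2, seed = s)$estimate
    ivw <- mr_ivw(p)$estimate
    if (abs(wm - 0.5) < abs(ivw - 0.5)) closer <- closer + 1
  }
  expect_gte(closer / n_rep, 0.75)

  # and it is consistent: in the low-sampling-noise limit the planted
  # contamination is the only error and the estimate converges to theta
  lown <- sim_config(n_snps = 18, theta = 0.5, gamma_dist = "selected",
                     pleiotropy = "directional", mu_alpha = 0.02,
                     sigma_alpha = 0.005, pleiotropy_frac = 0.4,
                     n_exp = 5e7, n_out = 5e7)
  est <- vapply(1:60, function(s) {
    sim <- simulate_two_sample(lown, seed = 8000 + s)
    p <- pairs_from_sim(sim)
    # the guarantee is conditional on valid instruments holding >50% of the
    # weight; weights are random, so condition on the premise explicitly
    w <- (p$beta_exp / p$se_out)^2
    if (sum(w[sim$truth$alpha != 0]) / sum(w) >= 0.5) return(NA_real_)
    mr_weighted_median(p, n_boot = 2, seed = s)$estimate
  }, numeric(1))
  expect_lt(abs(mean(est, na.rm = TRUE) - 0.5), 0.02)
})

test_that("mr_analysis assembles the battery and degrades gracefully below minimums", {
  sim <- simulate_two_sample(scenario_preset("causal_clean"), seed = 5)
  fit <- mr_analysis(pairs_from_sim(sim), seed = 1)
  expect_setequal(fit$results$method, c("ivw", "egger", "weighted_median"))
  expect_equal(fit$results$or, exp(fit$results$estimate))
  expect_true(all(fit$results$ci_low < fit$results$ci_high))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  gl <- glance(fit)
  expect_equal(gl$nsnp, 18)

  two <- mr_analysis(pairs_from_sim(sim)[1:2, ], seed = 1)
  expect_equal(two$results$method, "ivw")
  expect_true(length(two$skipped) > 0)
  one <- mr_analysis(pairs_from_sim(sim)[1, ], seed = 1)
  expect_equal(one$results$method, "wald_ratio")
})
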