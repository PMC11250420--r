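---
title: "Drug-target Mendelian randomization with targetmr: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization with targetmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

## The causal model

Two-sample Mendelian randomization (MR) treats genetic variants as
instrumental variables for a modifiable exposure. For variant $j$ with
per-allele effect $\hat\beta_{Xj}$ (standard error $\sigma_{Xj}$) on the
exposure in one GWAS and effect $\hat\beta_{Yj}$ ($\sigma_{Yj}$, log-odds
for a disease outcome) in an independent GWAS, the working model is

$$\hat\beta_{Yj} = \theta\,\beta_{Xj} + \alpha_j + \epsilon_j,$$

where $\theta$ is the causal effect of the exposure on the outcome
(log-odds per exposure unit) and $\alpha_j$ is the direct (horizontally
pleiotropic) effect of variant $j$, which is zero for a valid instrument.

*Drug-target* MR restricts the instruments to variants in or near the gene
encoding a drug target, so that $\theta$ proxies pharmacological modulation
of that target. The motivating application is SGLT1/SGLT2 inhibition:
variants within ±500 kb of *SLC5A1* or ±1000 kb of *SLC5A2* that associate
with HbA1c proxy the glucose-lowering action of gliflozin-class drugs, and
their harmonized effects on disease outcomes estimate the causal effect of
that inhibition.

## Instrument construction

`select_cis_instruments()` applies, in order:

1. **cis window + significance.** Variants on the gene's chromosome inside
   the *closed* interval $[\mathrm{start}-\mathrm{flank},\,
   \mathrm{end}+\mathrm{flank}]$ with association $p$ below the threshold.
   The window boundary is treated as inclusive — "within ±500 kb" reads
   naturally as a closed interval, and boundary variants are vanishingly
   rare either way. Thresholds are per-target configuration: the SGLT1
   design used $5\times10^{-7}$ (a deliberately relaxed cut labelled
   genome-wide significance in the source analysis — the conventional
   $5\times10^{-8}$ would leave too few *SLC5A1* variants), SGLT2
   $5\times10^{-8}$.
2. **Greedy LD clumping.** Repeatedly keep the smallest-$p$ remaining
   variant and discard remaining variants with $r^2$ above the threshold
   *and* distance within the window (defaults $r^2 > 0.3$, 100 kb; a
   stricter $r^2 > 0.1$ override reproduces sensitivity re-selections, and
   genome-wide mode uses $r^2 > 0.001$ over 10,000 kb as appropriate when
   candidates span the genome). Ties in $p$ break by position then rsid,
   making the output deterministic and order-invariant. Pairs absent from
   the LD reference are treated as unlinked with a warning — reference
   panels never cover every variant, and silent failure would be worse.
3. **Exclusions.** Minor-allele frequency $\ge 0.01$; instrument strength
   $F \ge 10$ where $R^2 = \frac{2f(1-f)\beta^2}{2f(1-f)\beta^2 +
   2f(1-f)N\sigma^2}$ (algebraically $\beta^2/(\beta^2+N\sigma^2)$) and
   $F = R^2(N-2)/(1-R^2)$; presence in the outcome GWAS; and outcome
   association $p \ge 5\times10^{-5}$, so no retained instrument is
   directly associated with the outcome (exclusion restriction). All
   inequalities are strict on the exclusion side, exactly as the design
   states them. Every step logs before/after counts into the instrument
   set's provenance.

Gene coordinates ship as an editable YAML fixture
(`inst/extdata/gene_regions.yaml`) per genome build rather than being
hard-coded; datasets are matched across studies by rsID only, never by
position, which makes a build mismatch between exposure (GRCh37-era
resources) and outcome (GRCh38 releases) harmless.

## Harmonization

`harmonize()` aligns outcome effects onto the exposure's effect allele:
identical pairs pass, swapped alleles negate the outcome beta and
complement its frequency, strand-complement labels are relabelled first.
Palindromic variants (A/T, C/G) carry no strand information, so in the
conservative default their orientation is inferred from allele-frequency
concordance when both frequencies lie outside the ambiguity band
[0.42, 0.58], and they are dropped as ambiguous otherwise (also when either
frequency is missing). The permissive mode assumes a shared strand. The
band and the conservative default follow common two-sample MR practice;
the source analysis names the alignment step but not its rules. Indels and
multi-allelic records are dropped as incompatible. Every action is logged
per variant.

## Estimators

All estimators consume the harmonized pairs table and return tidy one-row
results on both the log-odds and odds-ratio scales (95% CIs throughout).

- **Wald ratio** (1 variant): $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$,
  first-order SE $\sigma_{Yj}/|\hat\beta_{Xj}|$.
- **IVW** (primary): weighted regression of outcome on exposure effects
  through the origin, weights $1/\sigma_{Yj}^2$. The default
  *multiplicative random-effects* model inflates the fixed-effects SE by
  $\max\{1, \sqrt{Q/(J-1)}\}$, so it never claims more precision than the
  fixed-effects model; the fixed model is exposed as an option. P-values
  are two-sided normal. The random-effects default makes the reported test
  deliberately conservative under the null (rejection ~3.5% at nominal 5%
  in our calibration runs, versus ~4.5–5% for the exact fixed-effects
  test, which is the variant whose nominal calibration we assert in the
  acceptance suite).
- **MR-Egger**: weighted least squares *with* intercept after orienting
  all pairs to non-negative exposure effects; the intercept estimates mean
  directional pleiotropy, the slope is robust to it under InSIDE. Residual
  scale $\max\{1,\sqrt{\mathrm{RSS}/(J-2)}\}$ multiplies both SEs;
  inference uses $t_{J-2}$. Requires $J\ge3$.
- **Weighted median**: the weighted median of Wald ratios with weights
  proportional to inverse first-order ratio variance, interpolated at the
  0.5 crossing of standardized cumulative weights; SE by seeded parametric
  bootstrap (default 1,000 resamples; the seed is a mandatory argument so
  results are reproducible by construction). Requires $J\ge3$.
- **Cochran's Q**: $Q=\sum_j w_j(\hat\theta_j-\hat\theta)^2$ with
  $w_j=(\hat\beta_{Xj}/\sigma_{Yj})^2$, $\chi^2_{J-1}$ reference; the
  Egger-context heterogeneity is the Egger regression's weighted RSS on
  $\chi^2_{J-2}$.
- **Leave-one-out**: IVW re-estimated with each variant omitted.

## MR-PRESSO

`mr_presso()` implements the residual-sum-of-squares framework. The
observed statistic sums, over variants, the weighted squared deviation of
each outcome effect from the prediction of the leave-one-out IVW fit. The
Monte-Carlo null redraws exposure and outcome effects from normal
distributions with the reported SEs, expected outcome effects given by the
observed leave-one-out slopes, and recomputes the statistic identically;
the global empirical p is $(1+\#\{RSS^* \ge RSS\})/(n_{\mathrm{sim}}+1)$,
floored at $1/(n_{\mathrm{sim}}+1)$ so empirical p-values are never zero.
Per-variant outlier p-values compare each observed term with its own
simulated distribution and are Bonferroni-adjusted ($\times J$) before the
0.05 call — the source analysis names no multiplicity rule, and Bonferroni
is the conservative standard. The distortion test compares the relative
change in the IVW estimate after removing flagged outliers with the same
statistic under seeded random removal of equally many variants.
`run_presso_and_refit()` reruns the whole estimator battery on the reduced
set when outliers are found, reporting both passes; estimators whose
minimum count is no longer met are skipped with a logged reason.

Because the Monte-Carlo null conditions on the observed leave-one-out
slopes, it is coupled to the observed statistic and the global test is
conservative in the extreme tail (we measure ~0.5–1% rejection at nominal
5% under the null, with the bulk of the p distribution calibrated). This
conservatism is inherent to the published scheme, not an implementation
artifact; power against a planted outlier of 10 outcome-SE remains
essentially 1.

## The synthetic-data generator

`simulate_two_sample()` draws, per variant: minor-allele frequency
$f_j\sim U(\texttt{maf\_range})$; a true exposure effect $\gamma_j$; summary
sampling error with the single-variant approximation
$\sigma = 1/\sqrt{2f(1-f)n}$ in each sample; pleiotropy $\alpha_j$ by
regime; and observed effects
$\hat\beta_{Xj}\sim N(\gamma_j,\sigma_{Xj}^2)$,
$\hat\beta_{Yj}\sim N(\theta\gamma_j+\alpha_j,\sigma_{Yj}^2)$. Outcome
effects are log-odds throughout; for a binary outcome `n_out` plays the
role of the effective sample size $4v(1-v)n$, and the default 50,000
reflects a FinnGen-scale case-control outcome (the largest outcome in the
motivating study, type 2 diabetes, has effective size ~194,000; the
neurodegenerative outcomes are far smaller). The exposure default
`n_exp = 344182` matches a large biomarker GWAS.

Three generator choices deserve emphasis:

- **Selected instrument strengths.** All presets except
  `weak_instruments` draw $|\gamma_j|\sim U(0.02, 0.06)$ with random signs
  rather than a zero-centred normal: they emulate *post-selection*
  instrument sets, and an instrument set that has passed an $F\ge10$
  screen contains no near-null effects. This is the standard design in the
  MR methods-evaluation literature, and it matters: a planted outlier
  attached to a near-null instrument produces an arbitrarily small IVW
  distortion, making correction claims untestable.
- **Oriented directional pleiotropy.** Directional $\alpha_j$ is drawn
  relative to the exposure-raising allele (its sign follows
  $\mathrm{sign}(\gamma_j)$), matching how instruments are oriented before
  an Egger fit; under random allele labelling a fixed-sign $\alpha$ would
  average to zero and no intercept could recover it. Balanced pleiotropy
  is symmetric, so orientation is irrelevant there.
- **Exact contamination counts.** Pleiotropy carriers are planted as
  exactly $\mathrm{round}(\texttt{frac}\cdot J)$ variants, so a sub-half
  nominal fraction cannot drift above half of the instruments in a single
  replicate — the weighted median's guarantee is conditional on valid
  instruments holding the weight majority.

What the generator does *not* emulate: real LD of any locus (LD is a
separate synthetic block-matrix input), allele-frequency differences
between cohorts beyond optional noise, sample overlap, winner's curse from
in-sample selection, or individual-level case-control sampling. Passing
tests therefore demonstrate correctness of the estimators and pipeline
under the stated generative model, not robustness to those additional
real-data complications.

## Operating characteristics, and two honest caveats

The test battery (reproduced by `scripts/acceptance.R`) measures, among
others: exact-oracle equivalence of every estimator at $10^{-10}$; type-I
error of the fixed-effects IVW within [0.035, 0.065] over 2,000 null
replicates; mean IVW estimate within 0.02 of $\theta=0.5$ over 500 clean
replicates; Egger intercept recovery of planted $\mu_\alpha=0.02$;
MR-PRESSO outlier detection and correction rates on the single-outlier
scenario (detection ~100%, corrected estimate closer to truth in ~94% of
runs); and byte-identical pipeline determinism under a fixed seed.

Two finite-sample effects are worth stating plainly:

- **Weighted median under contamination.** With 40% of instruments
  carrying one-sided pleiotropy, the weighted median's 0.5-weight crossing
  sits at the $0.5/(1-0.4)\approx0.83$ quantile of the *valid* ratio
  distribution, so its finite-noise bias is roughly
  $\Phi^{-1}(0.83)\cdot\sigma_Y/|\gamma|$ — about +0.13 at the default
  outcome noise, shrinking only as sampling noise does (we verify
  consistency in a low-noise regime). The median's robustness guarantee is
  asymptotic; at realistic summary-statistic noise it is *less biased than
  IVW* under directional contamination (which we assert), not unbiased.
- **Egger intercept attenuation leakage.** Exposure-effect measurement
  error attenuates the Egger slope (NOME violation; ~6% at the preset's
  instrument strengths), and the lost slope times the weighted mean
  instrument effect appears in the intercept (~+0.0013 on a planted 0.02).
  SIMEX-type corrections exist but are out of scope here, as they were in
  the motivating analysis.

## Pipeline conventions

`run_study()` crosses every configured exposure with every outcome;
failures in one pair (for example an emptied instrument set, reported with
the name of the filter that emptied it) never abort the rest. Estimates
are computed natively per unit *increase* of the exposure and flipped at
reporting time when the `lowering` sign convention is chosen — an
inhibitor of a trait-raising target acts in the lowering direction, so
reported odds ratios describe the drug direction; the flip is an exact
involution (ORs reciprocate, CI bounds swap) and is logged. No
multiple-testing correction is applied across outcomes; raw p-values are
reported, matching the source design. Positive-control outcomes are
flagged in the report so instrument validity can be read first. All
randomness (weighted-median bootstrap, PRESSO simulations, generator)
derives from a single master seed via independent sub-streams; identical
configuration and seed give byte-identical report files.

Problem sizes used by the packaged checks — 2,000 null replicates, 500
recovery replicates, 200 seeded PRESSO runs with 300 Monte-Carlo draws
each — were chosen as the smallest sizes at which the binomial/Monte-Carlo
error of each assertion is comfortably below its tolerance.

## Worked example

```{r example, eval = FALSE}
library(targetmr)

# a synthetic drug-target study with known truth (theta = -0.5)
sim <- simulate_two_sample(scenario_preset("drug_target_cis"), seed = 7)
ld  <- simulate_ld_block(sim$exposure$rsid, block_size = 4, rho = 0.5)

region <- load_gene_regions(genome_build = "GRCh37")$SLC5A2
# synthetic positions live in the packaged SLC5A2 window already

cfg <- study_config(
  exposures = list(SGLT2i = list(
    sumstats = sim$exposure, region = region,
    config = selection_config(p_threshold = 5e-8)
  )),
  outcomes = list(T2D = sim$outcome),
  ld = ld, positive_controls = "T2D",
  sign_convention = "raising", seed = 7
)
study <- run_study(cfg)
tidy(study)
autoplot(study)
render_report(study, "mr_report")
```
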