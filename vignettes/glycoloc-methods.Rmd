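---
title: "Methods: comparing the genetic regulation of N-glycosylation on two proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing the genetic regulation of N-glycosylation on two proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`glycoloc` packages the statistical cascade used to decide whether two
proteins share the genetic control of their N-glycosylation: per-cohort
GWAS of glycan peaks, cross-cohort meta-analysis, locus definition,
summary-statistic conditional analysis, approximate-Bayes-factor
colocalisation with pairwise-conditional fallback, and SMR/HEIDI plus
Mendelian randomisation. This vignette records the models, the defaults and
the design choices that were genuinely open, and what the synthetic cohorts
do and do not establish about real data.

## Phenotype model and preprocessing

Glycan peaks are compositional: each peak area is divided by the sample's
total chromatogram area, so traits are relative abundances summing to one,
and then log10-transformed (`preprocess_glycans`). The log scale reflects
the multiplicative error and right skew of chromatographic quantification.
Total-area normalisation makes the pipeline invariant to per-sample scaling
of raw areas — a property asserted by test — but it also couples traits:
perturbing one abundant peak perturbs every relative abundance of the same
protein. The synthetic generator reproduces this coupling deliberately; in
the end-to-end scenarios some peaks without a planted causal variant still
reach genome-wide significance through the shared denominator, exactly as
relative abundances would in real data. Batch effects can be simulated
(`batch_count > 1`) but no batch correction is implemented; empirical-Bayes
batch correction on plate covariates belongs to primary data cleaning and
is out of scope here, so tests and defaults use a single batch.

Before association each trait is rank-transformed to normality with
Φ⁻¹((rank − ½)/n) (`rank_inverse_normal`). Ties are averaged by default;
a seeded random split is available because the transform's upstream
implementations differ and neither choice is canonical. The transform is
invariant to monotone rescaling and makes per-trait test statistics
comparable across peaks with very different dynamic ranges.

## Association model

Traits are adjusted for age and sex as fixed effects by OLS and the
residuals tested per SNP under an additive dosage model with a two-sided
one-degree-of-freedom Wald test (`gwas_additive`). The cohorts that
motivated this design are population isolates analysed with a kinship
random effect; the synthetic cohorts are unrelated by construction, so a
mixed model would estimate a zero variance component and the fixed-effects
OLS is the correct reduction. This is the one deliberate structural
deviation from the motivating analysis and it matters only if the generator
ever grows pedigree structure.

The `nested_lrt` ladder formalises the pQTL-vs-glyQTL question: M0
(covariates), M1 (+pQTL), M2 (+glyQTL), M3 (+both), with likelihood-ratio
tests M0–M1, M1–M3 and M2–M3 via `lmtest::lrtest`. In the source material
the M3 formula swaps the two rs-numbers relative to the M1/M2 definitions;
the package follows the surrounding definitions (pQTL = the protein-level
variant, glyQTL = the glycan-level variant) rather than the formula line,
and the ladder is symmetric in any case.

## Meta-analysis and multiplicity

Cohorts are harmonised on SNP id and alleles (swapped effect/other alleles
flip the sign and frequency; anything else is removed as
`allele_mismatch`). QC removes SNPs whose effect-allele frequencies differ
by more than 0.3 in absolute value — read strictly, |Δ| > 0.3 — and SNPs
with minor allele count 2·N·min(EAF, 1−EAF) ≤ 6 in *either* cohort, using
each cohort's own N (the filter describes per-cohort data quality, so the
per-cohort count is the meaningful one). Fixed-effect inverse-variance
weighting then combines effects; genomic control estimates
λ = median(z²)/0.4549364 and inflates standard errors by √λ only when
λ > 1, the no-deflation convention of standard meta-analysis software.
Genomic control is applied to the meta-analysed statistics, not per cohort.
Genome-wide significance is Bonferroni-corrected per protein panel:
5×10⁻⁸/35 ≈ 1.43×10⁻⁹ for a 35-peak panel and 5×10⁻⁸/24 ≈ 2.08×10⁻⁹ for a
24-peak panel.

λ is a genome-wide diagnostic; on a single simulated region of ~250
correlated SNPs the median is noisy and per-trait λ values spread widely.
The calibration property (λ within (0.97, 1.03)) is therefore asserted on
10⁵ independent null draws, which is what the statistic is designed for.

## Locus definition

Per trait, the most significant unassigned SNP seeds a ±250 kb window;
assignment repeats until no significant SNP remains. Across traits,
sentinel–trait pairs within ±500 kb merge transitively and the lowest-p
pair leads the merged locus. The motivating workflow resolved overlapping
association patterns by visual inspection of regional plots; a visual step
cannot be reproduced deterministically, so the package automates it as
transitive merging plus lowest-p representative selection, with p-value
ties broken by (chromosome, position, SNP id). This is a documented
deviation: it is reproducible and, on every architecture the generator can
produce, coincides with what inspection would conclude.

## Approximate conditional and joint analysis

`cojo_slct` reconstructs the single-trait normal equations from summary
statistics and an external LD reference: the diagonal uses
D_j = (N_j − 1)·Var_ref(g_j) — equal to 2f(1−f)N under Hardy–Weinberg —
off-diagonals r_jk·√(D_j·D_k) with r from the reference panel, X'y_j =
D_j·β_j, and the phenotypic sum of squares reconstructed per SNP as
D_j·SE_j²·(N_j−1) + D_j·β_j² and summarised by the median across SNPs,
which is robust to the handful of truly associated SNPs. Using the
reference variance rather than the allele-frequency formula makes the
joint estimates exactly reproduce individual-level multiple regression
when the reference *is* the GWAS sample — the package's oracle test — and
differs from it only through Hardy–Weinberg deviation otherwise.

Selection is greedy forward from the lowest-p SNP, adding the smallest
conditional p-value while it stays at or below the threshold and the
candidate's r² with every selected SNP stays at or below 0.9 (the
collinearity cap), with a backward pass dropping any selected SNP whose
joint p rises above the threshold. Per-SNP sample sizes come from the
summary file; the joint fit uses the minimum N over included SNPs, a
conservative choice where the source is silent. Joint p-values can be
deflated by an externally supplied genomic-control λ (`lambda` argument) as
a post-hoc scalar — the genome-wide λ, since a within-locus λ is not
estimable from a handful of SNPs. Singular normal equations fall back to a
small proportional ridge and are flagged. `cojo_cond` holds a conditioning
set's joint effects fixed and reports every other SNP's residual effect;
conditioned SNPs themselves are reported with an exactly zero residual
effect, and SNPs with r² > 0.9 to the conditioning set are returned missing
with reason `collinear`.

## Colocalisation

Per SNP and trait the Wakefield approximate Bayes factor is
log ABF = ½[log(1−r) + r·z²], r = W/(W + SE²). The prior effect variance
W = 0.15² is the standard quantitative-trait default of the method; the
motivating analysis does not state it, and none of the package's
conclusions move within a factor of two of this W. Hypothesis weights
follow the single-causal-variant-per-trait enumeration — H0: 1;
H1: p1·ΣL1; H2: p2·ΣL2; H3: p1·p2·(ΣL1·ΣL2 − Σ L1L2); H4: p12·Σ L1L2 —
normalised with log-sum-exp stabilisation; the brute-force enumeration over
all single-SNP and SNP-pair causal configurations is the test oracle and
agrees to 10⁻¹⁰. Priors default to p1 = p2 = 10⁻⁴, p12 = 10⁻⁵, and 0.8 on a
posterior probability is the evidence threshold throughout.

Traits whose pairwise PP.H4 exceeds the threshold are pooled transitively
(A with B and B with C pools all three) via union–find; each group is
represented by its lowest-p trait. At multi-signal loci `pwcoco` runs
colocalisation on every combination of full and signal-conditioned
statistics — (k₁+1)×(k₂+1) runs, nine when both traits carry two signals —
with conditioning models selected at 5×10⁻⁸. The verdict rule formalises
prose evidence interpretation: "colocalises" when any combination reaches
PP.H4 > 0.8, "distinct" when all informative (non-missing) combinations
reach PP.H3 > 0.8, otherwise "inconclusive". Mixed outcomes therefore land
on "inconclusive" rather than being forced.

## SMR, HEIDI and Mendelian randomisation

The SMR statistic at the top instrument is T_SMR = z_x²z_y²/(z_x²+z_y²)
against χ²₁, with ratio estimate b = β_y/β_x. Instrument selection follows
the iterative filtration: eligible SNPs lie within ±250 kb of the sentinel,
are present in both datasets, have MAF ≥ 0.03 in both, and z² ≥ 10 in the
primary GWAS; the top SNP is the lowest-p eligible SNP with r² > 0.8 to the
sentinel; remaining SNPs are visited in ascending SMR p-value and rejected
when r² > 0.9 with any accepted SNP, stopping at 20; below 3 accepted SNPs
HEIDI is skipped.

T_HEIDI = Σᵢ z_d(i)² with d_i = b_i − b_top. SE(d_i) comes from the delta
method: var(b_i) = (SE_y,i² + b_i²·SE_x,i²)/β_x,i², with covariance between
instruments i and j driven by LD, cov(β̂_i, β̂_j) ≈ r_ij·SE_i·SE_j within
each trait and traits independent. The source states only the statistic,
not the covariance; this delta-method form is the package's documented
choice and is validated by simulation calibration (type-I rate at the 0.001
threshold stays below 0.05 under a shared variant) rather than against an
external implementation. The null of T_HEIDI is a sum of correlated 1-df
chi-squares; the p-value uses a moment-matched scaled chi-square
(Satterthwaite: T/a ~ χ²_g with a = Σλ²/Σλ, g = (Σλ)²/Σλ² over the
eigenvalues of the z_d correlation matrix), which is stable and
dependency-free; an exact weighted-chi-square inversion would change
nothing at the 10⁻³ decision threshold in the calibration experiments. A
singular z_d covariance drops the most collinear SNP, logs it, and
recomputes.

MR instruments are exposure SNPs below 5×10⁻⁸, greedily clumped to mutual
r² ≤ 0.001 against the LD reference; each contributes a Wald ratio
β_out/β_exp with SE_out/|β_exp| and the IVW estimate combines them with
inverse-squared-SE weights, run in both directions. The SMR significance
level is a configuration value (the motivating study's 0.05/302 is
study-specific); MR significance defaults likewise to a configurable level.

## The synthetic generator and what it emulates

Haplotypes come from a latent first-order autoregressive Gaussian along the
SNP index — cor(z_i, z_j) = exp(−|i−j|/ld_decay) — thresholded at each
SNP's target frequency, drawn uniformly from `maf_range`. This gives
controllable, monotone LD decay; it does not reproduce human LD blocks,
recombination hotspots, or allele-frequency spectra, so distances here are
calibrated in SNP units (defaults: 2 kb spacing, decay 15 SNPs ≈ 30 kb
correlation half-length, a plausible within-locus scale). Cohorts draw
disjoint haplotypes from one panel, mimicking two populations with shared
LD; the LD reference cohort (default 2000 individuals, standing in for a
much larger external panel) is drawn the same way, so reference LD error is
realistic but ancestry mismatch is not modelled.

Latent trait values are Σ β·standardised dosage + age and sex effects +
Gaussian noise (sd 1), exponentiated as 10^(μ_t + 0.15·latent) into
strictly positive peak areas with fixed decreasing baselines μ_t (shares
roughly 10% down to 1%), so total-area normalisation and the log10
transform are meaningful and the planted β is recoverable after INT up to
the compositional share and the INT variance rescaling. Default study
conditions mirror the motivating design: two cohorts of 1000 individuals,
35 + 24 trait panels, age and sex effects of 0.005/year and 0.1.

Two preset architectures drive the end-to-end tests: `scenario_shared`
plants one mid-region variant for 4 + 3 traits of the two proteins
(β 0.35–0.5); `scenario_distinct` plants two variants 260 kb apart
(r² ≈ 0), one per protein, within one mergeable region — the "same gene
region, different variants" situation. Passing these establishes that the
cascade discriminates the two architectures under clean LD and Gaussian
noise; it does not establish robustness to allele-frequency mismatch
between cohorts, imputation error, pedigree structure or batch artefacts,
none of which the generator emulates.

## Problem sizes and numerical choices

Test and acceptance runs use: 251-SNP regions for the end-to-end cascade
(two cohorts × 1000 individuals, 59 traits); 100 simulated locus pairs per
architecture at n = 2000, β = 0.4 for discrimination; 200 replicates at
n = 5000 for HEIDI calibration and power; 2000 near-independent SNPs for
meta-analysis null calibration and 10⁵ draws for λ; 10 seeded end-to-end
runs per architecture. These sizes give stable rates while keeping the
whole suite in the low minutes on one CPU.

Numerically: all hypothesis weights and Bayes factors are kept in natural
log with log-sum-exp; Wald p-values are floored at the smallest positive
double rather than underflowing to zero; a perfect-fit regression reports
the floored p rather than dividing by a zero SE; monomorphic SNPs propagate
as missing with a reason instead of being dropped; all stochastic
procedures consume explicit integer seeds and every tie (p-value order,
representative choice, merge order) is broken lexicographically so results
are reproducible bit-for-bit.

## Known limitations

* Single-causal-variant assumption inside each colocalisation run; PwCoCo
  mitigates but multi-causal fine-mapping (e.g. SuSiE-style) is out of
  scope.
* No mixed-model association or relatedness handling; the generator makes
  unrelated individuals, so this is consistent but limits realism.
* The HEIDI covariance is a first-order delta-method approximation; very
  weak instruments (|z_x| near the eligibility floor) inflate ratio-SE
  nonlinearity, which the z² ≥ 10 eligibility rule is there to prevent.
* X-chromosome models, dosage-uncertainty propagation and
  heterogeneity-aware (random-effects) meta-analysis are not implemented.
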