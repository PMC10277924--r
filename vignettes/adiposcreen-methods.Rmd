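---
title: "Methods: screening adipose-origin NAFLD biomarkers across two tissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening adipose-origin NAFLD biomarkers across two tissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adiposcreen)
```

## The scientific problem

Non-alcoholic fatty liver disease (NAFLD) is diagnosed by liver histology
(steatosis, fibrosis, NASH grades), an invasive procedure. Adipose tissue
dysfunction is thought to drive part of NAFLD pathogenesis, which suggests a
screening strategy: find genes that respond to NAFLD in *subcutaneous
adipose tissue but not in liver*, encode *secreted* proteins, and are
*adipose-enriched* — their protein products are plausible serum biomarker
candidates (SBCs) of adipose origin. `adiposcreen` implements that screen as
a reusable pipeline over paired adipose/liver RNA-seq from the same
individuals, together with the genetic follow-up stages: co-expression
networks, cis-eQTL mapping, colocalization with GWAS signals, and two-sample
Mendelian randomization (MR) of serum triglycerides (TG) on NAFLD status.

Because the cohort-scale inputs (paired biopsies, biobank GWAS, reference
TPM atlases, secretome annotations) cannot be redistributed, the package
ships a synthetic-data module that emulates the entire input surface with
*planted* effects, so that every stage can be scored against a known truth.

## Differential expression

Counts are filtered to genes with nonzero expression in at least 90% of
samples (`filter_expressed`); genes below that threshold have zero-inflated
bimodal distributions that rank-based normalisation cannot repair. Library
composition is normalised by trimmed-mean-of-M-values (TMM) scaling factors
(`tmm_factors`): the reference sample is the one whose 75th-percentile count
fraction is closest to the sample mean; per sample, gene-wise log-ratios M
and abundances A against the reference are doubly trimmed (30% of M and 5%
of A from each tail) and the factor is 2 to the precision-weighted mean of
the surviving M values, rescaled to geometric mean 1. The trim fractions are
the established convention; the agreement of this implementation with the
edgeR reference is asserted in the test suite.

Case/control design follows the histology rule: cases have a nonzero grade
for the tested trait; controls have grade zero in *all three* traits;
everyone else is excluded (`build_case_control`). Log-CPM values enter a
weighted linear model with precision weights from the mean-variance trend
(`voom_weights`): a lowess curve of sqrt(residual SD) against mean log2
count, evaluated at each observation's fitted log-count, inverted to the
fourth power. Per-gene variances are then shrunk toward a common prior by
empirical Bayes (`fit_moderated`): the prior `(d0, s0²)` is estimated by
moment matching on the log sample variances (mean and variance of `log s²`
against the digamma/trigamma moments of the scaled-F model, with the
trigamma inverted by Newton iteration), and the moderated t statistic uses
`d0 + d_g` degrees of freedom. This closed-form moment matching agrees with
the limma reference implementation to numerical precision on count fixtures
in the test suite.

Benjamini–Hochberg FDR control is reimplemented (`bh_adjust`) because the
step-up rule is load-bearing for every stage; it is tested against a
definitional oracle and against `p.adjust`.

**Aware DE sets.** A gene is "aware DE" for adipose if it is DE (FDR < 0.05)
in adipose for some trait and not DE in liver. The removal rule is read as
*any-trait* by default: a liver DE hit for any of the three traits removes
the gene. A strict per-trait mode (`mode = "per_trait"`) is provided because
the narrower reading is also defensible; the default matches the phrase
"also DE for any of the same three traits".

**Restricted DE** (`de_restricted`) reuses the same machinery for
knockdown/treatment designs: two groups, no covariates, genes prefiltered by
a summed-count rule (> 10 within at least one group — the one-group reading
is the default because a gene silenced by the knockdown itself would fail a
both-groups rule, which would defeat the design), BH within the tested
subset only.

## Co-expression networks

Unsigned weighted networks: adjacency `|cor|^β`, with the soft power chosen
by inspecting scale-free fit and mean connectivity (`pick_soft_threshold`;
the scale-free index bins connectivity into equal-width bins and reports the
signed r² of log-frequency on log-connectivity). The topological overlap
matrix (`tom_similarity`) is computed by the matrix-product identity and
verified against a naive triple loop. Genes are clustered by average linkage
on `1 − TOM`; branches are cut at a *static* height (default 0.99 of the
maximum merge height) and clusters smaller than `min_module_size` (default
30) are relabeled grey. A static cut replaces the dynamic hybrid tree cut of
the WGCNA tooling: the dynamic cut is a separate algorithm family with many
unstated parameters, while the static cut preserves the testable contract
(planted blocks must be recovered exactly). Module counts from a dynamic cut
are therefore not comparable and are not treated as targets.

Module eigengenes are first right singular vectors of the gene-standardized
module submatrix, sign-oriented to correlate positively with the module mean;
module membership (kME) is the Pearson correlation of a member with the
eigengene. Modules whose eigengene dissimilarity `1 − cor` falls below the
merge height (0.10 adipose / 0.25 liver in the motivating study) are merged
iteratively to a fixed point. All module–trait, module–module and SBC
correlation analyses run through `correlate_bonferroni`, which controls the
family-wise error at 0.05 over the exact family of tested pairs.

## The SBC filter cascade

`apply_sbc_filters` applies, in order: aware-DE membership, the secreted
flag, adipose median TPM **strictly greater** than 30, and adipose/liver
median TPM ratio **strictly greater** than 10. Both inequalities are strict
because the thresholds are stated as "> 30" and "> 10"; the boundary cases
are excluded and covered by tests. A liver TPM of zero with positive adipose
TPM passes the ratio filter (the ratio is +∞) and is logged. Genes missing
from the annotation fail conservatively into a distinct audit bucket. The
audit trail records input/output counts and removed genes per step; the
final set is provably order-insensitive (the filters are independent
predicates), which the suite asserts on random fixtures.

## Best-subset selection with a permutation null

`best_subset_search` enumerates all subsets of the candidate pool (pools are
small — the motivating analysis had ≤ 10 candidates; exhaustive enumeration
replaces branch-and-bound, which is an optimization, not a different
estimator), minimizing RSS per size and choosing the size by
BIC = n·ln(RSS/n) + (k+1)·ln(n) with the intercept counted as a parameter.
Ties break lexicographically by gene id. Trait grades enter as a numeric
response in a linear model, matching the original linear-model usage; a
binary mode is available by dichotomizing upstream.

Significance is a permutation null (`permutation_pvalue`): B random gene
sets of the chosen size, drawn from all expressed genes (the 90%-nonzero
universe), refitted on the same covariate-residualized design; the p-value
is the proportion of random models with r² **strictly greater** than the
observed model. The default B is 10,000 for interactive use; B = 100,000
reproduces the original setting. The add-one-smoothed estimate and the
non-strict version are reported alongside, since the plain proportion can
be exactly zero. The permutation refit includes the covariates identically
for random sets — the fair comparison, and the reading we adopt of the
original procedure.

## cis-eQTL mapping, colocalization, MR

Expression for eQTL mapping is inverse-normal transformed (Blom constant
c = 3/8; the tie-averaged rank transform makes any gene-length factor
irrelevant, so FPKM vs CPM input is immaterial), adjusted for expression
principal components (defaults 25 adipose / 10 liver, mirroring the factor
counts of the probabilistic residual approach they replace), and transformed
again. `map_cis_eqtls` tests a variant for a gene when it lies within 1 Mb
of either gene boundary; an `anchor = "end"` mode reproduces the literal
"±1 Mb from the end of the gene" reading. FDR is controlled over all tested
pairs per tissue.

Colocalization (`coloc_abf`) scores the five sharing hypotheses with
Wakefield approximate Bayes factors
`log ABF = ½(ln(1−r) + r z²)`, `r = W/(W+se²)`, with prior effect SD 0.15
for quantitative traits (0.2 for binary) and priors
p1 = p2 = 1e-4, p12 = 1e-5 — the conventions of the coloc tooling, which the
motivating study does not override. All sums run in log space
(log-sum-exp / log-diff-exp); the linear-space enumeration is the test
oracle. Secondary signals are handled by an LD mask (`mask_second_signal`):
remove the lead and everything with r² above the mask, rerun — a transparent
stand-in for conditioning on the lead variant. "Significant colocalization"
defaults to PP4 ≥ 0.8.

**Instrument selection** (`select_ivs`) follows the cascade in its stated
order: candidate regions need a significant cis-eQTL and an exposure GWAS
hit (p < 5e-8) that is not an outcome GWAS hit (p ≥ 5e-8); regions must
colocalize (PP4 ≥ 0.8); candidates are the colocalized regions' significant
eQTL variants; candidates in LD (r² > 0.2) with outcome hits are removed
(within the region's variant set by default); LD pruning at r² > 0.2 keeps
the variant with the smallest *sum of ranks* of eQTL p and GWAS p — the
"most significant eQTL and GWAS results" criterion has no stated formula, so
a rank-sum with eQTL-p then variant-id tie-breaks makes it deterministic;
strand-ambiguous (A/T, C/G) variants are dropped; effects are harmonized to
the exposure's effect allele. An empty result is an explicit failure state,
as in the reverse-direction analysis of the motivating study.

Estimators: fixed-effect IVW (`mr_ivw`; single instrument reduces to the
Wald ratio; Cochran's Q and an optional multiplicative random-effects
inflation are reported), Egger regression (`mr_egger`; pairs oriented so
βX ≥ 0, SEs inflated by max(1, √(RSS/(J−2)))), and a PRESSO-style global
test (`mr_presso`; leave-one-out weighted RSS against a parametric
bootstrap, default 1,000 simulations, per-instrument outlier flags with
Bonferroni control).

## Added-value regression

`compare_models` quantifies what a gene's adipose expression adds over serum
TG for explaining NAFLD status: log10-transformed TG, inverse-normal
transformed gene CPM, base vs augmented logistic and linear fits, compared
by Nagelkerke pseudo-r² `(1 − (L0/L1)^{2/n}) / (1 − L0^{2/n})`, ROC AUC via
the rank (Mann–Whitney) formula with ties counted one half, and (adjusted)
linear r². Logistic fitting delegates to the standard IRLS fitter; separable
data produce a warning and finite capped-iteration estimates rather than a
penalized fit, keeping the estimator pure. The elastic-net model family of
the original comparison is out of scope here; the logistic and linear
models cover the claims the pipeline exercises.

## The synthetic-data generator

`simulate_study` generates, from one master seed (stage streams derive from
fixed offsets of it, so each piece is reproducible in isolation):

* **Annotation** — genes spaced 2.5 Mb apart (cis windows never overlap, so
  planted cis signals are attributable to one gene), secreted flags,
  adipose/liver median TPM, marker-set labels.
* **Genotypes** — dosages Binomial(2, MAF) with block-copy LD: each block
  shares a MAF, members copy the anchor's haplotypes with a configurable
  probability; a configurable fraction of variants gets palindromic alleles.
* **Phenotypes** — serum TG from a genetic score over the exposure
  architecture plus noise; NAFLD grades 0–3 thresholded from a Gaussian
  liability with a shared component across the three traits (so grade-0-in-
  all controls are plentiful, as in the motivating cohort), a TG loading
  equal to `theta_causal`, and trait case fractions defaulting to
  0.60/0.45/0.35 — the approximate case proportions of the motivating
  cohort (158/118/85 cases, 87 controls among ~250).
* **Counts** — negative binomial, gene baselines log-normal, dispersion
  shared, covariates (age, sex, four technical metrics) with small
  log-scale loadings; planted DE genes shift case means by the planted
  log2FC in their tissue only; planted eQTLs add a per-allele log2 shift
  calibrated as `slope · sqrt(dispersion)/ln 2` so the post-INT slope
  approximates the planted SD-per-allele value.
* **GWAS summary statistics** — analytic: `beta_hat ~ N(true, se²)` with
  `se = 1/sqrt(2·MAF·(1−MAF)·n_eff)`; outcome true effects are
  `theta_causal` times the exposure's at shared causal variants plus any
  direct (pleiotropic) outcome effects.

Three deliberate truth-identifiability choices, made once and documented
here rather than tuned: (i) planted SBC genes are forced to satisfy every
annotation filter and *no other gene* satisfies the full conjunction, so
the cascade's expected output is exactly the planted list; (ii) planted
cis-regulated genes draw their baseline from the well-expressed stratum,
because regulation of a near-zero-count gene is statistically unidentifiable
and would corrupt the truth record; (iii) in the MR fixtures the outcome
GWAS uses a smaller effective sample size (1e5 vs 5e5) — an imputed
composite liver phenotype is genuinely less powered than a directly
measured lipid — which keeps "valid" instrument regions comfortably below
the outcome genome-wide threshold so the planted region count is a stable
truth.

**What the generator does not emulate:** realistic human LD maps (block
copies only), sequence-level variation, single-nucleus data, batch structure
beyond six covariates, and trans-regulation. Passing tests therefore show
the *procedures* are correct and calibrated under a faithful generative
model; they do not certify performance on real cohort data, where
normalisation and confounding are harsher.

## Problem sizes and numerical choices

The test suite and the acceptance script use desk-scale versions of the
study design, chosen to make every property measurable in minutes on one
core: 250 samples × 2,000 genes per tissue for the end-to-end screen
(600 planted DE genes incl. 10 SBCs), 300 samples × 400 variants for the
instrument cascade (6 valid + 2 contaminated regions), 500 replicates for
causal-effect recovery, B = 2,000 for permutation calibration, 10 seeds ×
90 genes for module recovery. Other conventions: prior count 0.5 for
log-CPM; lowess span 0.5 for the mean-variance trend; constant vectors map
to all-zero INT output with a warning; monomorphic variants are skipped in
eQTL mapping and reported; zero-variance profiles are excluded from
correlation families; permutation and bootstrap p-values report their
resolution (warnings below B = 100 / n_sim = 100); eigengene and PC signs
follow a largest-loading-positive convention so results are bit-reproducible
under a fixed seed.

## Known limitations

* The static tree cut needs a sensible `cut_height` for very heterogeneous
  dissimilarity scales; the default (0.99 of maximum height) recovers
  well-separated blocks but is not a substitute for dynamic cutting on
  messy real networks.
* The PRESSO-style global test implements the published residual-bootstrap
  logic but not the distortion test; weighted-median/mode MR estimators are
  deliberately out of scope.
* `best_subset_search` is exhaustive and limited to 20 candidates.
* GWAS summary statistics are generated analytically; there is no
  individual-level biobank simulation, so sample-overlap biases between
  exposure and outcome cannot be studied with this generator.
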