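---
title: "Testing differential susceptibility in gene-environment interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing differential susceptibility in gene-environment interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question the package answers

A significant gene-by-environment (GxE) interaction says that two genotype
groups respond differently to an environmental exposure; it does not say
*how*. Under the **diathesis-stress** model, risk-allele carriers do worse
than non-carriers only under adverse environments. Under **differential
susceptibility**, the same "risk" carriers are better thought of as
*plastic*: they do worse under adversity *and better under supportive
environments* ("for better and for worse"). **Vantage sensitivity** is the
mirror case in which carriers differ only on the positive-environment side.
Distinguishing these patterns matters because they imply different
aetiologies and different intervention logic, yet they can produce
identical regression output when only the negative half of the environment
is measured.

`gxeds` implements the standard moderated-regression machinery for making
this distinction with a binary genetic moderator and a continuous,
full-spectrum environment score, together with everything around it: the
construction of risk-carrier moderators from raw SNP genotypes, the
pre-checks that make the interaction interpretable, and a synthetic-data
generator for validating the whole pipeline.

## The model and the indices

Everything is built on the ordinary-least-squares crossover model

$$Y = b_0 + b_1 X + b_2 Z + b_3 XZ + \varepsilon,$$

where $X$ is the environment score (in the worked examples, the mean
subjective impact of recent life events on a $-3\ldots+3$ scale), $Z$ is a
binary risk-carrier indicator, and $Y$ a continuous outcome. The classical
homoskedastic coefficient covariance is used throughout — no sandwich
correction — matching the standard regression output this style of
analysis has historically been built on. $X$ enters **uncentred** by
default: the crossover point and its derived indices live on the raw
environment scale, and centring is an explicit opt-in re-expression
(`fit_gxe(center = TRUE)`), never applied silently.

From a fit the package derives:

* **Simple slopes** — the environment effect per group: $b_1$ at $Z=0$ and
  $b_1 + b_3$ at $Z=1$, the latter with delta-method variance
  $\operatorname{var}(b_1)+\operatorname{var}(b_3)+2\operatorname{cov}(b_1,b_3)$
  and t-based intervals on the residual degrees of freedom.
* **Crossover point** $x_c = -b_2/b_3$ — the environment value where the
  group lines intersect. $b_3 = 0$ is an error (parallel lines have no
  crossover), and a $|b_3|$ that is negligible against $|b_2|$ draws a
  warning because the implied crossover is arbitrarily far outside any
  observable range.
* **Regions of significance on X** (Johnson–Neyman): the $x$ values
  solving $(b_2+b_3x)^2 = t^2_{\alpha/2,\,df}\,
  [\operatorname{var}(b_2)+x^2\operatorname{var}(b_3)+2x\operatorname{cov}(b_2,b_3)]$,
  a quadratic whose roots bound the band of non-significant group
  difference. Side significance is assessed *within the evaluation range*
  by the pointwise test at each range endpoint; this is equivalent to the
  root-position rule in the regular configuration and remains well defined
  when the quadratic has no real roots (the stated fallback).
* **Proportion of Interaction (PoI)** — the fraction of the total area
  between the two lines, over the evaluation range, lying on the
  *for-better* side of the crossover. For straight lines both areas are
  triangles, so with the for-better side on the right,
  $\mathrm{PoI} = (x_u - x_c)^2 / [(x_u - x_c)^2 + (x_c - x_l)^2]$.
  A crossover outside $[x_l, x_u]$ clamps PoI to 0 or 1, and
  classification then cannot be differential susceptibility.
* **Proportion Affected (PA)** — the proportion of the population on the
  for-better side of the crossover under a normality assumption for $X$:
  $1-\Phi((x_c-\mu_X)/\sigma_X)$ for a right-hand for-better side. The
  normality assumption is why the pipeline runs a Shapiro–Wilk check on
  $X$ first.

**Orientation.** Which side is "for better" is not hard-coded: it is
derived from the declared outcome polarity (`outcome_polarity()`;
higher-is-worse for all anxiety-spectrum outcomes in the examples) and the
sign of $b_3$ — the for-better side is where the risk group's predicted
outcome is better than the reference group's. For every published fit the
package reproduces this is the right-hand side, recovering the standard
right-side PoI formula, while mirrored data keep a meaningful index
instead of a nonsensical one.

**Evaluation range.** RoS and PoI depend on the range of $X$, so by
convention they are evaluated at $\pm 2$ SD around its mean. The default
range is recomputed from the analysed sample; an explicit override is
accepted (`analysis_plan(eval_range =)`), which is how the published
worked example's printed range $[-1.401, 2.532]$ is reproduced exactly.

**Classification.** Following the established decision thresholds:
differential susceptibility requires both RoS sides significant, PoI in
$[0.40, 0.60]$ and PA $> 0.16$; diathesis-stress requires a significant
left (negative-environment) side only with PoI $< 0.40$; vantage
sensitivity a significant right side only with PoI $> 0.60$. Neither side
significant is reported as `no_interaction`, anything else as
`inconclusive` with all component verdicts available.

Two guards precede any pattern claim: a **curvilinearity check** refits
the model with $X^2$ and $X^2 Z$ terms and flags the joint F test of the
two quadratic terms at $\alpha$ (a nonlinear main effect can masquerade as
a crossover interaction), and a **gene-environment correlation check**
(pooled t-test of $X$ across the $Z$ groups, with Cohen's d) screens for
the G-E association that would make a moderation reading unsafe. For an
essentially exact linear fit the curvilinearity F ratio is numerical noise
over noise; the check reports no detection in that degenerate case. A
**Keller-style covariate adjustment** is available
(`fit_keller_adjusted()`): each covariate enters with its main effect plus
covariate-by-environment and covariate-by-gene products (no three-way
terms), and the interaction p-value is read from the expanded model.

$\alpha = 0.05$ two-sided is used throughout and no multiple-testing
correction is applied; indices are computed only for interactions passing
the significance gate (configurable to "always"), mirroring how published
interaction tables leave non-significant rows blank.

## From genotypes to moderators

The genetics layer works on risk-allele dosages (0/1/2) with risk and
non-risk alleles declared per SNP (`snp_def()`), read from CSV/TSV (allele
pairs or dosages, auto-detected) or a minimal VCF (GT fields via the
suggested `vcfR`; REF/ALT must match the declared alleles — no silent
strand flipping).

* **Hardy-Weinberg**: 1-df chi-square without continuity correction
  against the $p^2, 2pq, q^2$ expectation; monomorphic SNPs are degenerate
  (chi-square 0, flagged) rather than errors. An exact test is not needed
  at these sample sizes and effect questions — the check is a data-quality
  screen, not an inference target.
* **Linkage disequilibrium**: $D' = |D|/D_{max}$ and
  $r^2 = D^2/[p_A(1-p_A)p_B(1-p_B)]$ from two-locus haplotype
  frequencies; a monomorphic margin is an error, which is deliberately
  distinct from zero LD.
* **Haplotype phasing**: maximum-likelihood haplotype frequencies by EM
  under random union of haplotypes, with ten seeded random restarts
  (deterministic given the seed) to guard against local optima — for a
  three-SNP block this is entirely adequate and removes any external
  phasing tool from the loop. Each individual receives the
  posterior-argmax diplotype; posterior ties break lexicographically by
  haplotype string so results are reproducible. The EM cost depends on
  the number of distinct multilocus genotypes ($\le 3^k$), not the sample
  size. Missing genotypes exclude an individual from the phased analysis
  only (listwise per analysis), which is why a haplotype moderator can
  analyse fewer individuals than the single-SNP moderators from the same
  table.
* **Moderators**: dominant coding for single SNPs (non-risk homozygotes
  vs carriers of at least one risk allele); for the haplotype block, risk
  = at least one copy of the risk haplotype, reference = at least one
  reference haplotype and no risk copy, and carriers of neither are
  excluded.

## What the synthetic generator emulates — and what it does not

`synthetic_study_config()` describes the study conditions the analysis
assumes, with defaults emulating a small (n = 86) nonclinical young-adult
cohort:

* **Genotypes.** The three-SNP block is drawn as two independent
  haplotypes per individual from block frequencies derived from the
  published diplotype table (AGC 0.634, CAT 0.273, remainder split over
  two minor haplotypes), which induces Hardy-Weinberg equilibrium at the
  haplotype level and the implied LD. The two remaining SNPs are
  independent binomial draws at their observed risk-allele frequencies.
  Monomorphic settings are rejected.
* **Environment.** Normal within sex with a between-sex difference of
  d = 0.49 (females higher), truncated to the instrument's theoretical
  range $[-3, 3]$ by resampling. The pre-truncation parameters are
  calibrated by a deterministic fixed-point on the analytic
  truncated-normal moments so that the *marginal* mean and SD equal the
  configured 0.57 and 0.98 — truncation alone would otherwise shrink the
  SD by about 2% and the unbalanced sex split (60.5% female) would shift
  the mean.
* **Outcomes.** $Y = b_0+b_1X+b_2Z+b_3XZ+\varepsilon$ with
  $\varepsilon \sim N(0, \sigma^2)$. Published tables report adjusted
  $R^2$, not residual SDs, so $\sigma$ is derived analytically from a
  target adjusted $R^2$ (`derive_noise_sd()`): the variance of the linear
  predictor is computed in closed form for normal $X$ independent of
  Bernoulli $Z$, and the target is equated with the population $R^2$,
  of which adjusted $R^2$ is the standard nearly unbiased estimator.
* **Pattern regimes.** Presets place the crossover mid-range
  (differential susceptibility; the published haplotype-neuroticism
  coefficients), exactly at the upper evaluation limit
  (diathesis-stress), exactly at the lower limit (vantage sensitivity),
  or remove the interaction (null), all at noise levels giving adjusted
  $R^2 \approx 0.10$–$0.12$, the magnitude the published fits report.
  Placing the boundary crossovers *at* the $\pm 2$ SD limits (rather than
  beyond) keeps the off-side group difference near zero at the evaluated
  endpoint, which is what the one-sided patterns mean operationally.
* **Reproducibility.** One RNG stream per component (genotypes,
  environment, per-outcome noise), each derived from the master seed, so
  components can be regenerated independently; a fixed config yields
  byte-identical fixture files. Sex affects only $X$ by default (no sex
  effect on the criteria), with covariate hooks available for
  Keller-model testing.

The generator does **not** emulate: item-level life-event responses (only
the summary score's first two moments and range), population
stratification, genotyping error, or any empirical non-normality of the
real environment score beyond truncation. Passing calibration tests on
this generator therefore shows that the *methods* behave as designed under
their own assumptions — not that any particular real dataset satisfies
those assumptions.

## Numerical and validation choices

* Index identities are validated against independent oracles rather than
  against themselves: Johnson–Neyman roots against a grid of pointwise t
  tests (step $10^{-4}$, tolerance $10^{-3}$), the triangle-ratio PoI
  against trapezoidal integration of the absolute between-line gap
  ($10^5$ points, tolerance $10^{-6}$, including clamped crossovers), EM
  frequencies against exhaustive two-stage grid search over the
  frequency simplex on small instances (tolerance $10^{-3}$), and OLS
  against the normal equations (tolerance $10^{-8}$).
* Statistical calibration uses the generator at the study's own scale:
  the interaction test's type-I error sits at $0.05 \pm 0.02$ over 2,000
  null studies of n = 86; the $b_3$ estimator recovers the generative
  $-12.651$ within 3 Monte-Carlo SE over 2,000 replicates; and the full
  pipeline recovers each generative pattern regime in at least 90% of
  100 studies at n = 2,000. Recovery at n = 86 is far weaker — small
  samples mainly lose the significance gate — which is precisely the
  power limitation such designs face; the n = 2,000 figure isolates the
  classifier's correctness from that sample-size problem. These problem
  sizes keep the whole suite to a few minutes while leaving the
  Monte-Carlo error well inside the asserted bands.
* Degenerate inputs fail loudly and descriptively: constant moderators or
  environments, collinear covariates, monomorphic LD margins, all-missing
  SNPs, out-of-range Shapiro–Wilk inputs.

## Reproducing the published worked example

The raw participant data behind the published analysis are not available,
so the regression coefficients themselves cannot be re-estimated. But the
crossover, PoI and risk-group simple slope are exact functions of the
*printed* coefficients and the printed evaluation range, and
`published_fits()` ships that table: feeding each significant row through
`crossover()`, `poi()` and `simple_slopes()` reproduces the printed values
at their printed precision — with one documented exception. In the
social-anxiety table's first SNP row the printed $b_2 = 5.106$,
$b_3 = -6.037$ give $x_c = 0.846$ and PoI $= 0.36$, while the row prints
1.278 and 0.18; those two printed values are instead mutually consistent
with $b_2 \approx 7.72$, so the printed coefficient and the printed
indices cannot both be right. The package reports what the printed
coefficients imply. The printed PA values are likewise not reproducible
from the stated normal-model definition with the published mean and SD
(e.g. the first neuroticism row prints 0.37 where the definition gives
0.60); the original web tool may have used the unavailable empirical
distribution, so PA is implemented exactly per its stated normal-model
definition and validated through its analytic properties instead. The
published RoS bounds depend on the unpublished coefficient covariance and
are validated qualitatively (side-significance patterns) on synthetic
fits.

The published internal-consistency coefficients are also out of reach
without item-level data; `describe()` computes Cronbach's alpha only when
an explicit item-to-scale mapping is supplied.

## Known limitations

These are the three classical indices; newer methodological work proposes
refinements with better properties, which are deliberately out of scope
here. Regions of significance on the moderator (rather than the
environment) are not implemented. The regression layer is plain OLS — no
robust, Bayesian or mixed-effects variants — and the genetics layer does
no imputation, large-panel phasing, population-structure inference or
strand-flip heuristics. PA inherits its normality assumption; with a
skewed environment score it is an approximation and the Shapiro–Wilk
check should be taken seriously.
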