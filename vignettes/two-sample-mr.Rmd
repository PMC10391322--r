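---
title: "Two-sample Mendelian randomization with mrkit: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The problem and the model

Observational associations between circulating inflammatory markers
(cytokines) and late-life outcomes such as Alzheimer's disease are prone to
reverse causation and confounding. Two-sample Mendelian randomization (MR)
sidesteps both by using genetic variants as instruments: SNP-exposure
associations $\hat\beta_{Xj}$ (in SD units of the cytokine) come from one
GWAS, SNP-outcome associations $\hat\beta_{Yj}$ (log odds for a binary
outcome) from a second, non-overlapping GWAS. If variant $j$ is a valid
instrument — associated with the exposure, independent of confounders, and
affecting the outcome only through the exposure — then
$\beta_{Yj} = \theta\,\beta_{Xj}$ and the causal effect $\theta$ is
identified by the ratio $\beta_{Yj}/\beta_{Xj}$.

`mrkit` implements the estimator battery this design standardly uses:

* **Wald ratio** (single variant): $\hat\theta = \hat\beta_Y/\hat\beta_X$,
  with the first-order standard error $\mathrm{se}_Y/|\hat\beta_X|$. This
  neglects exposure-side noise; with instrument F-statistics well above 10 the
  understatement is modest (the test suite measures it against a parametric
  bootstrap: about 2% at F = 625, about 11% at F = 100).
* **IVW**: weighted regression of $\hat\beta_Y$ on $\hat\beta_X$ through the
  origin with weights $1/\mathrm{se}_Y^2$, i.e.
  $\hat\theta = \sum w_j\hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j\hat\beta_{Xj}^2$.
  The default variance model is multiplicative random effects: the
  fixed-effect variance is inflated by $\max(1, Q/(J-1))$, which never
  narrows the interval and widens it under heterogeneity. The fixed-effect
  model is one flag away (`effects_model = "fixed"`).
* **MR-Egger**: the same regression with a free intercept, after orienting
  every pair so $\hat\beta_X \ge 0$. The slope is robust to directional
  pleiotropy under the InSIDE assumption (pleiotropic effects uncorrelated
  with instrument strength); the intercept estimates the average direct
  effect and its test is the directional-pleiotropy test. Both standard
  errors are scaled by $\max(1, \sqrt{RSS_w/(J-2)})$.
* **Weighted median**: the ordered ratio estimates interpolated at cumulative
  weight 0.5 (weights $\hat\beta_{Xj}^2/\mathrm{se}_{Yj}^2$, normalised);
  consistent while instruments carrying less than half the weight are
  invalid. Its SE comes from a seeded parametric bootstrap (default 1000
  replicates) because no closed form exists.
* **Cochran's Q** about the IVW estimate with first-order weights, df $J-1$;
  **leave-one-out** IVW re-estimation for influence diagnostics.

`mr_fit()` runs the whole battery and returns a classed object with `print`,
`summary`, `coef`, `confint`, `residuals` (weighted residuals, whose squared
sum about the IVW line is Q) and `plot` methods. MR-Egger, the weighted
median and leave-one-out require at least three variants; with fewer they are
flagged infeasible rather than computed.

```{r fit-example}
sim <- simulate_summary_level(sim_config(n_snps = 30, theta = 0.1,
                                         outcome_type = "binary", seed = 7))
h <- harmonise(sim$exposure, sim$outcome)
fit <- mr_fit(retained(h), outcome_type = "binary", seed = 1,
              exposure = "cytokine", outcome = "AD")
summary(fit)
```

## Instrument selection

`select_instruments()` takes variants below $5\times10^{-8}$, falling back to
$5\times10^{-7}$ when none qualifies (the split observed across cytokines:
most instrumentable at genome-wide significance, a minority only at the
relaxed threshold), then prunes by greedy LD clumping: repeatedly take the
smallest-p variant as an index and remove same-chromosome variants within
10,000 kb with $r^2 \ge 0.01$ to it. Ties in p-value break by chromosome,
position, then ID, so the output is invariant to row order. LD comes from a
local matrix (square or triplet file) — no web queries, for reproducibility.

Instrument strength is quantified per variant by $F = (\beta/\mathrm{se})^2$
and variance explained $r^2 = 2\beta^2\,\mathrm{eaf}(1-\mathrm{eaf})$ (with
the $F/(F+n-2)$ fallback when the frequency is missing), and cumulatively by
the joint-regression form $F = \frac{R^2}{1-R^2}\cdot\frac{n-k-1}{k}$ with
$R^2 = \sum_j r^2_j$. "Cumulative F" has no single standard definition; the
joint-$R^2$ form is used here because it reduces to the per-variant $F$
(up to the $(n-2)$ df factor) at $k = 1$, and the per-variant list is always
reported alongside so either reading is available.

Proxy lookup (`find_proxy()`) substitutes the highest-$r^2$ available variant
at $r^2 \ge 0.8$ — the community default for proxies; ties break by distance
then ID. Cis restriction (`cis_filter()`) keeps variants within 100 kb
(configurable) of the encoding gene, 1-based inclusive bounds; cis variants
are less prone to horizontal pleiotropy than trans variants, at the cost of
many exposures becoming uninstrumentable.

## Allele harmonisation

`harmonise()` matches variants by ID and re-expresses the outcome effect on
the exposure's effect allele. Non-palindromic variants are decided by letters
alone: swapped alleles negate the outcome beta and complement its frequency;
pairs matching only after A/T, C/G complementation are strand flips
(numerically no-ops). Palindromic variants (A/T, C/G pairs) carry no strand
information in their letters, so orientation is resolved from allele
frequencies: with both frequencies outside the window (0.42, 0.58), same side
of 0.5 keeps the sign and opposite sides flip it; frequencies inside the
window (or missing) are ambiguous and the variant is dropped by default. The
window default is the conservative standard in two-sample MR; it is the
package's choice where published pipelines differ, and it is configurable.
The frequency-resolution rule (rather than dropping all palindromic
variants) is what makes a seeded corruption round-trip exactly: the test
suite scrambles allele coding (swaps, strand flips, palindromic designation)
and verifies that every non-ambiguous variant recovers its original effect
pair bit-for-bit and that exactly the ambiguous palindromic variants drop.

## Power

For a binary outcome, `binary_outcome_power()` uses the normal-approximation
non-centrality $\sqrt{N R^2 p(1-p)}\,|\log \mathrm{OR}|$ (N total samples,
case fraction $p$, instruments explaining $R^2$ of the exposure):
$\mathrm{power} = \Phi(\mathrm{ncp} - z_{1-\alpha/2}) +
\Phi(-\mathrm{ncp} - z_{1-\alpha/2})$. It is symmetric in
$\mathrm{OR} \mapsto 1/\mathrm{OR}$, monotone in each driver, and equals
$\alpha$ at the null. In the motivating scenario — an outcome GWAS of 79,145
with 24,087 clinically diagnosed cases, OR 1.1 per SD, $\alpha = 0.05$ —
computed power is 57% at $R^2 = 3\%$ and 86% at $R^2 = 6\%$:

```{r power}
power_grid(n_total = 79145, n_cases = 24087, or_alt = 1.1, r2 = c(0.03, 0.06))
```

## The synthetic-data generator

Real cytokine and disease GWAS cannot be redistributed with a package, so
validation runs on `simulate_summary_level()`: true SNP-exposure effects
$\gamma_j \sim N(0.15, 0.05^2)$ SD per allele, standard errors from the
standard GWAS approximation $\mathrm{se}_X = 1/\sqrt{2 n_X\,
\mathrm{maf}(1-\mathrm{maf})}$ (binary outcomes inflate by
$1/\sqrt{p(1-p)}$), estimates drawn from their sampling distributions around
$\gamma_j$ and $\theta\gamma_j + \alpha_j$. Defaults describe the study the
package targets and were fixed once: exposure GWAS of 8,000 (the largest
cytokine cohorts), outcome GWAS of 79,145 with case fraction 24,087/79,145,
MAF uniform on (0.05, 0.5) as for post-QC variants. The $\gamma$ distribution
gives per-variant F around 40–130, consistent with instruments that reached
genome-wide significance in cohorts of that size. Pleiotropy regimes:
`balanced` (zero-mean direct effects), `directional` (non-zero mean,
InSIDE holding), `inside_violating` (direct effects correlated with
$\gamma$); `invalid_fraction` controls how many variants are affected.

`simulate_individual_level()` generates genotypes explicitly
($G_j \sim \mathrm{Bin}(2, \mathrm{maf}_j)$), builds the exposure with
residual variance $1 - \mathrm{var(genetic)} - c^2$ so that
$\mathrm{Var}(X) = 1$ by construction — keeping $\gamma$ in SD units so the
two generator paths agree in law, which the suite checks by KS test — and
reduces to summary statistics by per-SNP linear regression or, for binary
outcomes, the logistic score test. A guard refuses runs needing more than
$10^8$ genotype draws. `scramble_alleles()` corrupts allele coding for
harmonisation tests; it draws the palindromic designation from the seed
before the corruption draws, so the same seed reproduces the designation on
the exposure side.

What the generator does **not** emulate: LD between instruments (they are
post-clumping independent by construction), covariate adjustment (sex, age,
BMI) and any collider bias it could induce, sample overlap between the two
GWAS, and winner's curse from selecting instruments in the same sample that
estimates them. Passing recovery tests therefore demonstrates correctness of
the estimators under the stated model, not robustness to those
real-data complications.

## Validation design and problem sizes

The acceptance suite (also re-run by `scripts/acceptance.R`) uses these
experiment sizes, chosen to make Monte-Carlo error small relative to the
quantities checked: 1000 replicates of 30-instrument studies for recovery
(mean IVW within 0.005 of $\theta = 0.1$) and for type-I error (99% binomial
band 3.2–6.8% around 5%); 500 replicates for the directional-pleiotropy
comparison (weighted median less biased than IVW, Egger intercept tracking
the mean simulated direct effect); 2000 replicates of 10-variant homogeneous
studies for Q calibration against $\chi^2_9$; 200 random instances against an
independently coded WLS oracle at $10^{-10}$; 500 random instances against a
brute-force clumping oracle; a 200-variant corruption round-trip. Q
calibration uses exposure and outcome GWAS of 20,000 each: first-order
weights ignore the $\theta^2\mathrm{se}_X^2$ term, and at these sizes that
inflates Q by about 1%, invisible to a KS test at this scale.

## Numerical choices and edge cases

* Confidence intervals use the fixed 95% normal quantile 1.959964; Egger
  p-values use the normal reference (some implementations use t — reconcile
  by $J-2$ df).
* Missing p-values are recomputed as two-sided normal from beta/se; stated
  p-values inconsistent with beta/se by more than a factor of two warn but do
  not drop the row. Duplicate variant IDs keep the smallest-p row.
* `ivw()` with one pair delegates to `wald_ratio()` (exactly, by construction);
  a zero exposure effect in a Wald ratio is an error, all-zero exposure
  effects make IVW undefined.
* The weighted-median bootstrap requires an explicit seed; all seeded helpers
  restore the caller's RNG state.
* Clumping treats variants absent from the LD matrix as unlinked (with a
  warning) rather than failing, matching how partial LD panels are used in
  practice.

## Limitations

The package deliberately omits multivariable MR, MR-PRESSO, mode-based
estimators, Steiger directionality filtering and the I²GX weak-instrument
correction for Egger. The power formula is a normal approximation; its
accuracy is verified against a Monte-Carlo oracle at matched non-centrality,
not against individual-level logistic simulation. OR-scale reporting for
score (non-binary) outcomes mirrors common practice in published tables but
is labelled, since $\exp(\beta)$ of an SD-scale effect is not an odds ratio.
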