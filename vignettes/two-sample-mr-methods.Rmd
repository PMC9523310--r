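---
title: "Two-sample Mendelian randomization: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ironmr)
```

## The scientific problem

Observational associations between systemic iron status and liver
dysfunction are confounded (diet, alcohol, adiposity) and plausibly
reverse-causal: a damaged liver disturbs iron homeostasis because the liver
both stores iron and synthesizes its regulatory proteins. Mendelian
randomization (MR) sidesteps both problems by using genetic variants as
instrumental variables: alleles are assigned at conception, so an allele
that raises iron status is not correlated with lifestyle confounders, and
disease onset cannot alter it.

`ironmr` implements the two-sample flavour of this design, in which the
variant–exposure associations ($\hat\beta_{Xj}$, with standard error
$\sigma_{Xj}$) and the variant–outcome associations ($\hat\beta_{Yj}$,
$\sigma_{Yj}$) come from two different GWAS. The motivating application is
iron status — four indicators: serum iron, ferritin, transferrin
saturation, and transferrin (which *falls* as iron status rises) —
instrumented by three strong variants in *HFE* and *TMPRSS6*, against liver
function biomarkers (ALT, AST, ALP, GGT, bilirubins) and liver diseases
(NAFLD, alcoholic liver disease, fibrosis/cirrhosis, viral hepatitis,
malignant neoplasm), with sex-stratified and reverse-direction analyses.
Everything is driven by summary statistics; no individual-level data are
touched.

## The causal model and its estimators

For variant $j$, the structural model is

$$\beta_{Yj} = \theta\,\beta_{Xj} + \alpha_j,$$

where $\theta$ is the causal effect of one SD of exposure on the outcome
(SD units for continuous outcomes, log odds for binary ones) and
$\alpha_j$ is the variant's direct ("horizontally pleiotropic") effect on
the outcome. A valid instrument has $\alpha_j = 0$.

**Wald ratio.** Per variant, $\hat\theta_j = \hat\beta_{Yj} /
\hat\beta_{Xj}$. The default standard error is the first-order delta-method
term $\sigma_{Yj} / |\hat\beta_{Xj}|$; the second-order expansion
$\sqrt{\sigma_{Yj}^2/\hat\beta_{Xj}^2 + \hat\beta_{Yj}^2
\sigma_{Xj}^2/\hat\beta_{Xj}^4}$ is available via `se_order = "second"`.
First order is the package default because with strong instruments
(F well above 10) the exposure-side term is negligible, and it is the
convention most summary-data MR software follows; the choice is a flag, not
a fork.

**Fixed-effect IVW.** The inverse-variance-weighted pool
$\hat\theta = \sum_j w_j \hat\theta_j / \sum_j w_j$ with $w_j =
\mathrm{se}(\hat\theta_j)^{-2}$ and $\mathrm{se}(\hat\theta) =
(\sum_j w_j)^{-1/2}$. This is the main analysis; it is consistent only when
every instrument is valid. With a single instrument it reduces exactly to
that instrument's Wald ratio. `heterogeneity_q()` provides the companion
Cochran Q against the pooled value.

**MR-Egger.** Weighted least squares of $\hat\beta_{Yj}$ on
$\hat\beta_{Xj}$ with a free intercept, weights $\sigma_{Yj}^{-2}$,
after orienting every variant so $\hat\beta_{Xj} > 0$. The intercept
estimates the average direct effect: a non-null intercept is evidence of
directional pleiotropy and hence that the IVW estimate is invalid. The
slope remains consistent for $\theta$ when instrument strength is
independent of the direct effects (InSIDE). Standard errors use the
multiplicative random-effects convention with the residual scale floored
at 1: over-dispersion inflates the SEs, under-dispersion is never allowed
to shrink them below their fixed-effect values. The fit itself is an
ordinary `stats::lm` weighted fit; only the SE convention is adjusted.

**Weighted median.** The 50% weighted quantile of the per-variant ratios,
with normalized first-order weights $w_j \propto
(\sigma_{Yj}/|\hat\beta_{Xj}|)^{-2}$: ratios are sorted, the centred
cumulative weights $s_j = \sum_{k \le j} w_k - w_j/2$ computed, and the
estimate interpolated linearly at $s = 0.5$. It is consistent as long as
valid instruments contribute more than half of the total weight, which is
what makes it the standard sensitivity analysis against invalid
instruments. Its standard error has no closed form; the package uses a
parametric bootstrap (default 10,000 draws, seedable) resampling both
$\hat\beta_{Xj}$ and $\hat\beta_{Yj}$ from their sampling distributions.
`n_boot = 0` returns the point estimate alone (`NA` SE) for simulation
studies that only need the estimate — the replicate loops in the package's
own tests use this mode.

Binary-outcome estimates live on the log-odds scale throughout;
`to_odds_ratio()` exponentiates the estimate and its confidence bounds at
the end. All confidence intervals use the fixed multiplier
$z_{0.975} = 1.959964$ (written out to six decimals rather than calling
`qnorm` at run time) so interval bounds are bit-reproducible.

## Harmonization

Two GWAS rarely report the same variant against the same allele.
`harmonize()` aligns each shared rsid to the exposure's effect allele:
matching alleles pass through; swapped alleles negate
$\hat\beta_{Yj}$ and reflect the allele frequency; complementary alleles
(strand difference) are complemented first and then matched. Both files
are assumed to report the forward strand — summary tables carry no strand
column — so complement resolution is attempted only after direct and
swapped matching fail.

Palindromic variants (A/T, C/G) are the unresolvable case: a strand flip
is indistinguishable from an allele swap. The default policy
(`drop_ambiguous`, window 0.5 ± 0.08) drops them when either study's
allele frequency is missing or too close to 0.5, and otherwise aligns by
comparing which side of 0.5 the two frequencies fall on. This mirrors
common MR practice; the iron application is insensitive to the choice
because its three instruments are non-palindromic. Duplicated rsids within
one file are a hard error rather than a silent dedup — instrument sets
here are small and curated, and a duplicate signals an upstream problem.

`orient_exposure(..., "decrease")` expresses an exposure per SD *decrease*
by negating the exposure betas, used for transferrin so all four iron
indicators point in the iron-raising direction. This is deliberately a
trait sign flip and not an allele re-encoding: negating the beta *and*
swapping the allele labels would describe the identical association, which
harmonization would re-align, cancelling the sign and leaving every
estimate unchanged. The pipeline test
("exposure direction is honoured") pins the intended behaviour — the
decrease-oriented estimate is exactly the negative of the
increase-oriented one.

## Instrument selection and strength

`gw_filter()` applies the conventional genome-wide threshold
$P < 5\times10^{-8}$. `ld_prune()` enforces pairwise independence
($r^2 < 0.01$ by default) by greedy selection on ascending p-value, with
lexicographic rsid order as the deterministic tie-break; the $r^2$ matrix
is user-supplied (read from a square TSV) because the intended instrument
sets are a handful of curated variants, not genome-wide clumping input.

`f_statistic()` reports both common strength formulations, because
published instrument tables rarely say which was used: the squared Wald
ratio $(\hat\beta/\sigma)^2$, always available, and
$R^2(n-2)/(1-R^2)$ with per-variant variance explained
$R^2 = 2\,\mathrm{EAF}(1-\mathrm{EAF})\hat\beta^2$ (standardized trait),
available when EAF and sample size are present. $F > 10$ is the
conventional weak-instrument bar.

## Power

`mr_power_continuous()` uses the non-centrality approximation
$\mathrm{NCP} = n\,R^2_{GX}\,\theta^2$, power
$= \Phi(-z_{1-\alpha/2} + \sqrt{\mathrm{NCP}}) +
\Phi(-z_{1-\alpha/2} - \sqrt{\mathrm{NCP}})$ — equivalently the 1-df
non-central chi-square form. `mr_power_binary()` follows the published
calculator formula for binary outcomes: the odds ratio is attenuated to
$b = K\left(\frac{\mathrm{OR}}{1 + K(\mathrm{OR}-1)} - 1\right)$ at case
fraction $K$, with variance $(K(1-K) - b^2)/(nR^2_{GX})$, and the same
NCP-to-power mapping. At the null both variants return exactly $\alpha$.
One consequence of using the exact attenuation rather than its small-effect
linearization $b \approx K(1-K)\ln \mathrm{OR}$: power is symmetric in
$\mathrm{OR} \leftrightarrow 1/\mathrm{OR}$ exactly only at $K = 0.5$,
and approximately (to well under a percentage point) elsewhere; the tests
assert exact symmetry only where the formula provides it.

## The synthetic-data generator

`simulate_two_sample()` simulates at the *summary* level: true instrument
effects $\beta_{Xj}$ are fixed (or drawn from a configured range), direct
effects $\alpha_j$ are zero for valid instruments and
$\mathcal{N}(\mu, \sigma_\alpha^2)$ draws for a configured invalid
fraction ($\mu = 0$ for balanced pleiotropy, $\mu \ne 0$ for
directional), true outcome effects follow
$\beta_{Yj} = \theta\beta_{Xj} + \alpha_j$, and the observed estimates are
normal draws with the stated SEs. Direct effects are drawn independently
of instrument strength, so InSIDE holds by construction — the regime in
which the Egger intercept estimates the mean direct effect. Defaults
emulate the iron design: three instruments with per-allele effects of
0.08–0.35 SD estimated in a study of ~49,000 subjects (F in the tens to
hundreds) against a far larger outcome study. A configurable fraction of
outcome rows is re-emitted with swapped or strand-complemented allele
labels — pure re-encodings that harmonization must undo exactly, which the
tests verify.

What this emulates well: the sampling model every summary-statistic
estimator actually assumes, with known ground truth for $\theta$ and
$\alpha_j$. What it does not emulate: linkage disequilibrium between
instruments (the intended design prunes to $r^2 < 0.01$, so instruments
are independent by construction), sample overlap between the two studies,
individual-level binary-trait generation (binary outcomes are simulated
directly on the log-odds scale, an approximation accurate for small
per-variant effects), allele-frequency differences between studies, and
population stratification. Passing tests therefore certify the estimators
and plumbing under the assumed sampling model, not robustness to
violations the model excludes.

`make_iron_fixture()` is a deterministic, noise-free three-variant set at
realistic magnitudes (documented true effect 0.4 SD/SD, one row shipped
with swapped alleles) used in documentation and integration tests; its
allele labels and effect sizes are synthetic, not the published
per-variant estimates.

## The study runner

`run_study()` evaluates every exposure × outcome × method cell:
instrument subsetting, harmonization, optional outcome-scale transforms,
per-variant Wald ratios, pooling. Scale transforms are explicit per-outcome
configuration — `sd_scale` divides natural-unit betas by a supplied
phenotype SD, and `case_fraction` converts linear-model betas on a binary
trait to log odds by dividing by $K(1-K)$ — never inferred from the data.
Sex strata are pure configuration: a stratum differs only in which summary
file it points at, since sex-specific instrument effects for iron are not
available and the pooled exposure effects are reused. Instruments missing
from an outcome GWAS are dropped with a per-cell note in the run manifest
and the analysis proceeds with the remaining subset (real outcome GWAS do
lack some variants); estimators needing three instruments yield flagged
`NA` rows rather than errors. Reverse MR (`run_reverse()`) is the same
pure function with exposure and outcome roles swapped in the
configuration. Significance is annotated at the nominal level only
(default $P < 0.05$), with no multiplicity correction, matching the
analysis the package was designed around; the `significant_nominal` column
is a label, not an inferential claim.

Determinism: every stochastic step (simulation, weighted-median bootstrap)
is seeded from the configuration, and a repeated `run_study()` call is
byte-identical.

## Numerical and testing choices

* Degenerate inputs error early and name the offending variant: zero
  exposure beta (undefined ratio), non-positive SE, fewer than three
  instruments for Egger/median, an Egger design with all exposure effects
  equal after orientation.
* The weighted-quantile interpolation clamps to the extreme ratio when one
  instrument holds all the weight.
* The test suite's simulation studies use 1,000 replicates for parameter
  recovery, 2,000 for test size (binomial 95% bounds around 0.05), and 300
  for the contamination and Egger-recovery checks — sizes chosen so
  Monte-Carlo error is well below the effects being detected while the
  whole suite runs in a few minutes on one CPU. The robustness check uses
  40% invalid instruments with directional pleiotropy (mean 0.1): the
  weighted median is required to keep less than half of IVW's median bias.
  The Egger-recovery check draws a direct effect for *every* instrument,
  because the intercept estimates the mean direct effect across all
  instruments, not the mean of the invalid subset.
* Estimator algebra is pinned against independent oracles (explicit
  weighted sums; normal-equations WLS) to $10^{-10}$ on random instrument
  sets.

## Limitations

The package implements the standard summary-data MR toolkit and its
standard assumptions; it does not implement outlier-removal estimators
(MR-PRESSO), mode-based or mixture estimators, multivariable MR, LD-aware
methods, or any individual-level analysis. Binary-outcome Wald estimators
carry a known small non-collapsibility bias (typically within 10%), which
is inherited from the design, not corrected. The simulator's scope is
described above; conclusions about real-data behaviour beyond its sampling
model require real data.
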