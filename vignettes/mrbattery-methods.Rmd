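---
title: "Methods and design notes for mrbattery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mrbattery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrbattery)
```

## The causal model

Two-sample Mendelian randomization treats genetic variants as instrumental
variables. For SNP $j$, let $\beta_{Xj}$ be its effect on the exposure
(in phenotype SDs) and $\beta_{Yj}$ its effect on the outcome (log-odds for
a binary outcome). If the only path from SNP to outcome runs through the
exposure, then $\beta_{Yj} = \theta\,\beta_{Xj}$ for all valid instruments,
and $\theta$ — the change in outcome per SD of exposure — is the causal
quantity of interest. The estimators consume only the GWAS summary
estimates $\hat\beta_{Xj}, \hat\sigma_{Xj}, \hat\beta_{Yj}, \hat\sigma_{Yj}$
from two non-overlapping samples.

Three assumptions carry the interpretation: the instruments are truly
associated with the exposure (enforced by the $p < 5\times10^{-8}$
selection threshold); they are unconfounded with the outcome (justified by
random allele allocation); and they act on the outcome only through the
exposure (no pleiotropy — untestable directly, hence the sensitivity
analyses below).

## Harmonization

Exposure and outcome tables are inner-joined on variant id and the outcome
effect is re-signed onto the exposure's effect allele, recognising both
allele-swap and strand (reverse-complement) representations. Two filters
are applied before any analysis:

* **Palindromic variants** (A/T or C/G) are always dropped: their strand
  cannot be resolved from the alleles, so an apparent match may silently be
  a flip. No frequency-based strand inference is attempted.
* **Imputation quality**: variants with info score below 0.9 are dropped.
  The filter is applied *symmetrically* — a variant fails if either the
  exposure or the outcome record falls below the threshold. Which side's
  info should govern is genuinely open; the symmetric rule is the
  conservative choice and is what the `n_dropped_info` counter reports.

When several exclusion rules fire for one variant, the counter precedence
is palindromic > low info > allele mismatch; retention is unaffected.
Drop accounting is exact: shared variants = retained + the three counters.

Missing genetic-map positions are imputed as `pos_bp / 1e6` (1 cM per Mb,
the genome-wide average recombination rate) with a warning. This keeps the
centimorgan-window thinning available when no genetic map is distributed
with the summary statistics; users with a real map should supply `CM`.

## Instrument selection

Selection is greedy by ascending selection-side p-value — standard clumping
practice — with ties broken by (chromosome, position, variant id) so output
is deterministic under any input order. A candidate is kept iff no
already-kept variant is simultaneously within `window_cm` (inclusive, 3 cM
default) and correlated above `r2_max` (0.05 default). Both conditions must
hold: distant correlated pairs and near uncorrelated pairs are allowed.
Pairs absent from the LD table count as $r^2 = 0$ rather than erroring —
real LD references are sparse, and pairs on different chromosomes are
rarely listed at all. The test suite certifies the output by exhaustive
pair checking and by comparison with an independently coded brute-force
greedy pass on all instances of up to 12 SNPs.

## Variance explained

For a quantitative trait in SD units the instrument set explains
$100\sum_j 2p_j(1-p_j)\beta_j^2$ percent of phenotypic variance, $p_j$ the
effect-allele frequency. For a binary trait there is no single canonical
formula; the one implemented maps each log-odds effect to the observed 0/1
scale via the logistic derivative at the sample case fraction $P$
($\beta_{obs} = \beta P(1-P)$), sums as above, and converts to the
liability scale with the threshold-model factor
$K^2(1-K)^2 / (z^2 P(1-P))$, where $K$ is the population prevalence and $z$
the standard-normal density at the $(1-K)$ quantile. It is validated
against an independently coded transform, not against any external table;
treat the output as approximate.

## Estimators

All four analyses run on the instrumented, harmonized rows; weights are
always the inverse squared outcome SEs, $w_j = 1/\sigma_{Yj}^2$.

**IVW.** Weighted regression through the origin:
$\hat\theta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j \hat\beta_{Xj}^2$.
Heterogeneity is summarised by Cochran's
$Q = \sum w_j(\hat\beta_{Yj} - \hat\theta\hat\beta_{Xj})^2$. The standard
error is the fixed-effect SE times $\max(1, \sqrt{Q/(J-1)})$ — the
multiplicative random-effects model with the dispersion floored at one.
This matches the common default of standard MR software; pass
`random_effects = FALSE` for the pure fixed-effect SE. The floor makes
intervals slightly conservative when the data are under-dispersed, which
shows up as 95% CI coverage a little above 0.95 in the calibration tests.

**Pleiotropy exclusion.** The per-SNP contribution
$Q_j = w_j(\hat\beta_{Yj} - \hat\theta\hat\beta_{Xj})^2$ is referred to
$\chi^2_1$; SNPs with $p_j < 0.05/N$ ($N$ = number of instruments) are
excluded and IVW re-run. A per-SNP "evidence of pleiotropy" test can be
formulated several ways (leave-one-out, direct outcome association,
software-specific variants); the Q-contribution form was chosen because it
needs nothing beyond the summary statistics already in hand and reduces to
the familiar Cochran decomposition. With fewer than 2 survivors the
operation errors rather than report a meaningless fit.

**Weighted median.** Wald ratios $\hat\beta_{Yj}/\hat\beta_{Xj}$ are
ordered; with normalized weights $w'_j$ and cumulative sums $S_j$, the
estimate is the ratio at which $S_j - w'_j/2$ crosses $1/2$, linearly
interpolated between adjacent ratios. It is consistent while at least half
the weight comes from valid instruments. Ratio SEs are first-order
($\sigma_{Yj}/|\hat\beta_{Xj}|$); the second-order correction is out of
scope. The slope SE comes from a parametric bootstrap (default 1000
replicates): resample $\hat\beta^*_{Yj}\sim N(\hat\beta_{Yj},\sigma_{Yj}^2)$,
$\hat\beta^*_{Xj}\sim N(\hat\beta_{Xj},\sigma_{Xj}^2)$, recompute, and take
the SD across replicates. The seed is part of the call signature, recorded
in the result, and the caller's RNG state is restored, so identical seeds
give bit-identical results. `n_boot = 0` skips the bootstrap (SE and
p-value `NA`) for simulation studies that need only the point estimate.

**MR-Egger.** Before fitting, every SNP is oriented so its exposure effect
is positive (the outcome effect re-signed with it); without a fixed
orientation the intercept of the with-intercept weighted regression has no
meaning. The intercept estimates the average directional pleiotropic
effect; its two-sided test at 0.05 is the directional-pleiotropy check.
Slope and intercept SEs use the same multiplicative inflation as IVW with
$J-2$ residual degrees of freedom. P-values throughout the package are
two-sided normal; at typical instrument counts (dozens to hundreds) the
normal-vs-t distinction is negligible, and using one reference everywhere
keeps the significance flag exactly equivalent to the `critical_z()` route.

## The battery

`run_battery()` runs each trait against the outcome in both directions. The
two directions are asymmetric by construction: instruments are always
re-selected on whichever table is the exposure, and different source tables
can serve instrument selection versus genome-wide outcome lookup (a
case-control GWAS that only publishes its top SNPs can still provide
instruments, while the direction that needs genome-wide coverage uses a
fully released companion GWAS).

Significance is attached to the *all-SNP IVW* slope only, at
$p < \alpha/n_{tests}$; the other three analyses are sensitivity checks and
never drive the flag. `n_tests` is a configuration constant (default 42,
i.e. 21 traits × 2 directions), not derived from the cells actually run, so
partial runs keep the same threshold. The equivalent absolute-z threshold
is `critical_z(0.05, 42)` ≈ 3.24; note the commonly quoted round figure of
"3 SDs" for this threshold actually corresponds to the one-sided quantile
(≈ 3.04) — the package always uses the exact two-sided value, and the test
suite asserts the p-value and z routes agree cell by cell. Per-cell
failures (too few instruments after selection or exclusion) are recorded in
the report's `notes` column and do not abort the battery.

## The simulator

`simulate_pair()` draws summary statistics directly at the estimate level
rather than simulating genotypes: each SNP gets a true effect, and the
"GWAS" estimate is normal noise around it with the analytic SE
$1/\sqrt{2p(1-p)n}$ (quantitative) or $1/\sqrt{2p(1-p)n\,v(1-v)}$
(binary, $v$ the case fraction, log-odds scale). This gives exact control
of the noise model, runs in milliseconds, and suffices for every property
the pipeline tests. Defaults emulate a large-biobank quantitative exposure
(n = 330,000) against a case-control psychiatric outcome (n = 173,000,
case fraction 0.346, population prevalence 0.15).

Choices worth knowing:

* **Instrument strength.** Causal SNPs receive association z-scores
  $\sim N(0, 40^2)$ at the exposure sample size, so roughly 88% of causal
  SNPs clear genome-wide significance; sub-threshold causal SNPs simply go
  unselected. Strong instruments keep winner's-curse and regression-dilution
  bias negligible, which is what the parameter-recovery checks require.
* **Pleiotropy** is applied to a configurable fraction of causal SNPs as a
  direct outcome effect $N(\mu, \sigma^2)$ *on the exposure-increasing
  allele*. Because alleles are randomly oriented, a direct effect drawn
  independently of the exposure sign would cancel after Egger's
  orientation, making "directional" pleiotropy undetectable by
  construction; anchoring it to the exposure-increasing allele makes $\mu$
  the actual Egger intercept magnitude. The truth ledger stores the signed
  direct effect, so outcome truth = θ·(exposure truth) + direct effect
  holds exactly per SNP.
* **LD and maps.** SNPs sit in blocks whose members share a single
  $r^2$ (default 0.9) and lie within 1 cM; blocks are ≥ 5 cM apart, and
  causal SNPs are placed one per block at a randomized within-block slot so
  independent simulations do not share causal positions. This is a
  caricature of real LD — no decay with distance, no inter-block leakage —
  but it is exactly the structure the 3 cM/0.05 thinning rule is defined
  over, which is what needs testing.
* **Contamination.** Configurable fractions of SNPs (disjointly) receive
  palindromic allele pairs or outcome-side info scores in [0.5, 0.89];
  harmonization is expected to remove precisely these.

What the simulator does **not** emulate: sample overlap between the two
GWAS (estimation noise is independent by design — a true two-sample
setting), realistic LD decay, allele-frequency–dependent architecture,
population stratification, and binary-trait non-collapsibility subtleties
(the logistic SE formula is the standard approximation; tests compare
against the simulator's own ledger, so exactness is immaterial). Passing
tests therefore demonstrate correctness of the pipeline's logic and the
estimators' statistical behaviour under the stated model, not robustness
to the full messiness of real GWAS.

## Problem sizes and numerical tolerances

The statistical test battery uses 150-instrument simulations at
300,000/173,000-scale sample sizes: 300 replicates for parameter recovery
(mean IVW within 0.2 ± 0.01, coverage in [0.92, 0.97]), 500 for type-I
error ([0.03, 0.07] nominal), 200 for the directional-pleiotropy ordering
(IVW bias exceeds weighted-median bias in ≥ 95%, Egger intercept power
≥ 80% at μ = 0.05) and 500 for balanced-pleiotropy Egger calibration
([0.03, 0.07]) — sizes at which the Monte-Carlo bands above have
comfortable margins. Estimator/oracle agreement is required to $10^{-10}$
relative error against `lm()`-based weighted-least-squares fits on 1000
random instances; selection agreement with the brute-force oracle is
required exactly on 200 instances of ≤ 12 SNPs. P-values written by the
simulator are floored at $10^{-300}$ (the two-sided normal p underflows
for $|z| \gtrsim 37$), and the read-time consistency check between p and
$\beta/\mathrm{SE}$ (10% relative tolerance) is skipped below that floor.

## Known limitations

* Palindromic SNPs are always discarded; no frequency-based rescue.
* No liftover: positions are taken as given, and cM imputation at
  1 cM/Mb is crude near recombination hotspots.
* First-order Wald-ratio SEs; weak-instrument corrections (e.g.
  second-order SEs) are not implemented.
* The estimator set is exactly: IVW, exclusion-IVW, weighted median,
  MR-Egger. No mode-based, multivariable, or outlier-search estimators.
* LD is an input; the package never computes it from genotype panels.
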