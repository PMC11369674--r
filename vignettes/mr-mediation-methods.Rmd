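---
title: "Methods: two-sample and mediation MR with mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample and mediation MR with mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The inference problem

`mrmediate` estimates causal effects of molecular exposures (for instance
individual lipid species) on a disease outcome (for instance deep venous
thrombosis, DVT) from GWAS summary statistics, and decomposes those effects
through candidate mediators (for instance circulating inflammatory
proteins). All estimators are valid under the three instrumental-variable
assumptions: each instrument is (1) strongly associated with the exposure,
(2) independent of exposure-outcome confounders, and (3) affects the
outcome only through the exposure. Assumption (1) is checkable and is
enforced by significance and F-statistic filters; (2) and (3) are not
checkable from summary data, which is why the estimator suite spans methods
with different failure modes (IVW, MR-Egger, medians) plus heterogeneity
and pleiotropy diagnostics.

## Instrument selection and strength

Instruments are variants with exposure p-value strictly below `p_threshold`
(default 5e-8, conventional genome-wide significance), thinned by greedy LD
clumping: repeatedly keep the smallest-p remaining variant and discard
remaining variants on the same chromosome within `window_kb` kilobases
(default 5000) whose r² with it exceeds `r2_max` (default 0.001). Ties on p
are broken by chromosome, position, then variant id so the result is
independent of row order; cross-chromosome pairs are never clumped
regardless of the supplied r².

Per-variant instrument strength uses the variance explained
r² = 2·MAF·(1−MAF)·(β/SD)² with SD = SE·√N, and
F = ((n − K − 1)/K)·(r²/(1 − r²)). Two conventions coexist in the applied
literature and both are served: the default per-variant F takes K = 1 with
that variant's r² (and `filter_weak()` drops variants with F ≤ 10, the
usual weak-instrument bar); `instrument_strength()` also reports a joint F
with K equal to the set size and r² summed. Likewise the variance-explained
formula is sometimes printed without the square, as 2·MAF·(1−MAF)·(β/SD);
because that expression is dimensionally inconsistent for a variance share
we default to the squared form, but `mode = "paper_verbatim"` evaluates the
unsquared expression exactly so published arithmetic can be replayed — the
discrepancy is surfaced, never silently corrected.

## Harmonization

Variants are matched across traits by identifier only (no position-based
rescue — the simplest auditable rule). When the outcome's effect/other
alleles are swapped relative to the exposure, the outcome beta is negated
and its EAF replaced by 1 − EAF. Palindromic variants (A/T, C/G) are kept
only when both aligned frequencies sit on the same side of 0.5 and both lie
outside (`palindrome_eaf_limit`, 1 − `palindrome_eaf_limit`); the default
limit 0.42 treats frequencies in (0.42, 0.58) as strand-unresolvable. This
threshold is a free parameter of convention, not an estimate. Variants with
missing EAF stay in the analysis when non-palindromic but are excluded
(with a warning) from r²/F computations that need allele frequency.

## Estimators

With bx, by the aligned effect vectors and sy the outcome SEs:

- **IVW**: weighted least squares of by on bx through the origin, weights
  1/sy². The fixed model reports the nominal SE (Σ bx²/sy²)^(−1/2); the
  multiplicative random-effects model inflates it by √max(1, Q/(K−1)). The
  default (`model = "auto"`) uses random-multiplicative with K ≥ 3 and
  fixed otherwise, mirroring dominant MR-package behaviour. Note the floor
  at the nominal SE makes the random model deliberately conservative under
  homogeneity; the calibration property (5% size under the null) is a
  property of the fixed-effect z-test, and that is what the calibration
  tests check.
- **MR-Egger**: the same regression with a free intercept. The fit depends
  on allele orientation, which published descriptions often leave implicit;
  we state the convention explicitly: every variant is re-signed so bx ≥ 0
  before fitting. Coefficient SEs are inflated by max(1, σ̂) with σ̂² the
  weighted residual mean square.
- **Weighted median**: the weighted 50th percentile (linear interpolation
  over cumulative normalized weights, midpoint convention for even counts)
  of the per-variant ratios by/bx. The weights are the inverse first-order
  variances of the ratios, bx²/sy² — the delta-method choice, since the
  estimator's description in the applied literature fixes no weighting.
  The simple median is the same machinery with uniform weights. SEs come
  from a parametric bootstrap (default 1000 replicates) resampling bx and
  by from normals with their reported SEs; the seed is mandatory so runs
  are bit-reproducible, and the sampler restores the caller's RNG state.
- **Multivariable MR**: weighted least squares of by on the matrix of
  exposure betas without intercept (the standard formulation), weights
  1/sy²; SEs from the weighted normal equations. Measurement error in the
  exposure betas is ignored, as in standard summary-data MVMR — a known
  limitation, stated rather than patched. An all-zero exposure column gets
  coefficient 0 with infinite SE instead of poisoning the design matrix.

All p-values use the standard-normal reference rather than t — the
summary-data convention — and 95% intervals use the conventional 1.96
multiplier, on the odds-ratio scale via exp(β ± 1.96·SE) for binary
outcomes.

## Sensitivity

Cochran's Q is Σ wj (rj − β̂_IVW-fixed)² with ratio weights wj = bx²/sy²,
referred to χ²(K−1); the fixed-effect IVW center is the standard choice
(descriptions in the applied literature rarely specify one). Leave-one-out
refits IVW excluding each variant in turn and flags exclusions that flip
the estimate's sign or move it across nominal significance (α = 0.05,
matching the screening convention).

## Two-step mediation

For a triplet with total effect c (exposure→outcome), a
(exposure→mediator) and b (mediator→outcome): indirect = a·b,
direct = c − a·b, proportion mediated = a·b/c (signed). By default b comes
from univariable mediator→outcome MR; an MVMR-adjusted b (conditioning on
the exposure) can be substituted by passing that estimate — published
workflows are usually silent on which they used, and the univariable choice
keeps the two-step decomposition self-contained.

The proportion's SE uses the delta method with the three estimates treated
as independent: var(a·b) ≈ a²·var(b) + b²·var(a), then
var(a·b/c) ≈ var(a·b)/c² + (a·b)²·var(c)/c⁴, CI = proportion ± 1.96·SE. A
seeded Monte-Carlo interval (normal resampling of a, b, c) is available as
an alternative; the two agree closely away from c ≈ 0, where any ratio
interval degrades. When c = 0 the proportion is reported missing.

Classification: *masking* when the indirect effect is nominally significant
and opposes the total effect's sign (the mediator suppresses part of the
direct effect), *mediation* when aligned and both significant, *none*
otherwise. When inputs are bare point values (replaying a published table)
significance cannot be assessed and the classification falls back to signs
alone. The table writer prints |proportion| with the classification flag,
matching the convention of reporting magnitudes for suppression rows, and
keeps the signed value alongside. One pitfall worth documenting: in
published decomposition tables the column labelled c′ sometimes matches
a·b rather than c − a·b; `mediated_proportion_table()` therefore emits both
`indirect` and `direct` under unambiguous names.

## The simulator

`structural_model()`/`simulate_sumstats()` generate marginal summary
statistics for three traits on a shared variant panel:

- exposure: β_X = γ + ε, with γ the variant→exposure effects;
- mediator: β_M = a·γ + δ + ε, with δ variant→mediator direct effects
  (pQTL-style instruments of the mediator itself);
- outcome (log-odds scale): β_Y = (direct + a·b)·γ + b·δ + pleiotropy + ε.

The mediator-specific δ effects are a deliberate design choice: with
exposure-driven instruments only, every variant significant for the
mediator would be an exposure instrument, whose outcome/mediator ratio
estimates c/a rather than b, and the two-step decomposition would be
unidentifiable. Giving the mediator its own instruments mirrors how real
mediation MR uses pQTLs for the protein.

SEs follow 1/√(2·MAF·(1−MAF)·N) for unit-variance traits, MAFs are uniform
on `maf_range` (default 0.05–0.5), noise is independent across traits —
the two-sample non-overlap assumption — and p-values are floored at the
smallest positive double to survive validation at extreme z-scores. When
instrument effects are auto-drawn, magnitudes are uniform on 0.02–0.08
with random signs: at the default sample sizes (2×10⁵ for the continuous
traits, 4×10⁵ for the outcome) that makes exposure instruments clearly
genome-wide significant (|z| ≈ 8–35) while keeping the a·γ shadow of the
exposure on the mediator below the significance threshold, so the two
instrument sets stay cleanly separated. Default structural effects
(a = 0.1, b = 0.3, direct = 0.06, hence c = 0.09 and proportion mediated
1/3) put all three links at comfortable but not extreme power — the regime
in which a mediation screen is informative. `make_masking_scenario()`
rescales the direct effect to −ratio·(a·b) (ratio 2 by default, so
|direct| > |a·b|), producing a total effect whose sign opposes the
indirect path.

LD is block-diagonal (default blocks of 4 at r² = 0.3, each block within a
clumping window on one chromosome, blocks separated beyond it) so the
clumping rule has verifiable structure to act on. Two simplifications are
documented rather than hidden: marginal betas are drawn independently even
within LD blocks (LD shapes the clumping problem, not the sampling
covariance of estimates), and there is no sample overlap, ancestry
structure, winner's-curse ascertainment or imputation noise. Passing tests
therefore demonstrate correctness of the algorithms under the stated
model, not robustness to every pathology of real GWAS.

## Screening workflow

`run_mediation_workflow()` chains the stages from one config: forward
screens of exposures and mediators against the outcome, pairwise
exposure→mediator MR among survivors, mediation for triplets whose three
links all pass `alpha`, and MVMR over all surviving traits jointly.
Screening uses raw p < 0.05 by default — matching the screening convention
of the applied workflows this package serves — with an optional
Benjamini–Hochberg mode clearly labelled as non-default behaviour. The
manifest records input checksums and every threshold; no output carries a
timestamp, so identical configs and seeds give byte-identical tables.
Exposures with no surviving instrument become `skipped` rows, not errors.
An option to exclude exposure instruments from the mediator's step-b
instrument set exists (`disjoint instruments` are obtained by passing a
pre-filtered mediator set); by default the sets are whatever significance
selection yields.

## Problem sizes in the test batteries

The shipped test suite verifies calibration with 2000 simulated null
replicates of 50 variants (binomial SE ≈ 0.5 percentage points on a 5%
rate), mediation-proportion coverage with 500 replicates of a 60-variant
mediated model, and masking classification with 200 replicates of a
ratio-3 masking scenario. These sizes give Monte-Carlo error comfortably
inside the asserted bands while keeping the whole suite inside a coffee
break on one core.

## Known limitations

- No genome-build liftover, VCF ingestion or proxy-variant lookup; variant
  matching is by id.
- MVMR ignores exposure-beta measurement error and reports no conditional
  F statistics.
- The delta-method proportion interval degrades when the total effect is
  near zero relative to its SE; the Monte-Carlo interval helps but no
  ratio interval is trustworthy there.
- The simulator's LD affects clumping only, and its effects are linear and
  homogeneous; real pleiotropic architectures can be nastier than the
  normal pleiotropy knob emulates.
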