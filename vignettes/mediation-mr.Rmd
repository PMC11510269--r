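---
title: "Methods: summary-statistics MR with mediation decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistics MR with mediation decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The causal model and its assumptions

`mrmediate` implements two-sample Mendelian randomization for a triad of
traits — an exposure X, one or more mediators M, and an outcome Y — from
GWAS summary statistics alone. Validity rests on the three instrumental
assumptions: each instrument is strongly associated with its trait, shares
no confounder with the outcome, and affects the outcome only through that
trait. The first is enforced empirically (genome-wide significance and an
F-statistic screen); the other two are untestable and are probed by the
sensitivity battery (Egger intercept, weighted median, MR-PRESSO,
leave-one-out).

The mediation engine assumes a *linear structural model with no
exposure–mediator interaction*: writing θ for the direct effect, α for the
exposure's effect on the mediator and β₂ for the mediator's effect on the
outcome, the total effect decomposes as

> β₁ = θ + α·β₂,

so the indirect effect is the product of coefficients and the proportion
mediated is PM = α·β₂\*/β₁, where β₂\* is the mediator's *direct*
(MVMR-conditional) effect. β₂\* rather than the univariable β₂ enters the
product because the univariable mediator→outcome leg is not protected
against instruments shared with the exposure: in our own simulations,
exposure SNPs whose mediator association α·γ reaches genome-wide
significance join the mediator's instrument list and carry the ratio
β₁/α rather than β₂, biasing the univariable leg. The univariable β₂ is
still computed and reported, as two-step MR convention expects, but it is
diagnostic only.

Uncertainties for α·β₂\* use the two-sample delta method with zero
covariance — appropriate because the two estimates come from
non-overlapping regressions (different instrument sets and outcome
columns); a seeded parametric bootstrap is available behind
`indirect_effect(method = "bootstrap")` for skewed cases. The PM interval
is the first-order delta method on the ratio. Inconsistent mediation
(indirect and total effects of opposite sign) is reported and flagged,
never clipped: a PM outside [0, 1] is information, not an error.

## Estimators and numerical choices

- **IVW** is the primary estimator, computed in closed form as the
  zero-intercept weighted least-squares slope with weights 1/SE_Γ². The
  default is *multiplicative random effects*: the fixed-effect SE is
  inflated by max(1, √(Q/(k−1))), so the two modes coincide exactly when
  heterogeneity is at or below its expectation. This default tolerates the
  low-to-moderate heterogeneity typical of dietary and anthropometric
  instruments without letting a handful of heterogeneous SNPs shrink the
  interval.
- **MR-Egger** orients all SNP–exposure effects non-negative before
  fitting, uses the same multiplicative scaling with k−2 degrees of
  freedom, and flags pleiotropy when the intercept's two-sided p is below
  0.05. P-values throughout use the standard normal rather than t — the
  usual many-instrument convention; with the 100-instrument regimes this
  package targets the difference is negligible.
- **Weighted median** sorts per-SNP Wald ratios with weights γ²/SE_Γ²
  normalized to one and interpolates where the midpoint cumulative weight
  crosses 0.5 (this reduces exactly to the ordinary median under equal
  weights). Its SE comes from a parametric bootstrap (default 1000
  replicates, mandatory seed) redrawing γ and Γ from their reported
  sampling distributions.
- **MR-PRESSO** follows the published algorithm: observed residual sum of
  squares against leave-one-out IVW expectations; a simulated null
  (default 1000 replicates) with its own leave-one-out slopes per
  replicate; plus-one empirical p-values (the global p can never reach 0,
  only 1/(n_sim+1)); per-SNP outlier p-values Bonferroni-corrected across
  instruments; and a distortion test whose null removes random
  size-matched subsets (1000 draws), skipped with a log note when nothing
  is flagged.
- **MVMR** solves the weighted normal equations directly after a
  condition-number guard (error above 1e12, reporting the number).
  Exposure columns with no association signal at all are excluded with a
  warning and returned as NA direct effects — a deliberate choice so that
  a degenerate mediator column reduces the fit exactly to the univariable
  model rather than poisoning the whole regression. The overdispersion
  scaling max(1, √(Q_mv/(k−m))) mirrors the univariable convention, and
  with m = 1 the routine reproduces univariable IVW to machine precision.
  The per-exposure conditional F statistic projects each exposure's
  associations on the others and rescales the residual on that exposure's
  own SE; summary data carry no cross-trait sampling covariance, so this
  is the standard covariance-free approximation.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `p_threshold` | 5×10⁻⁸ | p-value | genome-wide significance |
| `r2_max` / `window_kb` | 0.001 / 10,000 | r² / kb | clumping: independent iff different chromosome, or farther than the window, or (with an LD lookup) r² below the threshold; without LD data any same-chromosome pair inside the window is conservatively treated as correlated |
| `f_min` | 10 | F | conventional weak-instrument bound (strict inequality) |
| `palindrome_eaf_window` | 0.08 | allele freq | drop A/T and C/G SNPs with EAF in [0.42, 0.58], the common harmonization convention; outside the window strand is resolved by frequency agreement |
| `ivw_mode` | multiplicative random | — | see above; `fixed` available |
| `n_boot` | 1000 | replicates | weighted-median bootstrap; warning below 100 |
| `presso_n_sim` | 1000 | replicates | floor of the global empirical p is 1/1001 |
| `seed` | required | integer | every stochastic stage derives from it; reports are byte-identical across reruns |

Positions are 1-based and distance is |Δpos| in kb. Indels and
multi-allelic records are dropped at load with a reason, as are rows
violating the per-SNP invariants; every drop is auditable
(`write_dropped_audit`, and `dropped_snps.tsv` in pipeline output).

## What the generator emulates — and what it does not

`simulate_study()` draws summary statistics directly from the structural
model: instrument effects are sized as z-scores uniform on [7, 25] times
the theoretical SE 1/√(2Nf(1−f)) (binary outcome: 1/√(2Nφ(1−φ)f(1−f)),
case fraction default 0.08), so instruments pass the significance screen
with high probability and their F statistics land in the tens-to-hundreds
range reported by real strong-instrument screens. The defaults are the
package's reference study conditions, fixed once: θ = −0.19, α = −0.44,
β₂ = 0.19 (truth PM ≈ 0.3055, the geometry of a protective dietary
exposure mediated by adiposity), 100 instruments per trait, N = 200,000
per GWAS, independent noise across the three GWAS (no sample overlap, so
the zero-covariance delta method is exact in the generator's world).
Horizontal pleiotropy (balanced or directional), gross outliers of a given
SE multiple, and a mediator-independent null are all switchable.

Deliberate simplifications: no LD between SNPs (clumping is exercised
positionally; SNPs sit 20,000 kb apart), no population stratification, no
sample overlap, no winner's-curse in instrument effects, and only
non-palindromic allele pairs (a palindromic SNP near EAF 0.5 would be
dropped by design during harmonization, silently shrinking every planted
instrument set; strand and palindrome handling is instead exercised by
dedicated fixtures in the unit tests). Passing tests on this generator
therefore demonstrates the estimators' algebra and calibration, not
robustness to LD misspecification or overlapping samples.

## Verification at a glance

The suite checks, among others: exact hand-derived values for R²/F and the
IVW closed form; agreement with generic weighted-regression solvers to
1e-10; equivariance under outcome sign flips; uniformity of Cochran's Q
p-values and ~95% Egger-intercept coverage under a 500-replicate null;
recovery of (θ, α, β₂, PM) within 3 SE / the delta CI in ≥ 90% of 200
replicates at the reference conditions; MR-PRESSO detection of five
planted 10-SE outliers among 50 instruments with ≤ 2% false flags over 100
replicates; and byte-identical pipeline reports across reruns. Arithmetic
identities from a published dietary-habits mediation table (indirect
effects as α·β₂\*, proportions mediated as indirect/total) are reproduced
to printed precision from the printed inputs. These problem sizes keep the
full suite under a minute on a single core.

## Known limitations

- No Steiger directionality filtering, radial MR, mode-based or
  contamination-mixture estimators, and no MVMR-Egger.
- LD handling is lookup-based only; there is no reference-panel clumping
  or proxy-SNP search.
- The conditional F statistic ignores cross-trait sampling covariance.
- The mediation algebra is strictly linear; interaction or nonlinear
  mediation is out of scope.
- Binary-outcome effects are treated on the log-odds scale throughout;
  non-collapsibility of odds ratios is inherited from that choice.
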