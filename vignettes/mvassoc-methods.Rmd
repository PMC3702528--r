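---
title: "Partition-model Bayes factors for multivariate genetic association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partition-model Bayes factors for multivariate genetic association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvassoc)
```

## The model space

`mvassoc` assesses association between one genetic variant `g` (allele count
or dosage for `n` individuals) and `d` related quantitative phenotypes `Y`
(an `n × d` matrix). Every candidate explanation is a partition
`γ = (U, D, I)` of the traits:

* **U** (unassociated): `Y_U` is independent of `g`;
* **D** (directly associated);
* **I** (indirectly associated): `Y_I` is conditionally independent of `g`
  given `Y_D` — the association is mediated entirely by measured traits.

Since mediation needs a mediator, `D = ∅` forces `I = ∅`; the all-`U`
partition is the global null `H₀`. The space has `3^d − 2^d + 1` members
(6 for `d = 2`, 66 for `d = 4`, 212 for `d = 5`); `enumeratePartitions()`
refuses `d > 15`, where exhaustion stops being practical.

The point of the three-way split is that it embeds the familiar tests as
single partitions: the standard multivariate test is the all-`D` partition
(`BF_all`); the univariate test of trait `j` is the partition with `j`
direct and every other trait *indirect* (`BF_uni` averages these `d`
partitions with weight `1/d`); "test trait `j` controlling for the others"
is `j` direct, rest unassociated. Model-averaging over all partitions
(`BF_av`) therefore averages over all of these analyses at once, and the
posterior over partitions answers *which* traits are associated and *how*.

## Bayes factors from conjugate multivariate regression

Each non-null partition's support against `H₀` reduces to a ratio of two
Bayesian multivariate regressions (BMVRs) of the direct traits:

```
BF_γ = p(Y_D | Y_U, g) / p(Y_D | Y_U).
```

Indirect traits cancel from the ratio. For the BMVR `Y = XB + E` with rows
of `E` iid `N(0, Σ)` we use the conjugate pair `Σ ~ IW(H, m)` (inverse scale
`H`, `m` degrees of freedom) and `B | Σ ~ MN(0, K, Σ)` with diagonal `K`.
The coefficient rows get prior scales `σ_b` (intercept and conditioned-on
traits) and `σ_a` (the genotype row), both relative to the residual scale
because the prior covariance is `K ⊗ Σ`. Scaling by `Σ` means that a variant
raising one trait is a priori more likely to raise traits positively
correlated with it — a substantive but, absent contrary information,
reasonable default. `logMarginalBMVR()` evaluates the resulting matrix-t
marginal in closed form through Cholesky log-determinants:

```
log p(Y|X) = −(nd/2)·log π + log Γ_d((n+m)/2) − log Γ_d(m/2)
             + (m/2)·log|H| − ((n+m)/2)·log|S|
             − (d/2)·(log|K| + log|K⁻¹ + XᵀX|),
S = H + YᵀY − YᵀX (K⁻¹ + XᵀX)⁻¹ XᵀY.
```

The test suite verifies this expression against two independent oracles:
dense-grid quadrature over `(b₀, b₁, σ²)` for `d = 1` and a prior-sampling
Monte-Carlo average of the likelihood for `d = 2`.

## The limiting prior and its degrees-of-freedom convention

All default analyses use the limits `σ_b → ∞` and `H = λI, λ → 0`, which tie
the Bayes factors to classical statistics. Writing `g̃` for the OLS residual
of `g` on `(1, Y_U)`, `Λ_γ` for the maximized Gaussian likelihood ratio of
the two regressions (`Λ_γ = (det RSS₀ / det RSS₁)^{n/2}`, Wilks lambda to
the power `−n/2`), and `ν = σ_a² g̃ᵀg̃ / (1 + σ_a² g̃ᵀg̃)`:

```
log BF_γ = −(|D|/2)·log(1 + σ_a² g̃ᵀg̃)
           −((n + m − |I|)/2)·log(1 − ν·(1 − Λ_γ^{−2/n})).
```

Two conventions deserve explanation because they were genuine design
decisions.

**Degrees of freedom.** A single joint prior `Σ_d ~ IW(λI, m)` must induce
every partition's conditional regression consistently. Marginalizing an
inverse-Wishart over the `|I|` indirect coordinates lowers its degrees of
freedom by `|I|`, while conditioning on `Y_U` preserves them, so the
conditional residual covariance prior is `IW_{|D|}(λI, m − |I|)`; that is
where the `m − |I|` in the exponent comes from. The default is `m = d`, the
smallest integer making the joint prior proper, under which the exponent
simplifies to `(n + |U| + |D|)/2` — computable from the likelihood-ratio
record alone, which is what `prop1BF()` exploits.

**Limits of proper priors, not flat priors.** Taking `σ_b → ∞` as the limit
of a proper `N(0, σ_b² Σ)` prior is not the same as integrating the
intercepts against a flat prior: each vague-but-proper coefficient row
contributes an extra `|Σ|^{-1/2}` to the `Σ` integral, shifting the matrix-t
exponent up by one per row relative to the flat-prior calculation. We take
the proper-prior limits throughout, so that the limiting Bayes factor is the
actual limit of the finite-prior one — a property the tests check by driving
`σ_b` up and `λ` down and watching the finite `logBFPartition()` converge
monotonically to `logBFLimit()`.

Consequences verified in the test suite: the null partition has `BF ≡ 1`;
`BF_γ` is monotone increasing in `Λ_γ` at fixed `g̃ᵀg̃`; `BF_all` is
invariant to invertible affine transformations of `Y`; with per-variant
`σ_a = c/‖g̃‖` the `BF_all` ranking of variants coincides exactly with the
likelihood-ratio ranking; and the Wilks p-value from `lrtPvalue()` equals
`stats::manova()`'s to machine precision. Because the two routes to the
limiting Bayes factor — the determinant form above computed from sufficient
statistics, and the `Λ_γ` bridge computed from raw-data OLS — are
implemented independently, their agreement (to `1e−10` in `log10 BF`) pins
down the algebra.

## Sufficient statistics and summary-data approximations

`BF_γ` depends on the data only through `n`, `gᵀg`, `gᵀY` and `YᵀY`
(mean-centered). `sufficientFromRaw()` computes them exactly;
`handleMissing()` uses pairwise-complete cross-products rescaled to the
smallest per-trait sample size, repairing the cross-product matrix by
eigenvalue clipping when pairwise estimation leaves it indefinite. When only
meta-analysis summaries exist, `sufficientFromZ()` rebuilds the statistics
from per-trait Z-scores, a minor allele frequency `f` and a sample size `n`:
`gᵀg ≈ 2nf(1−f)` (Hardy-Weinberg), `gᵀy_j = z_j √(gᵀg)` (the OLS identity
for standardized phenotypes), and `YᵀY ≈ nR` with `R` the phenotype
correlation matrix. `R` itself is estimated by `estimateNullCorrelation()`
from variants whose Z-scores are all small — under the null, Z-score
correlation equals phenotype correlation. Two caveats are deliberate: the
`|z| < 2` default selection truncates the tails and mildly attenuates large
correlations (the tests compare against a truncated-normal reference rather
than the raw truth), and Z-scores are folded to be signed with respect to
the minor allele on ingest. In simulation the summary route tracks the exact
route to a median `|Δ log10 BF_av| < 0.01` at `n = 1000` — far inside the
0.15 budget we consider acceptable for screening work.

## Priors, averaging, and posterior summaries

The default partition prior (`partitionPrior()`) is hierarchical-uniform:
given non-null, the number of associated traits `p` is uniform on `1..d`;
given `p`, the number of direct traits is uniform on `1..p`; given both, all
consistent partitions are equally likely. It is exchangeable in the traits,
and the implied prior probability that a given trait is associated is
`(d+1)/(2d)`. The null mass `π₀` is separate (default 0.5 for single-variant
reports; genome scans should think of `π₀` as close to 1, and `p_null` is
reported rather than thresholded). Effect-size uncertainty is handled by
averaging `BF_γ` over a grid of `σ_a` values — default
`{0.05, 0.1, 0.2, 0.4, 0.8}` phenotype-SDs per allele with uniform weights,
spanning small to large GWAS effects; one shared grid is used across all
partitions. All averages are log-sum-exp; `p_null` is computed both from
`BF_av` and by normalizing the partition table, and the two are asserted
equal. Per-trait `P(U)/P(D)/P(I)` come from marginalizing the partition
posterior, which guarantees the logical coherence property that evidence
against the global null is never weaker than evidence against any single
univariate null.

`emFit()` replaces the subjective weights with maximum-likelihood mixture
weights over (partition, `σ_a`) cells, maximizing
`∏_i Σ_{γ,k} w_{γk} BF_i(γ,k)` by EM (responsibilities ∝ `w·BF`; M-step =
mean responsibility). Weights are floored at `1e−12` to keep the index space
stable, four seeded random starts guard against local optima, and the
log-likelihood trace is asserted non-decreasing. When fitted on variants
selected for strong association, the weights are enriched for associated
partitions — useful for classification among hits, biased upward as an
estimate of genome-wide frequencies.

## The two-stage scan

Genome-wide, `runScan()` first screens each variant with `d + 1` cheap
tests — `zᵀR⁻¹z` against `χ²_d` and each `z_j²` against `χ²_1`, promising if
the smallest p-value is below `1e−4` (configurable) — then runs the full
partition analysis on survivors, sorts by `log10 BF_av`, and greedily prunes
any variant within 0.5 Mb of a higher-ranked variant on the same chromosome
(ties broken by chromosome then position). Distance pruning is a crude proxy
for linkage-disequilibrium deduplication; genuine `r²`-based pruning is out
of scope. A permutation test (`permutationPvalue()`) provides frequentist
calibration for `BF_av` when raw data are available, using the add-one
estimator `p = (1 + #{perm ≥ obs})/(n_perm + 1)` so p-values are never zero.

## What the simulators emulate

`simulateBivariate()` implements the three canonical bivariate designs
(`Y_j = b_j g + e_j`, residual correlation `ρ`): trait 2 direct, trait 2
unassociated (`b₂ = 0`), and trait 2 indirect (`b₂ = ρ b₁`, the exact
conditional-independence configuration). The direct design uses
opposite-sign effects (`b₂ = −b₁`): with positively correlated residuals an
equal-sign effect near `ρ b₁` is statistically indistinguishable from the
indirect design, whereas opposite signs give a cleanly direct configuration
(and are the textbook case where joint analysis helps most). Defaults
`b = 0.25` SD/allele, MAF 0.2, `n = 1000` give mid-range power so that
orderings between statistics are visible. `simulate5d()` implements six
five-trait designs spanning one-direct/rest-unassociated through latent
factor (all direct), with noisy-copy noise SDs `{0.5, 1, 2, 4}`;
`simulateNullMatched()` rebuilds any design with genotype effects zeroed but
the error covariance intact, for size estimation.
`simulateSummaryRecords()` emulates a meta-analysis summary table: null
variants draw `z ~ N(0, R)`; associated variants get mean shifts consistent
with a drawn partition (indirect shifts are the regression-implied
`R_{ID} R_{DD}^{-1} μ_D`).

These generators emulate the *model*: Gaussian phenotypes, Hardy-Weinberg
genotypes, no linkage disequilibrium between variants, exact conditional
independences for indirect traits, and homogeneous per-variant sample sizes.
Passing tests therefore demonstrate internal correctness and the claimed
power orderings under those assumptions — not robustness to non-normal
phenotypes, LD, population structure or heterogeneous meta-analysis inputs,
which real data will add.

## Numerical choices and problem sizes

All determinant and solve operations go through Cholesky factorizations with
symmetrization and graded jitter up to `1e−10 ×` trace before failing;
near-singular inputs raise errors naming the offending quantity (collinear
design columns are named explicitly). Mixture sums use log-sum-exp in base
10. `Λ` is stored on the log scale, since `(det ratio)^{n/2}` overflows for
strong signals. Pairwise-complete covariance and null-Z correlation matrices
are repaired by eigenvalue clipping followed by rescaling to unit diagonal.
The intercept in limit mode is handled by mean-centering, which is exactly
the `σ_b → ∞` limit.

The shipped tests use deliberately modest problem sizes chosen to make every
claim checkable on a laptop: oracle comparisons at `n ≤ 8`, dual-path checks
on 100 random instances, power orderings at 1,000 alternative plus 1,000
null replicates per five-trait design, calibration at 1,000–2,000 replicate
null datasets with 199 permutations each, EM recovery on 5,000 variants, and
a 10,000-variant planted-signal scan. Larger runs change Monte-Carlo error,
not the logic.

## Limitations

The machinery assumes approximately multivariate-normal phenotypes within
genotype classes; rank-quantile transforming each trait first is prudent but
does not guarantee joint normality, and multivariate outliers bite harder
than univariate ones. Genotype effects act on means only, not (co)variances.
`K` is diagonal and one `σ_a` grid is shared across traits, limiting priors
in which a variant has large effects on some traits and tiny ones on others.
Exhaustive enumeration caps `d` at 15 in principle and at about 8–10 in
genome-wide practice. "Direct" and "indirect" are statements about
conditional independence among *measured* variables: unmeasured mediators
and measurement error can make a mechanistically indirect association look
direct. Finally, equal-correlation attenuation in the null-Z estimate of `R`
and the Hardy-Weinberg approximation to `gᵀg` are small but real
approximations inherited by every summary-statistic analysis.
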