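---
title: "Information-theoretic dependency scans: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-theoretic dependency scans: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cohort studies of child development collect three kinds of data that this
package connects: genome-wide SNP genotypes, discrete neurodevelopmental
composites (Bayley-type scales at around 24 months), and longitudinal head
circumference, summarized as per-subject growth-curve parameters. The
scientific question is whether individual loci are dependent on one
phenotype (pairwise effects) or on a *pair* of phenotypes jointly
(pleiotropy) — including dependencies with no pairwise trace, which
regression-based GWAS cannot see by construction.

`deltascan` implements the full path: a synthetic cohort generator (the
real cohorts of this kind are not public), genotype/phenotype
preprocessing, growth-model phenotype extraction, exact plug-in information
measures, permutation significance, confounding adjustment, and the scan
orchestration.

## Measures and estimation

All measures are computed on empirical joint distributions over small
discrete alphabets (`joint_distribution`, built by `joint_from_samples()`
with complete-case handling of the −2 missing sentinel).

* Mutual information `I(X,Y) = H(X) + H(Y) − H(X,Y)`.
* Interaction information `I(X,Y,Z) = I(X,Y) − I(X,Y|Z)`, symmetric in its
  arguments; negative values indicate synergy.
* Asymmetric deltas `Δ_X = I(X,Y,Z) − I(Y,Z)`. Algebraically
  `Δ_X = −I(Y;Z|X)`, so each delta is non-positive on exact distributions.
* Symmetric delta `Δ̄ = Δ_X·Δ_Y·Δ_Z` (bits³): zero whenever one variable is
  independent of the rest, large in magnitude for collectively
  interdependent triples; XOR on uniform binary inputs gives Δ̄ = −1 with
  all pairwise MIs exactly 0.
* Multi-information `Ω = ΣH(marginals) − H(joint)`.

Two conventions deserve comment:

**The delta/Ω identity.** Some presentations of these measures print the
relation between the asymmetric deltas and the multi-information with a
sign that is inconsistent with the definitions above (it fails on the XOR
joint). This package enforces the form that follows algebraically from the
definitions, `Δ_X = I(X,Y) + I(X,Z) − Ω`, which also guarantees Δ ≤ 0; the
inconsistent literal form is not exposed. The identity is verified to
1e−12 on randomized joints in the test suite.

**Plug-in estimation, log base 2.** Frequencies are maximum-likelihood
(no bias correction): downstream permutation nulls are computed with the
identical estimator and therefore absorb the estimator's bias, which is
the workflow the scans assume. Everything defaults to bits (`base = 2`);
every user-facing measure takes a `base` argument, and the preprocessing
MI-collapsing threshold of 1.2 is interpreted in the configured base.
0·log 0 is 0 throughout. Comparisons against oracles use *absolute*
tolerance 1e−12 — information measures near zero make relative tolerances
meaningless.

## Permutation significance

`scan_*` functions build a pooled permutation null with the identical
estimator as the observed scan:

* **Pairwise scans** shuffle the phenotype rows as one block, preserving
  all linkage between SNPs (and among phenotypes).
* **Three-way scans** permute the Bayley block and the growth block with
  independent permutations, additionally breaking the phenotype–phenotype
  link.

The pooled p-value of a tuple is the fraction of *all* randomized scores
(n_tuples × n_shuffles of them, 1000 shuffles by default) at least as
extreme as the observed one; extremeness is |score| everywhere, since MI is
non-negative and deltas are ranked by absolute value. Pooling across tuples
assumes tuple scores are exchangeable under the null — an approximation
inherited from the workflow this package reimplements; it is exact when
SNPs are iid, and the global-null calibration test (K-S uniformity of
p-values over 4,000 tuples at 1000 shuffles) passes on the synthetic
cohort. Nulls are pooled per scan; running separate scans per phenotype
class gives per-class nulls.

A p-value smaller than the attainable floor 1/(n_tuples × n_shuffles) is
reported *at* the floor and flagged (`at_floor`), with no pseudocount. The
family-wise error rate is the fraction of per-shuffle absolute-maximum
scores at least as extreme as the observed score; it dominates the pooled
p-value wherever the latter is not floored (at the floor, FWER can be
exactly 0 while the p-value is reported as 1/N — a deliberate reporting
convention, not a violation of the counting identity).

Default report cutoffs follow the conventions of the scans this package
reproduces: 2.7×10⁻⁶ for Bayley pairwise tuples, 8×10⁻⁶ for growth
pairwise tuples, 3.2×10⁻⁶ for three-way tuples. They are config values,
not hard-coded filters.

## Confounding adjustment

With two ethnicity groups ε₁, ε₂ (priors summing to 1), the adjusted MI
standardizes the phenotype conditional over groups:
π(b|s) = Σᵢ P(εᵢ)·p(b|s,εᵢ), and
Ĩ(b,s) = Σ_s p(s) Σ_b π(b|s)·log(π(b|s)/p(b)). The prior-weighted form is
used because it is a proper conditional distribution and reduces *exactly*
to the unadjusted MI when the conditionals do not depend on the group; the
unweighted literal sum (which totals the number of groups) is available
behind `literal = TRUE` for comparison only. Empty (genotype, group) cells
fall back to the group-free conditional and are counted in a `zero_cells`
attribute. On a pure-confounder construction (phenotype depends only on
ethnicity, allele frequencies differ by ethnicity) the standardized
conditional collapses to the marginal and Ĩ drops toward zero — the
directional behaviour the adjustment exists for.

## Preprocessing conventions

The genotype filter applies, in order: (1) constant SNPs removed; (2)
perfectly correlated SNPs collapsed; (3) SNPs with more than 25% missing
removed; (4) SNP pairs with MI above 1.2 collapsed (single-linkage
clusters; since MI ≤ min(H), only SNPs whose own entropy exceeds the
threshold can participate, which keeps the quadratic pair search small);
(5) SNPs with one genotype in more than 95% of observed subjects removed;
(6) X/Y SNPs (incl. pseudoautosomal) moved to a separate matrix for the
sex-stratified scans. Decisions taken where the procedure was genuinely
open:

* "Perfectly correlated" means identical genotype vectors on
  pairwise-complete subjects — the strictest reading, so step 2 never
  absorbs pairs that belong to step 4's MI clustering.
* The collapse representative is the SNP with the lowest (chromosome,
  position) — deterministic and reproducible.
* Step 4 operates on the already-collapsed matrix (outputs of steps 1–3),
  making the pipeline idempotent, which the tests assert.

Numeric phenotypes are discretized into four bins
(−∞,l], (l,μ], (μ,r], (r,∞) with μ the mean, l the median of values ≤ μ
and r the median of values > μ. The tie side (≤ μ into the lower half) is
a choice: it makes the four intervals exhaustive and puts a value exactly
at the mean into bin 2. Categorical phenotypes with more than 10 levels,
and any phenotype with one value in more than 95% of subjects, are
screened out.

**Missing-data subset selection.** The published formulation of
"maximize n + m subject to every subject having at least one observed
value and every variable's missing fraction ≤ τ" constrains fixed data
rather than decision variables; it is implemented here as the
corresponding 0/1 program over kept-subject and kept-variable indicator
sets. Small instances (up to ~2¹⁸ subset pairs) are solved exactly by
branch-and-bound enumeration; larger ones by alternating row/column
elimination, whose objective the exact search weakly dominates. The tests
prove exact-search equivalence with exhaustive enumeration on all random
instances up to 6×6. τ = 0 (the default for genotype scans) yields a
submatrix with no missing values at all.

## The growth model

Head circumference Y over post-menstrual age t (weeks, 8–290) follows a
Gompertz curve with an extra deceleration term:

Y = (L_p+L_i)·exp(−(α_p+α_i)·exp(−β_p t(1−θ_p(1−e^{−(λ_p+λ_i)t})))) + ε

Five population fixed effects; subject-level random effects on the limit
L, the log-ratio α and the deceleration nonlinearity λ only (β and θ are
population-fixed), mutually uncorrelated (diagonal covariance) and
independent of the residual. Default parameter values
(L_p = 49.97 cm, α_p = 5.620, β_p = 0.1045 /wk, θ_p = 0.7595,
λ_p = 0.01667 /wk; variances 1.306, 0.1648, 5.637e−4, residual 0.7218)
are point estimates from a large multi-cohort reference fit and serve as
simulation ground truth — never as fitting targets.

Fitting uses `nlme::nlme` (the Lindstrom–Bates alternating algorithm with
an approximate marginal likelihood) with an analytic gradient generated by
`stats::deriv()`, ML estimation, and data-driven starting values (grid +
population-curve `nls`). `subject_effects()` computes per-subject
conditional modes by penalized nonlinear least squares given the
population parameters — residual sum of squares plus the Gaussian penalty
b'D⁻¹b — so it can be applied to subjects outside the original fit; it
agrees with the mixed model's BLUPs to r > 0.99 on simulated data.
Subjects with fewer than two observations are flagged and get zero
deviations. Growth phenotypes (linf, alpha, lambda = population +
deviation) are discretized with the same four-bin rule as other numeric
phenotypes before scanning.

The simulated observation design is a realistic visit schedule — 18
candidate visits from antenatal ultrasounds (~12–33 wk) through birth and
postnatal check-ups to ~275 wk — attended independently with probability
0.6 and jittered by 1 week, keeping 2–18 observations per subject. This
covers the early window where λ acts, which uniform random times would
under-sample; it was fixed a priori, not tuned.

Parameter recovery at 500 subjects over 5 seeds (the acceptance test)
compares the *seed-averaged* estimates to the truth (fixed effects within
5%, variances within 25%): averaging replicates is the natural reading of
a stochastic tolerance over seeds, and single-seed λ estimates fluctuate
by ±5% at this n.

## The synthetic cohort: what it does and does not emulate

`simulate_genotypes()` draws biallelic SNPs in Hardy–Weinberg equilibrium
with per-SNP MAF uniform in [0.05, 0.5] (the lower bound mirrors the MAF
floor of standard array QC). Two ethnicity groups (fractions 0.6/0.4, the
approximate composition of the motivating cohort when binarized) can
differ in allele frequency by `ethnicity_af_delta` on a `confounded_fraction`
of SNPs, and `ethnicity_pheno_shift` adds a group-level phenotype shift —
together the minimal mechanism that makes confounding adjustment testable.
Both confounding knobs default to 0, so the default cohort is a clean
global null. X-chromosome SNPs (3% by default) are haploid-coded {0,2} in
males, reproducing the sex-pattern problem that forces stratified X/Y
scans. Missingness is iid at `missing_rate` (5% default; 0 for scan
substrates, which the source workflow takes from a τ=0 subset with no
missing values).

Bayley-like composites come from an equicorrelated Gaussian copula
(ρ = 0.3) cut into `n_levels` equiprobable ordinal levels; the alphabet
size after preprocessing is not fixed by the published description, so
n_levels is an exposed parameter defaulting to 4, matching the numeric
binning. The latent scores are kept so effects can be planted before
binning.

Planted effects define ground truth for scan tests:

* `additive_pairwise` shifts a numeric (or latent) phenotype by
  effect_size × minor-allele count before binning; size 0 is a byte-level
  no-op. A "strong" planted effect requires a common allele — the tests
  plant on SNPs with MAF ≈ 0.3, since variance explained scales with
  2f(1−f).
* `xor_pleiotropic` dichotomizes the SNP as {0} vs {1,2} (a three-level
  XOR is not defined by the source; binary is the cleanest null-marginal
  construction), binarizes the first phenotype at its most balanced cut,
  and sets the second to P1 ⊕ D with probability `effect_size` (else a
  fair coin). At penetrance 1 the two genotype–phenotype pairs carry
  exactly zero MI for any SNP frequency; the phenotype–phenotype pair is
  null when the dichotomized SNP is balanced (MAF ≈ 0.29 gives
  P(D=1) ≈ 0.5). `xor_joint_distribution()` provides the exact 8-cell
  joint for closed-form tests.

Not emulated: linkage-disequilibrium block structure (SNPs are
independent, so LD collapsing and `ld_r2()` are exercised on constructed
duplicates), structured/block missingness (iid only), array intensities,
and parental genotypes. A green scan test therefore establishes
calibration and detection power under independence and iid missingness —
not robustness to realistic LD or informative missingness.

## Determinism and numerical conventions

Every generator and every permutation null takes a seed and is
byte-identical under it; seeded code paths save and restore the caller's
RNG state. Scan rows are ordered by p-value, then |score| descending, then
identifier — fully deterministic. Genotype one-hot indicator matrices are
precomputed once per scan so a shuffle costs a handful of BLAS
crossproducts; the vectorized profiles are asserted numerically identical
(1e−12) to routing each tuple through the exact measures.

## Known limitations

* Deltas are implemented for exactly three variables; higher-order
  generalizations are out of scope.
* The pooled null's exchangeability assumption understates per-tuple
  variation when SNP entropies vary strongly; per-phenotype-class scans
  mitigate this.
* `subject_effects()` penalizes through fixed population variances; it
  does not propagate uncertainty in the variance components.
* The exact subset-selection solver is exponential and intentionally
  capped; large instances fall back to the heuristic with no optimality
  certificate.
* The SNP–SNP identical-collapse step is O(S²) in memory blocks of 2,000
  columns; genome-scale inputs should be chunked upstream.
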