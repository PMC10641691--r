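---
title: "Cross-generational genomic selection in RRS breeding programs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-generational genomic selection in RRS breeding programs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrsgs)
```

# Scope

`rrsgs` implements the statistical machinery of a cross-generational genomic
selection (GS) experiment in a reciprocal recurrent selection (RRS) hybrid
tree breeding program: relationship matrices, REML/BLUP evaluation, SNP
quality control, growth-curve age harmonization, prediction assessment, and
a synthetic breeding-program generator used to validate the whole chain
against known ground truth. This vignette documents the models, their
assumptions, the tunable parameters, the numerical choices, and the
limitations a user should know about.

# Relationship matrices

**Pedigree additive (`build_A`).** Wright's numerator relationship matrix by
the tabular method in topological order; unknown parents contribute zero and
the diagonal is `1 + F`. The inverse (`build_A_inverse`) is assembled
directly by Henderson's rules with Mendelian-sampling variances
`d = 1/2 - (F_s + F_d)/4` (both parents known), `3/4 - F_p/4` (one known),
1 (founder), so inbreeding is fully accounted for on both routes.

**Pedigree dominance (`build_D_pedigree`).** The classical non-inbred
formula `d_ij = (a_{s(i)s(j)} a_{d(i)d(j)} + a_{s(i)d(j)} a_{d(i)s(j)})/4`
with unit diagonal. Inbreeding is deliberately ignored in `D`: the designs
this package targets (polymix half-sib and outcrossed full-sib families of
two divergent species) produce essentially non-inbred offspring, and the
inbred dominance theory would add considerable machinery for no practical
gain here. This is a documented limitation, not an oversight.

**Genomic additive (`build_GA`).** The per-locus standardized form
`G_A = WW'/M` with `w_ij = (x_ij - 2p_j)/sqrt(2 p_j q_j)`. Allele
frequencies are computed from the supplied (post-QC, imputed) genotype set;
base-population frequencies are not estimated. Under Hardy–Weinberg
proportions the expected diagonal is 1, which the test suite verifies by
simulation. Monomorphic SNPs are an error by construction — the upstream
MAF filter removes them.

**Genomic dominance (`build_GD`).** Per-SNP entries `1 - 2pq` for
heterozygotes and `-2pq` for homozygotes, scaled by
`2 Σ_j p_j q_j (1 - 2 p_j q_j)`. With this scaling the expected diagonal
under Hardy–Weinberg proportions is exactly 1 (the heterozygosity-weighted
average of `(1-2pq)` and `2pq` contributions), making `σ²_d` interpretable
on the same footing as `σ²_a`.

**Single-step (`build_H`, `build_H_inverse`).** The blended matrix combines
expected relationships of ungenotyped individuals with realized genomic
relationships of the genotyped block, using the standard block formula and
`H⁻¹ = A⁻¹ + [0 0; 0 τ(G_A⁻¹ - A₂₂⁻¹)]`. The scaling factor defaults to
`τ = 1` (full genomic contribution) and `G_A` is **not** blended towards
`A₂₂`; both choices are exposed as arguments. Because `G_A` is singular
whenever individuals outnumber independently segregating loci,
`invert_kinship()` offers a ridge (`ε = 1e-6` recommended) that is applied
only at inversion time — `build_H` itself never modifies the inputs. The
suite checks that `build_H_inverse` agrees with dense inversion of
`build_H` to below `1e-6` when the same ridge is used on both routes.

# Mixed-model evaluation

## The models

ABLUP fits the individual-tree model
`y = Xβ + Wα + Za (+ Qd) + e` with fixed trial effects, random blocks
within trials (`α ~ N(0, σ²_b I)`), additive effects (`a ~ N(0, σ²_a A)`),
optional dominance (`d ~ N(0, σ²_d D)`) and homogeneous residuals. Residual
and block variances are homogeneous across trials — the parsimonious model;
heterogeneous-variance variants are out of scope.

The genomic stage is deliberately **two-stage**: GBLUP (`fit_gblup`) and
HBLUP (`fit_hblup`) take as response the vector of EBVs (additive models)
or EGVs (additive-dominance) from a prior ABLUP fit, with the overall mean
as the only fixed effect, and covariance `σ²_a G_A` (+ `σ²_d G_D`) or
`σ²_a H`. This matches the operational workflow where field data are
consolidated into breeding values once and genomic models are trained on
those pseudo-phenotypes. Raw phenotypes can be passed as the `value` column
for sensitivity work; nothing in the code assumes the response is an EBV.

Heritabilities are computed as `h²_a = σ²_a/(σ²_a + σ²_d + σ²_e)` and
`h²_g = (σ²_a + σ²_d)/(σ²_a + σ²_d + σ²_e)`; the block variance is
excluded from the denominator. This convention is required for the
worked-example variance components shipped with the package
(`reference_variance_components()`) to reproduce their published
heritabilities, and is therefore the package-wide definition.

## The REML solver

No pre-installed package fits arbitrary-covariance mixed models, so the
solver is implemented here:

* **Single random term** (the common case: ABLUP with fixed blocks, GBLUP,
  HBLUP): the covariance `ZKZ'` is eigendecomposed once, the restricted
  likelihood becomes a cheap function of two variance components on the
  rotated data, and `optim` (L-BFGS-B on the log scale) maximizes it. Cost
  is one `n × n` eigendecomposition regardless of iteration count.
* **Several terms**: average-information (AI) REML. Each iteration forms
  `P`, the scores `-½(tr(PV_k) - y'PV_kPy)` and the AI matrix
  `½ y'PV_kPV_lPy`. The AI step is tried with increasing Levenberg-style
  damping (`0, 1e-4, 1e-2, 1` times the mean AI diagonal) and step halving,
  and candidates are **projected** onto the parameter bounds rather than
  rejected; if no damped AI step improves the restricted likelihood, an EM
  step is taken. Components pinned at the lower bound with a negative score
  are held there (active set). The damping matters in practice: additive
  and dominance variances are nearly unidentifiable in small trials
  dominated by full sibs (their covariance contributions are proportional),
  the AI matrix is then near-singular, and an undamped solver either
  diverges or crawls.

Convergence is declared when the change in restricted log-likelihood falls
below `1e-8` (or the relative parameter change below `1e-8`); the lower
bound on every component is `1e-8 · var(y)`, so null components converge to
a boundary value rather than exactly zero. Non-convergence is flagged on
the returned object with the full iteration trace, never hidden.

BLUP solutions and prediction error variances are computed at the converged
components in the variance-matrix form (`û = σ²_k (Z K)' P y`,
`PEV = σ²_k diag(K) - σ⁴_k diag((ZK)'P(ZK))`), which requires no inversion
of `K` and therefore works with singular genomic matrices.
`solve_mme()` additionally provides the classical Henderson
coefficient-matrix route (used by the ridge-equivalence and reliability
tests). Dense linear algebra throughout: the intended problem sizes (up to
a few thousand individuals) sit comfortably in memory, and sparse methods
are future work.

# Genotype quality control

Filters are inclusive (`call rate ≥ 0.90`, `MAF ≥ 0.01`, sample call rate
`≥ 0.85` by default) and order-preserving. Imputation replaces each missing
call by the genotype expected from the SNP's B-allele frequency `p` computed
on the non-missing calls of the supplied matrix: 0 when `2p < 2/3`, 1 when
`2/3 ≤ 2p < 4/3` (both intervals closed on the left — the boundary
`p = 1/3` imputes to heterozygote), 2 when `2p ≥ 4/3`. The rule is
deterministic and idempotent. Frequencies are recomputed after platform
merging, i.e. per supplied matrix, not per training cohort. Parentage is
checked by the opposing-homozygote rate (0-vs-2 calls between parent and
offspring), flagged above `0.01` by default; gene-dropped data must show
rate zero, which the suite asserts.

# Growth-curve age harmonization

Field trials are rarely measured at identical ages. Four per-tree regression
models harmonize volumes to common reference ages (defaults 2.76 and 5.40
years, the "age 3" and "age 6" labels):

| model | form | linearization |
|---|---|---|
| linear | `y = β₀ + β₁x` | identity |
| Logistic 1 | `y = 1/(1+β₀e^{β₁x})` | `log(1/y - 1)` on `x` |
| Logistic 2 | `y = 1/(1+(x/β₀)^{β₁})` | `log(1/y - 1)` on `log x` |
| Gompertz | `y = e^{-e^{β₀-β₁x}}` | `log(-log y)` on `x` |

The Logistic 1 sign convention is exactly as written: growth requires
`β₀ > 0, β₁ < 0`. Bounded models operate on volumes scaled into `(0,1)` by
a per-trial maximum (default `1.2 ×` the largest observed volume — a
compromise between headroom and resolution; out-of-range records raise an
error naming the record). With the typical two measurements per tree the
fit is the exact two-point solve, so adjusting to a tree's own measurement
age returns the measured value. An empirical-Bayes shrinkage of per-tree
coefficients toward trial means is available for ≥3 points per tree; with
two points the within-tree residual is zero and shrinkage is a no-op, which
is why the exact solve is the default rather than a random-coefficient
`lmer` fit that would be degenerate in the two-point design.

`adjustment_diagnostics()` compares residual variances against a benchmark
(simulation truth, or any reference) and ranks models by mean percent
reduction. `growth_adjustment_experiment()` packages the self-consistency
benchmark: trees generated from exact Logistic 1 trajectories with
tree-specific parameters, a known common asymptote, trial-level age jitter
(±0.15 yr around measurement ages 2.9 and 5.6) and 1% multiplicative
measurement noise. On such data every adjusted dataset should beat the raw
one and Logistic 1 should rank first — the acceptance suite asserts both.

# The synthetic breeding program

`simulate_breeding_program()` emulates the population structure of an
operational RRS program:

* **G0:** `n` founders per species (default 30). Per-SNP ancestral
  frequencies are uniform on `[0.05, 0.95]`; species frequencies follow the
  Balding–Nichols beta model with divergence `fst` (default 0.15, a
  plausible divergence for two cross-compatible eucalypt species); founder
  genotypes are Hardy–Weinberg within species. Founder genetic models are
  rarely reported for operational breeding populations, so Balding–Nichols
  was chosen as the standard neutral-divergence model.
* **G1:** per species, polymix half-sib families (default 30 families of
  20): the dam is recorded, the true sire is drawn per offspring from the
  species' pollen pool and kept internally, and the exported *nominal*
  pedigree lists the sire as unknown — exactly the information a breeder
  has. Interspecific polymix hybrid families (default 20) alternate cross
  direction.
* **G2:** full-sib hybrid families (default 15) whose parents are G1
  pure-species trees selected on true breeding value (`"truncation"`), or
  at random (`"random"`). Both pedigrees (true and nominal) are returned.
* **Genotypes:** unlinked-locus gene dropping (each offspring allele is a
  Bernoulli draw with probability parent-dosage/2, independent across
  loci). No recombination map: linkage matters for none of the implemented
  estimators, which all operate on realized relationships.
* **Trait:** each SNP carries an additive effect on the centred dosage and
  a dominance effect on the centred heterozygosity indicator — the
  statistical (orthogonal-in-expectation) decomposition, calibrated
  empirically on the founder sample so that additive and dominance
  variances are exactly `target_h2` and `target_d2` of the phenotypic
  variance (default 0.4 and 0.15; the implied phenotypic variance is
  `σ²_e/(1 - h² - d²)`, with `phenotypic_variance` available explicitly
  for noise-free runs).
* **Phenotypes:** volume at age `x` is `L(x) · (μ + g + b + e)` where
  `L(x) = 1/(1 + 41.3 e^{-0.846x})` is a Logistic 1 curve anchored so that
  roughly 20% / 70% of mature volume is reached at ages 2.76 / 5.40, and
  `μ = 0.55` m³ is the mean mature volume. Block and residual effects are
  expressed through the same curve, so heritability is constant across
  measurement ages — a deliberate simplification that makes the
  age-adjustment and heritability-recovery experiments interpretable.
  Measurement ages receive a per-trial uniform jitter (±0.2 yr) to emulate
  heterogeneous trial ages. Heights follow the same curve and DBH is
  back-derived so the taper formula reproduces the simulated volume
  exactly.

What the generator does **not** emulate: linkage and LD decay, selection
over more than the built-in G1→G2 step, genotype-by-environment
interaction, heterogeneous residual variances across trials, genotyping
error, and breed-specific allele effects. Tests passing on this generator
therefore validate the estimators and their contracts, not the full
complexity of field data.

# Validation experiments

Three experiment drivers are exported because they *are* the package's
evidence, and the acceptance script reruns them from scratch:

* `heritability_recovery_experiment()`: replicate populations of 2,000
  phenotyped trees (2 species × 40 polymix families × 25 offspring) from a
  single random-mating base (`fst = 0`), analyzed with the true pedigree
  and fixed blocks. A single random-mating base is used because the
  founder-variance calibration is pooled across species; with diverged
  founders, part of the calibrated variance is between-species and a
  within-species analysis would see systematically less — a property of the
  design, not an estimator bias.
* `sib_ga_experiment()`: gene-dropped full-sib and paternal half-sib pairs
  at 5,000 SNPs; mean `G_A` off-diagonals against the pedigree expectations
  0.5 and 0.25.
* `relatedness_rpa_experiment()`: the central cross-generational property.
  Per replicate, a G0→G2 program is simulated; training pseudo-phenotypes
  come from a G1-only ABLUP fit and reference EBVs from a G2-only fit
  (training never sees target-generation data); GBLUP is trained either on
  the direct parents of the candidates or on pure-species families that
  contributed no parent. The experiment uses `g2_parent_selection =
  "random"`: selecting parents by *true* breeding value — a quantity no
  real program observes — restricts the true-value range within the elite
  group and decorrelates their EBVs from their true merit, masking the
  relatedness effect the experiment is about. Operational programs select
  on EBVs, which does not decouple the evaluation system from itself;
  random selection is the faithful stand-in that keeps the estimable
  structure intact. The generator's *default* remains truncation
  selection.

# Pipeline

`run_pipeline()` sequences simulate → QC (with a masked-missingness step so
imputation is exercised) → age adjustment → ABLUP (G1-only training fit and
G2-only reference fit, both on the nominal pedigree, as a breeder would) →
kinship → GBLUP/GBLUP_G+D/HBLUP per training set → assessment. Stages are
gated by the requested models: an ABLUP-only run builds no genomic
matrices. One master seed fans out to per-stage child seeds by a stable
hash (`child_seed`), so adding a stage never perturbs earlier stages and a
rerun with the same configuration is bit-identical. With an output
directory, every stage's artifacts are written as plain text alongside a
manifest of file hashes and the seed. The package's interface is its
functions; the pipeline entry point is `run_pipeline()` rather than a shell
executable.

# Numerical choices and degenerate inputs

* Variance components bounded to `[1e-8 · var(y), 1e4 · var(y)]`;
  boundary-pinned components are reported at the bound.
* `G_A` ridge `1e-6` applied only inside inversion, never to the stored
  matrix; `A₂₂` singularity raises an error carrying the reciprocal
  condition number.
* Top-k selection uses `k = round(pn)` to the nearest integer (half away
  from zero), minimum 1 — the mapping that yields 5 of 197 at a 2.5%
  selected proportion — with ties broken by id order for determinism.
* The bias regression is reference-on-genomic, directional as defined.
* Cross-validation folds are stratified by family by default so full sibs
  never straddle a train/test split; `k = n` is rejected because a one-point
  fold has no defined correlation.
* All matrix consumers join on ids (dimnames), never on position; id
  mismatches raise errors listing the offenders.

# Problem sizes

The shipped defaults are desk-scale: ~2,000 trees and 3,000 SNPs for the
default configuration, 2,000 phenotyped trees per replicate in the recovery
experiment, 5,000 SNPs in the sib-relationship experiment, and a few
hundred trees per replicate in the relatedness experiment. These sizes were
chosen so the complete validation (test suite plus acceptance script) runs
in minutes on a single CPU while keeping Monte-Carlo error inside the
stated tolerances; the full operational scale (~17,000 trees, ~16,000
SNPs) is reachable through the same configuration object, with dense
linear algebra as the only constraint.

# Known limitations

* Dominance relationships ignore inbreeding; no metafounders or
  unknown-parent groups.
* HBLUP is additive-only (no genomic dominance inside `H`).
* Homogeneous residual and block variances across trials.
* Dense algebra throughout; no sparse inverses.
* Single-trait models only; no Bayesian whole-genome regressions.
* The generator's trait acts through the statistical additive/dominance
  decomposition at founder frequencies; biological (functional) gene-action
  parameterizations would differ in inbred or strongly drifted populations.
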