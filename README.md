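# rrsgs

Genomic selection toolkit for **reciprocal recurrent selection (RRS)**
breeding programs of hybrid trees.

## The problem

RRS programs improve two pure-species populations (e.g. *Eucalyptus grandis*
and *E. urophylla*) for the performance of their interspecific hybrids. A
breeding cycle crosses selected pure-species parents, deploys the hybrid
full-sib families in a progeny trial, and waits until harvest age (~6 years)
to rank the candidates. Genomic selection (GS) promises to rank hybrid
seedlings at the nursery stage instead: a prediction model trained on
genotyped and phenotyped relatives of the prior generation assigns each
genotyped seedling a genomic breeding value (GEBV) or genotypic value
(GEGV), years before any phenotype exists.

`rrsgs` implements the full evaluation chain needed to study — and on real
data, run — this scheme, for breeders and quantitative geneticists:

* **Relationship matrices.** Pedigree additive `A` (tabular method) and its
  direct inverse (Henderson's rules with inbreeding), pedigree dominance
  `D`, genomic additive `G_A = WW'/M` with per-locus standardized dosages
  `w = (x - 2p)/sqrt(2pq)`, genomic dominance
  `G_D = KK' / (2 Σ p q (1 - 2pq))`, and the blended single-step matrix

  ```
  H = | A11 + A12 A22⁻¹ (G_A - A22) A22⁻¹ A21    A12 A22⁻¹ G_A |
      | G_A A22⁻¹ A21                             G_A           |

  H⁻¹ = A⁻¹ + [0 0; 0 τ(G_A⁻¹ - A22⁻¹)],  τ = 1
  ```

* **Mixed-model evaluation.** Average-information REML with EM fallback and
  an eigendecomposition fast path; ABLUP (`y = Xβ + Wα + Za (+ Qd) + e`
  with `a ~ N(0, σ²ₐA)`, `d ~ N(0, σ²_d D)`), and two-stage GBLUP / HBLUP
  where the response is the vector of EBVs or EGVs from the ABLUP stage.
  Heritabilities `h²ₐ = σ²ₐ/(σ²ₐ+σ²_d+σ²ₑ)`, reliabilities
  `r² = 1 - PEV/σ²ₐ`, de-regression `dEBV = EBV/r²`.

* **SNP quality control.** Call-rate and MAF filters, the expected-frequency
  imputation rule (missing call → 0 if `2p < 2/3`, 1 if `2/3 ≤ 2p < 4/3`,
  2 if `2p ≥ 4/3`), cross-platform marker intersection, and
  opposing-homozygote parentage verification.

* **Age harmonization.** Linear, Logistic 1 (`y = 1/(1+β₀e^{β₁x})`),
  Logistic 2 and Gompertz growth curves fitted per tree on their linearized
  scales, used to adjust measurements taken at heterogeneous trial ages onto
  common reference ages (defaults 2.76 and 5.40 years); stem volume from the
  taper formula `V = (π/4)(dbh/100)² · height · 0.45` and MAI
  `= V · 1200 / age`.

* **Assessment.** Realized predictive ability (Pearson correlation of
  GEBV vs EBV), bias `1 - b` from the regression of reference on genomic
  values, Spearman rank concordance, top-k coincidence rates, family-level
  aggregation, stratified k-fold and direct cross-validation, and the seven
  canonical training-set combinations (hybrids / parents / uncles and their
  unions).

* **Synthetic breeding programs.** A generator with known ground truth:
  two Balding–Nichols-divergent founder species, polymix half-sib
  pure-species G1 families (true sire recorded, exported as unknown),
  interspecific hybrid families, selected-parent full-sib G2 families,
  gene-dropped SNP genotypes, additive+dominance trait architecture with
  calibrated heritability, and logistic growth trajectories measured at
  jittered ages in randomized complete block trials.

## Worked example

Simulate a small G0→G2 program, run the full pipeline (QC → age adjustment
→ ABLUP → kinship → GBLUP/HBLUP → assessment), and inspect the report:

```r
library(rrsgs)
cfg <- sim_config(n_founders_per_species = 12, n_snps = 1000,
                  n_psp_families_per_species = 12, offspring_per_family = 10,
                  n_hybrid_families_g1 = 6, n_hybrid_families_g2 = 9,
                  seed = 2024)
res <- run_pipeline(cfg, models = c("ablup", "gblup", "hblup"),
                    training_sets = c("P", "H", "H+P"),
                    proportions = c(0.1, 0.2))
res$h2_table
#>   model age    scope h2_narrow h2_broad
#> 1 ablup 2.8 G2 trial      0.15     0.15
#> 2 ablup 5.4 G2 trial      0.32     0.32

res$report[res$report$age == 5.40,
  c("model","training_set","n_train","n_pred","rpa","bias","spearman")]
#>  model training_set n_train n_pred  rpa  bias spearman
#>  gblup            P       6     27 0.86 -1.37     0.85
#>  gblup            H      60     27 0.60 -0.63     0.55
#>  gblup          H+P      66     27 0.78 -0.61     0.76
#>  hblup            P       6     90 0.85 -1.25     0.85
#>  hblup            H      60     90 0.41 -0.12     0.40
#>  hblup          H+P      66     90 0.82 -0.76     0.84
```

Reading the output: `h2_table` holds the REML narrow/broad-sense
heritabilities of MAI in the G2 target trial at the two reference ages. In
the report, each row is one genomic model × training set: training on the
six direct **P**arents of the candidates yields a realized predictive
ability of 0.85–0.86 between seedling-stage genomic predictions and the
harvest-age breeding values, while the hundredfold larger but more distantly
related **H**ybrids cohort only reaches 0.41–0.60 — the relatedness between
training set and candidates, not its size, drives cross-generational
prediction. HBLUP (`n_pred = 90`) also ranks the ungenotyped candidates,
which GBLUP (`n_pred = 27` genotyped seedlings) cannot.

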