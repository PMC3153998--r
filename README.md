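# pleioscan

Genome-wide pleiotropy scans for correlated quantitative traits measured in
family samples.

Correlated phenotypes — the motivating case is osteoporosis proxies such as
femoral-neck and lumbar-spine bone mineral density, heel ultrasound (BUA,
SOS) and hip-geometry indices — may be correlated because the same variants
influence them (pleiotropy) or because relatives share environments. This
package implements both classic ways of telling these apart in
two-generational family data and ties them together:

* **Variance components on pedigrees.** Maximum-likelihood univariate and
  bivariate polygenic models built on the additive relationship matrix
  A = 2Φ yield heritabilities h², the genetic correlation ρ_G and the
  environmental correlation ρ_E for every trait pair, related to the
  phenotypic correlation by

  ρ_P = ρ_G √(h²₁ h²₂) + ρ_E √((1−h²₁)(1−h²₂)).

* **Association sharing.** A kinship-adjusted mixed-model GWAS
  (two-stage generalized least squares) is run per trait; for each pair the
  *shared-association percentage* is 100 × (SNPs significant for both at a
  nominal α = 0.01) / (SNPs significant for either). Observed sharing is
  calibrated against a gene-dropping simulation null and a closed-form
  bivariate-normal expectation (α²·n_snps for independent traits), and
  candidate pleiotropic SNPs (significant for both traits, sign-consistent,
  LD-clustered at r² ≥ 0.5) are extracted.

Support modules provide everything needed to run end-to-end without any
external data: VCF/FAM/TSV readers and writers, sample- and SNP-level QC
(call rate, heterozygosity, Mendelian errors, MAF, Hardy–Weinberg),
principal components fit on a maximal unrelated subset and projected onto
relatives, covariate residualization with inverse-normal rank transforms,
and a synthetic-data generator (pedigrees, gene-dropped genotypes with
block LD, multivariate phenotypes realizing any configured h²/ρ_G/ρ_E with
optional causal SNPs).

## Worked example

Simulate a family study with two traits sharing genetics (h² = 0.5 each,
ρ_G = 0.66, ρ_E = 0.43), run QC, residualize, fit the bivariate polygenic
model and scan both traits:

```r
library(pleioscan)

cfg <- sim_config(n_families = 150, n_snps = 2000, seed = 42)
ped <- simulate_pedigree(cfg)
gm  <- simulate_genotypes(ped, cfg)
tm  <- trait_model(h2 = c(0.5, 0.5), rho_g = 0.66, rho_e = 0.43,
                   trait_names = c("fn_bmd", "ls_bmd"))
ph  <- simulate_phenotypes(ped, gm, tm, seed = 43)

flt <- snp_filter(gm, ped)
res <- residualize_traits(ph, c("fn_bmd", "ls_bmd"),
                          covariates = c("age", "age2", "bmi", "estrogenic"),
                          transform = "rank", cohort = "cohort")

K  <- kinship_from_pedigree(ped)
bv <- fit_bivariate_polygenic(setNames(res$fn_bmd, res$sample_id),
                              setNames(res$ls_bmd, res$sample_id),
                              K, traits = c("fn_bmd", "ls_bmd"))
bv
#> <bivariate_polygenic_fit> fn_bmd ~ ls_bmd
#>   h2 = 0.478 / 0.538, rho_g = 0.590, rho_e = 0.455, rho_p = 0.523
#>   n = 890, logLik = -2290.53, converged = TRUE

s1 <- gwas_lmm(setNames(res$fn_bmd, res$sample_id), flt$genotypes, K, trait = "fn_bmd")
s2 <- gwas_lmm(setNames(res$ls_bmd, res$sample_id), flt$genotypes, K, trait = "ls_bmd")
pair_shared_table(list(fn_bmd = s1, ls_bmd = s2), alpha = 0.01)
#> # A tibble: 1 x 7
#>   trait1 trait2 shared_pct    n1    n2 shared union
#> 1 fn_bmd ls_bmd       9.30    23    24      4    43

analytic_expected_shared(bv$rho_p, 0.01, 2000)
#> [1] 2.2
```

The fitted decomposition recovers the generating parameters (ρ̂_G = 0.59
against a truth of 0.66 at this sample size), and the two traits share 4 of
43 associated SNPs (9.3%) where ~2.2 would be expected for a pair whose
statistics are only as correlated as ρ_P — the signature of the shared
polygenic background. `tidy()`/`glance()` methods return the fits as
tibbles, `autoplot()` draws a scan, and `plot_shared_vs_correlation()`
draws the per-pair sharing-versus-correlation scatter.

Packaged worked-example tables from a published nine-trait bone study are
available via `bone_assoc_counts()`, `bone_shared_matrix()`,
`bone_correlation_matrix()` and `bone_pair_table()`, and power the
reconstruction tests (shared percentages 6.8%/6.6%/28%, implied
ρ_P = 0.85 for BUA–SOS, sharing-vs-ρ_G correlation 0.84).

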