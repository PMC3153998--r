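test_that("simulated nuclear families have the requested structure", {
  cfg <- sim_config(n_families = 1, p_spouse = 0, seed = 1)
  ped <- simulate_pedigree(cfg, sizes = 4)
  founders <- ped$individual_id[is.na(ped$father_id)]
  kids <- ped$individual_id[!is.na(ped$father_id)]
  expect_length(founders, 2)
  expect_length(kids, 2)
  expect_true(all(ped$father_id[!is.na(ped$father_id)] == founders[1]))
  expect_true(all(ped$mother_id[!is.na(ped$mother_id)] == founders[2]))

  couple <- simulate_pedigree(sim_config(n_families = 1, seed = 2), sizes = 2)
  expect_equal(nrow(couple), 2)
  expect_true(all(is.na(couple$father_id)))

  expect_error(simulate_pedigree(cfg, sizes = 1), "size")
})

test_that("family sizes are respected exactly across many families", {
  cfg <- sim_config(n_families = 300, family_sizes = 3:8,
                    family_size_probs = rep(1, 6), seed = 11)
  ped <- simulate_pedigree(cfg)
  sizes <- table(ped$family_id)
  expect_equal(length(sizes), 300)
  expect_true(all(sizes >= 3 & sizes <= 8))
  # drawing the same config reproduces the same total
  ped2 <- simulate_pedigree(cfg)
  expect_identical(ped, ped2)
})

test_that("in-married spouses produce grandchildren at most two matings deep", {
  cfg <- sim_config(n_families = 40, family_sizes = 10:20, p_spouse = 0.5,
                    seed = 5)
  ped <- simulate_pedigree(cfg)
  depth <- setNames(rep(0L, nrow(ped)), ped$individual_id)
  for (id in pleioscan:::ped_topo_order(ped)) {
    pa <- ped$father_id[ped$individual_id == id]
    if (!is.na(pa)) depth[id] <- depth[pa] + 1L
  }
  expect_lte(max(depth), 2)
})

test_that("gene dropping reproduces Hardy-Weinberg proportions in founders", {
  n <- 2000
  cfg <- sim_config(n_families = n, n_snps = 40, maf_range = c(0.5, 0.5),
                    ld_block_size = 1, seed = 9)
  gm <- simulate_genotypes(singleton_ped(n), cfg)
  freq <- mean(gm$dosage) / 2
  se <- sqrt(0.5 * 0.5 / (2 * n * 40))
  expect_lt(abs(freq - 0.5), 3 * se)
  geno_freq <- tabulate(gm$dosage + 1L, 3) / (n * 40)
  expect_equal(geno_freq, c(0.25, 0.5, 0.25), tolerance = 0.02)
})

test_that("siblings share half their genotypic variation on average", {
  cfg <- sim_config(n_families = 250, family_sizes = 4, p_spouse = 0,
                    n_snps = 200, ld_block_size = 1, seed = 13)
  ped <- simulate_pedigree(cfg)
  gm <- simulate_genotypes(ped, cfg)
  kids <- ped |>
    dplyr::filter(!is.na(father_id)) |>
    dplyr::group_by(family_id) |>
    dplyr::summarise(k1 = individual_id[1], k2 = individual_id[2])
  r <- vapply(seq_len(ncol(gm$dosage)), function(j) {
    suppressWarnings(cor(gm$dosage[kids$k1, j], gm$dosage[kids$k2, j]))
  }, numeric(1))
  expect_equal(mean(r, na.rm = TRUE), 0.5, tolerance = 0.05)
})

test_that("transmission is Mendelian-consistent without injected errors", {
  cfg <- sim_config(n_families = 60, family_sizes = 4:8, n_snps = 100,
                    missing_rate = 0, mendel_error_rate = 0, seed = 17)
  ped <- simulate_pedigree(cfg)
  gm <- simulate_genotypes(ped, cfg)
  expect_equal(sum(count_mendelian_errors(gm, ped)$mendel_errors), 0)
})

test_that("LD blocks induce correlation between adjacent SNPs", {
  n <- 800
  cfg <- sim_config(n_families = n, n_snps = 100, ld_block_size = 5,
                    ld_flip_prob = 0.05, seed = 19)
  gm <- simulate_genotypes(singleton_ped(n), cfg)
  d <- gm$dosage
  within <- vapply(seq(1, 96, by = 5), function(j) cor(d[, j], d[, j + 1]),
                   numeric(1))
  between <- vapply(seq(5, 95, by = 5), function(j) cor(d[, j], d[, j + 1]),
                    numeric(1))
  expect_gt(mean(within), 0.6)
  expect_lt(abs(mean(between)), 0.1)
})

test_that("phenotypes of relatives are uncorrelated when nothing is shared", {
  cfg <- sim_config(n_families = 400, family_sizes = 3, p_spouse = 0, seed = 23)
  ped <- simulate_pedigree(cfg)
  tm <- trait_model(h2 = c(0, 0), rho_g = 0, rho_e = 0)
  ph <- simulate_phenotypes(ped, NULL, tm, seed = 29, covariates = FALSE)
  y <- pheno_vec(ph, "trait1")
  kids <- ped[!is.na(ped$father_id), ]
  r <- cor(y[kids$individual_id], y[kids$father_id])
  expect_lt(abs(r), 3 / sqrt(nrow(kids)))
})

test_that("fully heritable perfectly correlated traits are identical", {
  ped <- nuclear_ped(3)
  tm <- trait_model(h2 = c(1, 1), rho_g = 1, rho_e = 0)
  ph <- simulate_phenotypes(ped, NULL, tm, seed = 31, covariates = FALSE)
  expect_equal(ph$trait1, ph$trait2, tolerance = 1e-10)
})

test_that("parent-offspring cross-trait covariance matches kinship theory", {
  # cov(y1_parent, y2_child) = rho_g * sqrt(h2_1 h2_2) / 2
  cfg <- sim_config(n_families = 2000, family_sizes = 3, p_spouse = 0,
                    seed = 37)
  ped <- simulate_pedigree(cfg)
  tm <- trait_model(h2 = c(0.5, 0.5), rho_g = 0.66, rho_e = 0.43)
  ph <- simulate_phenotypes(ped, NULL, tm, seed = 41, covariates = FALSE)
  y1 <- pheno_vec(ph, "trait1"); y2 <- pheno_vec(ph, "trait2")
  kids <- ped[!is.na(ped$father_id), ]
  cv <- cov(y1[kids$father_id], y2[kids$individual_id])
  expect_lt(abs(cv - 0.5 * 0.66 * 0.5), 0.07)  # 3 MC SE at 2000 pairs
})

test_that("causal SNPs shift phenotypes by centered dosage effects", {
  n <- 500
  ped <- singleton_ped(n)
  cfg <- sim_config(n_families = n, n_snps = 10, ld_block_size = 1, seed = 43)
  gm <- simulate_genotypes(ped, cfg)
  causal <- tibble::tibble(snp_id = "snp00001", trait = "trait1", beta = 1)
  tm0 <- trait_model(h2 = c(0, 0), rho_g = 0, rho_e = 0,
                     trait_names = c("trait1", "trait2"))
  tm1 <- trait_model(h2 = c(0, 0), rho_g = 0, rho_e = 0, causal = causal,
                     trait_names = c("trait1", "trait2"))
  p0 <- simulate_phenotypes(ped, gm, tm0, seed = 47, covariates = FALSE)
  p1 <- simulate_phenotypes(ped, gm, tm1, seed = 47, covariates = FALSE)
  shift <- p1$trait1 - p0$trait1
  x <- gm$dosage[, "snp00001"]
  expect_equal(shift, unname(x - 2 * gm$snps$maf[1]), tolerance = 1e-10)
  expect_equal(p1$trait2, p0$trait2)
})

test_that("identical seeds give bit-identical simulations", {
  cfg <- sim_config(n_families = 20, n_snps = 50, missing_rate = 0.02,
                    mendel_error_rate = 0.01, seed = 53)
  p1 <- simulate_pedigree(cfg); p2 <- simulate_pedigree(cfg)
  expect_identical(p1, p2)
  g1 <- simulate_genotypes(p1, cfg); g2 <- simulate_genotypes(p2, cfg)
  expect_identical(g1$dosage, g2$dosage)
  tm <- trait_model(h2 = c(0.4, 0.6), rho_g = 0.3, rho_e = 0.2)
  f1 <- simulate_phenotypes(p1, g1, tm, seed = 59)
  f2 <- simulate_phenotypes(p2, g2, tm, seed = 59)
  expect_identical(f1, f2)
})

test_that("trait model validates correlation matrices and rates", {
  expect_error(trait_model(h2 = c(0.5, 1.2)), "\\[0, 1\\]")
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(trait_model(h2 = c(0.5, 0.5), rho_g = bad), "-1, 1")
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(trait_model(h2 = rep(0.5, 3), rho_g = R,
                           rho_e = diag(3)), "positive semidefinite")
  expect_error(sim_config(seed = 1, maf_range = c(0.001, 0.5)), "0.01")
  expect_error(sim_config(n_families = 2), "seed")
})
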