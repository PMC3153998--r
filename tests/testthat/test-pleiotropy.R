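test_that("shared counts cover disjoint, identical and published-count cases", {
  set.seed(241)
  a <- fake_results(200, sig_idx = 1:30)
  b <- fake_results(200, sig_idx = 61:90)
  sc <- shared_counts(a, b, 0.01)
  expect_equal(sc$shared, 0)
  expect_equal(sc$union, 60)

  sc2 <- shared_counts(a, a, 0.01)
  expect_equal(sc2$shared, sc2$n1)
  expect_equal(sc2$union, sc2$n1)

  # published per-trait counts: 5012 and 4806 significant, 622 in both
  m <- 10000
  A <- fake_results(m, sig_idx = 1:5012)
  B <- fake_results(m, sig_idx = 4391:9196)
  sc3 <- shared_counts(A, B, 0.01)
  expect_equal(unlist(sc3), c(n1 = 5012, n2 = 4806, shared = 622, union = 9196))

  # SNP order does not matter, mismatched SNP sets do
  B_shuffled <- B[sample(m), ]
  expect_equal(shared_counts(A, B_shuffled, 0.01), sc3)
  expect_error(shared_counts(A, B[-1, ], 0.01), "different SNPs")
})

test_that("shared percentage reproduces the published worked examples", {
  expect_equal(round(shared_percentage(5012, 4806, 622), 1), 6.8)
  expect_equal(round(shared_percentage(4281, 4272, 529), 1), 6.6)
  expect_equal(round(shared_percentage(4437, 4779, 2017), 0), 28)
  expect_true(is.na(shared_percentage(0, 0, 0)))
  expect_error(shared_percentage(5, 8, 6), "exceed")
})

test_that("the analytic joint-tail expectation matches limits and an oracle", {
  expect_equal(analytic_expected_shared(0, 0.01, 433510), 433510 * 1e-4,
               tolerance = 1e-8)
  expect_equal(analytic_expected_shared(1, 0.01, 1000), 10)
  expect_equal(analytic_expected_shared(-1, 0.01, 1000), 10)
  # independent bivariate-normal orthant oracle
  z <- qnorm(1 - 0.01 / 2)
  for (rho in c(0.3, 0.5, 0.8, -0.5)) {
    S <- matrix(c(1, rho, rho, 1), 2)
    up <- mvtnorm::pmvnorm(lower = c(z, z), upper = c(Inf, Inf), sigma = S)[1]
    mixed <- mvtnorm::pmvnorm(lower = c(z, -Inf), upper = c(Inf, -z),
                              sigma = S)[1]
    expect_equal(analytic_expected_shared(rho, 0.01, 1e6),
                 1e6 * (2 * up + 2 * mixed), tolerance = 1e-6)
  }
})

test_that("the simulation null matches the analytic expectation", {
  n <- 250
  ped <- singleton_ped(n)
  tm <- trait_model(h2 = c(0, 0), rho_g = 0, rho_e = 0.5)
  ph <- simulate_phenotypes(ped, NULL, tm, seed = 251, covariates = FALSE)
  pa <- pheno_vec(ph, "trait1"); pb <- pheno_vec(ph, "trait2")
  nl <- expected_shared_null(pa, pb, ped, n_snps = 10000, reps = 200,
                             alpha = 0.05, seed = 257, batch_snps = 300)
  an <- analytic_expected_shared(cor(ph$trait1, ph$trait2), 0.05, 10000)
  expect_lt(abs(nl$expected - an), 3 * nl$mc_se + 0.05 * an)

  # a duplicated phenotype makes joint significance marginal significance
  nl2 <- expected_shared_null(pa, pa, ped, n_snps = 10000, reps = 150,
                              alpha = 0.05, seed = 263, batch_snps = 300)
  expect_equal(nl2$expected, 0.05 * 10000, tolerance = 0.1 * 0.05 * 10000)

  expect_error(expected_shared_null(pa, pb, ped, 1000, reps = 50), "at least 100")
  expect_error(expected_shared_null(pa, pb, ped, 1000, reps = 150,
                                    gamma = 0.001), "quantile")
})

test_that("observed counts are judged against the null distribution", {
  n <- 200
  ped <- singleton_ped(n)
  tm <- trait_model(h2 = c(0, 0), rho_g = 0, rho_e = 0)
  ph <- simulate_phenotypes(ped, NULL, tm, seed = 269, covariates = FALSE)
  pa <- pheno_vec(ph, "trait1"); pb <- pheno_vec(ph, "trait2")
  nl <- expected_shared_null(pa, pb, ped, n_snps = 1000, reps = 120,
                             alpha = 0.1, seed = 271, batch_snps = 100,
                             observed = 1000)
  expect_equal(nl$empirical_p, 0)        # observed far beyond the null
  expect_true(nl$pleiotropic)
  nl0 <- expected_shared_null(pa, pb, ped, n_snps = 1000, reps = 120,
                              alpha = 0.1, seed = 271, batch_snps = 100,
                              observed = 0)
  expect_equal(nl0$empirical_p, 1)       # every null rep is at least 0
  expect_false(nl0$pleiotropic)
})

test_that("randomized empirical p-values are uniform under the null", {
  n <- 150
  ped <- singleton_ped(n)
  tm <- trait_model(h2 = c(0, 0), rho_g = 0, rho_e = 0.4)
  ph <- simulate_phenotypes(ped, NULL, tm, seed = 277, covariates = FALSE)
  pa <- pheno_vec(ph, "trait1"); pb <- pheno_vec(ph, "trait2")
  nl <- expected_shared_null(pa, pb, ped, n_snps = 60, reps = 1200,
                             alpha = 0.1, seed = 281, batch_snps = 60)
  counts <- nl$null_counts
  null_set <- counts[1:1000]
  obs_set <- counts[1001:1200]
  set.seed(283)
  pvals <- vapply(obs_set, function(o) {
    gt <- sum(null_set > o); ge <- sum(null_set >= o)
    (gt + runif(1) * (ge - gt + 1)) / (length(null_set) + 1)
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("sharing grows with the threshold when statistics are correlated", {
  set.seed(293)
  m <- 50000
  z1 <- rnorm(m)
  z2 <- 0.8 * z1 + sqrt(1 - 0.64) * rnorm(m)
  mk <- function(z) tibble::tibble(snp_id = sprintf("s%05d", 1:m), trait = "t",
                                   beta = z, se = 1, p = 2 * pnorm(-abs(z)),
                                   n_used = 1L, method = "gls",
                                   monomorphic = FALSE)
  a <- mk(z1); b <- mk(z2)
  pct <- vapply(c(0.002, 0.01, 0.05, 0.2), function(al) {
    sc <- shared_counts(a, b, al)
    shared_percentage(sc$n1, sc$n2, sc$shared)
  }, numeric(1))
  expect_true(all(diff(pct) >= 0))
  # and sharing is symmetric in trait order
  tab1 <- pair_shared_table(list(x = a, y = b), 0.01)
  tab2 <- pair_shared_table(list(x = b, y = a), 0.01)
  expect_equal(tab1$shared_pct, tab2$shared_pct)
})

test_that("observed/expected ratios summarize the published pair table", {
  flat <- tibble::tibble(trait1 = "a", trait2 = c("b", "c"),
                         observed = c(10, 20), expected = c(10, 20))
  r <- observed_expected_ratio(flat)
  expect_equal(attr(r, "summary")$mean_ratio, 1)

  pairs <- bone_pair_table()
  r2 <- observed_expected_ratio(pairs)
  # independent arithmetic on the packaged matrices
  sm <- bone_shared_matrix()
  idx <- utils::combn(9, 2)
  oracle <- mean(sm[cbind(idx[2, ], idx[1, ])] / sm[cbind(idx[1, ], idx[2, ])])
  expect_equal(attr(r2, "summary")$mean_ratio, oracle, tolerance = 1e-12)
  expect_equal(nrow(r2), 36)

  expect_warning(observed_expected_ratio(
    tibble::tibble(trait1 = "a", trait2 = c("b", "c"),
                   observed = c(1, 2), expected = c(0, 2))), "zero expected")
})

test_that("similarity-correlation handles affine, null and published cases", {
  set.seed(307)
  vc <- tibble::tibble(trait1 = letters[1:10], trait2 = LETTERS[1:10],
                       rho_g = runif(10, -1, 1), rho_e = runif(10, -1, 1))
  sim <- tibble::tibble(trait1 = vc$trait1, trait2 = vc$trait2,
                        shared_pct = 3 + 5 * abs(vc$rho_g))
  out <- correlate_similarity(sim, vc)
  expect_equal(out$r[out$term == "rho_g"], 1, tolerance = 1e-12)

  # permuted similarity: no real correlation
  sim_perm <- sim; sim_perm$shared_pct <- sample(sim$shared_pct)
  out_perm <- correlate_similarity(sim_perm, vc)
  expect_lt(abs(out_perm$r[out_perm$term == "rho_g"]), 0.7)

  expect_error(correlate_similarity(sim[1:2, ], vc), "3 retained")

  # reconstruction from the packaged tables, heel-ultrasound pair excluded
  pairs <- bone_pair_table()
  out_pub <- correlate_similarity(
    dplyr::select(pairs, trait1, trait2, shared_pct),
    dplyr::select(pairs, trait1, trait2, rho_p, rho_g, rho_e),
    exclusions = list(c("BUA", "SOS"))
  )
  expect_equal(out_pub$n_pairs, rep(35L, 3), ignore_attr = TRUE)
  keep <- !(pairs$trait1 == "BUA" & pairs$trait2 == "SOS")
  expect_equal(out_pub$r[out_pub$term == "rho_g"],
               cor(abs(pairs$rho_g[keep]), pairs$shared_pct[keep]))
  # the phenotypic-correlation relationship is the strongest, as published
  expect_gt(out_pub$r[out_pub$term == "rho_p"],
            out_pub$r[out_pub$term == "rho_e"])
})

test_that("pleiotropic SNP extraction applies thresholds, signs and LD", {
  set.seed(311)
  n <- 100
  dos <- matrix(rbinom(n * 5, 2L, 0.4), n, 5)
  dos[, 3] <- dos[, 2]  # identical dosages: r2 = 1
  rownames(dos) <- sprintf("i%03d", 1:n)
  gm <- gm_from_dosage(dos)
  res <- function(p, beta) {
    tibble::tibble(snp_id = gm$snps$snp_id, trait = "t", beta = beta, se = 1,
                   p = p, n_used = n, method = "gls", monomorphic = FALSE)
  }
  a <- res(c(5e-4, 1e-4, 1e-4, 5e-4, 0.5), c(1, 1, 1, -1, 1))
  b <- res(c(2e-3, 1e-4, 2e-4, 8e-4, 0.5), c(1, 1, 1, 1, 1))
  out <- extract_pleiotropic_snps(a, b, gm)
  # SNP 1 fails the second trait's threshold (p = 0.002), SNP 5 both
  expect_setequal(out$snp_id, gm$snps$snp_id[2:4])
  expect_equal(out$ld_cluster[out$snp_id == "s002"],
               out$ld_cluster[out$snp_id == "s003"])
  expect_false(out$sign_consistent[out$snp_id == "s004"])
  expect_true(all(out$sign_consistent[out$snp_id %in% c("s002", "s003")]))
})

test_that("planted pleiotropic SNPs are recovered with consistent signs", {
  n <- 300
  ped <- singleton_ped(n)
  K <- diag(n); dimnames(K) <- list(ped$individual_id, ped$individual_id)
  hits <- vapply(1:50, function(r) {
    cfg <- sim_config(n_families = n, n_snps = 30, ld_block_size = 1,
                      maf_range = c(0.3, 0.3), seed = 400 + r)
    gm <- simulate_genotypes(ped, cfg)
    causal <- tibble::tibble(snp_id = "snp00007", trait = c("t1", "t2"),
                             beta = 0.5)
    tm <- trait_model(h2 = c(0, 0), rho_g = 0, rho_e = 0.2,
                      trait_names = c("t1", "t2"), causal = causal)
    ph <- simulate_phenotypes(ped, gm, tm, seed = 900 + r, covariates = FALSE)
    s1 <- gwas_lmm(pheno_vec(ph, "t1"), gm, K, trait = "t1")
    s2 <- gwas_lmm(pheno_vec(ph, "t2"), gm, K, trait = "t2")
    out <- extract_pleiotropic_snps(s1, s2, gm)
    any(out$snp_id == "snp00007" & out$sign_consistent)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
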