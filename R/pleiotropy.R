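#' Shared-association counts for a trait pair
#'
#' Counts SNPs significant at `p < alpha` for each trait, for both traits,
#' and for either trait, over the common SNP set of two association scans.
#'
#' @param results_a,results_b `gwas_scan` objects or their `results` tibbles
#'   for the two traits; must cover identical SNP sets.
#' @param alpha Significance threshold.
#' @return A one-row tibble `n1`, `n2`, `shared`, `union`.
#' @export
shared_counts <- function(results_a, results_b, alpha) {
  if (inherits(results_a, "gwas_scan")) results_a <- results_a$results
  if (inherits(results_b, "gwas_scan")) results_b <- results_b$results
  if (!setequal(results_a$snp_id, results_b$snp_id) ||
      nrow(results_a) != nrow(results_b)) {
    abort("The two result sets cover different SNPs.")
  }
  b <- results_b[match(results_a$snp_id, results_b$snp_id), ]
  sig_a <- results_a$p < alpha
  sig_b <- b$p < alpha
  n1 <- sum(sig_a, na.rm = TRUE)
  n2 <- sum(sig_b, na.rm = TRUE)
  shared <- sum(sig_a & sig_b, na.rm = TRUE)
  tibble::tibble(n1 = n1, n2 = n2, shared = shared, union = n1 + n2 - shared)
}

#' Shared-association percentage
#'
#' The pleiotropy similarity measure for a trait pair: the number of SNPs
#' significantly associated with both traits divided by the number
#' associated with either (the union of the two significant sets), times
#' 100.
#'
#' @param n1,n2 Per-trait significant SNP counts.
#' @param shared Count of SNPs significant for both traits.
#' @return Percentage in `[0, 100]`; `NA` when the union is empty.
#' @export
shared_percentage <- function(n1, n2, shared) {
  if (any(shared > pmin(n1, n2))) abort("`shared` cannot exceed min(n1, n2).")
  u <- n1 + n2 - shared
  ifelse(u == 0, NA_real_, 100 * shared / u)
}

#' Analytic expected count of jointly significant SNPs
#'
#' Closed-form calibration oracle for the simulation null: if the two Wald
#' statistics of a null SNP are bivariate standard normal with correlation
#' `rho`, the probability that both exceed the two-sided `alpha` threshold
#' is `P(|Z1| > z, |Z2| > z)` with `z = qnorm(1 - alpha/2)`, evaluated by
#' 1-D numerical integration over the conditional normal. At `rho = 0` this
#' factorizes to `alpha^2`; at `|rho| = 1` it equals `alpha`.
#'
#' @param rho Correlation of the two test statistics (in practice, the
#'   residual correlation of the trait pair), in `[-1, 1]`.
#' @param alpha Per-trait two-sided significance level.
#' @param n_snps Number of SNPs tested.
#' @return Expected number of jointly significant SNPs.
#' @export
analytic_expected_shared <- function(rho, alpha, n_snps) {
  if (abs(rho) > 1) abort("`rho` must lie in [-1, 1].")
  z <- qnorm(1 - alpha / 2)
  if (abs(rho) > 1 - 1e-12) return(n_snps * alpha)
  s <- sqrt(1 - rho^2)
  tail2 <- function(z1) {
    dnorm(z1) * (pnorm((-z - rho * z1) / s) + pnorm((z - rho * z1) / s,
                                                    lower.tail = FALSE))
  }
  # P(|Z1|>z, |Z2|>z) is symmetric under z1 -> -z1
  pr <- 2 * integrate(tail2, z, Inf, rel.tol = 1e-10)$value
  n_snps * pr
}

#' Simulation null for the shared-association count
#'
#' Builds the null distribution of the number of SNPs jointly significant
#' for a fixed trait pair, using SNPs simulated with no phenotype effect:
#' gene-dropped through the pedigree (default, preserving family
#' correlation) or drawn independently of it. Each repetition tests a batch
#' of null SNPs against both traits with the two-stage GLS of [gwas_lmm()]
#' and records the jointly significant count; counts are scaled to `n_snps`
#' for reporting. When an observed count is supplied, the empirical p-value
#' is the fraction of null repetitions at or above it (`smooth = TRUE`
#' randomizes ties so the p-value is exactly uniform under the null), and
#' pleiotropy is declared when the observed count exceeds the null
#' `1 - gamma` quantile.
#'
#' @param pheno_a,pheno_b Named numeric vectors of residualized trait values.
#' @param ped Pedigree tibble for the samples.
#' @param n_snps Number of SNPs the expected count is scaled to.
#' @param reps Number of null repetitions (>= 100; the reference analysis
#'   used 20,000, 2,000 is the desk-scale default).
#' @param alpha Per-trait significance threshold.
#' @param seed Integer seed.
#' @param batch_snps Null SNPs tested per repetition (default 200).
#' @param observed Observed jointly significant count (on the `n_snps`
#'   scale), if any.
#' @param gamma Declaration quantile (default 0.05).
#' @param genotype_sim `"gene_drop"` (default) or `"independent"`.
#' @param kinship Optional precomputed relationship matrix.
#' @param maf_range Allele-frequency range for the null SNPs.
#' @param smooth Randomize ties in the empirical p-value (default `FALSE`).
#' @return An object of class `shared_null`: `null_counts` (per-rep counts
#'   on the batch scale), `expected` (mean count scaled to `n_snps`),
#'   `mc_se` (Monte-Carlo standard error of `expected`), `threshold`
#'   (declaration threshold on the `n_snps` scale), `empirical_p` and
#'   `pleiotropic` (when `observed` given).
#' @export
expected_shared_null <- function(pheno_a, pheno_b, ped, n_snps, reps = 2000,
                                 alpha = 0.01, seed = 1, batch_snps = 200,
                                 observed = NULL, gamma = 0.05,
                                 genotype_sim = c("gene_drop", "independent"),
                                 kinship = NULL, maf_range = c(0.05, 0.5),
                                 smooth = FALSE) {
  genotype_sim <- match.arg(genotype_sim)
  if (reps < 100) abort("`reps` must be at least 100.")
  if (reps * gamma < 1) {
    abort("`reps` is too small for the requested declaration quantile.")
  }
  validate_pedigree(ped)
  kinship <- kinship %||% kinship_from_pedigree(ped)
  ids <- intersect(intersect(names(pheno_a), names(pheno_b)),
                   ped$individual_id)
  ids <- ids[!is.na(pheno_a[ids]) & !is.na(pheno_b[ids])]
  if (length(ids) < 30) abort("Fewer than 30 samples with both traits.")
  ped_use <- ped[ped$individual_id %in% union(ids, c(ped$father_id, ped$mother_id)), ]
  eg <- kinship_eigen(kinship, ids)

  # null polygenic fit once per trait; per-SNP GLS reuses the rotation
  prep <- function(y) {
    ystar <- drop(crossprod(eg$U, y))
    opt <- optimize(uni_profile_loglik, c(0, 1), maximum = TRUE,
                    ystar = ystar, one = eg$one, d = eg$d, tol = 1e-10)
    h2 <- if (uni_profile_loglik(0, ystar, eg$one, eg$d) >= opt$objective) 0
          else opt$maximum
    w <- h2 * eg$d + (1 - h2)
    sw <- sqrt(w)
    a <- eg$one / sw
    b <- ystar / sw
    list(a = a, b_perp = b - sum(a * b) / sum(a^2) * a, sw = sw,
         Saa = sum(a^2))
  }
  pa <- prep(unname(pheno_a[ids]))
  pb <- prep(unname(pheno_b[ids]))
  n <- length(ids)

  set.seed(seed)
  chunk <- max(1L, floor(20000 / batch_snps))
  counts <- integer(reps)
  done <- 0L
  while (done < reps) {
    k <- min(chunk, reps - done)
    m <- k * batch_snps
    if (genotype_sim == "gene_drop") {
      cfg <- sim_config(n_families = 1, n_snps = m, ld_block_size = 1,
                        maf_range = maf_range, seed = 1)
      gm <- simulate_genotypes(ped_use, cfg,
                               seed = sample.int(.Machine$integer.max, 1))
      X <- gm$dosage[ids, , drop = FALSE]
    } else {
      maf <- runif(m, maf_range[1], maf_range[2])
      X <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), n, m)
    }
    storage.mode(X) <- "double"
    Xs <- crossprod(eg$U, X)
    pvals <- function(pp) {
      C <- Xs / pp$sw
      Sca <- drop(crossprod(C, pp$a))
      Scc_perp <- colSums(C^2) - Sca^2 / pp$Saa
      Scb_perp <- drop(crossprod(C, pp$b_perp))
      beta <- Scb_perp / pmax(Scc_perp, 1e-12)
      rss <- sum(pp$b_perp^2) - beta^2 * Scc_perp
      se <- sqrt(pmax(rss, 0) / (n - 2) / pmax(Scc_perp, 1e-12))
      p <- 2 * pnorm(-abs(beta / se))
      p[Scc_perp <= 1e-12] <- 1
      p
    }
    joint <- pvals(pa) < alpha & pvals(pb) < alpha
    grp <- rep(seq_len(k), each = batch_snps)
    counts[done + seq_len(k)] <- as.integer(tapply(joint, grp, sum))
    done <- done + k
  }

  scale_f <- n_snps / batch_snps
  null_scaled <- counts * scale_f
  expected <- mean(null_scaled)
  mc_se <- sd(null_scaled) / sqrt(reps)
  threshold <- quantile(null_scaled, 1 - gamma, names = FALSE)
  out <- list(
    null_counts = counts, batch_snps = batch_snps, n_snps = n_snps,
    alpha = alpha, reps = reps, expected = expected, mc_se = mc_se,
    gamma = gamma, threshold = threshold
  )
  if (!is.null(observed)) {
    ge <- sum(null_scaled >= observed)
    if (smooth) {
      gt <- sum(null_scaled > observed)
      out$empirical_p <- (gt + runif(1) * (ge - gt + 1)) / (reps + 1)
    } else {
      out$empirical_p <- ge / reps
    }
    out$observed <- observed
    out$pleiotropic <- observed > threshold
  }
  structure(out, class = "shared_null")
}

#' @export
print.shared_null <- function(x, ...) {
  cat(sprintf(
    "<shared_null> %d reps x %d SNPs: expected %.2f (MC SE %.2f) of %d at alpha = %g\n",
    x$reps, x$batch_snps, x$expected, x$mc_se, x$n_snps, x$alpha))
  if (!is.null(x$observed)) {
    cat(sprintf("  observed %.1f, threshold %.1f, empirical p = %.4g%s\n",
                x$observed, x$threshold, x$empirical_p,
                if (x$pleiotropic) " [pleiotropic]" else ""))
  }
  invisible(x)
}

#' Pairwise shared-association table from a set of scans
#'
#' Applies [shared_counts()] and [shared_percentage()] to every pair of
#' association scans.
#'
#' @param scans Named list of `gwas_scan` objects (or results tibbles), one
#'   per trait.
#' @param alpha Significance threshold.
#' @return A tibble with one row per pair: `trait1`, `trait2`, `n1`, `n2`,
#'   `shared`, `union`, `shared_pct`.
#' @export
pair_shared_table <- function(scans, alpha) {
  traits <- names(scans)
  if (is.null(traits) || length(traits) < 2) {
    abort("`scans` must be a named list of at least two scans.")
  }
  pairs <- utils::combn(traits, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    sc <- shared_counts(scans[[pr[1]]], scans[[pr[2]]], alpha)
    dplyr::mutate(sc, trait1 = pr[1], trait2 = pr[2],
                  shared_pct = shared_percentage(.data$n1, .data$n2, .data$shared),
                  .before = 1)
  })
}

#' Observed/expected ratios for shared associations
#'
#' @param similarities Tibble with per-pair columns `observed` and
#'   `expected` (and optionally `trait1`, `trait2` labels).
#' @return The input with a `ratio` column, plus a `summary` attribute
#'   (mean, min, max with pair labels); pairs with zero expected counts are
#'   skipped with a warning.
#' @export
observed_expected_ratio <- function(similarities) {
  if (!all(c("observed", "expected") %in% names(similarities))) {
    abort("`similarities` needs `observed` and `expected` columns.")
  }
  bad <- similarities$expected <= 0
  if (any(bad)) {
    warn(sprintf("Skipping %d pair(s) with zero expected count.", sum(bad)))
  }
  out <- similarities[!bad, , drop = FALSE]
  out$ratio <- out$observed / out$expected
  lab <- function(i) {
    if (all(c("trait1", "trait2") %in% names(out))) {
      paste(out$trait1[i], out$trait2[i], sep = "-")
    } else {
      as.character(i)
    }
  }
  attr(out, "summary") <- tibble::tibble(
    mean_ratio = mean(out$ratio),
    min_ratio = min(out$ratio), min_pair = lab(which.min(out$ratio)),
    max_ratio = max(out$ratio), max_pair = lab(which.max(out$ratio))
  )
  out
}

# canonical unordered pair key
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Correlate shared-association percentages with trait-pair correlations
#'
#' Pearson correlation, across trait pairs, of the shared-association
#' percentage with the absolute phenotypic, genetic and environmental
#' correlations from the variance-components decomposition. Pairs listed in
#' `exclusions` (e.g. a near-collinear pair measured on the same bone) are
#' removed first.
#'
#' @param pair_similarities Tibble with `trait1`, `trait2`, `shared_pct`.
#' @param varcomp_table Tibble with `trait1`, `trait2` and any of `rho_p`,
#'   `rho_g`, `rho_e` (e.g. from [fit_all_pairs()]).
#' @param exclusions List of length-2 character vectors naming pairs to
#'   exclude (order-insensitive), or `NULL`.
#' @return A tibble `term` (`rho_p`/`rho_g`/`rho_e`), `r`, `n_pairs`, with
#'   excluded pairs in attribute `"excluded"`.
#' @export
correlate_similarity <- function(pair_similarities, varcomp_table,
                                 exclusions = NULL) {
  key_s <- pair_key(pair_similarities$trait1, pair_similarities$trait2)
  key_v <- pair_key(varcomp_table$trait1, varcomp_table$trait2)
  dat <- dplyr::inner_join(
    dplyr::mutate(pair_similarities, ..key = key_s),
    dplyr::mutate(varcomp_table, ..key = key_v) |>
      dplyr::select(-dplyr::any_of(c("trait1", "trait2"))),
    by = "..key"
  )
  excluded <- character(0)
  if (!is.null(exclusions)) {
    drop_keys <- purrr::map_chr(exclusions, ~ pair_key(.x[1], .x[2]))
    excluded <- dat$..key[dat$..key %in% drop_keys]
    dat <- dat[!dat$..key %in% drop_keys, , drop = FALSE]
  }
  if (nrow(dat) < 3) abort("Fewer than 3 retained pairs.")
  terms <- intersect(c("rho_p", "rho_g", "rho_e"), names(dat))
  out <- purrr::map_dfr(terms, function(tm) {
    tibble::tibble(term = tm,
                   r = cor(abs(dat[[tm]]), dat$shared_pct),
                   n_pairs = nrow(dat))
  })
  attr(out, "excluded") <- gsub("\r", "-", excluded)
  attr(out, "pairs") <- dplyr::select(dat, -"..key")
  out
}

#' Extract candidate pleiotropic SNPs for a trait pair
#'
#' SNPs below `p_threshold` in both scans, annotated with effect-sign
#' consistency and linkage-disequilibrium clusters (single linkage at
#' squared dosage correlation `r2 >= ld_r2_cutoff`, within chromosome).
#'
#' @param results_a,results_b `gwas_scan` objects or results tibbles.
#' @param genotypes A [genotype_matrix()] covering the scanned SNPs.
#' @param p_threshold Per-trait threshold (default 0.001).
#' @param ld_r2_cutoff Clustering cutoff (default 0.5).
#' @return A tibble `snp_id`, `chrom`, `pos`, `beta_a`, `se_a`, `p_a`,
#'   `beta_b`, `se_b`, `p_b`, `sign_consistent`, `ld_cluster`.
#' @export
extract_pleiotropic_snps <- function(results_a, results_b, genotypes,
                                     p_threshold = 0.001,
                                     ld_r2_cutoff = 0.5) {
  if (inherits(results_a, "gwas_scan")) results_a <- results_a$results
  if (inherits(results_b, "gwas_scan")) results_b <- results_b$results
  joined <- dplyr::inner_join(
    dplyr::select(results_a, "snp_id", beta_a = "beta", se_a = "se", p_a = "p"),
    dplyr::select(results_b, "snp_id", beta_b = "beta", se_b = "se", p_b = "p"),
    by = "snp_id"
  ) |>
    dplyr::filter(.data$p_a < p_threshold, .data$p_b < p_threshold) |>
    dplyr::left_join(dplyr::select(genotypes$snps, "snp_id", "chrom", "pos"),
                     by = "snp_id") |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::mutate(sign_consistent = sign(.data$beta_a) == sign(.data$beta_b))
  if (nrow(joined) == 0) {
    return(dplyr::mutate(joined, ld_cluster = integer(0)))
  }
  # single-linkage LD clusters within chromosome via union-find
  parent <- seq_len(nrow(joined))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  X <- genotypes$dosage[, joined$snp_id, drop = FALSE]
  storage.mode(X) <- "double"
  cm <- colMeans(X, na.rm = TRUE)
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas) > 0) X[nas] <- cm[nas[, 2]]
  for (ch in unique(joined$chrom)) {
    idx <- which(joined$chrom == ch)
    if (length(idx) < 2) next
    r2 <- suppressWarnings(cor(X[, idx, drop = FALSE]))^2
    r2[is.na(r2)] <- 0
    for (a in seq_along(idx)) {
      for (b in seq_len(a - 1)) {
        if (r2[a, b] >= ld_r2_cutoff) {
          ra <- find(idx[a]); rb <- find(idx[b])
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
  }
  roots <- vapply(seq_len(nrow(joined)), find, integer(1))
  joined$ld_cluster <- match(roots, unique(roots))
  joined
}
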