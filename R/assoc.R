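#' Family random-intercept relationship structure
#'
#' Alternative to the kinship model: a block matrix that is 1 within a
#' family and 0 between families, i.e. the covariance structure of a
#' family-indexed random intercept. Pass it to [gwas_lmm()] or the polygenic
#' fits in place of the kinship matrix.
#'
#' @param ped Pedigree tibble.
#' @return A symmetric 0/1 matrix with sample ids as dimnames.
#' @export
family_relationship_matrix <- function(ped) {
  validate_pedigree(ped)
  B <- outer(ped$family_id, ped$family_id, `==`) * 1
  dimnames(B) <- list(ped$individual_id, ped$individual_id)
  B
}

#' Mixed-model single-SNP association scan
#'
#' Per-SNP additive association tests that account for family correlation.
#' The default is a two-stage generalized least squares: the null polygenic
#' model is fit once per trait (via the same machinery as
#' [fit_univariate_polygenic()]), then every SNP is tested by GLS with the
#' null covariance structure held fixed, re-estimating only the residual
#' scale per SNP (n - 2 denominator) so that with an identity relationship
#' matrix the scan reduces exactly to ordinary least squares. Wald p-values
#' come from the standard normal. `method = "exact"` refits the
#' heritability jointly with each SNP (slow; for verification on small
#' runs); `method = "ols"` ignores the relationship matrix entirely (for
#' demonstrating inflation on family data). Missing dosages are
#' mean-imputed per SNP; SNPs monomorphic after imputation are flagged and
#' reported with missing effect and p = 1.
#'
#' @param residuals Named numeric vector of residualized trait values, or a
#'   tibble with `sample_id` and one value column.
#' @param genotypes A [genotype_matrix()].
#' @param kinship Additive relationship matrix ([kinship_from_pedigree()])
#'   or a [family_relationship_matrix()].
#' @param trait Trait label carried into the results.
#' @param method `"gls"` (default), `"exact"`, or `"ols"`.
#' @param alpha_levels Significance thresholds summarized in the scan
#'   summary (default 0.01).
#' @param decomp Optional precomputed kinship eigendecomposition over the
#'   analysis samples (see [fit_univariate_polygenic()]); reused across
#'   scans on the same pedigree.
#' @return An object of class `gwas_scan`: `results` (tibble `snp_id`,
#'   `trait`, `beta`, `se`, `p`, `n_used`, `method`, `monomorphic`),
#'   `summary` (tibble `trait`, `n_snps`, one `n_sig_*` count per alpha,
#'   `min_p`), and `h2_null`.
#' @export
gwas_lmm <- function(residuals, genotypes, kinship, trait = "trait",
                     method = c("gls", "exact", "ols"),
                     alpha_levels = 0.01, decomp = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  al <- align_residuals(residuals, kinship)
  ids <- intersect(al$ids, genotypes$sample_ids)
  if (length(ids) < 30) abort("Fewer than 30 samples shared by residuals, kinship and genotypes.")
  y <- al$y[match(ids, al$ids)]
  X <- genotypes$dosage[ids, , drop = FALSE]
  storage.mode(X) <- "double"
  cm <- colMeans(X, na.rm = TRUE)
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas) > 0) X[nas] <- cm[nas[, 2]]
  mono <- matrixStats_colSds(X) == 0
  n <- length(ids)

  if (method == "ols") {
    d <- rep(1, n)
    U <- NULL
    h2 <- 0
    ystar <- y
    one <- rep(1, n)
    Xs <- X
  } else {
    eg <- get_decomp(decomp, kinship, ids)
    d <- eg$d
    ystar <- drop(crossprod(eg$U, y))
    one <- eg$one
    opt <- optimize(uni_profile_loglik, c(0, 1), maximum = TRUE,
                    ystar = ystar, one = one, d = d, tol = 1e-10)
    h2 <- opt$maximum
    if (uni_profile_loglik(0, ystar, one, d) >= opt$objective) h2 <- 0
    Xs <- crossprod(eg$U, X)
  }

  if (method == "exact") {
    out <- gwas_exact_scan(ystar, Xs, one, d, mono, h2)
  } else {
    w <- h2 * d + (1 - h2)
    sw <- sqrt(w)
    a <- one / sw
    b <- ystar / sw
    C <- Xs / sw
    Saa <- sum(a^2)
    # project out the intercept in the whitened metric
    b_perp <- b - sum(a * b) / Saa * a
    Sca <- drop(crossprod(C, a))
    Scc_perp <- colSums(C^2) - Sca^2 / Saa
    Scb_perp <- drop(crossprod(C, b_perp))
    beta <- Scb_perp / Scc_perp
    rss <- sum(b_perp^2) - beta^2 * Scc_perp
    se <- sqrt(pmax(rss, 0) / (n - 2) / Scc_perp)
    z <- beta / se
    p <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
    beta[mono] <- NA_real_
    se[mono] <- NA_real_
    p[mono] <- 1
    out <- list(beta = beta, se = se, p = p)
  }

  results <- tibble::tibble(
    snp_id = genotypes$snps$snp_id,
    trait = trait,
    beta = unname(out$beta), se = unname(out$se), p = unname(out$p),
    n_used = n, method = method, monomorphic = mono
  )
  sig <- purrr::map_int(alpha_levels, ~ count_significant(results, .x))
  summary_tbl <- tibble::tibble(trait = trait, n_snps = nrow(results))
  for (i in seq_along(alpha_levels)) {
    summary_tbl[[paste0("n_sig_", alpha_levels[i])]] <- sig[i]
  }
  summary_tbl$min_p <- min(results$p)
  structure(
    list(results = results, summary = summary_tbl, h2_null = h2,
         trait = trait, method = method),
    class = "gwas_scan"
  )
}

# per-SNP joint refit of the heritability (the "exact" LME mode)
gwas_exact_scan <- function(ystar, Xs, one, d, mono, h2_start) {
  n <- length(ystar)
  fit_one <- function(x) {
    prof <- function(h2) {
      w <- h2 * d + (1 - h2)
      Z <- cbind(one, x) / sqrt(w)
      b <- ystar / sqrt(w)
      qr_z <- qr(Z)
      rss <- sum(qr.resid(qr_z, b)^2)
      -0.5 * (n * log(2 * pi) + n * log(rss / n) + sum(log(w)) + n)
    }
    opt <- optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-8)
    h2 <- opt$maximum
    w <- h2 * d + (1 - h2)
    Z <- cbind(one, x) / sqrt(w)
    b <- ystar / sqrt(w)
    qr_z <- qr(Z)
    cf <- qr.coef(qr_z, b)
    rss <- sum(qr.resid(qr_z, b)^2)
    xtx_inv <- chol2inv(qr.R(qr_z))
    se <- sqrt(rss / (n - 2) * xtx_inv[2, 2])
    c(cf[2], se)
  }
  est <- apply(Xs, 2, fit_one)
  beta <- est[1, ]; se <- est[2, ]
  p <- pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin)
  beta[mono] <- NA_real_; se[mono] <- NA_real_; p[mono] <- 1
  list(beta = beta, se = se, p = p)
}

# column standard deviations without matrixStats
matrixStats_colSds <- function(X) {
  n <- nrow(X)
  cm <- colMeans(X)
  sqrt(pmax(colMeans(X^2) - cm^2, 0) * n / max(n - 1, 1))
}

#' @export
print.gwas_scan <- function(x, ...) {
  cat(sprintf("<gwas_scan> trait %s: %d SNPs, method %s, null h2 = %.3f, min p = %.3g\n",
              x$trait, nrow(x$results), x$method, x$h2_null,
              min(x$results$p)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gwas_scan <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.gwas_scan <- function(x, ...) x$summary

#' Count significant associations
#'
#' @param results A `gwas_scan` or its `results` tibble.
#' @param alpha Significance threshold; counts `p < alpha`.
#' @return Integer count.
#' @export
count_significant <- function(results, alpha) {
  if (inherits(results, "gwas_scan")) results <- results$results
  sum(results$p < alpha, na.rm = TRUE)
}

#' Genomic inflation factor
#'
#' Median Wald chi-square divided by its null median (0.4549); values near 1
#' indicate the model has absorbed relatedness/structure confounding.
#'
#' @param results A `gwas_scan` or its `results` tibble.
#' @return The inflation factor lambda.
#' @export
inflation_factor <- function(results) {
  if (inherits(results, "gwas_scan")) results <- results$results
  chi <- (results$beta / results$se)^2
  median(chi, na.rm = TRUE) / qchisq(0.5, 1)
}
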