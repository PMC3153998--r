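#' Count Mendelian errors per sample
#'
#' For every child with at least one genotyped parent, flags SNPs whose
#' genotypes are impossible under Mendelian transmission (e.g. parents both
#' homozygous reference with a non-reference child; a duo where parent and
#' child are opposite homozygotes). Each flagged SNP increments the child's
#' count and the counts of the genotyped parents involved in that check.
#' SNPs with a missing child genotype are skipped; a missing parent genotype
#' relaxes the check to the duo rule.
#'
#' @param genotypes A [genotype_matrix()].
#' @param ped Pedigree tibble; parent links outside the genotype matrix are
#'   ignored.
#' @return A tibble `sample_id`, `mendel_errors` covering every genotyped
#'   sample.
#' @export
count_mendelian_errors <- function(genotypes, ped) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  validate_pedigree(ped)
  ids <- genotypes$sample_ids
  counts <- setNames(integer(length(ids)), ids)
  D <- genotypes$dosage
  fa <- setNames(ped$father_id, ped$individual_id)
  mo <- setNames(ped$mother_id, ped$individual_id)
  in_gm <- function(x) !is.na(x) && x %in% ids
  for (child in intersect(ped$individual_id, ids)) {
    has_fa <- in_gm(fa[child])
    has_mo <- in_gm(mo[child])
    if (!has_fa && !has_mo) next
    dc <- D[child, ]
    df <- if (has_fa) D[fa[child], ] else rep(NA_integer_, ncol(D))
    dm <- if (has_mo) D[mo[child], ] else rep(NA_integer_, ncol(D))
    # impossible child dosage given parental gamete sets, vectorized:
    # father can transmit 0 iff dosage < 2, 1 iff dosage > 0 (NA: both)
    f0 <- is.na(df) | df < 2L; f1 <- is.na(df) | df > 0L
    m0 <- is.na(dm) | dm < 2L; m1 <- is.na(dm) | dm > 0L
    ok0 <- f0 & m0
    ok1 <- (f0 & m1) | (f1 & m0)
    ok2 <- f1 & m1
    bad <- !is.na(dc) &
      ((dc == 0L & !ok0) | (dc == 1L & !ok1) | (dc == 2L & !ok2))
    nbad <- sum(bad)
    if (nbad > 0) {
      counts[child] <- counts[child] + nbad
      if (has_fa) counts[fa[child]] <- counts[fa[child]] + sum(bad & !is.na(df))
      if (has_mo) counts[mo[child]] <- counts[mo[child]] + sum(bad & !is.na(dm))
    }
  }
  tibble::tibble(sample_id = ids, mendel_errors = unname(counts))
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Default is the 1-df chi-square goodness of fit of the observed genotype
#' counts against Hardy-Weinberg proportions at the sample allele frequency;
#' an exact test (summing probabilities of heterozygote counts no more
#' likely than the observed one, conditional on the allele counts) is
#' available. Monomorphic SNPs return p = 1 by convention.
#'
#' @param n_aa,n_ab,n_bb Counts of reference-homozygote, heterozygote and
#'   alternate-homozygote genotypes.
#' @param method `"chisq"` (default) or `"exact"`.
#' @return The HWE p-value.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb, method = c("chisq", "exact")) {
  method <- match.arg(method)
  n <- n_aa + n_ab + n_bb
  if (n <= 0) abort("Total genotype count must be positive.")
  n_alt <- n_ab + 2 * n_bb
  if (n_alt == 0 || n_alt == 2 * n) return(1)  # monomorphic
  if (method == "chisq") {
    p <- n_alt / (2 * n)
    expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((c(n_aa, n_ab, n_bb) - expd)^2 / expd)
    return(pchisq(stat, df = 1, lower.tail = FALSE))
  }
  # exact: conditional distribution of the heterozygote count given allele
  # counts; p = sum of probabilities <= that of the observed table
  rare <- min(n_alt, 2 * n - n_alt)
  hets <- seq(rare %% 2, rare, by = 2)
  # conditional pmf: P(h) proportional to 2^h / (n_rr! h! n_cc!) with
  # n_rr = (rare - h)/2 rare homozygotes and n_cc = n - n_rr - h common ones
  n_rr <- (rare - hets) / 2
  n_cc <- n - n_rr - hets
  logp <- hets * log(2) - lgamma(n_rr + 1) - lgamma(hets + 1) - lgamma(n_cc + 1)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(n_ab, hets)] * (1 + 1e-12)])
}

#' Per-sample quality control
#'
#' Computes call rate, heterozygosity (proportion of non-missing genotypes
#' that are heterozygous) with a z-score against the sample mean, and
#' Mendelian error counts, then applies the exclusion rules: call rate below
#' `min_call_rate`, |heterozygosity z| above `max_het_z`, or Mendelian
#' errors above a threshold (the empirical `mendel_quantile` of the current
#' data by default, or the fixed `max_mendel` count when given). A zero
#' heterozygosity standard deviation yields z = 0 for everyone and no
#' heterozygosity exclusions.
#'
#' @param genotypes A [genotype_matrix()].
#' @param ped Pedigree tibble (for Mendelian errors); `NULL` skips that rule.
#' @param min_call_rate Minimum per-sample call rate (default 0.97).
#' @param max_het_z Maximum |heterozygosity z-score| (default 5).
#' @param mendel_quantile Quantile of the empirical Mendelian-error
#'   distribution used as threshold (default 0.99).
#' @param max_mendel Optional fixed Mendelian-error count overriding the
#'   quantile rule; samples with strictly more errors are excluded.
#' @return A tibble `sample_id`, `call_rate`, `heterozygosity`, `het_z`,
#'   `mendel_errors`, `excluded`, `reasons` (list-column).
#' @export
sample_qc <- function(genotypes, ped = NULL, min_call_rate = 0.97,
                      max_het_z = 5, mendel_quantile = 0.99,
                      max_mendel = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  D <- genotypes$dosage
  call_rate <- unname(rowMeans(!is.na(D)))
  het <- ifelse(call_rate > 0, unname(rowMeans(D == 1L, na.rm = TRUE)), NA_real_)
  mu <- mean(het, na.rm = TRUE)
  sdev <- sd(het, na.rm = TRUE)
  het_z <- if (is.na(sdev) || sdev == 0) rep(0, length(het)) else (het - mu) / sdev
  het_z[is.na(het)] <- 0
  if (!is.null(ped)) {
    mend <- count_mendelian_errors(genotypes, ped)$mendel_errors
    mendel_thr <- max_mendel %||% quantile(mend, mendel_quantile, names = FALSE)
  } else {
    mend <- rep(0L, nrow(D))
    mendel_thr <- Inf
  }
  res <- tibble::tibble(
    sample_id = genotypes$sample_ids,
    call_rate = call_rate,
    heterozygosity = het,
    het_z = het_z,
    mendel_errors = mend
  )
  res$reasons <- purrr::pmap(
    list(res$call_rate, res$het_z, res$mendel_errors),
    function(cr, hz, me) {
      r <- character(0)
      if (cr < min_call_rate) r <- c(r, "call_rate")
      if (abs(hz) > max_het_z) r <- c(r, "heterozygosity")
      if (me > mendel_thr) r <- c(r, "mendelian_errors")
      r
    }
  )
  res$excluded <- lengths(res$reasons) > 0
  attr(res, "mendel_threshold") <- mendel_thr
  res
}

#' Per-SNP quality control and filtering
#'
#' Computes minor allele frequency, HWE p-value (on founders when a pedigree
#' is supplied, otherwise on all samples) and call rate per SNP, and passes
#' SNPs meeting all three thresholds. Filtering preserves SNP order and is
#' idempotent.
#'
#' @param genotypes A [genotype_matrix()].
#' @param ped Optional pedigree tibble restricting the HWE test to founders.
#' @param min_maf Minimum minor allele frequency (default 0.01).
#' @param min_hwe_p Minimum HWE p-value (default 1e-6).
#' @param min_call_rate Minimum per-SNP call rate (default 0.95).
#' @param hwe_method Passed to [hwe_test()].
#' @return A list with `snps` (tibble `snp_id`, `maf`, `hwe_p`, `call_rate`,
#'   `pass`) and `genotypes` (the filtered [genotype_matrix()]).
#' @export
snp_filter <- function(genotypes, ped = NULL, min_maf = 0.01,
                       min_hwe_p = 1e-6, min_call_rate = 0.95,
                       hwe_method = "chisq") {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  D <- genotypes$dosage
  call_rate <- unname(colMeans(!is.na(D)))
  af <- unname(colMeans(D, na.rm = TRUE)) / 2
  af[is.nan(af)] <- 0
  maf <- pmin(af, 1 - af)
  hwe_samples <- genotypes$sample_ids
  if (!is.null(ped)) {
    validate_pedigree(ped)
    founders <- ped$individual_id[is.na(ped$father_id) & is.na(ped$mother_id)]
    hwe_samples <- intersect(hwe_samples, founders)
  }
  Dh <- D[hwe_samples, , drop = FALSE]
  hwe_p <- vapply(seq_len(ncol(Dh)), function(j) {
    d <- Dh[, j]
    hwe_test(sum(d == 0L, na.rm = TRUE), sum(d == 1L, na.rm = TRUE),
             sum(d == 2L, na.rm = TRUE), method = hwe_method)
  }, numeric(1))
  report <- tibble::tibble(
    snp_id = genotypes$snps$snp_id,
    maf = maf, hwe_p = hwe_p, call_rate = call_rate,
    pass = maf >= min_maf & hwe_p >= min_hwe_p & call_rate >= min_call_rate
  )
  list(
    snps = report,
    genotypes = subset_genotypes(genotypes, snps = report$snp_id[report$pass])
  )
}
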