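#' Maximal unrelated subset of a pedigree
#'
#' Deterministic greedy selection of individuals with pairwise kinship zero:
#' iteratively pick the remaining individual with the fewest pedigree
#' relatives (ties broken lexicographically by id) and discard its
#' relatives. Spouses without shared ancestry count as unrelated, so both
#' founders of a nuclear family can be selected.
#'
#' @param ped Pedigree tibble.
#' @return Character vector of selected individual ids (sorted).
#' @export
select_unrelated <- function(ped) {
  A <- kinship_from_pedigree(ped)
  ids <- sort(rownames(A))
  A <- A[ids, ids] > 1e-12
  diag(A) <- FALSE
  selected <- character(0)
  remaining <- ids
  while (length(remaining) > 0) {
    deg <- rowSums(A[remaining, remaining, drop = FALSE])
    pick <- remaining[which.min(deg)]  # ids sorted, so ties go lexicographic
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, c(pick, remaining[A[pick, remaining]]))
  }
  sort(selected)
}

#' Principal components of genotype structure on an unrelated set
#'
#' Standardizes each SNP by its allele-frequency mean `2p` and scale
#' `sqrt(2p(1-p))` (missing dosages mean-imputed first), then takes the
#' leading `k` singular directions of the standardized unrelated-sample
#' matrix. SNP weights and the standardization constants are retained so
#' related individuals can be projected onto the same axes. Component signs
#' are fixed by making the largest-magnitude SNP weight positive.
#'
#' @param genotypes A [genotype_matrix()].
#' @param samples Character vector of (unrelated) sample ids to fit on;
#'   defaults to all samples.
#' @param k Number of components.
#' @return An object of class `structure_result`: `snp_weights` (SNPs x k),
#'   `sample_pcs` (fitted scores), `center`, `scale`, `k`, `samples`,
#'   `snp_ids`, `eigenvalues`.
#' @export
fit_pcs <- function(genotypes, samples = NULL, k = 10) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  samples <- samples %||% genotypes$sample_ids
  if (!all(samples %in% genotypes$sample_ids)) {
    abort("`samples` contains ids absent from the genotype matrix.")
  }
  X <- genotypes$dosage[samples, , drop = FALSE]
  storage.mode(X) <- "double"
  cm <- colMeans(X, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas) > 0) X[nas] <- cm[nas[, 2]]
  p <- cm / 2
  sc <- sqrt(2 * p * (1 - p))
  sc[sc == 0] <- Inf  # monomorphic SNPs carry no structure signal
  Xs <- sweep(sweep(X, 2, cm), 2, sc, "/")
  sv <- svd(Xs, nu = min(dim(Xs)), nv = min(dim(Xs)))
  rank <- sum(sv$d > sv$d[1] * 1e-8)
  if (k > rank) {
    abort(sprintf("k = %d exceeds the rank (%d) of the standardized matrix.",
                  k, rank))
  }
  V <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude weight positive
  flip <- vapply(seq_len(k), function(j) {
    sign(V[which.max(abs(V[, j])), j])
  }, numeric(1))
  V <- sweep(V, 2, flip, "*")
  scores <- Xs %*% V
  dimnames(scores) <- list(samples, paste0("PC", seq_len(k)))
  dimnames(V) <- list(genotypes$snps$snp_id, paste0("PC", seq_len(k)))
  structure(
    list(
      snp_weights = V, sample_pcs = scores, center = cm, scale = sc,
      k = k, samples = samples, snp_ids = genotypes$snps$snp_id,
      eigenvalues = (sv$d[seq_len(k)]^2) / (length(samples) - 1)
    ),
    class = "structure_result"
  )
}

#' @export
print.structure_result <- function(x, ...) {
  cat(sprintf("<structure_result> %d PCs fit on %d samples x %d SNPs\n",
              x$k, length(x$samples), length(x$snp_ids)))
  invisible(x)
}

#' Project samples onto fitted structure axes
#'
#' Applies the stored standardization constants and SNP weights, so samples
#' used in the fit reproduce their fitted scores exactly and projection is
#' linear in the genotype vector.
#'
#' @param genotypes A [genotype_matrix()] with the same SNPs, in the same
#'   order, as the fit.
#' @param structure_result A [fit_pcs()] result.
#' @return A tibble `sample_id`, `PC1` ... `PCk`.
#' @export
project_pcs <- function(genotypes, structure_result) {
  stopifnot(inherits(structure_result, "structure_result"))
  if (!identical(genotypes$snps$snp_id, structure_result$snp_ids)) {
    abort("SNP set/order differs from the one the PCs were fit on.")
  }
  X <- genotypes$dosage
  storage.mode(X) <- "double"
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas) > 0) X[nas] <- structure_result$center[nas[, 2]]
  Xs <- sweep(sweep(X, 2, structure_result$center), 2,
              structure_result$scale, "/")
  scores <- Xs %*% structure_result$snp_weights
  tibble::as_tibble(scores) |>
    dplyr::mutate(sample_id = genotypes$sample_ids, .before = 1)
}

#' Screen principal components for trait association
#'
#' Marginal simple regression of every trait on every PC; a PC is selected
#' for downstream covariate adjustment when its association with any trait
#' has p below `alpha`.
#'
#' @param sample_pcs Tibble from [project_pcs()] (`sample_id` + PC columns).
#' @param phenotypes Phenotype tibble with `sample_id` and trait columns.
#' @param traits Character vector of trait column names.
#' @param alpha Selection threshold (default 0.01).
#' @return Integer vector of selected PC indices (possibly empty), with the
#'   full screen table in attribute `"screen"`.
#' @export
pc_trait_screen <- function(sample_pcs, phenotypes, traits, alpha = 0.01) {
  pcs <- grep("^PC\\d+$", names(sample_pcs), value = TRUE)
  dat <- dplyr::inner_join(sample_pcs, phenotypes[, c("sample_id", traits)],
                           by = "sample_id")
  screen <- tidyr::expand_grid(pc = pcs, trait = traits) |>
    dplyr::mutate(p = purrr::map2_dbl(.data$pc, .data$trait, function(pc, tr) {
      fit <- lm(dat[[tr]] ~ dat[[pc]])
      summary(fit)$coefficients[2, 4]
    }))
  sel <- screen |>
    dplyr::group_by(.data$pc) |>
    dplyr::summarise(min_p = min(.data$p), .groups = "drop") |>
    dplyr::filter(.data$min_p < alpha)
  idx <- sort(as.integer(sub("^PC", "", sel$pc)))
  attr(idx, "screen") <- screen
  idx
}
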