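# Small fixtures built in code; everything deterministic given the seeds used
# inside each test.

# genotype matrix from a bare dosage matrix, default metadata
gm_from_dosage <- function(dosage, chrom = "1", maf = NULL) {
  m <- ncol(dosage)
  snps <- tibble::tibble(
    snp_id = sprintf("s%03d", seq_len(m)),
    chrom = rep_len(chrom, m),
    pos = seq_len(m) * 100L,
    ref = "A", alt = "G"
  )
  if (!is.null(maf)) snps$maf <- maf
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("ind%03d", seq_len(nrow(dosage)))
  }
  genotype_matrix(dosage, snps)
}

# pedigree of n unrelated singleton women
singleton_ped <- function(n, prefix = "S") {
  tibble::tibble(
    family_id = sprintf("F%04d", seq_len(n)),
    individual_id = sprintf("%s%04d", prefix, seq_len(n)),
    father_id = NA_character_, mother_id = NA_character_, sex = 2L
  )
}

# one nuclear family: fa, mo + n_children
nuclear_ped <- function(n_children = 2, fam = "F1") {
  tibble::tibble(
    family_id = fam,
    individual_id = c("fa", "mo", paste0("c", seq_len(n_children))),
    father_id = c(NA, NA, rep("fa", n_children)),
    mother_id = c(NA, NA, rep("mo", n_children)),
    sex = c(1L, 2L, rep_len(c(1L, 2L), n_children))
  )
}

# named residual vector from a phenotype tibble column
pheno_vec <- function(ph, col) setNames(ph[[col]], ph$sample_id)

# synthetic association results with prescribed significant index sets
fake_results <- function(m, sig_idx, trait = "t") {
  p <- runif(m, 0.02, 1)
  p[sig_idx] <- runif(length(sig_idx), 1e-8, 0.009)
  tibble::tibble(
    snp_id = sprintf("s%05d", seq_len(m)), trait = trait,
    beta = rnorm(m), se = 1, p = p, n_used = 100L,
    method = "gls", monomorphic = FALSE
  )
}
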