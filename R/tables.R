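#' Worked-example bone-trait tables
#'
#' Small packaged tables from a published genome-wide pleiotropy study of
#' nine osteoporosis-related traits (femoral neck and lumbar spine BMD, heel
#' ultrasound BUA and SOS, and five hip-geometry indices) in ~2000 women
#' from two-generational families, used for worked examples and
#' reconstruction tests:
#'
#' * `bone_assoc_counts()` — per-trait counts of SNPs significant at
#'   alpha = 0.01 out of 433,510 tested, with the smallest p-value.
#' * `bone_shared_matrix()` — 9 x 9 matrix: observed jointly significant
#'   SNP counts below the diagonal, simulation-expected counts above it,
#'   per-trait counts on the diagonal.
#' * `bone_correlation_matrix()` — 9 x 9 matrix: genetic correlations below
#'   the diagonal, environmental correlations above, univariate
#'   heritabilities on the diagonal.
#' * `bone_pair_table()` — the 36 trait pairs in long form, combining both
#'   matrices with the shared percentage, observed/expected ratio, and the
#'   implied phenotypic correlation from [implied_rho_p()].
#'
#' @return A tibble ([bone_assoc_counts()], [bone_pair_table()]) or a named
#'   numeric matrix.
#' @name bone_tables
NULL

example_path <- function(file) {
  system.file("extdata", file, package = "pleioscan", mustWork = TRUE)
}

#' @rdname bone_tables
#' @export
bone_assoc_counts <- function() {
  readr::read_tsv(example_path("table1_assoc_counts.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}

read_square <- function(file) {
  df <- utils::read.delim(example_path(file), row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' @rdname bone_tables
#' @export
bone_shared_matrix <- function() read_square("table2_shared_counts.tsv")

#' @rdname bone_tables
#' @export
bone_correlation_matrix <- function() read_square("table3_correlations.tsv")

#' @rdname bone_tables
#' @export
bone_pair_table <- function() {
  shared <- bone_shared_matrix()
  corr <- bone_correlation_matrix()
  traits <- rownames(shared)
  n <- diag(shared)
  h2 <- diag(corr)
  pairs <- utils::combn(length(traits), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(c_idx) {
    i <- pairs[1, c_idx]; j <- pairs[2, c_idx]
    obs <- shared[j, i]     # below diagonal: observed shared counts
    expd <- shared[i, j]    # above diagonal: simulation-expected counts
    rho_g <- corr[j, i]
    rho_e <- corr[i, j]
    tibble::tibble(
      trait1 = traits[i], trait2 = traits[j],
      n1 = n[i], n2 = n[j], observed = obs, expected = expd,
      union = n[i] + n[j] - obs,
      shared_pct = shared_percentage(n[i], n[j], obs),
      ratio = obs / expd,
      h2_1 = h2[i], h2_2 = h2[j], rho_g = rho_g, rho_e = rho_e,
      rho_p = implied_rho_p(h2[i], h2[j], rho_g, rho_e)
    )
  })
}
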