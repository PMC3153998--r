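#' Additive relationship matrix from a pedigree
#'
#' Computes the expected additive relationship matrix A = 2 * kinship by the
#' recursive tabular method in topological (parents-first) order:
#' `A[i,i] = 1 + A[fa,mo]/2` and `A[i,j] = (A[fa,j] + A[mo,j])/2` for
#' earlier individuals `j`, with founders mutually unrelated and an unknown
#' parent contributing nothing. For non-inbred pedigrees the diagonal is 1;
#' parent-offspring and full-sibling pairs are 0.5, half-siblings and
#' grandparent-grandchild pairs 0.25.
#'
#' @param ped Pedigree tibble.
#' @return A symmetric numeric matrix with sample ids as dimnames.
#' @export
kinship_from_pedigree <- function(ped) {
  validate_pedigree(ped)
  topo <- ped_topo_order(ped)
  n <- length(topo)
  fa <- match(setNames(ped$father_id, ped$individual_id)[topo], topo)
  mo <- match(setNames(ped$mother_id, ped$individual_id)[topo], topo)
  A <- matrix(0, n, n, dimnames = list(topo, topo))
  for (i in seq_len(n)) {
    f <- fa[i]; m <- mo[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      rel <- 0.5 * ((if (is.na(f)) 0 else A[f, j]) +
                      (if (is.na(m)) 0 else A[m, j]))
      A[i, j] <- rel
      A[j, i] <- rel
    }
    A[i, i] <- 1 + if (!is.na(f) && !is.na(m)) 0.5 * A[f, m] else 0
  }
  # return in the pedigree's own order
  A[ped$individual_id, ped$individual_id]
}
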