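#' Genotype matrix container
#'
#' Bundles an additive-dosage matrix (samples x SNPs, counting alternate
#' alleles, `NA` = missing) with its SNP metadata. This is the genotype
#' currency of the whole pipeline: readers produce it, QC filters it, the
#' association scan consumes it.
#'
#' @param dosage Integer matrix, samples in rows, SNPs in columns; values in
#'   `{0, 1, 2, NA}`.
#' @param snps Data frame with one row per SNP: `snp_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`, and optionally `maf` (the founder allele
#'   frequency used by the simulator).
#' @param sample_ids Character vector of sample identifiers, one per row of
#'   `dosage`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, snps, sample_ids = rownames(dosage)) {
  snps <- tibble::as_tibble(snps)
  stopifnot(is.matrix(dosage))
  if (is.null(sample_ids)) {
    abort("`sample_ids` must be supplied when `dosage` has no rownames.")
  }
  if (length(sample_ids) != nrow(dosage)) {
    abort("`sample_ids` length does not match the dosage rows.")
  }
  if (nrow(snps) != ncol(dosage)) {
    abort("SNP metadata rows do not match the dosage columns.")
  }
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(snps))
  if (length(miss) > 0) {
    abort(paste0("SNP metadata is missing column(s): ", toString(miss)))
  }
  if (anyDuplicated(snps$snp_id)) abort("Duplicate snp_id in SNP metadata.")
  if (anyDuplicated(sample_ids)) abort("Duplicate sample ids.")
  if (any(snps$pos <= 0)) abort("SNP positions must be positive (1-based).")
  if (any(snps$ref == snps$alt)) abort("ref and alt alleles must differ.")
  bad <- dosage[!is.na(dosage) & !(dosage %in% 0:2)]
  if (length(bad) > 0) abort("Dosages must be 0, 1, 2 or NA.")
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(sample_ids, snps$snp_id)
  structure(
    list(dosage = dosage, snps = snps, sample_ids = sample_ids),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d SNPs (%.1f%% missing)\n",
    length(x$sample_ids), nrow(x$snps),
    100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param gm A [genotype_matrix()].
#' @param samples Character vector of sample ids to keep (default all).
#' @param snps Character vector of snp ids to keep (default all).
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, samples = NULL, snps = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  samples <- samples %||% gm$sample_ids
  snps <- snps %||% gm$snps$snp_id
  if (!all(samples %in% gm$sample_ids)) abort("Unknown sample id in `samples`.")
  if (!all(snps %in% gm$snps$snp_id)) abort("Unknown snp id in `snps`.")
  keep <- match(snps, gm$snps$snp_id)
  genotype_matrix(
    gm$dosage[samples, snps, drop = FALSE],
    gm$snps[keep, , drop = FALSE],
    samples
  )
}

#' Read a VCF file into a genotype matrix
#'
#' Parses the GT field of a VCF v4.x file into additive alternate-allele
#' dosages. `./.` (or `.|.`) becomes missing. Multi-allelic records are
#' rejected by default because the downstream models are diallelic.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @param multiallelic `"error"` (default) or `"drop"` multi-allelic records.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, multiallelic = c("error", "drop")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  if (nrow(fix) == 0) abort("VCF contains no variant records.")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    if (multiallelic == "error") {
      abort(paste0(
        "Multi-allelic record(s) at: ",
        toString(head(fix$ID[multi], 5)),
        "; re-run with multiallelic = \"drop\" or split them upstream."
      ))
    }
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) abort("VCF has no GT field.")
  alleles <- gsub("\\|", "/", gt)
  ok <- is.na(alleles) | alleles %in% c("0/0", "0/1", "1/0", "1/1", "./.")
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Non-diploid or unexpected GT '%s' at record %d (%s), sample %s.",
      alleles[!ok][1], bad[1], rownames(gt)[bad[1]], colnames(gt)[bad[2]]
    ))
  }
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L, "./." = NA_integer_)
  dos <- matrix(code[alleles], nrow = nrow(gt), ncol = ncol(gt))
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  snps <- tibble::tibble(
    snp_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT
  )
  genotype_matrix(t(dos), snps, colnames(gt))
}

#' Write a genotype matrix as a plain-text VCF v4.2 file
#'
#' Inverse of [read_vcf()]: dosage 0/1/2 becomes GT `0/0`, `0/1`, `1/1`;
#' missing becomes `./.`. Round-tripping preserves dosages and SNP metadata.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(gm$snps), ncol = length(gm$sample_ids))
  d <- t(gm$dosage)
  gt[!is.na(d)] <- gt_code[d[!is.na(d)] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t")
  )
  body <- paste(
    gm$snps$chrom, gm$snps$pos, gm$snps$snp_id, gm$snps$ref, gm$snps$alt,
    ".", ".", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a 6-column FAM-style pedigree file
#'
#' Whitespace-delimited columns: family id, individual id, father id, mother
#' id, sex (1 = male, 2 = female, 0 = unknown), and an ignored phenotype
#' column. `"0"` in a parent column means unknown/founder. Duplicate
#' individual ids and cyclic parentage are rejected.
#'
#' @param path Path to the pedigree file.
#' @return A tibble with columns `family_id`, `individual_id`, `father_id`,
#'   `mother_id` (NA = founder) and `sex`.
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(
    path, header = FALSE, colClasses = "character",
    col.names = c("family_id", "individual_id", "father_id", "mother_id",
                  "sex", "phenotype")
  )
  ped <- tibble::tibble(
    family_id = raw$family_id,
    individual_id = raw$individual_id,
    father_id = dplyr::na_if(raw$father_id, "0"),
    mother_id = dplyr::na_if(raw$mother_id, "0"),
    sex = as.integer(raw$sex)
  )
  validate_pedigree(ped)
  ped
}

#' Write a pedigree tibble as a 6-column FAM file
#'
#' @param ped Pedigree tibble as returned by [read_pedigree()] or
#'   [simulate_pedigree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  validate_pedigree(ped)
  out <- data.frame(
    ped$family_id, ped$individual_id,
    ifelse(is.na(ped$father_id), "0", ped$father_id),
    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    ped$sex, "-9"
  )
  utils::write.table(out, path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate pedigree invariants
#'
#' Checks unique individual ids, that every named parent exists in the
#' pedigree, valid sex codes, and acyclicity (no individual is its own
#' ancestor). Called by all pedigree consumers; exported so synthetic or
#' hand-built pedigrees can be checked directly.
#'
#' @param ped Pedigree tibble (`family_id`, `individual_id`, `father_id`,
#'   `mother_id`, `sex`).
#' @return `ped`, invisibly.
#' @export
validate_pedigree <- function(ped) {
  need <- c("family_id", "individual_id", "father_id", "mother_id", "sex")
  miss <- setdiff(need, names(ped))
  if (length(miss) > 0) {
    abort(paste0("Pedigree is missing column(s): ", toString(miss)))
  }
  dup <- ped$individual_id[duplicated(ped$individual_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate individual id(s): ", toString(unique(dup))))
  }
  parents <- c(ped$father_id, ped$mother_id)
  unknown <- setdiff(parents[!is.na(parents)], ped$individual_id)
  if (length(unknown) > 0) {
    abort(paste0("Parent id(s) not present in pedigree: ", toString(unknown)))
  }
  if (!all(ped$sex %in% c(0L, 1L, 2L))) {
    abort("Sex must be coded 1 (male), 2 (female) or 0 (unknown).")
  }
  ped_topo_order(ped)  # errors on a cycle, naming its members
  invisible(ped)
}

#' Topological order of a pedigree (parents before children)
#'
#' @param ped Pedigree tibble.
#' @return Character vector of individual ids, every parent preceding its
#'   children. Errors on cyclic parentage.
#' @keywords internal
ped_topo_order <- function(ped) {
  ids <- ped$individual_id
  fa <- match(ped$father_id, ids)
  mo <- match(ped$mother_id, ids)
  placed <- logical(length(ids))
  order_out <- integer(0)
  fa_placed <- function() is.na(fa) | placed[ifelse(is.na(fa), 1L, fa)]
  mo_placed <- function() is.na(mo) | placed[ifelse(is.na(mo), 1L, mo)]
  repeat {
    ready <- !placed & fa_placed() & mo_placed()
    if (!any(ready)) break
    order_out <- c(order_out, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed)) {
    abort(paste0(
      "Cyclic parentage involving: ", toString(ids[!placed]),
      " (an individual is its own ancestor)."
    ))
  }
  ids[order_out]
}

#' Write a tibble as a canonical TSV
#'
#' The pipeline's on-disk dialect for intermediate tables: tab-separated,
#' header row, missing values coded `NA`, doubles printed with 6 significant
#' digits. Output is bit-identical across runs for identical input.
#'
#' @param records Data frame to write.
#' @param path Output path.
#' @param schema Character vector naming the ordered columns to write.
#'   Defaults to the columns of `records`.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, schema = names(records)) {
  miss <- setdiff(schema, names(records))
  if (length(miss) > 0) {
    abort(paste0("Record set is missing schema column(s): ", toString(miss)))
  }
  out <- records[, schema, drop = FALSE]
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::where(is.double),
    ~ ifelse(is.na(.x), NA_character_,
             format(signif(.x, 6), scientific = FALSE, trim = TRUE,
                    drop0trailing = TRUE))
  ))
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path Path to a TSV file with a header row and `NA` missing codes.
#' @return A tibble.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, na = "NA", show_col_types = FALSE, progress = FALSE)
}
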