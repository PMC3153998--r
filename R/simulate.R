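#' Trait model for the phenotype simulator
#'
#' Describes the multivariate quantitative-trait architecture the variance
#' decomposition assumes: per-trait narrow-sense heritabilities, a genetic
#' correlation matrix and an environmental correlation matrix, optionally a
#' set of causal SNPs with per-trait additive effects. The implied
#' phenotypic correlation of every pair is
#' `rho_G * sqrt(h2_i h2_j) + rho_E * sqrt((1 - h2_i)(1 - h2_j))`.
#'
#' @param h2 Numeric vector of heritabilities in `[0, 1]`, one per trait.
#' @param rho_g,rho_e Genetic / environmental correlations: a scalar (for two
#'   traits) or a symmetric correlation matrix with unit diagonal.
#' @param trait_names Optional character vector; defaults to `trait1 ...`.
#' @param causal Optional data frame of causal SNPs with columns `snp_id`,
#'   `trait` (name) and `beta` (effect per alternate allele, on the
#'   standardized-trait scale).
#' @param total_var Total phenotypic variance per trait (scalar or vector,
#'   default 1).
#' @return An object of class `trait_model`.
#' @export
trait_model <- function(h2, rho_g = 0, rho_e = 0, trait_names = NULL,
                        causal = NULL, total_var = 1) {
  k <- length(h2)
  if (k < 1) abort("At least one trait is required.")
  if (any(h2 < 0 | h2 > 1)) abort("Heritabilities must lie in [0, 1].")
  as_corr <- function(r, what) {
    if (is.matrix(r)) {
      R <- r
    } else if (length(r) == 1 && k == 2) {
      R <- matrix(c(1, r, r, 1), 2, 2)
    } else if (length(r) == 1 && k == 1) {
      R <- matrix(1, 1, 1)
    } else {
      abort(paste0("`", what, "` must be a scalar (2 traits) or a k x k matrix."))
    }
    if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-12)) {
      abort(paste0("`", what, "` must be symmetric with unit diagonal."))
    }
    if (any(R < -1 - 1e-12 | R > 1 + 1e-12)) {
      abort(paste0("`", what, "` entries must lie in [-1, 1]."))
    }
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      abort(paste0("`", what, "` is not positive semidefinite."))
    }
    R
  }
  R_G <- as_corr(rho_g, "rho_g")
  R_E <- as_corr(rho_e, "rho_e")
  total_var <- rep_len(total_var, k)
  if (any(total_var <= 0)) abort("Total variances must be positive.")
  trait_names <- trait_names %||% paste0("trait", seq_len(k))
  if (length(trait_names) != k || anyDuplicated(trait_names)) {
    abort("`trait_names` must be k unique names.")
  }
  # implied phenotypic covariance must itself be a valid covariance
  sg <- sqrt(total_var * h2)
  se <- sqrt(total_var * (1 - h2))
  Sigma_P <- outer(sg, sg) * R_G + outer(se, se) * R_E
  if (min(eigen(Sigma_P, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    abort("Implied phenotypic covariance is not positive semidefinite.")
  }
  if (!is.null(causal)) {
    causal <- tibble::as_tibble(causal)
    need <- c("snp_id", "trait", "beta")
    if (!all(need %in% names(causal))) {
      abort("`causal` needs columns snp_id, trait, beta.")
    }
    if (!all(causal$trait %in% trait_names)) {
      abort("Causal effect names a trait absent from `trait_names`.")
    }
  }
  structure(
    list(
      n_traits = k, h2 = h2, R_G = R_G, R_E = R_E,
      Sigma_G = outer(sg, sg) * R_G, Sigma_E = outer(se, se) * R_E,
      total_var = total_var, trait_names = trait_names, causal = causal
    ),
    class = "trait_model"
  )
}

#' Simulation configuration
#'
#' Study-design knobs for the synthetic family sample. Defaults emulate a
#' two-generational extended-family study: family sizes supported on 2..29
#' with a geometric preference for small (mostly nuclear) families, common
#' diallelic SNPs, and mild block LD among founder haplotypes.
#'
#' @param n_families Number of families.
#' @param family_sizes Integer support of the family-size distribution
#'   (subset of 2..29).
#' @param family_size_probs Sampling weights over `family_sizes`; default
#'   decays geometrically (`exp(-size/4)`), giving mostly nuclear families.
#' @param n_snps Number of SNPs.
#' @param maf_range Founder minor-allele-frequency range (uniform draw);
#'   must stay at or above 0.01.
#' @param ld_block_size SNPs per LD block among founder haplotypes
#'   (1 = independent SNPs).
#' @param ld_flip_prob Within a block, the probability that an adjacent
#'   founder allele is flipped rather than copied.
#' @param missing_rate Per-cell genotype missingness rate.
#' @param mendel_error_rate Per-cell rate of injected transmission-impossible
#'   genotype errors in non-founders.
#' @param p_spouse Probability that a new family member is an in-married
#'   spouse (enabling grandchildren) rather than a child.
#' @param seed Mandatory integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_families = 300,
                       family_sizes = 2:29,
                       family_size_probs = exp(-family_sizes / 4),
                       n_snps = 1000,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 5,
                       ld_flip_prob = 0.1,
                       missing_rate = 0,
                       mendel_error_rate = 0,
                       p_spouse = 0.25,
                       seed) {
  if (missing(seed)) abort("`seed` is mandatory in sim_config().")
  if (n_families < 1) abort("`n_families` must be at least 1.")
  if (any(family_sizes < 2 | family_sizes > 29)) {
    abort("Family sizes must lie in 2..29.")
  }
  rates <- c(ld_flip_prob, missing_rate, mendel_error_rate, p_spouse)
  if (any(rates < 0 | rates > 1)) abort("All rates must lie in [0, 1].")
  if (min(maf_range) < 0.01 || max(maf_range) > 0.5) {
    abort("`maf_range` must lie within [0.01, 0.5].")
  }
  if (ld_block_size < 1) abort("`ld_block_size` must be >= 1.")
  structure(
    list(
      n_families = n_families, family_sizes = as.integer(family_sizes),
      family_size_probs = family_size_probs / sum(family_size_probs),
      n_snps = as.integer(n_snps), maf_range = maf_range,
      ld_block_size = as.integer(ld_block_size), ld_flip_prob = ld_flip_prob,
      missing_rate = missing_rate, mendel_error_rate = mendel_error_rate,
      p_spouse = p_spouse, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a two-generational family sample
#'
#' Each family starts from a founder couple; further members are children of
#' the couple or, with probability `p_spouse`, in-married spouses of existing
#' children, whose own children are grandchildren of the founders (at most
#' two matings deep).
#'
#' @param config A [sim_config()].
#' @param sizes Optional integer vector of family sizes overriding the
#'   configured size distribution (length `n_families`).
#' @return A pedigree tibble (`family_id`, `individual_id`, `father_id`,
#'   `mother_id`, `sex`).
#' @export
simulate_pedigree <- function(config, sizes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(sizes)) {
    sizes <- config$family_sizes[sample.int(length(config$family_sizes),
                                            config$n_families, replace = TRUE,
                                            prob = config$family_size_probs)]
  }
  if (length(sizes) != config$n_families) {
    abort("`sizes` must have one entry per family.")
  }
  if (any(sizes < 2)) abort("Requested family size < 2.")
  fams <- purrr::map(seq_len(config$n_families), function(f) {
    fam_id <- sprintf("F%04d", f)
    s <- sizes[f]
    id <- function(i) sprintf("%s_I%02d", fam_id, i)
    rec <- tibble::tibble(
      individual_id = c(id(1), id(2)),
      father_id = NA_character_, mother_id = NA_character_,
      sex = c(1L, 2L)
    )
    couples <- list(c(id(1), id(2)))          # (father, mother)
    eligible <- character(0)                  # unmarried founder-couple children
    count <- 2L
    while (count < s) {
      count <- count + 1L
      new_id <- id(count)
      marry <- length(eligible) > 0 && count < s &&
        runif(1) < config$p_spouse
      if (marry) {
        child <- sample(eligible, 1)
        eligible <- setdiff(eligible, child)
        child_sex <- rec$sex[rec$individual_id == child]
        rec <- tibble::add_row(rec, individual_id = new_id,
                               father_id = NA_character_,
                               mother_id = NA_character_,
                               sex = if (child_sex == 1L) 2L else 1L)
        couples <- c(couples, list(
          if (child_sex == 1L) c(child, new_id) else c(new_id, child)
        ))
      } else {
        cpl <- couples[[sample.int(length(couples), 1)]]
        rec <- tibble::add_row(rec, individual_id = new_id,
                               father_id = cpl[1], mother_id = cpl[2],
                               sex = sample(1:2, 1))
        if (identical(cpl, couples[[1]])) eligible <- c(eligible, new_id)
      }
    }
    tibble::tibble(family_id = fam_id, rec)
  })
  ped <- dplyr::bind_rows(fams)
  validate_pedigree(ped)
  ped
}

#' Simulate genotypes by gene dropping through a pedigree
#'
#' Founder haplotypes are drawn at Hardy-Weinberg proportions at each SNP's
#' configured allele frequency; within an LD block each adjacent founder
#' allele is copied from the previous SNP on the same haplotype with a
#' per-SNP flip probability. Offspring receive one allele per parent by fair
#' Mendelian transmission (the transmitted parental haplotype is redrawn at
#' every block boundary). Missingness and transmission-impossible Mendelian
#' errors are injected afterwards at the configured rates; injected error
#' positions are recorded in the `injected_mendel` attribute.
#'
#' @param ped Pedigree tibble.
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed + 1`.
#' @return A [genotype_matrix()] whose SNP metadata carries the marginal
#'   founder allele frequency in a `maf` column.
#' @export
simulate_genotypes <- function(ped, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  validate_pedigree(ped)
  set.seed(seed)
  m <- config$n_snps
  ids <- ped$individual_id
  n <- length(ids)
  block <- rep(seq_len(ceiling(m / config$ld_block_size)),
               each = config$ld_block_size)[seq_len(m)]
  block_start <- !duplicated(block)
  p0 <- runif(m, config$maf_range[1], config$maf_range[2])
  # marginal allele frequency after copy-with-flip within a block
  p <- p0
  f <- config$ld_flip_prob
  for (j in seq_len(m)[-1]) {
    if (!block_start[j]) p[j] <- p[j - 1] * (1 - f) + (1 - p[j - 1]) * f
  }

  topo <- ped_topo_order(ped)
  fa <- setNames(ped$father_id, ped$individual_id)
  mo <- setNames(ped$mother_id, ped$individual_id)
  H1 <- matrix(0L, n, m, dimnames = list(ids, NULL))
  H2 <- H1
  founders <- ids[is.na(fa[ids]) & is.na(mo[ids])]
  nf <- length(founders)
  for (H in 1:2) {
    hap <- matrix(0L, nf, m)
    hap[, 1] <- rbinom(nf, 1L, p0[1])
    for (j in seq_len(m)[-1]) {
      if (block_start[j]) {
        hap[, j] <- rbinom(nf, 1L, p0[j])
      } else {
        hap[, j] <- as.integer(xor(hap[, j - 1], rbinom(nf, 1L, f)))
      }
    }
    if (H == 1) H1[founders, ] <- hap else H2[founders, ] <- hap
  }
  n_blocks <- max(block)
  for (i in topo) {
    if (i %in% founders) next
    pick <- function(parent) {
      choice <- rbinom(n_blocks, 1L, 0.5)[block] == 1L
      ifelse(choice, H1[parent, ], H2[parent, ])
    }
    # one known parent contributes a population allele for the unknown side
    H1[i, ] <- if (is.na(fa[i])) rbinom(m, 1L, p) else pick(fa[i])
    H2[i, ] <- if (is.na(mo[i])) rbinom(m, 1L, p) else pick(mo[i])
  }
  dosage <- H1 + H2

  injected <- tibble::tibble(individual_id = character(0), snp = integer(0))
  if (config$mendel_error_rate > 0) {
    nonf <- setdiff(ids, founders)
    cells <- which(matrix(runif(length(nonf) * m), length(nonf), m) <
                     config$mendel_error_rate, arr.ind = TRUE)
    if (nrow(cells) > 0) {
      for (r in seq_len(nrow(cells))) {
        child <- nonf[cells[r, 1]]
        j <- cells[r, 2]
        poss <- mendel_possible(dosage[fa[child], j], dosage[mo[child], j])
        imposs <- setdiff(0:2, poss)
        if (length(imposs) > 0) {
          dosage[child, j] <- imposs[sample.int(length(imposs), 1)]
          injected <- tibble::add_row(injected, individual_id = child, snp = j)
        }
      }
    }
  }
  if (config$missing_rate > 0) {
    drop <- matrix(runif(n * m) < config$missing_rate, n, m)
    dosage[drop] <- NA_integer_
  }
  snps <- tibble::tibble(
    snp_id = sprintf("snp%05d", seq_len(m)),
    chrom = as.character(block %% 22 + 1), # spread blocks over autosomes
    pos = as.integer(seq_len(m) * 1000L),
    ref = "A", alt = "G", maf = p
  )
  gm <- genotype_matrix(dosage, snps, ids)
  attr(gm, "injected_mendel") <- injected
  gm
}

# dosages a child can have given parental dosages (NA parent = unconstrained)
mendel_possible <- function(d_fa, d_mo) {
  gamete <- function(d) {
    if (is.na(d)) c(0L, 1L) else switch(d + 1L, 0L, c(0L, 1L), 1L)
  }
  sort(unique(outer(gamete(d_fa), gamete(d_mo), `+`)))
}

#' Simulate multivariate phenotypes on a pedigree
#'
#' Realizes the additive polygenic decomposition exactly: founder genetic
#' values are multivariate normal with covariance `Sigma_G`, a non-founder's
#' genetic value is the parental midpoint plus segregation noise
#' `MVN(0, Sigma_G / 2)` (halved for non-inbred parents), environmental
#' deviations are independent `MVN(0, Sigma_E)`, and configured causal SNPs
#' add `beta * (dosage - 2 * maf)` so trait means stay at zero. Optional
#' covariates (age, age squared, body-mass index, estrogenic status) enter
#' with fixed linear effects, and families are split into two cohorts.
#'
#' @param ped Pedigree tibble.
#' @param genotypes A [genotype_matrix()] (may be `NULL` when the model has
#'   no causal SNPs).
#' @param model A [trait_model()].
#' @param seed Integer seed.
#' @param covariates Add the default covariate block (default `TRUE`).
#' @return A phenotype tibble: `sample_id`, `cohort`, one column per trait,
#'   and covariate columns when requested.
#' @export
simulate_phenotypes <- function(ped, genotypes = NULL, model, seed,
                                covariates = TRUE) {
  stopifnot(inherits(model, "trait_model"))
  validate_pedigree(ped)
  set.seed(seed)
  ids <- ped$individual_id
  n <- length(ids)
  k <- model$n_traits
  topo <- ped_topo_order(ped)
  fa <- setNames(ped$father_id, ids)
  mo <- setNames(ped$mother_id, ids)

  chol_psd <- function(S) {
    # pivot-free chol with a ridge for exactly singular (boundary) models
    ev <- eigen(S, symmetric = TRUE)
    ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(S)) %*% t(ev$vectors)
  }
  L_G <- chol_psd(model$Sigma_G)
  L_seg <- L_G / sqrt(2)
  L_E <- chol_psd(model$Sigma_E)

  g <- matrix(0, n, k, dimnames = list(ids, NULL))
  noise <- matrix(rnorm(n * k), n, k, dimnames = list(ids, NULL))
  for (i in topo) {
    both <- !is.na(fa[i]) && !is.na(mo[i])
    one <- xor(is.na(fa[i]), is.na(mo[i]))
    if (both) {
      g[i, ] <- 0.5 * (g[fa[i], ] + g[mo[i], ]) + drop(noise[i, ] %*% L_seg)
    } else if (one) {
      parent <- if (is.na(fa[i])) mo[i] else fa[i]
      g[i, ] <- 0.5 * g[parent, ] + drop(noise[i, ] %*% (L_G * sqrt(3) / 2))
    } else {
      g[i, ] <- drop(noise[i, ] %*% L_G)
    }
  }
  e <- matrix(rnorm(n * k), n, k) %*% L_E
  y <- g + e

  if (!is.null(model$causal) && nrow(model$causal) > 0) {
    if (is.null(genotypes)) abort("Causal SNPs configured but no genotypes given.")
    if (!all(model$causal$snp_id %in% genotypes$snps$snp_id)) {
      abort("Causal snp_id absent from the genotype matrix.")
    }
    maf <- setNames(
      genotypes$snps$maf %||% (colMeans(genotypes$dosage, na.rm = TRUE) / 2),
      genotypes$snps$snp_id
    )
    for (r in seq_len(nrow(model$causal))) {
      cz <- model$causal[r, ]
      x <- genotypes$dosage[ids, cz$snp_id]
      x[is.na(x)] <- 2 * maf[cz$snp_id]
      t_idx <- match(cz$trait, model$trait_names)
      y[, t_idx] <- y[, t_idx] + cz$beta * (x - 2 * maf[cz$snp_id])
    }
  }

  out <- tibble::tibble(sample_id = ids)
  fam_idx <- match(ped$family_id, unique(ped$family_id))
  out$cohort <- ifelse(fam_idx %% 2 == 0, "offspring", "original")
  if (covariates) {
    age <- runif(n, 30, 80)
    bmi <- rnorm(n, 26, 4)
    estrogenic <- rbinom(n, 1, 0.45)
    # fixed covariate effects, identical across traits
    shift <- 0.02 * (age - 55) - 5e-4 * (age - 55)^2 + 0.05 * (bmi - 26) -
      0.3 * estrogenic
    y <- y + shift
    out$age <- age
    out$age2 <- age^2
    out$bmi <- bmi
    out$estrogenic <- estrogenic
  }
  colnames(y) <- model$trait_names
  dplyr::bind_cols(out, tibble::as_tibble(y))
}
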