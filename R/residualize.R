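#' Inverse-normal rank transform
#'
#' Maps values to normal scores `qnorm((r - 3/8) / (n + 1/4))` using Blom
#' offsets, with average ranks for ties. Missing values stay missing and do
#' not consume ranks. Scores are invariant under any strictly monotone
#' transform of the input.
#'
#' @param values Numeric vector with at least two distinct non-missing
#'   values.
#' @return Numeric vector of normal scores, same length as `values`.
#' @export
rank_normalize <- function(values) {
  obs <- !is.na(values)
  x <- values[obs]
  if (length(unique(x)) < 2) {
    abort("Need at least two distinct values to rank-normalize.")
  }
  n <- length(x)
  scores <- qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))
  out <- rep(NA_real_, length(values))
  out[obs] <- scores
  out
}

#' Covariate-adjusted residual phenotypes
#'
#' Within each cohort, ordinary least squares of the trait on the covariates
#' over complete cases; residuals are either variance-standardized
#' (`transform = "normalized"`) or replaced by inverse-normal scores of
#' their ranks (`transform = "rank"`, Blom offsets) within the cohort, then
#' cohorts are pooled. Collinear covariates and cohorts with fewer than
#' `length(covariates) + 2` complete cases are errors.
#'
#' @param phenotypes Phenotype tibble with `sample_id`, the trait, the
#'   covariates, and optionally a cohort column.
#' @param trait Name of the trait column.
#' @param covariates Character vector of covariate column names (may be
#'   empty: residuals are then the centered trait).
#' @param transform `"normalized"` (default) or `"rank"`.
#' @param cohort Name of the cohort column, or `NULL` for a single cohort.
#' @return A tibble `sample_id`, `cohort`, `residual` (missing where the
#'   trait or a covariate was missing).
#' @export
adjust_phenotype <- function(phenotypes, trait, covariates = character(0),
                             transform = c("normalized", "rank"),
                             cohort = NULL) {
  transform <- match.arg(transform)
  miss <- setdiff(c(trait, covariates, cohort), names(phenotypes))
  if (length(miss) > 0) {
    abort(paste0("Column(s) absent from phenotypes: ", toString(miss)))
  }
  dat <- phenotypes
  dat$..cohort <- if (is.null(cohort)) "all" else dat[[cohort]]
  out <- dat |>
    dplyr::group_by(.data$..cohort) |>
    dplyr::group_map(function(g, key) {
      cc <- complete.cases(g[, c(trait, covariates)])
      if (sum(cc) < length(covariates) + 2) {
        abort(sprintf("Cohort %s has only %d complete cases (need >= %d).",
                      key$..cohort, sum(cc), length(covariates) + 2))
      }
      if (length(covariates) > 0) {
        X <- as.matrix(g[cc, covariates, drop = FALSE])
        qrX <- qr(cbind(1, X))
        if (qrX$rank < ncol(X) + 1) {
          drop_idx <- qrX$pivot[seq(qrX$rank + 1, ncol(X) + 1)] - 1
          abort(paste0("Collinear covariate(s): ",
                       toString(covariates[drop_idx[drop_idx > 0]])))
        }
        fit <- lm(g[[trait]][cc] ~ X)
        res <- unname(resid(fit))
      } else {
        res <- g[[trait]][cc] - mean(g[[trait]][cc])
      }
      res <- switch(transform,
        normalized = {
          # a perfectly explained trait leaves numerically-zero residuals;
          # do not blow them up to unit variance
          s <- sd(res)
          if (s > 1e-8 * max(sd(g[[trait]][cc]), 1)) res / s else res
        },
        rank = rank_normalize(res)
      )
      full <- rep(NA_real_, nrow(g))
      full[cc] <- res
      tibble::tibble(sample_id = g$sample_id, cohort = key$..cohort,
                     residual = full)
    }) |>
    dplyr::bind_rows()
  out
}

#' Residualize several traits at once
#'
#' Applies [adjust_phenotype()] to each trait and returns a wide residual
#' table suitable for [fit_all_pairs()] and [gwas_lmm()].
#'
#' @inheritParams adjust_phenotype
#' @param traits Character vector of trait columns.
#' @return A tibble `sample_id`, `cohort`, one residual column per trait.
#' @export
residualize_traits <- function(phenotypes, traits, covariates = character(0),
                               transform = "normalized", cohort = NULL) {
  res <- purrr::map(traits, function(tr) {
    adjust_phenotype(phenotypes, tr, covariates, transform, cohort) |>
      dplyr::rename(!!tr := "residual")
  })
  purrr::reduce(res, dplyr::left_join, by = c("sample_id", "cohort"))
}
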