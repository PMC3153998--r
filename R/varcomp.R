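#' Implied phenotypic correlation from the variance decomposition
#'
#' For two traits with heritabilities `h2_1`, `h2_2`, genetic correlation
#' `rho_g` and environmental correlation `rho_e`, the phenotypic correlation
#' decomposes as
#' `rho_p = rho_g * sqrt(h2_1 * h2_2) + rho_e * sqrt((1 - h2_1) * (1 - h2_2))`.
#'
#' @param h2_1,h2_2 Heritabilities in `[0, 1]`.
#' @param rho_g,rho_e Genetic and environmental correlations in `[-1, 1]`.
#' @return The implied phenotypic correlation.
#' @export
implied_rho_p <- function(h2_1, h2_2, rho_g, rho_e) {
  if (any(c(h2_1, h2_2) < 0 | c(h2_1, h2_2) > 1)) {
    abort("Heritabilities must lie in [0, 1].")
  }
  if (any(abs(c(rho_g, rho_e)) > 1)) {
    abort("Correlations must lie in [-1, 1].")
  }
  rho_g * sqrt(h2_1 * h2_2) + rho_e * sqrt((1 - h2_1) * (1 - h2_2))
}

# Align a residual vector (named vector or tibble sample_id/value) with a
# kinship matrix; returns list(y, ids).
align_residuals <- function(residuals, kinship, min_n = 30) {
  if (is.data.frame(residuals)) {
    v <- setNames(residuals[[setdiff(names(residuals), "sample_id")[1]]],
                  residuals$sample_id)
  } else {
    v <- residuals
  }
  if (is.null(names(v))) abort("Residuals must carry sample ids.")
  ids <- intersect(names(v)[!is.na(v)], rownames(kinship))
  if (length(ids) < min_n) {
    abort(sprintf("Only %d samples overlap the kinship matrix (need >= %d).",
                  length(ids), min_n))
  }
  list(y = unname(v[ids]), ids = ids)
}

# Eigendecomposition of the relationship matrix restricted to `ids`,
# plus the rotated intercept. Shared by the polygenic fits and the GWAS.
kinship_eigen <- function(kinship, ids) {
  A <- kinship[ids, ids]
  ev <- eigen(A, symmetric = TRUE)
  if (min(ev$values) < -1e-6) abort("Kinship matrix is not positive semidefinite.")
  list(d = pmax(ev$values, 0), U = ev$vectors,
       one = drop(crossprod(ev$vectors, rep(1, length(ids)))), ids = ids)
}

# reuse a cached decomposition when it covers exactly the requested ids
get_decomp <- function(decomp, kinship, ids) {
  if (!is.null(decomp) && identical(decomp$ids, ids)) return(decomp)
  kinship_eigen(kinship, ids)
}

# Profile log-likelihood of the univariate polygenic model at a given h2:
# y ~ N(mu, s2 * (h2 * A + (1 - h2) * I)); mu and s2 profiled out.
uni_profile_loglik <- function(h2, ystar, one, d) {
  w <- h2 * d + (1 - h2)
  if (any(w <= 0)) return(-Inf)
  mu <- sum(one * ystar / w) / sum(one^2 / w)
  r <- ystar - mu * one
  n <- length(ystar)
  s2 <- sum(r^2 / w) / n
  -0.5 * (n * log(2 * pi) + n * log(s2) + sum(log(w)) + n)
}

#' Univariate polygenic model by maximum likelihood
#'
#' Fits `y ~ N(mu, sigma2_g * A + sigma2_e * I)` where `A` is the pedigree
#' additive-relationship matrix, via a one-time eigendecomposition of `A`
#' and a 1-D likelihood maximization over the heritability
#' `h2 = sigma2_g / (sigma2_g + sigma2_e)` on `[0, 1]`. Boundary estimates
#' are reported as such, not clipped away.
#'
#' @param residuals Named numeric vector of (covariate-adjusted) trait
#'   values, or a tibble with `sample_id` and one value column.
#' @param kinship Additive relationship matrix from
#'   [kinship_from_pedigree()].
#' @param trait Optional trait label carried into the result.
#' @param decomp Optional precomputed eigendecomposition of the kinship
#'   matrix over exactly the analysis samples (internal reuse across fits on
#'   one pedigree); refit from `kinship` when it does not match.
#' @return An object of class `polygenic_fit`: `h2`, `sigma2_g`, `sigma2_e`,
#'   `mu`, `loglik`, `n`, `converged`, `boundary`.
#' @export
fit_univariate_polygenic <- function(residuals, kinship, trait = "trait",
                                     decomp = NULL) {
  al <- align_residuals(residuals, kinship)
  if (var(al$y) == 0) abort("Trait has zero variance.")
  eg <- get_decomp(decomp, kinship, al$ids)
  ystar <- drop(crossprod(eg$U, al$y))
  opt <- optimize(uni_profile_loglik, c(0, 1), maximum = TRUE,
                  ystar = ystar, one = eg$one, d = eg$d, tol = 1e-10)
  # optimize() never quite reaches the ends of the interval; check them
  cand <- c(opt$maximum, 0, 1)
  ll <- c(opt$objective,
          uni_profile_loglik(0, ystar, eg$one, eg$d),
          uni_profile_loglik(1, ystar, eg$one, eg$d))
  h2 <- cand[which.max(ll)]
  w <- h2 * eg$d + (1 - h2)
  mu <- sum(eg$one * ystar / w) / sum(eg$one^2 / w)
  n <- length(ystar)
  s2 <- sum((ystar - mu * eg$one)^2 / w) / n
  structure(
    list(
      trait = trait, h2 = h2, sigma2_g = h2 * s2, sigma2_e = (1 - h2) * s2,
      mu = mu, loglik = max(ll), n = n,
      converged = TRUE, boundary = h2 < 1e-6 || h2 > 1 - 1e-6,
      ids = al$ids
    ),
    class = "polygenic_fit"
  )
}

#' @export
print.polygenic_fit <- function(x, ...) {
  cat(sprintf(
    "<polygenic_fit> %s: h2 = %.3f (sigma2_g = %.3f, sigma2_e = %.3f), n = %d, logLik = %.2f%s\n",
    x$trait, x$h2, x$sigma2_g, x$sigma2_e, x$n, x$loglik,
    if (x$boundary) " [boundary]" else ""
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.polygenic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("h2", "sigma2_g", "sigma2_e", "mu"),
    estimate = c(x$h2, x$sigma2_g, x$sigma2_e, x$mu)
  )
}

#' @exportS3Method generics::glance
glance.polygenic_fit <- function(x, ...) {
  tibble::tibble(
    trait = x$trait, h2 = x$h2, logLik = x$loglik, n = x$n,
    converged = x$converged, boundary = x$boundary
  )
}

# Negative log-likelihood of the bivariate polygenic model after rotation by
# the kinship eigenvectors; th = (log s1, log s2, logit h1, logit h2,
# atanh rho_g, atanh rho_e); the two trait means are profiled out by GLS.
biv_negloglik <- function(th, Y, one, d) {
  s <- exp(th[1:2])
  h <- plogis(th[3:4])
  rg <- tanh(th[5]); re <- tanh(th[6])
  sg <- sqrt(s * h); se <- sqrt(s * (1 - h))
  G <- outer(sg, sg) * matrix(c(1, rg, rg, 1), 2)
  E <- outer(se, se) * matrix(c(1, re, re, 1), 2)
  n <- nrow(Y)
  # per-eigenvalue 2x2 covariance blocks C_i = d_i G + E
  c11 <- d * G[1, 1] + E[1, 1]
  c12 <- d * G[1, 2] + E[1, 2]
  c22 <- d * G[2, 2] + E[2, 2]
  det <- c11 * c22 - c12^2
  if (any(det <= 0) || any(c11 <= 0) || any(c22 <= 0)) return(1e10)
  i11 <- c22 / det; i22 <- c11 / det; i12 <- -c12 / det
  # GLS means: minimize sum_i r_i' C_i^{-1} r_i over (mu1, mu2)
  a11 <- sum(one^2 * i11); a22 <- sum(one^2 * i22); a12 <- sum(one^2 * i12)
  b1 <- sum(one * (i11 * Y[, 1] + i12 * Y[, 2]))
  b2 <- sum(one * (i12 * Y[, 1] + i22 * Y[, 2]))
  dA <- a11 * a22 - a12^2
  if (dA <= 0) return(1e10)
  mu1 <- (b1 * a22 - b2 * a12) / dA
  mu2 <- (b2 * a11 - b1 * a12) / dA
  r1 <- Y[, 1] - mu1 * one
  r2 <- Y[, 2] - mu2 * one
  quad <- sum(i11 * r1^2 + 2 * i12 * r1 * r2 + i22 * r2^2)
  0.5 * (2 * n * log(2 * pi) + sum(log(det)) + quad)
}

#' Bivariate polygenic model by maximum likelihood
#'
#' Joint model for two traits on a pedigree: the genetic covariance is the
#' 2x2 matrix `Sigma_G` scaled along the additive relationship matrix `A`,
#' the environmental covariance `Sigma_E` along the identity. Maximizes the
#' bivariate normal likelihood over `(h2_1, h2_2, rho_g, rho_e)` plus the
#' two total variances (trait means profiled out), parameterized with logit
#' heritabilities and atanh correlations so `|rho| = 1` boundary solutions
#' are representable and flagged. Runs from three starts (univariate-fit
#' informed, zero-correlation, and a seeded random start) and keeps the best
#' likelihood. The implied phenotypic correlation is computed with
#' [implied_rho_p()].
#'
#' @param residuals1,residuals2 Residual vectors/tibbles as in
#'   [fit_univariate_polygenic()]; fitted on the intersection of their
#'   complete cases.
#' @param kinship Additive relationship matrix.
#' @param traits Character vector of two trait labels.
#' @param max_iter Maximum optimizer iterations per start (default 500).
#' @param seed Seed for the random start (default 1).
#' @param decomp Optional precomputed kinship eigendecomposition over the
#'   shared complete-case samples (see [fit_univariate_polygenic()]).
#' @param fix Optional named list pinning `rho_g` and/or `rho_e` to fixed
#'   values (e.g. `list(rho_g = 0)` for the likelihood-ratio test of no
#'   genetic correlation).
#' @return An object of class `bivariate_polygenic_fit` with elements
#'   `h2_1`, `h2_2`, `rho_g`, `rho_e`, `rho_p`, `loglik`, `converged`,
#'   `boundary_g`, `boundary_e`, `n`.
#' @export
fit_bivariate_polygenic <- function(residuals1, residuals2, kinship,
                                    traits = c("trait1", "trait2"),
                                    max_iter = 500, seed = 1, decomp = NULL,
                                    fix = list()) {
  al1 <- align_residuals(residuals1, kinship)
  al2 <- align_residuals(residuals2, kinship)
  ids <- intersect(al1$ids, al2$ids)
  if (length(ids) < 30) abort("Fewer than 30 samples with both traits.")
  y1 <- al1$y[match(ids, al1$ids)]
  y2 <- al2$y[match(ids, al2$ids)]
  if (var(y1) == 0 || var(y2) == 0) abort("A trait has zero variance.")
  eg <- get_decomp(decomp, kinship, ids)
  Y <- cbind(drop(crossprod(eg$U, y1)), drop(crossprod(eg$U, y2)))

  u1 <- fit_univariate_polygenic(setNames(y1, ids), kinship, traits[1], decomp = eg)
  u2 <- fit_univariate_polygenic(setNames(y2, ids), kinship, traits[2], decomp = eg)
  sq <- function(h) pmin(pmax(h, 1e-3), 1 - 1e-3)
  r0 <- cor(y1, y2)
  starts <- list(
    c(log(var(y1)), log(var(y2)), qlogis(sq(u1$h2)), qlogis(sq(u2$h2)),
      atanh(0.9 * r0), atanh(0.9 * r0)),
    c(log(var(y1)), log(var(y2)), qlogis(0.3), qlogis(0.3), 0, 0),
    local({
      set.seed(seed)
      c(log(var(y1)), log(var(y2)), rnorm(2, 0, 1), atanh(runif(2, -0.8, 0.8)))
    })
  )
  bound <- c(rep(20, 2), rep(15, 2), rep(10, 2))  # tanh(10) ~ 1 - 4e-9
  fixed <- rep(NA_real_, 6)
  if (!is.null(fix$rho_g)) fixed[5] <- atanh(fix$rho_g)
  if (!is.null(fix$rho_e)) fixed[6] <- atanh(fix$rho_e)
  free <- is.na(fixed)
  fill <- function(th_free) { th <- fixed; th[free] <- th_free; th }
  fits <- purrr::map(starts, function(st) {
    optim(st[free], function(th_free) {
      biv_negloglik(fill(th_free), Y = Y, one = eg$one, d = eg$d)
    }, method = "L-BFGS-B", lower = -bound[free], upper = bound[free],
    control = list(maxit = max_iter, factr = 1e4))
  })
  best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]
  th <- fill(best$par)
  h2_1 <- plogis(th[3]); h2_2 <- plogis(th[4])
  rho_g <- tanh(th[5]); rho_e <- tanh(th[6])
  structure(
    list(
      traits = traits,
      h2_1 = h2_1, h2_2 = h2_2, rho_g = rho_g, rho_e = rho_e,
      rho_p = implied_rho_p(h2_1, h2_2, rho_g, rho_e),
      var_1 = exp(th[1]), var_2 = exp(th[2]),
      loglik = -best$value, n = length(ids),
      converged = best$convergence == 0,
      boundary_g = abs(rho_g) > 1 - 1e-6,
      boundary_e = abs(rho_e) > 1 - 1e-6,
      univariate = list(u1, u2), ids = ids
    ),
    class = "bivariate_polygenic_fit"
  )
}

#' @export
print.bivariate_polygenic_fit <- function(x, ...) {
  cat(sprintf(
    "<bivariate_polygenic_fit> %s ~ %s\n  h2 = %.3f / %.3f, rho_g = %.3f%s, rho_e = %.3f%s, rho_p = %.3f\n  n = %d, logLik = %.2f, converged = %s\n",
    x$traits[1], x$traits[2], x$h2_1, x$h2_2,
    x$rho_g, if (x$boundary_g) "*" else "",
    x$rho_e, if (x$boundary_e) "*" else "",
    x$rho_p, x$n, x$loglik, x$converged
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bivariate_polygenic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("h2_1", "h2_2", "rho_g", "rho_e", "rho_p"),
    estimate = c(x$h2_1, x$h2_2, x$rho_g, x$rho_e, x$rho_p)
  )
}

#' @exportS3Method generics::glance
glance.bivariate_polygenic_fit <- function(x, ...) {
  tibble::tibble(
    trait1 = x$traits[1], trait2 = x$traits[2],
    h2_1 = x$h2_1, h2_2 = x$h2_2, rho_g = x$rho_g, rho_e = x$rho_e,
    rho_p = x$rho_p, logLik = x$loglik, n = x$n,
    converged = x$converged,
    boundary = x$boundary_g || x$boundary_e
  )
}

#' Fit all pairwise bivariate polygenic models
#'
#' Convenience wrapper running [fit_bivariate_polygenic()] over every pair
#' of trait columns in a residual table.
#'
#' @param residual_table Tibble with `sample_id` and one column per trait.
#' @param kinship Additive relationship matrix.
#' @param ... Passed to [fit_bivariate_polygenic()].
#' @return A tibble with one row per pair (the [glance()] of each fit).
#' @export
fit_all_pairs <- function(residual_table, kinship, ...) {
  traits <- setdiff(names(residual_table), c("sample_id", "cohort"))
  if (length(traits) < 2) abort("Need at least two trait columns.")
  pairs <- utils::combn(traits, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    r1 <- setNames(residual_table[[pr[1]]], residual_table$sample_id)
    r2 <- setNames(residual_table[[pr[2]]], residual_table$sample_id)
    glance(fit_bivariate_polygenic(r1, r2, kinship, traits = pr, ...))
  })
}
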