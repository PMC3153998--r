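#' Shared associations against a correlation component
#'
#' Scatter plot of the per-pair shared-association percentage against the
#' absolute phenotypic, genetic or environmental correlation, with the
#' Pearson r in the subtitle — the standard way to eyeball whether SNP
#' sharing tracks the genetic rather than the environmental component.
#'
#' @param pairs Tibble with `shared_pct` and the chosen correlation column
#'   (e.g. from [bone_pair_table()] or [correlate_similarity()]'s `"pairs"`
#'   attribute).
#' @param component One of `"rho_p"`, `"rho_g"`, `"rho_e"`.
#' @return A ggplot object.
#' @export
plot_shared_vs_correlation <- function(pairs,
                                       component = c("rho_p", "rho_g", "rho_e")) {
  component <- match.arg(component)
  lab <- c(rho_p = "|phenotypic correlation|",
           rho_g = "|genetic correlation|",
           rho_e = "|environmental correlation|")[component]
  r <- cor(abs(pairs[[component]]), pairs$shared_pct)
  ggplot2::ggplot(pairs, ggplot2::aes(x = abs(.data[[component]]),
                                      y = .data$shared_pct)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::labs(x = lab, y = "shared associated SNPs (%)",
                  subtitle = sprintf("Pearson r = %.2f over %d pairs",
                                     r, nrow(pairs))) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.gwas_scan <- function(object, alpha = 0.01, ...) {
  dat <- object$results
  dat$index <- seq_len(nrow(dat))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$index, y = -log10(.data$p))) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "SNP index", y = expression(-log[10](p)),
                  title = sprintf("Trait %s (lambda = %.3f)", object$trait,
                                  inflation_factor(object))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
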