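#' Tidy a recoil fit
#'
#' @param x A `recoil_fit` or `recoil_boot`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.recoil_fit <- function(x, ...) {
  tibble(term = c("v0", "tau"),
         estimate = c(x$v0, x$tau),
         conf.low = c(x$ci_v0[1], x$ci_tau[1]),
         conf.high = c(x$ci_v0[2], x$ci_tau[2]))
}

#' @rdname tidy.recoil_fit
#' @export
glance.recoil_fit <- function(x, ...) {
  tibble(n_samples = x$n_samples, converged = x$converged,
         identifiable = x$identifiable,
         n_boot = if (!is.null(x$n_boot)) x$n_boot else NA_integer_)
}

#' Tidy a permutation contrast
#' @param x A `recoil_contrast`.
#' @param ... Unused.
#' @return One-row tibble with the contrast estimate and p-value.
#' @export
tidy.recoil_contrast <- function(x, ...) {
  tibble(parameter = x$parameter,
         cell_a = x$cell_a, cell_b = x$cell_b,
         estimate_a = x$fit_a[[x$parameter]],
         estimate_b = x$fit_b[[x$parameter]],
         estimate = x$observed, p.value = x$p)
}

#' Tidy AR(1) GLS cell means
#' @param x A `cell_means` object.
#' @param ... Unused.
#' @return Tibble `cell`, `estimate`, `se`.
#' @export
tidy.cell_means <- function(x, ...) x$means

#' @rdname tidy.cell_means
#' @export
glance.cell_means <- function(x, ...) {
  tibble(rho = x$rho, n = x$n, sigma = x$fit$sigma,
         logLik = as.numeric(logLik(x$fit)))
}

#' Tidy a lifetime ANOVA
#' @param x A `lifetime_anova`.
#' @param ... Unused.
#' @return Per-group means with the shared F and p.
#' @export
tidy.lifetime_anova <- function(x, ...) x$means

#' @rdname tidy.lifetime_anova
#' @export
glance.lifetime_anova <- function(x, ...) {
  tibble(statistic = x$f, p.value = x$p, df = x$df[1], df.residual = x$df[2])
}

#' Tidy a Procrustes fit
#' @param x A `procrustes_fit`.
#' @param ... Unused.
#' @return Per-cell residual vectors and distances.
#' @export
tidy.procrustes_fit <- function(x, ...) x$residuals

#' @rdname tidy.procrustes_fit
#' @export
glance.procrustes_fit <- function(x, ...) {
  tibble(scale = x$scale, rmsd = x$rmsd, n_shared = nrow(x$residuals))
}

#' Tidy a sphericity mixed model
#' @param x A `sphericity_model`.
#' @param ... Unused.
#' @return Fixed-effect estimates with standard errors.
#' @export
tidy.sphericity_model <- function(x, ...) x$fixed

#' @rdname tidy.sphericity_model
#' @export
glance.sphericity_model <- function(x, ...) {
  tibble(category_chisq = x$category_lrt$chisq,
         category_df = x$category_lrt$df,
         category_p = x$category_lrt$p_value,
         random_slope_kept = x$random_slope_kept)
}

#' Tidy a quadratic time fit
#' @param x A `quad_fit`.
#' @param ... Unused.
#' @return Coefficients a, b, c with standard errors.
#' @export
tidy.quad_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         se = sqrt(diag(x$vcov)))
}

#' Tidy an interface asymmetry ANOVA
#' @param x An `interface_anova`.
#' @param ... Unused.
#' @return The ANOVA effect table.
#' @export
tidy.interface_anova <- function(x, ...) x$table
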