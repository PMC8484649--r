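#' Subtract measured background from cortical intensities
#'
#' First correction stage: the locally measured background (areas surrounding
#' the cortex, recorded per embryo, timepoint and plane in the `background`
#' column) is subtracted from the raw cortical signal. Differences are floored
#' at zero and flagged.
#'
#' @param records Intensity tibble with columns `embryo_id`, `cell`, `t`, `z`,
#'   `raw`, `background`.
#' @return The records with new columns `i_star` (background-subtracted
#'   signal) and `floored` (logical).
#' @export
subtract_background <- function(records) {
  stopifnot_cols(records, c("raw", "background"), "intensity records")
  records |>
    mutate(i_star = pmax(.data$raw - .data$background, 0),
           floored = .data$raw - .data$background < 0)
}

#' Per-embryo intensity scaling
#'
#' Second correction stage: systematic intensity differences between embryos
#' are removed by a multiplicative scaling factor per embryo,
#' `s_e = grand mean(I*) / mean(I* in embryo e)`, so that after scaling every
#' embryo's mean equals the grand mean.
#'
#' @param records Records carrying `i_star` (from [subtract_background()]).
#' @return The records with a new `i_scaled` column; the tibble of scaling
#'   factors is attached as attribute `"scale_factors"` and also available via
#'   [scale_factors()].
#' @export
embryo_scaling <- function(records) {
  stopifnot_cols(records, c("embryo_id", "i_star"), "intensity records")
  grand <- mean(records$i_star)
  sf <- records |>
    group_by(.data$embryo_id) |>
    summarise(embryo_mean = mean(.data$i_star), .groups = "drop") |>
    mutate(s_e = grand / .data$embryo_mean)
  if (any(!is.finite(sf$s_e)))
    abort(sprintf("embryo mean intensity is zero; cannot scale embryo(s): %s",
                  paste(sf$embryo_id[!is.finite(sf$s_e)], collapse = ", ")))
  out <- records |>
    left_join(select(sf, all_of(c("embryo_id", "s_e"))), by = "embryo_id") |>
    mutate(i_scaled = .data$s_e * .data$i_star) |>
    select(-all_of("s_e"))
  attr(out, "scale_factors") <- sf
  out
}

#' Scaling factors of a scaled record table
#' @param records Output of [embryo_scaling()].
#' @return Tibble `embryo_id`, `embryo_mean`, `s_e`.
#' @export
scale_factors <- function(records) {
  sf <- attr(records, "scale_factors")
  if (is.null(sf)) abort("records carry no scale factors; run embryo_scaling() first")
  sf
}

#' Fit and remove bleaching and imaging-depth confounders
#'
#' Third correction stage: an additive model `f(t, z)` with a linear effect of
#' imaging time `t` (bleaching) and a smoothing spline in `log(z)` (signal
#' degradation with plane depth) is fitted to the scaled intensities across
#' all embryos, by penalised regression with smoothness chosen by generalised
#' cross-validation. Each observation is then corrected and normalised as
#' `I+ = (I_scaled - f(t, z) + grand_mean) / grand_mean`, so corrected values
#' fluctuate around 1.
#'
#' @param records Records carrying `i_scaled` (from [embryo_scaling()]).
#' @param k Basis dimension of the depth spline (capped at the number of
#'   distinct planes).
#' @return Object of class `correction_model`: elements `records` (with a new
#'   `i_corr` column), `fit` (the underlying [mgcv::gam()] fit),
#'   `bleach_coef` (a.u. per unit t), `depth_spline` (function of z),
#'   `grand_mean`, and `terms` (which confounder terms were fitted).
#' @export
fit_confounders <- function(records, k = 10) {
  stopifnot_cols(records, c("i_scaled", "t", "z"), "intensity records")
  if (any(records$z < 1)) abort("plane index z must be >= 1")
  n_t <- length(unique(records$t))
  n_z <- length(unique(records$z))
  use_t <- n_t >= 2
  use_z <- n_z >= 3
  if (!use_t) warn("single timepoint: bleaching term dropped")
  if (!use_z) warn("fewer than 3 planes: depth spline dropped")

  dat <- data.frame(y = records$i_scaled, t = records$t, logz = log(records$z))
  rhs <- c(if (use_t) "t",
           if (use_z) sprintf("s(logz, k = %d)", min(k, n_z)))
  if (length(rhs) == 0) rhs <- "1"
  fit <- mgcv::gam(as.formula(paste("y ~", paste(rhs, collapse = " + "))),
                   data = dat, method = "GCV.Cp")
  grand <- mean(records$i_scaled)
  f_tz <- as.numeric(predict(fit, newdata = dat))
  out <- mutate(records, i_corr = (records$i_scaled - f_tz + grand) / grand)

  depth_spline <- if (use_z) {
    function(z) {
      nd <- data.frame(t = rep(mean(records$t), length(z)), logz = log(z))
      as.numeric(predict(fit, newdata = nd, type = "terms",
                         terms = sprintf("s(logz)")))
    }
  } else {
    function(z) rep(0, length(z))
  }

  structure(
    list(records = out, fit = fit,
         bleach_coef = if (use_t) unname(coef(fit)["t"]) else NA_real_,
         depth_spline = depth_spline, grand_mean = grand,
         terms = c(bleach = use_t, depth = use_z),
         scale_factors = attr(records, "scale_factors")),
    class = "correction_model"
  )
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf("<correction_model> grand mean %.4g a.u., bleach coefficient %.4g a.u./min%s\n",
              x$grand_mean, x$bleach_coef,
              if (x$terms[["depth"]]) ", depth spline on log(z)" else ""))
  invisible(x)
}

#' Full intensity correction cascade
#'
#' Convenience wrapper running the fixed-order cascade background subtraction
#' -> per-embryo scaling -> bleaching/depth correction, returning the
#' records with all intermediate columns (`i_star`, `i_scaled`, `i_corr`) and
#' the fitted [fit_confounders()] model as attribute `"correction_model"`.
#'
#' @param records Raw intensity records.
#' @param k Passed to [fit_confounders()].
#' @return Corrected records tibble.
#' @export
correct_intensity <- function(records, k = 10) {
  model <- records |>
    subtract_background() |>
    embryo_scaling() |>
    fit_confounders(k = k)
  out <- model$records
  attr(out, "correction_model") <- model
  out
}

#' Per-cell intensity means under AR(1) time correlation
#'
#' Estimates relative cortical intensity per cell from corrected records by
#' generalized least squares with a first-order autoregressive correlation
#' structure within each measurement series (an embryo x cell x plane time
#' series), then reports least-square means with standard errors from the
#' model covariance, and the estimated AR(1) correlation.
#'
#' @param records Corrected records (column `i_corr`, plus `embryo_id`,
#'   `cell`, `t`, and `z` if multiple planes).
#' @param value Name of the response column (default `"i_corr"`).
#' @return Object of class `cell_means`: `means` tibble (`cell`, `estimate`,
#'   `se`), `rho`, `vcov`, and the underlying [nlme::gls()] fit.
#' @export
cell_means_ar1 <- function(records, value = "i_corr") {
  stopifnot_cols(records, c("embryo_id", "cell", "t", value), "records")
  dat <- data.frame(
    y = records[[value]],
    cell = factor(records$cell),
    series = interaction(
      records$embryo_id, records$cell,
      if ("z" %in% names(records)) records$z else "",
      drop = TRUE
    ),
    t = records$t
  )
  dat <- dat[order(dat$series, dat$t), ]
  dat$idx <- stats::ave(seq_along(dat$y), dat$series, FUN = seq_along)
  series_len <- table(dat$series)

  if (all(series_len <= 1)) {
    warn("all series have length 1: falling back to ordinary least squares")
    fit <- nlme::gls(y ~ 0 + cell, data = dat)
    rho <- NA_real_
  } else {
    fit <- nlme::gls(y ~ 0 + cell, data = dat,
                     correlation = nlme::corAR1(form = ~ idx | series))
    rho <- coef(fit$modelStruct$corStruct, unconstrained = FALSE)[[1]]
  }
  v <- vcov(fit)
  est <- coef(fit)
  cells <- sub("^cell", "", names(est))
  structure(
    list(means = tibble(cell = cells, estimate = unname(est),
                        se = sqrt(diag(v))),
         rho = rho, vcov = v, fit = fit, n = nrow(dat)),
    class = "cell_means"
  )
}

#' @export
print.cell_means <- function(x, ...) {
  cat(sprintf("<cell_means> GLS with AR(1) errors, rho = %.3f, n = %d\n",
              x$rho, x$n))
  print(x$means)
  invisible(x)
}

#' Contrast two cells' intensity means
#'
#' Difference of least-square means between two cells from a [cell_means_ar1()]
#' fit, with standard error from the model covariance and a two-sided test.
#'
#' @param fit A `cell_means` object.
#' @param pair Character length-2, `c(cellA, cellB)`; the contrast is A - B.
#' @return Tibble with `contrast`, `estimate`, `se`, `statistic`, `p_value`.
#' @export
contrast_cells <- function(fit, pair) {
  stopifnot(inherits(fit, "cell_means"), length(pair) == 2)
  i <- match(pair, fit$means$cell)
  if (anyNA(i)) abort(sprintf("cell(s) not in the model: %s",
                              paste(pair[is.na(i)], collapse = ", ")))
  cvec <- rep(0, nrow(fit$means))
  cvec[i] <- c(1, -1)
  est <- sum(cvec * fit$means$estimate)
  se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
  z <- est / se
  tibble(contrast = paste(pair, collapse = " - "), estimate = est, se = se,
         statistic = z, p_value = 2 * pnorm(-abs(z)))
}

#' Quadratic time trend of corrected intensity per cell
#'
#' Fits `I+ ~ a + b t + c t^2` for one cell by generalized least squares with
#' AR(1) errors within each embryo (x plane) series, and evaluates the fitted
#' mean with a +/-1 SE band from the coefficient covariance.
#'
#' @param records Corrected records.
#' @param cell Cell to fit.
#' @param value Response column (default `"i_corr"`).
#' @param n_grid Number of evaluation points of the band.
#' @return Object of class `quad_fit`: `coefficients` (a, b, c), `vcov`,
#'   `band` tibble (`t`, `fit`, `se`), `rho`.
#' @export
quadratic_time_fit <- function(records, cell, value = "i_corr", n_grid = 50) {
  stopifnot_cols(records, c("embryo_id", "cell", "t", value), "records")
  rec <- filter(records, .data$cell == !!cell)
  if (nrow(rec) == 0) abort(sprintf("no records for cell '%s'", cell))
  if (length(unique(rec$t)) < 4) abort("need >= 4 distinct timepoints")
  dat <- data.frame(
    y = rec[[value]], t = rec$t,
    series = interaction(rec$embryo_id,
                         if ("z" %in% names(rec)) rec$z else "", drop = TRUE)
  )
  dat <- dat[order(dat$series, dat$t), ]
  dat$idx <- stats::ave(seq_along(dat$y), dat$series, FUN = seq_along)
  fit <- tryCatch(
    nlme::gls(y ~ t + I(t^2), data = dat,
              correlation = nlme::corAR1(form = ~ idx | series)),
    error = function(e) {
      warn(sprintf("AR(1) GLS failed (%s); falling back to ordinary least squares",
                   conditionMessage(e)))
      lm(y ~ t + I(t^2), data = dat)
    }
  )
  rho <- tryCatch(coef(fit$modelStruct$corStruct, unconstrained = FALSE)[[1]],
                  error = function(e) NA_real_)
  cf <- coef(fit)
  v <- vcov(fit)
  tg <- seq(min(dat$t), max(dat$t), length.out = n_grid)
  xg <- cbind(1, tg, tg^2)
  band <- tibble(t = tg, fit = drop(xg %*% cf),
                 se = sqrt(rowSums((xg %*% v) * xg)))
  structure(list(coefficients = setNames(unname(cf), c("a", "b", "c")),
                 vcov = v, band = band, rho = rho, cell = cell, fit = fit),
            class = "quad_fit")
}

#' @export
print.quad_fit <- function(x, ...) {
  cat(sprintf("<quad_fit> cell %s: I+ = %.4g + %.4g t + %.4g t^2 (AR1 rho = %.3f)\n",
              x$cell, x$coefficients[1], x$coefficients[2], x$coefficients[3],
              x$rho))
  invisible(x)
}

#' Spatiotemporal intensity surface around the cytokinetic furrow
#'
#' Fits a smooth 2D surface to cortical intensity samples indexed by signed
#' position along the cortex relative to the furrow centre (anterior negative,
#' posterior positive) and time relative to furrow closure. Samples are first
#' standardized per embryo (mean 0, SD 1); embryos with zero variance are
#' excluded. The surface is a tensor-product spline fitted to the pooled
#' standardized samples, evaluable on a regular grid, with iso-intensity
#' contour lines.
#'
#' @param samples Tibble with columns `embryo_id`, `position` (um from the
#'   furrow centre), `time` (s from closure), `value`.
#' @param k Tensor-spline marginal basis dimensions, length 2.
#' @param grid_n Grid resolution (length 2) for surface evaluation.
#' @param contour_levels Number of contour levels.
#' @return Object of class `st_surface`: `grid` tibble (`position`, `time`,
#'   `value`), `contours` tibble, and the underlying fit.
#' @export
spatiotemporal_surface <- function(samples, k = c(8, 8), grid_n = c(40, 40),
                                   contour_levels = 8) {
  stopifnot_cols(samples, c("embryo_id", "position", "time", "value"), "samples")
  std <- samples |>
    group_by(.data$embryo_id) |>
    mutate(emb_sd = sd(.data$value),
           value_std = (.data$value - mean(.data$value)) / .data$emb_sd) |>
    ungroup()
  bad <- unique(std$embryo_id[!is.finite(std$value_std)])
  if (length(bad) > 0) {
    warn(sprintf("excluding embryo(s) with degenerate (zero-variance) signal: %s",
                 paste(bad, collapse = ", ")))
    std <- filter(std, !.data$embryo_id %in% bad)
  }
  if (length(unique(std$embryo_id)) < 3)
    abort("need samples from >= 3 embryos")
  fit <- mgcv::gam(value_std ~ te(position, time, k = k), data = std)
  pg <- seq(min(std$position), max(std$position), length.out = grid_n[1])
  tg <- seq(min(std$time), max(std$time), length.out = grid_n[2])
  grid <- tidyr::expand_grid(position = pg, time = tg)
  grid$value <- as.numeric(predict(fit, newdata = grid))
  zmat <- t(matrix(grid$value, nrow = length(tg)))
  cl <- grDevices::contourLines(pg, tg, zmat, nlevels = contour_levels)
  contours <- purrr::imap_dfr(cl, function(li, i) {
    tibble(contour_id = i, level = li$level, position = li$x, time = li$y)
  })
  structure(list(grid = grid, contours = contours, fit = fit,
                 samples = std), class = "st_surface")
}

#' Intensity profile along a cell-cell contact
#'
#' Natural cubic spline fit of normalized intensity against position along a
#' cell-cell contact (e.g. an adhesion protein's distribution across the
#' interface of two cells), with a pointwise confidence band.
#'
#' @param samples Tibble with columns `position` (normalized position along
#'   the contact) and `value`; an `embryo_id` column is carried if present.
#' @param df Degrees of freedom of the natural spline basis.
#' @param n_grid Evaluation grid size.
#' @param level Confidence level of the band.
#' @return Tibble `position`, `fit`, `se`, `lo`, `hi`.
#' @export
interface_profile <- function(samples, df = 4, n_grid = 100, level = 0.95) {
  stopifnot_cols(samples, c("position", "value"), "samples")
  if (nrow(samples) < 10) abort("need >= 10 samples spanning the contact")
  fit <- lm(value ~ splines::ns(position, df = df), data = samples)
  pg <- data.frame(position = seq(min(samples$position), max(samples$position),
                                  length.out = n_grid))
  pr <- predict(fit, newdata = pg, se.fit = TRUE)
  zq <- qnorm(1 - (1 - level) / 2)
  tibble(position = pg$position, fit = unname(pr$fit), se = unname(pr$se.fit),
         lo = unname(pr$fit - zq * pr$se.fit),
         hi = unname(pr$fit + zq * pr$se.fit))
}

#' Scale values to the observed range per embryo
#'
#' Maps each embryo's contact-area intensity values onto [0, 1] by its own
#' observed minimum and maximum.
#'
#' @param samples Tibble with `embryo_id` and `value`.
#' @return The tibble with a new `value_scaled` column.
#' @export
range_scale <- function(samples) {
  stopifnot_cols(samples, c("embryo_id", "value"), "samples")
  samples |>
    group_by(.data$embryo_id) |>
    mutate(value_scaled = (.data$value - min(.data$value)) /
             (max(.data$value) - min(.data$value))) |>
    ungroup()
}

#' Mixed two-way ANOVA of interface asymmetry
#'
#' Tests whether the asymmetry of an interface signal between the two cell
#' sides of a contact differs between treatments. Values are first scaled to
#' each embryo's observed range, summarised to one mean per embryo x side, and
#' analysed by a two-way ANOVA with treatment as the between-embryo factor and
#' cell side as the repeated (within-embryo) factor, embryo being the
#' repeated-measures unit. Embryos missing one side are excluded with a
#' warning.
#'
#' @param samples Tibble with columns `embryo_id`, `treatment`, `side`,
#'   `value`.
#' @param scale Range-scale per embryo first (default TRUE).
#' @return Object of class `interface_anova`: `table` (tidy ANOVA table with
#'   effects `treatment`, `side`, `treatment:side`), and the per-embryo means.
#' @export
interface_asymmetry_test <- function(samples, scale = TRUE) {
  stopifnot_cols(samples, c("embryo_id", "treatment", "side", "value"), "samples")
  if (scale) {
    samples <- range_scale(samples)
    vcol <- "value_scaled"
  } else vcol <- "value"
  cellmeans <- samples |>
    group_by(.data$embryo_id, .data$treatment, .data$side) |>
    summarise(value = mean(.data[[vcol]]), .groups = "drop")
  n_sides <- length(unique(cellmeans$side))
  complete <- cellmeans |>
    group_by(.data$embryo_id) |>
    filter(n() == n_sides) |>
    ungroup()
  dropped <- setdiff(unique(cellmeans$embryo_id), unique(complete$embryo_id))
  if (length(dropped) > 0)
    warn(sprintf("excluding embryo(s) missing a cell side: %s",
                 paste(dropped, collapse = ", ")))
  per_treat <- complete |> distinct(.data$embryo_id, .data$treatment) |>
    dplyr::count(.data$treatment)
  if (any(per_treat$n < 2)) abort("need >= 2 embryos per treatment")

  dat <- data.frame(
    y = complete$value,
    embryo = factor(complete$embryo_id),
    treatment = factor(complete$treatment),
    side = factor(complete$side)
  )
  fit <- stats::aov(y ~ treatment * side + Error(embryo / side), data = dat)
  sm <- summary(fit)
  rows <- purrr::map_dfr(sm, function(stratum) {
    tab <- stratum[[1]]
    eff <- trimws(rownames(tab))
    tibble(effect = eff, df = tab$Df, f = tab$`F value`, p = tab$`Pr(>F)`)
  }) |>
    filter(.data$effect != "Residuals")
  structure(list(table = rows, cell_means = complete, fit = fit),
            class = "interface_anova")
}

#' @export
print.interface_anova <- function(x, ...) {
  cat("<interface_anova> mixed two-way ANOVA (side within embryo, treatment between)\n")
  print(x$table)
  invisible(x)
}
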