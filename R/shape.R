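# shift a 3D array by k voxels along one axis, zero-filling the vacated slab
shift3 <- function(arr, k, axis) {
  if (k == 0) return(arr)
  d <- dim(arr)
  out <- array(0, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (abs(k) >= n) return(out)
  if (k > 0) {
    idx_dst[[axis]] <- (k + 1):n
    idx_src[[axis]] <- 1:(n - k)
  } else {
    idx_dst[[axis]] <- 1:(n + k)
    idx_src[[axis]] <- (1 - k):n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# separable Gaussian smoothing of a 3D array (sigma in voxels per axis)
gauss_smooth3 <- function(arr, sigma = 1.5) {
  sigma <- rep(sigma, length.out = 3)
  for (axis in 1:3) {
    if (sigma[axis] <= 0) next
    r <- ceiling(3 * sigma[axis])
    w <- exp(-((-r:r)^2) / (2 * sigma[axis]^2))
    w <- w / sum(w)
    acc <- array(0, dim(arr))
    for (j in seq_along(w)) acc <- acc + w[j] * shift3(arr, j - r - 1, axis)
    arr <- acc
  }
  arr
}

labels_present <- function(volume) {
  setdiff(sort(unique(as.vector(volume$voxels))), 0L)
}

check_label <- function(volume, label) {
  if (!any(volume$voxels == label))
    abort(sprintf("label %s not found in volume (present: %s)", label,
                  paste(labels_present(volume), collapse = ", ")),
          class = "cortexdyn_label_error")
}

#' Cell volume from a labelled voxel volume
#'
#' @param volume A [label_volume()].
#' @param label Cell label.
#' @return Volume in cubic micrometres (voxel count times voxel volume).
#' @export
cell_volume <- function(volume, label) {
  stopifnot(inherits(volume, "label_volume"))
  check_label(volume, label)
  sum(volume$voxels == label) * prod(volume$spacing)
}

#' Wadell sphericity of a labelled cell
#'
#' Sphericity compares a body's surface area with that of the equal-volume
#' sphere: `psi = pi^(1/3) * (6 V)^(2/3) / A`, equal to 1 for a sphere and
#' smaller for any other shape. The volume V is the voxel-count volume; the
#' surface area A is estimated from the binary label mask after one Gaussian
#' smoothing pass, as the integral of the gradient magnitude of the smoothed
#' indicator field (the coarea formula: for a smoothed step across the
#' surface, the integral of |grad| over space equals the interface area).
#' This avoids the gross overestimation of voxel-face counting on discretised
#' surfaces. The returned value is clipped at 1; the raw estimate is attached
#' as attribute `"raw"`.
#'
#' @param volume A [label_volume()].
#' @param label Cell label.
#' @param sigma_vox Gaussian smoothing SD in voxels (per axis).
#' @param min_voxels Minimum voxel count for a stable surface estimate.
#' @return Sphericity in (0, 1], with attributes `raw`, `volume`, `area`.
#' @export
sphericity <- function(volume, label, sigma_vox = 0.65, min_voxels = 100) {
  stopifnot(inherits(volume, "label_volume"))
  check_label(volume, label)
  mask <- volume$voxels == label
  if (sum(mask) < min_voxels)
    abort(sprintf("label %s has only %d voxels (< %d); use a finer voxel spacing",
                  label, sum(mask), min_voxels))
  sp <- volume$spacing
  # smooth with an isotropic physical kernel: sigma in voxels scaled per axis
  sig_phys <- sigma_vox * min(sp)
  u <- gauss_smooth3(array(as.numeric(mask), dim(mask)), sig_phys / sp)
  gx <- (shift3(u, -1, 1) - shift3(u, 1, 1)) / (2 * sp[1])
  gy <- (shift3(u, -1, 2) - shift3(u, 1, 2)) / (2 * sp[2])
  gz <- (shift3(u, -1, 3) - shift3(u, 1, 3)) / (2 * sp[3])
  area <- sum(sqrt(gx^2 + gy^2 + gz^2)) * prod(sp)
  vol <- sum(mask) * prod(sp)
  raw <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area
  out <- min(raw, 1)
  attr(out, "raw") <- raw
  attr(out, "volume") <- vol
  attr(out, "area") <- area
  out
}

#' Morphometrics table of a labelled volume
#'
#' Volume and sphericity of every label.
#'
#' @param volume A [label_volume()].
#' @param labels Labels to measure (default all).
#' @return Tibble `label`, `volume`, `sphericity`.
#' @export
shape_metrics <- function(volume, labels = NULL) {
  labels <- labels %||% labels_present(volume)
  purrr::map_dfr(labels, function(l) {
    psi <- sphericity(volume, l)
    tibble(label = l, volume = cell_volume(volume, l),
           sphericity = as.numeric(psi))
  })
}

#' Daughter-cell volume ratio
#'
#' Asymmetry of a division quantified as `min(V) / (V_A + V_B)`, in (0, 0.5]
#' for any pair, 0.5 meaning an equal split.
#'
#' @param volume_a,volume_b Daughter volumes (any common unit).
#' @param names Optional daughter names for the orientation of the ratio.
#' @return Tibble `smaller`, `ratio`.
#' @export
volume_ratio <- function(volume_a, volume_b, names = c("A", "B")) {
  if (volume_a <= 0 || volume_b <= 0) abort("volumes must be > 0")
  tibble(smaller = names[which.min(c(volume_a, volume_b))],
         ratio = min(volume_a, volume_b) / (volume_a + volume_b))
}

#' Mixed-effects model of sphericity over time and treatment
#'
#' Fits `sphericity ~ 1 + time + category + (1 | embryo)` — fixed effects for
#' a linear time trend and the treatment category, with a random intercept per
#' embryo — by restricted maximum likelihood. The model-simplification step is
#' included: a random time slope per embryo is first considered and dropped
#' when a likelihood-ratio test does not support it (threshold
#' `slope_alpha`). The treatment effect is tested by a likelihood-ratio
#' chi-square test between maximum-likelihood refits with and without
#' `category`.
#'
#' @param data Tibble with columns `embryo`, `time`, `category`, `sphericity`.
#' @param slope_alpha Significance threshold for keeping the random slope.
#' @return Object of class `sphericity_model`: `fixed` tibble (term,
#'   estimate, se), `category_lrt` (chisq, df, p), `random_slope_kept`,
#'   `slope_lrt_p`, and the [lme4::lmer()] fit.
#' @export
sphericity_model <- function(data, slope_alpha = 0.05) {
  stopifnot_cols(data, c("embryo", "time", "category", "sphericity"), "data")
  per_cat <- data |> distinct(.data$embryo, .data$category) |>
    dplyr::count(.data$category)
  if (any(per_cat$n < 2)) abort("need >= 2 embryos per category")
  if (length(unique(data$time)) < 3) abort("need >= 3 timepoints")
  dat <- as.data.frame(data)
  dat$embryo <- factor(dat$embryo)
  dat$category <- factor(dat$category)

  fit_int <- lme4::lmer(sphericity ~ 1 + time + category + (1 | embryo),
                        data = dat, REML = TRUE)
  slope_p <- NA_real_
  keep_slope <- FALSE
  fit_slope <- tryCatch(
    lme4::lmer(sphericity ~ 1 + time + category + (1 + time | embryo),
               data = dat, REML = TRUE),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (!is.null(fit_slope) && !lme4::isSingular(fit_slope, tol = 1e-5)) {
    lrt <- suppressMessages(anova(fit_int, fit_slope, refit = TRUE))
    slope_p <- lrt$`Pr(>Chisq)`[2]
    keep_slope <- is.finite(slope_p) && slope_p < slope_alpha
  }
  fit <- if (keep_slope) fit_slope else fit_int

  # LRT for the category fixed effect on ML refits
  re_term <- if (keep_slope) "(1 + time | embryo)" else "(1 | embryo)"
  full_ml <- lme4::lmer(as.formula(paste("sphericity ~ 1 + time + category +", re_term)),
                        data = dat, REML = FALSE)
  null_ml <- lme4::lmer(as.formula(paste("sphericity ~ 1 + time +", re_term)),
                        data = dat, REML = FALSE)
  lrt_cat <- anova(null_ml, full_ml)
  cf <- summary(fit)$coefficients
  structure(
    list(fixed = tibble(term = rownames(cf), estimate = cf[, "Estimate"],
                        se = cf[, "Std. Error"]),
         category_lrt = tibble(chisq = lrt_cat$Chisq[2], df = lrt_cat$Df[2],
                               p_value = lrt_cat$`Pr(>Chisq)`[2]),
         random_slope_kept = keep_slope, slope_lrt_p = slope_p,
         fit = fit),
    class = "sphericity_model"
  )
}

#' @export
print.sphericity_model <- function(x, ...) {
  cat("<sphericity_model> sphericity ~ 1 + time + category + (1 | embryo)",
      if (x$random_slope_kept) "+ random time slope" else "", "\n")
  print(x$fixed)
  cat(sprintf("category LRT: chisq = %.4g (df %d), p = %.4g\n",
              x$category_lrt$chisq, x$category_lrt$df, x$category_lrt$p_value))
  invisible(x)
}

#' Simulate a sphericity study table
#'
#' Per-embryo longitudinal sphericity with a linear time trend, a treatment
#' (category) effect, random embryo intercepts (optionally slopes), and iid
#' residual noise — the generating model matched by [sphericity_model()].
#'
#' @param n_wt,n_treated Embryos per category.
#' @param n_time Timepoints per embryo.
#' @param intercept,time_slope,category_effect Fixed effects (treated embryos
#'   get `category_effect` added).
#' @param sd_embryo,sd_slope,sd_resid Random-intercept, random-slope and
#'   residual SDs.
#' @param seed Optional RNG seed.
#' @return Tibble `embryo`, `time`, `category`, `sphericity`.
#' @export
gen_sphericity <- function(n_wt = 7, n_treated = 5, n_time = 10,
                           intercept = 0.9, time_slope = -0.005,
                           category_effect = -0.03, sd_embryo = 0.02,
                           sd_slope = 0, sd_resid = 0.01, seed = NULL) {
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      embryo = sprintf("e%02d", seq_len(n_wt + n_treated)),
      time = seq(0, by = 1, length.out = n_time)
    )
    cat_of <- setNames(rep(c("wt", "treated"), c(n_wt, n_treated)),
                       sprintf("e%02d", seq_len(n_wt + n_treated)))
    b0 <- setNames(rnorm(n_wt + n_treated, 0, sd_embryo), names(cat_of))
    b1 <- setNames(rnorm(n_wt + n_treated, 0, sd_slope), names(cat_of))
    grid |>
      mutate(
        category = unname(cat_of[.data$embryo]),
        sphericity = intercept + b0[.data$embryo] +
          (time_slope + b1[.data$embryo]) * .data$time +
          ifelse(.data$category == "treated", category_effect, 0) +
          rnorm(n(), 0, sd_resid)
      )
  })
}
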