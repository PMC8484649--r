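test_that("background subtraction floors at zero and flags it", {
  rec <- tibble::tibble(embryo_id = "e1", cell = "E", t = 1:3, z = 1,
                        raw = c(100, 70, 10), background = c(0, 30, 30))
  out <- subtract_background(rec)
  expect_equal(out$i_star, c(100, 40, 0))
  expect_equal(out$floored, c(FALSE, FALSE, TRUE))
})

test_that("embryo scaling reproduces the two-embryo hand example", {
  rec <- tibble::tibble(
    embryo_id = rep(c("e1", "e2"), each = 4), cell = "E",
    t = rep(1:4, 2), z = 1,
    raw = c(8, 9, 11, 12, 18, 19, 21, 22), background = 0
  ) |> subtract_background()
  scaled <- embryo_scaling(rec)
  sf <- scale_factors(scaled)
  expect_equal(sf$embryo_mean, c(10, 20))
  expect_equal(sf$s_e, c(1.5, 0.75))
  post <- as.numeric(tapply(scaled$i_scaled, scaled$embryo_id, mean))
  expect_equal(post, c(15, 15))
  # grand mean is preserved exactly under equal counts
  expect_equal(mean(scaled$i_scaled), mean(rec$i_star))
})

test_that("single-embryo scaling is the identity and zero means error", {
  rec <- tibble::tibble(embryo_id = "e1", cell = "E", t = 1:3, z = 1,
                        raw = c(5, 6, 7), background = 0) |>
    subtract_background()
  expect_equal(scale_factors(embryo_scaling(rec))$s_e, 1)
  rec0 <- dplyr::mutate(rec, i_star = 0)
  expect_error(embryo_scaling(rec0), "cannot scale")
})

test_that("the correction cascade is the identity on confounder-free data", {
  rec <- gen_intensity(cell_effects = c(E = 80, MS = 80),
                       embryo_effects = c(e1 = 1, e2 = 1),
                       bleach_rate = 0, depth_fn = function(z) rep(1, length(z)),
                       ar1_rho = 0, noise_sd = 0, n_timepoints = 10, seed = 1)
  corr <- correct_intensity(rec)
  expect_equal(corr$i_corr, rep(1, nrow(corr)), tolerance = 1e-8)
})

test_that("the fitted bleaching coefficient recovers the generator slope", {
  bleach <- 0.012
  cells <- c(E = 60, MS = 100, ABpl = 95, ABpr = 95)
  rec <- gen_intensity(cell_effects = cells,
                       embryo_effects = c(e1 = 1, e2 = 1, e3 = 1, e4 = 1),
                       bleach_rate = bleach,
                       depth_fn = function(z) rep(1, length(z)),
                       ar1_rho = 0, noise_sd = 0.5, n_timepoints = 40,
                       planes = 1:3, seed = 2)
  model <- attr(correct_intensity(rec), "correction_model")
  implied <- -bleach * mean(cells)    # additive slope of the mean signal
  expect_rel_error(model$bleach_coef, implied, 0.05)
})

test_that("a monotone depth attenuation yields a monotone fitted spline", {
  rec <- gen_intensity(bleach_rate = 0,
                       depth_fn = function(z) exp(-(z - 1) / 6),
                       ar1_rho = 0, noise_sd = 0.5, planes = 1:6,
                       n_timepoints = 20, seed = 3)
  model <- attr(correct_intensity(rec), "correction_model")
  g <- model$depth_spline(1:6)
  expect_true(all(diff(g) < 0))
})

test_that("degenerate plane/timepoint structure drops terms with a warning", {
  rec <- gen_intensity(planes = 1, ar1_rho = 0, noise_sd = 1,
                       n_timepoints = 10, seed = 4) |>
    subtract_background() |> embryo_scaling()
  expect_warning(m <- fit_confounders(rec), "depth spline dropped")
  expect_false(m$terms[["depth"]])
  rec1 <- gen_intensity(n_timepoints = 1, ar1_rho = 0, noise_sd = 1,
                        planes = 1:4, seed = 5) |>
    subtract_background() |> embryo_scaling()
  expect_warning(m1 <- fit_confounders(rec1), "bleaching term dropped")
  expect_true(is.na(m1$bleach_coef))
})

test_that("AR(1) cell means reduce to per-cell means when rho = 0", {
  rec <- gen_intensity(ar1_rho = 0, noise_sd = 3, n_timepoints = 30, seed = 6)
  corr <- correct_intensity(rec)
  cm <- cell_means_ar1(corr)
  plain <- tapply(corr$i_corr, corr$cell, mean)
  expect_equal(cm$means$estimate, as.numeric(plain[cm$means$cell]),
               tolerance = 0.02)
  expect_lt(abs(cm$rho), 0.2)
})

test_that("AR(1) correlation is recovered from correlated series", {
  rec <- gen_intensity(ar1_rho = 0.6, noise_sd = 4, n_timepoints = 60,
                       seed = 7)
  cm <- cell_means_ar1(correct_intensity(rec))
  expect_gt(cm$rho, 0.45)
  expect_lt(cm$rho, 0.75)
})

test_that("cell contrasts are antisymmetric and detect injected differences", {
  rec <- gen_intensity(seed = 8)
  cm <- cell_means_ar1(correct_intensity(rec))
  ab <- contrast_cells(cm, c("E", "MS"))
  ba <- contrast_cells(cm, c("MS", "E"))
  expect_equal(ab$estimate, -ba$estimate)
  expect_equal(ab$p_value, ba$p_value)
  expect_lt(ab$estimate, 0)            # E is generated dimmer than MS
  expect_lt(ab$p_value, 0.001)
})

test_that("cell means are invariant to embryo relabelling and to a constant
           recorded background shift", {
  rec <- gen_intensity(seed = 9)
  cm1 <- cell_means_ar1(correct_intensity(rec))
  relab <- dplyr::mutate(rec, embryo_id = paste0("embryo_", embryo_id))
  cm2 <- cell_means_ar1(correct_intensity(relab))
  expect_equal(cm2$means$estimate, cm1$means$estimate, tolerance = 1e-8)
  shifted <- dplyr::mutate(rec, raw = raw + 50, background = background + 50)
  cm3 <- cell_means_ar1(correct_intensity(shifted))
  expect_equal(cm3$means$estimate, cm1$means$estimate, tolerance = 1e-8)
})

test_that("quadratic fits are exact on a parabola and flat on constants", {
  t <- seq(0, 10, 0.5)
  rec <- tibble::tibble(embryo_id = "e1", cell = "E", t = t, z = 1,
                        i_corr = 2 + 0.3 * t - 0.05 * t^2)
  q <- suppressWarnings(quadratic_time_fit(rec, "E"))
  expect_equal(unname(q$coefficients), c(2, 0.3, -0.05), tolerance = 1e-6)

  rec0 <- dplyr::mutate(rec, i_corr = 1)
  q0 <- suppressWarnings(quadratic_time_fit(rec0, "E"))
  expect_equal(unname(q0$coefficients[2:3]), c(0, 0), tolerance = 1e-8)
  expect_equal(nrow(q0$band), 50)
})

test_that("quadratic coefficient recovery under AR(1) noise is calibrated", {
  hits <- purrr::map_lgl(1:20, function(i) {
    withr::with_seed(500 + i, {
      t <- rep(seq(0, 10, 0.5), 3)
      emb <- rep(c("e1", "e2", "e3"), each = 21)
      mu <- 1 + 0.05 * t - 0.008 * t^2
      noise <- as.vector(replicate(3, {
        e <- numeric(21)
        e[1] <- rnorm(1, 0, 0.05)
        for (j in 2:21) e[j] <- 0.5 * e[j - 1] + rnorm(1, 0, 0.05 * sqrt(0.75))
        e
      }))
      rec <- tibble::tibble(embryo_id = emb, cell = "E", t = t, z = 1,
                            i_corr = mu + noise)
      q <- quadratic_time_fit(rec, "E")
      abs(q$coefficients[["c"]] - (-0.008)) < 2 * sqrt(diag(q$vcov))[3]
    })
  })
  expect_gte(mean(hits), 0.8)
})

test_that("surface samples are standardized per embryo before fitting", {
  samples <- gen_surface_samples(n_embryos = 3, seed = 10)
  surf <- spatiotemporal_surface(samples)
  std <- surf$samples |>
    dplyr::group_by(embryo_id) |>
    dplyr::summarise(m = mean(value_std), s = sd(value_std))
  expect_equal(std$m, rep(0, 3), tolerance = 1e-12)
  expect_equal(std$s, rep(1, 3), tolerance = 1e-12)
})

test_that("the tensor-spline surface recovers a known smooth field", {
  field <- function(p, t) -tanh(p / 5) * (1 + t / 200)
  samples <- gen_surface_samples(n_embryos = 4, n_per_embryo = 400,
                                 field = field, noise_sd = 0.1, seed = 11)
  surf <- spatiotemporal_surface(samples)
  # compare to the per-embryo standardized truth on the grid: standardization
  # maps the field through the same affine transform per embryo, so pooled
  # standardized truth is field scaled by its own sd
  truth <- field(surf$grid$position, surf$grid$time)
  truth_std <- (truth - mean(truth)) / sd(truth)
  rmse <- sqrt(mean((surf$grid$value - truth_std)^2))
  expect_lt(rmse, 0.1)
  expect_gt(nrow(surf$contours), 0)
  expect_s3_class(ggplot2::autoplot(surf), "ggplot")
})

test_that("constant-per-embryo input gives a flat surface and exclusions warn", {
  samples <- gen_surface_samples(n_embryos = 4, noise_sd = 0.05, seed = 12)
  flat <- dplyr::mutate(samples,
                        value = ifelse(embryo_id == "e1", 3, value))
  expect_warning(surf <- spatiotemporal_surface(flat), "degenerate")
  expect_false("e1" %in% surf$samples$embryo_id)

  all_flat <- dplyr::mutate(samples, value = as.numeric(factor(embryo_id)))
  expect_error(suppressWarnings(spatiotemporal_surface(all_flat)),
               ">= 3 embryos")
})

test_that("the natural-spline interface profile is exact for linear signal", {
  samples <- tibble::tibble(position = seq(0, 1, length.out = 25),
                            value = 2 - 1.5 * seq(0, 1, length.out = 25))
  prof <- interface_profile(samples)
  expect_equal(prof$fit, 2 - 1.5 * prof$position, tolerance = 1e-9)
  expect_error(interface_profile(samples[1:8, ]), ">= 10 samples")
})

test_that("a step-like interface asymmetry yields a monotone fitted profile", {
  withr::with_seed(13, {
    pos <- runif(200, 0, 1)
    val <- ifelse(pos < 0.5, 1, 0.3) + rnorm(200, 0, 0.05)
  })
  prof <- interface_profile(tibble::tibble(position = pos, value = val))
  mid <- prof$position > 0.25 & prof$position < 0.75
  expect_true(all(diff(prof$fit[mid]) < 0))
})

test_that("range scaling maps each embryo's values onto [0, 1]", {
  s <- tibble::tibble(embryo_id = rep(c("a", "b"), each = 4),
                      value = c(1, 3, 5, 7, 10, 20, 30, 40))
  out <- range_scale(s)
  rng <- out |> dplyr::group_by(embryo_id) |>
    dplyr::summarise(lo = min(value_scaled), hi = max(value_scaled))
  expect_equal(rng$lo, c(0, 0))
  expect_equal(rng$hi, c(1, 1))
})

test_that("the mixed two-way interface ANOVA tests side, treatment and their
           interaction with embryo as the repeated-measures unit", {
  withr::with_seed(14, {
    emb <- sprintf("e%02d", 1:10)
    treatment <- rep(c("wt", "rnai"), each = 5)
    dat <- purrr::map_dfr(1:10, function(i) {
      base <- rnorm(1, 5, 0.5)
      asym <- if (treatment[i] == "wt") 2 else 0.2
      tibble::tibble(
        embryo_id = emb[i], treatment = treatment[i],
        side = rep(c("anterior", "posterior"), each = 6),
        value = base + rep(c(asym, 0), each = 6) + rnorm(12, 0, 0.2)
      )
    })
  })
  res <- interface_asymmetry_test(dat)
  expect_setequal(res$table$effect,
                  c("treatment", "side", "treatment:side"))
  p_int <- res$table$p[res$table$effect == "treatment:side"]
  expect_lt(p_int, 0.01)

  # an embryo missing one side is excluded with a warning
  broken <- dplyr::filter(dat, !(embryo_id == "e01" & side == "posterior"))
  expect_warning(interface_asymmetry_test(broken), "e01")
})
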