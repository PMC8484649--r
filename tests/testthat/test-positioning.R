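test_that("time alignment returns the last full eight-cell timepoint", {
  series <- gen_embryo_series(n_frames = 20, dividing_cell = "ABar",
                              division_frame = 12, seed = 1)
  snap <- time_align(series)
  expect_equal(unique(snap$timepoint), 11)
  expect_setequal(snap$cell, reference_layout()$cell)

  # a series that ends while still at the eight-cell stage returns its end
  early <- dplyr::filter(series, timepoint <= 5)
  expect_equal(unique(time_align(early)$timepoint), 5)

  # a named cell absent throughout is an error
  no_abpl <- dplyr::filter(series, cell != "ABpl")
  expect_error(time_align(no_abpl), "ABpl",
               class = "cortexdyn_validation_error")
})

test_that("procrustes on identical snapshots is the identity", {
  s <- reference_layout()
  p <- procrustes(s, s)
  expect_equal(p$scale, 1, tolerance = 1e-12)
  expect_equal(p$rotation, diag(3), tolerance = 1e-12)
  expect_equal(p$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(p$rmsd, 0, tolerance = 1e-12)
})

test_that("procrustes recovers a constructed similarity transform to 1e-9", {
  s <- reference_layout()
  tgt <- transform_snapshot(s, s = 1.37, angle = 0.8, axis = 2,
                            translation = c(4, -7, 2))
  tf <- attr(tgt, "transform")
  p <- procrustes(s, tgt)
  expect_equal(p$scale, tf$scale, tolerance = 1e-9)
  expect_equal(p$rotation, tf$rotation, tolerance = 1e-9)
  expect_equal(p$translation, tf$translation, tolerance = 1e-9)
  expect_lt(p$rmsd, 1e-9)
})

test_that("reflections are disallowed: mirrored targets keep residuals", {
  s <- reference_layout()
  mirrored <- dplyr::mutate(s, x = -x)
  p <- procrustes(s, mirrored)
  expect_equal(det(p$rotation), 1, tolerance = 1e-9)
  expect_gt(p$rmsd, 0.5)
})

test_that("procrustes residuals are equivariant under source transforms", {
  s <- reference_layout()
  withr::with_seed(3, {
    tgt <- dplyr::mutate(s, x = x + rnorm(8, 0, 0.5), y = y + rnorm(8, 0, 0.5),
                         z = z + rnorm(8, 0, 0.5))
  })
  r1 <- procrustes(s, tgt)$rmsd
  moved <- transform_snapshot(s, s = 0.7, angle = 1.1, axis = 1,
                              translation = c(10, 3, -6))
  r2 <- procrustes(moved, tgt)$rmsd
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("procrustes agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  s <- reference_layout()
  withr::with_seed(4, {
    tgt <- dplyr::mutate(s, x = x + rnorm(8, 0, 1), y = y + rnorm(8, 0, 1),
                         z = z + rnorm(8, 0, 1))
  })
  mine <- procrustes(s, tgt)
  ref <- vegan::procrustes(as.matrix(tgt[, c("x", "y", "z")]),
                           as.matrix(s[, c("x", "y", "z")]))
  # vegan may choose a reflection; here the optimum is a proper rotation
  expect_equal(det(ref$rotation), 1, tolerance = 1e-8)
  aligned_mine <- as.matrix(mine$aligned[, c("x", "y", "z")])
  expect_equal(unname(aligned_mine), unname(predict(ref)), tolerance = 1e-8)
})

test_that("degenerate snapshots are rejected", {
  s <- reference_layout()
  expect_error(procrustes(s[1:3, ], s[1:3, ]), ">= 4")
  flat <- dplyr::mutate(s, z = 0)
  expect_error(procrustes(flat, flat), "coplanar",
               class = "cortexdyn_validation_error")
  renamed <- dplyr::mutate(s, cell = paste0("X", cell))
  expect_error(procrustes(renamed, s), ">= 4")
})

test_that("GPA of identical snapshots returns them up to normalization", {
  s <- reference_layout()
  ref <- gpa_reference(list(s, s, s))
  m <- as.matrix(ref[, c("x", "y", "z")])
  expect_equal(sqrt(sum(m^2)), 1, tolerance = 1e-9)   # unit centroid size
  so <- s[match(ref$cell, s$cell), ]        # reference rows are name-sorted
  sm <- as.matrix(so[, c("x", "y", "z")])
  sm <- sweep(sm, 2, colMeans(sm)); sm <- sm / sqrt(sum(sm^2))
  expect_equal(m, sm, tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(attr(ref, "converged"))
})

test_that("GPA reference is invariant to input order", {
  withr::with_seed(5, {
    snaps <- lapply(1:5, function(i) {
      s <- reference_layout()
      transform_snapshot(
        dplyr::mutate(s, x = x + rnorm(8, 0, 0.4), y = y + rnorm(8, 0, 0.4),
                      z = z + rnorm(8, 0, 0.4)),
        s = runif(1, 0.8, 1.2), angle = runif(1, 0, 2 * pi), axis = 3,
        translation = runif(3, -10, 10)
      )
    })
  })
  r1 <- gpa_reference(snaps)
  r2 <- gpa_reference(rev(snaps))
  # compare shapes after aligning one onto the other (frames may differ)
  expect_lt(procrustes(r2, r1)$rmsd, 1e-6)
})

test_that("GPA of similarity-transformed copies recovers the shape", {
  s <- reference_layout()
  snaps <- list(transform_snapshot(s, 1.2, 0.5, 3, c(3, 1, -2)),
                transform_snapshot(s, 0.8, -1.1, 1, c(-5, 2, 9)))
  ref <- gpa_reference(snaps)
  expect_lt(procrustes(s, ref)$rmsd, 1e-8)
})

test_that("GPA is a fixed point of align-and-average", {
  withr::with_seed(6, {
    snaps <- lapply(1:4, function(i) {
      s <- reference_layout()
      dplyr::mutate(s, x = x + rnorm(8, 0, 0.5), y = y + rnorm(8, 0, 0.5),
                    z = z + rnorm(8, 0, 0.5))
    })
  })
  ref <- gpa_reference(snaps)
  cells <- ref$cell
  aligned <- lapply(snaps, function(s) {
    m <- procrustes(s, ref)$aligned
    as.matrix(m[match(cells, m$cell), c("x", "y", "z")])
  })
  remean <- Reduce(`+`, aligned) / length(aligned)
  remean <- sweep(remean, 2, colMeans(remean))
  remean <- remean / sqrt(sum(remean^2))
  expect_equal(remean, as.matrix(ref[, c("x", "y", "z")]),
               tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("displacements vanish for the reference itself and sum to zero", {
  s <- reference_layout()
  withr::with_seed(7, {
    other <- dplyr::mutate(s, x = x + rnorm(8, 0, 1))
  })
  d_self <- axis_displacements(list(s), s)
  expect_equal(max(abs(d_self$displacement)), 0, tolerance = 1e-9)
  d <- axis_displacements(list(other), s)
  sums <- as.numeric(tapply(d$displacement, d$coord, sum))
  expect_equal(sums, c(0, 0, 0), tolerance = 1e-8)
})

test_that("an injected cell shift is recovered along the right axis", {
  emb <- gen_embryos(n_wt = 8, n_rnai = 6, jitter_sd = 0.2,
                     shift = list(cell = "ABpl", delta = c(3, 0, 0)),
                     seed = 8)
  snaps <- split(emb[, c("cell", "x", "y", "z")], emb$embryo_id)
  groups <- vapply(split(emb$group, emb$embryo_id), dplyr::first, character(1))
  ref <- gpa_reference(unname(snaps[groups == "wt"]),
                       orient_to = reference_layout(), size = "mean")
  expect_equal(attr(ref, "axes_meta"), c(x = "AP", y = "DV", z = "LR"))
  disp <- axis_displacements(snaps, ref)
  disp$group <- groups[disp$embryo_id]
  ap <- dplyr::filter(disp, cell == "ABpl", axis == "AP")
  diff_means <- mean(ap$displacement[ap$group == "rnai"]) -
    mean(ap$displacement[ap$group == "wt"])
  # Procrustes absorbs part of a single-cell shift; most of it must remain
  expect_gt(diff_means, 0.55 * 3)
  expect_lt(diff_means, 3.05)
})

test_that("the rank-sum displacement test matches exact enumeration", {
  res <- displacement_test(c(-1, 0, 1), c(9, 10, 11))
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  same <- displacement_test(c(-1, 0, 1), c(-1, 0, 1))
  expect_gt(same$p_value, 0.99)
  expect_error(displacement_test(c(1, 2), c(1, 2, 3)), ">= 3")
})

test_that("displacement_screen covers all cells and axes with optional BH", {
  emb <- gen_embryos(n_wt = 4, n_rnai = 3, jitter_sd = 0.3, seed = 9)
  snaps <- split(emb[, c("cell", "x", "y", "z")], emb$embryo_id)
  groups <- vapply(split(emb$group, emb$embryo_id), dplyr::first, character(1))
  ref <- gpa_reference(unname(snaps[groups == "wt"]),
                       orient_to = reference_layout())
  disp <- axis_displacements(snaps, ref)
  disp$group <- groups[disp$embryo_id]
  wt <- dplyr::filter(disp, group == "wt")
  rn <- dplyr::filter(disp, group == "rnai")
  out <- displacement_screen(wt, rn, adjust = TRUE)
  expect_equal(nrow(out), 8 * 3)
  expect_true(all(out$p_adj >= out$p_value))
})
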