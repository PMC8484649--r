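test_that("track velocities are forward differences at interval midpoints", {
  tr <- tibble::tibble(track_id = "a", t = c(0, 1, 2), x = c(0, 1, 3),
                       y = c(0, 0, 0))
  v <- track_velocities(tr)
  expect_equal(v$vx, c(1, 2))
  expect_equal(v$vy, c(0, 0))
  expect_equal(v$t_mid, c(0.5, 1.5))

  still <- tibble::tibble(track_id = "s", t = 0:4, x = 2, y = -1)
  vs <- track_velocities(still)
  expect_true(all(vs$vx == 0 & vs$vy == 0))
})

test_that("single-point tracks are skipped with a warning", {
  tr <- tibble::tibble(track_id = c("a", "a", "b"), t = c(0, 1, 0),
                       x = 0, y = 0)
  expect_warning(v <- track_velocities(tr), "single-point")
  expect_equal(unique(v$track_id), "a")
})

test_that("velocities of noiseless recoil markers match the model derivative", {
  v0 <- 1.4; tau <- 2.2
  ex <- gen_recoil(v0_true = v0, tau_true = tau, noise_sd = 0, n_markers = 4,
                   seed = 1)
  vel <- track_velocities(dplyr::filter(ex$tracks, role == "recoil"))
  nhat_speed <- abs(vel$vy)
  # interval-mean velocity has a closed form; midpoint evaluation is close
  exact <- v0 * tau * (exp(-vel$t0 / tau) - exp(-vel$t1 / tau)) / (vel$t1 - vel$t0)
  expect_equal(nhat_speed, exact, tolerance = 1e-9)
  midpoint <- v0 * exp(-vel$t_mid / tau)
  expect_equal(nhat_speed, midpoint, tolerance = 0.05)
})

test_that("mean_flow averages per timestep and opposite flows cancel", {
  tr <- dplyr::bind_rows(
    tibble::tibble(track_id = "f1", t = 0:3, x = 0.2 * (0:3), y = 0),
    tibble::tibble(track_id = "f2", t = 0:3, x = -0.2 * (0:3), y = 0)
  )
  mf <- mean_flow(track_velocities(tr))
  expect_equal(mf$flow_vx, rep(0, 3))
  expect_equal(mf$n, rep(2L, 3))

  single <- track_velocities(tr[tr$track_id == "f1", ])
  mf1 <- mean_flow(single)
  expect_equal(mf1$flow_vx, single$vx)

  expect_error(mean_flow(track_velocities(tr)[0, ]), "disable flow correction",
               class = "cortexdyn_flow_error")
})

test_that("flow correction removes an injected uniform flow exactly", {
  base <- gen_recoil(v0_true = 1, tau_true = 2, noise_sd = 0, n_markers = 8,
                     seed = 3)
  flow <- gen_recoil(v0_true = 1, tau_true = 2, noise_sd = 0, n_markers = 8,
                     flow = c(0.1, -0.05), seed = 3)
  s0 <- orthogonal_samples(base)
  s1 <- orthogonal_samples(flow)                       # auto flow-corrected
  expect_equal(s1$v_perp, s0$v_perp, tolerance = 1e-9)
  # without correction the fields differ
  s2 <- orthogonal_samples(flow, flow_correct = FALSE)
  expect_gt(max(abs(s2$v_perp - s0$v_perp)), 0.01)
})

test_that("flow correction is idempotent once residual mean flow is zero", {
  vel <- tibble::tibble(track_id = "a", t0 = 0:2, t1 = 1:3, t_mid = 0:2 + 0.5,
                        x_mid = 0, vx = c(1, 2, 3), vy = c(0.5, 0.5, 0.5))
  mf <- tibble::tibble(t_mid = 0:2 + 0.5, flow_vx = c(1, 1, 1),
                       flow_vy = c(0, 0, 0))
  once <- correct_flow(vel, mf)
  zero_flow <- dplyr::mutate(mf, flow_vx = 0, flow_vy = 0)
  twice <- correct_flow(once, zero_flow)
  expect_equal(twice, once)
  # zero flow leaves the table unchanged
  expect_equal(correct_flow(vel, zero_flow), vel)
})

test_that("orthogonal samples follow the outward-positive sign convention", {
  # cut along x; marker at +1 um moving +y and mirror at -1 um moving -y
  s <- 0.3
  tracks <- dplyr::bind_rows(
    tibble::tibble(track_id = "p", channel = "factin", role = "recoil",
                   t = 0:3, x = 0, y = 1 + s * (0:3)),
    tibble::tibble(track_id = "m", channel = "factin", role = "recoil",
                   t = 0:3, x = 0, y = -1 - s * (0:3)),
    tibble::tibble(track_id = "par", channel = "factin", role = "recoil",
                   t = 0:3, x = 0.5 * (0:3), y = 2)
  )
  ex <- ablation_experiment(tracks, cut_line(), "e1", "emb1", "E")
  samp <- orthogonal_samples(ex)
  expect_equal(samp$v_perp[samp$track_id == "p"], rep(s, 3))
  expect_equal(samp$v_perp[samp$track_id == "m"], rep(s, 3))
  # motion parallel to the cut projects to zero
  expect_equal(samp$v_perp[samp$track_id == "par"], rep(0, 3))
})

test_that("markers outside the 2.5 um band are excluded", {
  tracks <- dplyr::bind_rows(
    tibble::tibble(track_id = "in", channel = "factin", role = "recoil",
                   t = 0:3, x = 0, y = 2.0 + 0.1 * (0:3)),
    tibble::tibble(track_id = "out", channel = "factin", role = "recoil",
                   t = 0:3, x = 0, y = 3.0 + 0.1 * (0:3))
  )
  ex <- ablation_experiment(tracks, cut_line(), "e1", "emb1", "E")
  samp <- orthogonal_samples(ex)
  expect_setequal(unique(samp$track_id), "in")
})

test_that("samples respect the closed fitting window and the cut time", {
  tracks <- tibble::tibble(track_id = "a", channel = "factin", role = "recoil",
                           t = 10 + 0:8, x = 0, y = 1 + 0.1 * (0:8))
  ex <- ablation_experiment(tracks, cut_line(t_cut = 10), "e1", "emb1", "E",
                            fit_window = 6)
  samp <- orthogonal_samples(ex)
  expect_true(all(samp$t >= 0 & samp$t <= 6))
  expect_equal(max(samp$t), 5.5)
})

test_that("mirror symmetry: reflecting all markers preserves v_perp", {
  ex <- gen_recoil(v0_true = 1, tau_true = 2, noise_sd = 0.05, n_markers = 10,
                   seed = 8)
  s1 <- orthogonal_samples(ex)
  flipped <- ex
  flipped$tracks <- dplyr::mutate(ex$tracks, y = -y)
  s2 <- orthogonal_samples(flipped)
  expect_equal(s2$v_perp, s1$v_perp, tolerance = 1e-12)
})

test_that("projection commutes with flow correction", {
  ex <- gen_recoil(v0_true = 1, tau_true = 2, noise_sd = 0.02, n_markers = 6,
                   flow = c(0.08, -0.04), seed = 12)
  # correct-then-project (the implementation)
  a <- orthogonal_samples(ex, flow_correct = TRUE)
  # project-then-correct: project raw velocities, subtract projected mean flow
  cl <- ex$cutline
  nhat <- c(-cl$direction[2], cl$direction[1])
  raw <- orthogonal_samples(ex, flow_correct = FALSE)
  fl <- mean_flow(track_velocities(dplyr::filter(ex$tracks, role == "flow")))
  flow_perp <- fl$flow_vx * nhat[1] + fl$flow_vy * nhat[2]
  side_sign <- ifelse(raw$side == "plus", 1, -1)
  b <- raw$v_perp - side_sign * flow_perp[match(raw$t, fl$t_mid - cl$t_cut)]
  expect_equal(a$v_perp, b, tolerance = 1e-9)
})

test_that("flow_field bins uniform flow exactly and flags empty bins", {
  tr <- purrr::map_dfr(1:5, function(i) {
    tibble::tibble(track_id = paste0("t", i), t = 0:6,
                   x = i + 0.2 * (0:6), y = 0.1 * (0:6))
  })
  ff <- flow_field(tr, x_breaks = c(0, 3, 6, 9), t_breaks = c(0, 2, 4, 6))
  filled <- dplyr::filter(ff, !empty)
  expect_equal(filled$vx, rep(0.2, nrow(filled)), tolerance = 1e-12)
  expect_equal(filled$vy, rep(0.1, nrow(filled)), tolerance = 1e-12)
  expect_true(any(ff$empty))
  expect_true(all(is.na(ff$vx[ff$empty])))
  expect_equal(nrow(ff), 9)
})

test_that("lifetime ANOVA reproduces hand-computed sums of squares", {
  lt <- tibble::tibble(region = rep(c("A", "B"), each = 3),
                       lifetime = c(1, 2, 3, 4, 5, 6))
  # hand arithmetic: group means 2 and 5, SSB = 3*1.5^2 * 2 = 13.5,
  # SSW = 2 + 2 = 4 on 4 df so MSW = 1, F = 13.5; equivalently the pooled
  # two-sample t is 3 / sqrt(2/3) and F = t^2 = 13.5
  res <- lifetime_anova(lt)
  expect_equal(res$f, 13.5, tolerance = 1e-12)
  expect_equal(res$f,
               unname(stats::t.test(lifetime ~ region, data = lt,
                                    var.equal = TRUE)$statistic)^2,
               tolerance = 1e-12)
  expect_equal(res$p, 1 - pf(13.5, 1, 4), tolerance = 1e-12)
  expect_equal(res$means$mean, c(2, 5))

  same <- tibble::tibble(region = rep(c("A", "B"), each = 3),
                         lifetime = rep(c(1, 2, 3), 2))
  res0 <- lifetime_anova(same)
  expect_equal(res0$f, 0)
  expect_equal(res0$p, 1)
})

test_that("track lifetimes equal span plus one frame", {
  tr <- tibble::tibble(track_id = rep(c("a", "b"), c(3, 1)),
                       t = c(0, 1, 2, 5))
  lt <- track_lifetimes(tr, frame_dt = 1)
  expect_equal(lt$lifetime[lt$track_id == "a"], 3)
  expect_equal(lt$lifetime[lt$track_id == "b"], 1)
})
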