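# shared fixtures built in code

# pointwise velocity samples from the exact exponential decay
exact_samples <- function(v0, tau, t = seq(0.5, 5.5, by = 1)) {
  tibble::tibble(t = t, v_perp = v0 * exp(-t / tau))
}

# a minimal hand-built experiment: two markers mirrored across a cut along x
tiny_experiment <- function(v = 0.5, n_frames = 5, cell = "E",
                            experiment_id = "tiny1") {
  t <- seq(0, n_frames - 1)
  tracks <- dplyr::bind_rows(
    tibble::tibble(track_id = "m1", channel = "factin", role = "recoil",
                   t = t, x = 0, y = 1 + v * t),
    tibble::tibble(track_id = "m2", channel = "factin", role = "recoil",
                   t = t, x = 0, y = -1 - v * t)
  )
  ablation_experiment(tracks, cut_line(c(0, 0), c(1, 0)), experiment_id,
                      "emb1", cell)
}

# a snapshot under a known similarity transform
transform_snapshot <- function(snap, s = 1, angle = 0, axis = 3,
                               translation = c(0, 0, 0)) {
  m <- as.matrix(snap[, c("x", "y", "z")])
  cth <- cos(angle); sth <- sin(angle)
  r <- diag(3)
  ij <- setdiff(1:3, axis)
  r[ij[1], ij[1]] <- cth; r[ij[1], ij[2]] <- -sth
  r[ij[2], ij[1]] <- sth; r[ij[2], ij[2]] <- cth
  m2 <- s * m %*% t(r) + matrix(translation, nrow(m), 3, byrow = TRUE)
  out <- tibble::tibble(cell = snap$cell, x = m2[, 1], y = m2[, 2], z = m2[, 3])
  attr(out, "axes_meta") <- attr(snap, "axes_meta")
  attr(out, "transform") <- list(scale = s, rotation = r,
                                 translation = translation)
  out
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
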