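#' Simulate a laser-ablation recoil experiment
#'
#' Generates manually-annotated-style marker tracks for a single cortical
#' ablation, inverting the viscoelastic recoil model: the orthogonal
#' displacement of a marker on either side of the cut follows the integral of
#' `v0_true * exp(-t / tau_true)`, i.e. `v0_true * tau_true * (1 - exp(-t /
#' tau_true))`, outward-positive on both sides. An optional uniform cortical
#' flow advects all markers; tracking error is iid Gaussian positional jitter
#' per frame. When `flow` is nonzero, additional flow-role reference tracks are
#' placed outside the analysis band, mirroring how flow was annotated at a
#' distance from the cut.
#'
#' @param v0_true Initial outward recoil speed, um/s.
#' @param tau_true Relaxation time, s.
#' @param noise_sd Positional tracking noise SD per frame, um.
#' @param n_markers Number of recoil markers (split over the two sides).
#' @param frame_dt Frame interval, s (imaging at roughly one frame per second).
#' @param duration Length of the recorded recoil movie, s.
#' @param flow Optional uniform flow velocity `c(vx, vy)` um/s.
#' @param n_flow_markers Number of flow-role tracks when `flow` is nonzero.
#' @param band_halfwidth,fit_window Analysis settings carried into the
#'   experiment (markers are seeded inside the band).
#' @param cut_length Cut length, um.
#' @param experiment_id,embryo_id,cell Identifiers for the simulated experiment.
#' @param seed Optional RNG seed; the generator is deterministic given it.
#' @return An [ablation_experiment()] whose `truth` attribute records every
#'   generating parameter.
#' @examples
#' exp <- gen_recoil(v0_true = 1.2, tau_true = 2, noise_sd = 0, seed = 1)
#' fit_recoil(orthogonal_samples(exp))
#' @export
gen_recoil <- function(v0_true = 1.0, tau_true = 2.0, noise_sd = 0.05,
                       n_markers = 20, frame_dt = 1.0, duration = 7,
                       flow = NULL, n_flow_markers = 5,
                       band_halfwidth = 2.5, fit_window = 6, cut_length = 4,
                       experiment_id = "sim1", embryo_id = "embryo1",
                       cell = "E", seed = NULL) {
  if (v0_true < 0) abort("`v0_true` must be >= 0")
  if (tau_true <= 0) abort("`tau_true` must be > 0")
  if (frame_dt <= 0) abort("`frame_dt` must be > 0")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (n_markers < 1) abort("need at least one marker")
  flow <- if (is.null(flow)) c(0, 0) else as.numeric(flow)
  has_flow <- any(flow != 0)

  with_seed(seed, {
    times <- seq(0, duration, by = frame_dt)
    nt <- length(times)
    disp <- v0_true * tau_true * (1 - exp(-times / tau_true))

    side <- rep(c(1, -1), length.out = n_markers)
    d0 <- runif(n_markers, 0.25, 0.95 * band_halfwidth)
    x0 <- runif(n_markers, -cut_length / 2, cut_length / 2)

    recoil <- purrr::map_dfr(seq_len(n_markers), function(i) {
      tibble(
        track_id = sprintf("r%02d", i),
        channel = if (i %% 2 == 0) "nmy2" else "factin",
        role = "recoil",
        t = times,
        x = x0[i] + flow[1] * times + rnorm(nt, 0, noise_sd),
        y = side[i] * (d0[i] + disp) + flow[2] * times + rnorm(nt, 0, noise_sd)
      )
    })

    tracks <- recoil
    if (has_flow) {
      fside <- rep(c(1, -1), length.out = n_flow_markers)
      fd0 <- runif(n_flow_markers, band_halfwidth + 1.5, band_halfwidth + 3.5)
      fx0 <- runif(n_flow_markers, -cut_length, cut_length)
      flow_tracks <- purrr::map_dfr(seq_len(n_flow_markers), function(i) {
        tibble(
          track_id = sprintf("f%02d", i),
          channel = "factin",
          role = "flow",
          t = times,
          x = fx0[i] + flow[1] * times + rnorm(nt, 0, noise_sd),
          y = fside[i] * fd0[i] + flow[2] * times + rnorm(nt, 0, noise_sd)
        )
      })
      tracks <- bind_rows(tracks, flow_tracks)
    }

    exp <- ablation_experiment(
      tracks, cut_line(c(0, 0), c(1, 0), cut_length, t_cut = 0),
      experiment_id = experiment_id, embryo_id = embryo_id, cell = cell,
      band_halfwidth = band_halfwidth, fit_window = fit_window
    )
    attr(exp, "truth") <- list(
      v0_true = v0_true, tau_true = tau_true, noise_sd = noise_sd,
      n_markers = n_markers, frame_dt = frame_dt, duration = duration,
      flow = flow, seed = seed
    )
    exp
  })
}

# first-order autoregressive noise with marginal SD sigma, stationary start
ar1_noise <- function(n, rho, sigma) {
  if (sigma == 0 || n == 0) return(numeric(n))
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sigma)
  if (n > 1) {
    innov <- rnorm(n - 1, 0, sigma * sqrt(1 - rho^2))
    for (i in 2:n) e[i] <- rho * e[i - 1] + innov[i - 1]
  }
  e
}

#' Simulate cortical intensity records
#'
#' Generates per-(embryo, cell, plane) cortical fluorescence time series with
#' the confounders the correction cascade removes: multiplicative embryo
#' effects, linear-in-time bleaching, depth-dependent attenuation across
#' z-planes, an additive background, and AR(1)-correlated measurement noise
#' within each time series. The generating model is
#' `raw = cell_effect * embryo_effect * (1 - bleach_rate * t) * depth_fn(z) +
#' background + AR1(rho, sd)`, clipped at zero.
#'
#' @param cell_effects Named numeric vector of per-cell cortical signal levels
#'   (a.u.). Defaults to an eight-cell-stage pattern with a dim E cell and
#'   bright MS, mirroring the asymmetry the pipeline is designed to detect.
#' @param embryo_effects Named numeric vector of multiplicative embryo factors.
#' @param bleach_rate Fractional signal loss per minute of imaging (linear
#'   bleaching); `bleach_rate * max(t)` must stay below 1.
#' @param depth_fn Function of plane index z giving the depth attenuation
#'   factor; default exponential decay over ~10 planes.
#' @param ar1_rho AR(1) correlation of the noise within a series, in [0, 1).
#' @param noise_sd Marginal SD of the AR(1) noise, a.u.
#' @param background_mean Additive background level recorded in the
#'   `background` column, a.u.
#' @param n_timepoints Number of timepoints per series.
#' @param dt_min Time step between records, minutes.
#' @param planes Integer vector of z-plane indices (must be >= 1).
#' @param seed Optional RNG seed.
#' @return Tibble with columns `embryo_id`, `cell`, `t` (minutes), `z`, `raw`,
#'   `background`; the `truth` attribute stores every generating parameter.
#' @export
gen_intensity <- function(cell_effects = c(E = 60, MS = 100, ABpl = 95, ABpr = 95),
                          embryo_effects = c(e1 = 0.8, e2 = 1.0, e3 = 1.1, e4 = 1.3),
                          bleach_rate = 0.01, depth_fn = function(z) exp(-(z - 1) / 10),
                          ar1_rho = 0.6, noise_sd = 4, background_mean = 20,
                          n_timepoints = 40, dt_min = 0.5, planes = 1:3,
                          seed = NULL) {
  if (ar1_rho < 0 || ar1_rho >= 1) abort("`ar1_rho` must be in [0, 1)")
  if (any(cell_effects <= 0) || any(embryo_effects <= 0))
    abort("cell and embryo effects must be positive")
  if (any(planes < 1)) abort("plane indices must be >= 1 (log z must exist)")
  times <- seq(0, by = dt_min, length.out = n_timepoints)
  if (any(1 - bleach_rate * times < 0))
    abort("`bleach_rate` drives the mean signal negative within the movie")

  with_seed(seed, {
    grid <- tidyr::expand_grid(
      embryo_id = names(embryo_effects),
      cell = names(cell_effects),
      z = planes
    )
    out <- purrr::pmap_dfr(grid, function(embryo_id, cell, z) {
      mu <- cell_effects[[cell]] * embryo_effects[[embryo_id]] *
        (1 - bleach_rate * times) * depth_fn(z)
      tibble(
        embryo_id = embryo_id, cell = cell, t = times, z = z,
        raw = pmax(0, mu + background_mean + ar1_noise(length(times), ar1_rho, noise_sd)),
        background = background_mean
      )
    })
    attr(out, "truth") <- list(
      cell_effects = cell_effects, embryo_effects = embryo_effects,
      bleach_rate = bleach_rate, depth_fn = depth_fn, ar1_rho = ar1_rho,
      noise_sd = noise_sd, background_mean = background_mean,
      dt_min = dt_min, planes = planes, seed = seed
    )
    out
  })
}

#' Built-in eight-cell reference layout
#'
#' A fixed synthetic arrangement of the eight early blastomeres as two rings of
#' four nuclei (the four AB granddaughters anterior, MS/E/C/P3 posterior),
#' spanning roughly embryo scale in micrometres. The layout is deliberately
#' schematic: positioning methods are geometry-agnostic, so no attempt is made
#' to copy real embryo geometry.
#'
#' @return Snapshot tibble (`cell`, `x`, `y`, `z`) with an `axes_meta`
#'   attribute mapping x/y/z to AP/DV/LR.
#' @export
reference_layout <- function() {
  snap <- tibble(
    cell = c("ABal", "ABar", "ABpl", "ABpr", "MS", "E", "C", "P3"),
    x = c(-6, -6, -6, -6, 6, 6, 6, 6),
    y = c(5, 0, -5, 0, 5, 0, -5, 0),
    z = c(0, 5, 0, -5, 0, 5, 0, -5)
  )
  attr(snap, "axes_meta") <- c(x = "AP", y = "DV", z = "LR")
  snap
}

random_rotation <- function() {
  # uniform-ish proper rotation via QR of a Gaussian matrix, det forced to +1
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Simulate positioned embryos from the reference layout
#'
#' Each embryo is the [reference_layout()] with per-nucleus Gaussian jitter,
#' placed under a random similarity transform (scale, proper rotation,
#' translation). "rnai" embryos additionally shift one named cell by a fixed
#' vector in reference coordinates before transforming, emulating a directed
#' positioning phenotype.
#'
#' @param n_wt,n_rnai Numbers of wild-type and RNAi embryos.
#' @param jitter_sd Per-nucleus positional jitter SD, um.
#' @param shift Optional list `list(cell = "ABpl", delta = c(dx, dy, dz))`
#'   applied to RNAi embryos in reference coordinates.
#' @param scale_range,translation_range Sampling bounds of the similarity
#'   transform (scale uniform in `scale_range`, each translation component
#'   uniform in `translation_range`); rotations are uniform proper rotations.
#' @param seed Optional RNG seed.
#' @return Tibble with columns `embryo_id`, `group`, `cell`, `x`, `y`, `z`;
#'   attributes `truth` (list of per-embryo transforms and the shift) and
#'   `axes_meta` (reference axis labels).
#' @export
gen_embryos <- function(n_wt = 10, n_rnai = 8, jitter_sd = 0.5,
                        shift = NULL, scale_range = c(0.8, 1.2),
                        translation_range = c(-20, 20), seed = NULL) {
  if (n_wt < 1 || n_rnai < 0) abort("need n_wt >= 1 and n_rnai >= 0")
  if (jitter_sd < 0) abort("`jitter_sd` must be >= 0")
  ref <- reference_layout()
  refm <- snapshot_matrix(ref)
  with_seed(seed, {
    groups <- c(rep("wt", n_wt), rep("rnai", n_rnai))
    transforms <- list()
    rows <- purrr::map_dfr(seq_along(groups), function(i) {
      m <- refm
      if (groups[i] == "rnai" && !is.null(shift)) {
        j <- match(shift$cell, rownames(m))
        if (is.na(j)) abort(sprintf("shift cell '%s' not in reference layout", shift$cell))
        m[j, ] <- m[j, ] + shift$delta
      }
      m <- m + matrix(rnorm(length(m), 0, jitter_sd), nrow(m), 3)
      s <- runif(1, scale_range[1], scale_range[2])
      r <- random_rotation()
      tr <- runif(3, translation_range[1], translation_range[2])
      placed <- s * (m %*% t(r)) + matrix(tr, nrow(m), 3, byrow = TRUE)
      id <- sprintf("%s%02d", groups[i], i)
      transforms[[id]] <<- list(scale = s, rotation = r, translation = tr)
      tibble(embryo_id = id, group = groups[i], cell = rownames(m),
             x = placed[, 1], y = placed[, 2], z = placed[, 3])
    })
    attr(rows, "truth") <- list(transforms = transforms, shift = shift,
                                jitter_sd = jitter_sd, seed = seed)
    attr(rows, "axes_meta") <- attr(ref, "axes_meta")
    rows
  })
}

#' Simulate a timed snapshot series with one cell division
#'
#' Produces a per-timepoint series of eight-cell snapshots in which one AB
#' granddaughter divides at a given frame (replaced by two daughter nuclei),
#' as needed to exercise eight-cell-stage time alignment.
#'
#' @param n_frames Number of frames.
#' @param dividing_cell Cell that divides (default "ABar").
#' @param division_frame Frame index at which the daughters first appear.
#' @param jitter_sd Per-frame positional jitter SD, um.
#' @param embryo_id Identifier.
#' @param seed Optional RNG seed.
#' @return Tibble `embryo_id`, `timepoint`, `cell`, `x`, `y`, `z`.
#' @export
gen_embryo_series <- function(n_frames = 20, dividing_cell = "ABar",
                              division_frame = 12, jitter_sd = 0.1,
                              embryo_id = "embryo1", seed = NULL) {
  ref <- reference_layout()
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_frames), function(f) {
      snap <- ref
      if (f >= division_frame) {
        i <- match(dividing_cell, snap$cell)
        mother <- snap[i, ]
        snap <- snap[-i, ]
        d1 <- mother; d1$cell <- paste0(mother$cell, "a"); d1$x <- mother$x - 1.5
        d2 <- mother; d2$cell <- paste0(mother$cell, "p"); d2$x <- mother$x + 1.5
        snap <- bind_rows(snap, d1, d2)
      }
      snap$x <- snap$x + rnorm(nrow(snap), 0, jitter_sd)
      snap$y <- snap$y + rnorm(nrow(snap), 0, jitter_sd)
      snap$z <- snap$z + rnorm(nrow(snap), 0, jitter_sd)
      tibble(embryo_id = embryo_id, timepoint = f, cell = snap$cell,
             x = snap$x, y = snap$y, z = snap$z)
    })
  })
}

#' Generate a geometric solid on a voxel grid
#'
#' Rasterises an analytic solid (sphere, axis-aligned ellipsoid, or cube) onto
#' a regular voxel grid, for validating volume and sphericity estimators
#' against closed forms.
#'
#' @param shape `"sphere"`, `"ellipsoid"` or `"cube"`.
#' @param size Sphere radius, ellipsoid semi-axes (length 3), or cube side, um.
#' @param spacing Isotropic voxel spacing (scalar) or `c(dx, dy, dz)`, um.
#' @param label Integer label for the solid.
#' @param margin Margin of background voxels around the solid, um.
#' @return A [label_volume()].
#' @export
gen_solid <- function(shape = c("sphere", "ellipsoid", "cube"), size,
                      spacing = 0.5, label = 1L, margin = 2) {
  shape <- match.arg(shape)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  half <- switch(shape,
    sphere = rep(size, 3),
    ellipsoid = {
      if (length(size) != 3) abort("ellipsoid `size` must be three semi-axes")
      as.numeric(size)
    },
    cube = rep(size / 2, 3)
  )
  dims <- ceiling((2 * (half + margin)) / spacing)
  centers <- lapply(1:3, function(a) (seq_len(dims[a]) - (dims[a] + 1) / 2) * spacing[a])
  inside <- switch(shape,
    sphere = ,
    ellipsoid = {
      cx2 <- (centers[[1]] / half[1])^2
      cy2 <- (centers[[2]] / half[2])^2
      cz2 <- (centers[[3]] / half[3])^2
      outer(outer(cx2, cy2, `+`), cz2, `+`) <= 1
    },
    cube = {
      ix <- abs(centers[[1]]) <= half[1]
      iy <- abs(centers[[2]]) <= half[2]
      iz <- abs(centers[[3]]) <= half[3]
      outer(outer(ix, iy, `&`), iz, `&`)
    }
  )
  label_volume(array(as.integer(inside) * as.integer(label), dims), spacing)
}

#' Simulate cortical feature lifetimes by region
#'
#' Draws iid feature lifetimes per cortical region (e.g. anterior vs posterior
#' of a dividing cell) from an exponential or gamma family, for calibrating the
#' one-way ANOVA lifetime comparison. Defaults mirror the observed scale of
#' cortical F-actin feature persistence (~25 s anterior vs ~13 s posterior,
#' ~480 features per side).
#'
#' @param group_means Named numeric vector of mean lifetimes (s) per region.
#' @param n_per_group Features per region.
#' @param family `"exponential"` or `"gamma"`.
#' @param gamma_shape Shape parameter when `family = "gamma"`.
#' @param seed Optional RNG seed.
#' @return Tibble with columns `region`, `lifetime`.
#' @export
gen_lifetimes <- function(group_means = c(anterior = 25, posterior = 13),
                          n_per_group = 480,
                          family = c("exponential", "gamma"),
                          gamma_shape = 4, seed = NULL) {
  family <- match.arg(family)
  if (any(group_means <= 0)) abort("group means must be > 0")
  if (n_per_group < 1) abort("`n_per_group` must be >= 1")
  with_seed(seed, {
    purrr::map_dfr(names(group_means), function(g) {
      mu <- group_means[[g]]
      lt <- switch(family,
        exponential = stats::rexp(n_per_group, rate = 1 / mu),
        gamma = stats::rgamma(n_per_group, shape = gamma_shape,
                              rate = gamma_shape / mu)
      )
      tibble(region = g, lifetime = lt)
    })
  })
}
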