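#' Frame-to-frame marker velocities
#'
#' Manual-PIV velocity estimation: forward finite differences between
#' consecutive annotated frames of each track. Each velocity row represents the
#' mean velocity over one frame interval and is timestamped at the interval
#' midpoint (`t_mid`), with the interval endpoints (`t0`, `t1`) retained so
#' downstream model fits can account for interval averaging.
#'
#' @param tracks Tidy track tibble with columns `track_id`, `t`, `x`, `y` (and
#'   any extra columns such as `role`, carried through).
#' @return Tibble with one row per frame interval: `track_id`, carried
#'   grouping columns, `t0`, `t1`, `t_mid`, `x_mid`, `vx`, `vy`.
#' @export
track_velocities <- function(tracks) {
  stopifnot_cols(tracks, c("track_id", "t", "x", "y"), "tracks")
  singletons <- tracks |>
    dplyr::count(.data$track_id) |>
    filter(.data$n < 2)
  if (nrow(singletons) > 0) {
    warn(sprintf("skipping single-point track(s): %s",
                 paste(singletons$track_id, collapse = ", ")))
  }
  carry <- intersect(c("role", "channel"), names(tracks))
  tracks |>
    filter(!.data$track_id %in% singletons$track_id) |>
    group_by(.data$track_id, across(all_of(carry))) |>
    arrange(.data$t, .by_group = TRUE) |>
    dplyr::reframe(
      t0 = head(.data$t, -1), t1 = tail(.data$t, -1),
      x_mid = (head(.data$x, -1) + tail(.data$x, -1)) / 2,
      vx = diff(.data$x) / diff(.data$t),
      vy = diff(.data$y) / diff(.data$t)
    ) |>
    mutate(t_mid = (.data$t0 + .data$t1) / 2) |>
    select(all_of(c("track_id", carry, "t0", "t1", "t_mid", "x_mid", "vx", "vy")))
}

#' Mean cortical flow per timestep
#'
#' Averages the velocities of flow-role reference tracks per frame interval,
#' giving one mean flow vector per timestep for flow correction.
#'
#' @param flow_velocities Velocity tibble (from [track_velocities()]) of
#'   flow-role tracks.
#' @return Tibble `t_mid`, `flow_vx`, `flow_vy`, `n`.
#' @export
mean_flow <- function(flow_velocities) {
  if (nrow(flow_velocities) == 0) {
    abort("no flow tracks available; disable flow correction for this experiment",
          class = "cortexdyn_flow_error")
  }
  flow_velocities |>
    group_by(.data$t_mid) |>
    summarise(flow_vx = mean(.data$vx), flow_vy = mean(.data$vy), n = n(),
              .groups = "drop") |>
    arrange(.data$t_mid)
}

#' Subtract mean flow from a velocity field
#'
#' Per-timestep vector subtraction of the mean flow from every velocity.
#' Timesteps with no flow sample inherit the nearest preceding flow mean (the
#' first available mean if none precedes).
#'
#' @param velocities Velocity tibble from [track_velocities()].
#' @param flow Mean-flow tibble from [mean_flow()].
#' @return The velocity tibble with `vx`, `vy` flow-corrected.
#' @export
correct_flow <- function(velocities, flow) {
  if (nrow(flow) == 0) return(velocities)
  flow <- arrange(flow, .data$t_mid)
  idx <- findInterval(velocities$t_mid, flow$t_mid - 1e-9)
  idx[idx == 0] <- 1L
  velocities |>
    mutate(vx = .data$vx - flow$flow_vx[idx],
           vy = .data$vy - flow$flow_vy[idx])
}

#' Orthogonal outward velocity samples of an ablation experiment
#'
#' Projects each recoil-marker velocity onto the cut-line normal, with the
#' sign convention that motion away from the cut is positive on both sides.
#' A marker's side is its initial signed orthogonal offset (or its first
#' off-line position if it starts exactly on the cut). Samples are restricted
#' to markers whose initial orthogonal distance is at most `band_halfwidth`
#' and to the closed window `0 <= t <= fit_window` after the cut. When the
#' experiment contains flow-role tracks the velocity field is flow-corrected
#' first (unless `flow_correct = FALSE`).
#'
#' @param experiment An [ablation_experiment()].
#' @param flow_correct `NULL` (auto: correct when flow tracks exist), `TRUE`
#'   or `FALSE`.
#' @return Tibble of class-free velocity samples: `track_id`, `t` (interval
#'   midpoint, s since cut), `t0`, `t1`, `v_perp` (um/s, outward positive),
#'   `side` (`"plus"`/`"minus"`), `d0` (initial orthogonal distance, um).
#' @export
orthogonal_samples <- function(experiment, flow_correct = NULL) {
  stopifnot(inherits(experiment, "ablation_experiment"))
  cl <- experiment$cutline
  nhat <- cut_normal(cl)
  tracks <- experiment$tracks

  recoil <- filter(tracks, .data$role == "recoil")
  if (nrow(recoil) == 0) abort("experiment has no recoil tracks")
  vel <- track_velocities(recoil)

  has_flow <- any(tracks$role == "flow")
  do_flow <- if (is.null(flow_correct)) has_flow else isTRUE(flow_correct)
  if (do_flow) {
    fv <- track_velocities(filter(tracks, .data$role == "flow"))
    vel <- correct_flow(vel, mean_flow(fv))
  }

  # signed orthogonal offset of each track's annotated positions
  first_pts <- recoil |>
    group_by(.data$track_id) |>
    arrange(.data$t, .by_group = TRUE) |>
    summarise(
      offs = list((.data$x - cl$center[1]) * nhat[1] +
                    (.data$y - cl$center[2]) * nhat[2]),
      .groups = "drop"
    )
  eps <- 1e-9
  side_of <- function(offs) {
    nz <- offs[abs(offs) > eps]
    if (length(nz) == 0) return(NA_real_)
    sign(nz[1])
  }
  sides <- vapply(first_pts$offs, side_of, numeric(1))
  d0 <- vapply(first_pts$offs, function(o) abs(o[1]), numeric(1))
  on_line <- is.na(sides)
  if (any(on_line)) {
    warn(sprintf("excluding track(s) never off the cut line: %s",
                 paste(first_pts$track_id[on_line], collapse = ", ")))
  }
  info <- tibble(track_id = first_pts$track_id, side_sign = sides, d0 = d0)

  vel |>
    left_join(info, by = "track_id") |>
    filter(!is.na(.data$side_sign), .data$d0 <= experiment$band_halfwidth) |>
    mutate(
      t = .data$t_mid - cl$t_cut,
      t0 = .data$t0 - cl$t_cut,
      t1 = .data$t1 - cl$t_cut,
      v_perp = .data$side_sign * (.data$vx * nhat[1] + .data$vy * nhat[2]),
      side = ifelse(.data$side_sign > 0, "plus", "minus")
    ) |>
    filter(.data$t >= 0, .data$t <= experiment$fit_window) |>
    select(all_of(c("track_id", "t", "t0", "t1", "v_perp", "side", "d0")))
}

#' Binned cortical flow field
#'
#' Bins marker velocities on a (position along the anterior-posterior axis,
#' time) grid and reports per-bin mean velocity vectors, as used for quiver
#' maps of cortical flow. Empty bins are flagged, never interpolated.
#'
#' @param tracks Track tibble (columns `track_id`, `t`, `x`, `y`).
#' @param x_breaks,t_breaks Bin edges for position (um) and time (s).
#' @return Tibble `x_bin`, `t_bin` (bin midpoints), `vx`, `vy`, `n`, `empty`.
#' @export
flow_field <- function(tracks, x_breaks, t_breaks) {
  vel <- track_velocities(tracks)
  mids <- function(b) (head(b, -1) + tail(b, -1)) / 2
  vel |>
    mutate(
      xb = cut(.data$x_mid, x_breaks, labels = FALSE, include.lowest = TRUE),
      tb = cut(.data$t_mid, t_breaks, labels = FALSE, include.lowest = TRUE)
    ) |>
    filter(!is.na(.data$xb), !is.na(.data$tb)) |>
    group_by(.data$xb, .data$tb) |>
    summarise(vx = mean(.data$vx), vy = mean(.data$vy), n = n(),
              .groups = "drop") |>
    tidyr::complete(xb = seq_len(length(x_breaks) - 1),
                    tb = seq_len(length(t_breaks) - 1),
                    fill = list(n = 0L)) |>
    mutate(
      x_bin = mids(x_breaks)[.data$xb],
      t_bin = mids(t_breaks)[.data$tb],
      empty = .data$n == 0L
    ) |>
    select(all_of(c("x_bin", "t_bin", "vx", "vy", "n", "empty"))) |>
    arrange(.data$t_bin, .data$x_bin)
}

#' Feature lifetimes of annotated tracks
#'
#' Lifetime of a cortical feature = time between first and last annotation
#' plus one frame interval (a feature seen in a single frame lived ~one frame).
#'
#' @param tracks Track tibble with `track_id` and `t`.
#' @param frame_dt Frame interval, s.
#' @return Tibble `track_id`, `lifetime` (s).
#' @export
track_lifetimes <- function(tracks, frame_dt = 1) {
  stopifnot_cols(tracks, c("track_id", "t"), "tracks")
  tracks |>
    group_by(.data$track_id) |>
    summarise(lifetime = max(.data$t) - min(.data$t) + frame_dt,
              .groups = "drop")
}

#' One-way ANOVA on feature lifetimes by region
#'
#' Classical one-way analysis of variance comparing mean feature lifetimes
#' between cortical regions.
#'
#' @param lifetimes Tibble with a grouping column and a lifetime column.
#' @param value,group Column names (strings) of the lifetime and region.
#' @return List of class `lifetime_anova`: `f`, `p`, `df`, and a tibble of
#'   group means.
#' @export
lifetime_anova <- function(lifetimes, value = "lifetime", group = "region") {
  stopifnot_cols(lifetimes, c(value, group), "lifetimes")
  g <- factor(lifetimes[[group]])
  y <- lifetimes[[value]]
  if (nlevels(g) < 2) abort("need at least two groups")
  sizes <- table(g)
  if (any(sizes < 2))
    abort(sprintf("every group needs >= 2 observations (undefined within-group variance): %s",
                  paste(names(sizes)[sizes < 2], collapse = ", ")))
  fit <- lm(y ~ g)
  tab <- anova(fit)
  means <- lifetimes |>
    group_by(region = factor(.data[[group]])) |>
    summarise(mean = mean(.data[[value]]), n = n(), .groups = "drop")
  structure(
    list(f = tab$`F value`[1], p = tab$`Pr(>F)`[1],
         df = c(tab$Df[1], tab$Df[2]), means = means),
    class = "lifetime_anova"
  )
}

#' @export
print.lifetime_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA on lifetimes: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$f, x$p))
  print(x$means)
  invisible(x)
}
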