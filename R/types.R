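#' Construct a cut line
#'
#' Geometry of a laser-ablation cut: a line segment in the imaging plane along
#' which the cortex was severed. The time origin `t_cut` defines t = 0 for all
#' recoil kinematics of the experiment.
#'
#' @param center Numeric length-2, cut midpoint (x, y) in micrometres.
#' @param direction Numeric length-2 direction of the cut line; normalised to
#'   unit length internally.
#' @param length Cut length in micrometres (default 4, a typical cortical cut).
#' @param t_cut Time of ablation in seconds; marker times are interpreted
#'   relative to this origin.
#' @return An object of class `cut_line`.
#' @export
cut_line <- function(center = c(0, 0), direction = c(1, 0), length = 4,
                     t_cut = 0) {
  center <- as.numeric(center)
  direction <- as.numeric(direction)
  if (length(center) != 2 || any(!is.finite(center)))
    abort("`center` must be a finite (x, y) pair")
  nrm <- sqrt(sum(direction^2))
  if (length(direction) != 2 || !is.finite(nrm) || nrm == 0)
    abort("`direction` must be a nonzero (x, y) vector")
  if (!is.finite(length) || length <= 0) abort("`length` must be > 0")
  structure(
    list(center = center, direction = direction / nrm,
         length = as.numeric(length), t_cut = as.numeric(t_cut)),
    class = "cut_line"
  )
}

# unit normal of the cut line (rotate direction by +90 degrees)
cut_normal <- function(cutline) {
  c(-cutline$direction[2], cutline$direction[1])
}

#' @export
print.cut_line <- function(x, ...) {
  cat(sprintf("<cut_line> center (%.2f, %.2f) um, direction (%.3f, %.3f), length %.2f um, t_cut %.2f s\n",
              x$center[1], x$center[2], x$direction[1], x$direction[2],
              x$length, x$t_cut))
  invisible(x)
}

#' Construct an ablation experiment
#'
#' Bundles the cut-line geometry with the manually annotated marker tracks of
#' one laser-ablation experiment, plus the analysis window settings. Tracks are
#' stored as a tidy tibble with one row per annotated marker position.
#'
#' @param tracks Tibble with columns `track_id`, `channel` (`"factin"` or
#'   `"nmy2"`), `role` (`"recoil"` or `"flow"`), `t` (seconds), `x`, `y`
#'   (micrometres).
#' @param cutline A [cut_line()].
#' @param experiment_id,embryo_id,cell Identifiers; `cell` is the blastomere
#'   name (e.g. `"E"`, `"MS"`, `"ABpl"`).
#' @param band_halfwidth Maximum initial orthogonal distance (um) from the cut
#'   for a marker to enter the recoil fit; default 2.5.
#' @param fit_window Post-cut fitting window in seconds; default 6.
#' @return An object of class `ablation_experiment`.
#' @export
ablation_experiment <- function(tracks, cutline, experiment_id, embryo_id,
                                cell, band_halfwidth = 2.5, fit_window = 6) {
  tracks <- as_tibble(tracks)
  stopifnot_cols(tracks, c("track_id", "channel", "role", "t", "x", "y"),
                 "tracks")
  if (!inherits(cutline, "cut_line")) abort("`cutline` must be a cut_line")
  if (band_halfwidth <= 0) abort("`band_halfwidth` must be > 0")
  if (fit_window <= 0) abort("`fit_window` must be > 0")
  bad_role <- setdiff(unique(tracks$role), c("recoil", "flow"))
  if (length(bad_role) > 0)
    abort(sprintf("unknown track role(s): %s", paste(bad_role, collapse = ", ")))
  # validate in the order annotations were recorded: out-of-order or
  # duplicated frame times are data errors, not something to silently sort
  validate_track_times(tracks)
  tracks <- arrange(tracks, .data$track_id, .data$t)
  structure(
    list(experiment_id = as.character(experiment_id),
         embryo_id = as.character(embryo_id),
         cell = as.character(cell),
         cutline = cutline,
         tracks = tracks,
         band_halfwidth = band_halfwidth,
         fit_window = fit_window),
    class = "ablation_experiment"
  )
}

validate_track_times <- function(tracks) {
  bad <- tracks |>
    group_by(.data$track_id) |>
    summarise(ok = all(diff(.data$t) > 0), .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(sprintf("track time points must be strictly increasing; offending track_id(s): %s",
                  paste(bad$track_id, collapse = ", ")),
          class = "cortexdyn_validation_error")
  }
  invisible(tracks)
}

#' @export
print.ablation_experiment <- function(x, ...) {
  cat(sprintf("<ablation_experiment> %s: embryo %s, cell %s, %d tracks (%d recoil / %d flow)\n",
              x$experiment_id, x$embryo_id, x$cell,
              length(unique(x$tracks$track_id)),
              length(unique(x$tracks$track_id[x$tracks$role == "recoil"])),
              length(unique(x$tracks$track_id[x$tracks$role == "flow"]))))
  cat(sprintf("  band halfwidth %.2f um, fit window %.1f s\n",
              x$band_halfwidth, x$fit_window))
  invisible(x)
}

#' Construct a labelled voxel volume
#'
#' @param voxels 3D integer array of cell labels; 0 is background.
#' @param spacing Voxel spacing (dx, dy, dz) in micrometres.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(voxels, spacing = c(1, 1, 1)) {
  if (length(dim(voxels)) != 3) abort("`voxels` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("`spacing` must be three strictly positive values")
  if (any(voxels < 0)) abort("labels must be non-negative")
  structure(list(voxels = voxels, spacing = spacing), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  labs <- setdiff(sort(unique(as.vector(x$voxels))), 0)
  cat(sprintf("<label_volume> %d x %d x %d voxels, spacing (%g, %g, %g) um, labels: %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              if (length(labs)) paste(labs, collapse = ", ") else "none"))
  invisible(x)
}

#' Validate an embryo snapshot table
#'
#' A snapshot is a tidy tibble of named nuclei positions at one timepoint:
#' columns `cell`, `x`, `y`, `z` (micrometres), optionally `embryo_id` and
#' `timepoint`. An `axes_meta` attribute (named character, e.g.
#' `c(x = "AP", y = "DV", z = "LR")`) maps coordinate axes to anatomical axes.
#'
#' @param snapshot Tibble to validate.
#' @param require_3d Require at least 4 non-coplanar nuclei (needed for 3D
#'   Procrustes alignment).
#' @return The snapshot, invisibly, if valid; otherwise an error.
#' @export
validate_snapshot <- function(snapshot, require_3d = TRUE) {
  stopifnot_cols(snapshot, c("cell", "x", "y", "z"), "snapshot")
  if (anyDuplicated(snapshot$cell))
    abort("cell names within a snapshot must be unique",
          class = "cortexdyn_validation_error")
  if (require_3d) {
    if (nrow(snapshot) < 4)
      abort("need at least 4 nuclei for 3D alignment",
            class = "cortexdyn_validation_error")
    m <- as.matrix(snapshot[, c("x", "y", "z")])
    m <- sweep(m, 2, colMeans(m))
    if (qr(m)$rank < 3)
      abort("nuclei are coplanar; 3D alignment is degenerate",
            class = "cortexdyn_validation_error")
  }
  invisible(snapshot)
}

snapshot_matrix <- function(snapshot, cells = NULL) {
  if (!is.null(cells)) snapshot <- snapshot[match(cells, snapshot$cell), ]
  m <- as.matrix(snapshot[, c("x", "y", "z")])
  rownames(m) <- snapshot$cell
  m
}
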