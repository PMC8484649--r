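# canonical column schemas of the tidy CSV formats
.tracks_cols <- c("experiment_id", "embryo_id", "cell", "channel", "role",
                  "track_id", "t", "x", "y")
.cutline_cols <- c("experiment_id", "center_x", "center_y", "dir_x", "dir_y",
                   "length", "t_cut", "band_halfwidth", "fit_window")
.intensity_cols <- c("embryo_id", "cell", "t", "z", "raw", "background")
.nuclei_cols <- c("embryo_id", "timepoint", "cell", "x", "y", "z")

read_table_checked <- function(path, cols, what) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  stopifnot_cols(df, cols, what)
  df
}

#' Read ablation experiments from track and cut-line tables
#'
#' Reads the tidy one-row-per-annotation track CSV (columns `experiment_id`,
#' `embryo_id`, `cell`, `channel`, `role`, `track_id`, `t` seconds, `x`, `y`
#' micrometres) together with its cut-line side table (one row per experiment:
#' cut centre, direction, length, ablation time, and the analysis settings),
#' and assembles typed [ablation_experiment()] objects with tracks grouped and
#' sorted by time.
#'
#' @param tracks_path Path to the track CSV.
#' @param cutlines_path Path to the cut-line CSV.
#' @return Named list of [ablation_experiment()]s.
#' @export
read_tracks <- function(tracks_path, cutlines_path) {
  tr <- read_table_checked(tracks_path, .tracks_cols, "track table")
  cl <- read_table_checked(cutlines_path, .cutline_cols, "cut-line table")
  dup <- tr |>
    dplyr::count(.data$experiment_id, .data$track_id, .data$t) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0)
    abort(sprintf("duplicated (track_id, t) annotation(s) in track(s): %s",
                  paste(unique(dup$track_id), collapse = ", ")),
          class = "cortexdyn_validation_error")
  missing_cl <- setdiff(unique(tr$experiment_id), cl$experiment_id)
  if (length(missing_cl) > 0)
    abort(sprintf("no cut line for experiment(s): %s",
                  paste(missing_cl, collapse = ", ")))
  exps <- lapply(split(tr, tr$experiment_id), function(d) {
    row <- cl[cl$experiment_id == d$experiment_id[1], ][1, ]
    ablation_experiment(
      select(d, all_of(c("track_id", "channel", "role", "t", "x", "y"))),
      cut_line(c(row$center_x, row$center_y), c(row$dir_x, row$dir_y),
               row$length, row$t_cut),
      experiment_id = d$experiment_id[1], embryo_id = d$embryo_id[1],
      cell = d$cell[1], band_halfwidth = row$band_halfwidth,
      fit_window = row$fit_window
    )
  })
  exps[unique(tr$experiment_id)]
}

#' Write ablation experiments to track and cut-line tables
#'
#' Inverse of [read_tracks()]: `write_tracks()` then `read_tracks()` is the
#' identity up to column order.
#'
#' @param experiments List of [ablation_experiment()]s.
#' @param tracks_path,cutlines_path Output CSV paths.
#' @return The paths, invisibly.
#' @export
write_tracks <- function(experiments, tracks_path, cutlines_path) {
  if (inherits(experiments, "ablation_experiment")) experiments <- list(experiments)
  tr <- purrr::map_dfr(experiments, function(ex) {
    mutate(ex$tracks, experiment_id = ex$experiment_id,
           embryo_id = ex$embryo_id, cell = ex$cell) |>
      select(all_of(.tracks_cols))
  })
  cl <- purrr::map_dfr(experiments, function(ex) {
    tibble(experiment_id = ex$experiment_id,
           center_x = ex$cutline$center[1], center_y = ex$cutline$center[2],
           dir_x = ex$cutline$direction[1], dir_y = ex$cutline$direction[2],
           length = ex$cutline$length, t_cut = ex$cutline$t_cut,
           band_halfwidth = ex$band_halfwidth, fit_window = ex$fit_window)
  })
  write.csv(tr, tracks_path, row.names = FALSE)
  write.csv(cl, cutlines_path, row.names = FALSE)
  invisible(c(tracks_path, cutlines_path))
}

#' Read / write intensity record tables
#'
#' Tidy CSV of cortical intensity measurements: `embryo_id`, `cell`, `t`
#' (minutes relative to the reference event), `z` (plane index), `raw`,
#' `background` (a.u.).
#'
#' @param path CSV path.
#' @return A tibble of intensity records.
#' @export
read_intensity <- function(path) {
  read_table_checked(path, .intensity_cols, "intensity table")
}

#' @rdname read_intensity
#' @param records Intensity tibble.
#' @export
write_intensity <- function(records, path) {
  write.csv(select(records, all_of(.intensity_cols)), path, row.names = FALSE)
  invisible(path)
}

#' Read / write nuclei position tables
#'
#' Tidy CSV of lineaged nuclei: `embryo_id`, `timepoint`, `cell`, `x`, `y`,
#' `z` (micrometres). Extra columns (e.g. `group`) are preserved on write if
#' present.
#'
#' @param path CSV path.
#' @return A tibble of nuclei positions.
#' @export
read_nuclei <- function(path) {
  read_table_checked(path, .nuclei_cols, "nuclei table")
}

#' @rdname read_nuclei
#' @param nuclei Nuclei tibble.
#' @export
write_nuclei <- function(nuclei, path) {
  keep <- c(.nuclei_cols, intersect("group", names(nuclei)))
  write.csv(select(nuclei, all_of(keep)), path, row.names = FALSE)
  invisible(path)
}

#' Read / write label volumes as multi-page TIFF
#'
#' Stores a [label_volume()] as a 16-bit multi-page TIFF (one page per
#' z-slice) with a YAML sidecar recording the voxel spacing. Labels must be
#' below 65536.
#'
#' @param path TIFF path; the sidecar is `<path>.meta.yaml`.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path) {
  meta_path <- paste0(path, ".meta.yaml")
  if (!file.exists(meta_path)) abort(sprintf("missing spacing sidecar: %s", meta_path))
  meta <- yaml::read_yaml(meta_path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(dim(pages[[1]]), length(pages))
  vox <- array(0L, d)
  for (k in seq_along(pages)) vox[, , k] <- as.integer(round(pages[[k]] * 65535))
  label_volume(vox, as.numeric(meta$spacing))
}

#' @rdname read_label_volume
#' @param volume A [label_volume()].
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(inherits(volume, "label_volume"))
  if (max(volume$voxels) > 65535) abort("labels must fit in 16 bits")
  pages <- lapply(seq_len(dim(volume$voxels)[3]),
                  function(k) volume$voxels[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  yaml::write_yaml(list(spacing = as.numeric(volume$spacing)),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}
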