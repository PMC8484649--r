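#' Time-align an embryo snapshot series to the end of the eight-cell stage
#'
#' Returns the snapshot at the last timepoint of the eight-cell stage: the
#' last frame at which all four AB granddaughters (ABal, ABar, ABpl, ABpr)
#' exist undivided, i.e. the timepoint before the first of them divides.
#'
#' @param series Tibble with columns `timepoint`, `cell`, `x`, `y`, `z` (one
#'   embryo; an `embryo_id` column is carried through).
#' @param cells The cells whose joint presence defines the stage.
#' @return The selected snapshot (all cells at that timepoint), with the
#'   timepoint in column `timepoint`.
#' @export
time_align <- function(series,
                       cells = c("ABal", "ABar", "ABpl", "ABpr")) {
  stopifnot_cols(series, c("timepoint", "cell", "x", "y", "z"), "series")
  present <- series |>
    group_by(.data$timepoint) |>
    summarise(all_present = all(cells %in% .data$cell), .groups = "drop")
  ok <- present$timepoint[present$all_present]
  if (length(ok) == 0) {
    missing <- setdiff(cells, unique(series$cell))
    abort(sprintf("no timepoint has all of %s undivided%s",
                  paste(cells, collapse = ", "),
                  if (length(missing))
                    sprintf(" (never observed: %s)", paste(missing, collapse = ", "))
                  else ""),
          class = "cortexdyn_validation_error")
  }
  filter(series, .data$timepoint == max(ok))
}

#' Procrustes superimposition of one snapshot onto another
#'
#' Least-squares similarity alignment of the source nuclei onto the target
#' over their shared cell names: translation, proper rotation (reflections are
#' excluded — embryo chirality is biologically meaningful) and, optionally,
#' isotropic scaling. Returns the transform and per-cell residual vectors in
#' target coordinates.
#'
#' @param source,target Snapshot tibbles (`cell`, `x`, `y`, `z`).
#' @param scale Include isotropic scaling (default TRUE; FALSE gives a rigid
#'   alignment).
#' @return Object of class `procrustes_fit`: `scale`, `rotation` (3x3, det
#'   +1), `translation`, `aligned` (snapshot tibble of transformed source),
#'   `residuals` (per-cell vectors and distances), `rmsd`.
#' @export
procrustes <- function(source, target, scale = TRUE) {
  shared <- intersect(source$cell, target$cell)
  if (length(shared) < 4)
    abort("need >= 4 shared cell names for 3D alignment")
  validate_snapshot(source[source$cell %in% shared, ])
  validate_snapshot(target[target$cell %in% shared, ])
  x <- snapshot_matrix(source, shared)
  y <- snapshot_matrix(target, shared)

  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  m <- crossprod(y0, x0)             # 3x3 cross-covariance
  sv <- svd(m)
  d <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))  # forbid reflections
  r <- sv$u %*% d %*% t(sv$v)        # rotation: y0 ~ s * x0 %*% t(r)
  s <- if (scale) sum(diag(d) * sv$d) / sum(x0^2) else 1
  translation <- unname(cy - s * drop(r %*% cx))

  apply_tf <- function(mat) sweep(s * mat %*% t(r), 2, translation, `+`)
  aligned_shared <- apply_tf(x)
  res <- y - aligned_shared

  all_src <- snapshot_matrix(source)
  aligned_all <- apply_tf(all_src)
  aligned <- tibble(cell = rownames(all_src), x = aligned_all[, 1],
                    y = aligned_all[, 2], z = aligned_all[, 3])

  structure(
    list(scale = s, rotation = r, translation = translation,
         aligned = aligned,
         residuals = tibble(cell = shared, dx = res[, 1], dy = res[, 2],
                            dz = res[, 3],
                            distance = sqrt(rowSums(res^2))),
         rmsd = sqrt(mean(rowSums(res^2)))),
    class = "procrustes_fit"
  )
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat(sprintf("<procrustes_fit> scale %.4f, translation (%.2f, %.2f, %.2f) um, RMSD %.4g um over %d shared cells\n",
              x$scale, x$translation[1], x$translation[2], x$translation[3],
              x$rmsd, nrow(x$residuals)))
  invisible(x)
}

#' Generalized Procrustes reference embryo
#'
#' Builds a reference (consensus) embryo from several snapshots sharing the
#' same cell names by Generalized Procrustes Analysis: snapshots are
#' iteratively aligned to the evolving mean shape, the mean is recomputed and
#' rescaled to unit centroid size, until the mean shape changes by less than
#' `tol` (RMS) or `max_iter` iterations.
#'
#' The Procrustes mean shape has an arbitrary orientation, so anatomical axis
#' labels cannot be read off its coordinate frame. Supplying `orient_to`
#' rotates the reference onto a template of known orientation (whose
#' `axes_meta` is transferred), and `size = "mean"` rescales it to the mean
#' centroid size of the input embryos so that displacements from it are in
#' micrometres.
#'
#' @param snapshots List of snapshot tibbles with identical cell-name sets.
#' @param orient_to Optional snapshot of known orientation to rotate the
#'   reference onto.
#' @param size `"unit"` (unit centroid size, the default) or `"mean"` (the
#'   mean centroid size of the inputs, giving micrometre-scale
#'   displacements).
#' @param tol Convergence tolerance on the RMS change of the mean shape.
#' @param max_iter Iteration cap.
#' @return The reference snapshot (unit centroid size, centred), carrying the
#'   first snapshot's `axes_meta` attribute if present, plus attributes
#'   `iterations` and `converged`.
#' @export
gpa_reference <- function(snapshots, tol = 1e-8, max_iter = 100,
                          orient_to = NULL, size = c("unit", "mean")) {
  size <- match.arg(size)
  if (length(snapshots) < 2) abort("need >= 2 snapshots")
  cells <- sort(snapshots[[1]]$cell)
  same <- vapply(snapshots, function(s) setequal(s$cell, cells), logical(1))
  if (!all(same))
    abort("all snapshots must share the same cell-name set")
  mats <- lapply(snapshots, snapshot_matrix, cells = cells)

  unit_size <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  mean_shape <- unit_size(mats[[1]])
  as_snap <- function(m) tibble(cell = cells, x = m[, 1], y = m[, 2], z = m[, 3])

  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iterations <- it
    ref_snap <- as_snap(mean_shape)
    aligned <- lapply(mats, function(m) {
      snapshot_matrix(procrustes(as_snap(m), ref_snap)$aligned, cells)
    })
    new_mean <- unit_size(Reduce(`+`, aligned) / length(aligned))
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warn("GPA did not converge within max_iter")
  am <- attr(snapshots[[1]], "axes_meta")
  if (!is.null(orient_to)) {
    # rotate the mean shape onto the orientation template, then re-normalise
    rot <- procrustes(as_snap(mean_shape), orient_to)$rotation
    mean_shape <- unit_size(mean_shape %*% t(rot))
    am <- attr(orient_to, "axes_meta") %||% am
  }
  if (size == "mean") {
    sizes <- vapply(mats, function(m) {
      sqrt(sum(sweep(m, 2, colMeans(m))^2))
    }, numeric(1))
    mean_shape <- mean_shape * mean(sizes)
  }
  out <- as_snap(mean_shape)
  if (!is.null(am)) attr(out, "axes_meta") <- am
  attr(out, "iterations") <- iterations
  attr(out, "converged") <- converged
  out
}

#' Per-cell, per-axis displacements from a reference embryo
#'
#' Aligns each snapshot to the reference by Procrustes analysis and reports
#' the signed displacement of every cell along every axis (aligned position
#' minus reference position), labelled by the reference's `axes_meta` mapping
#' (e.g. AP/DV/LR) when available.
#'
#' @param snapshots List of snapshot tibbles (named by embryo, or carrying an
#'   `embryo_id` column).
#' @param reference Reference snapshot (e.g. from [gpa_reference()]).
#' @param scale Passed to [procrustes()].
#' @return Tibble `embryo_id`, `cell`, `axis`, `displacement` (and the raw
#'   coordinate axis in `coord`).
#' @export
axis_displacements <- function(snapshots, reference, scale = TRUE) {
  am <- attr(reference, "axes_meta") %||% c(x = "x", y = "y", z = "z")
  ids <- names(snapshots) %||% as.character(seq_along(snapshots))
  if (is.null(names(snapshots))) {
    ids <- vapply(seq_along(snapshots), function(i) {
      s <- snapshots[[i]]
      if ("embryo_id" %in% names(s)) as.character(s$embryo_id[1]) else sprintf("embryo%02d", i)
    }, character(1))
  }
  purrr::map_dfr(seq_along(snapshots), function(i) {
    fit <- procrustes(snapshots[[i]], reference, scale = scale)
    # residuals are reference - aligned; displacement is aligned - reference
    tidyr::pivot_longer(fit$residuals, cols = all_of(c("dx", "dy", "dz")),
                        names_to = "coord", values_to = "displacement") |>
      mutate(displacement = -.data$displacement,
             coord = sub("^d", "", .data$coord),
             axis = unname(am[.data$coord]),
             embryo_id = ids[i]) |>
      select(all_of(c("embryo_id", "cell", "coord", "axis", "displacement")))
  })
}

#' Rank-sum test of a cell's displacement between groups
#'
#' Two-sided Wilcoxon rank-sum test comparing the per-embryo displacement of
#' one cell along one axis between wild-type and treated embryos. Ties are
#' handled by midranks (exact p when there are no ties and groups are small).
#'
#' @param wt,treated Displacement tibbles from [axis_displacements()] for the
#'   two groups, or numeric vectors of per-embryo displacements.
#' @param cell,axis Cell and axis to test (ignored for numeric input).
#' @return Tibble `cell`, `axis`, `n_wt`, `n_treated`, `statistic`, `p_value`.
#' @export
displacement_test <- function(wt, treated, cell = NULL, axis = NULL) {
  pick <- function(d) {
    if (is.numeric(d)) return(d)
    stopifnot_cols(d, c("cell", "axis", "displacement"), "displacements")
    d |>
      filter(.data$cell == !!cell, .data$axis == !!axis) |>
      pull("displacement")
  }
  a <- pick(wt)
  b <- pick(treated)
  if (length(a) < 3 || length(b) < 3)
    abort("need >= 3 embryos per group")
  wt_test <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  tibble(cell = cell %||% NA_character_, axis = axis %||% NA_character_,
         n_wt = length(a), n_treated = length(b),
         statistic = unname(wt_test$statistic), p_value = wt_test$p.value)
}

#' Displacement screen across all cells and axes
#'
#' Runs [displacement_test()] for every (cell, axis) combination present in
#' both groups, optionally with Benjamini-Hochberg adjustment across tests.
#'
#' @param wt,treated Displacement tibbles from [axis_displacements()].
#' @param adjust Apply Benjamini-Hochberg correction (default FALSE; the
#'   default mirrors single-phenotype reporting).
#' @return Tibble of per-(cell, axis) test results, optionally with `p_adj`.
#' @export
displacement_screen <- function(wt, treated, adjust = FALSE) {
  combos <- dplyr::inner_join(distinct(wt, .data$cell, .data$axis),
                              distinct(treated, .data$cell, .data$axis),
                              by = c("cell", "axis"))
  out <- purrr::pmap_dfr(combos, function(cell, axis) {
    displacement_test(wt, treated, cell = cell, axis = axis)
  })
  if (adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}
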