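#' Simulate spatiotemporal surface samples
#'
#' Draws noisy samples of a known smooth intensity field over (position from
#' furrow, time from closure) for several embryos, with per-embryo offset and
#' gain, for exercising and validating the surface-fitting stage.
#'
#' @param n_embryos Number of embryos.
#' @param n_per_embryo Samples per embryo.
#' @param field Function `(position, time) -> value`; the default has a bright
#'   anterior and a dimming posterior over time.
#' @param noise_sd Residual noise SD (on the field's scale).
#' @param pos_range,time_range Sampling ranges.
#' @param seed Optional RNG seed.
#' @return Tibble `embryo_id`, `position`, `time`, `value`; attribute `field`.
#' @export
gen_surface_samples <- function(n_embryos = 3, n_per_embryo = 300,
                                field = function(p, t)
                                  -tanh(p / 5) * (1 + t / 200),
                                noise_sd = 0.1, pos_range = c(-15, 15),
                                time_range = c(-240, 120), seed = NULL) {
  with_seed(seed, {
    out <- purrr::map_dfr(seq_len(n_embryos), function(i) {
      p <- runif(n_per_embryo, pos_range[1], pos_range[2])
      t <- runif(n_per_embryo, time_range[1], time_range[2])
      gain <- runif(1, 0.8, 1.2)
      offset <- runif(1, -0.5, 0.5)
      tibble(embryo_id = sprintf("e%d", i), position = p, time = t,
             value = gain * field(p, t) + offset + rnorm(n_per_embryo, 0, noise_sd))
    })
    attr(out, "field") <- field
    out
  })
}

json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages against the tables in the output directory,
#' writing JSON results (and CSVs) per stage. The configuration is a YAML
#' file or an equivalent named list with at least `output_dir`, `seed` and
#' `stages` (any of `"simulate"`, `"recoil"`, `"contrast"`, `"flow"`,
#' `"intensity"`, `"heatmap"`, `"align"`, `"shape"`). The `simulate` stage
#' writes synthetic input tables (with a `truth.json`) that the analysis
#' stages then consume, so a full synthetic end-to-end run needs no external
#' data. Runs are deterministic given the seed: per-stage seeds are derived
#' from the base seed, and a `run_log.json` records seed, package version and
#' parameters.
#'
#' @param config Path to a YAML config, or a named list.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("`config` must be a file path or a named list")
  out_dir <- config$output_dir %||% abort("config needs `output_dir`")
  seed <- config$seed %||% 1L
  stages <- config$stages %||% "simulate"
  known <- c("simulate", "recoil", "contrast", "flow", "intensity", "heatmap",
             "align", "shape")
  bad <- setdiff(stages, known)
  if (length(bad) > 0)
    abort(sprintf("unknown stage name(s): %s (known: %s)",
                  paste(bad, collapse = ", "), paste(known, collapse = ", ")),
          class = "cortexdyn_config_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)

  for (stage in stages) {
    switch(stage,
      simulate = pipeline_simulate(config, pth, seed),
      recoil = pipeline_recoil(config, pth, seed),
      contrast = pipeline_contrast(config, pth, seed),
      flow = pipeline_flow(config, pth),
      intensity = pipeline_intensity(config, pth),
      heatmap = pipeline_heatmap(config, pth),
      align = pipeline_align(config, pth),
      shape = pipeline_shape(config, pth)
    )
  }
  json_out(list(seed = seed, package = "cortexdyn",
                version = as.character(utils::packageVersion("cortexdyn")),
                stages = as.list(stages),
                parameters = config[setdiff(names(config),
                                            c("output_dir", "stages"))]),
           pth("run_log.json"))
  invisible(out_dir)
}

pipeline_simulate <- function(config, pth, seed) {
  sim <- config$simulate %||% list()
  cells <- sim$cells %||% c("E", "E", "MS", "MS")
  v0 <- sim$v0 %||% ifelse(cells == "E", 1.5, 0.75)
  tau <- sim$tau %||% rep(2, length(cells))
  exps <- lapply(seq_along(cells), function(i) {
    gen_recoil(v0_true = v0[i], tau_true = tau[i],
               noise_sd = sim$noise_sd %||% 0.05,
               experiment_id = sprintf("exp%02d", i),
               embryo_id = sprintf("emb%02d", i), cell = cells[i],
               seed = derive_seed(seed, 100 + i))
  })
  write_tracks(exps, pth("tracks.csv"), pth("cutlines.csv"))
  intens <- gen_intensity(seed = derive_seed(seed, 200))
  write_intensity(intens, pth("intensity.csv"))
  emb <- gen_embryos(n_wt = sim$n_wt %||% 10, n_rnai = sim$n_rnai %||% 8,
                     shift = list(cell = "ABpl", delta = c(3, 0, 0)),
                     seed = derive_seed(seed, 300))
  write_nuclei(mutate(emb, timepoint = 1), pth("nuclei.csv"))
  surf <- gen_surface_samples(seed = derive_seed(seed, 400))
  write.csv(surf, pth("surface_samples.csv"), row.names = FALSE)
  truth_emb <- attr(emb, "truth")
  json_out(list(
    recoil = lapply(exps, function(e) attr(e, "truth")[c("v0_true", "tau_true", "noise_sd")]),
    intensity = attr(intens, "truth")[c("cell_effects", "embryo_effects",
                                        "bleach_rate", "ar1_rho", "noise_sd",
                                        "background_mean")],
    embryos = list(shift = truth_emb$shift, jitter_sd = truth_emb$jitter_sd)
  ), pth("truth.json"))
}

pipeline_read_experiments <- function(pth) {
  read_tracks(pth("tracks.csv"), pth("cutlines.csv"))
}

pipeline_recoil <- function(config, pth, seed) {
  exps <- pipeline_read_experiments(pth)
  by_cell <- split(exps, vapply(exps, function(e) e$cell, character(1)))
  n_boot <- config$recoil$n_boot %||% 1000
  fits <- lapply(by_cell, function(g) {
    b <- bootstrap_recoil(g, n_boot = n_boot, seed = derive_seed(seed, 500))
    list(v0 = b$v0, tau = b$tau, ci_v0 = b$ci_v0, ci_tau = b$ci_tau,
         n_samples = b$n_samples, n_experiments = b$n_experiments,
         converged = b$converged)
  })
  json_out(fits, pth("recoil.json"))
}

pipeline_contrast <- function(config, pth, seed) {
  exps <- pipeline_read_experiments(pth)
  by_cell <- split(exps, vapply(exps, function(e) e$cell, character(1)))
  if (length(by_cell) < 2) abort("contrast stage needs experiments from two cells")
  pair <- config$contrast$cells %||% names(by_cell)[1:2]
  param <- config$contrast$param %||% "v0"
  ct <- permutation_contrast(by_cell[[pair[1]]], by_cell[[pair[2]]],
                             parameter = param,
                             n_perm = config$contrast$n_perm %||% 1000,
                             seed = derive_seed(seed, 600))
  json_out(list(parameter = ct$parameter, cell_a = ct$cell_a,
                cell_b = ct$cell_b, observed_difference = ct$observed,
                p_value = ct$p, n_perm = ct$n_perm), pth("contrast.json"))
}

pipeline_flow <- function(config, pth) {
  exps <- pipeline_read_experiments(pth)
  tracks <- purrr::map_dfr(exps, function(e) {
    mutate(e$tracks, experiment_id = e$experiment_id)
  })
  rng_x <- range(tracks$x)
  rng_t <- range(tracks$t)
  ff <- flow_field(tracks,
                   x_breaks = seq(rng_x[1], rng_x[2], length.out = 7),
                   t_breaks = seq(rng_t[1], rng_t[2] + 1e-9, length.out = 4))
  write.csv(ff, pth("flow_field.csv"), row.names = FALSE)
}

pipeline_intensity <- function(config, pth) {
  rec <- read_intensity(pth("intensity.csv"))
  corr <- correct_intensity(rec)
  cm <- cell_means_ar1(corr)
  write.csv(select(corr, -dplyr::any_of("floored")), pth("intensity_corrected.csv"),
            row.names = FALSE)
  pair <- config$intensity$contrast %||% c("E", "MS")
  ct <- contrast_cells(cm, pair)
  json_out(list(
    rho = cm$rho,
    cell_means = purrr::pmap(cm$means, function(cell, estimate, se)
      list(cell = cell, estimate = estimate, se = se)),
    contrast = as.list(ct)
  ), pth("intensity.json"))
}

pipeline_heatmap <- function(config, pth) {
  samples <- as_tibble(read.csv(pth("surface_samples.csv")))
  surf <- spatiotemporal_surface(samples)
  write.csv(surf$grid, pth("surface_grid.csv"), row.names = FALSE)
  json_out(lapply(split(surf$contours, surf$contours$contour_id), function(d) {
    list(level = d$level[1], position = d$position, time = d$time)
  }), pth("surface_contours.json"))
}

pipeline_align <- function(config, pth) {
  nuc <- as_tibble(read.csv(pth("nuclei.csv")))
  stopifnot_cols(nuc, c(.nuclei_cols, "group"), "nuclei table")
  snaps <- split(select(nuc, all_of(c("cell", "x", "y", "z"))), nuc$embryo_id)
  groups <- vapply(split(nuc$group, nuc$embryo_id), function(g) g[1], character(1))
  ref <- gpa_reference(unname(snaps[groups == "wt"]),
                       orient_to = reference_layout(), size = "mean")
  disp <- axis_displacements(snaps, ref)
  disp$group <- groups[disp$embryo_id]
  write.csv(disp, pth("aligned_displacements.csv"), row.names = FALSE)
  cell <- config$align$cell %||% "ABpl"
  axis <- config$align$axis %||% "AP"
  test <- displacement_test(filter(disp, .data$group == "wt"),
                            filter(disp, .data$group != "wt"),
                            cell = cell, axis = axis)
  json_out(as.list(test), pth("align.json"))
}

pipeline_shape <- function(config, pth) {
  vols <- config$shape$volumes
  if (is.null(vols)) {
    vol <- gen_solid("sphere", size = 8, spacing = 0.4)
    write_label_volume(vol, pth("sphere.tif"))
    vols <- pth("sphere.tif")
  }
  metrics <- purrr::map_dfr(vols, function(v) {
    mutate(shape_metrics(read_label_volume(v)), file = basename(v))
  })
  write.csv(metrics, pth("shape_metrics.csv"), row.names = FALSE)
}
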