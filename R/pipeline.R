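# End-to-end orchestration: config, stage execution, outputs, run log.

#' Default pipeline configuration
#'
#' A single nested list drives [run_pipeline()]; it round-trips through
#' YAML via [write_run_config()] / [read_run_config()]. In "synth" mode
#' the scene generator supplies the cube, references and nuclear stain;
#' in "files" mode the `inputs` paths are read instead.
#'
#' @param out_dir output directory.
#' @param seed integer seed for all randomness in the run.
#' @return config list with entries mode, out_dir, seed, axis_regions,
#'   scene (overrides for [scene_layout()]), noise_sigma_frac, thresholds,
#'   analyses, histogram, inputs.
#' @export
default_run_config <- function(out_dir = "srsld_out", seed = 1) {
  list(
    mode = "synth",
    out_dir = out_dir,
    seed = as.integer(seed),
    axis_regions = srs_default_regions(),
    scene = list(),
    noise_sigma_frac = 0,
    thresholds = list(
      saturation_window_cm = 12, saturation_std = 50,
      saturation_value = 3500, max_saturated_fraction = 0.2,
      clip_fraction = 0.3, atrous_levels = 3, atrous_k_mad = 5,
      atrous_min_px = 4, propagate_lambda = 0.05,
      min_nucleus_area_px = 64, min_cell_diameter_um = 0),
    analyses = list(ne_comparison = TRUE, histogram = TRUE),
    histogram = list(radius_edges_um = c(0, 0.4, 0.8, 1.2, 1.6),
                     ce_edges = seq(0, 1, 0.2)),
    inputs = list(cube = NULL, references = NULL, nuclear_stain = NULL,
                  pixel_size_um = 1))
}

#' Write / read a run configuration as YAML
#'
#' @param config config list.
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly;
#'   `read_run_config` the config list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

run_stage <- function(name, log, expr) {
  log(paste0("stage: ", name))
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: axis and references, per-pixel NNLS
#' decomposition with saturation masking, cover-glass background and
#' mean collapse, nucleus / cell / droplet segmentation, per-droplet
#' records, per-cell summaries, and the configured analyses; writes
#' CSVs, a weight TIFF, a false-color PNG and a run log (package
#' version, seed, every threshold) into `config$out_dir`. With a fixed
#' seed the outputs are byte-identical across runs.
#'
#' @param config list from [default_run_config()] (possibly modified) or
#'   [read_run_config()].
#' @return Invisibly, a list with cube, refs, weights, masks, records,
#'   summaries, and analysis results.
#' @export
run_pipeline <- function(config = default_run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  log <- function(msg) {
    writeLines(msg, log_con)
    message("srsld: ", msg)
  }
  log(paste0("srsld version ", as.character(utils::packageVersion("srsld"))))
  log(paste0("seed: ", config$seed))
  th <- config$thresholds
  for (k in names(th)) log(paste0("threshold ", k, ": ", th[[k]]))
  set.seed(config$seed)

  axis <- run_stage("axis", log, build_spectral_axis(config$axis_regions))

  if (identical(config$mode, "synth")) {
    scene <- run_stage("synth", log, {
      spectra <- make_component_spectra(axis)
      render_scene(do.call(scene_layout, config$scene), spectra,
                   seed = config$seed)
    })
    cube <- scene$cube
    if (config$noise_sigma_frac > 0)
      cube <- corrupt_cube(cube, config$noise_sigma_frac,
                           seed = config$seed + 1)
    refs <- scene$refs
    stain <- scene$truth$nuclear_stain
    pixel_size <- scene$truth$pixel_size_um
    truth <- scene$truth
  } else {
    truth <- NULL
    cube <- run_stage("read cube", log, read_cube(config$inputs$cube))
    refs <- run_stage("read references", log,
                      read_reference_set(config$inputs$references))
    stain <- run_stage("read nuclear stain", log,
                       round(tiff::readTIFF(config$inputs$nuclear_stain) * 65535))
    pixel_size <- config$inputs$pixel_size_um
  }

  wi <- run_stage("decompose", log, {
    w <- decompose_cube(cube, refs, saturation = FALSE)
    w$saturation <- detect_saturation(cube, th$saturation_window_cm,
                                      th$saturation_std, th$saturation_value)
    w
  })
  collapsed <- run_stage("collapse", log,
                         mean_collapse(cube, cover_glass_background(cube)))
  masks <- run_stage("segment", log, {
    nuclei <- segment_nuclei(stain, min_area_px = th$min_nucleus_area_px)
    cells <- propagate_cells(nuclei, collapsed,
                             regularization = th$propagate_lambda)
    if (th$min_cell_diameter_um > 0)
      cells <- filter_small_cells(cells, th$min_cell_diameter_um, pixel_size)
    droplets <- detect_droplets_atrous(collapsed, th$atrous_levels,
                                       th$atrous_k_mad, th$atrous_min_px)
    segmentation_masks(nuclei, cells, droplets, pixel_size)
  })
  records <- run_stage("records", log,
                       droplet_records(wi, masks, th$max_saturated_fraction))
  summaries <- run_stage("summaries", log, cell_summaries(records, wi, masks))
  log(paste0("cells: ", nrow(summaries), ", droplets kept: ", nrow(records)))

  results <- list(cube = cube, refs = refs, weights = wi, masks = masks,
                  records = records, summaries = summaries, truth = truth)

  if (isTRUE(config$analyses$ne_comparison) &&
      sum(records$is_ne) >= 2 && sum(!records$is_ne) >= 2) {
    results$ne_comparison <- run_stage("ne comparison", log,
                                       compare_ne_vs_cyto(records))
    utils::write.csv(
      data.frame(results$ne_comparison[c("mean_ne", "mean_cyto",
                                         "difference", "statistic",
                                         "p_value", "n_ne", "n_cyto")]),
      file.path(config$out_dir, "ne_comparison.csv"), row.names = FALSE)
  } else if (isTRUE(config$analyses$ne_comparison)) {
    log("ne comparison skipped: fewer than 2 droplets in a group")
  }
  if (isTRUE(config$analyses$histogram)) {
    results$histogram <- run_stage("histogram", log,
      size_ce_histogram(records, config$histogram$radius_edges_um,
                        config$histogram$ce_edges))
    utils::write.csv(as.data.frame(results$histogram),
                     file.path(config$out_dir, "size_ce_histogram.csv"))
  }

  run_stage("write outputs", log, {
    utils::write.csv(records, file.path(config$out_dir, "droplet_records.csv"),
                     row.names = FALSE)
    utils::write.csv(summaries, file.path(config$out_dir, "cell_summaries.csv"),
                     row.names = FALSE)
    write_reference_set(refs, file.path(config$out_dir, "references.csv"))
    write_weights(wi, file.path(config$out_dir, "weights.tif"))
    write_falsecolor_png(render_falsecolor(wi, masks, th$clip_fraction),
                         file.path(config$out_dir, "falsecolor.png"))
  })
  log("done")
  invisible(results)
}
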