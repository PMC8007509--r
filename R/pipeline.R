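#' Read and validate a pipeline run configuration
#'
#' Pipeline stages are driven by a YAML config. Recognized top-level keys:
#'
#' * `seed` (integer) — used for every stochastic step and recorded in every
#'   output's provenance block.
#' * `output_dir` — where stage outputs are written.
#' * `channels` — `analytes` (vector) and `reference` (single name).
#' * `criteria` — optional overrides for [qc_criteria()] fields.
#' * `simulation` — optional overrides for [sim_params()] fields
#'   (`response_slope` as a mapping channel -> slope).
#' * `paths` — stage inputs: `array_grid`, `array_layout`, `section_grid`,
#'   `cell_density`, `rois` (mapping region -> vector of mask TSVs),
#'   `curves` (mapping channel -> calibration JSON), `modes` (list of
#'   `{instrument, mode, observations}` CSV paths).
#' * `calibration_density` — cells/pixel of the calibration homogenates.
#' * `transform` — optional 2x3 affine (list of two length-3 rows).
#'
#' Unknown keys are rejected.
#'
#' @param path YAML config path.
#' @return a list of class `run_config` (with attributes `config_path` and
#'   `config_md5`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "output_dir", "channels", "criteria", "simulation",
             "paths", "calibration_density", "transform")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$output_dir)) cfg$output_dir <- "."
  if (is.null(cfg$channels$reference)) cfg$channels$reference <- "lipid782"
  if (is.null(cfg$channels$analytes)) cfg$channels$analytes <- c("cmpdA",
                                                                 "cmpdB")
  cfg$channels$analytes <- unlist(cfg$channels$analytes)
  structure(cfg, class = "run_config", config_path = path,
            config_md5 = unname(tools::md5sum(path)))
}

config_provenance <- function(config) {
  list(seed = config$seed,
       config_md5 = attr(config, "config_md5"),
       package = "qmsi",
       package_version = as.character(utils::packageVersion("qmsi")))
}

config_criteria <- function(config) {
  do.call(qc_criteria, as.list(config$criteria))
}

config_sim_params <- function(config) {
  sim <- config$simulation
  if (!is.null(sim$response_slope)) {
    sim$response_slope <- unlist(sim$response_slope)
  } else {
    sim$response_slope <- setNames(rep(0.002,
                                       length(config$channels$analytes)),
                                   config$channels$analytes)
  }
  sim$seed <- config$seed
  sim$reference_channel <- config$channels$reference
  do.call(sim_params, sim)
}

require_path <- function(config, key, what) {
  p <- config$paths[[key]]
  if (is.null(p)) stop("config error: missing paths$", key, " (", what, ")",
                       call. = FALSE)
  if (is.character(p) && length(p) == 1L && !file.exists(p)) {
    stop("config error: ", what, " not found at ", p, call. = FALSE)
  }
  p
}

#' Simulate pipeline inputs
#'
#' Generates a mimetic calibration array and a demo dosed section with the
#' config's seed, and writes every downstream input to `output_dir`: array
#' grid (`array.tsv` + sidecar), realized layout (`layout.yaml`), ground
#' truth (`truth.csv`), section grid (`section.tsv`), a cell-density grid
#' (`cells.tsv`, channel `"cell_density"`), triplicate ROI masks
#' (`roi_<region>_<k>.tsv`) and a provenance block (`provenance.json`).
#'
#' @param config_path YAML config path.
#' @return (invisibly) a list with the written file paths.
#' @export
run_simulate <- function(config_path) {
  config <- read_run_config(config_path)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  params <- config_sim_params(config)
  layout <- default_array_layout(analytes = config$channels$analytes,
                                 pixel_size_um = params$pixel_size_um)
  arr <- generate_mimetic_array(layout, params)
  paths <- list(
    array_grid = file.path(out, "array.tsv"),
    array_layout = file.path(out, "layout.yaml"),
    truth = file.path(out, "truth.csv"),
    section_grid = file.path(out, "section.tsv"),
    cell_density = file.path(out, "cells.tsv"),
    provenance = file.path(out, "provenance.json")
  )
  write_grid(arr$grid, paths$array_grid)
  write_array_layout(arr$layout, paths$array_layout)
  write_truth_csv(arr$truth, paths$truth)

  rmap <- demo_region_map()
  sec_params <- params
  sec_params$seed <- params$seed + 1000L
  sec <- generate_dosed_section(rmap, sec_params)
  write_grid(sec$grid, paths$section_grid)
  cells <- channel_grid(list(cell_density = sec$cell_density),
                        params$pixel_size_um)
  write_grid(cells, paths$cell_density)
  regions <- names(rmap$region_concentrations)
  paths$rois <- list()
  for (r in regions) {
    masks <- region_replicate_masks(rmap, r, n = 3L,
                                    seed = config$seed + 2000L)
    paths$rois[[r]] <- vapply(seq_along(masks), function(k) {
      p <- file.path(out, sprintf("roi_%s_%d.tsv", r, k))
      write_roi_mask(masks[[k]], p)
      p
    }, character(1L))
  }
  jsonlite::write_json(config_provenance(config), paths$provenance,
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Calibrate from an array grid and layout
#'
#' For every analyte channel: extracts per-well summed ratios, builds the
#' calibration curve with below-LOD exclusion, evaluates both QC levels, and
#' writes `curve_<channel>.json` (with provenance), a per-level mean/SD
#' ratio table `levels_<channel>.csv`, and a combined `qc_report.csv`.
#'
#' @param config_path YAML config path (`paths$array_grid` and
#'   `paths$array_layout` required).
#' @return (invisibly) named list of `calibration_curve` objects.
#' @export
run_calibrate <- function(config_path) {
  config <- read_run_config(config_path)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  grid <- read_grid(require_path(config, "array_grid", "array grid TSV"))
  layout <- read_array_layout(require_path(config, "array_layout",
                                           "array layout"))
  criteria <- config_criteria(config)
  curves <- list(); qc_rows <- list()
  for (ch in config$channels$analytes) {
    obs <- extract_array_ratios(grid, layout, ch, config$channels$reference)
    curve <- build_calibration(obs[obs$role == "calibration", ],
                               obs$ratio[obs$role == "blank"])
    curves[[ch]] <- curve
    write_calibration_json(curve, file.path(out, paste0("curve_", ch,
                                                        ".json")),
                           provenance = config_provenance(config))
    lev <- aggregate(ratio ~ nominal_conc,
                     data = obs[obs$role == "calibration", ],
                     FUN = function(v) c(mean = mean(v), sd = sd(v),
                                         n = length(v)))
    lev <- do.call(data.frame, lev)
    names(lev) <- c("nominal_conc", "mean_ratio", "sd_ratio", "n")
    write.csv(lev, file.path(out, paste0("levels_", ch, ".csv")),
              row.names = FALSE, quote = FALSE)
    for (q in sort(unique(obs$nominal_conc[obs$role == "qc"]))) {
      ratios <- obs$ratio[obs$role == "qc" & obs$nominal_conc == q]
      if (length(ratios) < 2L) next
      qc <- evaluate_qc(back_calculate(curve, ratios)$conc, q, curve$lloq,
                        criteria)
      qc_rows[[length(qc_rows) + 1L]] <-
        data.frame(channel = ch, nominal_conc = q, n = qc$n,
                   mean_measured = qc$mean_measured,
                   precision_rsd = qc$precision_rsd,
                   accuracy_pct = qc$accuracy_pct,
                   below_lloq = qc$below_lloq,
                   passes_precision = qc$passes_precision,
                   passes_accuracy = qc$passes_accuracy,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(qc_rows) > 0L) {
    write.csv(do.call(rbind, qc_rows), file.path(out, "qc_report.csv"),
              row.names = FALSE, quote = FALSE)
  }
  invisible(curves)
}

#' Quantify ROIs on a dosed section
#'
#' Reads the section grid, cell-density grid, per-channel calibration curves
#' and replicate ROI masks, quantifies each region per analyte channel
#' (cell-count-corrected, flags propagated; a channel without signal yields
#' `ND` rows), and writes `quantification.csv` plus a fold-difference
#' appendix `fold_differences.csv`.
#'
#' @param config_path YAML config path (`paths$section_grid`,
#'   `paths$cell_density`, `paths$rois`, `paths$curves` and
#'   `calibration_density` required; `transform` optional).
#' @return (invisibly) the quantification data frame.
#' @export
run_quantify <- function(config_path) {
  config <- read_run_config(config_path)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  grid <- read_grid(require_path(config, "section_grid", "section grid"))
  cells <- read_grid(require_path(config, "cell_density",
                                  "cell-density grid"))
  roi_paths <- require_path(config, "rois", "ROI masks")
  rois <- lapply(roi_paths, function(ps) lapply(unlist(ps), read_roi_mask))
  curve_paths <- require_path(config, "curves", "calibration curves")
  cal_density <- config$calibration_density
  if (is.null(cal_density)) {
    stop("config error: missing calibration_density", call. = FALSE)
  }
  transform <- NULL
  if (!is.null(config$transform)) {
    transform <- registration_transform(
      matrix(unlist(config$transform), nrow = 2L, byrow = TRUE))
  }
  results <- list()
  for (ch in config$channels$analytes) {
    curve <- NULL
    cp <- curve_paths[[ch]]
    if (!is.null(cp) && file.exists(cp)) curve <- read_calibration_json(cp)
    res <- quantify_rois(grid, rois, curve, ch, config$channels$reference,
                         cells, cal_density, transform = transform)
    res <- cbind(data.frame(channel = ch, stringsAsFactors = FALSE), res)
    results[[ch]] <- res
  }
  results <- do.call(rbind, results)
  rownames(results) <- NULL
  write_roi_results_csv(results, file.path(out, "quantification.csv"))
  folds <- list()
  for (ch in unique(results$channel)) {
    sub <- results[results$channel == ch, ]
    fd <- fold_differences(sub$roi_name, sub$conc, sub$flag)
    if (nrow(fd) > 0L) {
      folds[[ch]] <- cbind(data.frame(channel = ch,
                                      stringsAsFactors = FALSE), fd)
    }
  }
  if (length(folds) > 0L) {
    write.csv(do.call(rbind, folds), file.path(out, "fold_differences.csv"),
              row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(config_provenance(config),
                       file.path(out, "provenance_quantify.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

#' Compare instrument/mode datasets
#'
#' Reads per-mode observation CSVs (columns `channel`, `well_id`, `role`,
#' `nominal_conc`, `ratio`, `replicate_id`), summarizes each against the
#' characterization criteria, ranks them, and writes `platform_table.csv`
#' (with `"<LOD"` cells) and `platform_ranking.csv`.
#'
#' @param config_path YAML config path (`paths$modes` required: a list of
#'   mappings with `instrument`, `mode`, `observations`).
#' @return (invisibly) the [rank_modes()] result.
#' @export
run_compare <- function(config_path) {
  config <- read_run_config(config_path)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  modes <- require_path(config, "modes", "mode datasets")
  criteria <- config_criteria(config)
  summaries <- do.call(rbind, lapply(modes, function(m) {
    obs <- read.csv(m$observations, stringsAsFactors = FALSE)
    summarize_mode(mode_dataset(m$instrument, m$mode, obs), criteria)
  }))
  format_platform_table(summaries, "csv",
                        path = file.path(out, "platform_table.csv"))
  ranked <- rank_modes(summaries, criteria)
  write.csv(ranked$ranking, file.path(out, "platform_ranking.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(ranked)
}
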