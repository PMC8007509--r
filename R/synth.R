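#' Simulation parameters for synthetic DESI-MRM data
#'
#' Houses the generative stand-ins for the tissue behaviour the pipeline
#' measures. The endogenous-lipid channel scales with intact-cell density;
#' analyte channels are parameterized on the ratio scale (expected summed
#' analyte/lipid ratio = `response_slope * concentration` at calibration
#' cell density), so ion suppression is implicitly shared between channels.
#' Pixel noise is multiplicative log-normal with relative standard deviation
#' `pixel_rsd` (mean exactly 1), plus additive Gaussian baseline noise
#' truncated at zero so intensities stay non-negative.
#'
#' @param response_slope named numeric vector, expected ratio units per
#'   (ug/g) for each analyte channel.
#' @param lipid_gain lipid counts per cell-density unit (> 0).
#' @param pixel_rsd pixel-to-pixel relative SD of the multiplicative noise,
#'   as a fraction in `[0, 1)`. The default 0.2 mirrors the ~20% RSD
#'   observed for the endogenous lipid in liver homogenates.
#' @param baseline_noise_sd SD of the additive baseline noise, counts.
#' @param diffusion_sigma_mm Gaussian diffusion length of signal into the
#'   surrounding gelatin, mm (0 disables diffusion).
#' @param pixel_size_um raster resolution, micrometres per pixel.
#' @param homogenate_cell_density intact-cell density of the spiked tissue
#'   homogenates, cells per pixel; this is the calibration density that
#'   cell-count correction refers back to.
#' @param seed integer RNG seed; a fixed seed reproduces grids exactly.
#' @param reference_channel name of the endogenous-lipid channel.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(response_slope = c(cmpdA = 0.002, cmpdB = 0.002),
                       lipid_gain = 20,
                       pixel_rsd = 0.2,
                       baseline_noise_sd = 5,
                       diffusion_sigma_mm = 0,
                       pixel_size_um = 100,
                       homogenate_cell_density = 50,
                       seed = 1L,
                       reference_channel = "lipid782") {
  if (is.null(names(response_slope)) || any(!nzchar(names(response_slope)))) {
    stop("`response_slope` must be a named vector (one entry per analyte ",
         "channel)", call. = FALSE)
  }
  if (any(response_slope <= 0)) stop("response_slope must be > 0",
                                     call. = FALSE)
  if (lipid_gain <= 0) stop("lipid_gain must be > 0", call. = FALSE)
  if (pixel_rsd < 0 || pixel_rsd >= 1) stop("pixel_rsd must be in [0, 1)",
                                            call. = FALSE)
  if (baseline_noise_sd < 0) stop("baseline_noise_sd must be >= 0",
                                  call. = FALSE)
  if (diffusion_sigma_mm < 0) stop("diffusion_sigma_mm must be >= 0",
                                   call. = FALSE)
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0", call. = FALSE)
  if (homogenate_cell_density <= 0) {
    stop("homogenate_cell_density must be > 0", call. = FALSE)
  }
  seed <- as.integer(seed)
  structure(
    list(response_slope = response_slope, lipid_gain = lipid_gain,
         pixel_rsd = pixel_rsd, baseline_noise_sd = baseline_noise_sd,
         diffusion_sigma_mm = diffusion_sigma_mm,
         pixel_size_um = pixel_size_um,
         homogenate_cell_density = homogenate_cell_density,
         seed = seed, reference_channel = reference_channel),
    class = "sim_params"
  )
}

# multiplicative log-normal (mean 1, relative SD = rsd) then additive
# baseline, truncated at zero
apply_pixel_noise <- function(expected, rsd, baseline_sd) {
  out <- expected
  if (rsd > 0) {
    sdlog <- sqrt(log(1 + rsd^2))
    out <- out * matrix(rlnorm(length(out), meanlog = -sdlog^2 / 2,
                               sdlog = sdlog),
                        nrow = nrow(out))
  }
  if (baseline_sd > 0) {
    out <- out + matrix(rnorm(length(out), 0, baseline_sd), nrow = nrow(out))
    out <- pmax(out, 0)
  }
  out
}

blur_field <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  EBImage::gblur(m, sigma = sigma_px, boundary = 0)
}

fill_wells <- function(mat, wells, values) {
  for (i in seq_len(nrow(wells))) {
    w <- wells[i, ]
    mat[(w$y0 + 1L):(w$y0 + w$height), (w$x0 + 1L):(w$x0 + w$width)] <-
      values[i]
  }
  mat
}

#' Generate a synthetic mimetic tissue-array section
#'
#' Simulates one cryosectioned slice of a spiked-homogenate gelatin array:
#' every well carries homogenate at the calibration cell density, the lipid
#' channel is `lipid_gain x cell density` per pixel, and each analyte
#' channel is generated so that the expected summed analyte/lipid ratio of a
#' well equals `response_slope x nominal concentration`. The gelatin
#' corridors between wells carry only baseline noise, plus diffusion
#' (Gaussian blur of the expected intensity fields with
#' `diffusion_sigma_mm`) when enabled. Well contents are assigned to pillar
#' positions in a randomized order drawn from the seeded RNG, mirroring the
#' randomized fill of the physical array.
#'
#' @param layout an [array_layout()]; its analyte channels must all have an
#'   entry in `params$response_slope`.
#' @param params a [sim_params()].
#' @param randomize permute well contents over pillar positions (seeded)?
#' @return a list with elements `grid` (a [channel_grid()] of all analyte
#'   channels plus the lipid reference), `layout` (the realized layout,
#'   i.e. after randomization), `cell_density` (matrix, cells/pixel) and
#'   `truth` (data frame: `well_id`, `role`, `replicate_id`, `channel`,
#'   `nominal_conc`).
#' @export
generate_mimetic_array <- function(layout, params, randomize = TRUE) {
  stopifnot(inherits(layout, "array_layout"), inherits(params, "sim_params"))
  analytes <- unique(layout$nominal$channel)
  missing_slope <- setdiff(analytes, names(params$response_slope))
  if (length(missing_slope) > 0L) {
    stop("no response_slope for channel(s): ",
         paste(missing_slope, collapse = ", "), call. = FALSE)
  }
  set.seed(params$seed)
  wells <- layout$wells
  if (randomize && nrow(wells) > 1L) {
    perm <- sample.int(nrow(wells))
    wells[, c("x0", "y0", "width", "height")] <-
      wells[perm, c("x0", "y0", "width", "height")]
    layout <- array_layout(wells, layout$nominal, layout$grid_width,
                           layout$grid_height, layout$pixel_size_um)
  }
  h <- layout$grid_height; w <- layout$grid_width
  density <- fill_wells(matrix(0, h, w), wells,
                        rep(params$homogenate_cell_density, nrow(wells)))
  sigma_px <- params$diffusion_sigma_mm * 1000 / params$pixel_size_um

  lipid_expected <- blur_field(params$lipid_gain * density, sigma_px)
  intensities <- list()
  for (ch in analytes) {
    nom <- layout$nominal[layout$nominal$channel == ch, ]
    conc <- nom$nominal_conc[match(wells$well_id, nom$well_id)]
    conc_field <- fill_wells(matrix(0, h, w), wells, conc)
    expected <- params$response_slope[[ch]] * params$lipid_gain *
      conc_field * density^2 / params$homogenate_cell_density
    expected <- blur_field(expected, sigma_px)
    intensities[[ch]] <- apply_pixel_noise(expected, params$pixel_rsd,
                                           params$baseline_noise_sd)
  }
  intensities[[params$reference_channel]] <-
    apply_pixel_noise(lipid_expected, params$pixel_rsd,
                      params$baseline_noise_sd)
  chans <- data.frame(
    name = c(analytes, params$reference_channel),
    kind = c(rep("analyte", length(analytes)), "reference"),
    mrm_precursor_mz = NA_real_, mrm_fragment_mz = NA_real_,
    stringsAsFactors = FALSE
  )
  grid <- channel_grid(intensities, params$pixel_size_um, chans)
  truth <- merge(wells[, c("well_id", "role", "replicate_id")],
                 layout$nominal, by = "well_id", sort = FALSE)
  list(grid = grid, layout = layout, cell_density = density, truth = truth)
}

#' Region map for a synthetic dosed tissue section
#'
#' @param labels character matrix of per-pixel region labels;
#'   `"background"` marks off-tissue pixels.
#' @param region_concentrations named list: region label -> named numeric
#'   vector of channel -> ug/g.
#' @param region_densities optional named numeric vector of intact-cell
#'   densities (cells/pixel) per region; regions default to the calibration
#'   homogenate density at generation time.
#' @return an object of class `region_map`.
#' @export
region_map <- function(labels, region_concentrations,
                       region_densities = NULL) {
  stopifnot(is.matrix(labels), is.character(labels))
  regions <- setdiff(unique(as.vector(labels)), "background")
  unknown <- setdiff(regions, names(region_concentrations))
  if (length(unknown) > 0L) {
    stop("config error: no concentrations for region(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (r in names(region_concentrations)) {
    v <- region_concentrations[[r]]
    if (any(v < 0)) stop("region concentrations must be >= 0", call. = FALSE)
  }
  if (!is.null(region_densities) && any(region_densities <= 0)) {
    stop("region densities must be > 0", call. = FALSE)
  }
  structure(list(labels = labels,
                 region_concentrations = region_concentrations,
                 region_densities = region_densities),
            class = "region_map")
}

#' Generate a synthetic dosed tissue section
#'
#' Produces a dosed-organ section on the same generative model as the array
#' wells: the lipid channel scales with local intact-cell density, and the
#' analyte expectation scales with region concentration and local cell
#' density such that the cell-count-corrected summed ratio of a region
#' back-calculates to its true concentration against an array calibration.
#' Background pixels carry baseline noise only.
#'
#' @param rmap a [region_map()].
#' @param params a [sim_params()].
#' @param cell_density_map optional numeric matrix (cells/pixel) of the same
#'   shape as `rmap$labels`; by default built from `rmap$region_densities`
#'   (falling back to the calibration homogenate density), 0 on background.
#' @return a list with `grid` (a [channel_grid()]), `cell_density` (matrix),
#'   `rmap`, and `truth` (the region concentration mapping).
#' @export
generate_dosed_section <- function(rmap, params, cell_density_map = NULL) {
  stopifnot(inherits(rmap, "region_map"), inherits(params, "sim_params"))
  labels <- rmap$labels
  h <- nrow(labels); w <- ncol(labels)
  if (is.null(cell_density_map)) {
    cell_density_map <- matrix(0, h, w)
    for (r in setdiff(unique(as.vector(labels)), "background")) {
      d <- if (!is.null(rmap$region_densities) &&
               r %in% names(rmap$region_densities)) {
        rmap$region_densities[[r]]
      } else {
        params$homogenate_cell_density
      }
      cell_density_map[labels == r] <- d
    }
  }
  if (!identical(dim(cell_density_map), dim(labels))) {
    stop("cell_density_map and region labels must share the grid shape",
         call. = FALSE)
  }
  analytes <- unique(unlist(lapply(rmap$region_concentrations, names)))
  missing_slope <- setdiff(analytes, names(params$response_slope))
  if (length(missing_slope) > 0L) {
    stop("no response_slope for channel(s): ",
         paste(missing_slope, collapse = ", "), call. = FALSE)
  }
  set.seed(params$seed)
  intensities <- list()
  for (ch in analytes) {
    conc_field <- matrix(0, h, w)
    for (r in names(rmap$region_concentrations)) {
      v <- rmap$region_concentrations[[r]]
      if (ch %in% names(v)) conc_field[labels == r] <- v[[ch]]
    }
    expected <- params$response_slope[[ch]] * params$lipid_gain *
      conc_field * cell_density_map^2 / params$homogenate_cell_density
    intensities[[ch]] <- apply_pixel_noise(expected, params$pixel_rsd,
                                           params$baseline_noise_sd)
  }
  lipid_expected <- params$lipid_gain * cell_density_map
  intensities[[params$reference_channel]] <-
    apply_pixel_noise(lipid_expected, params$pixel_rsd,
                      params$baseline_noise_sd)
  chans <- data.frame(
    name = c(analytes, params$reference_channel),
    kind = c(rep("analyte", length(analytes)), "reference"),
    mrm_precursor_mz = NA_real_, mrm_fragment_mz = NA_real_,
    stringsAsFactors = FALSE
  )
  grid <- channel_grid(intensities, params$pixel_size_um, chans)
  list(grid = grid, cell_density = cell_density_map, rmap = rmap,
       truth = rmap$region_concentrations)
}

#' Demo liver-section region map
#'
#' A stylized dosed liver section with the three regions quantified in
#' regional drug studies: a lesion focus, a connective-tissue/vessel band,
#' and surrounding parenchyma, inside a background frame. Default
#' concentrations place the lesion highest for the first compound and the
#' parenchyma highest for the second; default intact-cell densities make the
#' parenchyma denser and the connective tissue sparser than the calibration
#' homogenate, so cell-count correction is exercised.
#'
#' @param width,height raster extent, pixels.
#' @param concentrations named list region -> (channel -> ug/g).
#' @param densities named numeric vector region -> cells/pixel.
#' @param border background frame width, pixels.
#' @return a [region_map()].
#' @export
demo_region_map <- function(width = 120, height = 120,
                            concentrations = list(
                              lesion = c(cmpdA = 500, cmpdB = 300),
                              connective = c(cmpdA = 75, cmpdB = 170),
                              parenchyma = c(cmpdA = 240, cmpdB = 495)),
                            densities = c(lesion = 60, connective = 40,
                                          parenchyma = 80),
                            border = 6L) {
  labels <- matrix("parenchyma", nrow = height, ncol = width)
  labels[seq_len(border), ] <- "background"
  labels[height - seq_len(border) + 1L, ] <- "background"
  labels[, seq_len(border)] <- "background"
  labels[, width - seq_len(border) + 1L] <- "background"
  cx <- width * 0.33; cy <- height * 0.33; r <- min(width, height) * 0.14
  xs <- matrix(rep(seq_len(width), each = height), nrow = height)
  ys <- matrix(rep(seq_len(height), times = width), nrow = height)
  lesion <- (xs - cx)^2 + (ys - cy)^2 <= r^2
  band <- xs >= width * 0.60 & xs <= width * 0.72
  labels[band & labels != "background"] <- "connective"
  labels[lesion & labels != "background"] <- "lesion"
  region_map(labels, concentrations, densities)
}

#' Replicate ROI masks within a region
#'
#' Splits a region's pixels into `n` disjoint random subsets, emulating the
#' extraction of a region of interest in triplicate.
#'
#' @param rmap a [region_map()].
#' @param region region label.
#' @param n number of replicate masks.
#' @param seed RNG seed for the split.
#' @return a list of `n` [roi_mask()] objects named `<region>_1` ... .
#' @export
region_replicate_masks <- function(rmap, region, n = 3L, seed = 1L) {
  idx <- which(rmap$labels == region, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("region '", region, "' has no pixels",
                            call. = FALSE)
  if (nrow(idx) < n) stop("region '", region, "' has fewer pixels than ",
                          "replicates", call. = FALSE)
  set.seed(seed)
  ord <- sample.int(nrow(idx))
  grp <- rep_len(seq_len(n), nrow(idx))[order(ord)]
  lapply(seq_len(n), function(k) {
    sel <- idx[grp == k, , drop = FALSE]
    roi_mask(sel[, "col"] - 1L, sel[, "row"] - 1L,
             name = paste0(region, "_", k))
  })
}

#' Simulate a replicated calibration experiment
#'
#' Generates `n_sections` replicate array sections (replicate homogenate
#' preparations / slide sections) from the same layout and pools the
#' per-well summed-ratio observations; section `s` uses seed
#' `params$seed + s - 1` and its wells carry `replicate_id = s`.
#'
#' @param layout an [array_layout()].
#' @param params a [sim_params()].
#' @param analyte analyte channel to extract.
#' @param n_sections number of replicate sections.
#' @param randomize randomize well positions per section?
#' @return a list with `observations` (pooled data frame, see
#'   [extract_array_ratios()]), `sections` (list of generator outputs) and
#'   `calibration_density` (cells/pixel of the homogenate wells).
#' @export
simulate_calibration_experiment <- function(layout, params,
                                            analyte = names(params$response_slope)[1L],
                                            n_sections = 3L,
                                            randomize = TRUE) {
  sections <- vector("list", n_sections)
  obs <- vector("list", n_sections)
  for (s in seq_len(n_sections)) {
    p <- params
    p$seed <- params$seed + s - 1L
    sec <- generate_mimetic_array(layout, p, randomize = randomize)
    o <- extract_array_ratios(sec$grid, sec$layout, analyte,
                              params$reference_channel)
    o$replicate_id <- s
    sections[[s]] <- sec
    obs[[s]] <- o
  }
  list(observations = do.call(rbind, obs), sections = sections,
       calibration_density = params$homogenate_cell_density)
}
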