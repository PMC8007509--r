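#' Affine registration transform
#'
#' A 2x3 affine matrix mapping ROI-source coordinates (e.g. histology space)
#' to MSI pixel coordinates: `p' = A %*% p + b` with `A = m[, 1:2]`,
#' `b = m[, 3]`. The linear part must be invertible.
#'
#' @param m numeric 2x3 matrix (or 2x2 linear part with `b` supplied).
#' @param b optional length-2 translation when `m` is 2x2.
#' @return an object of class `registration_transform`.
#' @export
registration_transform <- function(m = diag(2), b = c(0, 0)) {
  if (is.matrix(m) && all(dim(m) == c(2L, 3L))) {
    b <- m[, 3L]; m <- m[, 1:2]
  }
  if (!is.matrix(m) || !all(dim(m) == c(2L, 2L))) {
    stop("transform must be a 2x3 (or 2x2 + translation) matrix",
         call. = FALSE)
  }
  if (abs(det(m)) < .Machine$double.eps) {
    stop("transform linear part is singular", call. = FALSE)
  }
  structure(list(A = m, b = as.numeric(b)), class = "registration_transform")
}

#' Register an ROI mask onto the MSI grid
#'
#' Maps each source pixel through the affine transform, rounds to the
#' nearest MSI pixel (no intensity interpolation: MRM counts are per-pixel
#' integrals, so fabricating intermediate values would invent signal),
#' de-duplicates, and drops pixels falling outside the grid with a message.
#'
#' @param grid a [channel_grid()].
#' @param mask an [roi_mask()] in source coordinates.
#' @param transform a [registration_transform()]; identity by default.
#' @return an [roi_mask()] in MSI pixel coordinates.
#' @export
register_and_extract <- function(grid, mask,
                                 transform = registration_transform()) {
  stopifnot(inherits(grid, "channel_grid"), inherits(mask, "roi_mask"),
            inherits(transform, "registration_transform"))
  src <- rbind(mask$x, mask$y)
  dst <- transform$A %*% src + transform$b
  x <- as.integer(round(dst[1L, ])); y <- as.integer(round(dst[2L, ]))
  inside <- x >= 0 & x < grid$width & y >= 0 & y < grid$height
  if (!any(inside)) {
    stop("empty ROI '", roi_name(mask),
         "' after registration: all pixels fall outside the grid",
         call. = FALSE)
  }
  if (any(!inside)) {
    message("register_and_extract '", roi_name(mask), "': dropped ",
            sum(!inside), " pixel(s) outside the grid")
  }
  n_in <- sum(inside)
  out <- suppressMessages(roi_mask(x[inside], y[inside],
                                   name = roi_name(mask)))
  if (nrow(out) < n_in) {
    message("register_and_extract '", roi_name(mask), "': ",
            n_in - nrow(out), " pixel(s) merged by rounding")
  }
  out
}

#' Cell-count-corrected summed ratio
#'
#' The endogenous-lipid reference scales with intact-cell density, so summed
#' analyte/lipid ratios from regions sparser than the calibration
#' homogenates are deflated relative to the calibrants (and vice versa). The
#' correction rescales the ROI ratio by the ratio of the calibration
#' homogenate cell density to the ROI's mean cell density:
#' `corrected = summed_ratio * calibration_density / roi_mean_density`,
#' reducing to the raw ratio when the densities match.
#'
#' @param grid a [channel_grid()].
#' @param pixels an [roi_mask()] in MSI coordinates.
#' @param analyte,reference channel names.
#' @param cell_density numeric matrix of cells/pixel on the grid raster (or
#'   a [channel_grid()] carrying a `"cell_density"` channel).
#' @param calibration_density mean cells/pixel of the homogenate calibration
#'   wells (> 0).
#' @return the corrected ratio (a single number).
#' @export
cell_corrected_ratio <- function(grid, pixels, analyte, reference,
                                 cell_density, calibration_density) {
  roi_cell_stats(grid, pixels, analyte, reference, cell_density,
                 calibration_density)$corrected_ratio
}

roi_cell_stats <- function(grid, pixels, analyte, reference, cell_density,
                           calibration_density) {
  if (inherits(cell_density, "channel_grid")) {
    cell_density <- grid_channel(cell_density, "cell_density")
  }
  if (!is.matrix(cell_density) ||
      !identical(dim(cell_density), c(grid$height, grid$width))) {
    stop("cell_density must be a matrix matching the grid shape",
         call. = FALSE)
  }
  if (calibration_density <= 0) {
    stop("calibration_density must be > 0", call. = FALSE)
  }
  check_mask_in_bounds(pixels, grid)
  raw <- summed_ratio(grid, pixels, analyte, reference)
  cells <- cell_density[cbind(pixels$y + 1L, pixels$x + 1L)]
  mean_density <- mean(cells)
  if (mean_density == 0) {
    stop("correction error: ROI '", roi_name(pixels),
         "' has zero mean cell density", call. = FALSE)
  }
  list(raw_ratio = raw,
       corrected_ratio = raw * calibration_density / mean_density,
       cell_count = sum(cells), n_pixels = nrow(pixels))
}

#' Quantify regions of interest on a dosed section
#'
#' For each region, every replicate mask is registered (optional transform),
#' its cell-count-corrected summed ratio back-calculated through the
#' calibration curve, and the replicates summarized as mean +/- sample SD
#' (SD only for n >= 2). Flags propagate conservatively: a region with any
#' replicate above the ULOQ is reported `">ULOQ"` without a concentration; a
#' region whose analyte channel carries no signal anywhere on the grid is
#' reported `"ND"`; regions whose mean falls below the LOD or LLOQ are
#' flagged `"<LOD"` / `"<LLOQ"`.
#'
#' @param grid a [channel_grid()] of the dosed section.
#' @param rois named list: region name -> list of replicate [roi_mask()]s.
#' @param curve a `calibration_curve` for `analyte`, or `NULL` (all regions
#'   reported `"ND"`, mirroring a channel that was not acquired).
#' @param analyte,reference channel names.
#' @param cell_density matrix of cells/pixel (or grid with a
#'   `"cell_density"` channel).
#' @param calibration_density cells/pixel of the calibration homogenates.
#' @param transform optional [registration_transform()] applied to every
#'   mask.
#' @return data frame with one row per region: `roi_name`, `n`, `n_pixels`,
#'   `cell_count`, `raw_ratio`, `corrected_ratio`, `conc`, `conc_sd`,
#'   `flag`.
#' @export
quantify_rois <- function(grid, rois, curve, analyte, reference,
                          cell_density, calibration_density,
                          transform = NULL) {
  stopifnot(is.list(rois), !is.null(names(rois)))
  analyte_absent <- is.null(curve) ||
    !analyte %in% grid_channels(grid) ||
    all(grid_channel(grid, analyte) == 0)
  rows <- lapply(names(rois), function(rn) {
    masks <- rois[[rn]]
    if (inherits(masks, "roi_mask")) masks <- list(masks)
    if (length(masks) < 1L) stop("region '", rn, "' has no replicate masks",
                                 call. = FALSE)
    if (!is.null(transform)) {
      masks <- lapply(masks, function(m) register_and_extract(grid, m,
                                                              transform))
    }
    if (analyte_absent) {
      return(data.frame(roi_name = rn, n = length(masks),
                        n_pixels = sum(vapply(masks, nrow, integer(1L))),
                        cell_count = NA_real_, raw_ratio = NA_real_,
                        corrected_ratio = NA_real_, conc = NA_real_,
                        conc_sd = NA_real_, flag = "ND",
                        stringsAsFactors = FALSE))
    }
    st <- lapply(masks, function(m) {
      roi_cell_stats(grid, m, analyte, reference, cell_density,
                     calibration_density)
    })
    corrected <- vapply(st, `[[`, numeric(1L), "corrected_ratio")
    bc <- back_calculate(curve, corrected)
    n <- length(masks)
    flag <- if (any(bc$flag == "above_uloq")) ">ULOQ"
            else if (mean(bc$conc) < curve$lod) "<LOD"
            else if (mean(bc$conc) < curve$lloq) "<LLOQ"
            else "ok"
    data.frame(
      roi_name = rn, n = n,
      n_pixels = sum(vapply(st, `[[`, numeric(1L), "n_pixels")),
      cell_count = sum(vapply(st, `[[`, numeric(1L), "cell_count")),
      raw_ratio = mean(vapply(st, `[[`, numeric(1L), "raw_ratio")),
      corrected_ratio = mean(corrected),
      conc = if (flag == ">ULOQ") NA_real_ else mean(bc$conc),
      conc_sd = if (n >= 2L && flag != ">ULOQ") sd(bc$conc) else NA_real_,
      flag = flag, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Pairwise fold differences between labelled concentrations
#'
#' For every pair of labels, reports `fold = larger / smaller` together with
#' the direction (which label is higher), keeping full precision and a
#' 1-decimal display value. Pairs involving a flagged value (`">ULOQ"`,
#' `"ND"`, ...) or a zero denominator are skipped and listed in the
#' `skipped` attribute.
#'
#' @param labels character vector of region/sample labels.
#' @param concs numeric concentrations, ug/g.
#' @param flags optional character vector; entries other than `"ok"` (or
#'   `NA`/`""`) mark values unusable for ratios.
#' @return data frame with columns `higher`, `lower`, `fold`,
#'   `fold_display`; attribute `"skipped"` is a character vector of notes.
#' @export
fold_differences <- function(labels, concs, flags = NULL) {
  stopifnot(length(labels) == length(concs))
  if (anyDuplicated(labels)) stop("labels must be unique", call. = FALSE)
  usable <- if (is.null(flags)) rep(TRUE, length(concs))
            else is.na(flags) | flags %in% c("", "ok")
  rows <- list(); skipped <- character()
  n <- length(labels)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    pair <- paste(labels[i], "vs", labels[j])
    if (!usable[i] || !usable[j]) {
      skipped <- c(skipped, paste0(pair, ": flagged value"))
      next
    }
    lo <- min(concs[i], concs[j]); hi <- max(concs[i], concs[j])
    if (lo == 0) {
      skipped <- c(skipped, paste0(pair, ": zero denominator"))
      next
    }
    hi_lab <- if (concs[i] >= concs[j]) labels[i] else labels[j]
    lo_lab <- if (concs[i] >= concs[j]) labels[j] else labels[i]
    rows[[length(rows) + 1L]] <- data.frame(
      higher = hi_lab, lower = lo_lab, fold = hi / lo,
      fold_display = round(hi / lo, 1), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(higher = character(), lower = character(), fold = numeric(),
               fold_display = numeric(), stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Concordance between regional MSI and bulk LC-MS concentrations
#'
#' LC-MS assays of homogenized whole organs are only comparable to the MSI
#' parenchyma values (the dominant contributor to the homogenate), and are
#' reported as concentration ranges. Concordance per sample is a fold
#' difference of at least 1: exactly 1 when the MSI value lies inside the
#' LC-MS range, otherwise the ratio to the nearest range bound (the
#' conservative reading of a range-valued reference).
#'
#' @param msi data frame with columns `sample_id`, `conc`, and optionally
#'   `flag` (rows flagged other than `"ok"` are excluded with a note).
#' @param lcms data frame with columns `sample_id`, `low`, `high` (ug/g,
#'   `0 < low <= high`).
#' @return list with `per_sample` (data frame: `sample_id`, `msi_conc`,
#'   `low`, `high`, `fold`) and `max_fold`; attribute `"skipped"` on
#'   `per_sample` lists excluded samples.
#' @export
lcms_concordance <- function(msi, lcms) {
  stopifnot(all(c("sample_id", "conc") %in% names(msi)),
            all(c("sample_id", "low", "high") %in% names(lcms)))
  if (any(lcms$low <= 0 | lcms$high < lcms$low)) {
    stop("LC-MS ranges must satisfy 0 < low <= high", call. = FALSE)
  }
  skipped <- character()
  if ("flag" %in% names(msi)) {
    bad <- !(is.na(msi$flag) | msi$flag %in% c("", "ok"))
    if (any(bad)) {
      skipped <- paste0(msi$sample_id[bad], ": flagged ", msi$flag[bad])
      msi <- msi[!bad, , drop = FALSE]
    }
  }
  unmatched <- setdiff(msi$sample_id, lcms$sample_id)
  if (length(unmatched) > 0L) {
    stop("no LC-MS range for sample(s): ", paste(unmatched, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(msi$sample_id, lcms$sample_id)
  low <- lcms$low[idx]; high <- lcms$high[idx]
  fold <- ifelse(msi$conc < low, low / msi$conc,
          ifelse(msi$conc > high, msi$conc / high, 1))
  per_sample <- data.frame(sample_id = msi$sample_id, msi_conc = msi$conc,
                           low = low, high = high, fold = fold,
                           stringsAsFactors = FALSE)
  attr(per_sample, "skipped") <- skipped
  list(per_sample = per_sample,
       max_fold = if (nrow(per_sample)) max(fold) else NA_real_)
}

#' Inter-well diffusion / cross-contamination check
#'
#' Measures how much analyte signal leaks from the wells into the gelatin
#' corridors. Corridor pixels lie between wells (inside the bounding box of
#' all wells) at least `corridor_margin_px` pixels from every well edge;
#' far-background pixels lie outside that bounding box expanded by the
#' margin. Per channel, the contamination fraction is
#' `(mean corridor intensity - mean far-background intensity) / (mean
#' intensity of the corridor pixels' nearest wells)`, clipped at 0.
#'
#' The far background is only a clean reference when the imaged area extends
#' well beyond the outer wells relative to the diffusion length probed
#' (e.g. `default_array_layout(margin_mm = 4)` for diffusion up to ~1 mm);
#' with a tight crop the background ring is itself contaminated and the
#' subtraction underestimates the leak.
#'
#' @param grid a [channel_grid()].
#' @param layout the realized [array_layout()] of the section.
#' @param corridor_margin_px margin in pixels (>= 1).
#' @param channels channels to report; defaults to all grid channels.
#' @return named numeric vector of contamination fractions per channel.
#' @export
diffusion_check <- function(grid, layout, corridor_margin_px = 3L,
                            channels = NULL) {
  stopifnot(inherits(grid, "channel_grid"), inherits(layout, "array_layout"))
  if (nrow(layout$wells) < 2L) {
    stop("geometry error: need >= 2 wells for a corridor", call. = FALSE)
  }
  if (is.null(channels)) channels <- grid_channels(grid)
  w <- grid$width; h <- grid$height
  xs <- matrix(rep(seq_len(w) - 1L, each = h), nrow = h)
  ys <- matrix(rep(seq_len(h) - 1L, times = w), nrow = h)
  wells <- layout$wells
  # Chebyshev distance of each pixel to each well rectangle, and nearest well
  dist_min <- matrix(Inf, h, w); nearest <- matrix(NA_integer_, h, w)
  for (i in seq_len(nrow(wells))) {
    wl <- wells[i, ]
    dx <- pmax(wl$x0 - xs, xs - (wl$x0 + wl$width - 1L), 0)
    dy <- pmax(wl$y0 - ys, ys - (wl$y0 + wl$height - 1L), 0)
    d <- pmax(dx, dy)
    upd <- d < dist_min
    nearest[upd] <- i
    dist_min[upd] <- d[upd]
  }
  bx0 <- min(wells$x0); bx1 <- max(wells$x0 + wells$width) - 1L
  by0 <- min(wells$y0); by1 <- max(wells$y0 + wells$height) - 1L
  in_bbox <- xs >= bx0 & xs <= bx1 & ys >= by0 & ys <= by1
  corridor <- in_bbox & dist_min >= corridor_margin_px
  m <- corridor_margin_px
  background <- !(xs >= bx0 - m & xs <= bx1 + m &
                  ys >= by0 - m & ys <= by1 + m)
  if (!any(corridor)) {
    stop("geometry error: no corridor pixels at margin ", corridor_margin_px,
         call. = FALSE)
  }
  out <- numeric(length(channels)); names(out) <- channels
  for (ch in channels) {
    mat <- grid_channel(grid, ch)
    well_means <- vapply(seq_len(nrow(wells)), function(i) {
      wl <- wells[i, ]
      mean(mat[(wl$y0 + 1L):(wl$y0 + wl$height),
               (wl$x0 + 1L):(wl$x0 + wl$width)])
    }, numeric(1L))
    denom <- mean(well_means[nearest[corridor]])
    if (denom == 0) {
      out[ch] <- 0
      next
    }
    bg <- if (any(background)) mean(mat[background]) else 0
    out[ch] <- max(0, (mean(mat[corridor]) - bg) / denom)
  }
  out
}

#' Write a regional quantification results CSV
#'
#' @param results data frame (rows from [quantify_rois()], possibly with
#'   extra columns `sample_id`, `dose`, `channel` prepended).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_roi_results_csv <- function(results, path) {
  write.csv(results, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
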