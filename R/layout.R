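#' Mimetic tissue-array layout
#'
#' Describes the geometry and contents of a gelatin tissue-array block:
#' well rectangles (0-based half-open pixel coordinates
#' `[x0, x0 + width) x [y0, y0 + height)`), each well's role
#' (`"calibration"`, `"blank"` or `"qc"`), its replicate id, and the nominal
#' spiked concentration of every analyte channel in micrograms of compound
#' per gram of tissue.
#'
#' @param wells data frame with columns `well_id`, `role`, `replicate_id`,
#'   `x0`, `y0`, `width`, `height`.
#' @param nominal data frame with columns `well_id`, `channel`,
#'   `nominal_conc` (one row per well x analyte channel). Blank wells must
#'   be 0 everywhere; calibration wells strictly positive.
#' @param grid_width,grid_height raster extent in pixels the wells live on.
#' @param pixel_size_um pixel edge length in micrometres.
#' @return an object of class `array_layout`.
#' @export
array_layout <- function(wells, nominal, grid_width, grid_height,
                         pixel_size_um) {
  need <- c("well_id", "role", "replicate_id", "x0", "y0", "width", "height")
  if (!is.data.frame(wells) || !all(need %in% names(wells))) {
    stop("`wells` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(wells$well_id)) {
    stop("well ids must be unique", call. = FALSE)
  }
  if (!all(wells$role %in% c("calibration", "blank", "qc"))) {
    stop("well role must be calibration, blank or qc", call. = FALSE)
  }
  if (any(wells$width < 1 | wells$height < 1)) {
    stop("well width/height must be >= 1 pixel", call. = FALSE)
  }
  out <- wells$x0 < 0 | wells$y0 < 0 |
    wells$x0 + wells$width > grid_width |
    wells$y0 + wells$height > grid_height
  if (any(out)) {
    stop("layout error: well(s) ",
         paste(wells$well_id[out], collapse = ", "),
         " fall outside the ", grid_width, "x", grid_height, " grid",
         call. = FALSE)
  }
  # pairwise disjoint (half-open rectangles)
  n <- nrow(wells)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      a <- wells[i, ]; b <- wells[j, ]
      overlap_x <- a$x0 < b$x0 + b$width && b$x0 < a$x0 + a$width
      overlap_y <- a$y0 < b$y0 + b$height && b$y0 < a$y0 + a$height
      if (overlap_x && overlap_y) {
        stop("layout error: wells ", a$well_id, " and ", b$well_id,
             " overlap", call. = FALSE)
      }
    }
  }
  if (!is.data.frame(nominal) ||
      !all(c("well_id", "channel", "nominal_conc") %in% names(nominal))) {
    stop("`nominal` must have columns well_id, channel, nominal_conc",
         call. = FALSE)
  }
  if (!all(nominal$well_id %in% wells$well_id)) {
    stop("`nominal` refers to unknown well ids", call. = FALSE)
  }
  if (any(nominal$nominal_conc < 0)) {
    stop("nominal concentrations must be >= 0", call. = FALSE)
  }
  role_of <- setNames(wells$role, wells$well_id)
  blk <- role_of[nominal$well_id] == "blank" & nominal$nominal_conc != 0
  if (any(blk)) stop("blank wells must have nominal concentration 0",
                     call. = FALSE)
  cal0 <- role_of[nominal$well_id] == "calibration" & nominal$nominal_conc <= 0
  if (any(cal0)) stop("calibration wells must have strictly positive nominal ",
                      "concentrations", call. = FALSE)
  rownames(wells) <- rownames(nominal) <- NULL
  structure(
    list(wells = wells, nominal = nominal,
         grid_width = as.integer(grid_width),
         grid_height = as.integer(grid_height),
         pixel_size_um = pixel_size_um),
    class = "array_layout"
  )
}

#' @export
print.array_layout <- function(x, ...) {
  cat("<array_layout> ", nrow(x$wells), " wells on ", x$grid_width, "x",
      x$grid_height, " px (", x$pixel_size_um, " um/px)\n", sep = "")
  print(table(x$wells$role))
  invisible(x)
}

#' Default 15-well mimetic array layout
#'
#' The standard high-throughput tissue-array design: a 20 x 20 mm gelatin
#' block cast from a mold with 16 pillar positions on a 4 x 4 grid (3 x 3 mm
#' square wells, 2 mm gelatin corridors, 1 mm outer margin), of which one
#' corner is left empty as an orientation marker, leaving 15 wells. The
#' default fill is an 8-level calibration ladder of 12.5, 25, 50, 125, 250,
#' 500, 1250 and 2500 ug/g, triplicate blanks, and duplicate QC wells at 25
#' and 1250 ug/g; replicate QC and blank homogenate preparations beyond one
#' section are modelled as replicate sections (see
#' [simulate_calibration_experiment()]).
#'
#' All analyte channels share the nominal ladder (the homogenates are spiked
#' with every compound).
#'
#' @param conc_levels calibration ladder, ug/g.
#' @param qc_levels QC nominal concentrations, ug/g.
#' @param qc_wells_per_level number of wells per QC level in one section.
#' @param blank_wells number of blank wells.
#' @param analytes names of the analyte channels.
#' @param pixel_size_um raster resolution, micrometres per pixel.
#' @param well_mm well edge length, mm.
#' @param spacing_mm gelatin corridor width between wells, mm.
#' @param margin_mm gelatin margin around the outer wells, mm.
#' @return an [array_layout()].
#' @export
default_array_layout <- function(conc_levels = c(12.5, 25, 50, 125, 250, 500,
                                                 1250, 2500),
                                 qc_levels = c(25, 1250),
                                 qc_wells_per_level = 2L,
                                 blank_wells = 3L,
                                 analytes = c("cmpdA", "cmpdB"),
                                 pixel_size_um = 100,
                                 well_mm = 3, spacing_mm = 2, margin_mm = 1) {
  specs <- rbind(
    data.frame(role = "calibration", conc = conc_levels,
               replicate_id = 1L, stringsAsFactors = FALSE),
    data.frame(role = "blank", conc = 0,
               replicate_id = seq_len(blank_wells), stringsAsFactors = FALSE),
    do.call(rbind, lapply(qc_levels, function(q) {
      data.frame(role = "qc", conc = q,
                 replicate_id = seq_len(qc_wells_per_level),
                 stringsAsFactors = FALSE)
    }))
  )
  n_wells <- nrow(specs)
  n_cols <- ceiling(sqrt(n_wells + 1))
  n_rows <- ceiling((n_wells + 1) / n_cols)

  px_per_mm <- 1000 / pixel_size_um
  wpx <- as.integer(round(well_mm * px_per_mm))
  spx <- as.integer(round(spacing_mm * px_per_mm))
  mpx <- as.integer(round(margin_mm * px_per_mm))
  grid_w <- mpx * 2L + n_cols * wpx + (n_cols - 1L) * spx
  grid_h <- mpx * 2L + n_rows * wpx + (n_rows - 1L) * spx

  # slot positions row-major; the last slot (a corner) stays empty
  slots <- expand.grid(col = seq_len(n_cols) - 1L, row = seq_len(n_rows) - 1L)
  slots <- slots[seq_len(n_wells), , drop = FALSE]
  id_num <- seq_len(n_wells)
  wells <- data.frame(
    well_id = sprintf("W%02d_%s", id_num,
                      ifelse(specs$role == "calibration",
                             paste0("cal", specs$conc),
                             ifelse(specs$role == "blank",
                                    paste0("blank", specs$replicate_id),
                                    paste0("qc", specs$conc, "_",
                                           specs$replicate_id)))),
    role = specs$role,
    replicate_id = specs$replicate_id,
    x0 = mpx + slots$col * (wpx + spx),
    y0 = mpx + slots$row * (wpx + spx),
    width = wpx, height = wpx,
    stringsAsFactors = FALSE
  )
  nominal <- expand.grid(well_id = wells$well_id, channel = analytes,
                         stringsAsFactors = FALSE)
  nominal$nominal_conc <- specs$conc[match(nominal$well_id, wells$well_id)]
  array_layout(wells, nominal, grid_w, grid_h, pixel_size_um)
}

#' Read / write an array layout (YAML or JSON)
#'
#' The on-disk format is a mapping with keys `pixel_size_um`, `grid_width`,
#' `grid_height` and `wells`, each well carrying `well_id`, `role`,
#' `replicate_id`, `x0`, `y0`, `width`, `height` and a `nominal` mapping of
#' channel name to ug/g. Extension `.json` selects JSON, anything else YAML.
#'
#' @param layout an [array_layout()].
#' @param path file path.
#' @return `read_array_layout` returns an [array_layout()];
#'   `write_array_layout` returns `path` invisibly.
#' @export
write_array_layout <- function(layout, path) {
  stopifnot(inherits(layout, "array_layout"))
  wl <- lapply(seq_len(nrow(layout$wells)), function(i) {
    w <- layout$wells[i, ]
    nom <- layout$nominal[layout$nominal$well_id == w$well_id, ]
    c(as.list(w), list(nominal = as.list(setNames(nom$nominal_conc,
                                                  nom$channel))))
  })
  obj <- list(pixel_size_um = layout$pixel_size_um,
              grid_width = layout$grid_width,
              grid_height = layout$grid_height,
              wells = wl)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' @rdname write_array_layout
#' @export
read_array_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path, call. = FALSE)
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  wl <- obj$wells
  wells <- do.call(rbind, lapply(wl, function(w) {
    data.frame(well_id = w$well_id, role = w$role,
               replicate_id = as.integer(w$replicate_id),
               x0 = as.integer(w$x0), y0 = as.integer(w$y0),
               width = as.integer(w$width), height = as.integer(w$height),
               stringsAsFactors = FALSE)
  }))
  nominal <- do.call(rbind, lapply(wl, function(w) {
    data.frame(well_id = w$well_id, channel = names(w$nominal),
               nominal_conc = as.numeric(unlist(w$nominal)),
               stringsAsFactors = FALSE)
  }))
  array_layout(wells, nominal, obj$grid_width, obj$grid_height,
               obj$pixel_size_um)
}

#' Well pixel mask
#'
#' @param layout an [array_layout()].
#' @param well_id well identifier.
#' @return an [roi_mask()] of the well's pixels.
#' @export
well_mask <- function(layout, well_id) {
  w <- layout$wells[layout$wells$well_id == well_id, ]
  if (nrow(w) != 1L) stop("unknown well id '", well_id, "'", call. = FALSE)
  rect_mask(w$x0, w$y0, w$width, w$height, name = well_id)
}
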