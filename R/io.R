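#' Write / read a channel grid (TSV + JSON sidecar)
#'
#' The native on-disk format is a long-format TSV with columns
#' `x`, `y`, `channel`, `intensity` (0-based pixel coordinates, one row per
#' pixel per channel) next to a JSON sidecar holding the grid dimensions,
#' pixel size and channel definitions. The sidecar path is the TSV path with
#' its extension replaced by `.json`. Values are written at full double
#' precision, so write-then-read restores the grid exactly.
#'
#' On read, pixels absent from the TSV are filled with 0 (a warning reports
#' the count); duplicate `(x, y, channel)` rows, coordinates outside the
#' declared dimensions, channels not declared in the sidecar, and negative
#' or non-finite intensities are format errors. A channel declared in the
#' sidecar but absent from the TSV is read as an all-zero image with a
#' warning.
#'
#' @param grid a [channel_grid()].
#' @param path TSV file path (the sidecar is derived from it).
#' @return `read_grid` returns a [channel_grid()]; `write_grid` returns
#'   `path` invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "channel_grid"))
  sidecar <- grid_sidecar_path(path)
  rows <- lapply(names(grid$intensities), function(ch) {
    m <- grid$intensities[[ch]]
    data.frame(
      x = rep(seq_len(grid$width) - 1L, each = grid$height),
      y = rep(seq_len(grid$height) - 1L, times = grid$width),
      channel = ch,
      intensity = as.vector(m),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  tab$intensity <- sprintf("%.17g", tab$intensity)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    width = grid$width, height = grid$height,
    pixel_size_um = grid$pixel_size_um,
    channels = grid$channels
  )
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

grid_sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  sidecar <- grid_sidecar_path(path)
  if (!file.exists(path)) stop("grid TSV not found: ", path, call. = FALSE)
  if (!file.exists(sidecar)) stop("grid sidecar not found: ", sidecar,
                                  call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  channels <- validate_channel_defs(as.data.frame(meta$channels))
  width <- as.integer(meta$width); height <- as.integer(meta$height)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("integer", "integer", "character",
                                   "numeric"))
  if (!identical(names(tab), c("x", "y", "channel", "intensity"))) {
    stop("format error: grid TSV must have columns x, y, channel, intensity",
         call. = FALSE)
  }
  unknown <- setdiff(unique(tab$channel), channels$name)
  if (length(unknown) > 0L) {
    stop("format error: TSV channel(s) not declared in sidecar: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(tab$x < 0 | tab$x >= width | tab$y < 0 | tab$y >= height)) {
    stop("format error: pixel coordinates outside the declared ",
         width, "x", height, " grid", call. = FALSE)
  }
  if (anyNA(tab$intensity) || any(!is.finite(tab$intensity))) {
    stop("format error: NA or non-finite intensities", call. = FALSE)
  }
  if (any(tab$intensity < 0)) {
    stop("format error: negative intensities", call. = FALSE)
  }
  key <- paste(tab$x, tab$y, tab$channel)
  if (anyDuplicated(key)) {
    stop("format error: duplicate (x, y, channel) rows", call. = FALSE)
  }
  n_expected <- width * height
  intensities <- list()
  n_missing <- 0L
  for (ch in channels$name) {
    sub <- tab[tab$channel == ch, ]
    m <- matrix(0, nrow = height, ncol = width)
    if (nrow(sub) == 0L) {
      warning("channel '", ch, "' declared in sidecar but absent from TSV; ",
              "read as all-zero", call. = FALSE)
    } else {
      m[cbind(sub$y + 1L, sub$x + 1L)] <- sub$intensity
      n_missing <- n_missing + (n_expected - nrow(sub))
    }
    intensities[[ch]] <- m
  }
  if (n_missing > 0L) {
    warning(n_missing, " missing pixel value(s) filled with 0", call. = FALSE)
  }
  channel_grid(intensities, meta$pixel_size_um, channels)
}

#' Write / read an ROI mask (TSV of 0-based pixel coordinates)
#'
#' The mask format is a two-column TSV (`x`, `y`) of 0-based pixel
#' coordinates, pixel centres on the MSI grid. Duplicate rows are collapsed
#' on read with a message; an empty mask file is an error.
#'
#' @param mask an [roi_mask()].
#' @param path file path.
#' @param name ROI label to attach on read (default: file name without
#'   extension).
#' @return `read_roi_mask` returns an [roi_mask()]; `write_roi_mask` returns
#'   `path` invisibly.
#' @export
write_roi_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  write.table(as.data.frame(mask)[, c("x", "y")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_mask
#' @export
read_roi_mask <- function(path, name = NULL) {
  if (!file.exists(path)) stop("ROI mask not found: ", path, call. = FALSE)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = "\t",
               colClasses = c("integer", "integer")),
    error = function(e) {
      stop("ROI '", name, "': cannot read mask (empty file?): ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (nrow(tab) == 0L) {
    stop("ROI '", name, "' is empty", call. = FALSE)
  }
  roi_mask(tab$x, tab$y, name = name)
}

#' Write the ground-truth table of a synthetic array
#'
#' @param truth data frame (e.g. from [generate_mimetic_array()]) with
#'   columns `well_id`, `role`, `replicate_id`, `channel`, `nominal_conc`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
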