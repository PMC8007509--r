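#' Multi-channel MSI intensity grid
#'
#' A `channel_grid` holds per-pixel intensities for one or more named MRM
#' channels on a rectangular raster. Intensities are stored as one numeric
#' matrix per channel with `height` rows and `width` columns; pixel (x, y)
#' with the 0-based convention (0, 0) = top-left, x growing rightward and y
#' downward, lives at matrix element `[y + 1, x + 1]`.
#'
#' Cell-density maps reuse this container under the reserved channel name
#' `"cell_density"`.
#'
#' @param intensities named list of numeric matrices, one per channel; all
#'   the same dimension, all values finite and non-negative.
#' @param pixel_size_um edge length of one pixel in micrometres.
#' @param channels optional data frame describing the channels with columns
#'   `name`, `kind` (`"analyte"` or `"reference"`), and optional
#'   `mrm_precursor_mz`, `mrm_fragment_mz`. Defaults to kind `"analyte"`
#'   for every channel except `"cell_density"` and names containing
#'   `"lipid"`, which default to `"reference"`.
#' @return an object of class `channel_grid`.
#' @export
channel_grid <- function(intensities, pixel_size_um, channels = NULL) {
  if (!is.list(intensities) || length(intensities) == 0L ||
      is.null(names(intensities)) || anyDuplicated(names(intensities))) {
    stop("`intensities` must be a non-empty list with unique channel names",
         call. = FALSE)
  }
  dims <- dim(intensities[[1L]])
  for (nm in names(intensities)) {
    m <- intensities[[nm]]
    if (!is.matrix(m) || !is.numeric(m)) {
      stop("channel '", nm, "' is not a numeric matrix", call. = FALSE)
    }
    if (!identical(dim(m), dims)) {
      stop("channel '", nm, "' has dimensions ", paste(dim(m), collapse = "x"),
           ", expected ", paste(dims, collapse = "x"), call. = FALSE)
    }
    if (anyNA(m) || any(!is.finite(m))) {
      stop("channel '", nm, "' contains NA or non-finite intensities",
           call. = FALSE)
    }
    if (any(m < 0)) {
      stop("channel '", nm, "' contains negative intensities", call. = FALSE)
    }
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  }
  if (is.null(channels)) {
    nms <- names(intensities)
    channels <- data.frame(
      name = nms,
      kind = ifelse(nms == "cell_density" | grepl("lipid", nms, fixed = TRUE),
                    "reference", "analyte"),
      mrm_precursor_mz = NA_real_,
      mrm_fragment_mz = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  channels <- validate_channel_defs(channels)
  if (!setequal(channels$name, names(intensities))) {
    stop("channel definitions do not match intensity channel names",
         call. = FALSE)
  }
  channels <- channels[match(names(intensities), channels$name), , drop = FALSE]
  rownames(channels) <- NULL
  structure(
    list(width = dims[2L], height = dims[1L], pixel_size_um = pixel_size_um,
         channels = channels, intensities = intensities),
    class = "channel_grid"
  )
}

validate_channel_defs <- function(channels) {
  if (!is.data.frame(channels) || !all(c("name", "kind") %in% names(channels))) {
    stop("`channels` must be a data frame with columns name and kind",
         call. = FALSE)
  }
  if (anyDuplicated(channels$name)) {
    stop("channel names must be unique", call. = FALSE)
  }
  if (!all(channels$kind %in% c("analyte", "reference"))) {
    stop("channel kind must be 'analyte' or 'reference'", call. = FALSE)
  }
  if (is.null(channels$mrm_precursor_mz)) channels$mrm_precursor_mz <- NA_real_
  if (is.null(channels$mrm_fragment_mz)) channels$mrm_fragment_mz <- NA_real_
  channels[, c("name", "kind", "mrm_precursor_mz", "mrm_fragment_mz")]
}

#' @export
print.channel_grid <- function(x, ...) {
  cat("<channel_grid> ", x$width, " x ", x$height, " px @ ",
      x$pixel_size_um, " um/px\n", sep = "")
  for (i in seq_len(nrow(x$channels))) {
    ch <- x$channels[i, ]
    cat("  ", ch$name, " [", ch$kind, "] total=",
        format(sum(x$intensities[[ch$name]])), "\n", sep = "")
  }
  invisible(x)
}

#' Extract one channel's intensity matrix
#'
#' @param grid a [channel_grid()].
#' @param channel channel name.
#' @return numeric matrix (`height` x `width`).
#' @export
grid_channel <- function(grid, channel) {
  stopifnot(inherits(grid, "channel_grid"))
  if (!channel %in% names(grid$intensities)) {
    stop("grid has no channel '", channel, "'", call. = FALSE)
  }
  grid$intensities[[channel]]
}

#' Channel names of a grid
#' @param grid a [channel_grid()].
#' @param kind optional filter: `"analyte"` or `"reference"`.
#' @return character vector of channel names.
#' @export
grid_channels <- function(grid, kind = NULL) {
  stopifnot(inherits(grid, "channel_grid"))
  ch <- grid$channels
  if (!is.null(kind)) ch <- ch[ch$kind == kind, , drop = FALSE]
  ch$name
}

#' Region-of-interest pixel mask
#'
#' A set of 0-based pixel coordinates on the MSI raster. Duplicate
#' coordinates are collapsed (set semantics) with a message.
#'
#' @param x,y integer vectors of equal length, 0-based pixel coordinates.
#' @param name label for the ROI (used in error messages and reports).
#' @return an object of class `roi_mask`: a data frame with columns `x`, `y`
#'   and attribute `name`.
#' @export
roi_mask <- function(x, y, name = "roi") {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) == 0L) stop("ROI '", name, "' is empty", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("ROI coordinates must not be NA", call. = FALSE)
  x <- as.integer(round(x)); y <- as.integer(round(y))
  df <- unique(data.frame(x = x, y = y))
  if (nrow(df) < length(x)) {
    message("roi_mask '", name, "': removed ", length(x) - nrow(df),
            " duplicate pixel(s)")
  }
  rownames(df) <- NULL
  structure(df, name = name, class = c("roi_mask", "data.frame"))
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> '", attr(x, "name"), "' with ", nrow(x), " pixels\n",
      sep = "")
  invisible(x)
}

roi_name <- function(mask) {
  nm <- attr(mask, "name")
  if (is.null(nm)) "roi" else nm
}

check_mask_in_bounds <- function(mask, grid) {
  bad <- mask$x < 0 | mask$x >= grid$width | mask$y < 0 | mask$y >= grid$height
  if (any(bad)) {
    stop("ROI '", roi_name(mask), "': ", sum(bad),
         " pixel(s) outside the ", grid$width, "x", grid$height, " grid",
         call. = FALSE)
  }
  invisible(TRUE)
}

mask_values <- function(grid, mask, channel) {
  check_mask_in_bounds(mask, grid)
  m <- grid_channel(grid, channel)
  m[cbind(mask$y + 1L, mask$x + 1L)]
}

#' Rectangular ROI helper
#'
#' Builds an [roi_mask()] covering the half-open pixel rectangle
#' `[x0, x0 + width) x [y0, y0 + height)`.
#'
#' @param x0,y0 top-left corner, 0-based.
#' @param width,height extent in pixels.
#' @param name ROI label.
#' @return an `roi_mask`.
#' @export
rect_mask <- function(x0, y0, width, height, name = "rect") {
  stopifnot(width >= 1, height >= 1)
  xs <- seq.int(x0, x0 + width - 1L)
  ys <- seq.int(y0, y0 + height - 1L)
  g <- expand.grid(x = xs, y = ys)
  roi_mask(g$x, g$y, name = name)
}
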