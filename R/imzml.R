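#' Import an imzML dataset as a channel grid
#'
#' Reads a (continuous or processed) imzML file plus its companion `.ibd`
#' binary and integrates, per pixel, the intensity within a set of m/z
#' windows, yielding one channel per window. This is the bridge from real
#' imaging data to the pipeline's native [channel_grid()]; the synthetic
#' generator and the plain TSV format are the primary path.
#'
#' Only the parts of the imzML vocabulary needed for targeted extraction are
#' interpreted: pixel positions (IMS:1000050/51), external binary offsets and
#' array lengths (IMS:1000102/103), array roles (MS:1000514 m/z,
#' MS:1000515 intensity) and encodings (32/64-bit float,
#' 32/64-bit integer), whether stated locally or via referenceable param
#' groups. Pixels without a spectrum are 0.
#'
#' @param path path to the `.imzML` XML file; the `.ibd` file must sit next
#'   to it with the same base name.
#' @param channel_windows data frame with columns `name`, `mz_center`,
#'   `tolerance`; per pixel, channel intensity is the sum of intensities at
#'   m/z within `mz_center +/- tolerance` (inclusive).
#' @param pixel_size_um pixel size override; if `NULL`, taken from the scan
#'   settings (IMS:1000046) when present, else 1.
#' @return a [channel_grid()] with one analyte channel per window.
#' @export
import_imzml <- function(path, channel_windows, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("imzML file not found: ", path, call. = FALSE)
  if (!is.data.frame(channel_windows) ||
      !all(c("name", "mz_center", "tolerance") %in% names(channel_windows))) {
    stop("`channel_windows` must have columns name, mz_center, tolerance",
         call. = FALSE)
  }
  if (any(channel_windows$tolerance < 0)) {
    stop("window tolerances must be >= 0", call. = FALSE)
  }
  ibd <- paste0(tools::file_path_sans_ext(path), ".ibd")
  if (!file.exists(ibd)) stop("companion .ibd not found: ", ibd, call. = FALSE)

  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  # referenceable param groups: id -> named accession vector (value strings)
  groups <- list()
  for (g in xml2::xml_find_all(doc, ".//referenceableParamGroup")) {
    id <- xml2::xml_attr(g, "id")
    groups[[id]] <- cv_params(g)
  }

  sc <- xml2::xml_find_first(doc, ".//scanSettings")
  sc_params <- if (!inherits(sc, "xml_missing")) cv_params(sc) else character()
  max_x <- as.integer(sc_params["IMS:1000042"])
  max_y <- as.integer(sc_params["IMS:1000043"])
  if (is.null(pixel_size_um)) {
    pixel_size_um <- suppressWarnings(as.numeric(sc_params["IMS:1000046"]))
    if (is.na(pixel_size_um)) pixel_size_um <- 1
  }

  spectra <- xml2::xml_find_all(doc, ".//spectrum")
  if (length(spectra) == 0L) stop("imzML contains no spectra", call. = FALSE)

  px <- integer(length(spectra)); py <- integer(length(spectra))
  arrays <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    scan <- xml2::xml_find_first(sp, ".//scan")
    sp_params <- c(cv_params(scan), group_params(scan, groups))
    px[i] <- as.integer(sp_params["IMS:1000050"])
    py[i] <- as.integer(sp_params["IMS:1000051"])
    bdas <- xml2::xml_find_all(sp, ".//binaryDataArray")
    arrays[[i]] <- lapply(bdas, function(bda) {
      p <- c(cv_params(bda), group_params(bda, groups))
      list(
        is_mz = "MS:1000514" %in% names(p),
        is_intensity = "MS:1000515" %in% names(p),
        offset = as.numeric(p["IMS:1000102"]),
        length = as.integer(p["IMS:1000103"]),
        what = if ("MS:1000523" %in% names(p)) list("double", 8L)
               else if ("MS:1000521" %in% names(p)) list("double", 4L)
               else if ("MS:1000522" %in% names(p)) list("integer", 8L)
               else if ("MS:1000519" %in% names(p)) list("integer", 4L)
               else stop("unsupported binary encoding in imzML",
                         call. = FALSE)
      )
    })
  }
  if (anyNA(px) || anyNA(py)) {
    stop("spectrum without pixel position (IMS:1000050/51)", call. = FALSE)
  }
  # imzML positions are conventionally 1-based; tolerate 0-based files
  off <- if (min(c(px, py)) >= 1L) 1L else 0L
  px <- px - off; py <- py - off
  width <- if (is.na(max_x)) max(px) + 1L else max(max_x, max(px) + 1L)
  height <- if (is.na(max_y)) max(py) + 1L else max(max_y, max(py) + 1L)

  win <- channel_windows
  intensities <- lapply(seq_len(nrow(win)), function(i) {
    matrix(0, nrow = height, ncol = width)
  })
  names(intensities) <- win$name

  con <- file(ibd, "rb")
  on.exit(close(con))
  for (i in seq_along(spectra)) {
    mz <- NULL; inten <- NULL
    for (a in arrays[[i]]) {
      seek(con, where = a$offset, origin = "start")
      v <- readBin(con, what = a$what[[1L]], n = a$length,
                   size = a$what[[2L]], endian = "little")
      if (a$is_mz) mz <- as.numeric(v)
      if (a$is_intensity) inten <- as.numeric(v)
    }
    if (is.null(mz) || is.null(inten)) {
      stop("spectrum ", i, " lacks an m/z or intensity array", call. = FALSE)
    }
    for (w in seq_len(nrow(win))) {
      sel <- abs(mz - win$mz_center[w]) <= win$tolerance[w]
      if (any(sel)) {
        intensities[[w]][py[i] + 1L, px[i] + 1L] <-
          intensities[[w]][py[i] + 1L, px[i] + 1L] + sum(inten[sel])
      }
    }
  }
  empty <- vapply(intensities, function(m) all(m == 0), logical(1L))
  if (any(empty)) {
    warning("no signal found in window(s): ",
            paste(win$name[empty], collapse = ", "),
            "; channel(s) read as all-zero", call. = FALSE)
  }
  chans <- data.frame(name = win$name, kind = "analyte",
                      mrm_precursor_mz = win$mz_center,
                      mrm_fragment_mz = NA_real_, stringsAsFactors = FALSE)
  channel_grid(intensities, pixel_size_um, chans)
}

cv_params <- function(node) {
  if (is.null(node) || inherits(node, "xml_missing")) return(character())
  ps <- xml2::xml_find_all(node, "./cvParam")
  setNames(xml2::xml_attr(ps, "value"), xml2::xml_attr(ps, "accession"))
}

group_params <- function(node, groups) {
  if (is.null(node) || inherits(node, "xml_missing")) return(character())
  refs <- xml2::xml_find_all(node, "./referenceableParamGroupRef")
  ids <- xml2::xml_attr(refs, "ref")
  out <- character()
  for (id in ids) out <- c(out, groups[[id]])
  out
}
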