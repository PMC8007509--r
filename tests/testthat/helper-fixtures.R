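# Shared fixtures: tiny grids, an independent least-squares oracle, a
# minimal single-well layout, and an imzML writer for import tests.

make_grid <- function(..., pixel_size_um = 100) {
  channel_grid(list(...), pixel_size_um = pixel_size_um)
}

# independent least-squares oracle: closed-form normal equations on the
# per-level means, never via lm()
ols_oracle <- function(x, y) {
  lev <- tapply(y, x, mean)
  xs <- as.numeric(names(lev)); ys <- as.numeric(lev)
  n <- length(xs)
  sx <- sum(xs); sy <- sum(ys); sxx <- sum(xs^2); sxy <- sum(xs * ys)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  fitted <- intercept + slope * xs
  ss_res <- sum((ys - fitted)^2)
  ss_tot <- sum((ys - mean(ys))^2)
  list(slope = slope, intercept = intercept,
       r_squared = if (ss_tot == 0) 0 else 1 - ss_res / ss_tot)
}

# sample SD oracle (n-1 convention), computed from first principles
sd_oracle <- function(v) sqrt(sum((v - mean(v))^2) / (length(v) - 1))

single_well_layout <- function(well_px = 13L, conc = 100, margin = 4L,
                               analyte = "cmpdA") {
  wells <- data.frame(well_id = "W1", role = "calibration",
                      replicate_id = 1L, x0 = margin, y0 = margin,
                      width = well_px, height = well_px,
                      stringsAsFactors = FALSE)
  nominal <- data.frame(well_id = "W1", channel = analyte,
                        nominal_conc = conc, stringsAsFactors = FALSE)
  array_layout(wells, nominal, well_px + 2L * margin, well_px + 2L * margin,
               pixel_size_um = 100)
}

# calibration observations on an exact line (ratio = slope * conc), one
# replicate per level
exact_line_obs <- function(slope = 0.001,
                           levels = c(12.5, 25, 50, 125, 250, 500, 1250,
                                      2500)) {
  data.frame(well_id = paste0("W", seq_along(levels)),
             role = "calibration", replicate_id = 1L,
             nominal_conc = levels, ratio = slope * levels,
             n_pixels = 100L, stringsAsFactors = FALSE)
}

# minimal continuous imzML + ibd writer (64-bit little-endian arrays),
# independent of the package reader
write_imzml_fixture <- function(path, spectra, max_x, max_y,
                                pixel_size_um = 100) {
  ibd <- paste0(tools::file_path_sans_ext(path), ".ibd")
  con <- file(ibd, "wb")
  writeBin(as.raw(rep(0L, 16L)), con)
  off <- 16
  meta <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    mz_off <- off
    writeBin(as.double(sp$mz), con, size = 8L, endian = "little")
    off <- off + 8 * length(sp$mz)
    int_off <- off
    writeBin(as.double(sp$intensity), con, size = 8L, endian = "little")
    off <- off + 8 * length(sp$intensity)
    meta[[i]] <- list(mz_off = mz_off, int_off = int_off,
                      n = length(sp$mz))
  }
  close(con)

  bda <- function(ref, offset, n) {
    sprintf(paste0(
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="%s"/>',
      '<cvParam accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam accession="IMS:1000103" name="external array length" value="%d"/>',
      '<cvParam accession="IMS:1000104" name="external encoded length" value="%d"/>',
      '<binary/></binaryDataArray>'), ref, offset, n, 8 * n)
  }
  spectra_xml <- vapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]; m <- meta[[i]]
    paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
              i - 1L, i, m$n),
      '<scanList count="1"><scan>',
      sprintf('<cvParam accession="IMS:1000050" name="position x" value="%d"/>',
              sp$x),
      sprintf('<cvParam accession="IMS:1000051" name="position y" value="%d"/>',
              sp$y),
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      bda("mzArray", m$mz_off, m$n),
      bda("intensityArray", m$int_off, m$n),
      '</binaryDataArrayList></spectrum>')
  }, character(1L))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam accession="MS:1000514" name="m/z array" value=""/>',
    '<cvParam accession="MS:1000523" name="64-bit float" value=""/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam accession="MS:1000515" name="intensity array" value=""/>',
    '<cvParam accession="MS:1000523" name="64-bit float" value=""/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<scanSettingsList count="1"><scanSettings id="ss1">',
    sprintf('<cvParam accession="IMS:1000042" name="max count of pixels x" value="%d"/>',
            max_x),
    sprintf('<cvParam accession="IMS:1000043" name="max count of pixels y" value="%d"/>',
            max_y),
    sprintf('<cvParam accession="IMS:1000046" name="pixel size x" value="%g"/>',
            pixel_size_um),
    '</scanSettings></scanSettingsList>',
    sprintf('<run id="r1"><spectrumList count="%d">', length(spectra)),
    paste(spectra_xml, collapse = ""),
    '</spectrumList></run></mzML>')
  writeLines(xml, path)
  invisible(path)
}
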