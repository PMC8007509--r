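# synthetic instrument/mode observation builders: a clean low-noise mode and
# one whose blank variability puts the low QC below the LOD
clean_mode_obs <- function(slope = 0.002, channel = "cmpdA") {
  cal <- exact_line_obs(slope = slope)
  cal$channel <- channel
  qc <- do.call(rbind, lapply(c(25, 1250), function(q) {
    data.frame(channel = channel, well_id = paste0("qc", q, "_", 1:3),
               role = "qc", nominal_conc = q,
               ratio = slope * q * c(0.98, 1.0, 1.02),
               replicate_id = 1:3, n_pixels = 100L,
               stringsAsFactors = FALSE)
  }))
  blank <- data.frame(channel = channel, well_id = paste0("b", 1:3),
                      role = "blank", nominal_conc = 0,
                      ratio = c(0.0009, 0.001, 0.0011),
                      replicate_id = 1:3, n_pixels = 100L,
                      stringsAsFactors = FALSE)
  rbind(cal, qc, blank)
}

noisy_blank_mode_obs <- function(channel = "cmpdA") {
  obs <- clean_mode_obs(channel = channel)
  # blank ratio SD 0.02 => LOD = 3 * 0.02 / 0.002 = 30 ug/g > low QC (25)
  obs$ratio[obs$role == "blank"] <- c(0.00, 0.02, 0.04)
  obs
}
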