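test_that("sim_params validates its invariants", {
  expect_error(sim_params(response_slope = c(a = -1)), "> 0")
  expect_error(sim_params(pixel_rsd = 1), "\\[0, 1\\)")
  expect_error(sim_params(lipid_gain = 0), "> 0")
  expect_error(sim_params(diffusion_sigma_mm = -0.1), ">= 0")
  expect_error(sim_params(response_slope = c(0.1, 0.2)), "named")
})

test_that("a fixed seed reproduces the array exactly; different seeds differ", {
  lay <- default_array_layout()
  p <- sim_params(seed = 11)
  a1 <- generate_mimetic_array(lay, p)
  a2 <- generate_mimetic_array(lay, p)
  expect_identical(a1$grid$intensities, a2$grid$intensities)
  expect_identical(a1$layout$wells, a2$layout$wells)
  p2 <- sim_params(seed = 12)
  a3 <- generate_mimetic_array(lay, p2)
  expect_false(identical(a1$grid$intensities, a3$grid$intensities))
})

test_that("noise-free wells satisfy the generative identity ratio = slope x conc", {
  lay <- default_array_layout()
  p <- sim_params(pixel_rsd = 0, baseline_noise_sd = 0, diffusion_sigma_mm = 0)
  arr <- generate_mimetic_array(lay, p)
  for (ch in c("cmpdA", "cmpdB")) {
    obs <- extract_array_ratios(arr$grid, arr$layout, ch, "lipid782")
    expect_equal(obs$ratio, p$response_slope[[ch]] * obs$nominal_conc,
                 tolerance = 1e-12)
    # blanks carry no analyte at all without baseline noise
    expect_equal(obs$ratio[obs$role == "blank"], rep(0, 3))
  }
  w250 <- obs$well_id[obs$nominal_conc == 250 & obs$role == "calibration"]
  r <- summed_ratio(arr$grid, well_mask(arr$layout, w250), "cmpdA",
                    "lipid782")
  expect_equal(r, p$response_slope[["cmpdA"]] * 250, tolerance = 1e-12)
})

test_that("noise-free truth is exactly linear through the origin (R^2 = 1)", {
  lay <- default_array_layout()
  p <- sim_params(pixel_rsd = 0, baseline_noise_sd = 0)
  arr <- generate_mimetic_array(lay, p)
  obs <- extract_array_ratios(arr$grid, arr$layout, "cmpdA", "lipid782")
  ft <- fit_line(obs[obs$role == "calibration", ])
  expect_equal(ft$slope, 0.002, tolerance = 1e-12)
  expect_equal(ft$intercept, 0, tolerance = 1e-12)
  expect_equal(ft$r_squared, 1, tolerance = 1e-12)
})

test_that("blank wells yield near-zero ratios under baseline noise", {
  lay <- default_array_layout()
  p <- sim_params(seed = 3)  # defaults: rsd 0.2, baseline sd 5
  arr <- generate_mimetic_array(lay, p)
  obs <- extract_array_ratios(arr$grid, arr$layout, "cmpdA", "lipid782")
  blank_ratio <- obs$ratio[obs$role == "blank"]
  # truncated baseline noise vs lipid ~ 1000 counts/px: ratio of order 1e-3
  expect_true(all(blank_ratio < 0.01))
  lowest_cal <- min(obs$ratio[obs$role == "calibration"])
  expect_true(all(blank_ratio < lowest_cal / 3))
})

test_that("the multiplicative noise model reproduces its own pixel RSD", {
  lay <- single_well_layout(well_px = 13L)  # 169 pixels
  mask <- well_mask(lay, "W1")
  rsds <- vapply(seq_len(100), function(s) {
    p <- sim_params(response_slope = c(cmpdA = 0.002), pixel_rsd = 0.2,
                    baseline_noise_sd = 0, seed = 5000 + s)
    arr <- generate_mimetic_array(lay, p, randomize = FALSE)
    v <- grid_channel(arr$grid, "lipid782")[cbind(mask$y + 1L, mask$x + 1L)]
    sd(v) / mean(v)
  }, numeric(1L))
  expect_gt(mean(rsds), 0.18)
  expect_lt(mean(rsds), 0.22)
})

test_that("dosed sections validate regions and respect cell-density scaling", {
  labels <- matrix("background", 20, 20)
  labels[5:15, 5:15] <- "lesion"
  expect_error(region_map(labels, list(other = c(cmpdA = 10))),
               "config error")

  rmap <- region_map(labels, list(lesion = c(cmpdA = 200)))
  p <- sim_params(response_slope = c(cmpdA = 0.002), pixel_rsd = 0,
                  baseline_noise_sd = 0)
  expect_error(generate_dosed_section(rmap, p,
                                      cell_density_map = matrix(1, 5, 5)),
               "shape")

  # at homogenate density the uncorrected ratio equals slope x conc;
  # halving the density halves it; correction restores it
  sec_full <- generate_dosed_section(rmap, p)
  rmap_half <- region_map(labels, list(lesion = c(cmpdA = 200)),
                          region_densities = c(lesion = 25))
  sec_half <- generate_dosed_section(rmap_half, p)
  mask <- roi_mask(rep(5:15, each = 11) , rep(5:15, times = 11),
                   name = "lesion")
  r_full <- summed_ratio(sec_full$grid, mask, "cmpdA", "lipid782")
  r_half <- summed_ratio(sec_half$grid, mask, "cmpdA", "lipid782")
  expect_equal(r_full, 0.002 * 200, tolerance = 1e-12)
  expect_equal(r_half, r_full / 2, tolerance = 1e-12)
  c_full <- cell_corrected_ratio(sec_full$grid, mask, "cmpdA", "lipid782",
                                 sec_full$cell_density, 50)
  c_half <- cell_corrected_ratio(sec_half$grid, mask, "cmpdA", "lipid782",
                                 sec_half$cell_density, 50)
  expect_equal(c_full, c_half, tolerance = 1e-12)
})

test_that("replicate region masks partition the region", {
  rmap <- demo_region_map()
  masks <- region_replicate_masks(rmap, "lesion", n = 3, seed = 9)
  expect_length(masks, 3L)
  tot <- do.call(rbind, lapply(masks, as.data.frame))
  expect_equal(nrow(tot), sum(rmap$labels == "lesion"))
  expect_equal(anyDuplicated(tot), 0L)
})

test_that("simulate_calibration_experiment pools per-section replicates", {
  lay <- default_array_layout()
  p <- sim_params(seed = 21)
  sim <- simulate_calibration_experiment(lay, p, "cmpdA", n_sections = 2)
  expect_equal(sort(unique(sim$observations$replicate_id)), 1:2)
  expect_equal(nrow(sim$observations), 2L * nrow(lay$wells))
  expect_equal(sim$calibration_density, p$homogenate_cell_density)
})
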