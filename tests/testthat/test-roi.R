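test_that("registration maps, rounds, de-duplicates and clips masks", {
  g <- make_grid(a = matrix(1, 10, 10), lipid782 = matrix(1, 10, 10))
  m <- roi_mask(c(1, 2, 3, 4), c(1, 1, 2, 2))

  ident <- register_and_extract(g, m)
  expect_equal(as.data.frame(ident), as.data.frame(m))

  shift <- registration_transform(diag(2), b = c(1, 0))
  shifted <- register_and_extract(g, m, shift)
  expect_equal(sort(shifted$x), c(2, 3, 4, 5))
  expect_equal(sort(shifted$y), c(1, 1, 2, 2))

  # 0.4x scaling lands two source pixels on the same MSI pixel
  shrink <- registration_transform(matrix(c(0.4, 0, 0, 0.4), 2))
  expect_message(merged <- register_and_extract(g, roi_mask(c(2, 3), c(0, 0)),
                                                shrink), "merged")
  expect_equal(nrow(merged), 1L)

  # large translation pushes everything off the grid
  far <- registration_transform(diag(2), b = c(100, 100))
  expect_error(register_and_extract(g, m, far), "empty ROI")
  # partial clip drops with a message
  edge <- registration_transform(diag(2), b = c(7, 0))
  expect_message(clipped <- register_and_extract(g, m, edge), "dropped")
  expect_equal(nrow(clipped), 2L)

  expect_error(registration_transform(matrix(c(1, 1, 2, 2), 2)), "singular")
})

test_that("cell-count correction rescales by calibration/ROI density", {
  a <- matrix(20, 2, 5); l <- matrix(100, 2, 5)
  g <- make_grid(drug = a, lipid782 = l)
  m <- roi_mask(0:4, rep(0, 5))
  dens2 <- matrix(2, 2, 5)
  expect_equal(cell_corrected_ratio(g, m, "drug", "lipid782", dens2, 1), 0.1)
  dens_eq <- matrix(7, 2, 5)
  expect_equal(cell_corrected_ratio(g, m, "drug", "lipid782", dens_eq, 7),
               summed_ratio(g, m, "drug", "lipid782"))
  expect_error(cell_corrected_ratio(g, m, "drug", "lipid782",
                                    matrix(0, 2, 5), 1), "correction error")
  expect_error(cell_corrected_ratio(g, m, "drug", "lipid782", dens2, 0),
               "> 0")
})

test_that("noise-free dosed sections round-trip exactly through quantify_rois", {
  p <- sim_params(pixel_rsd = 0, baseline_noise_sd = 0)
  lay <- default_array_layout()
  arr <- generate_mimetic_array(lay, p)
  obs <- extract_array_ratios(arr$grid, arr$layout, "cmpdA", "lipid782")
  cv <- build_calibration(obs, obs$ratio[obs$role == "blank"])

  rmap <- demo_region_map(concentrations = list(
    lesion = c(cmpdA = 500), connective = c(cmpdA = 75),
    parenchyma = c(cmpdA = 240)))
  sec <- generate_dosed_section(rmap, p)
  rois <- lapply(setNames(nm = c("lesion", "connective", "parenchyma")),
                 function(r) region_replicate_masks(rmap, r, 3, seed = 4))
  res <- quantify_rois(sec$grid, rois, cv, "cmpdA", "lipid782",
                       sec$cell_density, p$homogenate_cell_density)
  expect_equal(res$conc[match(c("lesion", "connective", "parenchyma"),
                              res$roi_name)],
               c(500, 75, 240), tolerance = 1e-9)
  expect_equal(res$flag, rep("ok", 3))
  expect_equal(res$n, rep(3L, 3))
  # replicate SD agrees with a direct oracle on the replicate values
  concs <- vapply(rois$lesion, function(m) {
    back_calculate(cv, cell_corrected_ratio(sec$grid, m, "cmpdA", "lipid782",
                                            sec$cell_density, 50))$conc
  }, numeric(1L))
  expect_equal(res$conc_sd[res$roi_name == "lesion"], sd_oracle(concs))
})

test_that("zero-concentration regions are flagged below LOD and silent channels ND", {
  p <- sim_params(response_slope = c(cmpdA = 0.002), seed = 8)
  rmap <- demo_region_map(concentrations = list(
    lesion = c(cmpdA = 0), connective = c(cmpdA = 0),
    parenchyma = c(cmpdA = 0)))
  sec <- generate_dosed_section(rmap, p)
  obs <- exact_line_obs(slope = 0.002)
  cv <- build_calibration(obs, c(0.002, 0.004, 0.006))  # LOD 3 ug/g
  rois <- lapply(setNames(nm = c("lesion", "parenchyma")),
                 function(r) region_replicate_masks(rmap, r, 3, seed = 4))
  res <- quantify_rois(sec$grid, rois, cv, "cmpdA", "lipid782",
                       sec$cell_density, p$homogenate_cell_density)
  expect_true(all(res$flag == "<LOD"))

  nd <- quantify_rois(sec$grid, rois, NULL, "cmpdA", "lipid782",
                      sec$cell_density, p$homogenate_cell_density)
  expect_true(all(nd$flag == "ND"))
  expect_true(all(is.na(nd$conc)))

  # any replicate above the ULOQ flags the region >ULOQ without a value
  rmap_hi <- demo_region_map(concentrations = list(
    lesion = c(cmpdA = 5000), connective = c(cmpdA = 100),
    parenchyma = c(cmpdA = 100)))
  p0 <- sim_params(response_slope = c(cmpdA = 0.002), pixel_rsd = 0,
                   baseline_noise_sd = 0)
  sec_hi <- generate_dosed_section(rmap_hi, p0)
  rois_hi <- list(lesion = region_replicate_masks(rmap_hi, "lesion", 3, 4))
  res_hi <- quantify_rois(sec_hi$grid, rois_hi, cv, "cmpdA", "lipid782",
                          sec_hi$cell_density, p0$homogenate_cell_density)
  expect_equal(res_hi$flag, ">ULOQ")
  expect_true(is.na(res_hi$conc))
})

test_that("fold differences report larger/smaller with direction and skip flags", {
  fd <- fold_differences(c("lesion", "connective"), c(526, 79))
  expect_equal(fd$fold, 526 / 79)
  expect_equal(fd$higher, "lesion")
  expect_equal(fd$fold_display, 6.7)

  fd2 <- fold_differences(c("lesion", "parenchyma"), c(588, 577))
  expect_equal(round(fd2$fold, 2), 1.02)

  fd3 <- fold_differences(c("a", "b"), c(100, 100))
  expect_equal(fd3$fold, 1)

  # symmetric under label swap: direction flips, magnitude identical
  fwd <- fold_differences(c("x", "y"), c(30, 120))
  rev <- fold_differences(c("y", "x"), c(120, 30))
  expect_equal(fwd$fold, rev$fold)
  expect_equal(fwd$higher, "y")
  expect_equal(rev$higher, "y")

  fd4 <- fold_differences(c("a", "b", "c"), c(10, NA, 0),
                          flags = c("ok", ">ULOQ", "ok"))
  expect_equal(nrow(fd4), 0L)
  expect_length(attr(fd4, "skipped"), 3L)
  expect_match(attr(fd4, "skipped"), "flagged|zero", all = TRUE)
})

test_that("LC-MS concordance folds use the nearest range bound and are >= 1", {
  msi <- data.frame(sample_id = c("s1", "s2", "s3"),
                    conc = c(480, 200, 242))
  lcms <- data.frame(sample_id = c("s1", "s2", "s3"),
                     low = c(1550, 150, 150), high = c(1650, 220, 220))
  cc <- lcms_concordance(msi, lcms)
  expect_equal(cc$per_sample$fold, c(1550 / 480, 1, 242 / 220))
  expect_equal(cc$max_fold, 1550 / 480)
  expect_true(all(cc$per_sample$fold >= 1))

  expect_error(lcms_concordance(data.frame(sample_id = "sX", conc = 1),
                                lcms), "sX")
  msi_f <- data.frame(sample_id = c("s1", "s2"), conc = c(NA, 200),
                      flag = c(">ULOQ", "ok"))
  cc2 <- lcms_concordance(msi_f, lcms)
  expect_equal(cc2$per_sample$sample_id, "s2")
  expect_match(attr(cc2$per_sample, "skipped"), "s1")

  # property: folds >= 1 for random values against random valid ranges
  set.seed(77)
  for (i in 1:25) {
    v <- runif(1, 1, 1000); lo <- runif(1, 1, 500); hi <- lo + runif(1, 0, 500)
    cc3 <- lcms_concordance(data.frame(sample_id = "s", conc = v),
                            data.frame(sample_id = "s", low = lo, high = hi))
    expect_gte(cc3$max_fold, 1)
  }
})

test_that("diffusion check is ~0 without diffusion and grows with sigma", {
  lay <- default_array_layout(margin_mm = 4)  # clean far background
  p0 <- sim_params(seed = 14, diffusion_sigma_mm = 0)
  arr0 <- generate_mimetic_array(lay, p0)
  f0 <- diffusion_check(arr0$grid, arr0$layout, corridor_margin_px = 3)
  expect_lt(f0[["cmpdA"]], 0.01)

  p5 <- sim_params(seed = 14, diffusion_sigma_mm = 0.5)
  p10 <- sim_params(seed = 14, diffusion_sigma_mm = 1.0)
  a5 <- generate_mimetic_array(lay, p5)
  a10 <- generate_mimetic_array(lay, p10)
  f5 <- diffusion_check(a5$grid, a5$layout, corridor_margin_px = 3)
  f10 <- diffusion_check(a10$grid, a10$layout, corridor_margin_px = 3)
  expect_gt(f5[["cmpdA"]], f0[["cmpdA"]])
  expect_gt(f10[["cmpdA"]], f5[["cmpdA"]])
})

test_that("diffusion fraction matches a direct oracle on a constructed field", {
  # two wells, piecewise-constant intensities: wells 10, corridor 3, bg 1
  wells <- data.frame(well_id = c("w1", "w2"), role = "blank",
                      replicate_id = 1:2, x0 = c(4, 24), y0 = 4,
                      width = 8, height = 8, stringsAsFactors = FALSE)
  nominal <- data.frame(well_id = c("w1", "w2"), channel = "chA",
                        nominal_conc = 0, stringsAsFactors = FALSE)
  lay <- array_layout(wells, nominal, 40, 16, 100)
  m <- matrix(1, 16, 40)
  m[5:12, 13:24] <- 3             # between the wells
  m[5:12, 5:12] <- 10; m[5:12, 25:32] <- 10
  g <- make_grid(chA = m)
  f <- diffusion_check(g, lay, corridor_margin_px = 3, channels = "chA")
  expect_equal(f[["chA"]], (3 - 1) / 10, tolerance = 1e-9)

  one_well <- array_layout(wells[1, ], nominal[1, ], 40, 16, 100)
  expect_error(diffusion_check(g, one_well), "geometry error")
})
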