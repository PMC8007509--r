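test_that("summed_ratio is a ratio of sums, order-invariant, zero-safe", {
  a <- matrix(c(10, 20, 30), 1, 3)
  l <- matrix(c(100, 100, 100), 1, 3)
  g <- make_grid(drug = a, lipid782 = l)
  m <- roi_mask(0:2, c(0, 0, 0))
  expect_equal(summed_ratio(g, m, "drug", "lipid782"), 0.2)  # 60/300
  m_perm <- roi_mask(c(2, 0, 1), c(0, 0, 0))
  expect_equal(summed_ratio(g, m_perm, "drug", "lipid782"), 0.2)

  g0 <- make_grid(drug = matrix(0, 1, 3), lipid782 = l)
  expect_equal(summed_ratio(g0, m, "drug", "lipid782"), 0)

  gz <- make_grid(drug = a, lipid782 = matrix(0, 1, 3))
  expect_error(summed_ratio(gz, roi_mask(0:2, c(0, 0, 0), name = "wellX"),
                            "drug", "lipid782"), "wellX")
})

test_that("fit_line matches perfect lines, degenerate cases and the OLS oracle", {
  obs <- exact_line_obs(slope = 0.001)
  ft <- fit_line(obs)
  expect_equal(ft$slope, 0.001, tolerance = 1e-12)
  expect_equal(ft$intercept, 0, tolerance = 1e-12)
  expect_equal(ft$r_squared, 1, tolerance = 1e-12)

  const <- data.frame(nominal_conc = c(10, 20, 30), ratio = 0.5)
  ftc <- fit_line(const)
  expect_equal(ftc$slope, 0)
  expect_equal(ftc$r_squared, 0)

  expect_error(fit_line(data.frame(nominal_conc = c(1, 2), ratio = c(1, 2))),
               "insufficient")
  expect_error(fit_line(data.frame(nominal_conc = rep(5, 4),
                                   ratio = c(1, 2, 3, 4))), "degenerate")

  set.seed(1)
  for (i in 1:20) {
    x <- sort(runif(5, 1, 100))
    y <- 0.01 * x + rnorm(5, sd = 0.05)
    ft <- fit_line(data.frame(nominal_conc = x, ratio = y))
    or <- ols_oracle(x, y)
    expect_equal(ft$slope, or$slope, tolerance = 1e-10)
    expect_equal(ft$intercept, or$intercept, tolerance = 1e-10)
    expect_equal(ft$r_squared, or$r_squared, tolerance = 1e-10)
  }
})

test_that("LOD and LLOQ follow the 3/5 x SD_blank / slope formulas", {
  expect_equal(compute_lod(0.006, 0.002), 9)
  expect_equal(compute_lloq(0.006, 0.002), 15)
  expect_equal(compute_lod(0, 0.002), 0)
  blanks <- c(0.001, 0.002, 0.003)
  expect_equal(sd_oracle(blanks), 0.001)
  expect_equal(compute_lod(sd(blanks), 0.001), 3)
  expect_error(compute_lod(0.01, 0), "invalid curve")
  expect_error(compute_lloq(0.01, -1), "invalid curve")
  expect_error(compute_lod(-0.1, 1), ">= 0")
})

test_that("build_calibration keeps all levels on clean data with n_refits = 1", {
  obs <- exact_line_obs(slope = 0.001)
  cv <- build_calibration(obs, c(0, 0, 0))
  expect_equal(cv$slope, 0.001, tolerance = 1e-12)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  expect_equal(cv$n_refits, 1L)
  expect_length(cv$excluded_levels, 0L)
  expect_equal(cv$uloq, 2500)
  cv_noisy <- build_calibration(obs, c(0.0011, 0.0008, 0.0013))
  expect_equal(cv_noisy$lloq / cv_noisy$lod, 5 / 3, tolerance = 1e-12)
})

test_that("inflated blanks exclude the ladder's lowest levels and refit", {
  obs <- exact_line_obs(slope = 0.001)
  # sample SD 0.01 ratio units => first-pass LOD = 3 * 0.01 / 0.001 = 30 ug/g
  blanks <- c(0, 0.01, 0.02)
  expect_equal(sd_oracle(blanks), 0.01)
  cv <- build_calibration(obs, blanks)
  expect_equal(cv$excluded_levels, c(12.5, 25))
  expect_equal(sort(cv$included_levels),
               c(50, 125, 250, 500, 1250, 2500))
  expect_equal(cv$lod, 30, tolerance = 1e-9)
  expect_equal(cv$n_refits, 2L)
  expect_equal(cv$uloq, 2500)
})

test_that("the exclusion-refit procedure is a fixpoint (idempotent)", {
  obs <- exact_line_obs(slope = 0.001)
  set.seed(33)
  obs$ratio <- 0.001 * obs$nominal_conc + rnorm(nrow(obs), sd = 1e-4)
  blanks <- c(0, 0.01, 0.02)
  cv <- build_calibration(obs, blanks)
  obs2 <- obs[obs$nominal_conc %in% cv$included_levels, ]
  cv2 <- build_calibration(obs2, blanks)
  expect_equal(cv2$included_levels, cv$included_levels)
  expect_equal(cv2$slope, cv$slope)
  expect_equal(cv2$lod, cv$lod)
  expect_equal(cv2$n_refits, 1L)
})

test_that("calibration fails with a reported LOD when exclusion leaves < 3 levels", {
  obs <- exact_line_obs(slope = 0.001, levels = c(12.5, 25, 50, 125))
  blanks <- c(0, 0.04, 0.08)  # SD 0.04 => LOD 120 => only one level left
  expect_error(build_calibration(obs, blanks), "calibration failure.*LOD")
  expect_error(build_calibration(obs, 0.001), ">= 2 blank")
})

test_that("back_calculate inverts the line and flags the quantification range", {
  obs <- exact_line_obs(slope = 0.001)
  cv <- build_calibration(obs, c(0.001, 0.002, 0.003))  # LOD 3, LLOQ 5
  bc <- back_calculate(cv, 0.25)
  expect_equal(bc$conc, 250, tolerance = 1e-9)
  expect_equal(bc$flag, "ok")

  high <- cv$slope * cv$uloq + cv$intercept + 0.1
  expect_equal(back_calculate(cv, high)$flag, "above_uloq")
  at_intercept <- back_calculate(cv, cv$intercept)
  expect_equal(at_intercept$conc, 0)
  expect_equal(at_intercept$flag, "below_lod")
  expect_equal(back_calculate(cv, cv$slope * 4 + cv$intercept)$flag,
               "below_lloq")
})

test_that("QC evaluation applies the 15/20% precision and 80-110% accuracy criteria", {
  qc <- evaluate_qc(c(24, 25, 26), nominal = 25, lloq = 5)
  expect_equal(qc$precision_rsd, 4)
  expect_equal(qc$accuracy_pct, 100)
  expect_true(qc$passes_precision && qc$passes_accuracy)

  qc2 <- evaluate_qc(c(30, 30, 30), nominal = 25, lloq = 5)
  expect_equal(qc2$precision_rsd, 0)
  expect_equal(qc2$accuracy_pct, 120)
  expect_false(qc2$passes_accuracy)
  expect_true(qc2$passes_precision)

  v <- c(20, 25, 30)
  expect_equal(sd_oracle(v), 5)
  qc3 <- evaluate_qc(v, nominal = 25, lloq = 5)    # strict 15% bound
  expect_equal(qc3$precision_rsd, 20)
  expect_false(qc3$passes_precision)
  qc4 <- evaluate_qc(v, nominal = 25, lloq = 25)   # at LLOQ: 20% bound
  expect_true(qc4$passes_precision)

  expect_error(evaluate_qc(c(25), 25, 5), "n >= 2")
  expect_error(evaluate_qc(c(-1, 1), 25, 5), "undefined RSD")
})

test_that("calibration curves serialize to JSON and back", {
  cv <- build_calibration(exact_line_obs(), c(0.001, 0.002, 0.003))
  p <- file.path(tempdir(), "curve.json")
  write_calibration_json(cv, p, provenance = list(seed = 1))
  cv2 <- read_calibration_json(p)
  for (f in c("slope", "intercept", "r_squared", "sd_blank", "lod", "lloq",
              "uloq", "included_levels", "excluded_levels")) {
    expect_equal(cv2[[f]], cv[[f]], info = f)
  }
  bc <- back_calculate(cv2, 0.5)
  expect_equal(bc$conc, (0.5 - cv$intercept) / cv$slope)
})
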