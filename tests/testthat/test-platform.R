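test_that("a low-noise mode quantifies both QC levels with R^2 ~ 1", {
  ds <- mode_dataset("QqQ", "MRM", clean_mode_obs())
  s <- summarize_mode(ds)
  expect_equal(nrow(s), 1L)
  expect_lt(s$lod, 1)
  expect_gt(s$r_squared, 0.999)
  expect_false(s$qc_low_below_lod)
  expect_false(is.na(s$precision_low))
  expect_false(is.na(s$accuracy_high))
  expect_true(s$criteria_pass)
})

test_that("QC levels below the mode's LOD are suppressed and rendered <LOD", {
  ds <- mode_dataset("QqQ", "MS scan", noisy_blank_mode_obs())
  s <- summarize_mode(ds)
  expect_gt(s$lod, 25)
  expect_true(s$qc_low_below_lod)
  expect_true(is.na(s$precision_low))
  expect_true(is.na(s$accuracy_low))
  expect_false(is.na(s$precision_high))  # high QC still quantifiable
  tab <- format_platform_table(s)
  expect_match(tab$precision_rsd_low_high, "^<LOD/")
  expect_match(tab$accuracy_pct_low_high, "^<LOD/")
})

test_that("summaries are deterministic and rows independent of other modes", {
  s1 <- summarize_mode(mode_dataset("QqQ", "MRM", clean_mode_obs()))
  s2 <- summarize_mode(mode_dataset("QqQ", "MRM", clean_mode_obs()))
  expect_identical(s1, s2)

  both <- rbind(
    summarize_mode(mode_dataset("QqQ", "MRM", clean_mode_obs())),
    summarize_mode(mode_dataset("QqQ", "MS scan", noisy_blank_mode_obs()))
  )
  expect_identical(both[1, ], s1)  # adding a mode leaves other rows intact
})

test_that("calibration failure becomes a failed row, not an exception", {
  obs <- clean_mode_obs()
  obs <- obs[!(obs$role == "calibration" & obs$nominal_conc > 50), ]
  # remaining ladder 12.5/25/50 with blanks forcing LOD 30 => < 3 levels
  obs$ratio[obs$role == "blank"] <- c(0.00, 0.02, 0.04)
  s <- summarize_mode(mode_dataset("QqQ", "broken", obs))
  expect_true(is.na(s$lod))
  expect_false(s$criteria_pass)
  expect_match(s$note, "calibration failed")
})

test_that("modes rank by criteria passed, then LOD, then R^2, ties by input order", {
  good <- summarize_mode(mode_dataset("QqQ", "MRM", clean_mode_obs()))
  bad <- summarize_mode(mode_dataset("QqQ", "MS scan",
                                     noisy_blank_mode_obs()))
  rk <- rank_modes(rbind(bad, good))
  expect_equal(rk$best[["cmpdA"]], "QqQ/MRM")
  expect_equal(rk$ranking$mode[rk$ranking$rank == 1], "MRM")

  # equal criteria: lower LOD first
  a <- good; a$mode <- "modeA"; a$lod <- 35.5
  b <- good; b$mode <- "modeB"; b$lod <- 2.5
  rk2 <- rank_modes(rbind(a, b))
  expect_equal(rk2$ranking$mode, c("modeB", "modeA"))

  # exact ties keep input order and are noted
  c1 <- good; c1$mode <- "dup1"
  c2 <- good; c2$mode <- "dup2"
  expect_message(rk3 <- rank_modes(rbind(c1, c2)), "tie")
  expect_equal(rk3$ranking$mode, c("dup1", "dup2"))

  expect_error(rank_modes(good), ">= 2")
})
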