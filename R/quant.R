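#' Summed analyte-to-reference intensity ratio of an ROI
#'
#' The quantification statistic: spectra over the ROI pixels are summed per
#' channel and the ratio of the two sums is returned (a ratio of sums, not a
#' mean of per-pixel ratios, so sparse noisy pixels cannot dominate).
#'
#' @param grid a [channel_grid()].
#' @param pixels an [roi_mask()] (non-empty, in bounds).
#' @param analyte,reference channel names.
#' @return the dimensionless summed ratio.
#' @export
summed_ratio <- function(grid, pixels, analyte, reference) {
  a <- sum(mask_values(grid, pixels, analyte))
  r <- sum(mask_values(grid, pixels, reference))
  if (r == 0) {
    stop("undefined ratio in ROI '", roi_name(pixels),
         "': reference channel '", reference, "' sums to 0", call. = FALSE)
  }
  a / r
}

#' Per-well ratio observations from an array section
#'
#' Computes the summed analyte/reference ratio of every well in a layout.
#'
#' @param grid a [channel_grid()] of one array section.
#' @param layout the (realized) [array_layout()] of that section.
#' @param analyte,reference channel names.
#' @return data frame with columns `well_id`, `role`, `replicate_id`,
#'   `nominal_conc` (for `analyte`), `ratio`, `n_pixels`.
#' @export
extract_array_ratios <- function(grid, layout, analyte, reference) {
  wells <- layout$wells
  nom <- layout$nominal[layout$nominal$channel == analyte, ]
  ratio <- numeric(nrow(wells)); npx <- integer(nrow(wells))
  for (i in seq_len(nrow(wells))) {
    m <- well_mask(layout, wells$well_id[i])
    ratio[i] <- summed_ratio(grid, m, analyte, reference)
    npx[i] <- nrow(m)
  }
  data.frame(
    well_id = wells$well_id, role = wells$role,
    replicate_id = wells$replicate_id,
    nominal_conc = nom$nominal_conc[match(wells$well_id, nom$well_id)],
    ratio = ratio, n_pixels = npx,
    stringsAsFactors = FALSE
  )
}

#' Ordinary least-squares calibration line
#'
#' Fits ratio versus nominal concentration by unweighted linear regression
#' on the per-level replicate means (weighted regression was evaluated for
#' this kind of data and found not beneficial). The intercept is free.
#'
#' @param observations data frame with columns `nominal_conc` and `ratio`
#'   (calibration observations only).
#' @return list with `slope`, `intercept`, `r_squared`, `level_means` (data
#'   frame of per-level mean ratios used in the fit).
#' @export
fit_line <- function(observations) {
  if (!all(c("nominal_conc", "ratio") %in% names(observations))) {
    stop("observations need columns nominal_conc and ratio", call. = FALSE)
  }
  lev <- aggregate(ratio ~ nominal_conc, data = observations, FUN = mean)
  if (nrow(lev) == 1L && nrow(observations) >= 3L) {
    stop("degenerate design: zero concentration variance", call. = FALSE)
  }
  if (nrow(lev) < 3L) {
    stop("insufficient points: need >= 3 distinct concentration levels, got ",
         nrow(lev), call. = FALSE)
  }
  fit <- lm(ratio ~ nominal_conc, data = lev)
  co <- coef(fit)
  fitted_y <- co[[1L]] + co[[2L]] * lev$nominal_conc
  ss_res <- sum((lev$ratio - fitted_y)^2)
  ss_tot <- sum((lev$ratio - mean(lev$ratio))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  list(slope = co[[2L]], intercept = co[[1L]], r_squared = r2,
       level_means = lev)
}

#' Limit of detection and lower limit of quantification
#'
#' `LOD = 3 * SD_blank / slope` and `LLOQ = 5 * SD_blank / slope`, where
#' `SD_blank` is the sample standard deviation of the blank-replicate summed
#' intensity ratios (analyte/lipid) and `slope` is the calibration slope.
#' Their ratio is 5/3 by construction.
#'
#' @param sd_blank sample SD of the blank replicate ratios (>= 0).
#' @param slope calibration slope in ratio units per (ug/g) (> 0).
#' @return concentration in ug/g.
#' @export
compute_lod <- function(sd_blank, slope) {
  if (!is.finite(slope) || slope <= 0) {
    stop("invalid curve: slope must be > 0", call. = FALSE)
  }
  if (sd_blank < 0) stop("sd_blank must be >= 0", call. = FALSE)
  3 * sd_blank / slope
}

#' @rdname compute_lod
#' @export
compute_lloq <- function(sd_blank, slope) {
  if (!is.finite(slope) || slope <= 0) {
    stop("invalid curve: slope must be > 0", call. = FALSE)
  }
  if (sd_blank < 0) stop("sd_blank must be >= 0", call. = FALSE)
  5 * sd_blank / slope
}

#' Build a calibration curve with iterative below-LOD exclusion
#'
#' Implements the calibration procedure: fit the line on all levels, compute
#' the LOD from the blank-ratio SD and the slope, exclude calibration levels
#' whose nominal concentration falls below the LOD, refit, and repeat until
#' the excluded set is stable (a fixpoint, so re-running the procedure on
#' its own included levels changes nothing) or fewer than 3 levels remain
#' (an error reporting the last LOD). The ULOQ is the highest included
#' level.
#'
#' @param observations data frame of calibration observations (columns
#'   `nominal_conc`, `ratio`; rows with `role != "calibration"` are dropped
#'   if a `role` column is present).
#' @param blanks numeric vector of blank replicate summed ratios (>= 2), or
#'   a data frame with a `ratio` column (e.g. the blank rows of
#'   [extract_array_ratios()] output).
#' @return an object of class `calibration_curve` with fields `slope`,
#'   `intercept`, `r_squared`, `sd_blank`, `lod`, `lloq`, `uloq`,
#'   `included_levels`, `excluded_levels`, `n_refits`, `level_means`.
#' @export
build_calibration <- function(observations, blanks) {
  if (is.data.frame(blanks)) blanks <- blanks$ratio
  if (length(blanks) < 2L) {
    stop("need >= 2 blank replicate ratios", call. = FALSE)
  }
  if ("role" %in% names(observations)) {
    observations <- observations[observations$role == "calibration", ,
                                 drop = FALSE]
  }
  all_levels <- sort(unique(observations$nominal_conc))
  sd_blank <- sd(blanks)
  included <- all_levels
  n_refits <- 0L
  repeat {
    obs_in <- observations[observations$nominal_conc %in% included, ,
                           drop = FALSE]
    ft <- fit_line(obs_in)
    n_refits <- n_refits + 1L
    lod <- compute_lod(sd_blank, ft$slope)
    keep <- all_levels[all_levels >= lod]
    if (setequal(keep, included)) break
    if (length(keep) < 3L) {
      stop("calibration failure: below-LOD exclusion left ", length(keep),
           " level(s); last LOD = ", format(lod), " ug/g", call. = FALSE)
    }
    included <- keep
  }
  structure(
    list(slope = ft$slope, intercept = ft$intercept,
         r_squared = ft$r_squared, sd_blank = sd_blank,
         lod = lod, lloq = compute_lloq(sd_blank, ft$slope),
         uloq = max(included),
         included_levels = as.numeric(included),
         excluded_levels = as.numeric(setdiff(all_levels, included)),
         n_refits = n_refits, level_means = ft$level_means),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve>\n",
      "  slope      ", format(x$slope), " ratio/(ug/g)\n",
      "  intercept  ", format(x$intercept), "\n",
      "  R^2        ", format(x$r_squared), "\n",
      "  LOD        ", format(x$lod), " ug/g\n",
      "  LLOQ       ", format(x$lloq), " ug/g\n",
      "  ULOQ       ", format(x$uloq), " ug/g\n",
      "  included   ", paste(x$included_levels, collapse = ", "), "\n",
      "  excluded   ",
      if (length(x$excluded_levels)) paste(x$excluded_levels, collapse = ", ")
      else "none", "  (", x$n_refits, " fit(s))\n", sep = "")
  invisible(x)
}

#' Back-calculate a concentration from a ratio
#'
#' Inverts the calibration line, `conc = (ratio - intercept) / slope`, and
#' flags the result: `below_lod` when conc < LOD, `below_lloq` when
#' LOD <= conc < LLOQ, `above_uloq` when conc > ULOQ, else `ok`. The flag
#' `nd` (not detected / not acquired) is reserved for channels with no
#' signal anywhere and is assigned by [quantify_rois()], not here.
#'
#' @param curve a `calibration_curve`.
#' @param ratio numeric vector of summed ratios.
#' @return data frame with columns `ratio`, `conc`, `flag`.
#' @export
back_calculate <- function(curve, ratio) {
  stopifnot(inherits(curve, "calibration_curve"))
  conc <- (ratio - curve$intercept) / curve$slope
  flag <- ifelse(conc < curve$lod, "below_lod",
          ifelse(conc < curve$lloq, "below_lloq",
          ifelse(conc > curve$uloq, "above_uloq", "ok")))
  data.frame(ratio = ratio, conc = conc, flag = flag,
             stringsAsFactors = FALSE)
}

#' QC characterization criteria
#'
#' Defaults follow the bioanalytical method-characterization criteria: QC
#' precision within 15% RSD (20% at or below the LLOQ) and QC accuracy
#' between -20% and +10% of nominal, i.e. 80-110%.
#'
#' @param precision_rsd_max maximum %RSD.
#' @param precision_rsd_max_lloq maximum %RSD when nominal <= LLOQ.
#' @param accuracy_min_pct,accuracy_max_pct accuracy bounds in % of nominal.
#' @return a list of class `qc_criteria`.
#' @export
qc_criteria <- function(precision_rsd_max = 15,
                        precision_rsd_max_lloq = 20,
                        accuracy_min_pct = 80,
                        accuracy_max_pct = 110) {
  structure(list(precision_rsd_max = precision_rsd_max,
                 precision_rsd_max_lloq = precision_rsd_max_lloq,
                 accuracy_min_pct = accuracy_min_pct,
                 accuracy_max_pct = accuracy_max_pct),
            class = "qc_criteria")
}

#' Evaluate a QC level
#'
#' Precision is the relative standard deviation (100 x sd/mean, sample SD)
#' of the back-calculated replicate concentrations; accuracy is
#' 100 x mean/nominal. The precision bound relaxes to the LLOQ bound when
#' the nominal concentration is at or below the LLOQ.
#'
#' @param replicate_concs back-calculated QC concentrations, ug/g (n >= 2).
#' @param nominal nominal QC concentration, ug/g.
#' @param lloq lower limit of quantification, ug/g.
#' @param criteria a [qc_criteria()].
#' @return a list of class `qc_result`: `nominal_conc`, `n`,
#'   `mean_measured`, `precision_rsd`, `accuracy_pct`, `below_lloq`,
#'   `passes_precision`, `passes_accuracy`.
#' @export
evaluate_qc <- function(replicate_concs, nominal, lloq,
                        criteria = qc_criteria()) {
  n <- length(replicate_concs)
  if (n < 2L) stop("need n >= 2 QC replicates for RSD", call. = FALSE)
  m <- mean(replicate_concs)
  if (m == 0) stop("undefined RSD: mean measured concentration is 0",
                   call. = FALSE)
  rsd <- 100 * sd(replicate_concs) / m
  acc <- 100 * m / nominal
  rsd_max <- if (nominal <= lloq) criteria$precision_rsd_max_lloq
             else criteria$precision_rsd_max
  structure(
    list(nominal_conc = nominal, n = n, mean_measured = m,
         precision_rsd = rsd, accuracy_pct = acc,
         below_lloq = m < lloq,
         passes_precision = rsd <= rsd_max,
         passes_accuracy = acc >= criteria$accuracy_min_pct &&
                           acc <= criteria$accuracy_max_pct),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result> nominal ", x$nominal_conc, " ug/g (n=", x$n, "): mean ",
      format(x$mean_measured), ", RSD ", format(round(x$precision_rsd, 1)),
      "% [", if (x$passes_precision) "pass" else "FAIL", "], accuracy ",
      format(round(x$accuracy_pct, 1)), "% [",
      if (x$passes_accuracy) "pass" else "FAIL", "]",
      if (x$below_lloq) " (below LLOQ)" else "", "\n", sep = "")
  invisible(x)
}

#' Serialize a calibration curve to JSON
#'
#' @param curve a `calibration_curve`.
#' @param path output file.
#' @param provenance optional named list written under `"provenance"`.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(curve, path, provenance = NULL) {
  stopifnot(inherits(curve, "calibration_curve"))
  obj <- unclass(curve)
  obj$level_means <- NULL
  if (!is.null(provenance)) obj$provenance <- provenance
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$provenance <- NULL
  obj$included_levels <- as.numeric(unlist(obj$included_levels))
  obj$excluded_levels <- as.numeric(unlist(obj$excluded_levels))
  structure(c(obj, list(level_means = NULL)), class = "calibration_curve")
}
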