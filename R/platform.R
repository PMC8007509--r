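#' Dataset for one instrument/mode combination
#'
#' Bundles the ratio observations of one acquisition mode (e.g. full MS
#' scan, ion-mobility HDMS/HDMSE, or MRM on a triple quadrupole) for one or
#' more compounds, ready for calibration and QC evaluation. For a fair
#' comparison all modes of a study should share the same array layout.
#'
#' @param instrument instrument name.
#' @param mode acquisition mode name (unique per instrument).
#' @param observations data frame with columns `channel`, `well_id`, `role`
#'   (`calibration`/`blank`/`qc`), `nominal_conc`, `ratio`, `replicate_id`
#'   (e.g. stacked [extract_array_ratios()] output with a `channel` column).
#' @return an object of class `mode_dataset`.
#' @export
mode_dataset <- function(instrument, mode, observations) {
  need <- c("channel", "well_id", "role", "nominal_conc", "ratio",
            "replicate_id")
  if (!is.data.frame(observations) || !all(need %in% names(observations))) {
    stop("`observations` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  structure(list(instrument = instrument, mode = mode,
                 observations = observations),
            class = "mode_dataset")
}

#' Summarize one instrument/mode against the characterization criteria
#'
#' Per compound: builds the calibration curve (with below-LOD exclusion),
#' back-calculates the QC replicate concentrations per QC level, and
#' evaluates precision and accuracy. QC levels whose nominal concentration
#' falls below the mode's LOD are suppressed (reported as `"<LOD"` in the
#' rendered table, `NA` metrics here) — a mode simply cannot see them. A
#' compound whose calibration fails is recorded as a failed row, not an
#' error for the whole table.
#'
#' @param dataset a [mode_dataset()].
#' @param criteria a [qc_criteria()].
#' @return data frame, one row per (instrument, mode, compound): `lod`,
#'   `lloq`, `r_squared`, `precision_low`, `precision_high`,
#'   `accuracy_low`, `accuracy_high` (low/high = QC levels in increasing
#'   nominal order), `qc_low_below_lod`, `criteria_pass`, `note`.
#' @export
summarize_mode <- function(dataset, criteria = qc_criteria()) {
  stopifnot(inherits(dataset, "mode_dataset"))
  obs <- dataset$observations
  rows <- lapply(unique(obs$channel), function(cmpd) {
    o <- obs[obs$channel == cmpd, , drop = FALSE]
    base <- data.frame(instrument = dataset$instrument, mode = dataset$mode,
                       compound = cmpd, stringsAsFactors = FALSE)
    curve <- tryCatch(
      build_calibration(o[o$role == "calibration", , drop = FALSE],
                        o$ratio[o$role == "blank"]),
      error = function(e) e)
    if (inherits(curve, "error")) {
      return(cbind(base, data.frame(
        lod = NA_real_, lloq = NA_real_, r_squared = NA_real_,
        precision_low = NA_real_, precision_high = NA_real_,
        accuracy_low = NA_real_, accuracy_high = NA_real_,
        qc_low_below_lod = NA, criteria_pass = FALSE,
        note = paste("calibration failed:", conditionMessage(curve)),
        stringsAsFactors = FALSE)))
    }
    qc_levels <- sort(unique(o$nominal_conc[o$role == "qc"]))
    prec <- acc <- rep(NA_real_, 2L)
    pass <- TRUE
    low_below <- FALSE
    for (k in seq_along(qc_levels)) {
      nominal <- qc_levels[k]
      if (nominal < curve$lod) {
        if (k == 1L) low_below <- TRUE
        next  # suppressed: this mode cannot see the level
      }
      ratios <- o$ratio[o$role == "qc" & o$nominal_conc == nominal]
      qc <- evaluate_qc(back_calculate(curve, ratios)$conc, nominal,
                        curve$lloq, criteria)
      prec[k] <- qc$precision_rsd
      acc[k] <- qc$accuracy_pct
      pass <- pass && qc$passes_precision && qc$passes_accuracy
    }
    cbind(base, data.frame(
      lod = curve$lod, lloq = curve$lloq, r_squared = curve$r_squared,
      precision_low = prec[1L], precision_high = prec[2L],
      accuracy_low = acc[1L], accuracy_high = acc[2L],
      qc_low_below_lod = low_below, criteria_pass = pass,
      note = "", stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Rank instrument/mode combinations per compound
#'
#' Ordering key: (1) more QC criteria passed (precision and accuracy at both
#' QC levels; a level suppressed as below-LOD counts as failed), (2) lower
#' LOD, (3) higher R-squared; remaining ties keep input order and are noted.
#'
#' @param summaries row-bound output of [summarize_mode()] for >= 2 modes.
#' @param criteria a [qc_criteria()].
#' @return list with `ranking` (data frame ordered best-first per compound,
#'   with `n_criteria_passed` and `rank`) and `best` (named character vector
#'   compound -> "instrument/mode").
#' @export
rank_modes <- function(summaries, criteria = qc_criteria()) {
  if (length(unique(paste(summaries$instrument, summaries$mode))) < 2L) {
    stop("need >= 2 instrument/mode combinations to rank", call. = FALSE)
  }
  n_passed <- function(r) {
    cnt <- 0L
    for (col in c("precision_low", "precision_high")) {
      v <- r[[col]]
      if (!is.na(v) && v <= criteria$precision_rsd_max) cnt <- cnt + 1L
    }
    for (col in c("accuracy_low", "accuracy_high")) {
      v <- r[[col]]
      if (!is.na(v) && v >= criteria$accuracy_min_pct &&
          v <= criteria$accuracy_max_pct) cnt <- cnt + 1L
    }
    cnt
  }
  out <- list(); best <- character()
  for (cmpd in unique(summaries$compound)) {
    sub <- summaries[summaries$compound == cmpd, , drop = FALSE]
    sub$n_criteria_passed <- vapply(seq_len(nrow(sub)),
                                    function(i) n_passed(sub[i, ]),
                                    integer(1L))
    sub$input_order <- seq_len(nrow(sub))
    lod_key <- ifelse(is.na(sub$lod), Inf, sub$lod)
    r2_key <- ifelse(is.na(sub$r_squared), -Inf, sub$r_squared)
    ord <- order(-sub$n_criteria_passed, lod_key, -r2_key, sub$input_order)
    sub <- sub[ord, , drop = FALSE]
    key <- paste(sub$n_criteria_passed, lod_key[ord], r2_key[ord])
    if (anyDuplicated(key)) {
      message("rank_modes: tie(s) for compound '", cmpd,
              "' broken by input order")
    }
    sub$rank <- seq_len(nrow(sub))
    sub$input_order <- NULL
    rownames(sub) <- NULL
    out[[cmpd]] <- sub
    best[cmpd] <- paste(sub$instrument[1L], sub$mode[1L], sep = "/")
  }
  list(ranking = do.call(rbind, out), best = best)
}

#' Render a platform summary table
#'
#' Formats [summarize_mode()] rows the way multiplatform comparison tables
#' are printed: one row per instrument/mode/compound with LOD, R-squared,
#' and `precision_low/high` and `accuracy_low/high` columns in which a QC
#' level below the mode's LOD appears as `"<LOD"`.
#'
#' @param summaries row-bound [summarize_mode()] output.
#' @param format `"data.frame"`, `"csv"` or `"markdown"`.
#' @param path output file for `"csv"`/`"markdown"` (required then).
#' @return the formatted data frame (invisibly for file outputs).
#' @export
format_platform_table <- function(summaries, format = c("data.frame", "csv",
                                                        "markdown"),
                                  path = NULL) {
  format <- match.arg(format)
  fmt1 <- function(x) ifelse(is.na(x), "<LOD", sprintf("%.1f", x))
  tab <- data.frame(
    instrument = summaries$instrument, mode = summaries$mode,
    compound = summaries$compound,
    lod_ug_g = sprintf("%.1f", summaries$lod),
    r_squared = sprintf("%.2f", summaries$r_squared),
    precision_rsd_low_high = paste(fmt1(summaries$precision_low),
                                   fmt1(summaries$precision_high),
                                   sep = "/"),
    accuracy_pct_low_high = paste(fmt1(summaries$accuracy_low),
                                  fmt1(summaries$accuracy_high), sep = "/"),
    criteria_pass = summaries$criteria_pass,
    stringsAsFactors = FALSE
  )
  if (format == "data.frame") return(tab)
  stopifnot(!is.null(path))
  if (format == "csv") {
    write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else {
    hdr <- paste0("| ", paste(names(tab), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
    body <- apply(tab, 1L, function(r) paste0("| ",
                                              paste(r, collapse = " | "),
                                              " |"))
    writeLines(c(hdr, sep, body), path)
  }
  invisible(tab)
}
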