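# Readings I/O and the end-to-end analysis pipeline: tidy per-timepoint
# results, a Pe summary table with "n.t." (no translocation detected)
# markers, percent-of-ID curve summaries, and pairwise Mann-Whitney tests.

READINGS_COLS <- c("condition", "regime", "compound", "replicate",
                   "time_h", "reading", "unit")

#' Read translocation readings from a tidy CSV
#'
#' Expects columns `condition`, `regime`, `compound`, `replicate`,
#' `time_h`, `reading`, `unit` (comma-separated, UTF-8, '.' decimal,
#' header required). Rows are grouped into one series per (condition,
#' regime, compound, replicate); row order is irrelevant. Readings with
#' unit `mg_per_ml` are used directly; any other unit requires a linear
#' calibration slope for the compound in the config. LODs from the config
#' are applied (readings below are stored as 0 and flagged). Parse
#' problems are reported with the offending line number.
#'
#' @param path CSV path.
#' @param config An [experiment_config()] supplying geometry, schedules,
#'   doses, LODs and calibration slopes.
#' @return Named list of validated [translocation_series()].
#' @export
read_readings <- function(path, config) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(READINGS_COLS, names(df))
  if (length(missing_cols)) {
    stop(sprintf("readings file %s is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  lines <- seq_len(nrow(df)) + 1L # header is line 1
  for (col in c("time_h", "reading")) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]))
    if (anyNA(df[[col]]) ) bad <- union(bad, which(is.na(df[[col]])))
    if (length(bad)) {
      stop(sprintf("unparseable %s at line %d of %s", col, lines[bad[1]], path),
           call. = FALSE)
    }
    df[[col]] <- vals
  }
  key <- paste(df$condition, df$regime, df$compound, df$replicate, sep = "|")
  dup <- duplicated(paste(key, df$time_h))
  if (any(dup)) {
    stop(sprintf("duplicated timepoint for series '%s' at line %d of %s",
                 key[dup][1], lines[dup][1], path), call. = FALSE)
  }

  out <- list()
  for (k in unique(key)) {
    rows <- df[key == k, ]
    rows <- rows[order(rows$time_h), ]
    compound <- rows$compound[1]
    sched <- config$schedule_overrides[[compound]] %||% config$schedule
    if (!isTRUE(all.equal(rows$time_h, sched$times_h))) {
      sched <- sampling_schedule(rows$time_h, sched$sample_volume_ml)
    }
    c0 <- config$dose[[compound]]
    if (is.null(c0)) {
      stop(sprintf("no dose entry in config for compound '%s'", compound),
           call. = FALSE)
    }
    conc <- rows$reading
    not_mass <- rows$unit != "mg_per_ml"
    if (any(not_mass)) {
      slope <- config$calibration[[compound]]
      if (is.null(slope)) {
        stop(sprintf("readings for '%s' are in '%s' but no calibration slope is configured",
                     compound, rows$unit[not_mass][1]), call. = FALSE)
      }
      conc[not_mass] <- conc[not_mass] * slope
    }
    s <- translocation_series(
      geometry = config$geometry, schedule = sched,
      dose = dose_spec(c0, compound, config$geometry),
      concentrations_mg_ml = conc,
      condition = rows$condition[1], regime = rows$regime[1],
      replicate_id = as.character(rows$replicate[1]),
      lod_mg_ml = config$lod[[compound]] %||% NA_real_,
      validate = FALSE)
    msg <- validate_series(s)
    if (length(msg)) {
      stop(sprintf("invalid series '%s' in %s: %s", k, path,
                   paste(msg, collapse = "; ")), call. = FALSE)
    }
    out[[k]] <- s
  }
  out
}

#' Write translocation series to a tidy readings CSV
#'
#' Inverse of [read_readings()]; concentrations are written in
#' `mg_per_ml`.
#'
#' @param series_list List of [translocation_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_readings <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    data.frame(condition = s$condition, regime = s$regime,
               compound = s$dose$compound, replicate = s$replicate_id,
               time_h = s$schedule$times_h,
               reading = s$concentrations_mg_ml,
               unit = "mg_per_ml", stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic study as pipeline-readable fixtures
#'
#' Emits `readings.csv`, `config.json` and a `truth.csv` sidecar carrying
#' the simulator ground truth, into a directory.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(readings = file.path(dir, "readings.csv"),
             config = file.path(dir, "config.json"),
             truth = file.path(dir, "truth.csv"))
  write_readings(study$series, paths[["readings"]])
  write_experiment_config(config_from_design(study$design), paths[["config"]])
  truth_rows <- mapply(function(tr, key) {
    cbind(series = key, as.data.frame(tr), stringsAsFactors = FALSE)
  }, study$truth, names(study$truth), SIMPLIFY = FALSE)
  utils::write.csv(do.call(rbind, truth_rows), paths[["truth"]], row.names = FALSE)
  invisible(paths)
}

series_meta <- function(s) {
  data.frame(compound = s$dose$compound, condition = s$condition,
             regime = s$regime, replicate = s$replicate_id,
             stringsAsFactors = FALSE)
}

#' Estimate the membrane-corrected apparent permeability of a condition
#'
#' Computes the whole-barrier permeability of every cell-condition
#' replicate at the reference timepoint, estimates the blank-membrane
#' permeability P_m from the control replicates (pooled median by
#' default, or matched per replicate), and applies the series-resistance
#' correction per replicate.
#'
#' @param cell_series List of [translocation_series()] for one cell
#'   condition.
#' @param control_series List of blank-membrane series for the same
#'   compound/regime.
#' @param at_time_h Reference timepoint (h), default 2.
#' @param pm_mode `"pooled"` (median control P, the default) or
#'   `"per_replicate"` (match control replicate ids).
#' @return List with `pe` (per-replicate apparent permeabilities;
#'   `NA` where not computable), `pe_median`, `pe_mad` (over computable
#'   values), `p_cell`, `p_membrane`.
#' @export
estimate_pe <- function(cell_series, control_series, at_time_h = 2,
                        pm_mode = c("pooled", "per_replicate")) {
  pm_mode <- match.arg(pm_mode)
  p_cell <- vapply(cell_series, permeability, numeric(1), at_time_h = at_time_h)
  p_ctrl <- vapply(control_series, permeability, numeric(1), at_time_h = at_time_h)
  if (pm_mode == "pooled") {
    p_m <- rep(stats::median(p_ctrl), length(p_cell))
  } else {
    ids <- vapply(control_series, function(s) s$replicate_id, character(1))
    want <- vapply(cell_series, function(s) s$replicate_id, character(1))
    p_m <- p_ctrl[match(want, ids)]
  }
  pe <- apparent_permeability(pmax(p_cell, 0), p_m)
  ok <- is.finite(pe)
  list(pe = pe,
       pe_median = if (any(ok)) stats::median(pe[ok]) else NA_real_,
       pe_mad = if (any(ok)) stats::median(abs(pe[ok] - stats::median(pe[ok]))) else NA_real_,
       p_cell = p_cell, p_membrane = p_m)
}

#' Analyse a full translocation study
#'
#' Runs the kinetic, dosimetric and statistical layers over a list of
#' series (measured or synthetic):
#' * `tidy` -- one row per (series, timepoint) with concentration,
#'   below-LOD flag, cumulative mass and percent of ID;
#' * `pe_summary` -- per (compound, cell condition, regime): median +/-
#'   MAD of the membrane-corrected Pe at `pe_time_h`, replicate count and
#'   the n.t. marker ("no translocation detected": every replicate's
#'   final reading below LOD);
#' * `percent_id_summary` -- per (compound, condition, regime,
#'   timepoint): median with replicate min/max;
#' * `pairwise` -- exact Mann-Whitney tests of each cell condition vs
#'   control on final percent of ID, and static vs shaken on per-replicate
#'   Pe where both regimes are present.
#'
#' @param series_list List of [translocation_series()].
#' @param pe_time_h Reference timepoint for Pe (default 2 h).
#' @param pm_mode Membrane-permeability mode, see [estimate_pe()].
#' @return An object of class `study_results` (list of the four
#'   data.frames).
#' @export
analyze_study <- function(series_list, pe_time_h = 2,
                          pm_mode = c("pooled", "per_replicate")) {
  pm_mode <- match.arg(pm_mode)
  meta <- do.call(rbind, lapply(series_list, series_meta))

  tidy <- do.call(rbind, lapply(series_list, function(s) {
    pct <- percent_of_initial_dose(s)
    cbind(series_meta(s)[rep(1, length(s$schedule$times_h)), ],
          data.frame(time_h = s$schedule$times_h,
                     concentration_mg_ml = s$concentrations_mg_ml,
                     below_lod = s$below_lod,
                     cumulative_mass_mg = cumulative_mass(s),
                     percent_id = as.numeric(pct)))
  }))
  rownames(tidy) <- NULL

  grp_key <- paste(meta$compound, meta$condition, meta$regime, sep = "|")
  groups <- split(seq_along(series_list), grp_key)

  final_pct <- function(s) {
    utils::tail(as.numeric(percent_of_initial_dose(s)), 1)
  }
  final_below_lod <- function(s) utils::tail(s$below_lod, 1)

  # percent-of-ID curve summaries (median with replicate min/max)
  pid_rows <- lapply(names(groups), function(k) {
    ss <- series_list[groups[[k]]]
    times <- ss[[1]]$schedule$times_h
    pct <- vapply(ss, function(s) as.numeric(percent_of_initial_dose(s)),
                  numeric(length(times)))
    pct <- matrix(pct, nrow = length(times))
    info <- series_meta(ss[[1]])
    data.frame(compound = info$compound, condition = info$condition,
               regime = info$regime, time_h = times,
               median = apply(pct, 1, stats::median),
               lower = apply(pct, 1, min), upper = apply(pct, 1, max),
               n = length(ss), stringsAsFactors = FALSE)
  })
  percent_id_summary <- do.call(rbind, pid_rows)

  # Pe summary for cell-bearing conditions, with n.t. markers
  pe_rows <- list()
  pairwise_rows <- list()
  for (cmp in unique(meta$compound)) {
    for (reg in unique(meta$regime)) {
      ctrl_idx <- which(meta$compound == cmp & meta$regime == reg &
                          meta$condition == "control")
      for (cond in setdiff(unique(meta$condition), "control")) {
        idx <- which(meta$compound == cmp & meta$regime == reg &
                       meta$condition == cond)
        if (!length(idx)) next
        ss <- series_list[idx]
        nt <- all(vapply(ss, final_below_lod, logical(1)))
        pe_med <- pe_mad <- NA_real_
        if (!nt && length(ctrl_idx)) {
          est <- estimate_pe(ss, series_list[ctrl_idx], at_time_h = pe_time_h,
                             pm_mode = pm_mode)
          pe_med <- est$pe_median
          pe_mad <- est$pe_mad
        }
        pe_rows[[length(pe_rows) + 1L]] <- data.frame(
          compound = cmp, condition = cond, regime = reg, n = length(ss),
          nt = nt, pe_median_cm_s = pe_med, pe_mad_cm_s = pe_mad,
          pe_time_h = pe_time_h, stringsAsFactors = FALSE)
        # cell condition vs control on final percent of ID
        if (length(ctrl_idx)) {
          tst <- mann_whitney_exact(
            vapply(ss, final_pct, numeric(1)),
            vapply(series_list[ctrl_idx], final_pct, numeric(1)))
          pairwise_rows[[length(pairwise_rows) + 1L]] <- data.frame(
            compound = cmp, comparison = paste0(cond, "_vs_control"),
            regime = reg, endpoint = "final_percent_id",
            u_statistic = tst$u_statistic, p_two_sided = tst$p_two_sided,
            n1 = tst$n1, n2 = tst$n2, method = tst$method,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  pe_summary <- do.call(rbind, pe_rows)

  # static vs shaken on per-replicate Pe
  if (all(c("static", "shaken") %in% meta$regime)) {
    for (cmp in unique(meta$compound)) {
      for (cond in setdiff(unique(meta$condition), "control")) {
        pe_by_regime <- lapply(c("static", "shaken"), function(reg) {
          idx <- which(meta$compound == cmp & meta$regime == reg &
                         meta$condition == cond)
          ctrl_idx <- which(meta$compound == cmp & meta$regime == reg &
                              meta$condition == "control")
          if (!length(idx) || !length(ctrl_idx)) return(numeric(0))
          est <- estimate_pe(series_list[idx], series_list[ctrl_idx],
                             at_time_h = pe_time_h, pm_mode = pm_mode)
          est$pe[is.finite(est$pe)]
        })
        if (all(lengths(pe_by_regime) >= 1)) {
          tst <- mann_whitney_exact(pe_by_regime[[1]], pe_by_regime[[2]])
          pairwise_rows[[length(pairwise_rows) + 1L]] <- data.frame(
            compound = cmp, comparison = "static_vs_shaken",
            regime = cond, endpoint = "pe",
            u_statistic = tst$u_statistic, p_two_sided = tst$p_two_sided,
            n1 = tst$n1, n2 = tst$n2, method = tst$method,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  pairwise <- if (length(pairwise_rows)) do.call(rbind, pairwise_rows) else NULL

  structure(list(tidy = tidy, pe_summary = pe_summary,
                 percent_id_summary = percent_id_summary,
                 pairwise = pairwise),
            class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("<study_results> %d tidy rows, %d Pe summaries, %d pairwise tests\n",
              nrow(x$tidy), nrow(x$pe_summary),
              if (is.null(x$pairwise)) 0L else nrow(x$pairwise)))
  invisible(x)
}

#' Run the full analysis pipeline on files
#'
#' Reads a config and a readings CSV, runs [analyze_study()], and writes
#' four CSVs (`results_tidy.csv`, `pe_summary.csv` with Pe in 1e-6
#' cm s^-1 and "n.t." markers rendered in a text column,
#' `percent_id_summary.csv`, `pairwise_tests.csv`) plus a `run_log.json`
#' with package version, seed and config hash. Identical inputs produce
#' byte-identical CSVs. If any stage fails, partial outputs are removed.
#'
#' @param config_path Path to the JSON config.
#' @param readings_path Path to the readings CSV.
#' @param out_dir Output directory (created if needed).
#' @param pe_time_h Reference timepoint for Pe.
#' @param pm_mode Membrane-permeability mode, see [estimate_pe()].
#' @param seed Seed recorded in the run log (the analysis itself is
#'   deterministic).
#' @return The [analyze_study()] results, invisibly.
#' @export
run_pipeline <- function(config_path, readings_path, out_dir,
                         pe_time_h = 2, pm_mode = "pooled", seed = NA) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out_files <- file.path(out_dir, c("results_tidy.csv", "pe_summary.csv",
                                    "percent_id_summary.csv",
                                    "pairwise_tests.csv", "run_log.json"))
  res <- tryCatch({
    config <- read_experiment_config(config_path)
    series <- read_readings(readings_path, config)
    results <- analyze_study(series, pe_time_h = pe_time_h, pm_mode = pm_mode)

    utils::write.csv(results$tidy, out_files[1], row.names = FALSE)
    pe <- results$pe_summary
    pe$pe_display <- ifelse(pe$nt, "n.t.",
                            sprintf("%.1f +/- %.1f",
                                    pe$pe_median_cm_s * 1e6,
                                    pe$pe_mad_cm_s * 1e6))
    utils::write.csv(pe, out_files[2], row.names = FALSE)
    utils::write.csv(results$percent_id_summary, out_files[3], row.names = FALSE)
    utils::write.csv(results$pairwise, out_files[4], row.names = FALSE)
    jsonlite::write_json(list(
      package = "transwellr",
      version = as.character(utils::packageVersion("transwellr")),
      seed = seed,
      config_hash = unname(tools::md5sum(config_path)),
      readings_hash = unname(tools::md5sum(readings_path)),
      n_series = length(series),
      timestamp = format(Sys.time(), tz = "UTC")
    ), out_files[5], auto_unbox = TRUE)
    results
  }, error = function(e) {
    unlink(out_files)
    stop(sprintf("pipeline failed: %s", conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
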