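#' Read a run configuration
#'
#' Run configurations are YAML files (or equivalent R lists) with
#' per-stage sections: `layout` (chips with condition/role/treatment),
#' `curves` (per-sample-chip ground truth), `kinetics`, `calibration`
#' (`cal_activity`, `Finf`, `F0`, `rate_window`), `derivative`
#' (`window`, `order`), `lag` (`lag_frac`, `lag_floor`), `permeability`
#' (`geometry`, scenario), `stats` (`control` label), and a mandatory
#' `seed` for simulation.
#'
#' @param path YAML file path.
#' @return The configuration as a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

config_scenario <- function(config) {
  if (is.null(config$seed))
    stop("config error: a 'seed' entry is mandatory for simulation",
         call. = FALSE)
  lay <- config$layout
  if (is.null(lay)) stop("config error: missing 'layout' section",
                         call. = FALSE)
  layout <- plate_layout(
    chip_id = vapply(lay, `[[`, "", "chip_id"),
    condition = vapply(lay, function(x) x$condition %||% "none", ""),
    role = vapply(lay, function(x) x$role %||% "sample", ""),
    treatment = vapply(lay, function(x) x$treatment %||% "none", ""),
    plate_type = config$plate_type %||% "graft-64")
  kin <- do.call(kinetics_spec, config$kinetics %||% list())
  curves <- lapply(config$curves %||% list(),
                   function(cv) do.call(thrombin_curve_spec, cv))
  synthetic_scenario(layout = layout, curves = curves, kinetics = kin,
                     cal_activity = config$calibration$cal_activity %||% 100,
                     seed = config$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a scenario and persist its outputs
#'
#' Runs [simulate_plate()] for the configured scenario and writes, under
#' `out_dir`: the per-chip traces as tidy CSV, the ground-truth table as
#' CSV, one multi-page TIFF stack per chip (rendered through
#' [render_image_stack()]), and a copy of the resolved configuration.
#' A run log records the seed.
#'
#' @param config Configuration list or YAML path (see
#'   [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @param write_tiffs Render and write image stacks (default `TRUE`;
#'   disable for trace-only runs).
#' @return Invisibly, the [simulate_plate()] result.
#' @export
run_simulate <- function(config, out_dir, write_tiffs = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  scn <- config_scenario(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_plate(scn)
  write_traces_csv(sim$traces, file.path(out_dir, "traces.csv"))
  utils::write.csv(sim$truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  if (isTRUE(write_tiffs)) {
    roi <- roi_spec(20, 20, 120, 60)
    for (tr in sim$traces) {
      stack <- render_image_stack(tr, roi, frame_dim = c(80, 160),
                                  background = scn$kinetics$F0)
      write_image_stack(stack,
                        file.path(out_dir, paste0(tr$chip_id, ".tif")))
    }
  }
  yaml::write_yaml(config, file.path(out_dir, "config_resolved.yaml"))
  writeLines(sprintf("seed: %d | chips: %d | frames: %d",
                     scn$seed, nrow(scn$layout), scn$kinetics$n_frames),
             file.path(out_dir, "run.log"))
  invisible(sim)
}

#' Run the thrombin-generation pipeline
#'
#' Executes the full inversion for every chip of a plate: calibrator
#' chips are fitted into a pooled [calibration_model()] (mean Cf across
#' calibrators), every other chip's trace is converted to a thrombogram
#' ([thrombin_curve_from_trace()]) and summarised
#' ([thrombogram_params()]), and, when a control condition is given,
#' conditions are compared with ANOVA + Dunnett on ETP.
#'
#' @param traces Named list of [roi_trace()] (or a traces CSV path).
#' @param layout A [plate_layout()] covering the trace chip ids.
#' @param cal_activity Calibrator activity (nM).
#' @param Finf,F0 Inner-filter parameters.
#' @param rate_window Calibrator slope window (frames; default `NULL`
#'   = all frames after the first, see [fit_calibrator()]).
#' @param window,order Savitzky-Golay parameters (defaults 9 and 3).
#' @param baseline_frames Baseline-drift correction frames (default 0,
#'   see [thrombin_curve_from_trace()]).
#' @param lag_frac,lag_floor Lag definition (see
#'   [thrombogram_params()]).
#' @param control Optional control condition label for group
#'   comparisons.
#' @param out_dir Optional directory; when given, the parameters and
#'   comparison tables and each thrombogram are persisted as CSV.
#' @return A list with `calibration`, `params` (per-chip data frame
#'   with condition/treatment columns), `thrombograms`, and (when
#'   `control` is given) `comparisons`.
#' @export
run_thrombin <- function(traces, layout, cal_activity = 100,
                         Finf = 60000, F0 = 200, rate_window = NULL,
                         window = 9, order = 3, baseline_frames = 0,
                         lag_frac = 0.05, lag_floor = 1, control = NULL,
                         out_dir = NULL) {
  if (is.character(traces)) traces <- read_traces_csv(traces)
  stopifnot(inherits(layout, "plate_layout"))
  cal_ids <- layout$chip_id[layout$role == "calibrator"]
  cal_ids <- intersect(cal_ids, names(traces))
  if (length(cal_ids) == 0L)
    stop("run_thrombin: the layout must provide at least one calibrator ",
         "chip with a trace", call. = FALSE)
  cals <- lapply(cal_ids, function(id) {
    fit_calibrator(traces[[id]], cal_activity = cal_activity,
                   Finf = Finf, F0 = F0, rate_window = rate_window)
  })
  cal <- calibration_model(cal_activity,
                           mean(vapply(cals, `[[`, 0, "cal_rate")),
                           Finf = Finf, F0 = F0)
  run_ids <- layout$chip_id[layout$role != "calibrator"]
  run_ids <- intersect(run_ids, names(traces))
  tgs <- list(); rows <- list()
  for (id in run_ids) {
    res <- tryCatch({
      tg <- thrombin_curve_from_trace(traces[[id]], cal,
                                      window = window, order = order,
                                      baseline_frames = baseline_frames)
      list(tg = tg,
           row = thrombogram_params(tg, lag_frac = lag_frac,
                                    lag_floor = lag_floor))
    }, error = function(e) {
      warning("chip '", id, "' skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    tgs[[id]] <- res$tg
    rows[[id]] <- res$row
  }
  params <- do.call(rbind, rows)
  params <- merge(params,
                  layout[, c("chip_id", "condition", "role", "treatment")],
                  by = "chip_id", sort = FALSE)
  out <- list(calibration = cal, params = params, thrombograms = tgs)
  if (!is.null(control)) {
    smp <- params[params$role == "sample", ]
    out$summary <- summarize_groups(smp$ETP_nM_min, smp$condition)
    sizes <- table(smp$condition)
    small <- names(sizes)[sizes < 2]
    if (length(small) && !control %in% small) {
      warning("condition(s) with n < 2 excluded from comparisons: ",
              paste(small, collapse = ", "))
      smp <- smp[!smp$condition %in% small, ]
    }
    if (length(unique(smp$condition)) >= 2L) {
      cc <- compare_to_control(smp$ETP_nM_min, smp$condition, control)
      cc$comparisons$fold_vs_control <- vapply(
        cc$comparisons$group, function(gp) {
          fold_change(smp$ETP_nM_min[smp$condition == gp],
                      smp$ETP_nM_min[smp$condition == control])
        }, numeric(1))
      cc$comparisons$label <- significance_label(cc$comparisons$p_adj)
      out$comparisons <- cc
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(params, file.path(out_dir, "thrombogram_params.csv"),
                     row.names = FALSE)
    tg_df <- do.call(rbind, lapply(tgs, as.data.frame))
    utils::write.csv(tg_df, file.path(out_dir, "thrombograms.csv"),
                     row.names = FALSE)
    if (!is.null(out$comparisons))
      utils::write.csv(out$comparisons$comparisons,
                       file.path(out_dir, "etp_comparisons.csv"),
                       row.names = FALSE)
  }
  out
}

#' Run the permeability pipeline
#'
#' Computes [papp()] for every chip with a donor/receiver trace pair;
#' chips with a missing pair are skipped with a warning so one failed
#' chip does not abort a plate.
#'
#' @param pairs Named list (by chip id) of lists with `donor` and
#'   `receiver` [roi_trace()] elements.
#' @param geometry Chip geometry (see [chip_geometry()]).
#' @param fit_window Frames used for the slope fit (default all).
#' @param out_dir Optional output directory for the results CSV.
#' @return Data frame of per-chip permeability results.
#' @export
run_permeability <- function(pairs, geometry = chip_geometry(),
                             fit_window = NULL, out_dir = NULL) {
  rows <- list()
  for (id in names(pairs)) {
    p <- pairs[[id]]
    if (is.null(p$donor) || is.null(p$receiver)) {
      warning("chip '", id, "' skipped: missing donor or receiver trace")
      next
    }
    rows[[id]] <- tryCatch(
      papp(p$donor, p$receiver, geometry = geometry,
           fit_window = fit_window),
      error = function(e) {
        warning("chip '", id, "' skipped: ", conditionMessage(e))
        NULL
      })
  }
  res <- do.call(rbind, rows)
  if (!is.null(out_dir) && !is.null(res)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res, file.path(out_dir, "papp.csv"),
                     row.names = FALSE)
  }
  res
}
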