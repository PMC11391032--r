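# Shared fixture builders: every fixture is generated in code from a
# fixed seed, nothing is read from disk.

default_curve <- function(P, t0 = 5, tp = 15, a = 3, tail_frac = 0) {
  thrombin_curve_spec(t0 = t0, tp = tp, P = P, a = a,
                      tail_frac = tail_frac)
}

# A plate with `n` sample chips per condition (all chips of a condition
# share one ground-truth curve), two calibrators and one blank.
condition_scenario <- function(peaks, n = 4, kin = kinetics_spec(),
                               cal_activity = 100, seed = 1,
                               curve_fun = default_curve) {
  ids <- character(); cond <- character(); role <- character()
  curves <- list()
  for (cname in names(peaks)) {
    for (i in seq_len(n)) {
      id <- sprintf("%s_%02d", cname, i)
      ids <- c(ids, id); cond <- c(cond, cname); role <- c(role, "sample")
      curves[[id]] <- curve_fun(peaks[[cname]])
    }
  }
  ids <- c(ids, "cal_01", "cal_02", "blank_01")
  cond <- c(cond, "calibrator", "calibrator", "blank")
  role <- c(role, "calibrator", "calibrator", "blank")
  lay <- plate_layout(ids, cond, role)
  synthetic_scenario(lay, curves, kin, cal_activity = cal_activity,
                     seed = seed)
}

# Run the full inversion on a scenario and return per-chip parameters
# joined with ground truth.
recover_params <- function(scn, ...) {
  sim <- simulate_plate(scn)
  res <- run_thrombin(sim$traces, scn$layout,
                      cal_activity = scn$cal_activity,
                      Finf = scn$kinetics$Finf, F0 = scn$kinetics$F0,
                      ...)
  merge(res$params, sim$truth[, c("chip_id", "true_peak_nM",
                                  "true_ETP_nM_min")],
        by = "chip_id", sort = FALSE)
}
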