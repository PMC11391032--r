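#' Fluorogenic substrate kinetics specification
#'
#' Parameters of the forward model that maps a thrombin concentration
#' curve to an observed fluorescence trace: Michaelis-Menten cleavage of
#' a fluorogenic substrate by thrombin, a linear fluorescence yield per
#' unit product, and a saturating (inner-filter) detector response.
#'
#' Defaults follow the assay schedule (one frame per minute for one
#' hour, i.e. 61 frames) and plausible plate-CAT substrate kinetics:
#' 416 uM substrate with Km = 161 uM. `kcat` is scaled so that total
#' substrate consumption over a run stays below ~1%, keeping the
#' fluorescence rate proportional to thrombin activity.
#'
#' @param kcat Substrate turnover rate constant (1/min).
#' @param Km Michaelis constant (uM).
#' @param S0 Initial substrate concentration (uM).
#' @param gain Fluorescence yield (RFU per uM cleaved product).
#' @param Finf Inner-filter saturation level F-infinity (RFU, `> 0`).
#' @param F0 Baseline fluorescence offset (RFU).
#' @param sigma Additive Gaussian noise SD per frame (RFU).
#' @param n_frames Number of frames (`>= 3`).
#' @param dt Sampling interval (min, `> 0`).
#' @return An object of class `kinetics_spec`.
#' @export
kinetics_spec <- function(kcat = 1, Km = 161, S0 = 416, gain = 1000,
                          Finf = 60000, F0 = 200, sigma = 0,
                          n_frames = 61, dt = 1) {
  for (nm in c("kcat", "Km", "S0", "gain", "Finf", "F0", "sigma",
               "n_frames", "dt")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("kinetics_spec: field '", nm, "' must be a finite number",
           call. = FALSE)
  }
  if (min(kcat, Km, S0, gain, sigma) < 0)
    stop("kinetics_spec: rates and concentrations must be >= 0",
         call. = FALSE)
  if (Finf <= 0) stop("kinetics_spec: Finf must be > 0", call. = FALSE)
  if (n_frames < 3) stop("kinetics_spec: n_frames must be >= 3",
                         call. = FALSE)
  if (dt <= 0) stop("kinetics_spec: dt must be > 0", call. = FALSE)
  structure(list(kcat = kcat, Km = Km, S0 = S0, gain = gain, Finf = Finf,
                 F0 = F0, sigma = sigma, n_frames = as.integer(n_frames),
                 dt = dt),
            class = "kinetics_spec")
}

#' Frame time grid of a kinetics specification
#' @param kin A [kinetics_spec()].
#' @param t_start Time of the first frame (min).
#' @return Numeric vector of frame times in minutes.
#' @export
kinetics_times <- function(kin, t_start = 0) {
  stopifnot(inherits(kin, "kinetics_spec"))
  t_start + (seq_len(kin$n_frames) - 1L) * kin$dt
}

# Fixed-step RK4 integration of dS/dt = -kcat * T(t) * S / (Km + S),
# with thrombin (nM) converted to uM inside the rate. Returns substrate
# at each frame time. `Tfun` is a function of time (min) returning nM.
integrate_substrate <- function(Tfun, kin, step = 0.05) {
  times <- kinetics_times(kin)
  n_sub <- max(1L, ceiling(kin$dt / step))
  h <- kin$dt / n_sub
  rate <- function(t, S) -kin$kcat * (Tfun(t) * 1e-3) * S / (kin$Km + S)
  S <- numeric(kin$n_frames)
  S[1] <- kin$S0
  s <- kin$S0
  for (i in seq_len(kin$n_frames - 1L)) {
    t <- times[i]
    for (j in seq_len(n_sub)) {
      k1 <- rate(t, s)
      k2 <- rate(t + h / 2, s + h / 2 * k1)
      k3 <- rate(t + h / 2, s + h / 2 * k2)
      k4 <- rate(t + h, s + h * k3)
      s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      s <- max(s, 0)
      t <- t + h
    }
    S[i + 1L] <- s
  }
  S
}

as_thrombin_fun <- function(curve, kin) {
  if (inherits(curve, "thrombin_curve_spec"))
    return(function(t) thrombin_curve(curve, t))
  if (is.function(curve)) return(curve)
  if (is.numeric(curve)) {
    times <- kinetics_times(kin)
    if (length(curve) != length(times))
      stop("curve length (", length(curve),
           ") does not match the kinetics time grid (", length(times), ")",
           call. = FALSE)
    return(stats::approxfun(times, curve, rule = 2))
  }
  stop("curve must be a thrombin_curve_spec, a function of time, or a ",
       "numeric vector on the kinetics time grid", call. = FALSE)
}

#' Simulate a fluorescence trace from a thrombin curve
#'
#' Forward model of the on-chip thrombin-generation readout. Substrate is
#' consumed following Michaelis-Menten kinetics driven by the thrombin
#' curve (`dS/dt = -kcat * T(t) * S / (Km + S)`, fixed-step RK4), cleaved
#' product yields fluorescence `F_lin = gain * (S0 - S)`, and the
#' detector saturates through an inner-filter response
#' `F = F0 + Finf * tanh(F_lin / Finf)` plus optional Gaussian noise.
#' With `sigma = 0` the trace is nondecreasing and bounded by
#' `F0 + Finf`.
#'
#' @param curve Thrombin input: a [thrombin_curve_spec()], a function of
#'   time (min) returning nM, or a numeric vector sampled on the
#'   kinetics frame grid (linearly interpolated internally).
#' @param kin A [kinetics_spec()].
#' @param seed Optional integer seed for the noise draw. Ignored when
#'   `sigma = 0`.
#' @param chip_id Identifier stored in the returned trace.
#' @return A [roi_trace()] with frame times and observed RFU.
#' @export
simulate_fluorescence <- function(curve, kin, seed = NULL,
                                  chip_id = "sim") {
  stopifnot(inherits(kin, "kinetics_spec"))
  Tfun <- as_thrombin_fun(curve, kin)
  S <- integrate_substrate(Tfun, kin)
  product <- kin$S0 - S
  F_lin <- kin$gain * product
  F_obs <- kin$F0 + kin$Finf * tanh(F_lin / kin$Finf)
  if (kin$sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    F_obs <- F_obs + stats::rnorm(length(F_obs), 0, kin$sigma)
  }
  roi_trace(chip_id = chip_id, t = kinetics_times(kin), F = F_obs)
}

#' Simulate a thrombin-calibrator trace
#'
#' A calibrator chip contains a reagent with constant thrombin-like
#' activity; its trace follows the same forward model with
#' `T(t) = cal_activity`. In the far-from-saturation regime its initial
#' fluorescence slope is `gain * kcat * cal_activity * S0 / (Km + S0)`
#' (with activity in uM), which anchors the calibrator factor.
#'
#' @param cal_activity Calibrator thrombin-equivalent activity (nM,
#'   `>= 0`).
#' @param kin A [kinetics_spec()].
#' @param seed Optional integer seed for the noise draw.
#' @param chip_id Identifier stored in the returned trace.
#' @return A [roi_trace()].
#' @export
simulate_calibrator <- function(cal_activity, kin, seed = NULL,
                                chip_id = "cal") {
  stopifnot(is.numeric(cal_activity), length(cal_activity) == 1L,
            is.finite(cal_activity))
  if (cal_activity < 0)
    stop("simulate_calibrator: cal_activity must be >= 0", call. = FALSE)
  simulate_fluorescence(function(t) rep_len(cal_activity, length(t)),
                        kin, seed = seed, chip_id = chip_id)
}

#' Analytic initial fluorescence rate of a calibrator
#'
#' `gain * kcat * cal_activity * S0 / (Km + S0)` in RFU/min, the
#' small-time slope of the noise-free calibrator trace (activity
#' converted from nM to uM).
#'
#' @inheritParams simulate_calibrator
#' @return Slope in RFU/min.
#' @export
calibrator_initial_rate <- function(cal_activity, kin) {
  stopifnot(inherits(kin, "kinetics_spec"))
  kin$gain * kin$kcat * (cal_activity * 1e-3) * kin$S0 / (kin$Km + kin$S0)
}
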