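#' Inner-filter (H-)transformation of a fluorescence trace
#'
#' Inverts the saturating detector response assumed throughout the
#' pipeline, `F = F0 + Finf * tanh(F_lin / Finf)`, via
#' `F_tilde = Finf * atanh((F - F0) / Finf)`. In the small-signal regime
#' `F_tilde` equals `F - F0`; near saturation it restores the linear
#' fluorescence the inner-filter effect compressed. Values at or above
#' saturation are clipped to `0.999 * Finf` with a warning.
#'
#' @param trace A [roi_trace()] of raw fluorescence.
#' @param Finf Inner-filter saturation level (RFU, `> 0`).
#' @param F0 Baseline offset (RFU).
#' @return A [roi_trace()] of linearised fluorescence (baseline
#'   removed).
#' @export
h_transform <- function(trace, Finf, F0 = 0) {
  stopifnot(inherits(trace, "roi_trace"))
  if (!is.numeric(Finf) || length(Finf) != 1L || !is.finite(Finf) ||
      Finf <= 0)
    stop("h_transform: Finf must be a positive number", call. = FALSE)
  x <- trace$F - F0
  sat <- x >= Finf
  if (all(sat))
    stop("h_transform: entire trace at or above saturation", call. = FALSE)
  if (any(sat)) {
    warning(sum(sat), " frame(s) at/above saturation clipped to 0.999*Finf")
    x[sat] <- 0.999 * Finf
  }
  # noise can push F slightly below F0; atanh handles (-1, 1) but guard
  # the lower branch the same way
  low <- x <= -Finf
  if (any(low)) {
    warning(sum(low), " frame(s) at/below -Finf clipped")
    x[low] <- -0.999 * Finf
  }
  roi_trace(trace$chip_id, trace$t, Finf * atanh(x / Finf), trace$roi)
}

#' Smoothed first derivative of a trace
#'
#' Savitzky-Golay local least-squares polynomial first derivative,
#' evaluated at every sample; edge samples use the one-sided
#' (asymmetric) fits of the same design, so the estimator is exact on
#' polynomials up to the fit order everywhere, including the ends.
#'
#' @param trace A [roi_trace()] with a uniform time grid.
#' @param window Odd window length in samples (default 7,
#'   `<= length(trace)`).
#' @param order Polynomial order (default 2, `< window`).
#' @return Numeric vector of derivatives (RFU/min), one per sample.
#' @export
smooth_derivative <- function(trace, window = 7, order = 2) {
  stopifnot(inherits(trace, "roi_trace"))
  n <- length(trace$F)
  if (window %% 2 != 1) stop("smooth_derivative: window must be odd",
                             call. = FALSE)
  if (window > n) stop("smooth_derivative: trace shorter than window",
                       call. = FALSE)
  if (order >= window) stop("smooth_derivative: order must be < window",
                            call. = FALSE)
  dt <- diff(trace$t)
  if (max(dt) - min(dt) > 1e-9 * max(dt))
    stop("smooth_derivative: non-uniform time grid", call. = FALSE)
  as.numeric(signal::sgolayfilt(trace$F, p = order, n = window, m = 1,
                                ts = dt[1]))
}

#' Calibration model of the thrombin-generation assay
#'
#' @param cal_activity Calibrator thrombin-equivalent activity (nM).
#' @param cal_rate Measured calibrator fluorescence rate after
#'   H-transformation (RFU/min, `> 0`).
#' @param Finf Inner-filter saturation (RFU, `> 0`).
#' @param F0 Baseline offset (RFU).
#' @return An object of class `calibration_model` with the conversion
#'   factor `Cf = cal_activity / cal_rate` (nM per RFU/min).
#' @export
calibration_model <- function(cal_activity, cal_rate, Finf, F0 = 0) {
  if (!is.numeric(cal_rate) || cal_rate <= 0 || !is.finite(cal_rate))
    stop("calibration_model: cal_rate must be positive", call. = FALSE)
  if (Finf <= 0) stop("calibration_model: Finf must be positive",
                      call. = FALSE)
  structure(list(cal_activity = cal_activity, cal_rate = cal_rate,
                 Cf = cal_activity / cal_rate, Finf = Finf, F0 = F0),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> activity %.4g nM, rate %.5g RFU/min, Cf %.5g nM.min/RFU, Finf %.5g, F0 %.4g\n",
    x$cal_activity, x$cal_rate, x$Cf, x$Finf, x$F0))
  invisible(x)
}

#' Fit the calibrator factor from a calibrator trace
#'
#' The calibrator chip has constant thrombin-equivalent activity, so its
#' H-transformed trace is (initially) linear in time. The calibrator
#' rate is the least-squares slope over an early-frame window, and the
#' calibrator factor is `Cf = cal_activity / cal_rate` (nM per RFU/min),
#' the conversion applied to every sample chip's fluorescence rate.
#'
#' @param trace A calibrator [roi_trace()] (raw fluorescence).
#' @param cal_activity Known calibrator activity (nM, `> 0`).
#' @param Finf,F0 Inner-filter parameters passed to [h_transform()].
#' @param rate_window Integer frame indices (1-based) of the slope fit
#'   window. The default (`NULL`) uses every frame after the first:
#'   with the corrected (H-transformed) trace the calibrator stays
#'   linear over the whole acquisition at these kinetics, and the long
#'   window keeps the slope variance - which propagates into every
#'   thrombin value - far below the per-frame noise. Pass an explicit
#'   early-frame window (e.g. `2:11`) when substrate depletion bends
#'   the calibrator late in a run.
#' @return A [calibration_model()].
#' @export
fit_calibrator <- function(trace, cal_activity, Finf, F0 = 0,
                           rate_window = NULL) {
  stopifnot(inherits(trace, "roi_trace"))
  if (!is.numeric(cal_activity) || cal_activity <= 0)
    stop("fit_calibrator: cal_activity must be > 0", call. = FALSE)
  if (is.null(rate_window)) rate_window <- 2:length(trace$t)
  rate_window <- rate_window[rate_window >= 1 &
                               rate_window <= length(trace$t)]
  if (length(rate_window) < 2L)
    stop("fit_calibrator: rate window has fewer than 2 frames",
         call. = FALSE)
  ht <- h_transform(trace, Finf = Finf, F0 = F0)
  tt <- ht$t[rate_window]
  yy <- ht$F[rate_window]
  slope <- sum((tt - mean(tt)) * (yy - mean(yy))) /
    sum((tt - mean(tt))^2)
  if (!is.finite(slope) || slope <= 0)
    stop("fit_calibrator: non-positive fitted slope (", format(slope),
         " RFU/min) - calibration failure for chip '", trace$chip_id, "'",
         call. = FALSE)
  calibration_model(cal_activity, slope, Finf = Finf, F0 = F0)
}

#' Thrombin concentration curve of one chip
#'
#' @param chip_id Chip identifier.
#' @param t Timestamps (min).
#' @param T_nM Thrombin concentration per timepoint (nM); may be signed
#'   (noise), see [thrombogram_params()] for the clipped view.
#' @return An object of class `thrombogram`.
#' @export
thrombogram <- function(chip_id, t, T_nM) {
  if (length(t) != length(T_nM) || !all(is.finite(t)) ||
      !all(is.finite(T_nM)))
    stop("thrombogram: t and T_nM must be finite and of equal length",
         call. = FALSE)
  structure(list(chip_id = as.character(chip_id), t = as.numeric(t),
                 T_nM = as.numeric(T_nM)),
            class = "thrombogram")
}

#' @export
print.thrombogram <- function(x, ...) {
  cat(sprintf("<thrombogram> chip '%s': %d points, peak %.4g nM\n",
              x$chip_id, length(x$t), max(pmax(x$T_nM, 0))))
  invisible(x)
}

#' @export
as.data.frame.thrombogram <- function(x, ...) {
  data.frame(chip_id = x$chip_id, t_min = x$t, T_nM = x$T_nM,
             stringsAsFactors = FALSE)
}

#' Convert a fluorescence trace to a thrombin curve
#'
#' The core inversion: H-transform the raw trace to undo inner-filter
#' saturation, differentiate with a Savitzky-Golay filter, and scale the
#' fluorescence rate by the calibrator factor,
#' `T[i] = Cf * d(F_tilde)/dt`. An optional baseline correction
#' subtracts the median derivative of the first `baseline_frames`
#' samples. It is off by default: on a drift-free trace it only injects
#' the (noisy) early derivative as a constant offset into every frame,
#' which the ETP integral then amplifies by the full run length. Enable
#' it (e.g. 3 frames) when real instrument drift is present; keep it
#' off for a calibrator trace pushed through its own calibration, whose
#' early derivative IS its signal.
#'
#' @param trace A sample [roi_trace()] (raw fluorescence).
#' @param cal A [calibration_model()].
#' @param window,order Savitzky-Golay parameters; the default (window
#'   9, order 3) trades peak attenuation against derivative noise - see
#'   the methods vignette for the measurements behind it.
#' @param baseline_frames Number of leading derivative samples whose
#'   median is subtracted as baseline drift (default 0 = disabled).
#' @param use_h_transform Logical; set `FALSE` to skip the inner-filter
#'   correction (exposed so its necessity can be demonstrated).
#' @return A [thrombogram()] with the signed thrombin estimate.
#' @export
thrombin_curve_from_trace <- function(trace, cal, window = 9, order = 3,
                                      baseline_frames = 0,
                                      use_h_transform = TRUE) {
  stopifnot(inherits(trace, "roi_trace"),
            inherits(cal, "calibration_model"))
  lin <- if (use_h_transform) {
    h_transform(trace, Finf = cal$Finf, F0 = cal$F0)
  } else {
    roi_trace(trace$chip_id, trace$t, trace$F - cal$F0, trace$roi)
  }
  dFdt <- smooth_derivative(lin, window = window, order = order)
  if (baseline_frames > 0) {
    nb <- min(baseline_frames, length(dFdt))
    dFdt <- dFdt - stats::median(dFdt[seq_len(nb)])
  }
  thrombogram(trace$chip_id, trace$t, cal$Cf * dFdt)
}

#' Scalar thrombogram parameters
#'
#' Extracts the standard descriptors from a thrombin curve. Peak, lag
#' and time-to-peak use a non-negative clipped copy of the (possibly
#' signed) estimate; the ETP integrates the signed curve, because
#' clipping would rectify zero-mean noise in the pre-lag and tail
#' phases into a systematic positive bias, whereas the signed trapezoid
#' is unbiased:
#' * `peak`: maximum clipped thrombin (nM); `t_peak` its earliest time;
#' * `lag`: earliest time at which clipped thrombin reaches
#'   `max(lag_floor, lag_frac * peak)` with the next sample also above
#'   the threshold (2-sample persistence); `NA` if never reached;
#' * `ETP`: trapezoidal integral of the signed thrombin curve over the
#'   full trace (nM*min);
#' * `velocity_index`: `peak / (t_peak - lag)` (nM/min), `NA` when
#'   `t_peak == lag` or lag is undefined.
#'
#' @param tg A [thrombogram()] with `>= 3` samples.
#' @param lag_frac Lag threshold as a fraction of peak (default 0.05).
#' @param lag_floor Absolute lag threshold floor (nM, default 1).
#' @return A one-row data frame with columns `chip_id, lag_min, peak_nM,
#'   t_peak_min, ETP_nM_min, velocity_index`.
#' @export
thrombogram_params <- function(tg, lag_frac = 0.05, lag_floor = 1) {
  stopifnot(inherits(tg, "thrombogram"))
  if (length(tg$t) < 3L)
    stop("thrombogram_params: need >= 3 samples", call. = FALSE)
  Tc <- pmax(tg$T_nM, 0)
  peak <- max(Tc)
  t_peak <- tg$t[which.max(Tc)]
  etp <- trapz(tg$t, tg$T_nM)
  lag <- NA_real_
  if (peak > 0) {
    thr <- max(lag_floor, lag_frac * peak)
    n <- length(Tc)
    hit <- which(Tc[-n] >= thr & Tc[-1] >= thr)
    if (length(hit)) lag <- tg$t[hit[1]]
  }
  vi <- if (!is.na(lag) && t_peak > lag) peak / (t_peak - lag)
        else NA_real_
  data.frame(chip_id = tg$chip_id, lag_min = lag, peak_nM = peak,
             t_peak_min = t_peak, ETP_nM_min = etp, velocity_index = vi,
             stringsAsFactors = FALSE)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)
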