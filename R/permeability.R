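#' Simulate a barrier-permeability trace pair
#'
#' Two-compartment model of tracer diffusion from a perfused vessel
#' (donor) into the adjacent gel (receiver): the receiver intensity
#' follows `C_r(t) = C_d * (1 - exp(-k t))` with
#' `k = Papp * A_int / V_r * 60` per minute, while the donor stays at
#' `donor0` (the vessel is continuously perfused). Default schedule:
#' 21 frames at 1-minute intervals.
#'
#' @param Papp_true True apparent permeability coefficient (cm/s,
#'   `>= 0`).
#' @param geometry List with `A_int` (interface area, cm^2) and `V_r`
#'   (receiver volume, cm^3), both `> 0`.
#' @param donor0 Donor intensity (RFU).
#' @param n_frames Number of frames (default 21).
#' @param dt Frame interval (min, default 1).
#' @param sigma Additive Gaussian noise SD (RFU) on both traces.
#' @param seed Optional integer noise seed.
#' @param chip_id Identifier stored in the traces.
#' @return A list with [roi_trace()] elements `donor` and `receiver`.
#' @export
simulate_permeability <- function(Papp_true, geometry = chip_geometry(),
                                  donor0 = 5000, n_frames = 21, dt = 1,
                                  sigma = 0, seed = NULL,
                                  chip_id = "perm") {
  stopifnot(is.numeric(Papp_true), length(Papp_true) == 1L,
            is.finite(Papp_true))
  if (Papp_true < 0)
    stop("simulate_permeability: Papp_true must be >= 0", call. = FALSE)
  check_geometry(geometry)
  t <- (seq_len(n_frames) - 1L) * dt
  k <- Papp_true * geometry$A_int / geometry$V_r * 60  # per minute
  recv <- donor0 * (1 - exp(-k * t))
  don <- rep(donor0, n_frames)
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    don <- don + stats::rnorm(n_frames, 0, sigma)
    recv <- recv + stats::rnorm(n_frames, 0, sigma)
  }
  list(donor = roi_trace(chip_id, t, don),
       receiver = roi_trace(chip_id, t, recv))
}

#' Default synthetic chip geometry
#'
#' Interface area and receiver (gel) volume used by the synthetic
#' permeability scenarios. These are synthetic-test values of a
#' plausible microfluidic magnitude, not the (unpublished) constants of
#' any commercial plate; override them with the real geometry when
#' physical units matter.
#'
#' @param A_int Vessel/gel interface area (cm^2).
#' @param V_r Receiver (gel) volume (cm^3).
#' @return A list with `A_int` and `V_r`.
#' @export
chip_geometry <- function(A_int = 0.005, V_r = 0.001) {
  g <- list(A_int = A_int, V_r = V_r)
  check_geometry(g)
  g
}

check_geometry <- function(geometry) {
  if (!is.list(geometry) || !all(c("A_int", "V_r") %in% names(geometry)))
    stop("geometry must be a list with A_int and V_r", call. = FALSE)
  if (!is.finite(geometry$A_int) || geometry$A_int <= 0)
    stop("geometry: A_int must be > 0", call. = FALSE)
  if (!is.finite(geometry$V_r) || geometry$V_r <= 0)
    stop("geometry: receiver volume V_r must be > 0", call. = FALSE)
  invisible(TRUE)
}

#' Apparent permeability coefficient from a donor/receiver trace pair
#'
#' Standard initial-slope two-compartment estimate: the receiver trace
#' is background-subtracted by its own first frame, its least-squares
#' slope over `fit_window` is converted to per-second units, and
#' `Papp = slope * V_r / (A_int * (donor0 - receiver0))` in cm/s, with
#' `donor0` and `receiver0` the first-frame intensities.
#'
#' @param donor,receiver [roi_trace()] pair on a shared time grid with
#'   `donor0 > receiver0`.
#' @param geometry List with `A_int` (cm^2) and `V_r` (cm^3).
#' @param fit_window Integer frame indices for the slope fit (default:
#'   all frames).
#' @return A one-row data frame of class `permeability_result` with
#'   `chip_id, Papp_cm_s, slope_RFU_min, donor0, A_int, V_r`.
#' @export
papp <- function(donor, receiver, geometry = chip_geometry(),
                 fit_window = NULL) {
  stopifnot(inherits(donor, "roi_trace"), inherits(receiver, "roi_trace"))
  if (length(donor$t) != length(receiver$t) ||
      any(abs(donor$t - receiver$t) > 1e-9))
    stop("papp: donor and receiver must share a time grid", call. = FALSE)
  check_geometry(geometry)
  donor0 <- donor$F[1]
  receiver0 <- receiver$F[1]
  if (donor0 <= receiver0)
    stop("papp: donor initial intensity must exceed receiver initial ",
         "intensity (got ", format(donor0), " vs ", format(receiver0), ")",
         call. = FALSE)
  if (is.null(fit_window)) fit_window <- seq_along(receiver$t)
  fit_window <- fit_window[fit_window >= 1 &
                             fit_window <= length(receiver$t)]
  if (length(fit_window) < 2L)
    stop("papp: fit window has fewer than 2 frames", call. = FALSE)
  tt <- receiver$t[fit_window]
  yy <- (receiver$F - receiver0)[fit_window]
  slope <- sum((tt - mean(tt)) * (yy - mean(yy))) /
    sum((tt - mean(tt))^2)                       # RFU/min
  Papp <- (slope / 60) * geometry$V_r /
    (geometry$A_int * (donor0 - receiver0))      # cm/s
  out <- data.frame(chip_id = receiver$chip_id, Papp_cm_s = Papp,
                    slope_RFU_min = slope, donor0 = donor0,
                    A_int = geometry$A_int, V_r = geometry$V_r,
                    stringsAsFactors = FALSE)
  class(out) <- c("permeability_result", "data.frame")
  out
}
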