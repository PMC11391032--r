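#' Render a fluorescence trace as a time-lapse image stack
#'
#' Emulates the acquisition the ROI quantification consumes: each frame
#' holds a constant background outside a rectangular channel region and
#' the trace intensity inside it, plus optional per-pixel Gaussian
#' noise. With zero noise, the in-rectangle mean of every frame equals
#' the trace value exactly, so [roi_mean_trace()] is an exact inverse.
#'
#' @param trace A [roi_trace()].
#' @param roi An [roi_spec()] (the channel rectangle), within the frame.
#' @param frame_dim Frame size `c(ny, nx)` in pixels.
#' @param background Background intensity outside the rectangle
#'   (default 100 counts).
#' @param noise_sd Per-pixel Gaussian noise SD (default 0).
#' @param seed Optional integer seed for the noise draw.
#' @return A 3D array `[y, x, frame]`.
#' @export
render_image_stack <- function(trace, roi, frame_dim = c(128, 256),
                               background = 100, noise_sd = 0,
                               seed = NULL) {
  stopifnot(inherits(trace, "roi_trace"), inherits(roi, "roi_spec"))
  check_roi_in_frame(roi, frame_dim)
  n <- length(trace$t)
  stack <- array(background, dim = c(frame_dim, n))
  rows <- roi_rows(roi); cols <- roi_cols(roi)
  for (i in seq_len(n)) stack[rows, cols, i] <- trace$F[i]
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    stack <- stack + array(stats::rnorm(length(stack), 0, noise_sd),
                           dim = dim(stack))
  }
  stack
}

#' Render a synthetic immunofluorescence field
#'
#' Generates a nuclei / marker / spot channel triplet with exact known
#' ground truth for testing the cell-level quantifications: nuclei are
#' Gaussian blobs at non-overlapping random centers, marker disks
#' surround the designated positive cells, and the spot channel holds
#' the requested number of punctae per cell.
#'
#' @param n_cells Number of cells (`>= 0`).
#' @param positive_ids Integer indices (subset of `1:n_cells`) of
#'   marker-positive cells.
#' @param spot_counts Integer vector of punctae per cell (length
#'   `n_cells`), or a single value recycled.
#' @param frame_dim Frame size `c(ny, nx)` in pixels.
#' @param seed Integer seed for cell placement.
#' @param min_sep Minimum center-to-center distance (px).
#' @param background Background level (counts, default 100).
#' @return A list with matrices `nuclei`, `marker`, `spots`, and the
#'   ground-truth `centers` data frame.
#' @export
render_cell_image <- function(n_cells, positive_ids = integer(),
                              spot_counts = 0,
                              frame_dim = c(160, 160), seed = 1,
                              min_sep = 18, background = 100) {
  stopifnot(n_cells >= 0, all(positive_ids %in% seq_len(n_cells)))
  spot_counts <- rep_len(as.integer(spot_counts), max(n_cells, 1L))
  if (n_cells > 0 && any(spot_counts < 0))
    stop("render_cell_image: spot counts must be >= 0", call. = FALSE)
  ny <- frame_dim[1]; nx <- frame_dim[2]
  nuclei <- matrix(background, ny, nx)
  marker <- matrix(background, ny, nx)
  spots <- matrix(background, ny, nx)
  centers <- data.frame(cell = integer(), y = numeric(), x = numeric())
  if (n_cells == 0L)
    return(list(nuclei = nuclei, marker = marker, spots = spots,
                centers = centers))
  set.seed(seed)
  margin <- ceiling(min_sep / 2) + 4
  pts <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(pts) < n_cells) {
    cand <- c(stats::runif(1, margin, ny - margin),
              stats::runif(1, margin, nx - margin))
    ok <- nrow(pts) == 0 ||
      all((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2 >= min_sep^2)
    if (ok) pts <- rbind(pts, cand)
    tries <- tries + 1L
    if (tries > 5000L * n_cells)
      stop("render_cell_image: cannot place ", n_cells,
           " cells without overlap at this density", call. = FALSE)
  }
  centers <- data.frame(cell = seq_len(n_cells), y = round(pts[, 1]),
                        x = round(pts[, 2]))
  yg <- matrix(seq_len(ny), ny, nx)
  xg <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  gauss_blob <- function(img, cy, cx, amp, sigma) {
    img + amp * exp(-((yg - cy)^2 + (xg - cx)^2) / (2 * sigma^2))
  }
  for (i in seq_len(n_cells)) {
    nuclei <- gauss_blob(nuclei, centers$y[i], centers$x[i],
                         amp = 2000, sigma = 3)
    if (i %in% positive_ids) {
      disk <- (yg - centers$y[i])^2 + (xg - centers$x[i])^2 <= 5^2
      marker[disk] <- marker[disk] + 1500
    }
    k <- spot_counts[i]
    if (k > 0) {
      ang <- 2 * pi * (seq_len(k) - 1) / max(k, 1) +
        stats::runif(1, 0, 2 * pi)
      r <- min_sep / 2 - 2
      sy <- centers$y[i] + r * sin(ang)
      sx <- centers$x[i] + r * cos(ang)
      for (j in seq_len(k))
        spots <- gauss_blob(spots, sy[j], sx[j], amp = 3000, sigma = 1.3)
    }
  }
  clip <- function(m) pmin(pmax(m, 0), 65535)
  list(nuclei = clip(nuclei), marker = clip(marker),
       spots = clip(spots), centers = centers)
}
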