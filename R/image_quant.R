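#' Rectangular region of interest
#'
#' Pixel bounds of a rectangular ROI, 0-based and half-open:
#' `[x0, x1) x [y0, y1)` with x along image columns and y along rows.
#'
#' @param x0,y0 Inclusive lower bounds (0-based pixel indices, `>= 0`).
#' @param x1,y1 Exclusive upper bounds (`x1 > x0`, `y1 > y0`).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(x0, y0, x1, y1) {
  v <- c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  if (!all(is.finite(v)) || any(v < 0) || any(v != round(v)))
    stop("roi_spec: bounds must be non-negative integers", call. = FALSE)
  if (x1 <= x0 || y1 <= y0)
    stop("roi_spec: need x1 > x0 and y1 > y0", call. = FALSE)
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1)),
            class = "roi_spec")
}

#' Per-chip fluorescence time series
#'
#' The universal currency between the imaging and numerical stages: mean
#' ROI fluorescence (RFU) at strictly increasing timestamps (minutes).
#'
#' @param chip_id Chip identifier.
#' @param t Numeric vector of timestamps (min), strictly increasing.
#' @param F Numeric vector of mean intensities (RFU), finite, same
#'   length as `t`.
#' @param roi Optional [roi_spec()] the trace was extracted from, or
#'   `NULL` for whole-trace imports.
#' @return An object of class `roi_trace`.
#' @export
roi_trace <- function(chip_id, t, F, roi = NULL) {
  if (length(t) != length(F))
    stop("roi_trace: t and F must have equal length", call. = FALSE)
  if (!is.numeric(t) || !is.numeric(F) || !all(is.finite(t)) ||
      !all(is.finite(F)))
    stop("roi_trace: t and F must be finite numeric vectors", call. = FALSE)
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("roi_trace: t must be strictly increasing", call. = FALSE)
  if (!is.null(roi)) stopifnot(inherits(roi, "roi_spec"))
  structure(list(chip_id = as.character(chip_id), t = as.numeric(t),
                 F = as.numeric(F), roi = roi),
            class = "roi_trace")
}

#' @export
print.roi_trace <- function(x, ...) {
  cat(sprintf("<roi_trace> chip '%s': %d frames, t %.4g..%.4g min, F %.5g..%.5g RFU\n",
              x$chip_id, length(x$t), min(x$t), max(x$t), min(x$F), max(x$F)))
  invisible(x)
}

#' @export
as.data.frame.roi_trace <- function(x, ...) {
  data.frame(chip_id = x$chip_id, t_min = x$t, F = x$F,
             stringsAsFactors = FALSE)
}

roi_rows <- function(roi) (roi$y0 + 1L):roi$y1
roi_cols <- function(roi) (roi$x0 + 1L):roi$x1

check_roi_in_frame <- function(roi, dim_yx) {
  if (roi$y1 > dim_yx[1] || roi$x1 > dim_yx[2])
    stop("ROI [", roi$x0, ",", roi$x1, ")x[", roi$y0, ",", roi$y1,
         ") exceeds the ", dim_yx[2], "x", dim_yx[1], " frame",
         call. = FALSE)
  invisible(TRUE)
}

#' Mean-intensity time trace of an ROI over an image stack
#'
#' For each frame of a time-lapse stack, the arithmetic mean of the
#' pixels inside the ROI; timestamps follow a uniform frame schedule.
#'
#' @param stack 3D numeric array `[y, x, frame]` (see
#'   [read_image_stack()]), or a list of equally-sized matrices.
#' @param roi An [roi_spec()] within the frame bounds.
#' @param dt Frame interval (min).
#' @param t_start Time of the first frame (min).
#' @param chip_id Identifier stored in the trace.
#' @param blank_offset Optional constant background (RFU) subtracted
#'   from every frame mean, e.g. measured on a blank ROI. Default 0.
#' @return A [roi_trace()].
#' @export
roi_mean_trace <- function(stack, roi, dt = 1, t_start = 0,
                           chip_id = "roi", blank_offset = 0) {
  stack <- as_stack(stack)
  if (dim(stack)[3] < 1L) stop("roi_mean_trace: empty stack", call. = FALSE)
  check_roi_in_frame(roi, dim(stack)[1:2])
  sub <- stack[roi_rows(roi), roi_cols(roi), , drop = FALSE]
  F <- apply(sub, 3, mean) - blank_offset
  roi_trace(chip_id = chip_id,
            t = t_start + (seq_len(dim(stack)[3]) - 1L) * dt,
            F = F, roi = roi)
}

as_stack <- function(stack) {
  if (is.list(stack)) {
    d <- dim(stack[[1]])
    stack <- array(unlist(stack, use.names = FALSE),
                   dim = c(d, length(stack)))
  }
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  if (!is.array(stack) || length(dim(stack)) != 3L)
    stop("expected a [y, x, frame] array or list of matrices", call. = FALSE)
  stack
}

#' Maximum-intensity projection of a z-stack
#'
#' Per-pixel maximum across the z dimension, as used to flatten confocal
#' z-series before 2D quantification.
#'
#' @param zstack 3D numeric array `[y, x, z]` or list of matrices;
#'   `>= 1` slice.
#' @return A 2D matrix.
#' @export
max_projection <- function(zstack) {
  zstack <- as_stack(zstack)
  if (dim(zstack)[3] < 1L) stop("max_projection: empty stack", call. = FALSE)
  apply(zstack, c(1, 2), max)
}

# Local maxima of a 2D response above `threshold`, with plateau
# tolerance and minimum center separation (greedy, strongest first).
find_local_maxima <- function(img, threshold, min_sep = 8) {
  ny <- nrow(img); nx <- ncol(img)
  pad <- matrix(-Inf, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- img
  ctr <- pad[2:(ny + 1L), 2:(nx + 1L)]
  is_max <- ctr >= threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2:(ny + 1L)) + dy, (2:(nx + 1L)) + dx]
    is_max <- is_max & (ctr >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(y = integer(), x = integer(), value = numeric()))
  vals <- img[idx]
  ord <- order(vals, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]; vals <- vals[ord]
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    kept <- idx[keep, , drop = FALSE]
    d2 <- (kept[, 1] - idx[i, 1])^2 + (kept[, 2] - idx[i, 2])^2
    if (all(d2 >= min_sep^2)) keep[i] <- TRUE
  }
  data.frame(y = idx[keep, 1], x = idx[keep, 2], value = vals[keep])
}

#' Detect nuclei and score marker-positive cells
#'
#' Generic reconstruction of a positive-cell count: nuclei are detected
#' as local maxima of a Gaussian-smoothed nuclei image above an Otsu
#' threshold with a minimum separation, and a cell is scored positive
#' when the mean marker intensity in a fixed-radius disk around its
#' center exceeds `marker_threshold`. With no detected cells the
#' fraction is undefined and reported as `NA` (not 0).
#'
#' @param nuclei 2D numeric matrix, nuclear stain.
#' @param marker 2D numeric matrix, same shape, marker channel.
#' @param marker_threshold Positivity threshold on the disk-mean marker
#'   intensity (RFU).
#' @param sigma Gaussian smoothing SD for nucleus detection (px).
#' @param min_sep Minimum separation between nucleus centers (px).
#' @param disk_radius Radius of the marker-scoring disk (px).
#' @return A list with `n_cells`, `n_positive`, `fraction` (NA when
#'   `n_cells == 0`), and the detected `centers` data frame.
#' @export
positive_cell_fraction <- function(nuclei, marker, marker_threshold,
                                   sigma = 2, min_sep = 8,
                                   disk_radius = 6) {
  stopifnot(is.matrix(nuclei), is.matrix(marker))
  if (!all(dim(nuclei) == dim(marker)))
    stop("positive_cell_fraction: images must share a shape", call. = FALSE)
  centers <- detect_nuclei(nuclei, sigma = sigma, min_sep = min_sep)
  n_cells <- nrow(centers)
  if (n_cells == 0L)
    return(list(n_cells = 0L, n_positive = 0L, fraction = NA_real_,
                centers = centers))
  pos <- vapply(seq_len(n_cells), function(i) {
    disk_mean(marker, centers$y[i], centers$x[i], disk_radius)
  }, numeric(1)) > marker_threshold
  list(n_cells = n_cells, n_positive = sum(pos),
       fraction = sum(pos) / n_cells, centers = centers)
}

detect_nuclei <- function(nuclei, sigma = 2, min_sep = 8) {
  rng <- range(nuclei)
  if (diff(rng) == 0)
    return(data.frame(y = integer(), x = integer(), value = numeric()))
  sm <- EBImage::gblur(nuclei, sigma = sigma)
  norm <- (sm - min(sm)) / diff(range(sm))
  thr <- EBImage::otsu(norm, range = c(0, 1))
  find_local_maxima(norm, threshold = thr, min_sep = min_sep)
}

disk_mean <- function(img, y, x, radius) {
  ys <- max(1, y - radius):min(nrow(img), y + radius)
  xs <- max(1, x - radius):min(ncol(img), x + radius)
  grid <- expand.grid(y = ys, x = xs)
  keep <- (grid$y - y)^2 + (grid$x - x)^2 <= radius^2
  mean(img[cbind(grid$y[keep], grid$x[keep])])
}

#' Mean number of punctate spots per cell
#'
#' Generic reconstruction of a granule-per-cell count (e.g.
#' Weibel-Palade bodies): punctae are detected as local maxima of a
#' difference-of-Gaussians band-pass response above a threshold set as a
#' fraction of the maximum response, and divided by the supplied cell
#' count.
#'
#' @param spot_img 2D numeric matrix, spot channel.
#' @param n_cells Number of cells in the field (`> 0`).
#' @param sigma_low,sigma_high DoG band-pass SDs (px).
#' @param threshold_frac Detection threshold as a fraction of the peak
#'   DoG response (default 0.2).
#' @param min_sep Minimum separation between detected spots (px).
#' @return A list with `n_spots`, `spots_per_cell`, and spot `centers`.
#' @export
spots_per_cell <- function(spot_img, n_cells, sigma_low = 1.5,
                           sigma_high = 3, threshold_frac = 0.2,
                           min_sep = 3) {
  stopifnot(is.matrix(spot_img))
  if (!is.numeric(n_cells) || n_cells <= 0)
    stop("spots_per_cell: n_cells must be > 0", call. = FALSE)
  dog <- EBImage::gblur(spot_img, sigma = sigma_low) -
    EBImage::gblur(spot_img, sigma = sigma_high)
  mx <- max(dog)
  if (mx <= 0)
    return(list(n_spots = 0L, spots_per_cell = 0,
                centers = data.frame(y = integer(), x = integer(),
                                     value = numeric())))
  centers <- find_local_maxima(dog, threshold = threshold_frac * mx,
                               min_sep = min_sep)
  list(n_spots = nrow(centers), spots_per_cell = nrow(centers) / n_cells,
       centers = centers)
}

#' Read a multi-page grayscale TIFF as an intensity stack
#'
#' @param path TIFF file path.
#' @param scale Count scale: pixel values in `[0, 1]` from the TIFF
#'   reader are multiplied by `scale` to recover intensity counts.
#'   Default 65535 (16-bit convention).
#' @return A 3D array `[y, x, frame]` of intensities.
#' @export
read_image_stack <- function(path, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  as_stack(lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p * scale
  }))
}

#' Write an intensity stack as a multi-page grayscale TIFF
#'
#' @param stack 3D array `[y, x, frame]` of intensity counts.
#' @param path Output file path.
#' @param bits Bits per sample: 32 (float, lossless round trip, the
#'   default) or 16 (integer counts).
#' @param scale Count scale; intensities are divided by `scale` before
#'   writing. Default 65535.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, bits = 32, scale = 65535) {
  stack <- as_stack(stack)
  if (any(stack < 0) || any(stack > scale))
    stop("write_image_stack: intensities must lie in [0, scale]",
         call. = FALSE)
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(i) stack[, , i] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Write traces to a tidy CSV
#'
#' One row per chip per frame: `chip_id, t_min, F`.
#'
#' @param traces A list of [roi_trace()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read traces from a tidy CSV
#'
#' @param path CSV with columns `chip_id, t_min, F`.
#' @return A named list of [roi_trace()] objects.
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chip_id", "t_min", "F")
  if (!all(need %in% names(df)))
    stop("traces CSV must have columns chip_id, t_min, F", call. = FALSE)
  out <- lapply(split(df, df$chip_id), function(d) {
    d <- d[order(d$t_min), ]
    roi_trace(d$chip_id[1], d$t_min, d$F)
  })
  out[unique(df$chip_id)]
}
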