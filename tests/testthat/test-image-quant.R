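test_that("roi_mean_trace averages the ROI and builds the time axis", {
  stack <- array(0, dim = c(40, 60, 61))
  roi <- roi_spec(10, 5, 30, 25)
  stack[6:25, 11:30, ] <- 500
  tr <- roi_mean_trace(stack, roi, dt = 1, t_start = 0)
  expect_equal(tr$F, rep(500, 61))
  expect_equal(tr$t, 0:60)   # one frame per minute for one hour
})

test_that("roi_mean_trace validates bounds and rejects empty stacks", {
  stack <- array(1, dim = c(20, 20, 3))
  expect_error(roi_mean_trace(stack, roi_spec(0, 0, 25, 10)), "exceeds")
  expect_error(roi_mean_trace(array(1, dim = c(20, 20, 0)),
                              roi_spec(0, 0, 5, 5)), "empty")
})

test_that("render_image_stack -> roi_mean_trace is an exact round trip", {
  kin <- kinetics_spec(sigma = 0)
  tr <- simulate_fluorescence(default_curve(80.78), kin)
  roi <- roi_spec(20, 20, 120, 60)
  stack <- render_image_stack(tr, roi, frame_dim = c(80, 160))
  back <- roi_mean_trace(stack, roi, dt = kin$dt)
  expect_equal(back$F, tr$F)
  # constant trace example
  const <- roi_trace("c", 0:4, rep(100, 5))
  st2 <- render_image_stack(const, roi, frame_dim = c(80, 160))
  expect_equal(roi_mean_trace(st2, roi)$F, rep(100, 5))
})

test_that("roi_mean_trace is linear in the stack", {
  set.seed(7)
  stack <- array(runif(30 * 30 * 5, 0, 100), dim = c(30, 30, 5))
  roi <- roi_spec(3, 4, 20, 25)
  base <- roi_mean_trace(stack, roi)
  scaled <- roi_mean_trace(2.5 * stack + 7, roi)
  expect_equal(scaled$F, 2.5 * base$F + 7)
})

test_that("pixel noise averages down as 1/sqrt(n_pixels)", {
  const <- roi_trace("n", 0:20, rep(1000, 21))
  roi <- roi_spec(0, 0, 200, 50)   # 10000 pixels
  stack <- render_image_stack(const, roi, frame_dim = c(60, 220),
                              noise_sd = 1, seed = 11)
  back <- roi_mean_trace(stack, roi)
  rmse <- sqrt(mean((back$F - 1000)^2))
  expect_lt(rmse, 0.1)  # SE = 1/sqrt(10000) = 0.01, generous margin
})

test_that("max projection is the per-pixel maximum", {
  one <- matrix(1:12, 3, 4)
  expect_equal(max_projection(list(one)), one)
  a <- matrix(0, 5, 5); a[2, 2] <- 10
  b <- matrix(0, 5, 5); b[4, 4] <- 7
  proj <- max_projection(list(a, b))
  expect_equal(proj[2, 2], 10)
  expect_equal(proj[4, 4], 7)
  expect_equal(sum(proj > 0), 2)
  expect_equal(max_projection(array(0, c(4, 4, 3))), matrix(0, 4, 4))
  expect_error(max_projection(array(0, c(4, 4, 0))), "empty")
})

test_that("positive-cell fraction recovers the rendered ground truth", {
  img <- render_cell_image(10, positive_ids = c(1, 4, 6, 9), seed = 3)
  res <- positive_cell_fraction(img$nuclei, img$marker,
                                marker_threshold = 400)
  expect_equal(res$n_cells, 10L)
  expect_equal(res$n_positive, 4L)
  expect_equal(res$fraction, 0.4)
  # all-zero marker: nothing is positive
  res0 <- positive_cell_fraction(img$nuclei,
                                 matrix(0, nrow(img$nuclei),
                                        ncol(img$nuclei)),
                                 marker_threshold = 400)
  expect_equal(res0$fraction, 0)
  # saturated marker: everything is positive
  img2 <- render_cell_image(25, positive_ids = 1:25, seed = 5,
                            frame_dim = c(240, 240))
  res1 <- positive_cell_fraction(img2$nuclei, img2$marker,
                                 marker_threshold = 400)
  expect_equal(res1$fraction, 1)
})

test_that("zero cells reports an undefined fraction, not zero", {
  img <- render_cell_image(0)
  res <- positive_cell_fraction(img$nuclei, img$marker,
                                marker_threshold = 400)
  expect_equal(res$n_cells, 0L)
  expect_true(is.na(res$fraction))
  expect_error(spots_per_cell(img$spots, 0), "n_cells")
})

test_that("spot counting recovers rendered punctae exactly", {
  img <- render_cell_image(5, spot_counts = c(0, 1, 2, 3, 4), seed = 9,
                           frame_dim = c(200, 200), min_sep = 30)
  res <- spots_per_cell(img$spots, n_cells = 5)
  expect_equal(res$n_spots, 10L)
  expect_equal(res$spots_per_cell, 2)
  # no spots at all
  none <- render_cell_image(5, spot_counts = 0, seed = 9,
                            frame_dim = c(200, 200), min_sep = 30)
  expect_equal(spots_per_cell(none$spots, 5)$spots_per_cell, 0)
  # three isolated spots in one cell
  three <- render_cell_image(1, spot_counts = 3, seed = 2,
                             frame_dim = c(120, 120), min_sep = 30)
  expect_equal(spots_per_cell(three$spots, 1)$n_spots, 3L)
})

test_that("detection is invariant to global intensity scaling", {
  img <- render_cell_image(8, positive_ids = c(2, 5), seed = 13)
  a <- positive_cell_fraction(img$nuclei, img$marker, 400)
  b <- positive_cell_fraction(3 * img$nuclei, 3 * img$marker, 3 * 400)
  expect_equal(a$n_cells, b$n_cells)
  expect_equal(a$fraction, b$fraction)
  s1 <- spots_per_cell(img$spots, 8)
  s2 <- spots_per_cell(10 * img$spots, 8)  # threshold is relative
  expect_equal(s1$n_spots, s2$n_spots)
})

test_that("image stacks survive a 32-bit TIFF disk round trip", {
  kin <- kinetics_spec(sigma = 0, n_frames = 5)
  tr <- simulate_fluorescence(default_curve(50), kin)
  roi <- roi_spec(2, 2, 30, 12)
  stack <- render_image_stack(tr, roi, frame_dim = c(16, 32))
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(stack, path)
  back <- read_image_stack(path)
  expect_equal(dim(back), dim(stack))
  expect_equal(back, stack, tolerance = 1e-6)
  tr2 <- roi_mean_trace(back, roi)
  expect_equal(tr2$F, tr$F, tolerance = 1e-5)
})

test_that("traces survive a CSV round trip", {
  kin <- kinetics_spec(sigma = 2, n_frames = 10)
  trs <- list(a = simulate_fluorescence(default_curve(30), kin, seed = 1,
                                        chip_id = "a"),
              b = simulate_calibrator(100, kin, seed = 2, chip_id = "b"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_traces_csv(trs, path)
  back <- read_traces_csv(path)
  expect_equal(names(back), c("a", "b"))
  expect_equal(back$a$F, trs$a$F)
  expect_equal(back$b$t, trs$b$t)
})
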