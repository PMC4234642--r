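test_that("a 15-fiber image yields at least 13 traces, one per truth fiber", {
  lay <- fiber_layout(15, fetal_control(), orientation_deg = 45,
                      image_px = 640)
  sim <- simulate_fiber_image(lay, image_px = 640, noise = 1, seed = 3)
  field <- estimate_orientation(sim$image)
  traces <- trace_fibers(sim$image, field)
  expect_gte(length(traces), 13)
  expect_lte(length(traces), 15)
  m <- match_traces(traces, sim$truth)
  expect_equal(length(unique(m$fiber_id)), length(traces))  # no duplicates
})

test_that("recovered centerlines track the truth within 2 px RMS (noise-free)", {
  lay <- fiber_layout(5, fetal_control(), orientation_deg = 45,
                      image_px = 448)
  sim <- simulate_fiber_image(lay, image_px = 448, noise = 0, seed = 4)
  field <- estimate_orientation(sim$image)
  traces <- trace_fibers(sim$image, field)
  expect_equal(length(traces), 5L)
  m <- match_traces(traces, sim$truth)
  expect_lt(max(m$mean_dist_px), 2)
  for (i in seq_len(nrow(m))) {
    f <- sim$truth[sim$truth$fiber_id == m$fiber_id[i], ]
    p <- traces[[m$trace_id[i]]]$points
    ex <- f$x1 - f$x0; ey <- f$y1 - f$y0
    len <- sqrt(ex^2 + ey^2)
    dperp <- (-(p[, 1] - f$x0) * ey + (p[, 2] - f$y0) * ex) / len
    expect_lt(sqrt(mean(dperp^2)), 2)
  }
})

test_that("tracing is deterministic and a blank image yields no traces", {
  sim <- quick_image(2, image_px = 384, seed = 6)
  field <- estimate_orientation(sim$image)
  t1 <- trace_fibers(sim$image, field)
  t2 <- trace_fibers(sim$image, field)
  expect_identical(lapply(t1, `[[`, "points"), lapply(t2, `[[`, "points"))

  blank <- shgm_image(matrix(5, 128, 128) * 1.0, 40, "blank")
  expect_length(trace_fibers(blank, estimate_orientation(blank)), 0)
})

test_that("profile extraction on an integer-row fiber is an identity", {
  lay <- fiber_layout(1, fetal_control(), orientation_deg = 0,
                      image_px = 641)
  sim <- simulate_fiber_image(lay, image_px = 641, noise = 0, seed = 7)
  f <- sim$truth
  trace <- cbind(x = seq(ceiling(f$x0), floor(f$x1)), y = f$y0)
  prof <- extract_profile(sim$image, trace, halfwidth_px = 0)
  row_vals <- sim$image$intensity[f$y0 + 1, trace[, 1] + 1]
  expect_equal(prof$samples, unname(row_vals), tolerance = 1e-12)
})

test_that("profile length bookkeeping matches the trace arc length", {
  sim <- quick_image(1, image_px = 448, seed = 8)
  field <- estimate_orientation(sim$image)
  tr <- trace_fibers(sim$image, field)[[1]]
  prof <- extract_profile(sim$image, tr)
  arc_um <- tr$length_um
  prof_um <- (prof$n - 1) * prof$spacing_nm / 1000
  expect_lt(abs(prof_um - arc_um), 1.5 * prof$spacing_nm / 1000)
})

test_that("profile period from an independent FFT oracle matches truth SL", {
  sim <- quick_image(1, image_px = 640, noise = 0, seed = 9)
  field <- estimate_orientation(sim$image)
  tr <- trace_fibers(sim$image, field)[[1]]
  prof <- extract_profile(sim$image, tr)
  period <- fft_period_um(prof$samples, prof$spacing_nm / 1000)
  expect_lt(abs(period - sim$truth$sl_um), 0.041)
})

test_that("degenerate traces are rejected with clear errors", {
  sim <- quick_image(1, image_px = 448, seed = 10)
  expect_error(extract_profile(sim$image, cbind(x = c(0, 500), y = c(0, 500))),
               "outside")
  expect_error(extract_profile(sim$image, cbind(x = c(10, 14), y = c(10, 10))),
               "too short")
})
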