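test_that("fit recovers exact model parameters to better than 1 nm", {
  p <- fetal_control()
  fit <- fit_sarcomere_model(synthetic_acf(p))
  expect_true(fit$converged)
  expect_lt(abs(fit$sl_um - p$sl_um), 1e-3)
  expect_lt(abs(fit$abl_um - p$abl_um), 1e-3)
  expect_lt(abs(fit$ttil_um - p$ttil_um), 1e-3)
  expect_equal(fit$ratio, fit$sl_um / fit$abl_um)
})

test_that("full pipeline recovers SL within 20 nm at default noise", {
  sim <- quick_image(1, image_px = 448, noise = 1, seed = 15)
  fits <- measure_image(sim$image)
  expect_equal(nrow(fits), 1L)
  expect_true(fits$converged[1])
  expect_lt(abs(fits$sl_um[1] - sim$truth$sl_um), 0.020)
  expect_lt(abs(fits$abl_um[1] - sim$truth$abl_um), 0.020)
  expect_lt(abs(fits$ttil_um[1] - sim$truth$ttil_um), 0.010)
})

test_that("the fit is invariant to profile shift and scale", {
  sim <- quick_image(1, image_px = 448, noise = 1, seed = 16)
  field <- estimate_orientation(sim$image)
  tr <- trace_fibers(sim$image, field)[[1]]
  prof <- extract_profile(sim$image, tr)
  f0 <- fit_sarcomere_model(compute_acf(prof))
  prof2 <- prof
  prof2$samples <- 3.1 * prof$samples + 40
  f1 <- fit_sarcomere_model(compute_acf(prof2))
  expect_equal(f0$sl_um, f1$sl_um, tolerance = 1e-9)
  expect_equal(f0$abl_um, f1$abl_um, tolerance = 1e-9)
  expect_equal(f0$ttil_um, f1$ttil_um, tolerance = 1e-9)
})

test_that("optimizer is at least as good as a coarse grid search", {
  set.seed(17)
  cfg <- sarcomorph_config()
  for (k in 1:5) {
    sl <- runif(1, 1.3, 2.1)
    abl <- sl / runif(1, 2.0, 2.2)
    ttil <- runif(1, 0.08, 0.13)
    acf <- synthetic_acf(c(sl, abl, ttil), noise_sd = 0.005, seed = 100 + k)
    fit <- fit_sarcomere_model(acf, config = cfg)
    expect_true(fit$converged)

    mask <- acf$lags_um >= cfg$fit_lag_min_um
    lags <- acf$lags_um[mask]; vals <- acf$values[mask]
    taper <- 1 - (lags / acf$spacing_um) / acf$n_samples
    cost <- function(sl, abl, ttil, amp, off) {
      sum((amp * taper * model_acf(c(sl, abl, ttil), lags) + off - vals)^2)
    }
    fit_cost <- cost(fit$sl_um, fit$abl_um, fit$ttil_um, fit$amp, fit$offset)
    grid <- expand.grid(
      sl = fit$sl_um + seq(-0.05, 0.05, by = 0.01),
      abl = fit$abl_um + seq(-0.05, 0.05, by = 0.01),
      ttil = fit$ttil_um + seq(-0.02, 0.02, by = 0.005)
    )
    grid <- grid[grid$ttil > 0 & grid$ttil < grid$abl & grid$abl < grid$sl, ]
    grid_cost <- mapply(function(s, a, t) cost(s, a, t, fit$amp, fit$offset),
                        grid$sl, grid$abl, grid$ttil)
    expect_lte(fit_cost, min(grid_cost) + 1e-12)
  }
})

test_that("a peakless ACF yields a flagged non-converged fit", {
  lags <- seq(0, 6, by = 0.04)
  vals <- exp(-lags / 2)  # monotone decay, no off-zero peak
  acf <- structure(list(lags_um = lags, values = vals, spacing_um = 0.04,
                        n_samples = 1000),
                   class = "sarc_acf")
  fit <- fit_sarcomere_model(acf)
  expect_false(fit$converged)
  expect_equal(fit$reason, "no_off_zero_peak")
})

test_that("QC excludes strictly above the ratio threshold", {
  fits <- tibble::tibble(
    fiber_id = 1:5,
    ratio = c(2.10, 2.20, 2.26, 2.25, 2.30),
    converged = TRUE
  )
  qc <- apply_qc(fits, max_ratio = 2.25)
  expect_equal(qc$kept$fiber_id, c(1L, 2L, 4L))       # 2.25 exactly: kept
  expect_equal(qc$excluded$fiber_id, c(3L, 5L))       # 2.26 and 2.30: out
  expect_true(all(qc$excluded$qc_reason == "ratio_above_threshold"))

  toy <- tibble::tibble(ratio = c(2.10, 2.20, 2.26), converged = TRUE)
  qc2 <- apply_qc(toy)
  expect_equal(nrow(qc2$kept), 2L)
  expect_equal(nrow(qc2$excluded), 1L)

  nc <- tibble::tibble(ratio = c(2.0, NA), converged = c(TRUE, FALSE))
  qc3 <- apply_qc(nc)
  expect_equal(qc3$excluded$qc_reason, "not_converged")
  expect_error(apply_qc(toy, max_ratio = 0.9))
})

test_that("SL estimate variance does not decrease with noise level", {
  sl_at <- function(noise, seeds) {
    vapply(seeds, function(s) {
      sim <- quick_image(1, orientation_deg = 0, image_px = 448,
                         noise = noise, seed = s)
      measure_image(sim$image)$sl_um[1]
    }, 0)
  }
  lo <- sl_at(0.8, 1:6)
  hi <- sl_at(2.5, 1:6)
  expect_true(all(is.finite(c(lo, hi))))
  expect_gte(sd(hi), sd(lo))
})
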