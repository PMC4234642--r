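test_that("parameter invariants are enforced", {
  p <- sarcomere_params(1.658, 0.772, 0.104)
  expect_equal(p$ratio, 1.658 / 0.772)
  expect_error(sarcomere_params(-1, 0.7, 0.1), "sl_um")
  expect_error(sarcomere_params(1.6, 1.7, 0.1), "abl_um")
  expect_error(sarcomere_params(1.6, 0.7, 0.8), "ttil_um")
  # peaks wider than half the inter-peak gap: pattern degenerate
  expect_error(axial_profile(0, 1.6, 0.8, 0.41, 5), "degenerate")
})

test_that("noise-free render matches the analytic axial profile on the centerline", {
  # horizontal fiber on an integer pixel row: the image row must equal
  # background + contrast * analytic pattern at the pixel abscissae
  lay <- fiber_layout(1, fetal_control(), orientation_deg = 0,
                      image_px = 641)
  expect_equal(lay$y0, 320)
  sim <- simulate_fiber_image(lay, image_px = 641, noise = 0, seed = 2)
  f <- sim$truth
  row <- sim$image$intensity[f$y0 + 1, ]
  xs <- 0:640
  u_um <- (xs - f$x0) * 40 / 1000
  inside <- u_um > 0 & u_um < (f$x1 - f$x0) * 0.04
  expected <- f$background + f$contrast *
    axial_profile(u_um, f$sl_um, f$abl_um, f$ttil_um, f$n_sarcomeres,
                  start_um = f$phase_um)
  expect_lt(max(abs(row[inside] - expected[inside])), 1e-3 * f$contrast)
})

test_that("centerline profile shows two peaks per sarcomere", {
  sim <- quick_image(1, orientation_deg = 45, image_px = 640, noise = 0)
  n_sarc <- sim$truth$n_sarcomeres
  prof <- extract_profile(sim$image, truth_centerline(sim$truth),
                          halfwidth_px = 0)
  peaks <- local_maxima(prof$samples)
  peaks <- peaks[prof$samples[peaks] >
                   sim$truth$background + 0.3 * sim$truth$contrast]
  expect_equal(length(peaks), 2L * n_sarc)
})

test_that("first major off-zero ACF peak of the rendered pattern sits at SL", {
  sim <- quick_image(1, orientation_deg = 45, image_px = 640, noise = 0)
  prof <- extract_profile(sim$image, truth_centerline(sim$truth))
  a <- compute_acf(prof)
  expect_equal(find_acf_peak(a), sim$truth$sl_um, tolerance = 0.041 / 1.658)
})

test_that("renders are bit-reproducible given the seed", {
  lay <- fiber_layout(2, fetal_control(), image_px = 384)
  s1 <- simulate_fiber_image(lay, image_px = 384, noise = 1, seed = 42)
  s2 <- simulate_fiber_image(lay, image_px = 384, noise = 1, seed = 42)
  s3 <- simulate_fiber_image(lay, image_px = 384, noise = 1, seed = 43)
  expect_identical(s1$image$intensity, s2$image$intensity)
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(s1$image$intensity, s3$image$intensity))
})

test_that("fibers outside the image are rejected", {
  lay <- fiber_layout(1, fetal_control(), image_px = 384)
  lay$x1 <- 500
  expect_error(simulate_fiber_image(lay, image_px = 384), "outside")
})

test_that("cohort with zero SDs reproduces the group means exactly", {
  g <- reference_cohorts()
  g <- g[g$age == "fetal", ]
  g$sl_sd <- 0; g$ratio_sd <- 0; g$ttil_sd <- 0
  spec <- cohort_spec(g, age = "fetal", n_hearts = 3, images_per_heart = 1,
                      fibers_per_image = 2,
                      within_sd = c(sl = 0, ratio = 0, ttil = 0), seed = 9)
  coh <- simulate_cohort(spec, render = FALSE)
  for (grp in c("control", "iugr")) {
    fb <- coh$fibers[coh$fibers$group == grp, ]
    expect_equal(unique(fb$sl_um), g$sl_mean[g$group == grp])
    expect_equal(unique(round(fb$abl_um, 12)),
                 round(g$sl_mean[g$group == grp] /
                         g$ratio_mean[g$group == grp], 12))
    expect_equal(unique(fb$ttil_um), g$ttil_mean[g$group == grp])
  }
})

test_that("cohorts are paired and reproducible", {
  spec <- cohort_spec_from_reference("fetal", n_hearts = 7,
                                     images_per_heart = 1,
                                     fibers_per_image = 2, seed = 5)
  c1 <- simulate_cohort(spec, render = FALSE)
  c2 <- simulate_cohort(spec, render = FALSE)
  expect_identical(c1$fibers, c2$fibers)
  expect_equal(nrow(c1$hearts), 14L)
  expect_setequal(c1$hearts$pair_id[c1$hearts$group == "control"],
                  c1$hearts$pair_id[c1$hearts$group == "iugr"])
  # moment matching: sample moments of heart-level truth match the spec
  ref <- reference_cohorts()
  sl_c <- c1$hearts$sl_um[c1$hearts$group == "control"]
  expect_equal(mean(sl_c), ref$sl_mean[ref$age == "fetal" &
                                         ref$group == "control"])
  expect_equal(sd(sl_c), ref$sl_sd[ref$age == "fetal" &
                                     ref$group == "control"])
})

test_that("rendered cohort images are seed-deterministic", {
  spec <- cohort_spec_from_reference("fetal", groups = "control",
                                     n_hearts = 1, images_per_heart = 1,
                                     fibers_per_image = 2, image_px = 384,
                                     seed = 21)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$images[[1]]$intensity, c2$images[[1]]$intensity)
})

test_that("ranked-list generator embeds the requested annotation block", {
  rl <- simulate_ranked_list(2000, frac_up = 0.016, frac_down = 0.0069,
                             seed = 3)
  ann <- rl$annotations[rl$annotations$term_id == "GO:0031430", ]
  ranks <- rl$ranked$rank[match(ann$gene_id, rl$ranked$gene_id)]
  expect_equal(sum(ranks <= 1000), 16L)   # 1.6% of the top half
  expect_equal(sum(ranks > 1000), 7L)     # 0.69% of the bottom half
  expect_false(anyDuplicated(rl$ranked$gene_id) > 0)
  expect_error(simulate_ranked_list(50, frac_up = 0.001, frac_down = 0),
               "too small")
  expect_error(simulate_ranked_list(1000, frac_up = 0.01, frac_down = 0.02),
               "frac_down")
})

test_that("symmetric fractions annotate both halves equally", {
  rl <- simulate_ranked_list(1000, frac_up = 0.05, frac_down = 0.05,
                             seed = 4)
  ann <- rl$annotations[rl$annotations$term_id == "GO:0031430", ]
  ranks <- rl$ranked$rank[match(ann$gene_id, rl$ranked$gene_id)]
  expect_equal(sum(ranks <= 500), sum(ranks > 500))
})
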