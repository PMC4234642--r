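# Shared fixtures and small independent oracles used across test files.

fetal_control <- function() sarcomere_params(1.658, 0.772, 0.104)

# circular distance between two orientations, degrees mod 180
angle_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# circular median orientation of a vector of angles (degrees mod 180)
circ_median_180 <- function(a) {
  a <- a[!is.na(a)]
  (0.5 * atan2(median(sin(2 * a * pi / 180)),
               median(cos(2 * a * pi / 180))) * 180 / pi) %% 180
}

# render one or more fibers at the fetal-control geometry
quick_image <- function(n_fibers = 1, orientation_deg = 45, image_px = 448,
                        noise = 1, seed = 1, params = fetal_control()) {
  lay <- fiber_layout(n_fibers, params, orientation_deg = orientation_deg,
                      image_px = image_px)
  simulate_fiber_image(lay, image_px = image_px, noise = noise, seed = seed,
                       id = sprintf("fix_s%d", seed))
}

# O(n^2) direct-sum autocorrelation oracle (biased estimator, same
# definition as compute_acf but written naively)
acf_bruteforce <- function(x, nlag) {
  x <- x - mean(x)
  denom <- sum(x^2)
  n <- length(x)
  out <- numeric(nlag + 1)
  for (l in 0:nlag) {
    s <- 0
    for (i in 1:(n - l)) s <- s + x[i] * x[i + l]
    out[l + 1] <- s / denom
  }
  out
}

# strict interior local maxima of a vector
local_maxima <- function(v) {
  n <- length(v)
  which(c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n], FALSE))
}

# fundamental period of a profile by zero-padded periodogram (independent of
# the ACF route). The biperiodic pattern has most of its power in the second
# harmonic (the two A-band peaks are nearly evenly spaced), so the search is
# restricted to the window around the fundamental, periods 1.2-3 um.
fft_period_um <- function(samples, spacing_um, pad = 8) {
  x <- samples - mean(samples)
  n <- length(x)
  m <- pad * 2^ceiling(log2(n))
  sp <- Mod(stats::fft(c(x, rep(0, m - n))))^2
  freqs <- (0:(m - 1)) / (m * spacing_um)
  half <- 2:(m %/% 2)
  ok <- half[freqs[half] > 1 / 3 & freqs[half] < 1 / 1.2]
  1 / freqs[ok[which.max(sp[ok])]]
}

# an ACF object built directly from the parametric model (optionally with
# additive noise), bypassing the image pipeline
synthetic_acf <- function(params, noise_sd = 0, n_samples = 1e6, seed = 1,
                          max_lag_um = 6, spacing_um = 0.04) {
  lags <- seq(0, max_lag_um, by = spacing_um)
  vals <- model_acf(params, lags) * (1 - (lags / spacing_um) / n_samples)
  if (noise_sd > 0) {
    set.seed(seed)
    vals <- vals + rnorm(length(vals), 0, noise_sd)
    vals[1] <- 1
  }
  structure(list(lags_um = lags, values = vals, spacing_um = spacing_um,
                 n_samples = n_samples),
            class = "sarc_acf")
}

# two-sided Fisher p by exhaustive hypergeometric enumeration
fisher_two_sided_oracle <- function(a, b, c, d) {
  K <- a + c; n_above <- a + b; N <- a + b + c + d
  xs <- max(0, K + n_above - N):min(K, n_above)
  dens <- stats::dhyper(xs, K, N - K, n_above)
  obs <- stats::dhyper(a, K, N - K, n_above)
  sum(dens[dens <= obs * (1 + 1e-7)])
}
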