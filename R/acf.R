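#' Normalized autocorrelation of a fiber intensity profile
#'
#' Mean-subtracted, variance-normalized autocorrelation over lags
#' `[0, max_lag_um]`, using the standard biased (1/n) estimator, which
#' guarantees values in `[-1, 1]`. The known triangular (Bartlett) taper
#' `1 - lag/n` that this estimator imposes is accounted for analytically in
#' the model fit (see [fit_sarcomere_model()]), not removed here.
#'
#' @param profile An `intensity_profile`, or a bare numeric vector together
#'   with `spacing_nm`.
#' @param max_lag_um Maximum lag, um. Default 6 (about three sarcomere
#'   periods). The profile must span at least twice this lag.
#' @param spacing_nm Sample pitch, nm; only used when `profile` is a bare
#'   vector.
#' @return A list of class `sarc_acf` with `lags_um` (0, pitch, 2*pitch, ...),
#'   `values` (value 1 at lag 0), `spacing_um` and `n_samples`.
#' @export
compute_acf <- function(profile, max_lag_um = 6, spacing_nm = NULL) {
  if (inherits(profile, "intensity_profile")) {
    x <- profile$samples
    pitch_um <- profile$spacing_nm / 1000
  } else {
    stopifnot(is.numeric(profile), !is.null(spacing_nm))
    x <- profile
    pitch_um <- spacing_nm / 1000
  }
  stopifnot(max_lag_um > 0)
  n <- length(x)
  nlag <- floor(max_lag_um / pitch_um)
  if (n < 2 * nlag) {
    stop("profile too short for the requested maximum lag", call. = FALSE)
  }
  x <- x - mean(x)
  denom <- sum(x * x)
  if (denom <= 0 || !is.finite(denom)) {
    stop("zero-variance profile: no striation signal", call. = FALSE)
  }
  vals <- vapply(0:nlag, function(l) {
    sum(x[seq_len(n - l)] * x[(l + 1):n]) / denom
  }, 0)
  structure(list(lags_um = (0:nlag) * pitch_um, values = vals,
                 spacing_um = pitch_um, n_samples = n),
            class = "sarc_acf")
}

#' Parametric autocorrelation model of the biperiodic striation profile
#'
#' Closed-form normalized autocorrelation of the generative profile model (an
#' infinite periodic train of Gaussian peak pairs, period SL, pair separation
#' ABL, peak FWHM = TTIL). The cross-correlation of two unit Gaussians of
#' sigma `s` at separation `d` is `s*sqrt(pi)*exp(-d^2/(4 s^2))`, so the ACF
#' of the mean-subtracted periodic profile is
#'
#' \deqn{R(\tau) \propto \sum_k \sum_{d \in \{0,0,+ABL,-ABL\}}
#'   e^{-(\tau - d - k\,SL)^2 / (4\sigma^2)} - \frac{2\sigma\sqrt{2\pi}}{SL}}
#'
#' normalized to 1 at lag 0, with `sigma = TTIL / (2*sqrt(2*log 2))`. Peaks
#' sit at lags `k*SL` (weight 2) and `k*SL +/- ABL` (weight 1).
#'
#' @param params A `sarcomere_params`, or a numeric vector
#'   `c(sl_um, abl_um, ttil_um)`.
#' @param lags_um Non-negative lags, um.
#' @return Numeric vector of model ACF values at `lags_um`.
#' @export
model_acf <- function(params, lags_um) {
  if (inherits(params, "sarcomere_params")) {
    sl <- params$sl_um; abl <- params$abl_um; ttil <- params$ttil_um
  } else {
    sl <- params[[1]]; abl <- params[[2]]; ttil <- params[[3]]
  }
  if (!valid_sarcomere_params(sl, abl, ttil)) {
    stop("invalid sarcomere parameters", call. = FALSE)
  }
  sigma <- ttil / FWHM_FACTOR
  raw <- model_acf_raw(sl, abl, sigma, lags_um)
  raw0 <- model_acf_raw(sl, abl, sigma, 0)
  raw / raw0
}

model_acf_raw <- function(sl, abl, sigma, lags) {
  kmax <- ceiling(max(abs(lags)) / sl) + 2
  acc <- numeric(length(lags))
  for (k in -kmax:kmax) {
    for (d in c(0, 0, abl, -abl)) {
      acc <- acc + exp(-(lags - d - k * sl)^2 / (4 * sigma^2))
    }
  }
  # subtract the squared-mean (DC) term of the periodic train; constant
  # factors common to acc and the DC term are kept so the two are on the
  # same scale: acc is in units of h(0) = sigma*sqrt(pi), and the DC term is
  # mu^2 * SL / h(0) with mu = 2*sigma*sqrt(2*pi)/SL.
  acc - 8 * sqrt(pi) * sigma / sl
}
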