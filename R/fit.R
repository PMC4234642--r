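#' Locate the first major off-zero peak of an ACF
#'
#' Finds the highest local maximum of the ACF inside a lag window (by default
#' the optimizer's SL bounds). This is the auto-initialization for SL: for a
#' sarcomeric striation the global ACF maximum in that window is the lag-SL
#' peak (the satellite peaks at `ABL` and `SL - ABL` lie below it in lag, and
#' carry half its weight).
#'
#' @param acf A `sarc_acf`.
#' @param window Lag window, um.
#' @return Lag of the peak, um, or `NA` if no local maximum exists in the
#'   window.
#' @export
find_acf_peak <- function(acf, window = c(1.0, 2.5)) {
  l <- acf$lags_um; v <- acf$values
  n <- length(v)
  if (n < 3) return(NA_real_)
  ismax <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n],
             FALSE)
  cand <- which(ismax & l >= window[1] & l <= window[2])
  if (!length(cand)) return(NA_real_)
  l[cand[which.max(v[cand])]]
}

#' Fit the parametric sarcomere model to an autocorrelation function
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt, [minpack.lm::nls.lm])
#' minimizing the squared error between the measured ACF and
#' `amp * (1 - lag/n) * model_acf(sl, abl, ttil) + offset` over lags in
#' `[fit_lag_min_um, max_lag]`. The `(1 - lag/n)` factor is the Bartlett
#' taper of the biased ACF estimator; `amp` absorbs the variance fraction
#' taken up by noise (white noise only contributes at lag 0, which is
#' excluded together with the first few lags); `offset` absorbs slow envelope
#' leakage. Auto-initialization: SL from [find_acf_peak()], ABL = SL / 2.15,
#' TTIL = 0.1 um.
#'
#' @param acf A `sarc_acf`.
#' @param init Optional `sarcomere_params` (or numeric
#'   `c(sl_um, abl_um, ttil_um)`) initial guess; default auto.
#' @param config A [sarcomorph_config()]; supplies bounds, tolerance and the
#'   minimum fitted lag.
#' @return A list of class `sarcomere_fit` with `sl_um`, `abl_um`, `ttil_um`,
#'   `ratio` (= sl/abl), `amp`, `offset`, `residual` (RMS), `converged`,
#'   `reason` and `niter`. If no off-zero ACF peak is found the fit is
#'   returned non-converged (`reason = "no_off_zero_peak"`), never silently
#'   dropped.
#' @export
fit_sarcomere_model <- function(acf, init = NULL,
                                config = sarcomorph_config()) {
  stopifnot(inherits(acf, "sarc_acf"))
  lo <- config$fit_lower; hi <- config$fit_upper
  mask <- acf$lags_um >= config$fit_lag_min_um
  lags <- acf$lags_um[mask]
  vals <- acf$values[mask]
  taper <- 1 - (acf$lags_um[mask] / acf$spacing_um) / acf$n_samples

  failed <- function(reason) {
    structure(list(sl_um = NA_real_, abl_um = NA_real_, ttil_um = NA_real_,
                   ratio = NA_real_, amp = NA_real_, offset = NA_real_,
                   residual = NA_real_, converged = FALSE, reason = reason,
                   niter = 0L),
              class = "sarcomere_fit")
  }
  if (length(lags) < 10) return(failed("too_few_lags"))

  if (is.null(init)) {
    sl0 <- find_acf_peak(acf, window = c(lo[["sl_um"]], hi[["sl_um"]]))
    if (is.na(sl0)) return(failed("no_off_zero_peak"))
    abl0 <- clamp(sl0 / 2.15, lo[["abl_um"]], hi[["abl_um"]])
    ttil0 <- 0.1
  } else {
    if (inherits(init, "sarcomere_params")) {
      sl0 <- init$sl_um; abl0 <- init$abl_um; ttil0 <- init$ttil_um
    } else {
      sl0 <- init[[1]]; abl0 <- init[[2]]; ttil0 <- init[[3]]
    }
  }
  m0 <- model_acf(c(sl0, abl0, ttil0), sl0)
  peak_val <- vals[which.min(abs(lags - sl0))]
  amp0 <- clamp(peak_val / max(m0, 0.1), lo[["amp"]], hi[["amp"]])
  par0 <- c(sl_um = clamp(sl0, lo[["sl_um"]], hi[["sl_um"]]),
            abl_um = abl0, ttil_um = ttil0, amp = amp0, offset = 0)

  resid_fn <- function(p) {
    sl <- p[1]; abl <- p[2]; ttil <- p[3]
    if (!valid_sarcomere_params(sl, abl, ttil)) {
      return(rep(10, length(vals)))  # outside the physical region
    }
    p[4] * taper * model_acf(c(sl, abl, ttil), lags) + p[5] - vals
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lo, upper = hi, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = config$fit_maxiter,
                         ftol = config$fit_ftol, ptol = 1e-10)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(failed("optimizer_error"))
  p <- fit$par
  ok <- fit$info %in% 1:4 &&
    valid_sarcomere_params(p[[1]], p[[2]], p[[3]])
  structure(list(
    sl_um = p[[1]], abl_um = p[[2]], ttil_um = p[[3]],
    ratio = p[[1]] / p[[2]], amp = p[[4]], offset = p[[5]],
    residual = sqrt(mean(fit$fvec^2)),
    converged = ok,
    reason = if (ok) "converged" else "no_convergence",
    niter = fit$niter
  ), class = "sarcomere_fit")
}

#' @export
print.sarcomere_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<sarcomere_fit: SL %.4f um, ABL %.4f um, TTIL %.4f um, ratio %.3f, rms %.4f>\n",
      x$sl_um, x$abl_um, x$ttil_um, x$ratio, x$residual))
  } else {
    cat(sprintf("<sarcomere_fit: not converged (%s)>\n", x$reason))
  }
  invisible(x)
}

#' Apply the SL/ABL quality-control rule to a table of fits
#'
#' Fibers whose fitted SL/ABL ratio is strictly greater than `max_ratio`
#' (default 2.25) are excluded: above that ratio the typical biperiodic SHG
#' pattern of cardiac sarcomeres is lost. A ratio exactly at the threshold is
#' kept. Non-converged fits are always excluded, with their own reason.
#'
#' @param fits Tibble with at least columns `ratio` and `converged` (e.g.
#'   from [measure_image()]).
#' @param max_ratio QC threshold; must exceed 1.
#' @return A list with `kept` and `excluded` tibbles; `excluded` gains a
#'   `qc_reason` column (`"not_converged"` or `"ratio_above_threshold"`).
#' @export
apply_qc <- function(fits, max_ratio = 2.25) {
  stopifnot(max_ratio > 1)
  fits <- tibble::as_tibble(fits)
  bad_conv <- !fits$converged
  bad_ratio <- !bad_conv & fits$ratio > max_ratio
  excluded <- fits[bad_conv | bad_ratio, ]
  if (nrow(excluded)) {
    excluded$qc_reason <- ifelse(!excluded$converged, "not_converged",
                                 "ratio_above_threshold")
  } else {
    excluded$qc_reason <- character(0)
  }
  list(kept = fits[!(bad_conv | bad_ratio), ], excluded = excluded)
}
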