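#' @importFrom stats approxfun fisher.test median na.omit p.adjust phyper quantile
#'   rnorm rpois runif sd t.test aov anova lm setNames dist complete.cases
#' @importFrom utils head tail read.csv write.csv read.delim
#' @importFrom rlang .data
NULL

# FWHM of a Gaussian = 2*sqrt(2*log(2)) * sigma. TTIL is defined as the FWHM of
# the A-band-related intensity peak; this single constant converts between the
# two everywhere (simulator and fitter share it).
FWHM_FACTOR <- 2 * sqrt(2 * log(2))

#' Sarcomere geometry parameters
#'
#' Bundles the three distances that characterise a resting sarcomere in an SHG
#' striation image: sarcomere length (SL, Z-disc to Z-disc), intra-sarcomeric
#' A-band length (ABL, distance between the two A-band segments split by the
#' M-band) and thick-thin filament interaction length (TTIL, the full width at
#' half maximum of each A-band-related intensity peak). All lengths are in
#' micrometres.
#'
#' @param sl_um Sarcomere length, um. Must be positive.
#' @param abl_um Intra-sarcomeric A-band length, um. Must satisfy
#'   `0 < abl_um < sl_um`.
#' @param ttil_um Thick-thin filament interaction length, um. Must satisfy
#'   `0 < ttil_um < abl_um`.
#' @return A named list of class `sarcomere_params` with fields `sl_um`,
#'   `abl_um`, `ttil_um` and the derived `ratio` (`sl_um / abl_um`).
#' @examples
#' sarcomere_params(1.658, 0.772, 0.104)
#' @export
sarcomere_params <- function(sl_um, abl_um, ttil_um) {
  stopifnot(is.numeric(sl_um), is.numeric(abl_um), is.numeric(ttil_um))
  if (!is.finite(sl_um) || sl_um <= 0) {
    stop("sl_um must be positive and finite", call. = FALSE)
  }
  if (!is.finite(abl_um) || abl_um <= 0 || abl_um >= sl_um) {
    stop("abl_um must satisfy 0 < abl_um < sl_um", call. = FALSE)
  }
  if (!is.finite(ttil_um) || ttil_um <= 0 || ttil_um >= abl_um) {
    stop("ttil_um must satisfy 0 < ttil_um < abl_um", call. = FALSE)
  }
  structure(
    list(sl_um = sl_um, abl_um = abl_um, ttil_um = ttil_um,
         ratio = sl_um / abl_um),
    class = "sarcomere_params"
  )
}

valid_sarcomere_params <- function(sl_um, abl_um, ttil_um) {
  is.finite(sl_um) & is.finite(abl_um) & is.finite(ttil_um) &
    sl_um > 0 & abl_um > 0 & ttil_um > 0 & abl_um < sl_um & ttil_um < abl_um
}

#' Reference cohort configurations
#'
#' Group-level summaries (mean and SD over hearts) of SL, ABL, TTIL and the
#' SL/ABL ratio for the four study groups of the rabbit IUGR model: paired
#' control and growth-restricted (IUGR) hearts, at the fetal stage (30 days of
#' gestation) and at young adulthood (70 postnatal days). These are the
#' configurations the synthetic cohort generator reproduces. `ratio_mean` is
#' derived as `sl_mean / abl_mean`; `ratio_sd` is the reported SD of the
#' per-heart ratio, which is far smaller than independent SL and ABL draws
#' would produce -- SL and ABL are strongly coupled across hearts, and the
#' generator honours that coupling.
#'
#' @return A tibble with one row per age x group combination and columns
#'   `age`, `group`, `sl_mean`, `sl_sd`, `abl_mean`, `abl_sd`, `ttil_mean`,
#'   `ttil_sd`, `ratio_mean`, `ratio_sd`, `n_hearts` (all lengths um).
#' @export
reference_cohorts <- function() {
  ref <- tibble::tribble(
    ~age,     ~group,    ~sl_mean, ~sl_sd, ~abl_mean, ~abl_sd, ~ttil_mean, ~ttil_sd, ~ratio_sd,
    "fetal",  "control", 1.658,    0.094,  0.772,     0.044,   0.104,      0.006,    0.02,
    "fetal",  "iugr",    1.531,    0.114,  0.705,     0.060,   0.096,      0.007,    0.03,
    "adult",  "control", 1.720,    0.068,  0.817,     0.036,   0.103,      0.005,    0.02,
    "adult",  "iugr",    1.626,    0.084,  0.772,     0.041,   0.097,      0.005,    0.01
  )
  ref$ratio_mean <- ref$sl_mean / ref$abl_mean
  ref$n_hearts <- 7L
  ref
}

#' Pipeline configuration defaults
#'
#' Single place where every tunable constant of the measurement pipeline
#' lives. Values can be overridden by name; unknown names are an error.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A named list of class `sarcomorph_config`.
#' @section Defaults:
#' \describe{
#'   \item{pixel_nm}{Physical pixel pitch, nm (40).}
#'   \item{qc_max_ratio}{SL/ABL ratio above which a fiber is excluded (2.25).}
#'   \item{alpha}{Significance threshold for group comparisons (0.05).}
#'   \item{orientation_scale_nm}{Structure-tensor integration scale, nm (400).}
#'   \item{coherence_min}{Minimum structure-tensor coherence for tracing (0.2).}
#'   \item{expected_sl_um}{Prior expectation of SL used for minimum trace
#'     length and envelope smoothing, um (1.7).}
#'   \item{min_fiber_periods}{Minimum trace length in units of expected SL (5).}
#'   \item{transverse_halfwidth_px}{Half-width of transverse averaging when
#'     extracting profiles, px (3).}
#'   \item{profile_interp}{Image interpolation for profile extraction:
#'     "cubic" (Catmull-Rom, width-preserving) or "bilinear".}
#'   \item{max_lag_um}{Maximum autocorrelation lag, um (6).}
#'   \item{fit_lag_min_um}{Smallest lag included in the model fit, um (0.12);
#'     excludes the white-noise spike at lag 0.}
#'   \item{fit_lower, fit_upper}{Optimizer bounds on
#'     (sl_um, abl_um, ttil_um, amplitude, offset).}
#'   \item{fit_maxiter, fit_ftol}{Optimizer iteration cap (500) and relative
#'     cost tolerance (1e-8).}
#' }
#' @export
sarcomorph_config <- function(...) {
  cfg <- list(
    pixel_nm = 40,
    qc_max_ratio = 2.25,
    alpha = 0.05,
    orientation_scale_nm = 400,
    coherence_min = 0.2,
    expected_sl_um = 1.7,
    min_fiber_periods = 5,
    transverse_halfwidth_px = 3L,
    profile_interp = "cubic",
    max_lag_um = 6,
    fit_lag_min_um = 0.12,
    fit_lower = c(sl_um = 1.0, abl_um = 0.4, ttil_um = 0.04,
                  amp = 0.05, offset = -0.5),
    fit_upper = c(sl_um = 2.5, abl_um = 1.2, ttil_um = 0.2,
                  amp = 2.0, offset = 0.5),
    fit_maxiter = 500L,
    fit_ftol = 1e-8
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) {
      stop("unknown config fields: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "sarcomorph_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
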