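#' Measure all fibers in one striation image
#'
#' Runs the single-image measurement chain: orientation field, fiber tracing,
#' profile extraction, autocorrelation, parametric model fit. One row per
#' accepted trace; traces whose profile or fit fails are kept as
#' non-converged rows (with the failure reason), never silently dropped.
#'
#' @param image An `shgm_image`.
#' @param config A [sarcomorph_config()].
#' @return Tibble with columns `image_id`, `fiber_id` (trace index), `sl_um`,
#'   `abl_um`, `ttil_um`, `ratio`, `residual`, `converged`, `reason`,
#'   `trace_um` (trace length) and `n_samples`.
#' @export
measure_image <- function(image, config = sarcomorph_config()) {
  stopifnot(inherits(image, "shgm_image"))
  field <- estimate_orientation(image, scale_nm = config$orientation_scale_nm)
  traces <- trace_fibers(image, field, config)
  if (!length(traces)) {
    return(tibble::tibble(
      image_id = character(), fiber_id = integer(), sl_um = numeric(),
      abl_um = numeric(), ttil_um = numeric(), ratio = numeric(),
      residual = numeric(), converged = logical(), reason = character(),
      trace_um = numeric(), n_samples = integer()
    ))
  }
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    fit <- tryCatch({
      prof <- extract_profile(image, tr,
                              halfwidth_px = config$transverse_halfwidth_px,
                              method = config$profile_interp)
      max_lag <- min(config$max_lag_um,
                     floor(prof$n / 2) * prof$spacing_nm / 1000)
      acf <- compute_acf(prof, max_lag_um = max_lag)
      fit_sarcomere_model(acf, config = config)
    }, error = function(e) {
      structure(list(sl_um = NA_real_, abl_um = NA_real_, ttil_um = NA_real_,
                     ratio = NA_real_, amp = NA_real_, offset = NA_real_,
                     residual = NA_real_, converged = FALSE,
                     reason = conditionMessage(e), niter = 0L),
                class = "sarcomere_fit")
    })
    tibble::tibble(
      image_id = image$id, fiber_id = i,
      sl_um = fit$sl_um, abl_um = fit$abl_um, ttil_um = fit$ttil_um,
      ratio = fit$ratio, residual = fit$residual,
      converged = fit$converged, reason = fit$reason,
      trace_um = tr$length_um, n_samples = length(traces[[i]]$points[, 1])
    )
  })
  dplyr::bind_rows(rows)
}

#' Aggregate QC-passing fiber fits to heart-level summaries
#'
#' Unweighted mean and SD (n-1 denominator) over a heart's QC-passing fibers,
#' pooled directly across that heart's images (fiber -> heart aggregation).
#' Hearts with zero passing fibers are reported in the `excluded_hearts`
#' attribute rather than silently vanishing.
#'
#' @param fits Tibble of fiber fits carrying `heart_id`, `group`, `age`,
#'   `pair_id`, `image_id` metadata plus the fit columns; only rows that
#'   passed QC should be supplied (see [apply_qc()]).
#' @return Tibble with one row per heart: means and SDs of SL/ABL/TTIL, mean
#'   ratio, `n_fibers`, `n_images`.
#' @export
summarize_hearts <- function(fits) {
  fits <- tibble::as_tibble(fits)
  need <- c("heart_id", "group", "age", "pair_id", "image_id",
            "sl_um", "abl_um", "ttil_um", "ratio")
  miss <- setdiff(need, names(fits))
  if (length(miss)) {
    stop("fits lack columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(fits, .data$heart_id, .data$group, .data$age,
                    .data$pair_id),
    sl_sd_um = sd(.data$sl_um), sl_um = mean(.data$sl_um),
    abl_sd_um = sd(.data$abl_um), abl_um = mean(.data$abl_um),
    ttil_sd_um = sd(.data$ttil_um), ttil_um = mean(.data$ttil_um),
    ratio = mean(.data$ratio),
    n_fibers = dplyr::n(),
    n_images = dplyr::n_distinct(.data$image_id),
    .groups = "drop"
  )
  dplyr::select(out, "heart_id", "group", "age", "pair_id",
                "sl_um", "sl_sd_um", "abl_um", "abl_sd_um",
                "ttil_um", "ttil_sd_um", "ratio", "n_fibers", "n_images")
}

#' Compare control vs IUGR heart summaries on one variable
#'
#' Runs the group contrast the study design calls for: a paired two-sided
#' t-test on the within-pair differences (control minus IUGR), or a classical
#' one-way ANOVA across the two groups. Group means and SDs are reported in
#' the mean +/- SD convention at the heart level.
#'
#' Degenerate inputs are flagged rather than erroring: if every within-pair
#' difference is identical the t statistic is undefined (0/0 when the common
#' difference is zero), and the comparison is returned with `degenerate =
#' TRUE`, statistic 0 or +/-Inf, and p-value 1 or 0 accordingly.
#'
#' @param hearts Heart summaries from [summarize_hearts()] (both groups).
#' @param variable Column to compare, e.g. `"sl_um"`.
#' @param test `"paired_t"` or `"anova"`.
#' @return One-row tibble: `variable`, `test`, `n_pairs`, `mean_control`,
#'   `sd_control`, `mean_iugr`, `sd_iugr`, `statistic`, `p_value`,
#'   `degenerate`.
#' @export
compare_groups <- function(hearts, variable,
                           test = c("paired_t", "anova")) {
  test <- match.arg(test)
  hearts <- tibble::as_tibble(hearts)
  stopifnot(variable %in% names(hearts))
  ctl <- hearts[hearts$group == "control", ]
  iugr <- hearts[hearts$group == "iugr", ]
  if (!nrow(ctl) || !nrow(iugr)) {
    stop("both groups must be present", call. = FALSE)
  }
  x <- ctl[[variable]]; y <- iugr[[variable]]

  if (test == "paired_t") {
    unpaired <- c(setdiff(ctl$pair_id, iugr$pair_id),
                  setdiff(iugr$pair_id, ctl$pair_id))
    if (length(unpaired)) {
      stop("unpaired hearts for paired test, pair ids: ",
           paste(sort(unique(unpaired)), collapse = ", "), call. = FALSE)
    }
    ctl <- ctl[order(ctl$pair_id), ]; iugr <- iugr[order(iugr$pair_id), ]
    x <- ctl[[variable]]; y <- iugr[[variable]]
    d <- x - y
    if (sd(d) < 1e-10 * max(abs(d), 1)) {  # differences numerically constant
      zero_mean <- abs(mean(d)) < 1e-10 * max(abs(c(x, y)), 1)
      stat <- if (zero_mean) 0 else sign(mean(d)) * Inf
      pval <- if (zero_mean) 1 else 0
      degen <- TRUE
    } else {
      tt <- t.test(x, y, paired = TRUE)
      stat <- unname(tt$statistic); pval <- tt$p.value; degen <- FALSE
    }
    n <- length(d)
  } else {
    val <- c(x, y)
    grp <- factor(rep(c("control", "iugr"), c(length(x), length(y))))
    if (sd(val) == 0) {
      stat <- 0; pval <- 1; degen <- TRUE
    } else {
      av <- anova(lm(val ~ grp))
      stat <- av[["F value"]][1]; pval <- av[["Pr(>F)"]][1]
      degen <- !is.finite(stat)
      if (degen) { stat <- Inf; pval <- 0 }
    }
    n <- min(length(x), length(y))
  }
  tibble::tibble(
    variable = variable, test = test, n_pairs = n,
    mean_control = mean(x), sd_control = sd(x),
    mean_iugr = mean(y), sd_iugr = sd(y),
    statistic = stat, p_value = pval, degenerate = degen
  )
}

#' Run the full measurement and comparison pipeline on a simulated cohort
#'
#' Measures every image of a [simulate_cohort()] result, attaches heart/group
#' metadata, applies the SL/ABL QC rule per fiber (and reports the per-image
#' mean ratio against the same threshold), aggregates to heart level, and
#' runs both the paired t-test and the ANOVA contrast for SL, ABL and TTIL.
#' A failing image is logged and skipped; the run fails only if every image
#' fails.
#'
#' @param cohort Result of [simulate_cohort()] (rendered).
#' @param config A [sarcomorph_config()].
#' @param verbose Emit per-image progress messages.
#' @return List with `fits` (all fibers, QC columns included), `hearts`,
#'   `comparisons` (3 variables x 2 tests), `image_qc` (per-image mean
#'   ratio and flag) and `counts` (traced / converged / qc_pass funnel).
#' @export
run_cohort <- function(cohort, config = sarcomorph_config(),
                       verbose = FALSE) {
  if (is.null(cohort$images)) {
    stop("cohort has no rendered images; call simulate_cohort(render = TRUE)",
         call. = FALSE)
  }
  fits <- list(); failed <- 0L
  for (id in names(cohort$images)) {
    f <- tryCatch(measure_image(cohort$images[[id]], config),
                  error = function(e) {
                    message("image ", id, " failed: ", conditionMessage(e))
                    NULL
                  })
    if (is.null(f)) { failed <- failed + 1L; next }
    if (verbose) {
      message(sprintf("%s: %d traces, %d converged", id, nrow(f),
                      sum(f$converged)))
    }
    fits[[id]] <- f
  }
  if (failed == length(cohort$images)) {
    stop("all images failed to measure", call. = FALSE)
  }
  fits <- dplyr::bind_rows(fits)
  fits <- dplyr::left_join(fits, cohort$manifest, by = "image_id")

  qc <- apply_qc(fits, max_ratio = config$qc_max_ratio)
  fits$qc_pass <- !(paste(fits$image_id, fits$fiber_id) %in%
                      paste(qc$excluded$image_id, qc$excluded$fiber_id))
  image_qc <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(fits[fits$converged, ]), .data$image_id),
    mean_ratio = mean(.data$ratio), n_fibers = dplyr::n(),
    .groups = "drop"
  )
  image_qc$qc_pass <- image_qc$mean_ratio <= config$qc_max_ratio

  hearts <- summarize_hearts(fits[fits$qc_pass, ])
  comparisons <- if (all(c("control", "iugr") %in% hearts$group)) {
    dplyr::bind_rows(lapply(
      c("sl_um", "abl_um", "ttil_um"),
      function(v) dplyr::bind_rows(
        compare_groups(hearts, v, "paired_t"),
        compare_groups(hearts, v, "anova")
      )
    ))
  } else {
    tibble::tibble()  # single-group cohort: nothing to contrast
  }
  counts <- c(traced = nrow(fits), converged = sum(fits$converged),
              qc_pass = sum(fits$qc_pass))
  list(fits = tibble::as_tibble(fits), hearts = hearts,
       comparisons = comparisons, image_qc = image_qc, counts = counts)
}

#' Cohort-level mean of a heart summary variable
#'
#' Mean over hearts of one group (the aggregation the group summaries use:
#' fiber -> heart -> group).
#'
#' @param hearts Heart summaries.
#' @param variable Column name.
#' @param group Group label.
#' @return Scalar mean.
#' @export
cohort_mean <- function(hearts, variable, group = "control") {
  mean(hearts[[variable]][hearts$group == group])
}
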