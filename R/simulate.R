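#' Lay out parallel fibers across a square image
#'
#' Constructs the ground-truth geometry for a field of parallel muscle fibers:
#' straight centerlines at a common orientation, evenly spaced perpendicular
#' offsets, each fiber spanning the full chord of the image at its offset.
#' The number of sarcomeres per fiber follows from the chord length and the
#' fiber's SL, leaving one period of slack so that the train can be phase
#' jittered at render time.
#'
#' @param n_fibers Number of fibers.
#' @param params A `sarcomere_params` object, or a data frame with columns
#'   `sl_um`, `abl_um`, `ttil_um` (one row per fiber, recycled if one row).
#' @param orientation_deg Fiber axis angle, degrees counterclockwise from the
#'   image x axis (columns), in `[0, 180)`. Default 45, the acquisition
#'   convention that maximises SHG signal-to-noise.
#' @param image_px Image side, pixels.
#' @param pixel_nm Pixel pitch, nm.
#' @param spacing_px Perpendicular spacing between fiber centerlines, px. If
#'   `NULL`, fibers are spread evenly over the usable offset range.
#' @param margin_px Border margin that centerlines must respect, px.
#' @param contrast Peak signal amplitude per fiber, photons.
#' @param background Background level, photons.
#' @return A tibble (one row per fiber) with the fiber geometry and true
#'   sarcomere parameters; columns include the clipped centerline endpoints
#'   `x0, y0, x1, y1` (0-based pixel coordinates) and `n_sarcomeres`.
#' @export
fiber_layout <- function(n_fibers, params,
                         orientation_deg = 45,
                         image_px = 512L,
                         pixel_nm = 40,
                         spacing_px = NULL,
                         margin_px = 6,
                         contrast = 30,
                         background = 2) {
  stopifnot(n_fibers >= 1, image_px >= 64, pixel_nm > 0)
  if (inherits(params, "sarcomere_params")) {
    params <- tibble::tibble(sl_um = params$sl_um, abl_um = params$abl_um,
                             ttil_um = params$ttil_um)
  }
  params <- tibble::as_tibble(params)[, c("sl_um", "abl_um", "ttil_um")]
  if (nrow(params) == 1L) params <- params[rep(1L, n_fibers), ]
  stopifnot(nrow(params) == n_fibers)
  if (!all(valid_sarcomere_params(params$sl_um, params$abl_um, params$ttil_um))) {
    stop("invalid sarcomere parameters in layout", call. = FALSE)
  }

  orientation_deg <- orientation_deg %% 180
  theta <- orientation_deg * pi / 180
  u <- c(cos(theta), sin(theta))       # fiber axis
  v <- c(-sin(theta), cos(theta))      # perpendicular
  ctr <- (image_px - 1) / 2
  px_um <- pixel_nm / 1000
  # chord must fit >= 7 periods so that even the shortest rendered train
  # (chord minus one period of slack) clears the tracer's minimum length
  min_chord_px <- 1000 * max(params$sl_um) * 7 / pixel_nm

  # usable perpendicular offsets: chord at offset d must be long enough
  max_off <- max_offset_for_chord(image_px, margin_px, theta, min_chord_px)
  if (is.null(spacing_px)) {
    offsets <- if (n_fibers == 1L) 0 else
      seq(-max_off, max_off, length.out = n_fibers)
  } else {
    offsets <- (seq_len(n_fibers) - (n_fibers + 1) / 2) * spacing_px
    if (max(abs(offsets)) > max_off) {
      stop("fiber layout does not fit within the image at this spacing",
           call. = FALSE)
    }
  }

  rows <- lapply(seq_len(n_fibers), function(i) {
    p0 <- c(ctr, ctr) + offsets[i] * v
    tr <- clip_line_to_box(p0, u, margin_px, image_px - 1 - margin_px)
    if (is.null(tr)) {
      stop("fiber ", i, " falls outside the image", call. = FALSE)
    }
    chord_um <- (tr[2] - tr[1]) * px_um
    n_sarc <- floor(chord_um / params$sl_um[i]) - 1L
    if (n_sarc < 1L) {
      stop("fiber ", i, " is too short for a single sarcomere", call. = FALSE)
    }
    a <- p0 + tr[1] * u
    b <- p0 + tr[2] * u
    tibble::tibble(
      fiber_id = i,
      sl_um = params$sl_um[i], abl_um = params$abl_um[i],
      ttil_um = params$ttil_um[i],
      orientation_deg = orientation_deg,
      offset_px = offsets[i],
      n_sarcomeres = as.integer(n_sarc),
      x0 = a[1], y0 = a[2], x1 = b[1], y1 = b[2],
      contrast = contrast, background = background
    )
  })
  dplyr::bind_rows(rows)
}

# largest |perpendicular offset| at which the chord of a line at angle theta
# through the box [m, n-1-m]^2 still exceeds min_chord (px)
max_offset_for_chord <- function(image_px, margin_px, theta, min_chord_px) {
  u <- c(cos(theta), sin(theta))
  v <- c(-sin(theta), cos(theta))
  ctr <- (image_px - 1) / 2
  lo <- 0; hi <- image_px  # bisection on offset
  chord_at <- function(d) {
    tr <- clip_line_to_box(c(ctr, ctr) + d * v, u, margin_px,
                           image_px - 1 - margin_px)
    if (is.null(tr)) 0 else tr[2] - tr[1]
  }
  if (chord_at(0) < min_chord_px) {
    stop("image too small for the requested fiber length", call. = FALSE)
  }
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (chord_at(mid) >= min_chord_px) lo <- mid else hi <- mid
  }
  lo
}

# parameter range t such that p0 + t*u stays inside [lo, hi]^2, or NULL
clip_line_to_box <- function(p0, u, lo, hi) {
  t0 <- -Inf; t1 <- Inf
  for (k in 1:2) {
    if (abs(u[k]) < 1e-12) {
      if (p0[k] < lo || p0[k] > hi) return(NULL)
    } else {
      ta <- (lo - p0[k]) / u[k]; tb <- (hi - p0[k]) / u[k]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  if (t0 >= t1) NULL else c(t0, t1)
}

#' Analytic axial intensity profile of a sarcomere train
#'
#' Intensity along the fiber axis of `n_sarcomeres` consecutive sarcomeres:
#' each sarcomere contributes two Gaussian peaks (the two A-band segments,
#' split by the SHG-silent M-band) of FWHM equal to TTIL, centered ABL apart
#' around the sarcomere midpoint; the pattern repeats with period SL. Z-discs
#' carry no signal of their own (SHG arises from myosin), so the dark Z-disc
#' is simply the gap between periods.
#'
#' @param s_um Axial positions, um (numeric vector).
#' @param sl_um,abl_um,ttil_um Sarcomere geometry, um.
#' @param n_sarcomeres Number of repeats.
#' @param start_um Axial position where the first sarcomere begins, um.
#' @return Numeric vector of unit-amplitude intensities at `s_um`.
#' @export
axial_profile <- function(s_um, sl_um, abl_um, ttil_um, n_sarcomeres,
                          start_um = 0) {
  if (!valid_sarcomere_params(sl_um, abl_um, ttil_um)) {
    stop("invalid sarcomere parameters", call. = FALSE)
  }
  if (ttil_um >= min(abl_um, sl_um - abl_um) / 2) {
    stop("ttil too wide for the inter-peak gaps: striation pattern degenerate",
         call. = FALSE)
  }
  sigma <- ttil_um / FWHM_FACTOR
  mids <- start_um + (seq_len(n_sarcomeres) - 0.5) * sl_um
  centers <- c(mids - abl_um / 2, mids + abl_um / 2)
  out <- numeric(length(s_um))
  for (c0 in centers) {
    out <- out + exp(-(s_um - c0)^2 / (2 * sigma^2))
  }
  out
}

#' Render a ground-truthed SHG-like striation image
#'
#' Renders the fibers described by a truth table (see [fiber_layout()]) into a
#' single-channel image: each fiber is the product of a transverse Gaussian
#' envelope and the axial biperiodic pattern of [axial_profile()], on top of a
#' constant background, with optional photon (Poisson) and Gaussian read
#' noise. The phase of each fiber's sarcomere train is drawn uniformly within
#' the slack left by the layout, and written back into the returned truth
#' table (`phase_um`, the axial offset of the first Z-disc from the
#' centerline start).
#'
#' @param truth Truth table from [fiber_layout()] (or same columns).
#' @param image_px Image side, pixels.
#' @param pixel_nm Pixel pitch, nm.
#' @param noise Noise level: 0 renders the noise-free analytic image; 1 (the
#'   default) applies Poisson photon noise at the nominal photon budget plus
#'   read noise; a level `v` scales the photon budget by `1/v^2` (exposure
#'   scaling), so SNR is proportional to `1/v`.
#' @param trans_sigma_um Transverse envelope sigma, um.
#' @param read_sd Read noise SD, photons, at `noise = 1`.
#' @param seed Integer seed; the render is bit-reproducible given
#'   (truth, seed).
#' @param id Image identifier string.
#' @return A list with `image` (an `shgm_image`) and `truth` (the input truth
#'   table with `phase_um` filled in).
#' @export
simulate_fiber_image <- function(truth, image_px = 512L, pixel_nm = 40,
                                 noise = 1, trans_sigma_um = 0.32,
                                 read_sd = 1.5, seed = 1L,
                                 id = "sim") {
  stopifnot(pixel_nm > 0, noise >= 0, nrow(truth) >= 1)
  px_um <- pixel_nm / 1000
  n <- as.integer(image_px)
  if (any(truth$x0 < 0 | truth$x1 > n - 1 | truth$y0 < 0 | truth$y1 > n - 1 |
          truth$x1 < 0 | truth$x0 > n - 1 | truth$y1 < 0 | truth$y0 > n - 1)) {
    stop("fiber centerline outside image bounds", call. = FALSE)
  }
  set.seed(as.integer(seed))
  sig_t_px <- trans_sigma_um / px_um

  # pixel center coordinates, 0-based: x = column, y = row
  xs <- matrix(rep(0:(n - 1), each = n), nrow = n)   # [row, col] = col index
  ys <- matrix(rep(0:(n - 1), times = n), nrow = n)  # [row, col] = row index

  clean <- matrix(0, n, n)
  phases <- numeric(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    f <- truth[i, ]
    theta <- f$orientation_deg * pi / 180
    ux <- cos(theta); uy <- sin(theta)
    chord_px <- sqrt((f$x1 - f$x0)^2 + (f$y1 - f$y0)^2)
    chord_um <- chord_px * px_um
    train_um <- f$n_sarcomeres * f$sl_um
    slack <- chord_um - train_um
    phase <- runif(1, 0, min(f$sl_um, slack))
    phases[i] <- phase

    # axial/transverse coordinates of every pixel relative to centerline start
    dx <- xs - f$x0; dy <- ys - f$y0
    ucoord <- (dx * ux + dy * uy) * px_um           # um along fiber
    vcoord <- (-dx * uy + dy * ux)                  # px across fiber
    band <- abs(vcoord) < 4 * sig_t_px
    idx <- which(band)
    if (!length(idx)) next

    # tabulated axial pattern, 2 nm grid, linear interpolation (max error
    # ~3e-4 of peak amplitude relative to the analytic profile)
    sgrid <- seq(phase - 4 * f$ttil_um, phase + train_um + 4 * f$ttil_um,
                 by = 0.002)
    pat <- axial_profile(sgrid, f$sl_um, f$abl_um, f$ttil_um,
                         f$n_sarcomeres, start_um = phase)
    pfun <- approxfun(sgrid, pat, yleft = 0, yright = 0)
    ax <- pfun(ucoord[idx])
    ax[is.na(ax)] <- 0
    env <- exp(-vcoord[idx]^2 / (2 * sig_t_px^2))
    clean[idx] <- clean[idx] + f$contrast * env * ax
  }
  clean <- clean + truth$background[1]

  if (noise > 0) {
    counts <- rpois(length(clean), clean / noise^2) * noise^2
    img <- counts + rnorm(length(clean), 0, read_sd * noise)
    img <- matrix(pmax(img, 0), n, n)
  } else {
    img <- clean
  }
  truth$phase_um <- phases
  list(image = shgm_image(img, pixel_nm = pixel_nm, id = id),
       truth = truth)
}

#' True centerline points of a fiber
#'
#' @param fiber One row of a truth table.
#' @param step_px Sampling step along the centerline, px.
#' @return Matrix with columns `x`, `y` (0-based pixel coordinates).
#' @export
truth_centerline <- function(fiber, step_px = 1) {
  len <- sqrt((fiber$x1 - fiber$x0)^2 + (fiber$y1 - fiber$y0)^2)
  t <- seq(0, len, by = step_px)
  cbind(x = fiber$x0 + t / len * (fiber$x1 - fiber$x0),
        y = fiber$y0 + t / len * (fiber$y1 - fiber$y0))
}

#' Specify a paired synthetic study cohort
#'
#' Describes a two-group (control vs IUGR), paired cohort of hearts for one
#' age stage, in terms of heart-level distributions of SL, the SL/ABL ratio
#' and TTIL. ABL is derived per heart as `SL / ratio`: in the real data SL and
#' ABL are tightly coupled across hearts (per-heart ratio SD is an order of
#' magnitude smaller than independent draws would give), and the generator
#' reproduces that coupling. Pairing is modelled by a litter effect shared by
#' the two hearts of a pair, giving a between-pair correlation `pair_cor`.
#'
#' @param groups Data frame with one row per group and columns `group`
#'   (`"control"`/`"iugr"`), `sl_mean`, `sl_sd`, `ratio_mean`, `ratio_sd`,
#'   `ttil_mean`, `ttil_sd` (lengths um). See [reference_cohorts()].
#' @param age Age label (`"fetal"` or `"adult"`).
#' @param n_hearts Hearts per group; hearts are paired 1:1 across groups.
#' @param images_per_heart Images rendered per heart.
#' @param fibers_per_image Fibers per image.
#' @param image_px,pixel_nm,noise Imaging parameters, see
#'   [simulate_fiber_image()].
#' @param orientation_deg Fiber orientation, degrees.
#' @param within_sd Named numeric: fiber-to-fiber SDs within a heart for
#'   `sl` (um), `ratio` (dimensionless) and `ttil` (um).
#' @param pair_cor Correlation between paired hearts induced by the shared
#'   litter effect, in `[0, 1)`.
#' @param match_moments If `TRUE` (default), the drawn heart-level values are
#'   affinely standardised so that each group's sample mean and SD equal the
#'   specified ones exactly -- i.e. the cohort is conditioned on the group
#'   summary statistics, which is the right conditioning when the target of a
#'   recovery experiment is the group mean itself. Set `FALSE` to study
#'   sampling variation (e.g. power).
#' @param seed Integer RNG seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, age = "fetal",
                        n_hearts = 7L, images_per_heart = 3L,
                        fibers_per_image = 8L,
                        image_px = 512L, pixel_nm = 40, noise = 1,
                        orientation_deg = 45,
                        within_sd = c(sl = 0.05, ratio = 0.05, ttil = 0.004),
                        pair_cor = 0.5, match_moments = TRUE, seed = 1L) {
  groups <- tibble::as_tibble(groups)
  need <- c("group", "sl_mean", "sl_sd", "ratio_mean", "ratio_sd",
            "ttil_mean", "ttil_sd")
  if (!all(need %in% names(groups))) {
    stop("groups must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(n_hearts >= 1, images_per_heart >= 1, fibers_per_image >= 1,
            pair_cor >= 0, pair_cor < 1,
            all(groups$sl_sd >= 0), all(groups$ratio_sd >= 0),
            all(groups$ttil_sd >= 0),
            all(c("sl", "ratio", "ttil") %in% names(within_sd)),
            all(within_sd >= 0))
  structure(
    list(groups = groups, age = age, n_hearts = as.integer(n_hearts),
         images_per_heart = as.integer(images_per_heart),
         fibers_per_image = as.integer(fibers_per_image),
         image_px = as.integer(image_px), pixel_nm = pixel_nm, noise = noise,
         orientation_deg = orientation_deg, within_sd = within_sd,
         pair_cor = pair_cor, match_moments = isTRUE(match_moments),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Cohort spec from the reference configurations
#'
#' @param age `"fetal"` or `"adult"`.
#' @param groups Which groups to include (default both).
#' @param ... Passed on to [cohort_spec()].
#' @export
cohort_spec_from_reference <- function(age = c("fetal", "adult"),
                                       groups = c("control", "iugr"), ...) {
  age <- match.arg(age)
  ref <- reference_cohorts()
  g <- ref[ref$age == age & ref$group %in% groups, ]
  cohort_spec(groups = g, age = age, ...)
}

draw_moment_matched <- function(n, mean, sd, z_pair, pair_cor, match) {
  e <- rnorm(n)
  x <- sqrt(pair_cor) * z_pair + sqrt(1 - pair_cor) * e
  if (match && n >= 2 && sd > 0) {
    x <- (x - mean(x)) / sd(x)          # exact sample moments
  }
  mean + sd * x
}

#' Simulate a paired study cohort
#'
#' Draws heart-level true sarcomere parameters from the group distributions
#' of a [cohort_spec()] (with the litter-effect pairing and optional moment
#' matching described there), jitters fiber-level parameters around the heart
#' means, and optionally renders every image. Any drawn parameter set that
#' violates the sarcomere invariants is redrawn (at most 100 times, then an
#' error). Fully reproducible given the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @param render If `TRUE`, render images; if `FALSE`, return ground truth
#'   only (fast; useful for statistical studies that do not need pixels).
#' @return A list with `spec`, `hearts` (heart-level truth tibble), `fibers`
#'   (fiber-level truth tibble with heart/image metadata), `manifest`
#'   (image-level metadata) and, if rendered, `images` (named list of
#'   `shgm_image` keyed by `image_id`).
#' @export
simulate_cohort <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  ng <- nrow(spec$groups)
  n <- spec$n_hearts

  z_pair <- rnorm(n)  # litter effects shared across groups within a pair
  hearts <- dplyr::bind_rows(lapply(seq_len(ng), function(gi) {
    g <- spec$groups[gi, ]
    redraw <- 0L
    repeat {
      sl <- draw_moment_matched(n, g$sl_mean, g$sl_sd, z_pair,
                                spec$pair_cor, spec$match_moments)
      ratio <- draw_moment_matched(n, g$ratio_mean, g$ratio_sd, z_pair,
                                   spec$pair_cor, spec$match_moments)
      ttil <- draw_moment_matched(n, g$ttil_mean, g$ttil_sd, z_pair,
                                  spec$pair_cor, spec$match_moments)
      abl <- sl / ratio
      if (all(valid_sarcomere_params(sl, abl, ttil))) break
      redraw <- redraw + 1L
      if (redraw > 100L) {
        stop("could not draw valid heart parameters for group ", g$group,
             call. = FALSE)
      }
    }
    tibble::tibble(
      heart_id = sprintf("%s_%s_h%02d", spec$age, g$group, seq_len(n)),
      group = g$group, age = spec$age, pair_id = seq_len(n),
      sl_um = sl, abl_um = abl, ttil_um = ttil, ratio = ratio,
      ttil_true = ttil
    )
  }))
  hearts$ttil_true <- NULL

  n_images <- nrow(hearts) * spec$images_per_heart
  render_seeds <- sample.int(.Machine$integer.max - 1L, n_images)

  fibers <- list(); manifest <- list(); images <- list()
  img_i <- 0L
  for (h in seq_len(nrow(hearts))) {
    hr <- hearts[h, ]
    for (im in seq_len(spec$images_per_heart)) {
      img_i <- img_i + 1L
      image_id <- sprintf("%s_img%d", hr$heart_id, im)
      nf <- spec$fibers_per_image
      redraw <- 0L
      repeat {
        sl <- rnorm(nf, hr$sl_um, spec$within_sd[["sl"]])
        ratio <- rnorm(nf, hr$ratio, spec$within_sd[["ratio"]])
        ttil <- rnorm(nf, hr$ttil_um, spec$within_sd[["ttil"]])
        abl <- sl / ratio
        ok <- valid_sarcomere_params(sl, abl, ttil)
        if (all(ok)) break
        redraw <- redraw + 1L
        if (redraw > 100L) {
          stop("could not draw valid fiber parameters for ", image_id,
               call. = FALSE)
        }
      }
      truth <- fiber_layout(nf,
                            tibble::tibble(sl_um = sl, abl_um = abl,
                                           ttil_um = ttil),
                            orientation_deg = spec$orientation_deg,
                            image_px = spec$image_px,
                            pixel_nm = spec$pixel_nm)
      if (render) {
        sim <- simulate_fiber_image(truth, image_px = spec$image_px,
                                    pixel_nm = spec$pixel_nm,
                                    noise = spec$noise,
                                    seed = render_seeds[img_i],
                                    id = image_id)
        truth <- sim$truth
        images[[image_id]] <- sim$image
      }
      truth$image_id <- image_id
      truth$heart_id <- hr$heart_id
      truth$group <- hr$group
      truth$age <- hr$age
      truth$pair_id <- hr$pair_id
      fibers[[img_i]] <- truth
      manifest[[img_i]] <- tibble::tibble(
        image_id = image_id, heart_id = hr$heart_id, group = hr$group,
        age = hr$age, pair_id = hr$pair_id
      )
    }
  }
  out <- list(spec = spec, hearts = hearts,
              fibers = dplyr::bind_rows(fibers),
              manifest = dplyr::bind_rows(manifest))
  if (render) out$images <- images
  out
}

#' Simulate a ranked gene list with an embedded enriched block
#'
#' Generates a list of `n_genes` genes ordered by a simulated
#' differential-expression statistic (most up-regulated first), in which a
#' chosen annotation term (default the sarcomeric M-band, GO:0031430) labels a
#' fraction `frac_up` of the top half of the list and `frac_down` of the
#' bottom half (rounded to counts), emulating an expression block
#' concentrated among up-regulated genes. A small built-in GO-style DAG
#' ([mband_dag()]) is attached, and a few sibling terms annotate genes at a
#' rank-independent rate for realism.
#'
#' @param n_genes List length; must be large enough for the rounded counts to
#'   realise both fractions.
#' @param block_term Term id carrying the enrichment block.
#' @param frac_up,frac_down Annotated fraction of the top and bottom half;
#'   `0 <= frac_down <= frac_up <= 1`.
#' @param null_frac Rank-independent annotation rate of the sibling terms.
#' @param seed Integer RNG seed.
#' @return A list with `ranked` (tibble `gene_id`, `stat`, `rank`),
#'   `annotations` (tibble `gene_id`, `term_id`; direct, unpropagated) and
#'   `dag` (tibble `child`, `parent`).
#' @export
simulate_ranked_list <- function(n_genes, block_term = "GO:0031430",
                                 frac_up = 0.016, frac_down = 0.0069,
                                 null_frac = 0.05, seed = 1L) {
  stopifnot(n_genes >= 2, frac_down >= 0, frac_up <= 1)
  if (frac_down > frac_up) {
    stop("frac_down must not exceed frac_up", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n_half <- floor(n_genes / 2)
  k_up <- round(frac_up * n_half)
  k_down <- round(frac_down * n_half)
  if ((frac_up > 0 && k_up == 0) || (frac_down > 0 && k_down == 0)) {
    stop("n_genes too small to realise the annotation fractions",
         call. = FALSE)
  }
  gene_id <- sprintf("g%05d", seq_len(n_genes))
  stat <- sort(rnorm(n_genes, 0, 0.3), decreasing = TRUE)
  ranked <- tibble::tibble(gene_id = gene_id, stat = stat,
                           rank = seq_len(n_genes))

  top <- gene_id[seq_len(n_half)]
  bottom <- gene_id[(n_genes - n_half + 1):n_genes]
  ann <- list(tibble::tibble(
    gene_id = c(sample(top, k_up), sample(bottom, k_down)),
    term_id = block_term
  ))
  dag <- mband_dag()
  sibs <- setdiff(setdiff(dag$child, dag$parent), block_term)
  for (s in sibs) {
    k <- round(null_frac * n_genes)
    if (k > 0) {
      ann[[length(ann) + 1]] <- tibble::tibble(
        gene_id = sample(gene_id, k), term_id = s
      )
    }
  }
  list(ranked = ranked,
       annotations = dplyr::distinct(dplyr::bind_rows(ann)),
       dag = dag)
}

#' Built-in miniature GO cellular-component DAG
#'
#' A small child-to-parent edge list covering the ancestry of the sarcomeric
#' M-band term (GO:0031430) up to the cellular_component root, plus its
#' sarcomere sibling terms (Z disc, A band, I band). Term ids follow the Gene
#' Ontology; the edge list is a simplified subset for testing and simulation.
#'
#' @return Tibble with columns `child`, `parent`.
#' @export
mband_dag <- function() {
  tibble::tribble(
    ~child,        ~parent,
    "GO:0031430",  "GO:0030017",  # M band -> sarcomere
    "GO:0030018",  "GO:0030017",  # Z disc -> sarcomere
    "GO:0031672",  "GO:0030017",  # A band -> sarcomere
    "GO:0031674",  "GO:0030017",  # I band -> sarcomere
    "GO:0030017",  "GO:0030016",  # sarcomere -> myofibril
    "GO:0030016",  "GO:0043292",  # myofibril -> contractile fiber
    "GO:0043292",  "GO:0099512",  # contractile fiber -> supramolecular fiber
    "GO:0099512",  "GO:0099081",  # -> supramolecular polymer
    "GO:0099081",  "GO:0099080",  # -> supramolecular complex
    "GO:0099080",  "GO:0110165",  # -> cellular anatomical entity
    "GO:0110165",  "GO:0005575"   # -> cellular_component (root)
  )
}
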