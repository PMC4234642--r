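# Bilinear sampling of a matrix at continuous 0-based (x, y); clamped at the
# borders. x indexes columns, y indexes rows.
sample_bilinear <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x <- clamp(x, 0, nc - 1); y <- clamp(y, 0, nr - 1)
  x0 <- clamp(floor(x), 0, nc - 2); y0 <- clamp(floor(y), 0, nr - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0) * nr + y0 + 1
  v00 <- m[i00];        v01 <- m[i00 + nr]
  v10 <- m[i00 + 1];    v11 <- m[i00 + nr + 1]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

catmull_rom_w <- function(t) {
  # weights for taps at offsets -1, 0, 1, 2; interpolating, zero second moment
  t2 <- t * t; t3 <- t2 * t
  cbind(
    0.5 * (-t + 2 * t2 - t3),
    0.5 * (2 - 5 * t2 + 3 * t3),
    0.5 * (t + 4 * t2 - 3 * t3),
    0.5 * (-t2 + t3)
  )
}

# Separable Catmull-Rom (cubic) sampling; preserves peak widths to second
# order, unlike bilinear which blurs by ~pitch^2/6 per axis.
sample_cubic <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x <- clamp(x, 0, nc - 1); y <- clamp(y, 0, nr - 1)
  x0 <- floor(x); y0 <- floor(y)
  wx <- catmull_rom_w(x - x0); wy <- catmull_rom_w(y - y0)
  out <- numeric(length(x))
  for (dj in -1:2) {
    cx <- clamp(x0 + dj, 0, nc - 1)
    rowacc <- numeric(length(x))
    for (di in -1:2) {
      cy <- clamp(y0 + di, 0, nr - 1)
      rowacc <- rowacc + wy[, di + 2] * m[cx * nr + cy + 1]
    }
    out <- out + wx[, dj + 2] * rowacc
  }
  out
}

#' Striation-free fiber envelope of an image
#'
#' Smooths the image with an anisotropic Gaussian aligned with the dominant
#' fiber orientation: a long axial sigma (about one sarcomere period, which
#' suppresses the striation harmonics by ~1e-3) and a short transverse sigma
#' (keeping neighboring fibers separated). The result is a smooth ridge map
#' whose crests are the fiber centerlines; the tracer marches along these
#' crests.
#'
#' @param image An `shgm_image`.
#' @param field Orientation field from [estimate_orientation()].
#' @param axial_sigma_um Axial smoothing sigma, um.
#' @param trans_sigma_px Transverse smoothing sigma, px.
#' @return List with `envelope` matrix and the `theta_deg` used.
#' @keywords internal
fiber_envelope <- function(image, field, axial_sigma_um = 1.0,
                           trans_sigma_px = 2) {
  theta <- dominant_angle(field)
  if (is.na(theta)) theta <- 0
  th <- theta * pi / 180
  sa <- axial_sigma_um * 1000 / image$pixel_nm
  st <- trans_sigma_px
  r <- min(ceiling(2.5 * sa),
           floor((min(dim(image$intensity)) - 1) / 2))
  g <- seq(-r, r)
  xg <- matrix(rep(g, each = length(g)), length(g))   # column offset
  yg <- matrix(rep(g, times = length(g)), length(g))  # row offset
  uu <- xg * cos(th) + yg * sin(th)
  vv <- -xg * sin(th) + yg * cos(th)
  k <- exp(-(uu^2 / (2 * sa^2) + vv^2 / (2 * st^2)))
  k <- k / sum(k)
  list(envelope = EBImage::filter2(image$intensity, k, boundary = "replicate"),
       theta_deg = theta)
}

march_trace <- function(env, field, start, coh_min, e_stop, margin = 2) {
  nr <- nrow(env); nc <- ncol(env)
  step_dir <- function(pos, prev_u) {
    cx <- as.integer(round(pos[1])) + 1L; cy <- as.integer(round(pos[2])) + 1L
    if (cx < 1L || cx > nc || cy < 1L || cy > nr) return(NULL)
    if (field$coherence[cy, cx] < coh_min) return(NULL)
    a <- field$angle_deg[cy, cx]
    if (is.na(a)) return(NULL)
    u <- c(cos(a * pi / 180), sin(a * pi / 180))
    if (!is.null(prev_u) && sum(u * prev_u) < 0) u <- -u
    u
  }
  walk <- function(u0) {
    pts <- list(); pos <- start; u <- u0
    for (i in seq_len(2L * (nr + nc))) {
      u <- step_dir(pos, u)
      if (is.null(u)) break
      cand <- pos + u
      if (cand[1] < margin || cand[1] > nc - 1 - margin ||
          cand[2] < margin || cand[2] > nr - 1 - margin) break
      # re-center on the envelope crest
      v <- c(-u[2], u[1])
      w <- -3:3
      vals <- sample_bilinear(env, cand[1] + w * v[1], cand[2] + w * v[2])
      wts <- vals - min(vals)
      shift <- if (sum(wts) > 0) clamp(sum(w * wts) / sum(wts), -1, 1) else 0
      cand <- cand + shift * v
      if (sample_bilinear(env, cand[1], cand[2]) < e_stop) break
      pts[[length(pts) + 1L]] <- cand
      pos <- cand
    }
    if (length(pts)) do.call(rbind, pts) else NULL
  }
  u0 <- step_dir(start, NULL)
  if (is.null(u0)) return(NULL)
  fwd <- walk(u0)
  bwd <- walk(-u0)
  pts <- rbind(if (!is.null(bwd)) bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
               matrix(start, 1), fwd)
  pts
}

#' Trace fibers along the orientation field
#'
#' Seeds are local crests of the striation-free envelope (see
#' [fiber_envelope()]) inside the coherent region; from each unclaimed seed,
#' the tracer marches in 1 px steps along the local fiber-axis angle in both
#' directions, re-centering on the envelope crest at every step, and stops at
#' low coherence, low envelope (below a fraction of the seed value), or the
#' image border. Traces shorter than the minimum fiber length
#' (`min_fiber_periods * expected_sl_um`) are discarded; overlapping traces
#' of the same ridge are deduplicated keeping the longer one. Tracing is
#' deterministic (no RNG).
#'
#' @param image An `shgm_image`.
#' @param field Matching orientation field.
#' @param config A [sarcomorph_config()].
#' @return A list of traces; each is a list with `points` (matrix, columns
#'   x, y, 0-based pixel coordinates at ~1 px arc spacing), `length_um` and
#'   `image_id`. Empty list if no coherent region exists.
#' @export
trace_fibers <- function(image, field, config = sarcomorph_config()) {
  stopifnot(inherits(image, "shgm_image"),
            inherits(field, "orientation_field"))
  nr <- nrow(image$intensity); nc <- ncol(image$intensity)
  fe <- fiber_envelope(image, field,
                       axial_sigma_um = 0.6 * config$expected_sl_um)
  env <- fe$envelope
  px_um <- image$pixel_nm / 1000
  min_len_px <- config$min_fiber_periods * config$expected_sl_um / px_um

  q <- quantile(env, c(0.10, 0.99))
  e_floor <- q[1] + 0.25 * (q[2] - q[1])
  if (q[2] - q[1] < 1e-9) return(list())  # flat envelope: nothing to trace

  th <- fe$theta_deg * pi / 180
  vperp <- c(-sin(th), cos(th))
  ok <- field$coherence >= max(config$coherence_min, 0.3) & env >= e_floor
  idx <- which(ok)
  if (!length(idx)) return(list())
  ys <- (idx - 1L) %% nr; xs <- (idx - 1L) %/% nr
  # ridge test: envelope higher than both perpendicular neighbours
  e0 <- env[idx]
  ep <- sample_bilinear(env, xs + 1.2 * vperp[1], ys + 1.2 * vperp[2])
  em <- sample_bilinear(env, xs - 1.2 * vperp[1], ys - 1.2 * vperp[2])
  ridge <- e0 >= ep & e0 >= em
  xs <- xs[ridge]; ys <- ys[ridge]; e0 <- e0[ridge]
  if (!length(xs)) return(list())
  ord <- order(e0, decreasing = TRUE)
  xs <- xs[ord]; ys <- ys[ord]; e0 <- e0[ord]

  claimed <- matrix(FALSE, nr, nc)
  claim <- function(pts, radius = 4L) {
    for (i in seq_len(nrow(pts))) {
      x <- as.integer(round(pts[i, 1])); y <- as.integer(round(pts[i, 2]))
      xr <- max(1L, x + 1L - radius):min(nc, x + 1L + radius)
      yr <- max(1L, y + 1L - radius):min(nr, y + 1L + radius)
      claimed[yr, xr] <<- TRUE
    }
  }

  traces <- list()
  bg <- q[1]
  for (i in seq_along(xs)) {
    if (claimed[ys[i] + 1L, xs[i] + 1L]) next
    seed <- c(xs[i], ys[i])
    e_seed <- e0[i]
    e_stop <- bg + 0.25 * (e_seed - bg)
    pts <- march_trace(env, field, seed, config$coherence_min, e_stop)
    if (is.null(pts)) { claim(matrix(seed, 1)); next }
    claim(pts)
    if (nrow(pts) < 2) next
    seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                            pts[-nrow(pts), , drop = FALSE])^2))
    len_px <- sum(seglen)
    if (len_px < min_len_px) next
    traces[[length(traces) + 1L]] <- list(
      points = pts, length_um = len_px * px_um, image_id = image$id
    )
  }
  # dedup: keep longer of any pair of traces sharing > 50% of points
  if (length(traces) > 1L) {
    lens <- vapply(traces, function(t) t$length_um, 0)
    ord <- order(lens, decreasing = TRUE)
    kept <- list(); mask <- matrix(FALSE, nr, nc)
    for (j in ord) {
      pts <- traces[[j]]$points
      xi <- clamp(as.integer(round(pts[, 1])) + 1L, 1L, nc)
      yi <- clamp(as.integer(round(pts[, 2])) + 1L, 1L, nr)
      overlap <- mean(mask[cbind(yi, xi)])
      if (overlap <= 0.5) {
        kept[[length(kept) + 1L]] <- traces[[j]]
        for (i in seq_along(xi)) {
          xr <- max(1L, xi[i] - 3L):min(nc, xi[i] + 3L)
          yr <- max(1L, yi[i] - 3L):min(nr, yi[i] + 3L)
          mask[yr, xr] <- TRUE
        }
      }
    }
    traces <- kept
  }
  traces
}

#' Flatten traces to an audit table
#'
#' @param traces List from [trace_fibers()].
#' @return Tibble with columns `trace_id`, `idx`, `x`, `y`.
#' @export
traces_to_df <- function(traces) {
  dplyr::bind_rows(lapply(seq_along(traces), function(i) {
    p <- traces[[i]]$points
    tibble::tibble(trace_id = i, idx = seq_len(nrow(p)),
                   x = p[, 1], y = p[, 2])
  }))
}

#' Extract the 1-D intensity profile along a fiber trace
#'
#' The trace is resampled at a constant arc-length pitch equal to the pixel
#' pitch, and the image is sampled at each resampled point, averaged over
#' `2 * halfwidth + 1` transverse offsets (1 px apart, perpendicular to the
#' local trace direction) to boost SNR. Sampling uses Catmull-Rom cubic
#' interpolation by default, which preserves peak widths; `"bilinear"` is
#' available as an option.
#'
#' @param image An `shgm_image`.
#' @param trace One trace from [trace_fibers()], or a 2-column matrix of
#'   0-based (x, y) points.
#' @param halfwidth_px Transverse averaging half-width, px.
#' @param method `"cubic"` or `"bilinear"`.
#' @param min_samples Minimum number of resampled points; shorter traces are
#'   an error.
#' @return A list of class `intensity_profile` with `samples`, `spacing_nm`
#'   and `n`.
#' @export
extract_profile <- function(image, trace, halfwidth_px = 3L,
                            method = c("cubic", "bilinear"),
                            min_samples = 32L) {
  stopifnot(inherits(image, "shgm_image"))
  method <- match.arg(method)
  pts <- if (is.list(trace) && !is.null(trace$points)) trace$points else trace
  stopifnot(is.matrix(pts), ncol(pts) == 2)
  nr <- nrow(image$intensity); nc <- ncol(image$intensity)
  if (any(pts[, 1] < 0 | pts[, 1] > nc - 1 | pts[, 2] < 0 | pts[, 2] > nr - 1)) {
    stop("trace extends outside image bounds", call. = FALSE)
  }

  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  s_grid <- seq(0, s[length(s)], by = 1)  # 1 px pitch
  if (length(s_grid) < min_samples) {
    stop("trace too short to extract a profile", call. = FALSE)
  }
  xg <- stats::approx(s, pts[, 1], xout = s_grid)$y
  yg <- stats::approx(s, pts[, 2], xout = s_grid)$y

  # local tangent by central differences of the resampled points
  n <- length(s_grid)
  tx <- c(xg[2] - xg[1], (xg[-(1:2)] - xg[-((n - 1):n)]) / 2,
          xg[n] - xg[n - 1])
  ty <- c(yg[2] - yg[1], (yg[-(1:2)] - yg[-((n - 1):n)]) / 2,
          yg[n] - yg[n - 1])
  nrm <- sqrt(tx^2 + ty^2); nrm[nrm == 0] <- 1
  px <- -ty / nrm; py <- tx / nrm

  hw <- as.integer(halfwidth_px)
  offs <- (-hw):hw
  sampler <- if (method == "cubic") sample_cubic else sample_bilinear
  acc <- numeric(n)
  for (w in offs) {
    acc <- acc + sampler(image$intensity, xg + w * px, yg + w * py)
  }
  structure(list(samples = acc / length(offs),
                 spacing_nm = image$pixel_nm, n = n),
            class = "intensity_profile")
}

#' Match traces to ground-truth fibers
#'
#' Assigns each trace to the closest truth centerline by mean point-to-line
#' distance (the simulator's fibers are straight, so the perpendicular
#' distance to the infinite line through the truth endpoints is used), then
#' resolves conflicts greedily by distance so that each truth fiber is
#' claimed at most once.
#'
#' @param traces List from [trace_fibers()].
#' @param truth Truth table from the simulator.
#' @return Tibble with `trace_id`, `fiber_id`, `mean_dist_px`.
#' @export
match_traces <- function(traces, truth) {
  if (!length(traces)) {
    return(tibble::tibble(trace_id = integer(), fiber_id = integer(),
                          mean_dist_px = numeric()))
  }
  d <- matrix(Inf, length(traces), nrow(truth))
  for (j in seq_len(nrow(truth))) {
    f <- truth[j, ]
    ex <- f$x1 - f$x0; ey <- f$y1 - f$y0
    len <- sqrt(ex^2 + ey^2); ex <- ex / len; ey <- ey / len
    for (i in seq_along(traces)) {
      p <- traces[[i]]$points
      d[i, j] <- mean(abs(-(p[, 1] - f$x0) * ey + (p[, 2] - f$y0) * ex))
    }
  }
  out <- list()
  free_t <- rep(TRUE, length(traces)); free_f <- rep(TRUE, nrow(truth))
  repeat {
    dd <- d; dd[!free_t, ] <- Inf; dd[, !free_f] <- Inf
    if (!any(is.finite(dd))) break
    ij <- arrayInd(which.min(dd), dim(dd))
    out[[length(out) + 1L]] <- tibble::tibble(
      trace_id = ij[1], fiber_id = truth$fiber_id[ij[2]],
      mean_dist_px = d[ij[1], ij[2]]
    )
    free_t[ij[1]] <- FALSE; free_f[ij[2]] <- FALSE
  }
  dplyr::bind_rows(out)
}
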