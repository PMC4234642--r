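gaussian_kernel_1d <- function(sigma, radius = ceiling(3.5 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_kernel_2d <- function(sigma, radius = ceiling(3.5 * sigma)) {
  k <- gaussian_kernel_1d(sigma, radius)
  outer(k, k)
}

# FFT convolution with replicated borders (EBImage)
smooth2 <- function(x, sigma, radius = ceiling(3.5 * sigma)) {
  EBImage::filter2(x, gaussian_kernel_2d(sigma, radius),
                   boundary = "replicate")
}

# central-difference gradients with replicated edges; x = columns, y = rows
image_gradients <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  xr <- m[, c(2:nc, nc)]; xl <- m[, c(1, 1:(nc - 1))]
  yd <- m[c(2:nr, nr), ]; yu <- m[c(1, 1:(nr - 1)), ]
  list(gx = (xr - xl) / 2, gy = (yd - yu) / 2)
}

#' Estimate the local fiber orientation field of a striation image
#'
#' Structure-tensor orientation estimation: image gradients are computed with
#' central differences after a light pre-smoothing, the tensor components
#' (gx^2, gx*gy, gy^2) are averaged over a Gaussian window of physical scale
#' `scale_nm`, and the per-pixel dominant orientation and coherence are read
#' off the tensor. Striations run perpendicular to the fiber axis, so the
#' dominant gradient-energy direction *is* the fiber axis.
#'
#' Angles are degrees counterclockwise from the image x axis (columns),
#' wrapped to `[0, 180)`. Coherence is `(l1 - l2) / (l1 + l2)` of the tensor
#' eigenvalues, in `[0, 1]`, and set to 0 (angle `NA`) where the neighborhood
#' carries no gradient energy -- a constant image yields coherence 0
#' everywhere.
#'
#' @param image An `shgm_image`.
#' @param scale_nm Integration window sigma, nm; must be at least twice the
#'   pixel pitch. Default 400 nm (10 px at 40 nm/px).
#' @param presmooth_px Pre-smoothing sigma, px.
#' @return A list of class `orientation_field` with matrices `angle_deg`
#'   (`NA` where undefined) and `coherence`, plus `pixel_nm`.
#' @export
estimate_orientation <- function(image, scale_nm = 400, presmooth_px = 1) {
  stopifnot(inherits(image, "shgm_image"))
  if (scale_nm < 2 * image$pixel_nm) {
    stop("scale_nm must be at least twice the pixel pitch", call. = FALSE)
  }
  m <- image$intensity
  if (presmooth_px > 0) m <- smooth2(m, presmooth_px)
  g <- image_gradients(m)
  sigma_w <- scale_nm / image$pixel_nm
  j11 <- smooth2(g$gx * g$gx, sigma_w)
  j12 <- smooth2(g$gx * g$gy, sigma_w)
  j22 <- smooth2(g$gy * g$gy, sigma_w)

  tr <- j11 + j22
  disc <- sqrt((j11 - j22)^2 + 4 * j12^2)
  eps <- 1e-12 * max(tr, 1e-300)
  coherence <- ifelse(tr > eps, disc / tr, 0)
  angle <- 0.5 * atan2(2 * j12, j11 - j22) * 180 / pi
  angle <- angle %% 180
  angle[tr <= eps | coherence <= 0] <- NA_real_
  structure(list(angle_deg = angle, coherence = coherence,
                 pixel_nm = image$pixel_nm),
            class = "orientation_field")
}

# coherence-weighted mean orientation via the doubled-angle vector
dominant_angle <- function(field, mask = NULL) {
  a <- field$angle_deg * pi / 180
  w <- field$coherence
  if (!is.null(mask)) w <- w * mask
  w[is.na(a)] <- 0
  a[is.na(a)] <- 0
  s <- sum(w * sin(2 * a)); c <- sum(w * cos(2 * a))
  if (abs(s) < 1e-30 && abs(c) < 1e-30) return(NA_real_)
  (0.5 * atan2(s, c) * 180 / pi) %% 180
}
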