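#' SHG image container
#'
#' A minimal container for a single-channel striation image: a numeric matrix
#' of non-negative intensities (rows = image y, columns = image x) plus the
#' physical pixel pitch in nanometres.
#'
#' @param intensity Numeric matrix of finite, non-negative intensities, at
#'   least 64 x 64.
#' @param pixel_nm Pixel pitch, nm (> 0).
#' @param id Identifier string.
#' @return Object of class `shgm_image`.
#' @export
shgm_image <- function(intensity, pixel_nm, id = "image") {
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    stop("intensity must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(intensity))) {
    stop("intensities must be finite", call. = FALSE)
  }
  if (any(intensity < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (nrow(intensity) < 64 || ncol(intensity) < 64) {
    stop("image must be at least 64 x 64 pixels", call. = FALSE)
  }
  if (!is.numeric(pixel_nm) || length(pixel_nm) != 1 || pixel_nm <= 0) {
    stop("pixel_nm must be a positive scalar", call. = FALSE)
  }
  structure(list(intensity = intensity, pixel_nm = pixel_nm,
                 id = as.character(id)),
            class = "shgm_image")
}

#' @export
print.shgm_image <- function(x, ...) {
  cat(sprintf("<shgm_image '%s': %d x %d px @ %g nm/px>\n",
              x$id, nrow(x$intensity), ncol(x$intensity), x$pixel_nm))
  invisible(x)
}

#' Write an SHG image as a 16-bit single-channel TIFF
#'
#' Intensities are rounded to integer photon counts and stored as 16-bit
#' grayscale; values above 65535 are clipped. The pixel pitch is not stored in
#' the TIFF and must be supplied again on read.
#'
#' @param image An `shgm_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shgm_image <- function(image, path) {
  stopifnot(inherits(image, "shgm_image"))
  m <- clamp(round(image$intensity), 0, 65535) / 65535
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a single-channel TIFF as an SHG image
#'
#' @param path TIFF path.
#' @param pixel_nm Physical pixel pitch, nm; required (plain TIFFs carry no
#'   calibrated pitch).
#' @param id Identifier; defaults to the file name.
#' @return An `shgm_image` with intensities in native integer units
#'   (0..255 for 8-bit files, 0..65535 for 16-bit).
#' @export
read_shgm_image <- function(path, pixel_nm, id = basename(path)) {
  if (missing(pixel_nm) || is.null(pixel_nm)) {
    stop("pixel_nm must be supplied: TIFF files carry no pixel pitch",
         call. = FALSE)
  }
  a <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] == 1L) {
      a <- a[, , 1]
    } else {
      stop("multi-channel TIFF not supported: ", path, call. = FALSE)
    }
  }
  shgm_image(a * 1.0, pixel_nm = pixel_nm, id = id)
}

#' Write a table as CSV with a header
#'
#' Thin wrapper used for all audit outputs (truth tables, traces, fits, heart
#' summaries, comparisons). Column names carry unit suffixes (`_um`, `_deg`,
#' `_px`) so that re-reading reproduces the in-memory tables.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_table_csv()]
#' @param path CSV path.
#' @return A tibble.
#' @export
read_table_csv <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
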