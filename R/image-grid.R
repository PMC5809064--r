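#' 2D portal image grid
#'
#' Container for a single-channel portal (EPID) image: a signal matrix with a
#' uniform pixel spacing and a physical origin. Rows index the y (inline)
#' direction and columns the x (crossline) direction; the coordinate of pixel
#' `[i, j]` centre is `(x0 + (j-1) dx, y0 + (i-1) dy)` in mm. By convention the
#' beam central axis (CAX) projects to `(0, 0)` mm, so the default origin
#' centres the grid on the CAX.
#'
#' @param signal numeric matrix of detector signal (a.u.) or dose (cGy).
#' @param spacing_mm pixel spacing `(dx, dy)` in mm; a scalar is recycled.
#' @param origin_mm physical coordinate (mm) of the centre of pixel `[1, 1]`;
#'   `NULL` centres the grid on `(0, 0)`.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(signal, spacing_mm = 2, origin_mm = NULL) {
  signal <- as.matrix(signal)
  if (!is.numeric(signal)) stop("signal must be numeric")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 2L)
  if (any(spacing_mm <= 0)) stop("pixel spacing must be positive")
  if (is.null(origin_mm)) {
    origin_mm <- -c((ncol(signal) - 1) / 2 * spacing_mm[1],
                    (nrow(signal) - 1) / 2 * spacing_mm[2])
  }
  structure(list(signal = signal, spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid: %d x %d pixels, spacing (%g, %g) mm, origin (%g, %g) mm\n",
              nrow(x$signal), ncol(x$signal), x$spacing_mm[1], x$spacing_mm[2],
              x$origin_mm[1], x$origin_mm[2]))
  cat(sprintf("  signal range [%g, %g]\n", min(x$signal), max(x$signal)))
  invisible(x)
}

#' @export
dim.image_grid <- function(x) dim(x$signal)

# x (mm) of each column / y (mm) of each row
grid_x <- function(img) img$origin_mm[1] + (seq_len(ncol(img$signal)) - 1) * img$spacing_mm[1]
grid_y <- function(img) img$origin_mm[2] + (seq_len(nrow(img$signal)) - 1) * img$spacing_mm[2]

# full coordinate matrices matching the signal layout
grid_xy <- function(img) {
  nr <- nrow(img$signal); nc <- ncol(img$signal)
  list(x = matrix(grid_x(img), nr, nc, byrow = TRUE),
       y = matrix(grid_y(img), nr, nc))
}

#' Bilinear interpolation of an image grid
#'
#' Samples `img` at arbitrary physical coordinates. Queries outside the grid's
#' spatial support return `NA` (no extrapolation) unless `clamp = TRUE`, in
#' which case coordinates are clamped to the grid edge.
#'
#' @param img an [image_grid].
#' @param xq,yq numeric vectors/matrices of query coordinates (mm).
#' @param clamp clamp out-of-range queries to the grid boundary instead of NA.
#' @return numeric array of interpolated values, shaped like `xq`.
#' @export
interp_bilinear <- function(img, xq, yq, clamp = FALSE) {
  nr <- nrow(img$signal); nc <- ncol(img$signal)
  px <- (xq - img$origin_mm[1]) / img$spacing_mm[1] + 1
  py <- (yq - img$origin_mm[2]) / img$spacing_mm[2] + 1
  if (clamp) {
    px <- pmin(pmax(px, 1), nc)
    py <- pmin(pmax(py, 1), nr)
  }
  valid <- px >= 1 & px <= nc & py >= 1 & py <= nr
  px[!valid] <- 1; py[!valid] <- 1
  j0 <- pmin(floor(px), nc - 1L); i0 <- pmin(floor(py), nr - 1L)
  if (nc == 1L) j0[] <- 1L
  if (nr == 1L) i0[] <- 1L
  tx <- px - j0; ty <- py - i0
  s <- img$signal
  v <- (1 - tx) * (1 - ty) * s[cbind(c(i0), c(j0))] +
       tx       * (1 - ty) * s[cbind(c(i0), c(pmin(j0 + 1, nc)))] +
       (1 - tx) * ty       * s[cbind(c(pmin(i0 + 1, nr)), c(j0))] +
       tx       * ty       * s[cbind(c(pmin(i0 + 1, nr)), c(pmin(j0 + 1, nc)))]
  v[!valid] <- NA_real_
  if (is.matrix(xq)) v <- matrix(v, nrow(xq), ncol(xq))
  v
}

#' Extract an inline or crossline profile
#'
#' Returns the signal along the row (crossline, varying x) or column (inline,
#' varying y) nearest to `position_mm`, the tool used to investigate
#' off-tolerance gamma tests by overlaying reference and current profiles.
#'
#' @param image an [image_grid].
#' @param axis `"crossline"` (profile along x at fixed y) or `"inline"`
#'   (profile along y at fixed x).
#' @param position_mm fixed coordinate (mm) at which to take the profile;
#'   default 0 (through the CAX).
#' @return data.frame with columns `pos_mm` and `signal`.
#' @export
profile_extract <- function(image, axis = c("crossline", "inline"), position_mm = 0) {
  axis <- match.arg(axis)
  xs <- grid_x(image); ys <- grid_y(image)
  if (axis == "crossline") {
    if (position_mm < min(ys) - image$spacing_mm[2] / 2 ||
        position_mm > max(ys) + image$spacing_mm[2] / 2)
      stop("position outside grid")
    i <- which.min(abs(ys - position_mm))
    data.frame(pos_mm = xs, signal = image$signal[i, ])
  } else {
    if (position_mm < min(xs) - image$spacing_mm[1] / 2 ||
        position_mm > max(xs) + image$spacing_mm[1] / 2)
      stop("position outside grid")
    j <- which.min(abs(xs - position_mm))
    data.frame(pos_mm = ys, signal = image$signal[, j])
  }
}

#' Write / read a portal image as TIFF with a sidecar text header
#'
#' Images are stored as single-channel 32-bit float TIFF; the pixel spacing,
#' origin and any extra scalar metadata go to a plain-text `.hdr` sidecar
#' (`key: value` lines) so the pair round-trips without binary metadata.
#'
#' @param img an [image_grid].
#' @param path output TIFF path; the header is written to `paste0(path, ".hdr")`.
#' @param extra named list of scalar metadata to store in the header.
#' @return `path`, invisibly (`write_image`); an [image_grid] with an
#'   attribute `header` (`read_image`).
#' @export
write_image <- function(img, path, extra = list()) {
  tiff::writeTIFF(img$signal / max(abs(img$signal), 1e-300), path,
                  bits.per.sample = 32L)
  hdr <- c(list(spacing_x_mm = img$spacing_mm[1], spacing_y_mm = img$spacing_mm[2],
                origin_x_mm = img$origin_mm[1], origin_y_mm = img$origin_mm[2],
                scale = max(abs(img$signal), 1e-300)), extra)
  writeLines(sprintf("%s: %.17g", names(hdr), unlist(hdr)), paste0(path, ".hdr"))
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  s <- tiff::readTIFF(path)
  if (length(dim(s)) > 2L) s <- s[, , 1]
  lines <- readLines(paste0(path, ".hdr"))
  kv <- strsplit(lines, ": ", fixed = TRUE)
  hdr <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                         vapply(kv, `[`, "", 1L))
  img <- image_grid(s * hdr[["scale"]],
                    spacing_mm = c(hdr[["spacing_x_mm"]], hdr[["spacing_y_mm"]]),
                    origin_mm = c(hdr[["origin_x_mm"]], hdr[["origin_y_mm"]]))
  attr(img, "header") <- as.list(hdr)
  img
}
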