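# Band-localized immunofluorescence quantification for retinal sections:
# ONL normalization, background thresholding, ROI averaging along the SAC
# bands, perpendicular profiles, and central-window totals.

#' Construct a section image
#'
#' @param img Numeric matrix of intensities (rows = y, columns = x), already
#'   z-projected (see [z_project()]).
#' @param scale_um_per_px Micrometres per pixel (> 0).
#' @param onl_mask Logical matrix, same dimensions as `img`, marking the
#'   outer nuclear layer (the non-specific background region). Must be
#'   non-empty.
#' @param bands List of polylines (two-column matrices, columns x then y, in
#'   pixel coordinates) drawn along the stained band centerlines.
#' @return Object of class `section_image`.
#' @export
section_image <- function(img, scale_um_per_px, onl_mask, bands = list()) {
  stopifnot(is.matrix(img), is.numeric(img), scale_um_per_px > 0,
            is.matrix(onl_mask), identical(dim(img), dim(onl_mask)))
  if (!any(onl_mask)) stop("ONL mask is empty")
  for (b in bands) {
    stopifnot(is.matrix(b), ncol(b) == 2L)
    if (any(b[, 1L] < 1 | b[, 1L] > ncol(img) |
            b[, 2L] < 1 | b[, 2L] > nrow(img)))
      stop("band polyline outside image bounds")
  }
  structure(list(img = img, scale_um_per_px = scale_um_per_px,
                 onl_mask = onl_mask, bands = bands),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image> %d x %d px @ %.3g um/px, %d band(s)\n",
              nrow(x$img), ncol(x$img), x$scale_um_per_px, length(x$bands)))
  invisible(x)
}

#' Mean z-projection of an image stack
#'
#' @param stack 3-D numeric array (y, x, slice) or list of matrices.
#' @return Matrix: the mean across slices.
#' @export
z_project <- function(stack) {
  if (is.list(stack)) stack <- simplify2array(stack)
  if (length(dim(stack)) == 2L) return(stack)
  apply(stack, c(1L, 2L), mean)
}

#' Normalize a section image by its ONL background
#'
#' Divides all intensities by the mean intensity inside the ONL mask, so the
#' non-specific background level becomes 1. Compensates exposure differences
#' between slides.
#'
#' @param si A [section_image()].
#' @return The normalized [section_image()].
#' @export
normalize_by_onl <- function(si) {
  m <- mean(si$img[si$onl_mask])
  if (!is.finite(m) || m == 0) stop("zero ONL mean; cannot normalize")
  si$img <- si$img / m
  si
}

## bilinear interpolation; coordinates in pixels (1-based), x = column,
## y = row; NA outside the image.
.bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(NA_real_, length(x))
  ok <- x >= 1 & x <= nc & y >= 1 & y <= nr
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  fx <- x - x0; fy <- y - y0
  v <- img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1L)] * fx * (1 - fy) +
    img[cbind(y0 + 1L, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1L, x0 + 1L)] * fx * fy
  out[ok] <- v
  out
}

## threshold an ONL-normalized image by the background level: pixels at or
## below `level` are set to zero, so a pure-background region measures 0
.threshold_bg <- function(img, level = 1) {
  img[img <= level] <- 0
  img
}

## resample a polyline at a fixed arc-length step (pixels); returns points
## and unit normals
.resample_polyline <- function(poly, step_px) {
  seg <- diff(poly)
  seglen <- sqrt(rowSums(seg^2))
  arclen <- c(0, cumsum(seglen))
  total <- arclen[length(arclen)]
  s <- seq(0, total, by = step_px)
  idx <- findInterval(s, arclen, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(poly) - 1L)
  frac <- (s - arclen[idx]) / seglen[idx]
  pts <- poly[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  tang <- seg[idx, , drop = FALSE] / seglen[idx]
  normals <- cbind(-tang[, 2L], tang[, 1L])
  list(points = pts, normals = normals, total_px = total)
}

#' Perpendicular intensity profile of a band
#'
#' Samples the background-thresholded, ONL-normalized image along
#' perpendiculars to the band polyline at pixel pitch (bilinear
#' interpolation) and averages across positions along the band.
#'
#' @param si A normalized [section_image()].
#' @param band Polyline matrix, or an index into `si$bands`.
#' @param half_width_um Profile half-width in micrometres.
#' @param threshold Apply the background threshold (level 1 in ONL units)?
#' @return data.frame with columns `offset_um` and `intensity`; attribute
#'   `spacing_um` gives the sample pitch.
#' @export
band_profile <- function(si, band = 1L, half_width_um = 3,
                         threshold = TRUE) {
  poly <- if (is.matrix(band)) band else si$bands[[band]]
  img <- if (threshold) .threshold_bg(si$img) else si$img
  px <- si$scale_um_per_px
  rs <- .resample_polyline(poly, step_px = 1)
  offs_px <- seq(-half_width_um / px, half_width_um / px, by = 1)
  prof <- vapply(offs_px, function(o) {
    xs <- rs$points[, 1L] + o * rs$normals[, 1L]
    ys <- rs$points[, 2L] + o * rs$normals[, 2L]
    mean(.bilinear(img, xs, ys), na.rm = TRUE)
  }, 1)
  out <- data.frame(offset_um = offs_px * px, intensity = prof)
  attr(out, "spacing_um") <- px
  out
}

#' Mean ROI intensity along a band
#'
#' Steps a square ROI (side `roi_size_um`, non-overlapping: one ROI side per
#' step) along the band polyline, computes the mean of the
#' background-thresholded pixels inside each ROI, and averages over
#' positions. Deterministic given the step size.
#'
#' @param si A normalized [section_image()].
#' @param band Polyline matrix, or index into `si$bands`.
#' @param roi_size_um ROI side length in micrometres.
#' @return Per-section mean intensity (scalar); the per-ROI means are
#'   attached as attribute `roi_means`.
#' @export
band_roi_intensity <- function(si, band = 1L, roi_size_um = 6) {
  poly <- if (is.matrix(band)) band else si$bands[[band]]
  px <- si$scale_um_per_px
  roi_px <- roi_size_um / px
  seg <- diff(poly)
  total <- sum(sqrt(rowSums(seg^2)))
  if (total < roi_px) stop("band polyline shorter than one ROI")
  img <- .threshold_bg(si$img)
  centers <- .resample_polyline(poly, step_px = roi_px)$points
  half <- roi_px / 2
  means <- vapply(seq_len(nrow(centers)), function(i) {
    x0 <- max(1L, ceiling(centers[i, 1L] - half))
    x1 <- min(ncol(img), floor(centers[i, 1L] + half))
    y0 <- max(1L, ceiling(centers[i, 2L] - half))
    y1 <- min(nrow(img), floor(centers[i, 2L] + half))
    mean(img[y0:y1, x0:x1])
  }, 1)
  out <- mean(means)
  attr(out, "roi_means") <- means
  out
}

#' Central-window total of a band profile
#'
#' Sums the profile over the central window (default 1.1 micrometres)
#' centered on the profile maximum; the window tracks the maximum, so the
#' total is invariant to lateral shifts of the profile.
#'
#' @param profile A [band_profile()] result (or data.frame with `offset_um`
#'   and `intensity`).
#' @param window_um Window width in micrometres.
#' @return The windowed total.
#' @export
central_window_sum <- function(profile, window_um = 1.1) {
  if (!nrow(profile) || all(!is.finite(profile$intensity)))
    stop("empty profile")
  imax <- which.max(profile$intensity)
  half <- window_um / 2 + 1e-9
  inside <- abs(profile$offset_um - profile$offset_um[imax]) <= half
  sum(profile$intensity[inside])
}

#' Per-section band measure: mean central-window total across bands
#'
#' Convenience wrapper: normalizes by the ONL, profiles each band, and
#' averages the central-window totals across the section's bands.
#'
#' @param si A raw (un-normalized) [section_image()] with bands attached.
#' @param window_um Central window width in micrometres.
#' @param half_width_um Profile half-width.
#' @return Scalar per-section measure.
#' @export
section_band_measure <- function(si, window_um = 1.1, half_width_um = 3) {
  nsi <- normalize_by_onl(si)
  totals <- vapply(seq_along(nsi$bands), function(b)
    central_window_sum(band_profile(nsi, b, half_width_um), window_um), 1)
  mean(totals)
}

#' Per-retina summary across sections
#'
#' Simple mean of 1 to 4 (or more) per-section values.
#'
#' @param values Numeric vector of per-section values.
#' @return Scalar mean.
#' @export
summarize_retina <- function(values) {
  if (!length(values)) stop("no sections for this retina")
  mean(values)
}

#' Two-stage cohort normalization
#'
#' First the average value of all samples on each slide is normalized to 1,
#' then the average of each WT/KO pair is normalized to 1, reducing
#' slide-to-slide and pair-to-pair experimental variation.
#'
#' @param df data.frame with columns `slide`, `pair`, and `value`.
#' @return The input with a `normalized` column appended.
#' @export
normalize_cohort <- function(df) {
  stopifnot(all(c("slide", "pair", "value") %in% names(df)))
  if (!nrow(df)) stop("empty group")
  slide_mean <- stats::ave(df$value, df$slide, FUN = mean)
  if (any(slide_mean == 0)) stop("slide with zero mean intensity")
  v1 <- df$value / slide_mean
  pair_mean <- stats::ave(v1, df$pair, FUN = mean)
  if (any(pair_mean == 0)) stop("pair with zero mean intensity")
  df$normalized <- v1 / pair_mean
  df
}

# ---------------------------------------------------------------------------
# IO: TIFF images and geometry sidecars
# ---------------------------------------------------------------------------

#' Write / read a section image as 16-bit TIFF plus a JSON geometry sidecar
#'
#' Intensities are stored as 16-bit gray (counts up to 65535); the sidecar
#' carries the pixel scale, the ONL polygon, and the band polylines.
#'
#' @param si A [section_image()].
#' @param path TIFF path; the sidecar is written next to it as
#'   `<path>.geometry.json`.
#' @return `read_section_tiff` returns a [section_image()].
#' @export
write_section_tiff <- function(si, path) {
  img <- round(pmin(pmax(si$img, 0), 65535)) / 65535
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  onl_poly <- attr(si$onl_mask, "polygon")
  if (is.null(onl_poly)) {
    ## fall back to the mask bounding box
    w <- which(si$onl_mask, arr.ind = TRUE)
    onl_poly <- cbind(x = c(min(w[, 2L]), max(w[, 2L]), max(w[, 2L]),
                            min(w[, 2L])),
                      y = c(min(w[, 1L]), min(w[, 1L]), max(w[, 1L]),
                            max(w[, 1L])))
  }
  geom <- list(scale_um_per_px = si$scale_um_per_px,
               onl_polygon = unname(apply(onl_poly, 1L, as.numeric,
                                          simplify = FALSE)),
               bands = lapply(si$bands, function(b)
                 unname(apply(b, 1L, as.numeric, simplify = FALSE))))
  jsonlite::write_json(geom, paste0(path, ".geometry.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_section_tiff
#' @export
read_section_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  img <- z_project(lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    p * 65535
  }))
  geom <- jsonlite::read_json(paste0(path, ".geometry.json"),
                              simplifyVector = FALSE)
  as_poly <- function(pts)
    do.call(rbind, lapply(pts, function(p) as.numeric(unlist(p))))
  onl_poly <- as_poly(geom$onl_polygon)
  mask <- polygon_mask(onl_poly, nrow(img), ncol(img))
  attr(mask, "polygon") <- onl_poly
  bands <- lapply(geom$bands, as_poly)
  section_image(img, as.numeric(geom$scale_um_per_px), mask, bands)
}

#' Rasterize a polygon into a logical mask
#'
#' Even-odd (ray casting) point-in-polygon test over pixel centers.
#'
#' @param poly Two-column matrix (x, y) of polygon vertices, pixel
#'   coordinates.
#' @param nrow,ncol Mask dimensions.
#' @return Logical matrix.
#' @export
polygon_mask <- function(poly, nrow, ncol) {
  xs <- poly[, 1L]; ys <- poly[, 2L]
  n <- length(xs)
  jx <- c(n, seq_len(n - 1L))
  grid_x <- matrix(rep(seq_len(ncol), each = nrow), nrow)
  grid_y <- matrix(rep(seq_len(nrow), times = ncol), nrow)
  inside <- matrix(FALSE, nrow, ncol)
  for (i in seq_len(n)) {
    j <- jx[i]
    crosses <- ((ys[i] > grid_y) != (ys[j] > grid_y)) &
      (grid_x < (xs[j] - xs[i]) * (grid_y - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
  }
  inside
}
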