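# Detection: segment the darkfield channel into labelled objects and compute
# the morphometry the selection cascade consumes. Segmentation itself is
# deliberately plain (threshold + connected components via EBImage): the
# platform's value is in what happens to the measurements afterwards, and
# touching objects are handled downstream by the proximity filter rather
# than by declumping here.

#' Detection configuration
#'
#' @param threshold_method `"otsu"` (default) computes Otsu's threshold on
#'   the darkfield channel; `"fixed"` uses `fixed_threshold` directly.
#' @param fixed_threshold Intensity threshold (a.u.); required iff
#'   `threshold_method = "fixed"`.
#' @param min_area Minimum object area in um^2; smaller components (debris
#'   specks, noise) are dropped.
#' @param fill_holes Fill enclosed holes before measuring (default `TRUE`).
#' @param smoothing_sigma Optional Gaussian pre-smoothing of the darkfield
#'   channel, in pixels (0 disables).
#' @return An object of class `detect_config`.
#' @export
detect_config <- function(threshold_method = c("otsu", "fixed"),
                          fixed_threshold = NULL, min_area = 100,
                          fill_holes = TRUE, smoothing_sigma = 0) {
  threshold_method <- match.arg(threshold_method)
  check_number(min_area, "min_area", nonneg = TRUE)
  check_number(smoothing_sigma, "smoothing_sigma", nonneg = TRUE)
  if (threshold_method == "fixed") {
    if (is.null(fixed_threshold)) {
      stopf("fixed_threshold is required when threshold_method = 'fixed'")
    }
    check_number(fixed_threshold, "fixed_threshold")
  } else if (!is.null(fixed_threshold)) {
    stopf("fixed_threshold is only meaningful with threshold_method = 'fixed'")
  }
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold, min_area = min_area,
                 fill_holes = isTRUE(fill_holes),
                 smoothing_sigma = smoothing_sigma),
            class = "detect_config")
}

#' Segment a darkfield chamber image into labelled objects
#'
#' Thresholds the image (Otsu or fixed), labels connected foreground
#' components, optionally fills holes, and discards components below
#' `min_area`. Surviving components are relabelled 1..K in raster order.
#' A constant (degenerate) image yields zero labels with a warning rather
#' than an error, so pipelines on empty chambers keep running.
#'
#' @param img Numeric matrix, darkfield channel in a.u.
#' @param config A [detect_config()].
#' @param pixel_size Micrometres per pixel.
#' @return Integer matrix of labels (0 = background).
#' @export
segment <- function(img, config = detect_config(), pixel_size = 2) {
  stopifnot(inherits(config, "detect_config"))
  check_number(pixel_size, "pixel_size", positive = TRUE)
  if (!is.matrix(img)) stopf("img must be a 2-D single-channel matrix")
  if (config$smoothing_sigma > 0) {
    img <- as.matrix(EBImage::gblur(img, sigma = config$smoothing_sigma))
  }
  if (config$threshold_method == "otsu") {
    rng <- range(img)
    if (diff(rng) <= 0) {
      warning("constant-intensity image: Otsu threshold undefined, returning zero labels")
      return(matrix(0L, nrow(img), ncol(img)))
    }
    thr01 <- EBImage::otsu(EBImage::Image((img - rng[1]) / diff(rng)),
                           range = c(0, 1))
    thr <- rng[1] + thr01 * diff(rng)
    # darkfield objects are sparse; a threshold that marks a large image
    # fraction as foreground means Otsu split the noise of an (effectively)
    # empty chamber, not objects from background
    if (mean(img > thr) > 0.25) {
      warning("Otsu threshold does not separate sparse foreground (empty chamber?); returning zero labels")
      return(matrix(0L, nrow(img), ncol(img)))
    }
  } else {
    thr <- config$fixed_threshold
  }
  bw <- (img > thr) * 1
  labels <- EBImage::bwlabel(bw)
  if (config$fill_holes) labels <- EBImage::fillHull(labels)
  labels <- matrix(as.integer(labels), nrow(img), ncol(img))
  k <- max(labels)
  if (k > 0) {
    counts <- tabulate(labels[labels > 0L], nbins = k)
    keep <- which(counts * pixel_size^2 >= config$min_area)
    remap <- integer(k)
    remap[keep] <- seq_along(keep)
    pos <- labels > 0L
    labels[pos] <- remap[labels[pos]]
  }
  labels
}

#' Measure labelled objects
#'
#' Computes, per label: centroid (um), area (pixel count * pixel_size^2),
#' perimeter (sub-pixel contour length, um), equivalent-circle diameter
#' `2*sqrt(area/pi)`, circularity `4*pi*area/perimeter^2` clipped at 1, and
#' the mean fluorescence intensity over the object's pixels (the viability
#' readout).
#'
#' @param labels Integer label matrix from [segment()].
#' @param fluor Numeric matrix, fluorescence channel, same shape as `labels`.
#' @param pixel_size Micrometres per pixel.
#' @return Data frame with one row per label: `id, center_x_um, center_y_um,
#'   area_um2, perimeter_um, diameter_um, circularity, mean_fluor`.
#' @export
measure <- function(labels, fluor, pixel_size = 2) {
  if (!all(dim(labels) == dim(fluor))) {
    stopf("label map (%d x %d) and fluorescence image (%d x %d) differ in shape",
          nrow(labels), ncol(labels), nrow(fluor), ncol(fluor))
  }
  check_number(pixel_size, "pixel_size", positive = TRUE)
  k <- max(labels)
  out <- data.frame(id = integer(), center_x_um = numeric(),
                    center_y_um = numeric(), area_um2 = numeric(),
                    perimeter_um = numeric(), diameter_um = numeric(),
                    circularity = numeric(), mean_fluor = numeric())
  if (k == 0) return(out)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rows <- (idx - 1L) %% nrow(labels) + 1L
  cols <- (idx - 1L) %/% nrow(labels) + 1L
  by_lab <- split(seq_along(idx), lab)
  res <- lapply(names(by_lab), function(key) {
    sel <- by_lab[[key]]
    r <- rows[sel]; c <- cols[sel]
    r0 <- min(r); r1 <- max(r); c0 <- min(c); c1 <- max(c)
    win <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
    win[cbind(r - r0 + 1L, c - c0 + 1L)] <- 1
    per_px <- mask_perimeter_px(win)
    area <- length(sel) * pixel_size^2
    per <- per_px * pixel_size
    data.frame(id = as.integer(key),
               center_x_um = (mean(c) - 0.5) * pixel_size,
               center_y_um = (mean(r) - 0.5) * pixel_size,
               area_um2 = area, perimeter_um = per,
               diameter_um = 2 * sqrt(area / pi),
               circularity = min(1, 4 * pi * area / per^2),
               mean_fluor = mean(fluor[idx[sel]]))
  })
  out <- do.call(rbind, res)
  out[order(out$id), , drop = FALSE]
}

#' Segment and measure a chamber image pair in one call
#'
#' @param darkfield,fluor Numeric image matrices (a.u.).
#' @inheritParams segment
#' @return The [measure()] data frame.
#' @export
detect_objects <- function(darkfield, fluor, config = detect_config(),
                           pixel_size = 2) {
  measure(segment(darkfield, config, pixel_size), fluor, pixel_size)
}

#' Write measurements to CSV
#'
#' @param measurements Data frame from [measure()].
#' @param path Output CSV path.
#' @export
write_measurements <- function(measurements, path) {
  write.csv(measurements, path, row.names = FALSE)
  invisible(path)
}
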