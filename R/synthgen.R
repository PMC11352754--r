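# Synthetic chamber generator: seeded spheroid/debris populations, paired
# darkfield + fluorescence renders with exact ground truth, and 1-D detector
# traces. Stands in for the platform optics so every downstream module can be
# exercised against known truth.
#
# Conventions (used throughout the package):
#   * physical coordinates in micrometres, origin at the chamber top-left
#     corner, x to the right, y downwards;
#   * raster images are numeric matrices, row = y, column = x; pixel
#     (r, c) covers x in [(c-1), c] * pixel_size and its centre sits at
#     ((c - 0.5) * pixel_size, (r - 0.5) * pixel_size);
#   * intensities are arbitrary units on a 16-bit scale (0..65535).

INTENSITY_RANGE <- 65535

#' Chamber specification for synthetic image generation
#'
#' Describes the imaged window of the biofabrication chamber: physical size,
#' sampling, and the intensity levels used to render background, object
#' bodies (darkfield channel) and Calcein-like fluorescence of viable
#' spheroids. Defaults give a 4 x 4 mm desk-scale window at 2 um/px with
#' additive Gaussian noise of 2% of the 16-bit dynamic range.
#'
#' @param width,height Chamber dimensions in micrometres.
#' @param pixel_size Sampling in micrometres per pixel.
#' @param background_level,foreground_level Darkfield intensities (a.u.) of
#'   empty chamber and object interior.
#' @param fluor_level Fluorescence intensity (a.u.) rendered over viable
#'   objects; non-viable objects and debris stay at background.
#' @param noise_sigma Standard deviation of additive Gaussian noise (a.u.).
#' @param seed Integer seed controlling noise and per-object shape draws.
#' @return An object of class `chamber_spec`.
#' @export
chamber_spec <- function(width = 4000, height = 4000, pixel_size = 2,
                         background_level = 500, foreground_level = 30000,
                         fluor_level = 20000,
                         noise_sigma = 0.02 * INTENSITY_RANGE,
                         seed = 1L) {
  check_number(width, "width", positive = TRUE)
  check_number(height, "height", positive = TRUE)
  check_number(pixel_size, "pixel_size", positive = TRUE)
  check_number(noise_sigma, "noise_sigma", nonneg = TRUE)
  check_number(background_level, "background_level", nonneg = TRUE)
  check_number(foreground_level, "foreground_level", positive = TRUE)
  check_number(fluor_level, "fluor_level", positive = TRUE)
  structure(list(width = width, height = height, pixel_size = pixel_size,
                 background_level = background_level,
                 foreground_level = foreground_level,
                 fluor_level = fluor_level, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "chamber_spec")
}

# ---- shape model -----------------------------------------------------------

# Radial cosine-series perturbation of a disc:
#   r(theta) = R * (1 + amp * sum_k w_k cos(k theta + phi_k)),  sum w_k = 1,
# with harmonics k in 2..6. The domain is star-shaped, hence always one
# connected component, and max radial excursion is bounded by R * (1 + amp).
shape_params <- function(seed) {
  with_seed(seed, {
    # harmonics 4..8: low enough to look like lobed spheroids, high enough
    # that any weight mix reaches circularity ~0.35 within the amplitude cap
    ks <- 4:8
    w <- runif(length(ks))
    list(ks = ks, w = w / sum(w), phi = runif(length(ks), 0, 2 * pi))
  })
}

# Rasterize the shape on the pixel grid of an nr x nc window whose top-left
# pixel is (row0, col0) in chamber coordinates (1-based). Centre in um.
rasterize_shape <- function(center_x, center_y, radius_um, amp, sp,
                            pixel_size, nr, nc, row0 = 1L, col0 = 1L) {
  xs <- (col0 - 1 + seq_len(nc) - 0.5) * pixel_size
  ys <- (row0 - 1 + seq_len(nr) - 0.5) * pixel_size
  dx <- matrix(xs - center_x, nr, nc, byrow = TRUE)
  dy <- matrix(ys - center_y, nr, nc)
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  rb <- matrix(1, nr, nc)
  if (amp > 0) {
    for (i in seq_along(sp$ks)) {
      rb <- rb + amp * sp$w[i] * cos(sp$ks[i] * theta + sp$phi[i])
    }
  }
  (rho <= radius_um * rb) * 1
}

# Perimeter of a binary window by sub-pixel marching squares: the mask is
# smoothed with a small Gaussian and contoured at 0.5, which removes the
# staircase bias of raw pixel contours (a digital disc then measures
# circularity 0.99-1.03 instead of ~0.87). Falls back to the raw contour for
# objects too small to survive smoothing.
mask_perimeter_px <- function(mask, blur_sigma = 1) {
  pad <- 4L
  m <- matrix(0, nrow(mask) + 2 * pad, ncol(mask) + 2 * pad)
  m[pad + seq_len(nrow(mask)), pad + seq_len(ncol(mask))] <- mask
  contour_len <- function(z) {
    cl <- grDevices::contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                                  z = z, levels = 0.5)
    if (!length(cl)) return(NA_real_)
    max(vapply(cl, function(cc) {
      x <- c(cc$x, cc$x[1]); y <- c(cc$y, cc$y[1])
      sum(sqrt(diff(x)^2 + diff(y)^2))
    }, numeric(1)))
  }
  p <- contour_len(as.matrix(EBImage::gblur(m, sigma = blur_sigma)))
  if (is.na(p)) p <- contour_len(m)
  if (is.na(p)) p <- 2 * sqrt(pi * sum(mask))   # single-pixel degenerate case
  p
}

# Measure a binary window with the same estimators the detect module uses.
measure_mask <- function(mask, pixel_size = 1) {
  area_px <- sum(mask)
  per_px <- mask_perimeter_px(mask)
  area <- area_px * pixel_size^2
  per <- per_px * pixel_size
  list(area = area, perimeter = per,
       diameter = 2 * sqrt(area / pi),
       circularity = min(1, 4 * pi * area / per^2),
       circularity_raw = 4 * pi * area / per^2)
}

#' Generate one synthetic spheroid-like shape of controlled circularity
#'
#' Draws a binary mask whose measured equivalent-circle diameter matches
#' `diameter` (within 5%) and whose measured circularity (the package's
#' 4*pi*A/P^2 estimator) matches `circularity_target` (within 0.05). Shapes
#' are radial cosine perturbations of a disc; the perturbation amplitude is
#' calibrated by bisection against the measured estimator, so generator and
#' detector agree by construction.
#'
#' @param diameter Target equivalent-circle diameter in micrometres; must be
#'   at least `4 * pixel_size`.
#' @param circularity_target Desired measured circularity in `[0.3, 1]`.
#' @param pixel_size Micrometres per pixel.
#' @param seed Integer seed selecting the harmonic content of the outline.
#' @return Binary matrix (attributes `measured` and `amplitude` record the
#'   calibration result).
#' @export
generate_shape <- function(diameter, circularity_target, pixel_size = 2,
                           seed = 1L) {
  check_number(diameter, "diameter", positive = TRUE)
  check_number(circularity_target, "circularity_target")
  if (diameter < 4 * pixel_size) {
    stopf("diameter (%g um) must be >= 4 * pixel_size (%g um)",
          diameter, 4 * pixel_size)
  }
  if (circularity_target < 0.3 || circularity_target > 1) {
    stopf("circularity_target must lie in [0.3, 1] (got %g)",
          circularity_target)
  }
  shape_core(diameter, circularity_target, pixel_size, seed, strict = TRUE)
}

# Shared rasterize-calibrate-renormalise core. In strict mode an infeasible
# circularity target is an error (the generate_shape contract); in
# best-effort mode (chamber rendering of e.g. tiny debris, whose measured
# shape is irrelevant downstream) the closest achievable amplitude is used.
shape_core <- function(diameter, circularity_target, pixel_size, seed,
                       strict = TRUE) {
  sp <- shape_params(seed)
  radius <- diameter / 2
  draw <- function(amp, r) {
    half <- ceiling((r * (1 + max(amp, 0.05)) ) / pixel_size) + 4L
    n <- 2L * half + 1L
    cx <- half * pixel_size + pixel_size / 2
    rasterize_shape(cx, cx, r, amp, sp, pixel_size, n, n)
  }
  tol <- 0.015
  # standalone shapes may deform up to amplitude 0.75; shapes rendered into
  # a chamber stay within 0.55 so outlines respect the collision margins
  cal <- if (strict) {
    calibrate_amplitude(draw, radius, circularity_target, tol,
                        amp_max = 0.75)
  } else {
    tryCatch(calibrate_amplitude(draw, radius, circularity_target, tol,
                                 amp_max = 0.55),
             error = function(e) list(amp = 0.55, circ = NA_real_))
  }
  mask <- draw(cal$amp, radius)
  meas <- measure_mask(mask, pixel_size)
  # one-shot area renormalisation so the equivalent diameter lands on target
  if (abs(meas$diameter - diameter) / diameter > 0.01) {
    radius <- radius * diameter / meas$diameter
    mask <- draw(cal$amp, radius)
    meas <- measure_mask(mask, pixel_size)
  }
  structure(mask, measured = meas, amplitude = cal$amp, radius_um = radius)
}

# Bisection of perturbation amplitude against the measured circularity.
# Measured circularity decreases (noisily, through rasterization) with
# amplitude; 50 steps is far beyond bisection's needs, so hitting the cap
# means the target is infeasible for this harmonic draw.
calibrate_amplitude <- function(draw, radius, target, tol, amp_max = 0.55,
                                max_steps = 50L) {
  # calibrate against the clipped estimator (what detection reports); tiny
  # discs can measure raw > 1 purely from discretization
  measure_amp <- function(a) measure_mask(draw(a, radius))$circularity
  c0 <- measure_amp(0)
  if (c0 <= target + tol) return(list(amp = 0, circ = c0))
  c_hi <- measure_amp(amp_max)
  if (c_hi > target + 0.05) {
    stopf(paste0("cannot calibrate shape to circularity %g: amplitude cap ",
                 "%.2f still measures %.3f"), target, amp_max, c_hi)
  }
  lo <- 0; hi <- amp_max
  best <- list(amp = amp_max, circ = c_hi)
  for (step in seq_len(max_steps)) {
    mid <- (lo + hi) / 2
    cm <- measure_amp(mid)
    if (abs(cm - target) < abs(best$circ - target)) {
      best <- list(amp = mid, circ = cm)
    }
    if (abs(cm - target) <= tol) return(list(amp = mid, circ = cm))
    if (cm > target) lo <- mid else hi <- mid
  }
  # rasterization makes the estimator slightly non-monotone at small sizes;
  # the best amplitude seen is accepted if it meets the shape contract
  if (abs(best$circ - target) <= 0.05) return(best)
  stopf("shape calibration did not converge to circularity %g in %d steps",
        target, max_steps)
}

# ---- populations -----------------------------------------------------------

sample_dist <- function(dist, n) {
  if (is.function(dist)) return(dist(n))
  if (is.numeric(dist) && length(dist) == 2L) {
    return(runif(n, dist[1], dist[2]))
  }
  stopf("distribution must be a sampling function or a c(min, max) range")
}

#' Sample a non-colliding synthetic object population
#'
#' Places `n` spheroids (plus optional debris fragments) in the chamber by
#' rejection sampling. Placements keep centres at least
#' `separation_factor * (r_i + r_j)` apart and the same factor times the
#' radius away from every wall, so that rendered outlines (whose radial
#' excursion is bounded by 1.5x the nominal radius) can never touch each
#' other or the chamber boundary.
#'
#' @param n Number of spheroids.
#' @param diameter_dist,circularity_dist Either a `c(min, max)` range
#'   (sampled uniformly) or a `function(n)` returning `n` draws.
#' @param viable_frac Probability that a spheroid is Calcein-positive.
#' @param chamber A [chamber_spec()].
#' @param seed Integer seed; fixed seeds give identical populations.
#' @param debris_frac Debris objects to add, as a fraction of `n`.
#' @param debris_diameter,debris_circularity Ranges for debris fragments
#'   (always non-viable).
#' @param separation_factor Collision margin multiplier on summed radii.
#' @param max_attempts Rejection-sampling budget per population.
#' @return Data frame with columns `id, center_x_um, center_y_um,
#'   diameter_um, circularity, viable, kind`.
#' @export
sample_population <- function(n, diameter_dist = c(100, 300),
                              circularity_dist = c(0.5, 1.0),
                              viable_frac = 0.8,
                              chamber = chamber_spec(), seed = 1L,
                              debris_frac = 0,
                              debris_diameter = c(20, 80),
                              debris_circularity = c(0.4, 0.8),
                              separation_factor = 1.7,
                              max_attempts = 10000L) {
  stopifnot(inherits(chamber, "chamber_spec"))
  check_number(viable_frac, "viable_frac", nonneg = TRUE)
  if (viable_frac > 1) stopf("viable_frac must be <= 1")
  n <- as.integer(n)
  n_debris <- as.integer(round(n * debris_frac))
  empty <- data.frame(id = integer(), center_x_um = numeric(),
                      center_y_um = numeric(), diameter_um = numeric(),
                      circularity = numeric(), viable = logical(),
                      kind = character(), stringsAsFactors = FALSE)
  if (n + n_debris == 0L) return(empty)

  with_seed(seed, {
    diam <- c(sample_dist(diameter_dist, n),
              sample_dist(debris_diameter, n_debris))
    circ <- c(sample_dist(circularity_dist, n),
              sample_dist(debris_circularity, n_debris))
    kind <- c(rep("spheroid", n), rep("debris", n_debris))
    viable <- c(runif(n) < viable_frac, rep(FALSE, n_debris))
    radius <- diam / 2
    xs <- numeric(0); ys <- numeric(0)
    attempts <- 0L
    for (i in seq_along(diam)) {
      margin <- separation_factor * radius[i]
      if (2 * margin >= chamber$width || 2 * margin >= chamber$height) {
        stopf("object %d (diameter %.0f um) cannot fit the chamber; use a larger chamber", i, diam[i])
      }
      repeat {
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          stopf(paste0("placement saturated after %d attempts while placing ",
                       "object %d of %d; use a larger chamber or fewer/",
                       "smaller objects"), max_attempts, i, length(diam))
        }
        x <- runif(1, margin, chamber$width - margin)
        y <- runif(1, margin, chamber$height - margin)
        if (!length(xs) ||
            all(sqrt((xs - x)^2 + (ys - y)^2) >=
                separation_factor * (radius[seq_along(xs)] + radius[i]))) {
          xs <- c(xs, x); ys <- c(ys, y)
          break
        }
      }
    }
    data.frame(id = seq_along(diam), center_x_um = xs, center_y_um = ys,
               diameter_um = diam, circularity = circ, viable = viable,
               kind = kind, stringsAsFactors = FALSE)
  })
}

# ---- chamber rendering -----------------------------------------------------

#' Render a synthetic darkfield/fluorescence chamber image pair
#'
#' The darkfield channel renders every object (spheroids and debris) at
#' `foreground_level`; the fluorescence channel renders only viable objects
#' at `fluor_level`, emulating Calcein staining. Independent additive
#' Gaussian noise is applied to both channels. Each object's outline is
#' drawn with the calibrated shape model, seeded per object id so renders
#' are reproducible.
#'
#' @param spec A [chamber_spec()].
#' @param objects Truth table as returned by [sample_population()].
#' @return List of class `chamber_images` with elements `darkfield`,
#'   `fluorescence` (numeric matrices, a.u.) and `truth` (the input table).
#' @export
generate_chamber <- function(spec, objects) {
  stopifnot(inherits(spec, "chamber_spec"))
  ps <- spec$pixel_size
  nr <- as.integer(round(spec$height / ps))
  nc <- as.integer(round(spec$width / ps))
  dark <- matrix(spec$background_level, nr, nc)
  fluo <- matrix(spec$background_level, nr, nc)

  if (nrow(objects) > 0) {
    r_max <- 1.6 * objects$diameter_um / 2    # amplitude cap 0.55 + margin
    bad <- which(objects$center_x_um - r_max < 0 |
                 objects$center_x_um + r_max > spec$width |
                 objects$center_y_um - r_max < 0 |
                 objects$center_y_um + r_max > spec$height)
    if (length(bad)) {
      stopf("object id %s extends outside the chamber",
            paste(objects$id[bad], collapse = ", "))
    }
    if (nrow(objects) > 1) {
      d <- as.matrix(stats::dist(objects[, c("center_x_um", "center_y_um")]))
      rsum <- outer(objects$diameter_um / 2, objects$diameter_um / 2, "+")
      diag(d) <- Inf
      if (any(d < rsum)) stopf("object footprints overlap; spread placements")
    }
    for (i in seq_len(nrow(objects))) {
      ob <- objects[i, ]
      sseed <- as.integer((as.numeric(spec$seed) * 1009 + ob$id * 7) %%
                            .Machine$integer.max)
      mask <- shape_core(ob$diameter_um, ob$circularity, ps, seed = sseed,
                         strict = FALSE)
      amp <- attr(mask, "amplitude")
      sp <- shape_params(sseed)
      # redraw the calibrated outline directly on the chamber grid so the
      # sub-pixel centre position is honoured
      rad <- attr(mask, "radius_um")
      half <- ceiling(rad * (1 + max(amp, 0.05)) / ps) + 4L
      cr <- round(ob$center_y_um / ps); cc <- round(ob$center_x_um / ps)
      rows <- max(1L, cr - half):min(nr, cr + half)
      cols <- max(1L, cc - half):min(nc, cc + half)
      m <- rasterize_shape(ob$center_x_um, ob$center_y_um, rad, amp, sp, ps,
                           length(rows), length(cols), rows[1], cols[1])
      idx <- m > 0
      dpatch <- dark[rows, cols]; dpatch[idx] <- spec$foreground_level
      dark[rows, cols] <- dpatch
      if (isTRUE(ob$viable)) {
        fpatch <- fluo[rows, cols]; fpatch[idx] <- spec$fluor_level
        fluo[rows, cols] <- fpatch
      }
    }
  }

  if (spec$noise_sigma > 0) {
    noise <- derive_seeds(spec$seed, 2L)
    dark <- dark + with_seed(noise[1], matrix(rnorm(nr * nc, 0, spec$noise_sigma), nr, nc))
    fluo <- fluo + with_seed(noise[2], matrix(rnorm(nr * nc, 0, spec$noise_sigma), nr, nc))
  }
  structure(list(darkfield = dark, fluorescence = fluo, truth = objects,
                 spec = spec),
            class = "chamber_images")
}

#' @export
print.chamber_images <- function(x, ...) {
  cat(sprintf("synthetic chamber %g x %g um (%d x %d px), %d objects (%d viable)\n",
              x$spec$width, x$spec$height, nrow(x$darkfield),
              ncol(x$darkfield), nrow(x$truth), sum(x$truth$viable)))
  invisible(x)
}

#' Write a chamber image pair and its truth table to disk
#'
#' Images go out as single-channel 16-bit TIFF (intensities clipped to the
#' 0..65535 a.u. scale), the truth table as CSV.
#'
#' @param images A `chamber_images` object.
#' @param dir Output directory (created if needed).
#' @param basename File stem for the three outputs.
#' @return Invisibly, the paths written.
#' @export
write_chamber <- function(images, dir, basename = "chamber") {
  stopifnot(inherits(images, "chamber_images"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(basename, c("_darkfield.tif",
                                             "_fluorescence.tif",
                                             "_truth.csv")))
  write_image(images$darkfield, paths[1])
  write_image(images$fluorescence, paths[2])
  write.csv(images$truth, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read/write single-channel images on the package's 16-bit a.u. scale
#'
#' @param path File path; `.tif`/`.tiff` and `.png` are supported.
#' @param img Numeric matrix of intensities (a.u., 0..65535).
#' @return `read_image` returns a numeric matrix in a.u.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stopf("unsupported image format: .%s", ext))
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  raw * INTENSITY_RANGE
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  scaled <- pmin(pmax(img / INTENSITY_RANGE, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 16L),
         png = png::writePNG(scaled, path),
         stopf("unsupported image format: .%s", ext))
  invisible(path)
}

# ---- detector traces -------------------------------------------------------

#' Specification of a synthetic point-detector fluorescence trace
#'
#' Models the signal seen by the fluorescence detection unit as GESs pass the
#' detector: a noisy baseline carrying one Gaussian-profile spike per
#' arrival. `spike_width` is the full width at half maximum in seconds.
#'
#' @param arrival_times Strictly increasing GES passage times (s).
#' @param sampling_rate Detector sampling rate (Hz).
#' @param duration Trace length (s); defaults to the last arrival plus 1 s.
#' @param baseline,baseline_sigma Baseline level and noise sd (a.u.).
#' @param spike_amplitude Peak height above baseline (a.u.).
#' @param spike_width Spike FWHM (s); must be smaller than the smallest gap
#'   between consecutive arrivals.
#' @param seed Integer seed for the baseline noise.
#' @return An object of class `trace_spec`.
#' @export
trace_spec <- function(arrival_times, sampling_rate = 1000, duration = NULL,
                       baseline = 100, baseline_sigma = 2,
                       spike_amplitude = 50, spike_width = 0.05, seed = 1L) {
  check_number(sampling_rate, "sampling_rate", positive = TRUE)
  check_number(spike_width, "spike_width", positive = TRUE)
  check_number(baseline_sigma, "baseline_sigma", nonneg = TRUE)
  if (length(arrival_times) && any(diff(arrival_times) <= 0)) {
    stopf("arrival_times must be strictly increasing")
  }
  if (length(arrival_times) > 1 && min(diff(arrival_times)) <= spike_width) {
    stopf("overlapping spikes: minimal arrival gap (%.3g s) must exceed spike_width (%.3g s)",
          min(diff(arrival_times)), spike_width)
  }
  duration <- duration %||%
    (if (length(arrival_times)) max(arrival_times) + 1 else 1)
  structure(list(arrival_times = as.numeric(arrival_times),
                 sampling_rate = sampling_rate, duration = duration,
                 baseline = baseline, baseline_sigma = baseline_sigma,
                 spike_amplitude = spike_amplitude, spike_width = spike_width,
                 seed = as.integer(seed)),
            class = "trace_spec")
}

#' Generate a detector intensity trace from a trace specification
#'
#' @param spec A [trace_spec()].
#' @return Data frame with columns `t_s` and `intensity`; sample `i` is taken
#'   at `t = (i - 1) / sampling_rate`.
#' @export
generate_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  t <- seq(0, spec$duration, by = 1 / spec$sampling_rate)
  y <- rep(spec$baseline, length(t))
  sigma_g <- spec$spike_width / (2 * sqrt(2 * log(2)))   # FWHM -> sd
  for (ta in spec$arrival_times) {
    y <- y + spec$spike_amplitude * exp(-(t - ta)^2 / (2 * sigma_g^2))
  }
  if (spec$baseline_sigma > 0) {
    y <- y + with_seed(spec$seed, rnorm(length(t), 0, spec$baseline_sigma))
  }
  data.frame(t_s = t, intensity = y)
}
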