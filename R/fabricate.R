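# Fabrication: turn selected coordinates into a photomask for the 405 nm
# projector and simulate the gel discs (GESs) the exposure produces. The
# crosslinking chemistry is not modelled; power density, exposure time and
# wavelength travel with the mask as provenance metadata and are carried
# verbatim into every downstream record.

#' Build a photomask from a selection result
#'
#' Renders one illumination disc of `spot_diameter` per selected coordinate
#' on the chamber raster. The selection cascade's pairwise guarantee (centre
#' separation of at least one footprint plus the edge gap) keeps the discs
#' disjoint whenever `spot_diameter` does not exceed the configured gel
#' footprint.
#'
#' @param selection A `selection_result` from [run_selection()], or a data
#'   frame with `center_x_um` / `center_y_um` columns.
#' @param spot_diameter Illuminated disc diameter (um).
#' @param chamber Chamber geometry (`width`, `height` in um).
#' @param pixel_size Micrometres per pixel of the mask raster.
#' @param power_density,exposure_s,wavelength_nm Exposure metadata recorded
#'   on the mask (mW/cm^2, s, nm).
#' @return Object of class `photomask`: list with binary `mask`,
#'   `spot_diameter`, `pixel_size`, `coordinates` and `exposure` metadata.
#' @export
build_photomask <- function(selection, spot_diameter = 550, chamber,
                            pixel_size = 2, power_density = 3,
                            exposure_s = 75, wavelength_nm = 405) {
  coords <- if (inherits(selection, "selection_result")) selection$selected
            else selection
  check_number(spot_diameter, "spot_diameter", positive = TRUE)
  if (is.null(chamber$width) || is.null(chamber$height)) {
    stopf("chamber must provide width and height (um)")
  }
  nr <- as.integer(round(chamber$height / pixel_size))
  nc <- as.integer(round(chamber$width / pixel_size))
  mask <- matrix(0L, nr, nc)
  r <- spot_diameter / 2
  for (i in seq_len(nrow(coords))) {
    x <- coords$center_x_um[i]; y <- coords$center_y_um[i]
    if (x < 0 || x > chamber$width || y < 0 || y > chamber$height) {
      stopf("selected coordinate (%g, %g) lies outside the chamber -- upstream contract violated", x, y)
    }
    half <- ceiling(r / pixel_size) + 2L
    cr <- round(y / pixel_size); cc <- round(x / pixel_size)
    rows <- max(1L, cr - half):min(nr, cr + half)
    cols <- max(1L, cc - half):min(nc, cc + half)
    xs <- (cols - 0.5) * pixel_size
    ys <- (rows - 0.5) * pixel_size
    inside <- outer(ys - y, xs - x, function(a, b) a^2 + b^2) <= r^2
    patch <- mask[rows, cols]
    patch[inside] <- 1L
    mask[rows, cols] <- patch
  }
  structure(list(mask = mask, spot_diameter = spot_diameter,
                 pixel_size = pixel_size, coordinates = coords,
                 exposure = list(power_density_mw_cm2 = power_density,
                                 exposure_s = exposure_s,
                                 wavelength_nm = wavelength_nm)),
            class = "photomask")
}

#' @export
print.photomask <- function(x, ...) {
  cat(sprintf("photomask: %d spot(s) of %g um on %d x %d px; %g mW/cm^2, %g s @ %g nm\n",
              nrow(x$coordinates), x$spot_diameter,
              nrow(x$mask), ncol(x$mask),
              x$exposure$power_density_mw_cm2, x$exposure$exposure_s,
              x$exposure$wavelength_nm))
  invisible(x)
}

#' Write a photomask as a 1-bit PNG plus a JSON metadata sidecar
#'
#' @param photomask A `photomask`.
#' @param png_path Binary mask image output path.
#' @param json_path Sidecar path for exposure metadata and coordinates.
#' @export
write_photomask <- function(photomask, png_path, json_path = NULL) {
  stopifnot(inherits(photomask, "photomask"))
  png::writePNG(photomask$mask * 1.0, png_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(spot_diameter_um = photomask$spot_diameter,
                              pixel_size_um = photomask$pixel_size,
                              exposure = photomask$exposure,
                              coordinates = photomask$coordinates),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(png_path)
}

#' Simulate gelatine encapsulation of the selected spheroids
#'
#' Produces one GES per selected spheroid. Gel disc diameters follow a
#' normal distribution centred on the illumination spot diameter with
#' coefficient of variation `gel_cv`, truncated at +/- 3 sd (re-sampled);
#' this models run-to-run spread of the crosslinked disc without any
#' photochemistry. Marker intensity is inherited from the spheroid's mean
#' Calcein fluorescence when available.
#'
#' @param selection A `selection_result`; its `objects` table supplies the
#'   spheroid diameters and fluorescence of the selected ids.
#' @param spot_diameter Illumination spot diameter (um).
#' @param gel_cv Coefficient of variation of the gel diameter (fraction).
#' @param seed Integer seed.
#' @param exposure Optional exposure metadata list carried onto the output
#'   (as produced by [build_photomask()]).
#' @return Data frame of class `ges_batch`: `id, source_spheroid_id,
#'   gel_diameter_um, spheroid_diameter_um, marker_intensity`, with the
#'   exposure metadata in `attr(, "exposure")`.
#' @export
simulate_encapsulation <- function(selection, spot_diameter = 550,
                                   gel_cv = 0.05, seed = 1L,
                                   exposure = list(power_density_mw_cm2 = 3,
                                                   exposure_s = 75,
                                                   wavelength_nm = 405)) {
  stopifnot(inherits(selection, "selection_result"))
  check_number(gel_cv, "gel_cv", nonneg = TRUE)
  check_number(spot_diameter, "spot_diameter", positive = TRUE)
  sel <- selection$objects[selection$objects$status == "SELECTED", ,
                           drop = FALSE]
  n <- nrow(sel)
  gel <- if (gel_cv == 0) rep(spot_diameter, n) else with_seed(seed, {
    sdv <- gel_cv * spot_diameter
    draw <- rnorm(n, spot_diameter, sdv)
    while (any(bad <- abs(draw - spot_diameter) > 3 * sdv)) {
      draw[bad] <- rnorm(sum(bad), spot_diameter, sdv)
    }
    draw
  })
  out <- data.frame(id = seq_len(n),
                    source_spheroid_id = sel$id,
                    gel_diameter_um = gel,
                    spheroid_diameter_um = sel$diameter_um,
                    marker_intensity = sel$mean_fluor)
  if (n && any(out$gel_diameter_um <= out$spheroid_diameter_um)) {
    stopf("gel disc smaller than its spheroid; increase spot_diameter or reduce gel_cv")
  }
  attr(out, "exposure") <- exposure
  class(out) <- c("ges_batch", "data.frame")
  out
}
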