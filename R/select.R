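# The selection cascade: a viability gate followed by four filters applied
# in fixed order -- spheroid (diameter/area/morphology), proximity, overlap,
# boundary. Each rejected object carries exactly one reason code, the first
# criterion it failed, which makes the cascade auditable and lets the
# pipeline report a rejection table that totals to the detected count.

REASON_CODES <- c("NOT_VIABLE", "SIZE", "AREA", "MORPHOLOGY",
                  "PROXIMITY", "OVERLAP", "BOUNDARY")

#' Selection cascade configuration
#'
#' Defaults target the platform's published output band: encapsulated
#' spheroids of 200-215 um equivalent diameter with circularity at least
#' 0.8, each sitting alone inside a 550 um gel footprint, footprints at
#' least 50 um apart, and nothing closer to a chamber wall than half a
#' footprint plus 50 um. The area window defaults to the disc-equivalent
#' areas of the diameter window (for an equivalent-circle diameter the two
#' constraints coincide; the window is kept separately configurable for
#' instruments that measure area and diameter independently).
#'
#' @param fluor_threshold Viability gate: objects with mean fluorescence
#'   `>= fluor_threshold` (a.u.) count as Calcein-positive.
#' @param diameter_min,diameter_max Accepted equivalent diameter window (um).
#' @param area_min,area_max Accepted area window (um^2).
#' @param circularity_min Minimum accepted circularity.
#' @param ges_footprint_diameter Diameter (um) of the crosslinked gel disc a
#'   selected spheroid will occupy.
#' @param min_edge_gap Minimum gap (um) between two gel footprints, so
#'   neighbouring discs cannot bridge.
#' @param boundary_margin Minimum distance (um) from a selected centre to
#'   every chamber wall; defaults to half a footprint plus 50 um.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(fluor_threshold = 5000,
                             diameter_min = 200, diameter_max = 215,
                             area_min = pi / 4 * diameter_min^2,
                             area_max = pi / 4 * diameter_max^2,
                             circularity_min = 0.8,
                             ges_footprint_diameter = 550,
                             min_edge_gap = 50,
                             boundary_margin = ges_footprint_diameter / 2 + 50) {
  check_number(fluor_threshold, "fluor_threshold", nonneg = TRUE)
  check_number(circularity_min, "circularity_min", positive = TRUE)
  if (circularity_min > 1) stopf("circularity_min must be <= 1")
  if (diameter_min >= diameter_max) stopf("diameter_min must be < diameter_max")
  if (area_min >= area_max) stopf("area_min must be < area_max")
  if (ges_footprint_diameter <= diameter_max) {
    stopf("ges_footprint_diameter (%g) must exceed diameter_max (%g)",
          ges_footprint_diameter, diameter_max)
  }
  check_number(min_edge_gap, "min_edge_gap", nonneg = TRUE)
  check_number(boundary_margin, "boundary_margin", nonneg = TRUE)
  structure(list(fluor_threshold = fluor_threshold,
                 diameter_min = diameter_min, diameter_max = diameter_max,
                 area_min = area_min, area_max = area_max,
                 circularity_min = circularity_min,
                 ges_footprint_diameter = ges_footprint_diameter,
                 min_edge_gap = min_edge_gap,
                 boundary_margin = boundary_margin),
            class = "selection_config")
}

#' Viability gate on Calcein fluorescence
#'
#' Flags each measured object viable iff its mean fluorescence is at or
#' above the threshold (`>=`, so an object exactly at threshold passes).
#'
#' @param objects Measurement data frame from [measure()].
#' @param fluor_threshold Intensity threshold (a.u.).
#' @return `objects` with a logical `viable` column.
#' @export
viability_gate <- function(objects, fluor_threshold) {
  check_number(fluor_threshold, "fluor_threshold", nonneg = TRUE)
  objects$viable <- if (nrow(objects)) objects$mean_fluor >= fluor_threshold
                    else logical(0)
  objects
}

#' Spheroid filter: diameter, area and morphology windows
#'
#' Checks, in order, diameter window, area window, circularity floor; the
#' failure reason is the first violated criterion.
#'
#' @param objects Measured objects (typically the viable subset).
#' @param config A [selection_config()].
#' @return Character vector per object: `"PASS"`, `"SIZE"`, `"AREA"` or
#'   `"MORPHOLOGY"`.
#' @export
spheroid_filter <- function(objects, config) {
  stopifnot(inherits(config, "selection_config"))
  vapply(seq_len(nrow(objects)), function(i) {
    d <- objects$diameter_um[i]; a <- objects$area_um2[i]
    if (d < config$diameter_min || d > config$diameter_max) return("SIZE")
    if (a < config$area_min || a > config$area_max) return("AREA")
    if (objects$circularity[i] < config$circularity_min) return("MORPHOLOGY")
    "PASS"
  }, character(1))
}

#' Proximity filter: no foreign object inside the gel footprint
#'
#' A candidate survives iff no *other* detected object -- debris included,
#' viable or not -- would end up inside its gel disc, i.e. no other object's
#' outline comes within the footprint radius of the candidate centre
#' (centre distance < footprint/2 + other radius).
#'
#' @param candidates Subset of `all_objects` still in play.
#' @param all_objects Every measured object in the chamber.
#' @param config A [selection_config()].
#' @return Logical vector, `TRUE` where the candidate survives.
#' @export
proximity_filter <- function(candidates, all_objects, config) {
  stopifnot(inherits(config, "selection_config"))
  fp_r <- config$ges_footprint_diameter / 2
  vapply(seq_len(nrow(candidates)), function(i) {
    dx <- all_objects$center_x_um - candidates$center_x_um[i]
    dy <- all_objects$center_y_um - candidates$center_y_um[i]
    dist <- sqrt(dx^2 + dy^2)
    other <- all_objects$id != candidates$id[i]
    !any(other & dist < fp_r + all_objects$diameter_um / 2)
  }, logical(1))
}

#' Overlap filter: greedy de-confliction of candidate footprints
#'
#' Two candidates conflict when their centres are closer than
#' `ges_footprint_diameter + min_edge_gap`, i.e. their gel discs would
#' bridge. Candidates are ranked by quality (circularity descending, then
#' diameter descending, then id ascending) and kept greedily: a candidate
#' survives iff it conflicts with no already-kept candidate.
#'
#' @param candidates Candidates surviving the proximity filter.
#' @param config A [selection_config()].
#' @return Logical vector, `TRUE` where the candidate is kept.
#' @export
overlap_filter <- function(candidates, config) {
  stopifnot(inherits(config, "selection_config"))
  n <- nrow(candidates)
  if (n == 0) return(logical(0))
  limit <- config$ges_footprint_diameter + config$min_edge_gap
  ord <- order(-candidates$circularity, -candidates$diameter_um,
               candidates$id)
  kept <- logical(n)
  for (i in ord) {
    k <- which(kept)
    if (!length(k)) { kept[i] <- TRUE; next }
    dist <- sqrt((candidates$center_x_um[k] - candidates$center_x_um[i])^2 +
                 (candidates$center_y_um[k] - candidates$center_y_um[i])^2)
    if (all(dist >= limit)) kept[i] <- TRUE
  }
  kept
}

#' Boundary filter: keep clear of the chamber walls
#'
#' Survives iff the centre is at least `boundary_margin` from all four walls
#' (`>=`, so a centre exactly at the margin passes).
#'
#' @param candidates Candidate objects.
#' @param chamber_width,chamber_height Chamber dimensions (um).
#' @param config A [selection_config()].
#' @return Logical vector, `TRUE` where the candidate survives.
#' @export
boundary_filter <- function(candidates, chamber_width, chamber_height,
                            config) {
  stopifnot(inherits(config, "selection_config"))
  m <- config$boundary_margin
  pmin(candidates$center_x_um, candidates$center_y_um,
       chamber_width - candidates$center_x_um,
       chamber_height - candidates$center_y_um) >= m
}

#' Run the full selection cascade
#'
#' Applies the viability gate, then the spheroid, proximity, overlap and
#' boundary filters in that order. Every input object ends up either
#' selected or rejected with exactly one (first-failing) reason code.
#'
#' @param objects Measurement data frame from [measure()].
#' @param chamber Chamber geometry: a [chamber_spec()] or any list with
#'   `width` and `height` in um.
#' @param config A [selection_config()].
#' @return An object of class `selection_result`: list with `selected`
#'   (`id, center_x_um, center_y_um`), `rejected` (`id, reason`), `objects`
#'   (input plus `viable`, `status`, `reason`) and `config`.
#' @export
run_selection <- function(objects, chamber, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  if (is.null(chamber$width) || is.null(chamber$height)) {
    stopf("chamber must provide width and height (um)")
  }
  objects <- viability_gate(objects, config$fluor_threshold)
  n <- nrow(objects)
  status <- rep(NA_character_, n)

  status[!objects$viable] <- "NOT_VIABLE"

  open <- which(is.na(status))
  if (length(open)) {
    verdict <- spheroid_filter(objects[open, , drop = FALSE], config)
    status[open[verdict != "PASS"]] <- verdict[verdict != "PASS"]
  }

  open <- which(is.na(status))
  if (length(open)) {
    ok <- proximity_filter(objects[open, , drop = FALSE], objects, config)
    status[open[!ok]] <- "PROXIMITY"
  }

  open <- which(is.na(status))
  if (length(open)) {
    ok <- overlap_filter(objects[open, , drop = FALSE], config)
    status[open[!ok]] <- "OVERLAP"
  }

  open <- which(is.na(status))
  if (length(open)) {
    ok <- boundary_filter(objects[open, , drop = FALSE],
                          chamber$width, chamber$height, config)
    status[open[!ok]] <- "BOUNDARY"
  }

  selected_idx <- which(is.na(status))
  objects$status <- ifelse(is.na(status), "SELECTED", "REJECTED")
  objects$reason <- ifelse(is.na(status), "", status)
  structure(list(
    selected = objects[selected_idx, c("id", "center_x_um", "center_y_um"),
                       drop = FALSE],
    rejected = data.frame(id = objects$id[!is.na(status)],
                          reason = status[!is.na(status)],
                          stringsAsFactors = FALSE),
    objects = objects,
    config = config,
    chamber = list(width = chamber$width, height = chamber$height)),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection: %d of %d objects selected\n",
              nrow(x$selected), nrow(x$objects)))
  if (nrow(x$rejected)) {
    tab <- table(factor(x$rejected$reason, levels = REASON_CODES))
    for (r in names(tab)) if (tab[[r]] > 0) cat(sprintf("  %-11s %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Write a selection result to CSV and JSON
#'
#' The CSV holds one row per object (`id,x_um,y_um,status,reason`); the JSON
#' snapshot carries the full configuration alongside the selected
#' coordinates for provenance.
#'
#' @param result A `selection_result`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @export
write_selection <- function(result, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "selection_result"))
  if (!is.null(csv_path)) {
    df <- data.frame(id = result$objects$id,
                     x_um = result$objects$center_x_um,
                     y_um = result$objects$center_y_um,
                     status = result$objects$status,
                     reason = result$objects$reason)
    write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(config = unclass(result$config),
                              chamber = result$chamber,
                              selected = result$selected,
                              rejected = result$rejected),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(result)
}
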