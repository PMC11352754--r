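# Digital twin of the downstream handling chain: the two-stage size-gated
# sorter chip, the point fluorescence detector, and the 96-well dispenser.
# Hydrodynamics are abstracted to a deterministic step function of object
# size plus Gaussian measurement noise on the effective diameter; the +/-50
# um slot tolerance of the physical chip is carried as metadata only.

#' Sorter gate geometry
#'
#' Two slot arrays partition objects by size: region 1 retains objects
#' smaller than `d1`, objects between `d1` and `d2` (inclusive at both
#' gates) reach the collection outlet, and anything larger goes to waste.
#'
#' @param d1,d2 Gate sizes in um (`0 < d1 < d2`).
#' @param tolerance Slot machining tolerance (um); metadata only.
#' @param measurement_sigma Sd (um) of Gaussian noise on the effective
#'   diameter seen by the gates during simulation.
#' @return An object of class `sorter_gates`.
#' @export
sorter_gates <- function(d1 = 400, d2 = 700, tolerance = 50,
                         measurement_sigma = 0) {
  check_number(d1, "d1", positive = TRUE)
  check_number(d2, "d2", positive = TRUE)
  if (d1 >= d2) stopf("d1 (%g) must be smaller than d2 (%g)", d1, d2)
  check_number(measurement_sigma, "measurement_sigma", nonneg = TRUE)
  structure(list(d1 = d1, d2 = d2, tolerance = tolerance,
                 measurement_sigma = measurement_sigma),
            class = "sorter_gates")
}

#' Route an object by effective diameter
#'
#' Deterministic gate logic: `< d1` -> `"region1"`, `[d1, d2]` ->
#' `"collect"`, `> d2` -> `"waste"`. Boundary diameters route to the
#' collection outlet.
#'
#' @param effective_diameter Diameter(s) in um, all positive.
#' @param gates A [sorter_gates()].
#' @return Character vector of outlets.
#' @export
route <- function(effective_diameter, gates = sorter_gates()) {
  stopifnot(inherits(gates, "sorter_gates"))
  if (any(!is.finite(effective_diameter)) || any(effective_diameter <= 0)) {
    stopf("effective_diameter must be positive")
  }
  ifelse(effective_diameter < gates$d1, "region1",
         ifelse(effective_diameter <= gates$d2, "collect", "waste"))
}

#' Sort a batch of objects and score routing accuracy
#'
#' Each object's ground-truth outlet is derived from its true diameter with
#' noise-free gates; the simulated routing then uses the true diameter plus
#' `Normal(0, measurement_sigma)` noise. Accuracy is the fraction of objects
#' whose simulated outlet matches the ground truth.
#'
#' @param true_diameter Vector of true object diameters (um), or a
#'   `ges_batch` (its `gel_diameter_um` is used).
#' @param gates A [sorter_gates()].
#' @param seed Integer seed for the measurement noise.
#' @return Object of class `sort_outcome`: data frame `diameter_um,
#'   effective_um, truth, routed` with `accuracy` and `gates` attributes.
#' @export
sort_batch <- function(true_diameter, gates = sorter_gates(), seed = 1L) {
  if (inherits(true_diameter, "ges_batch")) {
    true_diameter <- true_diameter$gel_diameter_um
  }
  stopifnot(inherits(gates, "sorter_gates"))
  n <- length(true_diameter)
  truth <- if (n) route(true_diameter, gates) else character(0)
  eff <- true_diameter
  if (gates$measurement_sigma > 0 && n) {
    eff <- eff + with_seed(seed, rnorm(n, 0, gates$measurement_sigma))
    eff <- pmax(eff, .Machine$double.eps)   # noise cannot make a size negative
  }
  routed <- if (n) route(eff, gates) else character(0)
  out <- data.frame(diameter_um = true_diameter, effective_um = eff,
                    truth = truth, routed = routed,
                    stringsAsFactors = FALSE)
  attr(out, "accuracy") <- if (n) mean(routed == truth) else NA_real_
  attr(out, "gates") <- gates
  class(out) <- c("sort_outcome", "data.frame")
  out
}

#' @export
print.sort_outcome <- function(x, ...) {
  tab <- table(factor(x$routed, levels = c("region1", "collect", "waste")))
  cat(sprintf("sorted %d objects: region1 %d, collect %d, waste %d; accuracy %.3f\n",
              nrow(x), tab[["region1"]], tab[["collect"]], tab[["waste"]],
              attr(x, "accuracy")))
  invisible(x)
}

#' Routing accuracy of a sort outcome
#' @param outcome A `sort_outcome`.
#' @return Fraction of objects routed to their ground-truth outlet.
#' @export
sort_accuracy <- function(outcome) {
  stopifnot(inherits(outcome, "sort_outcome"))
  attr(outcome, "accuracy")
}

#' Detect fluorescence spikes in a detector trace
#'
#' Baseline level and noise scale are estimated robustly (median and MAD, so
#' the spikes themselves do not inflate the estimate); events are upward
#' crossings of `baseline + threshold_k * sigma`, with crossings closer than
#' `refractory` seconds to the previous accepted event suppressed -- the
#' detector halts the flow briefly after each GES, so a single passage must
#' produce a single event.
#'
#' @param trace Data frame with `t_s` and `intensity` (as from
#'   [generate_trace()]), or a numeric vector with `sampling_rate` given.
#' @param threshold_k Detection threshold in multiples of the baseline noise
#'   sd.
#' @param refractory Dead time after each event (s); must be shorter than
#'   the trace.
#' @param sampling_rate Required when `trace` is a bare numeric vector.
#' @return Object of class `spike_events`: list with `event_times`,
#'   `threshold`, `baseline`, `sigma`, `refractory`.
#' @export
detect_spikes <- function(trace, threshold_k = 5, refractory = 0.1,
                          sampling_rate = NULL) {
  if (is.numeric(trace) && is.null(dim(trace))) {
    if (is.null(sampling_rate)) {
      stopf("sampling_rate is required when trace is a numeric vector")
    }
    trace <- data.frame(t_s = (seq_along(trace) - 1) / sampling_rate,
                        intensity = trace)
  }
  stopifnot(all(c("t_s", "intensity") %in% names(trace)))
  check_number(threshold_k, "threshold_k", positive = TRUE)
  check_number(refractory, "refractory", nonneg = TRUE)
  duration <- max(trace$t_s) - min(trace$t_s)
  if (refractory >= duration) {
    stopf("refractory (%g s) must be shorter than the trace (%g s)",
          refractory, duration)
  }
  y <- trace$intensity
  baseline <- median(y)
  sigma <- mad(y)
  thr <- baseline + threshold_k * sigma
  above <- y > thr   # strict, so a flat trace (sigma 0) yields no events
  crossing <- which(above & !c(FALSE, above[-length(above)]))
  events <- numeric(0)
  for (i in crossing) {
    ti <- trace$t_s[i]
    if (!length(events) || ti - events[length(events)] >= refractory) {
      events <- c(events, ti)
    }
  }
  structure(list(event_times = events, threshold = thr, baseline = baseline,
                 sigma = sigma, refractory = refractory),
            class = "spike_events")
}

#' @export
print.spike_events <- function(x, ...) {
  cat(sprintf("%d spike event(s); threshold %.2f (baseline %.2f, sigma %.3f), refractory %g s\n",
              length(x$event_times), x$threshold, x$baseline, x$sigma,
              x$refractory))
  invisible(x)
}

#' 96-well plate well labels in row-major fill order
#' @return Character vector `A1, A2, ..., H12`.
#' @export
plate_wells <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

#' Dispense GESs into a 96-well plate
#'
#' Fills wells row-major from A1, `per_well` GESs per well. Dispensing more
#' GESs than the plate holds is an error (the physical dispenser would
#' overflow), reporting the excess count.
#'
#' @param ges GES ids to dispense: an integer count, a vector of ids, a
#'   `ges_batch`, or a `spike_events` (one GES per detected event).
#' @param per_well GESs per well (default 1, the screening density).
#' @return Object of class `plate_map`: data frame `well, row, col, ges_id`
#'   with one row per dispensed GES.
#' @export
dispense <- function(ges, per_well = 1L) {
  per_well <- as.integer(per_well)
  if (per_well < 1L) stopf("per_well must be >= 1")
  ids <- if (inherits(ges, "spike_events")) seq_along(ges$event_times)
         else if (inherits(ges, "ges_batch")) ges$id
         else if (length(ges) == 1L && is.numeric(ges) && ges == round(ges) &&
                  is.null(names(ges))) seq_len(ges)
         else ges
  n <- length(ids)
  capacity <- 96L * per_well
  if (n > capacity) {
    stopf("plate overflow: %d GESs exceed capacity %d by %d",
          n, capacity, n - capacity)
  }
  wells <- plate_wells()
  slot <- (seq_len(n) - 1L) %/% per_well + 1L
  out <- data.frame(well = wells[slot],
                    row = substr(wells[slot], 1, 1),
                    col = as.integer(substring(wells[slot], 2)),
                    ges_id = ids,
                    stringsAsFactors = FALSE)
  class(out) <- c("plate_map", "data.frame")
  out
}

#' @export
print.plate_map <- function(x, ...) {
  occ <- table(x$well)
  cat(sprintf("plate map: %d GES(s) in %d well(s) (max %d per well)\n",
              nrow(x), length(occ), if (length(occ)) max(occ) else 0L))
  invisible(x)
}

#' Write a plate map as long-format CSV (`well,ges_id`)
#' @param plate A `plate_map`.
#' @param path Output path.
#' @export
write_plate_map <- function(plate, path) {
  write.csv(plate[, c("well", "ges_id")], path, row.names = FALSE)
  invisible(path)
}
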