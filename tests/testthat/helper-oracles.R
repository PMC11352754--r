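# Independent oracles used across the suite. These re-derive results with
# naive loops / flood fills so they share no code path with the package
# implementation they check.

# 4-connected component count by explicit flood fill.
flood_count <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  k <- 0L
  for (start in which(mask > 0 & lab == 0L)) {
    if (lab[start] > 0L) next
    k <- k + 1L
    queue <- start
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      if (lab[i] > 0L || mask[i] == 0) next
      lab[i] <- k
      r <- (i - 1L) %% nrow(mask) + 1L
      c <- (i - 1L) %/% nrow(mask) + 1L
      nb <- c(if (r > 1) i - 1L, if (r < nrow(mask)) i + 1L,
              if (c > 1) i - nrow(mask), if (c < ncol(mask)) i + nrow(mask))
      nb <- nb[mask[nb] > 0 & lab[nb] == 0L]
      queue <- c(queue, nb)
    }
  }
  k
}

# Random measured-object table for cascade tests. Area is jittered off the
# disc-equivalent value so the AREA criterion can fire independently of SIZE.
random_objects <- function(n, width = 5000, height = 5000) {
  d <- runif(n, 80, 320)
  data.frame(
    id = seq_len(n),
    center_x_um = runif(n, 0, width),
    center_y_um = runif(n, 0, height),
    area_um2 = pi / 4 * d^2 * runif(n, 0.85, 1.15),
    perimeter_um = pi * d,
    diameter_um = d,
    circularity = runif(n, 0.4, 1),
    mean_fluor = sample(c(300, 20000), n, replace = TRUE))
}

random_selection_config <- function() {
  selection_config(
    fluor_threshold = runif(1, 1000, 10000),
    diameter_min = runif(1, 120, 200),
    diameter_max = runif(1, 210, 300),
    area_min = runif(1, 1e4, 3e4),
    area_max = runif(1, 3.5e4, 8e4),
    circularity_min = runif(1, 0.5, 0.95),
    ges_footprint_diameter = runif(1, 320, 700),
    min_edge_gap = runif(1, 0, 120),
    boundary_margin = runif(1, 0, 600))
}

# Brute-force re-implementation of the whole cascade with explicit loops.
oracle_selection <- function(objects, width, height, config) {
  n <- nrow(objects)
  status <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (objects$mean_fluor[i] < config$fluor_threshold) status[i] <- "NOT_VIABLE"
  }
  for (i in seq_len(n)) {
    if (!is.na(status[i])) next
    if (objects$diameter_um[i] < config$diameter_min ||
        objects$diameter_um[i] > config$diameter_max) {
      status[i] <- "SIZE"
    } else if (objects$area_um2[i] < config$area_min ||
               objects$area_um2[i] > config$area_max) {
      status[i] <- "AREA"
    } else if (objects$circularity[i] < config$circularity_min) {
      status[i] <- "MORPHOLOGY"
    }
  }
  for (i in seq_len(n)) {
    if (!is.na(status[i])) next
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- sqrt((objects$center_x_um[i] - objects$center_x_um[j])^2 +
                  (objects$center_y_um[i] - objects$center_y_um[j])^2)
      if (dij < config$ges_footprint_diameter / 2 + objects$diameter_um[j] / 2) {
        status[i] <- "PROXIMITY"
        break
      }
    }
  }
  cand <- which(is.na(status))
  if (length(cand)) {
    ord <- cand[order(-objects$circularity[cand], -objects$diameter_um[cand],
                      objects$id[cand])]
    kept <- integer(0)
    limit <- config$ges_footprint_diameter + config$min_edge_gap
    for (i in ord) {
      ok <- TRUE
      for (j in kept) {
        dij <- sqrt((objects$center_x_um[i] - objects$center_x_um[j])^2 +
                    (objects$center_y_um[i] - objects$center_y_um[j])^2)
        if (dij < limit) { ok <- FALSE; break }
      }
      if (ok) kept <- c(kept, i) else status[i] <- "OVERLAP"
    }
    for (i in kept) {
      edge <- min(objects$center_x_um[i], objects$center_y_um[i],
                  width - objects$center_x_um[i],
                  height - objects$center_y_um[i])
      if (edge < config$boundary_margin) status[i] <- "BOUNDARY"
    }
  }
  list(selected = objects$id[is.na(status)], status = status)
}

# Small single-object chamber used by round-trip tests.
single_object_chamber <- function(diameter, circularity, viable = TRUE,
                                  pixel_size = 2, seed = 1L,
                                  noise_sigma = 0) {
  size <- max(4 * diameter, 600)
  spec <- chamber_spec(width = size, height = size, pixel_size = pixel_size,
                       noise_sigma = noise_sigma, seed = seed)
  truth <- data.frame(id = 1L, center_x_um = size / 2, center_y_um = size / 2,
                      diameter_um = diameter, circularity = circularity,
                      viable = viable, kind = "spheroid",
                      stringsAsFactors = FALSE)
  generate_chamber(spec, truth)
}
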