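mk_objects <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    defaults <- list(id = 1L, center_x_um = 2000, center_y_um = 2000,
                     diameter_um = 207, area_um2 = pi / 4 * 207^2,
                     perimeter_um = pi * 207, circularity = 0.95,
                     mean_fluor = 20000)
    as.data.frame(modifyList(defaults, r))
  }))
}

chamber4k <- list(width = 4000, height = 4000)

test_that("viability gate honours the >= threshold convention", {
  obj <- mk_objects(list(id = 1L, mean_fluor = 0),
                    list(id = 2L, mean_fluor = 4999),
                    list(id = 3L, mean_fluor = 5000),
                    list(id = 4L, mean_fluor = 20000))
  expect_true(all(viability_gate(obj, 0)$viable))
  g <- viability_gate(obj, 5000)
  expect_equal(g$viable, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(nrow(viability_gate(obj[0, ], 5000)), 0L)
})

test_that("viability gate separates a mixed fixture at the fluor midpoint", {
  spec <- chamber_spec(width = 6000, height = 6000, pixel_size = 4, seed = 12)
  pop <- sample_population(n = 10, diameter_dist = c(120, 250),
                           circularity_dist = c(0.7, 1), viable_frac = 1,
                           chamber = spec, seed = 12)
  pop$viable <- seq_len(10) <= 4
  img <- generate_chamber(spec, pop)
  obj <- detect_objects(img$darkfield, img$fluorescence, detect_config(),
                        spec$pixel_size)
  thr <- (spec$background_level + spec$fluor_level) / 2
  expect_equal(sum(viability_gate(obj, thr)$viable), 4L)
})

test_that("spheroid filter reports the first violated criterion", {
  cfg <- selection_config()
  obj <- mk_objects(list(id = 1L),                                  # in-window
                    list(id = 2L, diameter_um = 300),               # SIZE
                    list(id = 3L, circularity = 0.6),               # MORPHOLOGY
                    list(id = 4L, area_um2 = pi / 4 * 230^2),       # AREA
                    list(id = 5L, diameter_um = 300, circularity = 0.3))
  v <- spheroid_filter(obj, cfg)
  expect_equal(v, c("PASS", "SIZE", "MORPHOLOGY", "AREA", "SIZE"))
})

test_that("proximity filter rejects candidates with anything in their footprint", {
  cfg <- selection_config()
  lone <- mk_objects(list(id = 1L))
  expect_true(proximity_filter(lone, lone, cfg))

  pair <- mk_objects(list(id = 1L),
                     list(id = 2L, center_x_um = 2100, diameter_um = 40,
                          mean_fluor = 300))      # debris 100 um away
  expect_false(proximity_filter(pair[1, ], pair, cfg))
})

test_that("overlap filter keeps the better of two conflicting candidates", {
  cfg <- selection_config()
  far <- mk_objects(list(id = 1L),
                    list(id = 2L, center_x_um = 3000))
  expect_equal(overlap_filter(far, cfg), c(TRUE, TRUE))

  near <- mk_objects(list(id = 1L, circularity = 0.85),
                     list(id = 2L, center_x_um = 2500, circularity = 0.95))
  kept <- overlap_filter(near, cfg)
  expect_equal(kept, c(FALSE, TRUE))
})

test_that("boundary filter applies the >= margin convention", {
  cfg <- selection_config()   # margin 325
  obj <- mk_objects(list(id = 1L),
                    list(id = 2L, center_x_um = 325),
                    list(id = 3L, center_x_um = 10))
  ok <- boundary_filter(obj, chamber4k$width, chamber4k$height, cfg)
  expect_equal(ok, c(TRUE, TRUE, FALSE))
})

test_that("the cascade selects an isolated in-window spheroid and rejects it at the wall", {
  obj <- mk_objects(list(id = 1L))
  res <- run_selection(obj, chamber4k, selection_config())
  expect_equal(res$selected$id, 1L)
  expect_equal(nrow(res$rejected), 0L)

  wall <- mk_objects(list(id = 1L, center_x_um = 10))
  res2 <- run_selection(wall, chamber4k, selection_config())
  expect_equal(nrow(res2$selected), 0L)
  expect_equal(res2$rejected$reason, "BOUNDARY")

  empty <- run_selection(mk_objects(list(id = 1L))[0, ], chamber4k,
                         selection_config())
  expect_equal(nrow(empty$selected), 0L)
  expect_equal(nrow(empty$rejected), 0L)
})

test_that("cascade output equals the brute-force oracle on random instances", {
  set.seed(7)
  for (k in 1:150) {
    n <- sample(1:50, 1)
    obj <- random_objects(n)
    cfg <- random_selection_config()
    res <- run_selection(obj, list(width = 5000, height = 5000), cfg)
    orc <- oracle_selection(obj, 5000, 5000, cfg)
    expect_identical(res$selected$id, sort(orc$selected))
    expect_identical(res$objects$reason[match(res$rejected$id, res$objects$id)],
                     orc$status[!is.na(orc$status)])
  }
})

test_that("every selection partitions ids with one reason each", {
  set.seed(17)
  for (k in 1:20) {
    obj <- random_objects(40)
    res <- run_selection(obj, list(width = 5000, height = 5000),
                         random_selection_config())
    expect_setequal(c(res$selected$id, res$rejected$id), obj$id)
    expect_equal(nrow(res$selected) + nrow(res$rejected), nrow(obj))
    expect_true(all(res$rejected$reason %in%
                      c("NOT_VIABLE", "SIZE", "AREA", "MORPHOLOGY",
                        "PROXIMITY", "OVERLAP", "BOUNDARY")))
  }
})

test_that("selected sets satisfy the pairwise spacing and wall guarantees", {
  set.seed(27)
  for (k in 1:20) {
    obj <- random_objects(40)
    cfg <- random_selection_config()
    res <- run_selection(obj, list(width = 5000, height = 5000), cfg)
    s <- res$selected
    if (nrow(s) > 1) {
      dm <- as.matrix(dist(s[, c("center_x_um", "center_y_um")]))
      expect_gte(min(dm[upper.tri(dm)]),
                 cfg$ges_footprint_diameter + cfg$min_edge_gap)
    }
    if (nrow(s) > 0) {
      expect_gte(min(s$center_x_um, s$center_y_um,
                     5000 - s$center_x_um, 5000 - s$center_y_um),
                 cfg$boundary_margin)
    }
  }
})

test_that("tightening per-object filters never widens their pass sets", {
  set.seed(37)
  obj <- random_objects(60)
  base <- selection_config(fluor_threshold = 5000, diameter_min = 150,
                           diameter_max = 280, area_min = 1e4, area_max = 7e4,
                           circularity_min = 0.6,
                           ges_footprint_diameter = 400, min_edge_gap = 40,
                           boundary_margin = 300)
  tighter <- selection_config(fluor_threshold = 8000, diameter_min = 170,
                              diameter_max = 260, area_min = 1.5e4,
                              area_max = 6e4, circularity_min = 0.7,
                              ges_footprint_diameter = 450,
                              min_edge_gap = 60, boundary_margin = 360)
  gated_b <- viability_gate(obj, base$fluor_threshold)
  gated_t <- viability_gate(obj, tighter$fluor_threshold)
  expect_true(all(obj$id[gated_t$viable] %in% obj$id[gated_b$viable]))
  pass_b <- obj$id[spheroid_filter(obj, base) == "PASS"]
  pass_t <- obj$id[spheroid_filter(obj, tighter) == "PASS"]
  expect_true(all(pass_t %in% pass_b))
  prox_b <- obj$id[proximity_filter(obj, obj, base)]
  prox_t <- obj$id[proximity_filter(obj, obj, tighter)]
  expect_true(all(prox_t %in% prox_b))
  bnd_b <- obj$id[boundary_filter(obj, 5000, 5000, base)]
  bnd_t <- obj$id[boundary_filter(obj, 5000, 5000, tighter)]
  expect_true(all(bnd_t %in% bnd_b))
})

test_that("tightened selections only ever contain pre-overlap survivors of the base config", {
  # greedy conflict resolution makes the *final* set non-monotone (dropping
  # a kept candidate can free its neighbours), but a tightened run can never
  # promote an object the base config rejected for viability, the spheroid
  # windows, or proximity
  set.seed(47)
  for (k in 1:30) {
    obj <- random_objects(40)
    base <- selection_config(fluor_threshold = 2000, diameter_min = 140,
                             diameter_max = 290, area_min = 1e4,
                             area_max = 7.5e4, circularity_min = 0.55,
                             ges_footprint_diameter = 350,
                             min_edge_gap = 30, boundary_margin = 200)
    tight <- base
    tight$circularity_min <- base$circularity_min + runif(1, 0, 0.3)
    tight$diameter_min <- base$diameter_min + runif(1, 0, 40)
    tight$fluor_threshold <- base$fluor_threshold + runif(1, 0, 5000)
    res_t <- run_selection(obj, list(width = 5000, height = 5000), tight)
    gated <- viability_gate(obj, base$fluor_threshold)
    ok <- gated$viable & spheroid_filter(obj, base) == "PASS" &
      proximity_filter(obj, obj, base)
    expect_true(all(res_t$selected$id %in% obj$id[ok]))
  }
})

test_that("selection results serialize to CSV and JSON", {
  obj <- mk_objects(list(id = 1L), list(id = 2L, diameter_um = 300,
                                        center_x_um = 1000))
  res <- run_selection(obj, chamber4k, selection_config())
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "sel.csv"); js <- file.path(dir, "sel.json")
  write_selection(res, csv, js)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$status, c("SELECTED", "REJECTED"))
  snap <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(snap$config$diameter_min, 200)
  expect_equal(nrow(snap$selected), 1L)
})
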