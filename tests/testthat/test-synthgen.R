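test_that("unperturbed discs measure as near-perfect circles", {
  m <- generate_shape(200, 1.0, pixel_size = 2, seed = 1)
  meas <- attr(m, "measured")
  expect_gte(meas$circularity, 0.95)
  expect_lt(abs(meas$diameter - 200) / 200, 0.05)
  expect_equal(flood_count(m), 1L)

  # smallest legal disc at the precondition boundary
  tiny <- generate_shape(8, 1.0, pixel_size = 2, seed = 1)
  expect_equal(flood_count(tiny), 1L)
  expect_error(generate_shape(7.9, 1.0, pixel_size = 2), "4 \\* pixel_size")
  expect_error(generate_shape(200, 0.2, pixel_size = 2), "circularity_target")
})

test_that("calibrated shapes hit diameter and circularity targets", {
  cases <- expand.grid(d = c(120, 207, 300), circ = c(0.5, 0.6, 0.8))
  for (i in seq_len(nrow(cases))) {
    m <- generate_shape(cases$d[i], cases$circ[i], pixel_size = 2,
                        seed = 100 + i)
    meas <- attr(m, "measured")
    expect_lt(abs(meas$circularity - cases$circ[i]), 0.05)
    expect_lt(abs(meas$diameter - cases$d[i]) / cases$d[i], 0.05)
    expect_equal(flood_count(m), 1L)
  }
})

test_that("infeasible circularity targets raise a calibration error", {
  # at 4 px across, the raster cannot express a 0.3-circularity outline
  expect_error(generate_shape(20, 0.3, pixel_size = 5, seed = 1),
               "calibrate|calibration")
})

test_that("population sampling is reproducible and matches its distributions", {
  spec <- chamber_spec(width = 20000, height = 20000, pixel_size = 4, seed = 9)
  a <- sample_population(n = 100, diameter_dist = c(100, 300),
                         chamber = spec, seed = 7)
  b <- sample_population(n = 100, diameter_dist = c(100, 300),
                         chamber = spec, seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(sample_population(0, chamber = spec, seed = 1)), 0L)

  pop <- sample_population(n = 1000, diameter_dist = c(100, 300),
                           circularity_dist = c(0.5, 1), viable_frac = 0.7,
                           chamber = chamber_spec(width = 40000,
                                                  height = 40000,
                                                  pixel_size = 4, seed = 2),
                           seed = 11)
  expect_gt(ks.test(pop$diameter_um, "punif", 100, 300)$p.value, 0.01)
  expect_gt(ks.test(pop$circularity, "punif", 0.5, 1)$p.value, 0.01)
  # binomial 99% interval around 700 viable
  expect_true(abs(sum(pop$viable) - 700) < 2.58 * sqrt(1000 * 0.7 * 0.3) + 1)
})

test_that("saturated placement fails with a helpful error", {
  spec <- chamber_spec(width = 1200, height = 1200, seed = 1)
  expect_error(
    sample_population(n = 60, diameter_dist = c(250, 300), chamber = spec,
                      seed = 1, max_attempts = 2000),
    "larger chamber")
})

test_that("chamber renders objects in darkfield and viable objects in fluorescence", {
  spec <- chamber_spec(width = 3000, height = 3000, pixel_size = 2,
                       noise_sigma = 0, seed = 3)
  pop <- sample_population(n = 10, diameter_dist = c(100, 200),
                           circularity_dist = c(0.7, 1), viable_frac = 1,
                           chamber = spec, seed = 3)
  pop$viable <- c(rep(TRUE, 4), rep(FALSE, 6))
  img <- generate_chamber(spec, pop)
  mid <- (spec$background_level + spec$foreground_level) / 2
  expect_equal(flood_count(img$darkfield > mid), 10L)
  midf <- (spec$background_level + spec$fluor_level) / 2
  expect_equal(flood_count(img$fluorescence > midf), 4L)
  # fluorescence footprint is a subset of the darkfield footprint
  expect_true(all(img$darkfield[img$fluorescence > midf] > mid))
})

test_that("empty chambers render pure noise and placement errors name ids", {
  spec <- chamber_spec(width = 1000, height = 1000, noise_sigma = 0, seed = 1)
  img <- generate_chamber(spec, sample_population(0, chamber = spec))
  expect_true(all(img$darkfield == spec$background_level))
  expect_equal(nrow(img$truth), 0L)

  bad <- data.frame(id = 7L, center_x_um = 30, center_y_um = 500,
                    diameter_um = 100, circularity = 0.9, viable = TRUE,
                    kind = "spheroid")
  expect_error(generate_chamber(spec, bad), "id 7")
})

test_that("chamber generation is seed-deterministic", {
  spec <- chamber_spec(width = 1500, height = 1500, seed = 8)
  pop <- sample_population(n = 4, diameter_dist = c(80, 150),
                           chamber = spec, seed = 8)
  a <- generate_chamber(spec, pop)
  b <- generate_chamber(spec, pop)
  expect_identical(a$darkfield, b$darkfield)
  expect_identical(a$fluorescence, b$fluorescence)
  expect_identical(a$truth, b$truth)
})

test_that("chamber images survive a write/read round trip", {
  spec <- chamber_spec(width = 800, height = 800, seed = 4)
  pop <- sample_population(n = 2, diameter_dist = c(80, 120),
                           chamber = spec, seed = 4)
  img <- generate_chamber(spec, pop)
  dir <- withr::local_tempdir()
  paths <- write_chamber(img, dir)
  back <- read_image(paths[1])
  expect_equal(dim(back), dim(img$darkfield))
  # 16-bit quantisation: within one intensity step everywhere
  expect_lt(max(abs(back - pmin(pmax(img$darkfield, 0), 65535))), 1.01)
  truth <- read.csv(paths[3])
  expect_equal(truth$diameter_um, img$truth$diameter_um)
})

test_that("detector traces place spikes at their arrival times", {
  # noiseless: apex lands on the exact sample index
  sp <- trace_spec(arrival_times = 1, sampling_rate = 1000,
                   baseline_sigma = 0, spike_amplitude = 20)
  tr <- generate_trace(sp)
  expect_equal(which.max(tr$intensity), 1001L)   # t = 1 s is sample 1000 + 1

  # three arrivals at 10x sigma: exactly three upward crossings of +5 sigma
  sp3 <- trace_spec(arrival_times = c(1, 2, 3), sampling_rate = 1000,
                    baseline = 100, baseline_sigma = 0,
                    spike_amplitude = 20, spike_width = 0.05)
  y <- generate_trace(sp3)$intensity
  thr <- 100 + 5 * 2   # baseline + 5 * (the noisy case's sigma)
  crossings <- sum(y[-1] > thr & y[-length(y)] <= thr)
  expect_equal(crossings, 3L)
})

test_that("trace generation enforces spike separation and is deterministic", {
  expect_error(trace_spec(arrival_times = c(1, 1.02), spike_width = 0.05),
               "overlap")
  expect_error(trace_spec(arrival_times = c(2, 1)), "increasing")
  sp <- trace_spec(arrival_times = c(0.5, 1.5), seed = 6)
  expect_identical(generate_trace(sp), generate_trace(sp))
  # empty trace stays within 5 sigma of baseline (fixed seed)
  quiet <- generate_trace(trace_spec(arrival_times = numeric(0),
                                     baseline = 100, baseline_sigma = 2,
                                     duration = 2, seed = 1))
  expect_lt(max(abs(quiet$intensity - 100)), 5 * 2)
})
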