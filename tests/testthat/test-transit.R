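test_that("cell shape conserves volume exactly across the deformation family", {
  cell <- cell_model()
  V0 <- 4 / 3 * pi * 4^3
  sph <- cell_shape(4, 4, cell)
  expect_equal(sph$volume, V0, tolerance = 1e-12)
  expect_equal(sph$body_length, 0, tolerance = 1e-9)
  expect_equal(sph$a_cap, 4, tolerance = 1e-9)
  set.seed(11)
  for (i in 1:50) {
    w <- runif(1, 1.2, 4); h <- runif(1, 1.2, 6)
    shp <- cell_shape(w, h, cell)
    expect_equal(shp$volume, V0, tolerance = 1e-12)
    expect_gte(shp$body_length, 0)
    expect_equal(shp$area, 4 * w * h - (4 - pi) * min(w, h)^2)
  }
  expect_error(cell_shape(-1, 2, cell), "infeasible")
})

test_that("peak detection finds prominent maxima, including boundary peaks", {
  # interior peaks of a synthetic series
  v <- c(1, 5, 1, 2, 9, 2, 1)
  expect_equal(detect_velocity_peaks(v), c(2, 5))
  # twin bumps separated by a shallow dip: the lower twin has only the
  # dip's prominence and is filtered; the higher twin survives
  v2 <- c(1, 5, 4.9, 5.05, 1, 9, 1)
  expect_equal(detect_velocity_peaks(v2, prominence = 0.1), c(4, 6))
  # a series that starts at its maximum still yields that first peak
  # (the cell starts from rest, so the series is padded with zeros)
  v3 <- c(9, 5, 2, 6, 1)
  expect_equal(detect_velocity_peaks(v3), c(1, 4))
  expect_error(detect_velocity_peaks(c(1, 2)), "at least 3")
})

test_that("the control transit behaves like the reference transit", {
  rec <- simulate_transit(rect_channel())
  expect_s3_class(rec, "transit_record")
  expect_true(rec$completed)
  expect_false(rec$stalled)
  # two-peak velocity structure and a positive transit time between them
  expect_length(rec$peaks, 2)
  expect_equal(rec$T, transit_time(rec))
  expect_gt(rec$T, 0.05)
  expect_lt(rec$T, 2)
  # volume conserved, no wall penetration
  expect_lt(rec$volume_error_max, 1e-6)
  expect_gte(rec$clearance_min, -1e-9)
  # free flight in the straight region is fast; the crawl is slow
  expect_gt(max(rec$v), 250)
  expect_lt(min(rec$v[rec$v > 0]), 50)
  # the cell squeezes below the resting radius; after expulsion the
  # cortical tension is driving it back toward the resting shape (the run
  # ends shortly after the throat, so recovery is under way, not complete)
  expect_lt(min(rec$w), 4.368 / 2)
  expect_gt(rec$w[length(rec$w)], min(rec$w) + 0.5)
  expect_gt(rec$w[length(rec$w)], rec$w[length(rec$w) - 10])
  # most of the transit is spent upstream of the throat
  seg <- rec$peaks[1]:rec$peaks[2]
  expect_gt(mean(rec$x[seg] < 0), 0.9)
  # methods
  expect_output(print(rec), "completed")
  expect_output(summary(rec), "volume error")
  d <- as.data.frame(rec)
  expect_equal(nrow(d), length(rec$t))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(rec))
})

test_that("a wide-open constriction lets the cell pass without a transit signature", {
  # throat wider than the cell: no side contact, no slow crawl
  ch <- rect_channel(W_con = 8.5)
  expect_false(first_contact(ch, 4)$contact_exists)
  rec <- simulate_transit(ch, max_steps = 4000)
  expect_true(rec$completed)
  expect_gt(min(rec$v), 100)   # never slows to a crawl
})

test_that("transits respect a step budget and report incompleteness honestly", {
  rec <- simulate_transit(rect_channel(), max_steps = 50)
  expect_false(rec$completed)
  expect_true(is.na(rec$T))
  expect_length(rec$t, 50)
  expect_output(print(rec), "incomplete")
})
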