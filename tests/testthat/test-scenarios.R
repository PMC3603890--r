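test_that("reference scenario grids encode the study design", {
  asp <- scenario_grid("aspect")
  expect_s3_class(asp, "scenario_grid")
  hw <- t(vapply(asp$configs,
                 function(cf) c(cf$channel$H, cf$channel$W_con), numeric(2)))
  expect_equal(hw[, 1], c(7.2, 8.2, 10.2))
  expect_equal(hw[, 2], c(4.717, 4.368, 3.955))
  # all three share the 5.70-um nominal throat hydraulic diameter
  expect_equal(round(hydraulic_diameter(hw[, 1], hw[, 2]), 2), rep(5.70, 3))

  ctl <- scenario_grid("control")
  expect_length(ctl$configs, 1)
  ch <- ctl$configs[[1]]$channel
  expect_equal(round(hydraulic_diameter(ch$H, ch$W_con), 2), 5.70)

  rad <- scenario_grid("radius")
  Rs <- vapply(rad$configs, function(cf) cf$channel$R_con, numeric(1))
  expect_equal(Rs, c(16.15, 27.525, 42.15))
  # configs differ only in R_con
  others <- lapply(rad$configs, function(cf)
    cf$channel[c("W", "L", "H", "W_con", "delta")])
  expect_equal(others[[1]], others[[2]])
  expect_equal(others[[1]], others[[3]])

  hs <- vapply(scenario_grid("height")$configs,
               function(cf) cf$channel$H, numeric(1))
  expect_equal(range(hs), c(7.2, 16.2))
  expect_true(10.86 %in% hs)

  expect_s3_class(scenario_grid("axisym")$configs[[1]]$channel,
                  "axisym_channel")
  expect_error(scenario_grid("nope"))
  expect_output(print(asp), "aspect")
})

test_that("random scenario grids are valid and reproducible", {
  g1 <- random_scenarios(seed = 1, n = 5)
  g2 <- random_scenarios(seed = 1, n = 5)
  expect_identical(g1$configs, g2$configs)
  expect_false(identical(g1$configs,
                         random_scenarios(seed = 3, n = 5)$configs))
  for (cf in random_scenarios(seed = 2, n = 100)$configs) {
    ch <- cf$channel
    # cell contacts the constriction: imaginary half-throat below R_cell
    expect_lt(ch$W_con / 2 - ch$delta, cf$cell$R_cell)
    expect_true(first_contact(ch, cf$cell$R_cell)$contact_exists)
    expect_true(is.finite(squeeze_length(ch, cf$cell$R_cell)))
  }
  expect_error(random_scenarios(seed = 1, n = 2, W_con_range = c(9, 10)),
               "infeasible")
  # drawing a grid does not disturb the caller's RNG stream
  set.seed(7); before <- runif(1)
  set.seed(7); invisible(random_scenarios(seed = 1, n = 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("synthetic velocity traces exercise peak detection as designed", {
  tr <- synthetic_velocity_trace()
  pk <- detect_velocity_peaks(tr)
  expect_length(pk, 2)
  expect_equal(tr$t[pk], c(0.05, 0.90), tolerance = 1e-6)
  expect_equal(diff(tr$t[pk]), 0.85, tolerance = 1e-6)
  # single peak: transit time is undefined and errors as specified
  one <- synthetic_velocity_trace(peak_times = 0.3, peak_heights = 300,
                                  peak_widths = 0.01)
  expect_error(transit_time(one), "fewer than two")
  # 1% noise does not destroy the peaks
  nz <- synthetic_velocity_trace(noise = 0.01, seed = 5)
  pk2 <- detect_velocity_peaks(nz)
  expect_lt(abs(nz$t[pk2[1]] - 0.05), 0.02)
  expect_lt(abs(nz$t[pk2[length(pk2)]] - 0.90), 0.02)
})

test_that("synthetic power-law samples are exact at sigma = 0 and reproducible", {
  x <- c(16.15, 27.525, 42.15)
  d0 <- synthetic_powerlaw_samples(x, 6.10, -0.615)
  expect_equal(d0$y, 6.10 * x^-0.615)
  f <- fit_power_law(d0$x, d0$y)
  expect_equal(f$coeff, 6.10, tolerance = 1e-10)
  expect_equal(f$exponent, -0.615, tolerance = 1e-10)
  d1 <- synthetic_powerlaw_samples(x, 6.10, -0.615, sigma = 0.1, seed = 9)
  d2 <- synthetic_powerlaw_samples(x, 6.10, -0.615, sigma = 0.1, seed = 9)
  expect_identical(d1, d2)
  expect_error(synthetic_powerlaw_samples(c(-1, 2), 1, 1))
})

test_that("run configurations round-trip through YAML", {
  cfg <- scenario_grid("control")$configs[[1]]
  path <- tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_equal(back$channel, cfg$channel)
  expect_equal(back$cell, cfg$cell)
  expect_equal(back$plasma, cfg$plasma)
  expect_equal(back$dP_total, 40)
  expect_equal(back$dt, 0.001)
  # axisym round trip
  cfa <- scenario_grid("axisym")$configs[[1]]
  write_run_config(cfa, path)
  expect_equal(read_run_config(path)$channel, cfa$channel)
  unlink(path)
})
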