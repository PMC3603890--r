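test_that("rectangular duct conductance agrees with the exact series solution", {
  pl <- plasma_model()
  for (dims in list(c(22.36, 8.2), c(4.368, 8.2), c(5, 5), c(30, 3))) {
    c_corr <- rect_duct_conductance(dims[1], dims[2], 100, pl)
    c_exact <- rect_duct_conductance_series(dims[1], dims[2], 100, pl)
    expect_equal(c_corr, c_exact, tolerance = 5e-3)
  }
  # symmetric in width/height and inversely proportional to length
  expect_equal(rect_duct_conductance(8, 3, 50, pl),
               rect_duct_conductance(3, 8, 50, pl))
  expect_equal(rect_duct_conductance(8, 3, 50, pl),
               2 * rect_duct_conductance(8, 3, 100, pl))
})

test_that("gutter conductance reproduces Hagen-Poiseuille in the circular limit", {
  pl <- plasma_model()
  a <- 1.7; L <- 40
  expect_equal(gutter_conductance(pi * a^2, 2 * pi * a, L, pl),
               oracle_circular_conductance(a, L, pl), tolerance = 1e-12)
  # sums over gutters, and zero area (perfect seal) conducts nothing
  one <- gutter_conductance(2, 6, L, pl)
  expect_equal(gutter_conductance(rep(2, 4), rep(6, 4), L, pl), 4 * one)
  expect_equal(gutter_conductance(0, 1, L, pl), 0)
  expect_equal(gutter_conductance(c(0, 2), c(0, 6), L, pl), one)
})

test_that("pressure partition network has the correct limits", {
  # sealed (no gutters, no bypass): the whole drop loads the cell
  p <- pressure_partition(40, 1, 1, 0)
  expect_equal(p$dP_cell, 40)
  expect_equal(p$Q_total, 0)
  # short circuit: huge gutter conductance removes the load
  expect_lt(pressure_partition(40, 1, 1, 1e9)$dP_cell, 1e-6)
  # monotone decreasing in the gutter conductance
  dp <- vapply(c(0, 1, 10, 100),
               function(C) pressure_partition(40, 0.5, 0.5, C)$dP_cell,
               numeric(1))
  expect_true(all(diff(dp) < 0))
  # an open bypass path acts like an extra conductance
  expect_equal(pressure_partition(40, 1, 1, 2, R_occluded = 0.5)$dP_cell,
               pressure_partition(40, 1, 1, 4)$dP_cell)
  # piston flux of the advancing cell consumes part of the drop
  expect_lt(pressure_partition(40, 1, 1, 1, Q_cell = 5)$dP_cell,
            pressure_partition(40, 1, 1, 1)$dP_cell)
  # flow bookkeeping: total = gutter + bypass + piston
  p2 <- pressure_partition(40, 1, 2, 3, R_occluded = 2, Q_cell = 1)
  expect_equal(p2$Q_total, p2$Q_gutter + p2$Q_bypass + 1)
})

test_that("channel resistance is positive, additive and larger for narrower lumens", {
  pl <- plasma_model()
  ch <- rect_channel()
  r_all <- channel_resistance(ch, -50, 100, pl)
  r_a <- channel_resistance(ch, -50, 0, pl)
  r_b <- channel_resistance(ch, 0, 100, pl)
  expect_gt(r_all, 0)
  expect_equal(r_all, r_a + r_b, tolerance = 1e-9)
  # the constricted span resists more than an equal-length straight span
  expect_gt(channel_resistance(ch, -13, 13, pl),
            channel_resistance(ch, -45, -19, pl))
  # axisymmetric: matches the Hagen-Poiseuille integral in a straight span
  ca <- axisym_channel()
  expect_equal(channel_resistance(ca, -50, -30, pl),
               8 * pl$viscosity * 20 / (pi * 6^4), tolerance = 1e-6)
})
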