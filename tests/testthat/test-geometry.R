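test_that("channel constructors validate their arguments", {
  expect_s3_class(axisym_channel(), "axisym_channel")
  expect_s3_class(rect_channel(), "rect_channel")
  expect_error(axisym_channel(r_min = 7), "throat radius")
  expect_error(axisym_channel(delta = 3), "offset")
  expect_error(axisym_channel(r_con = 1), "arc never reaches")
  expect_error(rect_channel(W_con = 30), "throat width")
  expect_error(rect_channel(delta = 3), "offset")
  expect_error(rect_channel(R_con = 2), "arc never reaches")
  expect_error(rect_channel(H = 0.1), "height")
})

test_that("axisymmetric lumen profile has the reference throat and pipe radii", {
  ch <- axisym_channel()
  expect_equal(axisym_radius_at(ch, 0), 2.85)
  expect_equal(axisym_radius_at(ch, 0, imaginary = TRUE), 2.75)
  expect_equal(axisym_radius_at(ch, -40), 6)
  expect_equal(axisym_radius_at(ch, 90), 6)
  # monotone narrowing on the approach to the throat
  x <- seq(-13, 0, by = 0.5)
  expect_true(all(diff(axisym_radius_at(ch, x)) < 0))
  # symmetric about the throat plane
  expect_equal(axisym_radius_at(ch, -5), axisym_radius_at(ch, 5))
  expect_error(axisym_radius_at(ch, -60), "outside the channel")
})

test_that("rectangular lumen profile follows the side-wall arcs and the height ramp", {
  ch <- rect_channel()
  expect_equal(rect_half_width_at(ch, 0), 4.368 / 2)
  expect_equal(rect_half_width_at(ch, 0, imaginary = TRUE), 4.368 / 2 - 0.1)
  expect_equal(rect_half_width_at(ch, -45), 22.36 / 2)
  expect_equal(rect_height_at(ch, 0), 8.2)
  expect_equal(rect_height_at(ch, 0, imaginary = TRUE), 8.0)
  # constant height when H >= H_inlet
  expect_equal(rect_height_at(rect_channel(H = 12), c(-45, 0, 50)),
               rep(12, 3))
  # ramped height when H < H_inlet: H_inlet upstream, H downstream,
  # strictly decreasing across the ramp
  ch2 <- rect_channel(H = 7.2)
  expect_equal(rect_height_at(ch2, -45), 8.2)
  expect_equal(rect_height_at(ch2, -30), 7.2)
  xr <- seq(-40.17, -35, length.out = 9)
  expect_true(all(diff(rect_height_at(ch2, xr)) < 0))
})

test_that("lumen_section is consistent with the scalar accessors", {
  ch <- rect_channel()
  ls <- lumen_section(ch, c(-20, 0), imaginary = TRUE)
  expect_equal(ls$half_width, rect_half_width_at(ch, c(-20, 0), TRUE))
  expect_equal(ls$height, rect_height_at(ch, c(-20, 0), TRUE))
  expect_equal(ls$area, 2 * ls$half_width * ls$height)
  expect_equal(ls$D_h, 4 * ls$area / ls$perimeter)
  ca <- axisym_channel()
  la <- lumen_section(ca, 0)
  expect_equal(la$area, pi * 2.85^2)
  expect_equal(la$D_h, 2 * 2.85)
})

test_that("constricted region of the reference capillary is 26 um on the imaginary wall", {
  expect_equal(constricted_length(axisym_channel()), 26, tolerance = 0.005)
  # the physical (non-offset) surface has a slightly different span
  expect_false(isTRUE(all.equal(constricted_length(axisym_channel(), FALSE),
                                26, tolerance = 1e-3)))
  # wider arcs span longer constricted regions
  expect_gt(constricted_length(rect_channel(R_con = 42.15)),
            constricted_length(rect_channel(R_con = 16.15)))
})

test_that("hydraulic diameter and throat-width matching reproduce the design table", {
  expect_equal(hydraulic_diameter(8.2, 4.368), 5.70, tolerance = 1e-3)
  expect_equal(hydraulic_diameter(3, 7), hydraulic_diameter(7, 3))
  expect_error(hydraulic_diameter(0, 1), "positive")
  expect_equal(equal_area_width(8.2, 2.85), 3.112, tolerance = 1e-3)
  expect_equal(equal_dh_width(8.2, 5.7), 4.368, tolerance = 1e-3)
  expect_equal(equal_dh_width(7.2, 5.7), 4.717, tolerance = 1e-3)
  expect_equal(equal_dh_width(10.2, 5.7), 3.955, tolerance = 1e-3)
  expect_error(equal_dh_width(2.8, 5.7), "infeasible")
  # round trip: the matched width reproduces the target diameter exactly
  W <- equal_dh_width(9.7, 5.7)
  expect_equal(hydraulic_diameter(9.7, W), 5.7)
})

test_that("first contact exists iff the throat is narrower than the cell", {
  fc <- first_contact(rect_channel(), 4)
  expect_true(fc$contact_exists)
  expect_gt(fc$theta, 0)
  expect_lte(fc$theta, pi / 2)
  # a tiny cell passes without touching
  fc0 <- first_contact(rect_channel(), 0.5)
  expect_false(fc0$contact_exists)
  expect_true(is.na(fc0$s))
  expect_error(contact_angle_first_contact(rect_channel(), 0.5),
               "does not contact")
  # approaching the throat the squeeze length shrinks and the angle grows
  s1 <- first_contact(rect_channel(W_con = 3.112), 4)
  s2 <- first_contact(rect_channel(W_con = 5.7), 4)
  expect_gt(s1$s, s2$s)
  expect_lt(s1$theta, s2$theta)
})

test_that("squeeze length matches the brute-force tangency oracle on random geometries", {
  grid <- random_scenarios(seed = 2, n = 100)
  for (cf in grid$configs) {
    ch <- cf$channel
    s_pkg <- squeeze_length(ch, 4)
    s_orc <- oracle_squeeze_length(ch$R_con + ch$delta,
                                   ch$W_con / 2 + ch$R_con, 4)
    expect_equal(s_pkg, s_orc, tolerance = 1e-6)
  }
  # and for the axisymmetric reference
  ca <- axisym_channel()
  expect_equal(squeeze_length(ca, 4),
               oracle_squeeze_length(ca$r_con + ca$delta,
                                     ca$r_min + ca$r_con, 4),
               tolerance = 1e-6)
})

test_that("print methods run and return invisibly", {
  expect_output(print(axisym_channel()), "Axisymmetric")
  expect_output(print(rect_channel()), "Rectangular")
})
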