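test_that("expand_radial reproduces the radial function on the lattice", {
  r <- seq(0, 3, by = 0.01)
  flat <- radial_function(r, rep(1, length(r)))
  g <- expand_radial(flat, half_extent = 1.5, spacing = 0.1)
  expect_true(all(g$values == 1))
  expect_true(any(abs(g$x) < 1e-12))  # node exactly at the origin

  para <- radial_function(r, 1 - 0.01 * r^2)
  g <- expand_radial(para, half_extent = 1.5, spacing = 0.5)
  i1 <- which(abs(g$x - 1) < 1e-9)
  # linear interpolation of the sampled parabola: error O(h^2 / 4)
  expect_equal(g$values[i1, i1], 0.98, tolerance = 1e-6)

  # fine lattice agrees with the analytic parabola everywhere
  g <- expand_radial(para, half_extent = 1.2, spacing = 0.01)
  rr <- sqrt(outer(g$x^2, g$y^2, `+`))
  expect_lt(max(abs(g$values - (1 - 0.01 * rr^2))), 1e-6)

  expect_error(expand_radial(para, half_extent = 1, spacing = 0), "spacing")
})

test_that("prp matches the closed-form rectangle and chord oracles", {
  a <- 0.002
  cc <- closed_form_prp_case(a, 2.4, 0.6)
  g <- farmer_mask()

  expect_equal(prp(cc$oar, g), cc$factor, tolerance = 2e-4)
  expect_equal(round(prp(cc$oar, g), 5), 1.00102)

  chord_exact <- 1 / (1 - a * (2.4^2 / 12 + 0.6^2 / 16))
  expect_equal(prp(cc$oar, g, weighting = "chord_weighted"),
               chord_exact, tolerance = 2e-4)

  # a second geometry, same oracle
  g2 <- chamber_geometry(1.0, 0.35)
  cc2 <- closed_form_prp_case(0.01, 1.0, 0.35)
  expect_equal(prp(cc2$oar, g2), cc2$factor, tolerance = 2e-4)
})

test_that("prp is exactly 1 for a uniform field and monotone in the droop", {
  r <- seq(0, 3, by = 0.05)
  flat <- radial_function(r, rep(1, length(r)))
  expect_identical(prp(flat, farmer_mask()), 1)

  droops <- c(0, 0.001, 0.005, 0.01, 0.02)
  vals <- vapply(droops, function(a) {
    prp(closed_form_prp_case(a, 2.4, 0.6)$oar, farmer_mask())
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 1))
})

test_that("prp grid convergence: halving the spacing moves the default profile < 0.01%", {
  rf <- fold_profile(gen_profile(profile_params(noise_sd = 0)))
  p1 <- prp(rf, farmer_mask(), spacing = 0.02)
  p2 <- prp(rf, farmer_mask(), spacing = 0.01)
  expect_lt(abs(p1 / p2 - 1), 1e-4)
})

test_that("kvol_from_grid honors the point/volume-average contract", {
  r <- seq(0, 3, by = 0.01)
  flat <- radial_function(r, rep(1, length(r)))
  g <- expand_radial(flat, half_extent = 1.3, spacing = 0.01)
  expect_equal(kvol_from_grid(g, farmer_mask()), 1)

  # lattice linear in x (odd about the center): gradient cancels
  lin <- g
  lin$values <- outer(1 + 0.05 * lin$x, rep(1, length(lin$y)))
  expect_equal(kvol_from_grid(lin, farmer_mask()), 1, tolerance = 1e-9)

  # parabolic lattice matches the closed-form oracle
  para <- radial_function(r, 1 - 0.002 * r^2)
  gp <- expand_radial(para, half_extent = 1.3, spacing = 0.01)
  expect_equal(kvol_from_grid(gp, farmer_mask()),
               closed_form_prp_case(0.002, 2.4, 0.6)$factor,
               tolerance = 2e-4)

  # mask larger than the lattice is refused
  small <- expand_radial(flat, half_extent = 0.5, spacing = 0.01)
  expect_error(kvol_from_grid(small, farmer_mask()), "exceeds")
})

test_that("generic-kvol stripping and specific-kvol insertion are exact inverses", {
  stripped <- strip_generic_kvol(1.004, 1.011)
  expect_equal(round(stripped$value, 3), 0.993)
  expect_false(stripped$includes_volume_averaging)

  expect_equal(round(strip_generic_kvol(1.0004, 1.0072)$value, 4), 0.9932)

  # identity element
  k <- quality_correction(1.004, includes_volume_averaging = TRUE,
                          source = "trs483_table")
  expect_equal(strip_generic_kvol(k, 1.0)$value, k$value)

  # round-trip to machine precision, flag restored
  back <- apply_specific_kvol(stripped, 1.011)
  expect_equal(back$value, 1.004, tolerance = 1e-15)
  expect_true(back$includes_volume_averaging)

  # double application is rejected
  expect_error(apply_specific_kvol(back, 1.0107), "double-count")
  expect_error(strip_generic_kvol(stripped, 1.011), "does not include")
  expect_error(strip_generic_kvol(-1, 1.011), ">")
})

test_that("strip/apply combine uncertainties in quadrature", {
  k <- quality_correction(1.004, includes_volume_averaging = TRUE,
                          source = "trs483_table", rel_uncertainty = 0.003)
  out <- strip_generic_kvol(k, quantity(1.011, 0.004))
  expect_equal(out$rel_uncertainty, 0.005)
  out2 <- apply_specific_kvol(out, quantity(1.0107, 0))
  expect_equal(out2$rel_uncertainty, 0.005)
})
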