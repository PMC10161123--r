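test_that("influence-quantity corrections reduce to 1 at reference conditions", {
  expect_equal(ptp(env_conditions(22.0, 101.33)), 1)
  expect_equal(pion_two_voltage(1.23, 1.23, 300, 150), 1)
  expect_equal(ppol(1.0, -1.0), 1)
})

test_that("ptp follows the air-density closed form", {
  expect_equal(ptp(env_conditions(24.0, 101.33)), 297.2 / 295.2)
  expect_equal(ptp(env_conditions(22.0, 102.00)), 101.33 / 102.00)
  expect_error(env_conditions(-300, 101.33), "absolute zero")
  expect_error(env_conditions(22, 0), "pressure")
})

test_that("two-voltage recombination follows the pulsed-beam formula", {
  # voltage ratio 2, reading ratio 1.004
  expect_equal(pion_two_voltage(1.004, 1.000, 300, 150),
               (1 - 2) / (1.004 - 2))
  # magnitude of a typical clinical Pion
  expect_equal(pion_two_voltage(1.0065, 1.000, 300, 150), 1.006542,
               tolerance = 1e-6)
  expect_error(pion_two_voltage(2.0, 1.0, 300, 150), "zero")
  expect_error(pion_two_voltage(1, 1, 150, 300), "v_high > v_low")
})

test_that("polarity correction averages the two polarities", {
  expect_equal(ppol(1.000, -0.996), 0.998)
  expect_equal(ppol(1.000, -1.004), 1.002)
  expect_equal(ppol(1.000, -1.004, used = "negative"), 2.004 / 2.008)
  expect_error(ppol(0, -1), "non-zero")
})

test_that("corrected_reading multiplies the influence corrections (worked example)", {
  corr <- table3_corrections()
  raw <- raw_reading(0.1529 * 200, 200, repeats = 5)
  with_prp <- corrected_reading(raw, corr, include_prp = TRUE)
  expect_equal(with_prp$value, 0.154530, tolerance = 5e-6)
  expect_true(with_prp$includes_prp)

  without <- corrected_reading(raw, corr, include_prp = FALSE)
  expect_equal(without$value, 0.152894, tolerance = 5e-6)
  expect_false(without$includes_prp)

  # identity when every factor is 1
  unity <- correction_factors()
  expect_equal(corrected_reading(0.1529, unity)$value, 0.1529)

  # missing prp when requested
  expect_error(corrected_reading(0.1529, unity, include_prp = TRUE),
               "no prp")
})

test_that("kq_from_fit evaluates the quadratic specifier fit term by term", {
  expect_equal(kq_from_fit(66.94, kq_fit_coefficients(1, 0, 0))$value, 1.0)
  expect_equal(kq_from_fit(66.94, kq_fit_coefficients(0, 1, 0))$value,
               0.06694)
  expect_equal(kq_from_fit(66.94, kq_fit_coefficients(0, 0, 1))$value,
               66.94^2 * 1e-5)
  expect_false(kq_from_fit(66.94,
                           kq_fit_coefficients(1, 0, 0))$includes_volume_averaging)
  expect_warning(kq_from_fit(0.65, kq_fit_coefficients(1, 0, 0)), "window")
})

test_that("convert_specifier handles table, polynomial and identity strategies", {
  s1 <- convert_specifier(quality_specifier(64.90, 6.75))
  expect_equal(s1$pdd10_10, 66.94)
  s2 <- convert_specifier(quality_specifier(64.90, 6.25))
  expect_equal(s2$pdd10_10, 67.42)
  s3 <- convert_specifier(quality_specifier(64.90, 10.0))
  expect_equal(s3$pdd10_10, 64.90)
  expect_error(convert_specifier(quality_specifier(55, 4.2)), "no conversion")

  s4 <- convert_specifier(quality_specifier(64.90, 6.75),
                          strategy = "polynomial",
                          coefficients = c(2.04, 1.0))
  expect_equal(s4$pdd10_10, 66.94)
})

test_that("dose_per_mu applies the calibration chain and guards double averaging", {
  cal <- chamber_calibration(4.87, "a12")
  corr <- table3_corrections()
  raw <- raw_reading(0.1529, 1)

  kq_fit <- quality_correction(0.992, FALSE, "tg51_fit")
  d1 <- dose_per_mu(corrected_reading(raw, corr, TRUE), cal, kq_fit)
  expect_equal(d1$value, 0.7465, tolerance = 1e-3)
  expect_identical(d1$volume_averaging, "reading")

  kq_tab <- quality_correction(1.004, TRUE, "trs483_table")
  d3 <- dose_per_mu(corrected_reading(raw, corr, FALSE), cal, kq_tab)
  expect_identical(d3$volume_averaging, "quality_correction")

  # volume averaging twice is impossible
  expect_error(dose_per_mu(corrected_reading(raw, corr, TRUE), cal, kq_tab),
               "twice")

  # neither route is allowed but flagged
  d0 <- dose_per_mu(corrected_reading(raw, corr, FALSE), cal, kq_fit)
  expect_identical(d0$volume_averaging, "none")

  # zero reading gives zero dose
  z <- corrected_reading(0, corr)
  expect_equal(dose_per_mu(z, cal, kq_fit)$value, 0)
})

test_that("dose_per_mu is linear in reading, calibration coefficient and kq", {
  corr <- correction_factors()
  base <- dose_per_mu(corrected_reading(0.15, corr),
                      chamber_calibration(4.87),
                      quality_correction(0.992, TRUE))$value
  expect_equal(dose_per_mu(corrected_reading(0.30, corr),
                           chamber_calibration(4.87),
                           quality_correction(0.992, TRUE))$value, 2 * base)
  expect_equal(dose_per_mu(corrected_reading(0.15, corr),
                           chamber_calibration(9.74),
                           quality_correction(0.992, TRUE))$value, 2 * base)
  expect_equal(dose_per_mu(corrected_reading(0.15, corr),
                           chamber_calibration(4.87),
                           quality_correction(1.984, TRUE))$value, 2 * base)
})

test_that("the two formalisms agree when kQmsr = kQ * Prp (randomized)", {
  set.seed(7)
  cal <- chamber_calibration(4.87)
  for (i in 1:200) {
    kq <- runif(1, 0.95, 1.05)
    prp_v <- runif(1, 1.0, 1.02)
    corr <- correction_factors(ptp = runif(1, 0.97, 1.03),
                               pion = runif(1, 1.0, 1.01),
                               ppol = runif(1, 0.998, 1.002),
                               prp = prp_v)
    m <- runif(1, 0.1, 0.2)
    d_fit <- dose_per_mu(corrected_reading(m, corr, TRUE), cal,
                         quality_correction(kq, FALSE, "tg51_fit"))
    d_msr <- dose_per_mu(corrected_reading(m, corr, FALSE), cal,
                         quality_correction(kq * prp_v, TRUE, "derived"))
    expect_equal(d_fit$value, d_msr$value, tolerance = 1e-14)
  }
})
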