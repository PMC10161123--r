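test_that("the worked-example scenarios reproduce the published doses and differences", {
  rep <- run_scenarios(worked_example_config())
  d <- rep$scenarios$dose_cGy_per_MU
  # within one unit of the last printed digit (printed inputs are rounded)
  expect_lt(abs(d[1] - 0.746), 0.001 + 1e-12)
  expect_lt(abs(d[2] - 0.747), 0.001 + 1e-12)
  expect_lt(abs(d[3] - 0.748), 0.001 + 1e-12)
  expect_lt(abs(d[4] - 0.7449), 0.0001 + 1e-12)

  diffs <- rep$differences$diff_percent
  expect_equal(diffs[1], 0)
  expect_equal(round(diffs[2], 2), 0.11)
  expect_equal(round(diffs[3], 2), 0.14)
  expect_equal(round(diffs[4], 2), -0.22)

  # none of the disparities is significant at k = 1
  expect_false(any(rep$differences$significant[-1]))
})

test_that("percent_diff follows the candidate-minus-baseline convention", {
  expect_equal(round(percent_diff(0.747349, 0.746538), 2), 0.11)
  expect_equal(round(percent_diff(0.744889, 0.746538), 2), -0.22)
  expect_equal(percent_diff(0.75, 0.75), 0)
  expect_error(percent_diff(0.7, 0), "baseline")
  # antisymmetric under swap up to the baseline ratio:
  # d(a,b) = -d(b,a) * a / b exactly
  a <- 0.747; b <- 0.733
  expect_equal(percent_diff(a, b), -percent_diff(b, a) * a / b,
               tolerance = 1e-12)
})

test_that("two identical scenarios differ by exactly zero", {
  cfg <- worked_example_config()
  cfg$scenarios <- list(cfg$scenarios[[1]],
                        modifyList(cfg$scenarios[[1]],
                                   list(name = "copy", baseline = FALSE)))
  rep <- run_scenarios(cfg)
  expect_identical(rep$differences$diff_percent[2], 0)
})

test_that("a scenario with kQmsr = kQ * Prp matches the fit-route baseline exactly", {
  cfg <- worked_example_config()
  kq <- 0.992; prp_v <- cfg$corrections$prp
  cfg$scenarios[[2]] <- list(
    name = "equivalent-msr", formalism = "trs483",
    include_prp_in_reading = FALSE,
    quality = list(value = kq * prp_v, includes_volume_averaging = TRUE,
                   source = "derived"))
  cfg$scenarios <- cfg$scenarios[1:2]
  rep <- run_scenarios(cfg)
  expect_equal(rep$differences$diff_percent[2], 0, tolerance = 1e-12)
})

test_that("configuration errors are caught and named", {
  cfg <- worked_example_config()
  cfg$scenarios[[1]]$baseline <- NULL
  expect_error(run_scenarios(cfg), "baseline")

  cfg <- worked_example_config()
  # Prp in the reading AND a quality correction that includes averaging
  cfg$scenarios[[3]]$include_prp_in_reading <- TRUE
  expect_error(run_scenarios(cfg), "trs483-including-generic-kvol")
})

test_that("corrections can be given as raw instrument inputs", {
  cfg <- worked_example_config()
  cfg$corrections$ptp <- list(temperature = 24.0, pressure = 101.33)
  cfg$corrections$pion <- list(m_high = 1.0065, m_low = 1.0,
                               v_high = 300, v_low = 150)
  cfg$corrections$ppol <- list(m_positive = 1.0, m_negative = -1.0)
  rep <- run_scenarios(cfg)
  expect_equal(rep$scenarios$reading_nC_per_MU[1],
               0.1529 * (297.2 / 295.2) * ((1 - 2) / (1.0065 - 2)) * 1.0107,
               tolerance = 1e-12)
})

test_that("reports round-trip through the structured format at full precision", {
  rep <- run_scenarios(worked_example_config())
  path <- withr::local_tempfile(fileext = ".json")
  render_report(rep, path, format = "structured")
  back <- parse_report(path)
  expect_equal(back$scenarios$dose_cGy_per_MU,
               rep$scenarios$dose_cGy_per_MU, tolerance = 1e-15)
  expect_equal(back$differences$diff_percent,
               rep$differences$diff_percent, tolerance = 1e-15)
  expect_identical(back$provenance$config_digest,
                   rep$provenance$config_digest)
})

test_that("the table report has one row per scenario and honest n/a markers", {
  cfg <- worked_example_config()
  # drop all uncertainties: the report must say n/a, not zero
  for (i in seq_along(cfg$scenarios)) {
    cfg$scenarios[[i]]$quality$rel_uncertainty <- NULL
  }
  rep <- run_scenarios(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  render_report(rep, path, format = "table")
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 1 + length(cfg$scenarios))  # header + scenarios
  expect_true(all(grepl("\tn/a\t", body[-1], fixed = TRUE)))
  expect_true(any(grepl("config_digest", lines)))
})

test_that("re-running the same configuration is bit-identical", {
  cfg <- worked_example_config()
  r1 <- run_scenarios(cfg)
  r2 <- run_scenarios(cfg)
  expect_identical(r1$scenarios, r2$scenarios)
  expect_identical(r1$differences, r2$differences)
  expect_identical(r1$provenance$config_digest, r2$provenance$config_digest)
})
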