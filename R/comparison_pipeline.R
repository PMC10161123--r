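#' Read a calibration configuration file
#'
#' Configurations are YAML with blocks `calibration`, `readings`,
#' `corrections`, `specifier` (optional), `significance` (optional) and
#' a list of `scenarios`.  See the bundled worked example:
#' `system.file("extdata", "worked_example.yaml", package = "msrdose")`.
#'
#' @param path Path to a YAML configuration.
#' @return A nested list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

# Stable digest of a configuration for report provenance.
.config_digest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config, control = c("keepNA", "niceNames")), tmp)
  unname(tools::md5sum(tmp))
}

# A factor configured either as a bare number or as {value, rel_uncertainty}.
.cfg_quantity <- function(x, default = NULL) {
  if (is.null(x)) return(default)
  if (is.list(x)) quantity(x$value, x$rel_uncertainty %||% NA_real_)
  else quantity(x)
}

# Influence corrections from direct values and/or raw instrument inputs.
.resolve_corrections <- function(block) {
  block <- block %||% list()
  val <- function(name, raw_fn = NULL) {
    x <- block[[name]]
    if (is.list(x) && is.null(x$value) && !is.null(raw_fn)) return(raw_fn(x))
    .cfg_quantity(x, quantity(1))
  }
  correction_factors(
    ptp = val("ptp", function(x) {
      quantity(ptp(env_conditions(
        x$temperature, x$pressure,
        x$reference_temperature %||% 22.0,
        x$reference_pressure %||% 101.33)))
    }),
    pion = val("pion", function(x) {
      quantity(pion_two_voltage(x$m_high, x$m_low, x$v_high, x$v_low))
    }),
    ppol = val("ppol", function(x) {
      quantity(ppol(x$m_positive, x$m_negative, x$used %||% "positive"))
    }),
    pelec = val("pelec"),
    pleak = val("pleak"),
    prp = .cfg_quantity(block$prp, NULL))
}

# A scenario's quality correction from a direct value, a strip(/apply)
# recipe, or a specifier-fit recipe.
.resolve_quality <- function(q, specifier = NULL) {
  if (inherits(q, "quality_correction")) return(q)
  if (is.null(q)) stop("scenario lacks a 'quality' block")
  if (!is.null(q$recipe)) {
    return(switch(q$recipe,
      strip = {
        k <- quality_correction(q$tabulated,
                                includes_volume_averaging = TRUE,
                                source = "trs483_table",
                                rel_uncertainty = q$rel_uncertainty %||%
                                  NA_real_)
        out <- strip_generic_kvol(k, .cfg_quantity(q$kvol_generic))
        if (!is.null(q$kvol_specific)) {
          out <- apply_specific_kvol(out, .cfg_quantity(q$kvol_specific))
        }
        out
      },
      fit = {
        if (is.null(specifier)) stop("fit recipe needs a specifier block")
        spec <- convert_specifier(
          quality_specifier(specifier$pdd10_esfs, specifier$esfs_side),
          strategy = q$conversion %||% "table")
        kq_from_fit(spec$pdd10_10,
                    kq_fit_coefficients(q$A, q$B, q$C),
                    rel_uncertainty = q$rel_uncertainty %||% NA_real_)
      },
      stop("unknown quality recipe: ", q$recipe)))
  }
  quality_correction(q$value,
                     includes_volume_averaging =
                       isTRUE(q$includes_volume_averaging),
                     source = q$source %||% "derived",
                     rel_uncertainty = q$rel_uncertainty %||% NA_real_)
}

#' Run the calibration scenarios of a configuration
#'
#' Computes the absorbed dose to water per MU for every configured
#' scenario (each a formalism choice, a quality-correction recipe, and
#' whether the volume-averaging correction sits in the reading or in
#' the quality correction), then the percent difference of each
#' scenario against the designated baseline with a significance
#' adjudication at the configured coverage factor.
#'
#' @param config A nested list as returned by [read_config()].
#' @return An object of class `comparison_report`: data frames
#'   `scenarios` (name, formalism, kq, dose, uncertainties) and
#'   `differences` (percent difference vs baseline, significance),
#'   plus `baseline` and `provenance`.
#' @export
run_scenarios <- function(config) {
  stopifnot(is.list(config), length(config$scenarios) >= 1L)
  cal <- chamber_calibration(
    config$calibration$nd_w_cGy_per_nC,
    chamber_id = config$calibration$chamber_id %||% "",
    laboratory = config$calibration$laboratory %||% "",
    rel_uncertainty = config$calibration$rel_uncertainty %||% NA_real_)
  rd <- config$readings
  m_raw <- if (!is.null(rd$m_raw_per_mu_nC)) {
    raw_reading(rd$m_raw_per_mu_nC, 1, rd$repeats %||% 1L)
  } else {
    raw_reading(rd$charge_nC, rd$mu, rd$repeats %||% 1L)
  }
  corr <- .resolve_corrections(config$corrections)

  baseline_flags <- vapply(config$scenarios,
                           function(s) isTRUE(s$baseline), logical(1))
  if (!any(baseline_flags)) {
    stop("no scenario is marked 'baseline: true'")
  }
  ib <- which(baseline_flags)[1L]

  rows <- lapply(config$scenarios, function(s) {
    kq <- .resolve_quality(s$quality, config$specifier)
    include_prp <- isTRUE(s$include_prp_in_reading)
    reading <- corrected_reading(m_raw, corr, include_prp = include_prp)
    dose <- tryCatch(dose_per_mu(reading, cal, kq), error = function(e) {
      stop(sprintf("scenario '%s': %s", s$name, conditionMessage(e)),
           call. = FALSE)
    })
    data.frame(name = s$name,
               formalism = s$formalism %||% "tg51",
               kq = kq$value,
               kq_includes_volume_averaging = kq$includes_volume_averaging,
               prp_in_reading = include_prp,
               reading_nC_per_MU = reading$value,
               dose_cGy_per_MU = dose$value,
               dose_rel_u = dose$rel_u,
               volume_averaging = dose$volume_averaging,
               stringsAsFactors = FALSE)
  })
  scen <- do.call(rbind, rows)

  base_dose <- scen$dose_cGy_per_MU[ib]
  coverage <- config$significance$coverage %||% 1
  diffs <- lapply(seq_len(nrow(scen)), function(i) {
    d <- percent_diff(scen$dose_cGy_per_MU[i], base_dose)
    u2 <- c(scen$dose_rel_u[i], scen$dose_rel_u[ib])
    u_comb <- if (all(is.na(u2))) NA_real_ else
      sqrt(sum(u2^2, na.rm = TRUE)) * 100
    sig <- if (is.na(u_comb)) list(significant = NA, margin = NA_real_)
           else assess_significance(d, u_comb, coverage)
    data.frame(name = scen$name[i], diff_percent = d,
               u_combined_percent = u_comb,
               significant = sig$significant, margin = sig$margin,
               stringsAsFactors = FALSE)
  })
  diffs <- do.call(rbind, diffs)

  structure(list(
    scenarios = scen,
    differences = diffs,
    baseline = scen$name[ib],
    provenance = list(config_digest = .config_digest(config),
                      package_version =
                        as.character(utils::packageVersion("msrdose")),
                      timestamp = format(Sys.time(), tz = "UTC",
                                         usetz = TRUE))),
    class = "comparison_report")
}

#' Percent difference of a candidate dose against a baseline
#'
#' `(candidate - baseline) / baseline * 100`, the sign convention of a
#' "difference with baseline" report row.
#'
#' @param candidate Candidate dose (cGy/MU).
#' @param baseline Baseline dose (cGy/MU, > 0).
#' @return The difference in percent.
#' @export
percent_diff <- function(candidate, baseline) {
  if (!is.finite(baseline) || baseline <= 0) stop("baseline must be > 0")
  (candidate - baseline) / baseline * 100
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Calibration scenario comparison (baseline:", x$baseline, ")\n\n")
  s <- x$scenarios
  d <- x$differences
  fmt_u <- ifelse(is.na(d$u_combined_percent), "n/a",
                  sprintf("%.2f%%", d$u_combined_percent))
  tab <- data.frame(
    scenario = s$name,
    kQ = sprintf("%.4f", s$kq),
    `dose cGy/MU` = sprintf("%.4f", s$dose_cGy_per_MU),
    `diff vs baseline` = ifelse(s$name == x$baseline, "-",
                                sprintf("%+.2f%%", d$diff_percent)),
    `u(diff)` = fmt_u,
    significant = ifelse(is.na(d$significant), "n/a",
                         ifelse(d$significant, "yes", "no")),
    check.names = FALSE)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a comparison report to disk
#'
#' `format = "table"` writes a tab-separated table (one scenario per
#' row, the percent-difference and significance columns alongside, a
#' `-`/`n/a` marker where a value does not apply or lacks an
#' uncertainty).  `format = "structured"` writes the full-precision
#' report as JSON; [parse_report()] reads it back losslessly.  Both
#' embed the configuration digest.
#'
#' @param report A `comparison_report`.
#' @param path Output file path.
#' @param format `"table"` or `"structured"`.
#' @return Invisibly, `path`.
#' @export
render_report <- function(report, path, format = c("table", "structured")) {
  stopifnot(inherits(report, "comparison_report"))
  format <- match.arg(format)
  if (format == "structured") {
    ok <- tryCatch({
      jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                           digits = NA, null = "null", na = "null")
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("cannot write report: ", path)
    return(invisible(path))
  }
  s <- report$scenarios
  d <- report$differences
  lines <- c(
    paste0("# config_digest: ", report$provenance$config_digest),
    paste0("# package_version: ", report$provenance$package_version),
    paste0("# baseline: ", report$baseline),
    paste("scenario", "kQ", "dose_cGy_per_MU", "diff_vs_baseline_percent",
          "u_combined_percent", "significant", sep = "\t"))
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, paste(
      s$name[i],
      sprintf("%.4f", s$kq[i]),
      sprintf("%.4f", s$dose_cGy_per_MU[i]),
      if (s$name[i] == report$baseline) "-" else
        sprintf("%+.2f", d$diff_percent[i]),
      if (is.na(d$u_combined_percent[i])) "n/a" else
        sprintf("%.2f", d$u_combined_percent[i]),
      if (is.na(d$significant[i])) "n/a" else
        if (d$significant[i]) "yes" else "no",
      sep = "\t"))
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write report: ", path)
  invisible(path)
}

#' Read back a structured comparison report
#'
#' @param path A JSON report written by [render_report()] with
#'   `format = "structured"`.
#' @return A `comparison_report`.
#' @export
parse_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$scenarios <- as.data.frame(x$scenarios, stringsAsFactors = FALSE)
  x$differences <- as.data.frame(x$differences, stringsAsFactors = FALSE)
  structure(x, class = "comparison_report")
}
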