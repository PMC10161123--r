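#' Environmental conditions for the air-density correction
#'
#' @param temperature Chamber temperature, degrees C.
#' @param pressure Ambient pressure, kPa.
#' @param reference_temperature Calibration reference temperature,
#'   degrees C (22.0 by North American convention).
#' @param reference_pressure Calibration reference pressure, kPa
#'   (101.33).
#' @return An object of class `env_conditions`.
#' @export
env_conditions <- function(temperature, pressure,
                           reference_temperature = 22.0,
                           reference_pressure = 101.33) {
  if (temperature <= -273.2 || reference_temperature <= -273.2) {
    stop("temperature below absolute zero")
  }
  if (pressure <= 0 || reference_pressure <= 0) stop("pressure must be > 0")
  structure(list(temperature = temperature, pressure = pressure,
                 reference_temperature = reference_temperature,
                 reference_pressure = reference_pressure),
            class = "env_conditions")
}

#' Temperature-pressure (air density) correction
#'
#' `PTP = (273.2 + T) / (273.2 + T_ref) * P_ref / P`, correcting the
#' chamber reading to the air density of the calibration conditions.
#'
#' @param env An [env_conditions()] object.
#' @return The correction factor (numeric).
#' @examples
#' ptp(env_conditions(22, 101.33))   # 1 at reference conditions
#' ptp(env_conditions(24, 101.33))   # 297.2 / 295.2
#' @export
ptp <- function(env) {
  stopifnot(inherits(env, "env_conditions"))
  (273.2 + env$temperature) / (273.2 + env$reference_temperature) *
    env$reference_pressure / env$pressure
}

#' Ion-recombination correction by the two-voltage method
#'
#' Pulsed-beam two-voltage formula:
#' `Pion = (1 - VH/VL) / (MH/ML - VH/VL)`, from readings at the normal
#' operating voltage VH and a reduced voltage VL.
#'
#' @param m_high Reading at the operating voltage, nC (> 0).
#' @param m_low Reading at the reduced voltage, nC (> 0).
#' @param v_high Operating voltage, V.
#' @param v_low Reduced voltage, V (0 < v_low < v_high).
#' @return The correction factor (numeric).
#' @export
pion_two_voltage <- function(m_high, m_low, v_high, v_low) {
  if (!(v_high > v_low && v_low > 0)) stop("need v_high > v_low > 0")
  if (m_high <= 0 || m_low <= 0) stop("readings must be > 0")
  vr <- v_high / v_low
  denom <- m_high / m_low - vr
  if (abs(denom) < 1e-12) stop("two-voltage denominator is numerically zero")
  (1 - vr) / denom
}

#' Polarity correction
#'
#' `Ppol = (|M+| + |M-|) / (2 |M_used|)` with `M_used` the reading at
#' the polarity used clinically.
#'
#' @param m_positive Reading at positive polarity, nC (non-zero).
#' @param m_negative Reading at negative polarity, nC (non-zero).
#' @param used Which polarity is used clinically: `"positive"` or
#'   `"negative"`.
#' @return The correction factor (numeric).
#' @export
ppol <- function(m_positive, m_negative, used = c("positive", "negative")) {
  used <- match.arg(used)
  if (m_positive == 0 || m_negative == 0) stop("readings must be non-zero")
  m_used <- if (used == "positive") m_positive else m_negative
  (abs(m_positive) + abs(m_negative)) / (2 * abs(m_used))
}

#' Raw electrometer reading
#'
#' @param charge_nC Collected charge for one exposure, nC.
#' @param monitor_units Delivered monitor units (> 0).
#' @param repeats Number of repeated exposures averaged into
#'   `charge_nC` (>= 1).
#' @return An object of class `raw_reading`; field `m_per_mu` is the
#'   reading per MU in nC/MU.
#' @export
raw_reading <- function(charge_nC, monitor_units, repeats = 1L) {
  if (monitor_units <= 0) stop("monitor_units must be > 0")
  if (repeats < 1) stop("repeats must be >= 1")
  structure(list(charge_per_exposure = charge_nC,
                 monitor_units = monitor_units,
                 repeats = as.integer(repeats),
                 m_per_mu = charge_nC / monitor_units),
            class = "raw_reading")
}

#' Influence-quantity correction factors
#'
#' The multiplicative corrections applied to a raw chamber reading for
#' influence quantities other than beam quality: air density (PTP), ion
#' recombination (Pion), polarity (Ppol), electrometer gain (Pelec),
#' leakage (Pleak), and optionally the volume-averaging correction Prp
#' of the TG-51 addendum.  Each may be a numeric or a [quantity()]
#' carrying a relative standard uncertainty.
#'
#' @param ptp,pion,ppol,pelec,pleak Correction factors (> 0).
#' @param prp Optional volume-averaging correction; expected >= 1 for
#'   profiles peaked on the axis (a value < 1 draws a warning).
#' @return An object of class `correction_factors`.
#' @export
correction_factors <- function(ptp = 1, pion = 1, ppol = 1, pelec = 1,
                               pleak = 1, prp = NULL) {
  fs <- list(ptp = as_quantity(ptp), pion = as_quantity(pion),
             ppol = as_quantity(ppol), pelec = as_quantity(pelec),
             pleak = as_quantity(pleak))
  if (any(vapply(fs, function(q) q$value, numeric(1)) <= 0)) {
    stop("all correction factors must be > 0")
  }
  if (!is.null(prp)) {
    prp <- as_quantity(prp)
    if (prp$value <= 0) stop("prp must be > 0")
    if (prp$value < 1) {
      warning("prp < 1: unusual for a profile peaked on the beam axis")
    }
  }
  structure(c(fs, list(prp = prp)), class = "correction_factors")
}

#' Chamber calibration coefficient
#'
#' The absorbed-dose-to-water calibration coefficient ND,w (cGy/nC) at
#' the calibration quality (Co-60) in the conventional 10 x 10 cm
#' reference field, traceable to a primary standards laboratory.
#'
#' @param nd_w Calibration coefficient, cGy/nC (> 0).
#' @param chamber_id Free-text chamber identifier.
#' @param laboratory Issuing laboratory.
#' @param rel_uncertainty Optional relative standard uncertainty.
#' @return An object of class `chamber_calibration`.
#' @export
chamber_calibration <- function(nd_w, chamber_id = "",
                                laboratory = "", rel_uncertainty = NA_real_) {
  nd_w <- as_quantity(nd_w)
  if (nd_w$value <= 0) stop("nd_w must be > 0")
  if (!is.na(rel_uncertainty)) nd_w <- quantity(nd_w$value, rel_uncertainty)
  structure(list(nd_w = nd_w, chamber_id = chamber_id,
                 laboratory = laboratory),
            class = "chamber_calibration")
}

#' Corrected chamber reading per monitor unit
#'
#' The raw reading per MU multiplied by the influence-quantity
#' corrections PTP, Pion, Ppol, Pelec, Pleak and — only when
#' `include_prp` — the volume-averaging correction Prp.  Whether Prp is
#' in the reading is recorded on the result so the dose computation can
#' enforce that volume averaging enters exactly once (either here or
#' inside the beam-quality correction factor).  Uncertainties combine
#' in quadrature.
#'
#' @param raw A [raw_reading()] or a bare numeric reading per MU
#'   (nC/MU).
#' @param corr A [correction_factors()] object.
#' @param include_prp Apply `corr$prp` to the reading?
#' @return A `quantity` of class `corrected_reading` (nC/MU) with field
#'   `includes_prp`.
#' @export
corrected_reading <- function(raw, corr, include_prp = FALSE) {
  stopifnot(inherits(corr, "correction_factors"))
  m <- if (inherits(raw, "raw_reading")) raw$m_per_mu else as.numeric(raw)
  if (length(m) != 1L || !is.finite(m) || m < 0) {
    stop("raw reading per MU must be a finite non-negative scalar")
  }
  terms <- list(corr$ptp, corr$pion, corr$ppol, corr$pelec, corr$pleak)
  if (include_prp) {
    if (is.null(corr$prp)) {
      stop("include_prp = TRUE but no prp factor is configured")
    }
    terms <- c(terms, list(corr$prp))
  }
  prod_q <- propagate_product(terms)
  out <- quantity(m * prod_q$value, prod_q$rel_u)
  out$includes_prp <- include_prp
  class(out) <- c("corrected_reading", class(out))
  out
}

#' Chamber-specific fit coefficients for the beam-quality correction
#'
#' @param A,B,C Dimensionless coefficients of the quadratic fit of kQ
#'   against the photon-component percent depth dose specifier.
#' @return An object of class `kq_fit_coefficients`.
#' @export
kq_fit_coefficients <- function(A, B, C) {
  if (!all(is.finite(c(A, B, C)))) stop("coefficients must be finite")
  structure(list(A = A, B = B, C = C), class = "kq_fit_coefficients")
}

#' Beam-quality correction factor with provenance
#'
#' A beam-quality correction value together with whether it already
#' includes a volume-averaging component (tabulated msr factors and
#' Monte-Carlo factors do; TG-51 fit values do not — there Prp is
#' applied to the reading), its provenance, and its relative standard
#' uncertainty.
#'
#' @param value The correction factor (> 0).
#' @param includes_volume_averaging Logical flag.
#' @param source One of `"tg51_fit"`, `"trs483_table"`, `"monte_carlo"`,
#'   `"derived"`.
#' @param rel_uncertainty Relative standard uncertainty (k = 1) or `NA`.
#' @return An object of class `quality_correction`.
#' @export
quality_correction <- function(value, includes_volume_averaging = FALSE,
                               source = c("derived", "tg51_fit",
                                          "trs483_table", "monte_carlo"),
                               rel_uncertainty = NA_real_) {
  source <- match.arg(source)
  if (!is.numeric(value) || value <= 0) stop("value must be > 0")
  if (!is.na(rel_uncertainty) && rel_uncertainty < 0) {
    stop("relative uncertainty must be >= 0")
  }
  structure(list(value = as.numeric(value),
                 includes_volume_averaging = isTRUE(includes_volume_averaging),
                 source = source,
                 rel_uncertainty = as.numeric(rel_uncertainty)),
            class = "quality_correction")
}

#' @export
print.quality_correction <- function(x, ...) {
  cat(sprintf("<quality_correction: %.6g [%s]%s%s>\n", x$value, x$source,
              if (x$includes_volume_averaging) ", includes volume averaging"
              else "",
              if (is.na(x$rel_uncertainty)) ""
              else sprintf(", rel. u %.3g", x$rel_uncertainty)))
  invisible(x)
}

#' Beam-quality correction from the quadratic specifier fit
#'
#' `kQ = A + B * 1e-3 * x + C * 1e-5 * x^2` with x the photon-component
#' percent depth dose at 10 cm for the 10 x 10 cm field, in percent.
#' Chamber-specific A, B, C come from published fit tables and are
#' configuration here.  The result carries a cleared volume-averaging
#' flag: on this route the volume-averaging correction is applied to
#' the reading instead.
#'
#' @param pdd10_10 Specifier in percent; values outside the 40-90
#'   sanity window (a fraction/percent mix-up tell-tale) draw a warning.
#' @param coeffs A [kq_fit_coefficients()] object.
#' @param rel_uncertainty Optional relative standard uncertainty.
#' @return A [quality_correction()] with `source = "tg51_fit"`.
#' @export
kq_from_fit <- function(pdd10_10, coeffs, rel_uncertainty = NA_real_) {
  stopifnot(inherits(coeffs, "kq_fit_coefficients"))
  if (pdd10_10 < 40 || pdd10_10 > 90) {
    warning(sprintf(
      "specifier %.4g%% outside the 40-90%% sanity window; check units",
      pdd10_10))
  }
  v <- coeffs$A + coeffs$B * 1e-3 * pdd10_10 + coeffs$C * 1e-5 * pdd10_10^2
  quality_correction(v, includes_volume_averaging = FALSE,
                     source = "tg51_fit", rel_uncertainty = rel_uncertainty)
}

#' Beam-quality specifier for a non-standard field size
#'
#' The percent depth dose at 10 cm measured for the machine's
#' equivalent square field size (ESFS), from which the 10 x 10 value is
#' inferred by a conversion strategy.
#'
#' @param pdd10_esfs Measured %dd(10) for the ESFS, percent (0-100).
#' @param esfs_side Equivalent square side at 100 cm, cm (> 0).
#' @param pdd10_10 Converted 10 x 10 value, percent, or `NA` until
#'   [convert_specifier()] fills it.
#' @return An object of class `quality_specifier`.
#' @export
quality_specifier <- function(pdd10_esfs, esfs_side, pdd10_10 = NA_real_) {
  if (pdd10_esfs <= 0 || pdd10_esfs >= 100) {
    stop("pdd10_esfs must be in (0, 100) percent")
  }
  if (esfs_side <= 0) stop("esfs_side must be > 0")
  if (!is.na(pdd10_10) && (pdd10_10 <= 0 || pdd10_10 >= 100)) {
    stop("pdd10_10 must be in (0, 100) percent")
  }
  structure(list(pdd10_esfs = pdd10_esfs, esfs_side = esfs_side,
                 pdd10_10 = as.numeric(pdd10_10)),
            class = "quality_specifier")
}

#' Bundled specifier conversion pairs
#'
#' The lookup table shipped with the package for converting %dd(10)
#' measured at a machine's ESFS to the 10 x 10 cm specifier.  Each row
#' is one published (pdd10_esfs, esfs_side) -> pdd10_10 pair; users
#' supply their own table or polynomial for other beams.
#'
#' @return A data frame with columns `esfs_side`, `pdd10_esfs`,
#'   `pdd10_10`.
#' @export
default_conversion_table <- function() {
  path <- system.file("extdata", "pdd10_conversion.csv", package = "msrdose")
  utils::read.csv(path, comment.char = "#")
}

#' Convert a beam-quality specifier between field sizes
#'
#' Fills `pdd10_10` from `pdd10_esfs` using a pluggable strategy:
#' `"table"` looks the pair up in a conversion table (the bundled one by
#' default); `"polynomial"` evaluates user-supplied coefficients
#' `sum(coefficients[k] * pdd10_esfs^(k-1))`; `"identity"` (automatic
#' when `esfs_side = 10`) copies the value through.
#'
#' @param spec A [quality_specifier()].
#' @param strategy `"table"`, `"polynomial"`, or `"identity"`.
#' @param table Conversion table for the table strategy (defaults to
#'   [default_conversion_table()]).
#' @param coefficients Polynomial coefficients, constant term first.
#' @return The specifier with `pdd10_10` filled.
#' @export
convert_specifier <- function(spec, strategy = c("table", "polynomial",
                                                 "identity"),
                              table = NULL, coefficients = NULL) {
  stopifnot(inherits(spec, "quality_specifier"))
  strategy <- match.arg(strategy)
  if (abs(spec$esfs_side - 10) < 1e-9) strategy <- "identity"
  out <- switch(strategy,
    identity = spec$pdd10_esfs,
    polynomial = {
      if (is.null(coefficients)) {
        stop("polynomial strategy needs 'coefficients'")
      }
      sum(coefficients * spec$pdd10_esfs^(seq_along(coefficients) - 1))
    },
    table = {
      tab <- table %||% default_conversion_table()
      hit <- abs(tab$esfs_side - spec$esfs_side) < 1e-6 &
        abs(tab$pdd10_esfs - spec$pdd10_esfs) <= 0.005
      if (!any(hit)) {
        stop(sprintf(
          "no conversion entry for %%dd(10) = %.2f at ESFS %.2f cm",
          spec$pdd10_esfs, spec$esfs_side))
      }
      tab$pdd10_10[which(hit)[1L]]
    })
  quality_specifier(spec$pdd10_esfs, spec$esfs_side, pdd10_10 = out)
}

#' Absorbed dose to water per monitor unit
#'
#' `D = M * ND,w * kQ`, the common core of both formalisms: with the
#' quality correction from the specifier fit (flag cleared) the reading
#' must carry Prp; with a tabulated or Monte-Carlo msr factor (flag
#' set) the reading must not.  Exactly one of the two carries volume
#' averaging — carrying it twice is an error; carrying it in neither is
#' allowed only for a deliberately uncorrected run, which is flagged on
#' the result.
#'
#' @param reading A [corrected_reading()] (nC/MU).
#' @param cal A [chamber_calibration()].
#' @param kq A [quality_correction()].
#' @return A `quantity` (cGy/MU) with field `volume_averaging`, one of
#'   `"reading"`, `"quality_correction"`, `"none"`.
#' @export
dose_per_mu <- function(reading, cal, kq) {
  stopifnot(inherits(reading, "corrected_reading"),
            inherits(cal, "chamber_calibration"),
            inherits(kq, "quality_correction"))
  if (isTRUE(reading$includes_prp) && kq$includes_volume_averaging) {
    stop(paste("volume averaging applied twice: the reading includes Prp",
               "and the quality correction includes a kvol component"))
  }
  va <- if (isTRUE(reading$includes_prp)) "reading"
        else if (kq$includes_volume_averaging) "quality_correction"
        else "none"
  kq_q <- quantity(kq$value, kq$rel_uncertainty)
  if (reading$value == 0) {
    out <- quantity(0)
  } else {
    out <- propagate_product(list(quantity(reading$value, reading$rel_u),
                                  cal$nd_w, kq_q))
  }
  out$volume_averaging <- va
  out
}
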