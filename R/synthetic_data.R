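# Run fn with a locally seeded RNG, restoring any pre-existing global
# state afterwards: generators take explicit seeds, no hidden state.
.with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Parameters of the synthetic FFF profile model
#'
#' The generator emulates a flattening-filter-free circular field at
#' the measurement plane: a flat-ish top with a slight parabolic droop
#' and a steep logistic penumbra,
#' `OAR(r) = (1 - droop * r^2) / (1 + exp((|r| - field_radius) / penumbra_width))`,
#' renormalized to 1 on the axis, with multiplicative Gaussian noise.
#' Defaults describe a 6-cm nominal collimator projected to the
#' SDD-80 cm measurement plane (field radius 3 cm), a 0.25 cm logistic
#' penumbra scale, and an in-field droop of 0.018 cm^-2 — the curvature
#' scale a Farmer-type chamber sees as a ~1% volume-averaging
#' correction.
#'
#' @param field_radius 50% field radius at the measurement plane, cm.
#' @param penumbra_width Logistic penumbra scale, cm.
#' @param droop In-field parabolic falloff, cm^-2 (>= 0).
#' @param noise_sd Relative standard deviation of multiplicative noise.
#' @param seed Integer RNG seed.
#' @param position_range Scan half-range, cm.
#' @param step Scan step, cm.
#' @return An object of class `profile_params`.
#' @export
profile_params <- function(field_radius = 3.0, penumbra_width = 0.25,
                           droop = 0.018, noise_sd = 0.001, seed = 42L,
                           position_range = 4.5, step = 0.05) {
  if (field_radius <= 0 || penumbra_width <= 0 || step <= 0 ||
      position_range <= 0) {
    stop("field_radius, penumbra_width, step, position_range must be > 0")
  }
  if (droop < 0 || noise_sd < 0) stop("droop and noise_sd must be >= 0")
  structure(list(field_radius = field_radius,
                 penumbra_width = penumbra_width, droop = droop,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 position_range = position_range, step = step),
            class = "profile_params")
}

#' Generate a synthetic FFF dose profile
#'
#' Deterministic for a fixed seed.  The noiseless model value at the
#' axis is exactly 1; noise is multiplicative, emulating detector noise
#' that scales with signal.
#'
#' @param params A [profile_params()] object.
#' @return A profile [scan_curve()] with setup metadata (SSD 70 cm,
#'   depth 10 cm, 6 cm collimator).
#' @export
gen_profile <- function(params = profile_params()) {
  stopifnot(inherits(params, "profile_params"))
  if (params$droop * params$field_radius^2 >= 1) {
    stop("droop * field_radius^2 >= 1: model dose goes negative in-field")
  }
  p <- seq(-params$position_range, params$position_range, by = params$step)
  model <- function(r) {
    (1 - params$droop * r^2) /
      (1 + exp((abs(r) - params$field_radius) / params$penumbra_width))
  }
  v <- model(p) / model(0)
  if (params$noise_sd > 0) {
    v <- .with_seed(params$seed, function() {
      v * (1 + stats::rnorm(length(v), sd = params$noise_sd))
    })
  }
  v <- pmax(v, 0)
  scan_curve("profile", p, v,
             scan_meta(ssd = 70, depth = 10, collimator_diameter = 6,
                       detector_name = "synthetic-diode",
                       field_label = "fmsr: 6 cm circular, SDD 80 cm"))
}

#' Parameters of the synthetic percent-depth-dose model
#'
#' `%dd(z)` proportional to
#' `(1 - exp(-buildup * z)) * exp(-attenuation * max(0, z - zmax))`,
#' normalized to a maximum of 100: an exponential build-up to the depth
#' of maximum dose and exponential attenuation beyond.  Defaults are
#' solved so the curve reads 64.9% at 10 cm depth, the specifier value
#' of a 6 MV-class FFF beam measured with a 6-cm collimator.
#'
#' @param buildup_coefficient Build-up rate, cm^-1.
#' @param attenuation_coefficient Attenuation rate beyond zmax, cm^-1.
#' @param zmax Depth of maximum dose, cm.
#' @param depth_range Length-2 depth range, cm.
#' @param step Depth step, cm.
#' @return An object of class `pdd_params`.
#' @export
pdd_params <- function(buildup_coefficient = 3.5,
                       attenuation_coefficient = 0.0515,
                       zmax = 1.5, depth_range = c(0, 30), step = 0.1) {
  if (buildup_coefficient <= 0 || attenuation_coefficient <= 0 ||
      step <= 0) {
    stop("coefficients and step must be > 0")
  }
  if (length(depth_range) != 2L || diff(depth_range) <= step) {
    stop("degenerate depth range")
  }
  if (zmax <= depth_range[1L] || zmax >= depth_range[2L]) {
    stop("zmax must lie inside the depth range")
  }
  structure(list(buildup_coefficient = buildup_coefficient,
                 attenuation_coefficient = attenuation_coefficient,
                 zmax = zmax, depth_range = depth_range, step = step),
            class = "pdd_params")
}

#' Generate a synthetic percent-depth-dose curve
#'
#' @param params A [pdd_params()] object.
#' @return A pdd [scan_curve()] normalized to max 100 (SSD 100 cm
#'   metadata, 6 cm collimator).
#' @export
gen_pdd <- function(params = pdd_params()) {
  stopifnot(inherits(params, "pdd_params"))
  z <- seq(params$depth_range[1L], params$depth_range[2L], by = params$step)
  v <- (1 - exp(-params$buildup_coefficient * z)) *
    exp(-params$attenuation_coefficient * pmax(0, z - params$zmax))
  scan_curve("pdd", z, v,
             scan_meta(ssd = 100, collimator_diameter = 6,
                       detector_name = "synthetic-diode",
                       field_label = "6 cm circular collimator"))
}

#' Simulate repeated electrometer readings for a known dose
#'
#' Inverts the dose equation: the expected reading per MU is
#' `true_dose / (ND,w * kQ * corrections)`, where the corrections
#' include Prp exactly when the quality correction does not include
#' volume averaging (and a Prp factor is configured) — mirroring the
#' consistency rule the dose computation enforces.  `n` noisy repeats
#' are drawn with multiplicative Gaussian noise.
#'
#' @param true_dose_per_mu Generating dose, cGy/MU (> 0).
#' @param cal A [chamber_calibration()].
#' @param corr A [correction_factors()] object.
#' @param kq A [quality_correction()].
#' @param n Number of repeats (>= 1).
#' @param monitor_units MU per exposure (default 200, the usual
#'   five-repeats-of-200-MU acquisition).
#' @param noise_sd Relative noise standard deviation.
#' @param seed Integer RNG seed.
#' @return A list of `n` [raw_reading()] objects.
#' @export
gen_readings <- function(true_dose_per_mu, cal, corr, kq, n = 5L,
                         monitor_units = 200, noise_sd = 0.002,
                         seed = 42L) {
  stopifnot(inherits(cal, "chamber_calibration"),
            inherits(corr, "correction_factors"),
            inherits(kq, "quality_correction"))
  if (true_dose_per_mu <= 0) stop("true dose must be > 0")
  if (n < 1) stop("n must be >= 1")
  include_prp <- !kq$includes_volume_averaging && !is.null(corr$prp)
  terms <- list(corr$ptp, corr$pion, corr$ppol, corr$pelec, corr$pleak)
  if (include_prp) terms <- c(terms, list(corr$prp))
  p_all <- prod(vapply(terms, function(q) q$value, numeric(1)))
  if (p_all == 0 || cal$nd_w$value == 0 || kq$value == 0) {
    stop("zero correction or calibration factor")
  }
  m_per_mu <- true_dose_per_mu / (cal$nd_w$value * kq$value * p_all)
  eps <- if (noise_sd > 0) {
    .with_seed(seed, function() stats::rnorm(n, sd = noise_sd))
  } else rep(0, n)
  lapply(seq_len(n), function(i) {
    raw_reading(m_per_mu * monitor_units * (1 + eps[i]), monitor_units)
  })
}

#' Closed-form volume-averaging oracle case
#'
#' A pure parabolic OAR, `1 - droop * r^2` with no penumbra, paired
#' with the exact uniform-area volume-averaging factor over an L x D
#' rectangular mask, `1 / (1 - droop * (L^2 + D^2) / 12)` (second
#' moments of the centered rectangle).  Used as an independent oracle
#' for the numeric mask integration.
#'
#' @param droop Parabolic falloff, cm^-2 (>= 0).
#' @param length Mask length L, cm.
#' @param diameter Mask diameter D, cm.
#' @return A list with `oar` (a [radial_function()] sampled past the
#'   mask corner) and `factor` (the closed form).
#' @export
closed_form_prp_case <- function(droop, length, diameter) {
  if (droop < 0 || length <= 0 || diameter <= 0) {
    stop("need droop >= 0 and positive mask dimensions")
  }
  half_diag <- sqrt((length / 2)^2 + (diameter / 2)^2)
  if (droop * half_diag^2 >= 1) {
    stop("droop * (mask half-diagonal)^2 >= 1: parabola goes negative inside the mask")
  }
  rmax <- 2 * half_diag
  if (droop > 0) rmax <- min(rmax, 0.999 / sqrt(droop))
  radii <- seq(0, rmax, by = 0.005)
  oar <- radial_function(radii, pmax(0, 1 - droop * radii^2))
  factor <- 1 / (1 - droop * (length^2 + diameter^2) / 12)
  list(oar = oar, factor = factor)
}
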