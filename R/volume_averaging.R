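#' Cylindrical-chamber sensitive-volume geometry
#'
#' Dimensions of the chamber's sensitive volume, with the chamber axis
#' perpendicular to the beam axis and centered on the measurement point
#' (the standard scanning orientation).  The volume-averaging mask is
#' the rectangle sensitive_length x sensitive_diameter in the plane
#' perpendicular to the beam.
#'
#' @param sensitive_length Length along the chamber axis, cm (> 0).
#' @param sensitive_diameter Transverse diameter, cm (> 0).
#' @param chamber_id Free-text identifier.
#' @return An object of class `chamber_geometry`.
#' @examples
#' # nominal Farmer-scale placeholder dimensions (vendor values for
#' # specific chambers are confidential and must be configured)
#' chamber_geometry(2.4, 0.6, "farmer-nominal-synthetic")
#' @export
chamber_geometry <- function(sensitive_length, sensitive_diameter,
                             chamber_id = "chamber") {
  if (!is.numeric(sensitive_length) || sensitive_length <= 0 ||
      !is.numeric(sensitive_diameter) || sensitive_diameter <= 0) {
    stop("chamber dimensions must be > 0")
  }
  structure(list(sensitive_length = as.numeric(sensitive_length),
                 sensitive_diameter = as.numeric(sensitive_diameter),
                 chamber_id = as.character(chamber_id)),
            class = "chamber_geometry")
}

#' Expand a radial OAR function onto a 2-D lattice
#'
#' Builds the two-dimensional OAR distribution implied by cylindrical
#' symmetry: `values[i, j] = oar(sqrt(x_i^2 + y_j^2))`.  The lattice is
#' symmetric about the origin with a node exactly at (0, 0), so the
#' central-axis value is sampled, never interpolated.
#'
#' @param oar A [radial_function()].
#' @param half_extent Half-width of the lattice in each direction, cm.
#' @param spacing Lattice spacing, cm (> 0).
#' @return An object of class `oar_grid` with fields `x`, `y` (cm) and
#'   `values` (matrix, rows indexed by `x`).
#' @export
expand_radial <- function(oar, half_extent, spacing) {
  stopifnot(inherits(oar, "radial_function"))
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be > 0")
  if (!is.numeric(half_extent) || half_extent <= 0) {
    stop("half_extent must be > 0")
  }
  n <- ceiling(half_extent / spacing - 1e-9)
  x <- (-n:n) * spacing
  r <- sqrt(outer(x^2, x^2, `+`))
  vals <- matrix(curve_value(oar, as.vector(r)), nrow = length(x))
  structure(list(x = x, y = x, values = vals, spacing = spacing),
            class = "oar_grid")
}

#' @export
print.oar_grid <- function(x, ...) {
  cat(sprintf("<oar_grid: %d x %d nodes, spacing %g cm>\n",
              length(x$x), length(x$y), x$spacing))
  invisible(x)
}

# Quadrature nodes/weights over the rectangular chamber mask.
# x runs along the chamber axis (length L), y transverse (diameter D).
# Trapezoidal end weights along each axis keep the discrete mean of a
# quadratic within O(h^2) of the continuous one; the step is adjusted so
# nodes land exactly on the origin and the mask boundary.
.mask_quadrature <- function(geometry, spacing,
                             weighting = c("uniform_area", "chord_weighted")) {
  weighting <- match.arg(weighting)
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be > 0")
  axis_nodes <- function(half) {
    m <- max(1L, round(half / spacing))
    h <- half / m
    x <- (-m:m) * h
    w <- rep(1, length(x))
    w[c(1L, length(x))] <- 0.5
    list(x = x, w = w * h)
  }
  ax <- axis_nodes(geometry$sensitive_length / 2)
  ay <- axis_nodes(geometry$sensitive_diameter / 2)
  wy <- ay$w
  if (weighting == "chord_weighted") {
    R <- geometry$sensitive_diameter / 2
    wy <- wy * sqrt(pmax(0, R^2 - ay$x^2))
  }
  list(x = ax$x, y = ay$x, w = outer(ax$w, wy))
}

#' Volume-averaging correction from a radial OAR function
#'
#' The correction for the radial dose-distribution variation over the
#' chamber's sensitive volume: the central-axis OAR (= 1 after
#' normalization) divided by the weighted mean OAR over the rectangular
#' mask sensitive_length x sensitive_diameter centered at the origin.
#' `uniform_area` weights the mask area uniformly (the 2-D mask of the
#' scanning-orientation picture); `chord_weighted` weights each
#' transverse offset y by the chord length `sqrt((D/2)^2 - y^2)` to
#' emulate a cylinder's true volume average.  For any profile
#' non-increasing in r the result is >= 1.
#'
#' @param oar A normalized [radial_function()].
#' @param geometry A [chamber_geometry()].
#' @param spacing Integration grid spacing, cm (default 0.01; halving it
#'   changes the result of a realistic FFF profile by well under 0.01%).
#' @param weighting `"uniform_area"` (default) or `"chord_weighted"`.
#' @return The correction factor (dimensionless numeric).
#' @examples
#' oar <- radial_function(seq(0, 3, 0.01), 1 - 0.002 * seq(0, 3, 0.01)^2)
#' prp(oar, chamber_geometry(2.4, 0.6))  # closed form: 1.00102
#' @export
prp <- function(oar, geometry, spacing = 0.01,
                weighting = c("uniform_area", "chord_weighted")) {
  stopifnot(inherits(oar, "radial_function"),
            inherits(geometry, "chamber_geometry"))
  weighting <- match.arg(weighting)
  q <- .mask_quadrature(geometry, spacing, weighting)
  r <- sqrt(outer(q$x^2, q$y^2, `+`))
  vals <- matrix(curve_value(oar, as.vector(r)), nrow = length(q$x))
  mean_oar <- sum(q$w * vals) / sum(q$w)
  if (mean_oar <= 0) stop("mean OAR over the mask is not positive")
  1 / mean_oar
}

#' Volume-averaging correction from a supplied dose lattice
#'
#' The point-dose / volume-average contract applied to an externally
#' supplied dose distribution (no radiation transport performed): the
#' value at the reference position (origin) divided by the weighted mean
#' over the chamber-shaped region.  In-mask lattice nodes are weighted
#' equally (`uniform_area`) or by transverse chord length
#' (`chord_weighted`).
#'
#' @param dose An `oar_grid` (from [expand_radial()] or built from a
#'   3-column x/y/value lattice).
#' @param geometry A [chamber_geometry()].
#' @param weighting `"uniform_area"` or `"chord_weighted"`.
#' @return The correction factor (dimensionless numeric).
#' @export
kvol_from_grid <- function(dose, geometry,
                           weighting = c("uniform_area", "chord_weighted")) {
  stopifnot(inherits(dose, "oar_grid"),
            inherits(geometry, "chamber_geometry"))
  weighting <- match.arg(weighting)
  hl <- geometry$sensitive_length / 2
  hd <- geometry$sensitive_diameter / 2
  tol <- 1e-9
  if (hl > max(dose$x) + tol || hd > max(dose$y) + tol ||
      -hl < min(dose$x) - tol || -hd < min(dose$y) - tol) {
    stop("chamber mask exceeds the dose lattice extent")
  }
  i0 <- which(abs(dose$x) < tol)
  j0 <- which(abs(dose$y) < tol)
  if (length(i0) != 1L || length(j0) != 1L) {
    stop("dose lattice has no node at the reference position (0, 0)")
  }
  point <- dose$values[i0, j0]
  in_x <- abs(dose$x) <= hl + tol
  in_y <- abs(dose$y) <= hd + tol
  wy <- rep(1, sum(in_y))
  if (weighting == "chord_weighted") {
    wy <- sqrt(pmax(0, hd^2 - dose$y[in_y]^2))
    if (sum(wy) == 0) stop("chord weights vanish; lattice too coarse")
  }
  w <- outer(rep(1, sum(in_x)), wy)
  vol_mean <- sum(w * dose$values[in_x, in_y, drop = FALSE]) / sum(w)
  if (vol_mean <= 0) stop("mean dose over the mask is not positive")
  point / vol_mean
}

#' Strip the generic volume-averaging component from a tabulated factor
#'
#' Tabulated beam-quality correction factors for machine-specific
#' reference fields include a generic volume-averaging correction.  For
#' use with an in-house (machine-specific) volume-averaging correction,
#' the generic component is divided out first; the result carries a
#' cleared volume-averaging flag and the uncertainties combined in
#' quadrature.
#'
#' @param k_tabulated A [quality_correction()] with
#'   `includes_volume_averaging = TRUE`, or a bare numeric/`quantity`
#'   (assumed tabulated-with-averaging).
#' @param kvol_generic The generic volume-averaging factor (numeric or
#'   `quantity`), > 0.
#' @return A [quality_correction()] with the flag cleared and
#'   `source = "derived"`.
#' @examples
#' strip_generic_kvol(1.004, 1.011)$value  # 0.9931, prints as 0.993
#' @export
strip_generic_kvol <- function(k_tabulated, kvol_generic) {
  k <- if (inherits(k_tabulated, "quality_correction")) k_tabulated else
    quality_correction(as_quantity(k_tabulated)$value,
                       includes_volume_averaging = TRUE,
                       source = "trs483_table",
                       rel_uncertainty = as_quantity(k_tabulated)$rel_u)
  kv <- as_quantity(kvol_generic)
  if (k$value <= 0 || kv$value <= 0) stop("factors must be > 0")
  if (!k$includes_volume_averaging) {
    stop("k_tabulated does not include a volume-averaging component to strip")
  }
  us <- c(k$rel_uncertainty, kv$rel_u)
  rel_u <- if (all(is.na(us))) NA_real_ else sqrt(sum(us^2, na.rm = TRUE))
  quality_correction(k$value / kv$value,
                     includes_volume_averaging = FALSE,
                     source = "derived", rel_uncertainty = rel_u)
}

#' Fold a specific volume-averaging factor into a stripped factor
#'
#' Inverse of [strip_generic_kvol()]: multiplies a stripped beam-quality
#' correction by a machine-specific volume-averaging factor, setting the
#' flag.  Applying to a factor whose flag is already set is refused —
#' the guard that makes double-counting of volume averaging impossible.
#'
#' @param k_stripped A [quality_correction()] with the flag cleared
#'   (or bare numeric, assumed stripped).
#' @param kvol_specific The specific volume-averaging factor, > 0.
#' @return A [quality_correction()] with the flag set.
#' @export
apply_specific_kvol <- function(k_stripped, kvol_specific) {
  k <- if (inherits(k_stripped, "quality_correction")) k_stripped else
    quality_correction(as_quantity(k_stripped)$value,
                       includes_volume_averaging = FALSE,
                       source = "derived",
                       rel_uncertainty = as_quantity(k_stripped)$rel_u)
  if (k$includes_volume_averaging) {
    stop("quality correction already includes volume averaging; refusing to double-count")
  }
  kv <- as_quantity(kvol_specific)
  if (k$value <= 0 || kv$value <= 0) stop("factors must be > 0")
  us <- c(k$rel_uncertainty, kv$rel_u)
  rel_u <- if (all(is.na(us))) NA_real_ else sqrt(sum(us^2, na.rm = TRUE))
  quality_correction(k$value * kv$value,
                     includes_volume_averaging = TRUE,
                     source = "derived", rel_uncertainty = rel_u)
}
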