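#' Scan setup metadata
#'
#' Setup conditions attached to a water-tank scan: source-to-surface
#' distance, scan depth (profiles only), the nominal collimator diameter
#' (defined at 80 cm from the source for robotic circular-collimator
#' units), the detector used, and a free-text field label for the msr /
#' reference field descriptor.
#'
#' @param ssd Source-to-surface distance, cm (> 0 when given).
#' @param depth Scan depth, cm (profiles; >= 0 when given).
#' @param collimator_diameter Nominal collimator diameter, cm (> 0).
#' @param detector_name Free text.
#' @param field_label Free text (e.g. "fmsr: 6 cm circular").
#' @param extra Named list of unrecognized header keys, preserved on
#'   round-trip.
#' @return An object of class `scan_meta`.
#' @export
scan_meta <- function(ssd = NA_real_, depth = NA_real_,
                      collimator_diameter = NA_real_,
                      detector_name = NA_character_,
                      field_label = NA_character_,
                      extra = list()) {
  ssd <- as.numeric(ssd)
  depth <- as.numeric(depth)
  collimator_diameter <- as.numeric(collimator_diameter)
  if (!is.na(ssd) && ssd <= 0) stop("ssd must be > 0")
  if (!is.na(depth) && depth < 0) stop("depth must be >= 0")
  if (!is.na(collimator_diameter) && collimator_diameter <= 0) {
    stop("collimator_diameter must be > 0")
  }
  structure(list(ssd = ssd, depth = depth,
                 collimator_diameter = collimator_diameter,
                 detector_name = as.character(detector_name),
                 field_label = as.character(field_label),
                 extra = extra),
            class = "scan_meta")
}

#' A 1-D water-tank scan curve
#'
#' Either a dose profile (positions are signed off-axis distances) or a
#' percent-depth-dose curve (positions are depths).  Values are relative
#' dose.  PDD curves are normalized to a maximum of 100 at construction,
#' so every valid `scan_curve` round-trips through [write_scan()] /
#' [read_scan()] at full precision.
#'
#' @param kind `"profile"` or `"pdd"`.
#' @param positions Strictly increasing numeric vector, cm.
#' @param values Non-negative relative dose, same length as `positions`.
#' @param meta A [scan_meta()] object.
#' @return An object of class `scan_curve`.
#' @export
scan_curve <- function(kind = c("profile", "pdd"), positions, values,
                       meta = scan_meta()) {
  kind <- match.arg(kind)
  positions <- as.numeric(positions)
  values <- as.numeric(values)
  if (length(positions) < 2L) stop("a scan curve needs at least 2 points")
  if (length(values) != length(positions)) {
    stop("positions and values must have the same length")
  }
  if (anyNA(positions) || anyNA(values)) stop("scan data must be numeric")
  d <- diff(positions)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1L]
    stop(sprintf(
      "positions must be strictly increasing: position %g at row %d %s %g at row %d",
      positions[i + 1L], i + 1L,
      if (d[i] == 0) "duplicates" else "does not exceed",
      positions[i], i))
  }
  if (any(values < 0)) stop("dose values must be >= 0")
  if (!inherits(meta, "scan_meta")) stop("meta must be a scan_meta object")
  if (kind == "pdd") {
    if (positions[1L] < 0) stop("pdd depths must be >= 0")
    values <- values / max(values) * 100
  }
  structure(list(kind = kind, positions = positions, values = values,
                 meta = meta),
            class = "scan_curve")
}

#' @export
print.scan_curve <- function(x, ...) {
  cat(sprintf("<scan_curve: %s, %d points, %g to %g cm>\n",
              x$kind, length(x$positions),
              min(x$positions), max(x$positions)))
  invisible(x)
}

.meta_keys <- c("kind", "ssd", "depth", "collimator_diameter",
                "detector_name", "field_label")

#' Read a water-tank scan file
#'
#' The scan dialect is plain text: optional header lines of the form
#' `# key: value`, then two whitespace- or comma-separated numeric
#' columns (position in cm, relative dose).  Recognized header keys are
#' `kind`, `ssd`, `depth`, `collimator_diameter`, `detector_name` and
#' `field_label`; unknown keys are preserved in `meta$extra`.  Unicode
#' minus signs are tolerated.
#'
#' @param path Path to the scan file.
#' @param dialect Format descriptor; only `"default"` is defined.
#' @return A validated [scan_curve()].
#' @export
read_scan <- function(path, dialect = "default") {
  if (!identical(dialect, "default")) stop("unknown scan dialect: ", dialect)
  if (!file.exists(path)) stop("scan file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- gsub("−", "-", lines)  # unicode minus from instrument exports
  lines <- trimws(lines)
  is_header <- startsWith(lines, "#")
  header <- lines[is_header]
  data <- lines[!is_header & nzchar(lines)]

  meta_raw <- list()
  for (h in header) {
    m <- regmatches(h, regexec("^#\\s*([^:]+?)\\s*:\\s*(.*)$", h))[[1L]]
    if (length(m) == 3L) meta_raw[[m[2L]]] <- m[3L]
  }
  kind <- meta_raw[["kind"]] %||% "profile"
  num_or_na <- function(key) {
    v <- meta_raw[[key]]
    if (is.null(v)) NA_real_ else suppressWarnings(as.numeric(v))
  }
  meta <- scan_meta(
    ssd = num_or_na("ssd"),
    depth = num_or_na("depth"),
    collimator_diameter = num_or_na("collimator_diameter"),
    detector_name = meta_raw[["detector_name"]] %||% NA_character_,
    field_label = meta_raw[["field_label"]] %||% NA_character_,
    extra = meta_raw[setdiff(names(meta_raw), .meta_keys)])

  if (length(data) < 2L) stop("scan file has fewer than 2 data rows")
  parse_row <- function(i) {
    cells <- strsplit(data[i], "[,[:space:]]+")[[1L]]
    cells <- cells[nzchar(cells)]
    if (length(cells) != 2L) {
      stop(sprintf("data row %d does not have two columns: '%s'", i, data[i]))
    }
    vals <- suppressWarnings(as.numeric(cells))
    if (anyNA(vals)) {
      stop(sprintf("non-numeric cell in data row %d: '%s'", i, data[i]))
    }
    vals
  }
  mat <- t(vapply(seq_along(data), parse_row, numeric(2)))
  scan_curve(kind = kind, positions = mat[, 1L], values = mat[, 2L],
             meta = meta)
}

#' Write a water-tank scan file
#'
#' Emits the same dialect [read_scan()] accepts: `# key: value` header
#' lines first (including `kind`), then two space-separated numeric
#' columns at full double precision.
#'
#' @param curve A [scan_curve()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scan <- function(curve, path) {
  stopifnot(inherits(curve, "scan_curve"))
  m <- curve$meta
  hdr <- c(paste("# kind:", curve$kind))
  add <- function(key, val) {
    if (length(val) == 1L && !is.na(val)) c(hdr, paste0("# ", key, ": ", val))
    else hdr
  }
  hdr <- add("ssd", m$ssd)
  hdr <- add("depth", m$depth)
  hdr <- add("collimator_diameter", m$collimator_diameter)
  hdr <- add("detector_name", m$detector_name)
  hdr <- add("field_label", m$field_label)
  for (k in names(m$extra)) hdr <- c(hdr, paste0("# ", k, ": ", m$extra[[k]]))
  rows <- sprintf("%.17g %.17g", curve$positions, curve$values)
  ok <- tryCatch({
    writeLines(c(hdr, rows), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write scan file: ", path)
  invisible(path)
}

#' Radial off-axis-ratio function
#'
#' An OAR as a function of radius for a circularly symmetric field:
#' ascending radii starting at 0, values normalized so `oar(0) = 1`.
#' Evaluation between samples is linear; beyond the last sample the last
#' value is held (clamped), a fail-safe for chamber masks that nearly
#' reach the scanned range.
#'
#' @param radii Ascending radii, cm, first element 0.
#' @param oar OAR samples; normalized to `oar[1]` at construction.
#' @param symmetry Optional left/right symmetry report from
#'   [fold_profile()] (max relative deviation between the two halves).
#' @return An object of class `radial_function`.
#' @export
radial_function <- function(radii, oar, symmetry = NA_real_) {
  radii <- as.numeric(radii)
  oar <- as.numeric(oar)
  if (length(radii) < 2L || length(oar) != length(radii)) {
    stop("radii and oar must be equal-length vectors of length >= 2")
  }
  if (radii[1L] != 0) stop("radii must start at 0")
  if (any(diff(radii) <= 0)) stop("radii must be strictly increasing")
  if (oar[1L] <= 0) stop("oar(0) must be > 0")
  oar <- oar / oar[1L]
  structure(list(radii = radii, oar = oar, symmetry = symmetry),
            class = "radial_function")
}

#' @export
print.radial_function <- function(x, ...) {
  cat(sprintf("<radial_function: %d radii, 0 to %g cm%s>\n",
              length(x$radii), max(x$radii),
              if (is.na(x$symmetry)) "" else
                sprintf(", fold asymmetry %.2g", x$symmetry)))
  invisible(x)
}

#' Fold a measured profile into a radial OAR function
#'
#' Locates the beam axis as the midpoint of the two 50%-of-maximum
#' penumbra crossings (standard water-tank practice), mirrors the two
#' half-profiles onto r >= 0, resamples them on a common radial grid,
#' averages point-wise, and normalizes so `oar(0) = 1` — the cylindrical
#' symmetry assumption for a circular field.  A symmetry report (the
#' maximum relative deviation between the two halves over radii where
#' the folded value exceeds 5% of maximum) is attached.
#'
#' @param curve A profile [scan_curve()] spanning both sides of the axis.
#' @param center_tolerance Warn (not error) if the located center is
#'   farther than this from position 0, cm.
#' @return A [radial_function()].
#' @export
fold_profile <- function(curve, center_tolerance = 0.5) {
  stopifnot(inherits(curve, "scan_curve"))
  if (curve$kind != "profile") stop("fold_profile needs a profile curve")
  p <- curve$positions
  v <- curve$values
  vmax <- max(v)
  half <- vmax / 2
  imax <- which.max(v)

  cross <- function(i, j) {
    # linear interpolation of the 50% crossing between samples i and j
    p[i] + (half - v[i]) * (p[j] - p[i]) / (v[j] - v[i])
  }
  left_below <- which(v[seq_len(imax)] < half)
  if (length(left_below) == 0L) {
    stop("profile never falls below 50% of maximum on the left side; cannot locate penumbra")
  }
  il <- max(left_below)
  xl <- cross(il, il + 1L)
  right_below <- which(v[imax:length(v)] < half) + imax - 1L
  if (length(right_below) == 0L) {
    stop("profile never falls below 50% of maximum on the right side; cannot locate penumbra")
  }
  ir <- min(right_below)
  xr <- cross(ir, ir - 1L)

  center <- (xl + xr) / 2
  if (abs(center) > center_tolerance) {
    warning(sprintf(
      "located beam axis at %.3f cm, farther than %.3f cm from position 0",
      center, center_tolerance))
  }

  s <- p - center
  step <- stats::median(diff(p))
  rmax <- min(-min(s), max(s))
  if (rmax <= 0) stop("profile does not span both sides of the located axis")
  radii <- seq(0, rmax, by = step)
  vl <- stats::approx(s, v, xout = -radii)$y
  vr <- stats::approx(s, v, xout = radii)$y
  folded <- (vl + vr) / 2

  keep <- folded > 0.05 * max(folded)
  hi <- pmax(vl[keep], vr[keep])
  lo <- pmin(vl[keep], vr[keep])
  symmetry <- max(hi / lo - 1)

  radial_function(radii, folded / folded[1L], symmetry = symmetry)
}

#' Evaluate a scan curve or radial function at a position
#'
#' Linear interpolation between neighboring samples.  Scan curves error
#' on queries outside the sampled range; radial functions clamp to the
#' last value beyond the last radius (and are even in position, so
#' negative queries use |position|).  For a PDD normalized to max = 100
#' this yields the percent depth dose at the requested depth.
#'
#' @param curve A [scan_curve()] or [radial_function()].
#' @param position Position(s), cm (off-axis for profiles, depth for
#'   PDDs, radius for radial functions).
#' @return Relative dose value(s).
#' @export
curve_value <- function(curve, position) UseMethod("curve_value")

#' @export
curve_value.scan_curve <- function(curve, position) {
  p <- curve$positions
  if (any(position < p[1L] - 1e-12) || any(position > p[length(p)] + 1e-12)) {
    stop(sprintf("query outside sampled range [%g, %g] cm",
                 p[1L], p[length(p)]))
  }
  stats::approx(p, curve$values, xout = position, rule = 2)$y
}

#' @export
curve_value.radial_function <- function(curve, position) {
  stats::approx(curve$radii, curve$oar, xout = abs(position), rule = 2)$y
}
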