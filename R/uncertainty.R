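#' Scalar quantity with a relative standard uncertainty
#'
#' Light-weight value carrier used throughout the calibration chain.  A
#' `quantity` is a single numeric value plus an optional relative standard
#' uncertainty (coverage factor k = 1).  Factors without a stated
#' uncertainty carry `NA` and contribute nothing when combined in
#' quadrature.
#'
#' @param value Numeric scalar.
#' @param rel_u Relative standard uncertainty (k = 1), dimensionless;
#'   `NA` when unknown.
#' @return An object of class `quantity` with fields `value` and `rel_u`.
#' @examples
#' q <- quantity(1.004, rel_u = 0.01)
#' propagate_product(list(q, quantity(0.9935)))
#' @export
quantity <- function(value, rel_u = NA_real_) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop("'value' must be a finite numeric scalar")
  }
  rel_u <- as.numeric(rel_u)
  if (length(rel_u) != 1L) stop("'rel_u' must be a scalar")
  if (!is.na(rel_u) && rel_u < 0) {
    stop("relative uncertainty must be >= 0")
  }
  structure(list(value = as.numeric(value), rel_u = rel_u),
            class = "quantity")
}

#' Coerce to a quantity
#'
#' Numerics become quantities without uncertainty; quantities pass through.
#'
#' @param x A `quantity` or numeric scalar.
#' @return A `quantity`.
#' @export
as_quantity <- function(x) {
  if (inherits(x, "quantity")) return(x)
  if (inherits(x, "quality_correction")) {
    return(quantity(x$value, x$rel_uncertainty))
  }
  quantity(x)
}

#' @export
print.quantity <- function(x, ...) {
  if (is.na(x$rel_u)) {
    cat(format(x$value), "(no stated uncertainty)\n")
  } else {
    cat(format(x$value), "+-", format(x$rel_u * abs(x$value)),
        sprintf("(rel. %.3g, k = 1)\n", x$rel_u))
  }
  invisible(x)
}

#' Propagate uncertainty through a product of factors
#'
#' Multiplies the values and combines the relative standard uncertainties
#' in quadrature, `sqrt(sum(u_rel^2))`, treating factors as uncorrelated.
#' Terms without a stated uncertainty contribute zero; if no term carries
#' one, the result carries `NA`.
#'
#' @param terms A list of `quantity` objects or numeric scalars (all > 0).
#' @return A `quantity` holding the product and its combined relative
#'   uncertainty.
#' @examples
#' # 3-4-5: relative uncertainties 0.003 and 0.004 combine to 0.005
#' propagate_product(list(quantity(1, 0.003), quantity(1, 0.004)))$rel_u
#' @export
propagate_product <- function(terms) {
  if (!is.list(terms) || length(terms) == 0L) {
    stop("'terms' must be a non-empty list")
  }
  terms <- lapply(terms, as_quantity)
  vals <- vapply(terms, function(q) q$value, numeric(1))
  if (any(vals <= 0)) stop("all term values must be > 0")
  us <- vapply(terms, function(q) q$rel_u, numeric(1))
  rel_u <- if (all(is.na(us))) NA_real_ else sqrt(sum(us^2, na.rm = TRUE))
  quantity(prod(vals), rel_u)
}

#' Adjudicate the significance of a scenario difference
#'
#' A percent difference between two calibration scenarios is deemed
#' significant when its magnitude exceeds `coverage` times the combined
#' percent standard uncertainty.  The default coverage k = 1 mirrors the
#' common clinical comparison of a sub-percent calibration disparity
#' against the ~1% standard uncertainty quoted for tabulated beam-quality
#' correction factors.
#'
#' @param difference_percent Observed difference, in percent.
#' @param u_combined_percent Combined standard uncertainty of the
#'   difference, in percent (>= 0).
#' @param coverage Coverage factor k applied to the uncertainty.
#' @return A list with `significant` (logical) and `margin`, the ratio
#'   `|difference| / (k * u)` (`Inf` when u = 0 and the difference is
#'   non-zero).
#' @export
assess_significance <- function(difference_percent, u_combined_percent,
                                coverage = 1) {
  if (!is.finite(difference_percent)) stop("difference must be finite")
  if (is.na(u_combined_percent) || u_combined_percent < 0) {
    stop("combined uncertainty must be >= 0")
  }
  if (coverage <= 0) stop("coverage factor must be > 0")
  bound <- coverage * u_combined_percent
  margin <- if (bound == 0) {
    if (difference_percent == 0) 0 else Inf
  } else {
    abs(difference_percent) / bound
  }
  list(significant = abs(difference_percent) > bound, margin = margin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
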