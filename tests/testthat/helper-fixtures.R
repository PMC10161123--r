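# Shared fixtures, built in code.

# Symmetric triangle profile: 1 at 0, linear to 0 at +-3 cm.
triangle_profile <- function(shift = 0, step = 0.25) {
  p <- seq(-3, 3, by = step) + shift
  v <- pmax(0, 1 - abs(p - shift) / 3)
  scan_curve("profile", p, v, scan_meta(ssd = 70, depth = 10))
}

# Plateau-asymmetric profile: flat top (left side scaled), identical
# linear penumbrae from |p| = 1 to 2, so the 50% crossings sit at
# -+1.5 exactly and the located center stays 0.
plateau_profile <- function(left_scale = 1.02, step = 0.25) {
  p <- seq(-2, 2, by = step)
  v <- ifelse(abs(p) <= 1, 1, pmax(0, 2 - abs(p)))
  v[p < 0 & p >= -1] <- left_scale
  scan_curve("profile", p, v)
}

# Worked-example configuration: measured calibration constants and the
# four scenario definitions (fit-route baseline plus three msr routes).
worked_example_config <- function() {
  read_config(system.file("extdata", "worked_example.yaml",
                          package = "msrdose"))
}

farmer_mask <- function() chamber_geometry(2.4, 0.6, "farmer-nominal")

table3_corrections <- function(prp = 1.0107) {
  correction_factors(ptp = 0.9935, pion = 1.0065, ppol = 1, pelec = 1,
                     pleak = 1, prp = prp)
}
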