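---
title: "Reference dosimetry of machine-specific reference fields with msrdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference dosimetry of machine-specific reference fields with msrdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msrdose)
```

## The problem

Clinical reference dosimetry converts an ionization-chamber reading into
absorbed dose to water per monitor unit (MU) through a calibration
coefficient $N_{D,w}$ traceable to a primary standards laboratory.  The
coefficient is valid at the calibration quality (Co-60) in a
$10 \times 10$ cm reference field; a beam-quality correction factor
adjusts it to the clinical beam.  Machines such as robotic FFF units
with circular collimators cannot form a $10 \times 10$ cm field, so
calibration happens under *machine-specific reference* (msr)
conditions — here a 6-cm-diameter circular field at 80 cm from the
source, 10 cm deep in water — and the beam-quality correction must
account for the non-standard field, including the dose gradient the
chamber's finite volume averages over.

Two families of formalism coexist in clinics:

* **Specifier-fit route** (TG-51 with its addendum, manufacturer-adapted):
  $D_w = M \, k_Q \, N_{D,w}$, with
  $M = P_{TP} P_{ion} P_{pol} P_{elec} P_{leak} P_{rp} M_{raw}$.
  $k_Q$ comes from a chamber-specific quadratic fit in the beam-quality
  specifier $\%dd(10,10)_X$, and the volume-averaging correction
  $P_{rp}$ sits in the reading.
* **Tabulated-msr route** (TRS-483):
  $D_{w,Q_{msr}}^{f_{msr}} = N_{D,w} \, k_{Q_{msr},Q_0}^{f_{msr},f_{ref}} \, M_{Q_{msr}}^{f_{msr}}$,
  where the tabulated (or Monte-Carlo) factor already contains a
  volume-averaging component $k_{vol}$, so the corrected reading omits
  $P_{rp}$.

Because the msr formalism reduces to the conventional one when the same
reference conditions are used, the two routes should agree whenever
volume averaging enters exactly once and with the same value — the
central consistency property this package encodes, tests, and reports
on.

## What the package computes

**Scan handling.** `read_scan()`/`write_scan()` use a plain two-column
text dialect with `# key: value` headers.  `fold_profile()` converts a
measured transverse profile into a radial off-axis-ratio (OAR) function
under the cylindrical-symmetry assumption appropriate for a circular
field: the beam axis is located as the midpoint of the two
50%-of-maximum penumbra crossings (standard water-tank practice;
vendor software does the same), the two halves are
mirrored, resampled on a common radial grid, averaged, and normalized
to 1 on the axis.  A symmetry report — the maximum ratio deviation
between the halves where the signal exceeds 5% of maximum — is kept on
the result so asymmetric scans are visible, not silently averaged away.

**Volume averaging.** `prp()` integrates the OAR over the rectangular
footprint of the chamber's sensitive volume (length $L$ along the
chamber axis, diameter $D$ transverse) and returns
$\mathrm{OAR}(0) / \overline{\mathrm{OAR}}_{mask}$.  Two weightings are
offered: `uniform_area` treats the 2-D mask uniformly (the footprint
picture used when masking a measured profile), and `chord_weighted`
weights each transverse offset $y$ by the chord length
$\sqrt{(D/2)^2 - y^2}$, which is the exact volume average of a
cylinder.  Published workflows rarely state which was used; uniform is
the default and the two differ only in the $D^2$ term
($D^2/12$ vs $D^2/16$), well below $10^{-4}$ for Farmer-scale
chambers in these fields.  `kvol_from_grid()` applies the same
point-over-mean contract to an externally supplied dose lattice (for
example one produced by a treatment-planning or Monte Carlo system —
no transport is performed here).

**Factor algebra.** Tabulated msr beam-quality factors include a
*generic* volume-averaging component derived from earlier machine
models.  `strip_generic_kvol()` divides it out and clears the
volume-averaging flag; `apply_specific_kvol()` multiplies a
machine-specific value back in and sets the flag.  The flag is the
double-counting guard: `dose_per_mu()` refuses a reading that contains
$P_{rp}$ combined with a quality correction whose flag is set, so
volume averaging can enter a scenario exactly once (or, deliberately,
not at all — then the output is flagged `none`).

**Uncertainties.** All factors optionally carry relative standard
uncertainties ($k=1$), combined in quadrature under an
uncorrelated-factors assumption (no covariance information is ever
published for these budgets).  Scenario differences are adjudicated by
`assess_significance()` at a configurable coverage factor, default
$k=1$, mirroring how sub-percent calibration disparities are judged
against the ~1% standard uncertainty quoted for tabulated msr factors.

## The worked example

The bundled configuration
(`system.file("extdata", "worked_example.yaml", package = "msrdose")`)
carries the measured constants of a 6-cm circular FFF msr field —
$N_{D,w} = 4.87$ cGy/nC, $P_{TP} = 0.9935$, $P_{ion} = 1.0065$,
$P_{pol} = P_{elec} = P_{leak} = 1$, $M_{raw}/MU = 0.1529$ nC,
$P_{rp} = 1.0107$ from the measured profile — and four scenarios:

```{r worked}
cfg <- read_config(system.file("extdata", "worked_example.yaml",
                               package = "msrdose"))
run_scenarios(cfg)
```

The doses straddle 0.745–0.748 cGy/MU and none of the differences is
significant at $k = 1$.  Note the baseline dose, 0.74654 cGy/MU, sits
essentially on the 0.746/0.747 rounding boundary because the
configured inputs are themselves rounded to four digits; comparisons
against printed three-decimal values therefore use a one-unit-in-the-
last-digit tolerance.  Differences are computed from full-precision
doses, not from the rounded ones — full precision reproduces all three
printed differences (+0.11%, +0.14%, −0.22%), rounding first does not.

## The synthetic-data generator

No public scan data exist for this geometry, so the generator produces
the study conditions directly:

* **Profile** — $\mathrm{OAR}(r) = (1 - a r^2) / (1 + e^{(|r|-R)/w})$:
  a parabolic in-field droop $a$ (the defining FFF feature) under a
  logistic penumbra of scale $w$.  Defaults: $R = 3$ cm (the 6-cm
  collimator projected to the measurement plane at SDD 80 cm),
  $w = 0.25$ cm, $a = 0.018$ cm$^{-2}$ — the curvature that makes a
  $2.4 \times 0.6$ cm Farmer-scale mask see a $\sim$0.9% correction,
  inside the 1.005–1.012 band spanned by published experimental and
  simulated values for this machine class.  Multiplicative Gaussian
  noise (default 0.1%, the point-to-point scatter of an averaged diode
  scan) is applied under an explicit seed; generators never touch the
  global RNG stream.
* **PDD** — $(1 - e^{-b z}) \, e^{-\mu \max(0, z - z_{max})}$ with
  $b = 3.5$ cm$^{-1}$, $\mu = 0.0515$ cm$^{-1}$, $z_{max} = 1.5$ cm,
  solved so the curve reads 64.9% at 10 cm depth — the specifier value
  of a 6 MV-class FFF beam.  The model has no electron-contamination
  dip and no inverse-square structure; it is a fixture for specifier
  plumbing, not a beam model.
* **Readings** — `gen_readings()` inverts the dose equation for a known
  true dose and adds relative noise, following the usual
  five-repetitions-of-200-MU acquisition.

What passing tests on these synthetics do **not** show: real scans have
detector-size convolution, scatter tails, arm-position droop and
asymmetries the logistic/parabola model lacks, and the measured-profile
volume-averaging values (1.0107 experimental, 1.0078 simulated) depend
on profile details published only as a figure.  Those two values, and
the Monte-Carlo factors $k_{Q_{msr}} = 1.0004$ and $k_{vol} = 1.0072$
(which require full radiation transport with a proprietary beam model),
are therefore *configured inputs* here, exercised by the algebra, never
recomputed.

## Numerical choices

* **Interpolation** is linear everywhere (scan curves, radial
  functions, lattice expansion).  It is the transparent choice that an
  independent hand calculation can verify; with 0.01-cm integration
  grids the associated error is below $10^{-6}$ on the factors.
* **Mask integration** uses trapezoidal end-weights along each axis
  with the step snapped so nodes land exactly on the origin and the
  mask boundary.  This keeps the discrete mean of a quadratic within
  $O(h^2)$ of the continuous one; against the closed-form parabola
  oracle $1/(1 - a (L^2 + D^2)/12)$ the numeric result agrees to
  $<0.02\%$ at 0.01-cm spacing, and halving the spacing moves the
  default synthetic profile's correction by under 0.01%.
* **Radial clamping**: beyond the last sampled radius the OAR holds its
  last value.  Masks should never extend past the scanned range; when
  they do, clamping under-corrects gracefully instead of
  extrapolating.
* **PDD normalization** is to the curve's own maximum (= 100), and the
  photon-component specifier is taken equal to the measured value with
  no electron-contamination adjustment at this energy.
* **Specifier window**: `kq_from_fit()` warns outside 40–90%, the
  cheap guard against a fraction/percent unit mistake.
* **Specifier conversion** between field sizes is a pluggable strategy
  (lookup table or polynomial) because neither the manufacturer's
  method nor the code-of-practice coefficients are published alongside
  the example values; the shipped table carries the two published
  input/output pairs (64.90% at ESFS 6.75 → 66.94%; at ESFS 6.25 →
  67.42%).
* The **center-sample normalization** of `fold_profile()` makes a
  volume-averaging estimate from a noisy scan inherit the center
  sample's noise almost one-to-one; with 0.1% point noise that is a
  ±0.1%-scale jitter on the factor.  Averaging repeated scans (or
  folding, which already averages the two halves) is the measurement-
  side remedy; the package deliberately does not smooth.

## Test problem sizes

The suite runs the worked example exactly as configured (four
scenarios), checks the formalism-equivalence identity on 1000
randomized input sets, the parameter-recovery property on 1000 seeded
five-reading trials at 0.2% noise (pass when the recovered dose is
within $3\sigma/\sqrt{5}$ of truth in at least 99% of trials), and the
mask-integration oracles at 0.01-cm spacing — a few seconds in total.

## Known limitations

* Only cylindrical chambers perpendicular to the beam axis are
  modelled; no tilts, no stem/electrode perturbations, no gradient
  (P_gr) corrections — these are out of scope of the volume-averaging
  picture used here.
* The TPR-based beam-quality specifier route is not implemented.
* Chamber sensitive-volume dimensions are required configuration; the
  examples use nominal Farmer-scale placeholders because exact vendor
  dimensions are confidential.
* Scan handling assumes the plain-text dialect described above; vendor
  binary formats must be exported to text first, and no smoothing or
  divergence correction is applied.
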