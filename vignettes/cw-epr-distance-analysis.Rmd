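---
title: "Interspin distances and spin-label mobility from CW-EPR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interspin distances and spin-label mobility from CW-EPR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(spindist)
```

## The problem

Site-directed spin labeling places nitroxide radicals at engineered
cysteines.  When two labels sit within roughly 0.8–2.5 nm of each other,
their magnetic dipole–dipole coupling broadens the continuous-wave EPR
spectrum in a distance-dependent way; when a label is attached singly, the
room-temperature lineshape instead reports the side chain's rotational
mobility.  `spindist` implements both analyses for first-derivative,
field-swept X-band spectra:

* the **dipolar distance analysis** — a convolution forward model and a
  bounded 1-/2-Gaussian fitting engine that turns a pair of spectra
  (double-labeled and single-labeled) into a distance distribution
  P(r), the classic probe of whether an *i*, *i*+4 labeled segment is
  α-helical (a sharp population near 0.9 nm) or disordered (a broad
  0.8–2.5 nm distribution);
* the **mobility analysis** — effective outer splitting 2T~eff~, the
  Goldman empirical correlation-time calibration, a slow/fast peak-height
  ratio and two-component spectral subtraction.

Because instrument data for the motivating system are not redistributable,
the package carries a first-order spectrum simulator whose output feeds
every test; the registry `pair_models()` stores the published Gaussian
parameter sets used as ground truth for synthetic benchmarks.

## The forward model

The double-label spectrum is modeled as the convolution of the
interaction-free (single-label) spectrum S with a unit-area dipolar
broadening kernel, mixed over the model's components:

$$ D(B) = f_{\mathrm{non}}\,S(B) + \sum_i f_i\,(S \ast K_i)(B),
   \qquad f_{\mathrm{non}} + \sum_i f_i = 1 . $$

Working on the first-derivative spectrum is valid because differentiation
and convolution commute.  For a fixed distance r the kernel is the secular
Pake pattern: two lines at field offsets
$\pm\,\tfrac{C}{2r^3}(3\cos^2\theta - 1)$ averaged over a sin θ powder
distribution, giving perpendicular singularities at ±C/(2r³) and parallel
shoulders at ±C/r³.  The dipolar constant is computed from CODATA
constants at run time (`dipolar_constant()` = 52.04 MHz nm³, i.e.
18.57 G nm³ at g = g~e~) rather than hard-coded, so its provenance is
auditable.  A Gaussian distance component (centre r, FWHM Δr) averages
single-distance kernels over a 0.02 nm grid spanning ±3σ, truncated at the
grid bounds [0.4, 4.0] nm and renormalized.  Exchange coupling J is
deliberately not modeled; data that need it show up as poor χ² and
structured residuals, which the fit reports rather than absorbs.

Numerical notes:

* **θ grid.** 1800 sin θ-weighted points with linear-interpolation binning
  onto the field grid; the integrable perpendicular singularity needs the
  density, and a doubling test in the suite bounds the residual grid error.
* **Convolution.** FFT with zero padding; an O(nm) direct summation is kept
  as an oracle and the two agree to 1 × 10⁻¹⁰ on 256-point grids.
* **Kernel symmetry and area.** Kernels are symmetrized exactly
  (`w ← (w + rev(w))/2` on a symmetric offsets axis) and normalized to unit
  trapezoidal area, so the forward model conserves the double integral.
* **Window truncation.** Conservation holds on the recorded window only
  while the broadened support stays inside it.  Distribution tails reaching
  0.4 nm produce splittings of hundreds of Gauss, whose intensity leaves a
  200 G sweep; for such models the windowed double integral of the
  broadened spectrum falls a few percent below the reference's.  This is a
  physical property of windowed detection, not a numerical defect; it is
  why `fit_distance()` expects inputs normalized once upstream
  (`normalize_to_spins()`) and does not renormalize per evaluation.
* **Kernel flattening.** Widening Δr at fixed r flattens the kernel while
  the distribution tail stays in the strongly coupled range; once the tail
  reaches weakly coupled distances (≳ 2 nm), near-delta kernel
  contributions re-sharpen the centre.  The property test asserts
  flattening only in the regime where it is real.

## The inverse problem

`fit_distance()` minimizes
$\chi^2 = \sum_j \big(D_j - \hat D_j(\vartheta)\big)^2 / \sigma^2$
over ϑ = (r~i~, Δr~i~, f~i~), 3 parameters per Gaussian, inside the
conventional boxes r ∈ [0.8, 2.8] nm, Δr ∈ [0.04, 2] nm, f ∈ [0, 1], with
f~non~ = 1 − Σf~i~ kept in [0, 1] by a penalty residual (the parameters
stay directly interpretable against published tables; a simplex transform
would not).  σ defaults to the standard deviation of the outer 5% edge
windows of the data — the χ² scale is therefore internally comparable
between fits of the same data but not across instruments, and no absolute
published χ² value is treated as reproducible.  A small floor
(10⁻¹⁰ × max|D|) keeps noiseless synthetic data finite.

Because every objective evaluation is linear in the distance-grid weights,
the fitter precomputes the convolutions S ∗ K(r~j~) for all 181 grid
distances once per reference spectrum; an evaluation then costs one
matrix–vector product, which is what makes multistart fitting and
bootstrapping cheap.

**Optimizers.**  The default is bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) from seeded Latin-hypercube multistarts.  The
6-parameter 2-Gaussian landscape is genuinely multimodal — raw LHS starts
reliably fall into a broad-single-component basin — so the start set is
chosen by *ranked oversampling*: 25 × n~starts~ LHS candidates are scored
with one objective evaluation each and LM runs from the best n~starts~
(default 8).  A Monte-Carlo/simplex alternative (uniform random proposals
alternated with Nelder–Mead refinement in a logistic bound transform,
default budget 2000 evaluations) is available for cross-checking.
Components are always reported sorted by ascending r (ties by larger f) so
recovery comparisons are label-stable.  All stochastic pieces run under
`withr::with_seed`, so identical options and data give bit-identical
results.

**Model comparison and uncertainty.**  `compare_models()` reports
χ²(1G)/χ²(2G) and flags the 2-Gaussian model above a configurable
threshold (default 1.2, the smallest improvement treated as meaningful in
this assay class).  `estimate_uncertainty()` is a residual bootstrap
(default 100 seeded replicates refit from the optimum) cross-checked
against the local Jacobian covariance; the reported ± is the larger of the
two, and the estimate is flagged when more than 20% of refits fail.  The
published tables' uncertainty definition is unstated, so magnitudes — not
exact values — are the meaningful comparison.  Components fitted beyond
2.5 nm are pooled with f~non~ in reports ("> 2.5" column): a 2.5 nm kernel
changes a 3 G-linewidth spectrum by under 2% of its peak-to-peak, below CW
detectability.

## The synthetic generator

`simulate_powder()` builds rigid-limit nitroxide spectra from first-order
resonance fields
$B(\theta, \phi, m_I) = h\nu / (g(\theta,\phi)\mu_B) - A(\theta,\phi)m_I$
with standard ellipsoid interpolation of the principal values, a
sin θ-weighted 200 × 20 orientation grid (convergence asserted by a
doubling test, not assumed), Voigt broadening and analytic area
normalization, so the double integral of the derivative equals the
configured spin amplitude.  Defaults: g = (2.0086, 2.0066, 2.0032),
A = (6, 6, 35) G, Gaussian/Lorentzian linewidths 3/1 G FWHM, 9.6 GHz,
1024 points over a 200 G sweep.  A~zz~ = 35 G is fixed by the rigid-limit
constant of the mobility calibration; the g-values and linewidths are
declared fixture conventions (the real labels' intrinsic linewidths are
not published), chosen once as typical X-band nitroxide magnitudes.

`simulate_mobile()` models partial motional averaging by an order
parameter S scaling all tensor anisotropies about their isotropic means,
so T~eff~ ≈ a~iso~ + S(A~zz~ − a~iso~) by construction.  This is a control
knob for testing the mobility stage, *not* a dynamic lineshape theory:
real intermediate-regime spectra have asymmetric, correlation-time-
dependent shapes that tensor scaling cannot produce.  Consequently the
passing mobility tests demonstrate the correctness of the measurement
operators (extremum location, calibration arithmetic, subtraction
nulling), while their accuracy on real slow-motion spectra inherits the
approximations of the underlying calibration.  Noise is white Gaussian at
a stated peak-to-peak SNR under a fixed seed — no baseline drift, field
modulation distortion or phase error, so robustness to those artifacts is
untested by design.

## Mobility operators

* `measure_teff()` finds the outermost low-field maximum and high-field
  minimum above a prominence threshold (default 2% of peak-to-peak) and
  refines both by a 5-point parabola — at 0.2 G grid resolution the
  refinement is what makes a 1.5 G tolerance on T~eff~ testable.  Fully
  averaged spectra without resolvable outer features raise an error
  pointing to the fast-motion regime.
* `tau_eff()` evaluates the Goldman calibration
  τ~eff~ = a(1 − T~eff~/T~max~)^b with a = 5.4 × 10⁻¹⁰ s, b = −1.36,
  T~max~ = 35 G, exactly as published: Inf at the rigid limit, undefined
  (NaN with a warning) above it.  Its validity range is inherited, not
  re-derived.
* `subtract_component()` makes the by-eye two-component subtraction
  algorithmic: scan the removed fraction x over [0, 1] in 0.005 steps
  (parabolic refinement at the optimum), minimizing the residual power in
  the fast-feature windows — the three sharpest extrema of the reference,
  ±3 G — after a local quadratic detrend per window.  The detrend is the
  key design choice: the immobile background is smooth and locally
  quadratic over 6 G, so it drops out of the score, while the sharp mobile
  derivative features do not; without it the optimum is biased by
  whatever broad intensity sits under the sharp lines.  A guard keeps the
  difference's double integral above −1% of the composite's.  On noiseless
  two-component fixtures the known mixing fraction is recovered within
  ±0.01 across 0.2–0.6 (the test suite asserts ±0.02).  The removed
  fraction x refers unambiguously to the reference; the immobile
  remainder is 1 − x, and both readings of a published "subtracting N%"
  statement can be mapped onto it.

## Problem sizes and benchmarks

The test suite and the reproduction script run entirely on synthetic
data: 512-point spectra with 1200–2000 orientations for unit and property
tests, 1024 points with 4000 orientations for the headline recovery runs;
the seeded 20-model recovery grid spans r ∈ [0.8, 2.3] nm,
Δr ∈ [0.04, 1.6] nm, f ∈ [0.3, 0.9] — the region where a single Gaussian
is identifiable on a 200 G window (centres beyond ≈2.3 nm trade off
against f~non~, which is exactly the "> 2.5" pooling).
`run_benchmark_suite()` regenerates fixtures from the full registry and
marks components outside that region as non-identifiable instead of
scoring them.  These sizes were chosen as the smallest at which the grid
and orientation convergence tests hold with margin.

## Known limitations

* Secular dipolar kernel only: no exchange coupling, no pseudosecular
  terms below ≈0.8 nm, no half-field transitions, uncorrelated
  label-frame/interspin-vector orientations.
* First-order resonance fields; no field-modulation or saturation
  modeling; Bruker binary formats are out of scope (two-column ASCII and
  a JCAMP-DX-like header dialect are supported).
* χ² values are internally normalized (edge-window σ) and not comparable
  to values produced by other software or instruments.
* The order-parameter generator cannot emulate intermediate-regime
  dynamic lineshapes; mobility results on real spectra are only as good
  as the underlying empirical calibration.
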