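# spindist

Interspin distance distributions and spin-label mobility from CW-EPR
spectra of site-directed spin-labeled proteins.

When two nitroxide labels sit 0.8–2.5 nm apart, their dipole–dipole
coupling broadens the continuous-wave EPR spectrum; the broadened
(double-label) spectrum is the convolution of the interaction-free
(single-label) spectrum with a Pake dipolar kernel averaged over the
interspin distance distribution P(r),

    D(B) = f_non · S(B) + Σ_i f_i · (S ⊛ K_i)(B),

with P(r) modeled as one or two Gaussians (centre r, FWHM Δr, fraction f)
plus a non-interacting pool f_non.  `spindist` implements the forward
model, a bounded multistart Levenberg–Marquardt / Monte-Carlo-simplex
fitting engine with χ² model comparison and bootstrap uncertainties, spin
quantification by double integration, and the room-temperature mobility
toolkit: effective outer splitting 2T_eff, the Goldman calibration
τ_eff = a(1 − T_eff/T_max)^b (a = 5.4 × 10⁻¹⁰ s, b = −1.36,
T_max = 35 G), slow/fast peak-height ratios and two-component spectral
subtraction.  A first-order nitroxide powder simulator generates
rigid-limit, motionally averaged, dipolar-broadened and composite spectra
so the whole pipeline is testable without instrument data.  Typical
users: EPR/SDSL labs probing secondary structure of disordered protein
regions via i, i+4 labeling (a sharp ~0.9 nm population is the α-helix
signature) and side-chain immobilization upon complex formation.

## Worked example

Simulate a rigid-limit single-label reference, broaden it with a
published two-Gaussian distance model from the packaged registry, and
invert:

```r
library(spindist)
axis   <- default_field_axis(n = 1024)          # 3330–3530 G
single <- simulate_powder(nitroxide_system(), axis)
truth  <- pair_model("cTnI(43/47MTSL)+cTnC", 2) # registry parameter set
pair   <- forward_model(single, truth)

fit1 <- fit_distance(pair, single, n_gaussians = 1, n_starts = 8, seed = 1)
fit2 <- fit_distance(pair, single, n_gaussians = 2, n_starts = 8, seed = 1)
fit2
#> Gaussian distance-distribution fit (2 components, levenberg-marquardt)
#> 2 Gaussian distance component(s):
#>   r = 0.910 nm, dr(FWHM) = 0.100 nm, f = 48.0%
#>   r = 1.210 nm, dr(FWHM) = 1.320 nm, f = 29.0%
#>   non-interacting / >2.5 nm pool: 23.0%
#> chi2 = 6.049e-24 (6 parameters, 1024 points)
compare_models(fit1, fit2)
#> chi2 ratio (simple/complex): 2.6e+29  [chi2 = 1.573e+06 vs 6.049e-24]
#> preferred model: more complex (ratio above threshold 1.2)
```

The fitter recovers the generating model exactly (noiseless data): a 48%
population at 0.91 nm with 0.10 nm width — the helix-like component — a
29% broad component at 1.21 nm, and 23% of spins beyond CW detectability.
The χ² ratio says one Gaussian cannot explain the data.  `plot(fit2)`
shows data/fit, residuals and P(r); `summary(fit2, uncertainty = TRUE)`
adds residual-bootstrap ± values; `report_table()` formats fits in the
standard table layout.

Mobility side:

```r
mob <- simulate_mobile(nitroxide_system(), S = 0.55,
                       axis = default_field_axis(sweep = 100))
te  <- measure_teff(mob)
tau_eff(as.numeric(te))
#> T_eff = 26.3 G  ->  tau_eff = 3.59e-09 s
```

and `subtract_component(composite, reference)` decomposes a two-component
spectrum, returning the removed mobile fraction x (immobile remainder
1 − x).

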