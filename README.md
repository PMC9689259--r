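# tissopt

Optical characterization of turbid biological slabs from integrating-sphere
measurements, for tissue-optics and biophotonics work: estimation of the
absorption coefficient μa and reduced scattering coefficient μs′ = (1−g)μs
(cm⁻¹) from diffuse reflectance Rd and total transmittance Td via the
Kubelka–Munk two-flux model; simulation of surface fluence-rate maps by a
finite-element solution of the steady-state diffusion equation with an
internal-reflectance boundary; and validation of emission-spectra matrices
with partial least squares regression.  Everything runs on seeded synthetic
phantoms, so the whole chain is testable without instrument data.

## The models

**Two-flux inversion.**  A slab of thickness D is described by
A_KM = 2μa, S_KM = (3/4)μs′ − (1/4)μa, x = 1 + A_KM/S_KM, y = √(x²−1);
closed forms give (Rd, Td) from (x, y, S_KM D) and are inverted exactly:
x = (1 + Rd² − Td²)/(2Rd) and
S_KM = (arsinh(y/Td) − arsinh(y))/(yD) for the classical Kubelka solution.
A second "paper" dialect with the hyperbolic terms exchanged is kept behind
a flag; its inversion solves the cubic 2Rd·y³ − (1−Rd²−Td²)·y² + Td² = 0
and is *set-valued* — that equation pair is a two-to-one map, and
`km_invert()` documents and exposes every exact preimage (see the methods
vignette).  The effective attenuation coefficient is
μeff = √(3μa(μa+μs′)) ≡ S_KM·y.

**Fluence modelling.**  −∇·(D∇Φ) + μaΦ = f with D = 1/(3(μa+μs′)), a point
source at the centre of a disk, and the Robin condition D∂Φ/∂n + qΦ = 0,
where q = 1/(2A), A = (1+Reff)/(1−Reff), and
Reff = −1.44n⁻² + 0.7n⁻¹ + 0.063n + 0.668 for index ratio n.  P1 triangles
on a centrally refined ring mesh; verified by manufactured solutions
(L² order ≈ 2), exact discrete flux balance, and the 2-D Green's function
Φ(r) = P·K₀(μeff r)/(2πD).

**Spectral regression.**  Single-response SIMPLS with training R²;
cross-checked against NIPALS (`mixOmics`) and, at full rank, ordinary
least squares.

## Worked example

```r
library(tissopt)

props <- optical_properties(0.84, 26.2, n_rel = 1.4)  # hydrated skin, 808 nm
cf <- km_coeffs_from_optical(props)
#> KM coefficients: A_KM = 1.68, S_KM = 19.44 cm^-1 (x = 1.08642, y = 0.424627)

rt <- km_forward(cf, 0.2, "classical")   # 2 mm slab
#> Rd = 0.6479, Td = 0.1096
km_invert(diffuse_measurement(rt$rd, rt$td, 0.2), "classical")
#> Optical properties: mua = 0.84 cm^-1, musp = 26.2 cm^-1
#>   mueff = 8.25474 cm^-1, d_diff = 0.0123274 cm

mesh <- build_disk_mesh(2, h_far = 0.1, h_near = 0.005)
#> Graded disk mesh: radius 2 cm, 5921 nodes, 11714 triangles
#>   h_near = 0.005, h_far = 0.1 cm; min angle 31.8 deg
summary(solve_fluence(mesh, props, boundary_condition(1.4)))
#> log10(phi) range [-6.742, 1.632], e-fold radius 0.05802 cm (1/mueff = 0.1211 cm)
#> flux balance relative error 2.22e-16
```

The round trip returns the generating coefficients to machine precision;
the fluence summary says the field spans ~8 decades across the 2 cm disk,
the azimuthally averaged profile falls to 1/e of its near-source value
within 0.58 mm (strong attenuation), and the solver conserves the injected
power exactly.  A full synthetic study — generate noisy measurements for
the 12-entry phantom panel, invert each, aggregate replicates — is one
call:

```r
fit <- km_fit(simulate_measurements(make_phantom_panel(),
                                    generator_config(seed = 1), "classical"),
              dialect = "classical")
summary(fit)
#> Kubelka-Munk inversion (classical dialect), 60 measurements
#> Replicate aggregates (mean +/- sd):
#>   Hydrated skin             808 nm : mua  0.836 +/- 0.065, musp  26.37 +/- 1.66 cm^-1
#>   Dry skin                  830 nm : mua  0.135 +/- 0.038, musp  39.13 +/- 2.90 cm^-1
#>   ...
```

With the default 1% measurement noise and five replicates, the aggregated
means sit within a few percent of the generating panel values
(0.836 vs 0.84; 26.37 vs 26.2).  `run_pipeline(pipeline_config(seed = 1))`
chains generation, inversion, a fluence solve per condition/wavelength, and
per-tissue PLSR into a reproducible `report.json`; the same commands are
available from a shell via `inst/cli/tissopt.R`
(`generate`, `invert`, `fluence`, `plsr`, `run`).

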