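---
title: "Methods: two-flux inversion, diffuse fluence modelling, and spectral regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-flux inversion, diffuse fluence modelling, and spectral regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissopt)
```

`tissopt` implements the three computational stages of an integrating-sphere
tissue-characterization workflow on synthetic phantoms: (1) recovery of the
absorption coefficient $\mu_a$ and reduced scattering coefficient
$\mu_s' = (1-g)\mu_s$ (both cm$^{-1}$) of a turbid slab from its diffuse
reflectance $R_d$ and total transmittance $T_d$ via the Kubelka–Munk (KM)
two-flux model; (2) simulation of the steady-state surface fluence-rate
distribution produced by a point source, by solving the diffusion
approximation of radiative transfer with linear finite elements on a disk;
and (3) validation of emission-spectra matrices (laser-induced-fluorescence
style, a porphyrin-attributed peak near 700 nm) with single-response partial
least squares regression.  No raw measurements ship with the package; a
seeded generator emulates the study conditions so that every stage is
exercised end to end.

## The two-flux model and its two dialects

The two-flux parametrization describes a slab by an effective absorption
$A_{KM} = 2\mu_a$ and scattering $S_{KM} = \tfrac34\mu_s' - \tfrac14\mu_a$
(so physical validity requires $\mu_s' > \mu_a/3$), with dimensionless
auxiliaries $x = 1 + A_{KM}/S_{KM}$ and $y = \sqrt{x^2-1}$.  Two closed
forms for $(R_d, T_d)$ at slab thickness $D$ are implemented behind a
`dialect` flag:

* **classical** — the textbook Kubelka solution,
  $R_d = \sinh(S y D)\,/\,(x\sinh(S y D) + y\cosh(S y D))$ and
  $T_d = y\,/\,(x\sinh(S y D) + y\cosh(S y D))$;
* **paper** — the same expressions with the hyperbolic terms exchanged
  ($x\cosh + y\sinh$ in the denominator and $\sinh$ in the $R_d$
  numerator), kept because source material in this field sometimes prints
  the pair this way.

Only the classical dialect passes the basic physical limits: as $D \to 0$
it gives $T_d \to 1$, and as $\mu_a \to 0$ it conserves energy
($R_d + T_d \to 1$).  The paper dialect gives $T_d \to y/x$ in the thin
limit and is degenerate at zero absorption, which is why the package treats
the classical form as the physically consistent choice while keeping the
printed form available (it is the default of `km_forward()`/`km_invert()`
for fidelity; the pipeline defaults to classical, see below).

### Exact inversion, and why the printed form is not identifiable

Given $(R_d, T_d)$, the extraction
$x = (1 + R_d^2 - T_d^2)/(2R_d)$, $y = \sqrt{x^2 - 1}$ is algebraically
exact **for the classical dialect only** (substituting the classical closed
forms reproduces $x$ identically; `x - 1` is computed in the
cancellation-free form $(1-R_d-T_d)(1-R_d+T_d)/(2R_d)$).  The scattering
coefficient then follows in closed form from the $T_d$ equation,
$S_{KM} = (\operatorname{arsinh}(y/T_d) - \operatorname{arsinh}(y))/(yD)$,
and $A_{KM} = S_{KM}(x-1)$, $\mu_a = A_{KM}/2$,
$\mu_s' = \tfrac43 S_{KM} + \tfrac13\mu_a$.  For $y < 10^{-6}$ the
conservative series branch $S_{KM} = R_d/(T_d D)$ avoids the $0/0$ limit.
This inversion is unique and round-trips the forward model to machine
precision (the suite asserts $10^{-8}$ relative over a 12-condition
$\times$ 3-thickness grid; the achieved error is $\sim 10^{-15}$).

For the paper dialect the same extraction is *inconsistent* with the
printed closed forms (applying it to paper-dialect output of
$\mu_a = 0.84$, $\mu_s' = 26.2$, $D = 0.2$ cm yields $x = 1.1017$ against
the true $1.0864$).  Eliminating $S_{KM}$ exactly instead leads to the
cubic
$$2 R_d\, y^3 - (1 - R_d^2 - T_d^2)\, y^2 + T_d^2 = 0,$$
followed by $S_{KM} = (\operatorname{arcosh}(y/T_d) -
\operatorname{arcosh}(x))/(yD)$.  Solving it exposes a structural fact:
over much of the physical range the cubic has **two** admissible positive
roots and *both* reproduce the measured $(R_d, T_d)$ to machine precision.
The printed equation pair is a two-to-one map, so a single slab measurement
cannot identify $(\mu_a, \mu_s')$ under this dialect — the preimages can
differ by factors of 30 in $\mu_a$.  `km_invert()` therefore returns, by
documented convention, the smallest-$y$ (most scattering-dominated) exact
branch, attaches *all* exact preimages as the `"alternates"` attribute, and
accepts an optional prior (`near =`) that selects the admissible branch
closest in log-coefficient distance — the standard way to resolve an
ill-posed inversion when external knowledge exists.  Tests assert recovery
set-valuedly: the generating parameters must be among the exact preimages.
Because only the classical dialect is injective, the end-to-end pipeline
and the noisy recovery experiment use it by default.

A bisection root-finder on the $T_d$ equation, written independently in the
test suite and the acceptance script, confirms the closed-form $S_{KM}$ to
$10^{-10}$ on 100 random draws.  Numerically, all hyperbolics are evaluated
through exponentially scaled forms (only $e^{-(\cdot)}$ terms appear), so
large optical depths $S y D$ can never overflow or return `NaN`.

## Diffusion approximation and the finite-element solver

The fluence rate $\Phi$ of a continuous point source in a homogeneous
medium satisfies, in steady state, the Helmholtz-form diffusion equation
$$-\nabla\cdot(D_\mathrm{d}\nabla\Phi) + \mu_a\Phi = f,
  \qquad D_\mathrm{d} = \frac{1}{3(\mu_a+\mu_s')},$$
with the index-mismatch (Robin) boundary condition
$D_\mathrm{d}\,\partial\Phi/\partial n + q\,\Phi = 0$.  The impedance term
comes from the empirical polynomial for the effective internal reflection
coefficient, $R_\mathrm{eff} = -1.44n^{-2} + 0.7n^{-1} + 0.063n + 0.668$
with $n$ the inside-to-outside refractive-index ratio, through
$A = (1+R_\mathrm{eff})/(1-R_\mathrm{eff})$ and $q = 1/(2A)$.  The
polynomial is evaluated exactly as printed, without clamping: at $n = 1$ it
is slightly negative ($-0.009$), giving $A$ marginally below 1, and this is
passed through because no clamp is part of the published fit.  The
refractive indices actually used per tissue are not published; the package
defaults to $n = 1.4$, the usual soft-tissue-against-air value, as a
config key (`boundary.n_rel`, with a direct `reff` override).

Design choices, in order of consequence:

* **Dimensionality** — the solver is 2-D (a disk), matching the planar
  surface maps the workflow produces.  The published figures do not state
  2-D vs 3-D; 2-D was chosen and all oracles (below) use the matching 2-D
  Green's function.
* **Geometry** — disk radius 2 cm by default.  The source sits at the
  centre; only a central source is supported because the mesh grading is
  built around it.  Source power is 1 in arbitrary units (no published
  normalization), so meaningful outputs are shapes and ratios.
* **Mesh** — concentric node rings whose spacing grows linearly from
  `h_near` (default 0.005 cm) at the source to `h_far` (default 0.1 cm) at
  the boundary, stitched by an angular-sweep triangulation with staggered
  rings.  The audit (`mesh_quality()`) requires positive orientation and a
  minimum interior angle above 15°; the default meshes achieve ≈32°.
  No triangulation library is used; the ring construction is ~80 lines and
  keeps every node's radius exact, which the azimuthal averaging below
  exploits.
* **Discretization** — P1 (linear) triangles, exact element stiffness and
  mass, edge-lumped Robin mass, and a unit nodal load at the source node
  for the point source.  The sparse symmetric system is solved by direct
  factorization (`Matrix`).  Accuracy statements exclude $r < 3\,h_{near}$
  where the nodal delta dominates.

Verification is threefold.  First, the method of manufactured solutions:
$u^*(x,y) = \cos(kx)\cos(ky)$ defines the interior forcing and
inhomogeneous Robin data analytically, and the observed $L^2$ convergence
order across mesh sizes $h, h/2, h/4$ is ≥ 1.9 (measured 1.92–1.97,
the P1-optimal rate).  Second, the discrete flux balance
$\int \mu_a\Phi\,d\Omega + \oint q\Phi\,d\Gamma = $ source power holds by
construction of the weak form (testing with the constant function) and is
verified to $10^{-9}$ — machine precision in practice.  Third, away from
the source and boundary the field must match the infinite-medium Green's
function $\Phi(r) = P\,K_0(\mu_\mathrm{eff} r)/(2\pi D_\mathrm{d})$ with
$\mu_\mathrm{eff} = \sqrt{3\mu_a(\mu_a+\mu_s')}$; on the annulus
$0.15 \le r \le 0.5$ cm the four 808-nm tissue conditions agree within 5%
(measured ≤ 0.5%; the boundary truncation is negligible because
$\mu_\mathrm{eff}\,R \gg 1$ for all panel entries).  The identity
$\mu_\mathrm{eff} = S_{KM}\,y$, which links the two-flux and diffusion
parametrizations, is asserted to machine precision on a parameter grid.

`field_summary()` reports the base-10 log range of the field (excluding the
singular source node) and an *e-fold radius*: the radius at which the
azimuthally averaged profile (72 angular bins, linear interpolation in
angle along each ring, then in radius) first drops to $1/e$ of its value at
$r = 2h_{near}$.  Because the reference sits close to the source, where
$K_0$ falls much faster than a pure exponential, this radius is well below
$1/\mu_\mathrm{eff}$ (for hydrated skin at 808 nm the $K_0$ oracle gives
0.0578 cm against $1/\mu_\mathrm{eff} = 0.121$ cm); tests therefore
compare the FEM value against the exact $K_0$-based oracle (agreement
≤ 5%, measured ≈ 0.3%) rather than against $1/\mu_\mathrm{eff}$.  Across
the 12-entry phantom panel the e-fold radius decreases strictly with
$\mu_\mathrm{eff}$, reproducing the qualitative contrast between weakly
attenuating (wide, diffusive) and strongly attenuating (tight, collimated)
tissue conditions.

## PLSR of emission spectra

`plsr_fit()` implements single-response SIMPLS: components are extracted
sequentially to maximize covariance with the response under mutual
orthogonality of the scores; predictors and response are centered, never
scaled.  For one response SIMPLS coincides with NIPALS PLS1 — the suite
checks equality of fitted values against `mixOmics::pls` to $10^{-10}$ —
and at full rank the fitted values equal ordinary least squares (asserted
to $10^{-8}$ against `lm()`).  Training $R^2 = 1 - SS_{res}/SS_{tot}$ is
the default report, mirroring actual-vs-predicted fit quality; an optional
k-fold `cv_r_squared()` is provided but not used by default.  The response
variable for tissue spectra is a binary condition code (0 = native or
hydrated, 1 = dried or boiled), an assumption documented here because the
source workflow does not state its response encoding.  The component cap
defaults to 10, further limited by the centered-predictor rank, and a
per-component $R^2$ table is always available.

One regime deserves a caveat: with far more wavelengths than samples
(here 601 grid points against tens of spectra), *training* $R^2$ of even a
one-component fit approaches 1 on pure noise, because
$XX^\top \approx p\sigma^2 I$ makes the first score nearly proportional to
any response.  Monotone degradation of training $R^2$ with noise therefore
only holds while structured signal dominates; the property test runs with
the per-sample amplitude effect disabled so that spectral noise is the
single stochastic term, where the trend is cleanly negative.  This is a
property of high-dimensional regression, not of the implementation, and is
the reason published $R^2$ values from real spectra cannot be reproduced
from synthetic data — they depend on the raw measurements, which were not
deposited.

## The synthetic phantom generator

The generator defines the study conditions; its defaults are fixed and not
tuned per experiment:

* **Optical panel** — 4 tissue conditions (hydrated/dry skin, native/boiled
  adipose) × 3 near-infrared wavelengths (808, 830, 980 nm) with the
  reported central $\mu_a, \mu_s'$ values as ground truth (one published
  uncertainty entry is malformed and only the central value is carried).
* **Slab thicknesses** — Normal, truncated positive: 2 ± 0.5 mm for skin
  and 3 ± 0.4 mm for adipose tissue, the reported sample preparations;
  thickness is recorded with each measurement, so it contributes spread but
  no bias to the inversion.
* **Measurement noise** — additive Gaussian on $R_d$ and $T_d$ (default sd
  0.01, an assumed instrument-level figure since no error model is
  published), with up to 1000 rejections to stay inside the physical region
  $0 < R_d, T_d,\ R_d + T_d < 1$; 5 replicates per entry by default,
  matching the reported repetition count.
* **Spectra** — 300–900 nm at 1 nm: flat baseline (5 counts) + Gaussian
  peak at 700 nm (sd 25 nm, the minimal shape supporting the
  peak-position and amplitude claims; no band substructure), amplitude 100
  × condition multiplier × per-sample random effect (truncated Normal,
  sd 0.1), additive noise (sd 1), clamped at zero, 10 replicate locations
  per sample.  The default condition effect *increases* the dried/boiled
  amplitude by 1.5×, following the results section of the source workflow;
  its conclusions state the opposite direction, so the sign is a config
  knob (`lif_amp_by_condition`).

Everything is seeded: the pipeline derives the spectra stream seed from the
root seed, and a rerun with the same configuration produces a
byte-identical `report.json`.  What passing tests on these phantoms show is
that the *computational* chain — forward model, inversion, PDE solve,
regression — is correct and stable at realistic parameter magnitudes.
What they cannot show is agreement with wet-lab measurements: real spectra
carry instrument response, fluorophore substructure and scattering
distortions that the single-Gaussian generator deliberately omits, and real
$R_d/T_d$ noise is not Gaussian-additive.

## Problem sizes and numerical settings

Default verification sizes, chosen to exercise the asymptotic regime while
keeping a full run in seconds on one core: the KM grid is 12 conditions × 3
thicknesses × 2 dialects; the identity grid 10 × 10; bisection comparison
100 draws; the FEM reference mesh (radius 2 cm, `h_far` 0.1, `h_near`
0.005) has ≈ 6,000 nodes and solves in ≈ 0.2 s, the manufactured-solution
study uses radius 1 with $h \in \{0.2, 0.1, 0.05\}$; the recovery
experiment 100 replicates × 12 entries at 1% noise; PLSR examples use tens
of samples against 601 wavelengths.  Tolerances: machine-precision
identities are asserted at $10^{-12}$–$10^{-13}$ relative (allowing
accumulation), exact round trips at $10^{-8}$, oracle agreements at the
levels quoted above.  Ties in the peak finder go to the longer wavelength;
degenerate inputs (conservative slabs, zero-power sources, flat spectra,
singular pure-Neumann systems) either take documented series branches or
fail with named errors rather than returning garbage.

## Known limitations

Single homogeneous slabs and disks only (no layered media); central source
only; the paper-dialect inversion is inherently set-valued (see above); no
estimation of the anisotropy factor $g$ or refractive index from data; no
time-resolved or frequency-domain diffusion; published $R^2$ and
coefficient tables from the original instrument data are not reproducible
targets, only their structure and qualitative orderings are.
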