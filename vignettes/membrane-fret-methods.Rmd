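---
title: "Methods: membrane-frame FRET rates from ensemble photophysics and snapshot pairing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane-frame FRET rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memfret)
```

## The problem

Two chromophores anchored in opposite leaflets of a lipid bilayer — an
emissive donor such as an alkylated perylene diimide and an absorbing
acceptor such as a ruthenium tris-bipyridine complex — exchange electronic
excitation by Förster resonance energy transfer. The transfer rate depends
on three ingredients that live in different computational worlds: the
transition dipole moments (TDMs) and spectra come from excited-state
electronic-structure calculations, while the geometry — how deep each
chromophore sits and how its TDM tilts against the membrane plane — comes
from classical molecular dynamics. This package implements the bookkeeping
that joins them, in two complementary protocols, and every diagnostic
needed to decide whether the joining is trustworthy.

All electronic-structure and force-field computation is upstream: the
package consumes plain tables (conformer energies, TDM vectors and
strengths, vertical energies, stick spectra, per-frame coordinates or
precomputed pose series) and produces rate breakdowns and diagnostics.

## Model

The screened point-dipole coupling between donor and acceptor TDMs
separated by **r** in a medium of refractive index $\eta$ is

$$ V_{DA} \;=\; \frac{\kappa\,|\mu_D||\mu_A|}{4\pi\varepsilon_0\,\eta^2\,r^3},
\qquad
\kappa = \hat\mu_D\!\cdot\!\hat\mu_A - 3(\hat\mu_D\!\cdot\!\hat r)(\hat\mu_A\!\cdot\!\hat r), $$

with $\kappa^2 \in [0,4]$ and isotropic average $2/3$. The golden-rule
rate uses the spectral overlap $J$ of unit-area donor emission and
acceptor absorption line shapes on the wavenumber axis,

$$ k_\mathrm{FRET} = \frac{2\pi}{\hbar}\,|V_{DA}|^2\,\frac{J}{hc},
\qquad \tau = 1/k_\mathrm{FRET}, $$

where $J$ carries the unit cm and $hc$ (in J·cm) converts it into a
density of final states per energy. The screening enters as $\eta^2$ in
the denominator of $V$ (so $\eta^4$ in $|V|^2$); this convention is fixed
numerically by the published per-state couplings, which are reproduced
within a few percent with $\eta^2$ and are off by roughly $4.8\times$
without it. Rates are additive over acceptor states, and the total
lifetime is the inverse of the summed rate.

Everything internal is SI — energies in J, dipoles in C·m, distances in m
— because the squared couplings are conventionally reported in
kg² m⁴ s⁻⁴ (= J²). Debye, atomic units, eV, cm⁻¹ and Å appear only at the
interfaces. Constants are CODATA 2018 at full precision; nothing is
hand-rounded inside formulas.

One unit subtlety is documented rather than resolved: a Boltzmann-weighted
donor dipole strength of 23.8 au² corresponds to
$\sqrt{23.8}\times 2.5417\ \mathrm{D} = 12.40$ D, while the companion
value in circulation for this system is 12.3 D (plausibly
$\langle|\mu|\rangle$ rather than $\sqrt{\langle\mu^2\rangle}$). The
package converts exactly and leaves the choice of scalar to the caller;
the shipped examples use 12.3 D because the published couplings were
generated from it.

## Two-step protocol

`two_step_rates()` takes one row per acceptor state — dipole strength in
Debye, tilt against the membrane plane in degrees, spectral overlap in cm
— plus the donor strength/tilt, the separation and $\eta$.

The membrane constrains each TDM only through its tilt $\phi$: rotation
about the membrane normal (the z axis; the membrane is assumed to lie in
the xy-plane) is free. Representative dipoles are therefore placed in the
xz-plane, $\mu(\cos\phi\cos\varphi, \cos\phi\sin\varphi, \sin\phi)$, the
donor azimuth is held at $\varphi=0$, and the acceptor azimuth is swept
over a uniform grid (default 1°, configurable; results change by less
than $10^{-6}$ relative for any step below 5°). Averaging only the
acceptor azimuth is equivalent by symmetry to averaging both, since only
the azimuth difference enters $\kappa$. With the separation along z the
grid average has the closed form

$$ \langle\kappa^2\rangle = \tfrac12\cos^2\phi_D\cos^2\phi_A
   + 4\sin^2\phi_D\sin^2\phi_A, $$

which the implementation reproduces to machine precision; the test suite
keeps both routes and compares them, so the grid code and the calculus
check each other.

The separation is the sum of the two mean insertion depths along the
normal, which assumes the chromophores sit directly opposite and ignores
lateral displacement — a deliberate, systematic simplification: the
arithmetic mean distance underestimates the contribution of close
approaches (the rate scales as $r^{-6}$), so the two-step total is best
read as a lower bound.

### Tilt-sign and state-assignment conventions

The tilt is unsigned (angle to a plane whose normal has no preferred
sign); the azimuthal average is invariant under $\phi \to -\phi$, which is
tested. Where two acceptor states are near-degenerate and swap character
across conformers, they are treated as a degenerate group sharing an
averaged strength and overlap but keeping distinct orientations. The
shipped four-state example assigns the two states at tilt 49.6° to the
vector parallel to the complex's C₂ axis and the two at 29.6° to the
perpendicular vector; this assignment is the only one whose closed-form
$\langle\kappa^2\rangle$ ratio (0.297/0.403 = 0.737) matches the ratio of
the corresponding published couplings (7.15/9.76 = 0.733), and that
consistency check is part of the test suite rather than an assumption.

## One-step protocol

`one_step_rates()` takes per-snapshot records: for the donor one emissive
transition per frame (TDM vector in au, vertical energy in eV, insertion
depth in Å), for the acceptor one record per frame and state. For every
pair of one donor and one acceptor snapshot — the full Cartesian product,
not index-matched pairs — the separation is the sum of the two depths,
the acceptor TDMs are rotated about the membrane normal on the azimuth
grid (the QM vectors themselves are rotated; no membrane-frame
representative is substituted), the per-state overlap is the closed-form
overlap of two unit-area Gaussians centered at the two vertical energies
(default fwhm 0.05 eV for the donor emission and 0.2 eV for the acceptor
absorption), and the pair rate is the sum over states. The reported rate
is the arithmetic mean of the per-pair rates; the per-state columns are
means of the per-pair factors and are diagnostics only — recomposing a
rate from averaged factors would discard the correlation between close
approach and coupling strength, and a dedicated test verifies the two
disagree in the presence of such correlation.

The azimuthal mean is evaluated through the trigonometric moments of the
actual grid ($\kappa(\varphi) = X\cos\varphi + Y\sin\varphi + W$, so the
grid mean of $\kappa^2$ is a finite combination of grid moments). This is
algebraically identical to visiting every grid point and lets
100 × 100 × 10 pair-state combinations run vectorized; the equivalence to
the explicit loop is tested.

No spectral shift is applied in one-step mode by default: per-snapshot
vertical energies already carry the environment, and a shift calibrated
against band maxima has no analogue when the band structure is unresolved.

## Spectra and overlaps

`convolve_sticks()` builds line shapes as sums of unit-area Gaussians
(σ = fwhm/(2√(2 ln 2))), with fwhm supplied in eV and converted to cm⁻¹
before evaluation. The default grid is 1 cm⁻¹ steps spanning all sticks
± 5 fwhm; halving the step changes overlaps by under $10^{-4}$ relative,
and a grid that truncates any stick within its ± 5 fwhm support is
rejected naming the stick. Spectral shifts (e.g. the +0.44/+0.42 eV
blue-shifts used to align computed donor bands with experiment) are never
inferred — they are an explicit argument recorded in the result's
attributes, because the shift directly changes the overlap magnitude.

`overlap_numeric()` integrates the product of two normalized spectra by
the trapezoid rule after resampling onto the finer grid; it refuses
unnormalized input rather than silently renormalizing.
`overlap_gaussian_pair()` is the closed form for single-Gaussian pairs.
The two routes agree to $10^{-6}$ relative on shared grids and serve as
mutual oracles; the closed form is the one-step workhorse. Overlaps of
pairs detuned by many combined line widths underflow toward zero in both
routes; they are physically negligible and tested as such rather than to
relative precision.

## Ensemble weighting

`boltzmann_weights()` uses the max-shift evaluation of
$w_i = e^{-E_i/k_BT}/\sum_j e^{-E_j/k_BT}$, so large relative energies
cannot overflow. The weighting temperature is not dictated by the input
data; the default is 298.15 K (room-temperature spectroscopy context) and
is overridable. Weights are computed from the energies as supplied —
whether those are electronic or free energies is the caller's modelling
decision, declared via the conformer table, not second-guessed.

## Trajectory reduction

`pose_series()` reduces per-frame coordinates to the two observables the
two-step protocol consumes: depth (|z-COM difference| between the
chromophore and a membrane-center reference selection, default averaging
all matched atoms because "the terminal tail atom" is ambiguous across
leaflets) and tilt (arcsin(|v_z|/|v|) of an atomic-coordinate reference
vector, folded into [0, 90]°). The membrane is assumed to lie in the
xy-plane; inputs in another frame must be pre-rotated — the package does
not auto-detect the membrane normal. Trajectories in which the
chromophore detaches are screened by `detachment_screen()`: excluded when
the depth exceeds a threshold (default 40 Å, safely above the ~30 Å outer
binding mode) for more than 25% of frames, both parameters configurable
and reported.

Reference vectors are user-configurable linear combinations of atomic
positions (`ref_spec()`); the shipped defaults — the two-nitrogen
difference vector for the donor, and sum/difference combinations of the
six bipyridine nitrogens giving one vector along and one perpendicular to
the C₂ axis — are a reconstruction of the published scheme, whose exact
coefficients are not recoverable from the text, and are flagged as such.
In `alignment_profile()` a conformer is counted for whichever reference
vector has the larger cos²θ; exact ties count toward the parallel vector
(a documented, arbitrary rule — ties have measure zero in real data). The
profile's linearity score is 1 minus the RMS deviation of the sorted
cos²θ curve from the linear ramp, scaled by the worst-case (step-curve)
RMS: aligned ensembles score near 0, a 50/50 mixture scores low with a
sigmoid curve, and isotropic orientations score around 0.4 (their exact
quantile curve is $q^2$, not the ramp itself) — thresholds in the tests
are calibrated to those regimes.

## Synthetic data

`synth_conformer_ensemble()`, `synth_snapshot_set()` and
`synth_pose_trajectory()` generate every input class with mandatory seeds
(R's default Mersenne–Twister, wrapped in `withr::with_seed` so global
state is untouched). They emulate the statistical structure the pipeline
keys on, not the physics:

- conformer energies are cumulative exponential gaps (mean 4 kJ/mol by
  default) so that the three most stable conformers carry ≥95% of the
  room-temperature Boltzmann weight, mirroring the strongly concentrated
  ensembles the two-step protocol assumes;
- TDM orientations are a base direction perturbed by a normal angle about
  a random perpendicular axis (exactly controllable noise), switchable to
  isotropic or two-direction mixtures to exercise the alignment
  diagnostics in both their ordered and disordered regimes;
- donor emission energies are uniform over 2.0–2.4 eV, the window QM/MM
  snapshot emission spreads over; acceptor state energies are normal
  around per-state means spanning 1.9–2.8 eV;
- pose series are AR(1) (discretized Ornstein–Uhlenbeck) around the
  configured means (defaults 13.3 Å / 11.7° for the donor), with an
  optional two-state Markov switch between insertion depths (17 and 30 Å
  in the acceptor-like configuration);
- when a minimum depth is configured it is attained exactly (the smallest
  draw is pinned), so closest-approach contracts can be asserted, e.g. a
  21 Å minimum pair separation.

What passing tests on this scaffolding shows: the estimators recover the
parameters they are pointed at, the diagnostics separate the regimes they
claim to separate, and the rate assembly is exact on composed fixtures.
What it does not show: that real membrane dynamics are AR(1), that real
conformer energies are exponential, or that the point-dipole model is
adequate at 21 Å — those are properties of the inputs, not of this
package.

## Problem sizes and determinism

The default test run uses ensembles of ≤200 conformers, snapshot sets of
≤50 frames, pose series of ≤6000 frames and a Monte-Carlo κ² sample of
10⁶, which keeps the whole suite under half a minute while leaving every
statistical assertion at least three standard errors of headroom. All
stochastic tests fix seeds; reruns are byte-identical (and the driver
writes its resolved configuration next to its outputs for provenance).

## Known limitations

- Point-dipole coupling only: transition densities, higher multipoles and
  charge-transfer corrections are out of scope, and at the closest
  snapshot separations (~21 Å) the point-dipole approximation is near the
  edge of its validity.
- No lateral displacement of the chromophores along the membrane plane in
  the two-step separation model.
- Competing decay channels (fluorescence, Dexter transfer, charge
  transfer) are not modeled; rates here are FRET-only.
- Vibronic line shapes are upstream: the package convolutes and overlaps
  supplied sticks or curves, it does not compute Franck–Condon factors.
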