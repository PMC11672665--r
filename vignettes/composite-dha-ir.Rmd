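---
title: "Composite double-harmonic IR spectra: models, conventions, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite double-harmonic IR spectra: models, conventions, and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhaspec)
```

## The model

Within the double-harmonic approximation (DHA) the potential energy and the
molecular dipole are both Taylor-truncated around a stationary geometry: the
potential after the quadratic term, the dipole after the linear term. The
observables are then fully determined by two objects evaluated at one
geometry:

* the Hessian $H_{ij} = \partial^2 E / \partial x_i \partial x_j$
  (Cartesian, $E_h/a_0^2$), and
* the dipole gradient $D_{i\alpha} = \partial \mu_\alpha / \partial x_i$
  (atomic units), $\alpha \in \{x, y, z\}$.

Mass weighting $F^{(m)} = M^{-1/2} H M^{-1/2}$ (each atomic mass repeated for
its three coordinates) gives the force-constant matrix whose eigenvectors
$Q_p^{(m)}$ are the normal modes and whose eigenvalues $\epsilon_p$ convert
to wavenumbers,

$$\tilde\nu_p = \mathrm{sign}(\epsilon_p)\,\sqrt{|\epsilon_p|}\; C,$$

with $C \approx 5140.5\ \mathrm{cm^{-1}}$ for $\epsilon$ in
$E_h/(a_0^2\,\mathrm{amu})$, derived from CODATA 2018 constants
(`spectroscopy_constants()`). Negative (imaginary) eigenvalues are reported
as negative wavenumbers and trigger a warning: harmonic analysis is only
meaningful at a minimum.

Per-mode intensities are integral absorption coefficients

$$A_p = \frac{N_A}{12\,\varepsilon_0 c^2}
        \left|\frac{\partial\mu}{\partial Q_p}\right|^2 ,$$

where the normal-coordinate dipole derivative is the Cartesian dipole
gradient contracted with the *mass-back-transformed* mode vector,

$$\frac{\partial \mu_\alpha}{\partial Q_p}
  = \sum_i D_{i\alpha}\, Q^{(m)}_{ip}\, m_i^{-1/2}.$$

The $m^{-1/2}$ factor is easy to drop when the contraction is written
loosely; it is load-bearing. Two exact properties certify it in the test
suite: a neutral point-charge dipole has zero derivative along uniform
translations, and the sum of $|\partial\mu/\partial Q_p|^2$ over the full
(unprojected) eigenbasis equals the squared Frobenius norm of
$M^{-1/2}D$ (orthonormal-basis completeness). With $D$ in $e$ and masses in
amu the km/mol conversion constant is
$N_A e^2 / (12 \varepsilon_0 c^2\,\mathrm{amu}) / 1000 \approx
974.9\ \mathrm{km\,mol^{-1}}$; the paper-style prefactor is never printed
numerically anywhere we could compare against, so the constant is certified
by an independent dimensional-analysis oracle in the tests instead.

The point of the *composite* design is that $H$ and $D$ may come from
different providers — a cheap method for one, a better method for the other
— as long as both refer to the same geometry. `run_spectrum_job()` enforces
that with a geometry checksum and refuses mixed-geometry inputs outright.

## Seminumerical derivatives

Both $H$ and $D$ are assembled by two-sided central differences of
analytic first-order quantities (gradients, dipoles), displacing every
Cartesian coordinate by $\pm$`step`:

* cost: exactly $6N$ evaluations each, checked via calculator evaluation
  counters;
* default step $1.0\times10^{-3}\,a_0$, the value used throughout the
  underlying study; overridable per side;
* the Hessian is symmetrized as $(H + H^\top)/2$ before mass weighting —
  finite-difference asymmetry is numerical noise, and downstream code may
  assume exact symmetry.

Truncation error is $O(\mathrm{step}^2)$ with a prefactor set by third
derivatives of the potential. A consequence worth knowing: the displacement
directions are lab-frame axes, so the truncation error is **not**
rotation-covariant. Frequencies and intensities from the seminumerical route
are rotationally invariant only to roughly the truncation level
($\sim 10^{-7}$ relative at the default step for our toys), whereas the
analytic-Hessian route is invariant to machine precision. The test suite
asserts 8+ digit invariance on the exact route and the truncation level on
the seminumerical one.

## Rigid-motion projection

The six (five for linear molecules) translational and rotational directions
are removed *before* diagonalization with an Eckart-style projector
$P = I - BB^\top$, where $B$ is an orthonormal basis of mass-weighted
translation and rotation vectors; rotations about a vanishing principal
axis (linear molecules, detected by a smallest-to-largest
moment-of-inertia ratio below $10^{-8}$) drop out of the basis
automatically. Whether the original analysis code projects or post-filters
near-zero eigenvalues is not documented; projection was chosen because it
cleanly separates rigid from internal modes even when a toy potential
leaves some bends soft. Modes with $|\tilde\nu| < 1\ \mathrm{cm^{-1}}$ after
projection are labelled rigid, recorded in the output metadata, and excluded
from spectra and ZPVE.

## Spectra, broadening, scaling

Stick spectra $(\tilde\nu_p, A_p)$ are broadened with area-normalized
Lorentzians, default fwhm $30\ \mathrm{cm^{-1}}$, on a default grid of
0–4000 cm⁻¹ with 1 cm⁻¹ spacing. The source study states the fwhm but not
its grid; the grid here is a package decision, recorded in every output
file, and all similarity scores refuse to compare spectra on different
grids (resampling must be explicit). Area normalization keeps the
integrated area of each line equal to its stick intensity; with Lorentzian
tails, a grid must extend far beyond the sticks for quantitative area
conservation (the tail fraction beyond $\pm L$ is $\approx 2\gamma/\pi L$,
i.e. about 0.6% at $L = 50\times$fwhm — use wider grids when integrated
areas matter; matchscores are scale-invariant and unaffected).

The zero-point vibrational energy is $\tfrac12\sum_p \tilde\nu_p$ over
internal real modes, converted to kcal/mol. Linear frequency scaling
factors are derived as the set-average of per-molecule ZPVE ratios
reference/method; because ZPVE is linear in frequencies, a method uniformly
stiff by $1/f$ recovers exactly $f$. The synthetic fixture generator
(`make_fixture_set()`) emulates this: `factor` is defined as the scaling
the test method *needs* (reference $= f \times$ test before noise), so the
ZPVE route recovers it; defaults add zero-mean Gaussian frequency noise of
stated width and log-normal intensity perturbations, with a mandatory seed.
A nonlinear (e.g. mass-dependent) per-mode scaling is exposed only as a
hook taking externally supplied factors (`scale_frequencies_per_mode()`);
its parameterization is out of scope here.

## Similarity scores

All metrics operate on two broadened spectra on the identical grid:

* $r_\mathrm{msc} = (\sum_i a_i b_i)^2 / (\sum_i a_i^2 \sum_i b_i^2)$ —
  the Cauchy–Schwarz cosine-squared. This exact algebraic form is adopted
  as this package's definition (the original defining equation lives in
  supplementary material we do not reproduce); it is the unique
  scale-invariant $[0,1]$ form bounded by that inequality, 1 iff the
  spectra are proportional.
* $r_\mathrm{euc} = 1 - \|\hat a - \hat b\|_2/\sqrt2$ on unit-normalized
  spectra — likewise a package definition.
* $r_\mathrm{pcc}$, $r_\mathrm{scc}$: Pearson and Spearman correlations of
  grid intensities; Spearman uses average-rank ties because broadened grids
  contain long near-zero stretches.

Degenerate inputs error rather than return NaN: all-zero spectra
(matchscore, euclidean) and constant spectra (correlations) have no
defined score.

`combination_matrix()` assembles, for every pairing of a frequency source
with a dipole source, the composite spectrum of each molecule at one shared
geometry, and reports the matrix of set-mean matchscores against a
reference, the per-molecule scores, and the arg-max cell.

## Benchmark statistics

The dipole benchmark uses the regularized magnitude error
$\Delta\mu = (\|\mu\| - \|\mu_\mathrm{ref}\|)/\max\{\|\mu_\mathrm{ref}\|,
1\,\mathrm{D}\}$ — *signed*, differencing magnitudes rather than vectors
(a batch mean deviation can legitimately be negative) — and the alignment
cosine of the normalized vectors. Geometry comparisons use Kabsch
superposition RMSD (SVD with improper-rotation correction), assuming input
atom correspondence; hydrogens are included by default with an exclusion
flag, since the original protocol documents neither choice. The statistics
engine reports MD, MAE, RMSE and SD (sample, $n-1$), median and inclusive
threshold fractions; log-normal fits are maximum likelihood (location =
mean of logs, scale = population SD of logs).

## What the toy world does and does not establish

All tests run on analytic toys: a harmonic force field over internal
coordinates (bonds harmonic in $r$; bends harmonic in $\theta$, or
$k(1+\cos\theta)$ for linear equilibria where the plain angle gradient is
singular) plus fixed point charges. These provide exact energies,
gradients, Hessians (via complex-step differentiation of the analytic
gradient, exact to machine precision) and dipole gradients, so every stage
of the pipeline is checked against a closed form. Force constants are
moderate (mid-IR frequencies, truncation error comfortably within the
documented step-accuracy contract of $10^{-7}\,E_h/a_0^2$ at the default
step).

What a green suite establishes: the finite-difference assembly, mass
weighting, projection, diagonalization, intensity projection, unit chains,
broadening, scoring and statistics are each correct against independent
oracles. What it does not establish: behavior on real electronic-structure
output — anharmonic potentials whose gradients carry method noise,
geometry-dependent charge distributions (fixed charges make the dipole
exactly linear in coordinates, so the dipole-gradient step error is zero
here but not in reality), and the accuracy ranking of actual methods,
which requires external engines and reference sets and is out of scope.

## Numerical choices, in one place

| Quantity | Default | Why |
|---|---|---|
| FD displacement | $10^{-3}\,a_0$ | value used in the underlying protocol |
| Hessian symmetrization | $(H+H^\top)/2$ | FD asymmetry is noise |
| Rigid-mode threshold | $|\tilde\nu| < 1\ \mathrm{cm^{-1}}$ | separates projector null space from soft internal modes |
| Linearity test | $I_\mathrm{min}/I_\mathrm{max} < 10^{-8}$ | scale-free, robust for toys and near-linear chains |
| Lorentzian fwhm | 30 cm⁻¹ | protocol default |
| Grid | 0–4000 cm⁻¹, 1 cm⁻¹ | covers the fundamental region; a package decision |
| SD | sample ($n-1$) | benchmark-table convention |
| Log-normal scale | MLE ($n$) | literal maximum likelihood |
| Constants | CODATA 2018 | single recorded source for all factors |

## Worked example

```{r example}
model <- harmonic_ff(bonds = data.frame(i = 1, j = 2, k = 0.3, r0 = 2.4))
mol <- molecule(c("H", "Cl"), c(0, 0, 0, 2.4, 0, 0))
calc <- ff_calculator(model, charges = c(0.2, -0.2))

modes <- vibrational_analysis(mol, calc = calc)
modes$wavenumbers[modes$internal]

D <- seminumerical_dipole_gradient(calc, mol)
spec <- mode_spectrum(modes, D, mol)
spec$sticks

br <- broaden(spec)
matchscore(br, br)
zpve(spec$sticks$wavenumber)
```

## Known limitations

No anharmonicity (VPT2), no Raman/polarizability derivatives, no periodic
systems or curvilinear coordinates, no conformational or thermal averaging,
no peak assignment. RMSD assumes atom correspondence (no permutation or
symmetry correction). The calculator registry ships only analytic toys;
external engines plug in through the calculator contract but are not
bundled.
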