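# dhaspec

Gas-phase infrared spectra in the **double-harmonic approximation (DHA)**,
built for *composite* workflows: the Hessian (hence frequencies) and the
dipole derivatives (hence intensities) can come from two different methods,
as long as both refer to the same stationary geometry. The package targets
people benchmarking low-cost electronic-structure methods — semiempirical
Hamiltonians, force fields, machine-learned potentials, charge models —
against reference spectra, and provides the full measurement chain those
comparisons need.

## What it computes

For a molecule at a stationary geometry with Hessian `H` (Eh/a0², from any
gradient-capable provider by two-sided finite differences, 6N evaluations)
and Cartesian dipole gradient `D` (a.u., 6N dipole evaluations):

- mass-weighted force-constant matrix `F = M^{-1/2} H M^{-1/2}`, Eckart-style
  rigid-motion projection, normal modes `Q_p`, signed wavenumbers
  `nu_p = sign(eps_p) sqrt(|eps_p|) C` (imaginary modes negative);
- DHA intensities `A_p = N_A/(12 eps0 c^2) |dmu/dQ_p|^2` in km/mol, with
  `dmu/dQ_p = sum_i D_i Q_ip m_i^{-1/2}`;
- stick spectra, uniform linear frequency scaling, area-normalized
  Lorentzian broadening (default fwhm 30 cm⁻¹, grid 0–4000 cm⁻¹);
- harmonic ZPVE (`½ Σ nu_p`, kcal/mol) and ZPVE-ratio linear scaling
  factors (`mean(ZPVE_ref/ZPVE_method)`);
- spectral similarity: the Cauchy–Schwarz matchscore
  `r_msc = (Σ a b)² / (Σ a² Σ b²)` plus Euclidean/Pearson/Spearman
  alternatives, and frequency-method × dipole-method combination matrices;
- benchmark statistics: regularized dipole errors
  `Δμ = (|μ|−|μ_ref|)/max(|μ_ref|, 1 D)`, dipole alignment cosines, Kabsch
  RMSD, MD/MAE/RMSE/SD summaries, threshold fractions, log-normal fits.

Analytic toy models (harmonic force field + fixed point charges) ship as
exact oracles, so the whole pipeline is testable without any quantum
chemistry engine. Plain-text I/O covers XYZ geometries, Hessians, dipole
derivatives and two-column spectra with metadata headers.

## Worked example

A toy HCl-like diatomic (bond constant 0.3 Eh/a0², r0 = 2.4 a0, charges
±0.2 e):

```r
library(dhaspec)

model <- harmonic_ff(bonds = data.frame(i = 1, j = 2, k = 0.3, r0 = 2.4))
mol   <- molecule(c("H", "Cl"), c(0, 0, 0, 2.4, 0, 0))
calc  <- ff_calculator(model, charges = c(0.2, -0.2))

modes <- vibrational_analysis(mol, calc = calc)   # seminumerical, step 1e-3 a0
modes$wavenumbers[modes$internal]
#> [1] 2843.956

D    <- seminumerical_dipole_gradient(calc, mol)
spec <- mode_spectrum(modes, D, mol)
spec$sticks
#>   wavenumber intensity     dmudq2
#> 1   2843.956  39.78572 0.04081089

br <- broaden(spec)                    # Lorentzian, fwhm 30, grid 0..4000 by 1
matchscore(br, br)
#> [1] 1
zpve(spec$sticks$wavenumber)
#> [1] 4.06564
```

The single internal mode sits at 2843.956 cm⁻¹ — matching the closed form
`(1/2πc)·sqrt(k/μ_red)` to the printed digits — with an integral absorption
coefficient of 39.8 km/mol; the self-matchscore is exactly 1 (perfect
correlation) and the ZPVE is 4.066 kcal/mol. Both derivative assemblies cost
exactly 6N = 12 evaluations (`eval_counts(calc)`).

## Command line

`inst/cli/dhaspec` wraps `ir_cli()`:

```
dhaspec freq     --xyz mol.xyz --model model.json [--hessian-out h.hess]
dhaspec dipgrad  --xyz mol.xyz --model model.json --out d.dmu
dhaspec spectrum --xyz mol.xyz --hessian h.hess --dipgrad d.dmu \
                 --fwhm 30 --scale 0.9606 --out-prefix out
dhaspec compare  a_broadened.dat b_broadened.dat [--json scores.json]
dhaspec matrix   --manifest manifest.tsv
dhaspec scale    --table zpve.tsv      # columns: ref, method
dhaspec zpve     --spectrum out_sticks.dat
dhaspec rmsd     a.xyz b.xyz [--no-h]
dhaspec dipstats --table dipoles.tsv   # id, tx ty tz, rx ry rz (Debye)
```

Model files are JSON (`bonds`, `angles`, `linear_bends`, `charges`).
Defaults: displacement 1e-3 a0, fwhm 30 cm⁻¹, grid 0–4000 by 1 cm⁻¹. Exit
codes: 0 success, 1 validation error, 2 numerical failure. `spectrum`
refuses Hessian/dipole inputs whose recorded geometry checksum differs from
the given geometry — composite inputs must share one stationary point.

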