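# amideshell

Tools for connecting the **first hydration shell of peptide carbonyl groups
to their vibrational frequency** in the amide I region, from molecular
dynamics trajectories.

When water molecules hydrogen-bond to a peptide C=O group they weaken the
bond and red-shift its stretching frequency (~1580–1610 cm⁻¹ for solvated
peptides). `amideshell` implements the analysis chain that makes this
relation quantitative:

* **Hydrogen-bond statistics** — geometric criterion (H···A distance
  ≤ 2.5 Å, deviation from D–H···A linearity ≤ 45°), per-group hydrogen-bonded
  state time series, combined distance–angle distributions g(r), g(θ) with
  running integration, per-frame water ranking (W1–W4), and breadth-first
  **water-bridge** searches between polar groups (up to order 7).
* **Spectra** — power and IR spectra as the cosine transform of the
  (windowed, zero-padded) autocorrelation of bond-length / velocity / dipole
  series, with the axis in cm⁻¹: resolution `1/(c · pad · depth · dt)`
  (1.63 and 2.04 cm⁻¹ for the two standard operating points), plus
  parabolically refined peak extraction.
* **Wavelet analysis** — Morlet–Gabor continuous wavelet transform
  ψ(t) = π^(−1/4) e^{iω₀t} e^{−t²/2σ²} (ω₀ = 2π, σ = 8), spectrograms,
  per-frame **instantaneous stretching frequencies** from the modulus ridge,
  and filtering of sub-1500 cm⁻¹ ridge artifacts.
* **Interaction energies** — hydrogen-capped CONH fragments, supermolecular
  energies E(frag+water) − E(frag) − E(water) through a pluggable backend
  (built-in: deterministic Coulomb + Lennard-Jones toy model), k-means
  clustering of the energies into **strong / moderate / weak interaction
  zones**, and Pearson correlation of the second-closest water's energy with
  the instantaneous frequency.
* **Conformations** — backbone torsions, free-energy surfaces
  F = −k_B T ln(H/H_max), and α/β/left-handed-helix state assignment.
* **Synthetic data** — deterministic generators (oscillating C=O bond with a
  piecewise-constant frequency schedule, scheduled hydration shells with
  water exchange, zone-labeled interaction records, correlated series,
  metastable torsions) so the entire pipeline is testable with known ground
  truth.

Trajectories are read from multi-frame XYZ (Å, fs, optional orthorhombic
box); topologies and run configurations are JSON.

## Worked example

The default configuration generates a 50 ps synthetic scenario in which the
central carbonyl holds one hydrogen-bonded water up to 16 ps (C=O at
1600 cm⁻¹), a mixed one/two-water state to 36 ps (1594 cm⁻¹), and two waters
afterwards (1584 cm⁻¹):

```r
library(amideshell)
report <- run_pipeline(list(seed = 2148))
report$window_table
#>     window freq_fourier freq_wavelet hbond_mean hbond_sd strong moderate
#> 1  8-16 ps         1600       1598.9        1.0  0.00000    1.0    1.000
#> 2 16-36 ps         1594       1593.6        1.5  0.50001    1.5    0.495
#> 3 40-50 ps         1584       1583.7        2.0  0.00000    2.0    0.000
report$zones
#> <zone_model> k = 3 on energy: strong = -4.19, moderate = -0.28, weak = 0.52
round(report$correlation, 2)
#> [1] 0.7
```

Reading the table: the Fourier peak of each window's bond-length power
spectrum and the mean wavelet instantaneous frequency both recover the
scheduled red-shift as the mean hydrogen-bond count climbs 1.0 → 1.5 → 2.0;
the k-means zones separate hydrogen-bonded waters (strongly negative
energies, toy-model scale) from the moderate/weak shell, and the
second-closest water's interaction energy correlates positively with the
instantaneous frequency (weaker interaction, higher frequency).

Per-rank summaries live in `report$rank_table` — e.g. W1 stays bonded in all
three windows (r ≈ 1.8 Å, θ ≈ 12°, E ≈ −4.2 kcal/mol) while W2 moves from a
parked position (4.2 Å) into the shell as the schedule progresses.

## Command line

Every stage is also a subcommand of the installed launcher
(`inst/cli/amideshell`):

```sh
amideshell synth   --kind scenario --out traj.xyz --seed 2148
amideshell hbond   --xyz traj.xyz --dt 0.5 --group C2=O2 --out counts.tsv
amideshell spectrum --xyz traj.xyz --dt 0.5 --group C2=O2 --depth 4096 --out spec.tsv
amideshell wavelet --xyz traj.xyz --dt 0.5 --group C2=O2 --out instfreq.tsv
amideshell run     --out report/ --seed 2148
```

Exit codes: 0 success, 2 validation error, 1 stage failure.

## Documentation

See the methods vignette (`vignettes/amideshell-methods.Rmd`) for the models
and assumptions, the frequency-convention subtlety of wavelet ridges, the
toy energy backend's scope, and what the synthetic generators do and do not
emulate.
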