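---
title: "Methods: hydration shells and carbonyl frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydration shells and carbonyl frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amideshell)
```

# The scientific problem

The amide I band of a solvated peptide is dominated by C=O stretching, and
each hydrogen bond donated by a water molecule to a carbonyl oxygen weakens
the bond and lowers its frequency by roughly 10–20 cm⁻¹. Because waters
enter and leave the first shell on a picosecond timescale, a carbonyl's
observed frequency is a dynamic average over one-water, two-water and mixed
hydration states. `amideshell` implements the analysis machinery needed to
resolve that average in time: hydrogen-bond statistics, Fourier spectra,
wavelet instantaneous frequencies, fragment interaction energies, and
backbone conformational context — plus synthetic generators that make every
stage testable against known ground truth.

Conventions: coordinates in Å, time in fs, frequencies in cm⁻¹
(`c = 2.99792458e10` cm/s exactly), energies in kcal/mol, 1-based indexing
(the native R convention), orthorhombic boxes only (minimum-image wraps each
component into `[-L/2, L/2)`); deuteration is a mass override so geometric
analyses are unaffected.

# Hydrogen bonds

A water is counted as hydrogen-bonded to an acceptor when the
hydrogen–acceptor distance is at most `r_max = 2.5` Å **and** the deviation
of the donor–hydrogen–acceptor arrangement from linearity is at most
`ang_max = 45°`, both boundaries inclusive. The angle is measured as
*deviation from linearity* (0° = linear), not the 180° D–H···A convention —
a common source of confusion, fixed here once. For a carbonyl acceptor both
water hydrogens are tested; distance–angle histograms use the closest
hydrogen. Histograms default to 0.05 Å × 1° bins, normalized per frame so
the running integral of g(r) counts mean waters within a radius; the
angle-restricted variant integrates only waters passing the angle criterion,
with the integration bound exposed as a parameter (the unrestricted bound is
a user choice, not a guess).

Water bridges between two polar groups are shortest paths in the undirected
hydrogen-bond graph over waters (either water of a pair may donate). Only
minimal-length chains are returned — the *order* of a bridge is its number
of intermediate waters — and chains longer than `max_order = 7` are
discarded. The production search uses igraph's breadth-first machinery; the
test suite checks it exactly against an exhaustive path enumeration on
frames with up to 20 waters.

# Spectra

Power and IR spectra are cosine transforms of the windowed, zero-padded
autocorrelation of a scalar (bond length), vector (velocity, mass-weighted
per group) or dipole-derivative series. Numerical choices worth recording:

* The autocorrelation is the **unbiased** estimator (sum at lag k divided by
  n − k), normalized to 1 at lag 0, so a constant series has a flat ACF.
* The transform uses the **even extension** of the one-sided correlation
  (the ACF is symmetric in the lag), which is real by construction; taking
  the modulus of the one-sided transform instead would bury closely spaced
  components under the slowly decaying imaginary tail. Small negative ripple
  is clipped at zero. Consequence: `pad_factor >= 2`.
* Axis spacing is exactly `1/(c · pad_factor · depth · dt)`; with pad 8 this
  reproduces both standard operating points (dt 2.5 fs / depth 1024 →
  1.63 cm⁻¹; dt 0.5 fs / depth 4096 → 2.04 cm⁻¹). Pad 8 is the unique power
  of two consistent with both printed values and is therefore the default,
  overridable.
* The taper is a Hann half-window over the correlation depth (the upstream
  tooling's window choice is not documented anywhere; Hann suppresses
  sidelobes between carbonyl components ~12–14 cm⁻¹ apart). Under Hann,
  resolving such close components needs about twice the correlation depth
  the raw axis spacing suggests.
* Peak extraction takes the highest intensity in a range and refines it by
  three-point parabolic interpolation, only at a genuine local maximum and
  clamped to half a bin; exact ties return the leftmost maximum with a flag.

# Wavelet instantaneous frequencies

The mother wavelet is Morlet–Gabor,
`psi(t) = pi^(-1/4) exp(i w0 t) exp(-t^2 / (2 sigma^2))` with `w0 = 2*pi`,
`sigma = 8`. The discrete transform
`W(n, s) = s^(-1/2) * sum_n' f(n' dt) psi*((n' - n) dt / s)` is evaluated by
FFT cross-correlation with the kernel truncated at `|t| <= 7 sigma` (envelope
< 3e-11, far below the 1e-8 oracle tolerance); the test suite verifies
agreement with the direct O(n²) sum. The default grid is 512 log-spaced
scales covering 1000–2200 cm⁻¹ (≈0.15% spacing near the amide I band).

**Frequency conventions.** Two scale→frequency maps differ by ~1% at
`w0 = 2*pi` and must not be conflated:

* the *wavelength relation* `lambda = s·4*pi/(w0 + sqrt(2 + w0^2))` gives the
  effective frequency `nu = 1.01/s`;
* the *modulus-ridge condition* — the scale maximizing `|W|²` for a pure
  cosine satisfies `s·omega = w0` up to `O(1/(sigma² w0²))` — gives
  `nu = (w0/2π)/s`, exactly `1/s` at `w0 = 2*pi`.

Instantaneous frequencies are read off modulus ridges, so the package uses
the ridge convention there (this is also what makes wavelet window means
agree with Fourier peaks of the same signal); the wavelength factor remains
available as the quoted effective-frequency constant. Both are exposed via
an explicit `convention` argument.

Ridges are refined parabolically in log-scale space. No padding is applied
at the signal edges; frames within one envelope half-width (`sigma·s/dt`
samples) of either end are inside the cone of influence and flagged
lower-confidence rather than discarded. Ridge artifacts — sudden drops below
1500 cm⁻¹ that accompany water-exchange events — are invalidated, linearly
interpolated over, and smoothed with a 25-frame rolling median (the
smoothing method is a package choice; only the floor is prescribed by the
analysis it reproduces). `wavelet_ridge()` streams over scales in bounded
memory, so 10⁵-frame trajectories need no scale–time grid.

# Fragment interaction energies

The carbonyl's peptide-bond unit is excised as a CONH fragment; the broken
Cα–C and N–Cα bonds are capped by hydrogens along the former bond vectors at
1.09 Å (C–H) and 1.01 Å (N–H) — standard covalent geometry, since only the
capping itself is prescribed. The supermolecular interaction energy of the
fragment with one water is `E(frag+w) − E(frag) − E(w)`, all three terms from
the same backend. The backend contract (`evaluate(geometry)`, deterministic)
admits external quantum-chemistry engines; the built-in default is a frozen
fixed-point-charge Coulomb + Lennard-Jones model (TIP3P-like water; amide
charges rounded from common fixed-charge force fields; caps absorb the
residual so the fragment is neutral). Along the linear hydrogen-bond axis it
has a single minimum of −5.7 kcal/mol at 1.8 Å, a repulsive wall below
~1.45 Å, and ~r⁻³ multipole falloff — the right *trends* (the reference
quantum-chemical energies it stands in for are not reproducible by any
pairwise model, and no claim of magnitude agreement is made). No
counterpoise correction is applied, matching the workflow it emulates.

Records are sampled every 50 fs for the four closest waters (ranked per
frame by oxygen–oxygen distance, ties to the lower index, so a rank label
can change identity over time). k-means clustering of the energies — 1D by
default, because the zone classification is defined by average interaction
energies; joint standardized (E, r, θ) is an option — with 50 restarts under
a fixed seed yields strong/moderate/weak zones (k = 2 gives bonded vs not;
k = 4 splits "strong" into "very strong"/"strong").

# Conformations

Torsions follow the IUPAC sign convention (atan2 form, wrapped to
(−180, 180]). Free-energy surfaces are `F = −kB·T·ln(H/H_max)` on a 72×72
grid (5° bins) at 300 K with `kB = 0.0019872` kcal/(mol·K); empty bins are
reported as NA, not infinities, to keep grids serializable. Backbone states
are rectangular ±30° windows (wrap-aware, a documented choice — the
literature gives centers, not boundaries) around α(−57, −47), β(−130, +140)
and left-handed L(+80, +70); everything else is "other".

# Synthetic generators: the stated world

Every generator is deterministic given (parameters, seed) and attaches its
ground truth to the output. The default three-window scenario is the
package's stated world: 50 ps at dt = 0.5 fs; C=O frequency 1600 cm⁻¹ to
16 ps, 1594 to 36 ps, 1584 to 50 ps (amplitude 0.05 Å, bond noise 0.005 Å,
r0 = 1.23 Å, phase reset at segment boundaries — the wavelet should localize
the switch, continuity is not required); hydration targets 1.0 / 1.5 / 2.0
with a 2.5 ps exchange timescale.

Hydration targets are realized by construction: integer parts are
persistently bonded waters (r = 1.85 ± 0.08 Å, θ = 12 ± 6°, clipped inside
the criteria — the center of the observed first-shell band), fractional
parts by one water duty-cycling between the bonded geometry and a parked
position outside the criteria with cycle length 1/rate, so segment means hit
the target within ~0.05 and water *identities* exchange with background
waters (kept outside 4.5 Å) at the cycle events. The Markov torsion
generator jumps to its stationary distribution with probability 0.1 per
frame (a package choice: it keeps the effective sample size at n = 10⁴ large
enough that ±0.03 weight recovery is a meaningful test).

What the generators do **not** emulate: bulk water structure (no water–water
RDFs), realistic exchange kinetics beyond a single rate, vibrational
anharmonicity, or coupling between the oscillator and the hydration state.
A green end-to-end test therefore establishes that the *analysis chain*
recovers planted window frequencies, hydration means and zone structure —
not that any physical simulation would show them.

# Known limitations

* Only orthorhombic boxes; triclinic cells are rejected.
* The toy backend reproduces sign, distance and angle trends of
  water–carbonyl interactions, not quantum-chemical magnitudes.
* IR spectra require a dipole series as input (e.g. from maximally localized
  Wannier centers); the package does not compute dipoles.
* No synchrosqueezing or multi-ridge wavelet extraction; one ridge per
  signal.
* Whether the reference analysis transformed bond length or bond velocity is
  not documented; bond length is the default observable (it is the quantity
  displayed alongside published instantaneous frequencies), velocity is
  available.
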