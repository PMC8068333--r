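Package: amideshell
Title: Hydration-Shell and Carbonyl Vibrational-Frequency Analysis from Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("amideshell", "developers", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Connects the hydration shell of peptide carbonyl groups to their
    vibrational signature in the amide I region. Reads multi-frame XYZ
    trajectories, detects geometric hydrogen bonds and water bridges, computes
    power and infrared spectra from autocorrelation functions, extracts
    time-resolved instantaneous stretching frequencies with a Morlet-Gabor
    continuous wavelet transform, evaluates supermolecular interaction energies
    of capped peptide fragments with nearby water molecules through a pluggable
    energy backend, clusters those energies into interaction zones, and maps
    backbone torsions onto free-energy surfaces. Ships deterministic synthetic
    trajectory generators with known ground truth so the whole pipeline is
    testable without first-principles simulation data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, igraph, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
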