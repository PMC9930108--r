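Package: boconf
Title: Active-Learning Conformer Search on Gaussian-Process Surrogate Torsional Energy Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conformer search for a flexible molecule attached to a rigid
    environment, driven by Bayesian optimization over dihedral angles. A
    Gaussian-process surrogate of the potential-energy surface (squared
    exponential and standard-periodic kernels) is refined with an exploratory
    lower-confidence-bound acquisition function. Steric clashes between the
    molecule and its environment are handled by three selectable strategies:
    a restricted sampling domain, safe-distance constant-energy substitution,
    and logarithmic energy attenuation with a failure penalty. Includes
    surrogate-minima extraction, backend refinement, duplicate purging, and
    conformer analysis tools (dihedral-cosine similarity index, intramolecular
    hydrogen-bond detection and typing, carboxyl cis/trans classification,
    phase-space clash scans), plus a synthetic periodic multi-well landscape
    generator for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    bio3d,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
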