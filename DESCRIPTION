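Package: zdsum
Title: Zero-Dipole Summation Electrostatics and Cutoff-Method Benchmarking
    for Molecular Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Cutoff-based electrostatic energy and force evaluators for
    particle systems, centred on the zero-dipole summation (ZD) method, in
    which each atom's truncated interaction set is conceptually completed to
    zero net charge and zero net dipole, giving a pairwise kernel whose value
    and derivative vanish at the cutoff.  Includes the zero-charge Wolf and
    shifted-force kernels, a residue-based bare-Coulomb cutoff (RESA), a
    plain Ewald summation reference, energy-deviation decompositions by
    atom, molecule and residue, seeded generators for synthetic charged
    systems (ionic lattices, electrolytes, three-site water lattices, a
    coarse-grained DNA-like duplex with counterions), a minimal
    velocity-Verlet molecular dynamics engine, and trajectory analysis
    (superposition, rmsd, rmsf, dynamic cross-correlation matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
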