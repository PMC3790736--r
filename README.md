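# zdsum — zero-dipole summation electrostatics for molecular simulation

Cutoff truncation of Coulomb interactions is cheap but notoriously
destructive for charged molecular systems: a polyelectrolyte such as
double-stranded DNA, held together by counterion screening of its phosphate
backbone, falls apart within picoseconds of molecular dynamics under a bare
cutoff.  **Zero-dipole summation (ZD)** repairs the truncation without any
reciprocal-space machinery: the interaction set of each atom is conceptually
completed to zero net charge *and* zero net dipole, which converts the sum
into an ordinary pairwise sum with the reconstructed kernel

    u(r) = erfc(a r)/r + A r^2 + B,        u(r_c) = 0,  u'(r_c) = 0,

(damping factor `a >= 0`, cutoff `r_c`), plus a self-energy term
`k_C (B/2 - a/sqrt(pi)) * sum q_i^2`.  At `a = 0` the kernel is
`1/r + r^2/(2 r_c^3) - 3/(2 r_c)`.  The completion coefficients `A`, `B`
follow from smooth truncation; their signature property — implemented and
tested here — is that for any neutral, zero-dipole cluster inside the
cutoff the ZD energy equals the exact Coulomb sum to machine precision,
and for a cluster with dipole `D` it differs by exactly
`-k_C |D|^2 / (2 r_c^3)`.

The package is a desk-scale laboratory for studying this method against its
relatives:

* **evaluators** — ZD, zero-charge Wolf, shifted-force, residue-based bare
  cutoff (RESA), each with analytic forces and per-atom energy
  decompositions; a plain **Ewald** reference (tinfoil boundaries,
  auto-tuned splitting, validated by splitting invariance and the rock-salt
  Madelung constant);
* **deviation analysis** — per-frame relative deviations from Ewald over
  snapshot ensembles, partitioned by molecule/residue/group with exact
  signed bookkeeping;
* **synthetic systems** — seeded generators for rock-salt lattices, random
  electrolytes, three-site water lattices, and a coarse-grained DNA-like
  duplex (two antiparallel strands of -1 beads, B-DNA-like helix, +1
  counterions, optional solvent), plus composition arithmetic for the real
  d(5'-CGCGAATTCGCG-3')₂ box (27,958 atoms with 9,048 waters, 39 Na⁺,
  17 Cl⁻);
* **a toy MD engine** — velocity Verlet, NVE/NVT (Berendsen), enough to
  show that RESA dynamics deform the duplex while ZD dynamics track
  Ewald-force dynamics;
* **trajectory analysis** — Kabsch superposition, rmsd traces, per-group
  rmsf, dynamic cross-correlation matrices, Pearson agreement between
  methods.

See `vignettes/zero-dipole-electrostatics.Rmd` for the models, conventions
and design decisions.

## Worked example

```r
library(zdsum)

## exactness of the undamped ZD kernel on a neutral, zero-dipole cluster
set.seed(7)
pos <- matrix(runif(24, 0, 4), 8, 3)
q   <- rnorm(8); q <- q - mean(q)          # neutral
pos <- rbind(pos, c(1, 1, 1), c(1, 1, 1) + colSums(pos * q))
sys <- make_cluster(c(q, 1, -1), pos)      # appended pair cancels the dipole
zd  <- zd_energy(sys, electro_config("zd", r_c = 30, alpha = 0))
ref <- direct_cluster_energy(sys)
abs(zd$total - ref$total) / abs(ref$total)
#> [1] 1.342597e-16

## the Ewald reference reproduces the rock-salt Madelung constant
rs <- make_rocksalt(2)                     # 64 ions, a = 5.64 A
e  <- ewald_energy(rs, ewald_params(r_real = 5.5, accuracy = 1e-10))
-e$total * (5.64 / 2) / K_COULOMB / 32
#> [1] 1.747565

## composition arithmetic of the explicit-solvent dodecamer box
seqs <- rep("CGCGAATTCGCG", 2)
composition_count(seqs, n_waters = 9048, n_cations = 39, n_anions = 17)
#> [1] 27958
neutralizing_cation_count(dna_formal_charge(seqs), n_anions = 17)
#> [1] 39
```

The first number says the pairwise ZD sum (pair kernel plus self term)
reconstructs the exact Coulomb energy of a charge- and dipole-neutral
cluster to floating-point precision — the operational content of the
zero-dipole completion.  The Madelung constant (1.7475646...) validates
the Ewald oracle against a classical closed-form benchmark, and the
composition arithmetic reproduces the printed atom and ion counts of the
solvated DNA dodecamer system.

A typical accuracy comparison on the equilibrated solvated coarse duplex
(50 snapshots, `r_c` = 12 Å) puts the ZD deviation from Ewald far below
the residue-based bare cutoff; run `scripts/acceptance.R` (below) to
reproduce the exact numbers on your machine.

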