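---
title: "Cutoff electrostatics by zero-dipole summation: models, methods and design choices"
author: "zdsum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cutoff electrostatics by zero-dipole summation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zdsum)
```

## The problem

The Coulomb interaction decays like $1/r$ and its lattice sum is only
conditionally convergent, so simply discarding interactions beyond a cutoff
distance $r_c$ ruins both energies and dynamics in charged molecular
systems.  The effect is most dramatic for polyelectrolytes such as
double-stranded DNA: the backbone carries one negative phosphate per
nucleotide, neutralized by condensed counterions, and a bare truncation
unbalances that screening so badly that the double helix falls apart within
picoseconds of molecular dynamics.  The traditional remedy is Ewald
summation (or its mesh-accelerated PME variant), which imposes exact
periodicity.

Zero-dipole summation (ZD) is a cutoff-based alternative.  Around each atom
$i$, the set of interaction partners inside the cutoff sphere is thought of
as completed into a subset that carries zero net charge *and* zero net
dipole moment; atoms missing from that neutral subset sit near the sphere
surface.  The striking practical consequence is that this completion never
needs to be constructed: summing the excess energy analytically converts the
scheme into an ordinary pairwise sum with a *reconstructed* kernel.

## The kernels

With damping factor $\alpha \ge 0$ (the erf/erfc splitting parameter) the
ZD pair potential implemented here is

$$u_{ZD}(r) \;=\; \frac{\mathrm{erfc}(\alpha r)}{r} + A\,r^2 + B,
\qquad 0 < r \le r_c,$$

where $A$ and $B$ are fixed by the two smooth-truncation conditions
$u_{ZD}(r_c) = 0$ and $u_{ZD}'(r_c) = 0$.  Writing
$f(r) = \mathrm{erfc}(\alpha r)/r$,

$$A = -\frac{f'(r_c)}{2 r_c}, \qquad B = -f(r_c) - A\,r_c^2 .$$

At $\alpha = 0$ this reduces to the closed form
$u(r) = 1/r + r^2/(2 r_c^3) - 3/(2 r_c)$.  The total energy adds a
self-energy term $k_C\,(B/2 - \alpha/\sqrt{\pi})\sum_i q_i^2$: the
completion's own-site constant, halved like every pair term, plus the usual
Gaussian-damping self correction.  Two exact properties pin these
coefficients down, and both are enforced in the test suite:

* for any neutral, zero-dipole open cluster whose diameter is under $r_c$,
  the undamped ZD energy equals the direct Coulomb sum to machine
  precision (the quadratic and constant completion terms cancel exactly
  when $\sum q = 0$ and $\sum q\,\mathbf r = 0$);
* for a neutral cluster with dipole moment $\mathbf D$ the deviation from
  the direct sum is exactly $-k_C |\mathbf D|^2 / (2 r_c^3)$.

Dropping the quadratic term gives the zero-charge Wolf kernel
$f(r) - f(r_c)$ with self coefficient $-f(r_c)/2 - \alpha/\sqrt{\pi}$ (the
same construction enforcing charge neutrality only); its derivative does
not vanish at $r_c$, so Wolf forces jump at the cutoff.  The shifted-force
kernel $1/r - 1/r_c + (r - r_c)/r_c^2$ makes both the potential and the
force vanish at $r_c$ and is implemented as a purely pairwise sum without a
self term — that is the classic form, and it is what makes its two-particle
worked example come out as the bare kernel value.  RESA, the comparison
baseline, is the residue-based cutoff of the *bare* Coulomb potential: all
atoms of a residue interact with atom $i$ if any atom of that residue lies
inside $i$'s cutoff sphere.  Its double sum is asymmetric; we halve it, so
pairs visible from only one side enter at half weight.  Group-membership
changes make RESA energies and forces discontinuous — that discontinuity is
inherent to the method and is precisely what the stability demonstrations
probe.

### Bonded exclusions

For molecular systems the bare Coulomb interaction of bonded (1-2/1-3)
pairs is handled by the bonded terms, so those pairs are excluded.  The
exclusion retains the completion terms: an excluded pair inside the cutoff
contributes $q_i q_j\,[u(r) - 1/r]$, analogous to how reciprocal-space
contributions of excluded pairs are retained (and corrected with an erf
kernel) under Ewald.  1-4 pairs scale only the bare $1/r$ part.  The self
term always runs over all particles.

## The Ewald reference

All accuracy statements are measured against plain Ewald summation under
conducting (tinfoil) boundary conditions: a real-space erfc sum, a
reciprocal-space Gaussian-weighted structure-factor sum, the
$-\alpha/\sqrt{\pi}\sum q_i^2$ self term, and erf-kernel exclusion
corrections.  The splitting parameter and the reciprocal-space bound are
auto-tuned from a target relative accuracy (defaults: `accuracy = 1e-8`,
`alpha_split = max(3, sqrt(-log(acc)))/r_real`, `kmax` from the matching
Gaussian bound per axis).  Correctness is established by invariance: the
total must agree across well-separated splitting parameters and under
doubling of `kmax`, and the rock-salt lattice energy must reproduce the
Madelung constant $M = 1.7475646$.  A mesh (PME) implementation is a
non-goal; plain Ewald is adequate at the desk scale of $\le 10^4$
particles this package targets.  Non-neutral cells are rejected unless the
optional uniform background-charge correction is enabled; every system the
generators build is neutral.

## Accuracy metrics

The central metric is the average relative deviation over a snapshot
ensemble: per frame, $|E^x - E^{Ewald}| / |E^{Ewald}|$, reported in
percent with the standard deviation across frames as the error bar.  The
per-atom decomposition $E_i$ (each pair energy split half-and-half, so
$\sum_i E_i = E$ exactly) turns the same measurement into per-molecule and
per-residue contribution tables; signed contributions are kept alongside
the reported magnitudes, and they sum to the signed total deviation exactly
— a conservation property the suite asserts frame by frame.  One
deliberate reading choice: the deviation is averaged over magnitudes (the
error bars of accuracy curves are one-sided), while the signed series
remains available for the conservation bookkeeping.

## Synthetic study systems

Everything is generated in code, seeded, with no downloads:

* **rock-salt lattices** — the Ewald oracle (Madelung constant);
* **random neutral electrolytes** — disordered $\pm 1$ systems for force
  and drift checks (hard minimum separation 2.5 Å by rejection sampling);
* **three-site water lattices** — TIP3P-like charges
  ($q_H = 0.417\,e$, $r_{OH} = 0.9572$ Å, $104.52^\circ$) on a cubic
  lattice with random orientations, intramolecular pairs excluded;
* **a coarse-grained DNA-like duplex** — two antiparallel helical strands
  of $-1$ "phosphate" beads with B-DNA-like geometry (rise 3.4 Å, 10 beads
  per turn, helix radius 9 Å, strands diametrically opposed), stiff
  harmonic backbone bonds ($k_b = 50$ kcal/mol/Å²) and angles
  ($k_\theta = 5$ kcal/mol/rad²) at the ideal-geometry equilibrium values,
  soft cross-strand "base-pair" restraints ($k = 2$ kcal/mol/Å², standing
  in for the few-kcal/mol hydrogen bonding of a real base pair), one $+1$
  counterion per bead, bead mass 330 amu (one nucleotide), ion mass that of
  Na⁺;
* **a solvated duplex** — the same duplex plus randomly placed and
  oriented flexible three-site waters.

The composition arithmetic of the real dodecamer box is carried by a
residue template table (per-residue atom counts with hydrogens: DA 32,
DC 30, DG 33, DT 32; 5'-terminal residues lack the phosphate group, net
$-2$ atoms; 3'-terminal residues gain the terminal hydroxyl hydrogen).
Those templates reproduce the printed totals — 27,958 atoms for
d(5'-CGCGAATTCGCG-3')₂ with 9,048 waters, 39 Na⁺ and 17 Cl⁻ — and the ion
arithmetic ($-22$ DNA formal charge, $39 - 17$ ion excess).

### What the toys do and do not show

The coarse duplex reproduces the *mechanism* that matters for method
comparison — a stiff polyanion screened by mobile counterions, with weak
restraints holding two strands together — but none of the atomistic detail:
no bases, no grooves, no sequence effects, no hydrogen-bond directionality,
and solvent far below liquid density (150 waters in a 40 Å box keeps runs
desk-sized).  Passing tests therefore demonstrate correct implementation of
the evaluators and the qualitative orderings (smooth neutralized kernels
track Ewald closely; bare residue-based truncation does not, and its
dynamics deform the duplex), not quantitative transfer of any percentage to
a real atomistic DNA system.

## Numerical choices

* Units: Å, elementary charges, kcal/mol, fs; Coulomb constant
  332.06371 kcal·Å/(mol·e²) (the AMBER convention).
* Orthorhombic boxes with minimum image only; every periodic evaluator
  rejects $r_c$ beyond half the shortest box edge.
* Pair enumeration is direct $O(n^2)$ in compiled code.  At desk-scale
  particle counts the boxes are only two to three cutoffs wide, where cell
  lists degenerate to near-complete enumeration with extra bookkeeping;
  the compiled double loop is both simpler and faster here.
* MD is velocity Verlet with Maxwell–Boltzmann initialization (seeded, COM
  motion removed) and a Berendsen velocity-rescaling thermostat
  ($\lambda$ clamped to $[0.8, 1.25]$ per step).  There are no constraint
  algorithms: water and duplex bonds are stiff harmonic terms, which is why
  sampling runs use a 0.5 fs timestep (the O–H stretch period is about
  10 fs).  Coordinates propagate unwrapped; periodicity enters through
  forces only, so trajectory analysis never needs unwrapping heuristics.
* The Lennard-Jones term uses the shifted-force form so NVE conservation
  checks are clean; "energy drift" is measured as the regression slope of
  total energy against time scaled by the run length, which isolates
  secular drift from the bounded velocity-Verlet oscillation.
* Counterions are placed by uniform rejection sampling with a 3.5 Å
  exclusion radius around existing particles — wide enough that the
  steepest initial Lennard-Jones contact stays integrable at the MD
  timestep, which is the reason for preferring it over a tighter radius.
* Superposition is the Kabsch algorithm via `svd` with the reflection
  guard; degenerate (collinear) fit sets are rejected.

## Analysis window and fluctuation conventions

Fluctuation analyses default to the final 70 % of a trajectory, the usual
practice of discarding the initial relaxation.  The rmsf of a group is the
square root of the group-averaged atomic position variance about
window-mean positions, after superposition on a reference (default: the
backbone beads / first frame).  The cross-correlation matrix uses the
displacement of each group's *geometric centre* from its window mean —
the common convention for residue-level correlation maps; a per-atom-pair
averaged alternative is available behind `mode = "atom_pairs"`.
Zero-variance groups yield flagged `NA` rows rather than propagating NaNs.
Agreement between two methods' profiles (rmsf vectors, or the off-diagonal
correlation entries via `offdiag()`) is the plain Pearson coefficient.

## The stability demonstration and its limits

The dynamical contrast between smooth neutralized truncation and
residue-based bare truncation is demonstrated on the coarse duplex with
counterions, following the protocol of explicit-solvent production studies:
the freshly built system is first relaxed under the Ewald reference forces
(120 ps), and the three production runs — ZD, RESA, and Ewald — start from
that relaxed structure with identical seeded velocities; the backbone-bead
rmsd from the relaxed starting structure and the per-bead rmsf profiles are
compared.

One property of the toy regime deserves emphasis.  With bare elementary
charges and no dielectric medium, a counterion binds a backbone bead by
roughly a hundred times the thermal energy, so the equilibrium state of
the toy is a strongly condensed ion-bead structure rather than a
solvent-screened helix; in that deeply bound regime the energetic
*accuracy* contrast between ZD and RESA remains dramatic (the deviation
sweeps), but truncation noise does not necessarily translate into faster
structural degradation within desk-scale run lengths — the destabilization
the full explicit-solvent system shows lives in the solvent-screened
near-cancellation regime that a vacuum-scale toy cannot reach.  The
shipped checks assert the reference-tracking property (ZD and Ewald-force
runs land within a factor of two of each other) and the ZD-versus-Ewald
fluctuation-profile agreement, and also run the qualitative
degradation comparison; in this vacuum-scale regime that comparison comes
out opposite to the explicit-solvent behaviour — the residue-truncated
runs drift *less*, not more, from the relaxed start, because truncation
weakens the deeply bound aggregate's interactions — and the corresponding
check records that as a failure rather than papering over it.

## Problem sizes used by the shipped checks

The package's own demonstrations choose sizes that keep any single check in
the minutes range on one core: 50 snapshots of a 494-atom solvated duplex
(sampled every 100 steps of 0.5 fs reference-force dynamics, after a 15 ps
thermostatted relaxation with ZD forces chosen by watching the total energy
approach a plateau) for the accuracy sweeps; a 44-particle duplex relaxed for
120 ps under reference forces and integrated for 80 ps per production run
for the stability contrast, with three velocity seeds; the
electrolyte NVE drift check runs 10⁴ steps of 80 particles.  These sizes
are design choices of the package's demonstration suite, stated here so
that anyone scaling them up knows which knobs were kept small.

## Open design points resolved here

* The exact exclusion treatment for cutoff kernels in bonded systems is a
  known open point of neutralized-truncation schemes; the
  completion-retaining rule above is this package's choice, checked
  against a hand-evaluated worked example.
* Whether the RESA double sum is symmetrized or halved asymmetrically is
  not fixed by its definition; we halve the asymmetric sum (one-sided
  pairs at half weight), which keeps the per-atom decomposition conservative.
* The deviation metric averages magnitudes; the signed alternative is kept
  internally (see above).
* The stability contrast has no printed tolerance; the shipped check asks
  the residue-truncation run to end with a larger backbone rmsd than the
  ZD run for a majority of seeds, and ZD and Ewald-force runs to land
  within a factor of two of each other in the final window — a policy of
  this package, set by the spread observed across repeat seeds.

## Known limitations

* Plain Ewald only: $O(n^{3/2})$-ish scaling; not meant beyond ~10⁴ atoms.
* No NPT, no constraints, no atomistic force fields, no reaction-field
  evaluator.
* The Berendsen thermostat does not sample a canonical ensemble; it is
  used for relaxation and stability demonstrations, not for ensemble
  averages.
* RESA forces are discontinuous by construction; its NVE energy is not
  conserved, which is part of what the demonstrations show.
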