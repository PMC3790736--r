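# Seeded generators for every synthetic test-system class.  All randomness
# goes through a locally scoped RNG (the caller's .Random.seed is left
# untouched), so identical spec + seed gives a bit-identical system.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                      .GlobalEnv) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
      else assign(".Random.seed", old, .GlobalEnv)
    })
    set.seed(seed)
  }
  expr
}

#' Rock-salt ionic lattice
#'
#' Alternating +1/-1 charges on a simple cubic lattice (the rock-salt
#' arrangement), periodic and exactly neutral.  Primarily an oracle system:
#' its Ewald lattice energy per ion pair is `-M q^2 kC / r_nn` with the
#' rock-salt Madelung constant M = 1.74756...
#'
#' @param cells_per_edge number of conventional (8-ion) cells per box edge.
#' @param lattice_constant conventional cell edge, Angstrom (default: NaCl).
#' @return A neutral periodic [particle_system] with `8 * cells_per_edge^3`
#'   ions, groups `"Na+"` and `"Cl-"`.
#' @export
make_rocksalt <- function(cells_per_edge = 1, lattice_constant = 5.64) {
  stopifnot(cells_per_edge >= 1)
  m <- 2L * as.integer(cells_per_edge)       # ion sites per edge
  a2 <- lattice_constant / 2
  g <- expand.grid(i = 0:(m - 1), j = 0:(m - 1), k = 0:(m - 1))
  pos <- cbind(g$i, g$j, g$k) * a2
  q <- ifelse((g$i + g$j + g$k) %% 2 == 0, 1, -1)
  particle_system(pos, q, box = rep(cells_per_edge * lattice_constant, 3),
                  group_labels = list(`Na+` = which(q > 0),
                                      `Cl-` = which(q < 0)),
                  masses = ifelse(q > 0, 22.99, 35.45))
}

#' Random neutral electrolyte
#'
#' `n_pairs` +1 ions and `n_pairs` -1 ions placed uniformly in a periodic
#' box by rejection sampling with a hard minimum separation.
#'
#' @param n_pairs number of +/- ion pairs.
#' @param box length-3 edge lengths or a scalar cube edge, Angstrom.
#' @param min_separation hard lower bound on any min-image pair distance.
#' @param rng_seed integer seed.
#' @param max_attempts rejection-sampling bound per particle.
#' @return A neutral periodic [particle_system]; groups `"Na+"`, `"Cl-"`.
#' @export
make_electrolyte <- function(n_pairs, box, min_separation = 2.5,
                             rng_seed = 1, max_attempts = 2000) {
  if (length(box) == 1) box <- rep(box, 3)
  n <- 2L * as.integer(n_pairs)
  q <- rep(c(1, -1), length.out = n)
  if (n == 0)
    return(particle_system(matrix(numeric(0), 0, 3), numeric(0), box = box))
  pos <- with_seed(rng_seed,
                   place_random(n, box, min_separation, max_attempts))
  particle_system(pos, q, box = box,
                  group_labels = list(`Na+` = which(q > 0),
                                      `Cl-` = which(q < 0)),
                  masses = ifelse(q > 0, 22.99, 35.45))
}

# uniform placement with a hard min-image separation (rejection sampling)
place_random <- function(n, box, min_sep, max_attempts,
                         existing = matrix(numeric(0), 0, 3)) {
  pos <- matrix(NA_real_, n, 3)
  fixed <- existing
  for (i in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      p <- runif(3) * box
      others <- rbind(fixed, pos[seq_len(i - 1), , drop = FALSE])
      if (nrow(others)) {
        d <- sweep(others, 2, p)
        d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
        if (min(rowSums(d^2)) < min_sep^2) next
      }
      pos[i, ] <- p
      ok <- TRUE
      break
    }
    if (!ok) stop("placement failed after ", max_attempts,
                  " attempts (particle ", i, "): box too crowded")
  }
  pos
}

# one uniformly distributed 3x3 rotation matrix (from a random quaternion)
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# site coordinates of one water-like molecule at the origin (O, H, H)
water_sites <- function(geometry) {
  th <- geometry$angle * pi / 180
  r <- geometry$r_oh
  rbind(c(0, 0, 0),
        c(r * sin(th / 2), 0, r * cos(th / 2)),
        c(-r * sin(th / 2), 0, r * cos(th / 2)))
}

#' Lattice of three-site water-like molecules
#'
#' Rigid-geometry 3-site molecules (O charge `-2 q_h`, two H at `+q_h`,
#' TIP3P-style by default) on a cubic lattice with seeded random
#' orientations.  Each molecule is one residue and one molecule; the three
#' intramolecular pairs are excluded.
#'
#' @param n_per_edge molecules per box edge.
#' @param spacing lattice spacing, Angstrom.
#' @param geometry list with `r_oh` (Angstrom), `angle` (degrees), `q_h` (e).
#' @param rng_seed integer seed for orientations.
#' @return A neutral periodic [particle_system] with group `"water"`.
#' @export
make_water_lattice <- function(n_per_edge, spacing = 3.106,
                               geometry = list(r_oh = 0.9572, angle = 104.52,
                                               q_h = 0.417),
                               rng_seed = 1) {
  stopifnot(n_per_edge >= 1)
  nm <- as.integer(n_per_edge)^3
  sites <- water_sites(geometry)
  g <- expand.grid(i = 0:(n_per_edge - 1), j = 0:(n_per_edge - 1),
                   k = 0:(n_per_edge - 1))
  centers <- (cbind(g$i, g$j, g$k) + 0.5) * spacing
  pos <- with_seed(rng_seed, {
    do.call(rbind, lapply(seq_len(nm), function(m) {
      sweep(sites %*% t(random_rotation()), 2, centers[m, ], "+")
    }))
  })
  q <- rep(c(-2 * geometry$q_h, geometry$q_h, geometry$q_h), nm)
  mol <- rep(seq_len(nm), each = 3)
  base <- (seq_len(nm) - 1) * 3
  excl <- rbind(cbind(base + 1, base + 2), cbind(base + 1, base + 3),
                cbind(base + 2, base + 3))
  particle_system(pos, q, box = rep(n_per_edge * spacing, 3),
                  molecule_id = mol, residue_id = mol,
                  group_labels = list(water = seq_len(3 * nm)),
                  exclusions = excl,
                  masses = rep(c(15.999, 1.008, 1.008), nm))
}

#' Coarse-grained DNA-like duplex with counterions
#'
#' Two antiparallel helical strands of -1 "phosphate" beads (B-DNA-like rise
#' and ~10 beads per turn, diametrically opposed strands), harmonic backbone
#' bonds and angles along each strand, soft cross-strand "base-pair"
#' restraints between opposed beads, and optional +1 counterions placed by
#' rejection sampling.  Consecutive strand beads are 1-2 excluded.  The
#' bonded terms and per-particle LJ parameters are attached as attributes
#' `"bonds"`, `"angles"` and `"lj"` for [force_field()] to pick up.
#'
#' @param n_per_strand beads per strand (>= 2).
#' @param rise axial rise per bead, Angstrom.
#' @param radius helix radius, Angstrom.
#' @param twist helical twist per bead, degrees.
#' @param counterions add one +1 ion per bead (making the system neutral)?
#' @param box length-3 or scalar box edges, Angstrom.
#' @param rng_seed integer seed for counterion placement.
#' @param min_ion_distance rejection radius around existing particles for
#'   counterion placement, Angstrom.
#' @param k_bond,k_angle,k_pair harmonic force constants (kcal/mol/A^2 for
#'   bonds and pair restraints, kcal/mol/rad^2 for angles).  The angle
#'   stiffness default reproduces the ~500 Angstrom persistence length of
#'   B-DNA at the bead spacing used; the pair restraint is on the scale of
#'   the hydrogen bonding of one base pair.
#' @return A periodic [particle_system] with groups `"strand_A"`,
#'   `"strand_B"`, `"beads"` and (if present) `"counterions"`.
#' @export
make_coarse_duplex <- function(n_per_strand = 11, rise = 3.4, radius = 9,
                               twist = 36, counterions = TRUE, box = 40,
                               rng_seed = 1, min_ion_distance = 3.5,
                               k_bond = 50, k_angle = 23, k_pair = 5) {
  stopifnot(n_per_strand >= 2)
  if (length(box) == 1) box <- rep(box, 3)
  n <- as.integer(n_per_strand)
  m <- seq_len(n) - 1
  phi <- m * twist * pi / 180
  z <- m * rise - (n - 1) * rise / 2 + box[3] / 2
  cx <- box[1] / 2
  cy <- box[2] / 2
  strandA <- cbind(cx + radius * cos(phi), cy + radius * sin(phi), z)
  # antiparallel partner: same levels, diametrically opposite, reversed order
  strandB <- cbind(cx + radius * cos(phi + pi), cy + radius * sin(phi + pi),
                   z)[n:1, , drop = FALSE]
  beads <- rbind(strandA, strandB)
  nb <- 2L * n

  ionpos <- NULL
  if (counterions)
    ionpos <- with_seed(rng_seed,
                        place_random(nb, box, min_ion_distance, 2000,
                                     existing = beads))
  pos <- rbind(beads, ionpos)
  nion <- if (counterions) nb else 0L
  q <- c(rep(-1, nb), rep(1, nion))
  mol <- c(rep(1L, n), rep(2L, n), if (nion) 2L + seq_len(nion))
  res <- seq_len(nb + nion)

  # bonded topology on ideal geometry: r0/theta0 measured from the build
  bidx <- rbind(cbind(1:(n - 1), 2:n), nb / 2 + cbind(1:(n - 1), 2:n))
  r0 <- sqrt(rowSums((pos[bidx[, 1], ] - pos[bidx[, 2], ])^2))
  # base-pair restraints: bead m of A with its level partner on B
  pair_idx <- cbind(seq_len(n), nb + 1 - seq_len(n))
  rp <- sqrt(rowSums((pos[pair_idx[, 1], ] - pos[pair_idx[, 2], ])^2))
  bonds <- data.frame(i = c(bidx[, 1], pair_idx[, 1]),
                      j = c(bidx[, 2], pair_idx[, 2]),
                      k = c(rep(k_bond, nrow(bidx)), rep(k_pair, n)),
                      r0 = c(r0, rp))
  angles <- NULL
  if (n >= 3) {
    aidx <- rbind(cbind(1:(n - 2), 2:(n - 1), 3:n),
                  n + cbind(1:(n - 2), 2:(n - 1), 3:n))
    v1 <- pos[aidx[, 1], , drop = FALSE] - pos[aidx[, 2], , drop = FALSE]
    v2 <- pos[aidx[, 3], , drop = FALSE] - pos[aidx[, 2], , drop = FALSE]
    th0 <- acos(pmin(1, pmax(-1, rowSums(v1 * v2) /
                               sqrt(rowSums(v1^2) * rowSums(v2^2)))))
    angles <- data.frame(i = aidx[, 1], j = aidx[, 2], k_atom = aidx[, 3],
                         k = k_angle, theta0 = th0)
  }
  excl <- bidx                               # 1-2 along strands only

  groups <- list(strand_A = 1:n, strand_B = (n + 1):nb, beads = 1:nb)
  if (nion) groups$counterions <- nb + seq_len(nion)
  sys <- particle_system(pos, q, box = box, molecule_id = mol,
                         residue_id = res, group_labels = groups,
                         exclusions = excl,
                         masses = c(rep(330, nb), rep(22.99, nion)))
  attr(sys, "bonds") <- bonds
  attr(sys, "angles") <- angles
  attr(sys, "lj") <- data.frame(eps = c(rep(0.3, nb), rep(0.1, nion)),
                                sigma = c(rep(4.0, nb), rep(2.5, nion)))
  sys
}

#' Solvated coarse duplex
#'
#' A [make_coarse_duplex()] system plus `n_waters` randomly placed and
#' oriented three-site water-like molecules, emulating (at deliberately low,
#' desk-scale solvent density) the explicit-solvent DNA box.  Water O-H
#' bonds and the H-O-H angle are flexible harmonic terms.
#'
#' @inheritParams make_coarse_duplex
#' @param n_waters number of water-like molecules.
#' @param geometry water geometry, as in [make_water_lattice()].
#' @param h_mass hydrogen mass, amu.  The default is physical; setting it
#'   to 2-3 amu (hydrogen-mass repartitioning, with the oxygen mass reduced
#'   to keep the molecule at 18 amu) slows the O-H stretch and permits a
#'   longer MD timestep.
#' @return A neutral periodic [particle_system] with force-field attributes.
#' @export
make_solvated_duplex <- function(n_per_strand = 11, box = 40, n_waters = 150,
                                 rng_seed = 1,
                                 geometry = list(r_oh = 0.9572,
                                                 angle = 104.52,
                                                 q_h = 0.417),
                                 h_mass = 1.008, ...) {
  if (length(box) == 1) box <- rep(box, 3)
  duplex <- make_coarse_duplex(n_per_strand = n_per_strand, box = box,
                               rng_seed = rng_seed, ...)
  if (n_waters == 0) return(duplex)
  nd <- duplex$n_particles
  sites <- water_sites(geometry)
  wat <- with_seed(rng_seed + 1L, {
    centers <- place_random(n_waters, box, 3.0, 2000,
                            existing = duplex$positions)
    do.call(rbind, lapply(seq_len(n_waters), function(m) {
      sweep(sites %*% t(random_rotation()), 2, centers[m, ], "+")
    }))
  })
  pos <- rbind(duplex$positions, wat)
  q <- c(duplex$charges, rep(c(-2 * geometry$q_h, geometry$q_h,
                               geometry$q_h), n_waters))
  mol <- c(duplex$molecule_id,
           max(duplex$molecule_id) + rep(seq_len(n_waters), each = 3))
  res <- c(duplex$residue_id,
           max(duplex$residue_id) + rep(seq_len(n_waters), each = 3))
  base <- nd + (seq_len(n_waters) - 1) * 3
  wexcl <- rbind(cbind(base + 1, base + 2), cbind(base + 1, base + 3),
                 cbind(base + 2, base + 3))
  groups <- duplex$group_labels
  groups$water <- nd + seq_len(3 * n_waters)
  sys <- particle_system(pos, q, box = box, molecule_id = mol,
                         residue_id = res, group_labels = groups,
                         exclusions = rbind(duplex$exclusions, wexcl),
                         masses = c(duplex$masses,
                                    rep(c(18.015 - 2 * h_mass, h_mass,
                                          h_mass), n_waters)))
  owat <- nd + 3 * (seq_len(n_waters) - 1)
  attr(sys, "bonds") <- rbind(
    attr(duplex, "bonds"),
    data.frame(i = c(owat + 1, owat + 1), j = c(owat + 2, owat + 3),
               k = 450, r0 = geometry$r_oh))
  attr(sys, "angles") <- rbind(
    attr(duplex, "angles"),
    data.frame(i = owat + 2, j = owat + 1, k_atom = owat + 3,
               k = 55, theta0 = geometry$angle * pi / 180))
  attr(sys, "lj") <- rbind(
    attr(duplex, "lj"),
    data.frame(eps = rep(c(0.152, 0, 0), n_waters),
               sigma = rep(c(3.15, 1, 1), n_waters)))
  sys
}

#' Open cluster from an explicit charge/position list
#'
#' @param charges numeric charges (e).
#' @param positions n x 3 positions (Angstrom).
#' @return An open-boundary [particle_system].
#' @export
make_cluster <- function(charges, positions) {
  particle_system(positions, charges, box = NULL)
}
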