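# Shared fixture builders.  Everything is generated in code, seeded.

# Neutral cluster with exactly zero total charge and zero dipole moment,
# confined to a ball of the given radius: random neutral charges, then one
# +1/-1 pair appended whose separation cancels the accumulated dipole.
neutral_zero_dipole_cluster <- function(n = 8, radius = 3, seed = 1) {
  set.seed(seed)
  pos <- matrix(runif(n * 3, -radius / 2, radius / 2), n, 3)
  q <- rnorm(n)
  q <- q - mean(q)
  D <- colSums(pos * q)
  pos <- rbind(pos, c(0, 0, 0), D)   # pair dipole = +1*0 - 1*D = -D
  make_cluster(c(q, 1, -1), pos)
}

# Neutral cluster with a known nonzero dipole
neutral_dipole_cluster <- function(seed = 2, n = 6, radius = 3) {
  set.seed(seed)
  pos <- matrix(runif(n * 3, -radius / 2, radius / 2), n, 3)
  q <- rnorm(n)
  q <- q - mean(q)
  make_cluster(q, pos)
}

# maximum relative disagreement between analytic forces and central
# finite differences of the energy, over a few particles
fd_force_error <- function(system, energy_fn, forces, h = 1e-5,
                           particles = NULL) {
  if (is.null(particles))
    particles <- unique(round(seq(1, system$n_particles, length.out = 3)))
  err <- 0
  for (i in particles) for (d in 1:3) {
    p1 <- system$positions; p1[i, d] <- p1[i, d] + h
    p2 <- system$positions; p2[i, d] <- p2[i, d] - h
    num <- -(energy_fn(set_positions(system, p1)) -
               energy_fn(set_positions(system, p2))) / (2 * h)
    err <- max(err, abs(num - forces[i, d]) / max(abs(forces[i, d]), 1e-8))
  }
  err
}
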