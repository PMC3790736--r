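# Kernel-level and system-level checks of the cutoff evaluators against
# brute-force Coulomb oracles and analytic properties.

test_that("kernels vanish at the cutoff; smooth kernels have zero slope", {
  for (alpha in c(0, 0.06, 0.1, 0.14, 0.3)) {
    expect_equal(zd_pair_potential(12, alpha, 12), 0, tolerance = 1e-14)
    expect_equal(wolf_pair_potential(12, alpha, 12), 0, tolerance = 1e-14)
    h <- 1e-6
    dzd <- (zd_pair_potential(12 - h, alpha, 12) -
              zd_pair_potential(12 - 2 * h, alpha, 12)) / h
    expect_lt(abs(dzd), 1e-5)     # slope -> 0 approaching r_c
    if (alpha <= 0.1) {
      # Wolf slope stays finite at r_c (it decays like exp(-(a rc)^2),
      # so the contrast is only meaningful at small damping)
      dwolf <- (wolf_pair_potential(12 - h, alpha, 12) -
                  wolf_pair_potential(12 - 2 * h, alpha, 12)) / h
      expect_gt(abs(dwolf), 1e-3)
    }
  }
  expect_equal(sf_pair_potential(12, 12), 0, tolerance = 1e-14)
  h <- 1e-6
  dsf <- (sf_pair_potential(12 - h, 12) -
            sf_pair_potential(12 - 2 * h, 12)) / h
  expect_lt(abs(dsf), 1e-5)
  expect_error(zd_pair_potential(-1, 0, 12), "positive")
  expect_error(zd_pair_potential(13, 0, 12), "cutoff")
})

test_that("undamped ZD kernel matches its closed form and the alpha -> 0
           limit", {
  # 1/r + r^2/(2 rc^3) - 3/(2 rc) at r = 6, rc = 12
  expect_equal(zd_pair_potential(6, 0, 12), 1 / 6 + 36 / 3456 - 1 / 8,
               tolerance = 1e-14)
  r <- seq(0.5, 11.5, by = 0.5)
  expect_equal(zd_pair_potential(r, 1e-8, 12), zd_pair_potential(r, 0, 12),
               tolerance = 1e-6)
})

test_that("ZD is exact on neutral zero-dipole clusters and its dipole
           defect is analytic", {
  for (seed in 1:4) {
    sys <- neutral_zero_dipole_cluster(n = 8, radius = 3, seed = seed)
    zd <- zd_energy(sys, electro_config("zd", r_c = 30, alpha = 0))
    ref <- direct_cluster_energy(sys)
    expect_lt(abs(zd$total - ref$total) / abs(ref$total), 1e-12)
  }
  for (seed in 1:4) {
    sys <- neutral_dipole_cluster(seed = seed)
    rc <- 25
    D2 <- sum(dipole_moment(sys)^2)
    zd <- zd_energy(sys, electro_config("zd", r_c = rc, alpha = 0))
    ref <- direct_cluster_energy(sys)
    expect_equal(zd$total - ref$total, -K_COULOMB * D2 / (2 * rc^3),
                 tolerance = 1e-9)
  }
})

test_that("single particle carries only the self term", {
  sys <- make_cluster(2, matrix(c(0, 0, 0), 1))
  rep <- zd_energy(sys, electro_config("zd", r_c = 10, alpha = 0.1))
  expect_equal(rep$total, rep$components$self)
  co <- zd_coefficients(0.1, 10)
  expect_equal(rep$total, K_COULOMB * 4 * co$self, tolerance = 1e-12)
})

test_that("Wolf is exact on neutral clusters at alpha = 0; shifted force
           differs from Wolf", {
  sys <- neutral_dipole_cluster(seed = 5)
  wolf <- wolf_energy(sys, electro_config("wolf", r_c = 25, alpha = 0))
  ref <- direct_cluster_energy(sys)
  expect_lt(abs(wolf$total - ref$total) / abs(ref$total), 1e-12)
  el <- make_electrolyte(30, 24, rng_seed = 8)
  w <- wolf_energy(el, electro_config("wolf", r_c = 10, alpha = 0))
  s <- shifted_force_energy(el, electro_config("shifted_force", r_c = 10))
  expect_false(isTRUE(all.equal(w$total, s$total)))
})

test_that("shifted-force kernel value at r_c/2 matches the hand
           evaluation", {
  sys <- make_cluster(c(1, -1), rbind(c(0, 0, 0), c(5, 0, 0)))
  rep <- shifted_force_energy(sys, electro_config("shifted_force",
                                                  r_c = 10))
  # u(rc/2) = 2/rc - 1/rc - 1/(2 rc) = 1/(2 rc)
  expect_equal(rep$components$pair, -K_COULOMB * 0.5 / 10,
               tolerance = 1e-12)
})

test_that("RESA reduces to the direct sum without truncation and counts
           one-sided pairs at half weight", {
  sys <- neutral_dipole_cluster(seed = 6)
  resa <- resa_energy(sys, electro_config("resa", r_c = 50))
  ref <- direct_cluster_energy(sys)
  expect_equal(resa$total, ref$total, tolerance = 1e-12)
  # two single-atom residues beyond r_c: no interaction
  far <- particle_system(rbind(c(0, 0, 0), c(20, 0, 0)), c(1, -1))
  expect_equal(resa_energy(far, electro_config("resa", r_c = 10))$total, 0)
  # A--B--C line: B sees both, A and C do not see each other
  line <- particle_system(rbind(c(0, 0, 0), c(8, 0, 0), c(16, 0, 0)),
                          c(1, 1, 1))
  rep <- resa_energy(line, electro_config("resa", r_c = 10))
  # A-B and B-C at full weight (both sides see), A-C absent
  expect_equal(rep$total, K_COULOMB * 2 / 8, tolerance = 1e-12)
  # asymmetric case: make B a two-atom residue whose far atom pulls C
  # inside its residue sphere from B's side only
  sys2 <- particle_system(rbind(c(0, 0, 0), c(6, 0, 0), c(11, 0, 0)),
                          c(1, 1, 1), molecule_id = c(1, 1, 2),
                          residue_id = c(1, 1, 2))
  rep2 <- resa_energy(sys2, electro_config("resa", r_c = 10))
  # pairs 1-2 (4A, same residue always), 2-3 (5A, mutual), 1-3 (11A):
  # atom 3 sees residue {1,2} via atom 2, atom 1 does not see residue {3}
  # => half weight on 1-3
  expect_equal(rep2$total,
               K_COULOMB * (1 / 6 + 1 / 5 + 0.5 / 11), tolerance = 1e-12)
})

test_that("per-atom decompositions sum to the total for every method", {
  el <- make_electrolyte(40, 24, rng_seed = 12)
  wl <- make_water_lattice(3, rng_seed = 12)
  for (sys in list(el, wl)) {
    for (cfg in list(electro_config("zd", r_c = 10, alpha = 0.1),
                     electro_config("wolf", r_c = 10, alpha = 0.2),
                     electro_config("shifted_force", r_c = 10),
                     electro_config("resa", r_c = 4.5))) {
      cfg$r_c <- min(cfg$r_c, min(sys$box) / 2)
      rep <- electro_energy(sys, cfg)
      expect_lt(abs(sum(rep$per_atom) - rep$total) /
                  max(abs(rep$total), 1), 1e-10)
    }
  }
})

test_that("analytic forces agree with finite differences and conserve
           momentum", {
  sys <- make_electrolyte(25, 20, min_separation = 2.8, rng_seed = 3)
  for (cfg in list(electro_config("zd", r_c = 9, alpha = 0),
                   electro_config("zd", r_c = 9, alpha = 0.1),
                   electro_config("wolf", r_c = 9, alpha = 0.2),
                   electro_config("shifted_force", r_c = 9),
                   electro_config("resa", r_c = 9))) {
    F <- electro_forces(sys, cfg)
    err <- fd_force_error(sys, function(s) electro_energy(s, cfg)$total, F)
    expect_lt(err, 1e-6)
    expect_lt(max(abs(colSums(F))), 1e-9)
  }
})

test_that("an isolated pair at the cutoff feels no ZD force", {
  sys <- particle_system(rbind(c(0, 0, 0), c(9, 0, 0)), c(1, -1))
  F <- electro_forces(sys, electro_config("zd", r_c = 9, alpha = 0.1))
  expect_lt(max(abs(F)), 1e-10)
})

test_that("excluded pairs keep completion terms but lose bare Coulomb", {
  # two-molecule system: one bonded (excluded) pair + one spectator
  sys <- particle_system(rbind(c(0, 0, 0), c(1.5, 0, 0), c(5, 0, 0)),
                         c(0.5, -0.5, 0.2),
                         molecule_id = c(1, 1, 2),
                         residue_id = c(1, 1, 2),
                         exclusions = rbind(c(1, 2)))
  cfg <- electro_config("zd", r_c = 12, alpha = 0)
  rep <- zd_energy(sys, cfg)
  co <- zd_coefficients(0, 12)
  u <- function(r) 1 / r + co$A * r^2 + co$B
  manual <- K_COULOMB * (
    0.5 * -0.5 * (u(1.5) - 1 / 1.5) +      # excluded pair: no bare 1/r
      0.5 * 0.2 * u(5) + -0.5 * 0.2 * u(3.5) +
      co$self * sum(sys$charges^2))
  expect_equal(rep$total, manual, tolerance = 1e-12)
  expect_equal(rep$components$exclusion,
               K_COULOMB * 0.5 * -0.5 * (u(1.5) - 1 / 1.5),
               tolerance = 1e-12)
})

test_that("periodic cutoff larger than half the box is rejected", {
  el <- make_electrolyte(10, 18, rng_seed = 1)
  expect_error(zd_energy(el, electro_config("zd", r_c = 10)),
               "half the shortest box edge")
})
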