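# The Ewald reference is validated by internal consistency (splitting
# invariance, reciprocal-space convergence) and by the rock-salt Madelung
# constant.

test_that("rock-salt Ewald energy reproduces the Madelung constant and is
           splitting-invariant", {
  rs <- make_rocksalt(2)
  e1 <- ewald_energy(rs, ewald_params(r_real = 5.5, accuracy = 1e-10))
  e2 <- ewald_energy(rs, ewald_params(r_real = 5.5, alpha_split = 1.0,
                                      kmax = 16))
  expect_lt(abs(e1$total - e2$total) / abs(e1$total), 1e-6)
  r_nn <- 5.64 / 2
  M <- -e1$total * r_nn / K_COULOMB / (rs$n_particles / 2)
  expect_equal(M, 1.7475646, tolerance = 1e-6)
})

test_that("doubling kmax leaves a converged energy unchanged", {
  rs <- make_rocksalt(2)
  p <- zdsum:::resolve_ewald(ewald_params(r_real = 5.5, accuracy = 1e-8),
                             rs$box)
  e1 <- ewald_energy(rs, ewald_params(r_real = 5.5,
                                      alpha_split = p$alpha_split,
                                      kmax = p$kmax))
  e2 <- ewald_energy(rs, ewald_params(r_real = 5.5,
                                      alpha_split = p$alpha_split,
                                      kmax = 2 * p$kmax))
  expect_lt(abs(e1$total - e2$total) / abs(e1$total), 1e-8)
})

test_that("splitting invariance holds on a disordered electrolyte", {
  el <- make_electrolyte(250, 30, rng_seed = 21)
  e1 <- ewald_energy(el, ewald_params(r_real = 14, alpha_split = 0.25,
                                      kmax = 14))
  e2 <- ewald_energy(el, ewald_params(r_real = 14, alpha_split = 0.40,
                                      kmax = 22))
  expect_lt(abs(e1$total - e2$total) / abs(e1$total), 1e-6)
})

test_that("isolated-pair limit emerges as the box grows", {
  d <- 5
  target <- -K_COULOMB / d
  err <- vapply(c(50, 100, 200), function(L) {
    sys <- particle_system(rbind(c(0, 0, 0), c(d, 0, 0)), c(1, -1),
                           box = rep(L, 3))
    abs(ewald_energy(sys, ewald_params(r_real = 20,
                                       accuracy = 1e-8))$total - target)
  }, numeric(1))
  expect_true(all(diff(err) < 0))          # monotone approach
  expect_lt(err[3], 1e-3 * abs(target))
})

test_that("per-atom Ewald decomposition sums to the total", {
  wl <- make_water_lattice(3, rng_seed = 2)
  rep <- ewald_energy(wl, ewald_params(r_real = 4.5, accuracy = 1e-8))
  expect_lt(abs(sum(rep$per_atom) - rep$total) / abs(rep$total), 1e-10)
})

test_that("Ewald forces agree with finite differences", {
  el <- make_electrolyte(20, 20, min_separation = 2.8, rng_seed = 4)
  # force accuracy is bounded by the reciprocal-space truncation, which
  # carries an extra factor of k relative to the energy accuracy
  p <- ewald_params(r_real = 9, accuracy = 1e-10)
  F <- ewald_forces(el, p)
  err <- fd_force_error(el, function(s) ewald_energy(s, p)$total, F)
  expect_lt(err, 5e-6)
})

test_that("non-neutral systems are rejected unless background-corrected", {
  sys <- particle_system(rbind(c(0, 0, 0), c(3, 0, 0)), c(1, 1),
                         box = rep(20, 3))
  expect_error(ewald_energy(sys, ewald_params(r_real = 8)), "not neutral")
  rep <- ewald_energy(sys, ewald_params(r_real = 8, background = TRUE))
  expect_true(is.finite(rep$total))
  expect_lt(abs(sum(rep$per_atom) - rep$total) / abs(rep$total), 1e-10)
})

test_that("direct cluster energy matches hand sums", {
  expect_equal(direct_cluster_energy(
    make_cluster(c(1, -1), rbind(c(0, 0, 0), c(1, 0, 0))))$total,
    -K_COULOMB, tolerance = 1e-14)
  tri <- make_cluster(c(1, 1, -1),
                      rbind(c(0, 0, 0), c(2, 0, 0), c(1, sqrt(3), 0)))
  expect_equal(direct_cluster_energy(tri)$total,
               K_COULOMB * (1 / 2 - 1 / 2 - 1 / 2), tolerance = 1e-12)
  empty <- particle_system(matrix(numeric(0), 0, 3), numeric(0))
  expect_equal(direct_cluster_energy(empty)$total, 0)
  expect_error(direct_cluster_energy(make_rocksalt(1)), "open clusters")
  expect_error(ewald_energy(make_cluster(1, matrix(0, 1, 3))), "periodic")
})
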