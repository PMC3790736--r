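test_that("harmonic dimer conserves energy in NVE", {
  sys <- particle_system(rbind(c(0, 0, 0), c(2.2, 0, 0)), c(0, 0),
                         masses = c(12, 12))
  ff <- force_field(electro = NULL,
                    bonds = data.frame(i = 1, j = 2, k = 100, r0 = 2))
  # log densely (~10 samples per vibrational period) so the bounded
  # velocity-Verlet oscillation averages out of the drift regression
  run <- run_md(sys, ff, md_config(dt = 0.5, n_steps = 10000,
                                   ensemble = "nve", temperature = 300,
                                   seed = 2, stride_log = 10))
  expect_lt(energy_drift(run$log), 1e-5)
})

test_that("a frozen start without forces stays frozen", {
  sys <- particle_system(matrix(rnorm(9), 3, 3), c(0, 0, 0))
  ff <- force_field(electro = NULL)
  run <- run_md(sys, ff, md_config(dt = 1, n_steps = 200,
                                   ensemble = "nve", temperature = 0,
                                   seed = 1, stride_frames = 100))
  for (f in run$trajectory$frames)
    expect_equal(f, sys$positions, tolerance = 0)
})

test_that("identical seeds give bit-identical runs; different seeds do
           not", {
  el <- make_electrolyte(15, 20, min_separation = 3, rng_seed = 6)
  attr(el, "lj") <- data.frame(eps = rep(0.1, 30), sigma = rep(3, 30))
  ff <- force_field(electro = electro_config("zd", r_c = 8))
  cfg <- md_config(dt = 1, n_steps = 300, seed = 9, stride_log = 50)
  r1 <- run_md(el, ff, cfg)
  r2 <- run_md(el, ff, cfg)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$trajectory$frames, r2$trajectory$frames)
  cfg2 <- cfg
  cfg2$seed <- 10
  r3 <- run_md(el, ff, cfg2)
  expect_false(identical(r1$log$total, r3$log$total))
})

test_that("NVE with smooth ZD electrostatics keeps the drift small", {
  el <- make_electrolyte(40, 24, min_separation = 3, rng_seed = 5)
  attr(el, "lj") <- data.frame(eps = rep(0.1, 80), sigma = rep(3, 80))
  ff <- force_field(electro = electro_config("zd", r_c = 10, alpha = 0),
                    lj_cutoff = 10)
  run <- run_md(el, ff, md_config(dt = 0.5, n_steps = 10000,
                                  ensemble = "nve", temperature = 300,
                                  seed = 3, stride_log = 250))
  expect_lt(energy_drift(run$log), 1e-4)
  expect_lt(abs(run$log$total[nrow(run$log)] - run$log$total[1]) /
              abs(run$log$total[1]), 1e-4)
})

test_that("the Berendsen thermostat holds the target temperature in
           window averages", {
  wl <- make_water_lattice(3, rng_seed = 8)
  attr(wl, "lj") <- data.frame(eps = rep(c(0.152, 0, 0), 27),
                               sigma = rep(c(3.15, 1, 1), 27))
  nm <- 27
  ow <- 3 * (seq_len(nm) - 1)
  attr(wl, "bonds") <- data.frame(i = c(ow + 1, ow + 1),
                                  j = c(ow + 2, ow + 3),
                                  k = 450, r0 = 0.9572)
  attr(wl, "angles") <- data.frame(i = ow + 2, j = ow + 1,
                                   k_atom = ow + 3, k = 55,
                                   theta0 = 104.52 * pi / 180)
  ff <- force_field(electro = electro_config("zd", r_c = 4.5),
                    lj_cutoff = 4.5)
  run <- run_md(wl, ff, md_config(dt = 0.5, n_steps = 4000,
                                  ensemble = "nvt", temperature = 300,
                                  tau_t = 100, seed = 4,
                                  stride_log = 100))
  late <- run$log[run$log$step > 2000, ]
  expect_lt(abs(mean(late$temperature) - 300) / 300, 0.10)
})

test_that("non-finite forces abort with a located error", {
  sys <- particle_system(rbind(c(0, 0, 0), c(0, 0, 0)), c(1, 1),
                         masses = c(1, 1))
  ff <- force_field(electro = electro_config("zd", r_c = 10))
  expect_error(run_md(sys, ff, md_config(dt = 1, n_steps = 10,
                                         ensemble = "nve",
                                         temperature = 0, seed = 1)),
               "non-finite forces")
})
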