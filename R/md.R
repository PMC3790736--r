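# Minimal velocity-Verlet NVE/NVT dynamics over the toy force field:
# configured electrostatics + shifted-force Lennard-Jones + harmonic bonds
# and angles.  Enough to demonstrate the stability contrast between smooth
# cutoff electrostatics and residue-based bare truncation on the coarse
# duplex, and to generate snapshot ensembles for the analysis modules.

#' Toy force field
#'
#' @param electro an [electro_config()] (or [ewald_params()], wrapped as an
#'   ewald config) for the electrostatic term; `NULL` disables it.
#' @param lj data.frame with per-particle `eps` (kcal/mol) and `sigma`
#'   (Angstrom); rows of `eps = 0` feel no LJ.  Defaults to the `"lj"`
#'   attribute of the system passed to [run_md()].
#' @param lj_cutoff LJ cutoff, Angstrom (shifted-force form, smooth at the
#'   cutoff).
#' @param bonds data.frame `i, j, k, r0` (E = k (r - r0)^2).
#' @param angles data.frame `i, j, k_atom, k, theta0` (j is the vertex,
#'   theta0 in radians).
#' @return List of class `force_field`.
#' @export
force_field <- function(electro = electro_config("zd"), lj = NULL,
                        lj_cutoff = 10, bonds = NULL, angles = NULL) {
  if (inherits(electro, "ewald_params"))
    electro <- electro_config("ewald", r_c = electro$r_real,
                              ewald = electro)
  if (!is.null(electro)) stopifnot(inherits(electro, "electro_config"))
  structure(list(electro = electro, lj = lj, lj_cutoff = lj_cutoff,
                 bonds = bonds, angles = angles),
            class = "force_field")
}

#' MD run configuration
#'
#' @param dt timestep, fs.
#' @param n_steps number of integration steps.
#' @param ensemble `"nvt"` (Berendsen velocity rescaling) or `"nve"`.
#' @param temperature target temperature, K (NVT; also used for the
#'   Maxwell-Boltzmann velocity initialization).
#' @param tau_t Berendsen coupling time, fs.
#' @param seed integer seed for the initial velocities.
#' @param stride_log steps between energy-log rows.
#' @param stride_frames steps between stored trajectory frames.
#' @return List of class `md_config`.
#' @export
md_config <- function(dt = 1, n_steps = 1000, ensemble = c("nvt", "nve"),
                      temperature = 300, tau_t = 500, seed = 1,
                      stride_log = 50, stride_frames = 100) {
  ensemble <- match.arg(ensemble)
  stopifnot(dt > 0, n_steps >= 1)
  if (ensemble == "nvt") stopifnot(temperature > 0, tau_t > 0)
  structure(list(dt = dt, n_steps = n_steps, ensemble = ensemble,
                 temperature = temperature, tau_t = tau_t, seed = seed,
                 stride_log = stride_log, stride_frames = stride_frames),
            class = "md_config")
}

# total potential energy and forces of the toy force field
ff_eval <- function(system, ff, want_energy = TRUE) {
  n <- system$n_particles
  F <- matrix(0, n, 3)
  E <- 0
  if (!is.null(ff$electro)) {
    F <- F + electro_forces(system, ff$electro)
    if (want_energy) E <- E + electro_energy(system, ff$electro)$total
  }
  box <- system$box %||% numeric(0)
  if (!is.null(ff[["lj"]]) && any(ff[["lj"]]$eps > 0)) {
    ex <- excl_args(system)
    r <- cpp_lj(system$positions, box, ff[["lj"]]$eps, ff[["lj"]]$sigma,
                ff[["lj_cutoff"]], ex$idx, ex$w, TRUE)
    F <- F + r$forces
    E <- E + r$total
  }
  if (!is.null(ff$bonds) && nrow(ff$bonds)) {
    r <- cpp_bonds(system$positions, box, as.integer(ff$bonds$i - 1),
                   as.integer(ff$bonds$j - 1), ff$bonds$k, ff$bonds$r0,
                   TRUE)
    F <- F + r$forces
    E <- E + r$total
  }
  if (!is.null(ff$angles) && nrow(ff$angles)) {
    r <- cpp_angles(system$positions, box, as.integer(ff$angles$i - 1),
                    as.integer(ff$angles$j - 1),
                    as.integer(ff$angles$k_atom - 1),
                    ff$angles$k, ff$angles$theta0, TRUE)
    F <- F + r$forces
    E <- E + r$total
  }
  list(forces = F, energy = E)
}

maxwell_velocities <- function(masses, temperature, seed) {
  n <- length(masses)
  v <- with_seed(seed, matrix(rnorm(3 * n), n, 3)) *
    sqrt(K_BOLTZMANN * temperature * ACCEL_UNIT / masses)
  # remove centre-of-mass motion
  p <- colSums(v * masses)
  sweep(v, 2, p / sum(masses))
}

kinetic_energy <- function(v, masses)
  0.5 * sum(masses * rowSums(v^2)) / ACCEL_UNIT

#' Run molecular dynamics
#'
#' Velocity-Verlet integration with Maxwell-Boltzmann initial velocities
#' (seeded, centre-of-mass motion removed) and, for NVT, Berendsen velocity
#' rescaling.  Coordinates are propagated unwrapped; periodicity enters
#' through minimum-image forces only.
#'
#' @param system a [particle_system] (masses are taken from it).
#' @param ff a [force_field()].  If its `lj`/`bonds`/`angles` slots are
#'   `NULL` they are taken from the same-named attributes of `system` when
#'   present.
#' @param config an [md_config()].
#' @return List with `trajectory` (a [trajectory] including the initial
#'   frame) and `log` (data.frame: step, time_ps, kinetic, potential,
#'   total, temperature).
#' @export
run_md <- function(system, ff, config) {
  stopifnot(inherits(system, "particle_system"),
            inherits(ff, "force_field"), inherits(config, "md_config"))
  for (slot in c("lj", "bonds", "angles"))
    if (is.null(ff[[slot]]) && !is.null(attr(system, slot)))
      ff[[slot]] <- attr(system, slot)

  n <- system$n_particles
  m <- system$masses
  dt <- config$dt
  ndof <- 3 * n - 3
  x <- system$positions
  v <- maxwell_velocities(m, config$temperature, config$seed)
  sys <- system
  ev <- ff_eval(sys, ff)
  a <- ev$forces * ACCEL_UNIT / m

  frames <- list(x)
  frame_times <- 0
  log_rows <- vector("list")
  log_state <- function(step, pot) {
    ke <- kinetic_energy(v, m)
    data.frame(step = step, time_ps = step * dt / 1000, kinetic = ke,
               potential = pot, total = ke + pot,
               temperature = 2 * ke / (ndof * K_BOLTZMANN))
  }
  log_rows[[1]] <- log_state(0, ev$energy)

  for (step in seq_len(config$n_steps)) {
    v <- v + 0.5 * dt * a
    x <- x + dt * v
    sys$positions <- x
    want_e <- step %% config$stride_log == 0 || step == config$n_steps
    ev <- ff_eval(sys, ff, want_energy = want_e)
    if (any(!is.finite(ev$forces)))
      stop("non-finite forces at step ", step, " (particle ",
           which(!is.finite(rowSums(ev$forces)))[1], ")")
    a <- ev$forces * ACCEL_UNIT / m
    v <- v + 0.5 * dt * a
    if (config$ensemble == "nvt") {
      Tinst <- 2 * kinetic_energy(v, m) / (ndof * K_BOLTZMANN)
      if (Tinst > 0) {
        lambda <- sqrt(1 + dt / config$tau_t *
                         (config$temperature / Tinst - 1))
        v <- v * min(max(lambda, 0.8), 1.25)
      }
    }
    if (want_e)
      log_rows[[length(log_rows) + 1]] <- log_state(step, ev$energy)
    if (step %% config$stride_frames == 0) {
      frames[[length(frames) + 1]] <- x
      frame_times <- c(frame_times, step * dt / 1000)
    }
  }
  list(trajectory = trajectory(frames, frame_times, topology = system),
       log = do.call(rbind, log_rows))
}

#' Thermostatted relaxation of a generated system
#'
#' Runs NVT dynamics and returns the system with its final coordinates --
#' used to relax freshly generated configurations (random ion and solvent
#' placement) before production sampling.  Defaults to ZD forces, which
#' cost a fraction of the reference Ewald forces; the sampling run itself
#' can then use whichever method the analysis calls for.
#'
#' @param system a [particle_system] with force-field attributes.
#' @param n_steps relaxation steps.
#' @param dt timestep, fs.
#' @param temperature thermostat target, K.
#' @param seed velocity seed.
#' @param electro electrostatics used during relaxation.
#' @return The input system with updated positions.
#' @export
equilibrate <- function(system, n_steps = 5000, dt = 0.5,
                        temperature = 300, seed = 1,
                        electro = electro_config("zd", r_c = 10)) {
  run <- run_md(system, force_field(electro = electro),
                md_config(dt = dt, n_steps = n_steps, ensemble = "nvt",
                          temperature = temperature, tau_t = 100,
                          seed = seed, stride_log = n_steps,
                          stride_frames = n_steps))
  fr <- run$trajectory$frames
  set_positions(system, fr[[length(fr)]])
}

#' Relative secular energy drift of an MD log
#'
#' Least-squares slope of total energy versus time, scaled by the run
#' length and the mean magnitude: `|slope * (t_end - t_start)| / |mean(E)|`.
#' Velocity-Verlet total energy oscillates within a bounded band; the
#' regression slope isolates the secular drift from that oscillation.
#'
#' @param log the `log` data.frame of [run_md()].
#' @return Dimensionless relative drift.
#' @export
energy_drift <- function(log) {
  stopifnot(nrow(log) >= 3)
  fit <- stats::lm(total ~ time_ps, data = log)
  span <- log$time_ps[nrow(log)] - log$time_ps[1]
  abs(stats::coef(fit)[["time_ps"]] * span) / abs(mean(log$total))
}

#' Stability contrast between two electrostatic methods
#'
#' Builds one seeded coarse duplex, relaxes it under reference forces so
#' that production starts from an equilibrated structure, runs the same
#' thermostatted dynamics under two electrostatic configurations
#' (identical initial structure and velocities), and returns the
#' backbone-bead rmsd-vs-time trace of each run, superposed on the relaxed
#' starting structure.
#'
#' @param duplex_spec list of arguments to [make_coarse_duplex()].
#' @param method_a,method_b [electro_config()] (or [ewald_params()])
#'   objects.
#' @param config an [md_config()].
#' @param equil_steps relaxation steps before production (0 = start from
#'   the ideal-geometry build).
#' @param equil_electro electrostatics used for the relaxation (default:
#'   the Ewald reference over the largest legal real-space cutoff).
#' @return List with `trace_a`, `trace_b` (data.frames: time_ps, rmsd),
#'   `run_a`, `run_b` (full [run_md()] outputs), and `system` (the relaxed
#'   starting system).
#' @export
stability_demo <- function(duplex_spec = list(), method_a, method_b,
                           config = md_config(dt = 2, n_steps = 5000),
                           equil_steps = 0, equil_electro = NULL) {
  system <- do.call(make_coarse_duplex, duplex_spec)
  if (equil_steps > 0) {
    if (is.null(equil_electro)) {
      rr <- floor(min(system$box) / 2) - 1
      equil_electro <- electro_config("ewald", r_c = rr,
                                      ewald = ewald_params(r_real = rr,
                                                           accuracy = 1e-4))
    }
    system <- equilibrate(system, n_steps = equil_steps, dt = config$dt,
                          temperature = config$temperature,
                          seed = config$seed, electro = equil_electro)
  }
  beads <- system$group_labels$beads
  one <- function(method) {
    run <- run_md(system, force_field(electro = method), config)
    rmsd <- rmsd_trace(run$trajectory, system$positions, beads)
    list(run = run,
         trace = data.frame(time_ps = run$trajectory$times, rmsd = rmsd))
  }
  a <- one(method_a)
  b <- one(method_b)
  list(trace_a = a$trace, trace_b = b$trace, run_a = a$run, run_b = b$run,
       system = system)
}
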