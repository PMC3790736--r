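# Accuracy metrics: average relative deviation of a cutoff method from the
# Ewald reference over a snapshot ensemble, and its decomposition into
# per-molecule / per-residue / arbitrary-group contributions via the
# per-atom energies.  Deviations are reported as one-sided magnitudes
# (percent) with standard deviations across frames; signed per-frame
# bookkeeping is kept alongside so group contributions sum exactly to the
# total.

#' Replace the coordinates of a system
#'
#' @param system a [particle_system].
#' @param positions new n x 3 matrix.
#' @return The system with updated positions.
#' @export
set_positions <- function(system, positions) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == system$n_particles, ncol(positions) == 3)
  system$positions <- positions
  system
}

#' Per-frame electrostatic energies over a trajectory
#'
#' Evaluates the configured method on every frame of a snapshot set.
#'
#' @param traj a [trajectory].
#' @param config an [electro_config()] (or [ewald_params()] for the
#'   reference, which is wrapped as an ewald config).
#' @param per_atom keep the per-atom decompositions?
#' @return List with `totals` (numeric per frame) and, if requested,
#'   `per_atom` (frames x atoms matrix).
#' @export
frame_energies <- function(traj, config, per_atom = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  if (inherits(config, "ewald_params"))
    config <- electro_config("ewald", r_c = config$r_real, ewald = config)
  sys <- traj$topology
  nf <- length(traj$frames)
  totals <- numeric(nf)
  pa <- if (per_atom) matrix(NA_real_, nf, sys$n_particles)
  for (f in seq_len(nf)) {
    rep <- electro_energy(set_positions(sys, traj$frames[[f]]), config)
    totals[f] <- rep$total
    if (per_atom) pa[f, ] <- rep$per_atom
  }
  list(totals = totals, per_atom = pa)
}

#' Average relative deviation from a reference energy series
#'
#' Per frame, `|E_test - E_ref| / |E_ref|` in percent; the report carries
#' the per-frame values, their mean and standard deviation, and the signed
#' per-frame deviations used by the partition bookkeeping.
#'
#' @param test_energies,ref_energies equal-length numeric vectors
#'   (kcal/mol per frame).
#' @return A `deviation_report` list: `per_frame` (percent), `mean`, `sd`,
#'   `signed` (percent, signed).
#' @export
relative_deviation <- function(test_energies, ref_energies) {
  stopifnot(length(test_energies) == length(ref_energies),
            length(ref_energies) >= 1)
  if (any(ref_energies == 0)) stop("reference energies must be nonzero")
  signed <- 100 * (test_energies - ref_energies) / abs(ref_energies)
  per_frame <- abs(signed)
  structure(list(per_frame = per_frame, mean = mean(per_frame),
                 sd = if (length(per_frame) > 1) sd(per_frame) else 0,
                 signed = signed),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat("deviation_report:", length(x$per_frame), "frames, mean",
      format(x$mean, digits = 6), "% (sd", format(x$sd, digits = 6), "%)\n")
  if (!is.null(x$partition)) {
    cat("  partition:\n")
    print(x$partition)
  }
  invisible(x)
}

#' Partition the energy deviation over atom groups
#'
#' For each group g, the per-frame contribution
#' `sum_{i in g}(E_i^test - E_i^ref) / |E_ref|` (percent).  The report
#' tabulates the mean and sd of the magnitudes; the signed contributions
#' sum exactly to the signed total deviation per frame, which is verified.
#'
#' @param per_atom_test,per_atom_ref frames x atoms matrices of per-atom
#'   energies.
#' @param ref_totals per-frame reference totals.
#' @param partition named list of disjoint index sets covering all atoms.
#' @return A `deviation_report` with a `partition` data.frame (group,
#'   mean_abs, sd_abs, mean_signed) and a `signed_by_group` matrix.
#' @export
partition_deviation <- function(per_atom_test, per_atom_ref, ref_totals,
                                partition) {
  per_atom_test <- as.matrix(per_atom_test)
  per_atom_ref <- as.matrix(per_atom_ref)
  stopifnot(all(dim(per_atom_test) == dim(per_atom_ref)),
            nrow(per_atom_test) == length(ref_totals))
  n <- ncol(per_atom_test)
  idx <- unlist(partition, use.names = FALSE)
  if (length(idx) != n || anyDuplicated(idx) || !setequal(idx, seq_len(n)))
    stop("partition must cover all atoms exactly once")
  diff <- per_atom_test - per_atom_ref
  signed_by_group <- vapply(partition, function(g)
    rowSums(diff[, g, drop = FALSE]) / abs(ref_totals) * 100,
    numeric(nrow(diff)))
  signed_by_group <- matrix(signed_by_group, nrow = nrow(diff),
                            dimnames = list(NULL, names(partition)))
  tab <- data.frame(
    group = names(partition),
    mean_abs = colMeans(abs(signed_by_group)),
    sd_abs = apply(abs(signed_by_group), 2, function(v)
      if (length(v) > 1) sd(v) else 0),
    mean_signed = colMeans(signed_by_group),
    row.names = NULL)
  total <- relative_deviation(rowSums(per_atom_test), ref_totals)
  total$partition <- tab
  total$signed_by_group <- signed_by_group
  total
}

#' Deviation sweep over methods and cutoffs
#'
#' Evaluates every configuration on every snapshot and tabulates the mean
#' and standard deviation of the relative deviation from the Ewald
#' reference -- the machinery behind cutoff-distance / damping-factor
#' accuracy curves.
#'
#' @param snapshots a [trajectory] of snapshot structures.
#' @param configs list of [electro_config()] objects.
#' @param reference an [ewald_params()] object, or a precomputed numeric
#'   vector of per-frame reference energies.
#' @return data.frame with columns method, r_c, alpha, mean_dev, sd_dev
#'   (percent), n_frames.
#' @export
deviation_sweep <- function(snapshots, configs,
                            reference = ewald_params()) {
  stopifnot(length(configs) >= 1)
  ref_tot <- if (is.numeric(reference)) reference
             else frame_energies(snapshots, reference)$totals
  rows <- lapply(configs, function(cfg) {
    dev <- relative_deviation(frame_energies(snapshots, cfg)$totals,
                              ref_tot)
    data.frame(method = cfg$method, r_c = cfg$r_c, alpha = cfg$alpha,
               mean_dev = dev$mean, sd_dev = dev$sd,
               n_frames = length(ref_tot))
  })
  do.call(rbind, rows)
}
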