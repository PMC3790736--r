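# Plain-text readers/writers: XYZ structures, multi-frame extended XYZ
# trajectories, the topology sidecar (charges, grouping, exclusions), and a
# PDB coordinate reader (delegated to bio3d).  All writes are atomic
# (temp file + rename) and full precision, so structure and trajectory
# round trips are bit-exact.

atomic_write <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    file.remove(tmp)
    stop("could not write ", path)
  }
  invisible(path)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write / read a single-structure XYZ file
#'
#' Standard XYZ: atom count, comment line, then `label x y z` records.
#' Coordinates are written in full precision so a write/read round trip is
#' exact.
#'
#' @param system a [particle_system] (labels default to the sign of the
#'   charge) or an n x 3 matrix with `labels`.
#' @param path file path.
#' @param comment comment line content.
#' @export
write_xyz <- function(system, path, comment = "zdsum structure") {
  pos <- if (inherits(system, "particle_system")) system$positions
         else as.matrix(system)
  labels <- if (inherits(system, "particle_system"))
    ifelse(system$charges >= 0, "P", "N") else rep("X", nrow(pos))
  lines <- c(nrow(pos), comment,
             paste(labels, fmt_num(pos[, 1]), fmt_num(pos[, 2]),
                   fmt_num(pos[, 3])))
  atomic_write(lines, path)
}

#' @rdname write_xyz
#' @return `read_xyz`: list with `positions` (matrix), `labels`, `comment`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop(path, ": not an XYZ file (too short)")
  n <- as.integer(lines[1])
  if (is.na(n) || length(lines) < n + 2)
    stop(path, ": malformed XYZ header (", lines[1], " atoms declared, ",
         max(0, length(lines) - 2), " records present)")
  rec <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  pos <- suppressWarnings(
    t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3))))
  if (any(!is.finite(pos)))
    stop(path, ": malformed coordinate record at line ",
         which(!stats::complete.cases(pos))[1] + 2)
  list(positions = pos, labels = vapply(rec, `[`, character(1), 1),
       comment = lines[2])
}

#' Write / read the topology sidecar
#'
#' A structured plain-text companion to a coordinate file carrying
#' everything coordinates do not: per-particle charge, molecule and residue
#' ids, mass, the named group map, exclusions and scaled 1-4 pairs, and the
#' box.
#'
#' @param system a [particle_system].
#' @param path file path.
#' @export
write_topology <- function(system, path) {
  s <- system
  lines <- c("zdsum-topology 1",
             if (is.null(s$box)) "box open"
             else paste("box", paste(fmt_num(s$box), collapse = " ")),
             paste("scale14", fmt_num(s$scale14)),
             paste("atoms", s$n_particles),
             paste(fmt_num(s$charges), s$molecule_id, s$residue_id,
                   fmt_num(s$masses)))
  for (g in names(s$group_labels))
    lines <- c(lines, paste("group", g,
                            paste(s$group_labels[[g]], collapse = " ")))
  lines <- c(lines, paste("exclusions", nrow(s$exclusions)),
             if (nrow(s$exclusions))
               paste(s$exclusions[, 1], s$exclusions[, 2]),
             paste("scaled", nrow(s$scaled_pairs)),
             if (nrow(s$scaled_pairs))
               paste(s$scaled_pairs[, 1], s$scaled_pairs[, 2]))
  atomic_write(lines, path)
}

#' @rdname write_topology
#' @return `read_topology`: all sidecar fields as a list; combine with
#'   coordinates via [read_structure()].
#' @export
read_topology <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "zdsum-topology"))
    stop(path, ": not a zdsum topology file")
  boxf <- strsplit(lines[2], "\\s+")[[1]]
  box <- if (identical(boxf[2], "open")) NULL else as.numeric(boxf[-1])
  scale14 <- as.numeric(strsplit(lines[3], "\\s+")[[1]][2])
  n <- as.integer(strsplit(lines[4], "\\s+")[[1]][2])
  at <- strsplit(trimws(lines[5:(4 + n)]), "\\s+")
  atm <- t(vapply(at, function(r) as.numeric(r[1:4]), numeric(4)))
  cursor <- 5 + n
  groups <- list()
  while (cursor <= length(lines) && startsWith(lines[cursor], "group ")) {
    f <- strsplit(lines[cursor], "\\s+")[[1]]
    groups[[f[2]]] <- as.integer(f[-(1:2)])
    cursor <- cursor + 1
  }
  read_pairs <- function(tag) {
    f <- strsplit(lines[cursor], "\\s+")[[1]]
    if (!identical(f[1], tag))
      stop(path, ": expected '", tag, "' section at line ", cursor)
    m <- as.integer(f[2])
    cursor <<- cursor + 1
    if (m == 0) return(matrix(integer(0), 0, 2))
    p <- t(vapply(strsplit(trimws(lines[cursor:(cursor + m - 1)]), "\\s+"),
                  function(r) as.integer(r[1:2]), integer(2)))
    cursor <<- cursor + m
    p
  }
  excl <- read_pairs("exclusions")
  scaled <- read_pairs("scaled")
  list(n = n, charges = atm[, 1], molecule_id = as.integer(atm[, 2]),
       residue_id = as.integer(atm[, 3]), masses = atm[, 4], box = box,
       scale14 = scale14, group_labels = groups, exclusions = excl,
       scaled_pairs = scaled)
}

#' Read a structure (coordinates + topology sidecar)
#'
#' Coordinates come from an XYZ or PDB file (PDB parsing via the bio3d
#' package; 1-based residue numbering preserved), everything else from the
#' sidecar written by [write_topology()].
#'
#' @param path coordinate file (`.xyz` or `.pdb`).
#' @param topology_path sidecar path.
#' @return A [particle_system].
#' @export
read_structure <- function(path, topology_path) {
  top <- read_topology(topology_path)
  pos <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    if (!requireNamespace("bio3d", quietly = TRUE))
      stop("PDB reading requires the bio3d package")
    pdb <- bio3d::read.pdb(path)
    matrix(pdb$xyz, ncol = 3, byrow = TRUE)
  } else {
    read_xyz(path)$positions
  }
  if (nrow(pos) != top$n)
    stop("atom-count mismatch: ", path, " has ", nrow(pos), " atoms, ",
         topology_path, " declares ", top$n)
  particle_system(pos, top$charges, box = top$box,
                  molecule_id = top$molecule_id,
                  residue_id = top$residue_id,
                  group_labels = top$group_labels,
                  exclusions = top$exclusions,
                  scaled_pairs = top$scaled_pairs, scale14 = top$scale14,
                  masses = top$masses)
}

#' @rdname read_structure
#' @param system a [particle_system] to write.
#' @export
write_structure <- function(system, path, topology_path) {
  write_xyz(system, path)
  write_topology(system, topology_path)
  invisible(path)
}

#' Write / read a multi-frame extended XYZ trajectory
#'
#' Frames are concatenated XYZ blocks whose comment lines carry the frame
#' time (`time_ps= <t>`); counts and times round-trip exactly.
#'
#' @param traj a [trajectory].
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj$frames[[1]])
  labels <- if (!is.null(traj$topology))
    ifelse(traj$topology$charges >= 0, "P", "N") else rep("X", n)
  blocks <- unlist(lapply(seq_along(traj$frames), function(f) {
    p <- traj$frames[[f]]
    c(n, paste0("time_ps= ", fmt_num(traj$times[f])),
      paste(labels, fmt_num(p[, 1]), fmt_num(p[, 2]), fmt_num(p[, 3])))
  }))
  atomic_write(blocks, path)
}

#' @rdname write_trajectory
#' @param topology optional [particle_system] to attach.
#' @param stride keep every `stride`-th frame.
#' @return `read_trajectory`: a [trajectory].
#' @export
read_trajectory <- function(path, topology = NULL, stride = 1) {
  lines <- readLines(path)
  if (length(lines) == 0) stop(path, ": empty trajectory file")
  frames <- list()
  times <- numeric(0)
  cursor <- 1
  while (cursor <= length(lines)) {
    n <- as.integer(lines[cursor])
    if (is.na(n) || cursor + 1 + n > length(lines))
      stop(path, ": inconsistent frame block at line ", cursor)
    tm <- sub(".*time_ps=\\s*", "", lines[cursor + 1])
    rec <- strsplit(trimws(lines[(cursor + 2):(cursor + 1 + n)]), "\\s+")
    frames[[length(frames) + 1]] <-
      t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
    times <- c(times, as.numeric(tm))
    cursor <- cursor + 2 + n
  }
  keep <- seq(1, length(frames), by = stride)
  if (any(is.na(times))) times <- as.numeric(seq_along(frames))
  trajectory(frames[keep], times[keep], topology = topology)
}

#' Write a provenance record
#'
#' JSON record of the inputs, configuration and seed of a run, written next
#' to its outputs so archived runs can be reproduced.
#'
#' @param path output JSON path.
#' @param ... named fields (configs, seeds, file paths, ...).
#' @export
write_provenance <- function(path, ...) {
  rec <- c(list(package = "zdsum",
                version = as.character(utils::packageVersion("zdsum")),
                timestamp = format(Sys.time(), tz = "UTC")),
           list(...))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE, digits = NA)
  invisible(path)
}

#' Snapshot ensemble from reference-method dynamics
#'
#' Generates decorrelated snapshot structures by running thermostatted
#' dynamics with Ewald (reference) forces and keeping every
#' `stride`-th step, emulating how snapshot ensembles are sampled from a
#' production trajectory.
#'
#' @param system a [particle_system] with force-field attributes.
#' @param n_snapshots number of frames to keep.
#' @param stride steps between kept frames (>= 100 to decorrelate).
#' @param dt timestep, fs.
#' @param temperature thermostat target, K.
#' @param seed velocity seed.
#' @param ewald [ewald_params()] used for the generating forces.
#' @param n_equil discarded equilibration steps before sampling.
#' @return A [trajectory] of snapshots.
#' @export
sample_snapshots <- function(system, n_snapshots = 50, stride = 100,
                             dt = 0.5, temperature = 300, seed = 1,
                             ewald = ewald_params(r_real = 10,
                                                 accuracy = 1e-6),
                             n_equil = 200) {
  ff <- force_field(electro = ewald)
  run <- run_md(system, ff,
                md_config(dt = dt, n_steps = n_equil + n_snapshots * stride,
                          ensemble = "nvt", temperature = temperature,
                          tau_t = 100, seed = seed,
                          stride_log = 10 * stride,
                          stride_frames = stride))
  traj <- run$trajectory
  nf <- length(traj$frames)
  keep <- (nf - n_snapshots + 1):nf
  trajectory(traj$frames[keep], traj$times[keep], topology = system)
}
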