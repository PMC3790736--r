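# Particle-system data model: positions, charges, periodic box, structural
# grouping (molecule / residue / named groups), bonded exclusions.

#' Construct a particle system
#'
#' The central container of the package: `n` point charges with Cartesian
#' coordinates (Angstrom), partial charges (elementary charge units), an
#' orthorhombic periodic box or open (cluster) boundaries, and the structural
#' bookkeeping the evaluators need -- molecule and residue assignments, named
#' atom groups, and bonded exclusions.
#'
#' Residues must nest inside molecules: a residue id may not span two
#' molecule ids.  Exclusion pairs are stored unordered without duplicates or
#' self pairs; `scaled_pairs` (the 1-4 set) carry a common `scale14` factor
#' applied to the bare Coulomb part only.
#'
#' @param positions n x 3 numeric matrix, Angstrom.
#' @param charges length-n numeric, elementary charge units.
#' @param box length-3 positive numeric (orthorhombic edge lengths, Angstrom)
#'   or `NULL` for an open, non-periodic cluster.
#' @param molecule_id,residue_id length-n integer assignments (default: every
#'   particle its own molecule/residue).
#' @param group_labels named list of integer index vectors (1-based), e.g.
#'   `list(backbone = ..., "Na+" = ...)`.
#' @param exclusions two-column integer matrix of fully excluded (1-2/1-3)
#'   pairs, or `NULL`.
#' @param scaled_pairs two-column integer matrix of 1-4 pairs, or `NULL`.
#' @param scale14 scale applied to the bare Coulomb interaction of
#'   `scaled_pairs` (1 = no scaling).
#' @param masses length-n numeric, amu; defaults to 1 for every particle
#'   (only the MD engine uses masses).
#' @return An object of class `particle_system`.
#' @export
particle_system <- function(positions, charges, box = NULL,
                            molecule_id = NULL, residue_id = NULL,
                            group_labels = list(), exclusions = NULL,
                            scaled_pairs = NULL, scale14 = 1,
                            masses = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3)
    stop("positions must be an n x 3 matrix")
  n <- nrow(positions)
  charges <- as.numeric(charges)
  if (length(charges) != n)
    stop("charges length (", length(charges), ") != particle count (", n, ")")
  if (n > 0 && (!all(is.finite(positions)) || !all(is.finite(charges))))
    stop("positions and charges must be finite")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || !all(is.finite(box)) || any(box <= 0))
      stop("box must be three strictly positive edge lengths or NULL")
  }
  if (is.null(molecule_id)) molecule_id <- seq_len(n)
  if (is.null(residue_id)) residue_id <- seq_len(n)
  molecule_id <- as.integer(molecule_id)
  residue_id <- as.integer(residue_id)
  if (length(molecule_id) != n || length(residue_id) != n)
    stop("molecule_id and residue_id must have one entry per particle")
  if (n > 0) {
    mol_of_res <- tapply(molecule_id, residue_id,
                         function(m) length(unique(m)))
    if (any(mol_of_res > 1))
      stop("residue_id must nest inside molecule_id ",
           "(a residue spans several molecules)")
  }
  exclusions <- normalize_pairs(exclusions, n, "exclusions")
  scaled_pairs <- normalize_pairs(scaled_pairs, n, "scaled_pairs")
  if (nrow(scaled_pairs) > 0 &&
      (!is.finite(scale14) || scale14 < 0 || scale14 > 1))
    stop("scale14 must be in [0, 1]")
  if (nrow(exclusions) && nrow(scaled_pairs)) {
    both <- intersect(pair_keys(exclusions, n), pair_keys(scaled_pairs, n))
    if (length(both))
      stop("a pair cannot be both fully excluded and 1-4 scaled")
  }
  if (!is.list(group_labels) ||
      (length(group_labels) && is.null(names(group_labels))))
    stop("group_labels must be a named list of index vectors")
  for (g in names(group_labels)) {
    idx <- as.integer(group_labels[[g]])
    if (any(idx < 1 | idx > n)) stop("group '", g, "' has out-of-range indices")
    group_labels[[g]] <- idx
  }
  if (is.null(masses)) masses <- rep(1, n)
  masses <- as.numeric(masses)
  if (length(masses) != n || any(!is.finite(masses) | masses <= 0))
    stop("masses must be positive and one per particle")

  structure(list(n_particles = n, positions = positions, charges = charges,
                 box = box, molecule_id = molecule_id,
                 residue_id = residue_id, group_labels = group_labels,
                 exclusions = exclusions, scaled_pairs = scaled_pairs,
                 scale14 = scale14, masses = masses),
            class = "particle_system")
}

# canonical (i < j) pair matrix with validation
normalize_pairs <- function(p, n, what) {
  if (is.null(p) || (is.matrix(p) && nrow(p) == 0) || length(p) == 0)
    return(matrix(integer(0), 0, 2))
  p <- matrix(as.integer(p), ncol = 2)
  if (any(p < 1 | p > n)) stop(what, ": particle index out of range")
  if (any(p[, 1] == p[, 2])) stop(what, ": self-pairs not allowed")
  p <- cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
  if (anyDuplicated(pair_keys(p, n))) stop(what, ": duplicate pairs")
  p
}

pair_keys <- function(p, n) (p[, 1] - 1) * n + (p[, 2] - 1)

#' @export
print.particle_system <- function(x, ...) {
  cat("particle_system:", x$n_particles, "particles,",
      if (is.null(x$box)) "open cluster"
      else paste0("box ", paste(signif(x$box, 6), collapse = " x "), " A"),
      "\n  net charge:", format(net_charge(x)),
      " molecules:", length(unique(x$molecule_id)),
      " residues:", length(unique(x$residue_id)), "\n")
  if (length(x$group_labels))
    cat("  groups:", paste(names(x$group_labels), collapse = ", "), "\n")
  invisible(x)
}

#' Net charge of a system
#'
#' @param system a [particle_system].
#' @return Sum of all partial charges (elementary charge units).
#' @export
net_charge <- function(system) {
  stopifnot(inherits(system, "particle_system"))
  sum(system$charges)
}

#' Dipole moment of a particle subset
#'
#' Returns sum of q_i * r_i over the subset (e*Angstrom).  For subsets with
#' nonzero net charge the value depends on the coordinate origin; choosing a
#' meaningful origin is the caller's responsibility.
#'
#' @param system a [particle_system].
#' @param subset integer indices (default: all particles).
#' @return length-3 numeric vector.
#' @export
dipole_moment <- function(system, subset = seq_len(system$n_particles)) {
  stopifnot(inherits(system, "particle_system"))
  subset <- as.integer(subset)
  if (length(subset) == 0) stop("subset must be nonempty")
  if (any(subset < 1 | subset > system$n_particles))
    stop("subset index out of range")
  colSums(system$positions[subset, , drop = FALSE] * system$charges[subset])
}

# ---------------------------------------------------------------------------
# residue templates and composition arithmetic for nucleic-acid systems
# ---------------------------------------------------------------------------

#' Residue template table for composition accounting
#'
#' Per-residue atom counts (hydrogens included) and formal charges for the
#' standard deoxyribonucleotides, three-site water, and monovalent ions,
#' following the usual nucleic-acid force-field residue definitions in which
#' each internal nucleotide carries one phosphate group (formal charge -1).
#' 5'-terminal residues lack the phosphate group (three fewer atoms, one
#' extra hydroxyl hydrogen: net -2 atoms, formal charge 0 relative
#' adjustment +1); 3'-terminal residues gain the terminal hydroxyl hydrogen
#' (+1 atom).
#'
#' @param overrides optional named list replacing individual entries.
#' @return A list of class `residue_template_table` with components `atoms`
#'   (named integer), `formal_charge` (named integer), `five_prime_delta`
#'   and `three_prime_delta` (atom-count adjustments), and
#'   `five_prime_charge_delta`.
#' @export
residue_templates <- function(overrides = NULL) {
  tab <- list(
    atoms = c(DA = 32L, DC = 30L, DG = 33L, DT = 32L,
              water = 3L, `Na+` = 1L, `Cl-` = 1L),
    formal_charge = c(DA = -1L, DC = -1L, DG = -1L, DT = -1L,
                      water = 0L, `Na+` = 1L, `Cl-` = -1L),
    five_prime_delta = -2L,    # lose PO2, gain hydroxyl H
    three_prime_delta = 1L,    # gain terminal hydroxyl H
    five_prime_charge_delta = 1L)
  if (!is.null(overrides)) tab <- modifyList(tab, overrides)
  if (any(tab$atoms <= 0)) stop("template atom counts must be positive")
  structure(tab, class = "residue_template_table")
}

dna_letter_to_residue <- function(sequence) {
  letters <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(letters, c("A", "C", "G", "T"))
  if (length(bad))
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  paste0("D", letters)
}

#' Atom count of a nucleic-acid box composition
#'
#' Sums residue-template atom counts over one or more DNA strands (with
#' 5'/3'-terminal adjustments applied per strand), plus three-site waters and
#' monatomic ions.
#'
#' @param sequence character vector of strand sequences over {A,C,G,T}
#'   (e.g. `rep("CGCGAATTCGCG", 2)` for a duplex).
#' @param n_waters,n_cations,n_anions non-negative counts.
#' @param templates a [residue_templates()] table.
#' @return Total atom count (integer).
#' @export
composition_count <- function(sequence, n_waters = 0, n_cations = 0,
                              n_anions = 0,
                              templates = residue_templates()) {
  stopifnot(n_waters >= 0, n_cations >= 0, n_anions >= 0)
  strand_atoms <- vapply(sequence, function(s) {
    if (nchar(s) == 0) return(0L)
    res <- dna_letter_to_residue(s)
    sum(templates$atoms[res]) + templates$five_prime_delta +
      templates$three_prime_delta
  }, integer(1))
  as.integer(sum(strand_atoms) +
               templates$atoms[["water"]] * n_waters +
               templates$atoms[["Na+"]] * n_cations +
               templates$atoms[["Cl-"]] * n_anions)
}

#' Formal charge of DNA strands from residue templates
#'
#' One negative phosphate per non-5'-terminal residue.
#'
#' @inheritParams composition_count
#' @return Integer formal charge.
#' @export
dna_formal_charge <- function(sequence, templates = residue_templates()) {
  sum(vapply(sequence, function(s) {
    if (nchar(s) == 0) return(0L)
    res <- dna_letter_to_residue(s)
    as.integer(sum(templates$formal_charge[res]) +
                 templates$five_prime_charge_delta)
  }, integer(1)))
}

#' Total nucleotide count across strands
#'
#' @param sequence character vector of strand sequences.
#' @return Integer count of residues over all strands.
#' @export
nucleotide_count <- function(sequence) {
  as.integer(sum(vapply(sequence, function(s) {
    if (nchar(s)) length(dna_letter_to_residue(s)) else 0L
  }, integer(1))))
}

#' Cation count needed to neutralize a polyanion box
#'
#' @param dna_formal_charge integer formal charge of the polyanion (<= 0).
#' @param n_anions number of added monovalent anions.
#' @return `abs(dna_formal_charge) + n_anions`.
#' @export
neutralizing_cation_count <- function(dna_formal_charge, n_anions = 0) {
  stopifnot(dna_formal_charge == round(dna_formal_charge),
            n_anions == round(n_anions), n_anions >= 0)
  out <- abs(dna_formal_charge) + n_anions
  if (dna_formal_charge > 0)
    stop("polyanion expected: formal charge must be <= 0")
  as.integer(out)
}
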