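# Trajectory container and structural/dynamical comparison metrics:
# least-squares superposition, rmsd traces, per-group rmsf, dynamic
# cross-correlation matrices, and Pearson agreement between two methods'
# profiles.

#' Multi-frame trajectory
#'
#' @param frames list of n x 3 position matrices (Angstrom), all with the
#'   same particle count.
#' @param times frame times in ps, strictly increasing (default 1, 2, ...).
#' @param topology the [particle_system] the frames belong to (optional but
#'   required by energy evaluation and group-based analysis).
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(frames, times = NULL, topology = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    stopifnot(ncol(f) == 3)
    f
  })
  n <- nrow(frames[[1]])
  if (!all(vapply(frames, nrow, integer(1)) == n))
    stop("all frames must have the same particle count")
  if (is.null(times)) times <- as.numeric(seq_along(frames))
  stopifnot(length(times) == length(frames))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (!is.null(topology)) {
    stopifnot(inherits(topology, "particle_system"))
    if (topology$n_particles != n)
      stop("topology particle count (", topology$n_particles,
           ") != frame particle count (", n, ")")
  }
  structure(list(frames = frames, times = as.numeric(times),
                 topology = topology),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$frames), "frames x",
      nrow(x$frames[[1]]), "particles, t =",
      format(x$times[1]), "...", format(x$times[length(x$times)]), "ps\n")
  invisible(x)
}

# frame indices inside a [start, end] time window; default final 70 %
window_frames <- function(traj, window = NULL) {
  t <- traj$times
  if (is.null(window)) {
    span <- t[length(t)] - t[1]
    window <- c(t[length(t)] - 0.7 * span, t[length(t)])
  }
  idx <- which(t >= window[1] & t <= window[2])
  if (length(idx) == 0) stop("empty analysis window")
  idx
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimizing the rmsd of
#' `atom_set` onto the reference, applies it to the whole frame, and
#' reports the post-fit rmsd over `atom_set`.  Reflections are excluded.
#'
#' @param frame,reference n x 3 position matrices.
#' @param atom_set indices used for the fit (>= 3 non-collinear atoms;
#'   default all).
#' @return List with `positions` (transformed full frame), `rmsd`
#'   (Angstrom), `rotation`, `translation`.
#' @export
superpose <- function(frame, reference, atom_set = NULL) {
  frame <- as.matrix(frame)
  reference <- as.matrix(reference)
  stopifnot(all(dim(frame) == dim(reference)))
  if (is.null(atom_set)) atom_set <- seq_len(nrow(frame))
  if (length(atom_set) < 3)
    stop("superposition needs at least 3 atoms")
  X <- frame[atom_set, , drop = FALSE]
  Y <- reference[atom_set, , drop = FALSE]
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx)
  Yc <- sweep(Y, 2, cy)
  if (svd(Xc)$d[2] < 1e-8 * max(svd(Xc)$d[1], 1))
    stop("degenerate (collinear or coincident) superposition atom set")
  H <- t(Xc) %*% Yc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)     # Y ~ (X - cx) R^T + cy
  fitted <- sweep(sweep(frame, 2, cx) %*% t(R), 2, cy, "+")
  rmsd <- sqrt(mean(rowSums((fitted[atom_set, , drop = FALSE] - Y)^2)))
  list(positions = fitted, rmsd = rmsd, rotation = R,
       translation = cy - as.numeric(cx %*% t(R)))
}

#' Per-frame rmsd from a reference structure
#'
#' Superposes every frame on the reference over `atom_set` and returns the
#' post-fit rmsd series.
#'
#' @param traj a [trajectory].
#' @param reference n x 3 reference positions (default: first frame).
#' @param atom_set fit/evaluation indices (default all).
#' @return Numeric vector, one rmsd (Angstrom) per frame.
#' @export
rmsd_trace <- function(traj, reference = NULL, atom_set = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(reference)) reference <- traj$frames[[1]]
  vapply(traj$frames, function(f)
    superpose(f, reference, atom_set)$rmsd, numeric(1))
}

# superpose all frames of a trajectory onto a reference (NULL set = as-is)
superpose_trajectory <- function(traj, superpose_set, reference = NULL) {
  if (is.null(superpose_set)) return(traj)
  if (is.null(reference)) reference <- traj$frames[[1]]
  traj$frames <- lapply(traj$frames, function(f)
    superpose(f, reference, superpose_set)$positions)
  traj
}

#' Per-group root-mean-square fluctuation
#'
#' For each group m: `sqrt( mean_{i in m} < |r_i - <r_i>|^2 > )` -- the
#' time variance of each atom about its window-mean position, averaged over
#' the group's atoms, then square-rooted.
#'
#' @param traj a [trajectory] (already superposed, or give
#'   `superpose_set`).
#' @param groups named list of atom index vectors.
#' @param window `c(start, end)` times in ps; default the final 70 % of
#'   the trajectory.
#' @param superpose_set if non-NULL, frames are first superposed on
#'   `reference` (default: first frame) over these atoms.
#' @param reference reference positions for the superposition.
#' @return Named numeric vector of rmsf values (Angstrom).
#' @export
rmsf <- function(traj, groups, window = NULL, superpose_set = NULL,
                 reference = NULL) {
  stopifnot(inherits(traj, "trajectory"), length(groups) >= 1)
  if (any(lengths(groups) == 0)) stop("empty group")
  traj <- superpose_trajectory(traj, superpose_set, reference)
  idx <- window_frames(traj, window)
  arr <- simplify2array(traj$frames[idx])      # n x 3 x frames
  mean_pos <- apply(arr, c(1, 2), mean)
  msf <- apply((arr - array(mean_pos, dim(arr)))^2, 1, mean) * 3
  # msf above: mean over (3 coords x frames) of squared dev, times 3
  vapply(groups, function(g) sqrt(mean(msf[g])), numeric(1))
}

#' Dynamic cross-correlation matrix of group displacements
#'
#' `C_ij = <dR_i . dR_j> / sqrt(<|dR_i|^2> <|dR_j|^2>)` where `dR_i` is the
#' displacement of group i's representative position from its window mean.
#' `mode = "center"` (default) uses the geometric centre of each group per
#' frame; `mode = "atom_pairs"` averages the displacement dot products over
#' all atom pairs of the two groups before normalizing.
#'
#' @inheritParams rmsf
#' @param mode `"center"` or `"atom_pairs"`.
#' @return Symmetric matrix with unit diagonal and entries in `[-1, 1]`;
#'   rows/columns of zero-variance groups are `NA` and flagged in the
#'   `"undefined_groups"` attribute.
#' @export
cross_correlation <- function(traj, groups, window = NULL,
                              superpose_set = NULL, reference = NULL,
                              mode = c("center", "atom_pairs")) {
  mode <- match.arg(mode)
  stopifnot(inherits(traj, "trajectory"), length(groups) >= 2)
  traj <- superpose_trajectory(traj, superpose_set, reference)
  idx <- window_frames(traj, window)
  if (length(idx) < 2) stop("need at least 2 frames in the window")
  ng <- length(groups)
  nf <- length(idx)
  if (mode == "center") {
    # centers: frames x (3 ng)
    cen <- t(vapply(traj$frames[idx], function(f)
      as.numeric(vapply(groups, function(g)
        colMeans(f[g, , drop = FALSE]), numeric(3))), numeric(3 * ng)))
    cen <- sweep(cen, 2, colMeans(cen))
    cov <- matrix(0, ng, ng)
    for (i in seq_len(ng)) {
      ii <- (i - 1) * 3 + 1:3
      for (j in i:ng) {
        jj <- (j - 1) * 3 + 1:3
        cov[i, j] <- cov[j, i] <- mean(rowSums(cen[, ii, drop = FALSE] *
                                                 cen[, jj, drop = FALSE]))
      }
    }
  } else {
    arr <- simplify2array(traj$frames[idx])
    mean_pos <- apply(arr, c(1, 2), mean)
    dev <- arr - array(mean_pos, dim(arr))     # n x 3 x frames
    cov <- matrix(0, ng, ng)
    for (i in seq_len(ng)) {
      gi <- groups[[i]]
      for (j in i:ng) {
        gj <- groups[[j]]
        acc <- 0
        for (f in seq_len(nf)) {
          di <- dev[gi, , f, drop = FALSE]
          dj <- dev[gj, , f, drop = FALSE]
          acc <- acc + sum(di[, 1, ] %o% dj[, 1, ] + di[, 2, ] %o% dj[, 2, ]
                           + di[, 3, ] %o% dj[, 3, ])
        }
        cov[i, j] <- cov[j, i] <- acc / (nf * length(gi) * length(gj))
      }
    }
  }
  v <- diag(cov)
  undef <- which(v <= 0 | !is.finite(v))
  C <- cov / sqrt(outer(v, v))
  C[undef, ] <- NA_real_
  C[, undef] <- NA_real_
  diag(C)[setdiff(seq_len(ng), undef)] <- 1
  C <- pmin(pmax(C, -1), 1)
  dim(C) <- c(ng, ng)
  dimnames(C) <- list(names(groups), names(groups))
  attr(C, "undefined_groups") <- names(groups)[undef]
  C
}

#' Pearson agreement between two profiles
#'
#' Standard Pearson correlation between two equal-length numeric profiles
#' (rmsf vectors, or flattened off-diagonal cross-correlation entries).
#'
#' @param profile_a,profile_b numeric vectors of length >= 3.
#' @return Pearson correlation coefficient.
#' @export
method_agreement <- function(profile_a, profile_b) {
  stopifnot(length(profile_a) == length(profile_b),
            length(profile_a) >= 3)
  if (sd(profile_a) == 0 || sd(profile_b) == 0)
    stop("zero variance in a profile: Pearson correlation undefined")
  cor(profile_a, profile_b)
}

#' Off-diagonal entries of a square matrix as a vector
#'
#' Helper to compare two cross-correlation matrices with
#' [method_agreement()].
#'
#' @param C square matrix.
#' @return Upper-triangle entries (excluding the diagonal).
#' @export
offdiag <- function(C) C[upper.tri(C)]
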