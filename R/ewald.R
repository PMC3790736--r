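# Plain Ewald summation under conducting (tinfoil) boundary conditions:
# real-space erfc sum + reciprocal-space Fourier sum + self term
# (+ erf-kernel exclusion corrections).  This is the package's trusted
# reference for all deviation measurements; its primary correctness check is
# invariance of the total under changes of the splitting parameter.

#' Ewald summation parameters
#'
#' The splitting parameter `alpha_split` (distinct from the damping factor
#' of the cutoff kernels) and the reciprocal-space bound `kmax` are
#' auto-tuned from the real-space cutoff and the target relative accuracy
#' when not given: `alpha_split` is set so that
#' `erfc(alpha_split * r_real)` matches the target (at least `3/r_real`),
#' and `kmax` per axis so the neglected Gaussian reciprocal weight does too.
#'
#' @param r_real real-space cutoff, Angstrom (must be <= half the shortest
#'   box edge at evaluation time).
#' @param alpha_split Ewald splitting parameter, 1/Angstrom, or `NULL` to
#'   auto-tune.
#' @param kmax integer reciprocal bound per axis (length 1 or 3), or `NULL`
#'   to auto-tune from the box.
#' @param accuracy target relative accuracy of the tails.
#' @param background apply the uniform background-charge correction for
#'   non-neutral cells (otherwise such systems are rejected)?
#' @return List of class `ewald_params`.
#' @export
ewald_params <- function(r_real = 12, alpha_split = NULL, kmax = NULL,
                         accuracy = 1e-8, background = FALSE) {
  stopifnot(r_real > 0, accuracy > 0)
  structure(list(r_real = r_real, alpha_split = alpha_split, kmax = kmax,
                 accuracy = accuracy, background = background),
            class = "ewald_params")
}

resolve_ewald <- function(params, box) {
  p <- params
  if (is.null(p$alpha_split)) {
    # erfc(x) ~ exp(-x^2): solve exp(-(a rc)^2) = accuracy, floor 3/rc
    p$alpha_split <- max(3, sqrt(-log(p$accuracy))) / p$r_real
  }
  if (is.null(p$kmax)) {
    # neglect exp(-k^2 / 4a^2) below accuracy: k_cut = 2 a sqrt(-log(acc))
    kcut <- 2 * p$alpha_split * sqrt(-log(p$accuracy))
    p$kmax <- pmax(1L, as.integer(ceiling(kcut * box / (2 * pi))))
  }
  if (length(p$kmax) == 1) p$kmax <- rep(as.integer(p$kmax), 3)
  p
}

#' Ewald electrostatic energy
#'
#' @param system a periodic, neutral [particle_system] (non-neutral systems
#'   need `background = TRUE` in the parameters).
#' @param params an [ewald_params()] object.
#' @return An `energy_report` with real / reciprocal / self / exclusion
#'   components and a per-atom decomposition (the reciprocal part is
#'   attributed through each particle's structure-factor contribution).
#' @export
ewald_energy <- function(system, params = ewald_params()) {
  res <- ewald_call(system, params, want_forces = FALSE)
  cfg <- electro_config("ewald", r_c = params$r_real, ewald = params)
  new_energy_report(res, cfg, system$n_particles)
}

#' @rdname ewald_energy
#' @export
ewald_forces <- function(system, params = ewald_params()) {
  ewald_call(system, params, want_forces = TRUE)$forces
}

ewald_call <- function(system, params, want_forces) {
  stopifnot(inherits(system, "particle_system"),
            inherits(params, "ewald_params"))
  if (is.null(system$box))
    stop("Ewald summation requires a periodic box; ",
         "use direct_cluster_energy() for open clusters")
  if (!params$background && abs(net_charge(system)) > 1e-9)
    stop("system is not neutral (net charge ", net_charge(system),
         "); enable the background correction or neutralize")
  p <- resolve_ewald(params, system$box)
  if (p$r_real > min(system$box) / 2)
    stop("Ewald real-space cutoff exceeds half the shortest box edge")
  ex <- excl_args(system)
  cpp_ewald(system$positions, system$charges, system$box, p$alpha_split,
            p$r_real, p$kmax, ex$idx, ex$w, K_COULOMB, want_forces,
            p$background)
}

#' Direct Coulomb energy of an open cluster
#'
#' Brute-force pair sum `kC * sum_{i<j} w_ij q_i q_j / r_ij` over all
#' (non-excluded, possibly 1-4 scaled) pairs; the exact reference for open
#' boundaries.
#'
#' @param system an open (non-periodic) [particle_system].
#' @return An `energy_report`.
#' @export
direct_cluster_energy <- function(system) {
  stopifnot(inherits(system, "particle_system"))
  if (!is.null(system$box))
    stop("direct_cluster_energy is for open clusters; use ewald_energy ",
         "for periodic systems")
  ex <- excl_args(system)
  res <- cpp_direct(system$positions, system$charges, ex$idx, ex$w,
                    K_COULOMB, FALSE)
  res$pair <- res$total
  cfg <- structure(list(method = "direct", coulomb = K_COULOMB),
                   class = "electro_config")
  new_energy_report(res, cfg, system$n_particles)
}

#' @rdname direct_cluster_energy
#' @export
direct_cluster_forces <- function(system) {
  stopifnot(inherits(system, "particle_system"), is.null(system$box))
  ex <- excl_args(system)
  cpp_direct(system$positions, system$charges, ex$idx, ex$w, K_COULOMB,
             TRUE)$forces
}
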