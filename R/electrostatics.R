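# Cutoff-based electrostatic evaluators.
#
# The zero-dipole (ZD) kernel is the bare/damped Coulomb potential completed
# by the quadratic and constant terms fixed by smooth truncation,
#
#     u(r) = erfc(a r)/r + A r^2 + B,   u(rc) = 0,  u'(rc) = 0,
#
# which at a = 0 reduces to 1/r + r^2/(2 rc^3) - 3/(2 rc).  The completion
# terms are exactly what a charge- and dipole-neutral completion of each
# truncated interaction sphere contributes, so for a neutral zero-dipole
# cluster inside the cutoff the ZD energy (pair sum plus its self term)
# reproduces the direct Coulomb sum to machine precision.  The per-particle
# self coefficient is B/2 - a/sqrt(pi): the completion's own-site constant,
# halved like any pair term, plus the damping self-energy.
#
# The zero-charge Wolf kernel keeps only the constant (charge) completion,
# erfc(a r)/r - erfc(a rc)/rc, with self coefficient
# -erfc(a rc)/(2 rc) - a/sqrt(pi).  The shifted-force kernel
# 1/r - 1/rc + (r - rc)/rc^2 is purely pairwise (no self term).  RESA is the
# residue-based cutoff of the bare Coulomb potential.

#' Electrostatics configuration
#'
#' @param method one of `"zd"`, `"wolf"`, `"shifted_force"`, `"resa"`,
#'   `"ewald"`.
#' @param r_c cutoff distance, Angstrom (for `"ewald"` this is the
#'   real-space cutoff of [ewald_params()]).
#' @param alpha damping factor, 1/Angstrom, >= 0.
#' @param cutoff_mode `"atom_based"` (default for zd/wolf/shifted_force) or
#'   `"residue_based"` (forced for resa).
#' @param coulomb Coulomb constant (default [K_COULOMB]).
#' @param ewald an [ewald_params()] object, used when `method = "ewald"`.
#' @return A list of class `electro_config`.
#' @export
electro_config <- function(method = c("zd", "wolf", "shifted_force", "resa",
                                      "ewald"),
                           r_c = 12, alpha = 0, cutoff_mode = NULL,
                           coulomb = K_COULOMB, ewald = NULL) {
  method <- match.arg(method)
  if (!is.finite(r_c) || r_c <= 0) stop("r_c must be positive")
  if (!is.finite(alpha) || alpha < 0) stop("alpha must be >= 0")
  if (is.null(cutoff_mode))
    cutoff_mode <- if (method == "resa") "residue_based" else "atom_based"
  if (method == "resa" && cutoff_mode != "residue_based")
    stop("resa is residue-based by definition")
  structure(list(method = method, r_c = r_c, alpha = alpha,
                 cutoff_mode = cutoff_mode, coulomb = coulomb,
                 ewald = ewald),
            class = "electro_config")
}

#' Zero-dipole completion coefficients
#'
#' Coefficients A (quadratic) and B (constant) of the ZD kernel and the
#' per-particle self coefficient, for damping `alpha` and cutoff `r_c`.
#'
#' @inheritParams electro_config
#' @return List with `A`, `B`, `self`.
#' @export
zd_coefficients <- function(alpha, r_c) {
  f <- erfc(alpha * r_c) / r_c
  df <- -erfc(alpha * r_c) / r_c^2 -
    (2 * alpha / sqrt(pi)) * exp(-alpha^2 * r_c^2) / r_c
  A <- -df / (2 * r_c)
  B <- -f - A * r_c^2
  list(A = A, B = B, self = B / 2 - alpha / sqrt(pi))
}

erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' Pairwise electrostatic kernels
#'
#' `zd_pair_potential()` evaluates the reconstructed ZD kernel u(r) (in 1/
#' Angstrom, before multiplication by the Coulomb constant);
#' `wolf_pair_potential()` and `sf_pair_potential()` the zero-charge Wolf
#' and shifted-force kernels.  All vanish at `r_c`; the ZD and
#' shifted-force derivatives vanish there too.
#'
#' @param r distance(s), 0 < r <= r_c.
#' @param alpha damping factor (1/Angstrom); ignored by `sf_pair_potential`.
#' @param r_c cutoff (Angstrom).
#' @return Kernel value(s).
#' @export
zd_pair_potential <- function(r, alpha, r_c) {
  check_kernel_r(r, r_c)
  co <- zd_coefficients(alpha, r_c)
  erfc(alpha * r) / r + co$A * r^2 + co$B
}

#' @rdname zd_pair_potential
#' @export
wolf_pair_potential <- function(r, alpha, r_c) {
  check_kernel_r(r, r_c)
  erfc(alpha * r) / r - erfc(alpha * r_c) / r_c
}

#' @rdname zd_pair_potential
#' @export
sf_pair_potential <- function(r, r_c) {
  check_kernel_r(r, r_c)
  1 / r - 1 / r_c + (r - r_c) / r_c^2
}

check_kernel_r <- function(r, r_c) {
  if (any(r <= 0)) stop("r must be positive")
  if (any(r > r_c * (1 + 1e-12))) stop("r exceeds the cutoff r_c")
}

method_code <- function(method)
  switch(method, zd = 1L, wolf = 2L, shifted_force = 3L,
         stop("no pairwise kernel code for method '", method, "'"))

check_cutoff_box <- function(system, r_c) {
  if (!is.null(system$box) && r_c > min(system$box) / 2)
    stop("r_c = ", r_c, " exceeds half the shortest box edge (",
         min(system$box) / 2, "): minimum image is ambiguous")
}

excl_args <- function(system) {
  ex <- rbind(system$exclusions, system$scaled_pairs)
  w <- c(rep(0, nrow(system$exclusions)),
         rep(system$scale14, nrow(system$scaled_pairs)))
  list(idx = matrix(as.integer(ex - 1L), ncol = 2), w = w)
}

new_energy_report <- function(res, config, n) {
  rep <- list(total = res$total, per_atom = as.numeric(res$per_atom),
              components = res[setdiff(names(res),
                                       c("total", "per_atom", "forces"))],
              config = config)
  class(rep) <- "energy_report"
  rep
}

#' @export
print.energy_report <- function(x, ...) {
  cat("energy_report [", x$config$method, "]: total =",
      format(x$total, digits = 10), "kcal/mol\n  components:",
      paste(names(x$components),
            vapply(x$components, function(v) format(v, digits = 6),
                   character(1)),
            sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Electrostatic energy of a particle system
#'
#' Dispatches on `config$method` to the zero-dipole, Wolf, shifted-force,
#' RESA or Ewald evaluator.  Every report carries a per-atom decomposition
#' in which each pair energy is split half to each partner, so the per-atom
#' values sum exactly to the total.
#'
#' @param system a [particle_system].
#' @param config an [electro_config()].
#' @return An `energy_report`: `total` (kcal/mol), `per_atom`, `components`
#'   (pair / self / exclusion subtotals), `config`.
#' @export
electro_energy <- function(system, config) {
  stopifnot(inherits(system, "particle_system"),
            inherits(config, "electro_config"))
  switch(config$method,
         zd = zd_energy(system, config),
         wolf = wolf_energy(system, config),
         shifted_force = shifted_force_energy(system, config),
         resa = resa_energy(system, config),
         ewald = ewald_energy(system, config$ewald %||%
                                ewald_params(r_real = config$r_c)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pairwise_energy <- function(system, config, want_forces = FALSE) {
  check_cutoff_box(system, config$r_c)
  ex <- excl_args(system)
  res <- cpp_pair_electro(system$positions, system$charges,
                          system$box %||% numeric(0), config$r_c,
                          config$alpha, method_code(config$method),
                          ex$idx, ex$w, config$coulomb, want_forces)
  if (want_forces) return(res$forces)
  new_energy_report(res, config, system$n_particles)
}

#' @rdname electro_energy
#' @export
zd_energy <- function(system, config = electro_config("zd")) {
  stopifnot(config$method == "zd")
  pairwise_energy(system, config)
}

#' @rdname electro_energy
#' @export
wolf_energy <- function(system, config = electro_config("wolf")) {
  stopifnot(config$method == "wolf")
  pairwise_energy(system, config)
}

#' @rdname electro_energy
#' @export
shifted_force_energy <- function(system,
                                 config = electro_config("shifted_force")) {
  stopifnot(config$method == "shifted_force")
  pairwise_energy(system, config)
}

#' @rdname electro_energy
#' @export
resa_energy <- function(system, config = electro_config("resa")) {
  stopifnot(config$method == "resa")
  if (is.null(system$residue_id)) stop("resa requires residue assignments")
  check_cutoff_box(system, config$r_c)
  ex <- excl_args(system)
  res0 <- match(system$residue_id, unique(system$residue_id)) - 1L
  res <- cpp_resa(system$positions, system$charges,
                  system$box %||% numeric(0), config$r_c, res0,
                  ex$idx, ex$w, config$coulomb, FALSE)
  new_energy_report(res, config, system$n_particles)
}

#' Electrostatic forces
#'
#' Analytic negative gradient of the configured electrostatic energy,
#' kcal/mol/Angstrom.  For the ZD and shifted-force kernels the force is
#' continuous (zero) at the cutoff; the Wolf force jumps there; RESA
#' inherits the group-membership discontinuities of its energy (membership
#' changes are not differentiated).
#'
#' @inheritParams electro_energy
#' @return n x 3 numeric matrix.
#' @export
electro_forces <- function(system, config) {
  stopifnot(inherits(system, "particle_system"),
            inherits(config, "electro_config"))
  if (config$method %in% c("zd", "wolf", "shifted_force"))
    return(pairwise_energy(system, config, want_forces = TRUE))
  if (config$method == "resa") {
    check_cutoff_box(system, config$r_c)
    ex <- excl_args(system)
    res0 <- match(system$residue_id, unique(system$residue_id)) - 1L
    return(cpp_resa(system$positions, system$charges,
                    system$box %||% numeric(0), config$r_c, res0,
                    ex$idx, ex$w, config$coulomb, TRUE)$forces)
  }
  ewald_forces(system, config$ewald %||% ewald_params(r_real = config$r_c))
}
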