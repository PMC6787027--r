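#' Thermal energy constants
#'
#' Free energies are handled per mole, so the thermal energy is realized as
#' the molar gas constant R = 8.314 J mol^-1 K^-1 times the temperature:
#' 2.5773 kJ/mol at the default 310 K.
#'
#' @param temperature temperature in kelvin.
#' @return list with elements `temperature` (K) and `kT` (kJ/mol).
#' @examples
#' thermo_constants()$kT
#' @export
thermo_constants <- function(temperature = 310) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    stop("temperature must be a single positive number (kelvin)",
         call. = FALSE)
  list(temperature = temperature, kT = 8.314e-3 * temperature)
}

#' Boltzmann two-state frameshifting efficiency
#'
#' `fs_from_dg()` maps a total free-energy difference between the -1-frame
#' and the 0-frame onto the equilibrium frameshifting efficiency,
#' FS = exp(-dG/kT) / (1 + exp(-dG/kT)) = 1 / (1 + exp(dG/kT)),
#' evaluated in the overflow-safe logistic form.  `dg_from_fs()` is its
#' exact inverse, dG = -kT log(FS / (1 - FS)).  FS = 0 or 1 carries no
#' finite free energy (such measurements only bound dG) and is rejected.
#'
#' @param dg free-energy difference G(-1) - G(0) in kJ/mol.
#' @param fs frameshifting efficiency as a fraction in (0, 1).
#' @param constants see [thermo_constants()].
#' @return `fs_from_dg()`: fractions in (0, 1); `dg_from_fs()`: kJ/mol.
#' @examples
#' fs_from_dg(0)            # 0.5: frames equally likely
#' fs_from_dg(2.2)          # ~0.30
#' dg_from_fs(0.8)          # ~-3.57 kJ/mol
#' @export
fs_from_dg <- function(dg, constants = thermo_constants()) {
  stopifnot(is.numeric(dg))
  if (any(!is.finite(dg)))
    stop("dg must be finite", call. = FALSE)
  stats::plogis(-dg / constants$kT)
}

#' @rdname fs_from_dg
#' @export
dg_from_fs <- function(fs, constants = thermo_constants()) {
  stopifnot(is.numeric(fs))
  if (any(!is.finite(fs)) || any(fs <= 0) || any(fs >= 1))
    stop("fs must lie strictly inside (0, 1); FS values of exactly 0 or 1 ",
         "only bound the free-energy difference and have no finite inverse",
         call. = FALSE)
  -constants$kT * log(fs / (1 - fs))
}

#' Total free-energy difference of a variant
#'
#' Sum of the signed per-change free energies selected by one design-matrix
#' row: sum_j M_ij * dG_bp_j.
#'
#' @param row signed integer incidence vector (a design-matrix row).
#' @param dg_bp free-energy differences per change variable, kJ/mol.
#' @return kJ/mol.
#' @examples
#' total_dg(c(1, 1), c(5.1, -2.9))  # 2.2
#' @export
total_dg <- function(row, dg_bp) {
  if (length(row) != length(dg_bp))
    stop("row and dg_bp must have the same length", call. = FALSE)
  sum(row * dg_bp)
}

#' Kinetic factor of incomplete frame equilibration
#'
#' When the ribosome pause is too short for the tRNAs to equilibrate
#' between frames, the observed efficiency falls below the equilibrium
#' value: FS_kinetic = FS * (1 - kappa).  The kinetic factor follows from
#' a two-state master equation with Arrhenius rates over a barrier,
#' kappa = exp(-C * (1 + exp(dG/kT))), where C lumps attempt frequency,
#' pause duration and barrier height into a single nonnegative parameter.
#' `kappa_of_c()` evaluates kappa; `fs_kinetic()` applies it;
#' `solve_c_for_mean_kappa()` inverts the strictly decreasing map from C
#' to the mean kappa over a set of variants (bisection, relative
#' tolerance 1e-10).
#'
#' @param big_c nonnegative kinetic parameter C.
#' @param dg free-energy difference(s), kJ/mol.
#' @param fs equilibrium efficiency (fraction).
#' @param kappa kinetic factor(s) in [0, 1].
#' @param mean_kappa target mean kinetic factor, strictly inside (0, 1).
#' @param constants see [thermo_constants()].
#' @return `kappa_of_c()`: kinetic factors in [0, 1]; `fs_kinetic()`:
#'   fractions; `solve_c_for_mean_kappa()`: the parameter C.
#' @examples
#' kappa_of_c(1, 0)                       # exp(-2)
#' fs_kinetic(0.5, 0.1)                   # 0.45
#' solve_c_for_mean_kappa(exp(-2), 0)     # 1
#' @export
kappa_of_c <- function(big_c, dg, constants = thermo_constants()) {
  if (any(big_c < 0))
    stop("big_c must be nonnegative", call. = FALSE)
  exp(-big_c * (1 + exp(dg / constants$kT)))
}

#' @rdname kappa_of_c
#' @export
fs_kinetic <- function(fs, kappa) {
  if (any(kappa < 0 | kappa > 1))
    stop("kappa must lie in [0, 1]", call. = FALSE)
  fs * (1 - kappa)
}

#' @rdname kappa_of_c
#' @export
solve_c_for_mean_kappa <- function(mean_kappa, dg,
                                   constants = thermo_constants()) {
  if (length(mean_kappa) != 1L || !is.finite(mean_kappa))
    stop("mean_kappa must be a single finite number", call. = FALSE)
  if (mean_kappa <= 0 || mean_kappa >= 1)
    stop("mean_kappa must lie strictly inside (0, 1): the limits ",
         "correspond to the degenerate C = Inf and C = 0", call. = FALSE)
  solve_c_cpp(mean_kappa, as.numeric(dg), constants$kT)
}
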