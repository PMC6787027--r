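# truncated-Gaussian replicate noise: resample draws outside the open
# efficiency interval rather than clipping, so no point mass accumulates
# at the boundaries
truncnorm_fs <- function(mean_fs, sigma, lower = 0.001, upper = 0.999) {
  out <- stats::rnorm(length(mean_fs), mean_fs, sigma)
  bad <- which(out < lower | out > upper)
  guard <- 0
  while (length(bad) && guard < 10000) {
    out[bad] <- stats::rnorm(length(bad), mean_fs[bad], sigma[bad])
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1
  }
  if (length(bad)) out[bad] <- pmin(pmax(mean_fs[bad], lower), upper)
  out
}

#' Simulate a frameshifting dataset from known free energies
#'
#' Generates measured-looking efficiencies for a variant design from
#' ground-truth per-change free energies: FS_i = logistic model of the
#' design row's total free energy, times (1 - kappa_i) when a nonzero
#' mean kinetic factor is requested, plus Gaussian replicate noise of sd
#' `sigma`, truncated to [0.001, 0.999] by resampling.  The default
#' noise of 2 percentage points matches the replicate scatter of typical
#' in-vitro frameshifting assays.
#'
#' @param variants `fs_variants` design (efficiencies are overwritten).
#' @param dg_true named numeric vector of true free-energy differences,
#'   kJ/mol; names are canonical change-variable labels and define the
#'   registry of the simulation.
#' @param kappa_bar true mean kinetic factor over the design (0 =
#'   equilibrium).
#' @param sigma replicate noise sd (fraction), scalar or per-variant.
#' @param seed integer seed; same seed, same dataset.
#' @param constants see [thermo_constants()].
#' @return the `variants` table with `fs` and `sigma` filled in; the
#'   truth is attached as `attr(, "truth")` (list `dg_true`,
#'   `kappa_bar`, `sigma`, `seed`).
#' @examples
#' design <- enumerate_invitro_design()
#' truth <- setNames(seq(-3, 3, length.out = 16), invitro_registry())
#' dat <- simulate_fs_dataset(design, truth, seed = 1)
#' @export
simulate_fs_dataset <- function(variants, dg_true, kappa_bar = 0,
                                sigma = 0.02, seed = 1,
                                constants = thermo_constants()) {
  if (is.null(names(dg_true)))
    stop("dg_true must be named by change-variable label", call. = FALSE)
  if (any(sigma <= 0))
    stop("sigma must be > 0", call. = FALSE)
  if (kappa_bar < 0 || kappa_bar >= 1)
    stop("kappa_bar must lie in [0, 1)", call. = FALSE)
  registry <- normalize_label(names(dg_true))
  design <- build_design_matrix(variants, registry)
  dgtot <- as.numeric(design %*% dg_true)
  fs <- fs_from_dg(dgtot, constants)
  if (kappa_bar > 0) {
    kap <- kappa_of_c(solve_c_for_mean_kappa(kappa_bar, dgtot, constants),
                      dgtot, constants)
    fs <- fs_kinetic(fs, kap)
  }
  sigma <- rep_len(sigma, nrow(variants))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  variants$fs <- truncnorm_fs(fs, sigma)
  variants$sigma <- sigma
  attr(variants, "truth") <- list(dg_true = stats::setNames(as.numeric(dg_true),
                                                            registry),
                                  kappa_bar = kappa_bar, sigma = sigma,
                                  seed = seed)
  variants
}

#' Built-in dnaX slippery-site fixtures
#'
#' Returns, without any download: (a) the programmatically enumerated
#' 64-variant Lys/Phe design (`design`); (b) the subset of in-vitro
#' efficiencies quoted in the main text of the study this model family
#' comes from — wild type A1 AAA4 AAG7 about 0.80, its A1G mutant 0.28,
#' A4G 0.44, the frame-degenerate A1 AAA4 AAA7 and U1 UUU4 UUU7 about
#' 0.50, G1/C1 AAG4 AAG7 0.08-0.09 and C1 AAG4 AAA7 about 0.02
#' (`invitro_subset`; replicate sd not quoted per variant, set to the
#' typical 0.02); and (c) the 26-variable change registry of the
#' published in-vivo dnaX catalog (`tsuchihashi_registry`).  The full
#' 64-value and 21-value measurement tables are not public data files
#' and must be supplied by the user (see [read_variant_table()]).
#'
#' @return list with elements `design`, `invitro_subset`,
#'   `tsuchihashi_registry`.
#' @examples
#' dnax_fixtures()$invitro_subset
#' @export
dnax_fixtures <- function() {
  subset_path <- system.file("extdata", "dnax_invitro_subset.tsv",
                             package = "fsthermo")
  list(design = enumerate_invitro_design(),
       invitro_subset = read_variant_table(subset_path),
       tsuchihashi_registry = tsuchihashi_registry())
}
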