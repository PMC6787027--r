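#' Gaussian log-likelihood of measured frameshifting efficiencies
#'
#' Independent Gaussian measurement errors per variant:
#' sum_i [ -1/2 log(2 pi sigma_i^2) - (FS_exp_i - FS_model_i)^2 /
#' (2 sigma_i^2) ], with FS_model_i the Boltzmann two-state efficiency of
#' the variant's total free-energy difference, optionally reduced by a
#' per-variant kinetic factor.
#'
#' @param fs_exp measured efficiencies (fractions).
#' @param sigma_exp replicate standard deviations, all > 0.
#' @param dg_bp free-energy difference per change variable, kJ/mol.
#' @param design signed design matrix (variants x variables).
#' @param kappa optional per-variant kinetic factors in [0, 1].
#' @param constants see [thermo_constants()].
#' @return log-likelihood (single number).
#' @export
log_likelihood <- function(fs_exp, sigma_exp, dg_bp, design, kappa = NULL,
                           constants = thermo_constants()) {
  if (any(sigma_exp <= 0))
    stop("sigma_exp must be strictly positive", call. = FALSE)
  if (length(fs_exp) != nrow(design) || length(sigma_exp) != nrow(design) ||
      length(dg_bp) != ncol(design))
    stop("dimensions of data, design and dg_bp disagree", call. = FALSE)
  fs_model <- fs_from_dg(as.numeric(design %*% dg_bp), constants)
  if (!is.null(kappa)) fs_model <- fs_kinetic(fs_model, kappa)
  sum(-0.5 * log(2 * pi * sigma_exp^2) -
        (fs_exp - fs_model)^2 / (2 * sigma_exp^2))
}

#' Uniform box log-prior on the free-energy differences
#'
#' Unnormalized: 0 inside the closed box `[prior[1], prior[2]]` in every
#' component, -Inf outside.
#'
#' @param dg_bp free-energy differences, kJ/mol.
#' @param prior length-2 numeric, lower and upper bound in kJ/mol.
#' @return 0 or -Inf.
#' @export
log_prior <- function(dg_bp, prior = c(-25, 25)) {
  if (all(dg_bp >= prior[1] & dg_bp <= prior[2])) 0 else -Inf
}

# Pure-R Metropolis-within-Gibbs reference sampler.  Consumes R's RNG
# stream in the same order as the compiled sampler (per sub-step: one
# Gaussian proposal, then one acceptance uniform; out-of-box proposals are
# rejected after the uniform is drawn), so with the same seed both produce
# identical trajectories on the same target.  Kept as an independent,
# readable oracle; not exported.
metropolis_reference <- function(log_post, init, n_steps,
                                 proposal_sigma = 0.2,
                                 prior = c(-25, 25),
                                 pinned = rep(FALSE, length(init))) {
  n <- length(init)
  x <- init
  lp <- log_post(x)
  out <- matrix(NA_real_, n_steps, n)
  for (s in seq_len(n_steps)) {
    for (j in seq_len(n)) {
      if (pinned[j]) next
      prop <- stats::rnorm(1, x[j], proposal_sigma)
      u <- stats::runif(1)
      if (prop < prior[1] || prop > prior[2]) next
      xn <- x
      xn[j] <- prop
      lpn <- log_post(xn)
      if (log(u) <= lpn - lp) {
        x <- xn
        lp <- lpn
      }
    }
    out[s, ] <- x
  }
  out
}

#' Fit base-pair free-energy differences to frameshifting efficiencies
#'
#' Samples the Bayesian posterior of the per-change free-energy
#' differences given measured frameshifting efficiencies, using a
#' Metropolis-within-Gibbs random walk: each step makes one sequential
#' Gaussian proposal per free variable (sd `proposal_sigma`), accepted
#' with probability min(1, ratio of likelihood x prior).  All free
#' energies start at 0 kJ/mol; the prior is uniform on the closed box
#' `prior` kJ/mol.  With `kinetic = TRUE` the mean kinetic factor over
#' variants is sampled alongside as a nuisance parameter (uniform prior
#' on [0, 1], Gaussian proposals of sd `kappa_proposal_sigma`); at every
#' likelihood evaluation the lumped kinetic parameter C is re-solved so
#' that the per-variant kinetic factors average to the current value.
#'
#' Chains c = 1..`n_chains` are seeded with `seed + c - 1`; runs with the
#' same seed are bit-reproducible.  Summaries discard the first
#' `burn_in` fraction of each chain and pool the rest across chains.
#'
#' @param variants `fs_variants` table with measured `fs` and `sigma`
#'   (fractions); see [variant_table()].  Rows without `fs` are dropped
#'   with a warning.  `sigma` values of 0 are floored at 0.005 with a
#'   warning (the Gaussian likelihood is undefined at sigma = 0 and
#'   replicate scatter below half a percentage point is beyond the
#'   assay's resolution).
#' @param registry canonical change-variable labels; defaults to the 16
#'   variables of the Lys/Phe design ([invitro_registry()]).
#' @param n_steps Metropolis steps per chain.
#' @param n_chains number of independent chains.
#' @param proposal_sigma Gaussian proposal sd, kJ/mol.
#' @param prior uniform prior box, kJ/mol.
#' @param burn_in fraction of each chain discarded before summarizing.
#' @param kinetic sample the mean kinetic factor as a nuisance parameter.
#' @param kappa_proposal_sigma proposal sd for the mean kinetic factor.
#' @param kappa_init initial mean kinetic factor (0.01; exactly 0 makes
#'   the kinetic parameter C degenerate).
#' @param pin labels of variables pinned to 0 kJ/mol (identifiability
#'   analysis); see [pin_and_refit()].
#' @param seed integer seed for the first chain.
#' @param temperature kelvin.
#' @return object of class `fs_fit` with components `chains` (list of
#'   per-chain sample matrices), `kappa_chains`, `design`, `variants`,
#'   `labels`, `accept` (acceptance rates), `config`, and `posterior`
#'   (pooled summary data.frame, see [posterior_summary()]).
#' @examples
#' \donttest{
#' design <- enumerate_invitro_design()
#' truth <- setNames(rep(c(4, -2), 8), invitro_registry())
#' dat <- simulate_fs_dataset(design, truth, seed = 1)
#' fit <- fs_fit(dat, n_steps = 2000, seed = 1)
#' coef(fit)
#' }
#' @export
fs_fit <- function(variants, registry = invitro_registry(),
                   n_steps = 1e6, n_chains = 2, proposal_sigma = 0.2,
                   prior = c(-25, 25), burn_in = 0.2, kinetic = FALSE,
                   kappa_proposal_sigma = 0.001, kappa_init = 0.01,
                   pin = character(0), seed = 1, temperature = 310) {
  stopifnot(n_steps >= 1, n_chains >= 1, burn_in >= 0, burn_in < 1,
            length(prior) == 2, prior[1] < prior[2])
  constants <- thermo_constants(temperature)
  registry <- normalize_label(registry)

  keep <- !is.na(variants$fs)
  if (!any(keep))
    stop("no variant has a measured fs", call. = FALSE)
  if (any(!keep)) {
    warning(sum(!keep), " variant(s) without measured fs dropped from fit")
    variants <- variants[keep, , drop = FALSE]
  }
  sigma <- variants$sigma
  if (any(sigma == 0)) {
    warning("sigma values of 0 floored at 0.005")
    sigma[sigma == 0] <- 0.005
  }

  pin <- normalize_label(pin)
  bad_pin <- setdiff(pin, registry)
  if (length(bad_pin))
    stop("pin label(s) not in the registry: ",
         paste(bad_pin, collapse = ", "), call. = FALSE)
  pinned <- registry %in% pin
  if (all(pinned))
    stop("no free variables left after pinning", call. = FALSE)
  design <- build_design_matrix(variants, registry)

  chains <- vector("list", n_chains)
  kchains <- vector("list", n_chains)
  accept <- matrix(0, n_chains, length(registry),
                   dimnames = list(NULL, registry))
  kaccept <- numeric(n_chains)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch - 1L)
    res <- metropolis_cpp(design, variants$fs, sigma, as.integer(n_steps),
                          proposal_sigma, prior[1], prior[2], pinned,
                          constants$kT, kinetic, kappa_proposal_sigma,
                          if (kinetic) kappa_init else 0)
    colnames(res$dg_samples) <- registry
    chains[[ch]] <- res$dg_samples
    kchains[[ch]] <- if (kinetic) res$kappa_samples else NULL
    accept[ch, ] <- res$accept / n_steps
    kaccept[ch] <- if (kinetic) res$kappa_accept / n_steps else NA_real_
  }

  fit <- structure(list(
    chains = chains,
    kappa_chains = if (kinetic) kchains else NULL,
    design = design, variants = variants, labels = registry,
    accept = accept, kappa_accept = kaccept,
    config = list(n_steps = n_steps, n_chains = n_chains,
                  proposal_sigma = proposal_sigma, prior = prior,
                  burn_in = burn_in, kinetic = kinetic,
                  kappa_proposal_sigma = kappa_proposal_sigma,
                  kappa_init = kappa_init, pin = pin, seed = seed,
                  temperature = temperature, kT = constants$kT,
                  sigma_floored = any(variants$sigma == 0),
                  pooled_chains = TRUE,
                  package_version = as.character(utils::packageVersion("fsthermo")))),
    class = "fs_fit")
  fit$posterior <- posterior_summary(fit)
  fit
}

#' Pooled posterior samples of a fit
#'
#' Drops the first `burn_in` fraction of every chain and concatenates the
#' remainder across chains.  With `kappa = TRUE` the mean-kinetic-factor
#' samples are appended as a `kappa_bar` column.
#'
#' @param fit an `fs_fit` object.
#' @param burn_in burn-in fraction; defaults to the fit's configuration.
#' @param kappa append the kinetic nuisance parameter column if present.
#' @return numeric matrix, one column per variable.
#' @export
pooled_samples <- function(fit, burn_in = fit$config$burn_in,
                           kappa = FALSE) {
  take <- function(m) {
    drop_n <- floor(nrow(m) * burn_in)
    m[(drop_n + 1):nrow(m), , drop = FALSE]
  }
  out <- do.call(rbind, lapply(fit$chains, take))
  if (kappa && !is.null(fit$kappa_chains)) {
    kb <- unlist(lapply(fit$kappa_chains, function(k) {
      drop_n <- floor(length(k) * burn_in)
      k[(drop_n + 1):length(k)]
    }))
    out <- cbind(out, kappa_bar = kb)
  }
  out
}

#' Posterior summary per change variable
#'
#' Mean, standard deviation and a normalized histogram of every variable's
#' pooled post-burn-in samples (and of the mean kinetic factor, when
#' sampled).
#'
#' @inheritParams pooled_samples
#' @param breaks histogram bin specification passed to [graphics::hist()].
#' @return data.frame of class `fs_posterior` with columns `label`,
#'   `mean`, `sd`, `pinned`; histograms in `attr(, "histograms")`
#'   (densities integrate to 1), pooling flag in `attr(, "pooled")`.
#' @export
posterior_summary <- function(fit, burn_in = fit$config$burn_in,
                              breaks = 100) {
  s <- pooled_samples(fit, burn_in, kappa = TRUE)
  if (!nrow(s))
    stop("no samples left after burn-in", call. = FALSE)
  hists <- lapply(colnames(s), function(lb)
    graphics::hist(s[, lb], breaks = breaks, plot = FALSE))
  names(hists) <- colnames(s)
  out <- data.frame(label = colnames(s),
                    mean = colMeans(s),
                    sd = apply(s, 2, stats::sd),
                    pinned = colnames(s) %in% fit$config$pin,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "histograms") <- hists
  attr(out, "pooled") <- fit$config$pooled_chains && fit$config$n_chains > 1
  class(out) <- c("fs_posterior", "data.frame")
  out
}
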