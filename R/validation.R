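#' Posterior-predictive frameshifting efficiencies
#'
#' For every retained posterior sample, computes each design row's total
#' free-energy difference, converts it to an efficiency with the Boltzmann
#' two-state model, applies the kinetic factor when kinetic samples are
#' given (the lumped parameter C is re-solved per sample so that the
#' kinetic factors over the supplied rows average to the sampled mean),
#' and summarizes the per-variant efficiency distributions.
#'
#' @param samples numeric matrix of posterior draws, columns named by
#'   change variable; columns missing from the design contribute nothing,
#'   design columns missing from the samples are an error.
#' @param design signed design matrix (variants x variables).
#' @param kappa_samples optional vector of mean-kinetic-factor draws, one
#'   per sample row.
#' @param constants see [thermo_constants()].
#' @return data.frame with columns `variant_id`, `fs_mean`, `fs_sd`.
#' @export
predict_fs <- function(samples, design, kappa_samples = NULL,
                       constants = thermo_constants()) {
  miss <- setdiff(colnames(design), colnames(samples))
  if (length(miss))
    stop("posterior samples lack design variable(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  S <- samples[, colnames(design), drop = FALSE]
  res <- predict_fs_cpp(S, if (is.null(kappa_samples)) numeric(0)
                        else as.numeric(kappa_samples),
                        design, constants$kT)
  data.frame(variant_id = rownames(design), fs_mean = res$mean,
             fs_sd = res$sd, row.names = NULL, stringsAsFactors = FALSE)
}

#' Root-mean-square deviation between efficiency vectors
#'
#' Inputs are fractions; the result is reported in percentage points,
#' 100 * sqrt(mean((a - b)^2)).
#'
#' @param fs_model,fs_experiment efficiency vectors (fractions).
#' @return rmsd in percentage points.
#' @examples
#' fs_rmsd(0.5, 0.4)  # 10
#' @export
fs_rmsd <- function(fs_model, fs_experiment) {
  if (length(fs_model) != length(fs_experiment))
    stop("vectors must have the same length", call. = FALSE)
  100 * sqrt(mean((fs_model - fs_experiment)^2))
}

#' Convergence of the data rmsd with Metropolis steps
#'
#' For each checkpoint N, takes the first N steps of every chain,
#' discards the first `burn_in` fraction of that prefix, computes the
#' mean model efficiency per variant from the remaining samples and the
#' rmsd against the measurements.  Converged chains plateau at a common
#' value.
#'
#' @param fit an `fs_fit`.
#' @param checkpoints increasing step counts; default 10 log-spaced
#'   checkpoints up to the chain length.
#' @param burn_in burn-in fraction applied within each prefix.
#' @return data.frame with columns `chain`, `n_steps`, `rmsd`.
#' @export
convergence_curve <- function(fit, checkpoints = NULL,
                              burn_in = fit$config$burn_in) {
  n_total <- nrow(fit$chains[[1]])
  if (is.null(checkpoints))
    checkpoints <- unique(round(exp(seq(log(max(10, n_total / 100)),
                                        log(n_total), length.out = 10))))
  checkpoints <- as.integer(checkpoints)
  if (is.unsorted(checkpoints, strictly = FALSE))
    stop("checkpoints must be increasing", call. = FALSE)
  if (max(checkpoints) > n_total)
    stop("checkpoint exceeds chain length", call. = FALSE)
  constants <- thermo_constants(fit$config$temperature)
  ok <- !is.na(fit$variants$fs)
  rows <- list()
  for (ch in seq_along(fit$chains)) {
    for (N in checkpoints) {
      lo <- floor(N * burn_in) + 1L
      S <- fit$chains[[ch]][lo:N, , drop = FALSE]
      kb <- if (fit$config$kinetic) fit$kappa_chains[[ch]][lo:N] else NULL
      pred <- predict_fs(S, fit$design, kappa_samples = kb,
                         constants = constants)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, n_steps = N,
        rmsd = fs_rmsd(pred$fs_mean[ok], fit$variants$fs[ok]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Leave-one-out cross-validated predictions
#'
#' Refits the model once per variant, excluding that variant, and
#' predicts its efficiency from the reduced fit's posterior.  Variables
#' occurring only in the excluded variant stay prior-distributed in the
#' reduced fit, so their predictions honestly carry prior-wide
#' uncertainty.  Refits default to fewer steps than a headline fit to
#' keep N refits tractable.
#'
#' @param variants `fs_variants` table with measured `fs` and `sigma`.
#' @param registry canonical change-variable labels.
#' @param n_steps Metropolis steps per refit.
#' @param n_chains chains per refit.
#' @param seed base seed; refit i uses `seed + i * n_chains`.
#' @param ... further arguments passed to [fs_fit()].
#' @return list with `predictions` (data.frame `variant_id`,
#'   `fs_measured`, `fs_model_mean`, `fs_model_sd`) and `rmsd`
#'   (percentage points).
#' @export
loo_crossvalidate <- function(variants, registry = invitro_registry(),
                              n_steps = 2e5, n_chains = 2, seed = 1, ...) {
  if (nrow(variants) < 2)
    stop("leave-one-out needs at least 2 variants", call. = FALSE)
  preds <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    fit <- fs_fit(variants[-i, , drop = FALSE], registry,
                  n_steps = n_steps, n_chains = n_chains,
                  seed = seed + i * n_chains, ...)
    p <- suppressWarnings(predict(fit, newdata = variants[i, , drop = FALSE]))
    preds[[i]] <- data.frame(variant_id = variants$variant_id[i],
                             fs_measured = variants$fs[i],
                             fs_model_mean = p$fs_mean,
                             fs_model_sd = p$fs_sd,
                             stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  list(predictions = predictions,
       rmsd = fs_rmsd(predictions$fs_model_mean, predictions$fs_measured))
}
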