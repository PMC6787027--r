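#' @export
print.fs_fit <- function(x, ...) {
  cfg <- x$config
  cat("Base-pair free-energy model of -1 ribosomal frameshifting\n")
  cat(sprintf("  %d variants, %d change variables (%d pinned)\n",
              nrow(x$design), ncol(x$design), length(cfg$pin)))
  cat(sprintf("  %d chain(s) x %g Metropolis steps, burn-in %.0f%%%s\n",
              cfg$n_chains, cfg$n_steps, 100 * cfg$burn_in,
              if (cfg$kinetic) ", kinetic nuisance factor" else ""))
  cat(sprintf("  mean acceptance rate %.2f\n", mean(x$accept)))
  invisible(x)
}

#' @export
summary.fs_fit <- function(object, ...) {
  post <- object$posterior
  pred <- predict(object)
  ok <- !is.na(object$variants$fs)
  out <- list(posterior = post,
              rmsd = fs_rmsd(pred$fs_mean[ok], object$variants$fs[ok]),
              n_variants = nrow(object$design),
              config = object$config)
  class(out) <- "summary.fs_fit"
  out
}

#' @export
print.summary.fs_fit <- function(x, digits = 3, ...) {
  cat("Posterior free-energy differences (kJ/mol):\n")
  tab <- x$posterior
  tab$mean <- round(tab$mean, digits)
  tab$sd <- round(tab$sd, digits)
  print.data.frame(tab, row.names = FALSE)
  cat(sprintf("\nIn-sample rmsd: %.2f percentage points (%d variants)\n",
              x$rmsd, x$n_variants))
  if (attr(x$posterior, "pooled"))
    cat("Summaries pool post-burn-in samples across chains.\n")
  invisible(x)
}

#' @export
coef.fs_fit <- function(object, ...) {
  stats::setNames(object$posterior$mean, object$posterior$label)
}

#' Predict frameshifting efficiencies from a fitted model
#'
#' Pushes every retained posterior sample through the Boltzmann two-state
#' model (including the kinetic factor if it was sampled) for each variant
#' in `newdata` and summarizes the resulting efficiency distribution.
#' Change variables of `newdata` that the fit does not cover are sampled
#' from the prior box, with a warning: such predictions honestly carry
#' prior-wide uncertainty.
#'
#' @param object an `fs_fit`.
#' @param newdata `fs_variants` table; defaults to the training variants.
#' @param ... unused.
#' @return data.frame with columns `variant_id`, `fs_mean`, `fs_sd`.
#' @export
predict.fs_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    samples <- pooled_samples(object, kappa = FALSE)
    kb <- if (object$config$kinetic)
      pooled_samples(object, kappa = TRUE)[, "kappa_bar"] else NULL
    return(predict_fs(samples, object$design, kappa_samples = kb,
                      constants = thermo_constants(object$config$temperature)))
  }
  labels <- object$labels
  extra <- character(0)
  for (i in seq_len(nrow(newdata))) {
    ch <- derive_changes(newdata$heptamer[i], newdata$p_anticodon[i],
                         newdata$a_anticodon[i])
    for (lb in ch$label) {
      hit <- tryCatch(canonicalize(lb, labels), error = function(e) NULL)
      if (is.null(hit)) extra <- union(extra, lb)
    }
  }
  samples <- pooled_samples(object, kappa = FALSE)
  if (length(extra)) {
    warning("change variable(s) not covered by the fit, predicted with ",
            "prior-wide uncertainty: ", paste(extra, collapse = ", "))
    prior <- object$config$prior
    pad <- matrix(stats::runif(nrow(samples) * length(extra),
                               prior[1], prior[2]),
                  ncol = length(extra), dimnames = list(NULL, extra))
    samples <- cbind(samples, pad)
    labels <- c(labels, extra)
  }
  design <- build_design_matrix(newdata, labels)
  kb <- if (object$config$kinetic)
    pooled_samples(object, kappa = TRUE)[, "kappa_bar"] else NULL
  predict_fs(samples, design, kappa_samples = kb,
             constants = thermo_constants(object$config$temperature))
}

#' @export
residuals.fs_fit <- function(object, ...) {
  pred <- predict(object)
  stats::setNames(object$variants$fs - pred$fs_mean, pred$variant_id)
}

#' Posterior-predictive simulation from a fitted model
#'
#' Draws `nsim` replicate datasets: for each, one posterior sample of the
#' free-energy differences (and kinetic factor, if sampled) is drawn, the
#' model efficiencies are computed and Gaussian replicate noise of the
#' training-data sigmas is added, truncated to (0, 1) by resampling.
#'
#' @param object an `fs_fit`.
#' @param nsim number of replicate datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data.frame with one row per variant and one `sim_*` column per
#'   replicate.
#' @export
simulate.fs_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(seed)
  }
  samples <- pooled_samples(object, kappa = object$config$kinetic)
  constants <- thermo_constants(object$config$temperature)
  idx <- sample.int(nrow(samples), nsim, replace = TRUE)
  out <- data.frame(variant_id = rownames(object$design),
                    stringsAsFactors = FALSE)
  for (r in seq_len(nsim)) {
    dg <- samples[idx[r], object$labels]
    fs <- fs_from_dg(as.numeric(object$design %*% dg), constants)
    if (object$config$kinetic) {
      kb <- samples[idx[r], "kappa_bar"]
      if (kb > 0) {
        dgtot <- as.numeric(object$design %*% dg)
        kap <- kappa_of_c(solve_c_for_mean_kappa(min(kb, 1 - 1e-12), dgtot,
                                                 constants),
                          dgtot, constants)
        fs <- fs_kinetic(fs, kap)
      }
    }
    out[[paste0("sim_", r)]] <- truncnorm_fs(fs, object$variants$sigma)
  }
  out
}

#' Diagnostic plots for a fitted model
#'
#' `which = "fit"` draws measured versus model efficiencies with +-1 sd
#' bars; `which = "posterior"` draws per-variable posterior histograms.
#'
#' @param x an `fs_fit`.
#' @param which `"fit"` or `"posterior"`.
#' @param labels variables to show in the posterior panel (default all).
#' @param ... passed to the underlying plotting calls.
#' @export
plot.fs_fit <- function(x, which = c("fit", "posterior"),
                        labels = x$labels, ...) {
  which <- match.arg(which)
  if (which == "fit") {
    pred <- predict(x)
    fs_exp <- x$variants$fs
    graphics::plot(100 * fs_exp, 100 * pred$fs_mean,
                   xlab = "measured FS (%)", ylab = "model FS (%)",
                   xlim = c(0, 100), ylim = c(0, 100), pch = 15, ...)
    graphics::abline(0, 1, col = "grey")
    graphics::segments(100 * fs_exp, 100 * (pred$fs_mean - pred$fs_sd),
                       100 * fs_exp, 100 * (pred$fs_mean + pred$fs_sd))
  } else {
    hists <- attr(x$posterior, "histograms")[labels]
    old <- graphics::par(mfrow = grDevices::n2mfrow(length(hists)),
                         mar = c(2.5, 2.5, 1.5, 0.5))
    on.exit(graphics::par(old))
    for (lb in names(hists))
      graphics::plot(hists[[lb]], freq = FALSE, main = lb,
                     xlab = "kJ/mol", ...)
  }
  invisible(x)
}
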