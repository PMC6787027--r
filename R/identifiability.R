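#' Flag underdetermined change variables
#'
#' A variable is underdetermined when its posterior standard deviation
#' exceeds `sd_threshold`.  Determined variables in a well-constrained
#' fit have sub-kJ/mol posterior sd while prior-scale sd is about
#' 14 kJ/mol (uniform over 50 kJ/mol), so any threshold of a few kJ/mol
#' separates the two regimes; 2 kJ/mol is the default.  Pinned variables
#' and the kinetic nuisance parameter are never flagged.
#'
#' @param posterior an `fs_posterior` summary (or an `fs_fit`).
#' @param sd_threshold kJ/mol.
#' @return character vector of underdetermined labels.
#' @export
flag_underdetermined <- function(posterior, sd_threshold = 2) {
  if (inherits(posterior, "fs_fit")) posterior <- posterior$posterior
  drop <- posterior$label == "kappa_bar" |
    (if ("pinned" %in% names(posterior)) posterior$pinned else FALSE)
  posterior$label[!drop & posterior$sd > sd_threshold]
}

#' Pearson correlations of posterior sample series
#'
#' Correlation matrix of the pooled post-burn-in samples.  A sum of two
#' variables being determined while each alone is not shows up as strong
#' negative correlation between them; variables coupled to a common third
#' show strong positive correlation.  Zero-variance series (pinned
#' variables) yield undefined correlations, reported as 0 with a warning.
#'
#' @param fit an `fs_fit` (or a samples matrix with named columns).
#' @param burn_in burn-in fraction, defaulting to the fit's.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
sample_correlations <- function(fit, burn_in = NULL) {
  s <- if (inherits(fit, "fs_fit"))
    pooled_samples(fit, if (is.null(burn_in)) fit$config$burn_in else burn_in)
  else fit
  sds <- apply(s, 2, stats::sd)
  r <- suppressWarnings(stats::cor(s))
  if (any(sds == 0)) {
    warning("zero-variance sample series; correlations reported as 0 for: ",
            paste(colnames(s)[sds == 0], collapse = ", "))
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  diag(r) <- 1
  r
}

#' Refit with selected variables pinned to 0 kJ/mol
#'
#' Pinning an underdetermined variable collapses the flat directions it
#' spans: any variable strongly coupled to it becomes determined, and its
#' posterior then measures the free energy of the *combination* (pinned
#' change + variable) rather than of the variable alone.  The design
#' matrix is unchanged; only the sampler's free-variable set shrinks.
#'
#' @param variants `fs_variants` table with measurements.
#' @param registry canonical change-variable labels.
#' @param pin labels to pin at 0 kJ/mol.
#' @param sd_threshold determined/underdetermined boundary, kJ/mol.
#' @param strong_r absolute correlation treated as strong coupling.
#' @param reference_fit optional prior [fs_fit()] on the same data used to
#'   identify couplings and pre-pin sds (avoids refitting twice inside
#'   [iterative_pinning()]).
#' @param ... arguments passed to [fs_fit()] (n_steps, seed, ...).
#' @return list with `fit` (the pinned refit) and `combinations`
#'   (data.frame `labels`, `pinned`, `mean`, `sd`: newly determined
#'   pinned+variable combinations and their free energies).
#' @export
pin_and_refit <- function(variants, registry = invitro_registry(), pin,
                          sd_threshold = 2, strong_r = 0.9,
                          reference_fit = NULL, ...) {
  pin <- normalize_label(pin)
  if (is.null(reference_fit))
    reference_fit <- fs_fit(variants, registry, ...)
  ref_post <- reference_fit$posterior
  determined_before <- setdiff(
    setdiff(ref_post$label, flag_underdetermined(ref_post, sd_threshold)),
    "kappa_bar")
  if (any(pin %in% determined_before))
    warning("pinning variable(s) that are already determined: ",
            paste(intersect(pin, determined_before), collapse = ", "))
  fit <- fs_fit(variants, registry, pin = pin, ...)
  post <- fit$posterior
  newly <- setdiff(setdiff(determined_labels(post, sd_threshold),
                           determined_before), pin)
  r <- sample_correlations(reference_fit)
  combos <- lapply(newly, function(v) {
    partners <- pin[abs(r[v, pin]) >= strong_r]
    if (!length(partners)) partners <- pin[which.max(abs(r[v, pin]))]
    data.frame(labels = paste(c(partners, v), collapse = " + "),
               pinned = paste(partners, collapse = " + "),
               mean = post$mean[post$label == v],
               sd = post$sd[post$label == v],
               stringsAsFactors = FALSE)
  })
  combinations <- if (length(combos)) do.call(rbind, combos) else
    data.frame(labels = character(0), pinned = character(0),
               mean = numeric(0), sd = numeric(0))
  list(fit = fit, combinations = combinations)
}

determined_labels <- function(posterior, sd_threshold = 2) {
  keep <- posterior$label != "kappa_bar" & !posterior$pinned &
    posterior$sd <= sd_threshold
  posterior$label[keep]
}

#' Iterative pinning analysis of parameter identifiability
#'
#' Step 1 fits all variables and records which are determined (small
#' posterior sd).  Each subsequent step pins exactly one variable that
#' had a large sd in *all* previous steps — chosen as the one with the
#' most strong couplings among the persistent underdetermined variables,
#' ties broken by reverse-alphabetical label — and records which
#' variables that pin makes determined (their posteriors then measure
#' pinned+variable combinations).  A final step pins all chosen
#' representatives simultaneously.
#'
#' @inheritParams pin_and_refit
#' @param max_steps safety cap on pinning steps; a partial report is
#'   returned if the analysis has not converged by then.
#' @return object of class `fs_identifiability`: list with `steps` (one
#'   entry per step: `pin`, `determined`, `newly_determined`, `rmsd`,
#'   `posterior`), `final` (simultaneous-pin entry with `fit` and
#'   `combinations`), `pins`, `correlations`, `sd_threshold`,
#'   `converged`.
#' @export
iterative_pinning <- function(variants, registry = invitro_registry(),
                              sd_threshold = 2, strong_r = 0.9,
                              max_steps = NULL, ...) {
  registry <- normalize_label(registry)
  if (is.null(max_steps)) max_steps <- length(registry)
  fit1 <- fs_fit(variants, registry, ...)
  rmsd_of <- function(fit) {
    pred <- predict(fit)
    fs_rmsd(pred$fs_mean, fit$variants$fs)
  }
  r <- sample_correlations(fit1)
  det1 <- determined_labels(fit1$posterior, sd_threshold)
  steps <- list(list(pin = character(0), determined = det1,
                     newly_determined = det1, rmsd = rmsd_of(fit1),
                     posterior = fit1$posterior))
  always_large <- setdiff(fit1$posterior$label, c(det1, "kappa_bar"))
  pins <- character(0)
  converged <- TRUE
  while (length(always_large)) {
    if (length(steps) > max_steps) {
      converged <- FALSE
      warning("pinning did not converge within max_steps; partial report")
      break
    }
    cand <- setdiff(always_large, pins)
    if (!length(cand)) break
    n_strong <- vapply(cand, function(v)
      sum(abs(r[v, setdiff(always_large, v)]) >= strong_r), 0L)
    pick <- cand[n_strong == max(n_strong)]
    pick <- sort(pick, decreasing = TRUE)[1]  # reverse-alphabetical tie-break
    pins <- c(pins, pick)
    res <- pin_and_refit(variants, registry, pin = pick,
                         sd_threshold = sd_threshold, strong_r = strong_r,
                         reference_fit = fit1, ...)
    det_k <- determined_labels(res$fit$posterior, sd_threshold)
    steps[[length(steps) + 1L]] <- list(
      pin = pick, determined = det_k,
      newly_determined = setdiff(det_k, c(det1, pins)),
      rmsd = rmsd_of(res$fit), posterior = res$fit$posterior)
    always_large <- intersect(always_large, setdiff(registry, c(det_k, pick)))
  }
  final <- if (length(pins)) {
    res <- pin_and_refit(variants, registry, pin = pins,
                         sd_threshold = sd_threshold, strong_r = strong_r,
                         reference_fit = fit1, ...)
    list(pin = pins, determined = determined_labels(res$fit$posterior,
                                                    sd_threshold),
         rmsd = rmsd_of(res$fit), fit = res$fit,
         combinations = res$combinations)
  } else list(pin = character(0), determined = det1,
              rmsd = steps[[1]]$rmsd, fit = fit1,
              combinations = data.frame(labels = character(0),
                                        pinned = character(0),
                                        mean = numeric(0),
                                        sd = numeric(0)))
  structure(list(steps = steps, final = final, pins = pins,
                 correlations = r, sd_threshold = sd_threshold,
                 converged = converged),
            class = "fs_identifiability")
}

#' @export
print.fs_identifiability <- function(x, ...) {
  cat(sprintf("Identifiability by iterative pinning (%d step(s) + final)\n",
              length(x$steps)))
  cat(sprintf("  step 1: %d variable(s) determined, rmsd %.2f%%\n",
              length(x$steps[[1]]$determined), x$steps[[1]]$rmsd))
  for (k in seq_along(x$steps)[-1])
    cat(sprintf("  step %d: pin %s -> %d newly determined, rmsd %.2f%%\n",
                k, x$steps[[k]]$pin,
                length(x$steps[[k]]$newly_determined), x$steps[[k]]$rmsd))
  cat(sprintf("  final: pin {%s}, %d determined, rmsd %.2f%%\n",
              paste(x$final$pin, collapse = ", "),
              length(x$final$determined), x$final$rmsd))
  invisible(x)
}

#' Compare first-position base-pair free energies between P and A sites
#'
#' Derives free-energy differences that were not measured directly by
#' subtracting posterior series of the appropriate labels, per posterior
#' sample, under the assumption that A.U and U.A pairs are isoenergetic.
#' The default comparisons derive C.A -> C.U and G.A -> G.U in both
#' codon positions: in the first codon directly from the two P1
#' variables, in the second codon from the pinned-fit A1 columns (whose
#' posteriors hold wobble-pin + A1 combination energies; the shared
#' pinned contribution cancels in the difference).
#'
#' @param fit an `fs_fit` (typically the simultaneous-pin refit) or a
#'   samples matrix with named columns.
#' @param comparisons data.frame with columns `name`, `minuend`,
#'   `subtrahend` (labels); defaults to the P-vs-A first-position set.
#' @param burn_in burn-in fraction when `fit` is an `fs_fit`.
#' @return data.frame with columns `name`, `mean`, `sd` of the per-sample
#'   differences (kJ/mol).
#' @export
site_comparison <- function(fit, comparisons = default_site_comparisons(),
                            burn_in = NULL) {
  s <- if (inherits(fit, "fs_fit"))
    pooled_samples(fit, if (is.null(burn_in)) fit$config$burn_in else burn_in)
  else fit
  comparisons$minuend <- normalize_label(comparisons$minuend)
  comparisons$subtrahend <- normalize_label(comparisons$subtrahend)
  need <- unique(c(comparisons$minuend, comparisons$subtrahend))
  miss <- setdiff(need, colnames(s))
  if (length(miss))
    stop("posterior lacks label(s) needed for the comparison: ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- lapply(seq_len(nrow(comparisons)), function(k) {
    d <- s[, comparisons$minuend[k]] - s[, comparisons$subtrahend[k]]
    data.frame(name = comparisons$name[k], mean = mean(d),
               sd = if (length(d) > 1) stats::sd(d) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @rdname site_comparison
#' @export
default_site_comparisons <- function() {
  data.frame(
    name = c("P site C.A->C.U", "A site C.A->C.U",
             "P site G.A->G.U", "A site G.A->G.U"),
    minuend = normalize_label(c("P1 A.U->C.U", "A1 A.U->C.U",
                                "P1 A.U->G.U", "A1 A.U->G.U")),
    subtrahend = normalize_label(c("P1 U.A->C.A", "A1 U.A->C.A",
                                   "P1 U.A->G.A", "A1 U.A->G.A")),
    stringsAsFactors = FALSE)
}
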