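#' Read and write slippery-sequence variant tables
#'
#' UTF-8 TSV with header `variant_id  heptamer  p_anticodon_3to5
#' a_anticodon_3to5  fs  sigma`.  Efficiencies may be given as fractions
#' or as percent: a column whose maximum exceeds 1.5 is taken to be in
#' percent and divided by 100 (together with its sigmas).  `fs` and
#' `sigma` may be empty for prediction-only rows.  Rows failing
#' validation are reported with their line numbers.
#'
#' @param path file path.
#' @param registry nucleotide registry for anticodon validation.
#' @return `fs_variants` table (efficiencies as fractions).
#' @export
read_variant_table <- function(path, registry = nucleotide_registry()) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           fileEncoding = "UTF-8", na.strings = c("", "NA"))
  need <- c("variant_id", "heptamer", "p_anticodon_3to5",
            "a_anticodon_3to5", "fs", "sigma")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  fs <- suppressWarnings(as.numeric(tab$fs))
  sigma <- suppressWarnings(as.numeric(tab$sigma))
  bad_num <- which((!is.na(tab$fs) & is.na(fs)) |
                     (!is.na(tab$sigma) & is.na(sigma)))
  if (length(bad_num))
    stop("non-numeric fs/sigma in row(s) ",
         paste(bad_num + 1L, collapse = ", "), " of ", path, call. = FALSE)
  if (any(fs < 0 | fs > 100, na.rm = TRUE))
    stop("fs outside [0, 100] in row(s) ",
         paste(which(fs < 0 | fs > 100) + 1L, collapse = ", "), " of ",
         path, call. = FALSE)
  if (any(!is.na(fs)) && max(fs, na.rm = TRUE) > 1.5) { # percent convention
    fs <- fs / 100
    sigma <- sigma / 100
  }
  rows <- seq_len(nrow(tab))
  out <- tryCatch(
    variant_table(tab$heptamer, tab$p_anticodon_3to5, tab$a_anticodon_3to5,
                  fs = fs, sigma = sigma, variant_id = tab$variant_id,
                  registry = registry),
    error = function(e) {
      # re-validate row-wise to point at the offending line
      for (i in rows) {
        ok <- tryCatch({
          validate_heptamer(tab$heptamer[i])
          validate_anticodon(tab$p_anticodon_3to5[i], registry)
          validate_anticodon(tab$a_anticodon_3to5[i], registry)
          !(!is.na(fs[i]) && is.na(sigma[i]))
        }, error = function(e2) FALSE)
        if (!isTRUE(ok))
          stop("invalid variant in row ", i + 1L, " of ", path, ": ",
               conditionMessage(e), call. = FALSE)
      }
      stop(conditionMessage(e), call. = FALSE)
    })
  out
}

#' @rdname read_variant_table
#' @param variants `fs_variants` table to write.
#' @export
write_variant_table <- function(variants, path) {
  out <- data.frame(variant_id = variants$variant_id,
                    heptamer = variants$heptamer,
                    p_anticodon_3to5 = variants$p_anticodon,
                    a_anticodon_3to5 = variants$a_anticodon,
                    fs = variants$fs, sigma = variants$sigma,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read a change-variable registry from a text file
#'
#' One canonical label per line (unicode `P1 A·U→G·U` or ASCII
#' `P1 A.U->G.U` form); blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return character vector of canonical labels (unicode form).
#' @export
read_change_registry <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  labels <- normalize_label(lines)
  parse_change_label(labels) # validates
  labels
}

#' Export a design matrix as TSV
#'
#' Variant rows, change-variable columns, signed integer entries.
#'
#' @param design integer design matrix from [build_design_matrix()].
#' @param path file path.
#' @export
write_design_matrix <- function(design, path) {
  out <- data.frame(variant_id = rownames(design), design,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Export posterior samples, summaries, predictions and run manifests
#'
#' `write_posterior_csv()` writes the concatenated chains, one column per
#' change variable plus `chain`, `step`, optional `kappa_bar`, and a
#' `retained` flag marking post-burn-in rows.  `write_fit_summary_json()`
#' writes per-variable mean, sd and histogram plus the in-sample rmsd.
#' `write_predictions_tsv()` writes measured and model efficiencies per
#' variant.  `write_manifest()` records the full configuration, seed and
#' package version needed to reproduce the run.
#'
#' @param fit an `fs_fit`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_posterior_csv <- function(fit, path) {
  burn <- fit$config$burn_in
  blocks <- lapply(seq_along(fit$chains), function(ch) {
    m <- fit$chains[[ch]]
    d <- data.frame(chain = ch, step = seq_len(nrow(m)), m,
                    check.names = FALSE, stringsAsFactors = FALSE)
    if (fit$config$kinetic) d$kappa_bar <- fit$kappa_chains[[ch]]
    d$retained <- d$step > floor(nrow(m) * burn)
    d
  })
  utils::write.csv(do.call(rbind, blocks), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_posterior_csv
#' @export
write_fit_summary_json <- function(fit, path) {
  post <- fit$posterior
  hists <- attr(post, "histograms")
  vars <- lapply(seq_len(nrow(post)), function(k) {
    h <- hists[[post$label[k]]]
    list(label = post$label[k], mean = post$mean[k], sd = post$sd[k],
         pinned = post$pinned[k],
         histogram = list(breaks = h$breaks, density = h$density))
  })
  pred <- predict(fit)
  jsonlite::write_json(
    list(variables = vars,
         rmsd_percent = fs_rmsd(pred$fs_mean, fit$variants$fs),
         pooled_chains = attr(post, "pooled")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_posterior_csv
#' @param newdata optional `fs_variants` to predict; defaults to the
#'   training variants.
#' @export
write_predictions_tsv <- function(fit, path, newdata = NULL) {
  pred <- predict(fit, newdata = newdata)
  measured <- if (is.null(newdata)) fit$variants$fs else newdata$fs
  out <- data.frame(variant_id = pred$variant_id, fs_measured = measured,
                    fs_model_mean = pred$fs_mean,
                    fs_model_sd = pred$fs_sd, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' @rdname write_posterior_csv
#' @export
write_manifest <- function(fit, path) {
  jsonlite::write_json(
    c(fit$config,
      list(n_variants = nrow(fit$design), labels = fit$labels,
           mean_acceptance = mean(fit$accept))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
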