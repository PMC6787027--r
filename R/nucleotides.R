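#' Nucleotide code registry
#'
#' The mRNA alphabet is restricted to the four canonical bases A, C, G, U.
#' tRNA anticodons additionally use one-character codes for modified
#' nucleotides commonly found at position 34 of the anticodon loop.  The
#' default registry covers the modifications relevant to Lys/Phe slippery
#' sites and to the published in-vivo variant catalog: mnm5s2U (S),
#' mnm5U (\{), cmnm5U ()), queuosine (Q), cmo5U (V), ac4C (M) and
#' 2-lysidine (\}).
#'
#' @param extra optional named character vector of additional codes
#'   (names are the one-character codes, values human-readable names).
#' @return named character vector mapping code to nucleotide name.
#' @examples
#' nucleotide_registry()[["S"]]
#' @export
nucleotide_registry <- function(extra = NULL) {
  reg <- c(
    A = "adenosine",
    C = "cytidine",
    G = "guanosine",
    U = "uridine",
    S = "mnm5s2U",
    "{" = "mnm5U",
    ")" = "cmnm5U",
    Q = "queuosine",
    V = "cmo5U",
    M = "ac4C",
    "}" = "2-lysidine"
  )
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(!nzchar(names(extra))))
      stop("'extra' must be a named character vector", call. = FALSE)
    reg[names(extra)] <- extra
  }
  reg
}

#' Read a modified-nucleotide registry from a key/value text file
#'
#' Two tab-separated columns, `code` and `name`, one nucleotide per line.
#' The four canonical bases are always present and need not be listed.
#'
#' @param path path to a UTF-8 TSV file.
#' @return named character vector as in [nucleotide_registry()].
#' @export
read_nucleotide_registry <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           fileEncoding = "UTF-8")
  if (!all(c("code", "name") %in% names(tab)))
    stop("registry file must have columns 'code' and 'name'", call. = FALSE)
  bad <- nchar(tab$code) != 1L
  if (any(bad))
    stop("nucleotide codes must be single characters: ",
         paste(tab$code[bad], collapse = ", "), call. = FALSE)
  nucleotide_registry(extra = stats::setNames(tab$name, tab$code))
}

# validate a character vector of single-letter codes against the registry
check_codes <- function(codes, registry, what = "nucleotide") {
  unknown <- setdiff(unique(codes), names(registry))
  if (length(unknown))
    stop("unknown ", what, " code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}
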