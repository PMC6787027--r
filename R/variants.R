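#' @useDynLib fsthermo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# unicode pieces of a base-pair-change label, e.g. "P1 A·U→G·U"
DOT   <- "\u00b7"   # middle dot between codon and anticodon base
ARROW <- "\u2192"   # right arrow between 0-frame and -1-frame pair

SITE_POSITIONS <- c("P1", "P2", "P3", "A1", "A2", "A3")

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Compose and parse base-pair-change labels
#'
#' A change variable is written `"<site> <X>.<Y>-><X'>.<Y'>"` with a middle
#' dot between codon base (first) and anticodon base, and an arrow from the
#' 0-frame pair to the -1-frame pair, e.g. `"P1 A·U→G·U"`.
#' ASCII input using `"."` and `"->"` is accepted and normalised.
#'
#' @param site one of P1, P2, P3, A1, A2, A3.
#' @param from_codon,from_anti codon/anticodon base of the 0-frame pair.
#' @param to_codon,to_anti codon/anticodon base of the -1-frame pair.
#' @return `bp_change_label()`: a character label; `parse_change_label()`:
#'   a data.frame with columns `site`, `from_codon`, `from_anti`,
#'   `to_codon`, `to_anti`.
#' @examples
#' bp_change_label("P1", "A", "U", "G", "U")
#' parse_change_label("P1 A.U->G.U")
#' @export
bp_change_label <- function(site, from_codon, from_anti, to_codon, to_anti) {
  paste0(site, " ", from_codon, DOT, from_anti, ARROW, to_codon, DOT, to_anti)
}

#' @rdname bp_change_label
#' @param label character vector of labels (unicode or ASCII form).
#' @export
parse_change_label <- function(label) {
  norm <- normalize_label(label)
  m <- regmatches(norm, regexec(
    paste0("^([PA][123]) (.)", DOT, "(.)", ARROW, "(.)", DOT, "(.)$"), norm))
  bad <- vapply(m, length, 1L) != 6L
  if (any(bad))
    stop("malformed base-pair-change label(s): ",
         paste(label[bad], collapse = ", "), call. = FALSE)
  out <- do.call(rbind, lapply(m, function(g)
    data.frame(site = g[2], from_codon = g[3], from_anti = g[4],
               to_codon = g[5], to_anti = g[6], stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

# accept ASCII fallback "." for the dot and "->" for the arrow
normalize_label <- function(label) {
  x <- gsub("->", ARROW, label, fixed = TRUE)
  # replace "." only where it sits between two base codes
  gsub("(?<=.)\\.(?=.)", DOT, x, perl = TRUE)
}

reverse_label <- function(label) {
  p <- parse_change_label(label)
  bp_change_label(p$site, p$to_codon, p$to_anti, p$from_codon, p$from_anti)
}

validate_heptamer <- function(heptamer) {
  b <- chars(heptamer)
  if (length(b) != 7L)
    stop("slippery heptamer must have exactly 7 bases, got '", heptamer, "'",
         call. = FALSE)
  bad <- setdiff(unique(b), c("A", "C", "G", "U"))
  if (length(bad))
    stop("heptamer '", heptamer, "' contains non-mRNA base(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  b
}

validate_anticodon <- function(anticodon, registry) {
  b <- chars(anticodon)
  if (length(b) != 3L)
    stop("anticodon must have exactly 3 bases (written 3'->5'), got '",
         anticodon, "'", call. = FALSE)
  check_codes(b, registry, what = "anticodon nucleotide")
  b
}

#' Construct a table of slippery-sequence variants
#'
#' A variant couples a slippery heptamer (positions numbered 1-7) with the
#' anticodons of the tRNAs decoding its two codons.  Anticodons are written
#' 3' to 5' so that anticodon element k pairs with codon position k.  The
#' 0-frame codons are heptamer positions 2-4 (first, "P-site" codon) and
#' 5-7 (second, "A-site" codon); the -1-frame codons are positions 1-3 and
#' 4-6.  Measured frameshifting efficiencies (fractions in [0, 1]) and
#' their replicate standard deviations are optional; rows without them can
#' still be used for prediction.
#'
#' @param heptamer character vector of 7-base mRNA sequences (A/C/G/U).
#' @param p_anticodon,a_anticodon 3-base anticodons (3' to 5') of the tRNAs
#'   on the first and second slippery codon; may contain modified-nucleotide
#'   codes from the registry.
#' @param fs optional measured frameshifting efficiencies, fractions.
#' @param sigma optional replicate standard deviations, fractions.
#' @param variant_id optional ids; defaults to
#'   `"<N>1 <XXX>4 <XXX>7 / <anticodons>"`.
#' @param registry nucleotide registry, see [nucleotide_registry()].
#' @return data.frame of class `fs_variants` with columns `variant_id`,
#'   `heptamer`, `p_anticodon`, `a_anticodon`, `fs`, `sigma`.
#' @examples
#' variant_table("AAAAAAG", "UUS", "UUS", fs = 0.8, sigma = 0.02)
#' @export
variant_table <- function(heptamer, p_anticodon, a_anticodon,
                          fs = NA_real_, sigma = NA_real_,
                          variant_id = NULL,
                          registry = nucleotide_registry()) {
  n <- length(heptamer)
  p_anticodon <- rep_len(p_anticodon, n)
  a_anticodon <- rep_len(a_anticodon, n)
  fs <- rep_len(as.numeric(fs), n)
  sigma <- rep_len(as.numeric(sigma), n)
  for (i in seq_len(n)) {
    validate_heptamer(heptamer[i])
    validate_anticodon(p_anticodon[i], registry)
    validate_anticodon(a_anticodon[i], registry)
  }
  if (any(!is.na(fs) & (fs < 0 | fs > 1)))
    stop("fs must lie in [0, 1] (fractions, not percent)", call. = FALSE)
  if (any(!is.na(fs) & is.na(sigma)))
    stop("sigma must be given for every variant with a measured fs",
         call. = FALSE)
  if (any(!is.na(sigma) & sigma < 0))
    stop("sigma must be > 0", call. = FALSE)
  if (is.null(variant_id))
    variant_id <- default_variant_id(heptamer, p_anticodon, a_anticodon)
  if (anyDuplicated(variant_id))
    stop("variant ids must be unique", call. = FALSE)
  out <- data.frame(variant_id = variant_id, heptamer = heptamer,
                    p_anticodon = p_anticodon, a_anticodon = a_anticodon,
                    fs = fs, sigma = sigma, stringsAsFactors = FALSE)
  class(out) <- c("fs_variants", "data.frame")
  out
}

default_variant_id <- function(heptamer, p_anticodon, a_anticodon) {
  sprintf("%s1 %s4 %s7 / %s-%s",
          substr(heptamer, 1, 1), substr(heptamer, 2, 4),
          substr(heptamer, 5, 7), p_anticodon, a_anticodon)
}

#' Codon-anticodon base pairs of a variant in both reading frames
#'
#' Enumerates the six base pairs (P1-P3, A1-A3) formed by the two slippery
#' codons with their tRNA anticodons, in the 0-frame (heptamer positions
#' 2-4 and 5-7) and in the -1-frame (positions 1-3 and 4-6).  Pairs are
#' written codon base first.
#'
#' @param heptamer 7-base slippery sequence.
#' @param p_anticodon,a_anticodon anticodons written 3' to 5'.
#' @param registry nucleotide registry.
#' @return list with data.frames `frame0` and `frame_m1`, each with columns
#'   `site`, `codon_base`, `anticodon_base`.
#' @examples
#' pair_frames("GAAAAAG", "UUS", "UUS")
#' @export
pair_frames <- function(heptamer, p_anticodon, a_anticodon,
                        registry = nucleotide_registry()) {
  b <- validate_heptamer(heptamer)
  p <- validate_anticodon(p_anticodon, registry)
  a <- validate_anticodon(a_anticodon, registry)
  one <- function(codon_pos) data.frame(
    site = SITE_POSITIONS,
    codon_base = b[codon_pos],
    anticodon_base = c(p, a),
    stringsAsFactors = FALSE)
  list(frame0 = one(c(2:4, 5:7)), frame_m1 = one(c(1:3, 4:6)))
}

#' Base-pair changes between the 0-frame and the -1-frame
#'
#' Compares the six codon-anticodon pairs of a variant in the two frames
#' and returns one row per site whose pair differs; sites whose pair is
#' unchanged (always P2/A2 for slippery heptamers, and all sites when the
#' frames read identical codons) are omitted.
#'
#' @inheritParams pair_frames
#' @return data.frame with columns `site`, `from_codon`, `from_anti`,
#'   `to_codon`, `to_anti`, `label` (0-frame pair first).
#' @examples
#' derive_changes("GAAAAAG", "UUS", "UUS")   # A1G variant: P1 and A3 change
#' derive_changes("AAAAAAA", "UUS", "UUS")   # identical frames: no changes
#' @export
derive_changes <- function(heptamer, p_anticodon, a_anticodon,
                           registry = nucleotide_registry()) {
  fr <- pair_frames(heptamer, p_anticodon, a_anticodon, registry)
  f0 <- fr$frame0; f1 <- fr$frame_m1
  changed <- f0$codon_base != f1$codon_base |
    f0$anticodon_base != f1$anticodon_base
  out <- data.frame(site = f0$site[changed],
                    from_codon = f0$codon_base[changed],
                    from_anti = f0$anticodon_base[changed],
                    to_codon = f1$codon_base[changed],
                    to_anti = f1$anticodon_base[changed],
                    stringsAsFactors = FALSE)
  out$label <- if (nrow(out)) bp_change_label(out$site, out$from_codon,
                                              out$from_anti, out$to_codon,
                                              out$to_anti) else character(0)
  rownames(out) <- NULL
  out
}

#' Map a base-pair change onto its canonical signed variable
#'
#' Change variables have a canonical direction; a change matching the
#' canonical direction contributes with sign +1, the reverse change with
#' sign -1 (its free energy enters negated).
#'
#' @param label base-pair-change label(s), unicode or ASCII form.
#' @param registry character vector of canonical change-variable labels,
#'   e.g. [invitro_registry()].
#' @return data.frame with columns `label` (canonical) and `sign`.
#' @examples
#' canonicalize("A3 G.S->A.S", invitro_registry())
#' canonicalize("A3 A.S->G.S", invitro_registry())  # reverse: sign -1
#' @export
canonicalize <- function(label, registry) {
  registry <- normalize_label(registry)
  label <- normalize_label(label)
  rev_lab <- if (length(label)) vapply(label, reverse_label, "") else character(0)
  fwd <- match(label, registry)
  bwd <- match(rev_lab, registry)
  unknown <- is.na(fwd) & is.na(bwd)
  if (any(unknown))
    stop("base-pair change(s) unknown to the registry (in either direction): ",
         paste(label[unknown], collapse = ", "), call. = FALSE)
  data.frame(label = ifelse(is.na(fwd), registry[bwd], registry[fwd]),
             sign = ifelse(is.na(fwd), -1L, 1L),
             stringsAsFactors = FALSE)
}

#' Build the signed design matrix of a variant set
#'
#' Row i gives the signed incidence of each canonical change variable in
#' variant i: +1 if the variable's free energy contributes to the total
#' free-energy difference of the variant, -1 if its negative contributes,
#' 0 otherwise.  All-zero rows are legitimate (identical frames, total
#' free-energy difference 0).
#'
#' @param variants an `fs_variants` table, see [variant_table()].
#' @param registry canonical change-variable labels.
#' @param nucleotides nucleotide registry.
#' @return integer matrix with variant ids as row names and canonical
#'   labels as column names.
#' @examples
#' v <- variant_table("GAAAAAG", "UUS", "UUS")
#' build_design_matrix(v, invitro_registry())
#' @export
build_design_matrix <- function(variants, registry,
                                nucleotides = nucleotide_registry()) {
  registry <- normalize_label(registry)
  if (anyDuplicated(registry))
    stop("change-variable labels must be unique", call. = FALSE)
  M <- matrix(0L, nrow = nrow(variants), ncol = length(registry),
              dimnames = list(variants$variant_id, registry))
  for (i in seq_len(nrow(variants))) {
    ch <- derive_changes(variants$heptamer[i], variants$p_anticodon[i],
                         variants$a_anticodon[i], nucleotides)
    if (!nrow(ch)) next
    canon <- canonicalize(ch$label, registry)
    M[i, canon$label] <- M[i, canon$label] + canon$sign
  }
  M
}

#' Numerical rank of a design matrix
#'
#' Rank by singular-value decomposition: singular values above
#' `tol * max(singular value)` count.
#'
#' @param M numeric matrix.
#' @param tol relative tolerance on singular values.
#' @return integer rank.
#' @export
design_rank <- function(M, tol = 1e-8) {
  s <- svd(M, nu = 0, nv = 0)$d
  if (!length(s) || s[1] == 0) return(0L)
  sum(s > tol * s[1])
}

#' The 64-variant Lys/Phe slippery-sequence design
#'
#' Enumerates all slippery heptamers obtained by combining a free first
#' nucleotide (A, C, G or U) with every synonymous choice of two Lys
#' (AAA/AAG, tRNA-Lys anticodon 3'UUS5') or Phe (UUU/UUC, tRNA-Phe
#' anticodon 3'AAG5') codons: 4 tRNA pairs (Lys-Lys, Phe-Phe, Lys-Phe,
#' Phe-Lys) x 4 first nucleotides x 2 x 2 synonymous codons = 64 variants.
#' The wild-type dnaX slippery sequence A1 AAA4 AAG7 (Lys-Lys) is one of
#' them.  No measured efficiencies are attached.
#'
#' @return `fs_variants` table of 64 variants.
#' @examples
#' nrow(enumerate_invitro_design())
#' @export
enumerate_invitro_design <- function() {
  aa <- list(Lys = list(codons = c("AAA", "AAG"), anticodon = "UUS"),
             Phe = list(codons = c("UUU", "UUC"), anticodon = "AAG"))
  pairs <- list(c("Lys", "Lys"), c("Phe", "Phe"),
                c("Lys", "Phe"), c("Phe", "Lys"))
  rows <- list()
  for (pr in pairs) {
    p <- aa[[pr[1]]]; a <- aa[[pr[2]]]
    for (n1 in c("A", "C", "G", "U"))
      for (c1 in p$codons)
        for (c2 in a$codons) {
          hept <- paste0(n1, c1, c2)
          rows[[length(rows) + 1L]] <- data.frame(
            heptamer = hept, p_anticodon = p$anticodon,
            a_anticodon = a$anticodon,
            variant_id = sprintf("%s1 %s4 %s7 / %s-%s",
                                 n1, c1, c2, pr[1], pr[2]),
            stringsAsFactors = FALSE)
        }
  }
  tab <- do.call(rbind, rows)
  variant_table(tab$heptamer, tab$p_anticodon, tab$a_anticodon,
                variant_id = tab$variant_id)
}

#' Canonical change-variable registries
#'
#' `invitro_registry()` returns the 16 change variables spanned by the
#' 64-variant Lys/Phe design: six first-position changes in each codon
#' (P1 and A1), and two wobble-position changes in each codon (P3 and A3:
#' G.S->A.S with the modified Lys anticodon nucleotide mnm5s2U, and
#' C.G->U.G for the Phe wobble).  Second-position pairs never change in
#' this design.  `tsuchihashi_registry()` returns the 26 change variables
#' spanned by the published in-vivo dnaX variant catalog, which also
#' involves tRNAs with the modified nucleotides mnm5U, cmnm5U, queuosine,
#' cmo5U, ac4C and 2-lysidine.
#'
#' @return character vector of canonical labels (unicode form).
#' @examples
#' length(invitro_registry())
#' length(tsuchihashi_registry())
#' @export
invitro_registry <- function() {
  first_pos <- c("A.U->C.U", "A.U->U.U", "A.U->G.U",
                 "U.A->A.A", "U.A->C.A", "U.A->G.A")
  third_pos <- c("G.S->A.S", "C.G->U.G")
  normalize_label(c(paste("P1", first_pos), paste("P3", third_pos),
                    paste("A1", first_pos), paste("A3", third_pos)))
}

#' @rdname invitro_registry
#' @export
tsuchihashi_registry <- function() {
  normalize_label(c(
    paste("P1", c("A.U->C.U", "A.U->U.U", "A.U->G.U", "G.C->A.C")),
    paste("P2", c("A.U->G.U", "U.A->A.A", "G.C->A.C", "C.G->A.G")),
    paste("P3", c("G.S->A.S", "A.}->U.}", "A.{->G.{", "A.V->C.V",
                  "C.Q->A.Q", "U.Q->A.Q", "A.)->U.)")),
    paste("A1", c("A.U->U.U", "A.U->G.U", "A.U->C.U", "G.C->A.C")),
    paste("A2", c("A.U->G.U", "U.A->A.A")),
    paste("A3", c("G.S->A.S", "C.Q->A.Q", "G.M->U.M", "U.Q->A.Q",
                  "A.{->G.{"))))
}
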