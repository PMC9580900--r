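# Selection statistics: %GC with fractional expected contribution from
# degenerate bases, and melting temperature by unified nearest-neighbor
# thermodynamics (short oligos fall back to the Wallace 2/4 rule).

# expected GC fraction per IUPAC letter: |set intersect {G,C}| / |set|
IUPAC_GC_FRAC <- vapply(IUPAC_SETS, function(s) {
  mean(s %in% c("G", "C"))
}, numeric(1))

#' Percent GC of a sequence
#'
#' S counts as GC, W as AT; other degenerate codes contribute their expected
#' GC fraction (N = 0.5, R = 0.5, B = 2/3, ...).
#'
#' @param bases IUPAC string.
#' @return Percent in `[0, 100]`.
#' @export
gc_percent <- function(bases) {
  codes <- iupac_codes(bases)
  100 * mean(IUPAC_GC_FRAC[codes])
}

# Unified NN parameters (kcal/mol for dH; cal/mol/K for dS), keyed by the
# top-strand dinucleotide read 5'->3'.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Oligo melting temperature
#'
#' Nearest-neighbor thermodynamics with the unified parameter set; entropy
#' is salt-corrected with 0.368 (N-1) ln[Na+].  Tm = 1000 dH / (dS + R ln(C/4))
#' - 273.15, strand concentration C in mol/L.  Sequences shorter than 8 nt
#' use the Wallace 2/4 rule.  Degenerate bases are resolved to the first
#' base of their set for the thermodynamic sum.
#'
#' @param bases Primer/selection sequence.
#' @param na_mM Monovalent cation concentration, mM (default 50).
#' @param oligo_nM Oligo concentration, nM (default 250).
#' @return Tm in Celsius.
#' @export
tm_nn <- function(bases, na_mM = 50, oligo_nM = 250) {
  seq <- toupper(bases)
  check_iupac(seq)
  # collapse degeneracy deterministically
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch <- vapply(ch, function(x) IUPAC_SETS[[x]][1], character(1))
  n <- length(ch)
  if (n < 8L) {
    return(2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C")))
  }
  dinuc <- paste0(ch[-n], ch[-1])
  dH <- sum(NN_DH[dinuc])
  dS <- sum(NN_DS[dinuc])
  # terminal initiation penalties
  for (end in c(ch[1], ch[n])) {
    if (end %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  dS <- dS + 0.368 * (n - 1) * log(na_mM / 1000)
  R <- 1.9872
  ct <- oligo_nM * 1e-9
  1000 * dH / (dS + R * log(ct / 4)) - 273.15
}

#' Quick statistics for a selection
#'
#' @param bases Selected sequence text.
#' @param start 1-based start of the selection in its parent (used for the
#'   reading-frame offset).
#' @param na_mM,oligo_nM Tm model conditions; see [tm_nn()].
#' @return One-row tibble: `length`, `gc_percent`, `tm_celsius`,
#'   `frame_offset` (0/1/2, offset of the selection start from frame 1).
#' @examples
#' selection_stats("GGCC")
#' @export
selection_stats <- function(bases, start = 1L, na_mM = 50, oligo_nM = 250) {
  if (nchar(bases) == 0L) stop("empty selection", call. = FALSE)
  tibble::tibble(
    length = nchar(bases),
    gc_percent = gc_percent(bases),
    tm_celsius = tm_nn(bases, na_mM = na_mM, oligo_nM = oligo_nM),
    frame_offset = (as.integer(start) - 1L) %% 3L
  )
}
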