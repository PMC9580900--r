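# Genetic codes and translation.  Tables are inlined (NCBI numbering);
# translation itself is a plain codon walk so that degenerate codons fall
# back to 'X' unless every expansion agrees.

GENETIC_CODES <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0)))
  # NCBI table 1 amino acids in TCAG codon order
  aa1 <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  t1 <- stats::setNames(aa1, codons)
  t2 <- t1; t2[c("AGA", "AGG")] <- "*"; t2["ATA"] <- "M"; t2["TGA"] <- "W"
  t5 <- t1; t5[c("AGA", "AGG")] <- "S"; t5["ATA"] <- "M"; t5["TGA"] <- "W"
  t11 <- t1 # bacterial/plastid: same translations, different start policy
  list(`1` = t1, `2` = t2, `5` = t5, `11` = t11)
})

AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              E = "Glu", Q = "Gln", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              `*` = "***", X = "Xaa")

# average residue masses (Da); peptide MW = sum(residues) + water
AA_AVG_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                 C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
                 H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                 M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
                 T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_AVG_MASS <- 18.01524

translate_codon <- function(codon, table) {
  codon <- toupper(codon)
  aa <- table[codon]
  if (!is.na(aa)) return(unname(aa))
  # degenerate codon: translate every expansion; agreement or 'X'
  sets <- IUPAC_SETS[strsplit(codon, "", fixed = TRUE)[[1]]]
  if (any(vapply(sets, is.null, logical(1)))) return("X")
  combos <- expand.grid(sets[[1]], sets[[2]], sets[[3]], stringsAsFactors = FALSE)
  aas <- unique(table[paste0(combos[[1]], combos[[2]], combos[[3]])])
  if (length(aas) == 1L) unname(aas) else "X"
}

#' Translate a nucleotide sequence
#'
#' Codon-wise translation; a trailing partial codon is ignored; stop codons
#' render as `*`.  The returned string carries the amino-acid count and the
#' predicted average molecular weight (Da) as attributes `n_aa` and `mw`
#' (stops and X excluded from the mass).
#'
#' @param bases Nucleotide string (length >= 3).
#' @param code NCBI genetic-code table id (1, 2, 5 or 11).
#' @param letters 1 for one-letter, 3 for three-letter codes.
#' @return Protein string with attributes `n_aa` and `mw`.
#' @examples
#' translate_dna("ATGAAATAA")
#' translate_dna("ATGGCC", letters = 3)
#' @export
translate_dna <- function(bases, code = 1, letters = 1) {
  check_iupac(bases)
  if (nchar(bases) < 3L) stop("selection shorter than one codon", call. = FALSE)
  table <- GENETIC_CODES[[as.character(code)]]
  if (is.null(table)) stop(sprintf("unsupported genetic code table %s", code),
                           call. = FALSE)
  n_codon <- nchar(bases) %/% 3L
  aas <- vapply(seq_len(n_codon), function(i) {
    translate_codon(substr(bases, 3L * i - 2L, 3L * i), table)
  }, character(1))
  out <- if (letters == 3) paste(AA_THREE[aas], collapse = "")
         else paste(aas, collapse = "")
  res <- aas[!(aas %in% c("*", "X"))]
  structure(out, n_aa = length(aas),
            mw = if (length(res)) sum(AA_AVG_MASS[res]) + WATER_AVG_MASS
                 else WATER_AVG_MASS)
}

#' Average molecular weight of a peptide (one-letter string)
#' @param protein One-letter protein string; `*` and `X` ignored.
#' @return Weight in Daltons.
#' @export
protein_mw <- function(protein) {
  aas <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  aas <- aas[aas %in% names(AA_AVG_MASS)]
  sum(AA_AVG_MASS[aas]) + WATER_AVG_MASS
}
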