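# dCAPS assay design: a genotyping primer carrying a small number of
# template mismatches near (but not at) its 3' end creates a restriction
# site in the amplicon of exactly one allele.  Every returned design is
# verified end-to-end by simulating both allele amplicons and digesting
# them.

dcaps_one_strand <- function(template_seq, snp_position, ref_base, alt_base,
                             enzymes, max_primer_edits, amplicon_length_target,
                             primer_len, edit_zone, strand_label) {
  n <- nchar(template_seq)
  tch <- strsplit(toupper(template_seq), "", fixed = TRUE)[[1]]
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  if (tch[snp_position] != ref_base) {
    stop(sprintf("reference base at position %d is %s, not %s",
                 snp_position, tch[snp_position], ref_base), call. = FALSE)
  }
  rows <- list()
  p5 <- snp_position - primer_len # primer covers p5..snp-1
  if (p5 < 1L) return(rows)
  fpos <- p5 + amplicon_length_target - 1L # far (reverse) primer 3' end
  if (fpos > n || fpos <= snp_position + 10L) return(rows)
  far_primer <- reverse_complement(substr(template_seq, fpos - primer_len + 1L,
                                          fpos))
  allele_template <- function(base) {
    x <- tch; x[snp_position] <- base
    paste(x, collapse = "")
  }
  for (ei in seq_len(nrow(enzymes))) {
    e <- enzymes[ei, ]
    for (orient in c("+", "-")) {
      recog <- if (orient == "+") e$recognition else
        reverse_complement(e$recognition)
      if (orient == "-" && is_palindrome_iupac(e$recognition)) next
      m <- nchar(recog)
      rec_sets <- IUPAC_SETS[strsplit(toupper(recog), "", fixed = TRUE)[[1]]]
      for (q in (snp_position - m + 1L):snp_position) {
        if (q < p5 || q + m - 1L > n) next
        edits <- integer(0)
        feasible <- TRUE
        for (idx in seq_len(m)) {
          pos <- q + idx - 1L
          set <- rec_sets[[idx]]
          if (pos == snp_position) {
            if (!xor(ref_base %in% set, alt_base %in% set)) {
              feasible <- FALSE; break
            }
          } else if (pos < snp_position) {
            if (!(tch[pos] %in% set)) {
              dist <- snp_position - 1L - pos # 0 = primer 3' terminus
              if (dist < 1L || dist > edit_zone - 1L) { feasible <- FALSE; break }
              edits <- c(edits, pos)
            }
          } else {
            if (!(tch[pos] %in% set)) { feasible <- FALSE; break }
          }
        }
        if (!feasible || length(edits) > max_primer_edits ||
            length(edits) == 0L) next
        pch <- tch[p5:(snp_position - 1L)]
        for (pos in edits) {
          pch[pos - p5 + 1L] <- rec_sets[[pos - q + 1L]][1]
        }
        primer_seq <- paste(pch, collapse = "")
        # end-to-end verification on both alleles
        bands <- list()
        cut_flags <- logical(2)
        for (ai in 1:2) {
          base <- c(ref_base, alt_base)[ai]
          tmpl <- allele_template(base)
          amplicon <- paste0(primer_seq,
                             substr(tmpl, snp_position, fpos))
          frs <- digest(dna_record(amplicon), e)
          bands[[ai]] <- sort(fragments_tbl(frs)$size, decreasing = TRUE)
          cut_flags[ai] <- length(frs) > 1L
        }
        if (sum(cut_flags) != 1L) next
        rows[[length(rows) + 1L]] <- tibble::tibble(
          enzyme = e$name, strand = strand_label,
          primer = primer_seq, far_primer = far_primer,
          n_edits = length(edits),
          edits = list(sprintf("%s%d>%s", tch[edits], edits,
                               vapply(edits, function(p) {
                                 rec_sets[[p - q + 1L]][1]
                               }, character(1)))),
          cut_allele = c("ref", "alt")[cut_flags],
          amplicon_length = amplicon_length_target,
          bands_ref = bands[1], bands_alt = bands[2])
      }
    }
  }
  rows
}

#' Design dCAPS genotyping assays for a SNP
#'
#' For each enzyme, searches placements of the recognition sequence over
#' the SNP such that at most `max_primer_edits` primer-template mismatches
#' (confined to the last `edit_zone` primer bases, terminal base excluded)
#' create the site in exactly one allele's amplicon.  Designs are verified
#' by simulating and digesting both allele amplicons; expected band sizes
#' per allele are reported.  Both primer orientations are explored.
#'
#' @param template A [dna_record()] or string.
#' @param snp_position 1-based SNP position.
#' @param ref_base,alt_base The two allele bases; `ref_base` must match the
#'   template.
#' @param enzymes Enzyme tibble.
#' @param max_primer_edits Maximum primer-template differences (default 2).
#' @param amplicon_length_target Desired amplicon length (default 250).
#' @param primer_len Genotyping-primer length (default 20).
#' @param edit_zone Primer 3' window hosting edits (default 6, terminal
#'   excluded).
#' @return Tibble of designs; empty (with a message attribute) when no
#'   enzyme/edit combination works.
#' @export
design_dcaps <- function(template, snp_position, ref_base, alt_base, enzymes,
                         max_primer_edits = 2L, amplicon_length_target = 250L,
                         primer_len = 20L, edit_zone = 6L) {
  if (inherits(template, "dna_record")) template <- template$bases
  check_iupac(template)
  n <- nchar(template)
  fwd <- dcaps_one_strand(template, snp_position, ref_base, alt_base, enzymes,
                          max_primer_edits, amplicon_length_target,
                          primer_len, edit_zone, "+")
  rc <- reverse_complement(template)
  comp1 <- function(b) IUPAC_COMPLEMENT[toupper(b)]
  rev <- dcaps_one_strand(rc, n - snp_position + 1L,
                          comp1(ref_base), comp1(alt_base), enzymes,
                          max_primer_edits, amplicon_length_target,
                          primer_len, edit_zone, "-")
  out <- dplyr::bind_rows(c(fwd, rev))
  if (nrow(out) == 0L) {
    attr(out, "diagnostic") <-
      "no enzyme/edit combination creates an allele-specific site"
  }
  out
}
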