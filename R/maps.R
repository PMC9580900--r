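# Text renderings: the multi-track text map and the six-frame ORF map.

#' Fixed-width text map of a record
#'
#' 60 bases per line; requested tracks are stacked under (or above) each
#' sequence line: enzyme names above their recognition start column, the
#' 1-based position index at the line start, frame-1 translation, the
#' base-wise complement (bottom strand, not reversed) and feature bars.
#'
#' @param rec A [dna_record()].
#' @param tracks Subset of `c("enzymes", "index", "translation",
#'   "bottom_strand", "features")`.
#' @param enzymes Enzyme tibble for the enzyme track.
#' @param width Bases per line.
#' @return Character vector of lines.
#' @export
text_map <- function(rec, tracks = c("index", "features"),
                     enzymes = NULL, width = 60L) {
  n <- seq_length(rec)
  pad <- 10L # label gutter
  sites <- if ("enzymes" %in% tracks && !is.null(enzymes)) {
    find_cut_sites(rec, enzymes)
  } else NULL
  prot <- if ("translation" %in% tracks) {
    as.character(translate_dna(substr(rec$bases, 1, n - n %% 3L)))
  } else NULL
  out <- character()
  for (from in seq(1L, n, by = width)) {
    to <- min(from + width - 1L, n)
    seg <- substr(rec$bases, from, to)
    if (!is.null(sites) && nrow(sites)) {
      here <- sites[sites$recognition_start >= from & sites$recognition_start <= to, ]
      if (nrow(here)) {
        # greedy stacking of enzyme labels
        layers <- list()
        for (r in seq_len(nrow(here))) {
          col <- here$recognition_start[r] - from + 1L
          lab <- here$enzyme[r]
          placed <- FALSE
          for (li in seq_along(layers)) {
            line <- layers[[li]]
            span <- col:(col + nchar(lab) - 1L)
            if (all(substring(line, span, span) == " ")) {
              substr(line, col, col + nchar(lab) - 1L) <- lab
              layers[[li]] <- line
              placed <- TRUE
              break
            }
          }
          if (!placed) {
            line <- strrep(" ", width)
            substr(line, col, col + nchar(lab) - 1L) <- lab
            layers[[length(layers) + 1L]] <- line
          }
        }
        for (line in rev(layers)) {
          out <- c(out, paste0(strrep(" ", pad), line))
        }
      }
    }
    label <- if ("index" %in% tracks) sprintf("%8d  ", from) else strrep(" ", pad)
    out <- c(out, paste0(label, seg))
    if ("bottom_strand" %in% tracks) {
      out <- c(out, paste0(strrep(" ", pad), complement_bases(seg)))
    }
    if (!is.null(prot)) {
      tr <- strrep(" ", width)
      for (ci in seq(from, to, by = 1L)) {
        if ((ci - 1L) %% 3L == 0L && ci %/% 3L < nchar(prot) + 1L && ci %% 3L == 1L) {
          aa <- substr(prot, (ci + 2L) %/% 3L, (ci + 2L) %/% 3L)
          if (nzchar(aa)) substr(tr, ci - from + 1L, ci - from + 1L) <- aa
        }
      }
      out <- c(out, paste0(strrep(" ", pad), tr))
    }
    if ("features" %in% tracks && nrow(rec$features)) {
      for (fi in seq_len(nrow(rec$features))) {
        f <- rec$features[fi, ]
        if (f$hidden) next
        for (si in seq_len(nrow(f$segments[[1]]))) {
          s <- f$segments[[1]][si, "start"]; e <- f$segments[[1]][si, "end"]
          if (s > e) next # wrap segments rendered on their own lines
          if (e < from || s > to) next
          c1 <- max(s, from) - from + 1L
          c2 <- min(e, to) - from + 1L
          bar <- strrep(" ", width)
          substr(bar, c1, c2) <- strrep("=", c2 - c1 + 1L)
          out <- c(out, paste0(strrep(" ", pad), bar, " ", f$name))
        }
      }
    }
  }
  out
}

STOP_CLASS <- c(TAG = "amber", TAA = "ochre", TGA = "opal")

#' Six-frame ORF map as text
#'
#' Marks ATG starts (`M`) and stop codons (`*`) in all six frames;
#' stop-to-stop regions of at least `min_region` bases are highlighted
#' with dashes.  The regions are attached as attribute `regions`
#' (tibble: `frame`, `start`, `end`, `width`).
#'
#' @param rec A [dna_record()] or string.
#' @param min_region Minimum highlighted region width in bases.
#' @return Character vector of 6 lines (+1 index line), with attribute
#'   `regions`.
#' @export
orf_map_text <- function(rec, min_region = 300L) {
  if (is.character(rec)) rec <- dna_record(rec)
  n <- seq_length(rec)
  lines <- character(6)
  regions <- list()
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  for (fi in seq_along(frames)) {
    fr <- frames[fi]
    seq <- if (fr > 0L) toupper(rec$bases) else reverse_complement(toupper(rec$bases))
    off <- abs(fr) - 1L
    row <- strrep(".", n)
    n_codon <- (n - off) %/% 3L
    if (n_codon >= 1L) {
      codons <- substring(seq, off + 3L * seq_len(n_codon) - 2L,
                          off + 3L * seq_len(n_codon))
      marks <- ifelse(codons == "ATG", "M",
                      ifelse(codons %in% names(STOP_CLASS), "*", NA))
      stops <- which(codons %in% names(STOP_CLASS))
      seg_bounds <- c(0L, stops, n_codon + 1L)
      for (k in seq_len(length(seg_bounds) - 1L)) {
        first <- seg_bounds[k] + 1L
        last <- seg_bounds[k + 1L] - 1L
        if (first > last) next
        wbases <- (last - first + 1L) * 3L
        if (wbases < min_region) next
        s_local <- off + 3L * (first - 1L) + 1L
        e_local <- off + 3L * last
        s_top <- if (fr > 0L) s_local else n - e_local + 1L
        e_top <- if (fr > 0L) e_local else n - s_local + 1L
        regions[[length(regions) + 1L]] <- tibble::tibble(
          frame = fr, start = s_top, end = e_top, width = wbases)
        for (pp in s_top:e_top) {
          if (substr(row, pp, pp) == ".") substr(row, pp, pp) <- "-"
        }
      }
      for (ci in which(!is.na(marks))) {
        s_local <- off + 3L * ci - 2L
        p <- if (fr > 0L) s_local else n - (s_local + 2L) + 1L
        substr(row, p, p) <- marks[ci]
      }
    }
    lines[fi] <- sprintf("%+d %s", fr, row)
  }
  structure(lines, regions = if (length(regions)) dplyr::bind_rows(regions)
            else tibble::tibble(frame = integer(), start = integer(),
                                end = integer(), width = integer()))
}

#' Classify a stop codon
#' @param codon `"TAG"`, `"TAA"` or `"TGA"`.
#' @return `"amber"`, `"ochre"` or `"opal"`.
#' @export
stop_codon_class <- function(codon) {
  unname(STOP_CLASS[toupper(codon)])
}
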