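# Sequence search and ORF scanning.

# Positions of `query` in `subject` (both plain strings), degenerate
# semantics with up to max_mismatch mismatching positions; optionally the
# final `anchored_3prime` query bases must match exactly.
match_positions <- function(subject, query, max_mismatch = 0L,
                            anchored_3prime = 0L, degenerate = TRUE) {
  n <- nchar(subject); m <- nchar(query)
  if (m == 0L || n < m) return(integer(0))
  sb <- iupac_bits_vec(subject)
  qb <- if (degenerate) iupac_bits_vec(query) else NULL
  starts <- seq_len(n - m + 1L)
  mism <- integer(length(starts))
  ok_anchor <- rep(TRUE, length(starts))
  sq <- strsplit(toupper(subject), "", fixed = TRUE)[[1]]
  qq <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
  for (i in seq_len(m)) {
    hit <- if (degenerate) {
      bitwAnd(sb[starts + i - 1L], qb[i]) > 0L
    } else {
      sq[starts + i - 1L] == qq[i]
    }
    mism <- mism + !hit
    if (anchored_3prime > 0L && i > m - anchored_3prime) {
      ok_anchor <- ok_anchor & hit
    }
  }
  starts[mism <= max_mismatch & ok_anchor]
}

#' Search a record for a query string
#'
#' @param rec A [dna_record()] (or plain string, treated as a linear top
#'   strand).
#' @param query Query text. In `degenerate` mode letters are IUPAC sets
#'   (`N` matches any base); `literal` compares characters; `amino_acid`
#'   finds all codon spellings of the residue string across the frames of
#'   the searched strands.
#' @param mode One of `"degenerate"`, `"literal"`, `"amino_acid"`.
#' @param strand `"top"` or `"both"`.
#' @param case_sensitive Only meaningful for `literal` mode.
#' @param max_mismatch Allowed mismatches (nucleotide modes).
#' @param anchored_3prime Number of 3'-terminal query bases required to
#'   match exactly (mismatches allowed elsewhere).
#' @param code Genetic-code table for `amino_acid` mode.
#' @return Tibble: `start`, `end` (1-based, top-strand coordinates),
#'   `strand`, `match` (matched top-strand text).
#' @examples
#' pk_search(dna_record("AGATTCA"), "GANTC")
#' @export
pk_search <- function(rec, query, mode = c("degenerate", "literal", "amino_acid"),
                      strand = c("top", "both"), case_sensitive = FALSE,
                      max_mismatch = 0L, anchored_3prime = 0L, code = 1) {
  mode <- match.arg(mode)
  strand <- match.arg(strand)
  if (is.character(rec)) rec <- dna_record(rec, name = "query_subject")
  stopifnot(nchar(query) > 0L, max_mismatch >= 0L)
  n <- seq_length(rec)
  subject <- rec$bases
  # circular records: extend so matches can wrap the origin
  ext <- if (rec$topology == "circular") {
    k <- min(n, max(nchar(query) * 3L, nchar(query) + 2L))
    paste0(subject, substr(subject, 1, k - 1L))
  } else subject

  hits <- list()
  add_hits <- function(starts, width, str) {
    starts <- starts[starts <= n] # dedupe wrap-around duplicates
    if (!length(starts)) return()
    ends <- ((starts + width - 2L) %% n) + 1L
    hits[[length(hits) + 1L]] <<- tibble::tibble(
      start = as.integer(starts), end = as.integer(ends), strand = str,
      match = vapply(starts, function(s) subseq_bases(rec, s, ((s + width - 2L) %% n) + 1L),
                     character(1))
    )
  }

  if (mode == "amino_acid") {
    aa <- toupper(query)
    bad <- setdiff(strsplit(aa, "", fixed = TRUE)[[1]],
                   c(names(AA_AVG_MASS), "*"))
    if (length(bad)) {
      stop(sprintf("invalid amino-acid letter '%s'", bad[1]), call. = FALSE)
    }
    width <- 3L * nchar(aa)
    table <- GENETIC_CODES[[as.character(code)]]
    scan_aa <- function(subj_str, str) {
      nn <- nchar(subj_str)
      if (nn < width) return()
      up <- toupper(subj_str)
      for (off in 0:2) {
        n_codon <- (nn - off) %/% 3L
        if (n_codon < nchar(aa)) next
        codons <- substring(up, off + 3L * seq_len(n_codon) - 2L,
                            off + 3L * seq_len(n_codon))
        prot <- paste(unname(table[codons]), collapse = "")
        pos <- gregexpr(aa, prot, fixed = TRUE)[[1]]
        if (pos[1] == -1L) next
        starts_local <- off + 3L * (as.integer(pos) - 1L) + 1L
        if (str == "+") {
          add_hits(starts_local, width, "+")
        } else {
          # map bottom-strand local coords back to top strand
          ts <- nchar(subj_str) - (starts_local + width - 1L) + 1L
          ts <- ((ts - 1L) %% n) + 1L
          add_hits(ts, width, "-")
        }
      }
    }
    scan_aa(ext, "+")
    if (strand == "both") scan_aa(reverse_complement(ext), "-")
  } else {
    degenerate <- mode == "degenerate"
    subj <- ext; q <- query
    if (!case_sensitive || degenerate) { subj <- toupper(subj); q <- toupper(q) }
    if (mode == "literal") {
      ss <- strsplit(subj, "", fixed = TRUE)[[1]]
      qqv <- strsplit(q, "", fixed = TRUE)[[1]]
      m <- length(qqv)
      starts <- seq_len(max(0L, nchar(subj) - m + 1L))
      mism <- integer(length(starts))
      for (i in seq_len(m)) mism <- mism + (ss[starts + i - 1L] != qqv[i])
      add_hits(starts[mism <= max_mismatch], m, "+")
    } else {
      add_hits(match_positions(subj, q, max_mismatch, anchored_3prime), nchar(q), "+")
    }
    if (strand == "both") {
      rq <- reverse_complement(q)
      starts <- if (mode == "literal") {
        match_positions(subj, rq, max_mismatch, 0L, degenerate = FALSE)
      } else {
        # anchored 3' bases of the query are at the *left* end of the
        # reverse-complemented pattern on the top strand
        ss2 <- match_positions(subj, rq, max_mismatch, 0L)
        if (anchored_3prime > 0L) {
          keep <- vapply(ss2, function(s) {
            length(match_positions(substr(subj, s, s + anchored_3prime - 1L),
                                   substr(rq, 1, anchored_3prime), 0L)) > 0L
          }, logical(1))
          ss2[keep]
        } else ss2
      }
      add_hits(starts, nchar(q), "-")
    }
  }
  out <- if (length(hits)) dplyr::bind_rows(hits) else {
    tibble::tibble(start = integer(), end = integer(), strand = character(),
                   match = character())
  }
  dplyr::arrange(dplyr::distinct(out), .data$start, .data$strand)
}

#' Find open reading frames
#'
#' An ORF is a stop-to-stop frame segment; with `require_atg` the reported
#' span is trimmed to the first ATG.  The span runs to the stop codon
#' inclusive.  Circular records are scanned across the origin.
#'
#' @param rec A `dna_record` (or string).
#' @param min_len_codons Minimum length in codons (span/3, stop included).
#' @param require_atg Require the ORF to begin with ATG.
#' @param strand `"+"`, `"-"` or `"both"`.
#' @param from_position Optional anchor: with `direction = "next"` returns
#'   ORFs starting at/after it first; `"previous"` the reverse.
#' @param direction `"next"` or `"previous"` relative to `from_position`.
#' @param code Genetic-code table id.
#' @return Tibble: `start`, `end`, `strand`, `frame`, `n_codons`. Ordering:
#'   smallest start, then longest.
#' @export
find_orfs <- function(rec, min_len_codons = 1L, require_atg = TRUE,
                      strand = c("both", "+", "-"), from_position = NULL,
                      direction = c("next", "previous"), code = 1) {
  strand <- match.arg(strand)
  direction <- match.arg(direction)
  if (is.character(rec)) rec <- dna_record(rec)
  stopifnot(min_len_codons >= 1L)
  n <- seq_length(rec)
  table <- GENETIC_CODES[[as.character(code)]]
  stops <- names(table)[table == "*"]

  orf_scan <- function(seq, str) {
    res <- list()
    nn <- nchar(seq)
    up <- toupper(seq)
    for (off in 0:2) {
      n_codon <- (nn - off) %/% 3L
      if (n_codon < 1L) next
      codons <- substring(up, off + 3L * seq_len(n_codon) - 2L,
                          off + 3L * seq_len(n_codon))
      stop_idx <- which(codons %in% stops)
      seg_bounds <- c(0L, stop_idx) # segments end at each stop
      for (k in seq_along(stop_idx)) {
        first <- seg_bounds[k] + 1L
        last <- stop_idx[k]
        if (first > last) next
        if (require_atg) {
          atg <- which(codons[first:last] == "ATG")
          if (!length(atg)) next
          first <- first + atg[1] - 1L
        }
        len_codons <- last - first + 1L
        if (len_codons < min_len_codons) next
        s_local <- off + 3L * (first - 1L) + 1L
        e_local <- off + 3L * last
        res[[length(res) + 1L]] <- c(s_local, e_local, len_codons, off)
      }
    }
    if (!length(res)) return(NULL)
    m <- do.call(rbind, res)
    if (str == "+") {
      tibble::tibble(start = ((m[, 1] - 1L) %% n) + 1L,
                     end = ((m[, 2] - 1L) %% n) + 1L,
                     strand = "+", frame = m[, 4] + 1L, n_codons = m[, 3])
    } else {
      # local coords are on the reverse complement; map back
      s_top <- nchar(seq) - m[, 2] + 1L
      e_top <- nchar(seq) - m[, 1] + 1L
      tibble::tibble(start = ((s_top - 1L) %% n) + 1L,
                     end = ((e_top - 1L) %% n) + 1L,
                     strand = "-", frame = -(m[, 4] + 1L), n_codons = m[, 3])
    }
  }

  seq <- rec$bases
  ext <- if (rec$topology == "circular") paste0(seq, substr(seq, 1, n - 1L)) else seq
  out <- list()
  if (strand %in% c("both", "+")) out <- c(out, list(orf_scan(ext, "+")))
  if (strand %in% c("both", "-")) {
    out <- c(out, list(orf_scan(reverse_complement(ext), "-")))
  }
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character(), frame = integer(),
                          n_codons = integer()))
  }
  # circular extension can rediscover the same ORF shifted by n
  out <- dplyr::distinct(out, .data$start, .data$end, .data$strand,
                         .keep_all = TRUE)
  out <- dplyr::arrange(out, .data$start, dplyr::desc(.data$n_codons))
  if (!is.null(from_position)) {
    if (direction == "next") {
      out <- dplyr::arrange(out, .data$start < from_position, .data$start,
                            dplyr::desc(.data$n_codons))
    } else {
      out <- dplyr::arrange(out, .data$start >= from_position,
                            dplyr::desc(.data$start), dplyr::desc(.data$n_codons))
    }
  }
  out
}
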