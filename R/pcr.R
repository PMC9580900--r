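# Primer binding-site search (3'-anchored with mismatch tolerance), PCR
# product simulation, and de-novo primer scanning with hybridization
# screens.

#' Find primer binding sites on a template
#'
#' Alignment is anchored at the primer 3' end and walks 5'-ward: the
#' annealed region is the longest 3'-terminal run that keeps the mismatch
#' count within `max_mismatch`; any remaining primer 5' bases are treated
#' as a non-annealing tail and excluded from the mismatch count.  A site
#' is reported when the annealed region has at least `min_anneal`
#' template-matching bases and at most `max_3prime_mismatch` mismatches in
#' the 3'-terminal window (3 bases).  Both strands are searched; exact
#' 3'-hexamer candidates come from a position index (naive fallback when
#' 3' mismatches are allowed).
#'
#' @param template A [dna_record()] (or string).
#' @param primers Tibble with `name` and `sequence` columns (5'->3'), e.g.
#'   from [read_primer_list()].
#' @param min_anneal Minimum matched bases in the annealed region (>= 6).
#' @param max_mismatch Maximum mismatches in the annealed region (<= 10).
#' @param max_3prime_mismatch Mismatches allowed in the 3'-terminal window.
#' @param unique_only Keep only primers with exactly one site.
#' @param from_position Selection anchor used for `distance` reporting.
#' @return Tibble: `primer`, `sequence`, `strand`, `three_prime_position`,
#'   `match_count`, `mismatch_count`, `tm_matched_region`,
#'   `tm_full_primer`, `distance_from_selection`.
#' @export
find_binding_sites <- function(template, primers, min_anneal = 10L,
                               max_mismatch = 1L, max_3prime_mismatch = 0L,
                               unique_only = FALSE, from_position = 1L) {
  if (max_mismatch > 10L) {
    stop("at most ten mismatches are allowed in the primer", call. = FALSE)
  }
  stopifnot(min_anneal >= 6L)
  if (is.character(template)) template <- dna_record(template)
  n <- seq_length(template)
  top <- toupper(template$bases)
  circular <- template$topology == "circular"
  three_prime_window <- 3L

  strand_scan <- function(strand) {
    # work on the strand the primer anneals to as written 5'->3'
    subj <- if (strand == "+") top else reverse_complement(top)
    ext <- if (circular) paste0(subj, substr(subj, 1, n - 1L)) else subj
    sch <- strsplit(ext, "", fixed = TRUE)[[1]]
    rows <- list()
    for (pi in seq_len(nrow(primers))) {
      pseq <- toupper(primers$sequence[pi])
      pch <- strsplit(pseq, "", fixed = TRUE)[[1]]
      m <- length(pch)
      if (m < 6L) next
      # candidate 3'-end placements
      cand <- if (max_3prime_mismatch == 0L) {
        seed <- substr(pseq, m - 5L, m)
        hexamer_search(ext, seed) + 5L
      } else {
        seq_len(nchar(ext))
      }
      cand <- cand[cand >= min_anneal & cand <= nchar(ext)]
      for (e3 in cand) {
        # walk 5'-ward from the 3' end
        depth <- min(m, e3)
        pr <- pch[m:(m - depth + 1L)]
        tp <- sch[e3:(e3 - depth + 1L)]
        mm_cum <- cumsum(pr != tp)
        # annealed length: deepest extent within the mismatch budget that
        # ends (5'-most) on a matched base, so tail mismatches stay in the
        # tail
        ok <- which(mm_cum <= max_mismatch & pr == tp)
        if (!length(ok)) next
        L <- max(ok)
        mm <- mm_cum[L]
        matches <- L - mm
        if (matches < min_anneal) next
        if (sum((pr != tp)[seq_len(min(three_prime_window, L))]) >
            max_3prime_mismatch) next
        tpp <- if (strand == "+") ((e3 - 1L) %% n) + 1L else
          ((n - ((e3 - 1L) %% n) - 1L) %% n) + 1L
        rows[[length(rows) + 1L]] <- tibble::tibble(
          primer = primers$name[pi], sequence = primers$sequence[pi],
          strand = strand, three_prime_position = tpp,
          match_count = matches, mismatch_count = mm,
          tm_matched_region = tm_nn(substr(pseq, m - L + 1L, m)),
          tm_full_primer = tm_nn(pseq),
          distance_from_selection = abs(tpp - from_position))
      }
    }
    if (length(rows)) dplyr::bind_rows(rows) else NULL
  }
  out <- dplyr::bind_rows(strand_scan("+"), strand_scan("-"))
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble::tibble(primer = character(), sequence = character(),
                          strand = character(), three_prime_position = integer(),
                          match_count = integer(), mismatch_count = integer(),
                          tm_matched_region = numeric(), tm_full_primer = numeric(),
                          distance_from_selection = numeric()))
  }
  out <- dplyr::distinct(out, .data$primer, .data$strand,
                         .data$three_prime_position, .keep_all = TRUE)
  if (unique_only) {
    out <- out |>
      dplyr::group_by(.data$primer) |>
      dplyr::filter(dplyr::n() == 1L) |>
      dplyr::ungroup()
  }
  dplyr::arrange(out, .data$three_prime_position)
}

#' Read a primer list
#'
#' Accepts lines of `name<TAB>sequence` or bare sequences (auto-named).
#'
#' @param path File path, or `text` lines.
#' @param text Optional character vector of lines.
#' @return Tibble: `name`, `sequence`.
#' @export
read_primer_list <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) >= 2L) {
      tibble::tibble(name = f[1], sequence = toupper(gsub("\\s", "", f[2])))
    } else {
      tibble::tibble(name = sprintf("primer_%d", i),
                     sequence = toupper(gsub("\\s", "", f[1])))
    }
  })
  out <- dplyr::bind_rows(rows)
  for (s in out$sequence) check_iupac(s, "primer")
  out
}

#' Simulate a PCR reaction
#'
#' @param template A [dna_record()].
#' @param fwd,rev One row each from [find_binding_sites()]: a top-strand
#'   and a bottom-strand site with 3' ends facing each other.
#' @return Linear product [dna_record()]: full forward primer (tail
#'   included), the template span between the annealed regions, and the
#'   reverse complement of the full reverse primer; primer features and a
#'   provenance comment attached.
#' @export
simulate_pcr <- function(template, fwd, rev) {
  if (is.character(template)) template <- dna_record(template)
  n <- seq_length(template)
  if (fwd$strand == rev$strand) {
    stop("primers must sit on opposite strands with facing 3' ends",
         call. = FALSE)
  }
  if (fwd$strand != "+") { tmp <- fwd; fwd <- rev; rev <- tmp }
  a <- fwd$three_prime_position # top-strand 3' end
  b <- rev$three_prime_position # bottom-strand 3' end (top coordinate)
  if (template$topology == "linear" && a > b) {
    stop("forward 3' end lies beyond the reverse 3' end on a linear template",
         call. = FALSE)
  }
  gap_len <- if (a <= b) b - a - 1L else n - a + b - 1L
  middle <- if (gap_len > 0L) {
    subseq_bases(template, (a %% n) + 1L, ((a + gap_len - 1L) %% n) + 1L)
  } else ""
  product_seq <- paste0(fwd$sequence, middle, reverse_complement(rev$sequence))
  rec <- dna_record(product_seq,
                    name = sprintf("pcr_%s_%s", fwd$primer, rev$primer),
                    topology = "linear",
                    comment = provenance_comment(
                      "PCR", c(sprintf("template %s", template$name),
                               sprintf("fwd %s (%s)", fwd$primer, fwd$sequence),
                               sprintf("rev %s (%s)", rev$primer, rev$sequence))))
  np <- seq_length(rec)
  rec <- add_feature(rec, name = fwd$primer, start = 1L,
                     end = nchar(fwd$sequence), strand = "+",
                     type = "primer_bind")
  rec <- add_feature(rec, name = rev$primer,
                     start = np - nchar(rev$sequence) + 1L, end = np,
                     strand = "-", type = "primer_bind")
  rec
}

# longest complementary run between a and b (revcomp-sense pairing)
longest_comp_run <- function(a, b) {
  arc <- reverse_complement(toupper(a))
  bt <- toupper(b)
  best <- 0L
  na <- nchar(arc); nb <- nchar(bt)
  av <- strsplit(arc, "")[[1]]; bv <- strsplit(bt, "")[[1]]
  for (off in -(nb - 1L):(na - 1L)) {
    run <- 0L
    for (i in seq_len(min(na, nb))) {
      ia <- i + max(0L, off); ib <- i + max(0L, -off)
      if (ia > na || ib > nb) break
      if (av[ia] == bv[ib]) { run <- run + 1L; best <- max(best, run) }
      else run <- 0L
    }
  }
  best
}

# length of 3'-anchored complementary run of `a` against anywhere in `b`
three_prime_comp_run <- function(a, b) {
  au <- toupper(a); bu <- toupper(b)
  m <- nchar(au)
  for (L in m:1) {
    suffix <- substr(au, m - L + 1L, m)
    if (length(match_positions(bu, reverse_complement(suffix))) > 0L) return(L)
  }
  0L
}

#' Scan a selection for candidate primers
#'
#' Every window of the selection that satisfies the length, Tm, %GC and 3'
#' GC-clamp bounds is returned, minus candidates failing the hybridization
#' screens: longest self- (or cross-) complementary run >= `max_comp_run`,
#' complementary run against an immediately adjacent copy of the primer,
#' or a 3'-anchored complementary run >= `max_3p_run`.
#'
#' @param sel Selection sequence (string).
#' @param len_min,len_max Length bounds.
#' @param tm_min,tm_max Melting-temperature bounds (Celsius).
#' @param gc_min,gc_max Percent-GC bounds.
#' @param gc_clamp Number of terminal 3' bases required to be G/C.
#' @param against Optional primer sequence for the cross-hybridization
#'   screen.
#' @param max_comp_run,max_3p_run Screen thresholds (defaults 8 and 4).
#' @return Tibble: `start`, `end`, `sequence`, `length`, `tm`,
#'   `gc_percent`.
#' @export
find_candidate_primers <- function(sel, len_min = 18L, len_max = 25L,
                                   tm_min = 50, tm_max = 65,
                                   gc_min = 30, gc_max = 70, gc_clamp = 1L,
                                   against = NULL,
                                   max_comp_run = 8L, max_3p_run = 4L) {
  check_iupac(sel)
  ns <- nchar(sel)
  if (ns < len_min) {
    warning("selection shorter than the minimum primer length", call. = FALSE)
    return(tibble::tibble(start = integer(), end = integer(),
                          sequence = character(), length = integer(),
                          tm = numeric(), gc_percent = numeric()))
  }
  rows <- list()
  for (L in len_min:min(len_max, ns)) {
    for (s in seq_len(ns - L + 1L)) {
      cand <- toupper(substr(sel, s, s + L - 1L))
      gc <- gc_percent(cand)
      if (gc < gc_min || gc > gc_max) next
      tmv <- tm_nn(cand)
      if (tmv < tm_min || tmv > tm_max) next
      if (gc_clamp > 0L) {
        tail3 <- substr(cand, L - gc_clamp + 1L, L)
        if (!all(strsplit(tail3, "")[[1]] %in% c("G", "C"))) next
      }
      if (longest_comp_run(cand, cand) >= max_comp_run) next
      if (three_prime_comp_run(cand, cand) >= max_3p_run) next
      # adjacent hybridization: the primer against a tandem copy of itself
      if (longest_comp_run(cand, paste0(cand, cand)) >= max_comp_run) next
      if (!is.null(against)) {
        if (longest_comp_run(cand, against) >= max_comp_run) next
        if (three_prime_comp_run(cand, against) >= max_3p_run) next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        start = s, end = s + L - 1L, sequence = cand, length = L,
        tm = tmv, gc_percent = gc)
    }
  }
  if (!length(rows)) {
    warning("no candidate satisfies the constraints", call. = FALSE)
    return(tibble::tibble(start = integer(), end = integer(),
                          sequence = character(), length = integer(),
                          tm = numeric(), gc_percent = numeric()))
  }
  dplyr::bind_rows(rows)
}
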