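# Restriction analysis: hexamer-indexed site search with methylation
# blocking, digestion into typed fragments, partial digests, and the
# enzyme-set calculator.
#
# Cut-offset convention (documented once, used everywhere): offsets count
# inter-base positions from the 5' start of the top-strand recognition
# match, both measured on the top-strand coordinate line.  For EcoRI
# (G^AATTC) top_cut = 1 and bottom_cut = 5:
#
#        5'-G  A A T T  C-3'      top strand cut after offset 1
#        3'-C  T T A A  G-5'      bottom strand cut after offset 5
#             ^---------^         4-base 5' overhang AATT
#
# A cut site at recognition start p therefore cuts the top strand after
# position p - 1 + top_cut and the bottom strand after p - 1 + bottom_cut.
# Type IIS offsets may lie outside the recognition span.

# ---- hexamer index ------------------------------------------------------

HEX_SEED_CAP <- 4096L

build_hexamer_index <- function(seq) {
  n <- nchar(seq)
  if (n < 6L) return(NULL)
  hexes <- substring(seq, 1:(n - 5L), 6:n)
  split(seq_len(n - 5L), hexes)
}

# expansions of a degenerate window into concrete hexamers (NULL if too many)
expand_window <- function(window) {
  sets <- IUPAC_SETS[strsplit(toupper(window), "", fixed = TRUE)[[1]]]
  n_comb <- prod(lengths(sets))
  if (n_comb > HEX_SEED_CAP) return(NULL)
  combos <- do.call(expand.grid, c(sets, stringsAsFactors = FALSE))
  do.call(paste0, combos)
}

# choose the least-degenerate 6-wide window of the recognition as the seed
least_degenerate_window <- function(recognition) {
  m <- nchar(recognition)
  if (m < 6L) return(NULL)
  sets <- lengths(IUPAC_SETS[strsplit(toupper(recognition), "", fixed = TRUE)[[1]]])
  degeneracy <- vapply(1:(m - 5L), function(i) prod(sets[i:(i + 5L)]), numeric(1))
  offset <- which.min(degeneracy)
  list(offset = offset, window = substr(recognition, offset, offset + 5L))
}

# Hexamer-seeded degenerate pattern search; equals the naive sliding-window
# scan (its contract, enforced in the tests).  Falls back to the naive scan
# for short or hyper-degenerate patterns.
hexamer_search <- function(seq, pattern, index = NULL) {
  seed <- least_degenerate_window(pattern)
  sb <- iupac_bits_vec(seq)
  pb <- iupac_bits_vec(pattern)
  if (is.null(seed)) return(iupac_window_match(sb, pb))
  hexes <- expand_window(seed$window)
  if (is.null(hexes)) return(iupac_window_match(sb, pb))
  if (is.null(index)) index <- build_hexamer_index(toupper(seq))
  if (is.null(index)) return(iupac_window_match(sb, pb))
  cand <- sort(unique(unlist(index[hexes], use.names = FALSE))) - seed$offset + 1L
  cand <- cand[cand >= 1L & cand <= nchar(seq) - nchar(pattern) + 1L]
  if (!length(cand)) return(integer(0))
  m <- length(pb)
  ok <- rep(TRUE, length(cand))
  for (i in seq_len(m)) {
    ok <- ok & (bitwAnd(sb[cand + i - 1L], pb[i]) > 0L)
  }
  cand[ok]
}

# ---- site search --------------------------------------------------------

METHYLASE_PATTERNS <- c(dam = "GATC", dcm = "CCWGG")

# does any methylation rule fire for a site at recognition start p (strand
# of the *recognition match*); offsets in the rule are relative to the
# match start on the strand of the match.
methylation_blocked <- function(seq_bits, p, strand, rec_len,
                                rules, dam, dcm) {
  for (r in rules) {
    if ((r$methylase == "dam" && !dam) || (r$methylase == "dcm" && !dcm)) next
    pat_bits <- iupac_bits_vec(r$pattern)
    at <- if (strand == "+") p + r$offset
          else p + rec_len - 1L - r$offset - (nchar(r$pattern) - 1L)
    idx <- at + seq_along(pat_bits) - 1L
    if (any(idx < 1L | idx > length(seq_bits))) next
    if (all(bitwAnd(seq_bits[idx], pat_bits) > 0L)) return(TRUE)
  }
  FALSE
}

#' Locate restriction sites in a record
#'
#' Finds every occurrence of each enzyme's recognition sequence on both
#' strands via a hexamer position index with degenerate-expansion seeds
#' (equal, by contract, to a naive IUPAC sliding-window scan).  Sites whose
#' encoded Dam/Dcm methylation rule fires are suppressed when the
#' corresponding flag is on.  Circular records are scanned across the
#' origin.
#'
#' @param rec A [dna_record()] or plain string (treated as linear).
#' @param enzymes Tibble from [load_enzyme_file()] (subset rows to choose
#'   enzymes).
#' @param dam,dcm Treat the DNA as Dam/Dcm methylated.
#' @return Tibble: `enzyme`, `recognition_start`, `strand`, `top_cut`,
#'   `bottom_cut` (inter-base, cut after that position), `polarity`,
#'   `cuttable` (FALSE when a cut would fall off a linear end),
#'   `blocked` (methylation; blocked sites are excluded from the result).
#' @export
find_cut_sites <- function(rec, enzymes, dam = FALSE, dcm = FALSE) {
  if (is.character(rec)) rec <- dna_record(rec)
  n <- seq_length(rec)
  circular <- rec$topology == "circular"
  top <- toupper(rec$bases)
  max_rec <- max(c(nchar(enzymes$recognition),
                   abs(enzymes$top_cut), abs(enzymes$bottom_cut), 1L))
  ext <- if (circular) paste0(top, substr(top, 1, min(n, max_rec + 32L) - 1L)) else top
  ext_bits <- iupac_bits_vec(ext)
  index <- build_hexamer_index(ext)

  rows <- list()
  for (i in seq_len(nrow(enzymes))) {
    e <- enzymes[i, ]
    recog <- e$recognition
    L <- nchar(recog)
    palindrome <- is_palindrome_iupac(recog)
    orientations <- if (palindrome) "+" else c("+", "-")
    for (str in orientations) {
      pattern <- if (str == "+") recog else reverse_complement(recog)
      starts <- hexamer_search(ext, pattern, index)
      starts <- starts[starts <= n] # one hit per physical wrap site
      if (!length(starts)) next
      for (p in starts) {
        if (methylation_blocked(ext_bits, p, str, L,
                                e$methylation[[1]], dam, dcm)) next
        if (str == "+") {
          t_cut <- p - 1L + e$top_cut
          b_cut <- p - 1L + e$bottom_cut
        } else {
          t_cut <- p - 1L + (L - e$bottom_cut)
          b_cut <- p - 1L + (L - e$top_cut)
        }
        cuttable <- TRUE
        if (circular) {
          t_cut <- ((t_cut - 1L) %% n) + 1L
          b_cut <- ((b_cut - 1L) %% n) + 1L
        } else if (t_cut < 1L || t_cut > n - 1L || b_cut < 1L || b_cut > n - 1L) {
          cuttable <- FALSE
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          enzyme = e$name, recognition_start = ((p - 1L) %% n) + 1L,
          strand = str, top_cut = t_cut, bottom_cut = b_cut,
          polarity = e$polarity, cuttable = cuttable
        )
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    enzyme = character(), recognition_start = integer(), strand = character(),
    top_cut = integer(), bottom_cut = integer(), polarity = character(),
    cuttable = logical()
  )
  dplyr::arrange(dplyr::distinct(out), .data$top_cut, .data$enzyme)
}

# ---- digestion ----------------------------------------------------------

new_fragment <- function(extent, left_end, right_end, provenance = "",
                         size = NULL) {
  structure(list(extent = extent, left_end = left_end, right_end = right_end,
                 provenance = provenance,
                 size = size %||% nchar(extent)),
            class = "dna_fragment")
}

#' @export
print.dna_fragment <- function(x, ...) {
  fmt_end <- function(e) {
    if (e$polarity == "blunt") "blunt" else sprintf("%s/%s", e$polarity, e$seq)
  }
  cat(sprintf("<dna_fragment> %d bp [%s | %s] %s\n", x$size,
              fmt_end(x$left_end), fmt_end(x$right_end), x$provenance))
  invisible(x)
}

blunt_end <- function(phos = TRUE) list(polarity = "blunt", seq = "", phos = phos)

#' Digest a record with a set of enzymes
#'
#' A linear record with n cut sites yields n + 1 fragments; a circular
#' record with n >= 1 sites yields n fragments; an uncut circular record is
#' an explicit `"uncut"` condition, not a fragment list.  Fragment ends
#' carry the overhang sequence and polarity of the generating cut; fragment
#' order follows top-strand position and sizes are the distances between
#' successive top-strand cuts (they sum to the parent length).
#'
#' @inheritParams find_cut_sites
#' @return List of `dna_fragment` objects with attribute `sites` (the cut
#'   table).  For an uncut circular record, an error of class
#'   `pk_uncut_error`.
#' @export
digest <- function(rec, enzymes, dam = FALSE, dcm = FALSE) {
  if (is.character(rec)) rec <- dna_record(rec)
  n <- seq_length(rec)
  sites <- find_cut_sites(rec, enzymes, dam = dam, dcm = dcm)
  sites <- sites[sites$cuttable, , drop = FALSE]
  circular <- rec$topology == "circular"
  if (nrow(sites) == 0L) {
    if (circular) {
      stop(structure(class = c("pk_uncut_error", "error", "condition"),
                     list(message = sprintf("circular record '%s' is uncut",
                                            rec$name), call = NULL)))
    }
    f <- new_fragment(rec$bases, blunt_end(), blunt_end(),
                      provenance = sprintf("%s (undigested)", rec$name),
                      size = n)
    return(structure(list(f), sites = sites))
  }
  sites <- sites[order(sites$top_cut), , drop = FALSE]
  # two enzymes cutting at the same inter-base position are one cut event
  sites <- sites[!duplicated(sites$top_cut), , drop = FALSE]
  top <- rec$bases
  window_of <- function(k) {
    lo <- min(sites$top_cut[k], sites$bottom_cut[k])
    hi <- max(sites$top_cut[k], sites$bottom_cut[k])
    if (hi == lo) return("")
    s <- ((lo) %% n) + 1L; e <- ((hi - 1L) %% n) + 1L
    subseq_bases(rec, s, e)
  }
  site_end <- function(k) {
    if (sites$top_cut[k] == sites$bottom_cut[k]) return(blunt_end())
    list(polarity = if (sites$top_cut[k] < sites$bottom_cut[k]) "5p" else "3p",
         seq = window_of(k), phos = TRUE)
  }
  frags <- list()
  m <- nrow(sites)
  enz_of <- function(k) sites$enzyme[k]
  if (!circular) {
    bounds_t <- c(0L, sites$top_cut, n)
    for (k in seq_len(m + 1L)) {
      left_site <- if (k == 1L) NULL else k - 1L
      right_site <- if (k == m + 1L) NULL else k
      ext_from <- if (is.null(left_site)) 1L else
        min(sites$top_cut[left_site], sites$bottom_cut[left_site]) + 1L
      ext_to <- if (is.null(right_site)) n else
        max(sites$top_cut[right_site], sites$bottom_cut[right_site])
      frags[[k]] <- new_fragment(
        substr(top, ext_from, ext_to),
        if (is.null(left_site)) blunt_end() else site_end(left_site),
        if (is.null(right_site)) blunt_end() else site_end(right_site),
        provenance = sprintf("%s %d..%d (%s)", rec$name,
                             bounds_t[k] + 1L, bounds_t[k + 1L],
                             paste(unique(sites$enzyme), collapse = "+")),
        size = bounds_t[k + 1L] - bounds_t[k]
      )
    }
  } else {
    for (k in seq_len(m)) {
      nk <- if (k == m) 1L else k + 1L
      size <- sites$top_cut[nk] - sites$top_cut[k]
      if (size <= 0L) size <- size + n
      # extent runs from just after the upstream cut pair to the far edge
      # of the downstream one; with a single site it wraps the whole circle
      lw <- sites$top_cut[k] - min(sites$top_cut[k], sites$bottom_cut[k])
      rw <- max(sites$top_cut[nk], sites$bottom_cut[nk]) - sites$top_cut[nk]
      ext_from <- ((min(sites$top_cut[k], sites$bottom_cut[k])) %% n) + 1L
      frags[[k]] <- new_fragment(
        circ_substr(top, ext_from, size + lw + rw),
        site_end(k), site_end(nk),
        provenance = sprintf("%s cut %d..%d (%s)", rec$name,
                             sites$top_cut[k] + 1L, sites$top_cut[nk],
                             paste(unique(sites$enzyme), collapse = "+")),
        size = size
      )
    }
  }
  structure(frags, sites = sites)
}

#' Summarise fragments as a tibble
#' @param fragments List of `dna_fragment`s (e.g. from [digest()]).
#' @return Tibble: `size`, `left`, `right`, `provenance`.
#' @export
fragments_tbl <- function(fragments) {
  tibble::tibble(
    size = vapply(fragments, `[[`, numeric(1), "size"),
    left = vapply(fragments, function(f) f$left_end$polarity, character(1)),
    right = vapply(fragments, function(f) f$right_end$polarity, character(1)),
    provenance = vapply(fragments, `[[`, character(1), "provenance")
  )
}

# ---- partial digest -----------------------------------------------------

#' Partial digest of a record
#'
#' Enumerates all cut subsets of the located sites (capped at 16 sites);
#' each molecular species has molar abundance prod(p_cut) * prod(1 - p_cut),
#' fragments are aggregated by size, and mass share is proportional to
#' molar abundance times size, normalised to 100.
#'
#' @param rec A `dna_record`.
#' @param enzymes Enzyme tibble; one row per enzyme to apply.
#' @param fractions Named numeric vector: cut probability in `[0, 1]` per
#'   enzyme name (unnamed scalar recycles to all).
#' @param cap Maximum number of sites to enumerate (default 16).
#' @return Tibble lane: `size`, `molar_abundance`, `mass_percent`, sorted
#'   by decreasing size.
#' @export
partial_digest <- function(rec, enzymes, fractions, cap = 16L) {
  if (is.character(rec)) rec <- dna_record(rec)
  n <- seq_length(rec)
  circular <- rec$topology == "circular"
  sites <- find_cut_sites(rec, enzymes)
  sites <- sites[sites$cuttable, , drop = FALSE]
  sites <- sites[!duplicated(sites$top_cut), , drop = FALSE]
  m <- nrow(sites)
  if (m > cap) {
    stop(sprintf("%d sites exceeds the partial-digest cap (%d); run a full digest",
                 m, cap), call. = FALSE)
  }
  if (is.null(names(fractions))) {
    p_site <- rep(fractions[1], m)
  } else {
    p_site <- unname(fractions[sites$enzyme])
    if (anyNA(p_site)) stop("missing cut fraction for some enzyme", call. = FALSE)
  }
  species <- list()
  for (mask in 0:(2^m - 1)) {
    cut <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L)
    ab <- prod(p_site[cut], 1 - p_site[!cut])
    if (ab == 0) next
    cuts <- sort(sites$top_cut[cut])
    sizes <- if (!length(cuts)) {
      n
    } else if (circular) {
      d <- diff(c(cuts, cuts[1] + n))
      d
    } else {
      diff(c(0L, cuts, n))
    }
    species[[length(species) + 1L]] <- tibble::tibble(size = sizes,
                                                      molar_abundance = ab)
  }
  bands <- dplyr::bind_rows(species) |>
    dplyr::group_by(.data$size) |>
    dplyr::summarise(molar_abundance = sum(.data$molar_abundance),
                     .groups = "drop")
  bands$mass_percent <- 100 * bands$size * bands$molar_abundance /
    sum(bands$size * bands$molar_abundance)
  dplyr::arrange(bands, dplyr::desc(.data$size))
}

# ---- enzyme-set calculator ---------------------------------------------

#' Enzyme-set calculator
#'
#' Filters enzymes by site count (and optionally group membership) and
#' applies a set operation against the current selection.
#'
#' @param counts Tibble with columns `enzyme` and `n_sites` (e.g. counted
#'   from [find_cut_sites()]), plus optionally `groups` (list column).
#' @param want_count Single count or length-2 range accepted by the filter.
#' @param group Optional group tag the enzyme must carry.
#' @param current Character vector, the current enzyme set.
#' @param op `"select"` (union), `"deselect"` (difference) or `"and"`
#'   (intersection).
#' @return Character vector: the new enzyme set (sorted).
#' @export
enzyme_calculator <- function(counts, want_count, group = NULL,
                              current = character(),
                              op = c("select", "deselect", "and")) {
  op <- match.arg(op)
  rng <- if (length(want_count) == 1L) c(want_count, want_count) else range(want_count)
  filtered <- counts$enzyme[counts$n_sites >= rng[1] & counts$n_sites <= rng[2]]
  if (!is.null(group) && "groups" %in% names(counts)) {
    in_group <- counts$enzyme[vapply(counts$groups, function(g) group %in% g,
                                     logical(1))]
    filtered <- intersect(filtered, in_group)
  }
  out <- switch(op,
    select = union(current, filtered),
    deselect = setdiff(current, filtered),
    and = intersect(current, filtered)
  )
  sort(out)
}

#' Count cut sites per enzyme
#' @inheritParams find_cut_sites
#' @return Tibble: `enzyme`, `n_sites`, `groups`.
#' @export
count_sites <- function(rec, enzymes, dam = FALSE, dcm = FALSE) {
  sites <- find_cut_sites(rec, enzymes, dam = dam, dcm = dcm)
  tab <- table(factor(sites$enzyme, levels = enzymes$name))
  tibble::tibble(enzyme = enzymes$name, n_sites = as.integer(tab),
                 groups = enzymes$groups)
}

# ---- site-creating mutagenesis -----------------------------------------

#' Propose mutations that create a restriction site
#'
#' Silent mode enumerates every recognition placement in the selection
#' whose required edits leave the translation unchanged (the selection is
#' read in frame after `frame_offset` trimming); diagnostic mode accepts
#' any placement needing at most `max_changes` edits.  Existing (zero-edit)
#' sites are excluded.
#'
#' @param sel Selection sequence (string, read on the top strand).
#' @param enzymes Enzyme tibble.
#' @param mode `"silent"` or `"diagnostic"`.
#' @param max_changes Maximum base edits (diagnostic mode).
#' @param frame_offset 0, 1 or 2: bases to skip before the first codon
#'   (silent mode).
#' @param code Genetic-code table id.
#' @return Tibble: `enzyme`, `position` (placement start in selection
#'   coordinates), `strand`, `edits` (list of "A4>T" strings), `n_edits`,
#'   `site_start`, `site_end`.
#' @export
propose_site_mutations <- function(sel, enzymes, mode = c("silent", "diagnostic"),
                                   max_changes = 2L, frame_offset = 0L,
                                   code = 1) {
  mode <- match.arg(mode)
  check_iupac(sel)
  sel <- toupper(sel)
  n <- nchar(sel)
  sel_ch <- strsplit(sel, "", fixed = TRUE)[[1]]
  if (mode == "silent") {
    coding_len <- n - frame_offset
    if (coding_len %% 3L != 0L) {
      stop("silent mode requires selection length divisible by 3 after frame_offset trim",
           call. = FALSE)
    }
    ref_prot <- translate_dna(substr(sel, frame_offset + 1L, n), code = code)
  }
  rows <- list()
  for (i in seq_len(nrow(enzymes))) {
    e <- enzymes[i, ]
    for (str in c("+", "-")) {
      recog <- if (str == "+") e$recognition else reverse_complement(e$recognition)
      L <- nchar(recog)
      if (str == "-" && is_palindrome_iupac(e$recognition)) next
      if (L > n) next
      rec_sets <- IUPAC_SETS[strsplit(toupper(recog), "", fixed = TRUE)[[1]]]
      for (p in seq_len(n - L + 1L)) {
        idx <- p:(p + L - 1L)
        fits <- mapply(function(base, set) base %in% set, sel_ch[idx], rec_sets)
        mism <- idx[!fits]
        if (!length(mism)) next # existing site
        if (mode == "diagnostic") {
          if (length(mism) > max_changes) next
          edits <- vapply(mism, function(q) {
            set <- rec_sets[[q - p + 1L]]
            sprintf("%s%d>%s", sel_ch[q], q, set[1])
          }, character(1))
          rows[[length(rows) + 1L]] <- tibble::tibble(
            enzyme = e$name, position = p, strand = str,
            edits = list(edits), n_edits = length(mism),
            site_start = p, site_end = p + L - 1L)
        } else {
          # enumerate concrete base choices at the mismatch positions and
          # keep any combination that preserves the translation
          choices <- lapply(mism, function(q) rec_sets[[q - p + 1L]])
          grid <- do.call(expand.grid, c(choices, stringsAsFactors = FALSE))
          found <- NULL
          for (g in seq_len(nrow(grid))) {
            cand <- sel_ch
            cand[mism] <- as.character(grid[g, ])
            prot <- translate_dna(paste(cand[(frame_offset + 1L):n], collapse = ""),
                                  code = code)
            if (identical(as.character(prot), as.character(ref_prot))) {
              found <- as.character(grid[g, ]); break
            }
          }
          if (is.null(found)) next
          edits <- sprintf("%s%d>%s", sel_ch[mism], mism, found)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            enzyme = e$name, position = p, strand = str,
            edits = list(edits), n_edits = length(mism),
            site_start = p, site_end = p + L - 1L)
        }
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(enzyme = character(), position = integer(),
                          strand = character(), edits = list(),
                          n_edits = integer(), site_start = integer(),
                          site_end = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$enzyme, .data$position)
}
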