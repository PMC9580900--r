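# Golden Gate: assembly of type IIS fragments by overhang matching, and a
# designer that picks orthogonal overhangs by a seeded random walk and
# emits the PCR primers that realise them.

gg_internal_sites <- function(text, enzymes) {
  hits <- 0L
  for (i in seq_len(nrow(enzymes))) {
    recog <- enzymes$recognition[i]
    pats <- unique(c(recog, reverse_complement(recog)))
    for (p in pats) {
      hits <- hits + length(match_positions(text, p))
    }
  }
  hits
}

#' Simulate a Golden Gate assembly
#'
#' Digests every input with the chosen type IIS enzymes, keeps the
#' fragments carrying no residual recognition site (those flanked by
#' inward-facing sites), and searches for closed circular assemblies on
#' overhang compatibility.  All alternative closed circles are enumerated;
#' fragment reuse within one circle is not allowed.
#'
#' @param records List of [dna_record()]s (or `dna_fragment`s, used as-is).
#' @param enzymes 1-3 rows of an enzyme tibble; each must cut outside its
#'   recognition sequence.
#' @param max_products Stop after this many distinct products.
#' @return An `assembly_plan`; products carry no recognition sites for the
#'   chosen enzymes.
#' @export
golden_gate_assemble <- function(records, enzymes, max_products = 25L) {
  if (nrow(enzymes) < 1L || nrow(enzymes) > 3L) {
    stop("choose one to three type IIS enzymes", call. = FALSE)
  }
  outside <- enzymes$top_cut > nchar(enzymes$recognition) |
    enzymes$bottom_cut > nchar(enzymes$recognition)
  if (!all(outside)) {
    stop("Golden Gate requires enzymes cutting outside their recognition",
         call. = FALSE)
  }
  frags <- list()
  input_names <- character()
  for (r in records) {
    if (inherits(r, "dna_fragment")) {
      frags[[length(frags) + 1L]] <- r
      input_names <- c(input_names, r$provenance)
      next
    }
    input_names <- c(input_names, r$name)
    fl <- tryCatch(digest(r, enzymes), pk_uncut_error = function(e) NULL)
    if (is.null(fl)) next
    for (f in fl) {
      if (gg_internal_sites(f$extent, enzymes) == 0L &&
          f$left_end$polarity != "blunt" && f$right_end$polarity != "blunt") {
        frags[[length(frags) + 1L]] <- f
      }
    }
  }
  if (!length(frags)) stop("no usable type IIS fragments found", call. = FALSE)
  # both orientations of every fragment are available
  pool <- c(frags, lapply(frags, reverse_fragment))
  pool_id <- rep(seq_along(frags), 2L)

  products <- list()
  seen <- character()
  dangling <- character()
  # DFS over chains; a circle is only started at its smallest fragment id
  recurse <- function(chain, used) {
    if (length(products) >= max_products) return()
    last <- chain[[length(chain)]]
    first <- chain[[1]]
    if (length(chain) > 1L || junction_ok(last$right_end, first$left_end)) {
      if (junction_ok(last$right_end, first$left_end)) {
        seqn <- assemble_circle_sequence(chain)
        key <- canonical_rotation(seqn, strand_invariant = TRUE)
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          rec <- dna_record(
            seqn, name = sprintf("gg_product_%d", length(products) + 1L),
            topology = "circular",
            comment = provenance_comment(
              sprintf("Golden Gate (%s)", paste(enzymes$name, collapse = "+")),
              input_names))
          products[[length(products) + 1L]] <<- rec
        }
      }
    }
    for (ci in seq_along(pool)) {
      if (pool_id[ci] %in% used) next
      cand <- pool[[ci]]
      if (!junction_ok(last$right_end, cand$left_end)) next
      recurse(c(chain, list(cand)), c(used, pool_id[ci]))
    }
    if (length(chain) == 1L && !junction_ok(last$right_end, first$left_end)) {
      dangling <<- c(dangling, last$right_end$seq, first$left_end$seq)
    }
  }
  for (i in seq_along(frags)) {
    recurse(list(pool[[i]]), i)
  }
  if (!length(products)) {
    stop(sprintf("no closed circular assembly; dangling overhangs: %s",
                 paste(unique(dangling), collapse = ", ")), call. = FALSE)
  }
  new_assembly_plan(products, input_names,
                    sprintf("golden_gate(%s)", paste(enzymes$name, collapse = "+")),
                    ambiguous = length(products) > 1L)
}

# ---- designer -----------------------------------------------------------

gg_similarity <- function(a, b) {
  # positional identity between two equal-length overhangs
  sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

gg_penalty <- function(overhangs) {
  olen <- nchar(overhangs[1])
  hard <- 0L
  soft <- 0L
  k <- length(overhangs)
  rc <- vapply(overhangs, reverse_complement, character(1))
  for (i in seq_len(k)) {
    if (overhangs[i] == rc[i]) hard <- hard + 1L # palindrome
    if (i < k) {
      for (j in (i + 1L):k) {
        if (overhangs[i] == overhangs[j]) hard <- hard + 1L
        if (overhangs[i] == rc[j]) hard <- hard + 1L
        soft <- max(soft, gg_similarity(overhangs[i], overhangs[j]),
                    gg_similarity(overhangs[i], rc[j]))
      }
    }
  }
  1000L * hard + soft
}

circ_substr <- function(text, from, len) {
  n <- nchar(text)
  idx <- ((from - 1L + seq_len(len) - 1L) %% n) + 1L
  paste(substring(text, idx, idx), collapse = "")
}

#' Design a Golden Gate assembly
#'
#' Chooses one overhang per junction inside a sliding window around the
#' nominal junction point, minimising an orthogonality penalty by a seeded
#' hill-climbing random walk (identical or reverse-complement-identical
#' overhang pairs and palindromic overhangs are hard violations; the soft
#' term is the maximum pairwise positional similarity over the set and its
#' reverse complements).  Emits, per fragment, a primer pair whose 5'
#' tails add the enzyme site, an A-spacer sized to the cut offset, and the
#' junction bases, so that PCR + digestion + ligation reproduces the
#' designed product exactly.
#'
#' @param fragments List of `list(record=, start=, end=)`: the spans to
#'   join, in product order.
#' @param enzyme One row of an enzyme tibble (type IIS).
#' @param seed Integer seed for the random walk.
#' @param max_restarts Restarts before giving up on a violation-free set.
#' @param window Maximum junction shift in bases (default 3).
#' @param moves Walk length per restart.
#' @param anneal_length Primer annealing length (default 20).
#' @return An `assembly_plan` with the designed product, a `junctions`
#'   tibble (overhangs) and a `primers` tibble (the order sheet).
#' @export
golden_gate_design <- function(fragments, enzyme, seed = 1L, max_restarts = 10L,
                               window = 3L, moves = 500L, anneal_length = 20L) {
  stopifnot(length(fragments) >= 2L)
  olen <- enzyme$overhang_length
  if (olen < 1L || enzyme$top_cut <= nchar(enzyme$recognition)) {
    stop("designer needs a type IIS enzyme with a 5' overhang cut outside its site",
         call. = FALSE)
  }
  spans <- vapply(fragments, function(f) {
    subseq_bases(f$record, f$start, f$end)
  }, character(1))
  if (any(nchar(spans) < anneal_length + olen + window)) {
    stop("a fragment span is too short to host primers and an overhang",
         call. = FALSE)
  }
  product_seq <- paste(spans, collapse = "")
  P <- toupper(product_seq)
  np <- nchar(P)
  k <- length(spans)
  bounds <- cumsum(nchar(spans)) # junction j after position bounds[j]; j=k wraps

  overhang_at <- function(j, w) circ_substr(P, bounds[j] - olen + 1L + w, olen)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)

  best_w <- NULL; best_pen <- Inf
  for (restart in seq_len(max_restarts)) {
    set.seed(seed + (restart - 1L) * 7919L)
    w <- integer(k)
    pen <- gg_penalty(vapply(seq_len(k), function(j) overhang_at(j, w[j]),
                             character(1)))
    for (step in seq_len(moves)) {
      if (pen == 0L) break
      j <- sample.int(k, 1L)
      delta <- sample(c(-3:-1, 1:3), 1L)
      w2 <- w
      w2[j] <- max(-window, min(window, w[j] + delta))
      if (w2[j] == w[j]) next
      pen2 <- gg_penalty(vapply(seq_len(k), function(q) overhang_at(q, w2[q]),
                                character(1)))
      if (pen2 <= pen) { w <- w2; pen <- pen2 }
    }
    if (pen < best_pen) { best_pen <- pen; best_w <- w }
    if (best_pen < 1000L) break
  }
  if (best_pen >= 1000L) {
    stop(sprintf("no violation-free overhang set found after %d restarts (best penalty %d)",
                 max_restarts, best_pen), call. = FALSE)
  }
  w <- best_w
  overhangs <- vapply(seq_len(k), function(j) overhang_at(j, w[j]), character(1))

  spacer <- strrep("A", enzyme$top_cut - nchar(enzyme$recognition))
  tail5 <- paste0(enzyme$recognition, spacer)
  s_i <- c(1L, utils::head(bounds, -1L) + 1L)
  e_i <- bounds
  primer_rows <- list()
  pcr_lines <- character()
  for (i in seq_len(k)) {
    jl <- if (i == 1L) k else i - 1L # junction on the left of fragment i
    jr <- i
    o_start_l <- bounds[jl] - olen + 1L + w[jl]
    o_end_r <- bounds[jr] + w[jr]
    # non-templated bases between the left overhang start and the span start
    left_gap_len <- (s_i[i] - o_start_l) %% np
    left_gap <- if (left_gap_len > 0L) circ_substr(P, o_start_l, left_gap_len) else ""
    fwd <- paste0(tail5, left_gap,
                  circ_substr(P, s_i[i], anneal_length))
    right_gap_len <- (o_end_r - e_i[i]) %% np
    right_gap <- if (right_gap_len > 0L && right_gap_len <= olen + window) {
      circ_substr(P, e_i[i] + 1L, right_gap_len)
    } else ""
    rev_anchor_end <- if (nzchar(right_gap)) e_i[i] else o_end_r
    rev <- paste0(tail5, reverse_complement(right_gap),
                  reverse_complement(circ_substr(P, rev_anchor_end - anneal_length + 1L,
                                                 anneal_length)))
    fname <- sprintf("%s_fwd", fragments[[i]]$record$name)
    rname <- sprintf("%s_rev", fragments[[i]]$record$name)
    primer_rows[[i]] <- tibble::tibble(
      name = c(fname, rname), sequence = c(fwd, rev),
      fragment = fragments[[i]]$record$name)
    pcr_lines <- c(pcr_lines, sprintf("PCR %d: %s + %s on template %s",
                                      i, fname, rname,
                                      fragments[[i]]$record$name))
  }
  primers <- dplyr::bind_rows(primer_rows)
  order_sheet <- paste(sprintf("%s\t%s", primers$name, primers$sequence),
                       collapse = "\n")
  comment <- paste0(
    provenance_comment(sprintf("Golden Gate design (%s)", enzyme$name),
                       vapply(fragments, function(f) f$record$name, character(1))),
    "\nReactions:\n", paste(" ", pcr_lines, collapse = "\n"),
    "\nOrder sheet:\n", order_sheet)
  product <- dna_record(product_seq, name = "gg_design_product",
                        topology = "circular", comment = comment)
  # annotate primer annealing footprints
  for (i in seq_len(k)) {
    product <- add_feature(product, name = primers$name[2L * i - 1L],
                           start = s_i[i],
                           end = ((s_i[i] + anneal_length - 2L) %% np) + 1L,
                           strand = "+", type = "primer_bind")
    re <- e_i[i]
    product <- add_feature(product, name = primers$name[2L * i],
                           start = ((re - anneal_length) %% np) + 1L,
                           end = re, strand = "-", type = "primer_bind")
  }
  if (gg_internal_sites(P, enzyme) > 0L) {
    warning("designed product still contains recognition sites for the chosen enzyme",
            call. = FALSE)
  }
  junctions <- tibble::tibble(
    junction = seq_len(k),
    upstream = vapply(fragments, function(f) f$record$name, character(1)),
    downstream = vapply(fragments[c(2:k, 1L)], function(f) f$record$name,
                        character(1)),
    shift = w, overlap_sequence = overhangs)
  new_assembly_plan(list(product),
                    vapply(fragments, function(f) f$record$name, character(1)),
                    sprintf("golden_gate_design(%s)", enzyme$name),
                    junctions = junctions, primers = primers)
}
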