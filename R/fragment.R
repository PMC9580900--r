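# Fragment end algebra.
#
# A fragment stores `extent`: the top-strand reading of the full region
# between its outermost cut positions (overhang windows included), plus
# typed ends.  An end is list(polarity = "5p"/"3p"/"blunt", seq = the
# top-strand text of the single-stranded window, phos = logical).  With
# this convention a right end and a left end are compatible exactly when
# their window texts are equal, and ligation joins two fragments by
# dropping the downstream fragment's left window (the window bases already
# sit at the end of the upstream extent), which reconstitutes both parental
# cut sites.

#' Are two fragment ends ligatable?
#'
#' `a` is taken as a right (outgoing) end and `b` as a left (incoming) end.
#' Compatible when both are blunt, or when they share polarity and window
#' sequence.  Phosphorylation is checked at ligation time, not here.
#'
#' @param a,b Fragment ends (`$left_end` / `$right_end` of a
#'   `dna_fragment`).
#' @return Logical.
#' @export
ends_compatible <- function(a, b) {
  if (a$polarity == "blunt" && b$polarity == "blunt") return(TRUE)
  a$polarity == b$polarity && toupper(a$seq) == toupper(b$seq)
}

#' Reverse-complement a fragment
#' @param f A `dna_fragment`.
#' @return The flipped fragment.
#' @export
reverse_fragment <- function(f) {
  flip <- function(e) {
    e$seq <- if (nzchar(e$seq)) reverse_complement(e$seq) else ""
    e
  }
  new_fragment(reverse_complement(f$extent),
               left_end = flip(f$right_end), right_end = flip(f$left_end),
               provenance = paste0(f$provenance, " (reversed)"),
               size = f$size)
}

#' Modify a fragment end with a common enzymatic reaction
#'
#' `fill_in` (Klenow) blunts a 5' overhang by synthesising the recessed
#' strand; `chew_back` (T4 pol / exonuclease) blunts a 3' overhang by
#' removing the protrusion; `dephosphorylate` (CIP) clears the 5'
#' phosphate, so a junction between two dephosphorylated ends cannot
#' ligate.
#'
#' @param f A `dna_fragment`.
#' @param which `"left"` or `"right"`.
#' @param reaction `"fill_in"`, `"chew_back"` or `"dephosphorylate"`.
#' @return The modified fragment.
#' @export
modify_end <- function(f, which = c("left", "right"),
                       reaction = c("fill_in", "chew_back", "dephosphorylate")) {
  which <- match.arg(which)
  reaction <- match.arg(reaction)
  end_name <- paste0(which, "_end")
  e <- f[[end_name]]
  if (reaction == "dephosphorylate") {
    e$phos <- FALSE
    f[[end_name]] <- e
    return(f)
  }
  if (reaction == "fill_in") {
    if (e$polarity != "5p") stop("fill_in applies to 5' overhangs", call. = FALSE)
    # recessed strand synthesised across the window: extent already covers it
    f[[end_name]] <- list(polarity = "blunt", seq = "", phos = e$phos)
    return(f)
  }
  # chew_back
  if (e$polarity != "3p") stop("chew_back applies to 3' overhangs", call. = FALSE)
  w <- nchar(e$seq)
  f$extent <- if (which == "left") {
    substr(f$extent, w + 1L, nchar(f$extent))
  } else {
    substr(f$extent, 1L, nchar(f$extent) - w)
  }
  f[[end_name]] <- list(polarity = "blunt", seq = "", phos = e$phos)
  f
}

# junction helpers ---------------------------------------------------------

junction_ok <- function(right, left) {
  ends_compatible(right, left) && (right$phos || left$phos)
}

# circular sequence from an ordered, oriented list of compatible fragments:
# each fragment contributes its extent minus its left window
assemble_circle_sequence <- function(frags) {
  paste(vapply(frags, function(f) {
    substr(f$extent, nchar(f$left_end$seq) + 1L, nchar(f$extent))
  }, character(1)), collapse = "")
}

#' Lexicographically minimal rotation of a circular sequence
#'
#' Used to canonicalise circular products for deterministic comparison.
#' The smaller of the minimal rotations of the sequence and of its reverse
#' complement is returned when `strand_invariant` is `TRUE`.
#'
#' @param bases Sequence string.
#' @param strand_invariant Also consider the reverse complement.
#' @return The canonical rotation string.
#' @export
canonical_rotation <- function(bases, strand_invariant = FALSE) {
  n <- nchar(bases)
  if (n == 0L) return(bases)
  doubled <- paste0(bases, bases)
  rots <- substring(doubled, 1:n, n:(2L * n - 1L))
  best <- min(rots)
  if (strand_invariant) {
    best <- min(best, canonical_rotation(reverse_complement(bases)))
  }
  best
}

new_assembly_plan <- function(products, inputs, reaction, junctions = NULL,
                              primers = NULL, ambiguous = FALSE) {
  structure(list(products = products, inputs = inputs, reaction = reaction,
                 junctions = junctions, primers = primers,
                 ambiguous = ambiguous),
            class = "assembly_plan")
}

#' @export
print.assembly_plan <- function(x, ...) {
  cat(sprintf("<assembly_plan> %s: %d product(s)%s\n", x$reaction,
              length(x$products), if (x$ambiguous) " [ambiguous]" else ""))
  for (p in x$products) {
    cat(sprintf("  %s (%d bp, %s)\n", p$name, seq_length(p), p$topology))
  }
  invisible(x)
}

provenance_comment <- function(reaction, inputs) {
  paste0(reaction, " product.\nInputs:\n",
         paste(sprintf("  - %s", inputs), collapse = "\n"))
}

#' Simulate a restriction-ligation reaction
#'
#' Takes one to three fragments and searches for an orientation assignment
#' that closes a circle with every junction ligatable (compatible ends and
#' at least one phosphorylated partner).  All distinct circular products
#' are returned; more than one flags the plan as ambiguous.  No valid
#' circle is an error.
#'
#' @param fragments List of 1-3 `dna_fragment`s.
#' @param allow_reversal May fragments be flipped.
#' @return An `assembly_plan`; `$products` holds circular [dna_record()]s
#'   whose comments list every input.
#' @export
ligate <- function(fragments, allow_reversal = TRUE) {
  if (inherits(fragments, "dna_fragment")) fragments <- list(fragments)
  k <- length(fragments)
  if (k < 1L || k > 3L) {
    stop("the ligation simulator accepts one to three fragments", call. = FALSE)
  }
  inputs <- vapply(fragments, `[[`, character(1), "provenance")
  orders <- if (k == 1L) list(1L) else {
    perms <- function(v) {
      if (length(v) <= 1L) return(list(v))
      do.call(c, lapply(seq_along(v), function(i) {
        lapply(perms(v[-i]), function(rest) c(v[i], rest))
      }))
    }
    lapply(perms(seq_len(k)[-1]), function(rest) c(1L, rest))
  }
  flips <- if (allow_reversal) {
    expand.grid(rep(list(c(FALSE, TRUE)), k))
  } else {
    as.data.frame(matrix(FALSE, 1, k))
  }
  seen <- character()
  products <- list()
  for (ord in orders) {
    for (fi in seq_len(nrow(flips))) {
      fr <- lapply(seq_len(k), function(j) {
        f <- fragments[[ord[j]]]
        if (flips[fi, j][[1]]) reverse_fragment(f) else f
      })
      ok <- all(vapply(seq_len(k), function(j) {
        nxt <- if (j == k) 1L else j + 1L
        junction_ok(fr[[j]]$right_end, fr[[nxt]]$left_end)
      }, logical(1)))
      if (!ok) next
      seqn <- assemble_circle_sequence(fr)
      key <- canonical_rotation(seqn, strand_invariant = TRUE)
      if (key %in% seen) next
      seen <- c(seen, key)
      rec <- dna_record(seqn, name = sprintf("ligation_product_%d",
                                             length(products) + 1L),
                        topology = "circular",
                        comment = provenance_comment("Restriction ligation",
                                                     inputs))
      products[[length(products) + 1L]] <- rec
    }
  }
  if (!length(products)) {
    stop("no compatible circular arrangement of the given fragments",
         call. = FALSE)
  }
  new_assembly_plan(products, inputs, "restriction_ligation",
                    ambiguous = length(products) > 1L)
}
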