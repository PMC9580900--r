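# Synthetic fixture generator: seeded, self-contained study material for
# the simulators (a pUC-like plasmid with planted sites and features,
# Golden Gate and Gibson fragment sets with declared products, and dCAPS
# SNP scenarios with both allele templates).

#' Random DNA sequence (uses the current RNG state)
#' @param n Length.
#' @param gc GC fraction.
#' @return A string.
#' @export
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random sequence free of the given IUPAC patterns (both strands)
random_dna_avoiding <- function(n, patterns, gc = 0.5, tries = 200L) {
  pats <- unique(c(patterns, vapply(patterns, reverse_complement, character(1))))
  for (t in seq_len(tries)) {
    s <- random_dna(n, gc)
    hits <- sum(vapply(pats, function(p) length(match_positions(s, p)),
                       integer(1)))
    if (hits == 0L) return(s)
    # patch around hits rather than rerolling everything
    for (p in pats) {
      repeat {
        pos <- match_positions(s, p)
        if (!length(pos)) break
        at <- pos[1] + (nchar(p) %/% 2L)
        substr(s, at, at) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(s, at, at)), 1L)
      }
    }
    hits <- sum(vapply(pats, function(p) length(match_positions(s, p)),
                       integer(1)))
    if (hits == 0L) return(s)
  }
  stop("could not generate a sequence avoiding the requested patterns",
       call. = FALSE)
}

with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a synthetic fixture
#'
#' Deterministic per seed.  Kinds:
#' \describe{
#'   \item{plasmid}{A pUC-like circular plasmid (default 3000 bp) carrying
#'     one planted EcoRI site, two HindIII sites, a T7 promoter feature
#'     sequence and an M13-style primer site; no other occurrences of
#'     those sequences.}
#'   \item{gg_set}{A Golden Gate set: a random circular product split into
#'     `n_fragments` spans, with the designed PCR amplicons (enzyme site +
#'     spacer + junction tails) as linear records, plus the declared
#'     product.}
#'   \item{gibson_set}{Fragment records for a Gibson design of a random
#'     product.}
#'   \item{dcaps_case}{A template with a planted SNP scenario where one
#'     primer edit creates an EcoRI site in the alternate allele, tuned so
#'     the 250 bp amplicon cuts into 50 + 200.}
#' }
#'
#' @param kind One of `"plasmid"`, `"gg_set"`, `"gibson_set"`,
#'   `"dcaps_case"`.
#' @param seed Integer seed.
#' @param params Optional list of overrides (`length`, `n_fragments`,
#'   `span`, ...).
#' @return A list; contents depend on `kind` (see Details).
#' @export
make_fixture <- function(kind = c("plasmid", "gg_set", "gibson_set", "dcaps_case"),
                         seed = 1L, params = list()) {
  kind <- match.arg(kind)
  with_seed(seed, switch(kind,
    plasmid = fixture_plasmid(params),
    gg_set = fixture_gg_set(params),
    gibson_set = fixture_gibson_set(params),
    dcaps_case = fixture_dcaps(params)
  ))
}

fixture_plasmid <- function(params) {
  len <- params$length %||% 3000L
  t7 <- "TAATACGACTCACTATAG"
  m13f <- "GTAAAACGACGGCCAGT"
  avoid <- c("GAATTC", "AAGCTT", t7, m13f)
  backbone <- random_dna_avoiding(len, avoid)
  plant <- function(seqs, text, at) {
    for (i in seq_along(at)) {
      substr(text, at[i], at[i] + nchar(seqs[i]) - 1L) <- seqs[i]
    }
    text
  }
  at <- c(200L, 900L, 1800L, 2400L, 2700L)
  repeat {
    text <- plant(c("GAATTC", "AAGCTT", "AAGCTT", t7, m13f), backbone, at)
    # planting can create chimeric sites at patch borders; regenerate if so
    ok <- length(match_positions(text, "GAATTC")) == 1L &&
      length(match_positions(text, "AAGCTT")) == 2L &&
      length(match_positions(text, t7)) == 1L
    if (ok) break
    backbone <- random_dna_avoiding(len, avoid)
  }
  rec <- dna_record(text, name = "synthetic_puc_like", topology = "circular",
                    comment = "synthetic fixture plasmid")
  rec <- add_feature(rec, "T7 promoter", 2400L, 2400L + nchar(t7) - 1L,
                     type = "promoter", color = "#00cc44")
  rec <- add_feature(rec, "M13F", 2700L, 2700L + nchar(m13f) - 1L,
                     type = "primer_bind", color = "#cc8800")
  list(record = rec,
       planted = tibble::tibble(
         what = c("EcoRI", "HindIII", "HindIII", "T7", "M13F"),
         at = at))
}

gg_amplicon <- function(P, enzyme, s, e, left_tail, name,
                        anneal_length = 20L) {
  # textual amplicon: site+spacer+left junction bases+span+rc(site+spacer)
  spacer <- strrep("A", enzyme$top_cut - nchar(enzyme$recognition))
  tail5 <- paste0(enzyme$recognition, spacer)
  body <- substr(P, s, e)
  right_tail <- "" # overhang taken from the span end itself
  seqn <- paste0(tail5, left_tail, body, right_tail,
                 reverse_complement(tail5))
  dna_record(seqn, name = name, topology = "linear")
}

fixture_gg_set <- function(params) {
  k <- params$n_fragments %||% 3L
  span <- params$span %||% 300L
  enzyme <- params$enzyme %||% default_db("enzymes")[
    default_db("enzymes")$name == "SapI", ]
  olen <- enzyme$overhang_length
  avoid <- enzyme$recognition
  repeat {
    P <- random_dna_avoiding(span * k, avoid)
    bounds <- span * seq_len(k)
    overhangs <- vapply(seq_len(k), function(j) {
      substr(P, bounds[j] - olen + 1L, bounds[j])
    }, character(1))
    if (gg_penalty(overhangs) < 1000L) break
    # reroll until the natural junction overhangs have no hard violation
  }
  s_i <- c(1L, utils::head(bounds, -1L) + 1L)
  frags <- lapply(seq_len(k), function(i) {
    jl <- if (i == 1L) k else i - 1L
    left_tail <- overhangs[jl] # the olen bases preceding the span in P
    gg_amplicon(P, enzyme, s_i[i], bounds[i], left_tail,
                sprintf("gg_frag_%d", i))
  })
  list(fragments = frags,
       product = dna_record(P, name = "gg_declared_product",
                            topology = "circular"),
       enzyme = enzyme, overhangs = overhangs)
}

fixture_gibson_set <- function(params) {
  k <- params$n_fragments %||% 3L
  span <- params$span %||% 400L
  P <- random_dna(span * k)
  bounds <- span * seq_len(k)
  s_i <- c(1L, utils::head(bounds, -1L) + 1L)
  recs <- lapply(seq_len(k), function(i) {
    dna_record(substr(P, s_i[i], bounds[i]),
               name = sprintf("gib_frag_%d", i))
  })
  list(records = recs,
       product = dna_record(P, name = "gibson_declared_product",
                            topology = "circular"))
}

fixture_dcaps <- function(params) {
  len <- params$length %||% 600L
  snp <- params$snp_position %||% 300L
  primer_len <- params$primer_len %||% 50L
  text <- random_dna_avoiding(len, "ATCGAT")
  # planted ClaI (AT^CGAT) skeleton at snp-2..snp+3: reference reads
  # G T [A] G A T; one primer edit G>A two bases from the 3' terminus plus
  # the alternate allele C at the SNP yields A T C G A T in the alternate
  # amplicon only, with the cut falling 50 bases into a 250 bp amplicon
  substr(text, snp - 2L, snp + 3L) <- "GTAGAT"
  # keep the template free of accidental sites after planting
  stopifnot(length(match_positions(text, "ATCGAT")) == 0L)
  list(template = dna_record(text, name = "dcaps_template"),
       snp_position = snp, ref_base = "A", alt_base = "C",
       enzyme = "ClaI", primer_len = primer_len,
       amplicon_length_target = params$amplicon_length_target %||% 250L)
}
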