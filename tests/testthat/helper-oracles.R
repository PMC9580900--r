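# Independent oracles and generators used across the suite.  Each oracle is
# a deliberately naive, separate implementation of the operation it checks.

rnd_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a random record with a handful of planted features
rnd_record <- function(len = 300L, circular = sample(c(TRUE, FALSE), 1L),
                       n_features = sample(0:3, 1L)) {
  rec <- dna_record(rnd_dna(len), name = sprintf("r%06d", sample.int(1e6, 1L)),
                    topology = if (circular) "circular" else "linear")
  for (i in seq_len(n_features)) {
    s <- sample.int(len, 1L)
    e <- sample.int(len, 1L)
    if (!circular && s > e) { tmp <- s; s <- e; e <- tmp }
    rec <- add_feature(rec, sprintf("feat%d", i), s, e,
                       strand = sample(c("+", "-"), 1L),
                       type = sample(c("CDS", "misc_feature", "promoter"), 1L),
                       color = sprintf("#%06x", sample.int(16^6, 1L) - 1L))
  }
  rec
}

# naive degenerate sliding-window site scan (per-position loop, no index)
naive_iupac_scan <- function(subject, pattern) {
  n <- nchar(subject); m <- nchar(pattern)
  if (n < m) return(integer(0))
  subj <- strsplit(toupper(subject), "")[[1]]
  pat <- strsplit(toupper(pattern), "")[[1]]
  sets <- lapply(pat, function(p) IUPAC_SETS[[p]])
  out <- integer(0)
  for (s in seq_len(n - m + 1L)) {
    ok <- TRUE
    for (i in seq_len(m)) {
      if (!(subj[s + i - 1L] %in% sets[[i]])) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, s)
  }
  out
}

# brute-force six-frame ORF enumeration on a linear sequence
naive_orfs <- function(seq, min_len_codons, require_atg, code = 1) {
  table <- plasmidkit:::GENETIC_CODES[[as.character(code)]]
  stops <- names(table)[table == "*"]
  n <- nchar(seq)
  out <- list()
  scan_one <- function(s, strand) {
    nn <- nchar(s)
    for (off in 0:2) {
      n_codon <- (nn - off) %/% 3L
      if (n_codon < 1L) next
      codons <- substring(toupper(s), off + 3L * seq_len(n_codon) - 2L,
                          off + 3L * seq_len(n_codon))
      prev_stop <- 0L
      for (ci in seq_len(n_codon)) {
        if (!(codons[ci] %in% stops)) next
        first <- prev_stop + 1L
        prev_stop <- ci
        if (first > ci) next
        if (require_atg) {
          atg <- which(codons[first:ci] == "ATG")
          if (!length(atg)) next
          first <- first + atg[1] - 1L
        }
        if (ci - first + 1L < min_len_codons) next
        sl <- off + 3L * (first - 1L) + 1L
        el <- off + 3L * ci
        if (strand == "+") {
          out[[length(out) + 1L]] <<- c(sl, el)
        } else {
          out[[length(out) + 1L]] <<- c(nn - el + 1L, nn - sl + 1L)
        }
      }
    }
  }
  scan_one(seq, "+")
  scan_one(reverse_complement(seq), "-")
  if (!length(out)) return(character(0))
  sort(vapply(out, function(x) paste(x, collapse = "-"), character(1)))
}

orf_keys <- function(tbl) sort(paste(tbl$start, tbl$end, sep = "-"))

# translate a (context-free, uppercase) feature pattern to a lazy PCRE and
# list all distinct final spans, mirroring the matcher's contract
regex_pattern_hits <- function(raw, seq) {
  chars <- strsplit(raw, "")[[1]]
  rx <- paste(vapply(chars, function(ch) {
    if (ch == "#") return("[ACGT]*?")
    if (ch == "+") return("[ACGT]+?")
    paste0("[", paste(IUPAC_SETS[[toupper(ch)]], collapse = ""), "]")
  }, character(1)), collapse = "")
  n <- nchar(seq)
  spans <- character(0)
  for (s in seq_len(n)) {
    m <- regexpr(paste0("^(?:", rx, ")"), substr(seq, s, n), perl = TRUE)
    if (m == 1L) {
      spans <- c(spans, paste(s, s + attr(m, "match.length") - 1L))
    }
  }
  sort(unique(spans))
}

matcher_hit_spans <- function(raw, seq) {
  hits <- plasmidkit:::pattern_hits(compile_feature_pattern(raw), seq)
  sort(unique(vapply(hits, function(h) paste(h$start, h$end), character(1))))
}

# exhaustive anchored binding-site scan: for every 3' placement try every
# annealed depth explicitly
naive_binding_sites <- function(template, primer, min_anneal, max_mismatch,
                                max_3prime_mismatch, window = 3L) {
  hits <- list()
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") toupper(template) else
      reverse_complement(toupper(template))
    sv <- strsplit(subj, "")[[1]]
    pv <- strsplit(toupper(primer), "")[[1]]
    m <- length(pv)
    n <- length(sv)
    for (e3 in seq_len(n)) {
      depth <- min(m, e3)
      best <- NULL
      for (L in depth:1) {
        pr <- pv[(m - L + 1L):m]
        tp <- sv[(e3 - L + 1L):e3]
        mm <- sum(pr != tp)
        if (mm > max_mismatch) next
        if (pr[1] != tp[1]) next # annealed region starts on a match
        if (sum((rev(pr) != rev(tp))[seq_len(min(window, L))]) >
            max_3prime_mismatch) next
        if (L - mm < min_anneal) next
        best <- c(L, mm)
        break # longest valid depth
      }
      if (!is.null(best)) {
        tpp <- if (strand == "+") e3 else n - e3 + 1L
        hits[[length(hits) + 1L]] <- paste(strand, tpp, best[1], best[2])
      }
    }
  }
  sort(unique(as.character(unlist(hits))))
}

binding_keys <- function(tbl) {
  # reconstruct annealed depth from match + mismatch counts
  sort(unique(paste(tbl$strand, tbl$three_prime_position,
                    tbl$match_count + tbl$mismatch_count, tbl$mismatch_count)))
}

default_enzymes <- default_db("enzymes")

pick_enzymes <- function(names) {
  default_enzymes[default_enzymes$name %in% names, ]
}

plant <- function(text, at, what) {
  substr(text, at, at + nchar(what) - 1L) <- what
  text
}
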