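# Feature-definition pattern language.
#
# A pattern is IUPAC letters (upper/lower case), the variable-length
# wildcards '#' (>= 0 bases) and '+' (>= 1 base), both matched lazily, and
# optional context markers: characters before '<' and after '>' are not
# required for a match, but once the core matches, context characters are
# extended outward one by one for as long as they keep matching.
# Uppercase letters (and wildcard-matched runs) become feature segments;
# lowercase letters become gaps.  An all-lowercase pattern yields one
# contiguous feature.

pattern_tokens <- function(chars) {
  lapply(chars, function(ch) {
    if (ch == "#") return(list(kind = "wild", min = 0L, upper = TRUE))
    if (ch == "+") return(list(kind = "wild", min = 1L, upper = TRUE))
    up <- toupper(ch)
    if (!(up %in% IUPAC_CHARS)) {
      stop(sprintf("invalid pattern character '%s'", ch), call. = FALSE)
    }
    list(kind = "base", bits = unname(IUPAC_BITS[up]), upper = (ch == up))
  })
}

#' Compile a feature-library pattern
#'
#' @param raw_pattern Pattern text over IUPAC letters, `#`, `+`, `<`, `>`.
#' @return A `feature_pattern` object with compiled pre-context, core and
#'   post-context token lists.
#' @examples
#' compile_feature_pattern("ATG#TAA")
#' @export
compile_feature_pattern <- function(raw_pattern) {
  chars <- strsplit(raw_pattern, "", fixed = TRUE)[[1]]
  lt <- which(chars == "<"); gt <- which(chars == ">")
  if (length(lt) > 1L || length(gt) > 1L) {
    stop("at most one '<' and one '>' allowed", call. = FALSE)
  }
  if (length(lt) && length(gt) && lt > gt) {
    stop("'>' before '<' in pattern", call. = FALSE)
  }
  pre_chars <- if (length(lt)) chars[seq_len(lt - 1L)] else character()
  core_from <- if (length(lt)) lt + 1L else 1L
  core_to <- if (length(gt)) gt - 1L else length(chars)
  if (core_to < core_from) stop("empty pattern core", call. = FALSE)
  core_chars <- chars[core_from:core_to]
  post_chars <- if (length(gt) && gt < length(chars)) {
    chars[(gt + 1L):length(chars)]
  } else character()
  if (!length(core_chars)) stop("empty pattern core", call. = FALSE)
  structure(list(
    raw = raw_pattern,
    pre = pattern_tokens(pre_chars),
    core = pattern_tokens(core_chars),
    post = pattern_tokens(post_chars),
    all_lower = all(!vapply(c(pattern_tokens(pre_chars),
                              pattern_tokens(core_chars),
                              pattern_tokens(post_chars)),
                            `[[`, logical(1), "upper"))
  ), class = "feature_pattern")
}

#' @export
print.feature_pattern <- function(x, ...) {
  cat(sprintf("<feature_pattern> %s\n", x$raw))
  invisible(x)
}

# Lazy backtracking core match at a fixed start.  Returns NULL or a logical
# vector: one element per matched sequence position, TRUE = feature
# position (uppercase/wildcard), FALSE = gap (lowercase).
match_core_at <- function(tokens, seq_bits, start) {
  n <- length(seq_bits)
  rec <- function(ti, pos) {
    if (ti > length(tokens)) return(logical(0))
    tok <- tokens[[ti]]
    if (tok$kind == "base") {
      if (pos > n || bitwAnd(seq_bits[pos], tok$bits) == 0L) return(NULL)
      rest <- rec(ti + 1L, pos + 1L)
      if (is.null(rest)) return(NULL)
      return(c(tok$upper, rest))
    }
    # wildcard: lazy, try shortest runs first
    for (k in tok$min:(n - pos + 1L)) {
      if (pos + k - 1L > n) break
      rest <- rec(ti + 1L, pos + k)
      if (!is.null(rest)) return(c(rep(TRUE, k), rest))
    }
    NULL
  }
  rec(1L, start)
}

# Per-character greedy outward context extension.  Pre-context tokens are
# consumed right-to-left immediately before `start`; post-context
# left-to-right after `end`.  Wildcards are not meaningful in context and
# stop extension.
extend_context <- function(tokens, seq_bits, from, step) {
  flags <- logical(0)
  pos <- from
  idx <- if (step < 0) length(tokens) else 1L
  while (idx >= 1L && idx <= length(tokens) && pos >= 1L &&
         pos <= length(seq_bits)) {
    tok <- tokens[[idx]]
    if (tok$kind != "base") break
    if (bitwAnd(seq_bits[pos], tok$bits) == 0L) break
    flags <- if (step < 0) c(tok$upper, flags) else c(flags, tok$upper)
    pos <- pos + step
    idx <- idx + step
  }
  flags
}

# All core-match hits of a compiled pattern on a plain string.
# Returns list of list(start, end, flags) in local coordinates.
pattern_hits <- function(matcher, seq) {
  bits <- iupac_bits_vec(seq)
  n <- length(bits)
  hits <- list()
  for (s in seq_len(n)) {
    flags <- match_core_at(matcher$core, bits, s)
    if (is.null(flags)) next
    e <- s + length(flags) - 1L
    pre <- extend_context(matcher$pre, bits, s - 1L, -1L)
    post <- extend_context(matcher$post, bits, e + 1L, +1L)
    start <- s - length(pre)
    end <- e + length(post)
    all_flags <- c(pre, flags, post)
    if (matcher$all_lower) all_flags <- rep(TRUE, length(all_flags))
    hits[[length(hits) + 1L]] <- list(start = start, end = end,
                                      flags = all_flags)
  }
  # collapse hits with identical final spans
  if (length(hits) > 1L) {
    key <- vapply(hits, function(h) paste(h$start, h$end), character(1))
    hits <- hits[!duplicated(key)]
  }
  hits
}

flags_to_segments <- function(start, flags) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  keep <- r$values
  new_segment(start + begins[keep] - 1L, start + ends[keep] - 1L)
}

#' Scan a record with a feature library
#'
#' Each pattern is scanned on every strand its policy permits; matches are
#' converted to features (uppercase pattern positions become segments,
#' lowercase become gaps).  Features identical to ones already in the
#' record are not duplicated, so scanning is idempotent.
#'
#' @param rec A [dna_record()].
#' @param library Tibble from [load_feature_library()] (columns `name`,
#'   `matcher`, `color`, `type`, `strand_policy`).
#' @return The annotated record.
#' @export
scan_with_library <- function(rec, library) {
  stopifnot(inherits(rec, "dna_record"))
  n <- seq_length(rec)
  top <- toupper(rec$bases)
  ext_top <- if (rec$topology == "circular") paste0(top, substr(top, 1, n - 1L)) else top
  bottom <- reverse_complement(ext_top)

  existing_key <- function(tbl) {
    vapply(seq_len(nrow(tbl)), function(i) {
      paste(tbl$name[i], tbl$strand[i],
            paste(tbl$segments[[i]], collapse = ","), sep = "|")
    }, character(1))
  }
  seen <- existing_key(rec$features)

  for (i in seq_len(nrow(library))) {
    entry <- library[i, ]
    matcher <- entry$matcher[[1]]
    strands <- if (entry$strand_policy == "top") "+" else c("+", "-")
    for (str in strands) {
      seq <- if (str == "+") ext_top else bottom
      for (h in pattern_hits(matcher, seq)) {
      if (str == "+") {
          s <- h$start; flags <- h$flags
        } else {
          # map bottom-strand local hit back to top-strand coordinates
          s <- nchar(seq) - h$end + 1L
          flags <- rev(h$flags)
        }
        if (s < 1L || s > n) next # count each wrap hit once
        segs <- flags_to_segments(s, flags)
        # wrap segments that ran past the end of a circular record
        segs <- new_segment(((segs[, "start"] - 1L) %% n) + 1L,
                            ((segs[, "end"] - 1L) %% n) + 1L)
        key <- paste(entry$name, str, paste(segs, collapse = ","), sep = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        rec <- add_feature(rec, name = entry$name, segments = segs,
                           strand = str, type = entry$type,
                           color = entry$color)
      }
    }
  }
  rec
}
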