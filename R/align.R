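# Global alignment: three-state affine-gap Needleman-Wunsch with
# deterministic tie-breaking, an anchor heuristic that pins locally
# identical blocks and aligns only the regions between them, and stacking
# of pairwise alignments onto a shared reference.

#' Affine-gap global alignment
#'
#' Three-state dynamic program (match/mismatch, gap-in-a, gap-in-b); a gap
#' of length k costs `gap_open + k * gap_extend` (both negative).
#' Tie-breaking prefers diagonal over up over left, so alignments are
#' reproducible.
#'
#' @param a,b Sequences (strings, non-empty).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return An `alignment_result`: list with `rows` (gapped strings, `a`
#'   first), `score`, `unaligned_blocks` (empty here).
#' @export
nw_affine_align <- function(a, b, match = 1, mismatch = -1,
                            gap_open = -3, gap_extend = -1) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  # state matrices: M diagonal, X gap in b (consume a, "up"), Y gap in a
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1, 1] <- 0
  for (i in 2:(n + 1L)) X[i, 1] <- gap_open + (i - 1L) * gap_extend
  for (j in 2:(m + 1L)) Y[1, j] <- gap_open + (j - 1L) * gap_extend
  # traceback: 1 = from M, 2 = from X, 3 = from Y
  tbM <- matrix(0L, n + 1L, m + 1L)
  tbX <- matrix(0L, n + 1L, m + 1L)
  tbY <- matrix(0L, n + 1L, m + 1L)
  tbX[2:(n + 1L), 1] <- 2L; if (n >= 1L) tbX[2, 1] <- 1L
  tbY[1, 2:(m + 1L)] <- 3L; if (m >= 1L) tbY[1, 2] <- 1L
  for (i in 2:(n + 1L)) {
    s_row <- ifelse(av[i - 1L] == bv, match, mismatch)
    for (j in 2:(m + 1L)) {
      s <- s_row[j - 1L]
      cand <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      k <- which.max(cand) # ties: M > X > Y
      M[i, j] <- cand[k] + s
      tbM[i, j] <- k
      candx <- c(M[i - 1L, j] + gap_open + gap_extend,
                 X[i - 1L, j] + gap_extend,
                 Y[i - 1L, j] + gap_open + gap_extend)
      kx <- which.max(candx)
      X[i, j] <- candx[kx]; tbX[i, j] <- kx
      candy <- c(M[i, j - 1L] + gap_open + gap_extend,
                 X[i, j - 1L] + gap_open + gap_extend,
                 Y[i, j - 1L] + gap_extend)
      ky <- which.max(candy)
      Y[i, j] <- candy[ky]; tbY[i, j] <- ky
    }
  }
  finals <- c(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  state <- which.max(finals)
  score <- finals[state]
  # traceback
  ga <- character(0); gb <- character(0)
  i <- n + 1L; j <- m + 1L
  achars <- strsplit(a, "")[[1]]; bchars <- strsplit(b, "")[[1]]
  while (i > 1L || j > 1L) {
    if (state == 1L) {
      prev <- tbM[i, j]
      ga <- c(achars[i - 1L], ga); gb <- c(bchars[j - 1L], gb)
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      prev <- tbX[i, j]
      ga <- c(achars[i - 1L], ga); gb <- c("-", gb)
      i <- i - 1L
    } else {
      prev <- tbY[i, j]
      ga <- c("-", ga); gb <- c(bchars[j - 1L], gb)
      j <- j - 1L
    }
    state <- prev
  }
  structure(list(rows = c(paste(ga, collapse = ""), paste(gb, collapse = "")),
                 score = score, unaligned_blocks = list()),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> score %g, %d columns, %d unaligned block(s)\n",
              x$score, nchar(x$rows[1]), length(x$unaligned_blocks)))
  w <- 60L
  for (off in seq(1L, nchar(x$rows[1]), by = w)) {
    for (r in x$rows) cat(substr(r, off, min(off + w - 1L, nchar(r))), "\n")
    cat("\n")
  }
  invisible(x)
}

# maximal exact shared blocks of length >= k, collinear greedy chain
find_anchors <- function(a, b, k) {
  au <- toupper(a); bu <- toupper(b)
  n <- nchar(au); m <- nchar(bu)
  if (n < k || m < k) return(NULL)
  kmers <- substring(au, 1:(n - k + 1L), k:n)
  idx <- split(seq_len(n - k + 1L), kmers)
  bmers <- substring(bu, 1:(m - k + 1L), k:m)
  hits <- list()
  for (j in seq_along(bmers)) {
    pos_a <- idx[[bmers[j]]]
    if (is.null(pos_a)) next
    for (i in pos_a) hits[[length(hits) + 1L]] <- c(i, j)
  }
  if (!length(hits)) return(NULL)
  h <- unique(do.call(rbind, hits))
  # extend each seed maximally; dedupe by extended block
  blocks <- list()
  seen <- character()
  achr <- strsplit(au, "")[[1]]; bchr <- strsplit(bu, "")[[1]]
  for (r in seq_len(nrow(h))) {
    i <- h[r, 1]; j <- h[r, 2]
    s <- 0L
    while (i - s - 1L >= 1L && j - s - 1L >= 1L &&
           achr[i - s - 1L] == bchr[j - s - 1L]) s <- s + 1L
    e <- k - 1L
    while (i + e + 1L <= n && j + e + 1L <= m &&
           achr[i + e + 1L] == bchr[j + e + 1L]) e <- e + 1L
    bi <- i - s; bj <- j - s; len <- e + s + 1L
    key <- paste(bi, bj, len)
    if (key %in% seen) next
    seen <- c(seen, key)
    blocks[[length(blocks) + 1L]] <- c(bi, bj, len)
  }
  bm <- do.call(rbind, blocks)
  bm <- bm[order(-bm[, 3]), , drop = FALSE]
  # greedy collinear, non-overlapping chain by decreasing length
  chain <- list()
  for (r in seq_len(nrow(bm))) {
    cand <- bm[r, ]
    ok <- TRUE
    for (c0 in chain) {
      # must be strictly before or after in both sequences
      before <- cand[1] + cand[3] - 1L < c0[1] && cand[2] + cand[3] - 1L < c0[2]
      after <- cand[1] > c0[1] + c0[3] - 1L && cand[2] > c0[2] + c0[3] - 1L
      if (!before && !after) { ok <- FALSE; break }
    }
    if (ok) chain[[length(chain) + 1L]] <- cand
  }
  cm <- do.call(rbind, chain)
  cm[order(cm[, 1]), , drop = FALSE]
}

#' Anchored global alignment
#'
#' Finds maximal exact shared blocks (length >= `anchor_block`) as
#' anchors; the regions between anchors are aligned with
#' [nw_affine_align()], except that a region whose length product exceeds
#' `max_unaligned_product` is left unaligned (rendered as stacked,
#' gap-padded blocks and recorded in `unaligned_blocks`).
#'
#' @inheritParams nw_affine_align
#' @param anchor_block Minimum anchor length (default 12).
#' @param max_unaligned_product Skip NW for inter-anchor regions with
#'   `len_a * len_b` above this (default 250000); `Inf` disables skipping.
#' @return An `alignment_result`.
#' @export
anchored_align <- function(a, b, anchor_block = 12L,
                           max_unaligned_product = 250000,
                           match = 1, mismatch = -1, gap_open = -3,
                           gap_extend = -1) {
  if (!is.finite(max_unaligned_product)) {
    # the anchor heuristic exists only to bound the DP work; with the
    # threshold disabled the exact DP is the answer
    return(nw_affine_align(a, b, match, mismatch, gap_open, gap_extend))
  }
  anchors <- find_anchors(a, b, anchor_block)
  if (is.null(anchors)) {
    if (as.numeric(nchar(a)) * nchar(b) > max_unaligned_product) {
      rows <- c(paste0(a, strrep("-", nchar(b))),
                paste0(strrep("-", nchar(a)), b))
      return(structure(list(rows = rows, score = 0,
                            unaligned_blocks = list(c(1L, nchar(a)))),
                       class = "alignment_result"))
    }
    return(nw_affine_align(a, b, match, mismatch, gap_open, gap_extend))
  }
  ga <- ""; gb <- ""; score <- 0
  unaligned <- list()
  pa <- 1L; pb <- 1L
  emit_region <- function(sa, sb) {
    la <- nchar(sa); lb <- nchar(sb)
    if (la == 0L && lb == 0L) return(invisible())
    if (la == 0L) {
      ga <<- paste0(ga, strrep("-", lb)); gb <<- paste0(gb, sb)
      score <<- score + gap_open + lb * gap_extend
    } else if (lb == 0L) {
      ga <<- paste0(ga, sa); gb <<- paste0(gb, strrep("-", la))
      score <<- score + gap_open + la * gap_extend
    } else if (as.numeric(la) * lb > max_unaligned_product) {
      ga <<- paste0(ga, sa, strrep("-", lb))
      gb <<- paste0(gb, strrep("-", la), sb)
      unaligned[[length(unaligned) + 1L]] <<- c(pa, pa + la - 1L)
    } else {
      sub <- nw_affine_align(sa, sb, match, mismatch, gap_open, gap_extend)
      ga <<- paste0(ga, sub$rows[1]); gb <<- paste0(gb, sub$rows[2])
      score <<- score + sub$score
    }
  }
  for (r in seq_len(nrow(anchors))) {
    ai <- anchors[r, 1]; bj <- anchors[r, 2]; len <- anchors[r, 3]
    emit_region(substr(a, pa, ai - 1L), substr(b, pb, bj - 1L))
    ga <- paste0(ga, substr(a, ai, ai + len - 1L))
    gb <- paste0(gb, substr(b, bj, bj + len - 1L))
    score <- score + len * match
    pa <- ai + len; pb <- bj + len
  }
  emit_region(substr(a, pa, nchar(a)), substr(b, pb, nchar(b)))
  structure(list(rows = c(ga, gb), score = score,
                 unaligned_blocks = unaligned),
            class = "alignment_result")
}

ungap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Stack pairwise alignments onto a shared reference
#'
#' Merges alignments that all use the same (ungapped) reference as their
#' first row by inserting gaps so every row shares one gapped reference.
#' This is explicitly not a multiple sequence alignment.
#'
#' @param ref Reference sequence string.
#' @param pairwise List of `alignment_result`s whose first rows ungap to
#'   `ref`.
#' @return Character vector: gapped reference first, then one row per
#'   input.
#' @export
combine_pairwise <- function(ref, pairwise) {
  for (p in pairwise) {
    if (toupper(ungap(p$rows[1])) != toupper(ref)) {
      stop("an input's first row does not ungap to the reference", call. = FALSE)
    }
  }
  n <- nchar(ref)
  # gap runs inserted after each reference position (0 = before the first)
  gaps <- matrix(0L, length(pairwise), n + 1L)
  for (k in seq_along(pairwise)) {
    rr <- strsplit(pairwise[[k]]$rows[1], "")[[1]]
    pos <- 0L
    run <- 0L
    for (ch in rr) {
      if (ch == "-") run <- run + 1L
      else {
        gaps[k, pos + 1L] <- run
        run <- 0L; pos <- pos + 1L
      }
    }
    gaps[k, n + 1L] <- run
  }
  union_gaps <- apply(gaps, 2, max)
  pad_row <- function(row, own_gaps) {
    rr <- strsplit(row, "")[[1]]
    out <- character()
    i <- 1L
    for (pos in 0:n) {
      g_own <- own_gaps[pos + 1L]
      take <- g_own + (if (pos < n) 1L else 0L)
      chunk <- if (take > 0L) rr[i:(i + take - 1L)] else character()
      i <- i + take
      extra <- union_gaps[pos + 1L] - g_own
      # pad the row's gap run up to the union width
      out <- c(out, utils::head(chunk, g_own), rep("-", extra),
               utils::tail(chunk, length(chunk) - g_own))
    }
    paste(out, collapse = "")
  }
  ref_gapped <- pad_row(paste(strsplit(ref, "")[[1]], collapse = ""),
                        rep(0L, n + 1L))
  rows <- vapply(seq_along(pairwise), function(k) {
    pad_row(pairwise[[k]]$rows[2], gaps[k, ])
  }, character(1))
  c(ref_gapped, rows)
}

#' @method tidy alignment_result
#' @export
tidy.alignment_result <- function(x, ...) {
  cols <- nchar(x$rows[1])
  a <- strsplit(x$rows[1], "")[[1]]
  b <- strsplit(x$rows[2], "")[[1]]
  tibble::tibble(
    column = seq_len(cols), a = a, b = b,
    kind = dplyr::case_when(
      a == "-" | b == "-" ~ "gap",
      toupper(a) == toupper(b) ~ "match",
      TRUE ~ "mismatch"))
}

#' @method glance alignment_result
#' @export
glance.alignment_result <- function(x, ...) {
  td <- tidy.alignment_result(x)
  tibble::tibble(
    score = x$score, columns = nrow(td),
    matches = sum(td$kind == "match"),
    mismatches = sum(td$kind == "mismatch"),
    gap_columns = sum(td$kind == "gap"),
    unaligned_blocks = length(x$unaligned_blocks))
}
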