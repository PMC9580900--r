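# Gibson assembly designer: grows each junction overlap until a minimum
# melting temperature is reached, assigns the overlap (and any non-templated
# inserted bases) to primer 5' tails according to each fragment's kind, and
# reports the predicted circular product.

#' Design a Gibson assembly
#'
#' Fragments are joined in the given order with circular closure (the last
#' fragment joins the first).  At each junction the homologous overlap is
#' grown base by base from the junction point until its nearest-neighbor
#' melting temperature reaches `min_overlap_tm`.  The overlap tail is
#' carried by the downstream fragment's forward primer when that fragment
#' is a `pcr_with_tails`, otherwise by the upstream fragment's reverse
#' primer; a junction where neither neighbor can take a tail is an error.
#' Non-templated `inserted_bases` sit in the gap and ride in the adjacent
#' tail.  Stand-alone (non-PCR) fragments given as `dna_fragment`s have
#' their single-stranded ends resolved by `exo_direction` ("5p" keeps the
#' full extent, "3p" trims the overhang windows).
#'
#' @param fragments List of `list(record=, start=, end=, kind=)` where kind
#'   is `"pcr_with_tails"`, `"pcr_no_tails"` or `"fragment"`; a
#'   `dna_fragment` may be supplied as `record` for kind `"fragment"`.
#' @param min_overlap_tm Minimum overlap melting temperature, Celsius
#'   (default 50).
#' @param inserted_bases Character vector (recycled) of non-templated bases
#'   placed in each junction gap ("" for none); junction j sits after
#'   fragment j.
#' @param exo_direction `"5p"` or `"3p"`.
#' @param anneal_length Primer annealing length (default 20).
#' @param max_overlap Safety cap on overlap growth.
#' @return An `assembly_plan` with the product record, `junctions` tibble
#'   (`overlap_sequence`, `overlap_tm`, `inserted_bases`, primers) and a
#'   `primers` order sheet.
#' @export
gibson_design <- function(fragments, min_overlap_tm = 50,
                          inserted_bases = "", exo_direction = c("5p", "3p"),
                          anneal_length = 20L, max_overlap = 80L) {
  exo_direction <- match.arg(exo_direction)
  k <- length(fragments)
  stopifnot(k >= 2L)
  inserted_bases <- rep_len(inserted_bases, k)
  spans <- character(k)
  names_in <- character(k)
  kinds <- character(k)
  for (i in seq_len(k)) {
    f <- fragments[[i]]
    kinds[i] <- f$kind %||% "pcr_with_tails"
    if (inherits(f$record, "dna_fragment")) {
      kinds[i] <- "fragment"
      fr <- f$record
      spans[i] <- if (exo_direction == "3p") {
        substr(fr$extent, nchar(fr$left_end$seq) + 1L,
               nchar(fr$extent) - nchar(fr$right_end$seq))
      } else {
        fr$extent
      }
      names_in[i] <- fr$provenance
    } else {
      spans[i] <- if (is.null(f$start)) f$record$bases else
        subseq_bases(f$record, f$start, f$end)
      names_in[i] <- f$record$name
    }
  }
  blocks <- paste0(spans, inserted_bases) # junction j follows block j
  product_seq <- paste(blocks, collapse = "")
  np <- nchar(product_seq)

  grow_overlap <- function(host_down, j, min_len = 8L) {
    up <- j; down <- if (j == k) 1L else j + 1L
    # homology region: the terminal sequence of the non-host side
    src <- if (host_down) blocks[up] else spans[down]
    for (L in min_len:max_overlap) {
      if (L > nchar(src)) {
        stop(sprintf("fragment %d too short to host a %d-base overlap",
                     if (host_down) up else down, L), call. = FALSE)
      }
      ov <- if (host_down) substr(src, nchar(src) - L + 1L, nchar(src))
            else substr(src, 1L, L)
      if (tm_nn(ov) >= min_overlap_tm) return(ov)
    }
    stop("overlap melting temperature never reached the minimum", call. = FALSE)
  }

  junction_rows <- list()
  primer_rows <- list()
  fwd_tail <- character(k); rev_tail <- character(k)
  fwd_tail[] <- ""; rev_tail[] <- ""
  for (j in seq_len(k)) {
    up <- j; down <- if (j == k) 1L else j + 1L
    host_down <- kinds[down] == "pcr_with_tails"
    host_up <- kinds[up] == "pcr_with_tails"
    if (!host_down && !host_up) {
      stop(sprintf("junction %d: neither neighbor is a PCR with tails", j),
           call. = FALSE)
    }
    # the host tail must contain every non-templated inserted base plus
    # enough terminal homology, so the overlap may not be shorter than the
    # insert plus a seed
    ov <- grow_overlap(host_down, j,
                       min_len = max(8L, nchar(inserted_bases[j]) + 8L))
    if (host_down) {
      # downstream forward primer carries the upstream terminal overlap
      fwd_tail[down] <- ov
    } else {
      # upstream reverse primer reaches across the gap into the downstream start
      rev_tail[up] <- reverse_complement(paste0(inserted_bases[j], ov))
    }
    junction_rows[[j]] <- tibble::tibble(
      junction = j, upstream = names_in[up], downstream = names_in[down],
      overlap_sequence = ov, overlap_tm = tm_nn(ov),
      inserted_bases = inserted_bases[j], host = if (host_down) "fwd" else "rev")
  }
  for (i in seq_len(k)) {
    if (!(kinds[i] %in% c("pcr_with_tails", "pcr_no_tails"))) next
    fwd <- paste0(if (kinds[i] == "pcr_with_tails") fwd_tail[i] else "",
                  substr(spans[i], 1L, anneal_length))
    rev <- paste0(if (kinds[i] == "pcr_with_tails") rev_tail[i] else "",
                  reverse_complement(substr(spans[i],
                                            nchar(spans[i]) - anneal_length + 1L,
                                            nchar(spans[i]))))
    primer_rows[[length(primer_rows) + 1L]] <- tibble::tibble(
      name = c(sprintf("%s_gib_fwd", names_in[i]),
               sprintf("%s_gib_rev", names_in[i])),
      sequence = c(fwd, rev), fragment = names_in[i])
  }
  primers <- if (length(primer_rows)) dplyr::bind_rows(primer_rows) else
    tibble::tibble(name = character(), sequence = character(),
                   fragment = character())
  junctions <- dplyr::bind_rows(junction_rows)
  pcr_lines <- if (nrow(primers)) {
    sprintf("PCR: %s + %s on template %s",
            primers$name[c(TRUE, FALSE)], primers$name[c(FALSE, TRUE)],
            primers$fragment[c(TRUE, FALSE)])
  } else character()
  comment <- paste0(
    provenance_comment("Gibson assembly design", names_in),
    if (length(pcr_lines)) paste0("\nReactions:\n",
                                  paste(" ", pcr_lines, collapse = "\n")) else "",
    if (nrow(primers)) paste0("\nOrder sheet:\n",
                              paste(sprintf("%s\t%s", primers$name,
                                            primers$sequence),
                                    collapse = "\n")) else "")
  product <- dna_record(product_seq, name = "gibson_product",
                        topology = "circular", comment = comment)
  start_i <- c(1L, utils::head(cumsum(nchar(blocks)), -1L) + 1L)
  for (i in seq_len(k)) {
    if (!(kinds[i] %in% c("pcr_with_tails", "pcr_no_tails"))) next
    product <- add_feature(product, name = sprintf("%s_gib_fwd", names_in[i]),
                           start = start_i[i],
                           end = ((start_i[i] + anneal_length - 2L) %% np) + 1L,
                           strand = "+", type = "primer_bind")
    e <- start_i[i] + nchar(spans[i]) - 1L
    product <- add_feature(product, name = sprintf("%s_gib_rev", names_in[i]),
                           start = ((e - anneal_length) %% np) + 1L,
                           end = e, strand = "-", type = "primer_bind")
  }
  new_assembly_plan(list(product), names_in, "gibson_design",
                    junctions = junctions, primers = primers)
}
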