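# Recombinase/integrase-mediated joining driven by editable reaction
# prototypes.  A prototype names, per fragment slot, the ordered pair of
# recognition sites the slot must carry, whether the slot contributes the
# region between the sites ("inner") or outside them ("outer"), and how
# hybrid sites are renamed in the product.  Strand exchange happens at the
# start of the shared core of each reacting site pair.

find_site <- function(rec, site_seq) {
  # top-strand, exact orientation occurrences
  hits <- match_positions(toupper(rec$bases), toupper(site_seq))
  if (rec$topology == "circular") {
    n <- seq_length(rec)
    ext <- paste0(toupper(rec$bases), substr(toupper(rec$bases), 1,
                                             nchar(site_seq) - 1L))
    hits <- match_positions(ext, toupper(site_seq))
    hits <- hits[hits <= n]
  }
  hits
}

#' Simulate a recombinase-mediated assembly
#'
#' @param prototype Reaction name, looked up in `prototypes$reactions`.
#' @param records List of candidate [dna_record()]s (all "open windows").
#' @param prototypes Prototype database from [read_prototype_file()]
#'   (default: the bundled file).
#' @return An `assembly_plan`.  With several candidate records per slot all
#'   combinations are enumerated (plan flagged ambiguous).
#' @export
recombinase_assemble <- function(prototype, records,
                                 prototypes = default_db("prototypes")) {
  rx <- prototypes$reactions[[prototype]]
  if (is.null(rx)) stop(sprintf("unknown reaction prototype '%s'", prototype),
                        call. = FALSE)
  sites <- prototypes$sites
  slot_defs <- rx$fragments
  k <- length(slot_defs)

  # candidates per slot: record index + crossover coordinates
  slot_candidates <- vector("list", k)
  for (s in seq_len(k)) {
    def <- slot_defs[[s]]
    a <- def$sites[[1]]; b <- def$sites[[2]]
    take <- def$take %||% "inner"
    sa <- sites[[a]]; sb <- sites[[b]]
    if (is.null(sa) || is.null(sb)) {
      stop(sprintf("prototype site '%s' or '%s' undefined", a, b), call. = FALSE)
    }
    cands <- list()
    for (ri in seq_along(records)) {
      rec <- records[[ri]]
      ha <- find_site(rec, sa$sequence)
      hb <- find_site(rec, sb$sequence)
      if (!length(ha) || !length(hb)) next
      for (pa in ha) for (pb in hb) {
        xa <- pa + sa$core_start - 1L # crossover: start of core
        xb <- pb + sb$core_start - 1L
        # an inner slot's contribution runs A -> B; an outer slot's runs
        # B -> around -> A, so its start/end sites swap
        cands[[length(cands) + 1L]] <- list(
          record = ri, xa = xa, xb = xb, take = take, siteA = a, siteB = b,
          start_site = if (take == "inner") a else b,
          end_site = if (take == "inner") b else a)
      }
    }
    if (!length(cands)) {
      stop(sprintf("no record carries sites %s..%s for slot %d in the right orientation",
                   a, b, s), call. = FALSE)
    }
    slot_candidates[[s]] <- cands
  }

  contribution <- function(cand) {
    rec <- records[[cand$record]]
    n <- seq_length(rec)
    if (cand$take == "inner") {
      # from crossover of A up to (not including) crossover of B
      e <- ((cand$xb - 2L) %% n) + 1L
      subseq_bases(rec, cand$xa, e)
    } else {
      # outside the pair: from crossover of B around to before crossover of A
      if (rec$topology != "circular") {
        stop("an 'outer' slot requires a circular record", call. = FALSE)
      }
      e <- ((cand$xa - 2L) %% n) + 1L
      subseq_bases(rec, cand$xb, e)
    }
  }

  combos <- expand.grid(lapply(slot_candidates, seq_along))
  products <- list()
  for (ci in seq_len(nrow(combos))) {
    cands <- lapply(seq_len(k), function(s) {
      slot_candidates[[s]][[combos[ci, s][[1]]]]
    })
    seqn <- paste(vapply(cands, contribution, character(1)), collapse = "")
    input_names <- vapply(cands, function(cd) records[[cd$record]]$name,
                          character(1))
    rec <- dna_record(seqn, name = sprintf("%s_product_%d", prototype,
                                           length(products) + 1L),
                      topology = "circular",
                      comment = provenance_comment(
                        sprintf("Recombination (%s)", prototype), input_names))
    # rename hybrid sites: junction after slot s joins slot s's B-site arm
    # to slot s+1's A-site core; the product-site table names the hybrid
    offsets <- cumsum(vapply(cands, function(cd) {
      nchar(contribution(cd))
    }, numeric(1)))
    np <- seq_length(rec)
    for (s in seq_len(k)) {
      nxt <- if (s == k) 1L else s + 1L
      key <- paste0(cands[[s]]$end_site, "+", cands[[nxt]]$start_site)
      new_name <- rx$products[[key]]
      if (is.null(new_name)) next
      core_pos <- (offsets[s] %% np) + 1L
      hybrid_def <- sites[[new_name]] %||% sites[[cands[[nxt]]$start_site]]
      width <- nchar(hybrid_def$sequence)
      start <- ((core_pos - hybrid_def$core_start) %% np) + 1L
      rec <- add_feature(rec, name = new_name, start = start,
                         end = ((start + width - 2L) %% np) + 1L,
                         strand = "+", type = "protein_bind")
    }
    products[[length(products) + 1L]] <- rec
  }
  new_assembly_plan(products,
                    unique(vapply(records, `[[`, character(1), "name")),
                    sprintf("recombinase(%s)", prototype),
                    ambiguous = length(products) > 1L)
}
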