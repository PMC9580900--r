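# The DNA record: the universal currency of every tool in the package.
# A record is sequence text (case preserved), a topology flag, a feature
# table (tibble), a free-text comment, and the opaque header records kept
# from the source file.  Coordinates are 1-based and inclusive throughout,
# matching GenBank; a feature segment with start > end wraps the origin of a
# circular record.

#' Construct a DNA record
#'
#' @param bases IUPAC nucleotide string (case preserved).
#' @param name Record name (LOCUS name on write).
#' @param topology `"linear"` or `"circular"`.
#' @param features Feature table as returned by [feature_table()]; defaults
#'   to an empty table.
#' @param comment Free-text comment carried in the COMMENT header.
#' @param header_records Opaque list of `list(keyword=, text=)` pairs
#'   retained verbatim from a parsed file.
#' @return An object of class `dna_record`.
#' @examples
#' rec <- dna_record("ATGAAATAA", name = "demo")
#' seq_length(rec)
#' @export
dna_record <- function(bases, name = "unnamed", topology = c("linear", "circular"),
                       features = feature_table(), comment = "",
                       header_records = list()) {
  topology <- match.arg(topology)
  check_iupac(bases, what = sprintf("record '%s'", name))
  structure(
    list(name = name, bases = bases, topology = topology,
         features = features, comment = comment,
         header_records = header_records),
    class = "dna_record"
  )
}

#' An empty (or populated) feature table
#'
#' Columns: `name`, `segments` (list of integer matrices with columns
#' `start`,`end`), `strand` (`"+"`/`"-"`), `type` (GenBank feature key),
#' `qualifiers` (list of ordered key/value pair lists), `color`, `z`
#' (display priority) and `hidden`.
#'
#' @param name,segments,strand,type,qualifiers,color,z,hidden Column values.
#' @return A tibble with one row per feature.
#' @export
feature_table <- function(name = character(), segments = list(),
                          strand = character(), type = character(),
                          qualifiers = list(), color = character(),
                          z = integer(), hidden = logical()) {
  tibble::tibble(
    name = as.character(name),
    segments = segments,
    strand = as.character(strand),
    type = as.character(type),
    qualifiers = qualifiers,
    color = as.character(color),
    z = as.integer(z),
    hidden = as.logical(hidden)
  )
}

new_segment <- function(start, end) {
  cbind(start = as.integer(start), end = as.integer(end))
}

#' Add one feature to a record
#'
#' @param rec A [dna_record()].
#' @param name Feature name (stored as `/label`).
#' @param start,end 1-based inclusive span; `start > end` wraps the origin on
#'   circular records (an error on linear ones). Multi-segment features can be
#'   given via `segments`.
#' @param strand `"+"` or `"-"`.
#' @param type GenBank feature key.
#' @param segments Optional matrix with `start`/`end` columns overriding
#'   `start`/`end`.
#' @param qualifiers List of `list(key=, value=)` pairs.
#' @param color Display color (hex); `z` display priority; `hidden` flag.
#' @param z,hidden Display priority and visibility.
#' @return The record with the feature appended.
#' @export
add_feature <- function(rec, name, start = NULL, end = NULL, strand = "+",
                        type = "misc_feature", segments = NULL,
                        qualifiers = list(), color = "#88ccff", z = 0L,
                        hidden = FALSE) {
  stopifnot(inherits(rec, "dna_record"))
  if (is.null(segments)) segments <- new_segment(start, end)
  n <- seq_length(rec)
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, "start"]; e <- segments[i, "end"]
    if (s < 1L || e < 1L || s > n || e > n) {
      stop(sprintf("feature '%s' segment %d..%d outside 1..%d", name, s, e, n),
           call. = FALSE)
    }
    if (s > e && rec$topology != "circular") {
      stop(sprintf("feature '%s' wraps the origin of a linear record", name),
           call. = FALSE)
    }
  }
  rec$features <- dplyr::bind_rows(
    rec$features,
    feature_table(name = name, segments = list(segments), strand = strand,
                  type = type, qualifiers = list(qualifiers), color = color,
                  z = z, hidden = hidden)
  )
  rec
}

#' Sequence length of a record
#' @param rec A `dna_record`.
#' @export
seq_length <- function(rec) nchar(rec$bases)

#' @export
print.dna_record <- function(x, ...) {
  cat(sprintf("<dna_record> %s: %d bp, %s, %d feature(s)\n",
              x$name, seq_length(x), x$topology, nrow(x$features)))
  preview <- substr(x$bases, 1, 60)
  cat(" ", preview, if (seq_length(x) > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Extract subsequence respecting circular wrap
#'
#' @param rec A `dna_record`.
#' @param start,end 1-based inclusive; `start > end` wraps on circular
#'   records.
#' @return Subsequence string.
#' @export
subseq_bases <- function(rec, start, end) {
  n <- seq_length(rec)
  if (start <= end) return(substr(rec$bases, start, end))
  if (rec$topology != "circular") {
    stop("wrapping selection on a linear record", call. = FALSE)
  }
  paste0(substr(rec$bases, start, n), substr(rec$bases, 1, end))
}

span_width <- function(start, end, n) {
  ifelse(start <= end, end - start + 1L, n - start + end + 1L)
}

#' Rotate the origin of a circular record
#'
#' The base at `new_start` becomes position 1; feature segments are
#' renumbered, and features spanning the new origin become wrapping
#' features.
#'
#' @param rec A circular `dna_record`.
#' @param new_start Position that becomes 1.
#' @return The rotated record.
#' @export
rotate_origin <- function(rec, new_start) {
  stopifnot(inherits(rec, "dna_record"))
  if (rec$topology != "circular") {
    stop("rotate_origin requires a circular record", call. = FALSE)
  }
  n <- seq_length(rec)
  new_start <- ((as.integer(new_start) - 1L) %% n) + 1L
  if (new_start == 1L) return(rec)
  rec$bases <- paste0(substr(rec$bases, new_start, n),
                      substr(rec$bases, 1, new_start - 1L))
  remap <- function(p) ((p - new_start) %% n) + 1L
  rec$features$segments <- lapply(rec$features$segments, function(seg) {
    new_segment(remap(seg[, "start"]), remap(seg[, "end"]))
  })
  rec
}

#' Insert tandem repeats of a short unit into a record
#'
#' Downstream features shift right; features spanning the insertion point
#' grow by the inserted length.
#'
#' @param rec A `dna_record`.
#' @param position Insertion point: the repeat block is inserted *before*
#'   this 1-based position.
#' @param unit Repeat unit (IUPAC string).
#' @param count Number of copies (>= 1).
#' @return The modified record.
#' @export
insert_repeat <- function(rec, position, unit, count) {
  stopifnot(inherits(rec, "dna_record"), count >= 1)
  check_iupac(unit, "repeat unit")
  n <- seq_length(rec)
  position <- as.integer(position)
  if (position < 1L || position > n + 1L) {
    stop(sprintf("insert position %d outside 1..%d", position, n + 1L),
         call. = FALSE)
  }
  ins <- strrep(unit, count)
  k <- nchar(ins)
  rec$bases <- paste0(substr(rec$bases, 1, position - 1L), ins,
                      substr(rec$bases, position, n))
  rec$features$segments <- lapply(rec$features$segments, function(seg) {
    s <- seg[, "start"]; e <- seg[, "end"]
    # spans are treated as linear here; wrap-features keep their anchors
    s2 <- ifelse(s >= position, s + k, s)
    e2 <- ifelse(e >= position, e + k, e)
    new_segment(s2, e2)
  })
  rec
}
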