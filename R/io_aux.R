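# Auxiliary plain-text databases and free-form sequence input.
#
# The shipped formats are versioned, tab-delimited, line-oriented text with
# '#' comment lines:
#   enzymes:  name <TAB> recognition <TAB> top_cut <TAB> bottom_cut
#             <TAB> methylation ('-' or ';'-joined 'methylase:pattern@offset')
#             <TAB> groups ('-' or comma-joined tags)
#   ladders:  ladder_name <TAB> size_bp <TAB> relative_mass_weight
#   feature libraries: name <TAB> pattern <TAB> color <TAB> gb_type
#             <TAB> strand_policy (top|both)
# Recombination prototypes are YAML (see read_prototype_file).

#' Auto-detect and read a sequence file
#'
#' Sniffs GenBank (LOCUS header), FASTA (`>`), otherwise treats the input as
#' raw ASCII: whitespace, digits and all non-IUPAC characters are stripped.
#'
#' @param path File path, or `text` lines.
#' @param text Optional character vector of lines.
#' @return A list of [dna_record()]s (FASTA input may hold several).
#' @export
read_sequence_auto <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  body <- lines[nzchar(trimws(lines))]
  if (length(body) == 0L) stop("empty sequence input", call. = FALSE)
  if (any(grepl("^LOCUS", body))) {
    return(read_genbank_multi(lines))
  }
  if (startsWith(trimws(body[1]), ">")) {
    return(read_fasta(lines))
  }
  bases <- gsub("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn]", "",
                paste(lines, collapse = ""))
  if (!nzchar(bases)) stop("no sequence characters after cleaning", call. = FALSE)
  list(dna_record(bases, name = if (!is.null(path)) basename(path) else "raw"))
}

read_fasta <- function(lines) {
  heads <- which(startsWith(trimws(lines), ">"))
  if (!length(heads)) stop("no FASTA header", call. = FALSE)
  bounds <- c(heads, length(lines) + 1L)
  out <- vector("list", length(heads))
  for (i in seq_along(heads)) {
    name <- sub("^>\\s*", "", trimws(lines[heads[i]]))
    name <- strsplit(name, "\\s+")[[1]][1]
    seqs <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    bases <- gsub("[^A-Za-z]", "", paste(seqs, collapse = ""))
    if (!nzchar(bases)) stop(sprintf("FASTA record '%s' is empty", name),
                             call. = FALSE)
    out[[i]] <- dna_record(bases, name = name)
  }
  out
}

#' Write records as FASTA
#' @param recs A `dna_record` or list of them.
#' @param path Optional output path.
#' @param width Line width.
#' @return Lines (invisibly when `path` given).
#' @export
write_fasta <- function(recs, path = NULL, width = 70L) {
  if (inherits(recs, "dna_record")) recs <- list(recs)
  lines <- unlist(lapply(recs, function(r) {
    n <- seq_length(r)
    starts <- seq(1L, n, by = width)
    c(paste0(">", r$name), substring(r$bases, starts, pmin(starts + width - 1L, n)))
  }))
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

aux_lines <- function(path, text) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  list(lines = lines[keep], numbers = which(keep))
}

#' Load a restriction-enzyme database file
#'
#' @param path File path, or `text` lines.
#' @param text Optional character vector.
#' @return Tibble: `name`, `recognition`, `top_cut`, `bottom_cut`,
#'   `methylation` (list of `list(methylase=, pattern=, offset=)`),
#'   `groups` (list of character vectors), plus derived `overhang_length`
#'   and `polarity` (`"5p"`, `"3p"`, `"blunt"`). Duplicate names: last
#'   entry wins with a warning.
#' @export
load_enzyme_file <- function(path = NULL, text = NULL) {
  src <- aux_lines(path, text)
  rows <- lapply(seq_along(src$lines), function(i) {
    f <- strsplit(src$lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L) {
      stop(sprintf("unparsable enzyme line %d: expected >= 4 tab fields",
                   src$numbers[i]), call. = FALSE)
    }
    recognition <- toupper(f[2])
    check_iupac(recognition, sprintf("enzyme '%s' recognition", f[1]))
    top <- suppressWarnings(as.integer(f[3]))
    bottom <- suppressWarnings(as.integer(f[4]))
    if (is.na(top) || is.na(bottom)) {
      stop(sprintf("unparsable cut offsets on line %d", src$numbers[i]),
           call. = FALSE)
    }
    meth <- if (length(f) >= 5L && f[5] != "-" && nzchar(f[5])) {
      lapply(strsplit(f[5], ";", fixed = TRUE)[[1]], function(m) {
        parts <- regmatches(m, regexec("^(dam|dcm):([A-Za-z]+)@(-?\\d+)$", m))[[1]]
        if (length(parts) != 4L) {
          stop(sprintf("bad methylation rule '%s' on line %d", m, src$numbers[i]),
               call. = FALSE)
        }
        list(methylase = parts[2], pattern = toupper(parts[3]),
             offset = as.integer(parts[4]))
      })
    } else list()
    groups <- if (length(f) >= 6L && f[6] != "-" && nzchar(f[6])) {
      strsplit(f[6], ",", fixed = TRUE)[[1]]
    } else character()
    tibble::tibble(name = f[1], recognition = recognition,
                   top_cut = top, bottom_cut = bottom,
                   methylation = list(meth), groups = list(groups))
  })
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$name)) {
    warning("duplicate enzyme names; keeping the last entry of each",
            call. = FALSE)
    out <- out[!duplicated(out$name, fromLast = TRUE), ]
  }
  out$overhang_length <- abs(out$bottom_cut - out$top_cut)
  out$polarity <- dplyr::case_when(
    out$top_cut < out$bottom_cut ~ "5p",
    out$top_cut > out$bottom_cut ~ "3p",
    TRUE ~ "blunt"
  )
  out
}

#' Load a gel-ladder database file
#' @inheritParams load_enzyme_file
#' @return Tibble: `name`, `bands` (list of tibbles with `size`, `weight`).
#' @export
load_ladder_file <- function(path = NULL, text = NULL) {
  src <- aux_lines(path, text)
  f <- do.call(rbind, strsplit(src$lines, "\t", fixed = TRUE))
  if (is.null(f) || ncol(f) < 3L) {
    stop("ladder file needs name<TAB>size<TAB>weight lines", call. = FALSE)
  }
  long <- tibble::tibble(name = f[, 1],
                         size = as.numeric(f[, 2]),
                         weight = as.numeric(f[, 3]))
  if (any(is.na(long$size)) || any(long$size <= 0)) {
    stop("ladder sizes must be positive numbers", call. = FALSE)
  }
  parts <- split(long[c("size", "weight")], long$name)
  tibble::tibble(name = names(parts),
                 bands = lapply(parts, tibble::as_tibble))
}

#' Load a feature-definition library
#'
#' Patterns are compiled with [compile_feature_pattern()]; an entry with a
#' missing color receives a default palette color.
#'
#' @inheritParams load_enzyme_file
#' @return Tibble: `name`, `pattern` (raw text), `color`, `type`,
#'   `strand_policy`, `matcher` (compiled pattern objects).
#' @export
load_feature_library <- function(path = NULL, text = NULL) {
  src <- aux_lines(path, text)
  defaults <- generate_palette(max(1L, length(src$lines)), seed = 7L)$hex
  rows <- lapply(seq_along(src$lines), function(i) {
    f <- strsplit(src$lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) {
      stop(sprintf("unparsable feature definition on line %d", src$numbers[i]),
           call. = FALSE)
    }
    color <- if (length(f) >= 3L && nzchar(f[3])) f[3] else defaults[i]
    type <- if (length(f) >= 4L && nzchar(f[4])) f[4] else "misc_feature"
    policy <- if (length(f) >= 5L && nzchar(f[5])) f[5] else "both"
    matcher <- tryCatch(compile_feature_pattern(f[2]), error = function(e) {
      stop(sprintf("entry '%s': %s", f[1], conditionMessage(e)), call. = FALSE)
    })
    tibble::tibble(name = f[1], pattern = f[2], color = color, type = type,
                   strand_policy = policy, matcher = list(matcher))
  })
  dplyr::bind_rows(rows)
}

#' Read a recombination prototype file (YAML)
#'
#' The file declares named recognition sites (sequence plus the shared core
#' span where strand exchange happens) and reaction prototypes listing the
#' ordered site pairs each fragment slot must carry and the renaming of
#' sites in the product.
#'
#' @param path YAML file path.
#' @return List with elements `sites` (named list of
#'   `list(sequence=, core_start=, core_end=)`) and `reactions` (named list
#'   of `list(fragments = list of c(siteA, siteB), products = named map
#'   "siteA+siteB" -> product site name)`).
#' @export
read_prototype_file <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$sites), !is.null(y$reactions))
  y
}

pk_extdata <- function(file) {
  system.file("extdata", file, package = "plasmidkit", mustWork = TRUE)
}

#' Bundled default databases
#'
#' @param which One of `"enzymes"`, `"features"`, `"ladders"`,
#'   `"prototypes"`.
#' @return The loaded database (tibble, or prototype list).
#' @export
default_db <- function(which = c("enzymes", "features", "ladders", "prototypes")) {
  which <- match.arg(which)
  switch(which,
    enzymes = load_enzyme_file(pk_extdata("enzymes.tsv")),
    features = load_feature_library(pk_extdata("feature_library_generic.tsv")),
    ladders = load_ladder_file(pk_extdata("ladders.tsv")),
    prototypes = read_prototype_file(pk_extdata("recombination_prototypes.yaml"))
  )
}
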