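# GenBank flat-file reader/writer, including the ApEinfo display dialect:
# record-wide metadata rides in a COMMENT line starting "ApEinfo:", and
# per-feature display settings ride in /ApEinfo_* qualifiers.  Unknown
# header records and qualifiers are preserved verbatim, never fatal.

#' Options controlling the ApEinfo dialect on write
#'
#' With both flags `FALSE` the output is plain GenBank with no "ApEinfo"
#' content, acceptable to strict parsers.
#'
#' @param write_apeinfo_qualifiers Emit `/ApEinfo_*` feature qualifiers.
#' @param write_apeinfo_comment Emit the `ApEinfo:` COMMENT line.
#' @return A list of class `ape_dialect_options`.
#' @export
ape_dialect_options <- function(write_apeinfo_qualifiers = TRUE,
                                write_apeinfo_comment = TRUE) {
  structure(list(write_apeinfo_qualifiers = write_apeinfo_qualifiers,
                 write_apeinfo_comment = write_apeinfo_comment),
            class = "ape_dialect_options")
}

parse_location <- function(loc, line_no = NA) {
  loc <- gsub("[<>]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  spans <- lapply(parts, function(p) {
    p <- trimws(p)
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^\\d+$", p)) {
      rep(as.integer(p), 2L)
    } else {
      stop(sprintf("malformed location '%s' at line %s", p, line_no),
           call. = FALSE)
    }
  })
  list(strand = strand,
       segments = new_segment(vapply(spans, `[`, integer(1), 1L),
                              vapply(spans, `[`, integer(1), 2L)))
}

# collapse join(a..L, 1..b) into a single wrapping segment on circular recs
collapse_wrap <- function(segments, n, circular) {
  if (!circular || nrow(segments) != 2L) return(segments)
  if (segments[1, "end"] == n && segments[2, "start"] == 1L &&
      segments[1, "start"] > 1L) {
    return(new_segment(segments[1, "start"], segments[2, "end"]))
  }
  segments
}

#' Read a GenBank flat file
#'
#' Parses LOCUS (name, length, topology), retains all header records
#' verbatim, interprets `ApEinfo:` COMMENT lines and `/ApEinfo_*`
#' qualifiers, and reads joined/complemented feature locations.
#'
#' @param path File path, or a character vector of lines via `text`.
#' @param text Optional character vector of lines (overrides `path`).
#' @return A [dna_record()].
#' @export
read_genbank <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  recs <- read_genbank_multi(lines)
  if (length(recs) == 0L) stop("no GenBank record found", call. = FALSE)
  recs[[1]]
}

read_genbank_multi <- function(lines) {
  # split on record terminators
  ends <- which(trimws(lines) == "//")
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- list()
  for (k in seq_along(starts)) {
    chunk <- lines[starts[k]:ends[k]]
    if (!any(grepl("^LOCUS", chunk))) next
    out[[length(out) + 1L]] <- parse_genbank_record(chunk)
  }
  out
}

parse_genbank_record <- function(lines) {
  locus_i <- grep("^LOCUS", lines)[1]
  locus <- lines[locus_i]
  toks <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]]
  name <- toks[1]
  topology <- if (any(tolower(toks) == "circular")) "circular" else "linear"

  feat_i <- grep("^FEATURES", lines)[1]
  orig_i <- grep("^ORIGIN", lines)[1]
  if (is.na(orig_i)) stop("GenBank record lacks ORIGIN", call. = FALSE)

  # --- header records (between LOCUS and FEATURES), kept verbatim ---
  header_records <- list()
  comment <- character()
  ape_meta <- character()
  hdr_end <- if (!is.na(feat_i)) feat_i - 1L else orig_i - 1L
  i <- locus_i + 1L
  while (i <= hdr_end) {
    line <- lines[i]
    keyword <- trimws(substr(line, 1, 12))
    body <- substr(line, 13, nchar(line))
    j <- i + 1L
    while (j <= hdr_end && grepl("^\\s", lines[j]) &&
           trimws(substr(lines[j], 1, 12)) == "") {
      body <- paste(body, trimws(lines[j]), sep = "\n")
      j <- j + 1L
    }
    if (keyword == "COMMENT") {
      if (grepl("^ApEinfo:", trimws(body))) {
        ape_meta <- c(ape_meta, trimws(body))
      } else {
        comment <- c(comment, body)
      }
    } else if (nzchar(keyword)) {
      header_records[[length(header_records) + 1L]] <-
        list(keyword = keyword, text = body)
    }
    i <- j
  }

  # --- sequence ---
  seq_lines <- lines[(orig_i + 1L):length(lines)]
  seq_lines <- seq_lines[trimws(seq_lines) != "//"]
  bases <- gsub("[^A-Za-z]", "", paste(seq_lines, collapse = ""))
  check_iupac(bases, "ORIGIN sequence")
  n <- nchar(bases)

  rec <- dna_record(bases, name = name, topology = topology,
                    comment = paste(comment, collapse = "\n"),
                    header_records = header_records)
  if (length(ape_meta)) {
    rec$apeinfo <- sub("^ApEinfo:", "", ape_meta)
  }

  # --- features ---
  if (!is.na(feat_i)) {
    fl <- lines[(feat_i + 1L):(orig_i - 1L)]
    k <- 1L
    while (k <= length(fl)) {
      line <- fl[k]
      if (grepl("^ {5}\\S", line)) {
        key <- trimws(substr(line, 6, 20))
        loc <- trimws(substr(line, 21, nchar(line)))
        k <- k + 1L
        # location continuation lines (before any qualifier)
        while (k <= length(fl) && grepl("^ {21}", fl[k]) &&
               !grepl("^ {21}/", fl[k])) {
          loc <- paste0(loc, trimws(fl[k])); k <- k + 1L
        }
        quals <- list()
        while (k <= length(fl) && grepl("^ {21}/", fl[k])) {
          q <- trimws(fl[k]); k <- k + 1L
          while (k <= length(fl) && grepl("^ {21}", fl[k]) &&
                 !grepl("^ {21}/", fl[k])) {
            q <- paste(q, trimws(fl[k])); k <- k + 1L
          }
          eq <- regexpr("=", q, fixed = TRUE)
          if (eq == -1L) {
            quals[[length(quals) + 1L]] <- list(key = sub("^/", "", q), value = "")
          } else {
            qkey <- sub("^/", "", substr(q, 1, eq - 1L))
            qval <- substr(q, eq + 1L, nchar(q))
            qval <- sub('^"', "", sub('"$', "", qval))
            quals[[length(quals) + 1L]] <- list(key = qkey, value = qval)
          }
        }
        parsed <- parse_location(loc, line_no = feat_i + k)
        segs <- collapse_wrap(parsed$segments, n, topology == "circular")
        qget <- function(key) {
          for (q in quals) if (q$key == key) return(q$value)
          NULL
        }
        fname <- qget("label") %||% qget("gene") %||% qget("locus_tag") %||% key
        color <- if (parsed$strand == "-") {
          qget("ApEinfo_revcolor") %||% qget("ApEinfo_fwdcolor")
        } else {
          qget("ApEinfo_fwdcolor") %||% qget("ApEinfo_revcolor")
        }
        # interpreted qualifiers are lifted into fields, not duplicated
        lifted <- c("label", "ApEinfo_fwdcolor", "ApEinfo_revcolor",
                    "ApEinfo_z", "ApEinfo_hidden")
        kept <- Filter(function(q) !(q$key %in% lifted), quals)
        rec <- add_feature(
          rec, name = fname, segments = segs, strand = parsed$strand,
          type = key, qualifiers = kept,
          color = color %||% "#88ccff",
          z = as.integer(qget("ApEinfo_z") %||% 0L),
          hidden = identical(qget("ApEinfo_hidden"), "1")
        )
      } else {
        k <- k + 1L
      }
    }
  }
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

format_location <- function(segments, strand, n, circular) {
  parts <- vapply(seq_len(nrow(segments)), function(i) {
    s <- segments[i, "start"]; e <- segments[i, "end"]
    if (s > e && circular) {
      sprintf("%d..%d,1..%d", s, n, e)
    } else if (s == e) {
      sprintf("%d", s)
    } else {
      sprintf("%d..%d", s, e)
    }
  }, character(1))
  loc <- paste(parts, collapse = ",")
  if (grepl(",", loc, fixed = TRUE)) loc <- sprintf("join(%s)", loc)
  if (strand == "-") loc <- sprintf("complement(%s)", loc)
  loc
}

wrap_qualifier <- function(text, width = 58L) {
  # fold long qualifier values onto 21-space continuation lines
  if (nchar(text) <= width) return(paste0(strrep(" ", 21), text))
  out <- character()
  while (nchar(text) > width) {
    out <- c(out, paste0(strrep(" ", 21), substr(text, 1, width)))
    text <- substr(text, width + 1L, nchar(text))
  }
  c(out, paste0(strrep(" ", 21), text))
}

#' Write a record as GenBank text
#'
#' @param rec A [dna_record()].
#' @param opts [ape_dialect_options()]; with both flags off the output
#'   contains no "ApEinfo" content.
#' @param path Optional file path; when `NULL` the text is returned.
#' @return Character vector of lines (invisibly when `path` given).
#' @export
write_genbank <- function(rec, opts = ape_dialect_options(), path = NULL) {
  stopifnot(inherits(rec, "dna_record"))
  n <- seq_length(rec)
  lines <- sprintf("LOCUS       %-16s %d bp ds-DNA     %-8s     01-JAN-2000",
                   rec$name, n, rec$topology)
  for (h in rec$header_records) {
    body <- strsplit(h$text, "\n", fixed = TRUE)[[1]]
    lines <- c(lines, sprintf("%-12s%s", h$keyword, body[1]))
    if (length(body) > 1L) {
      lines <- c(lines, paste0(strrep(" ", 12), body[-1]))
    }
  }
  if (nzchar(rec$comment)) {
    body <- strsplit(rec$comment, "\n", fixed = TRUE)[[1]]
    lines <- c(lines, sprintf("%-12s%s", "COMMENT", body[1]))
    if (length(body) > 1L) {
      lines <- c(lines, paste0(strrep(" ", 12), body[-1]))
    }
  }
  if (opts$write_apeinfo_comment && !is.null(rec$apeinfo)) {
    lines <- c(lines, unname(vapply(rec$apeinfo, function(m) {
      sprintf("%-12sApEinfo:%s", "COMMENT", m)
    }, character(1))))
  }
  lines <- c(lines, "FEATURES             Location/Qualifiers")
  if (nrow(rec$features) > 0L) {
    for (i in seq_len(nrow(rec$features))) {
      f <- rec$features[i, ]
      loc <- format_location(f$segments[[1]], f$strand, n,
                             rec$topology == "circular")
      lines <- c(lines, sprintf("     %-16s%s", f$type, loc))
      quals <- f$qualifiers[[1]]
      written <- vapply(quals, function(q) q$key, character(1))
      emit <- function(key, value) {
        lines <<- c(lines, wrap_qualifier(sprintf('/%s="%s"', key, value)))
      }
      has_label <- "label" %in% written
      if (!has_label) emit("label", f$name)
      for (q in quals) {
        if (startsWith(q$key, "ApEinfo_") && !opts$write_apeinfo_qualifiers) next
        # display fields override stored ApEinfo qualifiers
        if (q$key %in% c("ApEinfo_fwdcolor", "ApEinfo_revcolor",
                         "ApEinfo_z", "ApEinfo_hidden", "label")) next
        emit(q$key, q$value)
      }
      if (opts$write_apeinfo_qualifiers) {
        emit("ApEinfo_fwdcolor", f$color)
        emit("ApEinfo_revcolor", f$color)
        emit("ApEinfo_z", f$z)
        if (f$hidden) emit("ApEinfo_hidden", "1")
      }
    }
  }
  lines <- c(lines, "ORIGIN")
  seq <- tolower(rec$bases)
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substr(seq, p, min(p + 59L, n))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", p, paste(groups, collapse = " ")))
  }
  lines <- c(lines, "//")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
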