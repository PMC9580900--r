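# Hand-built SVG 1.1 output for record maps (linear and circular) and
# virtual gels.  Every feature/enzyme element carries a `data-span`
# attribute with its 1-based span so elements stay linked to their parent
# sequence regions; circular maps put angle 0 at 12 o'clock, clockwise.

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

svg_doc <- function(body, width, height) {
  c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="%d" height="%d" viewBox="0 0 %d %d">'),
            width, height, width, height),
    body, "</svg>")
}

polar_xy <- function(cx, cy, r, frac) {
  # angle 0 at 12 o'clock, clockwise
  theta <- 2 * pi * frac - pi / 2
  c(cx + r * cos(theta), cy + r * sin(theta))
}

#' Render a record map or a gel as SVG
#'
#' @param subject A [dna_record()] or a `gel_model`.
#' @param circular For records: draw a circular map (defaults to the
#'   record's topology).
#' @param enzymes Optional enzyme tibble; cut sites are labelled.
#' @param width,height Canvas size in pixels.
#' @param path Optional output file.
#' @return Character vector of SVG lines (invisibly when `path` given).
#' @export
render_svg <- function(subject, circular = NULL, enzymes = NULL,
                       width = 600L, height = 400L, path = NULL) {
  lines <- if (inherits(subject, "gel_model")) {
    svg_gel(subject, width, height)
  } else {
    svg_record_map(subject, circular %||% (subject$topology == "circular"),
                   enzymes, width, height)
  }
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

svg_record_map <- function(rec, circular, enzymes, width, height) {
  n <- seq_length(rec)
  body <- character()
  feats <- rec$features
  sites <- if (!is.null(enzymes)) find_cut_sites(rec, enzymes) else NULL
  if (circular) {
    cx <- width / 2; cy <- height / 2; r <- min(width, height) / 2 - 60
    body <- c(body, sprintf(
      '<circle cx="%g" cy="%g" r="%g" fill="none" stroke="black" stroke-width="2"/>',
      cx, cy, r))
    for (i in seq_len(nrow(feats))) {
      f <- feats[i, ]
      if (f$hidden) next
      seg <- f$segments[[1]]
      for (si in seq_len(nrow(seg))) {
        s <- seg[si, "start"]; e <- seg[si, "end"]
        w <- span_width(s, e, n)
        # arc from s to e clockwise
        f0 <- (s - 1) / n; f1 <- (s - 1 + w) / n
        p0 <- polar_xy(cx, cy, r, f0); p1 <- polar_xy(cx, cy, r, f1)
        large <- if (w / n > 0.5) 1 else 0
        body <- c(body, sprintf(
          paste0('<path class="feature" data-span="%d..%d" data-name="%s" ',
                 'd="M %g %g A %g %g 0 %d 1 %g %g" stroke="%s" ',
                 'stroke-width="10" fill="none"/>'),
          s, e, svg_escape(f$name), p0[1], p0[2], r, r, large, p1[1], p1[2],
          f$color))
      }
    }
    if (!is.null(sites) && nrow(sites)) {
      for (k in seq_len(nrow(sites))) {
        fr <- (sites$recognition_start[k] - 1) / n
        p0 <- polar_xy(cx, cy, r, fr); p1 <- polar_xy(cx, cy, r + 15, fr)
        pt <- polar_xy(cx, cy, r + 25, fr)
        body <- c(body, sprintf(
          paste0('<line class="enzyme" data-span="%d..%d" x1="%g" y1="%g" ',
                 'x2="%g" y2="%g" stroke="grey"/>'),
          sites$recognition_start[k], sites$recognition_start[k],
          p0[1], p0[2], p1[1], p1[2]),
          sprintf('<text class="enzyme-label" x="%g" y="%g" font-size="10">%s</text>',
                  pt[1], pt[2], svg_escape(sites$enzyme[k])))
      }
    }
    body <- c(body, sprintf(
      '<text x="%g" y="%g" text-anchor="middle" font-size="14">%s (%d bp)</text>',
      cx, cy, svg_escape(rec$name), n))
  } else {
    x0 <- 40; x1 <- width - 40; y <- height / 2
    px <- function(pos) x0 + (pos - 1) / max(1L, n - 1L) * (x1 - x0)
    body <- c(body, sprintf(
      '<line x1="%g" y1="%g" x2="%g" y2="%g" stroke="black" stroke-width="2"/>',
      x0, y, x1, y))
    for (i in seq_len(nrow(feats))) {
      f <- feats[i, ]
      if (f$hidden) next
      seg <- f$segments[[1]]
      for (si in seq_len(nrow(seg))) {
        s <- seg[si, "start"]; e <- seg[si, "end"]
        if (s > e) next
        body <- c(body, sprintf(
          paste0('<rect class="feature" data-span="%d..%d" data-name="%s" ',
                 'x="%g" y="%g" width="%g" height="14" fill="%s"/>'),
          s, e, svg_escape(f$name), px(s), y - 7,
          max(1, px(e) - px(s)), f$color))
      }
    }
    if (!is.null(sites) && nrow(sites)) {
      for (k in seq_len(nrow(sites))) {
        xx <- px(sites$recognition_start[k])
        body <- c(body, sprintf(
          paste0('<line class="enzyme" data-span="%d..%d" x1="%g" y1="%g" ',
                 'x2="%g" y2="%g" stroke="grey"/>'),
          sites$recognition_start[k], sites$recognition_start[k],
          xx, y - 20, xx, y),
          sprintf('<text class="enzyme-label" x="%g" y="%g" font-size="10">%s</text>',
                  xx, y - 24, svg_escape(sites$enzyme[k])))
      }
    }
  }
  svg_doc(body, width, height)
}

svg_gel <- function(gel, width, height) {
  df <- tibble::as_tibble(gel)
  lanes <- unique(df$lane)
  lane_w <- (width - 80) / length(lanes)
  top <- 40; bottom <- height - 20
  body <- character()
  for (li in seq_along(lanes)) {
    x <- 40 + (li - 1) * lane_w
    sub <- df[df$lane == lanes[li], ]
    band_lines <- vapply(seq_len(nrow(sub)), function(bi) {
      yy <- top + sub$migration[bi] * (bottom - top)
      op <- 0.2 + 0.8 * sub$mass_percent[bi] / 100
      sprintf(paste0('<rect class="band" data-size="%g" x="%g" y="%g" ',
                     'width="%g" height="3" fill="black" opacity="%.3f"/>'),
              sub$size[bi], x + 5, yy, lane_w - 10, op)
    }, character(1))
    body <- c(body,
              sprintf('<g class="lane" data-label="%s">', svg_escape(lanes[li])),
              sprintf('<text x="%g" y="%g" font-size="11">%s</text>',
                      x + 5, top - 10, svg_escape(lanes[li])),
              band_lines, "</g>")
  }
  svg_doc(body, width, height)
}
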