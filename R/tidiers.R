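# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Feature table of a record as a flat tibble
#'
#' One row per feature segment.
#'
#' @param x A [dna_record()].
#' @param ... Unused.
#' @return Tibble: `feature`, `segment`, `start`, `end`, `strand`, `type`,
#'   `color`, `hidden`.
#' @method tidy dna_record
#' @export
tidy.dna_record <- function(x, ...) {
  if (nrow(x$features) == 0L) {
    return(tibble::tibble(feature = character(), segment = integer(),
                          start = integer(), end = integer(),
                          strand = character(), type = character(),
                          color = character(), hidden = logical()))
  }
  rows <- lapply(seq_len(nrow(x$features)), function(i) {
    f <- x$features[i, ]
    seg <- f$segments[[1]]
    tibble::tibble(feature = f$name, segment = seq_len(nrow(seg)),
                   start = seg[, "start"], end = seg[, "end"],
                   strand = f$strand, type = f$type, color = f$color,
                   hidden = f$hidden)
  })
  dplyr::bind_rows(rows)
}

#' @method glance dna_record
#' @export
glance.dna_record <- function(x, ...) {
  tibble::tibble(name = x$name, length = seq_length(x), topology = x$topology,
                 n_features = nrow(x$features),
                 gc_percent = gc_percent(x$bases))
}

#' @method tidy assembly_plan
#' @export
tidy.assembly_plan <- function(x, ...) {
  tibble::tibble(
    product = vapply(x$products, `[[`, character(1), "name"),
    length = vapply(x$products, seq_length, integer(1)),
    topology = vapply(x$products, `[[`, character(1), "topology"))
}

#' @method glance assembly_plan
#' @export
glance.assembly_plan <- function(x, ...) {
  tibble::tibble(reaction = x$reaction, n_products = length(x$products),
                 n_inputs = length(x$inputs), ambiguous = x$ambiguous)
}

#' Linear feature map of a record
#' @param object A [dna_record()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dna_record
#' @export
autoplot.dna_record <- function(object, ...) {
  td <- tidy.dna_record(object)
  td <- td[!td$hidden, , drop = FALSE]
  ggplot2::ggplot(td) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$feature, yend = .data$feature,
                   colour = .data$feature),
      linewidth = 4, show.legend = FALSE) +
    ggplot2::xlim(1, seq_length(object)) +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = sprintf("%s (%d bp, %s)", object$name,
                                  seq_length(object), object$topology)) +
    ggplot2::theme_minimal()
}
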