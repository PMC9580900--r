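# Virtual agarose gels.  Band migration follows a - b*log10(size), scaled
# to [0, 1] using the ladder extrema (largest ladder band migrates 0,
# smallest 1); within a lane, bands closer than 2% in size merge into a
# doublet.

#' Build a multi-lane virtual gel
#'
#' @param lanes Named list; each element is either a numeric vector of
#'   fragment sizes (bp), a tibble with columns `size` and
#'   `molar_abundance` (e.g. from [partial_digest()]), or the string
#'   `"ladder"` for a ladder lane.
#' @param ladder One row of [load_ladder_file()] output, or a tibble with
#'   `size`/`weight` columns.
#' @param resolution Fractional size difference under which two bands in a
#'   lane merge (default 0.02).
#' @return A `gel_model`: tibble with `lane`, `size`, `molar_abundance`,
#'   `mass_percent`, `migration`, `doublet`.
#' @export
gel_lanes <- function(lanes, ladder, resolution = 0.02) {
  if (is.data.frame(ladder) && "bands" %in% names(ladder)) {
    ladder <- ladder$bands[[1]]
  }
  stopifnot(all(c("size", "weight") %in% names(ladder)))
  lmax <- max(ladder$size); lmin <- min(ladder$size)
  migrate <- function(size) {
    (log10(lmax) - log10(size)) / (log10(lmax) - log10(lmin))
  }
  one_lane <- function(label, x) {
    if (identical(x, "ladder")) {
      tb <- tibble::tibble(size = ladder$size, molar_abundance = ladder$weight / ladder$size)
    } else if (is.data.frame(x)) {
      tb <- tibble::tibble(size = x$size,
                           molar_abundance = x$molar_abundance %||% rep(1, nrow(x)))
    } else {
      if (any(x < 1)) stop("fragment sizes must be >= 1", call. = FALSE)
      tb <- tibble::tibble(size = as.numeric(x)) |>
        dplyr::count(.data$size, name = "molar_abundance")
    }
    tb <- dplyr::arrange(tb, dplyr::desc(.data$size))
    # merge near-coincident bands into doublets
    out <- list()
    i <- 1L
    while (i <= nrow(tb)) {
      j <- i
      while (j < nrow(tb) &&
             (tb$size[i] - tb$size[j + 1L]) / tb$size[i] < resolution) {
        j <- j + 1L
      }
      chunk <- tb[i:j, ]
      out[[length(out) + 1L]] <- tibble::tibble(
        size = sum(chunk$size * chunk$molar_abundance) / sum(chunk$molar_abundance),
        molar_abundance = sum(chunk$molar_abundance),
        doublet = (j > i)
      )
      i <- j + 1L
    }
    band <- dplyr::bind_rows(out)
    band$mass_percent <- 100 * band$size * band$molar_abundance /
      sum(band$size * band$molar_abundance)
    band$migration <- migrate(band$size)
    band$lane <- label
    band
  }
  labels <- names(lanes) %||% paste("lane", seq_along(lanes))
  gel <- dplyr::bind_rows(lapply(seq_along(lanes), function(k) {
    one_lane(labels[k], lanes[[k]])
  }))
  gel <- gel[, c("lane", "size", "molar_abundance", "mass_percent",
                 "migration", "doublet")]
  structure(gel, class = c("gel_model", class(gel)), ladder = ladder)
}

#' Plot a virtual gel
#'
#' Band darkness reflects mass share; the y axis is migration distance.
#'
#' @param object A `gel_model` from [gel_lanes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gel_model
#' @export
autoplot.gel_model <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lane, y = .data$migration)) +
    ggplot2::geom_tile(ggplot2::aes(alpha = .data$mass_percent),
                       width = 0.6, height = 0.01, fill = "grey10") +
    ggplot2::scale_y_reverse(limits = c(1.05, -0.05)) +
    ggplot2::scale_alpha_continuous(range = c(0.25, 1), guide = "none") +
    ggplot2::labs(x = NULL, y = "migration") +
    ggplot2::theme_minimal()
}
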