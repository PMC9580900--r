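# Palette generator: hues evenly spaced on the color wheel, saturation and
# lightness drawn from seeded randomness, then lightness adjusted so every
# color keeps a WCAG contrast ratio above 3 against both black and white
# (i.e. relative luminance strictly inside (0.10, 0.30)).

hsl_to_rgb <- function(h, s, l) {
  h <- (h %% 360) / 60
  c <- (1 - abs(2 * l - 1)) * s
  x <- c * (1 - abs(h %% 2 - 1))
  m <- l - c / 2
  rgb1 <- switch(floor(h) %% 6 + 1,
    c(c, x, 0), c(x, c, 0), c(0, c, x),
    c(0, x, c), c(x, 0, c), c(c, 0, x))
  rgb1 + m
}

srgb_linear <- function(c) ifelse(c <= 0.03928, c / 12.92, ((c + 0.055) / 1.055)^2.4)

#' WCAG relative luminance of an sRGB color
#' @param rgb Numeric length-3 vector in `[0, 1]`.
#' @return Relative luminance in `[0, 1]`.
#' @export
relative_luminance <- function(rgb) {
  lin <- srgb_linear(rgb)
  sum(c(0.2126, 0.7152, 0.0722) * lin)
}

#' WCAG contrast ratio between two colors
#' @param rgb1,rgb2 sRGB vectors in `[0, 1]`.
#' @return Contrast ratio (>= 1).
#' @export
contrast_ratio <- function(rgb1, rgb2) {
  l1 <- relative_luminance(rgb1); l2 <- relative_luminance(rgb2)
  (max(l1, l2) + 0.05) / (min(l1, l2) + 0.05)
}

#' Generate a readable, evenly spaced color palette
#'
#' Hues sit at i*360/n; saturation and target luminance are drawn from the
#' seeded RNG, and lightness is then tuned by bisection so that each
#' color's contrast ratio exceeds 3 against both pure black and pure
#' white.  Deterministic for a given seed.
#'
#' @param n Number of colors (>= 1).
#' @param seed Integer seed.
#' @return Tibble: `hue`, `hex`, `luminance`, `contrast_black`,
#'   `contrast_white`.
#' @examples
#' generate_palette(4, seed = 1)
#' @export
generate_palette <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  hues <- (seq_len(n) - 1L) * 360 / n
  rows <- lapply(hues, function(h) {
    s <- stats::runif(1, 0.35, 0.95)
    target <- stats::runif(1, 0.12, 0.28) # strictly inside the (0.1, 0.3) window
    lo <- 0; hi <- 1
    for (iter in 1:40) {
      mid <- (lo + hi) / 2
      lum <- relative_luminance(hsl_to_rgb(h, s, mid))
      if (lum < target) lo <- mid else hi <- mid
    }
    rgb <- hsl_to_rgb(h, s, (lo + hi) / 2)
    lum <- relative_luminance(rgb)
    tibble::tibble(
      hue = h,
      hex = grDevices::rgb(rgb[1], rgb[2], rgb[3]),
      luminance = lum,
      contrast_black = contrast_ratio(rgb, c(0, 0, 0)),
      contrast_white = contrast_ratio(rgb, c(1, 1, 1))
    )
  })
  dplyr::bind_rows(rows)
}
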