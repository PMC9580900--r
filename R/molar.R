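# Molar-ratio calculator for assembly and ligation reactions.

#' Volumes needed to hit a molar ratio
#'
#' Molarity of a double-stranded DNA stock is concentration divided by
#' (length x 650 g/mol/bp); volumes are scaled so the parts sit at the
#' requested molar ratio.
#'
#' @param parts Tibble (or data.frame) with columns `name`, `length_bp`,
#'   `conc_ng_ul`, `ratio`.
#' @param total_pmol Total picomoles to dispense across all parts
#'   (partitioned by `ratio`); alternatively give `reference` instead.
#' @param reference List `list(name=, volume_ul=)`: the named part is fixed
#'   at that volume and the others scale to honor the ratio.
#' @return Tibble: input columns plus `pmol_per_ul` and `volume_ul`.
#' @examples
#' parts <- tibble::tibble(name = c("vector", "insert"),
#'                         length_bp = c(3000, 1000),
#'                         conc_ng_ul = c(50, 25), ratio = c(1, 3))
#' molar_ratio_volumes(parts, total_pmol = 0.2)
#' @export
molar_ratio_volumes <- function(parts, total_pmol = NULL, reference = NULL) {
  stopifnot(all(c("name", "length_bp", "conc_ng_ul", "ratio") %in% names(parts)))
  if (any(parts$conc_ng_ul <= 0)) stop("zero or negative concentration", call. = FALSE)
  if (any(parts$length_bp <= 0) || any(parts$ratio <= 0)) {
    stop("lengths and ratios must be positive", call. = FALSE)
  }
  # ng/uL / (bp * 650 g/mol) = 1e-9 g/uL / (g/mol) -> nmol/uL; x1000 -> pmol/uL
  pmol_per_ul <- parts$conc_ng_ul / (parts$length_bp * 650) * 1000
  if (!is.null(reference)) {
    i <- match(reference$name, parts$name)
    if (is.na(i)) stop("reference part not found", call. = FALSE)
    ref_pmol <- pmol_per_ul[i] * reference$volume_ul
    pmol <- ref_pmol * parts$ratio / parts$ratio[i]
  } else {
    if (is.null(total_pmol)) stop("give total_pmol or reference", call. = FALSE)
    pmol <- total_pmol * parts$ratio / sum(parts$ratio)
  }
  tibble::tibble(tibble::as_tibble(parts),
                 pmol_per_ul = pmol_per_ul,
                 volume_ul = pmol / pmol_per_ul)
}
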