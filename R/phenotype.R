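# Deterministic phenotype derivations: pigment absorbance standardization,
# nectar capillary-height to volume conversion, herkogamy.

#' Mass-standardized pigment absorbance
#'
#' Corolla size varies among floral morphs, so absorbance readings (total
#' anthocyanins at 525 nm, total carotenoids at 450 nm) are standardized by
#' the line's mean fresh corolla mass. Samples diluted to escape detector
#' saturation carry their dilution factor explicitly.
#'
#' @param absorbance Absorbance units (AU), >= 0.
#' @param dilution_factor Multiplicative dilution applied before reading
#'   (>= 1; 1 = undiluted).
#' @param mean_corolla_mass Mean fresh corolla mass for the line (grams,
#'   > 0).
#' @return Standardized absorbance, AU per gram:
#'   `absorbance * dilution_factor / mean_corolla_mass`.
#' @export
#' @examples
#' standardize_pigment(0.8, dilution_factor = 2, mean_corolla_mass = 0.05)
standardize_pigment <- function(absorbance, dilution_factor = 1,
                                mean_corolla_mass) {
  if (any(absorbance < 0)) stop("absorbance must be non-negative")
  if (any(dilution_factor < 1)) stop("dilution_factor must be >= 1")
  if (any(mean_corolla_mass <= 0)) stop("mean corolla mass must be positive")
  absorbance * dilution_factor / mean_corolla_mass
}

#' Nectar volume from capillary column height
#'
#' Nectar is drawn into a microcapillary (internal diameter 1.15 mm, length
#' 100 mm) and the column height measured in mm. Volume follows the
#' cylinder formula with the capillary's full-length volume of 103.87 uL:
#' `volume = h / 100 * 103.87`, equivalently `h * pi * 0.575^2`.
#'
#' @param height_mm Column height in mm, in `[0, 100]`.
#' @return Volume in microlitres.
#' @export
#' @examples
#' nectar_volume(100)  # full capillary: 103.87 uL
nectar_volume <- function(height_mm) {
  if (any(height_mm < 0 | height_mm > 100))
    stop("column height must lie in [0, 100] mm")
  height_mm / 100 * 103.87
}

#' Herkogamy (stigma-anther separation)
#'
#' Herkogamy is pistil length minus stamen length, in mm. The sign is
#' preserved: negative values indicate stamens exserted beyond the stigma.
#'
#' @param pistil_length_mm,stamen_length_mm Lengths in mm, >= 0.
#' @return Herkogamy in mm (may be negative).
#' @export
herkogamy <- function(pistil_length_mm, stamen_length_mm) {
  if (any(pistil_length_mm < 0) || any(stamen_length_mm < 0))
    stop("lengths must be non-negative")
  pistil_length_mm - stamen_length_mm
}
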