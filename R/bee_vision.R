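# Trichromatic bee colour-hexagon model: replicate averaging of reflectance
# spectra, visual-pigment templates, von Kries quantum catches and hexagon
# coordinates (chromatic contrast = distance from the achromatic centre,
# i.e. from the adapting green background).

#' Hierarchically average replicate reflectance spectra
#'
#' Reflectance is measured as technical replicates within flowers, flowers
#' within plants, plants within lines. Averaging proceeds pointwise at each
#' wavelength up the hierarchy so that every flower, then every plant, then
#' every line contributes equally.
#'
#' @param spectra Long-format data.frame with columns `wavelength_nm`,
#'   `reflectance` and the grouping columns named in `hierarchy`.
#' @param hierarchy Character vector of grouping columns ordered from
#'   outermost to innermost (default line > plant > flower; technical
#'   replicates are whatever remains within the innermost level).
#' @param level The level to average up to: one of the entries of
#'   `hierarchy`.
#' @return Long-format data.frame averaged to the requested level. All
#'   spectra must share an identical wavelength grid.
#' @export
average_spectra <- function(spectra,
                            hierarchy = c("line", "plant_id", "flower_id"),
                            level = "line") {
  need <- c(hierarchy, "wavelength_nm", "reflectance")
  miss <- setdiff(need, names(spectra))
  if (length(miss)) stop("spectra missing columns: ", paste(miss, collapse = ", "))
  if (!level %in% hierarchy) stop("'level' must be one of the hierarchy columns")
  grids <- split(spectra$wavelength_nm,
                 interaction(spectra[hierarchy], drop = TRUE))
  ref_grid <- sort(unique(grids[[1]]))
  same <- vapply(grids, function(g) identical(sort(unique(g)), ref_grid), logical(1))
  if (!all(same)) stop("all spectra must share an identical wavelength grid")
  out <- spectra
  depth <- length(hierarchy)
  target <- match(level, hierarchy)
  # collapse innermost levels one at a time: replicates -> flower -> plant -> line
  for (d in seq(depth, target)) {
    keys <- c(hierarchy[seq_len(d)], "wavelength_nm")
    out <- stats::aggregate(out["reflectance"], by = out[keys], FUN = mean)
  }
  out[order(interaction(out[hierarchy[seq_len(target)]], drop = TRUE),
            out$wavelength_nm), , drop = FALSE]
}

#' Visual-pigment sensitivity template
#'
#' A1 visual-pigment absorbance template (Govardovskii-family nomogram),
#' evaluated on a wavelength grid and normalized to peak 1. Used to build
#' receptor sensitivity curves from a single wavelength of maximum
#' sensitivity. By default only the main (alpha) absorbance band is used,
#' so the curve peaks at the grid point nearest `lambda_max`; setting
#' `beta = TRUE` adds the short-wavelength beta band of the same template
#' family (for UV pigments the two bands overlap and the combined peak can
#' shift by a few nm).
#'
#' @param lambda_max Wavelength of peak sensitivity (nm), in `[300, 700]`.
#' @param grid Wavelength grid (nm).
#' @param beta Add the beta absorbance band (default `FALSE`).
#' @return Numeric sensitivity curve on `grid`, peak-normalized to 1.
#' @export
#' @examples
#' s <- receptor_template(436, 300:700)
#' (300:700)[which.max(s)]
receptor_template <- function(lambda_max, grid, beta = FALSE) {
  if (lambda_max < 300 || lambda_max > 700)
    stop("'lambda_max' must lie in [300, 700] nm")
  x <- lambda_max / grid
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  s <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
            exp(-14.9 * (1.104 - x)) + 0.674)
  if (beta) {
    lam_beta <- 189 + 0.315 * lambda_max
    b_beta <- -40.5 + 0.195 * lambda_max
    s <- s + 0.26 * exp(-((grid - lam_beta) / b_beta)^2)
  }
  s / max(s)
}

#' Trichromatic bee receptor set
#'
#' Builds the three receptor sensitivity curves of a trichromatic bee
#' (UV, blue, green) from their peak wavelengths. Defaults are standard
#' honeybee values.
#'
#' @param grid Wavelength grid (nm).
#' @param lambda_max Named numeric vector of peak wavelengths for the
#'   `uv`, `blue` and `green` receptors.
#' @return Matrix with one column per receptor (`uv`, `blue`, `green`),
#'   rows on `grid`, each column peak-normalized to 1.
#' @export
bee_receptors <- function(grid = 300:700,
                          lambda_max = c(uv = 344, blue = 436, green = 544)) {
  if (!all(c("uv", "blue", "green") %in% names(lambda_max)))
    stop("'lambda_max' needs named entries uv, blue, green")
  sapply(lambda_max[c("uv", "blue", "green")], receptor_template, grid = grid)
}

#' Interpolate a spectrum onto a reference grid
#'
#' Linear interpolation onto a common (default 1-nm, 300-700 nm) grid so
#' that spectra, illuminant, background and receptor curves integrate on
#' the same support.
#'
#' @param wavelength,reflectance Numeric vectors describing the spectrum.
#' @param grid Target wavelength grid; must lie within the measured range.
#' @return Reflectance on `grid`.
#' @export
interpolate_spectrum <- function(wavelength, reflectance, grid = 300:700) {
  if (min(grid) < min(wavelength) || max(grid) > max(wavelength))
    stop("target grid extends beyond the measured wavelength range")
  stats::approx(wavelength, reflectance, xout = grid)$y
}

#' Quantum catch, von Kries adaptation and receptor excitation
#'
#' Raw quantum catch is the Riemann sum
#' \deqn{Q = \sum_\lambda R(\lambda) S(\lambda) I(\lambda) \Delta\lambda}
#' over stimulus reflectance R, receptor sensitivity S and illuminant I.
#' von Kries adaptation divides by the catch of the adapting (green
#' vegetative) background, and the hexagon transduction maps adapted catch
#' q to excitation \eqn{E = q / (q + 1)}, so a stimulus identical to the
#' background gives E = 0.5 in every receptor.
#'
#' @param reflectance Stimulus reflectance on `grid`.
#' @param sensitivity Receptor sensitivity curve on `grid` (or a matrix with
#'   one receptor per column).
#' @param background Background reflectance on `grid`.
#' @param illuminant Illuminant spectrum on `grid`; default flat
#'   (equal-energy).
#' @param grid Wavelength grid (nm), equally spaced.
#' @return List with `Q` (raw catch), `q` (adapted catch) and `E`
#'   (excitation), each a vector with one entry per receptor.
#' @export
quantum_catch <- function(reflectance, sensitivity, background,
                          illuminant = NULL, grid = 300:700) {
  if (is.null(illuminant)) illuminant <- rep(1, length(grid))
  sens <- as.matrix(sensitivity)
  lens <- c(length(reflectance), nrow(sens), length(background),
            length(illuminant), length(grid))
  if (length(unique(lens)) != 1L)
    stop("reflectance, sensitivity, background, illuminant and grid must share one grid")
  dl <- diff(grid)
  if (length(unique(round(dl, 9))) != 1L) stop("grid must be equally spaced")
  dlam <- dl[1]
  Q <- colSums(reflectance * sens * illuminant) * dlam
  Qb <- colSums(background * sens * illuminant) * dlam
  if (any(Qb <= 0)) stop("background quantum catch must be positive in every receptor")
  q <- Q / Qb
  list(Q = unname(Q), q = unname(q), E = unname(q / (q + 1)))
}

#' Colour-hexagon coordinates and chromatic contrast
#'
#' Maps the three receptor excitations into the planar colour hexagon:
#' \deqn{x = \frac{\sqrt{3}}{2} (E_{green} - E_{uv}), \quad
#'       y = E_{blue} - \frac{E_{uv} + E_{green}}{2}.}
#' The adapting background sits at the origin; Euclidean distance from the
#' origin approximates chromatic contrast against that background.
#'
#' @param e_uv,e_blue,e_green Receptor excitations in (0, 1); vectors are
#'   accepted.
#' @return Data.frame with `x`, `y` and `contrast`.
#' @export
#' @examples
#' hexagon_coords(0.2, 0.5, 0.8)
hexagon_coords <- function(e_uv, e_blue, e_green) {
  es <- cbind(e_uv, e_blue, e_green)
  if (any(es <= 0 | es >= 1))
    stop("excitations must lie strictly inside (0, 1)")
  x <- sqrt(3) / 2 * (e_green - e_uv)
  y <- e_blue - (e_uv + e_green) / 2
  data.frame(x = x, y = y, contrast = sqrt(x^2 + y^2))
}

#' Hexagon position of a spectrum against a background
#'
#' Convenience wrapper chaining [quantum_catch()] and [hexagon_coords()]
#' for one stimulus spectrum.
#'
#' @inheritParams quantum_catch
#' @param receptors Receptor matrix from [bee_receptors()] (columns uv,
#'   blue, green) on `grid`.
#' @return One-row data.frame with `x`, `y`, `contrast`.
#' @export
hexagon_point <- function(reflectance, background, receptors = bee_receptors(grid),
                          illuminant = NULL, grid = 300:700) {
  qc <- quantum_catch(reflectance, receptors, background, illuminant, grid)
  hexagon_coords(qc$E[1], qc$E[2], qc$E[3])
}

#' Synthetic green-leaf background reflectance
#'
#' A smooth synthetic stand-in for a standard green vegetative background:
#' a chlorophyll-style green reflectance bump near 550 nm over a low
#' baseline. Used as the default adapting background when no measured leaf
#' spectrum is supplied.
#'
#' @param grid Wavelength grid (nm).
#' @return Reflectance on `grid`, in (0, 1).
#' @export
green_leaf_background <- function(grid = 300:700) {
  0.05 + 0.10 * exp(-((grid - 550) / 40)^2)
}
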