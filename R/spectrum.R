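#' Wavelength grids and spectra
#'
#' All spectral quantities in silentsub live on uniform wavelength grids.
#' The canonical grid is 390--780 nm in 2 nm steps; every imported spectrum
#' is resampled onto it on load. A `spectrum` is a numeric vector of
#' per-wavelength values plus a declared semantic unit.
#'
#' @name spectrum-class
NULL

#' Construct a uniform wavelength grid
#'
#' @param start first wavelength (nm)
#' @param stop last wavelength (nm); must exceed `start`
#' @param step increment (nm); `stop - start` must be an integer multiple
#' @return numeric vector of wavelengths from `start` to `stop`
#' @examples
#' wavelength_grid(400, 700, 5)
#' @export
wavelength_grid <- function(start = 390, stop = 780, step = 2) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step))
  if (step <= 0) stop("wavelength grid step must be > 0")
  if (stop <= start) stop("wavelength grid requires stop > start")
  n <- (stop - start) / step
  if (abs(n - round(n)) > 1e-9)
    stop("(stop - start) must be an integer multiple of step")
  seq(start, stop, by = step)
}

#' The canonical 390--780 nm, 2 nm wavelength grid
#'
#' @return numeric vector of 196 wavelengths
#' @export
canonical_grid <- function() wavelength_grid(390, 780, 2)

#' Create a spectrum
#'
#' @param wl uniform wavelength grid (nm), strictly increasing
#' @param values numeric vector, one value per wavelength; must be finite.
#'   Non-negative for every unit except `"OD"` (optical density), which may
#'   take any finite real value.
#' @param unit semantic unit: `"relative"` (uncalibrated intensities),
#'   `"W/(m2.sr.nm)"` (spectral radiance), `"sensitivity"` (dimensionless
#'   spectral sensitivity), or `"OD"` (optical density)
#' @return object of class `spectrum`
#' @export
spectrum <- function(wl, values, unit = c("relative", "W/(m2.sr.nm)",
                                          "sensitivity", "OD")) {
  unit <- match.arg(unit)
  wl <- as.numeric(wl)
  values <- as.numeric(values)
  if (length(wl) < 2L) stop("a spectrum needs at least two grid points")
  if (length(wl) != length(values))
    stop("values must have one entry per wavelength")
  d <- diff(wl)
  if (any(d <= 0)) stop("wavelengths must be strictly increasing")
  if (max(d) - min(d) > 1e-9) stop("wavelength grid must be uniform")
  if (any(!is.finite(values))) stop("spectrum values must be finite")
  if (unit != "OD" && any(values < 0))
    stop("spectrum values must be non-negative for unit '", unit, "'")
  structure(list(wl = wl, values = values, unit = unit),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %g-%g nm (step %g nm), unit %s\n",
              length(x$wl), min(x$wl), max(x$wl), grid_step(x), x$unit))
  cat(sprintf("  peak %.4g at %g nm; AUC %.4g\n",
              max(x$values), x$wl[which.max(x$values)], spectrum_auc(x)))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ..., xlab = "Wavelength (nm)", ylab = x$unit,
                          type = "l") {
  graphics::plot(x$wl, x$values, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Grid step of a spectrum (nm)
#' @param s a `spectrum`
#' @return numeric scalar
#' @export
grid_step <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  (max(s$wl) - min(s$wl)) / (length(s$wl) - 1L)
}

same_grid <- function(a, b) {
  length(a$wl) == length(b$wl) && all(abs(a$wl - b$wl) < 1e-9)
}

stop_if_grid_mismatch <- function(a, b, what = "spectra") {
  if (!same_grid(a, b))
    stop(what, " must share the same wavelength grid; resample first")
}

#' Numerical integral of a spectrum over wavelength
#'
#' Left-Riemann rule on the uniform grid: `sum(values) * step`. This is the
#' single integration convention used throughout the package (excitations,
#' luminance, tristimulus values, area normalization), matching the usual
#' treatment of tabulated spectra.
#'
#' @param s a `spectrum`
#' @return numeric scalar (value-unit times nm)
#' @export
spectrum_auc <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  sum(s$values) * grid_step(s)
}

#' Resample a spectrum onto a target wavelength grid
#'
#' Linear interpolation; wavelengths outside the source support are set to
#' zero. Errors if source and target ranges do not overlap at all.
#'
#' @param s a `spectrum`
#' @param wl target wavelength grid (numeric vector, uniform, increasing)
#' @return a `spectrum` on `wl`, unit preserved
#' @export
resample_spectrum <- function(s, wl = canonical_grid()) {
  stopifnot(inherits(s, "spectrum"))
  wl <- as.numeric(wl)
  if (min(s$wl) > max(wl) || max(s$wl) < min(wl))
    stop("no overlap between source spectrum (", min(s$wl), "-", max(s$wl),
         " nm) and target grid (", min(wl), "-", max(wl), " nm)")
  v <- stats::approx(s$wl, s$values, xout = wl, method = "linear",
                     yleft = 0, yright = 0, ties = "ordered")$y
  spectrum(wl, v, unit = s$unit)
}

#' Normalize a spectrum to unit area under the curve
#'
#' Rescales an emission spectrum so that its integral over wavelength is
#' exactly 1 W/(m^2 sr). Because the result is a pure rescaling, the unit of
#' the input intensities is irrelevant; the output is declared as spectral
#' radiance per nm.
#'
#' @param s a `spectrum` with at least one strictly positive value
#' @return a `spectrum` with AUC 1 and unit `"W/(m2.sr.nm)"`
#' @export
normalize_auc <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  a <- spectrum_auc(s)
  if (a <= 0) stop("cannot area-normalize an all-zero spectrum")
  spectrum(s$wl, s$values / a, unit = "W/(m2.sr.nm)")
}

#' Luminance of a spectral power distribution
#'
#' \eqn{L = K_m \sum_\lambda \Phi(\lambda) V(\lambda) \Delta\lambda} with
#' \eqn{K_m = 683} lm/W, the maximum luminous efficacy of radiation.
#'
#' @param spd spectral radiance, unit W/(m2.sr.nm)
#' @param vlambda photopic luminous efficiency function on the same grid
#' @param Km luminous efficacy constant (lm/W), default 683
#' @return luminance in cd/m^2
#' @export
luminance_of <- function(spd, vlambda, Km = 683) {
  stopifnot(inherits(spd, "spectrum"), inherits(vlambda, "spectrum"))
  stop_if_grid_mismatch(spd, vlambda, "spd and V(lambda)")
  Km * sum(spd$values * vlambda$values) * grid_step(spd)
}

#' Scale an area-normalized spectrum to a target luminance
#'
#' @param s area-normalized emission spectrum (AUC 1)
#' @param L target luminance (cd/m^2), strictly positive -- a primary set to
#'   zero luminance would effectively remove it from the device
#' @param vlambda luminous efficiency function on the same grid
#' @return `spectrum` with `luminance_of()` equal to `L`
#' @export
scale_to_luminance <- function(s, L, vlambda) {
  if (!is.numeric(L) || length(L) != 1L || L <= 0)
    stop("target luminance must be a single value > 0; ",
         "no primary can be set to zero luminance")
  lum <- luminance_of(s, vlambda)
  if (lum <= 0) stop("spectrum has zero luminance; cannot scale")
  spectrum(s$wl, s$values * (L / lum), unit = "W/(m2.sr.nm)")
}

#' CIE 1964 10-degree chromaticity coordinates
#'
#' Tristimulus values are computed as
#' \eqn{X = \sum \Phi(\lambda)\bar{x}_{10}(\lambda)\Delta\lambda} (same for
#' Y, Z) and the chromaticity is \eqn{(X, Y) / (X + Y + Z)}.
#'
#' @param spd spectral power distribution
#' @param cmfs list with components `x`, `y`, `z`: the three 10-degree
#'   colour-matching functions as `spectrum` objects on the same grid
#' @return named numeric vector `c(x = , y = )`
#' @export
cie1964_xy <- function(spd, cmfs) {
  stopifnot(inherits(spd, "spectrum"),
            all(c("x", "y", "z") %in% names(cmfs)))
  for (k in c("x", "y", "z")) stop_if_grid_mismatch(spd, cmfs[[k]], "spd and CMFs")
  if (all(spd$values == 0))
    stop("chromaticity is undefined for an all-zero spectrum")
  d <- grid_step(spd)
  X <- sum(spd$values * cmfs$x$values) * d
  Y <- sum(spd$values * cmfs$y$values) * d
  Z <- sum(spd$values * cmfs$z$values) * d
  c(x = X / (X + Y + Z), y = Y / (X + Y + Z))
}
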