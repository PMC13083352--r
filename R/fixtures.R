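#' Synthetic spectra: Gaussian LED primaries
#'
#' A Gaussian emission profile with given peak wavelength and full width at
#' half maximum, area-normalized to 1 -- a realistic stand-in for a
#' narrowband LED channel.
#'
#' @param peak peak wavelength (nm), within the grid
#' @param fwhm full width at half maximum (nm), > 0
#' @param wl wavelength grid (default canonical)
#' @return area-normalized `spectrum`
#' @export
gaussian_led <- function(peak, fwhm, wl = canonical_grid()) {
  if (fwhm <= 0) stop("fwhm must be > 0")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  v <- exp(-0.5 * ((wl - peak) / sigma)^2)
  normalize_auc(spectrum(wl, v, unit = "relative"))
}

#' Synthetic photoreceptor fundamental
#'
#' A smooth unimodal Gaussian sensitivity, peak-normalized to 1. Used as a
#' stand-in for measured corneal fundamentals so that every computation in
#' the package runs without downloading observer tables. The five presets
#' place lambda-max at the field's approximate values: S 440 nm, mel
#' 480 nm, rod 500 nm, M 530 nm, L 560 nm.
#'
#' @param lambda_max wavelength of peak sensitivity (nm)
#' @param width full width at half maximum (nm); the 100 nm default
#'   mimics the breadth of real photoreceptor sensitivities
#' @param wl wavelength grid
#' @return peak-normalized `spectrum` (unit `"sensitivity"`)
#' @export
synthetic_fundamental <- function(lambda_max, width = 100,
                                  wl = canonical_grid()) {
  if (width <= 0) stop("width must be > 0")
  sigma <- width / (2 * sqrt(2 * log(2)))
  v <- exp(-0.5 * ((wl - lambda_max) / sigma)^2)
  spectrum(wl, v, unit = "sensitivity")
}

#' Lambda-max presets of the synthetic observer (nm)
#' @return named numeric vector over L, M, S, rod, mel
#' @export
synthetic_lambda_max <- function() {
  c(L = 560, M = 530, S = 440, rod = 500, mel = 480)
}

#' Synthetic five-photoreceptor standard observer
#'
#' Builds an `ss_observer` from [synthetic_fundamental()] presets
#' (L 560, M 530, S 440, rod 500, mel 480 nm) at the baseline parameters
#' (MPOD 0.3, lens age 40). Deterministic; no external data.
#'
#' @param width fundamental FWHM (nm), see [synthetic_fundamental()]
#' @param wl wavelength grid
#' @return `ss_observer`
#' @export
synthetic_observer <- function(width = 100, wl = canonical_grid()) {
  lm <- synthetic_lambda_max()
  funds <- lapply(lm, synthetic_fundamental, width = width, wl = wl)
  observer(funds)
}

#' Synthetic photopic luminous efficiency function
#'
#' Gaussian approximation peaking at 555 nm with 105 nm FWHM, peak 1 --
#' the shape and scale of the photopic V(lambda) curve.
#'
#' @param wl wavelength grid
#' @return `spectrum` (unit `"sensitivity"`)
#' @export
synthetic_vlambda <- function(wl = canonical_grid()) {
  synthetic_fundamental(555, width = 105, wl = wl)
}

#' Synthetic pre-receptoral density templates
#'
#' Macular pigment: Gaussian optical-density template peaking at 460 nm
#' (60 nm FWHM), peak-normalized to 1. Lens: two non-negative components
#' decaying from short to long wavelengths, an age-dependent one (`tl1`)
#' and an age-independent one (`tl2`), mimicking the shape of lens media
#' density curves.
#'
#' @param wl wavelength grid
#' @return `ss_templates`
#' @export
synthetic_templates <- function(wl = canonical_grid()) {
  mac <- exp(-0.5 * ((wl - 460) / (60 / (2 * sqrt(2 * log(2)))))^2)
  mac <- mac / max(mac)
  tl1 <- 0.4 * exp(-(wl - min(wl)) / 60)
  tl2 <- 0.9 * exp(-(wl - min(wl)) / 40)
  density_templates(
    macular = spectrum(wl, mac, unit = "OD"),
    lens_tl1 = spectrum(wl, tl1, unit = "OD"),
    lens_tl2 = spectrum(wl, tl2, unit = "OD"))
}

#' Synthetic CIE 1964 colour-matching functions
#'
#' Smooth Gaussian-lobe stand-ins for the 10-degree colour-matching
#' functions (x-bar with its secondary short-wave lobe), each rescaled to
#' integrate to 1 so that an equal-energy spectrum maps to the white point
#' x = y = 1/3.
#'
#' @param wl wavelength grid
#' @return list of `spectrum` objects `x`, `y`, `z`
#' @export
synthetic_cmfs <- function(wl = canonical_grid()) {
  g <- function(mu, fwhm) {
    s <- fwhm / (2 * sqrt(2 * log(2)))
    exp(-0.5 * ((wl - mu) / s)^2)
  }
  xb <- g(600, 80) + 0.35 * g(442, 45)
  yb <- g(557, 100)
  zb <- g(446, 55)
  step <- wl[2] - wl[1]
  mk <- function(v) spectrum(wl, v / (sum(v) * step), unit = "sensitivity")
  list(x = mk(xb), y = mk(yb), z = mk(zb))
}

#' Synthetic multiprimary stimulator device
#'
#' The default emulates a 4-primary full-field stimulator with blue, green,
#' amber and red LED channels (peaks 460 / 520 / 590 / 640 nm, FWHM 20 nm)
#' at the mean luminance settings recommended for feasible rod and cone
#' contrasts: blue 4, green 40, amber 100, red 80 cd/m^2. Each luminance
#' range defaults to `[0, 2 L]`, the span a primary modulated at 100\%
#' contrast around its mean just fills.
#'
#' @param peaks peak wavelengths (nm), 3--5 entries
#' @param fwhms FWHM per primary (nm; recycled)
#' @param luminances mean luminances (cd/m^2)
#' @param ranges optional list of length-2 luminance ranges; default
#'   `[0, 2 * luminance]` per primary
#' @param names primary labels; defaults to the LED colour names for the
#'   default peaks, otherwise `P1..Pn`
#' @param vlambda luminous efficiency function for calibration
#' @param wl wavelength grid
#' @return `ss_device`
#' @export
synthetic_device <- function(peaks = c(460, 520, 590, 640),
                             fwhms = 20,
                             luminances = c(4, 40, 100, 80),
                             ranges = NULL,
                             names = NULL,
                             vlambda = synthetic_vlambda(wl),
                             wl = canonical_grid()) {
  n <- length(peaks)
  stopifnot(length(luminances) == n)
  fwhms <- rep_len(fwhms, n)
  if (is.null(names)) {
    names <- if (identical(peaks, c(460, 520, 590, 640)))
      c("blue", "green", "amber", "red") else paste0("P", seq_len(n))
  }
  if (is.null(ranges)) ranges <- lapply(luminances, function(L) c(0, 2 * L))
  prims <- vector("list", n)
  for (j in seq_len(n))
    prims[[j]] <- primary(names[j], gaussian_led(peaks[j], fwhms[j], wl),
                          luminances[j], lum_range = ranges[[j]])
  device(prims, vlambda = vlambda)
}

#' Randomized synthetic device for property testing
#'
#' Draws 3--5 well-separated Gaussian primaries and log-uniform mean
#' luminances; deterministic under a fixed seed.
#'
#' @param seed integer seed
#' @param n_primaries 3, 4 or 5 (default: drawn from the seed)
#' @return `ss_device`
#' @export
random_device <- function(seed, n_primaries = NULL) {
  set.seed(seed)
  if (is.null(n_primaries)) n_primaries <- sample(3:5, 1)
  # well-separated peaks keep the A-matrix comfortably invertible
  lo <- seq(430, 660, length.out = n_primaries + 1)
  peaks <- vapply(seq_len(n_primaries), function(i)
    stats::runif(1, lo[i] + 8, lo[i + 1] - 8), 0)
  fwhms <- stats::runif(n_primaries, 15, 35)
  lums <- 10^stats::runif(n_primaries, log10(2), log10(150))
  synthetic_device(peaks = peaks, fwhms = fwhms, luminances = lums,
                   names = paste0("P", seq_len(n_primaries)))
}

#' Random contrast request with silenced classes, for property testing
#'
#' Draws a signed contrast for a random non-empty subset of the controlled
#' classes and silences (sets to exactly 0) the rest, so at least one class
#' is silenced whenever the device controls more than one target.
#'
#' @param seed integer seed
#' @param controlled character vector of controlled classes
#' @param max_targets maximal number of non-silenced classes
#' @return named numeric contrast vector over `controlled`
#' @export
random_request <- function(seed, controlled, max_targets = 2) {
  set.seed(seed)
  k <- sample(seq_len(min(max_targets, length(controlled) - 1L)), 1)
  targets <- sample(controlled, k)
  req <- stats::setNames(numeric(length(controlled)), controlled)
  req[targets] <- stats::runif(k, -0.5, 0.5)
  req
}
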