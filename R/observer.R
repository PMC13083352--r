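#' Photoreceptor classes, in the fixed package order
#' @return character vector `c("L", "M", "S", "rod", "mel")`
#' @export
photoreceptor_classes <- function() c("L", "M", "S", "rod", "mel")

#' Pre-receptoral filter density templates
#'
#' Bundles the spectral templates needed to modify photoreceptor
#' fundamentals for individual pre-receptoral filtering:
#' the macular pigment optical density template (peak-normalized to 1, so
#' the modification parameter is the peak OD) and the two lens density
#' components of the Pokorny--Smith--Lutze lens ageing model, one scaled
#' with age (`tl1`) and one age-independent (`tl2`).
#'
#' @param macular `spectrum` (unit `"OD"`), macular pigment density,
#'   peak value 1
#' @param lens_tl1 `spectrum` (unit `"OD"`), age-dependent lens component
#' @param lens_tl2 `spectrum` (unit `"OD"`), age-independent lens component
#' @return object of class `ss_templates`
#' @export
density_templates <- function(macular, lens_tl1, lens_tl2) {
  for (s in list(macular, lens_tl1, lens_tl2)) {
    stopifnot(inherits(s, "spectrum"))
    if (any(s$values < 0)) stop("density templates must be non-negative")
  }
  stop_if_grid_mismatch(macular, lens_tl1, "density templates")
  stop_if_grid_mismatch(macular, lens_tl2, "density templates")
  if (abs(max(macular$values) - 1) > 1e-9)
    stop("macular template must be peak-normalized to 1")
  structure(list(macular = macular, lens_tl1 = lens_tl1,
                 lens_tl2 = lens_tl2),
            class = "ss_templates")
}

#' Construct an observer
#'
#' An observer is the set of five corneal photoreceptor fundamentals
#' (L-, M-, S-cones, rods, melanopsin) on the canonical grid, together with
#' the physiological parameters they embody. The baseline 10-degree standard
#' observer assumes a macular pigment peak optical density of 0.3 and a lens
#' age of 40 years; those are therefore the defaults, and an observer built
#' with default parameters is the unmodified baseline.
#'
#' @param fundamentals named list of five `spectrum` objects (names
#'   `L, M, S, rod, mel`), all on the same grid, values >= 0
#' @param mpod macular pigment peak optical density (OD units)
#' @param lens_age lens age (years)
#' @param shift_L,shift_M lambda-max displacement of the L / M fundamental
#'   (nm)
#' @return object of class `ss_observer`
#' @export
observer <- function(fundamentals, mpod = 0.3, lens_age = 40,
                     shift_L = 0, shift_M = 0) {
  cls <- photoreceptor_classes()
  if (!all(cls %in% names(fundamentals)))
    stop("fundamentals must be named ", paste(cls, collapse = ", "))
  fundamentals <- fundamentals[cls]
  for (p in cls) {
    f <- fundamentals[[p]]
    stopifnot(inherits(f, "spectrum"))
    if (any(f$values < 0)) stop("fundamental '", p, "' has negative values")
    stop_if_grid_mismatch(fundamentals[[1L]], f, "fundamentals")
  }
  structure(list(fundamentals = fundamentals, mpod = mpod,
                 lens_age = lens_age, shift_L = shift_L, shift_M = shift_M),
            class = "ss_observer")
}

#' @export
print.ss_observer <- function(x, ...) {
  cat("<ss_observer> five-photoreceptor observer\n")
  cat(sprintf("  MPOD %.3g, lens age %g y, L shift %+g nm, M shift %+g nm\n",
              x$mpod, x$lens_age, x$shift_L, x$shift_M))
  for (p in photoreceptor_classes()) {
    f <- x$fundamentals[[p]]
    cat(sprintf("  %-3s peak at %g nm\n", p, f$wl[which.max(f$values)]))
  }
  invisible(x)
}

#' Adjust a fundamental for macular pigment optical density
#'
#' The corneal fundamental already includes filtering by the baseline
#' macular pigment (peak OD `base_mpod`, 0.3 for the 10-degree standard
#' observer). To model a different peak density `d`, the baseline filtering
#' is replaced:
#' \deqn{f'(\lambda) = f(\lambda)\,10^{-(d - d_0)\,m(\lambda)}}
#' where \eqn{m(\lambda)} is the peak-normalized macular density template.
#'
#' @param fund `spectrum`, a corneal fundamental
#' @param target_mpod desired peak OD (>= 0)
#' @param base_mpod peak OD already embedded in `fund` (default 0.3)
#' @param templates `ss_templates`
#' @return modified `spectrum`
#' @export
apply_macular <- function(fund, target_mpod, base_mpod = 0.3,
                          templates = synthetic_templates()) {
  stopifnot(inherits(fund, "spectrum"), inherits(templates, "ss_templates"))
  if (!is.numeric(target_mpod) || target_mpod < 0)
    stop("macular pigment optical density must be >= 0")
  m <- templates$macular
  stop_if_grid_mismatch(fund, m, "fundamental and macular template")
  spectrum(fund$wl, fund$values * 10^(-(target_mpod - base_mpod) * m$values),
           unit = fund$unit)
}

#' Lens optical density at a given age
#'
#' Pokorny--Smith--Lutze model:
#' \deqn{D(\lambda, A) = T_{L1}(\lambda)\,(1 + 0.02(A - 32)) + T_{L2}(\lambda)}
#' for \eqn{20 \le A \le 60}, and
#' \deqn{D(\lambda, A) = T_{L1}(\lambda)\,(1.56 + 0.0667(A - 60)) + T_{L2}(\lambda)}
#' for \eqn{A > 60}. The two branches agree at A = 60.
#'
#' @param age years (>= 20, the model's domain)
#' @param templates `ss_templates`
#' @return `spectrum` of optical densities (unit `"OD"`)
#' @export
lens_density <- function(age, templates = synthetic_templates()) {
  stopifnot(inherits(templates, "ss_templates"))
  if (!is.numeric(age) || age < 20)
    stop("lens ageing model is defined for ages >= 20 years")
  tl1 <- templates$lens_tl1
  tl2 <- templates$lens_tl2
  fac <- if (age <= 60) 1 + 0.02 * (age - 32) else 1.56 + 0.0667 * (age - 60)
  spectrum(tl1$wl, tl1$values * fac + tl2$values, unit = "OD")
}

#' Adjust a fundamental for lens age
#'
#' Replaces the lens filtering embedded in the corneal fundamental (baseline
#' age `base_age`, 40 years for the standard observer) by the filtering of a
#' lens of a different age:
#' \eqn{f'(\lambda) = f(\lambda)\,10^{-(D(\lambda,A) - D(\lambda,A_0))}}.
#'
#' @param fund `spectrum`, a corneal fundamental
#' @param age target lens age (years, >= 20)
#' @param base_age lens age embedded in `fund` (default 40)
#' @param templates `ss_templates`
#' @return modified `spectrum`
#' @export
apply_lens_age <- function(fund, age, base_age = 40,
                           templates = synthetic_templates()) {
  stopifnot(inherits(fund, "spectrum"))
  d_new <- lens_density(age, templates)
  d_old <- lens_density(base_age, templates)
  stop_if_grid_mismatch(fund, d_new, "fundamental and lens template")
  spectrum(fund$wl, fund$values * 10^(-(d_new$values - d_old$values)),
           unit = fund$unit)
}

#' Shift the wavelength of peak sensitivity of a fundamental
#'
#' `out(lambda) = fund(lambda - delta)` by linear interpolation on the same
#' grid, zero where the shifted argument leaves the grid. Models lambda-max
#' displacement of the L or M photopigment, e.g. from opsin-gene
#' polymorphisms. The shift is applied to the corneal fundamental directly,
#' an approximation adequate for the small (few-nm) shifts it is meant for.
#'
#' @param fund `spectrum`
#' @param delta displacement in nm; positive moves the curve toward longer
#'   wavelengths. Must satisfy `abs(delta) <= 20`.
#' @return shifted `spectrum`
#' @export
shift_lambda_max <- function(fund, delta) {
  stopifnot(inherits(fund, "spectrum"))
  if (abs(delta) > 20)
    stop("lambda-max shifts are limited to +/- 20 nm")
  if (delta == 0) return(fund)
  v <- stats::approx(fund$wl, fund$values, xout = fund$wl - delta,
                     method = "linear", yleft = 0, yright = 0,
                     ties = "ordered")$y
  spectrum(fund$wl, v, unit = fund$unit)
}

#' Build an individually modified observer
#'
#' Applies the macular pigment and lens age adjustments to all five
#' fundamentals (pre-receptoral filters act on all light reaching the
#' retina, so rods and melanopsin are filtered too), and the lambda-max
#' shifts to the L and M fundamentals only. With all parameters at their
#' defaults the base observer is returned unchanged.
#'
#' @param base `ss_observer`, the baseline observer
#' @param mpod target macular pigment peak OD
#' @param lens_age target lens age (years)
#' @param shift_L,shift_M lambda-max displacement (nm) of L / M
#' @param templates `ss_templates` used for the density adjustments
#' @return a new `ss_observer` carrying the modification parameters
#' @export
modify_observer <- function(base, mpod = base$mpod, lens_age = base$lens_age,
                            shift_L = 0, shift_M = 0,
                            templates = synthetic_templates()) {
  stopifnot(inherits(base, "ss_observer"))
  if (mpod == base$mpod && lens_age == base$lens_age &&
      shift_L == 0 && shift_M == 0)
    return(base)
  funds <- base$fundamentals
  for (p in names(funds)) {
    f <- funds[[p]]
    if (mpod != base$mpod)
      f <- apply_macular(f, mpod, base_mpod = base$mpod,
                         templates = templates)
    if (lens_age != base$lens_age)
      f <- apply_lens_age(f, lens_age, base_age = base$lens_age,
                          templates = templates)
    funds[[p]] <- f
  }
  if (shift_L != 0) funds$L <- shift_lambda_max(funds$L, shift_L)
  if (shift_M != 0) funds$M <- shift_lambda_max(funds$M, shift_M)
  observer(funds, mpod = mpod, lens_age = lens_age,
           shift_L = shift_L, shift_M = shift_M)
}
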