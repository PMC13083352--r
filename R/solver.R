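#' Solve for the primary contrasts realizing desired photoreceptor contrasts
#'
#' Inverts the contrast relation \eqn{C = W c}: given the desired signed
#' Michelson contrasts \eqn{C} of the controlled photoreceptor classes
#' (zero for every silenced class in a silent substitution condition), the
#' per-primary luminance contrasts are \eqn{c = W^{-1} C}, where W is the
#' square contrast-normalized block of the A-matrix.
#'
#' @param amat an `ss_amatrix`
#' @param request named numeric vector of desired signed Michelson
#'   contrasts (fractions in \[-1, 1\]) covering exactly the controlled
#'   photoreceptor classes; order is irrelevant. Silenced classes are
#'   exactly 0.
#' @return named numeric vector of signed primary contrasts (fractions; may
#'   exceed 1 in magnitude -- check feasibility)
#' @export
solve_contrasts <- function(amat, request) {
  stopifnot(inherits(amat, "ss_amatrix"), is.numeric(request))
  ctrl <- amat$controlled
  extra <- setdiff(names(request), ctrl)
  if (length(extra))
    stop("photoreceptor(s) ", paste(extra, collapse = ", "),
         " cannot be controlled by a ", length(ctrl), "-primary device: ",
         "3 primaries control L, M, S; 4 add rod; 5 add mel")
  if (!setequal(names(request), ctrl))
    stop("request must name every controlled class: ",
         paste(ctrl, collapse = ", "))
  C <- request[ctrl]
  if (any(abs(C) > 1))
    stop("photoreceptor Michelson contrasts must lie in [-1, 1]")
  c_prim <- drop(solve(amat$W, C))
  if (max(abs(drop(amat$W %*% c_prim) - C)) > 1e-10)
    stop("solver failed the forward check; A-matrix is too ill-conditioned")
  names(c_prim) <- colnames(amat$W)
  c_prim
}

#' Rescale primary contrasts to the maximal feasible modulation
#'
#' Multiplies the contrast vector by \eqn{1 / \max_j |c_j|} so that exactly
#' one primary reaches 100\% contrast and all others stay at or below it.
#' Because stimulus and photoreceptor contrasts are proportional, all
#' photoreceptor contrasts scale by the same factor and contrast ratios are
#' preserved.
#'
#' @param contrasts signed primary contrast vector, not all zero
#' @return list with `contrasts` (rescaled vector, `max(abs(.)) == 1`) and
#'   `factor` (the scale applied)
#' @export
maximize_contrasts <- function(contrasts) {
  stopifnot(is.numeric(contrasts))
  m <- max(abs(contrasts))
  if (m == 0) stop("cannot maximize an all-zero contrast vector")
  f <- 1 / m
  out <- contrasts * f
  out[which.max(abs(out))] <- sign(out[which.max(abs(out))]) # exact 1
  list(contrasts = out, factor = f)
}

#' Check the technical feasibility of a primary contrast vector
#'
#' Each primary modulates between \eqn{L_j(1 - |c_j|)} and
#' \eqn{L_j(1 + |c_j|)} (absolute value, so the reported envelope does not
#' depend on modulation phase). A primary is infeasible if its contrast
#' magnitude exceeds 100\% or the luminance envelope leaves the device's
#' configured range. Very small nonzero contrasts trigger an advisory
#' warning: the luminance resolution of real devices may be insufficient
#' to render them.
#'
#' @param contrasts signed primary contrast vector (one entry per primary)
#' @param dev the `ss_device`
#' @param resolution_warn_threshold advisory threshold for "very small"
#'   contrasts (fraction, default 0.005 = 0.5\%)
#' @param scale_applied maximization factor to record (default 1)
#' @return object of class `ss_solution`: a per-primary table of contrast,
#'   min/max luminance and feasibility, an overall flag and warnings
#' @export
check_feasibility <- function(contrasts, dev,
                              resolution_warn_threshold = 0.005,
                              scale_applied = 1) {
  stopifnot(inherits(dev, "ss_device"))
  L <- mean_luminances(dev)
  if (length(contrasts) != length(L))
    stop("need one contrast per primary")
  if (is.null(names(contrasts))) names(contrasts) <- names(L)
  contrasts <- contrasts[names(L)]
  lo <- L * (1 - abs(contrasts))
  hi <- L * (1 + abs(contrasts))
  rng <- vapply(dev$primaries, `[[`, numeric(2), "lum_range")
  ok_mag <- abs(contrasts) <= 1
  ok_rng <- lo >= rng[1, ] & hi <= rng[2, ]
  feasible <- ok_mag & ok_rng
  warnings <- character()
  tiny <- abs(contrasts) > 0 & abs(contrasts) < resolution_warn_threshold
  if (any(tiny))
    warnings <- c(warnings, paste0(
      "very small contrast in primary ", paste(names(L)[tiny], collapse = ", "),
      " (<", 100 * resolution_warn_threshold,
      "%): device resolution may be insufficient"))
  tab <- data.frame(primary = names(L),
                    contrast = as.numeric(contrasts),
                    min_luminance = as.numeric(lo),
                    max_luminance = as.numeric(hi),
                    feasible = as.logical(feasible),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, feasible = all(feasible),
                 scale_applied = scale_applied, warnings = warnings),
            class = "ss_solution")
}

#' @export
print.ss_solution <- function(x, ...) {
  cat("<ss_solution>", if (x$feasible) "feasible" else "NOT feasible",
      sprintf("(scale applied %.4g)\n", x$scale_applied))
  tab <- x$table
  tab$contrast <- sprintf("%+.2f%%", 100 * tab$contrast)
  names(tab) <- c("primary", "Contrast", "MinLuminance", "MaxLuminance",
                  "feasible")
  print(tab, row.names = FALSE)
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' Per-primary luminance waveforms of a periodic stimulus
#'
#' Sinusoidal modulation around the mean setting:
#' \eqn{L_j(t) = L_j (1 + c_j \sin 2\pi f t)}. A negative contrast yields
#' exact counterphase modulation relative to a positive one.
#'
#' @param dev an `ss_device`
#' @param contrasts signed primary contrast vector
#' @param frequency temporal frequency (Hz), > 0
#' @param n_samples number of time samples (>= 2)
#' @param duration total duration (s); default one period
#' @return data.frame with column `time` (s) and one luminance column
#'   (cd/m^2) per primary
#' @export
waveform <- function(dev, contrasts, frequency = 8, n_samples = 200,
                     duration = 1 / frequency) {
  stopifnot(inherits(dev, "ss_device"))
  if (frequency <= 0) stop("frequency must be > 0")
  if (n_samples < 2) stop("need at least 2 samples")
  L <- mean_luminances(dev)
  if (is.null(names(contrasts))) names(contrasts) <- names(L)
  t <- seq(0, duration, length.out = n_samples)
  out <- data.frame(time = t)
  for (nm in names(L))
    out[[nm]] <- L[[nm]] * (1 + contrasts[[nm]] * sin(2 * pi * frequency * t))
  out
}

#' Compute a silent substitution stimulus
#'
#' The central one-call interface: builds the A-matrix for the device and
#' observer, solves for the primary contrasts realizing the requested
#' photoreceptor contrasts, optionally rescales them to the maximal
#' feasible modulation, checks technical feasibility, and forward-evaluates
#' the achieved contrasts of all five photoreceptor classes (including the
#' uncontrolled ones).
#'
#' @param dev an `ss_device`
#' @param request named numeric vector of desired photoreceptor Michelson
#'   contrasts over the controlled set (signed fractions); e.g.
#'   `c(L = 0, M = 0, S = 0, rod = 0.2)` isolates rods on a 4-primary
#'   device
#' @param obs the `ss_observer` used for calculation (a standard observer;
#'   individual modification belongs to validation, not calculation)
#' @param maximize if `TRUE`, rescale so one primary reaches 100\% contrast
#' @param resolution_warn_threshold see [check_feasibility()]
#' @return `ss_solution` with additional components `request`, `contrasts`
#'   (the primary contrast vector), `achieved` (all five photoreceptor
#'   contrasts), `amatrix`, `device`, `observer`
#' @examples
#' dev <- synthetic_device()
#' obs <- synthetic_observer()
#' sol <- silent_substitution(dev, c(L = 0, M = 0, S = 0, rod = 0.2), obs,
#'                            maximize = TRUE)
#' print(sol)
#' @export
silent_substitution <- function(dev, request, obs = synthetic_observer(),
                                maximize = FALSE,
                                resolution_warn_threshold = 0.005) {
  amat <- build_a_matrix(dev, obs)
  c_prim <- solve_contrasts(amat, request)
  fac <- 1
  if (maximize) {
    mx <- maximize_contrasts(c_prim)
    c_prim <- mx$contrasts
    fac <- mx$factor
  }
  sol <- check_feasibility(c_prim, dev,
                           resolution_warn_threshold = resolution_warn_threshold,
                           scale_applied = fac)
  sol$request <- request
  sol$contrasts <- c_prim
  sol$achieved <- drop(amat$normalized %*% c_prim)
  sol$amatrix <- amat
  sol$device <- dev
  sol$observer <- obs
  sol
}

#' @export
summary.ss_solution <- function(object, ...) {
  print(object)
  if (!is.null(object$achieved)) {
    cat("achieved photoreceptor contrasts (all classes):\n")
    ach <- sprintf("%+.3f%%", 100 * object$achieved)
    names(ach) <- names(object$achieved)
    print(ach, quote = FALSE)
    unctrl <- setdiff(photoreceptor_classes(), object$amatrix$controlled)
    if (length(unctrl))
      cat("not controlled by this device:", paste(unctrl, collapse = ", "),
          "\n")
  }
  invisible(object)
}

#' @export
plot.ss_solution <- function(x, frequency = 8, n_samples = 200, ...) {
  if (is.null(x$device)) stop("solution carries no device; cannot plot")
  wf <- waveform(x$device, x$contrasts, frequency = frequency,
                 n_samples = n_samples)
  prim <- names(wf)[-1]
  rng <- vapply(x$device$primaries, `[[`, numeric(2), "lum_range")
  ylim <- range(0, unlist(wf[prim]), rng[2, is.finite(rng[2, ])])
  graphics::matplot(wf$time, as.matrix(wf[prim]), type = "l", lty = 1,
                    xlab = "Time (s)", ylab = "Luminance (cd/m2)",
                    ylim = ylim, ...)
  graphics::abline(h = rng[is.finite(rng)], col = "black", lty = 3)
  graphics::legend("topright", legend = prim, lty = 1,
                   col = seq_along(prim), bty = "n")
  invisible(x)
}
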