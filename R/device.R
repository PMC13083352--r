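#' Define one primary of a multiprimary stimulator
#'
#' The emission spectrum is area-normalized on construction (so the unit of
#' the supplied intensities is irrelevant); the primary's absolute output is
#' fully described by its mean luminance and the luminance range the device
#' can physically produce.
#'
#' @param name primary label (e.g. `"red"`)
#' @param emission `spectrum` of the primary's relative emission
#' @param mean_luminance time-averaged luminance setting (cd/m^2), > 0
#' @param lum_range length-2 numeric, the device's attainable luminance
#'   range for this primary (cd/m^2). Default `c(0, Inf)` means "not
#'   specified": contrast-magnitude feasibility is still checked, range
#'   containment never fails.
#' @return object of class `ss_primary`
#' @export
primary <- function(name, emission, mean_luminance, lum_range = c(0, Inf)) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(emission, "spectrum"))
  if (!is.numeric(mean_luminance) || mean_luminance <= 0)
    stop("mean luminance must be > 0; a zero-luminance primary is a ",
         "device with one fewer primary")
  lum_range <- as.numeric(lum_range)
  if (length(lum_range) != 2L || lum_range[1] < 0 ||
      lum_range[1] > mean_luminance || mean_luminance > lum_range[2])
    stop("lum_range must satisfy 0 <= min <= mean_luminance <= max")
  structure(list(name = name, emission = normalize_auc(emission),
                 mean_luminance = mean_luminance, lum_range = lum_range),
            class = "ss_primary")
}

#' Assemble a stimulator device from its primaries
#'
#' A device has 3 to 5 spectrally distinct primaries: three suffice to
#' control the L-, M- and S-cones, a fourth adds rod control, a fifth adds
#' melanopsin control. Emission spectra are resampled to the canonical
#' 390--780 nm / 2 nm grid.
#'
#' @param primaries list of `ss_primary` objects, in device channel order
#' @param vlambda photopic luminous efficiency function used for luminance
#'   calibration (a `spectrum`); defaults to the synthetic bundled table
#' @return object of class `ss_device`
#' @export
device <- function(primaries, vlambda = synthetic_vlambda()) {
  n <- length(primaries)
  if (n < 3L || n > 5L)
    stop("a device needs between 3 and 5 primaries, got ", n)
  stopifnot(all(vapply(primaries, inherits, TRUE, "ss_primary")),
            inherits(vlambda, "spectrum"))
  grid <- canonical_grid()
  primaries <- lapply(primaries, function(p) {
    p$emission <- normalize_auc(resample_spectrum(p$emission, grid))
    p
  })
  vlambda <- resample_spectrum(vlambda, grid)
  nm <- vapply(primaries, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("primary names must be unique")
  names(primaries) <- nm
  # pairwise linear independence of the emission spectra
  E <- vapply(primaries, function(p) p$emission$values, numeric(length(grid)))
  cor_ok <- TRUE
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    cs <- sum(E[, i] * E[, j]) /
      sqrt(sum(E[, i]^2) * sum(E[, j]^2))
    if (cs > 1 - 1e-10) cor_ok <- FALSE
  }
  if (!cor_ok) stop("two primaries have (near-)identical emission spectra")
  structure(list(primaries = primaries, vlambda = vlambda),
            class = "ss_device")
}

#' @export
print.ss_device <- function(x, ...) {
  cat(sprintf("<ss_device> %d primaries, mean field %.4g cd/m2\n",
              length(x$primaries),
              sum(vapply(x$primaries, `[[`, 0, "mean_luminance"))))
  for (p in x$primaries) {
    rng <- ifelse(is.finite(p$lum_range), format(p$lum_range), "-")
    cat(sprintf("  %-8s peak %g nm, mean %g cd/m2, range [%s, %s]\n",
                p$name, p$emission$wl[which.max(p$emission$values)],
                p$mean_luminance, rng[1], rng[2]))
  }
  invisible(x)
}

#' Mean luminances of a device's primaries
#' @param dev an `ss_device`
#' @return named numeric vector (cd/m^2)
#' @export
mean_luminances <- function(dev) {
  stopifnot(inherits(dev, "ss_device"))
  vapply(dev$primaries, `[[`, 0, "mean_luminance")
}

scaled_spds <- function(dev) {
  lapply(dev$primaries, function(p)
    scale_to_luminance(p$emission, p$mean_luminance, dev$vlambda))
}

#' Photoreceptor excitation produced by a spectral power distribution
#'
#' \eqn{a = \sum_\lambda R(\lambda)\,\Phi(\lambda)\,\Delta\lambda}: the
#' inner product of a photoreceptor fundamental with an SPD on the shared
#' wavelength grid.
#'
#' @param fund photoreceptor fundamental (`spectrum`)
#' @param spd spectral power distribution (`spectrum`)
#' @return excitation (arbitrary units)
#' @export
excitation <- function(fund, spd) {
  stopifnot(inherits(fund, "spectrum"), inherits(spd, "spectrum"))
  stop_if_grid_mismatch(fund, spd, "fundamental and SPD")
  sum(fund$values * spd$values) * grid_step(spd)
}

#' Photoreceptor classes controlled by an n-primary device
#'
#' A device can silence or modulate only as many photoreceptor classes as
#' it has primaries. Rod and melanopsin modulation are ignored with three
#' primaries, melanopsin with four.
#'
#' @param n_primaries 3, 4 or 5
#' @return ordered character vector of controlled photoreceptor labels
#' @export
controlled_set <- function(n_primaries) {
  if (!n_primaries %in% 3:5)
    stop("controlled set is defined for 3-5 primaries only")
  photoreceptor_classes()[seq_len(n_primaries)]
}

#' Build the photoreceptor excitation (A-) matrix
#'
#' Computes the raw excitation of each of the five photoreceptor classes by
#' each primary at its mean luminance setting,
#' \eqn{a_{pj} = \sum_\lambda R_p(\lambda) E_j(\lambda) \Delta\lambda},
#' and the contrast-normalized matrix
#' \eqn{w_{pj} = a_{pj} / \sum_k a_{pk}} whose rows sum to 1. With primary
#' Michelson contrasts \eqn{c_j}, the photoreceptor excitation contrasts
#' are exactly \eqn{C = W c}: the excitation swings
#' \eqn{\pm\sum_j a_{pj} c_j} around the mean \eqn{\sum_j a_{pj}}, so the
#' per-photoreceptor normalization turns luminance contrasts into
#' excitation contrasts. The square sub-matrix over the controlled classes
#' is what the solver inverts; the full 5-row matrix is kept for
#' validation of the uncontrolled classes.
#'
#' @param dev an `ss_device`
#' @param obs an `ss_observer`
#' @return object of class `ss_amatrix` with components `raw` (5 x n),
#'   `normalized` (5 x n, rows sum to 1), `controlled` (labels of the
#'   square block), `W` (the n x n controlled block of `normalized`) and
#'   `condition` (condition number of `W`)
#' @export
build_a_matrix <- function(dev, obs) {
  stopifnot(inherits(dev, "ss_device"), inherits(obs, "ss_observer"))
  grid <- canonical_grid()
  spds <- scaled_spds(dev)
  cls <- photoreceptor_classes()
  raw <- matrix(0, nrow = 5L, ncol = length(spds),
                dimnames = list(cls, names(dev$primaries)))
  for (p in cls) {
    f <- resample_spectrum(obs$fundamentals[[p]], grid)
    for (j in seq_along(spds)) raw[p, j] <- excitation(f, spds[[j]])
  }
  rs <- rowSums(raw)
  if (any(rs <= 0))
    stop("photoreceptor '", cls[which(rs <= 0)[1]],
         "' receives no excitation from any primary")
  W_all <- raw / rs
  ctrl <- controlled_set(length(spds))
  W <- W_all[ctrl, , drop = FALSE]
  kap <- kappa(W, exact = TRUE)
  if (kap > 1e8) {
    pr <- most_collinear_pair(dev)
    stop(sprintf(paste0(
      "controlled A-matrix block is near-singular (condition number ",
      "%.3g): primaries '%s' and '%s' are the most spectrally similar ",
      "pair; use more distinct primaries"), kap, pr[1], pr[2]))
  }
  structure(list(raw = raw, normalized = W_all, controlled = ctrl,
                 W = W, condition = kap),
            class = "ss_amatrix")
}

most_collinear_pair <- function(dev) {
  E <- vapply(dev$primaries, function(p) p$emission$values,
              numeric(length(canonical_grid())))
  n <- ncol(E)
  best <- c(1L, 2L); best_cs <- -1
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    cs <- sum(E[, i] * E[, j]) / sqrt(sum(E[, i]^2) * sum(E[, j]^2))
    if (cs > best_cs) { best_cs <- cs; best <- c(i, j) }
  }
  colnames(E)[best]
}

#' @export
print.ss_amatrix <- function(x, ...) {
  cat("<ss_amatrix> contrast-normalized excitation matrix (rows sum to 1)\n")
  print(round(x$normalized, 4))
  cat(sprintf("  controlled: %s; condition number %.3g\n",
              paste(x$controlled, collapse = ", "), x$condition))
  invisible(x)
}

#' Mean-field spectral power distribution of a device
#'
#' The sum over primaries of each area-normalized emission spectrum scaled
#' to its mean luminance: the time-averaged SPD the stimulus is modulated
#' around. Its luminance is the sum of the primaries' mean luminances.
#'
#' @param dev an `ss_device`
#' @return `spectrum` in W/(m2.sr.nm)
#' @export
mean_spd <- function(dev) {
  stopifnot(inherits(dev, "ss_device"))
  spds <- scaled_spds(dev)
  v <- Reduce(`+`, lapply(spds, `[[`, "values"))
  spectrum(canonical_grid(), v, unit = "W/(m2.sr.nm)")
}
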