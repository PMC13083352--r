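#' Forward-evaluate the achieved photoreceptor contrasts of a stimulus
#'
#' Given solved primary contrasts, builds the full five-row
#' contrast-normalized excitation matrix \eqn{W'} for the (possibly
#' individually modified) observer and returns the achieved signed
#' Michelson contrasts \eqn{C' = W' c} of all five photoreceptor classes,
#' together with the per-primary contribution matrix. With the unmodified
#' standard observer the achieved contrasts over the controlled set
#' reproduce the solver's request; for 3- or 4-primary devices the rows for
#' the uncontrolled classes quantify rod / melanopsin intrusion; with a
#' modified observer the silenced rows show the residual contrasts caused
#' by individual deviations in pre-receptoral filtering or photopigment
#' lambda-max.
#'
#' @param dev an `ss_device`
#' @param contrasts signed primary contrast vector (`abs(c) <= 1`)
#' @param obs the `ss_observer` to evaluate under (possibly built with
#'   [modify_observer()])
#' @return object of class `ss_validation` with components `achieved`
#'   (named 5-vector of signed contrasts), `contribution` (5 x n matrix,
#'   row sums equal `achieved`), `controlled`, `uncontrolled` and
#'   `observer_params`
#' @export
achieved_contrasts <- function(dev, contrasts, obs) {
  stopifnot(inherits(dev, "ss_device"), inherits(obs, "ss_observer"))
  if (any(abs(contrasts) > 1 + 1e-12))
    stop("primary contrasts must satisfy abs(c) <= 1; maximize or rescale")
  amat <- build_a_matrix(dev, obs)
  n <- length(dev$primaries)
  if (length(contrasts) != n) stop("need one contrast per primary")
  if (is.null(names(contrasts))) names(contrasts) <- names(dev$primaries)
  contrasts <- contrasts[names(dev$primaries)]
  contrib <- sweep(amat$normalized, 2, contrasts, `*`)
  ach <- rowSums(contrib)
  ctrl <- amat$controlled
  structure(list(achieved = ach, contribution = contrib,
                 controlled = ctrl,
                 uncontrolled = setdiff(photoreceptor_classes(), ctrl),
                 observer_params = list(mpod = obs$mpod,
                                        lens_age = obs$lens_age,
                                        shift_L = obs$shift_L,
                                        shift_M = obs$shift_M)),
            class = "ss_validation")
}

#' Per-primary contribution to each photoreceptor's excitation modulation
#'
#' Entry \eqn{[p, j] = w'_{pj} c_j}: the fractional excitation modulation
#' that primary j alone imposes on photoreceptor p. Row sums equal the
#' achieved contrasts; in a silent substitution condition a silenced row
#' sums to zero although its individual entries are not -- the increases
#' from some primaries are exactly cancelled by decreases from the others.
#'
#' @inheritParams achieved_contrasts
#' @return 5 x n numeric matrix (photoreceptor rows, primary columns)
#' @export
contribution_matrix <- function(dev, contrasts, obs) {
  achieved_contrasts(dev, contrasts, obs)$contribution
}

#' @export
print.ss_validation <- function(x, ...) {
  p <- x$observer_params
  cat("<ss_validation> achieved photoreceptor contrasts\n")
  cat(sprintf("  observer: MPOD %.3g, lens age %g y, L %+g nm, M %+g nm\n",
              p$mpod, p$lens_age, p$shift_L, p$shift_M))
  for (pc in photoreceptor_classes()) {
    tag <- if (pc %in% x$uncontrolled)
      sprintf("  (not controlled by %d-primary device)",
              ncol(x$contribution)) else ""
    cat(sprintf("  %-3s %+8.4f%%%s\n", pc, 100 * x$achieved[[pc]], tag))
  }
  invisible(x)
}

#' @export
plot.ss_validation <- function(x, ...) {
  graphics::barplot(t(x$contribution), beside = TRUE,
                    legend.text = colnames(x$contribution),
                    xlab = "Photoreceptor",
                    ylab = "Excitation-modulation contribution",
                    args.legend = list(bty = "n"), ...)
  graphics::abline(h = 0)
  invisible(x)
}
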