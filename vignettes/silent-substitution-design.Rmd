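---
title: "Designing silent substitution stimuli with silentsub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing silent substitution stimuli with silentsub}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silentsub)
```

## The problem

Silent substitution exchanges lights of different spectral composition so
that the excitation of selected photoreceptor classes stays constant while
a target class is modulated. By the principle of univariance a
photoreceptor's excitation depends only on the quantum catch, not on the
spectral composition that produced it, so a stimulator with $n$ spectrally
distinct primaries can independently control the excitation modulation of
exactly $n$ photoreceptor classes. silentsub computes, for devices with 3
to 5 primaries, the per-primary Michelson contrasts that realize a
requested vector of photoreceptor contrasts, checks whether the resulting
luminance modulations are technically feasible, and quantifies the residual
contrasts that remain when the observer deviates from the standard
fundamentals. It is aimed at periodic full-field stimuli (e.g. for flicker
electroretinography) modulated sinusoidally around a fixed mean setting.

## The model

Each primary $j$ is described by its area-normalized emission spectrum
$E_j(\lambda)$ (any input unit; normalized so
$\sum_\lambda E_j(\lambda)\,\Delta\lambda = 1$ W m$^{-2}$ sr$^{-1}$) and a
mean luminance $L_j$ in cd/m$^2$. The scaled spectral power distribution of
primary $j$ is $E_j(\lambda) \cdot L_j / (K_m \sum E_j V \Delta\lambda)$
with $K_m = 683$ lm/W. The excitation of photoreceptor class $p$ with
corneal fundamental $R_p(\lambda)$ by primary $j$ at its mean setting is

$$a_{pj} = \sum_\lambda R_p(\lambda)\,\Phi_j(\lambda)\,\Delta\lambda .$$

When primary $j$ is modulated sinusoidally with Michelson contrast $c_j$
around its mean, the excitation of class $p$ swings by
$\pm\sum_j a_{pj} c_j$ around the mean $\sum_j a_{pj}$. Its excitation
Michelson contrast is therefore exactly

$$C_p = \sum_j w_{pj}\, c_j, \qquad
  w_{pj} = \frac{a_{pj}}{\sum_k a_{pk}},$$

i.e. $C = W c$ with a matrix $W$ whose rows (one per photoreceptor) sum
to 1. Note the direction of this normalization: it is across the *primary*
index for each photoreceptor, which is what turns luminance contrasts into
excitation contrasts; the transposed description sometimes seen (columns
summing to one, with primaries as rows) is the same object in the other
layout. Only the contrast relation $C = Wc$ is contractual in this package,
and it is what the tests verify.

The stimulus is obtained by inverting the square block of $W$ over the
*controlled* classes — L, M, S for 3 primaries, plus rods for 4, plus
melanopsin for 5:

$$c = W^{-1} C .$$

A silent substitution condition is simply a request with $C_p = 0$ for the
silenced classes. Both relations are linear, so contrasts are proportional
(scaling the request scales all primary contrasts) and invariant to a
global rescaling of all mean luminances.

`maximize_contrasts()` rescales a solution by $1/\max_j |c_j|$, putting
exactly one primary at 100% contrast and all others below — the largest
modulation the device can produce with that contrast *ratio*.
`check_feasibility()` computes the luminance envelope
$[L_j(1-|c_j|),\ L_j(1+|c_j|)]$ per primary and flags any $|c_j|>1$ or any
envelope leaving the device's configured range. The absolute value makes
the reported envelope independent of modulation phase (a negative contrast
is counterphase modulation, not a different envelope).

## The observer model

An observer is the set of five corneal fundamentals plus the physiological
parameters they embody. The baseline standard observer assumes a macular
pigment peak optical density (MPOD) of 0.3 and a lens age of 40 years, so
modification at those values is the identity. For validation the
fundamentals can be modified:

* **Macular pigment.** $f'(\lambda) = f(\lambda)\,
  10^{-(d - 0.3)\,m(\lambda)}$ with $m$ the macular density template,
  peak-normalized to 1 at its tabulated maximum so the parameter $d$ is the
  peak OD.
* **Lens age.** Pokorny–Smith–Lutze two-component model:
  $D(\lambda, A) = T_{L1}(\lambda)(1 + 0.02(A-32)) + T_{L2}(\lambda)$ for
  $20 \le A \le 60$ and
  $T_{L1}(\lambda)(1.56 + 0.0667(A-60)) + T_{L2}(\lambda)$ above 60 (the
  branches agree at 60); the fundamental is multiplied by
  $10^{-(D(\lambda,A) - D(\lambda,40))}$.
* **λ-max shifts** of the L and M fundamentals (e.g. opsin polymorphisms):
  the corneal curve is translated by `delta` nm with linear interpolation,
  up to ±20 nm.

Three design choices deserve a note. First, the pre-receptoral density
adjustments are applied to *all five* fundamentals, including rods and
melanopsin — the lens and macular pigment filter all light reaching the
retina. Second, the λ-max shift is applied to the corneal fundamental
directly rather than deconvolving to the photopigment level and re-applying
the filters; at the few-nm shifts the slider is meant for, the difference
is negligible relative to the contrast quantities of interest. Third,
modified fundamentals are *not* renormalized to unit peak: every contrast
computed here is invariant to a global scalar on a fundamental (the row
normalization of $W$ divides it out), so renormalization would be purely
cosmetic. For the same reason the melanopsin table's absolute calibration
does not matter; the bundle documents the assumption that it embeds the
same 0.3/40-year baseline filtering as the cone fundamentals.

Validation (`achieved_contrasts()`) rebuilds the full 5-row $W'$ for the
modified observer and reports $C' = W'c$ with sign, so counterphase
intrusion is visible, plus the contribution matrix $w'_{pj} c_j$ whose row
sums are the achieved contrasts — in a silent substitution the entries of a
silenced row are individually nonzero but cancel exactly. This package
computes excitation-modulation contrast only; recorded response amplitudes
additionally depend on adaptation, temporal frequency and other physiology
that is out of scope, so residual contrasts should be read as optical, not
electrophysiological, predictions.

## Numerical conventions

* **Grid.** All computation happens on the canonical uniform grid
  390–780 nm in 2 nm steps (196 points); imported spectra are resampled on
  load.
* **Integration.** Left-Riemann rule, $\sum v(\lambda)\Delta\lambda$, the
  usual convention for tabulated spectra; the test-suite oracles use the
  identical rule so agreement is demanded to 1e-12 relative, and no claim
  of exact numerical equality with tools integrating by trapezoid is made.
* **Interpolation.** Linear, zero outside the source support; resampling
  onto a grid the spectrum already lives on is the identity.
* **Luminance.** $K_m = 683$ lm/W exactly; the calibration $V(\lambda)$ is
  a configurable table on the device.
* **Conditioning.** The controlled block is rejected when its exact
  condition number exceeds 1e8, with an error naming the most spectrally
  similar primary pair (cosine similarity of emission spectra) as the
  likeliest culprit; the forward product $Wc$ is additionally checked
  against the request to 1e-10 after every solve.
* **Small contrasts.** Primary contrasts below 0.5% (configurable) trigger
  an advisory warning only — device luminance resolution, not the algebra,
  is the concern.
* **Waveform.** Sinusoidal, phase 0 at $t=0$; square waves and other
  periodic shapes are an extension point, not implemented.
* **Serialization.** JSON round-trips numbers at full double precision
  (jsonlite `digits = NA`, ~15 significant digits); round-trip equality is
  asserted at that precision, not at binary identity.

## Synthetic data: what it emulates and what it does not

Every computation and test in this package runs against synthetic spectral
data, generated in code:

* `gaussian_led(peak, fwhm)` — area-normalized Gaussian emission, a good
  shape model for single-color LED channels;
* `synthetic_fundamental()` — unit-peak Gaussians with λ-max at 560 (L),
  530 (M), 440 (S), 500 (rod), 480 nm (mel) and 100 nm FWHM, matching the
  breadth and ordering of real corneal sensitivities;
* `synthetic_vlambda()`, `synthetic_cmfs()`, `synthetic_templates()` —
  analytic stand-ins for the luminous efficiency function, the 10°
  colour-matching functions (rescaled so an equal-energy spectrum maps to
  x = y = 1/3) and the macular/lens density templates.

The default `synthetic_device()` is a 4-primary stimulator (blue 460,
green 520, amber 590, red 640 nm; FWHM 20 nm) at the mean-luminance
settings recommended as a feasible starting point for rod and cone
stimulation — blue 4, green 40, amber 100, red 80 cd/m², a 224 cd/m² mean
field. Each luminance range defaults to $[0, 2L_j]$, the span that a 100%
modulation around the mean just fills. Randomized fixtures
(`random_device()`, `random_request()`) draw well-separated peaks,
log-uniform luminances in 2–150 cd/m² and partial-silencing requests,
deterministically per seed.

What passing tests therefore demonstrate is the *algebraic* correctness of
the pipeline — normalization, inversion, silence, proportionality,
feasibility logic, round trips — under realistic spectral shapes. They do
not certify colorimetric accuracy for real observers: real cone
fundamentals are asymmetric with long short-wavelength tails, real CMFs
are not Gaussian lobes, and real LED spectra have shoulders. The packaged
bundle under `inst/extdata/synthetic_cvrl/` is exactly these synthetic
tables written in the observer-bundle CSV dialect (see
`tools/make_synthetic_bundle.R`); `tools/fetch_cvrl.R` documents how to
build an interchangeable bundle from the published standard-observer
tables for production stimulus design.

## Problem sizes

The property suites use 100 random seeded device/request fixtures for the
solver–oracle equivalence and silence checks, 10–25 for the slower
matrix-level invariants, all on the 196-point canonical grid; the full
test suite runs in well under a minute on one core, and
`scripts/acceptance.R` recomputes the headline quantities (silence
residuals, row-sum deviations, maximized contrast, mean-field luminance,
oracle agreement, feasibility flags) in a few seconds.

## Known limitations

* Mean luminances are taken as exact (no gamma/nonlinearity model, no
  threshold or saturation effects near the range ends) and are not
  optimized — choosing them well is the user's task; the package only
  reports which primary limits the contrast after maximization.
* Only excitation-modulation contrast is predicted, not response
  amplitudes.
* Individual-observer *calibration* (e.g. heterochromatic flicker
  photometry) is out of scope: observer modification here estimates the
  consequences of individual deviations for a stimulus computed for the
  standard observer, which is the appropriate validation question for
  full-field work.
* Exports are JSON (round-tripping, schema-versioned) and CSV; the result
  table schema is fixed as primary / Contrast (%) / MinLuminance /
  MaxLuminance / feasible.
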