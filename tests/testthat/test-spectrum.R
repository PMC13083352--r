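test_that("wavelength grids validate their invariants", {
  expect_equal(canonical_grid()[1], 390)
  expect_equal(canonical_grid()[196], 780)
  expect_equal(length(canonical_grid()), 196)
  expect_error(wavelength_grid(400, 400, 2), "stop > start")
  expect_error(wavelength_grid(400, 500, -1), "step")
  expect_error(wavelength_grid(400, 500, 3), "integer multiple")
})

test_that("spectrum constructor enforces shape, finiteness and sign", {
  wl <- tiny_grid()
  expect_error(spectrum(wl, rep(1, 3)), "one entry per wavelength")
  expect_error(spectrum(wl, c(NA, rep(1, 10))), "finite")
  expect_error(spectrum(wl, c(-1, rep(1, 10))), "non-negative")
  # optical densities may be negative
  expect_s3_class(spectrum(wl, c(-1, rep(1, 10)), unit = "OD"), "spectrum")
  expect_error(spectrum(c(400, 410, 405), 1:3), "increasing")
})

test_that("resampling interpolates linearly and zero-fills outside support", {
  wl1 <- seq(400, 700, 1)
  v1 <- sin(wl1 / 50)^2 + 0.1
  s <- spectrum(wl1, v1)
  out <- resample_spectrum(s, canonical_grid())
  # on-grid points of a 1 nm table are reproduced exactly
  even <- canonical_grid()[canonical_grid() >= 400 & canonical_grid() <= 700]
  expect_equal(out$values[match(even, out$wl)], v1[match(even, wl1)])
  # outside the source support the convention is zero
  expect_true(all(out$values[out$wl < 400] == 0))
  expect_true(all(out$values[out$wl > 701] == 0))
  # identity when already on the target grid, and idempotence
  s2 <- spectrum(canonical_grid(), runif(196))
  expect_equal(resample_spectrum(s2, canonical_grid())$values, s2$values)
  expect_equal(resample_spectrum(out, canonical_grid()), out)
  expect_error(resample_spectrum(spectrum(800:900, rep(1, 101)),
                                 canonical_grid()), "no overlap")
})

test_that("area normalization yields AUC 1, idempotent and scale-invariant", {
  set.seed(11)
  for (i in 1:5) {
    s <- spectrum(canonical_grid(), runif(196))
    n1 <- normalize_auc(s)
    expect_equal(spectrum_auc(n1), 1, tolerance = 1e-14)
    # unit of the input intensities is irrelevant
    expect_equal(normalize_auc(spectrum(s$wl, s$values * 1000))$values,
                 n1$values)
    expect_equal(normalize_auc(n1)$values, n1$values)
  }
  expect_error(normalize_auc(spectrum(tiny_grid(), rep(0, 11))), "all-zero")
})

test_that("luminance matches the definition of Km and a brute-force sum", {
  wl <- canonical_grid()
  vl <- synthetic_vlambda()
  # a monochromatic line carrying 1/(683 V) W/(m2 sr) gives 1 cd/m2 by the
  # definition of Km
  peak_idx <- which.max(vl$values)
  mono <- numeric(196)
  mono[peak_idx] <- 1 / (683 * vl$values[peak_idx] * 2)  # AUC over 2 nm bin
  expect_equal(luminance_of(spectrum(wl, mono, unit = "W/(m2.sr.nm)"), vl), 1)
  expect_equal(luminance_of(spectrum(wl, numeric(196), "W/(m2.sr.nm)"), vl), 0)
  # Gaussian LED against the independent Riemann oracle
  led <- gaussian_led(520, 25)
  oracle <- 0
  for (k in seq_along(wl)) oracle <- oracle + 683 * led$values[k] * vl$values[k] * 2
  expect_equal(luminance_of(led, vl), oracle, tolerance = 1e-12)
  # linearity
  s1 <- gaussian_led(460, 20); s2 <- gaussian_led(620, 30)
  comb <- spectrum(wl, 2 * s1$values + 3 * s2$values, "W/(m2.sr.nm)")
  expect_equal(luminance_of(comb, vl),
               2 * luminance_of(s1, vl) + 3 * luminance_of(s2, vl),
               tolerance = 1e-12)
  expect_error(luminance_of(spectrum(tiny_grid(), rep(1, 11)), vl), "grid")
})

test_that("scaling to a luminance is exact, linear and rejects L <= 0", {
  vl <- synthetic_vlambda()
  led <- gaussian_led(640, 20)
  out <- scale_to_luminance(led, 80, vl)
  expect_equal(luminance_of(out, vl), 80, tolerance = 1e-10)
  expect_equal(scale_to_luminance(led, 160, vl)$values, 2 * out$values)
  fix <- scale_to_luminance(led, luminance_of(led, vl), vl)
  expect_equal(fix$values, led$values)
  expect_error(scale_to_luminance(led, 0, vl), "zero luminance")
  expect_error(scale_to_luminance(led, -5, vl), "zero luminance")
})

test_that("CIE 1964 chromaticity: white point, scale invariance, oracle", {
  cmfs <- synthetic_cmfs()
  wl <- canonical_grid()
  ee <- spectrum(wl, rep(1, 196), "W/(m2.sr.nm)")
  xy <- cie1964_xy(ee, cmfs)
  expect_equal(unname(xy), c(1 / 3, 1 / 3), tolerance = 1e-3)
  led <- gaussian_led(600, 30)
  xy1 <- cie1964_xy(led, cmfs)
  led5 <- spectrum(wl, 5 * led$values, "W/(m2.sr.nm)")
  expect_equal(cie1964_xy(led5, cmfs), xy1, tolerance = 1e-14)
  # brute-force tristimulus oracle
  X <- Y <- Z <- 0
  for (k in seq_along(wl)) {
    X <- X + led$values[k] * cmfs$x$values[k] * 2
    Y <- Y + led$values[k] * cmfs$y$values[k] * 2
    Z <- Z + led$values[k] * cmfs$z$values[k] * 2
  }
  expect_equal(unname(xy1), c(X, Y) / (X + Y + Z), tolerance = 1e-12)
  expect_true(xy1["x"] >= 0 && xy1["y"] >= 0 && sum(xy1) <= 1)
  expect_error(cie1964_xy(spectrum(wl, numeric(196), "W/(m2.sr.nm)"), cmfs),
               "all-zero")
})
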