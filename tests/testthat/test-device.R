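test_that("excitation is the inner product on the shared grid", {
  led <- gaussian_led(520, 20)
  # disjoint supports give zero
  far <- synthetic_fundamental(760, width = 10)
  expect_lt(excitation(far, led), 1e-12)
  # constant-1 fundamental recovers the AUC
  one <- spectrum(canonical_grid(), rep(1, 196), unit = "sensitivity")
  expect_equal(excitation(one, led), spectrum_auc(led), tolerance = 1e-14)
  # brute-force oracle on a Gaussian pair
  f <- synthetic_fundamental(530)
  acc <- 0
  for (k in 1:196) acc <- acc + f$values[k] * led$values[k] * 2
  expect_equal(excitation(f, led), acc, tolerance = 1e-14)
  expect_error(excitation(spectrum(tiny_grid(), rep(1, 11), "sensitivity"),
                          led), "grid")
})

test_that("controlled set grows L,M,S -> +rod -> +mel with primary count", {
  expect_equal(controlled_set(3), c("L", "M", "S"))
  expect_equal(controlled_set(4), c("L", "M", "S", "rod"))
  expect_equal(controlled_set(5), c("L", "M", "S", "rod", "mel"))
  expect_error(controlled_set(2), "3-5")
  expect_error(controlled_set(6), "3-5")
})

test_that("device constructor enforces 3-5 distinct primaries", {
  leds <- lapply(c(460, 520, 590, 640), gaussian_led, fwhm = 20)
  p <- function(i, nm) primary(nm, leds[[i]], 10)
  expect_error(device(list(p(1, "a"), p(2, "b"))), "3 and 5")
  expect_error(device(list(p(1, "a"), p(1, "b"), p(2, "c"))),
               "identical emission")
  expect_error(primary("x", leds[[1]], 0), "> 0")
  expect_error(primary("x", leds[[1]], 100, c(0, 50)), "lum_range")
})

test_that("A-matrix: shape, row normalization, diagonal dominance,
           invariance to fundamental and luminance scaling", {
  dev <- synthetic_device()
  obs <- synthetic_observer()
  amat <- build_a_matrix(dev, obs)
  expect_equal(dim(amat$raw), c(5L, 4L))
  expect_equal(dim(amat$W), c(4L, 4L))
  expect_equal(amat$controlled, c("L", "M", "S", "rod"))
  expect_true(all(amat$raw >= 0))
  expect_equal(unname(rowSums(amat$normalized)), rep(1, 5),
               tolerance = 1e-12)
  # narrowband primaries aligned to narrow, distinct fundamentals give a
  # diagonally dominant raw matrix
  obs_n <- observer(lapply(c(L = 640, M = 590, S = 460, rod = 520,
                             mel = 480), synthetic_fundamental, width = 25))
  amat_n <- build_a_matrix(dev, obs_n)
  raw4 <- amat_n$raw[c("S", "rod", "M", "L"), ]  # reorder rows to peaks
  for (i in 1:4) expect_equal(which.max(raw4[i, ]), i, ignore_attr = TRUE)
  # scaling a fundamental leaves its normalized row unchanged
  obs_k <- obs
  obs_k$fundamentals$M$values <- 7 * obs_k$fundamentals$M$values
  expect_equal(build_a_matrix(dev, obs_k)$normalized["M", ],
               amat$normalized["M", ], tolerance = 1e-13)
  # scaling all luminances leaves the whole normalized matrix unchanged
  dev_k <- synthetic_device(luminances = 3 * c(4, 40, 100, 80))
  expect_equal(build_a_matrix(dev_k, obs)$normalized, amat$normalized,
               tolerance = 1e-12)
})

test_that("a spectrally degenerate controlled block is rejected with a
           diagnostic error", {
  # two identical fundamentals make the controlled block exactly singular
  obs_dup <- observer(lapply(c(L = 530, M = 530, S = 440, rod = 500,
                               mel = 480), synthetic_fundamental))
  dev3 <- synthetic_device(peaks = c(460, 530, 630), fwhms = 20,
                           luminances = c(10, 50, 80))
  expect_error(build_a_matrix(dev3, obs_dup), "near-singular")
})

test_that("mean SPD is additive and carries the summed luminance", {
  dev <- synthetic_device()
  vl <- dev$vlambda
  spd <- mean_spd(dev)
  expect_equal(luminance_of(spd, vl), 224, tolerance = 1e-9)
  # removing one primary subtracts exactly its scaled spectrum
  dev3 <- synthetic_device(peaks = c(460, 520, 590), fwhms = 20,
                           luminances = c(4, 40, 100))
  red <- scale_to_luminance(dev$primaries$red$emission, 80, vl)
  expect_equal(mean_spd(dev)$values - red$values, mean_spd(dev3)$values,
               tolerance = 1e-12)
})
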