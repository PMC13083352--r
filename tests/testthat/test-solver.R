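test_that("solver inverts the contrast relation and round-trips", {
  dev <- synthetic_device()
  obs <- synthetic_observer()
  amat <- build_a_matrix(dev, obs)
  req <- c(L = 0, M = 0, S = 0, rod = 0.2)
  c_prim <- solve_contrasts(amat, req)
  expect_equal(drop(amat$W %*% c_prim), req[amat$controlled],
               tolerance = 1e-10, ignore_attr = TRUE)
  # identity-matrix case
  id <- amat
  id$W <- diag(3); colnames(id$W) <- paste0("P", 1:3)
  id$controlled <- c("L", "M", "S")
  expect_equal(unname(solve_contrasts(id, c(L = 0.2, M = 0, S = 0))),
               c(0.2, 0, 0))
  # linearity
  expect_equal(solve_contrasts(amat, 3 * req), 3 * c_prim,
               tolerance = 1e-12)
  # naming an uncontrolled class explains the 3/4/5-primary rule
  expect_error(solve_contrasts(amat, c(L = 0, M = 0, S = 0, mel = 0.1)),
               "cannot be controlled")
  expect_error(solve_contrasts(amat, c(L = 0, M = 0, S = 0)),
               "every controlled class")
  expect_error(solve_contrasts(amat, c(L = 0, M = 0, S = 0, rod = 1.2)),
               "\\[-1, 1\\]")
})

test_that("solver agrees with the independent brute-force oracle", {
  for (seed in 1:25) {
    dev <- random_device(seed)
    obs <- synthetic_observer()
    amat <- build_a_matrix(dev, obs)
    req <- random_request(seed + 1000, amat$controlled)
    expect_equal(unname(solve_contrasts(amat, req)),
                 oracle_solve(dev, obs, req), tolerance = 1e-9)
  }
})

test_that("maximization puts exactly one primary at 100% and preserves
           signs and photoreceptor contrast ratios", {
  mx <- maximize_contrasts(c(0.5, -0.25, 0.1, 0.05))
  expect_equal(mx$contrasts, c(1, -0.5, 0.2, 0.1))
  expect_equal(mx$factor, 2)
  expect_equal(maximize_contrasts(mx$contrasts)$factor, 1)
  expect_equal(maximize_contrasts(mx$contrasts)$contrasts, mx$contrasts)
  expect_error(maximize_contrasts(c(0, 0, 0)), "all-zero")
  # photoreceptor contrasts scale by the same factor (proportionality)
  dev <- synthetic_device()
  amat <- build_a_matrix(dev, synthetic_observer())
  c1 <- solve_contrasts(amat, c(L = 0, M = 0, S = 0, rod = 0.1))
  mx <- maximize_contrasts(c1)
  expect_equal(drop(amat$normalized %*% mx$contrasts),
               mx$factor * drop(amat$normalized %*% c1), tolerance = 1e-10)
})

test_that("feasibility: luminance envelope, contrast and range flags,
           resolution warning", {
  vl <- synthetic_vlambda()
  mk_dev <- function(range3) {
    prims <- list(
      primary("a", gaussian_led(460, 20), 100, c(0, 200)),
      primary("b", gaussian_led(550, 20), 100, c(0, 200)),
      primary("c", gaussian_led(640, 20), 100, range3))
    device(prims, vlambda = vl)
  }
  dev <- mk_dev(c(0, 200))
  sol <- check_feasibility(c(0.5, 0.5, 0.5), dev)
  expect_equal(sol$table$min_luminance, rep(50, 3))
  expect_equal(sol$table$max_luminance, rep(150, 3))
  expect_true(sol$feasible)
  # contrast beyond 100% is flagged
  sol2 <- check_feasibility(c(1.2, 0.5, 0.5), dev)
  expect_false(sol2$table$feasible[1])
  expect_true(all(sol2$table$feasible[2:3]))
  expect_false(sol2$feasible)
  # envelope leaving the configured range is flagged
  dev3 <- mk_dev(c(0, 120))
  sol3 <- check_feasibility(c(0.5, 0.5, 0.5), dev3)
  expect_equal(sol3$table$max_luminance[3], 150)
  expect_false(sol3$table$feasible[3])
  # negative contrast gives the same (phase-independent) envelope
  sol_neg <- check_feasibility(c(-0.5, 0.5, 0.5), dev)
  expect_equal(sol_neg$table$min_luminance, sol$table$min_luminance)
  expect_equal(sol_neg$table$max_luminance, sol$table$max_luminance)
  # tiny nonzero contrasts trigger the advisory resolution warning
  solw <- check_feasibility(c(0.001, 0.5, 0.5), dev)
  expect_match(solw$warnings, "resolution")
  # maximized vectors never violate the contrast-magnitude rule
  mx <- maximize_contrasts(c(0.3, -1.7, 0.2))
  solm <- check_feasibility(mx$contrasts, mk_dev(c(0, Inf)))
  expect_true(all(abs(solm$table$contrast) <= 1))
})

test_that("waveform is sinusoidal around the mean with exact counterphase", {
  dev <- synthetic_device()
  ctr <- c(blue = 0.5, green = -0.25, amber = 0.1, red = 1)
  f <- 8
  wf <- waveform(dev, ctr, frequency = f, n_samples = 101,
                 duration = 1 / f)
  L <- mean_luminances(dev)
  expect_equal(unlist(wf[1, -1]), L, tolerance = 1e-12, ignore_attr = TRUE)
  # quarter period hits L * (1 + c) exactly
  iq <- which.min(abs(wf$time - 1 / (4 * f)))
  expect_equal(unlist(wf[iq, -1]), L * (1 + ctr), tolerance = 1e-9,
               ignore_attr = TRUE)
  wf_neg <- waveform(dev, -ctr, frequency = f, n_samples = 101,
                     duration = 1 / f)
  for (nm in names(L))
    expect_equal(wf[[nm]] + wf_neg[[nm]], rep(2 * L[[nm]], 101),
                 tolerance = 1e-10)
  expect_error(waveform(dev, ctr, frequency = 0), "> 0")
  expect_error(waveform(dev, ctr, n_samples = 1), "2 samples")
})

test_that("one-call silent_substitution composes solve, maximize,
           feasibility and forward evaluation", {
  dev <- synthetic_device()
  obs <- synthetic_observer()
  sol <- silent_substitution(dev, c(L = 0, M = 0, S = 0, rod = 0.2), obs,
                             maximize = TRUE)
  expect_s3_class(sol, "ss_solution")
  expect_equal(max(abs(sol$contrasts)), 1)
  expect_lt(max(abs(sol$achieved[c("L", "M", "S")])), 1e-10)
  expect_gt(sol$achieved[["rod"]], 0)
  expect_true(sol$feasible)
  expect_output(summary(sol), "not controlled by this device: mel")
})
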