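# Independent brute-force oracle for the contrast solver: excitations by
# naive per-wavelength loops, linear system by hand-written Gaussian
# elimination with partial pivoting. Deliberately shares no code with R/.

gauss_solve <- function(A, b) {
  n <- nrow(A)
  M <- cbind(A, b)
  for (k in seq_len(n - 1L)) {
    piv <- which.max(abs(M[k:n, k])) + k - 1L
    if (abs(M[piv, k]) < 1e-14) stop("singular matrix in oracle")
    if (piv != k) {
      tmp <- M[k, ]; M[k, ] <- M[piv, ]; M[piv, ] <- tmp
    }
    for (i in seq.int(k + 1L, n)) {
      f <- M[i, k] / M[k, k]
      M[i, ] <- M[i, ] - f * M[k, ]
    }
  }
  x <- numeric(n)
  for (i in rev(seq_len(n))) {
    s <- M[i, n + 1L]
    if (i < n) for (j in seq.int(i + 1L, n)) s <- s - M[i, j] * x[j]
    if (abs(M[i, i]) < 1e-14) stop("singular matrix in oracle")
    x[i] <- s / M[i, i]
  }
  x
}

# Per-wavelength Riemann sum, written as an explicit loop.
riemann <- function(values, step) {
  acc <- 0
  for (v in values) acc <- acc + v * step
  acc
}

oracle_amatrix <- function(dev, obs, n_rows = length(dev$primaries)) {
  wl <- dev$vlambda$wl
  step <- wl[2] - wl[1]
  n <- length(dev$primaries)
  cls <- c("L", "M", "S", "rod", "mel")[seq_len(n_rows)]
  A <- matrix(0, n_rows, n, dimnames = list(cls, NULL))
  for (j in seq_len(n)) {
    pr <- dev$primaries[[j]]
    e <- pr$emission$values
    en <- e / riemann(e, step)
    lum <- 0
    for (k in seq_along(en))
      lum <- lum + 683 * en[k] * dev$vlambda$values[k] * step
    spd <- en * (pr$mean_luminance / lum)
    for (p in seq_len(n_rows)) {
      fund <- obs$fundamentals[[cls[p]]]$values
      acc <- 0
      for (k in seq_along(spd)) acc <- acc + fund[k] * spd[k] * step
      A[p, j] <- acc
    }
  }
  A
}

oracle_solve <- function(dev, obs, request) {
  A <- oracle_amatrix(dev, obs)
  W <- A
  for (p in seq_len(nrow(A))) W[p, ] <- A[p, ] / sum(A[p, ])
  cls <- rownames(A)
  gauss_solve(W, as.numeric(request[cls]))
}

# Small non-canonical grid fixtures for unit tests.
tiny_grid <- function() wavelength_grid(400, 500, 10)
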