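test_that("the Wiener mode update matches its closed form", {
  set.seed(5)
  n <- 16
  fh <- complex(real = rnorm(n), imaginary = rnorm(n))
  others <- complex(real = rnorm(n), imaginary = rnorm(n))
  lam <- complex(real = rnorm(n), imaginary = rnorm(n))
  grid <- seq(0, 0.5, length.out = n)
  omega <- 0.22
  alpha <- 1500
  got <- updateModeSpectrum(fh, others, lam, omega, alpha, grid)
  ## independent element-wise evaluation
  for (i in seq_len(n)) {
    expect_equal(got[i],
                 (fh[i] - others[i] + lam[i] / 2) /
                   (1 + 2 * alpha * (grid[i] - omega)^2))
  }

  ## gain exactly 1 at the bin whose grid frequency equals omega
  at <- updateModeSpectrum(fh, 0 * fh, 0 * fh, grid[4], alpha, grid)
  expect_identical(at[4], fh[4])

  ## huge alpha suppresses bins far from omega
  big <- updateModeSpectrum(fh, 0 * fh, 0 * fh, 0, 1e12, grid)
  expect_lt(max(Mod(big[-1])), 1e-6 * max(Mod(fh)))

  expect_error(updateModeSpectrum(fh, others[-1], lam, 0.1, alpha, grid),
               "shape")
})

test_that("the center-frequency update is the spectral power centroid", {
  grid <- seq(0, 0.5, length.out = 32)
  ## point mass
  s <- complex(32)
  s[9] <- 3 + 2i
  expect_equal(updateCenterFrequency(s, grid), grid[9])
  ## symmetric two-bin mass
  s2 <- complex(32)
  s2[5] <- 2
  s2[13] <- 2i
  expect_equal(updateCenterFrequency(s2, grid), (grid[5] + grid[13]) / 2)
  ## random spectrum vs direct summation
  set.seed(8)
  r <- complex(real = rnorm(32), imaginary = rnorm(32))
  expect_equal(updateCenterFrequency(r, grid),
               sum(grid * Mod(r)^2) / sum(Mod(r)^2))
  ## zero power falls back to the previous value
  expect_identical(updateCenterFrequency(complex(32), grid,
                                         previous = 0.3), 0.3)
})

test_that("the convergence criterion follows the summed relative change", {
  set.seed(2)
  U <- lapply(1:3, function(i)
    complex(real = rnorm(20), imaginary = rnorm(20)))
  expect_true(checkConvergence(U, U, 1e-12))

  V <- U
  V[[2]] <- V[[2]] * (1 + 1e-3)
  expect_false(checkConvergence(U, V, 1e-7))
  ## agreement with the direct formula
  tot <- sum(vapply(1:3, function(m)
    sum(Mod(V[[m]] - U[[m]])^2) / sum(Mod(U[[m]])^2), numeric(1)))
  expect_identical(checkConvergence(U, V, tot * 1.0001), TRUE)
  expect_identical(checkConvergence(U, V, tot * 0.9999), FALSE)

  ## a zero-norm mode blocks convergence only if it changed
  Z <- c(U[1:2], list(complex(20)))
  Z2 <- Z
  expect_true(checkConvergence(Z, Z2, 1e-9))
  Z2[[3]][1] <- 1e-8 + 0i
  expect_false(checkConvergence(Z, Z2, 1))
})

test_that("degenerate inputs are handled: zero signal, bad arguments", {
  res <- vmdDecompose(rep(0, 450), vmdConfig(nModes = 3))
  expect_true(all(res@modes == 0))
  expect_lte(res@iterations, 2L)
  expect_true(res@converged)

  expect_error(vmdDecompose(c(1, NA, 3, 4), vmdConfig(nModes = 1)))
  expect_error(vmdDecompose(rnorm(10), vmdConfig(nModes = 3)), "short")
})

test_that("decompositions are band-sorted, bounded, and deterministic", {
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(300)
    res <- vmdDecompose(x, vmdConfig(nModes = 3, maxIter = 100))
    expect_true(all(res@omegas >= 0 & res@omegas <= 0.5))
    expect_false(is.unsorted(res@omegas))
    expect_identical(ncol(res@modes), 300L)
    expect_lte(res@iterations, 100L)
  }
  x <- amplitudes(generateSignal(1, seed = 9))
  r1 <- vmdDecompose(x, vmdConfig())
  r2 <- vmdDecompose(x, vmdConfig())
  expect_identical(r1@modes, r2@modes)
})
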