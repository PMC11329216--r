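# spherical-harmonic basis, fitting, Funk-Radon transform, argmax

test_that("basis dimensions, Y00 constant, and orthonormality", {
  expect_equal(ncol(real_sh_basis(matrix(c(0, 0, 1), 1), 0L)), 1L)
  expect_equal(real_sh_basis(matrix(c(0.6, 0.8, 0), 1), 0L)[1, 1],
               1 / sqrt(4 * pi), tolerance = 1e-12)
  expect_equal(ncol(real_sh_basis(fib60, 6L)), 28L)
  # Gram matrix under equal-weight quadrature on a dense uniform grid
  g <- sphere_fibonacci(8000)
  B <- real_sh_basis(g, 6L)
  G <- crossprod(B) * (4 * pi / nrow(g))
  expect_equal(diag(G), rep(1, 28), tolerance = 1e-3)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-3)
})

test_that("odd orders and degenerate directions are rejected", {
  expect_error(real_sh_basis(fib60, 3L), "even")
  expect_error(real_sh_basis(matrix(c(0, 0, 0), 1), 2L), "norm")
  expect_error(fit_sh(rep(1, 10), fib60[1:10, ], 6L, 0), "directions")
})

test_that("constant and band-limited functions are fitted exactly", {
  co <- fit_sh(rep(2.5, 60), fib60, 6L, 0)
  expect_equal(co$coeffs[1], 2.5 * sqrt(4 * pi), tolerance = 1e-10)
  expect_lt(max(abs(co$coeffs[-1])), 1e-10)
  # random order-4 function: synthesize then refit
  set.seed(7)
  truth <- rnorm(15)
  vals <- drop(real_sh_basis(fib60, 4L) %*% truth)
  refit <- fit_sh(vals, fib60, 4L, 0)
  expect_equal(refit$coeffs, truth, tolerance = 1e-8)
  # round-trip synthesis at arbitrary directions
  probe <- sphere_fibonacci(20)
  expect_equal(eval_sh(refit, probe),
               drop(real_sh_basis(probe, 4L) %*% truth),
               tolerance = 1e-8)
})

test_that("Laplace-Beltrami penalty spares degree 0 and shrinks the rest", {
  set.seed(11)
  truth <- rnorm(15)
  vals <- drop(real_sh_basis(fib60, 4L) %*% truth)
  f0 <- fit_sh(vals, fib60, 4L, 0)
  f1 <- fit_sh(vals, fib60, 4L, 0.001)
  # the degree-0 penalty is zero; with a finite direction set the normal
  # equations couple degrees weakly, so C00 moves only at the per-mille
  # level while higher degrees shrink substantially
  expect_equal(f1$coeffs[1], f0$coeffs[1], tolerance = 5e-3)
  high <- 2:15
  expect_lt(sum(f1$coeffs[high]^2), sum(f0$coeffs[high]^2))
})

test_that("fitting is linear in the samples", {
  set.seed(3)
  f <- rnorm(60); g <- rnorm(60)
  lhs <- fit_sh(2 * f - 3 * g, fib60, 6L, 0.001)$coeffs
  rhs <- 2 * fit_sh(f, fib60, 6L, 0.001)$coeffs -
    3 * fit_sh(g, fib60, 6L, 0.001)$coeffs
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("Legendre-at-zero values and odd-degree rejection", {
  expect_identical(legendre_at_zero(0L), 1)
  expect_identical(legendre_at_zero(2L), -0.5)
  expect_equal(legendre_at_zero(c(4L, 6L)), c(0.375, -0.3125))
  expect_error(legendre_at_zero(3L), "odd")
})

test_that("Funk-Radon transform: constants, eigenvalues, quadrature", {
  co <- fit_sh(rep(1.5, 60), fib60, 6L, 0)
  frt <- funk_radon_sh(co)
  expect_equal(eval_sh(frt, matrix(c(0, 0, 1), 1)), 2 * pi * 1.5,
               tolerance = 1e-10)
  # pure degree-2 component scales by -pi
  c2 <- sh_coefficients(c(0, 0, 0, 1, 0, 0, rep(0, 22)), 6L)
  expect_equal(funk_radon_sh(c2)$coeffs[4], -pi, tolerance = 1e-12)
  # applying twice scales degree-l terms by (2 pi P_l(0))^2 exactly
  set.seed(5)
  cr <- sh_coefficients(rnorm(28), 6L)
  twice <- funk_radon_sh(funk_radon_sh(cr))
  fac <- (2 * pi * legendre_at_zero(c(0, rep(2, 5), rep(4, 9),
                                      rep(6, 13))))^2
  expect_equal(twice$coeffs, cr$coeffs * fac, tolerance = 1e-12)
  # FRT at random poles equals the 2048-point equator quadrature of the
  # band-limited input
  set.seed(13)
  for (i in 1:10) {
    pole <- random_unit()
    ref <- diag(3)[, which.min(abs(pole))]
    b1 <- ref - sum(ref * pole) * pole; b1 <- b1 / sqrt(sum(b1^2))
    b2 <- c(pole[2] * b1[3] - pole[3] * b1[2],
            pole[3] * b1[1] - pole[1] * b1[3],
            pole[1] * b1[2] - pole[2] * b1[1])
    ang <- (seq_len(2048) - 1) * 2 * pi / 2048
    eq <- outer(cos(ang), b1) + outer(sin(ang), b2)
    quad <- mean(eval_sh(cr, eq)) * 2 * pi
    expect_equal(eval_sh(funk_radon_sh(cr), matrix(pole, 1)), quad,
                 tolerance = 1e-4 * max(1, abs(quad)))
  }
})

test_that("degree-0 coefficient is rotation invariant", {
  set.seed(17)
  truth <- rnorm(28)
  vals <- drop(real_sh_basis(fib60, 6L) %*% truth)
  qr_ <- qr.Q(qr(matrix(rnorm(9), 3)))
  co_rot <- fit_sh(vals, fib60 %*% t(qr_), 6L, 0)
  expect_equal(co_rot$coeffs[1], truth[1], tolerance = 1e-8)
})

test_that("max_direction: argmax, ties, sign, and refinement", {
  grid <- sphere_grid_symmetric()
  adc <- tensor_signal(c(1.7, 0.3, 0.3) * 1e-3, c(0, 0, 1), fib60)
  co <- fit_sh(-log(adc) / 1000, fib60, 6L, 0)
  d <- max_direction(co, grid)
  expect_lt(angle_deg(d, c(0, 0, 1)), 5)
  expect_gte(d[which(abs(d) > 0)[1]], 0)
  # exactly constant expansion: deterministic tie-break on the first
  # grid point (fitted constants carry 1e-16 coefficient noise, so the
  # exact-tie rule is exercised on clean coefficients)
  iso <- sh_coefficients(c(sqrt(4 * pi), rep(0, 27)), 6L)
  g1 <- grid[1, ]
  if (g1[which(abs(g1) > 0)[1]] < 0) g1 <- -g1
  expect_equal(max_direction(iso, grid), g1)
  # oblate tensor: maximum in the equatorial plane normal to the axis
  adc_ob <- rowSums((fib60 %*% tensor_from_axis(
    c(0.3, 1.7, 1.7) * 1e-3, c(0, 0, 1))) * fib60)
  co_ob <- fit_sh(adc_ob, fib60, 6L, 0)
  d_ob <- max_direction(co_ob, grid)
  expect_lt(abs(d_ob[3]), sin(5 * pi / 180))
  # refined search on a rotated prolate tensor gets within 1 degree
  set.seed(23)
  ax <- random_unit()
  adc_r <- rowSums((fib60 %*% tensor_from_axis(
    c(1.7, 0.3, 0.3) * 1e-3, ax)) * fib60)
  dr <- max_direction_refined(fit_sh(adc_r, fib60, 6L, 0))
  expect_lt(angle_deg(dr, ax), 1)
  expect_error(max_direction(co, grid[0, , drop = FALSE]), "empty")
})

test_that("coefficients round-trip through CSV serialization", {
  set.seed(29)
  co <- sh_coefficients(rnorm(28), 6L)
  path <- tempfile(fileext = ".csv")
  write_sh_coefficients(co, path)
  back <- read_sh_coefficients(path)
  expect_equal(back$coeffs, co$coeffs, tolerance = 1e-12)
  expect_identical(back$order, 6L)
})
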