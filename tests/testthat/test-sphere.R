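test_that("antipodal grid satisfies its geometric invariants", {
  g <- make_antipodal_grid(250L)
  expect_equal(nrow(g$directions), 500L)
  expect_equal(g$n_half, 250L)
  # unit norms
  expect_lt(max(abs(sqrt(rowSums(g$directions^2)) - 1)), 1e-12)
  # exact antipodal pairing with equal weights
  n <- g$n_half
  expect_equal(g$directions[n + seq_len(n), ], -g$directions[seq_len(n), ])
  expect_equal(g$weights[n + seq_len(n)], g$weights[seq_len(n)])
  expect_true(all(g$weights > 0))
  # weights sum to the sphere surface
  expect_lt(abs(sum(g$weights) - 4 * pi), 1e-10)
})

test_that("grid integrates low-order polynomials exactly", {
  g <- test_grid()
  # constant function
  expect_lt(abs(sum(g$weights) - 4 * pi), 1e-10)
  # <a, u>^2 integrates to 4 pi / 3 for any unit a (1D quadrature oracle:
  # 2 pi int_{-1}^1 c^2 dc = 4 pi / 3)
  oracle <- 2 * pi * stats::integrate(function(c) c^2, -1, 1)$value
  for (s in 1:5) {
    a <- random_unit(s)
    val <- sum(g$weights * as.vector(g$directions %*% a)^2)
    expect_lt(abs(val - oracle), 1e-3)
    expect_lt(abs(val - 4 * pi / 3), 1e-3)
  }
})

test_that("grid construction rejects too-small requests", {
  expect_error(make_antipodal_grid(3), "n_half")
  expect_error(make_antipodal_grid(-1), "n_half")
})

test_that("real SH basis is orthonormal under grid quadrature", {
  g <- test_grid()
  B <- real_sh_basis(g$directions, 8L)
  expect_equal(ncol(B), 45L)
  expect_lt(max(abs(B[, 1L] - 1 / (2 * sqrt(pi)))), 1e-14)
  G <- crossprod(B, g$weights * B)
  expect_lt(max(abs(G - diag(45L))), 1e-6)
})

test_that("SH basis validates its arguments", {
  expect_error(real_sh_basis(diag(3), 7), "even")
  expect_error(real_sh_basis(c(1, 1, 0), 8L), "unit")
})

test_that("zonal coefficients of simple kernels match analytic expansions", {
  # constant kernel: only order 0 survives; convolution returns total mass
  lam <- zonal_kernel_coefficients(function(c) rep(1 + 0i, length(c)), 8L)
  expect_lt(abs(lam[1L] - 4 * pi), 1e-10)
  expect_lt(max(Mod(lam[-1L])), 1e-10)
  expect_lt(Mod(funk_hecke_convolve(uniform_odf(), lam, c(0, 0, 1)) - 1), 1e-10)
  o <- random_odf(7)
  expect_lt(Mod(funk_hecke_convolve(o, lam, c(0, 1, 0)) - 1), 1e-10)

  # 1 - c^2: orders 0 and 2 only, with known Legendre coefficients
  lam2 <- zonal_kernel_coefficients(function(c) 1 - c^2, 8L)
  expect_lt(abs(lam2[1L] - 8 * pi / 3), 1e-10)
  expect_lt(abs(lam2[2L] + 8 * pi / 15), 1e-10)
  expect_lt(max(Mod(lam2[3:5])), 1e-10)
  expect_lt(Mod(funk_hecke_convolve(uniform_odf(), lam2, c(1, 0, 0)) - 2 / 3),
            1e-10)
})

test_that("band-limited reconstruction of the phase kernel is accurate", {
  # exp(i a (1 - c^2)) with |a| <= pi, expanded at elevated order
  for (a in c(-pi, -1, 0.5, pi)) {
    kern <- function(c) exp(1i * a * (1 - c^2))
    lam <- zonal_kernel_coefficients(kern, 24L)
    cs <- seq(-1, 1, length.out = 64L)
    rec <- rep(0 + 0i, 64L)
    ls <- seq(0L, 24L, by = 2L)
    for (i in seq_along(ls)) {
      # reconstruction: sum_l (2l+1)/(4pi) lambda_l P_l(c)
      rec <- rec + (2 * ls[i] + 1) / (4 * pi) * lam[i] *
        msai:::legendre_poly(ls[i], cs)
    }
    expect_lt(max(Mod(rec - kern(cs))), 1e-8)
  }
})

test_that("zonal coefficients reject non-finite kernels", {
  expect_error(zonal_kernel_coefficients(function(c) 1 / (c - c), 4L),
               "non-finite")
})

test_that("Funk-Hecke convolution agrees with direct grid quadrature", {
  g <- test_grid()
  t0 <- 0.0045
  t <- 0.0405
  worst <- 0
  for (s in 1:25) {
    o <- random_odf(100 + s)
    b0 <- random_unit(200 + s)
    omega <- stats::runif(1, -pi, pi) / (t - t0)
    kern <- function(c) exp(1i * omega * (t - t0) * (1 - c^2))
    lam <- zonal_kernel_coefficients(kern, 8L)
    sh_val <- funk_hecke_convolve(o, lam, b0)
    quad_val <- sum(g$weights * kern(as.vector(g$directions %*% b0)) *
                    odf_density(o, g$directions))
    worst <- max(worst, Mod(sh_val - quad_val))
  }
  expect_lt(worst, 1e-6)
})

test_that("convolution of the uniform ODF is rotationally invariant", {
  lam <- zonal_kernel_coefficients(function(c) exp(1i * (1 - c^2)), 8L)
  u <- uniform_odf()
  vals <- vapply(1:6, function(s) funk_hecke_convolve(u, lam, random_unit(s)),
                 complex(1))
  expect_lt(max(Mod(vals - vals[1L])), 1e-12)
  # and equals the kernel's spherical mean (order-0 projection / 4 pi)
  expect_lt(Mod(vals[1L] - lam[1L] / (4 * pi)), 1e-12)
})

test_that("convolution rejects kernels with too few orders", {
  lam <- zonal_kernel_coefficients(function(c) 1 - c^2, 4L)
  expect_error(funk_hecke_convolve(random_odf(3), lam, c(0, 0, 1)),
               "fewer orders")
})
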