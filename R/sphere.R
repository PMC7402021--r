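#' Number of real even-order spherical-harmonic coefficients
#'
#' `sum(2l + 1)` over even orders `l <= max_order`; 45 for order 8.
#'
#' @param max_order Even non-negative integer.
#' @return Integer coefficient count.
#' @export
sh_n_coef <- function(max_order) {
  ls <- seq(0L, max_order, by = 2L)
  sum(2L * ls + 1L)
}

# Even orders present in a basis of max_order
sh_orders <- function(max_order) seq(0L, max_order, by = 2L)

# Per-coefficient order labels, in basis ordering (orders ascending, m = -l..l)
sh_order_index <- function(max_order) {
  rep(sh_orders(max_order), times = 2L * sh_orders(max_order) + 1L)
}

#' Antipodally symmetric quadrature grid on the unit sphere
#'
#' Constructs `2 * n_half` unit directions arranged in exact antipodal pairs.
#' The hemisphere point set is a deterministic spherical Fibonacci lattice
#' (golden-angle spiral in azimuth, uniform spacing in height) which is then
#' mirrored through the origin.  Quadrature weights start from the uniform
#' value `4 * pi / (2 * n_half)` and receive a minimal-norm correction so that
#' all even-order real spherical harmonics up to order 16 integrate exactly;
#' products of two order-8 band-limited functions are therefore integrated to
#' machine precision.  Antipodal partners share the same weight.
#'
#' @param n_half Number of hemisphere directions (at least 4); the grid has
#'   `2 * n_half` directions in total.
#' @param exact_order Highest even spherical-harmonic order integrated
#'   exactly by the corrected weights (reduced automatically when `n_half` is
#'   too small to support it, or when the correction would drive a weight
#'   non-positive).
#' @return An object of class `sphere_grid`: a list with `directions`
#'   (numeric matrix, `2 * n_half` rows of unit 3-vectors), `weights`
#'   (positive, summing to `4 * pi`) and `n_half`.
#' @examples
#' g <- make_antipodal_grid(250)
#' sum(g$weights)            # 4 * pi
#' @export
make_antipodal_grid <- function(n_half, exact_order = 16L) {
  if (!is.numeric(n_half) || length(n_half) != 1L || n_half < 4 ||
      n_half != round(n_half)) {
    stop("'n_half' must be a single integer >= 4", call. = FALSE)
  }
  n_half <- as.integer(n_half)
  j <- seq_len(n_half) - 0.5
  z <- j / n_half                       # heights in (0, 1): open upper hemisphere
  golden_angle <- pi * (3 - sqrt(5))
  phi <- golden_angle * (seq_len(n_half) - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  hemi <- cbind(r * cos(phi), r * sin(phi), z)

  # largest supported even exactness order given the point budget
  ord <- as.integer(exact_order)
  while (ord > 0L && sh_n_coef(ord) > n_half) ord <- ord - 2L

  w_half <- rep(4 * pi / (2 * n_half), n_half)
  while (ord >= 0L) {
    if (ord == 0L) {
      w_try <- rep(4 * pi / (2 * n_half), n_half)
      break
    }
    B <- real_sh_basis(hemi, ord)
    # full-sphere integral of an even SH via mirrored pairs: 2 * t(B) %*% w
    target <- c(2 * sqrt(pi), rep(0, ncol(B) - 1L))
    resid <- target - 2 * as.vector(crossprod(B, w_half))
    # minimal-norm correction for the constraint 2 t(B) w = target
    corr <- as.vector(B %*% solve(crossprod(B), resid)) / 2
    w_try <- w_half + corr
    if (all(w_try > 0)) break
    ord <- ord - 2L
  }
  structure(list(
    directions = rbind(hemi, -hemi),
    weights    = rep(w_try, 2L),
    n_half     = n_half
  ), class = "sphere_grid")
}

#' @export
print.sphere_grid <- function(x, ...) {
  cat(sprintf("sphere_grid: %d directions (%d antipodal pairs), weight sum %.6f\n",
              2L * x$n_half, x$n_half, sum(x$weights)))
  invisible(x)
}

#' Real even-order spherical-harmonic basis
#'
#' Evaluates the real, orthonormal spherical harmonics of even order
#' `0, 2, ..., max_order` at a set of unit directions.  Coefficient ordering
#' is orders ascending with degrees `m = -l, ..., l` within each order; the
#' `m < 0` entries carry `sin(|m| * phi)`, `m > 0` entries `cos(m * phi)`
#' (both scaled by `sqrt(2)`), with associated Legendre functions including
#' the Condon-Shortley phase.  This ordering and sign convention is used by
#' every spherical-harmonic coefficient vector and 4D volume in the package.
#'
#' @param directions Numeric matrix with unit 3-vectors in rows (a single
#'   vector is accepted).
#' @param max_order Even integer, at most 16.
#' @return Numeric matrix, `nrow(directions)` by `sh_n_coef(max_order)`.
#' @examples
#' B <- real_sh_basis(diag(3), 8)
#' dim(B)          # 3 x 45
#' B[, 1]          # constant 1 / (2 sqrt(pi))
#' @export
real_sh_basis <- function(directions, max_order) {
  if (length(max_order) != 1L || max_order %% 2 != 0 || max_order < 0 ||
      max_order > 16) {
    stop("'max_order' must be a single even integer in 0..16", call. = FALSE)
  }
  if (is.null(dim(directions))) directions <- matrix(directions, nrow = 1L)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-8)) {
    stop("'directions' must be unit vectors", call. = FALSE)
  }
  ct <- pmin(1, pmax(-1, directions[, 3]))
  phi <- atan2(directions[, 2], directions[, 1])
  n <- nrow(directions)
  out <- matrix(0, n, sh_n_coef(max_order))
  col <- 1L
  for (l in sh_orders(max_order)) {
    P <- pracma::legendre(l, ct)        # (l+1) x n, m = 0..l, Condon-Shortley
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1L)
    for (m in seq(-l, l)) {
      am <- abs(m)
      nrm_lm <- sqrt((2 * l + 1) / (4 * pi) *
                     exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      v <- if (m == 0L) {
        nrm_lm * P[1L, ]
      } else if (m > 0L) {
        sqrt(2) * nrm_lm * P[am + 1L, ] * cos(m * phi)
      } else {
        sqrt(2) * nrm_lm * P[am + 1L, ] * sin(am * phi)
      }
      out[, col] <- v
      col <- col + 1L
    }
  }
  out
}

#' Legendre coefficients of a zonal kernel for Funk-Hecke convolution
#'
#' Expands a zonal kernel `f(cos theta)` in Legendre polynomials of even
#' order, scaled so that spherical convolution against a unit-mass
#' orientation distribution reproduces the integral
#' `int_{S^2} f(<b0, u>) p(u) du` via the Funk-Hecke theorem: the order-l
#' coefficient is `lambda_l = 2 * pi * int_{-1}^{1} f(c) P_l(c) dc`,
#' computed by fixed-order Gauss-Legendre quadrature.
#'
#' @param kernel Function of the cosine of the polar angle, returning real or
#'   complex values; must be vectorised or vectorisable over its argument.
#' @param max_order Even integer: highest Legendre order returned.
#' @param n_nodes Number of Gauss-Legendre nodes (default `2 * max_order + 16`,
#'   ample for polynomial-times-smooth-oscillatory kernels with phase
#'   excursions up to about pi).
#' @return Complex vector of length `max_order / 2 + 1`, the coefficients for
#'   orders `0, 2, ..., max_order`.
#' @examples
#' lam <- zonal_kernel_coefficients(function(c) 1 - c^2, 8)
#' Re(lam[1:2])   # 8 pi / 3 and -8 pi / 15; higher orders vanish
#' @export
zonal_kernel_coefficients <- function(kernel, max_order,
                                      n_nodes = 2 * max_order + 16) {
  if (length(max_order) != 1L || max_order %% 2 != 0 || max_order < 0) {
    stop("'max_order' must be a single even non-negative integer", call. = FALSE)
  }
  gl <- pracma::gaussLegendre(n_nodes, -1, 1)
  fv <- kernel(gl$x)
  if (length(fv) != length(gl$x)) fv <- vapply(gl$x, kernel, complex(1))
  if (any(!is.finite(fv))) {
    stop("kernel returned non-finite values", call. = FALSE)
  }
  orders <- sh_orders(max_order)
  vapply(orders, function(l) {
    Pl <- legendre_poly(l, gl$x)
    2 * pi * sum(gl$w * fv * Pl)
  }, complex(1))
}

# Legendre polynomial P_l by three-term recurrence, vectorised in x
legendre_poly <- function(l, x) {
  if (l == 0L) return(rep(1, length(x)))
  if (l == 1L) return(x)
  pm2 <- rep(1, length(x)); pm1 <- x
  for (k in 2:l) {
    p <- ((2 * k - 1) * x * pm1 - (k - 1) * pm2) / k
    pm2 <- pm1; pm1 <- p
  }
  pm1
}

#' Funk-Hecke zonal convolution of an ODF
#'
#' Evaluates the rotationally aligned spherical convolution
#' `int_{S^2} f(<b0, u>) p(u) du` at field direction `b0` from the ODF's
#' spherical-harmonic coefficients and the kernel's Legendre coefficients
#' (see [zonal_kernel_coefficients()]).  By the Funk-Hecke theorem the
#' convolution is diagonal per order: each SH coefficient is scaled by its
#' order's kernel coefficient and the result re-evaluated at `b0`.
#'
#' @param odf An [odf] object.
#' @param kernel_coeffs Complex per-order coefficients covering at least the
#'   ODF's orders.
#' @param b0 Unit 3-vector.
#' @return A single complex value.
#' @export
funk_hecke_convolve <- function(odf, kernel_coeffs, b0) {
  stopifnot(inherits(odf, "odf"))
  n_ord <- length(sh_orders(odf$max_order))
  if (length(kernel_coeffs) < n_ord) {
    stop("kernel coefficients cover fewer orders than the ODF", call. = FALSE)
  }
  b0 <- check_unit(b0)
  y <- real_sh_basis(b0, odf$max_order)[1L, ]
  lam_per_coef <- kernel_coeffs[match(sh_order_index(odf$max_order),
                                      sh_orders(odf$max_order))]
  sum(lam_per_coef * odf$sh * y)
}

# validate/normalize a unit 3-vector
check_unit <- function(v, tol = 1e-6) {
  if (length(v) != 3L || !is.numeric(v)) {
    stop("expected a numeric 3-vector", call. = FALSE)
  }
  n <- sqrt(sum(v^2))
  if (abs(n - 1) > tol) stop("vector is not unit-norm", call. = FALSE)
  v / n
}
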