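#' Microscopic frequency shift of a single microdomain
#'
#' Effective frequency shift `omega_A * sin(theta)^2` of one tissue
#' microdomain (for example a myelinated axon segment) whose axis makes the
#' angle `theta` with the magnetic field direction.  A microdomain parallel
#' to the field contributes no shift; one perpendicular to it contributes
#' the full microscopic frequency shift `omega_A`.
#'
#' @param omega_A Microscopic frequency shift (rad/s) of a perpendicular
#'   microdomain, relative to the reference echo.
#' @param theta Angle(s) in radians between the microdomain axis and the
#'   field direction.
#' @return Frequency shift(s) in rad/s.
#' @export
micro_frequency_shift <- function(omega_A, theta) {
  omega_A * sin(theta)^2
}

#' Microscopic gradient-echo signal component
#'
#' Unit-modulus complex phase factor accumulated by a single microdomain
#' between the reference time `t0` and echo time `t`:
#' `exp(i * omega_A * sin(theta)^2 * (t - t0))`.
#'
#' @inheritParams micro_frequency_shift
#' @param t Echo time in seconds.
#' @param t0 Reference echo time in seconds (`t >= t0`).
#' @return Complex value(s) of modulus 1.
#' @export
micro_signal_shift <- function(omega_A, theta, t, t0) {
  stopifnot(all(t >= t0))
  exp(1i * micro_frequency_shift(omega_A, theta) * (t - t0))
}

#' Voxel-scale ensemble signal of a microdomain population
#'
#' The macroscopic gradient-echo signal shift of an orientation-dispersed
#' microdomain population,
#' `deltaE = int_{S^2} exp(i * omega_A * (1 - <b0, u>^2) * (t - t0)) p(u) du`,
#' where `p` is the orientation distribution.  Two evaluation routes are
#' provided: `"quadrature"` sums the integrand over an antipodal sphere grid
#' (weights carry the surface measure, and `p` is a true density with unit
#' mass), while `"sh"` uses the Funk-Hecke theorem, expanding the zonal
#' kernel in Legendre polynomials and contracting against the ODF's
#' spherical-harmonic coefficients.  Both agree to high precision for
#' band-limited ODFs; the `"sh"` route needs no grid and is the fitting
#' default.  The modulus of the result never exceeds 1; a dispersed
#' population attenuates it, but only the phase is used downstream.
#'
#' @param odf An [odf] object.
#' @param omega_A Microscopic frequency shift in rad/s.
#' @param b0 Unit 3-vector: magnetic field direction.
#' @param t,t0 Echo and reference times in seconds (`t >= t0`).
#' @param grid A [make_antipodal_grid()] grid (required for
#'   `method = "quadrature"`).
#' @param method `"sh"` (default) or `"quadrature"`.
#' @param n_nodes Gauss-Legendre node count for the `"sh"` kernel expansion.
#' @return A single complex value with `Mod(.) <= 1`.
#' @export
ensemble_signal <- function(odf, omega_A, b0, t, t0, grid = NULL,
                            method = c("sh", "quadrature"), n_nodes = 64L) {
  method <- match.arg(method)
  stopifnot(inherits(odf, "odf"), t >= t0)
  b0 <- check_unit(b0)
  a <- omega_A * (t - t0)
  if (method == "quadrature") {
    if (is.null(grid)) grid <- make_antipodal_grid(250L)
    stopifnot(inherits(grid, "sphere_grid"))
    p <- odf_density(odf, grid$directions)
    c2 <- as.vector(grid$directions %*% b0)^2
    sum(grid$weights * exp(1i * a * (1 - c2)) * p)
  } else {
    lam <- zonal_kernel_coefficients(function(c) exp(1i * a * (1 - c^2)),
                                     odf$max_order, n_nodes = n_nodes)
    funk_hecke_convolve(odf, lam, b0)
  }
}

# Gauss-Legendre node/Legendre-polynomial table shared by the profile
# evaluations; 64 nodes resolve the kernel exp(i a (1 - c^2)) for |a| up to
# several pi at order 8.
gl_kernel_cache <- function(max_order, n_nodes = 64L) {
  gl <- pracma::gaussLegendre(n_nodes, -1, 1)
  ls <- sh_orders(max_order)
  P <- vapply(ls, function(l) gl$w * legendre_poly(l, gl$x), numeric(n_nodes))
  list(one_minus_c2 = 1 - gl$x^2, P = P)
}

# Per-order contraction of an ODF's SH coefficients with the basis at each
# field direction: n_b0 x n_orders matrix, constant across omega and echoes.
odf_b0_projection <- function(odf, b0_mat) {
  if (is.null(dim(b0_mat))) b0_mat <- matrix(b0_mat, nrow = 1L)
  ls <- sh_orders(odf$max_order)
  Y <- real_sh_basis(b0_mat, odf$max_order)
  ordidx <- sh_order_index(odf$max_order)
  A <- vapply(ls, function(l) {
    sel <- ordidx == l
    as.vector(Y[, sel, drop = FALSE] %*% odf$sh[sel])
  }, numeric(nrow(b0_mat)))
  if (is.null(dim(A))) A <- matrix(A, nrow = 1L)
  A
}

# Ensemble phasor profile from precomputed projections:
# length(omega) x nrow(A) complex matrix.
profile_from_projection <- function(A, omega, tau, cache) {
  E <- exp(1i * tau * outer(omega, cache$one_minus_c2))
  lambda <- 2 * pi * (E %*% cache$P)            # n_omega x n_orders
  lambda %*% t(A)
}

# Vectorised ensemble phasor over a vector of omega_A values, shared
# odf/b0 set: returns length(omega) x nrow(b0_mat) complex matrix.
ensemble_signal_profile <- function(odf, omega, b0_mat, t, t0, n_nodes = 64L) {
  cache <- gl_kernel_cache(odf$max_order, n_nodes)
  A <- odf_b0_projection(odf, b0_mat)
  profile_from_projection(A, omega, t - t0, cache)
}

#' Tabulated microscopic frequency shift time course
#'
#' Ground-truth or fitted values of the microscopic frequency shift at a
#' set of echo times, relative to a reference echo.  Used by the phantom
#' generator to carry per-tissue truth curves; linear interpolation between
#' the tabulated echoes is provided by [curve_function()].
#'
#' @param echo_times_ms Strictly increasing echo times in milliseconds, all
#'   after the reference time.
#' @param omega_A Microscopic frequency shift in rad/s at each echo.
#' @param reference_time_ms Reference echo time in milliseconds.
#' @return An object of class `micro_shift_curve`.
#' @export
micro_shift_curve <- function(echo_times_ms, omega_A, reference_time_ms = 0) {
  if (any(diff(echo_times_ms) <= 0)) {
    stop("echo times must be strictly increasing", call. = FALSE)
  }
  if (any(echo_times_ms <= reference_time_ms)) {
    stop("all echo times must lie after the reference time", call. = FALSE)
  }
  if (length(omega_A) != length(echo_times_ms) || any(!is.finite(omega_A))) {
    stop("'omega_A' must be finite, one value per echo", call. = FALSE)
  }
  structure(list(echo_times_ms = as.numeric(echo_times_ms),
                 omega_A = as.numeric(omega_A),
                 reference_time_ms = as.numeric(reference_time_ms)),
            class = "micro_shift_curve")
}

#' @rdname micro_shift_curve
#' @param curve A `micro_shift_curve` (or already a function of time in
#'   seconds, returned unchanged).
#' @return `curve_function()` returns a function mapping echo time in
#'   seconds to omega_A in rad/s (linear interpolation, constant beyond the
#'   tabulated range).
#' @export
curve_function <- function(curve) {
  if (is.function(curve)) return(curve)
  stopifnot(inherits(curve, "micro_shift_curve"))
  t_s <- curve$echo_times_ms / 1000
  om <- curve$omega_A
  function(t) stats::approx(t_s, om, xout = t, rule = 2L)$y
}
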