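#' Multi-orientation multi-echo acquisition scheme
#'
#' Describes a gradient-echo acquisition at one or more head positions:
#' the magnetic field direction per position (expressed in the head-fixed
#' image frame, so it changes when the head rotates), the echo-train timing,
#' the reference echo used for frequency differencing, and the echo
#' selection mask (by default only odd-numbered echoes are analysed, since
#' even echoes of a bipolar readout may differ in signal formation).
#'
#' @param b0_directions Numeric matrix of unit 3-vectors (rows), one per
#'   head position.  Vectors within `1e-6` of unit norm are renormalised.
#' @param echo_times_ms Strictly increasing echo times in milliseconds.
#' @param reference_time_ms Reference echo time; must equal the first
#'   selected echo time.
#' @param echo_mask Logical vector over echoes marking which are analysed.
#' @return An object of class `acquisition_scheme`.
#' @export
acquisition_scheme <- function(b0_directions, echo_times_ms,
                               reference_time_ms = NULL,
                               echo_mask = rep(TRUE, length(echo_times_ms))) {
  if (is.null(dim(b0_directions))) {
    b0_directions <- matrix(b0_directions, nrow = 1L)
  }
  b0_directions <- t(apply(b0_directions, 1L, check_unit, tol = 1e-4))
  if (any(diff(echo_times_ms) <= 0)) {
    stop("echo times must be strictly increasing", call. = FALSE)
  }
  if (length(echo_mask) != length(echo_times_ms)) {
    stop("echo mask length must match the number of echoes", call. = FALSE)
  }
  if (!any(echo_mask)) stop("no echoes selected", call. = FALSE)
  sel <- echo_times_ms[echo_mask]
  if (is.null(reference_time_ms)) reference_time_ms <- sel[1L]
  if (abs(reference_time_ms - sel[1L]) > 1e-9) {
    stop("reference time must equal the first selected echo time", call. = FALSE)
  }
  structure(list(
    b0_directions     = b0_directions,
    echo_times_ms     = as.numeric(echo_times_ms),
    reference_time_ms = as.numeric(reference_time_ms),
    echo_mask         = as.logical(echo_mask)
  ), class = "acquisition_scheme")
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat(sprintf("acquisition_scheme: %d position(s), %d echoes (%d selected), reference %.2f ms\n",
              nrow(x$b0_directions), length(x$echo_times_ms),
              sum(x$echo_mask), x$reference_time_ms))
  invisible(x)
}

#' Selected and fitted echo times of a scheme
#'
#' `scheme_selected_times_ms()` returns the echo times retained by the echo
#' mask; `scheme_fit_times_ms()` additionally drops the reference echo
#' (which carries no frequency-difference information about itself).
#'
#' @param scheme An [acquisition_scheme()].
#' @return Numeric vector of echo times in milliseconds.
#' @export
scheme_selected_times_ms <- function(scheme) {
  scheme$echo_times_ms[scheme$echo_mask]
}

#' @rdname scheme_selected_times_ms
#' @export
scheme_fit_times_ms <- function(scheme) {
  sel <- scheme_selected_times_ms(scheme)
  sel[sel > scheme$reference_time_ms + 1e-12]
}

#' Per-voxel frequency-shift measurements
#'
#' Container for frequency-difference measurements `y(b0, t)` in rad/s,
#' indexed voxel by head position by (fitted) echo.
#'
#' @param values Numeric array `n_voxels x n_positions x n_echoes` (the echo
#'   axis runs over `scheme_fit_times_ms(scheme)`).
#' @param scheme The [acquisition_scheme()] the data were acquired with.
#' @param noise_sigma Optional known noise level in rad/s.
#' @return An object of class `frequency_shift_data`.
#' @export
frequency_shift_data <- function(values, scheme, noise_sigma = NA_real_) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    stop("'values' must be a voxel x position x echo array", call. = FALSE)
  }
  n_pos <- nrow(scheme$b0_directions)
  n_k <- length(scheme_fit_times_ms(scheme))
  if (dim(values)[2L] != n_pos || dim(values)[3L] != n_k) {
    stop(sprintf("value dimensions %s do not match scheme (%d positions, %d fitted echoes)",
                 paste(dim(values), collapse = "x"), n_pos, n_k), call. = FALSE)
  }
  structure(list(values = values, scheme = scheme, noise_sigma = noise_sigma),
            class = "frequency_shift_data")
}

#' @export
print.frequency_shift_data <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("frequency_shift_data: %d voxels, %d position(s), %d echoes\n",
              d[1L], d[2L], d[3L]))
  invisible(x)
}

#' Frequency difference between two echoes
#'
#' Converts per-echo phase to a frequency shift relative to the reference
#' echo: `y = wrap(phase_t - phase_t0) / (t - t0)`.  The phases are
#' differenced on the complex circle (through the argument of the phasor
#' ratio), so any common multiple of `2 pi` in the inputs cancels and the
#' result is wrap-consistent.
#'
#' @param phase_t,phase_t0 Phase volumes in radians (any shape, matched).
#' @param t_ms,t0_ms Echo and reference times in milliseconds (`t > t0`).
#' @return Frequency shift in rad/s, same shape as the input.
#' @export
frequency_difference <- function(phase_t, phase_t0, t_ms, t0_ms) {
  if (t_ms <= t0_ms) stop("'t_ms' must exceed 't0_ms'", call. = FALSE)
  dphi <- Arg(exp(1i * (phase_t - phase_t0)))
  out <- dphi / ((t_ms - t0_ms) / 1000)
  if (!is.null(dim(phase_t))) dim(out) <- dim(phase_t)
  out
}

#' Remove slowly varying background fields from a frequency map
#'
#' Fits a 3D polynomial (least squares over the mask) to a frequency-shift
#' volume and subtracts it, removing residual large-scale field variation
#' such as the initial phase offset.  Because the constant term is part of
#' the background, the residual is determined only up to a spatially
#' constant offset per field direction and echo; that global constant is
#' recovered downstream by [estimate_offsets()].
#'
#' @param frequency_map 3D numeric array (rad/s).
#' @param mask Logical array of the same shape; the fit uses masked voxels
#'   only, the fitted surface is evaluated everywhere.
#' @param poly_order Polynomial order 0..4 (default 2).
#' @return List with `residual`, `background` (both full volumes) and
#'   `coefficients`.
#' @export
remove_background <- function(frequency_map, mask, poly_order = 2L) {
  if (!(poly_order %in% 0:4)) {
    stop("'poly_order' must be an integer in 0..4", call. = FALSE)
  }
  d <- dim(frequency_map)
  if (length(d) != 3L) stop("'frequency_map' must be a 3D array", call. = FALSE)
  mask <- array(as.logical(mask), dim = d)
  X <- poly3d_design(d, poly_order)
  if (sum(mask) < ncol(X)) {
    stop(sprintf("mask has %d voxels but the order-%d fit needs at least %d",
                 sum(mask), poly_order, ncol(X)), call. = FALSE)
  }
  fit <- stats::lm.fit(X[as.vector(mask), , drop = FALSE],
                       frequency_map[mask])
  bg <- array(as.vector(X %*% fit$coefficients), dim = d)
  list(residual = frequency_map - bg, background = bg,
       coefficients = fit$coefficients)
}

# monomial design on coordinates normalised to [-1, 1] per axis
poly3d_design <- function(dims, order) {
  axes <- lapply(dims, function(n) {
    if (n == 1L) 0 else seq(-1, 1, length.out = n)
  })
  gr <- expand.grid(x = axes[[1L]], y = axes[[2L]], z = axes[[3L]])
  cols <- list()
  for (i in 0:order) for (j in 0:(order - i)) for (k in 0:(order - i - j)) {
    cols[[length(cols) + 1L]] <- gr$x^i * gr$y^j * gr$z^k
  }
  do.call(cbind, cols)
}
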