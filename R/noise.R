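#' Noise amplification (g-factor) of the microscopic shift estimate
#'
#' Linearises the phase-metric fit around the estimate `omega_hat`: the
#' sensitivity of the model phasor to the microscopic frequency shift is
#' approximated per field direction by the central difference
#' `J_b0 = D(sgn deltaE(omega + eps), sgn deltaE(omega - eps)) / (2 eps)`,
#' and the amplification factor is `g = (J^T J)^{-1}`.  Large `g` marks
#' voxels where the acquired field directions carry little information about
#' the microscopic shift (fibers running parallel to every acquired B0);
#' appending a head orientation can only decrease the unnormalised `g`.
#' With `normalize = TRUE` the factor is additionally multiplied by the
#' number of positions, referencing it to plain signal averaging so that
#' acquisitions of different scan time become comparable.
#'
#' @param omega_hat Estimate of the microscopic frequency shift (rad/s).
#' @param odf The voxel's [odf].
#' @param b0_directions Matrix of unit field directions (rows).
#' @param t,t0 Echo and reference times in seconds.
#' @param epsilon Central-difference step (rad/s); default `1e-6` of the
#'   wrap-tracking interval width `2 pi / t`.
#' @param normalize Apply the scan-time correction (default `FALSE`).
#' @return List with `g` (possibly `Inf` for ill-posed voxels) and the
#'   per-direction gradient vector `J`.
#' @export
g_factor <- function(omega_hat, odf, b0_directions, t, t0,
                     epsilon = NULL, normalize = FALSE) {
  if (is.null(dim(b0_directions))) {
    b0_directions <- matrix(b0_directions, nrow = 1L)
  }
  if (is.null(epsilon)) epsilon <- 1e-6 * (2 * pi / t)
  stopifnot(epsilon > 0)
  dE <- ensemble_signal_profile(odf, c(omega_hat + epsilon, omega_hat - epsilon),
                                b0_directions, t, t0)
  m <- Mod(dE); m[m < 1e-300] <- 1
  s <- dE / m
  J <- phase_distance(s[1L, ], s[2L, ]) / (2 * epsilon)
  jtj <- sum(J^2)
  if (jtj < 1e-300) {
    warning("J^T J vanishes: noise amplification is unbounded", call. = FALSE)
    return(list(g = Inf, J = J))
  }
  g <- 1 / jtj
  if (normalize) g <- g * nrow(b0_directions)
  list(g = g, J = J)
}

#' Monte Carlo standard deviation of the microscopic shift estimate
#'
#' Empirical oracle for the linearised noise propagation: repeatedly
#' perturbs the model-implied frequency shifts with i.i.d. Gaussian noise of
#' level `sigma_y` (equal across field directions, matching the assumed
#' noise model), refits the voxel, and returns the standard deviation of
#' the estimates.  In the small-noise regime this should match the
#' linearised prediction `sqrt(g) * sigma_y * (t - t0)`.
#'
#' @param omega_true True microscopic frequency shift (rad/s).
#' @param odf The voxel's [odf].
#' @param b0_directions Matrix of unit field directions (rows).
#' @param t,t0 Echo and reference times in seconds.
#' @param sigma_y Noise level in rad/s; should satisfy
#'   `sigma_y * (t - t0) <= 0.1` rad so wrap events stay rare.
#' @param n_reps Number of replicates (at least 100).
#' @param seed RNG seed; results are reproducible.
#' @param n_grid Grid density of each fit.
#' @return Empirical standard deviation of the estimate (rad/s), with the
#'   replicate estimates attached as attribute `estimates`.
#' @export
monte_carlo_std <- function(omega_true, odf, b0_directions, t, t0,
                            sigma_y, n_reps, seed = 1L, n_grid = 721L) {
  if (n_reps < 100L) {
    stop("'n_reps' must be at least 100 for a stable standard deviation",
         call. = FALSE)
  }
  if (is.null(dim(b0_directions))) {
    b0_directions <- matrix(b0_directions, nrow = 1L)
  }
  tau <- t - t0
  dE <- ensemble_signal_profile(odf, omega_true, b0_directions, t, t0)[1L, ]
  y_clean <- Arg(dE) / tau
  half <- pi / t
  interval <- if (abs(omega_true) < 0.8 * half) {
    c(-half, half)
  } else {
    omega_true + c(-half, half)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  est <- vapply(seq_len(n_reps), function(r) {
    y <- y_clean + stats::rnorm(length(y_clean), 0, sigma_y)
    fit_voxel(y, odf, b0_directions, t, t0, interval, n_grid = n_grid)$omega
  }, numeric(1))
  out <- stats::sd(est)
  attr(out, "estimates") <- est
  out
}
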