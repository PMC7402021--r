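#' Phase distance between complex phasors
#'
#' The angular distance `D(z1, z2) = arccos(Re(sgn(z1)* x sgn(z2)))` between
#' the phases of two non-zero complex numbers, where `sgn(z) = z / |z|` and
#' the first argument is conjugated.  Symmetric, zero exactly when the
#' phases agree, and bounded by `pi`.
#'
#' @param z1,z2 Non-zero complex values (vectorised, recycled).
#' @return Angle(s) in `[0, pi]`.
#' @export
phase_distance <- function(z1, z2) {
  if (any(z1 == 0) || any(z2 == 0)) {
    stop("phase distance is undefined for zero input", call. = FALSE)
  }
  acos(pmin(1, pmax(-1, Re(Conj(z1 / Mod(z1)) * (z2 / Mod(z2))))))
}

#' Fit the microscopic frequency shift in one voxel at one echo
#'
#' Estimates `omega_A` by minimising the summed squared phase distance
#' between the measured frequency phasors `exp(i y (t - t0))` and the model
#' ensemble phasors `sgn(deltaE(omega_A))` over the acquired field
#' directions.  The objective is one-dimensional but may be multimodal under
#' phase wrapping, so the search is a dense deterministic grid scan over the
#' given interval followed by bounded local refinement; ties are broken
#' toward the smallest `|omega_A|`.
#'
#' @param y Measured frequency shifts in rad/s, one per head position.
#' @param odf The voxel's [odf].
#' @param b0_directions Matrix of unit field directions (rows), one per
#'   position.
#' @param t,t0 Echo and reference times in seconds.
#' @param interval Numeric length-2 search interval (rad/s).
#' @param n_grid Number of grid points of the scan (default 721).
#' @param offsets Optional per-position global frequency offsets (rad/s)
#'   subtracted from `y` before fitting.
#' @param refine Run bounded local refinement around the best grid point.
#' @param context Optional precomputed fitting context from
#'   [fit_context()]; saves repeated basis evaluations when the same voxel
#'   is fitted at several echoes or iterations.
#' @return List with `omega` (rad/s), `objective` (rad^2 at the optimum) and
#'   `flagged` (`TRUE` when the orientation weighting is below `1e-3` for
#'   every acquired direction, i.e. the voxel is essentially insensitive).
#' @export
fit_voxel <- function(y, odf, b0_directions, t, t0, interval,
                      n_grid = 721L, offsets = NULL, refine = TRUE,
                      context = NULL) {
  if (length(interval) != 2L || !all(is.finite(interval)) ||
      interval[2L] <= interval[1L]) {
    stop("'interval' must be a finite non-empty (lo, hi) pair", call. = FALSE)
  }
  if (is.null(context)) context <- fit_context(odf, b0_directions)
  stopifnot(length(y) == nrow(context$A))
  if (!is.null(offsets)) y <- y - offsets
  tau <- t - t0
  z_data <- exp(1i * y * tau)

  omega_grid <- seq(interval[1L], interval[2L], length.out = n_grid)
  dE <- profile_from_projection(context$A, omega_grid, tau, context$cache)
  # guard the sgn: deltaE can pass near zero for strongly dispersed ODFs
  m <- Mod(dE); m[m < 1e-300] <- 1
  cosd <- pmin(pmax(Re(sweep(dE / m, 2L, Conj(z_data), `*`)), -1), 1)
  obj <- rowSums(matrix(acos(cosd)^2, nrow = n_grid))
  best <- which(obj <= min(obj) + 1e-15)
  i0 <- best[which.min(abs(omega_grid[best]))]
  omega_hat <- omega_grid[i0]
  obj_hat <- obj[i0]

  if (refine && n_grid > 1L) {
    h <- omega_grid[2L] - omega_grid[1L]
    lo <- max(interval[1L], omega_hat - h)
    hi <- min(interval[2L], omega_hat + h)
    f <- function(w) {
      dE1 <- profile_from_projection(context$A, w, tau, context$cache)[1L, ]
      m1 <- Mod(dE1); m1[m1 < 1e-300] <- 1
      sum(acos(pmin(pmax(Re(Conj(z_data) * dE1 / m1), -1), 1))^2)
    }
    op <- stats::optimize(f, lower = lo, upper = hi, tol = 1e-10)
    if (op$objective < obj_hat) {
      omega_hat <- op$minimum
      obj_hat <- op$objective
    }
  }

  list(omega = omega_hat, objective = obj_hat, flagged = context$flagged)
}

#' Precomputed per-voxel fitting context
#'
#' Caches the quantities of the phase-metric objective that do not depend
#' on the candidate frequency shift: the per-order contraction of the ODF
#' with the spherical-harmonic basis at each field direction, the
#' Gauss-Legendre kernel table, and the insensitivity flag (orientation
#' weighting below `1e-3` at every acquired direction).
#'
#' @param odf The voxel's [odf].
#' @param b0_directions Matrix of unit field directions (rows).
#' @return A list consumed by [fit_voxel()] and [track_echo_train()].
#' @export
fit_context <- function(odf, b0_directions) {
  if (is.null(dim(b0_directions))) {
    b0_directions <- matrix(b0_directions, nrow = 1L)
  }
  w_all <- apply(b0_directions, 1L, function(b) orientation_weighting(odf, b))
  list(A = odf_b0_projection(odf, b0_directions),
       cache = gl_kernel_cache(odf$max_order),
       flagged = all(w_all < 1e-3))
}

#' Track the microscopic frequency shift across an echo train
#'
#' Fits `omega_A(t)` echo by echo in increasing time order.  Phase wrapping
#' makes late-echo fits ambiguous, so the search interval is adapted under
#' the assumption that the microscopic frequency shift evolves smoothly: the
#' first fitted echo searches an interval centred at 0 with half-width
#' `pi / t1`, and each subsequent echo `t_{k+1}` searches the interval
#' centred at the previous estimate with half-width `pi / t_{k+1}`.  By
#' default the half-width uses the absolute echo time; `interval_mode =
#' "relative"` uses the time since the reference echo instead (a wider,
#' more permissive variant for sensitivity analyses).
#'
#' @param y_train Matrix `n_positions x n_echoes` of frequency shifts
#'   (rad/s) at the fitted echoes (`scheme_fit_times_ms(scheme)`); a vector
#'   is accepted for a single position.
#' @param odf The voxel's [odf].
#' @param scheme An [acquisition_scheme()].
#' @param interval_mode `"absolute"` (default) or `"relative"` half-width
#'   denominator.
#' @param offsets Optional `n_positions x n_echoes` matrix of global
#'   frequency offsets subtracted from the data.
#' @param n_grid Grid density per echo fit.
#' @return An object of class `micro_shift_fit`: per-echo `omega` (rad/s),
#'   `residual`, `intervals` (2 x K), `flagged`, and `echo_times_s`.
#' @export
track_echo_train <- function(y_train, odf, scheme,
                             interval_mode = c("absolute", "relative"),
                             offsets = NULL, n_grid = 721L, context = NULL) {
  interval_mode <- match.arg(interval_mode)
  stopifnot(inherits(scheme, "acquisition_scheme"))
  tk_s <- scheme_fit_times_ms(scheme) / 1000
  t0_s <- scheme$reference_time_ms / 1000
  if (is.null(dim(y_train))) y_train <- matrix(y_train, nrow = 1L)
  n_pos <- nrow(scheme$b0_directions)
  K <- length(tk_s)
  if (!all(dim(y_train) == c(n_pos, K))) {
    stop(sprintf("'y_train' must be %d positions x %d echoes", n_pos, K),
         call. = FALSE)
  }
  if (is.null(offsets)) offsets <- matrix(0, n_pos, K)

  if (is.null(context)) context <- fit_context(odf, scheme$b0_directions)
  omega <- residual <- numeric(K)
  flagged <- logical(K)
  intervals <- matrix(NA_real_, 2L, K)
  center <- 0
  for (k in seq_len(K)) {
    denom <- if (interval_mode == "absolute") tk_s[k] else tk_s[k] - t0_s
    half <- pi / denom
    intervals[, k] <- center + c(-half, half)
    fit <- fit_voxel(y_train[, k], odf, scheme$b0_directions,
                     t = tk_s[k], t0 = t0_s, interval = intervals[, k],
                     offsets = offsets[, k], n_grid = n_grid,
                     context = context)
    omega[k] <- fit$omega
    residual[k] <- fit$objective
    flagged[k] <- fit$flagged
    center <- fit$omega
  }
  structure(list(omega = omega, residual = residual, intervals = intervals,
                 flagged = flagged, echo_times_s = tk_s,
                 reference_time_s = t0_s),
            class = "micro_shift_fit")
}

#' @export
print.micro_shift_fit <- function(x, ...) {
  cat("micro_shift_fit:\n")
  print(data.frame(echo_ms = x$echo_times_s * 1000,
                   omega_rad_s = x$omega,
                   omega_hz = x$omega / (2 * pi),
                   residual = x$residual))
  invisible(x)
}

#' Jointly estimate global frequency offsets and microscopic shifts
#'
#' After background-field removal the frequency-difference signal is known
#' only up to a spatially constant offset per field direction and echo.
#' This routine estimates those constants jointly with the voxelwise
#' microscopic frequency shift by alternating minimisation over a region of
#' interest: (i) holding the offsets fixed, every voxel is fitted by
#' [track_echo_train()]; (ii) holding the fits fixed, each offset is updated
#' towards the circular mean of that (position, echo)'s per-voxel phase
#' residuals, accepting the update only if it lowers the total squared
#' phase error given the current fits (so the total objective never
#' increases between iterations).  The alternating map contracts slowly
#' along the near-degenerate direction that trades a common offset against
#' voxelwise shifts, so every few sweeps the offset sequence is
#' extrapolated geometrically (Aitken); an extrapolation that fails to
#' lower the total error is rolled back.  At least two head orientations
#' are required; with one, the offsets and the shifts are not separable.
#'
#' @param data A [frequency_shift_data()] object.
#' @param odfs List of per-voxel [odf] objects (length `n_voxels`).
#' @param scheme Scheme override (defaults to the data's scheme).
#' @param roi Logical vector over voxels (default: all).
#' @param max_iter,tol Stop after `max_iter` sweeps or when the total error
#'   decreases by less than `tol` (rad^2).
#' @param n_grid Grid density for the per-voxel fits.
#' @param interval_mode Passed to [track_echo_train()].
#' @return List with `offsets` (`n_positions x n_echoes`, rad/s), `fits`
#'   (per-voxel `micro_shift_fit` for ROI voxels), `total_error` trajectory,
#'   and `converged`.
#' @export
estimate_offsets <- function(data, odfs, scheme = data$scheme, roi = NULL,
                             max_iter = 100L, tol = 1e-8, n_grid = 721L,
                             interval_mode = "absolute") {
  stopifnot(inherits(data, "frequency_shift_data"))
  n_pos <- nrow(scheme$b0_directions)
  if (n_pos < 2L) {
    stop("offset estimation requires at least 2 head orientations", call. = FALSE)
  }
  n_vox <- dim(data$values)[1L]
  if (length(odfs) != n_vox) {
    stop("'odfs' must provide one ODF per voxel", call. = FALSE)
  }
  if (is.null(roi)) roi <- rep(TRUE, n_vox)
  vox <- which(roi)
  if (length(vox) == 0L) stop("empty region of interest", call. = FALSE)

  tk_s <- scheme_fit_times_ms(scheme) / 1000
  t0_s <- scheme$reference_time_ms / 1000
  tau <- tk_s - t0_s
  K <- length(tk_s)
  offsets <- matrix(0, n_pos, K)
  trace <- numeric(0)
  converged <- FALSE
  fits <- vector("list", length(vox))

  contexts <- lapply(vox, function(v) fit_context(odfs[[v]], scheme$b0_directions))

  # one sweep of step (i): refit every ROI voxel at the given offsets
  fit_sweep <- function(off) {
    model_phasor <- array(0i, c(length(vox), n_pos, K))
    sweep_fits <- vector("list", length(vox))
    total <- 0
    for (vi in seq_along(vox)) {
      v <- vox[vi]
      ctx <- contexts[[vi]]
      fit <- track_echo_train(matrix(data$values[v, , ], nrow = n_pos),
                              odfs[[v]], scheme, offsets = off,
                              n_grid = n_grid, interval_mode = interval_mode,
                              context = ctx)
      sweep_fits[[vi]] <- fit
      total <- total + sum(fit$residual)
      for (k in seq_len(K)) {
        dE <- profile_from_projection(ctx$A, fit$omega[k], tau[k], ctx$cache)[1L, ]
        m <- Mod(dE); m[m < 1e-300] <- 1
        model_phasor[vi, , k] <- dE / m
      }
    }
    list(total = total, fits = sweep_fits, model_phasor = model_phasor)
  }

  # step (ii): circular-mean offset update, guarded so the total squared
  # phase error at fixed fits cannot increase
  update_offsets <- function(off, model_phasor) {
    for (p in seq_len(n_pos)) {
      for (k in seq_len(K)) {
        z_raw <- exp(1i * data$values[vox, p, k] * tau[k])
        psi <- Arg(z_raw * Conj(model_phasor[, p, k]))
        cand_phase <- Arg(mean(exp(1i * psi)))
        err <- function(ph) sum(Arg(exp(1i * (psi - ph)))^2)
        if (err(cand_phase) < err(off[p, k] * tau[k])) {
          off[p, k] <- cand_phase / tau[k]
        }
      }
    }
    off
  }

  off_hist <- list()
  prev_state <- NULL
  extrapolated <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    state <- fit_sweep(offsets)
    if (extrapolated && length(trace) &&
        state$total > trace[length(trace)]) {
      # extrapolation overshot: roll back and resume the plain iteration
      offsets <- prev_state$offsets
      state <- prev_state$state
      off_hist <- list()
      extrapolated <- FALSE
    }
    fits <- state$fits
    trace <- c(trace, state$total)
    if (length(trace) > 1L &&
        trace[length(trace) - 1L] - state$total < tol) {
      converged <- TRUE
      break
    }
    prev_state <- list(offsets = offsets, state = state)
    offsets <- update_offsets(offsets, state$model_phasor)
    off_hist <- c(off_hist, list(offsets))
    extrapolated <- FALSE
    nh <- length(off_hist)
    if (nh >= 3L) {
      d1 <- off_hist[[nh]] - off_hist[[nh - 1L]]
      d2 <- off_hist[[nh - 1L]] - off_hist[[nh - 2L]]
      r <- sum(d1 * d2) / max(sum(d2 * d2), 1e-300)
      if (r > 0.1 && r < 0.999) {
        offsets <- off_hist[[nh]] + d1 * r / (1 - r)
        off_hist <- list()
        extrapolated <- TRUE
      }
    }
  }
  list(offsets = offsets, fits = fits, total_error = trace,
       converged = converged, roi_voxels = vox)
}
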