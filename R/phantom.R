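#' Default multi-orientation gradient-echo scheme
#'
#' The reference acquisition geometry: a train of 11 gradient echoes with
#' first echo time 4.5 ms and inter-echo spacing 4.5 ms, odd-numbered echoes
#' selected (reference at 4.5 ms), measured at up to three head orientations
#' rotated about the left-right axis.  In the head frame the field direction
#' is the superior axis at standard position and tilts by +/- 29.9 degrees
#' for the upward / downward positions, so the extreme positions subtend
#' 59.8 degrees.
#'
#' @param n_positions 1 (standard), 2 (downward, upward) or 3 (downward,
#'   standard, upward).
#' @return An [acquisition_scheme()].
#' @export
default_scheme <- function(n_positions = 3L) {
  if (!(n_positions %in% 1:3)) {
    stop("'n_positions' must be 1, 2 or 3", call. = FALSE)
  }
  tilt <- 29.9 * pi / 180
  angles <- switch(n_positions, 0, c(-tilt, tilt), c(-tilt, 0, tilt))
  b0 <- t(vapply(angles, function(a) c(0, -sin(a), cos(a)), numeric(3)))
  echoes <- 4.5 * seq_len(11L)
  mask <- seq_len(11L) %% 2L == 1L
  acquisition_scheme(b0, echoes, reference_time_ms = 4.5, echo_mask = mask)
}

# default ground-truth time course: omega_A / (2 pi) ramps linearly from 0
# at the reference echo to hz_last at the final selected echo (illustrative
# white-matter-like behaviour: the shift grows more negative with echo time)
ramp_curve <- function(hz_last, t_last_s, t0_s) {
  force(hz_last); force(t_last_s); force(t0_s)
  function(t_s) 2 * pi * hz_last * (t_s - t0_s) / (t_last_s - t0_s)
}

#' Default phantom tissue classes
#'
#' Five tissue archetypes mirroring the orientational contrasts of brain
#' white and gray matter: a coherent fiber parallel to the standard field
#' direction, a coherent perpendicular fiber, a dispersed fiber (Watson
#' concentration 5), a 50/50 orthogonal two-fiber crossing, and isotropic
#' tissue.  White-matter-like classes share a microscopic frequency shift
#' ramping to `wm_hz_last` Hz at the last selected echo; the isotropic class
#' has none.  Coherent classes intentionally exceed the order-8 band limit
#' (their low-order moments remain exact).
#'
#' @param scheme Scheme providing the echo timing for the truth curves.
#' @param wm_hz_last Microscopic frequency shift (Hz) of the white-matter
#'   classes at the last selected echo (default -3).
#' @param kappa_coherent Watson concentration of the coherent classes.
#' @return Named list of classes, each with `odf` and `curve` (a function of
#'   echo time in seconds returning rad/s).
#' @export
default_tissue_classes <- function(scheme = default_scheme(3L),
                                   wm_hz_last = -3, kappa_coherent = 100) {
  t0_s <- scheme$reference_time_ms / 1000
  t_last_s <- max(scheme_fit_times_ms(scheme)) / 1000
  wm <- ramp_curve(wm_hz_last, t_last_s, t0_s)
  iso <- function(t_s) rep(0, length(t_s))
  sq <- 1 / sqrt(2)
  suppressWarnings(list(
    parallel      = list(odf = watson_odf(c(0, 0, 1), kappa_coherent), curve = wm),
    perpendicular = list(odf = watson_odf(c(1, 0, 0), kappa_coherent), curve = wm),
    dispersed     = list(odf = watson_odf(c(0, sq, sq), 5), curve = wm),
    crossing      = list(odf = mixture_odf(list(
                           list(0.5, watson_odf(c(1, 0, 0), 20)),
                           list(0.5, watson_odf(c(0, 0, 1), 20)))),
                         curve = wm),
    isotropic     = list(odf = uniform_odf(), curve = iso)
  ))
}

#' Build a synthetic phantom with known ground truth
#'
#' Assembles a voxel grid whose voxels carry known orientation
#' distributions and microscopic frequency shift time courses, plus the
#' per-(position, echo) global offsets and smooth background fields to be
#' injected at simulation time.  Voxels are assigned to tissue classes in
#' contiguous blocks of the flattened grid, so the phantom is fully
#' deterministic given its configuration; the seed governs only the random
#' background-field coefficients.
#'
#' @param grid_shape Integer voxel counts per axis (default `c(10, 10, 5)`).
#' @param scheme The acquisition the phantom will be simulated under.
#' @param classes Tissue classes as from [default_tissue_classes()].
#' @param offsets_true Optional `n_positions x n_echoes` matrix of true
#'   global frequency offsets in rad/s (default zero).
#' @param background_scale Amplitude (rad/s) of the random order-2
#'   polynomial background fields.
#' @param seed RNG seed for the background coefficients.
#' @return An object of class `phantom`.
#' @export
build_phantom <- function(grid_shape = c(10L, 10L, 5L),
                          scheme = default_scheme(3L),
                          classes = default_tissue_classes(scheme),
                          offsets_true = NULL, background_scale = 0.5,
                          seed = 1L) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  if (is.null(names(classes)) || any(names(classes) == "")) {
    stop("tissue classes must be named", call. = FALSE)
  }
  for (cl in classes) {
    if (!inherits(cl$odf, "odf") ||
        !(is.function(cl$curve) || inherits(cl$curve, "micro_shift_curve"))) {
      stop("each tissue class needs an 'odf' and a 'curve' (function or micro_shift_curve)",
           call. = FALSE)
    }
  }
  classes <- lapply(classes, function(cl) {
    cl$curve <- curve_function(cl$curve)
    cl
  })
  n_vox <- prod(grid_shape)
  n_cls <- length(classes)
  cls_idx <- rep(seq_len(n_cls), each = ceiling(n_vox / n_cls))[seq_len(n_vox)]
  labels <- array(names(classes)[cls_idx], dim = grid_shape)

  n_pos <- nrow(scheme$b0_directions)
  K <- length(scheme_fit_times_ms(scheme))
  if (is.null(offsets_true)) offsets_true <- matrix(0, n_pos, K)
  stopifnot(all(dim(offsets_true) == c(n_pos, K)))

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  n_terms <- ncol(poly3d_design(c(2L, 2L, 2L), 2L))
  background_coeffs <- array(stats::rnorm(n_pos * K * n_terms, 0,
                                          background_scale / sqrt(n_terms)),
                             dim = c(n_pos, K, n_terms))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  structure(list(
    grid_shape = as.integer(grid_shape),
    tissue_labels = labels,
    class_index = cls_idx,
    classes = classes,
    scheme = scheme,
    offsets_true = offsets_true,
    background_coeffs = background_coeffs,
    seed = as.integer(seed)
  ), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %s grid, %d voxels, classes: %s\n",
              paste(x$grid_shape, collapse = "x"), prod(x$grid_shape),
              paste(names(x$classes), collapse = ", ")))
  invisible(x)
}

#' Per-voxel ODF list of a phantom
#'
#' @param phantom A [build_phantom()] object.
#' @return List of [odf] objects, one per voxel of the flattened grid.
#' @export
phantom_odfs <- function(phantom) {
  lapply(phantom$class_index, function(i) phantom$classes[[i]]$odf)
}

#' Ground-truth microscopic shift per tissue class and echo
#'
#' @param phantom A [build_phantom()] object.
#' @return Matrix `n_classes x n_echoes` of omega_A in rad/s at the fitted
#'   echo times.
#' @export
phantom_truth <- function(phantom) {
  tk_s <- scheme_fit_times_ms(phantom$scheme) / 1000
  out <- t(vapply(phantom$classes, function(cl) cl$curve(tk_s),
                  numeric(length(tk_s))))
  dimnames(out) <- list(names(phantom$classes),
                        format(tk_s * 1000, trim = TRUE))
  out
}

#' Simulate frequency-shift measurements from a phantom
#'
#' Forward-simulates the frequency-difference signal of every voxel:
#' `y = Arg(deltaE) / (t - t0)` from the ensemble model at the class's true
#' microscopic shift, plus the phantom's global offsets, plus (optionally) a
#' smooth polynomial background field, plus i.i.d. Gaussian noise of level
#' `sigma_y` applied to the frequency measurements (equal across field
#' directions and echoes).  Bit-reproducible for a fixed seed.
#'
#' @param phantom A [build_phantom()] object.
#' @param scheme Scheme override (defaults to the phantom's).
#' @param sigma_y Noise level in rad/s (0 for noise-free).
#' @param with_background Add the phantom's polynomial background fields.
#' @param seed RNG seed for the noise.
#' @return A [frequency_shift_data()] object with attribute `grid_shape`.
#' @export
simulate_measurements <- function(phantom, scheme = phantom$scheme,
                                  sigma_y = 0, with_background = FALSE,
                                  seed = 1L) {
  stopifnot(inherits(phantom, "phantom"))
  if (sigma_y < 0) stop("'sigma_y' must be non-negative", call. = FALSE)
  tk_s <- scheme_fit_times_ms(scheme) / 1000
  t0_s <- scheme$reference_time_ms / 1000
  tau <- tk_s - t0_s
  n_pos <- nrow(scheme$b0_directions)
  K <- length(tk_s)
  n_vox <- prod(phantom$grid_shape)

  # model-implied clean frequencies per class
  y_class <- array(0, c(length(phantom$classes), n_pos, K))
  for (ci in seq_along(phantom$classes)) {
    cl <- phantom$classes[[ci]]
    om <- cl$curve(tk_s)
    for (k in seq_len(K)) {
      dE <- ensemble_signal_profile(cl$odf, om[k], scheme$b0_directions,
                                    tk_s[k], t0_s)[1L, ]
      y_class[ci, , k] <- Arg(dE) / tau[k]
    }
  }
  values <- y_class[phantom$class_index, , , drop = FALSE]
  values <- values + rep(phantom$offsets_true, each = n_vox)

  if (with_background) {
    X <- poly3d_design(phantom$grid_shape, 2L)
    for (p in seq_len(n_pos)) for (k in seq_len(K)) {
      values[, p, k] <- values[, p, k] +
        as.vector(X %*% phantom$background_coeffs[p, k, ])
    }
  }
  if (sigma_y > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(seed)
    values <- values + array(stats::rnorm(length(values), 0, sigma_y),
                             dim = dim(values))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  out <- frequency_shift_data(values, scheme, noise_sigma = sigma_y)
  attr(out, "grid_shape") <- phantom$grid_shape
  out
}
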