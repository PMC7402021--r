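test_that("phase distance behaves like an angle metric", {
  for (z in c(1 + 2i, -3i, 0.5 - 0.5i)) {
    # acos near 1 amplifies rounding to ~sqrt(eps)
    expect_lt(phase_distance(z, z), 1e-7)
  }
  expect_equal(phase_distance(1 + 0i, -1 + 0i), pi)
  expect_equal(phase_distance(1 + 0i, 1i), pi / 2)
  expect_equal(phase_distance(2i, 1 + 0i), phase_distance(1 + 0i, 2i))
  expect_error(phase_distance(0 + 0i, 1 + 0i), "zero")
})

test_that("fit_voxel recovers model-consistent shifts", {
  t <- 0.0405; t0 <- 0.0045; tau <- t - t0
  # near-delta perpendicular fiber, single field direction
  o <- delta_odf(c(1, 0, 0))
  b0 <- matrix(c(0, 0, 1), 1)
  for (om_true in c(-40, -5, 12.5)) {
    y <- Arg(msai:::ensemble_signal_profile(o, om_true, b0, t, t0)[1L, ]) / tau
    f <- fit_voxel(y, o, b0, t, t0, interval = c(-pi / t, pi / t))
    expect_lt(abs(f$omega - om_true), 1e-6 * max(1, abs(om_true)))
    expect_false(f$flagged)
  }

  # 50/50 orthogonal crossing, three field directions
  sch <- default_scheme(3L)
  oc <- suppressWarnings(mixture_odf(list(
    list(0.5, watson_odf(c(1, 0, 0), 20)),
    list(0.5, watson_odf(c(0, 0, 1), 20)))))
  om_true <- -20
  y <- Arg(msai:::ensemble_signal_profile(oc, om_true, sch$b0_directions,
                                          t, t0)[1L, ]) / tau
  f <- fit_voxel(y, oc, sch$b0_directions, t, t0, interval = c(-pi / t, pi / t))
  expect_lt(abs(f$omega - om_true) / abs(om_true), 1e-3)
})

test_that("a fiber parallel to the only field direction is flagged", {
  o <- delta_odf(c(0, 0, 1))
  b0 <- matrix(c(0, 0, 1), 1)
  y <- 0
  f <- fit_voxel(y, o, b0, 0.0405, 0.0045, interval = c(-50, 50))
  expect_true(f$flagged)
})

test_that("fit_voxel rejects degenerate intervals", {
  o <- uniform_odf()
  expect_error(fit_voxel(0, o, c(0, 0, 1), 0.04, 0.0045, interval = c(2, 1)),
               "interval")
  expect_error(fit_voxel(0, o, c(0, 0, 1), 0.04, 0.0045,
                         interval = c(-Inf, Inf)), "interval")
})

test_that("returned optimum beats random interval points", {
  t <- 0.0405; t0 <- 0.0045; tau <- t - t0
  sch <- default_scheme(3L)
  o <- small_phantom_data()$odfs[[25L]]
  set.seed(77)
  y <- Arg(msai:::ensemble_signal_profile(o, -15, sch$b0_directions,
                                          t, t0)[1L, ]) / tau + stats::rnorm(3, 0, 0.5)
  interval <- c(-pi / t, pi / t)
  f <- fit_voxel(y, o, sch$b0_directions, t, t0, interval)
  obj_at <- function(w) {
    dE <- msai:::ensemble_signal_profile(o, w, sch$b0_directions, t, t0)[1L, ]
    sum(phase_distance(exp(1i * y * tau), dE)^2)
  }
  rand <- stats::runif(50, interval[1L], interval[2L])
  expect_true(all(f$objective <= vapply(rand, obj_at, numeric(1)) + 1e-12))
})

test_that("echo-train tracking recovers constant and drifting shifts", {
  sp <- small_phantom_data()
  sch <- sp$scheme
  tk <- scheme_fit_times_ms(sch) / 1000
  # constant omega_A over the train, noise-free
  o <- sp$odfs[[1L]]
  om_const <- -12
  y <- vapply(seq_along(tk), function(k) {
    Arg(msai:::ensemble_signal_profile(o, om_const, sch$b0_directions,
                                       tk[k], 0.0045)[1L, ]) / (tk[k] - 0.0045)
  }, numeric(3L))
  fit <- track_echo_train(y, o, sch)
  # the parallel-fiber voxel has a shallow objective, so allow a little
  # slack beyond the optimiser's nominal precision
  expect_lt(max(abs(fit$omega - om_const)), 1e-5)
  # first-echo interval is centred at zero with half-width pi / t1
  expect_equal(fit$intervals[, 1L], c(-pi / tk[1L], pi / tk[1L]))
})

test_that("wrap tracking follows the truth where the naive fit aliases", {
  sch <- default_scheme(3L)
  classes <- default_tissue_classes(sch, wm_hz_last = -16)
  ph <- build_phantom(c(2L, 2L, 1L), sch, classes = classes)
  dat <- simulate_measurements(ph)
  truth <- phantom_truth(ph)
  odfs <- phantom_odfs(ph)
  tk <- scheme_fit_times_ms(sch) / 1000
  K <- length(tk)
  v <- 1L
  tr <- truth[ph$class_index[v], ]
  # late-echo phase exceeds pi: the wrap scenario
  expect_gt(abs(tr[K]) * (tk[K] - 0.0045), pi)
  fit <- track_echo_train(matrix(dat$values[v, , ], nrow = 3L), odfs[[v]], sch)
  expect_lt(max(abs(fit$omega - tr) / abs(tr)), 1e-3)
  # an independent centred-at-zero fit of the last echo lands on an alias
  naive <- fit_voxel(dat$values[v, , K], odfs[[v]], sch$b0_directions,
                     tk[K], 0.0045, interval = c(-pi / tk[K], pi / tk[K]))
  expect_gt(abs(naive$omega - tr[K]), 10)
})

test_that("tracking validates the data layout", {
  sch <- default_scheme(2L)
  o <- uniform_odf()
  expect_error(track_echo_train(matrix(0, 3, 2), o, sch), "positions")
})

test_that("noise-free estimates are consistent across phantom tissues", {
  sp <- small_phantom_data()
  sch <- sp$scheme
  n_vox <- prod(sp$phantom$grid_shape)
  worst <- 0
  for (v in seq_len(n_vox)) {
    fit <- track_echo_train(matrix(sp$data$values[v, , ], nrow = 3L),
                            sp$odfs[[v]], sch)
    tr <- sp$truth[sp$phantom$class_index[v], ]
    worst <- max(worst, max(abs(fit$omega - tr) / pmax(1, abs(tr))))
  }
  expect_lt(worst, 1e-3)
})

test_that("offset estimation recovers injected global offsets", {
  sch <- default_scheme(2L)
  K <- length(scheme_fit_times_ms(sch))
  set.seed(11)
  off_true <- matrix(stats::runif(2 * K, -2, 2), 2L, K)
  ph <- build_phantom(c(5L, 5L, 2L), sch, offsets_true = off_true)
  dat <- simulate_measurements(ph)
  res <- estimate_offsets(dat, phantom_odfs(ph))
  expect_lt(max(abs(res$offsets - off_true)), 1e-3)
  # the alternating optimisation never increases the total error
  expect_true(all(diff(res$total_error) <= 1e-12))
  # and the fitted shifts match the truth
  truth <- phantom_truth(ph)
  worst <- 0
  for (vi in seq_along(res$roi_voxels)) {
    v <- res$roi_voxels[vi]
    tr <- truth[ph$class_index[v], ]
    worst <- max(worst, max(abs(res$fits[[vi]]$omega - tr) / pmax(1, abs(tr))))
  }
  expect_lt(worst, 1e-3)
})

test_that("offsets at a simulated-zero-offset fixed point stay near zero", {
  sch <- default_scheme(2L)
  ph <- build_phantom(c(3L, 3L, 1L), sch)
  dat <- simulate_measurements(ph)
  res <- estimate_offsets(dat, phantom_odfs(ph), max_iter = 20L)
  expect_lt(max(abs(res$offsets)), 1e-4)
})

test_that("offset estimation requires at least two head orientations", {
  sch <- default_scheme(1L)
  ph <- build_phantom(c(2L, 2L, 1L), sch)
  dat <- simulate_measurements(ph)
  expect_error(estimate_offsets(dat, phantom_odfs(ph)),
               "at least 2 head orientations")
})
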