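test_that("default scheme reproduces the reference acquisition geometry", {
  sch <- default_scheme(3L)
  expect_equal(length(sch$echo_times_ms), 11L)
  expect_equal(sch$echo_times_ms, 4.5 * (1:11))
  expect_equal(sch$reference_time_ms, 4.5)
  expect_equal(sch$echo_mask, rep(c(TRUE, FALSE), length.out = 11L))
  expect_equal(scheme_selected_times_ms(sch),
               c(4.5, 13.5, 22.5, 31.5, 40.5, 49.5))
  ang <- acos(sum(sch$b0_directions[1L, ] * sch$b0_directions[3L, ])) * 180 / pi
  expect_lt(abs(ang - 59.8), 0.01)
  # two-position variant spans the same extreme angle
  sch2 <- default_scheme(2L)
  ang2 <- acos(sum(sch2$b0_directions[1L, ] * sch2$b0_directions[2L, ])) * 180 / pi
  expect_lt(abs(ang2 - 59.8), 0.01)
  expect_error(default_scheme(4L), "1, 2 or 3")
})

test_that("phantom construction is deterministic and valid", {
  ph1 <- build_phantom(c(10L, 10L, 5L), seed = 7L)
  ph2 <- build_phantom(c(10L, 10L, 5L), seed = 7L)
  expect_identical(ph1$tissue_labels, ph2$tissue_labels)
  expect_identical(ph1$background_coeffs, ph2$background_coeffs)
  expect_equal(sort(unique(as.vector(ph1$tissue_labels))),
               sort(names(ph1$classes)))
  # every class ODF has unit mass
  g <- test_grid()
  for (cl in ph1$classes) {
    mass <- sum(g$weights * odf_density(cl$odf, g$directions))
    expect_lt(abs(mass - 1), 1e-6)
  }
})

test_that("coherent phantom fibers give the intended orientation weighting", {
  ph <- build_phantom(c(4L, 4L, 2L))
  b0 <- c(0, 0, 1)   # standard position field direction
  expect_lt(orientation_weighting(ph$classes$parallel$odf, b0), 0.1)
  expect_gt(orientation_weighting(ph$classes$perpendicular$odf, b0), 0.9)
})

test_that("noise-free simulation matches the forward model exactly", {
  sch <- default_scheme(2L)
  ph <- build_phantom(c(3L, 3L, 1L), sch)
  dat <- simulate_measurements(ph, sigma_y = 0, with_background = FALSE)
  tk <- scheme_fit_times_ms(sch) / 1000
  t0 <- sch$reference_time_ms / 1000
  v <- 5L
  cl <- ph$classes[[ph$class_index[v]]]
  for (k in seq_along(tk)) {
    dE <- ensemble_signal(cl$odf, cl$curve(tk[k]), sch$b0_directions[1L, ],
                          tk[k], t0)
    expect_lt(abs(dat$values[v, 1L, k] - Arg(dE) / (tk[k] - t0)), 1e-12)
  }
})

test_that("simulation is reproducible and its noise level is calibrated", {
  sch <- default_scheme(2L)
  ph <- build_phantom(c(10L, 10L, 5L), sch)
  d1 <- simulate_measurements(ph, sigma_y = 0.5, seed = 13L)
  d2 <- simulate_measurements(ph, sigma_y = 0.5, seed = 13L)
  expect_identical(d1$values, d2$values)
  clean <- simulate_measurements(ph, sigma_y = 0)
  resid <- d1$values - clean$values
  expect_equal(length(resid), 5000L)
  expect_lt(abs(stats::sd(resid) - 0.5) / 0.5, 0.02)
  expect_error(simulate_measurements(ph, sigma_y = -1), "non-negative")
})

test_that("background injection adds the phantom's polynomial fields", {
  sch <- default_scheme(2L)
  ph <- build_phantom(c(6L, 5L, 4L), sch, background_scale = 1)
  clean <- simulate_measurements(ph)
  dirty <- simulate_measurements(ph, with_background = TRUE)
  bgdiff <- dirty$values[, 1L, 1L] - clean$values[, 1L, 1L]
  # the injected field is an order-2 polynomial: detrending removes it
  res <- remove_background(array(bgdiff, dim = ph$grid_shape),
                           array(TRUE, ph$grid_shape), 2L)
  expect_lt(max(abs(res$residual)), 1e-10)
  expect_gt(stats::sd(bgdiff), 0)
})

test_that("round trip: simulate then fit recovers all tissue classes", {
  sp <- small_phantom_data()
  truth <- sp$truth
  # one voxel per class suffices: classes are homogeneous blocks
  picks <- vapply(seq_along(sp$phantom$classes),
                  function(ci) which(sp$phantom$class_index == ci)[1L],
                  integer(1))
  for (v in picks) {
    fit <- track_echo_train(matrix(sp$data$values[v, , ], nrow = 3L),
                            sp$odfs[[v]], sp$scheme)
    tr <- truth[sp$phantom$class_index[v], ]
    expect_lt(max(abs(fit$omega - tr) / pmax(1, abs(tr))), 1e-3)
  }
})

test_that("unknown tissue classes are rejected", {
  bad <- list(strange = list(odf = "not an odf", curve = function(t) 0))
  expect_error(build_phantom(c(2L, 2L, 1L), classes = bad), "odf")
})
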