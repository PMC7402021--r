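# Shared fixtures, built once per test run.

# dense grid for quadrature-based oracles
test_grid <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- make_antipodal_grid(250L)
    g
  }
})

# delta-like Watson ODFs (beyond the order-8 band limit by design)
delta_odf <- function(axis, kappa = 1e4) {
  suppressWarnings(watson_odf(axis, kappa))
}

# random valid order-8 ODF: mixture of in-band Watson components plus a
# uniform floor, non-negative by construction
random_odf <- function(rng_seed) {
  set.seed(rng_seed)
  n_comp <- sample(1:3, 1L)
  axes <- matrix(stats::rnorm(3L * n_comp), n_comp, 3L)
  axes <- axes / sqrt(rowSums(axes^2))
  kappas <- stats::runif(n_comp, 0, 4)
  w <- stats::runif(n_comp + 1L)
  w <- w / sum(w)
  comps <- c(
    list(list(w[1L], uniform_odf())),
    lapply(seq_len(n_comp), function(i) {
      list(w[i + 1L], watson_odf(axes[i, ], kappas[i]))
    })
  )
  mixture_odf(comps)
}

random_unit <- function(rng_seed) {
  set.seed(rng_seed)
  v <- stats::rnorm(3L)
  v / sqrt(sum(v^2))
}

# small phantom + noise-free measurements for estimator tests
small_phantom_data <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      sch <- default_scheme(3L)
      ph <- build_phantom(c(5L, 5L, 2L), sch)
      memo <<- list(phantom = ph, scheme = sch,
                    data = simulate_measurements(ph),
                    odfs = phantom_odfs(ph),
                    truth = phantom_truth(ph))
    }
    memo
  }
})
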