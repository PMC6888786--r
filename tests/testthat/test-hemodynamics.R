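test_that("event detection finds amplitude peaks and nothing in flat series", {
  expect_equal(detect_pseudo_events(rep(3.7, 50)), integer(0))
  # one HRF-shaped bump on a flat baseline: exactly one suprathreshold maximum
  bump <- double_gamma_hrf(seq(0, 30, by = 1))
  x <- c(rep(0, 40), 5 * bump, rep(0, 40))
  ev <- detect_pseudo_events(x, threshold_sd = 1)
  expect_length(ev, 1)
  expect_lte(abs(ev - (40 + which.max(bump))), 1)
})

test_that("threshold zero returns the positive local maxima", {
  set.seed(51)
  x <- stats::rnorm(200)
  ev <- detect_pseudo_events(x, threshold_sd = 0)
  # independent recomputation of the definition
  z <- as.numeric(scale(stats::residuals(stats::lm(x ~ seq_along(x)))))
  mid <- 2:199
  expected <- mid[z[mid] > z[mid - 1] & z[mid] >= z[mid + 1] & z[mid] > 0]
  expect_equal(ev, expected)
})

test_that("event detection is invariant to affine rescaling", {
  set.seed(52)
  x <- stats::rnorm(150)
  expect_equal(detect_pseudo_events(10 + 3 * x), detect_pseudo_events(x))
})

test_that("HRF estimation recovers a canonical response from clean data", {
  dt <- 3
  n <- 400
  t_grid <- seq(0, 30, by = dt)
  basis <- hrf_basis(t_grid, block_s = dt)
  set.seed(61)
  onsets <- sort(sample(5:(n - 15), 40))
  u <- numeric(n); u[onsets] <- 1
  h <- basis[, 1]
  x <- stats::filter(c(rep(0, length(h) - 1), u), h,
                     method = "convolution", sides = 1)
  x <- as.numeric(x[(length(h) - 1) + seq_len(n)])
  fit <- estimate_hrf(x, events = onsets, dt = dt, window_s = 30,
                      lag_grid = 0:2)
  w <- fit$basis_weights / max(abs(fit$basis_weights))
  expect_equal(unname(w[1]), 1, tolerance = 1e-3)
  expect_lt(max(abs(w[2:3])), 0.01)
  expect_equal(fit$curve, basis[, 1] / max(abs(basis[, 1])), tolerance = 1e-3)
})

test_that("a delayed response loads the temporal derivative with negative sign", {
  dt <- 3
  n <- 400
  t_grid <- seq(0, 30, by = dt)
  basis <- hrf_basis(t_grid, block_s = dt, delta_t = 1)
  delayed <- basis[, 1] - 1 * basis[, 2]  # canonical shifted ~1 s later
  set.seed(62)
  onsets <- sort(sample(5:(n - 15), 40))
  u <- numeric(n); u[onsets] <- 1
  x <- stats::filter(c(rep(0, length(delayed) - 1), u), delayed,
                     method = "convolution", sides = 1)
  x <- as.numeric(x[(length(delayed) - 1) + seq_len(n)])
  fit <- estimate_hrf(x, events = onsets, dt = dt, window_s = 30,
                      lag_grid = 0)
  expect_lt(fit$basis_weights[2] / fit$basis_weights[1], -0.5)
})

test_that("too few events is an explicit condition", {
  expect_error(estimate_hrf(stats::rnorm(100), events = c(10, 20), dt = 3),
               class = "cpgcnet_no_events")
})

test_that("Wiener inversion is exact for noiseless data at nsr zero", {
  hrf <- canonical_hrf(dt = 1, window_s = 30)
  L <- length(hrf$curve)
  n <- 200
  set.seed(71)
  neural <- c(stats::rnorm(n - L - 10), rep(0, L + 10))
  obs <- stats::filter(c(rep(0, L - 1), neural), hrf$curve,
                       method = "convolution", sides = 1)
  obs <- as.numeric(obs[(L - 1) + seq_len(n)])
  rec <- wiener_deconvolve(obs, hrf, nsr = 0)
  expect_equal(rec, neural, tolerance = 1e-8)
})

test_that("Wiener output vanishes as regularization dominates", {
  set.seed(72)
  x <- stats::rnorm(120)
  out <- wiener_deconvolve(x, canonical_hrf(dt = 1), nsr = 1e12)
  expect_lt(max(abs(out)), 1e-6)
})

test_that("an all-zero HRF is rejected", {
  fake <- structure(list(curve = rep(0, 11), dt = 3), class = "hrf_model")
  expect_error(wiener_deconvolve(stats::rnorm(50), fake), "not invertible")
  expect_error(hrf_model(rep(0, 11), dt = 3), "all-zero")
})

test_that("deconvolve-reconvolve error shrinks with the true noise level", {
  hrf <- canonical_hrf(dt = 3, window_s = 30, block_s = 3)
  L <- length(hrf$curve)
  set.seed(73)
  neural <- stats::rnorm(140)
  clean <- stats::filter(c(rep(0, L - 1), neural), hrf$curve,
                         method = "convolution", sides = 1)
  clean <- as.numeric(clean[(L - 1) + seq_len(140)])
  relerr <- vapply(c(1, 0.3, 0.05), function(s) {
    obs <- clean + stats::rnorm(140, sd = s)
    lat <- wiener_deconvolve(obs, hrf, nsr = 0.02)
    rec <- stats::filter(c(rep(0, L - 1), lat), hrf$curve,
                         method = "convolution", sides = 1)
    rec <- as.numeric(rec[(L - 1) + seq_len(140)])
    sqrt(mean((rec - obs)^2)) / stats::sd(obs)
  }, numeric(1))
  expect_true(all(diff(relerr) < 0))
})

test_that("subject deconvolution treats columns independently", {
  net <- make_ground_truth_network(q = 8, n_middlemen = 2, density = 0.2,
                                   seed = 5)
  coh <- generate_cohort(net, group_sizes = c(1, 1, 1, 1),
                         pruning_fractions = c(0, 0, 0, 0), seed = 81, T = 120)
  obs <- coh$timeseries[[1]]
  dup <- roi_timeseries(obs$data[, c(1, 1, 2)], dt = obs$dt,
                        roi_labels = c("a", "b", "c"))
  out <- deconvolve_subject(dup)
  expect_identical(out$data[, 1], out$data[, 2])
  # permuting ROI order permutes the output identically
  perm <- c(3, 1, 5, 2, 8, 6, 4, 7)
  d1 <- deconvolve_subject(obs)
  obs_p <- roi_timeseries(obs$data[, perm], dt = obs$dt,
                          roi_labels = obs$roi_labels[perm])
  d2 <- deconvolve_subject(obs_p)
  expect_equal(d2$data, d1$data[, perm], ignore_attr = TRUE)
  expect_equal(d1$log$n_events[perm], d2$log$n_events)
})

test_that("columns with too few events fall back or fail as configured", {
  set.seed(82)
  q <- 3
  flat <- matrix(stats::rnorm(120 * q, sd = 1e-3), 120, q)
  flat[, 2] <- seq_len(120) * 1e-4  # trend only: no suprathreshold maxima
  obs <- roi_timeseries(flat, dt = 3, roi_labels = c("a", "b", "c"))
  out <- deconvolve_subject(obs, threshold_sd = 10)
  expect_true(all(out$log$fallback))
  expect_error(deconvolve_subject(obs, threshold_sd = 10,
                                  on_too_few_events = "error"),
               "ROI")
})
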