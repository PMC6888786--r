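test_that("ground-truth networks plant verifiable middlemen and are stable", {
  net <- make_ground_truth_network(q = 8, n_middlemen = 3, density = 0.15,
                                   seed = 1)
  dn <- as_directed_network(net)
  for (m in net$middleman_nodes) expect_true(middleman_oracle(dn, m))
  expect_lte(max(Mod(eigen(net$coeff, only.values = TRUE)$values)), 0.9 + 1e-12)
  expect_false(any(diag(net$adjacency)))
  expect_true(all((net$coeff != 0) == net$adjacency))
  # same seed twice: identical networks
  net2 <- make_ground_truth_network(q = 8, n_middlemen = 3, density = 0.15,
                                    seed = 1)
  expect_identical(net$adjacency, net2$adjacency)
  expect_identical(net$coeff, net2$coeff)
})

test_that("feeder-only topology makes the hub a middleman", {
  net <- make_ground_truth_network(q = 6, n_middlemen = 1, density = 0,
                                   seed = 3)
  dn <- as_directed_network(net)
  expect_true(middleman_oracle(dn, net$middleman_nodes[1]))
  # the feeder has a single outgoing edge, into the middleman
  f <- net$feeder_nodes[1]
  expect_equal(sum(net$adjacency[, f]), 1L)
  expect_true(net$adjacency[net$middleman_nodes[1], f])
})

test_that("inconsistent ground-truth parameters fail loudly", {
  expect_error(make_ground_truth_network(q = 5, n_middlemen = 1, density = 0.1),
               "q >= 6")
  expect_error(make_ground_truth_network(q = 6, n_middlemen = 3, density = 0.1),
               "too small")
})

test_that("uncoupled simulation gives white columns", {
  net <- list(coeff = matrix(0, 3, 3), node_labels = c("a", "b", "c"))
  x <- simulate_neural(net, T_hr = 4000, dt_hr = 1, noise_sd = 1, seed = 9)
  ac <- apply(x, 2, function(col) stats::acf(col, plot = FALSE)$acf[2])
  expect_true(all(abs(ac) < 0.06))
  expect_true(abs(stats::sd(x[, 1]) - 1) < 0.05)
})

test_that("two-node chain matches the analytic VAR(1) covariance", {
  A <- rbind(c(0, 0), c(0.5, 0))  # node 2 driven by node 1
  net <- list(coeff = A, node_labels = c("a", "b"))
  x <- simulate_neural(net, T_hr = 10000, dt_hr = 1, noise_sd = 1, seed = 11)
  S_theory <- var1_stationary_cov(A)
  G1_theory <- A %*% S_theory      # lag-1 cross-covariance E[x(t) x(t-1)']
  S_hat <- stats::cov(x)
  n <- nrow(x)
  G1_hat <- crossprod(x[-1, , drop = FALSE], x[-n, , drop = FALSE]) / (n - 1)
  expect_equal(S_hat, S_theory, tolerance = 0.05, ignore_attr = TRUE)
  expect_lt(max(abs(G1_hat - G1_theory)), 0.05 * max(abs(S_theory)))
})

test_that("simulation is reproducible and detects instability", {
  net <- make_ground_truth_network(q = 8, n_middlemen = 2, density = 0.2,
                                   seed = 5)
  x1 <- simulate_neural(net, T_hr = 200, dt_hr = 0.5, seed = 7, lag_steps = 6)
  x2 <- simulate_neural(net, T_hr = 200, dt_hr = 0.5, seed = 7, lag_steps = 6)
  expect_identical(x1, x2)
  bad <- list(coeff = diag(1.2, 3), node_labels = letters[1:3])
  expect_error(simulate_neural(bad, 100, 1, seed = 1), "unstable")
})

test_that("zero neural input yields pure observation noise", {
  neural <- matrix(0, 600, 2)
  obs <- observe_bold(neural, dt_hr = 0.5, TR = 3, obs_noise_sd = 0.7,
                      seed = 21)
  expect_equal(dim(obs$data), c(100, 2))
  expect_equal(stats::sd(obs$data), 0.7, tolerance = 0.1)
  expect_error(observe_bold(neural, dt_hr = 0.5, TR = 1.3), "integer multiple")
})

test_that("a noiseless impulse reproduces the sampled HRF", {
  neural <- matrix(0, 600, 1)
  t0 <- 60  # impulse on the fine grid
  neural[t0, 1] <- 1
  obs <- observe_bold(neural, dt_hr = 0.5, TR = 3, obs_noise_sd = 0, seed = 1)
  h <- double_gamma_hrf(seq(0, 30, by = 0.5))
  # sample k*TR on the fine grid: y[k] = h(6k - t0) for 6k >= t0
  expected <- vapply(seq_len(100), function(k) {
    idx <- 6 * k - t0 + 1
    if (idx >= 1 && idx <= length(h)) h[idx] else 0
  }, numeric(1))
  expect_equal(as.numeric(obs$data[, 1]), expected, tolerance = 1e-10)
})

test_that("regional HRF delay differences shift the BOLD cross-correlation", {
  set.seed(31)
  common <- matrix(rep(stats::rnorm(500), 2), ncol = 2)
  hp <- data.frame(peak_time = c(5, 7), under_time = c(16, 16), disp = c(1, 1))
  obs <- observe_bold(common, hp, dt_hr = 0.5, TR = 3, obs_noise_sd = 0,
                      seed = 1)
  cc <- stats::ccf(obs$data[, 2], obs$data[, 1], lag.max = 3, plot = FALSE)
  # region 2 peaks 2 s later; at TR = 3 s the peak lag rounds to one sample
  expect_gte(cc$lag[which.max(cc$acf)], 0)
  cc0 <- stats::ccf(obs$data[, 1], obs$data[, 1], lag.max = 3, plot = FALSE)
  expect_equal(cc0$lag[which.max(cc0$acf)], 0)
})

test_that("cohort generation is reproducible with coherent structure", {
  net <- make_ground_truth_network(q = 8, n_middlemen = 2, density = 0.2,
                                   seed = 5)
  coh1 <- generate_cohort(net, group_sizes = c(3, 3, 3, 3),
                          pruning_fractions = c(0, 0.3, 0.6, 0.9),
                          seed = 17, T = 60)
  coh2 <- generate_cohort(net, group_sizes = c(3, 3, 3, 3),
                          pruning_fractions = c(0, 0.3, 0.6, 0.9),
                          seed = 17, T = 60)
  expect_identical(coh1$cohort, coh2$cohort)
  expect_identical(coh1$timeseries[[5]]$data, coh2$timeseries[[5]]$data)
  expect_equal(as.character(unique(coh1$cohort$group)),
               c("NC", "EMCI", "LMCI", "AD"))
  expect_equal(nrow(coh1$timeseries[[1]]$data), 60)
  # NC subjects keep the full network; AD subjects lose middleman-incident edges
  expect_identical(coh1$subject_networks[[1]]$adjacency, net$adjacency)
  ad <- coh1$subject_networks[[12]]$adjacency
  expect_lt(sum(ad), sum(net$adjacency))
  lost <- which(net$adjacency & !ad, arr.ind = TRUE)
  expect_true(all(lost[, 1] %in% net$middleman_nodes |
                  lost[, 2] %in% net$middleman_nodes))
})

test_that("behavioral scores follow the clinical sign pattern", {
  net <- make_ground_truth_network(q = 8, n_middlemen = 2, density = 0.2,
                                   seed = 5)
  coh <- generate_cohort(net, group_sizes = c(8, 8, 8, 8),
                         pruning_fractions = c(0, 0.3, 0.6, 0.9),
                         seed = 23, T = 30)
  m <- coh$cohort
  nc <- m$group == "NC"; ad <- m$group == "AD"
  expect_gt(mean(m$mmse[nc]), mean(m$mmse[ad]))
  expect_lt(mean(m$npiq[nc]), mean(m$npiq[ad]))
  expect_lt(mean(m$faq[nc]), mean(m$faq[ad]))
  expect_lt(mean(m$cdr[nc]), mean(m$cdr[ad]))
  expect_true(all(m$age >= 55 & m$age <= 90))
  expect_true(all(m$sex %in% 0:1))
})
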