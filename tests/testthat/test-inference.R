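make_cov <- function(n) data.frame(age = stats::rnorm(n, 73, 7),
                                   sex = stats::rbinom(n, 1, 0.5))

test_that("one-sided p-values center at one half under the null", {
  set.seed(121)
  p <- replicate(300, {
    g <- rep(c("NC", "AD"), each = 12)
    adjusted_one_sided_test(stats::rnorm(24), g, "NC", "AD",
                            make_cov(24))$p
  })
  expect_equal(mean(p), 0.5, tolerance = 0.06)
})

test_that("rejection rate matches the analytic one-sided power", {
  set.seed(122)
  n <- 30
  rate <- mean(replicate(400, {
    v <- c(stats::rnorm(n, 1), stats::rnorm(n, 0))
    g <- rep(c("NC", "AD"), each = n)
    adjusted_one_sided_test(v, g, "NC", "AD", covariates = NULL)$p < 0.05
  }))
  ref <- stats::power.t.test(n = n, delta = 1, sd = 1, sig.level = 0.05,
                             type = "two.sample",
                             alternative = "one.sided")$power
  expect_equal(rate, ref, tolerance = 0.05)
})

test_that("covariate adjustment removes an age-driven confound", {
  set.seed(123)
  sim <- replicate(300, {
    n <- 25
    age <- c(stats::rnorm(n, 70, 4), stats::rnorm(n, 78, 4))
    v <- 0.12 * age + stats::rnorm(2 * n, sd = 0.5)  # age effect only
    g <- rep(c("NC", "AD"), each = n)                # older group tested first
    cov <- data.frame(age = age, sex = stats::rbinom(2 * n, 1, 0.5))
    c(adj = adjusted_one_sided_test(v, g, "AD", "NC", cov)$p < 0.05,
      raw = adjusted_one_sided_test(v, g, "AD", "NC", NULL)$p < 0.05)
  })
  expect_lt(mean(sim["adj", ]), 0.1)   # near nominal alpha
  expect_gt(mean(sim["raw", ]), 0.5)   # confounded test rejects wildly
})

test_that("group comparisons demand at least three subjects per group", {
  g <- c("NC", "NC", "AD", "AD", "AD")
  expect_error(adjusted_one_sided_test(stats::rnorm(5), g, "NC", "AD"),
               "at least 3")
})

test_that("BH selection matches a hand-worked example and edge cases", {
  p <- c(0.001, 0.01, 0.02, 0.04, 0.2)
  # adjusted: 0.005, 0.025, 0.0333, 0.05, 0.2 -> strict < 0.05 keeps three
  expect_equal(fdr_bh(p, 0.05), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_true(all(fdr_bh(rep(0.001, 200), 0.05)))
})

test_that("BH controls the expected null rejection count", {
  set.seed(131)
  rejections <- replicate(300, sum(fdr_bh(stats::runif(50), 0.05)))
  expect_lte(mean(rejections), 0.05 * 50)
})

test_that("progressive analysis intersects exactly the six significant sets", {
  set.seed(141)
  n_per <- 12
  groups <- factor(rep(c("NC", "EMCI", "LMCI", "AD"), each = n_per),
                   levels = c("NC", "EMCI", "LMCI", "AD"), ordered = TRUE)
  lvl <- as.integer(groups)
  # node 1 declines at every step; node 2 is flat between LMCI and AD;
  # node 3 is pure noise
  m <- cbind(10 - 2 * lvl + stats::rnorm(48, sd = 0.3),
             10 - 2 * pmin(lvl, 3) + stats::rnorm(48, sd = 0.3),
             stats::rnorm(48))
  colnames(m) <- c("drop_all", "drop_until_lmci", "flat")
  cohort <- data.frame(subject_id = sprintf("s%02d", 1:48), group = groups,
                       age = stats::rnorm(48, 73, 5),
                       sex = stats::rbinom(48, 1, 0.5))
  rep <- progressive_nodes(m, cohort, "MP", alpha = 0.05)
  expect_equal(rep$common_nodes, "drop_all")
  sig5 <- rep$per_comparison[["EMCI>AD"]]
  expect_true(sig5$significant[sig5$node == "drop_until_lmci"])
  expect_false("flat" %in% rep$common_nodes)
  # relaxing alpha never shrinks any significant set
  strict <- progressive_nodes(m, cohort, "MP", alpha = 0.01)
  loose <- progressive_nodes(m, cohort, "MP", alpha = 0.2)
  for (nm in names(strict$per_comparison)) {
    s1 <- strict$per_comparison[[nm]]$significant
    s2 <- loose$per_comparison[[nm]]$significant
    expect_true(all(s2[s1]))
  }
  expect_true(all(strict$common_nodes %in% loose$common_nodes))
})

test_that("degenerate nodes are reported untestable, not fatal", {
  set.seed(142)
  groups <- factor(rep(c("NC", "EMCI", "LMCI", "AD"), each = 5),
                   levels = c("NC", "EMCI", "LMCI", "AD"), ordered = TRUE)
  m <- cbind(all_zero = rep(0, 20), noise = stats::rnorm(20))
  cohort <- data.frame(subject_id = sprintf("s%02d", 1:20), group = groups,
                       age = stats::rnorm(20, 73, 5),
                       sex = stats::rbinom(20, 1, 0.5))
  rep <- progressive_nodes(m, cohort, "MP")
  df <- rep$per_comparison[[1]]
  expect_true(is.na(df$p[df$node == "all_zero"]))
  expect_false(df$significant[df$node == "all_zero"])
})

test_that("behavioral correlation handles identity, null and degenerate input", {
  v <- c(1, 2, 3, 4, 5)
  expect_equal(behavioral_correlation(v, v)$r, 1)
  set.seed(151)
  null_r <- replicate(200, behavioral_correlation(stats::rnorm(100),
                                                  stats::rnorm(100))$r)
  expect_gte(mean(abs(null_r) < 1.96 / sqrt(97)), 0.9)
  expect_error(behavioral_correlation(rep(1, 10), stats::rnorm(10)),
               "zero-variance")
  expect_error(behavioral_correlation(1:3, 1:3), "at least 4")
})

test_that("behavioral coupling yields the clinical sign pattern against true MP", {
  net <- make_ground_truth_network(q = 10, n_middlemen = 2, density = 0.15,
                                   seed = 155)
  coh <- generate_cohort(net, group_sizes = c(10, 10, 10, 10),
                         pruning_fractions = c(0, 0.3, 0.6, 0.9),
                         seed = 156, T = 20)
  # middleman power of the true (pruned) subject networks, no estimation
  mm <- net$middleman_nodes
  true_mp <- vapply(coh$subject_networks, function(sn) {
    mean(middleman_power(as_directed_network(sn))[mm])
  }, numeric(1))
  expect_gt(behavioral_correlation(true_mp, coh$cohort$mmse)$r, 0)
  expect_lt(behavioral_correlation(true_mp, coh$cohort$npiq)$r, 0)
  expect_lt(behavioral_correlation(true_mp, coh$cohort$faq)$r, 0)
  expect_lt(behavioral_correlation(true_mp, coh$cohort$cdr)$r, 0)
})

test_that("FC networks binarize correlations and feed undirected BC", {
  set.seed(161)
  hub <- stats::rnorm(300)
  leaves <- sapply(1:4, function(i) 0.8 * hub + stats::rnorm(300, sd = 0.6))
  x <- cbind(hub, leaves)
  colnames(x) <- c("hub", paste0("leaf", 1:4))
  net <- fc_network(x, alpha = 0.05)
  expect_true(isSymmetric(net$adjacency))
  expect_true(all(net$adjacency["hub", -1]))
  bc <- betweenness_directed(net)
  expect_equal(names(which.max(bc)), "hub")
})

test_that("the FC comparison arm runs the six-test pipeline on BC", {
  net <- make_ground_truth_network(q = 8, n_middlemen = 2, density = 0.2,
                                   seed = 5)
  coh <- generate_cohort(net, group_sizes = c(3, 3, 3, 3),
                         pruning_fractions = c(0, 0.3, 0.6, 0.9),
                         seed = 171, T = 80)
  rep <- fc_bc_comparison_arm(coh$timeseries, coh$cohort)
  expect_s3_class(rep, "progressive_report")
  expect_equal(rep$measure_name, "BC_FC")
  expect_length(rep$per_comparison, 6)
  expect_equal(dim(attr(rep, "bc")), c(12, 8))
})
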