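#' ROI time-series container
#'
#' Observed (BOLD-like) multivariate series for one subject: a T x q matrix
#' with one column per region, a sampling interval (the TR) and region
#' labels.
#'
#' @param data T x q numeric matrix, rows = timepoints.
#' @param dt Sampling interval, seconds.
#' @param roi_labels Character vector of q unique region labels.
#' @param subject_id Subject identifier.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, dt, roi_labels = colnames(data),
                           subject_id = NA_character_) {
  data <- as.matrix(data)
  if (anyNA(data) || !all(is.finite(data))) stopf("time series contain non-finite values")
  if (nrow(data) < 3) stopf("need at least 3 timepoints, got %d", nrow(data))
  if (is.null(roi_labels)) roi_labels <- paste0("ROI", seq_len(ncol(data)))
  if (length(roi_labels) != ncol(data)) stopf("roi_labels length mismatch")
  colnames(data) <- roi_labels
  structure(list(data = data, dt = dt, roi_labels = as.character(roi_labels),
                 subject_id = subject_id),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI time series '%s': %d timepoints x %d regions, TR = %.2f s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$dt))
  invisible(x)
}

#' Ground-truth directed network for simulation
#'
#' Builds a sparse stable lag-1 coupling structure with designated middleman
#' nodes. Each middleman is guaranteed the middleman property by
#' construction: it receives the single outgoing edge of a dedicated feeder
#' node, so deleting the middleman blocks all of the feeder's information
#' flow. Remaining ("core") nodes are wired randomly at the requested edge
#' density; feeders get no other outgoing edges.
#'
#' The coefficient matrix follows the package-wide causal-coefficient
#' orientation: `coeff[i, j]` is the lag-1 influence of node `j` on node `i`
#' (so `adjacency[i, j]` means an edge `j -> i`). Use
#' [as_directed_network()] for graph analysis, which transposes into
#' source-by-target orientation.
#'
#' @param q Number of nodes (>= 6).
#' @param n_middlemen Number of designated middleman nodes (>= 1); an equal
#'   number of feeder nodes is reserved, so `2 * n_middlemen < q`.
#' @param density Probability of each background edge among non-feeder nodes.
#' @param coeff_scale Typical magnitude of nonzero lag-1 coefficients.
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling attempts before giving up.
#' @return An object of class `ground_truth_network` with fields
#'   `adjacency`, `coeff`, `middleman_nodes`, `feeder_nodes`, `node_labels`.
#' @export
make_ground_truth_network <- function(q, n_middlemen, density,
                                      coeff_scale = 0.5, seed = NULL,
                                      max_tries = 100L) {
  stopifnot(q >= 6, n_middlemen >= 1, density >= 0, density < 1)
  if (2 * n_middlemen >= q)
    stopf("q = %d too small for %d middlemen plus feeders", q, n_middlemen)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      net <- try_ground_truth(q, n_middlemen, density, coeff_scale)
      if (!is.null(net)) {
        net$seed <- seed
        return(net)
      }
    }
    stopf("could not satisfy middleman/stability constraints in %d attempts; parameters inconsistent",
          max_tries)
  })
}

try_ground_truth <- function(q, n_middlemen, density, coeff_scale) {
  mm <- seq_len(n_middlemen)
  feeders <- n_middlemen + seq_len(n_middlemen)
  core <- setdiff(seq_len(q), c(mm, feeders))
  # adjacency in target-by-source orientation: adj[i, j] means j -> i
  adj <- matrix(FALSE, q, q)
  for (k in seq_along(mm)) {
    adj[mm[k], feeders[k]] <- TRUE                       # feeder -> middleman
    out <- sample(core, min(2, length(core)))
    adj[out, mm[k]] <- TRUE                              # middleman -> core
  }
  # background edges among non-feeder nodes; feeders keep a single out-edge
  nonfeeder <- c(mm, core)
  for (s in nonfeeder) for (t in nonfeeder) {
    if (s != t && !adj[t, s] && stats::runif(1) < density) adj[t, s] <- TRUE
  }
  diag(adj) <- FALSE
  coeff <- matrix(0, q, q)
  nz <- which(adj)
  coeff[nz] <- coeff_scale * stats::runif(length(nz), 0.75, 1.25) *
    sample(c(-1, 1), length(nz), replace = TRUE, prob = c(0.3, 0.7))
  rho <- max(Mod(eigen(coeff, only.values = TRUE)$values))
  if (rho > 0.9) coeff <- coeff * (0.9 / rho)
  labels <- paste0("ROI", seq_len(q))
  net <- structure(list(adjacency = adj, coeff = coeff,
                        middleman_nodes = mm, feeder_nodes = feeders,
                        node_labels = labels),
                   class = "ground_truth_network")
  dn <- as_directed_network(net)
  ok <- all(vapply(mm, function(m) middleman_oracle(dn, m), logical(1)))
  if (!ok) return(NULL)
  net
}

#' Convert objects to a directed binary network
#'
#' @param x A `ground_truth_network` or `cpgc_result`.
#' @param ... Unused.
#' @return A [directed_network()] in source-by-target orientation (the
#'   stored causal matrices are target-by-source and are transposed here).
#' @export
as_directed_network <- function(x, ...) UseMethod("as_directed_network")

#' @export
as_directed_network.ground_truth_network <- function(x, ...) {
  directed_network(t(x$adjacency), x$node_labels)
}

#' @export
as_directed_network.directed_network <- function(x, ...) x

#' @export
print.ground_truth_network <- function(x, ...) {
  cat(sprintf("Ground-truth network: %d nodes, %d edges, middlemen: %s\n",
              nrow(x$adjacency), sum(x$adjacency),
              paste(x$node_labels[x$middleman_nodes], collapse = ", ")))
  invisible(x)
}

#' Simulate latent neural dynamics from a lag-1 coupling matrix
#'
#' First-order linear dynamics `X(t) = A X(t - lag_steps) + E(t)` with
#' independent Gaussian innovations, on a (possibly high-resolution) grid.
#' With `lag_steps > 1` the causal lag spans several grid steps, so that
#' downsampling by `lag_steps` yields an exact first-order vector
#' autoregression at the coarse resolution. A burn-in period is discarded.
#'
#' @param net A `ground_truth_network` (or any list with a `coeff` matrix).
#' @param T_hr Number of output timepoints on the simulation grid.
#' @param dt_hr Grid step, seconds.
#' @param noise_sd Innovation standard deviation.
#' @param seed Integer seed (NULL uses the ambient RNG stream).
#' @param lag_steps Causal lag in grid steps (>= 1).
#' @param burnin Discarded initial steps (defaults to `200 * lag_steps`).
#' @return T_hr x q numeric matrix with attribute `dt`.
#' @export
simulate_neural <- function(net, T_hr, dt_hr = 0.5, noise_sd = 1,
                            seed = NULL, lag_steps = 1L,
                            burnin = 200L * lag_steps) {
  A <- net$coeff
  q <- nrow(A)
  stopifnot(T_hr >= 2L * lag_steps + 1L, lag_steps >= 1L)
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (rho >= 1) stopf("unstable coefficient matrix (spectral radius %.3f)", rho)
  with_seed(seed, {
    n_tot <- T_hr + burnin
    X <- matrix(0, n_tot, q)
    E <- matrix(stats::rnorm(n_tot * q, sd = noise_sd), n_tot, q)
    X[seq_len(lag_steps), ] <- E[seq_len(lag_steps), ]
    for (t in (lag_steps + 1L):n_tot) {
      X[t, ] <- as.numeric(A %*% X[t - lag_steps, ]) + E[t, ]
    }
    if (any(abs(X) > 1e6)) stopf("simulation diverged; coefficient matrix unstable")
    out <- X[(burnin + 1L):n_tot, , drop = FALSE]
    attr(out, "dt") <- dt_hr
    colnames(out) <- net$node_labels %||% paste0("ROI", seq_len(q))
    out
  })
}

#' Convolve latent neural series with regional HRFs and sample at the TR
#'
#' Each column is convolved with its region's double-gamma HRF on the
#' high-resolution grid, sampled every `TR / dt_hr` steps, and corrupted
#' with white observation noise. This injects the hemodynamic variability
#' that blind deconvolution must subsequently remove.
#'
#' @param neural T_hr x q matrix from [simulate_neural()].
#' @param hrf_params_per_roi Data frame with q rows and columns `peak_time`,
#'   `under_time`, `disp` (NULL = canonical parameters for every region).
#' @param dt_hr Grid step of `neural`, seconds.
#' @param TR Acquisition repetition time, seconds; must be an integer
#'   multiple of `dt_hr`.
#' @param obs_noise_sd Observation noise standard deviation.
#' @param seed Integer seed (NULL uses the ambient RNG stream).
#' @param subject_id Identifier for the resulting series.
#' @param hrf_window_s HRF support used for the convolution, seconds.
#' @return A [roi_timeseries()] with `floor(T_hr * dt_hr / TR)` timepoints.
#' @export
observe_bold <- function(neural, hrf_params_per_roi = NULL, dt_hr = 0.5,
                         TR = 3, obs_noise_sd = 1, seed = NULL,
                         subject_id = NA_character_, hrf_window_s = 30) {
  step <- TR / dt_hr
  if (abs(step - round(step)) > 1e-9) stopf("TR must be an integer multiple of dt_hr")
  step <- as.integer(round(step))
  q <- ncol(neural)
  if (is.null(hrf_params_per_roi)) {
    hrf_params_per_roi <- data.frame(peak_time = rep(6, q),
                                     under_time = rep(16, q),
                                     disp = rep(1, q))
  }
  stopifnot(nrow(hrf_params_per_roi) == q)
  t_hrf <- seq(0, hrf_window_s, by = dt_hr)
  with_seed(seed, {
    n_hr <- nrow(neural)
    keep <- seq(step, n_hr, by = step)
    bold <- matrix(0, length(keep), q)
    for (j in seq_len(q)) {
      h <- double_gamma_hrf(t_hrf,
                            peak_time = hrf_params_per_roi$peak_time[j],
                            under_time = hrf_params_per_roi$under_time[j],
                            disp = hrf_params_per_roi$disp[j])
      L <- length(h)
      conv <- stats::filter(c(rep(0, L - 1), neural[, j]), h,
                            method = "convolution", sides = 1)
      bold[, j] <- conv[(L - 1) + keep]
    }
    bold <- bold + matrix(stats::rnorm(length(bold), sd = obs_noise_sd),
                          nrow(bold), q)
    roi_timeseries(bold, dt = TR,
                   roi_labels = colnames(neural) %||% paste0("ROI", seq_len(q)),
                   subject_id = subject_id)
  })
}

# Behavioral score model: group means anchored at typical clinical values
# for cognitively normal elders and linearly coupled to the subject's
# pruning fraction (full pruning ~ advanced disease). MMSE decreases with
# severity; NPI-Q, FAQ and CDR increase.
behav_anchors <- function() {
  data.frame(score = c("npiq", "mmse", "faq", "cdr"),
             intercept = c(0.6, 28.8, 0.2, 0.0),
             slope_per_unit_pruning = c(2.7, -8.8, 17.9, 0.9),
             noise_sd = c(2.3, 2.3, 4.7, 0.12))
}

#' Generate a synthetic four-group cohort
#'
#' Produces observed ROI time series plus a cohort manifest for four ordered
#' clinical groups (NC, EMCI, LMCI, AD). Every subject's individual network
#' is the ground truth with a group-specific fraction of middleman-incident
#' edges deleted at random (a subject-specific realization), so that
#' middleman power at the planted middleman nodes declines progressively
#' across groups. Regional HRF parameters are jittered per subject and
#' region; ages are drawn from one distribution across groups and sex by
#' fair coin; behavioral scores are linear in the pruning fraction plus
#' noise, with MMSE decreasing and NPI-Q/FAQ/CDR increasing.
#'
#' @param net A `ground_truth_network`.
#' @param group_sizes Integer vector of 4 subject counts (NC, EMCI, LMCI, AD).
#' @param pruning_fractions Non-decreasing fractions in `[0, 1]`, one per group.
#' @param behav_coupling Multiplier on the behavioral slope (1 = anchored values).
#' @param seed Integer master seed.
#' @param T Observed timepoints per subject.
#' @param TR Repetition time, seconds.
#' @param dt_hr Simulation grid step, seconds.
#' @param noise_sd Neural innovation standard deviation.
#' @param obs_noise_sd Observation noise standard deviation.
#' @param hrf_jitter If TRUE, jitter HRF peak time in 5-7 s, undershoot time
#'   in 14-18 s and dispersion in 0.8-1.2 s per region and subject.
#' @return A list with `timeseries` (list of [roi_timeseries()]), `cohort`
#'   (data.frame manifest), `subject_networks` (list of
#'   `ground_truth_network`), `pruning` (per-subject fractions) and
#'   `ground_truth`.
#' @export
generate_cohort <- function(net, group_sizes = c(35, 34, 32, 29),
                            pruning_fractions = c(0, 0.3, 0.6, 0.9),
                            behav_coupling = 1, seed = 1, T = 140, TR = 3,
                            dt_hr = 0.5, noise_sd = 1, obs_noise_sd = 1,
                            hrf_jitter = TRUE) {
  stopifnot(length(group_sizes) == 4, all(group_sizes >= 1),
            length(pruning_fractions) == 4,
            all(diff(pruning_fractions) >= 0),
            pruning_fractions[1] >= 0, pruning_fractions[4] <= 1)
  groups <- c("NC", "EMCI", "LMCI", "AD")
  n_total <- sum(group_sizes)
  seeds <- derive_seeds(seed, 2L * n_total + 1L)
  group_of <- rep(groups, times = group_sizes)
  frac_of <- rep(pruning_fractions, times = group_sizes)
  q <- nrow(net$adjacency)
  step <- as.integer(round(TR / dt_hr))
  # neural dynamics evolve at the acquisition timescale (causal lag = one
  # TR); activity is held constant within each TR on the fine grid so the
  # hemodynamic convolution operates at dt_hr. A lead-in absorbs the
  # convolution ramp and is discarded.
  lead <- 15L
  anchors <- behav_anchors()

  ts_list <- vector("list", n_total)
  nets <- vector("list", n_total)
  rows <- vector("list", n_total)
  for (s in seq_len(n_total)) {
    sid <- sprintf("sub-%03d", s)
    sn <- with_seed(seeds[s], prune_middleman_edges(net, frac_of[s]))
    neural_tr <- simulate_neural(sn, T_hr = T + lead, dt_hr = TR,
                                 noise_sd = noise_sd,
                                 seed = seeds[n_total + s])
    neural <- neural_tr[rep(seq_len(T + lead), each = step), , drop = FALSE]
    attr(neural, "dt") <- dt_hr
    colnames(neural) <- colnames(neural_tr)
    hp <- with_seed(seeds[s] + 1L, {
      if (hrf_jitter) {
        data.frame(peak_time = stats::runif(q, 5, 7),
                   under_time = stats::runif(q, 14, 18),
                   disp = stats::runif(q, 0.8, 1.2))
      } else {
        data.frame(peak_time = rep(6, q), under_time = rep(16, q),
                   disp = rep(1, q))
      }
    })
    obs_full <- observe_bold(neural, hp, dt_hr = dt_hr, TR = TR,
                             obs_noise_sd = obs_noise_sd,
                             seed = seeds[s] + 2L, subject_id = sid)
    ts_list[[s]] <- roi_timeseries(obs_full$data[lead + seq_len(T), , drop = FALSE],
                                   dt = TR, roi_labels = obs_full$roi_labels,
                                   subject_id = sid)
    nets[[s]] <- sn
    rows[[s]] <- with_seed(seeds[s] + 3L, {
      f <- frac_of[s]
      sc <- anchors$intercept +
        behav_coupling * anchors$slope_per_unit_pruning * f +
        stats::rnorm(4, sd = anchors$noise_sd)
      names(sc) <- anchors$score
      sc["mmse"] <- min(max(sc["mmse"], 0), 30)
      sc[c("npiq", "faq", "cdr")] <- pmax(sc[c("npiq", "faq", "cdr")], 0)
      data.frame(subject_id = sid, group = group_of[s],
                 age = min(max(stats::rnorm(1, 73, 7), 55), 90),
                 sex = stats::rbinom(1, 1, 0.5),
                 npiq = sc[["npiq"]], mmse = sc[["mmse"]],
                 faq = sc[["faq"]], cdr = sc[["cdr"]],
                 stringsAsFactors = FALSE)
    })
  }
  cohort <- do.call(rbind, rows)
  cohort$group <- factor(cohort$group, levels = groups, ordered = TRUE)
  rownames(cohort) <- NULL
  list(timeseries = ts_list, cohort = cohort, subject_networks = nets,
       pruning = frac_of, ground_truth = net)
}

# Delete a fraction of the edges incident to middleman nodes (as source or
# target), uniformly at random; uses the ambient RNG stream.
prune_middleman_edges <- function(net, fraction) {
  if (fraction <= 0) return(net)
  adj <- net$adjacency
  coeff <- net$coeff
  mm <- net$middleman_nodes
  idx <- which(adj, arr.ind = TRUE)
  incident <- idx[idx[, 1] %in% mm | idx[, 2] %in% mm, , drop = FALSE]
  n_remove <- round(fraction * nrow(incident))
  if (n_remove > 0) {
    pick <- incident[sample.int(nrow(incident), n_remove), , drop = FALSE]
    adj[pick] <- FALSE
    coeff[pick] <- 0
  }
  out <- net
  out$adjacency <- adj
  out$coeff <- coeff
  out
}
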