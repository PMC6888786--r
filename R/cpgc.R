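#' Fit a zero-lag-augmented multivariate autoregressive model
#'
#' For each region `i`, regresses its series on the contemporaneous values
#' of all other regions (the zero-lag terms, which absorb instantaneous
#' covariance so it cannot leak into lagged estimates) and on all regions at
#' lags `1..p`. All columns are demeaned first. The zero-lag system is used
#' purely to purge instantaneous correlation, not as an identified
#' structural model.
#'
#' When the per-equation design approaches or exceeds the number of
#' usable timepoints (predictors >= `ridge_ratio` * samples) the equation is
#' estimated by ridge regression with the penalty chosen by generalized
#' cross-validation, and a message is emitted. With `ridge = "never"` a
#' rank-deficient design is an error naming the equation.
#'
#' @param neural A `neural_timeseries`, [roi_timeseries()] or plain T x q
#'   matrix.
#' @param order Model order `p` (>= 1); the default first-order model
#'   captures causal lags up to one sampling interval.
#' @param ridge `"auto"`, `"never"` or `"always"`.
#' @param ridge_ratio Design-saturation ratio triggering ridge under
#'   `"auto"`.
#' @return An object of class `mvar_fit` with `a0` (q x q zero-lag
#'   coefficients, zero diagonal), `a_lag` (q x q x p lagged coefficients;
#'   `a_lag[i, j, n]` is the influence of region `j` on region `i` at lag
#'   `n`), `residuals` ((T - p) x q) and `order`.
#' @export
fit_mvar_zero_lag <- function(neural, order = 1L,
                              ridge = c("auto", "never", "always"),
                              ridge_ratio = 0.8) {
  ridge <- match.arg(ridge)
  Y <- as_matrix_series(neural)
  p <- as.integer(order)
  stopifnot(p >= 1)
  Tn <- nrow(Y)
  q <- ncol(Y)
  if (Tn < 2L * p + 1L) stopf("series too short (T = %d) for order %d", Tn, p)
  Y <- sweep(Y, 2, colMeans(Y))
  rows <- (p + 1L):Tn
  n_obs <- length(rows)
  Zc <- Y[rows, , drop = FALSE]
  Zl <- do.call(cbind, lapply(seq_len(p), function(n) Y[rows - n, , drop = FALSE]))
  Z <- cbind(Zc, Zl)
  n_pred <- q - 1L + p * q
  use_ridge <- ridge == "always" ||
    (ridge == "auto" && n_pred >= ridge_ratio * n_obs)
  if (use_ridge)
    message(sprintf("mvar fit: %d predictors vs %d samples per equation; using ridge (GCV)",
                    n_pred, n_obs))
  a0 <- matrix(0, q, q)
  a_lag <- array(0, dim = c(q, q, p))
  resid <- matrix(0, n_obs, q)
  G <- if (!use_ridge) crossprod(Z) else NULL
  B <- if (!use_ridge) crossprod(Z, Zc) else NULL
  for (i in seq_len(q)) {
    keep <- setdiff(seq_len(ncol(Z)), i)
    if (!use_ridge) {
      beta <- tryCatch(
        solve(G[keep, keep], B[keep, i]),
        error = function(e) {
          if (ridge == "never")
            stopf("rank-deficient design in equation %d; enable ridge or supply more data", i)
          NULL
        })
      if (is.null(beta)) beta <- ridge_gcv(Z[, keep, drop = FALSE], Zc[, i])
    } else {
      beta <- ridge_gcv(Z[, keep, drop = FALSE], Zc[, i])
    }
    a0[i, -i] <- beta[seq_len(q - 1L)]
    for (n in seq_len(p)) {
      a_lag[i, , n] <- beta[(q - 1L) + (n - 1L) * q + seq_len(q)]
    }
    resid[, i] <- Zc[, i] - Z[, keep, drop = FALSE] %*% beta
  }
  structure(list(a0 = a0, a_lag = a_lag, residuals = resid, order = p,
                 ridge_used = use_ridge),
            class = "mvar_fit")
}

as_matrix_series <- function(x) {
  if (inherits(x, c("roi_timeseries", "neural_timeseries"))) return(x$data)
  as.matrix(x)
}

# Ridge regression with the penalty chosen by generalized cross-validation
# over a log-spaced grid, via one SVD of the design.
ridge_gcv <- function(X, y, n_lambda = 30) {
  sv <- svd(X)
  d <- sv$d
  uty <- crossprod(sv$u, y)
  n <- nrow(X)
  lambdas <- mean(d^2) * 10^seq(-6, 2, length.out = n_lambda)
  gcv <- vapply(lambdas, function(l) {
    shrink <- d^2 / (d^2 + l)
    df <- sum(shrink)
    fit_rot <- shrink * uty
    rss <- sum((uty - fit_rot)^2) + sum(y^2) - sum(uty^2)
    n * rss / (n - df)^2
  }, numeric(1))
  l <- lambdas[which.min(gcv)]
  as.numeric(sv$v %*% (d / (d^2 + l) * uty))
}

#' Correlation-purged Granger causality from a model fit
#'
#' The causal strength from region `j` to region `i` is the sum over lags of
#' the squared lagged coefficients, `sum_n a_ij(n)^2`. Zero-lag terms are
#' excluded by construction and the diagonal is zero.
#'
#' @param fit An [fit_mvar_zero_lag()] result.
#' @return q x q non-negative matrix; entry `(i, j)` is the influence of
#'   `j` on `i`.
#' @export
compute_cpgc <- function(fit) {
  m <- apply(fit$a_lag^2, c(1, 2), sum)
  diag(m) <- 0
  m
}

#' Phase-randomization surrogate of one series
#'
#' Preserves the discrete-Fourier magnitude spectrum (hence the mean, the
#' per-frequency power and the autocovariance) while replacing the phases of
#' all non-DC, non-Nyquist frequencies with i.i.d. uniform draws, with
#' conjugate symmetry maintained so the output is real.
#'
#' @param series Real-valued numeric vector.
#' @param seed Integer seed (NULL uses the ambient RNG stream).
#' @return Numeric surrogate series of the same length.
#' @export
phase_randomize <- function(series, seed = NULL) {
  n <- length(series)
  if (n < 3) return(series)
  with_seed(seed, {
    F <- stats::fft(series)
    half <- floor((n - 1) / 2)
    idx <- seq(2, 1 + half)
    ph <- stats::runif(half, 0, 2 * pi)
    F[idx] <- Mod(F[idx]) * exp(1i * ph)
    F[n + 2 - idx] <- Conj(F[idx])
    Re(stats::fft(F, inverse = TRUE)) / n
  })
}

#' Surrogate-thresholded causal network for one subject
#'
#' Computes the observed causal-strength matrix, builds a per-connection
#' null distribution by repeatedly phase-randomizing every column
#' independently (destroying lagged and instantaneous cross-structure) and
#' refitting, converts each connection's null exceedance count to a
#' p-value with the plus-one correction `p = (1 + #(null >= obs)) /
#' (1 + n_surr)`, and applies Benjamini-Hochberg across the `q(q-1)`
#' off-diagonal connections. Connections with adjusted p below `alpha` form
#' the binary directed network.
#'
#' @param neural A `neural_timeseries` or T x q matrix.
#' @param order Model order.
#' @param n_surr Number of surrogate replicates (>= 19).
#' @param alpha FDR level for edge selection.
#' @param seed Integer seed for the surrogate stream.
#' @param surrogate_mode `"independent"` randomizes each column with its own
#'   phases (null of no interaction); `"common"` applies one shared phase
#'   vector to all columns, preserving cross-spectra.
#' @param keep_null Retain the full null sample array (n_surr x q x q).
#' @param ... Passed to [fit_mvar_zero_lag()].
#' @return An object of class `cpgc_result`: `cpgc` (q x q, entry (i, j) =
#'   influence of j on i), `pvals`, `padj`, `adjacency` (same orientation),
#'   `null_samples` (or NULL), `order`, `n_surr`, `alpha`, `roi_labels`.
#'   Use [as_directed_network()] to obtain the source-by-target graph.
#' @export
surrogate_null_and_threshold <- function(neural, order = 1L, n_surr = 1000L,
                                         alpha = 0.05, seed = NULL,
                                         surrogate_mode = c("independent", "common"),
                                         keep_null = FALSE, ...) {
  surrogate_mode <- match.arg(surrogate_mode)
  stopifnot(n_surr >= 19)
  Y <- as_matrix_series(neural)
  q <- ncol(Y)
  labels <- colnames(Y) %||% paste0("ROI", seq_len(q))
  fit <- fit_mvar_zero_lag(Y, order = order, ...)
  obs <- compute_cpgc(fit)
  counts <- matrix(0L, q, q)
  null_samples <- if (keep_null) array(NA_real_, c(n_surr, q, q)) else NULL
  with_seed(seed, {
    for (r in seq_len(n_surr)) {
      Ys <- if (surrogate_mode == "independent") {
        apply(Y, 2, phase_randomize)
      } else {
        common_phase_randomize(Y)
      }
      cp <- tryCatch(
        compute_cpgc(fit_mvar_zero_lag(Ys, order = order, ...)),
        error = function(e) stopf("surrogate replicate %d failed: %s", r,
                                  conditionMessage(e)))
      counts <- counts + (cp >= obs)
      if (keep_null) null_samples[r, , ] <- cp
    }
  })
  pvals <- (1 + counts) / (1 + n_surr)
  diag(pvals) <- 1
  off <- row(pvals) != col(pvals)
  padj <- matrix(1, q, q)
  padj[off] <- stats::p.adjust(pvals[off], method = "BH")
  adjacency <- padj < alpha & off
  dimnames(adjacency) <- dimnames(pvals) <- dimnames(padj) <- list(labels, labels)
  structure(list(cpgc = obs, pvals = pvals, padj = padj,
                 adjacency = adjacency, null_samples = null_samples,
                 order = as.integer(order), n_surr = as.integer(n_surr),
                 alpha = alpha, roi_labels = labels),
            class = "cpgc_result")
}

# One shared phase vector for all columns: preserves the cross-spectrum
# while destroying phase alignment with any external reference.
common_phase_randomize <- function(Y) {
  n <- nrow(Y)
  half <- floor((n - 1) / 2)
  ph <- stats::runif(half, 0, 2 * pi)
  idx <- seq(2, 1 + half)
  apply(Y, 2, function(x) {
    F <- stats::fft(x)
    F[idx] <- Mod(F[idx]) * exp(1i * ph)
    F[n + 2 - idx] <- Conj(F[idx])
    Re(stats::fft(F, inverse = TRUE)) / n
  })
}

#' @export
as_directed_network.cpgc_result <- function(x, ...) {
  directed_network(t(x$adjacency), x$roi_labels)
}

#' @export
print.cpgc_result <- function(x, ...) {
  cat(sprintf("CPGC result: %d regions, %d significant directed edges (alpha = %g, %d surrogates)\n",
              length(x$roi_labels), sum(x$adjacency), x$alpha, x$n_surr))
  invisible(x)
}

#' Write a CPGC result to disk
#'
#' The dense strength and adjacency matrices are written as CSV in
#' target-by-source orientation (row = target, column = source); the edge
#' list TSV is source -> target with the strength and p-value per edge; a
#' JSON sidecar records order, surrogate count, alpha and orientation.
#'
#' @param result A `cpgc_result`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, e.g. the subject id.
#' @return The directory, invisibly.
#' @export
write_cpgc_result <- function(result, dir, prefix = "subject") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- result$cpgc
  dimnames(m) <- list(result$roi_labels, result$roi_labels)
  utils::write.csv(as.data.frame(m),
                   file.path(dir, paste0(prefix, "_cpgc.csv")), row.names = TRUE)
  utils::write.csv(as.data.frame(result$adjacency * 1L),
                   file.path(dir, paste0(prefix, "_adjacency.csv")), row.names = TRUE)
  net <- as_directed_network(result)
  write_edgelist_tsv(net, file.path(dir, paste0(prefix, "_edges.tsv")),
                     weights = t(result$cpgc))
  meta <- list(order = result$order, n_surr = result$n_surr,
               alpha = result$alpha,
               orientation = "matrix entry (i,j): influence of source j on target i; edge list is source->target")
  jsonlite::write_json(meta, file.path(dir, paste0(prefix, "_meta.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
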