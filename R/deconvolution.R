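#' Detect pseudo-events in a resting-state series
#'
#' Resting-state fluctuations are treated as spontaneous event-related
#' responses; candidate events are the local maxima of the standardized
#' (linearly detrended, zero-mean, unit-variance) series that exceed a
#' threshold expressed in standard deviations. Each maximum is counted once
#' (plateaus count at their first sample). Detection is invariant to affine
#' rescaling of the input because of the internal standardization.
#'
#' @param series Numeric vector (one ROI's series).
#' @param threshold_sd Threshold in standard deviations; local maxima at or
#'   below this level are ignored.
#' @return Integer vector of event indices (possibly empty).
#' @export
detect_pseudo_events <- function(series, threshold_sd = 1) {
  x <- standardize(detrend_linear(series))
  n <- length(x)
  if (n < 3) return(integer(0))
  mid <- 2:(n - 1)
  is_max <- x[mid] > x[mid - 1] & x[mid] >= x[mid + 1]
  ev <- mid[is_max & x[mid] > threshold_sd]
  as.integer(ev)
}

#' Estimate an HRF from event-locked responses
#'
#' Least-squares fit of a three-function basis (canonical double-gamma,
#' temporal derivative, dispersion derivative) to the series, with event
#' onsets placed on a small grid of candidate lags before each detected
#' peak (BOLD peaks trail neural events by the hemodynamic delay). The lag
#' minimizing residual variance wins.
#'
#' @param series Numeric vector (one ROI's series).
#' @param events Event indices from [detect_pseudo_events()].
#' @param dt Sampling interval, seconds.
#' @param window_s HRF window, seconds (>= 24).
#' @param lag_grid Candidate onset lags in samples before each peak.
#' @return An [hrf_model()].
#' @export
estimate_hrf <- function(series, events, dt, window_s = 30, lag_grid = 0:2) {
  if (length(events) < 3)
    stopf("need at least 3 events to estimate an HRF, got %d", length(events),
          class = "cpgcnet_no_events")
  n <- length(series)
  t_grid <- seq(0, window_s, by = dt)
  # basis block-averaged over one sampling interval: detected events stand
  # for neural activity sustained across a TR, not instantaneous impulses
  basis <- hrf_basis(t_grid, block_s = dt)
  y <- standardize(detrend_linear(series))
  best <- NULL
  for (lag in lag_grid) {
    onsets <- events - lag
    onsets <- onsets[onsets >= 1 & onsets <= n]
    if (!length(onsets)) next
    u <- numeric(n)
    u[onsets] <- 1
    X <- sapply(seq_len(ncol(basis)), function(k) {
      h <- basis[, k]
      conv <- stats::filter(c(rep(0, length(h) - 1), u), h,
                            method = "convolution", sides = 1)
      as.numeric(conv[(length(h) - 1) + seq_len(n)])
    })
    fit <- stats::lm.fit(cbind(1, X), y)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(rss = rss, lag = lag, coef = fit$coefficients[-1],
                   r2 = 1 - rss / sum((y - mean(y))^2))
    }
  }
  if (is.null(best)) stopf("no usable event onsets", class = "cpgcnet_no_events")
  w <- best$coef
  w[is.na(w)] <- 0
  curve <- as.numeric(basis %*% w)
  if (max(abs(curve)) == 0)
    stopf("degenerate HRF fit (all-zero curve)", class = "cpgcnet_no_events")
  out <- hrf_model(curve, dt = dt, basis_weights = w, window_s = window_s,
                   onset_lag = as.integer(best$lag),
                   n_events = length(events))
  out$r2 <- best$r2
  out
}

#' Wiener deconvolution of one series
#'
#' Frequency-domain inversion with a constant noise-to-signal regularizer:
#' the latent spectrum is `conj(H) * S / (|H|^2 + nsr)`, inverse-transformed
#' to the time domain. Computed on a zero-padded grid (length >= T + HRF
#' length) so that the inversion acts on the linear, not circular,
#' convolution. With `nsr = 0` and an invertible HRF this is the exact
#' inverse filter; as `nsr` grows the output shrinks toward zero.
#'
#' @param series Numeric vector of length T.
#' @param hrf An [hrf_model()] sampled at the same interval.
#' @param nsr Noise-to-signal ratio (>= 0), or `"auto"` to estimate it from
#'   the ratio of mean periodogram power in the upper quartile of
#'   frequencies (noise-dominated) to the remainder (signal-dominated).
#' @return Numeric vector of length T (the estimated latent series).
#' @export
wiener_deconvolve <- function(series, hrf, nsr = 0.1) {
  if (max(abs(hrf$curve)) == 0) stopf("all-zero HRF is not invertible")
  n <- length(series)
  L <- length(hrf$curve)
  if (identical(nsr, "auto")) nsr <- estimate_nsr(series)
  stopifnot(is.numeric(nsr), nsr >= 0)
  N <- stats::nextn(n + L, 2)
  S <- stats::fft(c(series, rep(0, N - n)))
  H <- stats::fft(c(hrf$curve, rep(0, N - L)))
  denom <- Mod(H)^2 + nsr
  gain <- ifelse(denom < 1e-300, 0 + 0i, Conj(H) / denom)
  latent <- Re(stats::fft(S * gain, inverse = TRUE)) / N
  latent[seq_len(n)]
}

# Crude spectral noise-level estimate: mean periodogram power above the
# upper-quartile frequency over mean power below it.
estimate_nsr <- function(series) {
  x <- series - mean(series)
  p <- Mod(stats::fft(x))^2
  half <- p[2:(floor(length(x) / 2) + 1)]
  k <- length(half)
  hi <- half[ceiling(0.75 * k):k]
  lo <- half[1:floor(0.75 * k)]
  max(mean(hi) / max(mean(lo), .Machine$double.eps), 0)
}

#' Blind deconvolution of a whole subject
#'
#' Applies pseudo-event detection, HRF estimation and Wiener inversion to
#' every ROI column independently. Columns whose event count is too small
#' for an HRF fit either fall back to the canonical HRF (default, recorded
#' in the per-ROI log) or raise an error naming the column.
#'
#' @param obs A [roi_timeseries()].
#' @param threshold_sd Event threshold in standard deviations.
#' @param nsr Wiener noise-to-signal regularizer (or `"auto"`).
#' @param window_s HRF window, seconds.
#' @param on_too_few_events `"canonical"` (fall back to the canonical HRF)
#'   or `"error"`.
#' @return An object of class `neural_timeseries`: list with `data` (T x q
#'   matrix), `dt`, `roi_labels`, `subject_id`, `hrfs` (per-ROI
#'   [hrf_model()]s) and `log` (per-ROI event counts, fit R^2, fallback flag).
#' @export
deconvolve_subject <- function(obs, threshold_sd = 1, nsr = 0.1,
                               window_s = 30,
                               on_too_few_events = c("canonical", "error")) {
  on_too_few_events <- match.arg(on_too_few_events)
  q <- ncol(obs$data)
  out <- matrix(0, nrow(obs$data), q)
  hrfs <- vector("list", q)
  log <- data.frame(roi = obs$roi_labels, n_events = NA_integer_,
                    r2 = NA_real_, fallback = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(q)) {
    x <- standardize(detrend_linear(obs$data[, j]))
    ev <- detect_pseudo_events(obs$data[, j], threshold_sd)
    log$n_events[j] <- length(ev)
    hrf <- tryCatch(
      estimate_hrf(obs$data[, j], ev, dt = obs$dt, window_s = window_s),
      cpgcnet_no_events = function(e) {
        if (on_too_few_events == "error")
          stopf("ROI %s ('%s'): %s", j, obs$roi_labels[j], conditionMessage(e))
        log$fallback[j] <<- TRUE
        canonical_hrf(obs$dt, window_s, block_s = obs$dt)
      })
    log$r2[j] <- hrf$r2 %||% NA_real_
    hrfs[[j]] <- hrf
    out[, j] <- wiener_deconvolve(x, hrf, nsr)
  }
  colnames(out) <- obs$roi_labels
  structure(list(data = out, dt = obs$dt, roi_labels = obs$roi_labels,
                 subject_id = obs$subject_id, hrfs = hrfs, log = log),
            class = "neural_timeseries")
}

#' @export
print.neural_timeseries <- function(x, ...) {
  cat(sprintf("Deconvolved neural series '%s': %d timepoints x %d regions (%d canonical fallbacks)\n",
              x$subject_id, nrow(x$data), ncol(x$data), sum(x$log$fallback)))
  invisible(x)
}
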