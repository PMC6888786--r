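#' Double-gamma hemodynamic response function
#'
#' The canonical two-gamma impulse response linking neural events to the
#' BOLD signal: a positive lobe peaking around 6 s followed by a weaker
#' undershoot around 16 s. Parameterized by the mode (peak time) and
#' dispersion of each lobe so that regional and subject variability can be
#' injected by jittering interpretable quantities.
#'
#' @param t Time grid in seconds (>= 0).
#' @param peak_time Mode of the positive lobe, seconds.
#' @param under_time Mode of the undershoot lobe, seconds.
#' @param disp Dispersion (gamma scale) of the positive lobe, seconds.
#' @param under_disp Dispersion of the undershoot lobe, seconds.
#' @param under_ratio Amplitude ratio of undershoot to peak.
#' @return Numeric vector, normalized to unit peak absolute amplitude.
#' @export
double_gamma_hrf <- function(t, peak_time = 6, under_time = 16,
                             disp = 1, under_disp = 1, under_ratio = 1 / 6) {
  stopifnot(all(t >= 0), peak_time > 0, under_time > 0, disp > 0, under_disp > 0)
  h <- stats::dgamma(t, shape = 1 + peak_time / disp, rate = 1 / disp) -
    under_ratio * stats::dgamma(t, shape = 1 + under_time / under_disp,
                                rate = 1 / under_disp)
  m <- max(abs(h))
  if (m > 0) h <- h / m
  h
}

#' HRF basis set: canonical curve plus two derivatives
#'
#' Three regressors sampled on a time grid: the canonical double-gamma
#' response, its temporal derivative (finite difference with respect to
#' onset shift, capturing latency differences) and its dispersion
#' derivative (finite difference with respect to the peak dispersion,
#' capturing width differences).
#'
#' When `block_s > 0` each basis function is convolved with a boxcar of that
#' duration before sampling, giving the effective response to neural
#' activity sustained over one acquisition interval rather than to an
#' instantaneous impulse -- the appropriate kernel for slowly sampled
#' resting-state data.
#'
#' @param t Time grid in seconds.
#' @param delta_t Onset-shift step for the temporal derivative, seconds.
#' @param delta_d Dispersion step for the dispersion derivative, seconds.
#' @param block_s Boxcar duration for block averaging, seconds (0 = none).
#' @inheritParams double_gamma_hrf
#' @return A length(t) x 3 matrix with columns `canonical`, `temporal`,
#'   `dispersion`.
#' @export
hrf_basis <- function(t, peak_time = 6, under_time = 16, disp = 1,
                      under_disp = 1, under_ratio = 1 / 6,
                      delta_t = 1, delta_d = 0.01, block_s = 0) {
  gen <- function(pt, dsp) {
    if (block_s <= 0) {
      double_gamma_hrf(t, pt, under_time, dsp, under_disp, under_ratio)
    } else {
      block_averaged_hrf(t, block_s, pt, under_time, dsp, under_disp, under_ratio)
    }
  }
  shift <- function(h) {
    # shift a sampled curve later by delta_t via linear interpolation
    tt <- t - delta_t
    stats::approx(t, h, xout = pmax(tt, 0), rule = 2)$y
  }
  h0 <- gen(peak_time, disp)
  cbind(canonical = h0,
        temporal = (h0 - shift(h0)) / delta_t,
        dispersion = (h0 - gen(peak_time, disp + delta_d)) / delta_d)
}

# Effective kernel for neural activity sustained over `block_s` seconds:
# double-gamma response convolved with a unit boxcar on a fine internal
# grid, then sampled at the requested times.
block_averaged_hrf <- function(t, block_s, peak_time = 6, under_time = 16,
                               disp = 1, under_disp = 1, under_ratio = 1 / 6,
                               dt_fine = 0.1) {
  t_fine <- seq(0, max(t) + block_s, by = dt_fine)
  h <- double_gamma_hrf(t_fine, peak_time, under_time, disp, under_disp,
                        under_ratio)
  w <- max(1L, round(block_s / dt_fine))
  conv <- stats::filter(c(rep(0, w - 1), h), rep(1 / w, w),
                        method = "convolution", sides = 1)
  heff <- as.numeric(conv[(w - 1) + seq_along(t_fine)])
  out <- stats::approx(t_fine, heff, xout = t, rule = 2)$y
  m <- max(abs(out))
  if (m > 0) out <- out / m
  out
}

#' Construct an HRF model object
#'
#' @param curve Sampled impulse response on the acquisition grid.
#' @param dt Sampling interval of `curve`, seconds.
#' @param basis_weights Length-3 weights on (canonical, temporal, dispersion).
#' @param window_s Length of the response window, seconds (>= 24 s).
#' @param onset_lag Event-onset lag (samples before the detected peak) chosen
#'   during fitting.
#' @param n_events Number of pseudo-events that informed the fit.
#' @return An object of class `hrf_model`. The curve is normalized to unit
#'   peak absolute amplitude.
#' @export
hrf_model <- function(curve, dt, basis_weights = c(NA_real_, NA_real_, NA_real_),
                      window_s = (length(curve) - 1) * dt,
                      onset_lag = NA_integer_, n_events = NA_integer_) {
  curve <- as.numeric(curve)
  if (!all(is.finite(curve))) stopf("HRF curve must be finite")
  if (window_s < 24) stopf("HRF window must cover at least 24 s, got %.1f", window_s)
  m <- max(abs(curve))
  if (m == 0) stopf("all-zero HRF curve is not a valid model")
  structure(list(curve = curve / m, dt = dt, basis_weights = basis_weights / m,
                 window_s = window_s, onset_lag = onset_lag, n_events = n_events),
            class = "hrf_model")
}

#' Canonical HRF model on a sampling grid
#'
#' @param dt Sampling interval, seconds.
#' @param window_s Response window, seconds.
#' @param block_s Boxcar duration for block averaging, seconds (0 gives the
#'   impulse response; set to `dt` for the effective kernel of activity
#'   sustained over one sampling interval).
#' @return An [hrf_model()] with the canonical double-gamma curve and basis
#'   weights `(1, 0, 0)`.
#' @export
canonical_hrf <- function(dt, window_s = 30, block_s = 0) {
  t <- seq(0, window_s, by = dt)
  curve <- if (block_s > 0) block_averaged_hrf(t, block_s)
           else double_gamma_hrf(t)
  hrf_model(curve, dt = dt, basis_weights = c(1, 0, 0),
            window_s = window_s, onset_lag = 0L)
}

#' @export
print.hrf_model <- function(x, ...) {
  cat(sprintf("HRF model: %d samples at dt = %.2f s (window %.0f s), peak at %.1f s\n",
              length(x$curve), x$dt, x$window_s,
              (which.max(x$curve) - 1) * x$dt))
  invisible(x)
}

#' Export an HRF curve as CSV
#'
#' Two columns: time in seconds and amplitude.
#'
#' @param hrf An [hrf_model()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_hrf_csv <- function(hrf, path) {
  df <- data.frame(time = (seq_along(hrf$curve) - 1) * hrf$dt,
                   amplitude = hrf$curve)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
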