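# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Remove a linear trend from a series
#'
#' Ordinary least-squares detrending against time index; used as minimal
#' conditioning before event detection and spectral operations.
#'
#' @param x Numeric vector.
#' @return Numeric vector of residuals from the linear fit.
#' @keywords internal
detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  stats::lm.fit(cbind(1, t), x)$residuals
}

# Zero mean, unit variance; constant series map to all zeros.
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Derive a deterministic stream of sub-seeds from a master seed, so that
# per-subject and per-stage randomness is reproducible yet decoupled.
# All sub-seeds stay within 32-bit integer range.
derive_seeds <- function(master_seed, n, salt = 0L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed((as.integer(master_seed) + 7919L * as.integer(salt)) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run an expression under a local RNG seed (NULL seed = ambient stream).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# FNV-1a hash of a character scalar, as 8 hex digits; stamps configs into
# output metadata without a heavyweight digest dependency.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) + (h %/% 2^31) * 2^31
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  if (is.null(class)) stop(msg, call. = FALSE)
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}
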