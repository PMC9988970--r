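#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Robust standard deviation (MAD-based)
#'
#' Median absolute deviation scaled for consistency with the Gaussian SD.
#' Used wherever a spread estimate must not be inflated by artifacts.
#'
#' @param x numeric vector.
#' @return scalar robust SD estimate.
#' @keywords internal
robust_sd <- function(x) stats::mad(x, constant = 1.4826, na.rm = TRUE)

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

# Zero-phase Butterworth band-pass, forward-backward (signal::filtfilt).
# The filter object is cached by (order, band, fs) within a session.
bandpass_filter <- function(fs, band_hz, order = 3) {
  ny <- fs / 2
  if (band_hz[2] >= ny)
    stop_invalid("band upper edge %.3f Hz must be below Nyquist %.3f Hz",
                 band_hz[2], ny)
  signal::butter(order, band_hz / ny, type = "pass")
}

zero_phase <- function(filt, x) signal::filtfilt(filt, x)

# filtfilt is linear in its input, so its action on fixed-length windows is a
# matrix; precomputing it turns thousands of per-window filter calls into one
# matrix product, bit-identical to calling signal::filtfilt per window.
zero_phase_operator <- function(filt, n) {
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    A[, j] <- signal::filtfilt(filt, e)
  }
  A
}

# half-open [start, end) sample intervals in seconds -> logical mask
intervals_to_mask <- function(n, fs, intervals) {
  mask <- logical(n)
  if (is.null(intervals) || nrow(intervals) == 0) return(mask)
  for (i in seq_len(nrow(intervals))) {
    a <- max(1L, floor(intervals$start_s[i] * fs) + 1L)
    b <- min(n, ceiling(intervals$end_s[i] * fs))
    if (b >= a) mask[a:b] <- TRUE
  }
  mask
}

# merge sorted/unsorted half-open intervals (two-column df start_s, end_s)
merge_intervals <- function(df) {
  if (is.null(df) || nrow(df) == 0)
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  df <- df[order(df$start_s), , drop = FALSE]
  out <- df[1, , drop = FALSE]
  for (i in seq_len(nrow(df))[-1]) {
    k <- nrow(out)
    if (df$start_s[i] <= out$end_s[k]) {
      out$end_s[k] <- max(out$end_s[k], df$end_s[i])
    } else {
      out <- rbind(out, df[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}
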