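#' Build the nuisance-regression design
#'
#' Fourier sine/cosine pairs at frequencies `m/T` (T = `n_samples/fs`) for
#' every integer `m` with `m/T > cutoff_hz` and `m/T < fs/2`, plus discrete
#' orthogonal polynomials of the requested orders (order 0 is the constant).
#' Regressing these out and keeping the residual acts like a band-pass of
#' roughly 0.004-0.09 Hz: the Fourier block removes everything above the
#' cutoff, the polynomial block removes slow drift. All columns are
#' unit-normalized; on the uniform sample grid the Fourier block is exactly
#' orthonormal (it is a subset of the DFT basis), which the regression
#' exploits.
#'
#' The polynomial block uses discrete orthogonal (Gram) polynomials
#' (`stats::poly`), which are exactly orthogonal on the sample grid and
#' converge to Legendre polynomials; "orders 0-4" means constant through
#' quartic.
#'
#' @param n_samples number of samples.
#' @param fs sampling rate, Hz.
#' @param cutoff_hz frequency above which Fourier regressors are included.
#' @param legendre_orders polynomial orders to include (default 0:4).
#' @return `nuisance_design`: `X` (n x k matrix), `labels`, index vectors of
#'   the Fourier and polynomial blocks, and bookkeeping fields.
#' @export
build_design <- function(n_samples, fs, cutoff_hz = 0.09,
                         legendre_orders = 0:4) {
  key <- paste(n_samples, fs, cutoff_hz, paste(legendre_orders, collapse = ","))
  cached <- .design_cache[[key]]
  if (!is.null(cached)) return(cached)
  n <- as.integer(n_samples)
  T_s <- n / fs
  m_min <- floor(cutoff_hz * T_s) + 1L          # smallest m with m/T > cutoff
  if (m_min / T_s == cutoff_hz) m_min <- m_min + 1L
  m_max <- as.integer(ceiling(n / 2) - 1L)       # largest m with m/T < fs/2
  ms <- if (m_min <= m_max) seq.int(m_min, m_max) else integer(0)
  j <- seq_len(n) - 1L
  four <- matrix(0, n, 2L * length(ms))
  labels <- character(2L * length(ms))
  if (length(ms)) {
    ang <- outer(j, ms) * (2 * pi / n)
    # sin/cos at DFT frequencies have exact norm sqrt(n/2)
    four[, seq(1L, 2L * length(ms), 2L)] <- sin(ang) / sqrt(n / 2)
    four[, seq(2L, 2L * length(ms), 2L)] <- cos(ang) / sqrt(n / 2)
    f <- ms / T_s
    labels[seq(1L, 2L * length(ms), 2L)] <- sprintf("fourier_sin(%.6g)", f)
    labels[seq(2L, 2L * length(ms), 2L)] <- sprintf("fourier_cos(%.6g)", f)
  }

  legendre_orders <- sort(unique(as.integer(legendre_orders)))
  poly_cols <- NULL
  if (length(legendre_orders)) {
    maxo <- max(legendre_orders)
    P <- if (maxo >= 1) stats::poly(j, degree = maxo) else NULL
    cols <- lapply(legendre_orders, function(o) {
      if (o == 0) rep(1 / sqrt(n), n) else P[, o] / sqrt(sum(P[, o]^2))
    })
    poly_cols <- do.call(cbind, cols)
    labels <- c(labels, sprintf("legendre(%d)", legendre_orders))
  }
  X <- cbind(four, poly_cols)
  k <- ncol(X)
  if (k >= n)
    stop_invalid("design has %d columns for %d samples; rank-deficient by construction", k, n)
  colnames(X) <- labels
  out <- structure(list(X = X, labels = labels,
                 fourier_idx = seq_len(ncol(four)),
                 poly_idx = if (length(legendre_orders))
                   ncol(four) + seq_along(legendre_orders) else integer(0),
                 fourier_orthonormal = TRUE,
                 n = n, fs = fs, cutoff_hz = cutoff_hz,
                 legendre_orders = legendre_orders,
                 fourier_freqs = if (length(ms)) ms / T_s else numeric(0)),
            class = "nuisance_design")
  .design_cache[[key]] <- out
  out
}

# session-scoped cache: designs depend only on (n, fs, cutoff, orders)
.design_cache <- new.env(parent = emptyenv())

# exact OLS residual of Y on [F | B] where F is an orthonormal block:
# project out F, orthonormalize the remaining columns (QR), project them out
ols_residual_fast <- function(Y, F, B, labels_B = NULL) {
  R <- Y - F %*% crossprod(F, Y)
  if (!is.null(B) && ncol(B)) {
    Bt <- B - F %*% crossprod(F, B)
    qrB <- qr(Bt)
    rd <- abs(diag(qr.R(qrB)))
    dep <- which(rd < 1e-8 * max(rd, 1))
    if (length(dep))
      stop_invalid("design rank-deficient; dependent columns: %s",
                   paste(labels_B[qrB$pivot[dep]] %||% qrB$pivot[dep],
                         collapse = ", "))
    Q <- qr.Q(qrB)
    R <- R - Q %*% crossprod(Q, R)
  }
  R
}

#' Nuisance regression: temporal filtering plus global signal
#'
#' Per channel, returns the ordinary-least-squares residual of the series on
#' the nuisance design, optionally augmented with the global signal (mean
#' over valid channels, per chromophore). HbO and HbR are cleaned
#' independently; HbT is recomputed as cleaned HbO + cleaned HbR. No
#' pre-whitening is applied.
#'
#' @param hemo a `hemo_series`.
#' @param design a `nuisance_design` (built for the series length if NULL).
#' @param include_global append the mean signal over valid channels as a
#'   regressor.
#' @param validity optional `channel_validity` defining the channels entering
#'   the global mean (all non-NA channels if NULL).
#' @return cleaned `hemo_series` (same shape) with regression provenance.
#' @export
regress_nuisance <- function(hemo, design = NULL, include_global = TRUE,
                             validity = NULL) {
  n <- nrow(hemo$hbo)
  design <- design %||% build_design(n, hemo$fs)
  if (design$n != n) stop_invalid("design built for %d samples, series has %d",
                                  design$n, n)
  valid <- if (is.null(validity)) !apply(is.na(hemo$hbo), 2, any)
           else validity$valid & !apply(is.na(hemo$hbo), 2, any)
  if (include_global && sum(valid) < 2)
    stop_invalid("global signal regression needs at least 2 valid channels")
  Fb <- design$X[, design$fourier_idx, drop = FALSE]
  Pb <- design$X[, -design$fourier_idx, drop = FALSE]
  if (!length(design$fourier_idx)) { Fb <- matrix(0, n, 0); Pb <- design$X }
  k_total <- ncol(design$X) + as.integer(include_global)
  if (n <= k_total) stop_invalid("fewer samples (%d) than regressors (%d)",
                                 n, k_total)
  clean_one <- function(M) {
    out <- M
    g <- if (include_global) rowMeans(M[, valid, drop = FALSE]) else NULL
    if (!is.null(g)) {
      nrm <- sqrt(sum(g^2))
      g <- if (nrm > 0) g / nrm else NULL
    }
    B <- cbind(Pb, g)
    labs <- c(colnames(Pb), if (!is.null(g)) "global_signal")
    cols <- which(!apply(is.na(M), 2, any))
    out[, cols] <- ols_residual_fast(M[, cols, drop = FALSE], Fb, B, labs)
    out
  }
  hemo$hbo <- clean_one(hemo$hbo)
  hemo$hbr <- clean_one(hemo$hbr)
  hemo$hbt <- hemo$hbo + hemo$hbr
  hemo$provenance$nuisance <- list(
    cutoff_hz = design$cutoff_hz, legendre_orders = design$legendre_orders,
    k = ncol(design$X), include_global = include_global,
    prewhitening = FALSE)
  hemo
}

#' Resample a hemoglobin series to 1 Hz
#'
#' Zero-phase anti-alias low-pass (4th-order Butterworth, 0.45 Hz cutoff,
#' forward-backward) followed by interpolation onto the integer-second grid.
#' Output length is `floor(n_samples / fs)`; DC is preserved exactly and the
#' 0.01-0.08 Hz passband to within 2%.
#'
#' @param hemo a `hemo_series` at `fs >= 1` Hz.
#' @return `hemo_series` with `fs = 1`.
#' @export
resample_to_1hz <- function(hemo) {
  fs <- hemo$fs
  if (fs < 1) stop_invalid("fs must be >= 1 Hz")
  n <- nrow(hemo$hbo)
  n_out <- floor(n / fs)
  if (fs == 1) return(hemo)
  filt <- signal::butter(4, 0.45 / (fs / 2), type = "low")
  t_in <- (seq_len(n) - 1) / fs
  t_out <- seq_len(n_out) - 1
  pad <- min(n - 1L, ceiling(10 * fs))   # odd-reflection padding tames
  res_one <- function(M) {               # the filter's edge transients
    out <- matrix(NA_real_, n_out, ncol(M), dimnames = list(NULL, colnames(M)))
    for (ch in seq_len(ncol(M))) {
      v <- M[, ch]
      if (anyNA(v)) next
      vp <- c(2 * v[1] - v[pad:2], v, 2 * v[n] - v[(n - 1):(n - pad + 1)])
      f <- signal::filtfilt(filt, vp)[pad:(pad + n - 1)]
      out[, ch] <- stats::approx(t_in, f, xout = t_out, rule = 2)$y
    }
    out
  }
  hemo$hbo <- res_one(hemo$hbo)
  hemo$hbr <- res_one(hemo$hbr)
  hemo$hbt <- hemo$hbo + hemo$hbr
  hemo$fs <- 1
  hemo
}
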