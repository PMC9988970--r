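#' Windowed signal-quality metrics (SCI and PSP)
#'
#' Computes, in sliding windows (default 5 s with 50% overlap), the scalp
#' coupling index and peak spectral power of every channel. Per window, both
#' wavelength signals are linearly detrended (slow hemodynamics would
#' otherwise leak through the short-window filter), band-pass filtered to
#' the cardiac band (default 90-210 bpm, i.e. 1.5-3.5 Hz) with a zero-phase
#' forward-backward Butterworth filter (order 3) and amplitude-normalized.
#' SCI is the
#' zero-lag Pearson correlation of the two filtered signals; PSP is the
#' maximum of the power spectrum of their normalized cross-correlation
#' restricted to the cardiac band. Window and hop lengths are
#' `floor(window_s * fs)` and `floor(window_s * fs * (1 - overlap))` samples.
#'
#' @param raw a `raw_recording`.
#' @param window_s window length, seconds.
#' @param overlap fractional overlap of consecutive windows.
#' @param cardiac_bpm cardiac range in beats per minute.
#' @param filter_order Butterworth order of the cardiac band-pass.
#' @return `quality_metrics`: window start times (s), SCI and PSP matrices
#'   (window x channel), window/overlap/band bookkeeping, and a `flat`
#'   logical matrix flagging zero-variance windows (SCI defined as 0 there).
#' @export
compute_windowed_quality <- function(raw, window_s = 5, overlap = 0.5,
                                     cardiac_bpm = c(90, 210),
                                     filter_order = 3) {
  fs <- raw$fs
  n <- dim(raw$intensity)[1]
  nch <- dim(raw$intensity)[2]
  win_len <- floor(window_s * fs)
  hop <- max(1L, floor(window_s * fs * (1 - overlap)))
  if (win_len > n) stop_invalid("window longer than recording")
  band <- cardiac_bpm / 60
  if (band[2] >= fs / 2)
    stop_invalid("cardiac band upper edge must be below fs/2")
  starts <- seq(1L, n - win_len + 1L, by = hop)
  nwin <- length(starts)
  filt <- bandpass_filter(fs, band, order = filter_order)
  # detrend + filtfilt are both linear; compose them into one operator
  Xd <- cbind(1, seq_len(win_len))
  P <- diag(win_len) - Xd %*% solve(crossprod(Xd), t(Xd))
  A <- zero_phase_operator(filt, win_len) %*% P

  sci <- matrix(NA_real_, nwin, nch)
  psp <- matrix(NA_real_, nwin, nch)
  flat <- matrix(FALSE, nwin, nch)
  win_idx <- outer(seq_len(win_len) - 1L, starts, `+`)  # win_len x nwin
  L2 <- 2L * win_len
  band_bins <- which((seq_len(L2) - 1) * fs / L2 >= band[1] &
                     (seq_len(L2) - 1) * fs / L2 <= band[2])
  for (ch in seq_len(nch)) {
    W1 <- matrix(raw$intensity[, ch, 1][win_idx], win_len, nwin)
    W2 <- matrix(raw$intensity[, ch, 2][win_idx], win_len, nwin)
    F1 <- A %*% W1
    F2 <- A %*% W2
    F1 <- sweep(F1, 2, colMeans(F1))
    F2 <- sweep(F2, 2, colMeans(F2))
    s1 <- sqrt(colSums(F1^2))
    s2 <- sqrt(colSums(F2^2))
    zero <- s1 < 1e-14 | s2 < 1e-14
    flat[, ch] <- zero
    r <- colSums(F1 * F2) / ifelse(zero, 1, s1 * s2)
    r[zero] <- 0
    sci[, ch] <- clamp(r, -1, 1)
    # amplitude-normalized (unit-SD) windows
    sd1 <- s1 / sqrt(win_len - 1); sd2 <- s2 / sqrt(win_len - 1)
    U <- sweep(F1, 2, ifelse(zero, 1, sd1), `/`)
    V <- sweep(F2, 2, ifelse(zero, 1, sd2), `/`)
    # biased normalized cross-correlation via FFT (circular on 2L grid gives
    # the full linear cross-correlation of zero-padded windows)
    Up <- rbind(U, matrix(0, win_len, nwin))
    Vp <- rbind(V, matrix(0, win_len, nwin))
    CC <- Re(stats::mvfft(stats::mvfft(Up) * Conj(stats::mvfft(Vp)),
                          inverse = TRUE)) / (L2 * win_len)
    P <- abs(stats::mvfft(CC))^2 / L2
    pk <- apply(P[band_bins, , drop = FALSE], 2, max)
    pk[zero] <- 0
    psp[, ch] <- pk
  }
  colnames(sci) <- colnames(psp) <- raw$montage$channels$name
  structure(list(window_start_s = (starts - 1) / fs, start_idx = starts,
                 sci = sci, psp = psp, flat = flat,
                 window_s = window_s, overlap = overlap,
                 cardiac_hz = band, win_len = win_len, hop = hop, fs = fs),
            class = "quality_metrics")
}

#' Detect signal-dropout intervals
#'
#' A channel is in dropout while its intensity (either wavelength) stays
#' below `rel_threshold` times the channel's median intensity for longer
#' than `min_dur_s` (optodes lifting off the scalp).
#'
#' @param raw a `raw_recording`.
#' @param rel_threshold fraction of the channel median intensity.
#' @param min_dur_s minimum sustained duration, seconds.
#' @return data.frame with columns `channel`, `start_s`, `end_s`
#'   (half-open intervals).
#' @export
detect_dropout <- function(raw, rel_threshold = 0.01, min_dur_s = 0.5) {
  fs <- raw$fs
  n <- dim(raw$intensity)[1]
  out <- data.frame(channel = integer(0), start_s = numeric(0),
                    end_s = numeric(0))
  for (ch in seq_len(dim(raw$intensity)[2])) {
    low <- rep(FALSE, n)
    for (w in seq_len(dim(raw$intensity)[3])) {
      v <- raw$intensity[, ch, w]
      low <- low | (v < rel_threshold * stats::median(v))
    }
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values & r$lengths / fs > min_dur_s
    if (any(keep))
      out <- rbind(out, data.frame(channel = ch,
                                   start_s = (starts[keep] - 1) / fs,
                                   end_s = ends[keep] / fs))
  }
  out
}

#' Select the contiguous best-quality subsample
#'
#' Returns the contiguous span of `floor(duration_s * fs)` samples maximizing
#' the mean, over fully covered windows and non-excluded channels, of the
#' rank-normalized SCI plus rank-normalized PSP. Candidate starts lie on the
#' quality-window hop grid. Any span overlapping a dropout interval scores
#' `-Inf`; if every candidate overlaps dropout, the least-contaminated span
#' is returned with a warning. Ties break to the earliest start.
#'
#' @param quality a `quality_metrics`.
#' @param raw the corresponding `raw_recording`.
#' @param duration_s subsample length, seconds (default 150 = 2.5 min).
#' @param dropout dropout table from [detect_dropout()] (computed if NULL).
#' @param validity optional `channel_validity`; invalid channels are excluded
#'   from the score.
#' @return `sample_window`: `start`/`end` (0-based half-open sample indices),
#'   `score`, `dropout_free`, `fs`.
#' @export
select_best_subsample <- function(quality, raw, duration_s = 150,
                                  dropout = NULL, validity = NULL) {
  fs <- quality$fs
  n <- dim(raw$intensity)[1]
  span_len <- floor(duration_s * fs)
  if (span_len > n)
    stop_invalid("session invalid: recording (%d samples) shorter than requested subsample (%d)",
                 n, span_len)
  dropout <- dropout %||% detect_dropout(raw)
  ch_keep <- if (is.null(validity)) seq_len(ncol(quality$sci)) else
    which(validity$valid)
  if (!length(ch_keep)) stop_invalid("no valid channels to score")

  # rank-normalize each metric over all window x channel entries
  rank_norm <- function(m) {
    r <- m
    r[] <- rank(m, ties.method = "average") / length(m)
    r
  }
  score_mat <- rank_norm(quality$sci)[, ch_keep, drop = FALSE] +
    rank_norm(quality$psp)[, ch_keep, drop = FALSE]
  win_score <- rowMeans(score_mat)

  starts <- quality$start_idx[quality$start_idx + span_len - 1L <= n]
  if (!length(starts)) starts <- 1L
  drop_mask <- intervals_to_mask(n, fs, dropout)
  scores <- numeric(length(starts))
  overlap_amt <- numeric(length(starts))
  for (k in seq_along(starts)) {
    s0 <- starts[k]; s1 <- s0 + span_len - 1L
    covered <- quality$start_idx >= s0 &
      (quality$start_idx + quality$win_len - 1L) <= s1
    scores[k] <- if (any(covered)) mean(win_score[covered]) else -Inf
    overlap_amt[k] <- sum(drop_mask[s0:s1])
  }
  clean <- overlap_amt == 0
  if (any(clean)) {
    cand <- which(clean)
    best <- cand[which.max(scores[cand])]
    dropout_free <- TRUE
  } else {
    warning("no dropout-free span of the requested length; returning the least-contaminated span")
    least <- overlap_amt == min(overlap_amt)
    cand <- which(least)
    best <- cand[which.max(scores[cand])]
    dropout_free <- FALSE
  }
  structure(list(start = starts[best] - 1L, end = starts[best] - 1L + span_len,
                 score = scores[best], dropout_free = dropout_free, fs = fs),
            class = "sample_window")
}

#' Detect channels with cardiac pulsation
#'
#' A channel is valid iff (i) the fraction of quality windows with
#' `SCI >= sci_threshold` and `PSP >= psp_threshold` is at least
#' `min_good_window_fraction`, and (ii) the channel's full-subsample power
#' spectrum has a local maximum inside the cardiac band exceeding the band's
#' median power by `peak_factor`. The spectral criterion is a declared
#' reconstruction of the study's frequency-domain check; thresholds are
#' configuration, not reported study values.
#'
#' @param raw a `raw_recording`.
#' @param window optional `sample_window`; metrics and spectra are computed on
#'   the subsample when given.
#' @param sci_threshold,psp_threshold,min_good_window_fraction,peak_factor
#'   detection parameters (defaults 0.7, 0.1, 0.6, 2).
#' @param cardiac_bpm cardiac range, beats per minute.
#' @param quality optional precomputed `quality_metrics` (matching `window`).
#' @return `channel_validity` data.frame: `channel`, `name`, `valid`,
#'   `reason` (`"ok"` or `"no_cardiac"`).
#' @export
detect_cardiac_channels <- function(raw, window = NULL,
                                    sci_threshold = 0.7, psp_threshold = 0.1,
                                    min_good_window_fraction = 0.6,
                                    peak_factor = 2,
                                    cardiac_bpm = c(90, 210),
                                    quality = NULL) {
  x <- raw$intensity
  if (!is.null(window)) x <- x[(window$start + 1):window$end, , , drop = FALSE]
  sub <- structure(list(intensity = x, fs = raw$fs, montage = raw$montage),
                   class = "raw_recording")
  quality <- quality %||% compute_windowed_quality(sub, cardiac_bpm = cardiac_bpm)
  band <- cardiac_bpm / 60
  n <- dim(x)[1]
  freqs <- (seq_len(n) - 1) * raw$fs / n
  in_band <- freqs >= band[1] & freqs <= band[2] & freqs <= raw$fs / 2
  nch <- dim(x)[2]
  valid <- logical(nch)
  for (ch in seq_len(nch)) {
    frac <- mean(quality$sci[, ch] >= sci_threshold &
                 quality$psp[, ch] >= psp_threshold)
    # full-subsample spectrum, averaged over wavelengths of the normalized,
    # detrended intensity
    pow <- rep(0, n)
    for (w in seq_len(dim(x)[3])) {
      v <- x[, ch, w]
      v <- v - mean(v)
      s <- stats::sd(v)
      if (s > 0) v <- v / s
      pow <- pow + abs(stats::fft(v))^2 / n
    }
    bp <- pow[in_band]
    k <- length(bp)
    local_max <- k >= 3 && any(bp[2:(k - 1)] > bp[1:(k - 2)] &
                               bp[2:(k - 1)] > bp[3:k] &
                               bp[2:(k - 1)] > peak_factor * stats::median(bp))
    valid[ch] <- frac >= min_good_window_fraction && isTRUE(local_max)
  }
  structure(data.frame(channel = seq_len(nch),
                       name = raw$montage$channels$name,
                       valid = valid,
                       reason = ifelse(valid, "ok", "no_cardiac")),
            class = c("channel_validity", "data.frame"))
}

#' Apply manual channel exclusions
#'
#' Marks the listed channels invalid with the given reason. Idempotent: an
#' already-invalid channel keeps its first reason.
#'
#' @param validity a `channel_validity`.
#' @param channels channel indices or names to exclude.
#' @param reason one of `"manual"`, `"hardware"`, `"motion"`, `"dropout"`.
#' @return updated `channel_validity`.
#' @export
apply_manual_exclusions <- function(validity, channels,
                                    reason = c("manual", "hardware",
                                               "motion", "dropout")) {
  reason <- match.arg(reason)
  if (!length(channels)) return(validity)
  idx <- if (is.character(channels)) match(channels, validity$name)
         else match(channels, validity$channel)
  if (anyNA(idx))
    stop_invalid("unknown channel(s): %s",
                 paste(channels[is.na(idx)], collapse = ", "))
  newly <- idx[validity$valid[idx]]
  validity$valid[newly] <- FALSE
  validity$reason[newly] <- reason
  validity
}
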