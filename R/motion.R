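#' Detect abrupt motion artifacts in a single series
#'
#' A sample is artifact-flagged when, within a moving window, the standard
#' deviation exceeds `std_mult` times the series' robust SD, or the
#' peak-to-peak amplitude exceeds `amp_mult` times it while the window SD is
#' also elevated (a lone extreme of clean noise raises peak-to-peak but not
#' the SD), or the first difference jumps by more than `amp_mult` times the
#' robust SD of the differences (a baseline step is edge-preserved by the
#' median high-pass and only visible in the first difference). The rolling
#' statistics and the robust SD are computed on a running-median high-passed
#' copy of the series so that slow physiology and baseline steps do not
#' inflate the reference scale; flagged samples are dilated by
#' `dilate_s` on each side and merged.
#'
#' @param x numeric series (e.g. optical density of one channel/wavelength).
#' @param fs sampling rate, Hz.
#' @param window_s moving-window length, seconds.
#' @param std_mult,amp_mult thresholds in multiples of the robust SD.
#' @param dilate_s dilation applied around flagged samples, seconds.
#' @return data.frame of half-open artifact intervals (`start_s`, `end_s`),
#'   sorted and non-overlapping; zero rows when the series is clean.
#' @export
detect_motion <- function(x, fs, window_s = 1, std_mult = 13.5,
                          amp_mult = 5, dilate_s = 0.5) {
  if (!all(is.finite(x))) stop_invalid("series must be finite")
  n <- length(x)
  w <- max(3L, floor(window_s * fs))
  if (w >= n) w <- n - 1L
  k <- min(n - (1 - n %% 2), 2L * floor(w / 2) + 1L)
  z <- as.vector(x - stats::runmed(x, k))
  rsd <- robust_sd(z)
  if (rsd < .Machine$double.eps) rsd <- stats::sd(z) + .Machine$double.eps
  E <- stats::embed(z, w)                    # (n-w+1) x w, reversed windows
  roll_sd <- sqrt(pmax(rowMeans(E^2) - rowMeans(E)^2, 0) * w / (w - 1))
  roll_p2p <- apply(E, 1, max) - apply(E, 1, min)
  # amplitude hits must coincide with an elevated window SD: a genuine spike
  # raises both, while rare peak-to-peak extremes of clean noise do not
  hit_win <- roll_sd > std_mult * rsd |
    (roll_p2p > amp_mult * rsd & roll_sd > 3 * rsd)
  # abrupt jumps (steps) are edge-preserved by the running median and only
  # visible in the first difference
  dx <- diff(x)
  rsd_d <- robust_sd(dx)
  if (rsd_d < .Machine$double.eps) rsd_d <- stats::sd(dx) + .Machine$double.eps
  hit_jump <- abs(dx) > amp_mult * rsd_d
  flagged <- logical(n)
  if (any(hit_win)) {
    # window i of embed covers samples i .. i+w-1
    for (i in which(hit_win)) flagged[i:(i + w - 1L)] <- TRUE
  }
  if (any(hit_jump)) {
    j <- which(hit_jump)
    flagged[j] <- TRUE
    flagged[j + 1L] <- TRUE
  }
  if (!any(flagged))
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  r <- rle(flagged)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  seg <- data.frame(start_s = (starts[r$values] - 1) / fs - dilate_s,
                    end_s = ends[r$values] / fs + dilate_s)
  seg$start_s <- pmax(seg$start_s, 0)
  seg$end_s <- pmin(seg$end_s, n / fs)
  merge_intervals(seg)
}

#' Spline interpolation of motion-artifact segments
#'
#' Within each artifact segment a smoothing spline (parameter `smoothing`,
#' the weight on fidelity; the roughness penalty is mapped as
#' `(1 - smoothing)/smoothing * 1e-8` on the normalized abscissa, tight
#' enough to track step artifacts) is fitted and subtracted, and the
#' residual segment is re-leveled onto a linear ramp between the mean
#' levels of the adjacent clean data, so both segment boundaries stay
#' continuous even across an unflagged baseline shift. Samples outside the
#' segments are returned unchanged. A segment covering the entire series
#' has no clean anchor: the series is linearly de-trended with a warning.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param segments artifact intervals as returned by [detect_motion()].
#' @param smoothing fidelity weight in (0, 1); values near 1 make the spline
#'   follow the artifact closely.
#' @return corrected series, same length as `x`.
#' @export
spline_correct <- function(x, fs, segments, smoothing = 0.99) {
  if (is.null(segments) || nrow(segments) == 0) return(x)
  if (smoothing <= 0 || smoothing >= 1)
    stop_invalid("smoothing must lie strictly between 0 and 1")
  n <- length(x)
  segments <- merge_intervals(segments)
  if (any(segments$start_s < 0) || any(segments$end_s > n / fs + 1e-9))
    stop_invalid("segments outside series bounds")
  seg_mask <- intervals_to_mask(n, fs, segments)
  if (all(seg_mask)) {
    # no clean data remains to anchor a correction; remove the linear trend
    # only, leaving genuine signal content intact
    warning("artifact segment covers the entire series; returning de-trended series")
    tt <- seq_len(n)
    return(stats::residuals(stats::lm(x ~ tt)) + mean(x))
  }
  out <- x
  tt <- (seq_len(n) - 1) / fs
  for (i in seq_len(nrow(segments))) {
    a <- max(1L, floor(segments$start_s[i] * fs) + 1L)
    b <- min(n, ceiling(segments$end_s[i] * fs))
    if (b <= a) next
    idx <- a:b
    sp <- fit_segment_spline(tt[idx], x[idx], smoothing)
    resid <- x[idx] - sp
    ctx <- max(round(fs), length(idx))        # context window per side
    left <- if (a > 1) setdiff(seq(max(1, a - ctx), a - 1), which(seg_mask))
            else integer(0)
    right <- if (b < n) setdiff(seq(b + 1, min(n, b + ctx)), which(seg_mask))
             else integer(0)
    # ramp between the two adjacent clean levels: continuous at both
    # boundaries even across an (unflagged) baseline shift
    lev_l <- if (length(left)) mean(out[left]) else NA_real_
    lev_r <- if (length(right)) mean(x[right]) else NA_real_
    if (is.na(lev_l) && is.na(lev_r)) lev_l <- lev_r <- mean(x[!seg_mask])
    if (is.na(lev_l)) lev_l <- lev_r
    if (is.na(lev_r)) lev_r <- lev_l
    ramp <- seq(lev_l, lev_r, length.out = length(idx))
    out[idx] <- resid - mean(resid) + ramp
  }
  out
}

fit_segment_spline <- function(t, y, smoothing) {
  if (length(y) < 4) return(rep(mean(y), length(y)))
  lam <- (1 - smoothing) / smoothing * 1e-8
  fit <- try(stats::smooth.spline(t, y, lambda = lam, all.knots = TRUE,
                                  keep.data = FALSE),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(rep(mean(y), length(y)))
  stats::predict(fit, t)$y
}

#' Detect and spline-correct motion artifacts over an OD series
#'
#' Applies [detect_motion()] and [spline_correct()] to every
#' channel/wavelength of an optical-density series (artifact amplitude is
#' multiplicative in intensity, hence additive in OD).
#'
#' @param od an `od_series`.
#' @inheritParams detect_motion
#' @param smoothing passed to [spline_correct()].
#' @return the `od_series` with corrected `od` and a `motion_segments` list
#'   (per channel, per wavelength).
#' @export
motion_correct_od <- function(od, window_s = 1, std_mult = 13.5,
                              amp_mult = 5, dilate_s = 0.5,
                              smoothing = 0.99) {
  d <- dim(od$od)
  segs <- vector("list", d[2])
  for (ch in seq_len(d[2])) {
    segs[[ch]] <- vector("list", d[3])
    if (ch %in% od$invalid_channels) next
    for (w in seq_len(d[3])) {
      s <- detect_motion(od$od[, ch, w], od$fs, window_s = window_s,
                         std_mult = std_mult, amp_mult = amp_mult,
                         dilate_s = dilate_s)
      segs[[ch]][[w]] <- s
      if (nrow(s))
        od$od[, ch, w] <- spline_correct(od$od[, ch, w], od$fs, s,
                                         smoothing = smoothing)
    }
  }
  od$motion_segments <- segs
  od
}
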