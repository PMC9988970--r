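# shared fixture builders; everything is generated in code at test time

small_montage <- function(n = 3) generate_montage(n_channels_per_hemisphere = n)

# wrap a bare intensity array as a raw_recording
as_recording <- function(intensity, fs, montage) {
  stopifnot(dim(intensity)[2] == montage$n_channels, dim(intensity)[3] == 2)
  dimnames(intensity) <- list(NULL, montage$channels$name,
                              paste0("wl", montage$wavelengths))
  structure(list(intensity = intensity, fs = fs, montage = montage,
                 meta = list(cap_scale = montage$cap_scale)),
            class = "raw_recording")
}

# two-wavelength recording with a shared sinusoid (plus noise) per channel
sinusoid_recording <- function(duration_s = 60, fs = 10, f_hz = 2,
                               amp = 0.01, noise = 1e-5, montage = NULL,
                               seed = 1) {
  set.seed(seed)
  montage <- montage %||% small_montage(2)
  n <- floor(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  nch <- montage$n_channels
  arr <- array(0, c(n, nch, 2))
  for (ch in seq_len(nch)) {
    s <- amp * sin(2 * pi * f_hz * t + ch)
    arr[, ch, 1] <- exp(-(s + rnorm(n, 0, noise)))
    arr[, ch, 2] <- exp(-(0.8 * s + rnorm(n, 0, noise)))
  }
  as_recording(arr, fs, montage)
}

# plain hemo_series from matrices
as_hemo <- function(hbo, hbr, fs) {
  structure(list(hbo = hbo, hbr = hbr, hbt = hbo + hbr, fs = fs,
                 provenance = list()), class = "hemo_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fraction of signal power at frequency f_hz (periodogram bin closest to f)
power_at <- function(x, fs, f_hz) {
  n <- length(x)
  p <- abs(stats::fft(x - mean(x)))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  half <- seq_len(floor(n / 2))
  p[half][which.min(abs(f[half] - f_hz))]
}
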