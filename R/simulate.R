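#' Default target correlation structure for a montage
#'
#' Builds the clustered positive / interhemispheric anti-correlated structure
#' the connectivity analysis assumes, via a quadrant factor model: every
#' channel loads on its hemisphere x region factor, factors within a
#' hemisphere are mildly positively correlated and factors across hemispheres
#' anti-correlated. The result is positive semidefinite by construction with
#' unit diagonal.
#'
#' @param montage an `fnirs_montage`.
#' @param loading channel loading on its quadrant factor (within-quadrant
#'   correlation is `loading^2`).
#' @param within_hemi correlation between the two factors of one hemisphere.
#' @param between_hemi correlation between factors of opposite hemispheres.
#' @return channel x channel correlation matrix.
#' @export
default_target_correlation <- function(montage, loading = 0.75,
                                       within_hemi = 0.3,
                                       between_hemi = -0.5) {
  ch <- montage$channels
  quad <- paste(ch$hemisphere, ch$region, sep = "_")
  quads <- unique(quad)
  k <- length(quads)
  phi <- matrix(NA_real_, k, k, dimnames = list(quads, quads))
  hemi_of <- sub("_.*", "", quads)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    phi[a, b] <- if (a == b) 1
      else if (hemi_of[a] == hemi_of[b]) within_hemi else between_hemi
  }
  A <- outer(quad, quads, `==`) * 1
  sigma <- loading^2 * (A %*% phi %*% t(A))
  diag(sigma) <- 1
  dimnames(sigma) <- list(ch$name, ch$name)
  sigma
}

# factorize a correlation matrix allowing semi-definiteness; errors on a
# clearly negative eigenvalue, naming it
psd_factor <- function(sigma, tol = 1e-8) {
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) < -tol)
    stop_invalid("target correlation matrix is not positive semidefinite (eigenvalue %.3g)",
                 min(e$values))
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = length(e$values))
}

# project a symmetric matrix with unit diagonal to the PSD cone (eigenvalue
# clamping + diagonal renormalization); used after per-session attenuation
project_psd_corr <- function(sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) >= 0) return(sigma)
  s <- e$vectors %*% diag(pmax(e$values, 0), nrow = length(e$values)) %*% t(e$vectors)
  d <- sqrt(pmax(diag(s), .Machine$double.eps))
  s <- s / tcrossprod(d)
  diag(s) <- 1
  dimnames(s) <- dimnames(sigma)
  (s + t(s)) / 2
}

# band-limited unit-variance Gaussian noise via Fourier synthesis: complex
# Gaussian coefficients on the bins inside [band[1], band[2]] Hz, zero
# elsewhere; exact band limitation with no filter transients. When
# `orthonormal` (and enough bins are available) the coefficient vectors are
# orthogonalized across columns so the returned series are *empirically*
# exactly uncorrelated; mixing them through a Cholesky-type factor then
# realizes the requested correlation matrix exactly at any duration.
band_limited_noise <- function(n, fs, band, ncol = 1, orthonormal = TRUE) {
  freqs <- (seq_len(n) - 1) * fs / n
  half <- seq(2, floor(n / 2) + 1)
  keep <- half[freqs[half] >= band[1] & freqs[half] <= band[2]]
  K <- length(keep)
  if (K < 1) stop_invalid("no Fourier bins inside the requested band")
  M <- matrix(stats::rnorm(2 * K * ncol), 2 * K, ncol)
  if (orthonormal && 2 * K >= ncol) M <- qr.Q(qr(M))
  out <- matrix(0, n, ncol)
  for (j in seq_len(ncol)) {
    spec <- complex(real = rep(0, n), imaginary = rep(0, n))
    co <- complex(real = M[seq_len(K), j], imaginary = M[K + seq_len(K), j])
    spec[keep] <- co
    spec[n - keep + 2] <- Conj(co)
    x <- Re(stats::fft(spec, inverse = TRUE)) / n
    out[, j] <- x / stats::sd(x)
  }
  out
}

sim_truth_defaults <- function() {
  list(
    target_correlation = NULL,   # default_target_correlation(montage)
    hemo_band = c(0.01, 0.08),   # Hz, slow hemodynamic oscillations
    hbo_sd = 0.01,               # mM, amplitude of HbO fluctuations
    hbr_ratio = -0.5,            # HbR tracks HbO in antiphase
    hbr_noise_sd = 0.3,          # independent HbR noise, x (|hbr_ratio|*hbo_sd)
    cardiac_hz_range = c(1.5, 3.5),  # 90-210 bpm
    cardiac_amp = 0.5,           # x hemodynamic OD SD
    cardiac_free_prob = 0.15,    # channels lacking cardiac pulsation
    wl_cardiac_scale = c(1, 0.8),
    drift_amp = 2,               # slow drift, x hemodynamic OD SD
    motion_rate_per_min = 0.5,
    motion_amp_range = c(5, 20), # x hemodynamic OD SD
    dropout_rate_per_min = 0.2,
    dropout_dur_s = c(1, 5),
    baseline_intensity = 1.0,
    ppf = c(0.1063, 0.0845),
    sensor_noise_od = 2e-4       # white measurement noise in OD units
  )
}

#' Simulate a single bedside fNIRS recording
#'
#' Generates a two-wavelength intensity recording whose log-attenuation is the
#' sum of (i) a hemodynamic component realizing a requested channel
#' correlation matrix inside the 0.01-0.08 Hz band through a latent factor
#' model and the Beer-Lambert forward model, (ii) a shared quasi-periodic
#' cardiac oscillation (drifting rate inside 90-210 bpm) with per-channel
#' amplitude, (iii) slow polynomial drift, (iv) Poisson motion spikes
#' (step + decaying transient), and (v) signal-dropout intervals where
#' intensity collapses to near zero. `intensity = baseline * exp(-attenuation)`.
#'
#' @param montage an `fnirs_montage`.
#' @param duration_s recording length in seconds (default 408 s, the study's
#'   mean session length of 6.8 min).
#' @param fs sampling rate, Hz (default 10.17).
#' @param truth named list overriding entries of the generator truth
#'   parameters; see `ventsfc:::sim_truth_defaults()`.
#' @param seed RNG seed; the same seed and parameters give bit-identical
#'   output.
#' @param keep_clean store the artifact-free intensity in the ground truth
#'   (for motion-correction scoring).
#' @param keep_latent store the latent hemodynamic factor series (for
#'   correlation-recovery checks).
#' @return list with elements `recording` (class `raw_recording`: intensity
#'   array time x channel x wavelength, `fs`, `montage`) and `truth` (class
#'   `sim_truth`: target correlation, motion spike times, dropout intervals,
#'   per-channel cardiac amplitudes, seed, parameters).
#' @export
simulate_recording <- function(montage, duration_s = 408, fs = 10.17,
                               truth = list(), seed = 1,
                               keep_clean = FALSE, keep_latent = FALSE) {
  if (duration_s < 150)
    stop_invalid("duration_s must be >= 150 s (minimum usable session)")
  p <- utils::modifyList(sim_truth_defaults(), truth)
  if (fs <= 2 * p$cardiac_hz_range[2])
    stop_invalid("fs must exceed twice the maximum cardiac frequency")
  set.seed(seed)
  nch <- montage$n_channels
  n <- floor(duration_s * fs)
  sigma <- p$target_correlation %||% default_target_correlation(montage)
  if (nrow(sigma) != nch) stop_invalid("target correlation size mismatch")
  L <- psd_factor(sigma)

  # hemodynamic chromophore series (mM)
  latent <- band_limited_noise(n, fs, p$hemo_band, ncol = nch)
  h <- latent %*% t(L)
  hbo <- p$hbo_sd * h
  hbr <- p$hbr_ratio * hbo +
    (abs(p$hbr_ratio) * p$hbo_sd * p$hbr_noise_sd) *
      band_limited_noise(n, fs, p$hemo_band, ncol = nch)

  # forward Beer-Lambert: OD per wavelength
  eps <- extinction_coefficients(montage$wavelengths)
  d_cm <- montage$channels$sep_mm / 10
  od <- array(0, dim = c(n, nch, 2))
  for (w in 1:2) {
    od[, , w] <- (hbo * eps[w, "HbO"] + hbr * eps[w, "HbR"]) *
      matrix(d_cm * p$ppf[w], n, nch, byrow = TRUE)
  }
  hemo_od_sd <- mean(apply(od[, , 1, drop = FALSE], 2, stats::sd))

  # shared cardiac oscillation with slowly drifting instantaneous frequency
  f0 <- stats::runif(1, p$cardiac_hz_range[1] + 0.3, p$cardiac_hz_range[2] - 0.3)
  fr <- clamp(f0 + cumsum(stats::rnorm(n, 0, 0.005)),
              p$cardiac_hz_range[1], p$cardiac_hz_range[2])
  phase <- 2 * pi * cumsum(fr) / fs
  pulse <- sin(phase) + 0.15 * sin(2 * phase)
  cardiac_free <- stats::runif(nch) < p$cardiac_free_prob
  card_amp <- p$cardiac_amp * hemo_od_sd * stats::runif(nch, 0.6, 1.4)
  card_amp[cardiac_free] <- 0

  # slow polynomial drift per channel/wavelength
  t01 <- seq(-1, 1, length.out = n)
  drift <- array(0, dim = c(n, nch, 2))
  for (w in 1:2) {
    co <- matrix(stats::rnorm(3 * nch, 0, p$drift_amp * hemo_od_sd), 3, nch) *
      c(1, 0.6, 0.4)
    drift[, , w] <- cbind(t01, t01^2, t01^3) %*% co
  }

  # motion spikes: step + decaying transient, shared across channels with
  # per-channel scale; amplitude in multiples of the hemodynamic OD SD
  n_spikes <- stats::rpois(1, p$motion_rate_per_min * duration_s / 60)
  spike_t <- sort(stats::runif(n_spikes, 2, duration_s - 2))
  motion <- array(0, dim = c(n, nch, 2))
  tt <- (seq_len(n) - 1) / fs
  for (s in seq_len(n_spikes)) {
    amp <- stats::runif(1, p$motion_amp_range[1], p$motion_amp_range[2]) *
      hemo_od_sd * sample(c(-1, 1), 1)
    ch_scale <- stats::runif(nch, 0.5, 1)
    dt <- tt - spike_t[s]
    shape <- ifelse(dt >= 0, exp(-dt / 0.3) + 0.3 * exp(-dt / 5), 0)
    for (w in 1:2) {
      motion[, , w] <- motion[, , w] +
        outer(shape, ch_scale * amp * c(1, 0.9)[w])
    }
  }

  sens <- array(stats::rnorm(n * nch * 2, 0, p$sensor_noise_od),
                dim = c(n, nch, 2))
  card <- array(0, dim = c(n, nch, 2))
  for (w in 1:2) card[, , w] <- outer(pulse, card_amp * p$wl_cardiac_scale[w])
  atten_clean <- od + drift + card + sens
  atten <- atten_clean + motion
  intensity <- p$baseline_intensity * exp(-atten)
  clean_intensity <- if (keep_clean) p$baseline_intensity * exp(-atten_clean)

  # dropout: optode lift-off -> near-zero intensity plus noise
  n_drop <- stats::rpois(1, p$dropout_rate_per_min * duration_s / 60)
  dropouts <- data.frame(channel = integer(0), start_s = numeric(0),
                         end_s = numeric(0))
  for (k in seq_len(n_drop)) {
    ch <- sample.int(nch, 1)
    dur <- stats::runif(1, p$dropout_dur_s[1], p$dropout_dur_s[2])
    st <- stats::runif(1, 0, duration_s - dur)
    i0 <- floor(st * fs) + 1; i1 <- min(n, floor((st + dur) * fs))
    noise <- abs(stats::rnorm(i1 - i0 + 1, 0, 0.001))
    intensity[i0:i1, ch, 1] <- 0.002 + noise
    intensity[i0:i1, ch, 2] <- 0.002 + noise
    dropouts <- rbind(dropouts,
                      data.frame(channel = ch, start_s = st, end_s = st + dur))
  }

  dimnames(intensity) <- list(NULL, montage$channels$name,
                              paste0("wl", montage$wavelengths))
  recording <- structure(
    list(intensity = intensity, fs = fs, montage = montage,
         meta = list(cap_scale = montage$cap_scale, seed = seed,
                     duration_s = duration_s)),
    class = "raw_recording")
  truth_out <- structure(
    list(target_correlation = sigma, spike_times_s = spike_t,
         dropouts = dropouts, cardiac_amp = card_amp,
         cardiac_free = cardiac_free, seed = seed, params = p,
         clean_intensity = clean_intensity,
         latent = if (keep_latent) h),
    class = "sim_truth")
  list(recording = recording, truth = truth_out)
}

#' @export
print.raw_recording <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("raw fNIRS recording: %d samples x %d channels x %d wavelengths @ %.2f Hz (%.1f s)\n",
              d[1], d[2], d[3], x$fs, d[1] / x$fs))
  invisible(x)
}

#' Simulate a longitudinal ventricle-volume trajectory
#'
#' Linear growth per side with optional Gaussian session noise and step
#' decreases at CSF-diversion events. Total volume is exactly left + right at
#' every session. Volumes are truncated at `floor_ml` (a step larger than the
#' current volume is clipped, with a warning).
#'
#' @param n_sessions number of measurement sessions (>= 2).
#' @param ga_weeks gestational age at each session (weeks); default weekly
#'   sessions starting at 30 weeks.
#' @param baseline_ml length-2 vector, left/right volume (mL) at the first
#'   session.
#' @param growth_ml_wk linear growth rate per side, mL/week.
#' @param noise_sd per-session volume noise SD, mL (applied per side).
#' @param events data.frame with columns `ga_weeks`, `step_ml_total`: each
#'   event subtracts `step_ml_total` (split across sides in proportion to the
#'   current volumes) from every later session.
#' @param floor_ml minimum volume per side after truncation.
#' @param seed optional RNG seed for the noise.
#' @return data.frame: session, ga_weeks, vv_left_ml, vv_right_ml,
#'   vv_total_ml, diversion_before.
#' @export
simulate_vv_trajectory <- function(n_sessions, ga_weeks = NULL,
                                   baseline_ml = c(5, 5),
                                   growth_ml_wk = 1, noise_sd = 0,
                                   events = NULL, floor_ml = 0.5,
                                   seed = NULL) {
  if (n_sessions < 2) stop_invalid("at least two sessions required")
  if (!is.null(seed)) set.seed(seed)
  ga <- ga_weeks %||% (30 + seq_len(n_sessions) - 1)
  if (length(ga) != n_sessions) stop_invalid("ga_weeks length mismatch")
  if (is.unsorted(ga, strictly = TRUE)) stop_invalid("ga_weeks must increase")
  if (!is.null(events) && nrow(events) > 0)
    events <- events[order(events$ga_weeks), , drop = FALSE]
  noise <- matrix(stats::rnorm(2 * n_sessions, 0, noise_sd), n_sessions, 2)
  offset <- c(0, 0)
  ev_idx <- 1L
  out <- data.frame(session = seq_len(n_sessions), ga_weeks = ga,
                    vv_left_ml = NA_real_, vv_right_ml = NA_real_,
                    vv_total_ml = NA_real_, diversion_before = FALSE)
  for (i in seq_len(n_sessions)) {
    while (!is.null(events) && ev_idx <= nrow(events) &&
           events$ga_weeks[ev_idx] <= ga[i]) {
      cur <- baseline_ml + growth_ml_wk * (events$ga_weeks[ev_idx] - ga[1]) + offset
      cur <- pmax(cur, floor_ml)
      share <- cur / sum(cur)
      step <- events$step_ml_total[ev_idx] * share
      if (any(cur - step < floor_ml)) {
        warning("diversion step exceeds current volume; clipped to floor")
        step <- pmin(step, cur - floor_ml)
      }
      offset <- offset - step
      out$diversion_before[i] <- TRUE
      ev_idx <- ev_idx + 1L
    }
    v <- baseline_ml + growth_ml_wk * (ga[i] - ga[1]) + offset + noise[i, ]
    v <- pmax(v, floor_ml)
    out$vv_left_ml[i] <- v[1]
    out$vv_right_ml[i] <- v[2]
    out$vv_total_ml[i] <- v[1] + v[2]
  }
  out
}

#' Cohort specification for the synthetic study
#'
#' Defaults emulate the study arms: 23 patients without CSF diversion with
#' 2-8 sessions and mostly mild ventricular dilatation, and 7 patients with
#' CSF diversion, 3-15 sessions, progressive dilatation and step volume
#' decreases (mean 19.93 mL total) at diversion events with same-day pre/post
#' sessions. The |sFC| magnitude of every channel pair is attenuated linearly
#' in the pair's ventricle volume with slope `coupling_beta` (correlation
#' units per mL), signs preserved.
#'
#' @param ... overrides of any default field.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(...) {
  spec <- list(
    n_no_diversion = 23, n_diversion = 7,
    sessions_no_diversion = c(2, 8), sessions_diversion = c(3, 15),
    ga_birth_mean = 26.6, ga_birth_sd = 2.6, ga_birth_range = c(23, 32),
    first_session_wk = c(1, 3), session_interval_wk = c(0.7, 1.6),
    vv_baseline_no_div = c(1.5, 8), vv_growth_no_div = c(-0.3, 1.0),
    vv_noise_no_div = 0.5,
    vv_baseline_div = c(10, 25), vv_growth_div = c(1, 3.5),
    vv_noise_div = 1.0,
    diversion_step_mean = 19.93, diversion_step_sd = 8,
    diversion_step_min = 2, vv_floor_ml = 0.5,
    coupling_beta = 0.002, interhemi_rule = "mean",
    sfc_noise_sd = 0.1,
    duration_s = 408, fs = 10.17,
    target_correlation = NULL,
    truth = list())
  over <- list(...)
  unknown <- setdiff(names(over), names(spec))
  if (length(unknown))
    stop_invalid("unknown cohort_spec fields: %s", paste(unknown, collapse = ", "))
  spec <- utils::modifyList(spec, over)
  if (spec$sessions_no_diversion[1] < 2 || spec$sessions_diversion[1] < 2)
    stop_invalid("sessions per patient must be >= 2")
  structure(spec, class = "cohort_spec")
}

# per-session attenuated correlation target:
# |rho_s| = max(0, |rho0| - beta * VV_pair), sign preserved; VV_pair is the
# hemisphere's volume for within-hemisphere pairs and the configured rule
# (default mean of L/R) for interhemispheric pairs
attenuate_correlation <- function(sigma0, montage, beta, vv_left, vv_right,
                                  interhemi_rule = "mean") {
  ch <- montage$channels
  hemi <- ch$hemisphere
  vv_inter <- switch(interhemi_rule,
                     mean = (vv_left + vv_right) / 2,
                     left = vv_left, right = vv_right,
                     total = vv_left + vv_right,
                     stop_invalid("unknown interhemi_rule '%s'", interhemi_rule))
  n <- nrow(sigma0)
  vvmat <- matrix(vv_inter, n, n)
  both_left <- outer(hemi == "left", hemi == "left", `&`)
  both_right <- outer(hemi == "right", hemi == "right", `&`)
  vvmat[both_left] <- vv_left
  vvmat[both_right] <- vv_right
  s <- sign(sigma0) * pmax(0, abs(sigma0) - beta * vvmat)
  diag(s) <- 1
  if (all(abs(s[upper.tri(s)]) < .Machine$double.eps))
    warning("attenuation drove all off-diagonal correlations to zero")
  project_psd_corr(s)
}

# shared longitudinal skeleton: patients, session GAs, events, VV
cohort_skeleton <- function(spec, montage) {
  patients <- list()
  pid <- 0L
  for (group in c("no_diversion", "diversion")) {
    n_pat <- if (group == "no_diversion") spec$n_no_diversion else spec$n_diversion
    s_rng <- if (group == "no_diversion") spec$sessions_no_diversion else spec$sessions_diversion
    for (k in seq_len(n_pat)) {
      pid <- pid + 1L
      ga_birth <- clamp(stats::rnorm(1, spec$ga_birth_mean, spec$ga_birth_sd),
                        spec$ga_birth_range[1], spec$ga_birth_range[2])
      n_sess <- if (s_rng[1] == s_rng[2]) s_rng[1] else
        sample(seq(s_rng[1], s_rng[2]), 1)
      ga <- ga_birth + stats::runif(1, spec$first_session_wk[1],
                                    spec$first_session_wk[2]) +
        c(0, cumsum(stats::runif(n_sess - 1, spec$session_interval_wk[1],
                                 spec$session_interval_wk[2])))
      events <- NULL
      if (group == "diversion") {
        n_ev <- max(1L, floor(n_sess / 4))
        # events sit between sessions j and j+1; make those sessions same-day
        cand <- seq_len(n_sess - 1)
        jj <- sort(sample(cand, min(n_ev, length(cand))))
        jj <- jj[c(TRUE, diff(jj) > 1)]          # keep events separated
        for (j in jj) ga[j + 1] <- ga[j] + 0.04  # ~ same day pre/post
        ga <- cummax_strict(ga)
        events <- data.frame(
          ga_weeks = ga[jj] + 0.02,
          step_ml_total = pmax(spec$diversion_step_min,
                               stats::rnorm(length(jj), spec$diversion_step_mean,
                                            spec$diversion_step_sd)))
      }
      if (group == "no_diversion") {
        base <- stats::runif(2, spec$vv_baseline_no_div[1], spec$vv_baseline_no_div[2])
        growth <- stats::runif(1, spec$vv_growth_no_div[1], spec$vv_growth_no_div[2])
        noise <- spec$vv_noise_no_div
      } else {
        base <- stats::runif(2, spec$vv_baseline_div[1], spec$vv_baseline_div[2])
        growth <- stats::runif(1, spec$vv_growth_div[1], spec$vv_growth_div[2])
        noise <- spec$vv_noise_div
      }
      vv <- simulate_vv_trajectory(n_sess, ga_weeks = ga, baseline_ml = base,
                                   growth_ml_wk = growth, noise_sd = noise,
                                   events = events, floor_ml = spec$vv_floor_ml)
      patients[[pid]] <- list(patient_id = sprintf("P%02d", pid), group = group,
                              ga_birth = ga_birth, events = events, vv = vv)
    }
  }
  patients
}

cummax_strict <- function(x, eps = 1e-3) {
  for (i in seq_along(x)[-1]) if (x[i] <= x[i - 1]) x[i] <- x[i - 1] + eps
  x
}

#' Simulate a longitudinal multi-patient cohort of fNIRS recordings
#'
#' Draws the two study arms (no CSF diversion / CSF diversion), each patient's
#' session gestational ages, ventricle-volume trajectory (with step decreases
#' at diversion events), and one raw fNIRS recording per session whose latent
#' correlation magnitudes are attenuated as `max(0, |rho0| - beta * VV)` with
#' signs preserved, using the hemisphere's volume for within-hemisphere pairs
#' and the configured interhemispheric rule.
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed; fully determines the cohort.
#' @param montage montage to use (default [generate_montage()]).
#' @param keep_clean,keep_latent passed to [simulate_recording()].
#' @return `sfc_cohort`: montage, spec, seed, and a list of patients, each
#'   holding session records (`ga_weeks`, volumes, `diversion_before`,
#'   `recording`, `truth`).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1, montage = NULL,
                            keep_clean = FALSE, keep_latent = FALSE) {
  set.seed(seed)
  montage <- montage %||% generate_montage()
  sigma0 <- spec$target_correlation %||% default_target_correlation(montage)
  patients <- cohort_skeleton(spec, montage)
  # session seeds drawn up front so per-session simulation stays deterministic
  n_total <- sum(vapply(patients, function(p) nrow(p$vv), 1L))
  seeds <- sample.int(.Machine$integer.max - 1, n_total)
  s_i <- 0L
  for (p in seq_along(patients)) {
    pat <- patients[[p]]
    sessions <- vector("list", nrow(pat$vv))
    for (i in seq_len(nrow(pat$vv))) {
      s_i <- s_i + 1L
      sigma_s <- attenuate_correlation(sigma0, montage, spec$coupling_beta,
                                       pat$vv$vv_left_ml[i], pat$vv$vv_right_ml[i],
                                       spec$interhemi_rule)
      tr <- utils::modifyList(spec$truth, list(target_correlation = sigma_s))
      sim <- simulate_recording(montage, duration_s = spec$duration_s,
                                fs = spec$fs, truth = tr, seed = seeds[s_i],
                                keep_clean = keep_clean,
                                keep_latent = keep_latent)
      sessions[[i]] <- list(
        session_idx = i, ga_weeks = pat$vv$ga_weeks[i],
        vv_left_ml = pat$vv$vv_left_ml[i], vv_right_ml = pat$vv$vv_right_ml[i],
        vv_total_ml = pat$vv$vv_total_ml[i],
        diversion_before = pat$vv$diversion_before[i],
        recording = sim$recording, truth = sim$truth)
    }
    patients[[p]]$sessions <- sessions
    patients[[p]]$vv <- NULL
  }
  structure(list(montage = montage, spec = spec, seed = seed,
                 coupling_beta = spec$coupling_beta, patients = patients),
            class = "sfc_cohort")
}

#' Simulate a cohort at the connectivity level (no time series)
#'
#' Session-level counterpart of [simulate_cohort()]: instead of raw optical
#' recordings, each session carries a connectivity matrix drawn directly from
#' the attenuation model, `r = sign(rho0) * max(0, |rho0| - beta*VV) + noise`,
#' emulating the sampling noise of a finite-duration sFC estimate
#' (`sfc_noise_sd`, default 0.1). Used to exercise the statistics layer
#' (slope estimators, group maps, diversion tests) at scale where the signal
#' pipeline itself is not under study.
#'
#' @inheritParams simulate_cohort
#' @return `sfc_cohort` whose sessions hold `conn` matrices instead of
#'   recordings.
#' @export
simulate_sfc_cohort <- function(spec = cohort_spec(), seed = 1, montage = NULL) {
  set.seed(seed)
  montage <- montage %||% generate_montage()
  sigma0 <- spec$target_correlation %||% default_target_correlation(montage)
  patients <- cohort_skeleton(spec, montage)
  nch <- montage$n_channels
  for (p in seq_along(patients)) {
    pat <- patients[[p]]
    sessions <- vector("list", nrow(pat$vv))
    for (i in seq_len(nrow(pat$vv))) {
      sigma_s <- attenuate_correlation(sigma0, montage, spec$coupling_beta,
                                       pat$vv$vv_left_ml[i], pat$vv$vv_right_ml[i],
                                       spec$interhemi_rule)
      noise <- matrix(stats::rnorm(nch * nch, 0, spec$sfc_noise_sd), nch, nch)
      noise[lower.tri(noise, diag = TRUE)] <- 0
      conn <- clamp(sigma_s + noise + t(noise), -1, 1)
      diag(conn) <- 1
      dimnames(conn) <- list(montage$channels$name, montage$channels$name)
      attr(conn, "chromophore") <- "HbT"
      sessions[[i]] <- list(
        session_idx = i, ga_weeks = pat$vv$ga_weeks[i],
        vv_left_ml = pat$vv$vv_left_ml[i], vv_right_ml = pat$vv$vv_right_ml[i],
        vv_total_ml = pat$vv$vv_total_ml[i],
        diversion_before = pat$vv$diversion_before[i],
        conn = conn, truth = list(target_correlation = sigma_s))
    }
    patients[[p]]$sessions <- sessions
    patients[[p]]$vv <- NULL
  }
  structure(list(montage = montage, spec = spec, seed = seed,
                 coupling_beta = spec$coupling_beta, patients = patients),
            class = "sfc_cohort")
}

#' @export
print.sfc_cohort <- function(x, ...) {
  ns <- vapply(x$patients, function(p) length(p$sessions), 1L)
  grp <- vapply(x$patients, function(p) p$group, "")
  cat(sprintf("synthetic cohort: %d patients (%d no-diversion, %d diversion), %d sessions\n",
              length(x$patients), sum(grp == "no_diversion"),
              sum(grp == "diversion"), sum(ns)))
  invisible(x)
}
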