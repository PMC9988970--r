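test_that("window and hop sample counts follow floor(window * fs)", {
  m <- small_montage(2)
  rec <- sinusoid_recording(duration_s = 30, fs = 10.17, montage = m)
  q <- compute_windowed_quality(rec)
  expect_equal(q$win_len, 50)    # floor(5 * 10.17)
  expect_equal(q$hop, 25)        # floor(5 * 10.17 * 0.5)
  expect_true(all(q$sci >= -1 & q$sci <= 1))
  expect_true(all(q$psp >= 0))
})

test_that("identical cardiac sinusoids on both wavelengths give SCI near 1", {
  rec <- sinusoid_recording(duration_s = 60, fs = 10, f_hz = 2, noise = 1e-6)
  q <- compute_windowed_quality(rec)
  expect_true(all(q$sci > 0.95))
})

test_that("independent white noise gives mean SCI near 0", {
  set.seed(21)
  m <- small_montage(1)
  n <- 260 * 10
  arr <- array(exp(rnorm(n * 2 * 2, 0, 0.01)), c(n, 2, 2))
  rec <- as_recording(arr, 10, m)
  q <- compute_windowed_quality(rec)   # > 100 windows
  expect_gt(nrow(q$sci), 100)
  expect_lt(abs(mean(q$sci)), 0.1)
})

test_that("windowed SCI equals a brute-force filtered-window Pearson oracle", {
  # oracle: per window, linear detrend, independent forward-backward filter,
  # plain cor(); implementation uses a precomputed linear operator
  m <- small_montage(2)
  sim <- simulate_recording(m, duration_s = 160, fs = 10.17, seed = 31)
  rec <- sim$recording
  q <- compute_windowed_quality(rec)
  filt <- signal::butter(3, c(1.5, 3.5) / (10.17 / 2), type = "pass")
  for (ch in c(1, 4)) {
    for (w in c(1, 7, nrow(q$sci))) {
      idx <- q$start_idx[w] + seq_len(q$win_len) - 1
      detrend <- function(v) stats::residuals(stats::lm(v ~ seq_along(v)))
      f1 <- signal::filtfilt(filt, detrend(rec$intensity[idx, ch, 1]))
      f2 <- signal::filtfilt(filt, detrend(rec$intensity[idx, ch, 2]))
      expect_equal(unname(q$sci[w, ch]), cor(f1, f2), tolerance = 1e-10)
    }
  }
})

test_that("SCI and PSP are invariant to rescaling both wavelengths", {
  m <- small_montage(1)
  sim <- simulate_recording(m, duration_s = 160, seed = 5)
  rec <- sim$recording
  q1 <- compute_windowed_quality(rec)
  rec2 <- rec
  rec2$intensity <- rec$intensity * 37.5
  q2 <- compute_windowed_quality(rec2)
  expect_equal(q1$sci, q2$sci, tolerance = 1e-9)
  expect_equal(q1$psp, q2$psp, tolerance = 1e-9)
})

test_that("flat windows get SCI 0 and a flag", {
  m <- small_montage(1)
  n <- 400
  arr <- array(1, c(n, 2, 2))   # constant intensity
  rec <- as_recording(arr, 10, m)
  q <- compute_windowed_quality(rec)
  expect_true(all(q$sci == 0))
  expect_true(all(q$flat))
})

test_that("subsample selection avoids the dropout-contaminated half", {
  m <- small_montage(1)
  sim <- simulate_recording(m, duration_s = 400, fs = 10, seed = 8,
                            truth = list(motion_rate_per_min = 0,
                                         dropout_rate_per_min = 0,
                                         cardiac_free_prob = 0))
  rec <- sim$recording
  n <- dim(rec$intensity)[1]
  rec$intensity[(n %/% 2):n, , ] <- 0.001   # dropout second half
  q <- compute_windowed_quality(rec)
  win <- select_best_subsample(q, rec, duration_s = 150)
  expect_equal(win$end - win$start, floor(150 * 10))
  expect_lte(win$end, n %/% 2)
  expect_true(win$dropout_free)
})

test_that("uniform quality breaks ties to the earliest span", {
  m <- small_montage(1)
  rec <- as_recording(array(1, c(2000, 2, 2)), 10, m)  # identical everywhere
  q <- compute_windowed_quality(rec)
  win <- select_best_subsample(q, rec, duration_s = 150)
  expect_equal(win$start, 0)
})

test_that("selected span attains the exhaustive maximum score", {
  # instances small enough to enumerate every candidate start
  for (seed in 1:20) {
    m <- small_montage(1)
    sim <- simulate_recording(m, duration_s = 200, fs = 8, seed = seed,
                              truth = list(dropout_rate_per_min = 0))
    q <- compute_windowed_quality(sim$recording)
    win <- select_best_subsample(q, sim$recording, duration_s = 150)
    span_len <- floor(150 * 8)
    n <- dim(sim$recording$intensity)[1]
    rank_norm <- function(mm) { mm[] <- rank(mm) / length(mm); mm }
    score_mat <- rank_norm(q$sci) + rank_norm(q$psp)
    ws <- rowMeans(score_mat)
    best <- -Inf
    for (s0 in q$start_idx[q$start_idx + span_len - 1 <= n]) {
      cov <- q$start_idx >= s0 & q$start_idx + q$win_len - 1 <= s0 + span_len - 1
      sc <- mean(ws[cov])
      if (sc > best) best <- sc
    }
    expect_equal(win$score, best, tolerance = 1e-12)
  }
})

test_that("a dropout inside the selected span never raises its score", {
  m <- small_montage(1)
  sim <- simulate_recording(m, duration_s = 250, fs = 10, seed = 77,
                            truth = list(dropout_rate_per_min = 0))
  rec <- sim$recording
  q <- compute_windowed_quality(rec)
  win <- select_best_subsample(q, rec, duration_s = 150)
  mid <- floor((win$start + win$end) / 2)
  rec$intensity[mid:(mid + 15), 1, ] <- 0.001
  q2 <- compute_windowed_quality(rec)
  win2 <- suppressWarnings(select_best_subsample(q2, rec, duration_s = 150))
  # the previously chosen span is now dropout-contaminated
  drop <- detect_dropout(rec)
  expect_gt(nrow(drop), 0)
  expect_false(win2$start == win$start && !win2$dropout_free)
})

test_that("a recording shorter than the subsample is an invalid session", {
  m <- small_montage(1)
  rec <- sinusoid_recording(duration_s = 100, fs = 10, montage = m)
  q <- compute_windowed_quality(rec)
  expect_error(select_best_subsample(q, rec, duration_s = 150),
               "session invalid")
})

test_that("cardiac detection separates constructed positives and negatives", {
  set.seed(12)
  m <- small_montage(2)
  n <- 160 * 10
  t <- (seq_len(n) - 1) / 10
  arr <- array(0, c(n, 4, 2))
  card <- 0.005 * sin(2 * pi * 2 * t)
  for (ch in 1:4) for (w in 1:2) {
    a <- if (ch == 3) 0 else 1            # channel 3: cardiac zeroed
    arr[, ch, w] <- exp(-(a * c(1, 0.8)[w] * card + rnorm(n, 0, 5e-4)))
  }
  rec <- as_recording(arr, 10, m)
  v <- detect_cardiac_channels(rec)
  expect_true(all(v$valid[c(1, 2, 4)]))
  expect_false(v$valid[3])
  expect_equal(v$reason[3], "no_cardiac")
  expect_equal(v$reason[1], "ok")
})

test_that("manual exclusions count, preserve first reasons, and are idempotent", {
  m <- generate_montage()
  v <- structure(data.frame(channel = 1:20, name = m$channels$name,
                            valid = TRUE, reason = "ok"),
                 class = c("channel_validity", "data.frame"))
  v2 <- apply_manual_exclusions(v, c(3, 7, 11), "hardware")
  expect_equal(sum(v2$valid), 17)
  expect_equal(v2$reason[3], "hardware")
  v3 <- apply_manual_exclusions(v2, 3, "manual")   # already invalid
  expect_identical(v2, v3)
  expect_identical(apply_manual_exclusions(v, integer(0)), v)
  expect_error(apply_manual_exclusions(v, 99), "unknown channel")
  expect_error(apply_manual_exclusions(v, "nope"), "unknown channel")
})
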