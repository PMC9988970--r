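test_that("recording length follows duration and sampling rate", {
  m <- small_montage(2)
  sim <- simulate_recording(m, duration_s = 408, fs = 10.17, seed = 3)
  expect_equal(dim(sim$recording$intensity), c(floor(408 * 10.17), 4, 2))
  expect_equal(dim(sim$recording$intensity)[1], 4149)
})

test_that("the generator is deterministic in the seed", {
  m <- small_montage(2)
  a <- simulate_recording(m, duration_s = 160, seed = 11)
  b <- simulate_recording(m, duration_s = 160, seed = 11)
  expect_identical(a$recording$intensity, b$recording$intensity)
  expect_identical(a$truth$spike_times_s, b$truth$spike_times_s)
  c <- simulate_recording(m, duration_s = 160, seed = 12)
  expect_false(identical(a$recording$intensity, c$recording$intensity))
})

test_that("identity target correlation yields near-zero empirical correlations", {
  m <- small_montage(3)
  devs <- replicate(5, {
    s <- simulate_recording(
      m, duration_s = 408, seed = sample.int(1e6, 1), keep_latent = TRUE,
      truth = list(target_correlation = diag(m$n_channels),
                   motion_rate_per_min = 0, dropout_rate_per_min = 0,
                   cardiac_free_prob = 0))
    max(abs(cor(s$truth$latent)[upper.tri(diag(m$n_channels))]))
  })
  expect_true(all(devs < 0.15))
})

test_that("latent correlations converge to the target at long duration", {
  m <- small_montage(3)
  sig <- default_target_correlation(m)
  s <- simulate_recording(m, duration_s = 1800, seed = 5, keep_latent = TRUE,
                          truth = list(motion_rate_per_min = 0,
                                       dropout_rate_per_min = 0))
  emp <- cor(s$truth$latent)
  expect_lt(max(abs(emp - sig)), 0.1)
})

test_that("a non-PSD correlation target is rejected naming the eigenvalue", {
  m <- small_montage(2)
  bad <- diag(4); bad[1, 2] <- bad[2, 1] <- 0.9
  bad[1, 3] <- bad[3, 1] <- 0.9; bad[2, 3] <- bad[3, 2] <- -0.9
  expect_error(
    simulate_recording(m, duration_s = 160, seed = 1,
                       truth = list(target_correlation = bad)),
    "positive semidefinite \\(eigenvalue")
})

test_that("VV trajectories follow the linear recurrence and bookkeeping", {
  tr <- simulate_vv_trajectory(4, ga_weeks = 30:33, baseline_ml = c(10, 10),
                               growth_ml_wk = 2, noise_sd = 0)
  expect_equal(tr$vv_left_ml, c(10, 12, 14, 16))
  expect_equal(tr$vv_right_ml, c(10, 12, 14, 16))
  expect_equal(tr$vv_total_ml, tr$vv_left_ml + tr$vv_right_ml)

  const <- simulate_vv_trajectory(3, ga_weeks = c(30, 31, 32),
                                  baseline_ml = c(7, 6), growth_ml_wk = 0,
                                  noise_sd = 0)
  expect_equal(const$vv_total_ml, rep(13, 3))
})

test_that("diversion events apply the configured step decrease exactly", {
  ev <- data.frame(ga_weeks = 31.5, step_ml_total = 19.93)
  tr <- simulate_vv_trajectory(4, ga_weeks = 30:33, baseline_ml = c(15, 15),
                               growth_ml_wk = 0, noise_sd = 0, events = ev)
  expect_equal(tr$vv_total_ml[2] - tr$vv_total_ml[3], 19.93, tolerance = 1e-12)
  expect_true(tr$diversion_before[3])
  expect_false(any(tr$diversion_before[-3]))
})

test_that("oversized steps are clipped to the floor with a warning", {
  ev <- data.frame(ga_weeks = 30.5, step_ml_total = 100)
  expect_warning(
    tr <- simulate_vv_trajectory(2, ga_weeks = c(30, 31),
                                 baseline_ml = c(5, 5), growth_ml_wk = 0,
                                 noise_sd = 0, events = ev, floor_ml = 0.5),
    "clipped")
  expect_true(all(tr$vv_left_ml >= 0.5 & tr$vv_right_ml >= 0.5))
})

test_that("attenuation follows the closed form |rho| - beta * VV", {
  m <- generate_montage()
  sig <- matrix(0, 20, 20); diag(sig) <- 1
  sig[1, 2] <- sig[2, 1] <- 0.5   # channels 1,2 are both left-hemisphere
  for (vv in c(10, 60)) {
    a <- ventsfc:::attenuate_correlation(sig, m, beta = 0.002,
                                         vv_left = vv, vv_right = vv)
    expect_equal(a[1, 2], 0.5 - 0.002 * vv, tolerance = 1e-9)
  }
})

test_that("cohorts reproduce the study arm sizes and session ranges", {
  spec <- cohort_spec()
  co <- suppressWarnings(simulate_sfc_cohort(spec, seed = 2))
  grp <- vapply(co$patients, `[[`, "", "group")
  ns <- vapply(co$patients, function(p) length(p$sessions), 1L)
  expect_equal(sum(grp == "no_diversion"), 23)
  expect_equal(sum(grp == "diversion"), 7)
  expect_true(all(ns[grp == "no_diversion"] >= 2 & ns[grp == "no_diversion"] <= 8))
  expect_true(all(ns[grp == "diversion"] >= 3 & ns[grp == "diversion"] <= 15))
  # every diversion patient has at least one event
  for (p in co$patients[grp == "diversion"])
    expect_gte(nrow(p$events), 1)
  # determinism after serialization
  co2 <- suppressWarnings(simulate_sfc_cohort(spec, seed = 2))
  expect_identical(serialize(co, NULL), serialize(co2, NULL))
})

test_that("null coupling gives identical session targets within patient", {
  spec <- cohort_spec(coupling_beta = 0, n_no_diversion = 2, n_diversion = 2,
                      sessions_no_diversion = c(2, 3),
                      sessions_diversion = c(3, 4))
  co <- simulate_sfc_cohort(spec, seed = 4)
  for (p in co$patients) {
    tgts <- lapply(p$sessions, function(s) s$truth$target_correlation)
    for (k in seq_along(tgts)[-1]) expect_equal(tgts[[k]], tgts[[1]])
  }
})

test_that("GA strictly increases within patient and volumes stay positive", {
  co <- suppressWarnings(simulate_sfc_cohort(cohort_spec(), seed = 9))
  for (p in co$patients) {
    ga <- vapply(p$sessions, `[[`, 0, "ga_weeks")
    expect_false(is.unsorted(ga, strictly = TRUE))
    vv <- vapply(p$sessions, `[[`, 0, "vv_total_ml")
    expect_true(all(vv > 0))
    tot <- vapply(p$sessions, function(s) s$vv_left_ml + s$vv_right_ml, 0)
    expect_equal(tot, vv)
  }
})
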