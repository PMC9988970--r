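test_that("robust correlation handles exact linear relations", {
  x <- rnorm(100)
  expect_equal(robust_correlation(x, x), 1)
  expect_equal(robust_correlation(x, -2 * x + 5), -1)
  # exact linear fit leaves all weights at 1: equals classical Pearson
  y <- 2 * x + 3
  expect_equal(robust_correlation(x, y), cor(x, y), tolerance = 1e-12)
})

test_that("robust correlation tracks Pearson on clean bivariate data", {
  set.seed(41)
  for (k in 1:20) {
    x <- rnorm(149)
    y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(149)
    expect_lt(abs(robust_correlation(x, y) - cor(x, y)), 0.02)
  }
})

test_that("robust correlation resists gross outliers better than Pearson", {
  set.seed(42)
  wins <- 0
  for (k in 1:50) {
    n <- 149
    x <- rnorm(n)
    y <- 0.5 * x + sqrt(0.75) * rnorm(n)
    out <- sample(n, 15)
    y[out] <- y[out] + rnorm(15, 0, 10)
    err_rob <- abs(robust_correlation(x, y) - 0.5)
    err_pear <- abs(cor(x, y) - 0.5)
    if (err_rob < err_pear) wins <- wins + 1
  }
  expect_gte(wins, 45)
})

test_that("robust correlation degenerate inputs are handled", {
  expect_error(robust_correlation(rnorm(5), rnorm(5)), ">= 10")
  expect_error(robust_correlation(rnorm(20), rnorm(19)), "equal length")
  x <- c(rep(0, 18), 1, 2)  # MAD zero
  expect_warning(r <- robust_correlation(x, rnorm(20)), "zero MAD")
  expect_true(r >= -1 && r <= 1)
})

test_that("session sFC masks invalid channels as missing and keeps symmetry", {
  set.seed(43)
  m <- small_montage(2)
  hb <- matrix(rnorm(149 * 4), 149, 4,
               dimnames = list(NULL, m$channels$name))
  hemo <- as_hemo(hb, -0.5 * hb, 1)
  v <- structure(data.frame(channel = 1:4, name = m$channels$name,
                            valid = c(TRUE, TRUE, FALSE, TRUE),
                            reason = c("ok", "ok", "no_cardiac", "ok")),
                 class = c("channel_validity", "data.frame"))
  conn <- session_sfc(hemo, v)
  expect_true(all(is.na(conn[3, ])) && all(is.na(conn[, 3])))
  expect_equal(conn, t(conn))
  expect_equal(unname(diag(conn)[-3]), rep(1, 3))
  expect_equal(attr(conn, "chromophore"), "HbT")
})

test_that("session sFC requires 1 Hz input and 2 valid channels", {
  m <- small_montage(1)
  hb <- matrix(rnorm(100 * 2), 100, 2)
  expect_error(session_sfc(as_hemo(hb, hb, 10)), "1 Hz")
  v <- structure(data.frame(channel = 1:2, name = m$channels$name,
                            valid = c(TRUE, FALSE), reason = "ok"),
                 class = c("channel_validity", "data.frame"))
  expect_error(session_sfc(as_hemo(hb, hb, 1), v), "fewer than 2")
})

make_records <- function(pat_means, sd_within = 0.01, nch = 4, seed = 1) {
  # one session per patient whose conn entries are pat_means[k] + noise
  set.seed(seed)
  lapply(seq_along(pat_means), function(k) {
    m <- matrix(NA_real_, nch, nch)
    v <- pat_means[k] + rnorm(choose(nch, 2), 0, sd_within)
    m[upper.tri(m)] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 1
    list(patient_id = sprintf("P%02d", k), group = "g", session_idx = 1,
         ga_weeks = 30, vv_left_ml = 5, vv_right_ml = 5, vv_total_ml = 10,
         diversion_before = FALSE, conn = m)
  })
}

test_that("group t-map separates strong consistent sFC from null sFC", {
  rec_hi <- make_records(rep(0.5, 8) + rnorm(8, 0, 0.01))
  tm <- group_tmap(rec_hi)
  expect_true(all(tm$t > 10))
  expect_true(all(tm$df == 7))

  rec_null <- make_records(c(-0.15, 0.15, -0.05, 0.05, -0.1, 0.1) * 0.667,
                           seed = 2)
  tm0 <- group_tmap(rec_null)
  # patient means symmetric around zero: small t
  expect_true(all(abs(tm0$t) < 3))
})

test_that("pairs below the minimum sample size are low-confidence", {
  recs <- make_records(rep(0.4, 5))
  expect_warning(tm <- group_tmap(recs, min_patients = 10),
                 "low-confidence")
  expect_true(all(tm$low_confidence))
  expect_true(all(is.na(tm$t)))
  tm2 <- group_tmap(recs, min_patients = 5)
  expect_false(any(tm2$low_confidence))
})

test_that("cluster summaries average |sFC| with missing-entry handling", {
  cl <- list(a = cbind(ch_i = c(1, 1, 2, 3), ch_j = c(2, 3, 4, 4)))
  conn <- matrix(NA_real_, 4, 4)
  conn[1, 2] <- 0.5; conn[1, 3] <- 0.5; conn[2, 4] <- 0.5; conn[3, 4] <- 0.5
  expect_equal(unname(cluster_summary(conn, cl)), 0.5)
  conn[1, 2] <- 0.4; conn[1, 3] <- 0.6; conn[2, 4] <- NA; conn[3, 4] <- NA
  expect_equal(unname(cluster_summary(conn, cl)), 0.5)
  conn[1, 2] <- -0.5; conn[1, 3] <- 0.5; conn[2, 4] <- -0.5; conn[3, 4] <- 0.5
  expect_equal(unname(cluster_summary(conn, cl)), 0.5)  # |sFC| first
  conn[] <- NA
  expect_true(is.na(cluster_summary(conn, cl)))
})
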