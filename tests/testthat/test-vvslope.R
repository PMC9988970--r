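# helper: build session records with prescribed conn values for a tiny montage
slope_records <- function(vv_per_session, sfc_fun, nch = 4,
                          patient_id = "P01", group = "diversion",
                          ga0 = 30) {
  lapply(seq_along(vv_per_session), function(i) {
    vv <- vv_per_session[i]
    m <- matrix(NA_real_, nch, nch); diag(m) <- 1
    for (a in 1:(nch - 1)) for (b in (a + 1):nch)
      m[a, b] <- m[b, a] <- sfc_fun(vv, a, b)
    list(patient_id = patient_id, group = group, session_idx = i,
         ga_weeks = ga0 + i - 1, vv_left_ml = vv, vv_right_ml = vv,
         vv_total_ml = 2 * vv, diversion_before = FALSE, conn = m)
  })
}

test_that("abs_sfc takes elementwise absolute values and keeps missingness", {
  m <- matrix(c(1, -0.7, NA, -0.7, 1, 0, NA, 0, 1), 3, 3)
  attr(m, "chromophore") <- "HbT"
  a <- abs_sfc(m)
  expect_equal(a[1, 2], 0.7)
  expect_equal(a[2, 3], 0)
  expect_true(is.na(a[1, 3]))
  expect_equal(attr(a, "chromophore"), "HbT")
})

test_that("pair volumes follow the hemisphere and interhemispheric rules", {
  m <- small_montage(2)   # channels 1,2 left; 3,4 right
  recs <- lapply(1:2, function(i) list(
    patient_id = "P01", group = "g", session_idx = i, ga_weeks = 30 + i,
    vv_left_ml = 10, vv_right_ml = 20, vv_total_ml = 30,
    diversion_before = FALSE,
    conn = {
      cm <- matrix(0.5, 4, 4); diag(cm) <- 1
      cm[1, 3] <- cm[3, 1] <- NA     # one missing interhemispheric pair
      cm
    }))
  left <- pair_vv(recs, 1, 2, montage = m)
  expect_equal(unique(left$vv), 10)
  right <- pair_vv(recs, 3, 4, montage = m)
  expect_equal(unique(right$vv), 20)
  inter <- pair_vv(recs, 2, 3, montage = m)
  expect_equal(unique(inter$vv), 15)
  inter_l <- pair_vv(recs, 2, 3, montage = m, interhemi_rule = "left")
  expect_equal(unique(inter_l$vv), 10)
  # missing sFC excluded from the tuple list
  miss <- pair_vv(recs, 1, 3, montage = m)
  expect_true(is.null(miss) || nrow(miss) == 0)
})

test_that("per-patient OLS reproduces the two-point slope", {
  m <- small_montage(2)
  recs <- slope_records(c(10, 20), function(vv, a, b) 0.5 - 0.01 * (vv - 10))
  long <- sfc_long(recs, m)
  res <- slope_ols(long)
  expect_s3_class(res, "slope_result")
  expect_true(all(abs(res$pairs$slope - (-0.01)) < 1e-12, na.rm = TRUE))
})

test_that("consistent negative slopes across patients give a strongly negative t", {
  set.seed(50)
  m <- small_montage(2)
  recs <- list()
  for (p in 1:8) {
    vv <- c(10, 20, 30) + rnorm(3, 0, 0.01)
    r <- slope_records(vv, function(v, a, b) 0.6 - 0.01 * v +
                         rnorm(1, 0, 1e-4),
                       patient_id = sprintf("P%02d", p))
    recs <- c(recs, r)
  }
  long <- sfc_long(recs, m)
  res <- slope_ols(long)
  expect_true(all(res$pairs$t < -10, na.rm = TRUE))
  expect_true(all(res$hemispheres$slope < 0, na.rm = TRUE))
  expect_true(all(res$hemispheres$t < -5, na.rm = TRUE))
})

test_that("patients with constant VV are dropped with a warning", {
  m <- small_montage(2)
  recs <- c(slope_records(c(10, 20), function(v, a, b) 0.5 - 0.01 * v,
                          patient_id = "P01"),
            slope_records(c(15, 15), function(v, a, b) 0.4,
                          patient_id = "P02"))
  long <- sfc_long(recs, m)
  expect_warning(res <- slope_ols(long), "constant VV")
  expect_true(all(res$pairs$n_patients == 1))
})

test_that("LME slope recovery on a synthetic multi-patient design", {
  set.seed(51)
  m <- small_montage(2)
  recs <- list()
  for (p in 1:10) {
    ns <- sample(4:8, 1)
    vv <- sort(runif(ns, 10, 60))
    icpt <- 0.62 + rnorm(1, 0, 0.03)
    r <- slope_records(vv, function(v, a, b) icpt - 0.002 * v +
                         rnorm(1, 0, 0.05),
                       patient_id = sprintf("P%02d", p), ga0 = 28 + p / 10)
    recs <- c(recs, r)
  }
  long <- sfc_long(recs, m)
  res <- slope_lme(long)
  expect_equal(res$method, "lme")
  ok <- !is.na(res$pairs$slope)
  expect_true(any(ok))
  expect_true(all(abs(res$pairs$slope[ok] + 0.002) <
                    2.5 * res$pairs$se[ok] + 1e-3))
  res_ga <- slope_lme(long, include_ga = TRUE)
  expect_equal(res_ga$method, "lme_ga")
  expect_true(any(!is.na(res_ga$pairs$slope)))
})

test_that("LME requires at least two patients", {
  m <- small_montage(2)
  recs <- slope_records(c(10, 20, 30, 40, 50, 60, 70),
                        function(v, a, b) 0.5 - 0.001 * v)
  long <- sfc_long(recs, m)
  res <- slope_lme(long)
  expect_true(all(is.na(res$pairs$slope)))
})

test_that("GA post-hoc models recover a volume growth rate", {
  set.seed(52)
  m <- small_montage(2)
  recs <- list()
  for (p in 1:8) {
    ga <- 28 + p / 7 + 0:4
    vv <- 5 + 2 * (ga - 28) + rnorm(5, 0, 0.3)   # 2 mL/week per side
    for (i in 1:5) {
      cm <- matrix(0.5, 4, 4); diag(cm) <- 1
      recs[[length(recs) + 1]] <- list(
        patient_id = sprintf("P%02d", p), group = "g", session_idx = i,
        ga_weeks = ga[i], vv_left_ml = vv[i], vv_right_ml = vv[i],
        vv_total_ml = 2 * vv[i], diversion_before = FALSE, conn = cm)
    }
  }
  long <- sfc_long(recs, m)
  res <- ga_posthoc(long)
  vvrow <- res[res$outcome == "vv_total", ]
  expect_lt(abs(vvrow$slope - 4), 2 * vvrow$se + 0.2)  # total = 2 sides
  sfcrow <- res[res$outcome == "mean_abs_sfc", ]
  expect_lt(abs(sfcrow$slope), 0.02)                   # GA-independent |sFC|
})

test_that("diversion paired tests recover step magnitudes and skip unmatched events", {
  set.seed(53)
  mg <- generate_montage()
  spec <- cohort_spec(n_no_diversion = 0, n_diversion = 7)
  co <- suppressWarnings(simulate_sfc_cohort(spec, seed = 60))
  res <- diversion_paired_tests(co)
  expect_false(is.null(res$deltas))
  tr <- res$tests[res$tests$variable == "d_vv_total", ]
  # recovered mean step within 2 SE of the realized mean step
  realized <- numeric(0)
  for (p in co$patients) {
    ga <- vapply(p$sessions, `[[`, 0, "ga_weeks")
    for (e in seq_len(nrow(p$events))) {
      pre <- max(which(ga <= p$events$ga_weeks[e]))
      post <- min(which(ga >= p$events$ga_weeks[e]))
      if (is.finite(pre) && is.finite(post) && post > pre)
        realized <- c(realized,
                      p$sessions[[post]]$vv_total_ml - p$sessions[[pre]]$vv_total_ml)
    }
  }
  expect_lt(abs(tr$mean - mean(realized)), 2 * tr$sd / sqrt(tr$n) + 1e-9)
  expect_lt(tr$mean, 0)   # volumes decrease after diversion
  expect_lt(tr$p, 0.05)
})

test_that("zero-difference events give zero deltas", {
  mg <- small_montage(2)
  cm <- matrix(0.5, 4, 4); diag(cm) <- 1
  mk_sess <- function(i, ga) list(session_idx = i, ga_weeks = ga,
                                  vv_left_ml = 10, vv_right_ml = 10,
                                  vv_total_ml = 20, diversion_before = FALSE,
                                  conn = cm)
  pat <- list(patient_id = "P01", group = "diversion",
              events = data.frame(ga_weeks = 30.05, step_ml_total = 0),
              sessions = list(mk_sess(1, 30), mk_sess(2, 30.1)))
  co <- list(montage = mg, patients = list(pat))
  res <- diversion_paired_tests(co, clusters = list(
    a = cbind(ch_i = 1, ch_j = 2)))
  expect_equal(res$deltas$d_vv_total, 0)
  expect_equal(res$deltas$d_sfc_a, 0)
  # event with no post session inside the window is skipped
  pat2 <- pat
  pat2$events$ga_weeks <- 31.5
  co2 <- list(montage = mg, patients = list(pat2))
  res2 <- diversion_paired_tests(co2, clusters = list(
    a = cbind(ch_i = 1, ch_j = 2)))
  expect_null(res2$deltas)
  expect_length(res2$skipped, 1)
})

test_that("case-study tables are complete, sorted, and carry event markers", {
  spec <- cohort_spec(n_no_diversion = 0, n_diversion = 1,
                      sessions_diversion = c(11, 11))
  co <- suppressWarnings(simulate_sfc_cohort(spec, seed = 61))
  pat <- co$patients[[1]]
  tab <- case_study_series(pat, co$montage$clusters)
  expect_equal(nrow(tab), 11)
  expect_equal(ncol(tab), 2 + 2 + 4)  # id, ga, 2 VV, 4 clusters
  expect_false(is.unsorted(tab$ga_weeks))
  expect_equal(attr(tab, "events"), pat$events$ga_weeks)
  # shuffled sessions come back sorted by GA
  pat_sh <- pat
  pat_sh$sessions <- pat$sessions[sample(length(pat$sessions))]
  tab2 <- case_study_series(pat_sh, co$montage$clusters)
  expect_equal(tab2$ga_weeks, tab$ga_weeks)
  # no events -> empty marker list
  pat0 <- pat; pat0$events <- NULL
  expect_length(attr(case_study_series(pat0, co$montage$clusters), "events"), 0)
})
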