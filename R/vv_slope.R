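#' Absolute connectivity matrix
#'
#' Elementwise absolute value; missing entries stay missing. |sFC| measures
#' overall disruption of connectivity regardless of each pair's polarity.
#'
#' @param conn connectivity matrix.
#' @return matrix of |sFC|.
#' @export
abs_sfc <- function(conn) {
  out <- abs(conn)
  attr(out, "chromophore") <- attr(conn, "chromophore")
  out
}

# ventricle volume relevant to a channel pair: the hemisphere's volume for
# within-hemisphere pairs, the configured rule for interhemispheric pairs
pair_volume <- function(hemisphere, vv_left, vv_right, interhemi_rule) {
  switch(hemisphere,
         left = vv_left, right = vv_right,
         inter = switch(interhemi_rule,
                        mean = (vv_left + vv_right) / 2,
                        left = vv_left, right = vv_right,
                        total = vv_left + vv_right,
                        stop_invalid("unknown interhemi_rule '%s'",
                                     interhemi_rule)),
         stop_invalid("unknown hemisphere '%s'", hemisphere))
}

#' Long-format |sFC| / VV table
#'
#' One row per session x channel pair with the pair's |sFC|, its hemisphere
#' assignment and the matched ventricle volume. Sessions with a missing
#' correlation for a pair are dropped from that pair.
#'
#' @param records list of session records (see [flatten_cohort()] inputs) or
#'   an `sfc_cohort` whose sessions carry connectivity.
#' @param montage the montage (taken from the cohort when one is passed).
#' @param interhemi_rule volume rule for interhemispheric pairs
#'   (`"mean"`, `"left"`, `"right"`, `"total"`).
#' @param pairs optional data.frame (`ch_i`, `ch_j`) restricting the pairs.
#' @return data.frame: patient_id, group, session_idx, ga_weeks, pair_id,
#'   ch_i, ch_j, hemisphere, abs_sfc, vv, vv_left_ml, vv_right_ml.
#' @export
sfc_long <- function(records, montage = NULL, interhemi_rule = "mean",
                     pairs = NULL) {
  if (inherits(records, "sfc_cohort")) {
    montage <- montage %||% records$montage
    records <- flatten_cohort(records)
  }
  if (is.null(montage)) stop_invalid("montage required")
  cp <- channel_pairs(montage)
  if (!is.null(pairs))
    cp <- merge(cp, pairs[, c("ch_i", "ch_j")], by = c("ch_i", "ch_j"))
  chunks <- lapply(records, function(r) {
    sfc <- abs(r$conn[cbind(cp$ch_i, cp$ch_j)])
    keep <- !is.na(sfc)
    if (!any(keep)) return(NULL)
    vv <- mapply(pair_volume, cp$hemisphere[keep],
                 MoreArgs = list(vv_left = r$vv_left_ml,
                                 vv_right = r$vv_right_ml,
                                 interhemi_rule = interhemi_rule))
    data.frame(patient_id = r$patient_id, group = r$group,
               session_idx = r$session_idx, ga_weeks = r$ga_weeks,
               pair_id = paste0(cp$ch_i[keep], "_", cp$ch_j[keep]),
               ch_i = cp$ch_i[keep], ch_j = cp$ch_j[keep],
               hemisphere = cp$hemisphere[keep],
               abs_sfc = sfc[keep], vv = vv,
               vv_left_ml = r$vv_left_ml, vv_right_ml = r$vv_right_ml)
  })
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  out
}

#' Per-session (|sFC|, VV) tuples for one channel pair
#'
#' @param records session records or an `sfc_cohort`.
#' @param ch_i,ch_j channel indices of the pair.
#' @param interhemi_rule volume rule for interhemispheric pairs.
#' @param montage montage (taken from the cohort when one is passed).
#' @return data.frame: patient_id, ga_weeks, abs_sfc, vv.
#' @export
pair_vv <- function(records, ch_i, ch_j, interhemi_rule = "mean",
                    montage = NULL) {
  long <- sfc_long(records, montage, interhemi_rule,
                   pairs = data.frame(ch_i = min(ch_i, ch_j),
                                      ch_j = max(ch_i, ch_j)))
  if (is.null(long)) return(NULL)
  long[, c("patient_id", "ga_weeks", "abs_sfc", "vv")]
}

hemisphere_test <- function(pair_df) {
  out <- data.frame(hemisphere = c("left", "right"), slope = NA_real_,
                    t = NA_real_, df = NA_real_, p = NA_real_, n_pairs = 0L)
  for (i in 1:2) {
    v <- pair_df$slope[pair_df$hemisphere == out$hemisphere[i] &
                       !is.na(pair_df$slope)]
    out$n_pairs[i] <- length(v)
    if (length(v) >= 2 && stats::sd(v) > 0) {
      tt <- stats::t.test(v, mu = 0)
      out$slope[i] <- mean(v)
      out$t[i] <- unname(tt$statistic)
      out$df[i] <- unname(tt$parameter)
      out$p[i] <- tt$p.value
    } else if (length(v)) {
      out$slope[i] <- mean(v)
    }
  }
  out
}

#' |sFC|/VV slope: per-patient simple linear regression
#'
#' Method 1 of the three incremental estimators: per channel pair, an OLS
#' slope of |sFC| on VV is fit for every patient with at least
#' `min_sessions` sessions (patients with constant VV are dropped with a
#' warning), the patient slopes are combined with a one-sample t-test
#' against zero, and a hemisphere-level one-sample t-test pools the
#' group-level slopes of all within-hemisphere pairs.
#'
#' @param long a long table from [sfc_long()] (or an `sfc_cohort`).
#' @param min_sessions minimum sessions per contributing patient.
#' @return `slope_result`: `method`, `pairs` (slope, SE, t, p, n per pair),
#'   `hemispheres` (pooled slope, t, p).
#' @export
slope_ols <- function(long, min_sessions = 2) {
  long <- as_long(long)
  dropped_const <- FALSE
  per_pair <- lapply(split(long, long$pair_id), function(d) {
    sl <- vapply(split(d, d$patient_id), function(pd) {
      if (nrow(pd) < min_sessions) return(NA_real_)
      if (stats::var(pd$vv) <= 0) { dropped_const <<- TRUE; return(NA_real_) }
      stats::cov(pd$abs_sfc, pd$vv) / stats::var(pd$vv)
    }, numeric(1))
    sl <- sl[!is.na(sl)]
    res <- data.frame(pair_id = d$pair_id[1], ch_i = d$ch_i[1],
                      ch_j = d$ch_j[1], hemisphere = d$hemisphere[1],
                      slope = NA_real_, se = NA_real_, t = NA_real_,
                      p = NA_real_, n_patients = length(sl),
                      n_sessions = nrow(d))
    if (length(sl) >= 2 && stats::sd(sl) > 0) {
      res$slope <- mean(sl)
      res$se <- stats::sd(sl) / sqrt(length(sl))
      res$t <- res$slope / res$se
      res$p <- 2 * stats::pt(-abs(res$t), length(sl) - 1)
    } else if (length(sl)) res$slope <- mean(sl)
    res
  })
  pairs <- do.call(rbind, per_pair)
  rownames(pairs) <- NULL
  if (dropped_const)
    warning("patients with constant VV dropped from per-patient OLS slopes")
  structure(list(method = "ols_per_patient", pairs = pairs,
                 hemispheres = hemisphere_test(pairs)),
            class = "slope_result")
}

as_long <- function(x) {
  if (inherits(x, "sfc_cohort")) x <- sfc_long(x)
  if (!is.data.frame(x)) stop_invalid("expected a long table or sfc_cohort")
  x
}

fit_lme_pair <- function(d, include_ga) {
  fixed <- if (include_ga) abs_sfc ~ vv + ga_weeks else abs_sfc ~ vv
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  ok <- function(m) {
    msgs <- m@optinfo$conv$lme4$messages
    is.null(msgs) || !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  }
  # random VV slope attempted first; intercept-only fallback
  m <- tryCatch(suppressWarnings(suppressMessages(
    lme4::lmer(stats::update(fixed, . ~ . + (vv | patient_id)), data = d,
               REML = TRUE, control = ctrl))), error = function(e) NULL)
  random_slope <- TRUE
  if (is.null(m) || !ok(m) || lme4::isSingular(m, tol = 1e-5)) {
    random_slope <- FALSE
    m <- tryCatch(suppressWarnings(suppressMessages(
      lme4::lmer(stats::update(fixed, . ~ . + (1 | patient_id)), data = d,
                 REML = TRUE, control = ctrl))), error = function(e) NULL)
    if (!is.null(m) && !ok(m)) m <- NULL
  }
  list(fit = m, random_slope = random_slope)
}

#' |sFC|/VV slope: linear mixed-effects estimators
#'
#' Methods 2 and 3: per channel pair, `|sFC| ~ 1 + VV (+ GA)` with a random
#' intercept per patient; a random VV slope is attempted first and dropped
#' on convergence failure or singular fit (logged in the result). The
#' fixed-effect VV slope is reported with its Wald t and normal-approximation
#' p-value. Including GA (method 3) adjusts both |sFC| and VV for their
#' trends across gestational age. Hemisphere-level pooled tests are
#' one-sample t-tests over the pairs' fixed-effect slopes, as in
#' [slope_ols()].
#'
#' @param long a long table from [sfc_long()] (or an `sfc_cohort`).
#' @param include_ga add gestational age at session as a fixed effect.
#' @param min_patients,min_sessions_total minimum design size per pair.
#' @return `slope_result` with `method` `"lme"` or `"lme_ga"`.
#' @export
slope_lme <- function(long, include_ga = FALSE, min_patients = 2,
                      min_sessions_total = 6) {
  long <- as_long(long)
  per_pair <- lapply(split(long, long$pair_id), function(d) {
    res <- data.frame(pair_id = d$pair_id[1], ch_i = d$ch_i[1],
                      ch_j = d$ch_j[1], hemisphere = d$hemisphere[1],
                      slope = NA_real_, se = NA_real_, t = NA_real_,
                      p = NA_real_,
                      n_patients = length(unique(d$patient_id)),
                      n_sessions = nrow(d), random_slope = NA)
    if (res$n_patients < min_patients || res$n_sessions < min_sessions_total)
      return(res)
    f <- fit_lme_pair(d, include_ga)
    if (is.null(f$fit)) return(res)
    co <- summary(f$fit)$coefficients
    res$slope <- co["vv", "Estimate"]
    res$se <- co["vv", "Std. Error"]
    res$t <- co["vv", "t value"]
    res$p <- 2 * stats::pnorm(-abs(res$t))
    res$random_slope <- f$random_slope
    res
  })
  pairs <- do.call(rbind, per_pair)
  rownames(pairs) <- NULL
  structure(list(method = if (include_ga) "lme_ga" else "lme",
                 pairs = pairs, hemispheres = hemisphere_test(pairs)),
            class = "slope_result")
}

#' @export
print.slope_result <- function(x, ...) {
  cat(sprintf("|sFC|/VV slopes, method %s: %d pairs\n", x$method,
              nrow(x$pairs)))
  print(x$hemispheres, row.names = FALSE)
  invisible(x)
}

#' Post-hoc gestational-age models
#'
#' Linear mixed-effects models evaluating VV and session-mean |sFC|
#' independently across gestational age (`outcome ~ 1 + GA + (1 | patient)`),
#' the context check for the GA-adjusted slope method.
#'
#' @param long a long table from [sfc_long()] (or an `sfc_cohort`).
#' @return data.frame: outcome, slope (per week), se, t, p, n_patients,
#'   n_sessions.
#' @export
ga_posthoc <- function(long) {
  long <- as_long(long)
  sess <- unique(long[, c("patient_id", "session_idx", "ga_weeks",
                          "vv_left_ml", "vv_right_ml")])
  sess$vv_total <- sess$vv_left_ml + sess$vv_right_ml
  msfc <- stats::aggregate(abs_sfc ~ patient_id + session_idx, long, mean)
  sess <- merge(sess, msfc, by = c("patient_id", "session_idx"))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit_one <- function(fml, label) {
    base <- data.frame(outcome = label, slope = NA_real_, se = NA_real_,
                       t = NA_real_, p = NA_real_,
                       n_patients = length(unique(sess$patient_id)),
                       n_sessions = nrow(sess))
    resp <- all.vars(fml)[1]
    if (stats::var(sess[[resp]]) == 0) {   # degenerate: constant outcome
      base$slope <- 0; base$se <- 0
      return(base)
    }
    co <- tryCatch({
      m <- suppressWarnings(suppressMessages(
        lme4::lmer(fml, data = sess, REML = TRUE, control = ctrl)))
      summary(m)$coefficients
    }, error = function(e) NULL)
    if (is.null(co)) return(base)
    base$slope <- co["ga_weeks", "Estimate"]
    base$se <- co["ga_weeks", "Std. Error"]
    base$t <- co["ga_weeks", "t value"]
    base$p <- 2 * stats::pnorm(-abs(base$t))
    base
  }
  rbind(fit_one(vv_total ~ ga_weeks + (1 | patient_id), "vv_total"),
        fit_one(abs_sfc ~ ga_weeks + (1 | patient_id), "mean_abs_sfc"))
}

#' Pre/post CSF-diversion paired comparisons
#'
#' For every diversion event with a session pair inside the matching window
#' (default same-day), computes the change in ventricle volumes (left,
#' right, total) and in the four cluster mean |sFC| values, then group-level
#' paired t-tests of each change against zero. Events without a matching
#' pre or post session are skipped (listed in `skipped`).
#'
#' @param cohort an `sfc_cohort` whose sessions carry connectivity, or a
#'   list with `patients` of the same shape.
#' @param match_window_wk maximum |GA(session) - GA(event)| in weeks
#'   (default 0.15 wk, about one day).
#' @param clusters channel-pair clusters (default: the cohort montage's).
#' @return list: `deltas` (per event), `tests` (per variable: mean, sd, t,
#'   df, p, n), `skipped`.
#' @export
diversion_paired_tests <- function(cohort, match_window_wk = 0.15,
                                   clusters = NULL) {
  clusters <- clusters %||% cohort$montage$clusters
  deltas <- NULL
  skipped <- character(0)
  for (pat in cohort$patients) {
    if (is.null(pat$events) || !nrow(pat$events)) next
    ga <- vapply(pat$sessions, `[[`, 0, "ga_weeks")
    for (e in seq_len(nrow(pat$events))) {
      ga_e <- pat$events$ga_weeks[e]
      pre_ok <- which(ga <= ga_e & ga_e - ga <= match_window_wk)
      post_ok <- which(ga >= ga_e & ga - ga_e <= match_window_wk)
      if (!length(pre_ok) || !length(post_ok)) {
        skipped <- c(skipped, sprintf("%s event %d (no matched %s session)",
                                      pat$patient_id, e,
                                      if (length(pre_ok)) "post" else "pre"))
        next
      }
      pre <- pat$sessions[[max(pre_ok)]]
      post <- pat$sessions[[min(post_ok)]]
      row <- data.frame(patient_id = pat$patient_id, event = e,
                        ga_weeks = ga_e,
                        d_vv_left = post$vv_left_ml - pre$vv_left_ml,
                        d_vv_right = post$vv_right_ml - pre$vv_right_ml,
                        d_vv_total = post$vv_total_ml - pre$vv_total_ml)
      if (length(clusters)) {
        cs_pre <- cluster_summary(pre$conn, clusters)
        cs_post <- cluster_summary(post$conn, clusters)
        dsfc <- as.data.frame(as.list(cs_post - cs_pre))
        names(dsfc) <- paste0("d_sfc_", names(clusters))
        row <- cbind(row, dsfc)
      }
      deltas <- rbind(deltas, row)
    }
  }
  if (is.null(deltas))
    return(list(deltas = NULL, tests = NULL, skipped = skipped))
  vars <- setdiff(names(deltas), c("patient_id", "event", "ga_weeks"))
  tests <- do.call(rbind, lapply(vars, function(v) {
    x <- deltas[[v]][!is.na(deltas[[v]])]
    if (length(x) >= 2 && stats::sd(x) > 0) {
      tt <- stats::t.test(x, mu = 0)
      data.frame(variable = v, mean = mean(x), sd = stats::sd(x),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, n = length(x))
    } else {
      data.frame(variable = v, mean = if (length(x)) mean(x) else NA_real_,
                 sd = NA_real_, t = NA_real_, df = NA_real_, p = NA_real_,
                 n = length(x))
    }
  }))
  list(deltas = deltas, tests = tests, skipped = skipped)
}

#' Longitudinal case-study table for one patient
#'
#' Tidy per-session table of gestational age, left/right ventricle volumes
#' and the four cluster mean |sFC| values, sorted by GA, with the patient's
#' CSF-diversion event times attached for plotting as vertical markers.
#'
#' @param patient one element of `cohort$patients` (needs >= 2 sessions with
#'   connectivity).
#' @param clusters channel-pair clusters.
#' @return data.frame with attribute `events` (GA weeks of diversions).
#' @export
case_study_series <- function(patient, clusters) {
  if (length(patient$sessions) < 2) stop_invalid("need at least 2 sessions")
  rows <- lapply(patient$sessions, function(s) {
    cs <- cluster_summary(s$conn, clusters)
    cbind(data.frame(patient_id = patient$patient_id,
                     ga_weeks = s$ga_weeks,
                     vv_left_ml = s$vv_left_ml, vv_right_ml = s$vv_right_ml),
          as.data.frame(as.list(cs)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$ga_weeks), ]
  rownames(out) <- NULL
  attr(out, "events") <- if (!is.null(patient$events))
    patient$events$ga_weeks else numeric(0)
  out
}
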