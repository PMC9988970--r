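#' Robust correlation of two series
#'
#' Iteratively reweighted correlation: both series are standardized robustly
#' (median/MAD), bisquare weights (tuning constant 4.685) are computed from
#' each sample's joint standardized residual distance to the current
#' weighted line fit (the bivariate Mahalanobis distance, so the weighting
#' is symmetric in the two series), and the fit is iterated to convergence
#' (change below `tol` or `max_iter` iterations). A final reweighting step
#' -- standard in robust covariance estimation -- returns the Pearson
#' correlation over the samples whose converged bisquare weight is positive:
#' samples beyond the redescending cutoff are excluded, and on clean data,
#' where every weight stays positive (and the limit weights are 1), the
#' result equals the classical Pearson correlation. A zero MAD on either
#' input falls back to classical Pearson with a warning.
#'
#' @param x,y numeric series of equal length >= 10.
#' @param tuning bisquare tuning constant.
#' @param max_iter,tol iteration controls.
#' @return correlation in `[-1, 1]`.
#' @export
robust_correlation <- function(x, y, tuning = 4.685, max_iter = 50,
                               tol = 1e-6) {
  n <- length(x)
  if (length(y) != n) stop_invalid("x and y must have equal length")
  if (n < 10) stop_invalid("robust correlation needs length >= 10")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_invalid("inputs must be finite")
  madx <- robust_sd(x); mady <- robust_sd(y)
  if (madx < .Machine$double.eps || mady < .Machine$double.eps) {
    warning("zero MAD; falling back to classical Pearson correlation")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    return(clamp(stats::cor(x, y), -1, 1))
  }
  xs <- (x - stats::median(x)) / madx
  ys <- (y - stats::median(y)) / mady
  w <- rep(1, n)
  r_old <- Inf
  r <- stats::cor(xs, ys)
  for (it in seq_len(max_iter)) {
    sw <- sum(w)
    mx <- sum(w * xs) / sw; my <- sum(w * ys) / sw
    dx <- xs - mx; dy <- ys - my
    vx <- sum(w * dx^2) / sw; vy <- sum(w * dy^2) / sw
    if (vx <= 0 || vy <= 0) break
    r <- (sum(w * dx * dy) / sw) / sqrt(vx * vy)
    if (abs(r - r_old) < tol || abs(r) >= 1 - 1e-12) break
    r_old <- r
    # joint standardized residual distance of each sample to the fit
    z1 <- dx / sqrt(vx); z2 <- dy / sqrt(vy)
    d2 <- (z1^2 + z2^2 - 2 * r * z1 * z2) / (1 - r^2)
    u <- sqrt(pmax(d2, 0)) / tuning
    w <- ifelse(u < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < 3) {                # degenerate weighting
      w <- rep(1, n)
      r <- stats::cor(xs, ys)
      break
    }
  }
  keep <- w > 0
  if (abs(r) < 1 - 1e-12 && sum(keep) >= 3 &&
      stats::sd(xs[keep]) > 0 && stats::sd(ys[keep]) > 0)
    r <- stats::cor(xs[keep], ys[keep])
  clamp(r, -1, 1)
}

#' Session connectivity matrix (robust correlation sFC)
#'
#' Applies [robust_correlation()] to every pair of valid channels of the
#' 1 Hz hemoglobin series. Entries involving invalid channels are missing
#' (`NA`), never zero.
#'
#' @param hemo a `hemo_series` at 1 Hz.
#' @param validity optional `channel_validity`.
#' @param chromophore one of `"HbT"`, `"HbO"`, `"HbR"`.
#' @return symmetric channel x channel matrix with unit diagonal on valid
#'   channels; attribute `chromophore`.
#' @export
session_sfc <- function(hemo, validity = NULL,
                        chromophore = c("HbT", "HbO", "HbR")) {
  chromophore <- match.arg(chromophore)
  if (hemo$fs != 1)
    stop_invalid("connectivity is computed on 1 Hz series; resample first")
  M <- switch(chromophore, HbT = hemo$hbt, HbO = hemo$hbo, HbR = hemo$hbr)
  nch <- ncol(M)
  valid <- rep(TRUE, nch)
  if (!is.null(validity)) valid <- validity$valid
  valid <- valid & !apply(is.na(M), 2, any)
  if (sum(valid) < 2)
    stop_invalid("session invalid: fewer than 2 valid channels")
  conn <- matrix(NA_real_, nch, nch,
                 dimnames = list(colnames(M), colnames(M)))
  vs <- which(valid)
  for (a in seq_along(vs)) {
    conn[vs[a], vs[a]] <- 1
    for (b in seq_along(vs)) {
      if (b <= a) next
      r <- robust_correlation(M[, vs[a]], M[, vs[b]])
      conn[vs[a], vs[b]] <- r
      conn[vs[b], vs[a]] <- r
    }
  }
  attr(conn, "chromophore") <- chromophore
  conn
}

# flatten an sfc_cohort into a list of session records (patient_id, group,
# ga, volumes, conn, diversion flag); sessions must carry connectivity
flatten_cohort <- function(cohort) {
  out <- list()
  for (pat in cohort$patients) {
    for (s in pat$sessions) {
      if (is.null(s$conn))
        stop_invalid("session lacks a connectivity matrix; run the pipeline first")
      out[[length(out) + 1]] <- list(
        patient_id = pat$patient_id, group = pat$group,
        session_idx = s$session_idx, ga_weeks = s$ga_weeks,
        vv_left_ml = s$vv_left_ml, vv_right_ml = s$vv_right_ml,
        vv_total_ml = s$vv_total_ml, diversion_before = s$diversion_before,
        conn = s$conn)
    }
  }
  out
}

#' Group t-map of spontaneous functional connectivity
#'
#' Per channel pair, raw correlations are first averaged across sessions to
#' one mean per patient, then a one-sample t-test against zero is computed
#' across patients. Pairs contributed by fewer than `min_patients` patients
#' are flagged `low_confidence` and excluded from the test.
#'
#' @param records list of session records (each with `patient_id` and
#'   `conn`), e.g. from a processed cohort.
#' @param min_patients minimum-sample-size threshold (study thresholds: 10 of
#'   23 in the no-diversion arm, 5 of 7 in the diversion arm).
#' @return data.frame of class `group_tmap`: `ch_i`, `ch_j`, `mean_sfc`,
#'   `t`, `df`, `p`, `n_patients`, `low_confidence`.
#' @export
group_tmap <- function(records, min_patients = 2) {
  if (!length(records)) stop_invalid("no records")
  nch <- nrow(records[[1]]$conn)
  pats <- unique(vapply(records, `[[`, "", "patient_id"))
  if (length(pats) < 2) stop_invalid("at least 2 patients required")
  # patient means per pair
  arr <- array(NA_real_, c(nch, nch, length(pats)))
  for (k in seq_along(pats)) {
    cs <- Filter(function(r) r$patient_id == pats[k], records)
    stack <- simplify2array(lapply(cs, `[[`, "conn"))
    arr[, , k] <- apply(stack, c(1, 2), function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  }
  idx <- which(upper.tri(matrix(0, nch, nch)), arr.ind = TRUE)
  res <- data.frame(ch_i = idx[, 1], ch_j = idx[, 2], mean_sfc = NA_real_,
                    t = NA_real_, df = NA_real_, p = NA_real_,
                    n_patients = 0L, low_confidence = TRUE)
  for (r in seq_len(nrow(res))) {
    v <- arr[res$ch_i[r], res$ch_j[r], ]
    v <- v[!is.na(v)]
    res$n_patients[r] <- length(v)
    if (length(v) >= max(2, min_patients)) {
      res$low_confidence[r] <- FALSE
      res$mean_sfc[r] <- mean(v)
      s <- stats::sd(v)
      res$df[r] <- length(v) - 1
      if (s > 0) {
        res$t[r] <- mean(v) / (s / sqrt(length(v)))
        res$p[r] <- 2 * stats::pt(-abs(res$t[r]), res$df[r])
      }
    }
  }
  if (all(res$low_confidence))
    warning("all channel pairs are low-confidence at this threshold")
  class(res) <- c("group_tmap", "data.frame")
  res
}

#' Cluster summaries of |sFC|
#'
#' Mean absolute connectivity over each named cluster's channel pairs,
#' skipping missing entries; a cluster with no available pair yields `NA`.
#'
#' @param conn connectivity matrix.
#' @param clusters named list of two-column matrices (`ch_i`, `ch_j`), as in
#'   `montage$clusters`.
#' @return named numeric vector of cluster mean |sFC|.
#' @export
cluster_summary <- function(conn, clusters) {
  if (!length(clusters)) stop_invalid("no clusters defined")
  vapply(clusters, function(cl) {
    v <- abs(conn[cbind(cl[, 1], cl[, 2])])
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}
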