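#' Ventricle volumes from a segmentation label map
#'
#' Volume = voxel count x voxel volume, converted mm^3 to mL. Labels:
#' 0 background, 1 left ventricle, 2 right ventricle.
#'
#' @param labels integer 3D array (any voxel grid).
#' @param voxel_mm length-3 voxel dimensions in mm.
#' @return named vector `vv_left_ml`, `vv_right_ml`, `vv_total_ml`.
#' @export
volume_from_labelmap <- function(labels, voxel_mm) {
  if (length(voxel_mm) != 3 || any(voxel_mm <= 0))
    stop_invalid("voxel_mm must be 3 positive dimensions")
  u <- unique(as.vector(labels))
  bad <- setdiff(u, c(0L, 1L, 2L))
  if (length(bad))
    stop_invalid("unknown label value(s): %s", paste(bad, collapse = ", "))
  vox_ml <- prod(voxel_mm) / 1000
  left <- sum(labels == 1L) * vox_ml
  right <- sum(labels == 2L) * vox_ml
  c(vv_left_ml = left, vv_right_ml = right, vv_total_ml = left + right)
}

#' Write / read the sessions table
#'
#' Interchange CSV for the volumetric and grouping data: one row per
#' session with columns `patient_id, session_idx, ga_weeks, vv_left_ml,
#' vv_right_ml, vv_total_ml, diversion_before, group`.
#'
#' @param cohort an `sfc_cohort` (or a list with the same `patients` shape).
#' @param path CSV path.
#' @return (invisibly) the data.frame written; `read_sessions_csv` returns
#'   the data.frame.
#' @export
write_sessions_csv <- function(cohort, path) {
  rows <- lapply(cohort$patients, function(pat) {
    do.call(rbind, lapply(pat$sessions, function(s) data.frame(
      patient_id = pat$patient_id, session_idx = s$session_idx,
      ga_weeks = s$ga_weeks, vv_left_ml = s$vv_left_ml,
      vv_right_ml = s$vv_right_ml, vv_total_ml = s$vv_total_ml,
      diversion_before = s$diversion_before, group = pat$group)))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname write_sessions_csv
#' @export
read_sessions_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a recording as plain text
#'
#' Serializes a `raw_recording` as a CSV intensity matrix (one column per
#' channel x wavelength, full double precision) plus a JSON sidecar holding
#' the sampling rate, wavelengths and montage geometry. The round trip
#' preserves intensities to 1e-9, `fs` exactly and optode positions to
#' 1e-6 mm.
#'
#' @param rec a `raw_recording`.
#' @param prefix path prefix; files `<prefix>_intensity.csv` and
#'   `<prefix>_meta.json` are written.
#' @return (invisibly) the two file paths.
#' @export
write_recording_csv <- function(rec, prefix) {
  d <- dim(rec$intensity)
  flat <- matrix(rec$intensity, d[1], d[2] * d[3])
  colnames(flat) <- as.vector(outer(dimnames(rec$intensity)[[2]],
                                    dimnames(rec$intensity)[[3]], paste,
                                    sep = "."))
  csv <- paste0(prefix, "_intensity.csv")
  con <- file(csv, "w")
  writeLines(paste(colnames(flat), collapse = ","), con)
  utils::write.table(format(flat, digits = 15, scientific = TRUE, trim = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  close(con)
  meta <- list(fs = rec$fs, wavelengths = rec$montage$wavelengths,
               cap_scale = rec$montage$cap_scale,
               separation_mm = rec$montage$separation_mm,
               n_channels_per_hemisphere =
                 sum(rec$montage$channels$hemisphere == "left"),
               meta = rec$meta,
               channels = rec$montage$channels,
               sources = rec$montage$sources,
               detectors = rec$montage$detectors)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(c(csv, paste0(prefix, "_meta.json")))
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(prefix) {
  meta_path <- paste0(prefix, "_meta.json")
  csv <- paste0(prefix, "_intensity.csv")
  if (!file.exists(meta_path) || !file.exists(csv))
    stop_invalid("missing recording files at prefix '%s'", prefix)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$wavelengths) || length(meta$wavelengths) != 2)
    stop_invalid("malformed recording container: missing wavelength table in %s",
                 meta_path)
  montage <- generate_montage(meta$n_channels_per_hemisphere,
                              meta$separation_mm, meta$cap_scale,
                              meta$wavelengths)
  # restore exact geometry (positions serialized at full precision)
  montage$channels <- as.data.frame(meta$channels)
  montage$sources <- as.data.frame(meta$sources)
  montage$detectors <- as.data.frame(meta$detectors)
  flat <- as.matrix(utils::read.csv(csv, check.names = FALSE))
  nch <- nrow(montage$channels)
  arr <- array(as.numeric(flat), dim = c(nrow(flat), nch, 2),
               dimnames = list(NULL, montage$channels$name,
                               paste0("wl", meta$wavelengths)))
  structure(list(intensity = arr, fs = meta$fs, montage = montage,
                 meta = meta$meta),
            class = "raw_recording")
}

#' Rebuild session records from written pipeline artifacts
#'
#' Inverse of the pipeline's CSV outputs: reads `sessions.csv` and
#' `connectivity.csv` from an output directory and reassembles the list of
#' session records (with sparse missing entries restored as `NA`).
#'
#' @param dir pipeline output directory.
#' @param montage the montage the connectivity matrices refer to.
#' @return list of session records as used by [group_tmap()], [sfc_long()]
#'   and [diversion_paired_tests()].
#' @export
read_pipeline_records <- function(dir, montage) {
  sess <- utils::read.csv(file.path(dir, "sessions.csv"))
  conn <- utils::read.csv(file.path(dir, "connectivity.csv"))
  nch <- montage$n_channels
  records <- vector("list", nrow(sess))
  for (i in seq_len(nrow(sess))) {
    rows <- conn[conn$patient_id == sess$patient_id[i] &
                 conn$session_idx == sess$session_idx[i], ]
    m <- matrix(NA_real_, nch, nch,
                dimnames = list(montage$channels$name,
                                montage$channels$name))
    m[cbind(rows$ch_i, rows$ch_j)] <- rows$sfc
    m[cbind(rows$ch_j, rows$ch_i)] <- rows$sfc
    present <- sort(unique(c(rows$ch_i, rows$ch_j)))
    diag(m)[present] <- 1
    if (nrow(rows)) attr(m, "chromophore") <- rows$chromophore[1]
    records[[i]] <- list(
      patient_id = sess$patient_id[i], group = sess$group[i],
      session_idx = sess$session_idx[i], ga_weeks = sess$ga_weeks[i],
      vv_left_ml = sess$vv_left_ml[i], vv_right_ml = sess$vv_right_ml[i],
      vv_total_ml = sess$vv_total_ml[i],
      diversion_before = sess$diversion_before[i], conn = m)
  }
  records
}

#' Pipeline configuration
#'
#' All stage parameters in one serializable list; together with the seed it
#' reproduces a run bit-for-bit. See the stage functions for the meaning of
#' each field.
#'
#' @param ... overrides of the defaults.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    window_s = 5, overlap = 0.5, cardiac_bpm = c(90, 210),
    subsample_s = 150,
    sci_threshold = 0.7, psp_threshold = 0.1,
    min_good_window_fraction = 0.6, peak_factor = 2,
    motion_window_s = 1, motion_std_mult = 13.5, motion_amp_mult = 5,
    motion_dilate_s = 0.5, spline_smoothing = 0.99,
    ppf = c(0.1063, 0.0845), extinction_table = "gratzer",
    cutoff_hz = 0.09, legendre_orders = 0:4, include_global = TRUE,
    chromophore = "HbT",
    interhemi_rule = "mean",
    min_patients = c(no_diversion = 10, diversion = 5),
    manual_exclusions = list())
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_invalid("unknown pipeline_config fields: %s",
                 paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, over)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# dependency-free polynomial rolling hash of a serialized object, for
# provenance (stays below 2^53 so double arithmetic is exact)
config_hash <- function(x) {
  # canonicalize through JSON so YAML round-trips (integer vs double,
  # named vector vs list) hash identically
  bytes <- utf8ToInt(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                                   digits = 12)))
  h <- 17
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483629
  sprintf("%08x", h)
}

#' Process one session through the signal chain
#'
#' Fixed stage order: windowed quality -> best 2.5-min subsample -> cardiac
#' channel validity (+ manual exclusions) -> optical density -> spline
#' motion correction -> modified Beer-Lambert -> nuisance regression ->
#' 1 Hz resampling -> robust-correlation connectivity.
#'
#' @param recording a `raw_recording`.
#' @param config a [pipeline_config()].
#' @return list: `conn`, `validity`, `window`, `n_excluded_channels`,
#'   `motion_segments`, `hemo_1hz`.
#' @export
process_session <- function(recording, config = pipeline_config()) {
  q <- compute_windowed_quality(recording, config$window_s, config$overlap,
                                config$cardiac_bpm)
  win <- select_best_subsample(q, recording, config$subsample_s)
  validity <- detect_cardiac_channels(
    recording, win, sci_threshold = config$sci_threshold,
    psp_threshold = config$psp_threshold,
    min_good_window_fraction = config$min_good_window_fraction,
    peak_factor = config$peak_factor, cardiac_bpm = config$cardiac_bpm)
  if (length(config$manual_exclusions))
    for (ex in config$manual_exclusions)
      validity <- apply_manual_exclusions(validity, ex$channels, ex$reason)
  od <- intensity_to_od(recording, win)
  od <- motion_correct_od(od, window_s = config$motion_window_s,
                          std_mult = config$motion_std_mult,
                          amp_mult = config$motion_amp_mult,
                          dilate_s = config$motion_dilate_s,
                          smoothing = config$spline_smoothing)
  hemo <- od_to_hemoglobin(od, mbll_params(ppf = config$ppf,
                                           extinction_table = config$extinction_table))
  hemo <- regress_nuisance(hemo, include_global = config$include_global,
                           validity = validity)
  hemo <- resample_to_1hz(hemo)
  conn <- session_sfc(hemo, validity, chromophore = config$chromophore)
  list(conn = conn, validity = validity, window = win,
       n_excluded_channels = sum(!validity$valid),
       motion_segments = od$motion_segments, hemo_1hz = hemo)
}

#' Run the full analysis pipeline on a cohort
#'
#' Processes every session of a simulated (or loaded) cohort through
#' [process_session()], then computes group t-maps, the three |sFC|/VV slope
#' methods per group, the gestational-age post-hoc models, the pre/post
#' diversion paired tests and the longitudinal case-study tables. Sessions
#' failing validity (too short, fewer than 2 valid channels) are excluded
#' and enumerated, never fatal. When `out_dir` is given, per-stage CSV
#' artifacts and a provenance record (config hash, seed, package version)
#' are written.
#'
#' @param cohort an `sfc_cohort` with raw recordings (from
#'   [simulate_cohort()]) or with precomputed connectivity (from
#'   [simulate_sfc_cohort()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list: `cohort` (with `conn` filled in), `records`, `tmap` (per
#'   group), `slopes` (per group x method), `ga` (per group),
#'   `diversion`, `case_studies`, `excluded_sessions`, `exclusion_fraction`,
#'   `provenance`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  excluded <- character(0)
  n_excl_ch <- 0L; n_tot_ch <- 0L
  for (p in seq_along(cohort$patients)) {
    keep <- logical(length(cohort$patients[[p]]$sessions))
    for (i in seq_along(cohort$patients[[p]]$sessions)) {
      s <- cohort$patients[[p]]$sessions[[i]]
      if (!is.null(s$conn)) { keep[i] <- TRUE; next }
      res <- tryCatch(process_session(s$recording, config),
                      error = function(e) e)
      if (inherits(res, "error")) {
        excluded <- c(excluded, sprintf("%s session %d: %s",
                                        cohort$patients[[p]]$patient_id, i,
                                        conditionMessage(res)))
        next
      }
      keep[i] <- TRUE
      n_excl_ch <- n_excl_ch + res$n_excluded_channels
      n_tot_ch <- n_tot_ch + nrow(res$validity)
      s$conn <- res$conn
      s$validity <- res$validity
      s$window <- res$window
      s$recording <- NULL      # processed; drop the raw array
      cohort$patients[[p]]$sessions[[i]] <- s
    }
    cohort$patients[[p]]$sessions <- cohort$patients[[p]]$sessions[keep]
  }
  # study exclusion flow: patients need >= 2 valid sessions
  n_sess <- vapply(cohort$patients, function(p) length(p$sessions), 1L)
  dropped_pat <- vapply(cohort$patients[n_sess < 2], `[[`, "", "patient_id")
  if (length(dropped_pat))
    excluded <- c(excluded, sprintf("%s: fewer than 2 valid sessions",
                                    dropped_pat))
  cohort$patients <- cohort$patients[n_sess >= 2]

  records <- flatten_cohort(cohort)
  groups <- unique(vapply(records, `[[`, "", "group"))
  tmap <- list(); slopes <- list(); ga <- list()
  for (g in groups) {
    recs_g <- Filter(function(r) r$group == g, records)
    mp <- unname(config$min_patients[g] %||% 2)
    tmap[[g]] <- tryCatch(group_tmap(recs_g, min_patients = mp),
                          error = function(e) NULL)
    long_g <- sfc_long(recs_g, cohort$montage, config$interhemi_rule)
    lc <- tmap[[g]]
    if (!is.null(lc)) {
      ok_pairs <- lc[!lc$low_confidence, c("ch_i", "ch_j")]
      long_g <- merge(long_g, ok_pairs, by = c("ch_i", "ch_j"))
    }
    slopes[[g]] <- list(
      ols = slope_ols(long_g),
      lme = slope_lme(long_g, include_ga = FALSE),
      lme_ga = slope_lme(long_g, include_ga = TRUE))
    ga[[g]] <- tryCatch(ga_posthoc(long_g), error = function(e) NULL)
  }
  diversion <- diversion_paired_tests(cohort)
  case_studies <- lapply(
    Filter(function(p) p$group == "diversion" && length(p$sessions) >= 2,
           cohort$patients),
    case_study_series, clusters = cohort$montage$clusters)
  prov <- list(config_hash = config_hash(unclass(config)),
               seed = cohort$seed,
               package_version = as.character(utils::packageVersion("ventsfc")),
               timestamp = format(Sys.time(), tz = "UTC"))
  out <- list(cohort = cohort, records = records, tmap = tmap,
              slopes = slopes, ga = ga, diversion = diversion,
              case_studies = case_studies, excluded_sessions = excluded,
              exclusion_fraction = if (n_tot_ch) n_excl_ch / n_tot_ch else NA,
              provenance = prov)
  if (!is.null(out_dir)) write_pipeline_outputs(out, config, out_dir)
  out
}

write_pipeline_outputs <- function(out, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_sessions_csv(out$cohort, file.path(out_dir, "sessions.csv"))
  # connectivity in long channel-pair format
  conn_rows <- do.call(rbind, lapply(out$records, function(r) {
    m <- r$conn
    idx <- which(upper.tri(m) & !is.na(m), arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(patient_id = r$patient_id, session_idx = r$session_idx,
               ch_i = idx[, 1], ch_j = idx[, 2],
               sfc = m[idx], chromophore = attr(m, "chromophore") %||% "HbT")
  }))
  utils::write.csv(conn_rows, file.path(out_dir, "connectivity.csv"),
                   row.names = FALSE)
  for (g in names(out$tmap))
    if (!is.null(out$tmap[[g]]))
      utils::write.csv(out$tmap[[g]],
                       file.path(out_dir, sprintf("tmap_%s.csv", g)),
                       row.names = FALSE)
  for (g in names(out$slopes)) for (m in names(out$slopes[[g]])) {
    utils::write.csv(out$slopes[[g]][[m]]$pairs,
                     file.path(out_dir, sprintf("slopes_%s_%s.csv", g, m)),
                     row.names = FALSE)
    utils::write.csv(out$slopes[[g]][[m]]$hemispheres,
                     file.path(out_dir,
                               sprintf("slopes_%s_%s_hemisphere.csv", g, m)),
                     row.names = FALSE)
  }
  if (!is.null(out$diversion$tests))
    utils::write.csv(out$diversion$tests,
                     file.path(out_dir, "diversion_tests.csv"),
                     row.names = FALSE)
  prov <- c(out$provenance,
            list(excluded_sessions = out$excluded_sessions,
                 exclusion_fraction = out$exclusion_fraction))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
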