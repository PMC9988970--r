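#' fNIRS montage for the neonatal cap
#'
#' Builds the optode/channel geometry used throughout the pipeline. The
#' default layout reproduces the study cap: 8 sources and 8 detectors in a
#' checkerboard 2 x 4 grid per hemisphere, giving 10 channels of 22 mm
#' nominal separation per hemisphere (20 total), two wavelengths
#' (760, 850 nm), and four fully symmetric functional clusters
#' (left/right x anterior/posterior), each containing 4 channel pairs
#' derived from 5 channels.
#'
#' For `n_channels_per_hemisphere != 10` a linear source-detector chain is
#' generated instead (no clusters defined).
#'
#' @param n_channels_per_hemisphere channels per hemisphere (default 10).
#' @param separation_mm nominal source-detector separation in mm (default 22).
#' @param cap_scale multiplicative cap-size factor; physical separations are
#'   `separation_mm * cap_scale`.
#' @param wavelengths ordered pair of wavelengths in nm.
#' @return an object of class `fnirs_montage`: lists of sources, detectors,
#'   a channel table (source, detector, separation, hemisphere, region,
#'   midpoint position), wavelengths, and named clusters of channel pairs.
#' @examples
#' m <- generate_montage()
#' nrow(m$channels)  # 20
#' @export
generate_montage <- function(n_channels_per_hemisphere = 10,
                             separation_mm = 22,
                             cap_scale = 1,
                             wavelengths = c(760, 850)) {
  if (separation_mm <= 0) stop_invalid("separation_mm must be positive")
  if (cap_scale <= 0) stop_invalid("cap_scale must be positive")
  if (n_channels_per_hemisphere < 1)
    stop_invalid("need at least one channel per hemisphere")
  if (length(wavelengths) != 2) stop_invalid("exactly two wavelengths required")

  sep <- separation_mm * cap_scale
  if (n_channels_per_hemisphere == 10) {
    m <- default_grid_montage(sep)
  } else {
    m <- chain_montage(n_channels_per_hemisphere, sep)
  }
  m$wavelengths <- wavelengths
  m$cap_scale <- cap_scale
  m$separation_mm <- separation_mm
  m$n_channels <- nrow(m$channels)
  class(m) <- "fnirs_montage"
  m
}

# Checkerboard 2 x 4 optode grid per hemisphere; grid-adjacent optodes form
# the 10 channels. Columns 1-2 are anterior, 3-4 posterior; the two edges
# bridging columns 2-3 are split one to each region so every hemisphere x
# region quadrant holds exactly 5 channels.
default_grid_montage <- function(sep) {
  optodes <- data.frame()
  channels <- data.frame()
  src_n <- 0L; det_n <- 0L; ch_n <- 0L
  for (hemi in c("left", "right")) {
    sgn <- if (hemi == "left") -1 else 1
    pos <- expand.grid(row = 1:2, col = 1:4)
    pos$x <- sgn * (15 + (pos$row - 1) * sep)
    pos$y <- (pos$col - 1) * sep
    pos$is_source <- (pos$row + pos$col) %% 2 == 0
    pos$id <- NA_character_
    for (i in seq_len(nrow(pos))) {
      if (pos$is_source[i]) {
        src_n <- src_n + 1L; pos$id[i] <- paste0("S", src_n)
      } else {
        det_n <- det_n + 1L; pos$id[i] <- paste0("D", det_n)
      }
    }
    optodes <- rbind(optodes, cbind(pos, hemisphere = hemi))
    edges <- rbind(
      # horizontal (same row, adjacent columns)
      do.call(rbind, lapply(1:2, function(r) data.frame(
        r1 = r, c1 = 1:3, r2 = r, c2 = 2:4))),
      # vertical (same column, rows 1-2)
      data.frame(r1 = 1, c1 = 1:4, r2 = 2, c2 = 1:4))
    for (i in seq_len(nrow(edges))) {
      a <- pos[pos$row == edges$r1[i] & pos$col == edges$c1[i], ]
      b <- pos[pos$row == edges$r2[i] & pos$col == edges$c2[i], ]
      stopifnot(a$is_source != b$is_source)
      s <- if (a$is_source) a else b
      d <- if (a$is_source) b else a
      cmin <- min(edges$c1[i], edges$c2[i]); cmax <- max(edges$c1[i], edges$c2[i])
      region <- if (cmax <= 2) "anterior"
        else if (cmin >= 3) "posterior"
        else if (edges$r1[i] == edges$r2[i] && edges$r1[i] == 1) "anterior"
        else "posterior"
      ch_n <- ch_n + 1L
      channels <- rbind(channels, data.frame(
        channel = ch_n,
        name = sprintf("%s%02d", toupper(substr(hemi, 1, 1)),
                       ch_n - if (hemi == "left") 0L else 10L),
        source = s$id, detector = d$id,
        sep_mm = sqrt((s$x - d$x)^2 + (s$y - d$y)^2),
        hemisphere = hemi, region = region,
        x = (s$x + d$x) / 2, y = (s$y + d$y) / 2))
    }
  }
  clusters <- list()
  for (hemi in c("left", "right")) for (reg in c("anterior", "posterior")) {
    ch <- sort(channels$channel[channels$hemisphere == hemi &
                                channels$region == reg])
    stopifnot(length(ch) == 5)
    clusters[[paste(hemi, reg, sep = "_")]] <-
      cbind(ch_i = ch[1:4], ch_j = ch[2:5])
  }
  list(sources = optodes[optodes$is_source, c("id", "x", "y", "hemisphere")],
       detectors = optodes[!optodes$is_source, c("id", "x", "y", "hemisphere")],
       channels = channels, clusters = clusters)
}

chain_montage <- function(n_per_hemi, sep) {
  optodes <- data.frame(); channels <- data.frame()
  src_n <- 0L; det_n <- 0L; ch_n <- 0L
  for (hemi in c("left", "right")) {
    sgn <- if (hemi == "left") -1 else 1
    n_opt <- n_per_hemi + 1L
    ids <- character(n_opt)
    for (k in seq_len(n_opt)) {
      if (k %% 2 == 1) { src_n <- src_n + 1L; ids[k] <- paste0("S", src_n) }
      else             { det_n <- det_n + 1L; ids[k] <- paste0("D", det_n) }
    }
    x <- sgn * 20; y <- (seq_len(n_opt) - 1) * sep
    optodes <- rbind(optodes, data.frame(
      id = ids, x = x, y = y, hemisphere = hemi,
      is_source = seq_len(n_opt) %% 2 == 1))
    for (k in seq_len(n_per_hemi)) {
      ch_n <- ch_n + 1L
      s_first <- k %% 2 == 1
      channels <- rbind(channels, data.frame(
        channel = ch_n,
        name = sprintf("%s%02d", toupper(substr(hemi, 1, 1)), k),
        source = if (s_first) ids[k] else ids[k + 1],
        detector = if (s_first) ids[k + 1] else ids[k],
        sep_mm = sep, hemisphere = hemi,
        region = if (k <= ceiling(n_per_hemi / 2)) "anterior" else "posterior",
        x = x, y = (y[k] + y[k + 1]) / 2))
    }
  }
  list(sources = optodes[optodes$is_source, c("id", "x", "y", "hemisphere")],
       detectors = optodes[!optodes$is_source, c("id", "x", "y", "hemisphere")],
       channels = channels, clusters = list())
}

#' @export
print.fnirs_montage <- function(x, ...) {
  cat(sprintf(
    "fNIRS montage: %d sources, %d detectors, %d channels (%d left / %d right)\n",
    nrow(x$sources), nrow(x$detectors), nrow(x$channels),
    sum(x$channels$hemisphere == "left"),
    sum(x$channels$hemisphere == "right")))
  cat(sprintf("separation %.1f mm (cap_scale %.2f), wavelengths %d/%d nm, %d clusters\n",
              mean(x$channels$sep_mm), x$cap_scale,
              x$wavelengths[1], x$wavelengths[2], length(x$clusters)))
  invisible(x)
}

# all unordered channel pairs of a montage with hemisphere assignment:
# "left"/"right" when both channels share a hemisphere, "inter" otherwise
channel_pairs <- function(montage) {
  ch <- montage$channels
  idx <- utils::combn(ch$channel, 2)
  hemi_i <- ch$hemisphere[match(idx[1, ], ch$channel)]
  hemi_j <- ch$hemisphere[match(idx[2, ], ch$channel)]
  data.frame(ch_i = idx[1, ], ch_j = idx[2, ],
             hemisphere = ifelse(hemi_i == hemi_j, hemi_i, "inter"))
}
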