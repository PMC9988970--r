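#' Hemoglobin extinction coefficients
#'
#' Compiled molar extinction coefficients for oxy- and deoxyhemoglobin at the
#' instrument wavelengths, embedded as versioned constants (Gratzer/Kollias
#' compilation as distributed with the Homer ecosystem; table id
#' `"gratzer"`), in 1/(mM cm).
#'
#' @param wavelengths numeric wavelengths in nm (must be tabulated).
#' @param table table identifier, recorded in conversion provenance.
#' @return matrix with one row per wavelength, columns `HbO`, `HbR`.
#' @export
extinction_coefficients <- function(wavelengths = c(760, 850),
                                    table = "gratzer") {
  if (table != "gratzer") stop_invalid("unknown extinction table '%s'", table)
  tab <- matrix(c(
    690, 0.2763, 2.0520,
    730, 0.3900, 1.1022,
    760, 1.4866, 3.8437,
    780, 0.7360, 1.1050,
    808, 0.8160, 0.8304,
    830, 0.9744, 0.6931,
    850, 2.5264, 1.7986),
    ncol = 3, byrow = TRUE,
    dimnames = list(NULL, c("nm", "HbO", "HbR")))
  idx <- match(wavelengths, tab[, "nm"])
  if (anyNA(idx))
    stop_invalid("no tabulated extinction coefficients at %s nm",
                 paste(wavelengths[is.na(idx)], collapse = ", "))
  out <- tab[idx, c("HbO", "HbR"), drop = FALSE]
  rownames(out) <- paste0("wl", wavelengths)
  out
}

#' Parameters of the modified Beer-Lambert conversion
#'
#' The partial pathlength factors default to the age-appropriate values used
#' for the neonatal cap (0.1063 at 760 nm, 0.0845 at 850 nm). They act as
#' opaque multiplicative pathlength terms: their absolute scale rescales the
#' concentration units uniformly and cancels in any correlation-based
#' connectivity analysis.
#'
#' @param ppf numeric length-2, partial pathlength factor per wavelength
#'   (ordered as the montage wavelengths).
#' @param cap_scale additional channel-length scaling applied on top of the
#'   montage geometry (the montage separations already include the cap scale
#'   used at generation; this override supports re-scaling a nominal montage).
#' @param extinction_table table id passed to [extinction_coefficients()].
#' @return list of class `mbll_params`.
#' @export
mbll_params <- function(ppf = c(0.1063, 0.0845), cap_scale = 1,
                        extinction_table = "gratzer") {
  if (any(ppf <= 0)) stop_invalid("ppf must be positive")
  if (cap_scale <= 0) stop_invalid("cap_scale must be positive")
  structure(list(ppf = ppf, cap_scale = cap_scale,
                 extinction_table = extinction_table),
            class = "mbll_params")
}

#' Convert raw intensity to optical-density change
#'
#' `dOD(t) = -ln(I(t) / Ibar)` per channel and wavelength, with `Ibar` the
#' mean intensity over the (sub)sample. Non-positive samples are replaced by
#' the channel's minimum positive value and flagged; an all-non-positive
#' channel is marked invalid.
#'
#' @param raw a `raw_recording`.
#' @param window optional `sample_window` restricting the conversion to a
#'   contiguous subsample.
#' @return `od_series`: list with `od` (time x channel x wavelength),
#'   `ref` (mean intensity per channel/wavelength), `fs`, `montage`,
#'   `invalid_channels`, `n_replaced`.
#' @export
intensity_to_od <- function(raw, window = NULL) {
  x <- raw$intensity
  if (!is.null(window)) {
    idx <- (window$start + 1):window$end
    x <- x[idx, , , drop = FALSE]
  }
  d <- dim(x)
  invalid <- integer(0)
  n_replaced <- 0L
  for (ch in seq_len(d[2])) for (w in seq_len(d[3])) {
    v <- x[, ch, w]
    bad <- v <= 0
    if (all(bad)) { invalid <- union(invalid, ch); next }
    if (any(bad)) {
      v[bad] <- min(v[!bad])
      n_replaced <- n_replaced + sum(bad)
      x[, ch, w] <- v
    }
  }
  ref <- apply(x, c(2, 3), mean)
  od <- array(NA_real_, d, dimnames = dimnames(x))
  for (w in seq_len(d[3]))
    od[, , w] <- -log(sweep(x[, , w, drop = FALSE][, , 1], 2, ref[, w], `/`))
  structure(list(od = od, ref = ref, fs = raw$fs, montage = raw$montage,
                 invalid_channels = invalid, n_replaced = n_replaced),
            class = "od_series")
}

#' Modified Beer-Lambert conversion to hemoglobin concentration changes
#'
#' Solves, per channel and sample, the 2 x 2 linear system
#' `dOD(lambda) = (eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR) * d_cm * ppf(lambda)`
#' for the relative concentration changes, and forms `dHbT = dHbO + dHbR`
#' exactly. Channel distances come from the montage geometry (mm, converted
#' to cm) times `params$cap_scale`.
#'
#' @param od an `od_series` from [intensity_to_od()].
#' @param params an [mbll_params()].
#' @param montage montage override (defaults to the recording's montage).
#' @return `hemo_series`: `hbo`, `hbr`, `hbt` (time x channel), `fs`,
#'   and conversion provenance (ppf, extinction table, distances).
#' @export
od_to_hemoglobin <- function(od, params = mbll_params(), montage = NULL) {
  montage <- montage %||% od$montage
  d <- dim(od$od)
  if (d[3] != 2) stop_invalid("two wavelengths required")
  eps <- extinction_coefficients(montage$wavelengths, params$extinction_table)
  d_cm <- montage$channels$sep_mm / 10 * params$cap_scale
  n <- d[1]; nch <- d[2]
  hbo <- matrix(NA_real_, n, nch); hbr <- matrix(NA_real_, n, nch)
  colnames(hbo) <- colnames(hbr) <- montage$channels$name
  for (ch in seq_len(nch)) {
    M <- eps * (d_cm[ch] * params$ppf)  # rows scaled by d*ppf per wavelength
    detM <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
    if (abs(detM) < 1e-12)
      stop_invalid("singular extinction system for channel %d", ch)
    Minv <- matrix(c(M[2, 2], -M[2, 1], -M[1, 2], M[1, 1]), 2, 2) / detM
    sol <- od$od[, ch, ] %*% t(Minv)
    hbo[, ch] <- sol[, 1]
    hbr[, ch] <- sol[, 2]
  }
  if (length(od$invalid_channels)) {
    hbo[, od$invalid_channels] <- NA_real_
    hbr[, od$invalid_channels] <- NA_real_
  }
  structure(list(hbo = hbo, hbr = hbr, hbt = hbo + hbr, fs = od$fs,
                 provenance = list(ppf = params$ppf,
                                   extinction_table = params$extinction_table,
                                   distances_cm = d_cm,
                                   cap_scale = params$cap_scale)),
            class = "hemo_series")
}

#' @export
print.hemo_series <- function(x, ...) {
  cat(sprintf("hemoglobin series: %d samples x %d channels @ %g Hz (HbO/HbR/HbT)\n",
              nrow(x$hbt), ncol(x$hbt), x$fs))
  invisible(x)
}
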