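#' R-aligned averaged beat
#'
#' A `beat_template` holds the R-aligned average of the beats of a record:
#' a 12-lead by 1 s matrix (500 samples at 500 Hz), the sample index of the
#' R peak inside the window, the number of beats averaged, and a single
#' template-level fiducial set.
#'
#' @param samples lead x sample matrix (mV).
#' @param fs sampling rate (Hz).
#' @param r_index 1-based sample index of the R peak within the window.
#' @param n_beats_averaged number of beats that entered the average.
#' @param fiducials one-row tibble of fiducial indices (see
#'   [locate_fiducials()]), or `NULL`.
#' @return A `beat_template` object.
#' @export
beat_template <- function(samples, fs, r_index, n_beats_averaged = 1L,
                          fiducials = NULL) {
  samples <- as.matrix(samples)
  structure(list(samples = samples, fs = fs, r_index = as.integer(r_index),
                 n_beats_averaged = as.integer(n_beats_averaged),
                 lead_names = rownames(samples), fiducials = fiducials),
            class = "beat_template")
}

#' @export
print.beat_template <- function(x, ...) {
  cat(sprintf("<beat_template> %d leads x %d samples @ %g Hz, R at %d, %d beat(s) averaged\n",
              nrow(x$samples), ncol(x$samples), x$fs, x$r_index,
              x$n_beats_averaged))
  invisible(x)
}

fiducial_names <- function() {
  c("P_on", "P_peak", "P_off", "QRS_on", "Q", "R", "S", "J",
    "T_on", "T_peak", "T_off")
}

#' Detect R peaks
#'
#' A Pan-Tompkins-style detector: 5-15 Hz band-pass, derivative, squaring,
#' 150 ms moving-window integration and thresholding at a fraction of the
#' integrated-signal peak, with a 200 ms refractory period. Peak positions
#' are refined to the local extremum of the band-passed signal. Detection
#' runs on one lead, by default the lead with the largest peak-to-peak
#' amplitude (a proxy for the largest R).
#'
#' @param rec an [ecg_record()].
#' @param lead lead name to run detection on; `NULL` auto-selects.
#' @return Integer vector of strictly increasing R sample indices.
#' @export
detect_r_peaks <- function(rec, lead = NULL) {
  stopifnot(inherits(rec, "ecg_record"))
  fs <- rec$fs
  if (n_samples(rec) < 2 * fs) stop("need at least 2 s of signal")
  if (is.null(lead)) {
    ptp <- apply(rec$samples, 1, function(x) diff(range(x)))
    lead <- rec$lead_names[which.max(ptp)]
  }
  x <- rec$samples[lead, ]
  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xb <- as.numeric(signal::filtfilt(bf, x))
  feat <- c(0, diff(xb))^2
  w <- max(1L, as.integer(round(0.15 * fs)))
  integ <- as.numeric(stats::filter(feat, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- 0.25 * max(integ)
  refractory <- as.integer(round(0.2 * fs))
  above <- integ > thr
  peaks <- integer(0)
  i <- 1L
  n <- length(integ)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      seg <- i:j
      # refine on |band-passed| signal around the integrated burst
      lo <- max(1L, i - as.integer(0.05 * fs))
      hi <- min(n, j + as.integer(0.05 * fs))
      cand <- lo - 1L + which.max(abs(xb[lo:hi]))
      if (length(peaks) == 0 || cand - tail(peaks, 1) >= refractory) {
        peaks <- c(peaks, cand)
      }
      i <- j + 1L
    }
    i <- i + 1L
  }
  # snap to extremum of the raw lead within +/- 40 ms
  hw <- as.integer(round(0.04 * fs))
  peaks <- vapply(peaks, function(p) {
    lo <- max(1L, p - hw); hi <- min(n, p + hw)
    lo - 1L + which.max(abs(x[lo:hi]))
  }, integer(1))
  peaks <- unique(sort(peaks))
  if (length(peaks) < 2) stop("insufficient beats")
  peaks
}

# Locate fiducials on a single-beat window `x` with the R peak at `r`.
# Rule-based derivative/threshold searches in physiological windows;
# anything not found confidently is NA, never guessed.
delineate_beat <- function(x, r, fs) {
  n <- length(x)
  idx_at <- function(s) as.integer(round(s * fs))
  win <- function(lo_s, hi_s) {
    lo <- max(1L, r + idx_at(lo_s)); hi <- min(n, r + idx_at(hi_s))
    if (lo >= hi) NULL else lo:hi
  }
  r_amp <- abs(x[r])
  out <- stats::setNames(rep(NA_integer_, 11), fiducial_names())
  out["R"] <- r

  # Q and S: nearest opposite-sign extremum flanking R
  qw <- win(-0.06, -0.008)
  if (!is.null(qw)) out["Q"] <- qw[which.min(x[qw] * sign(x[r]))]
  sw <- win(0.008, 0.07)
  if (!is.null(sw)) out["S"] <- sw[which.min(x[sw] * sign(x[r]))]

  # QRS onset / J: where the slope dies away outside Q/S
  slope <- abs(c(0, diff(x)))
  max_slope <- max(slope[max(1, r - idx_at(0.06)):min(n, r + idx_at(0.06))])
  if (!is.na(out["Q"])) {
    k <- out["Q"]
    lo <- max(1L, r - idx_at(0.1))
    while (k > lo && slope[k] > 0.03 * max_slope) k <- k - 1L
    out["QRS_on"] <- k
  }
  if (!is.na(out["S"])) {
    k <- out["S"]
    hi <- min(n, r + idx_at(0.12))
    while (k < hi && slope[k] > 0.03 * max_slope) k <- k + 1L
    out["J"] <- k
  }

  # Deflection boundaries on top of a linear local baseline (slow drift
  # survives the wavelet stage, so a fixed level would bias the bounds):
  # peak = largest |deviation| from the line joining the window edges;
  # onset/offset = where the deviation falls below 5% of the peak.
  wave_bounds <- function(wseg, min_amp, max_amp = Inf) {
    nb <- min(5L, length(wseg) %/% 4L)
    bl <- stats::median(x[wseg[seq_len(nb)]])
    br <- stats::median(x[wseg[length(wseg) - seq_len(nb) + 1L]])
    base <- bl + (br - bl) * (seq_along(wseg) - 1) / (length(wseg) - 1)
    dev <- x[wseg] - base
    pk <- which.max(abs(dev))
    amp <- abs(dev[pk])
    if (amp < min_amp || amp >= max_amp) return(NULL)
    below <- abs(dev) <= 0.05 * amp
    k <- pk
    while (k > 1L && !below[k]) k <- k - 1L
    on <- k
    k <- pk
    while (k < length(wseg) && !below[k]) k <- k + 1L
    off <- k
    list(on = wseg[on], peak = wseg[pk], off = wseg[off])
  }

  # P wave: largest |deflection| 300-60 ms before R
  pw <- win(-0.3, -0.06)
  if (!is.null(pw) && !is.na(out["QRS_on"])) pw <- pw[pw <= out["QRS_on"]]
  if (!is.null(pw) && length(pw) > 20) {
    b <- wave_bounds(pw, min_amp = 0.015, max_amp = 0.6 * max(r_amp, 1e-9))
    if (!is.null(b)) {
      out["P_on"] <- b$on; out["P_peak"] <- b$peak; out["P_off"] <- b$off
    }
  }

  # T wave: largest |deflection| 120-450 ms after R
  tw <- win(0.12, 0.45)
  if (!is.null(tw) && !is.na(out["J"])) tw <- tw[tw >= out["J"]]
  if (!is.null(tw) && length(tw) > 20) {
    b <- wave_bounds(tw, min_amp = 0.03)
    if (!is.null(b)) {
      out["T_on"] <- b$on; out["T_peak"] <- b$peak; out["T_off"] <- b$off
    }
  }

  # enforce ordering: drop anything out of sequence
  ord <- fiducial_names()
  vals <- out[ord]
  last <- -Inf
  for (i in seq_along(vals)) {
    if (!is.na(vals[i])) {
      if (vals[i] < last) vals[i] <- NA_integer_ else last <- vals[i]
    }
  }
  tibble::as_tibble(as.list(vals))
}

#' Locate wave boundaries around each R peak
#'
#' Rule-based delineation of P, QRS and T fiducials in physiological search
#' windows around each supplied R peak (P searched 300-60 ms before R, T
#' 120-450 ms after). Points that cannot be located confidently are marked
#' missing. If the record carries externally supplied fiducial annotations
#' (labels matching the fiducial names), those are returned verbatim.
#'
#' @param rec an [ecg_record()].
#' @param r_peaks integer vector of R sample indices.
#' @param lead lead to delineate on; `NULL` auto-selects the limb lead with
#'   the largest R amplitude.
#' @return A tibble with one row per beat and one column per fiducial.
#' @export
locate_fiducials <- function(rec, r_peaks, lead = NULL) {
  stopifnot(inherits(rec, "ecg_record"), length(r_peaks) >= 1)
  ext <- rec$annotations
  if (nrow(ext) > 0 && any(ext$label %in% setdiff(fiducial_names(), "R"))) {
    # external delineation: pass through, grouped by nearest R
    return(external_fiducials(ext, r_peaks))
  }
  if (is.null(lead)) {
    limb <- intersect(limb_lead_names(), rec$lead_names)
    if (length(limb) == 0) limb <- rec$lead_names
    amp <- vapply(limb, function(l) max(abs(rec$samples[l, r_peaks])),
                  numeric(1))
    lead <- limb[which.max(amp)]
  }
  x <- rec$samples[lead, ]
  purrr::map_dfr(r_peaks, function(r) delineate_beat(x, r, rec$fs))
}

# Group externally supplied fiducial annotations by beat (nearest R peak).
external_fiducials <- function(ann, r_peaks) {
  rows <- lapply(r_peaks, function(r) {
    out <- stats::setNames(rep(NA_integer_, 11), fiducial_names())
    out["R"] <- as.integer(r)
    near <- ann[abs(ann$sample - r) <= 250, , drop = FALSE]
    for (i in seq_len(nrow(near))) {
      lb <- near$label[i]
      if (lb %in% fiducial_names()) out[lb] <- as.integer(near$sample[i])
    }
    tibble::as_tibble(as.list(out))
  })
  dplyr::bind_rows(rows)
}

#' Build the R-aligned averaged beat
#'
#' Averages all beats whose full window (0.4 s before to 0.6 s after the R
#' peak by default) fits inside the record; clipped beats are excluded.
#' Template-level fiducials are then located on the averaged beat.
#'
#' @param rec an [ecg_record()].
#' @param r_peaks integer vector of R sample indices.
#' @param pre_s,post_s window extent before/after R (s); defaults give the
#'   1 s window.
#' @param delineate locate fiducials on the template (default `TRUE`).
#' @return A [beat_template()].
#' @export
average_beat <- function(rec, r_peaks, pre_s = 0.4, post_s = 0.6,
                         delineate = TRUE) {
  stopifnot(inherits(rec, "ecg_record"))
  fs <- rec$fs
  pre <- as.integer(round(pre_s * fs))
  post <- as.integer(round(post_s * fs))
  n <- n_samples(rec)
  ok <- r_peaks[r_peaks - pre >= 1 & r_peaks + post - 1 <= n]
  if (length(ok) < 1) stop("insufficient beats: no complete window fits")
  acc <- matrix(0, nrow(rec$samples), pre + post)
  for (r in ok) {
    acc <- acc + rec$samples[, (r - pre):(r + post - 1L), drop = FALSE]
  }
  avg <- acc / length(ok)
  rownames(avg) <- rec$lead_names
  r_index <- pre + 1L
  fid <- NULL
  if (delineate) {
    tpl_rec <- ecg_record(avg, fs = fs, lead_names = rec$lead_names)
    fid <- locate_fiducials(tpl_rec, r_index)
  }
  beat_template(avg, fs = fs, r_index = r_index,
                n_beats_averaged = length(ok), fiducials = fid)
}
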