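#' Resample an ECG record
#'
#' Polyphase resampling of every lead to a target rate. Annotation indices
#' are rescaled by the rate ratio.
#'
#' @param rec an [ecg_record()].
#' @param target_fs target sampling rate (Hz).
#' @return A resampled [ecg_record()].
#' @export
resample_record <- function(rec, target_fs = 500) {
  stopifnot(inherits(rec, "ecg_record"))
  if (target_fs <= 0) stop("target_fs must be > 0")
  if (target_fs == rec$fs) return(rec)
  ratio <- target_fs / rec$fs
  frac <- MASS::fractions(ratio)
  pq <- as.integer(strsplit(attr(frac, "fracs"), "/")[[1]])
  if (length(pq) == 1L) pq <- c(pq, 1L)
  out <- t(apply(rec$samples, 1, function(x) {
    as.numeric(signal::resample(x, pq[1], pq[2]))
  }))
  ann <- rec$annotations
  if (nrow(ann) > 0) {
    ann$sample <- as.integer(round((ann$sample - 1L) * ratio)) + 1L
  }
  res <- ecg_record(out, fs = target_fs, lead_names = rec$lead_names,
                    annotations = ann)
  res$p_truth <- NULL
  res$beat_spec <- rec$beat_spec
  res
}

#' Remove baseline wander by wavelet decomposition
#'
#' Per lead: 8-level discrete wavelet decomposition with the Symlet-10
#' wavelet, the level-8 approximation coefficients set to zero, and the
#' signal reconstructed by the inverse transform. At 500 Hz the removed
#' approximation band is roughly 0-1 Hz, which captures DC offset and
#' respiratory-scale wander while leaving the P-wave band untouched.
#'
#' @param rec an [ecg_record()].
#' @param level decomposition level (default 8).
#' @return An [ecg_record()] with the low-frequency trend removed.
#' @export
remove_baseline_wavelet <- function(rec, level = 8L) {
  stopifnot(inherits(rec, "ecg_record"))
  out <- t(apply(rec$samples, 1, dwt_remove_approx, level = level))
  res <- ecg_record(out, fs = rec$fs, lead_names = rec$lead_names,
                    annotations = rec$annotations)
  res$p_truth <- rec$p_truth
  res$beat_spec <- rec$beat_spec
  res
}

#' Fixed-cutoff noise filter
#'
#' Zero-phase (forward-backward) 4th-order Butterworth filter applied per
#' lead. The default is a 32 Hz low-pass, which removes broadband and
#' muscle noise while passing the whole P-wave band (P energy lies below
#' ~15 Hz); `mode = "highpass"` is available for completeness.
#'
#' @param rec an [ecg_record()].
#' @param cutoff cutoff frequency (Hz), must be below Nyquist.
#' @param mode `"lowpass"` (default) or `"highpass"`.
#' @param order design order of the forward pass (default 4).
#' @return A filtered [ecg_record()].
#' @export
noise_filter <- function(rec, cutoff = 32, mode = c("lowpass", "highpass"),
                         order = 4) {
  stopifnot(inherits(rec, "ecg_record"))
  mode <- match.arg(mode)
  if (cutoff >= rec$fs / 2) stop("cutoff must be below Nyquist")
  bf <- signal::butter(order, cutoff / (rec$fs / 2),
                       type = if (mode == "lowpass") "low" else "high")
  out <- t(apply(rec$samples, 1, function(x) {
    as.numeric(signal::filtfilt(bf, x))
  }))
  res <- ecg_record(out, fs = rec$fs, lead_names = rec$lead_names,
                    annotations = rec$annotations)
  res$p_truth <- rec$p_truth
  res$beat_spec <- rec$beat_spec
  res
}

#' Trim edge artefacts
#'
#' Drops the first and last `trim_s` seconds of the record. Annotations in
#' the trimmed zones are dropped; the rest are re-indexed.
#'
#' @param rec an [ecg_record()].
#' @param trim_s seconds to remove at each edge (default 0.5).
#' @return A shortened [ecg_record()].
#' @export
trim_edges <- function(rec, trim_s = 0.5) {
  stopifnot(inherits(rec, "ecg_record"))
  n <- n_samples(rec)
  k <- as.integer(round(trim_s * rec$fs))
  if (n <= 2L * k) stop("record not longer than 2 * trim_s")
  keep <- (k + 1L):(n - k)
  ann <- rec$annotations
  if (nrow(ann) > 0) {
    ann <- dplyr::filter(ann, .data$sample > k, .data$sample <= n - k)
    ann$sample <- ann$sample - k
  }
  res <- ecg_record(rec$samples[, keep, drop = FALSE], fs = rec$fs,
                    lead_names = rec$lead_names, annotations = ann)
  if (!is.null(rec$p_truth)) res$p_truth <- rec$p_truth[, keep, drop = FALSE]
  res$beat_spec <- rec$beat_spec
  res
}

#' Full preprocessing chain
#'
#' Resampling to 500 Hz, wavelet baseline removal, 32 Hz zero-phase noise
#' filtering and 0.5 s edge trimming, in that order.
#'
#' @param rec an [ecg_record()].
#' @param target_fs resampling target (Hz).
#' @param cutoff,filter_mode noise-filter parameters, see [noise_filter()].
#' @param trim_s edge trim (s); set to 0 to disable.
#' @return A preprocessed [ecg_record()].
#' @export
preprocess_record <- function(rec, target_fs = 500, cutoff = 32,
                              filter_mode = "lowpass", trim_s = 0.5) {
  rec <- resample_record(rec, target_fs)
  rec <- remove_baseline_wavelet(rec)
  rec <- noise_filter(rec, cutoff = cutoff, mode = filter_mode)
  if (trim_s > 0) rec <- trim_edges(rec, trim_s)
  rec
}
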