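#' Dipole beat specification
#'
#' The synthetic generator models one heartbeat as five Gaussian dipole
#' components (P, Q, R, S, T). Each wave has a centre time relative to the
#' R peak (s), a Gaussian width sigma (s), an amplitude (mV) and a unit 3-D
#' dipole direction; the dipole is projected onto the 12 standard leads
#' through a fixed lead matrix (see [dower_matrix()]). This Gaussian-bump
#' construction gives a closed-form P-wave ground truth against which any
#' extraction method can be scored.
#'
#' The nominal wave duration used for ground-truth fiducials is 5 sigma
#' (the support that holds ~99% of the Gaussian's area), so the default
#' P width of 0.02 s corresponds to a 100 ms P duration.
#'
#' @param heart_rate heart rate in beats per minute.
#' @param fs sampling rate (Hz).
#' @param waves named list of wave components `P`, `Q`, `R`, `S`, `T`, each a
#'   list with `center` (s, relative to R), `width` (s, Gaussian sigma),
#'   `amplitude` (mV) and `direction` (unit 3-vector).
#' @param lead_matrix 8 x 3 lead-vector matrix for leads I, II, V1-V6.
#'
#' @return A `dipole_beat_spec` object.
#' @export
dipole_beat_spec <- function(heart_rate = 60, fs = 500,
                             waves = default_waves(),
                             lead_matrix = dower_matrix()) {
  stopifnot(heart_rate > 0, fs > 0,
            all(c("P", "Q", "R", "S", "T") %in% names(waves)),
            nrow(lead_matrix) == 8, ncol(lead_matrix) == 3)
  for (nm in names(waves)) {
    w <- waves[[nm]]
    if (w$width <= 0) stop("wave '", nm, "': width must be > 0")
    nrm <- sqrt(sum(w$direction^2))
    if (w$amplitude != 0 && abs(nrm - 1) > 1e-6) {
      stop("wave '", nm, "': direction must be a unit vector")
    }
  }
  if (waves$P$center >= waves$Q$center) {
    stop("P centre must precede Q centre")
  }
  structure(list(heart_rate = heart_rate, fs = fs, waves = waves,
                 lead_matrix = lead_matrix),
            class = "dipole_beat_spec")
}

#' @rdname dipole_beat_spec
#' @export
default_waves <- function() {
  unit <- function(v) v / sqrt(sum(v^2))
  d_r <- unit(c(0.65, 0.70, -0.30))
  list(
    P = list(center = -0.160, width = 0.020, amplitude = 0.22,
             direction = unit(c(0.55, 0.80, -0.24))),
    Q = list(center = -0.028, width = 0.008, amplitude = 0.12,
             direction = -d_r),
    R = list(center = 0.000, width = 0.013, amplitude = 1.20,
             direction = d_r),
    S = list(center = 0.028, width = 0.009, amplitude = 0.35,
             direction = unit(c(-0.40, -0.60, 0.69))),
    T = list(center = 0.300, width = 0.055, amplitude = 0.45,
             direction = unit(c(0.60, 0.60, -0.53)))
  )
}

# Gaussian bump evaluated on a time grid.
gauss_bump <- function(t, center, width) exp(-((t - center)^2) / (2 * width^2))

# 12 x n contribution of a single wave on time grid `t` (s, relative to R).
wave_contribution <- function(spec, wave, t) {
  w <- spec$waves[[wave]]
  lead12 <- expand_to_12_leads(spec$lead_matrix %*% cbind(w$direction))
  (lead12 * w$amplitude) %*% rbind(gauss_bump(t, w$center, w$width))
}

# Ground-truth fiducial samples for a template window with R at `r_index`.
# Wave boundaries at center +/- 2.5 sigma (the 5-sigma nominal duration).
truth_fiducials <- function(spec, r_index, fs) {
  idx <- function(t_s) as.integer(round(t_s * fs)) + r_index
  w <- spec$waves
  has_p <- w$P$amplitude != 0
  has_t <- w$T$amplitude != 0
  tibble::tibble(
    P_on   = if (has_p) idx(w$P$center - 2.5 * w$P$width) else NA_integer_,
    P_peak = if (has_p) idx(w$P$center) else NA_integer_,
    P_off  = if (has_p) idx(w$P$center + 2.5 * w$P$width) else NA_integer_,
    QRS_on = idx(w$Q$center - 2.5 * w$Q$width),
    Q      = idx(w$Q$center),
    R      = r_index,
    S      = idx(w$S$center),
    J      = idx(w$S$center + 2.5 * w$S$width),
    T_on   = if (has_t) idx(w$T$center - 2.5 * w$T$width) else NA_integer_,
    T_peak = if (has_t) idx(w$T$center) else NA_integer_,
    T_off  = if (has_t) idx(w$T$center + 2.5 * w$T$width) else NA_integer_
  )
}

#' Generate a single noiseless beat with P-wave ground truth
#'
#' Evaluates the dipole model on a 1 s window (0.4 s before the R peak to
#' 0.6 s after) and returns both the full 12-lead beat and the exact P-only
#' contribution.
#'
#' @param spec a [dipole_beat_spec()].
#' @param pre_s,post_s window extent before/after the R peak (s); defaults
#'   give the 1 s window used throughout.
#' @return A list with `template` (a [beat_template()]) and `p_truth`
#'   (12 x n matrix, mV).
#' @export
generate_beat <- function(spec, pre_s = 0.4, post_s = 0.6) {
  stopifnot(inherits(spec, "dipole_beat_spec"))
  fs <- spec$fs
  n <- as.integer(round((pre_s + post_s) * fs))
  r_index <- as.integer(round(pre_s * fs)) + 1L
  t <- (seq_len(n) - r_index) / fs
  contrib <- lapply(c("P", "Q", "R", "S", "T"),
                    function(wv) wave_contribution(spec, wv, t))
  beat <- Reduce(`+`, contrib)
  p_truth <- contrib[[1]]
  rownames(beat) <- rownames(p_truth) <- lead_names_12()
  tpl <- beat_template(beat, fs = fs, r_index = r_index,
                       n_beats_averaged = 1L,
                       fiducials = truth_fiducials(spec, r_index, fs))
  list(template = tpl, p_truth = p_truth)
}

#' Generate a synthetic 12-lead ECG record
#'
#' Concatenates identical model beats at the specified heart rate and adds
#' Gaussian broadband noise and sinusoidal baseline wander. Noise and wander
#' are generated on the 8 electrically independent leads (I, II, V1-V6) and
#' expanded to 12, so the derived-lead identities (III = II - I, ...) hold
#' exactly on every record. R-peak ground truth is attached as annotations,
#' and the noiseless P-only contribution is stored in `$p_truth`.
#'
#' @param spec a [dipole_beat_spec()].
#' @param duration_s record length (s); must exceed one beat interval.
#' @param noise_sd broadband noise SD (mV), >= 0.
#' @param wander_amplitude baseline wander amplitude (mV).
#' @param wander_freq baseline wander frequency (Hz), default 0.25.
#' @param seed integer seed; fully determines the record.
#' @return An [ecg_record()] with extra fields `p_truth` and `beat_spec`.
#' @export
generate_record <- function(spec, duration_s = 10, noise_sd = 0,
                            wander_amplitude = 0, wander_freq = 0.25,
                            seed = NULL) {
  stopifnot(inherits(spec, "dipole_beat_spec"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  rr <- 60 / spec$heart_rate
  if (duration_s <= rr) stop("duration_s must exceed one beat interval")
  fs <- spec$fs
  n <- as.integer(round(duration_s * fs))
  t <- (seq_len(n) - 1) / fs
  pre_s <- 0.4
  r_times <- seq(pre_s, duration_s - (1 - pre_s), by = rr)
  samples <- matrix(0, 12, n, dimnames = list(lead_names_12(), NULL))
  p_truth <- samples
  for (wv in c("P", "Q", "R", "S", "T")) {
    w <- spec$waves[[wv]]
    if (w$amplitude == 0) next
    g <- numeric(n)
    for (tr in r_times) g <- g + gauss_bump(t, tr + w$center, w$width)
    lead12 <- expand_to_12_leads(spec$lead_matrix %*% cbind(w$direction))
    add <- (lead12 * w$amplitude) %*% rbind(g)
    samples <- samples + add
    if (wv == "P") p_truth <- p_truth + add
  }
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd > 0 || wander_amplitude > 0) {
    noise8 <- matrix(rnorm(8 * n, sd = noise_sd), 8, n)
    phases <- runif(8, 0, 2 * pi)
    if (wander_amplitude > 0) {
      for (i in 1:8) {
        noise8[i, ] <- noise8[i, ] +
          wander_amplitude * sin(2 * pi * wander_freq * t + phases[i])
      }
    }
    samples <- samples + expand_to_12_leads(noise8)
  }
  rec <- ecg_record(samples, fs = fs,
                    annotations = tibble::tibble(
                      sample = as.integer(round(r_times * fs)) + 1L,
                      label = "R"))
  rec$p_truth <- p_truth
  rec$beat_spec <- spec
  rec
}

#' Cohort specification for two-group simulations
#'
#' Defines a control group and a case group whose P waves carry a known
#' perturbation: prolongation (`dP_duration_ms`, applied as a widening of
#' the P Gaussian so the 5-sigma nominal duration grows by the stated
#' amount), a rotation of the atrial dipole axis about the anteroposterior
#' axis (`p_axis_rotation_deg`), and/or an amplitude change
#' (`dP_amplitude_mV`). The seed fully determines the cohort.
#'
#' @param n_control,n_case group sizes (>= 1).
#' @param dP_duration_ms P-duration prolongation applied to cases (ms).
#' @param p_axis_rotation_deg atrial-axis rotation applied to cases (deg).
#' @param dP_amplitude_mV P-amplitude change applied to cases (mV).
#' @param noise_sd broadband noise SD (mV).
#' @param wander_amplitude,wander_freq baseline wander parameters (mV, Hz).
#' @param seed integer seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_control, n_case, dP_duration_ms = 0,
                        p_axis_rotation_deg = 0, dP_amplitude_mV = 0,
                        noise_sd = 0.03, wander_amplitude = 0.05,
                        wander_freq = 0.25, seed = 1) {
  stopifnot(n_control >= 1, n_case >= 1, noise_sd >= 0)
  structure(list(n_control = n_control, n_case = n_case,
                 dP_duration_ms = dP_duration_ms,
                 p_axis_rotation_deg = p_axis_rotation_deg,
                 dP_amplitude_mV = dP_amplitude_mV,
                 noise_sd = noise_sd, wander_amplitude = wander_amplitude,
                 wander_freq = wander_freq, seed = seed),
            class = "cohort_spec")
}

# Apply the case perturbation to a beat spec.
perturb_beat_spec <- function(spec, cohort) {
  w <- spec$waves
  w$P$width <- w$P$width + cohort$dP_duration_ms / 1000 / 5
  w$P$amplitude <- w$P$amplitude + cohort$dP_amplitude_mV
  w$P$direction <- rotate_z(w$P$direction, cohort$p_axis_rotation_deg)
  dipole_beat_spec(heart_rate = spec$heart_rate, fs = spec$fs, waves = w,
                   lead_matrix = spec$lead_matrix)
}

#' Generate a labelled two-group cohort of synthetic records
#'
#' Controls use `beat` unchanged; cases use `beat` with the cohort's P-wave
#' perturbations applied. Per-record seeds are drawn from the cohort seed,
#' so the whole cohort is reproducible.
#'
#' @param cohort a [cohort_spec()].
#' @param beat a [dipole_beat_spec()] for the control group.
#' @param duration_s record length (s).
#' @return A tibble with columns `id`, `label` (0 control / 1 case) and a
#'   list-column `record` of [ecg_record()] objects.
#' @export
generate_cohort <- function(cohort, beat = dipole_beat_spec(),
                            duration_s = 10) {
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(beat, "dipole_beat_spec"))
  n <- cohort$n_control + cohort$n_case
  set.seed(cohort$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  case_beat <- perturb_beat_spec(beat, cohort)
  labels <- c(rep(0L, cohort$n_control), rep(1L, cohort$n_case))
  records <- purrr::map2(labels, seeds, function(lab, sd_i) {
    generate_record(if (lab == 1L) case_beat else beat,
                    duration_s = duration_s,
                    noise_sd = cohort$noise_sd,
                    wander_amplitude = cohort$wander_amplitude,
                    wander_freq = cohort$wander_freq,
                    seed = sd_i)
  })
  tibble::tibble(id = sprintf("rec%03d", seq_len(n)), label = labels,
                 record = records)
}
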