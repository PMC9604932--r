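test_that("reference leads are the largest-R limb and chest leads", {
  spec <- dipole_beat_spec()
  tpl <- generate_beat(spec)$template
  leads <- select_reference_leads(tpl)
  r <- tpl$r_index
  limb_amp <- abs(tpl$samples[limb_lead_names <- c("I", "II", "III", "aVR", "aVL", "aVF"), r])
  expect_equal(unname(leads["limb"]), names(which.max(limb_amp)))
  # tie broken by order
  m <- matrix(0, 12, 500, dimnames = list(lead_names_12(), NULL))
  m[c("I", "II"), 201] <- 1
  m["V4", 201] <- 0.5
  tpl2 <- beat_template(m, 500, 201L,
                        fiducials = tibble::tibble(R = 201L))
  expect_equal(unname(select_reference_leads(tpl2)), c("I", "V4"))
  flat <- beat_template(matrix(0, 12, 500,
                               dimnames = list(lead_names_12(), NULL)),
                        500, 201L)
  expect_error(select_reference_leads(flat), "flat")
})

test_that("morphology features compute durations, amplitudes and ST voltage", {
  spec <- dipole_beat_spec()
  rec <- generate_record(spec, 10, seed = 1)
  pp <- preprocess_record(rec)
  tpl <- average_beat(pp, detect_r_peaks(pp))
  mf <- morphology_features(tpl)
  expect_equal(mf$P_dur, 100, tolerance = 0.2)
  expect_gt(mf$L_AMP_R, 0.5)
  expect_gt(mf$L_AMP_P, 0.05)
  expect_lt(mf$L_AMP_Q, 0)   # opposite polarity to R
  expect_gt(mf$L_T_PR, 80)   # physiologic PR range for this geometry
  expect_lt(mf$L_T_PR, 250)
  expect_gt(mf$L_T_QT, 250)
  expect_false(any(is.na(unlist(mf[paste0("C_AMP_", c("P", "R", "T"))]))))
})

test_that("interval arithmetic follows the fiducial definitions", {
  x <- rep(0, 500)
  x[141:180] <- 0.1  # flat 0.1 mV between J and T_on
  tpl <- beat_template(matrix(rep(x, each = 12), 12, 500,
                              dimnames = list(lead_names_12(), NULL)),
                       500, 120L)
  fid <- tibble::tibble(P_on = 50L, P_peak = 75L, P_off = 110L,
                        QRS_on = 112L, Q = 115L, R = 120L, S = 125L,
                        J = 141L, T_on = 180L, T_peak = 200L, T_off = 220L)
  out <- pwaveiso:::lead_morphology(x, fid, 500, "L")
  expect_equal(out$L_T_PR, (112 - 50) * 2)
  expect_equal(out$L_T_QRS, (141 - 112) * 2)
  expect_equal(out$L_T_QT, (220 - 112) * 2)
  expect_equal(out$L_STvol_R, 0.1, tolerance = 0.01)
})

test_that("P-loop PCA satisfies the eigen identities", {
  set.seed(5)
  # rank-1: all leads scalar multiples of one waveform
  w <- sin(2 * pi * 5 * (0:499) / 500)
  X1 <- outer(w, runif(8, -1, 1))
  p1 <- pca_ploop(X1)
  expect_equal(unname(p1$weights["PC1w"]), 1)
  expect_equal(unname(p1$weights["PC2w"]), 0, tolerance = 1e-12)
  # trace identity and descending weights on general data
  X <- matrix(rnorm(500 * 8), 500, 8)
  p <- pca_ploop(X)
  expect_equal(sum(p$eigenvalues), sum(diag(crossprod(X))))
  expect_true(all(diff(p$eigenvalues) <= 1e-9))
  expect_true(p$weights[1] >= p$weights[2] && p$weights[2] >= p$weights[3])
  # orthonormal loadings, sign convention
  expect_equal(crossprod(p$loadings), diag(3), tolerance = 1e-12)
  for (j in 1:3) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
  expect_error(pca_ploop(matrix(0, 500, 8)), "zero")
})

test_that("a 3-D dipole source gives loadings spanning the lead space", {
  set.seed(6)
  L <- matrix(rnorm(24), 8, 3)          # lead matrix
  S <- matrix(rnorm(500 * 3), 500, 3)   # dipole time courses
  X <- S %*% t(L)
  p <- pca_ploop(X)
  ang <- oracle_principal_angles(p$loadings, L)
  expect_lt(max(ang), 1e-6)
})

test_that("ellipse loop descriptors match analytic area and the raster oracle", {
  th <- seq(0, 2 * pi, length.out = 400)[-400]
  ld <- loop_descriptors(3 * cos(th), 1.5 * sin(th))
  expect_equal(ld$LoopArea, 100 * pi / 4, tolerance = 0.03)
  expect_equal(ld$LoopLength,
               oracle_loop_length(3 * cos(th), 1.5 * sin(th)))
  expect_equal(ld$LAratio, ld$LoopLength / ld$LoopArea)
})

test_that("loop length matches the independent supercover oracle", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(50:200, 1)
    px <- cumsum(rnorm(n)); py <- cumsum(rnorm(n))
    ld <- loop_descriptors(px, py)
    expect_equal(ld$LoopLength, oracle_loop_length(px, py),
                 info = paste("seed", s))
  }
})

test_that("degenerate trajectories give missing loop descriptors", {
  ld <- loop_descriptors(c(1, 2, 3, 2, 1), rep(0, 5))
  expect_true(is.na(ld$LoopArea))
})

test_that("loop descriptors are translation and scale invariant", {
  th <- seq(0, 2 * pi, length.out = 200)[-200]
  px <- cos(th) + 0.3 * cos(3 * th); py <- sin(th)
  a <- loop_descriptors(px, py)
  b <- loop_descriptors(px + 100, py - 40)
  expect_equal(a$LoopArea, b$LoopArea)
  expect_equal(a$LoopLength, b$LoopLength)
  cc <- loop_descriptors(px * 7.3, py * 7.3)
  expect_equal(a$LoopArea, cc$LoopArea)
})

test_that("inter-lead angles follow vector geometry, 28 entries", {
  L <- matrix(0, 8, 3, dimnames = list(lead_names_8(), NULL))
  L["I", ] <- c(1, 0, 0)
  L["II", ] <- c(0, 1, 0)
  L["V1", ] <- c(1, 0, 0)
  L["V2", ] <- c(-1, 0, 0)
  ang <- interlead_angles(L)
  expect_equal(ncol(ang), 28)
  expect_equal(names(ang)[1], "I_II")
  expect_equal(ang$I_II, 90)
  expect_equal(ang$I_V1, 0)
  expect_equal(ang$I_V2, 180)
  expect_true(is.na(ang$V3_V4))  # zero-norm rows
})

test_that("angles are invariant under global 3-D rotations", {
  set.seed(8)
  L <- matrix(rnorm(24), 8, 3, dimnames = list(lead_names_8(), NULL))
  a0 <- unlist(interlead_angles(L))
  for (i in 1:5) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    a1 <- unlist(interlead_angles(L %*% Q))
    expect_lt(max(abs(a1 - a0)), 1e-6)
  }
})

test_that("band-power ratio splits the spectrum at 20 Hz", {
  t <- (0:499) / 500
  expect_lt(band_power_ratio(sin(2 * pi * 10 * t)), 0.01)
  both <- sin(2 * pi * 10 * t) + sin(2 * pi * 30 * t)
  expect_equal(band_power_ratio(both), 1, tolerance = 0.05)
  expect_true(is.na(band_power_ratio(rep(0, 500))))
})

test_that("white-noise band-power ratio matches the flat-spectrum bin count", {
  set.seed(9)
  r <- replicate(300, band_power_ratio(rnorm(500)))
  # numerator 20-50 Hz inclusive = 31 bins; denominator 1-19 Hz = 19 bins
  expect_equal(mean(r), 31 / 19, tolerance = 0.1)
})

test_that("the assembled vector has exactly the 56 published names", {
  nm <- feature_names_56()
  expect_length(nm, 56)
  expect_length(unique(nm), 56)
  expect_length(pwaveiso:::angle_pair_names(), 28)
  fx <- assemble_features()
  expect_identical(names(fx), nm)
  expect_true(all(is.na(unlist(fx))))
})

test_that("a complete synthetic record fills all 56 features", {
  spec <- dipole_beat_spec()
  rec <- generate_record(spec, 10, noise_sd = 0.02,
                         wander_amplitude = 0.05, seed = 12)
  pp <- preprocess_record(rec)
  rp <- detect_r_peaks(pp)
  tpl <- average_beat(pp, rp)
  iso <- isolate_p_wave(tpl)
  fx <- extract_features(tpl, iso$p_wave)
  expect_identical(names(fx), feature_names_56())
  expect_equal(sum(is.na(unlist(fx))), 0)
})

test_that("missing P on the isolation propagates to the loop block", {
  spec <- dipole_beat_spec()
  tpl <- generate_beat(spec)$template
  pw <- matrix(NA_real_, 12, 500, dimnames = list(lead_names_12(), NULL))
  fx <- extract_features(tpl, pw)
  expect_true(is.na(fx$PC1w))
  expect_true(is.na(fx$I_II))
  expect_true(is.na(fx$LoopArea))
  expect_false(is.na(fx$L_AMP_R))  # morphology still present
})

test_that("rotating the atrial dipole moves an inter-lead angle monotonically", {
  base <- dipole_beat_spec()
  angs <- vapply(c(0, 10, 20, 30), function(th) {
    spec <- pwaveiso:::perturb_beat_spec(
      base, cohort_spec(1, 1, p_axis_rotation_deg = th))
    rec <- generate_record(spec, 10)
    pp <- preprocess_record(rec)
    tpl <- average_beat(pp, detect_r_peaks(pp))
    iso <- isolate_p_wave(tpl)
    p <- pca_ploop(t(iso$p_wave[lead_names_8(), ]))
    unlist(interlead_angles(p$loadings))
  }, numeric(28))
  monotone <- apply(angs, 1, function(a) {
    all(diff(a) > 0) || all(diff(a) < 0)
  })
  expect_true(any(monotone))
})
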