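test_that("spline envelopes reproduce lines and bridge two knots linearly", {
  kn <- data.frame(index = c(10, 50, 120, 300), value = 0.5 + 0.01 * c(10, 50, 120, 300))
  env <- spline_envelope(300, kn)
  expect_equal(env, 0.5 + 0.01 * (1:300), tolerance = 1e-9)
  kn2 <- data.frame(index = c(100, 200), value = c(1, 3))
  env2 <- spline_envelope(300, kn2)
  expect_equal(env2[100], 1)
  expect_equal(env2[200], 3)
  expect_equal(diff(env2), rep(0.02, 299), tolerance = 1e-12)
  expect_error(spline_envelope(100, data.frame(index = 5, value = 1)),
               "2 knots")
})

test_that("envelope through sine extrema tracks the +1 line", {
  t <- (0:999) / 500
  x <- sin(2 * pi * 5 * t)
  mx <- which(diff(sign(diff(x))) == -2) + 1
  env <- spline_envelope(1000, data.frame(index = mx, value = x[mx]))
  interior <- min(mx):max(mx)
  expect_lt(max(abs(env[interior] - 1)), 0.01)
})

test_that("min-arclength pulls a spiked knot back to a flat envelope", {
  idx <- c(10, 30, 50, 70, 90)
  val <- c(0.2, 0.2, 1.5, 0.2, 0.2)  # spike at 50
  res <- min_arclength_knot(100, data.frame(index = idx, value = val), 50)
  expect_equal(res$value, 0.2, tolerance = 0.01)
  expect_false(res$boundary)
})

test_that("the replacement never increases the envelope arclength", {
  arc <- function(knots, span) {
    env <- spline_envelope(200, knots)
    sum(sqrt(1 + (diff(env[span]) / 0.01)^2))
  }
  for (s in 1:10) {
    set.seed(s)
    idx <- sort(sample(5:195, 7))
    val <- rnorm(7, 0, 0.2)
    kn <- data.frame(index = idx, value = val)
    j <- 4
    res <- min_arclength_knot(200, kn, idx[j])
    kn2 <- kn; kn2$value[j] <- res$value
    span <- idx[j - 1]:idx[j + 1]
    expect_lte(arc(kn2, span), arc(kn, span) + 1e-6)
  }
})

test_that("a spiked sine crest is restored near the true sine value", {
  # upper-envelope knots: the sine maxima, with the middle crest spiked
  t <- (0:499) / 500
  x <- 0.3 * sin(2 * pi * 6 * t)
  mx <- which(diff(sign(diff(x))) == -2) + 1
  crest <- mx[3]
  xs <- x
  xs[crest] <- xs[crest] + 2  # 2 mV spike on the crest
  kn <- data.frame(index = mx, value = xs[mx])
  res <- min_arclength_knot(500, kn, crest)
  # brute-force grid oracle with the same integrand over the flanking span
  j <- 3
  span <- mx[j - 1]:mx[j + 1]
  grid <- seq(min(kn$value) - 0.1, max(kn$value) + 0.1, length.out = 4000)
  arcs <- vapply(grid, function(v) {
    k2 <- kn; k2$value[j] <- v
    env <- spline_envelope(500, k2)
    sum(sqrt(1 + (diff(env[span]) / 0.01)^2))
  }, numeric(1))
  v_star <- grid[which.min(arcs)]
  expect_equal(res$value, v_star, tolerance = 0.02)
  expect_lt(abs(res$value - x[crest]), 0.05 * 2)
})

test_that("a boundary spike knot falls back to its neighbour", {
  kn <- data.frame(index = c(10, 40, 80), value = c(2, 0.1, 0.1))
  res <- min_arclength_knot(100, kn, 10)
  expect_true(res$boundary)
  expect_equal(res$value, 0.1)
})

test_that("sifting conserves the signal and extracts a pure fast tone", {
  t <- (0:499) / 500
  x <- sin(2 * pi * 30 * t)
  s <- sift_ma(x)
  expect_equal(s$detail + s$local_mean, x, tolerance = 1e-12)
  expect_lt(sqrt(mean(s$local_mean^2)) / sqrt(mean(x^2)), 0.02)
})

test_that("a narrow spike on a slow sine stays out of the masked local mean", {
  # a bare 2 Hz sine is itself the first sifting component, so the slow
  # wave is recovered in the residual through the masked route: the mask
  # supplies the fast extrema whose envelopes hug the slow wave, and the
  # min-arclength criterion keeps the spike out of the mean
  t <- (0:499) / 500
  slow <- 0.5 * sin(2 * pi * 2 * t)
  spike <- pmax(0, 1 - abs((1:500) - 250) / 8)  # narrow triangle, 1 mV
  x <- slow + spike
  d <- maupemd_extract(x, mask_spec(30, 0.1, 4), spikes = 250L)
  expect_gt(cor(d$residual, slow), 0.99)
  # most of the spike's peak survives in the separated component
  expect_gt(d$separated[250], 0.7)
})

test_that("too few extrema returns the signal as mean, flagged", {
  s <- sift_ma(seq(0, 1, length.out = 100))
  expect_true(s$flagged)
  expect_equal(s$local_mean, seq(0, 1, length.out = 100))
  expect_equal(s$detail, rep(0, 100))
})

test_that("degenerate mask (a = 0, K = 1) equals plain sifting", {
  set.seed(7)
  t <- (0:499) / 500
  x <- sin(2 * pi * 12 * t) + 0.5 * sin(2 * pi * 3 * t) + rnorm(500, 0, 0.05)
  plain <- sift_ma(x)
  deg <- maupemd_extract(x, mask_spec(30, 0, 1))
  expect_equal(deg$separated, plain$detail, tolerance = 1e-12)
  expect_equal(deg$residual, plain$local_mean, tolerance = 1e-12)
})

test_that("degenerate masked extraction matches an independent plain EMD", {
  for (s in 1:5) {
    set.seed(s)
    t <- (0:799) / 500
    x <- sin(2 * pi * 15 * t) + 0.6 * sin(2 * pi * 3 * t + 1) +
      rnorm(800, 0, 0.05)
    deg <- maupemd_extract(x, mask_spec(30, 0, 1))
    imf1 <- oracle_emd_imf1(x)
    expect_lt(sqrt(mean((deg$separated - imf1)^2)), 1e-6)
  }
})

test_that("a mask-frequency tone is captured in the separated component", {
  t <- (0:499) / 500
  x <- 0.5 * sin(2 * pi * 30 * t + 0.3)
  d <- maupemd_extract(x, mask_spec(30, 0.04, 4))
  expect_gt(sum(d$separated^2) / sum(x^2), 0.95)
})

test_that("masked extraction conserves the input exactly", {
  set.seed(3)
  x <- rnorm(500, 0, 0.3)
  d <- maupemd_extract(x, mask_spec(30, 0.04, 4), spikes = c(100L, 250L))
  expect_lt(max(abs(d$separated + d$residual - x)), 1e-9)
})

test_that("phase-uniform masks cancel in the residual", {
  # with integer mask cycles in the window the ensemble of K = 4 uniform
  # phases sums to zero, so the residual must not depend on a global phase
  # offset of the ensemble; a non-cancelling mask would shift the residual
  # by O(amplitude) when the ensemble is rotated
  t <- (0:499) / 500
  x <- 0.4 * sin(2 * pi * 2 * t) + 0.2 * sin(2 * pi * 25 * t)
  a <- 0.02
  ens_residual <- function(offset) {
    means <- vapply(0:3, function(k) {
      m <- a * sin(2 * pi * 10 * t + offset + k * pi / 2)
      sift_ma(x + m)$local_mean - sift_ma(m)$local_mean
    }, numeric(length(t)))
    x - (x - rowMeans(means))  # residual = mean of corrected means
  }
  r0 <- ens_residual(0)
  r1 <- ens_residual(0.9)
  expect_lt(sqrt(mean((r1 - r0)^2)), 0.05 * a)
})

test_that("two-stage isolation recovers the P wave on a noiseless beat", {
  spec <- dipole_beat_spec()
  gb <- generate_beat(spec)
  iso <- isolate_p_wave(gb$template)
  f <- gb$template$fiducials
  w <- (f$P_on - 20):(f$P_off + 20)
  for (l in lead_names_12()) {
    if (max(abs(gb$p_truth[l, ])) > 0.02) {
      expect_gt(cor(iso$p_wave[l, w], gb$p_truth[l, w]), 0.95)
    }
  }
  # strict two-stage conservation
  recon <- iso$qrs + iso$p_wave + iso$remainder
  expect_lt(max(abs(recon - gb$template$samples)), 1e-8)
})

test_that("a zero-P template yields near-zero isolated P energy", {
  w <- default_waves()
  w$P$amplitude <- 0
  spec <- dipole_beat_spec(waves = w)
  gb <- generate_beat(spec)
  tpl <- gb$template
  # force P boundaries where a P would be, to exercise stage 2
  tpl$fiducials$P_on <- 96L; tpl$fiducials$P_peak <- 121L
  tpl$fiducials$P_off <- 146L
  iso <- isolate_p_wave(tpl)
  # inside the (forced) P window the isolated P must be essentially zero;
  # outside it the separated component may carry some T-slope leakage,
  # which the P-window features never see
  win <- 76:166
  expect_lt(sum(iso$p_wave[, win]^2) / sum(tpl$samples^2), 0.001)
  expect_lt(max(abs(iso$p_wave[, win])), 0.02)
})

test_that("missing P boundaries mark the P output missing, QRS still runs", {
  spec <- dipole_beat_spec()
  gb <- generate_beat(spec)
  tpl <- gb$template
  tpl$fiducials$P_on <- NA_integer_
  iso <- isolate_p_wave(tpl)
  expect_true(all(is.na(iso$p_wave)))
  expect_false(any(is.na(iso$qrs)))
  expect_false(iso$p_available)
})
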