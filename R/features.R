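#' Names of the 56 features
#'
#' The full feature schema: P duration; P/Q/R/S/T amplitudes and PR/QRS/QT
#' intervals and ST voltage on the reference limb (`L_`) and chest (`C_`)
#' leads; the three principal-component weights of the P loop; the 28
#' inter-lead dispersion angles; the three loop descriptors; and the three
#' 20-50 Hz / 1-20 Hz band-power ratios.
#'
#' @return Character vector of length 56.
#' @export
feature_names_56 <- function() {
  c("P_dur",
    paste0("L_AMP_", c("P", "Q", "R", "S", "T")),
    paste0("C_AMP_", c("P", "Q", "R", "S", "T")),
    paste0("L_T_", c("PR", "QRS", "QT")),
    paste0("C_T_", c("PR", "QRS", "QT")),
    "L_STvol_R", "C_STvol_R",
    "PC1w", "PC2w", "PC3w",
    angle_pair_names(),
    "LoopArea", "LoopLength", "LAratio",
    paste0("r2050_PC", 1:3))
}

# The 28 unordered lead pairs, in the published listing order.
angle_pair_names <- function() {
  c("I_II", "II_V1", "V1_V2", "V2_V3", "V3_V4", "V4_V5", "V5_V6",
    "I_V1", "II_V2", "V1_V3", "V2_V4", "V3_V5", "V4_V6",
    "I_V2", "II_V3", "V1_V4", "V2_V5", "V3_V6",
    "I_V3", "II_V4", "V1_V5", "V2_V6",
    "I_V4", "II_V5", "V1_V6",
    "I_V5", "II_V6",
    "I_V6")
}

#' Reference-lead selection
#'
#' Picks the limb lead and the chest lead with the largest absolute R
#' amplitude (measured at the template R index); ties broken by
#' conventional lead order.
#'
#' @param template a [beat_template()].
#' @return Named character vector `c(limb = ..., chest = ...)`.
#' @export
select_reference_leads <- function(template) {
  stopifnot(inherits(template, "beat_template"))
  r <- template$r_index
  pick <- function(group) {
    grp <- intersect(group, rownames(template$samples))
    if (length(grp) == 0) stop("no leads in group")
    amp <- abs(template$samples[grp, r])
    if (all(amp == 0)) stop("all leads flat at R in group")
    grp[which.max(amp)]
  }
  c(limb = pick(limb_lead_names()), chest = pick(chest_lead_names()))
}

# Morphology block for one lead given its fiducials (one-row tibble).
lead_morphology <- function(x, fid, fs, prefix) {
  ms <- function(a, b) if (is.na(a) || is.na(b)) NA_real_ else (b - a) / fs * 1000
  at <- function(i) if (is.na(i)) NA_real_ else x[i]
  stv <- if (is.na(fid$J[1]) || is.na(fid$T_on[1]) || fid$J[1] >= fid$T_on[1]) {
    NA_real_
  } else {
    mean(x[fid$J[1]:fid$T_on[1]])
  }
  out <- list(at(fid$P_peak[1]), at(fid$Q[1]), at(fid$R[1]), at(fid$S[1]),
              at(fid$T_peak[1]),
              ms(fid$P_on[1], fid$QRS_on[1]),
              ms(fid$QRS_on[1], fid$J[1]),
              ms(fid$QRS_on[1], fid$T_off[1]),
              stv)
  names(out) <- c(paste0(prefix, "_AMP_", c("P", "Q", "R", "S", "T")),
                  paste0(prefix, "_T_", c("PR", "QRS", "QT")),
                  paste0(prefix, "_STvol_R"))
  out
}

#' Morphology features from an averaged beat
#'
#' Wave amplitudes (signed peak values, mV), P duration and the PR, QRS and
#' QT intervals (ms), and the mean ST-segment voltage between the J point
#' and T onset (mV), measured on the reference limb and chest leads.
#' Fiducials are located separately per reference lead; missing fiducials
#' propagate to missing features.
#'
#' @param template a [beat_template()].
#' @param leads optional named vector from [select_reference_leads()].
#' @return A one-row tibble of the 19 morphology features (including
#'   `P_dur`).
#' @export
morphology_features <- function(template, leads = NULL) {
  stopifnot(inherits(template, "beat_template"))
  if (is.null(leads)) leads <- select_reference_leads(template)
  fs <- template$fs
  fid_for <- function(lead) {
    x <- template$samples[lead, ]
    delineate_beat(x, template$r_index, fs)
  }
  fid_l <- fid_for(leads[["limb"]])
  fid_c <- fid_for(leads[["chest"]])
  p_dur <- if (is.na(fid_l$P_on[1]) || is.na(fid_l$P_off[1])) NA_real_ else {
    (fid_l$P_off[1] - fid_l$P_on[1]) / fs * 1000
  }
  tibble::as_tibble(c(
    list(P_dur = p_dur),
    lead_morphology(template$samples[leads[["limb"]], ], fid_l, fs, "L"),
    lead_morphology(template$samples[leads[["chest"]], ], fid_c, fs, "C")))
}

#' P-loop principal-component projection
#'
#' Builds the n x 8 P-wave matrix from leads I, II, V1-V6 of the isolated
#' P wave and eigendecomposes the uncentred second-moment matrix `t(X) X`.
#' Loadings are the first three eigenvectors (sign fixed so each column's
#' largest-magnitude entry is positive); the PC time courses are the
#' projections `X %*% loadings`; the weights are eigenvalue fractions of
#' the total (all eight eigenvalues).
#'
#' @param X numeric n x 8 matrix, columns ordered I, II, V1-V6 (mV).
#' @param center centre columns before decomposition (default `FALSE`,
#'   matching the uncentred `t(X) X` definition).
#' @return A `p_loop_pca` list: `loadings` (8 x 3), `eigenvalues` (all 8),
#'   `pc_series` (3 x n), `weights` (PC1w-PC3w).
#' @export
pca_ploop <- function(X, center = FALSE) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == 8)
  if (any(!is.finite(X))) stop("X must be finite")
  if (all(X == 0)) stop("X is all zero")
  if (center) X <- scale(X, center = TRUE, scale = FALSE)
  C <- crossprod(X)
  eig <- eigen(C, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  V <- eig$vectors[, 1:3, drop = FALSE]
  for (j in 1:3) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- lead_names_8()
  pc <- t(X %*% V)
  structure(list(loadings = V, eigenvalues = lam, pc_series = pc,
                 weights = stats::setNames(lam[1:3] / sum(lam),
                                           c("PC1w", "PC2w", "PC3w"))),
            class = "p_loop_pca")
}

#' @export
print.p_loop_pca <- function(x, ...) {
  cat("<p_loop_pca> weights:",
      paste(sprintf("%s=%.3f", names(x$weights), x$weights), collapse = " "),
      "\n")
  invisible(x)
}

# Grid cells (1-based (ix, iy)) crossed by the closed polyline, by
# Amanatides-Woo traversal per segment.
traverse_cells <- function(px, py, x0, y0, dx, dy, side) {
  cell_of <- function(x, x0, dx) {
    pmin(pmax(floor((x - x0) / dx) + 1L, 1L), side)
  }
  ids <- integer(0)
  buf <- integer(4096); nb <- 0L
  add <- function(ix, iy) {
    nb <<- nb + 1L
    if (nb > length(buf)) buf <<- c(buf, integer(length(buf)))
    buf[nb] <<- (iy - 1L) * side + ix
  }
  np <- length(px)
  for (s in seq_len(np - 1L)) {
    ax <- px[s]; ay <- py[s]; bx <- px[s + 1L]; by <- py[s + 1L]
    ix <- cell_of(ax, x0, dx); iy <- cell_of(ay, y0, dy)
    ixb <- cell_of(bx, x0, dx); iyb <- cell_of(by, y0, dy)
    add(ix, iy)
    vx <- bx - ax; vy <- by - ay
    stepx <- sign(vx); stepy <- sign(vy)
    tmaxx <- if (vx == 0) Inf else {
      edge <- x0 + (ix - (stepx < 0)) * dx
      (edge - ax) / vx
    }
    tmaxy <- if (vy == 0) Inf else {
      edge <- y0 + (iy - (stepy < 0)) * dy
      (edge - ay) / vy
    }
    tdx <- if (vx == 0) Inf else abs(dx / vx)
    tdy <- if (vy == 0) Inf else abs(dy / vy)
    guard <- 0L
    while ((ix != ixb || iy != iyb) && guard < 4L * side) {
      if (tmaxx < tmaxy) {
        ix <- ix + stepx; tmaxx <- tmaxx + tdx
      } else {
        iy <- iy + stepy; tmaxy <- tmaxy + tdy
      }
      if (ix < 1L || ix > side || iy < 1L || iy > side) break
      add(ix, iy)
      guard <- guard + 1L
    }
    add(ixb, iyb)
  }
  length(unique(buf[seq_len(nb)]))
}

# Even-odd point-in-polygon test for points (qx, qy) against the polygon
# (px, py) (closed implicitly). Scanline evaluation per distinct qy value,
# so a regular grid of query points costs one edge sweep per grid row.
points_in_polygon <- function(qx, qy, px, py) {
  np <- length(px)
  xi <- px; yi <- py
  xj <- c(px[np], px[-np]); yj <- c(py[np], py[-np])
  slope <- ifelse(yj == yi, 0, (xj - xi) / (yj - yi))
  inside <- logical(length(qx))
  for (y in unique(qy)) {
    sel <- (yi > y) != (yj > y)
    rows <- which(qy == y)
    if (!any(sel)) next
    xs <- sort(xi[sel] + (y - yi[sel]) * slope[sel])
    # odd number of crossings strictly to the right = inside
    inside[rows] <- findInterval(qx[rows], xs, left.open = TRUE) %% 2L == 1L
  }
  inside
}

#' Grid-based P-loop descriptors
#'
#' The (PC1, PC2) trajectory is closed (last point joined to first) and its
#' bounding rectangle divided into `n_cells` equal cells (70 x 70 by
#' default). `LoopLength` is the number of distinct cells the closed
#' polyline passes through; `LoopArea` is the percentage of cells whose
#' centre falls strictly inside the closed polygon (even-odd rule);
#' `LAratio` is their ratio.
#'
#' @param pc1,pc2 numeric series of equal length >= 3.
#' @param n_cells number of grid cells, a perfect square (default 4900).
#' @return A one-row tibble `LoopArea`, `LoopLength`, `LAratio` (all `NA`
#'   for a degenerate zero-extent trajectory).
#' @export
loop_descriptors <- function(pc1, pc2, n_cells = 4900) {
  stopifnot(length(pc1) == length(pc2), length(pc1) >= 3)
  side <- as.integer(round(sqrt(n_cells)))
  if (side * side != n_cells) stop("n_cells must be a perfect square")
  x0 <- min(pc1); x1 <- max(pc1)
  y0 <- min(pc2); y1 <- max(pc2)
  if (x1 - x0 <= 0 || y1 - y0 <= 0) {
    return(tibble::tibble(LoopArea = NA_real_, LoopLength = NA_real_,
                          LAratio = NA_real_))
  }
  dx <- (x1 - x0) / side
  dy <- (y1 - y0) / side
  px <- c(pc1, pc1[1])
  py <- c(pc2, pc2[1])
  len <- traverse_cells(px, py, x0, y0, dx, dy, side)
  centers <- expand.grid(ix = seq_len(side), iy = seq_len(side))
  cx <- x0 + (centers$ix - 0.5) * dx
  cy <- y0 + (centers$iy - 0.5) * dy
  inside <- points_in_polygon(cx, cy, pc1, pc2)
  area <- 100 * sum(inside) / n_cells
  tibble::tibble(LoopArea = area, LoopLength = as.numeric(len),
                 LAratio = if (area > 0) len / area else NA_real_)
}

#' Inter-lead dispersion angles
#'
#' Each of the eight leads maps to a 3-vector in the space of the first
#' three principal components (a row of the loading matrix). The feature
#' block is the angle, in degrees, between every unordered pair of lead
#' vectors, in the published listing order. Zero-norm rows give missing
#' angles.
#'
#' @param loadings 8 x 3 matrix with rows named I, II, V1-V6.
#' @return A one-row tibble with 28 angle columns (degrees, 0-180).
#' @export
interlead_angles <- function(loadings) {
  stopifnot(nrow(loadings) == 8, ncol(loadings) == 3)
  if (is.null(rownames(loadings))) rownames(loadings) <- lead_names_8()
  pairs <- strsplit(angle_pair_names(), "_")
  vals <- vapply(pairs, function(p) {
    u <- loadings[p[1], ]; v <- loadings[p[2], ]
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) return(NA_real_)
    acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
  }, numeric(1))
  tibble::as_tibble(as.list(stats::setNames(vals, angle_pair_names())))
}

#' Band-power ratio of a PC time course
#'
#' Periodogram power ratio between the 20-50 Hz and 1-20 Hz bands. With a
#' 1 s series at 500 Hz the DFT bins fall on integer frequencies; the
#' boundary 20 Hz bin is assigned to the numerator band, so the numerator
#' sums bins 20-50 Hz and the denominator bins 1-19 Hz.
#'
#' @param x numeric series (one PC time course).
#' @param fs sampling rate (Hz).
#' @return The ratio, or `NA` if the denominator power is zero.
#' @export
band_power_ratio <- function(x, fs = 500) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1) * fs / n
  num <- sum(p[freq >= 20 & freq <= 50])
  den <- sum(p[freq >= 1 & freq < 20])
  if (den == 0) return(NA_real_)
  num / den
}

#' Assemble the 56-feature vector
#'
#' Combines the morphology block, PC weights, inter-lead angles, loop
#' descriptors and band-power ratios into a single one-row tibble with
#' exactly the 56 published names. Missing parts propagate as `NA`.
#'
#' @param morph one-row tibble from [morphology_features()].
#' @param ploop a [pca_ploop()] result, or `NULL`.
#' @return One-row tibble with the 56 columns of [feature_names_56()].
#' @export
assemble_features <- function(morph = NULL, ploop = NULL) {
  out <- stats::setNames(as.list(rep(NA_real_, 56)), feature_names_56())
  fill <- function(out, tbl) {
    for (nm in intersect(names(tbl), names(out))) out[[nm]] <- tbl[[nm]][1]
    out
  }
  if (!is.null(morph)) out <- fill(out, morph)
  if (!is.null(ploop)) {
    out <- fill(out, tibble::as_tibble(as.list(ploop$weights)))
    out <- fill(out, interlead_angles(ploop$loadings))
    out <- fill(out, loop_descriptors(ploop$pc_series[1, ],
                                      ploop$pc_series[2, ]))
    for (i in 1:3) {
      out[[paste0("r2050_PC", i)]] <- band_power_ratio(ploop$pc_series[i, ])
    }
  }
  tibble::as_tibble(out)
}

#' Features from one isolated P wave
#'
#' Convenience wrapper: builds the P-wave matrix from a [isolate_p_wave()]
#' (or band-pass) result, runs the PC projection and assembles the full
#' 56-feature vector together with the morphology block of the original
#' template.
#'
#' @param template the [beat_template()] the P wave was extracted from.
#' @param p_wave 12 x n matrix of the isolated P wave (rows named with the
#'   12 leads); leads with `NA` rows are excluded (and if any of the eight
#'   PCA leads is missing, the loop/angle block is missing).
#' @return One-row tibble of 56 features.
#' @export
extract_features <- function(template, p_wave) {
  morph <- tryCatch(morphology_features(template), error = function(e) NULL)
  ploop <- NULL
  leads8 <- lead_names_8()
  if (all(leads8 %in% rownames(p_wave))) {
    X <- t(p_wave[leads8, , drop = FALSE])
    if (!any(is.na(X)) && !all(X == 0)) {
      ploop <- tryCatch(pca_ploop(X), error = function(e) NULL)
    }
  }
  assemble_features(morph, ploop)
}

#' Feature table for a synthetic cohort
#'
#' Runs the full extraction pipeline on every record of a
#' [generate_cohort()] tibble: preprocessing, R detection, beat averaging,
#' P isolation by the requested method, and feature assembly.
#'
#' @param cohort tibble from [generate_cohort()].
#' @param method `"maupemd"` (default) or `"bandpass"`.
#' @param preprocess apply [preprocess_record()] first (default `TRUE`).
#' @return Tibble with `id`, `label` and the 56 feature columns.
#' @export
cohort_features <- function(cohort, method = c("maupemd", "bandpass"),
                            preprocess = TRUE) {
  method <- match.arg(method)
  rows <- purrr::pmap(cohort, function(id, label, record, ...) {
    feats <- tryCatch({
      rec <- if (preprocess) preprocess_record(record) else record
      rp <- detect_r_peaks(rec)
      tpl <- average_beat(rec, rp)
      pw <- if (method == "maupemd") {
        isolate_p_wave(tpl)$p_wave
      } else {
        bandpass_p_extract(rec, rp)$samples
      }
      extract_features(tpl, pw)
    }, error = function(e) {
      tibble::as_tibble(stats::setNames(as.list(rep(NA_real_, 56)),
                                        feature_names_56()))
    })
    dplyr::bind_cols(tibble::tibble(id = id, label = label), feats)
  })
  dplyr::bind_rows(rows)
}
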