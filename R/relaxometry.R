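#' T1 relaxometry and signal-concentration conversion
#'
#' The pre-contrast T1 map is estimated from variable-TR, 90-degree-flip
#' saturation-recovery calibration scans, S(TR) = S0 * (1 - exp(-TR/T1)).
#' The dynamic series uses the spoiled gradient-echo (SPGR) steady-state
#' signal, S = M * sin(a) * (1 - E1) / (1 - cos(a) * E1) with
#' E1 = exp(-TR * R1), and the linear relaxivity model
#' R1(t) = 1/T10 + r1 * C(t) to move between signal and gadolinium
#' concentration. T2*/TE effects are neglected (TE = 1 ms).
#'
#' @name relaxometry
NULL

T1_BOUNDS_MS <- c(50, 5000)

# residual sum of squares of the saturation-recovery model at a given T1,
# with the optimal S0 profiled out in closed form (model is linear in S0)
sr_rss <- function(t1, s, trs) {
  f <- 1 - exp(-trs / t1)
  s0 <- sum(s * f) / sum(f * f)
  sum((s - s0 * f)^2)
}

fit_t10_voxel <- function(s, trs, grid) {
  if (all(s == 0) || !all(is.finite(s)))
    return(c(t1 = NA_real_, s0 = NA_real_, ok = 0))
  rss <- vapply(grid, sr_rss, numeric(1), s = s, trs = trs)
  i <- which.min(rss)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(sr_rss, c(lo, hi), s = s, trs = trs, tol = 1e-4)
  t1 <- opt$minimum
  f <- 1 - exp(-trs / t1)
  s0 <- sum(s * f) / sum(f * f)
  ok <- as.numeric(s0 > 0 &&
                     t1 > T1_BOUNDS_MS[1] * 1.02 && t1 < T1_BOUNDS_MS[2] * 0.98)
  c(t1 = t1, s0 = s0, ok = ok)
}

#' Fit a pre-contrast T1 map from variable-TR calibration images
#'
#' Per-voxel least squares of the saturation-recovery model
#' S(TR) = S0 * (1 - exp(-TR/T1)), with S0 profiled out analytically and T1
#' located by a log-spaced grid search plus local refinement. Voxels with
#' all-zero or non-finite signal, non-positive S0, or T1 at the search bounds
#' (50-5000 ms, i.e. no usable recovery curvature) are flagged `fit_ok = FALSE`.
#'
#' @param calib list with `volumes` (list of 3D arrays or `vol3d`, one per TR)
#'   and `trs_ms` (repetition times, ms; at least 3 distinct values).
#' @param mask optional logical array; voxels outside are not fitted.
#' @return list with 3D arrays `t1_ms`, `s0` and logical `fit_ok`.
#' @export
fit_t10 <- function(calib, mask = NULL) {
  vols <- lapply(calib$volumes, function(v) if (inherits(v, "vol3d")) v$data else v)
  trs <- as.numeric(calib$trs_ms)
  if (length(unique(trs)) < 3L)
    stop("fit_t10 needs at least 3 distinct TRs, got ", length(unique(trs)))
  if (length(vols) != length(trs)) stop("one volume per TR required")
  dm <- dim(vols[[1]])
  s_mat <- matrix(unlist(lapply(vols, as.numeric)), nrow = prod(dm))  # nvox x nTR
  if (min(s_mat, na.rm = TRUE) < 0) stop("calibration signals must be non-negative")
  t1 <- array(NA_real_, dm); s0 <- array(NA_real_, dm)
  ok <- array(FALSE, dm)
  idx <- if (is.null(mask)) seq_len(prod(dm)) else which(mask)
  grid <- exp(seq(log(T1_BOUNDS_MS[1]), log(T1_BOUNDS_MS[2]), length.out = 60))
  for (v in idx) {
    r <- fit_t10_voxel(s_mat[v, ], trs, grid)
    t1[v] <- r[1]; s0[v] <- r[2]; ok[v] <- r[3] > 0
  }
  list(t1_ms = t1, s0 = s0, fit_ok = ok)
}

spgr_shape <- function(e1, flip_deg) {
  a <- flip_deg * pi / 180
  sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

#' SPGR forward model: concentration to signal
#'
#' Exact spoiled gradient-echo steady-state signal for a concentration curve
#' under the linear relaxivity model. Strictly increasing in C for flip angles
#' in (0, 90] degrees and TR > 0.
#'
#' @param conc concentration values (mM), vector or array.
#' @param t10_ms pre-contrast T1 (ms), scalar or same shape as `conc`.
#' @param r1 contrast relaxivity (per mM per s).
#' @param tr_ms repetition time of the dynamic sequence (ms).
#' @param flip_deg flip angle (degrees).
#' @param s_scale equilibrium-signal scale factor.
#' @return signal values, same shape as `conc`.
#' @export
concentration_to_signal <- function(conc, t10_ms, r1, tr_ms, flip_deg, s_scale = 1) {
  if (any(t10_ms <= 0)) stop("t10_ms must be positive")
  if (flip_deg <= 0 || flip_deg > 90) stop("flip_deg must be in (0, 90]")
  r1t <- 1000 / t10_ms + r1 * conc           # R1 in 1/s
  e1 <- exp(-tr_ms / 1000 * r1t)
  s_scale * spgr_shape(e1, flip_deg)
}

#' Convert a signal curve to a concentration curve
#'
#' Inverts the SPGR equation per frame. The unknown equilibrium scale is
#' calibrated from the mean of the first `baseline_frames` (pre-contrast)
#' samples together with the voxel's T10. Frames whose signal lies outside the
#' invertible SPGR range are returned as NA ("missing"). Concentrations are
#' floored at -0.05 mM (noise allowance) and negative residuals then set to 0.
#'
#' @param signal numeric vector, one value per frame.
#' @param t10_ms voxel pre-contrast T1 (ms), positive scalar.
#' @param r1 relaxivity (per mM per s).
#' @param tr_ms dynamic-series TR (ms).
#' @param flip_deg flip angle (degrees).
#' @param baseline_frames number of leading pre-contrast frames (>= 1).
#' @return numeric vector of concentrations (mM) with attribute `baseline`
#'   (the mean baseline signal).
#' @export
signal_to_concentration <- function(signal, t10_ms, r1, tr_ms, flip_deg,
                                    baseline_frames) {
  if (length(t10_ms) != 1L || !is.finite(t10_ms) || t10_ms <= 0)
    stop("t10_ms must be a positive scalar")
  if (flip_deg <= 0 || flip_deg > 90) stop("flip_deg must be in (0, 90]")
  if (baseline_frames < 1L) stop("baseline_frames must be >= 1")
  ca <- cos(flip_deg * pi / 180)
  sb <- mean(signal[seq_len(baseline_frames)])
  e10 <- exp(-tr_ms / 1000 * (1000 / t10_ms))
  scale <- sb / spgr_shape(e10, flip_deg)   # recovers s_scale * sin(a) implicitly
  a <- flip_deg * pi / 180
  y <- signal / (scale * sin(a))            # = (1-E1)/(1-cos a * E1)
  e1 <- (1 - y) / (1 - y * ca)
  bad <- !is.finite(e1) | e1 <= 0 | e1 > 1
  e1[bad] <- NA_real_
  r1t <- -1000 / tr_ms * log(e1)            # 1/s
  conc <- (r1t - 1000 / t10_ms) / r1
  conc[conc < -0.05] <- -0.05
  conc[conc < 0] <- 0
  attr(conc, "baseline") <- sb
  conc
}
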