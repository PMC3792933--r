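#' Semi-quantitative enhancement-curve features
#'
#' Six model-free features of the signal-intensity curve, computed on the
#' enhancement e(t) = S(t) - S_baseline: maximum enhancement (Smax),
#' time-to-peak (TTP, relative to the first post-baseline frame), area under
#' the whole enhancement curve (AUC) and under its first 60 s (AUC60), the
#' wash-in slope between the 10% and 90% points of the rising curve, and the
#' wash-out slope between the peak and the final time point. These can be
#' computed without any T1 calibration, which is what makes them attractive
#' clinically.
#'
#' @param signal numeric vector of signal intensities, one per frame.
#' @param times_s strictly increasing frame times (s).
#' @param baseline_frames number of leading pre-contrast frames (>= 1); the
#'   enhancement reference is their mean.
#' @return named list: `smax`, `ttp`, `auc`, `auc60`, `wash_in`, `wash_out`,
#'   plus logical flags `wash_in_defined`, `wash_out_defined`.
#' @export
compute_features <- function(signal, times_s, baseline_frames) {
  n <- length(signal)
  if (length(times_s) != n) stop("signal and times_s lengths differ")
  if (any(diff(times_s) <= 0)) stop("times_s must be strictly increasing")
  if (baseline_frames < 1L || n - baseline_frames < 2L)
    stop("need >= 2 frames after the baseline window")
  sb <- mean(signal[seq_len(baseline_frames)])
  e <- signal[(baseline_frames + 1L):n] - sb
  tt <- times_s[(baseline_frames + 1L):n]
  t_start <- tt[1]

  i_peak <- which.max(e)                    # first maximum on ties
  smax <- e[i_peak]
  ttp <- tt[i_peak] - t_start

  auc <- trapz(tt, e)
  auc60 <- trapz_window(tt, e, t_start, t_start + 60)

  wash_in <- NA_real_; wi_ok <- FALSE
  if (smax > 0) {
    t10 <- first_upcross(tt, e, 0.1 * smax)
    t90 <- first_upcross(tt, e, 0.9 * smax)
    if (is.finite(t10) && is.finite(t90) && t90 > t10) {
      wash_in <- (0.9 - 0.1) * smax / (t90 - t10)
      wi_ok <- TRUE
    }
  }
  wash_out <- NA_real_; wo_ok <- FALSE
  if (i_peak < length(e)) {
    wash_out <- (e[length(e)] - smax) / (tt[length(e)] - tt[i_peak])
    wo_ok <- TRUE
  }
  list(smax = smax, ttp = ttp, auc = auc, auc60 = auc60,
       wash_in = wash_in, wash_out = wash_out,
       wash_in_defined = wi_ok, wash_out_defined = wo_ok)
}

trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

# trapezoid over [a, b], linearly interpolating partial end sub-intervals
trapz_window <- function(x, y, a, b) {
  b <- min(b, x[length(x)])
  if (b <= a) return(0)
  keep <- x >= a & x <= b
  xs <- x[keep]; ys <- y[keep]
  if (xs[length(xs)] < b - 1e-12) {
    xs <- c(xs, b); ys <- c(ys, stats::approx(x, y, xout = b)$y)
  }
  if (xs[1] > a + 1e-12 && a >= x[1]) {
    xs <- c(a, xs); ys <- c(stats::approx(x, y, xout = a)$y, ys)
  }
  trapz(xs, ys)
}

# first upward crossing of level L, linear interpolation, ties toward earlier t
first_upcross <- function(tt, e, level) {
  at <- which(e >= level)
  if (!length(at)) return(NA_real_)
  j <- at[1]
  if (j == 1L) return(tt[1])
  t0 <- tt[j - 1]; t1 <- tt[j]
  y0 <- e[j - 1]; y1 <- e[j]
  t0 + (level - y0) / (y1 - y0) * (t1 - t0)
}

#' Semi-quantitative feature maps for a DCE series
#'
#' Applies [compute_features()] to every masked voxel of a 4D series.
#'
#' @param dce a `vol4d`.
#' @param mask logical 3D array of voxels to process.
#' @param baseline_frames leading pre-contrast frame count.
#' @return named list of `vol3d` maps (`smax`, `ttp`, `auc`, `auc60`,
#'   `wash_in`, `wash_out`); undefined features are NA.
#' @export
compute_feature_maps <- function(dce, mask, baseline_frames) {
  dm <- dim(dce$data)[1:3]
  idx <- which(mask)
  nt <- dim(dce$data)[4]
  mat <- matrix(dce$data, ncol = nt)[idx, , drop = FALSE]
  out <- lapply(1:6, function(i) array(NA_real_, dm))
  names(out) <- c("smax", "ttp", "auc", "auc60", "wash_in", "wash_out")
  for (r in seq_along(idx)) {
    f <- compute_features(mat[r, ], dce$times_s, baseline_frames)
    out$smax[idx[r]] <- f$smax
    out$ttp[idx[r]] <- f$ttp
    out$auc[idx[r]] <- f$auc
    out$auc60[idx[r]] <- f$auc60
    out$wash_in[idx[r]] <- if (f$wash_in_defined) f$wash_in else NA_real_
    out$wash_out[idx[r]] <- if (f$wash_out_defined) f$wash_out else NA_real_
  }
  lapply(out, vol3d, affine = dce$affine)
}

#' Min-max normalize a parameter map
#'
#' Linear scaling x_norm = (x - x_min) / (x_max - x_min) over the masked,
#' defined voxels, mapping the in-mask minimum to 0 and maximum to 1. MRI
#' signal scales are arbitrary and differ between animals and scanners;
#' normalization makes the semi-quantitative maps comparable across datasets.
#' Undefined (NA) voxels stay undefined; voxels outside the mask are NA.
#'
#' @param map `vol3d` (or 3D array).
#' @param mask logical 3D array.
#' @param name parameter name used in error messages.
#' @return normalized `vol3d`.
#' @export
normalize_map <- function(map, mask, name = deparse(substitute(map))) {
  v <- if (inherits(map, "vol3d")) map else vol3d(map)
  vals <- v$data[mask]
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2L) stop("normalize_map(", name, "): fewer than 2 defined voxels")
  rng <- range(vals)
  if (diff(rng) == 0)
    stop("normalize_map(", name, "): constant map, zero range")
  out <- array(NA_real_, dim(v$data))
  out[mask] <- (v$data[mask] - rng[1]) / diff(rng)
  vol3d(out, v$affine)
}
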