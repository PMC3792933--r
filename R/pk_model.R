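#' Standard Tofts pharmacokinetic model with a bi-exponential AIF
#'
#' The tissue concentration is the convolution
#' Ct(t) = Ktrans * integral_0^t Cp(tau) * exp(-kep * (t - tau)) dtau,
#' with Ktrans (1/s) the capillary transfer constant between the intravascular
#' and the extravascular-extracellular compartments and kep (1/s) the return
#' rate (kep = Ktrans / ve). The plasma input Cp is modelled per dataset as
#' Cp(t) = a1 * exp(-m1 (t - t0)) + a2 * exp(-m2 (t - t0)) for t >= t0 and 0
#' before arrival, for which the convolution has a closed form (sums of
#' exponential differences, with the (t - tau)-type limit when kep matches a
#' decay rate).
#'
#' @name pk_model
NULL

#' Bi-exponential arterial input function
#'
#' @param a1,a2 amplitudes (mM), non-negative; by convention the fast term
#'   comes first (m1 > m2 after fitting).
#' @param m1,m2 decay rates (1/s), positive.
#' @param t_arrival bolus arrival time (s); Cp = 0 before it.
#' @return object of class `aif_model`.
#' @export
aif_model <- function(a1, m1, a2, m2, t_arrival = 0) {
  if (a1 < 0 || a2 < 0) stop("AIF amplitudes must be >= 0")
  if (m1 <= 0 || m2 <= 0) stop("AIF decay rates must be > 0")
  structure(list(a = c(a1, a2), m = c(m1, m2), t_arrival = t_arrival),
            class = "aif_model")
}

#' Evaluate the AIF plasma concentration
#' @param aif an `aif_model`.
#' @param times_s times (s).
#' @return Cp values (mM); 0 before arrival.
#' @export
aif_cp <- function(aif, times_s) {
  s <- times_s - aif$t_arrival
  out <- numeric(length(s))
  p <- s >= 0
  out[p] <- aif$a[1] * exp(-aif$m[1] * s[p]) + aif$a[2] * exp(-aif$m[2] * s[p])
  out
}

# Stable evaluation of (exp(-m*s) - exp(-kep*s)) / (kep - m) for s >= 0,
# including the kep -> m limit s * exp(-m*s). Vectorized over s, scalar d.
expconv <- function(m, kep, s) {
  d <- kep - m
  ds <- d * s
  out <- numeric(length(s))
  tiny <- abs(ds) < 1e-8
  if (any(tiny)) out[tiny] <- s[tiny] * exp(-m * s[tiny]) * (1 + ds[tiny] / 2)
  if (any(!tiny)) out[!tiny] <- exp(-kep * s[!tiny]) * expm1(ds[!tiny]) / d
  out
}

# d/d(kep) of expconv; stable near kep == m (limit -s^2/2 * exp(-m*s))
expconv_grad <- function(m, kep, s) {
  d <- kep - m
  ds <- d * s
  out <- numeric(length(s))
  tiny <- abs(ds) < 1e-4
  if (any(tiny)) {
    st <- s[tiny]
    out[tiny] <- exp(-m * st) * (-st^2 / 2 + d * st^3 / 3)
  }
  if (any(!tiny)) {
    st <- s[!tiny]
    out[!tiny] <- (st * exp(-kep * st) - expconv(m, kep, st)) / d
  }
  out
}

#' Closed-form standard Tofts forward model
#'
#' @param ktrans,kep rate constants (1/s), non-negative.
#' @param aif an `aif_model`.
#' @param times_s evaluation times (s).
#' @return tissue concentration Ct (mM) at `times_s`.
#' @export
tofts_forward <- function(ktrans, kep, aif, times_s) {
  if (ktrans < 0 || kep < 0) stop("ktrans and kep must be >= 0")
  s <- pmax(times_s - aif$t_arrival, 0)
  ktrans * (aif$a[1] * expconv(aif$m[1], kep, s) +
            aif$a[2] * expconv(aif$m[2], kep, s))
}

# Vectorized forward over voxels: kt, kep vectors -> nvox x ntime matrix.
tofts_forward_matrix <- function(kt, kep, aif, times_s) {
  s <- pmax(times_s - aif$t_arrival, 0)
  nv <- length(kt); nt <- length(s)
  ct <- matrix(0, nv, nt)
  S <- matrix(s, nv, nt, byrow = TRUE)
  for (i in 1:2) {
    m <- aif$m[i]
    D <- matrix(kep - m, nv, nt)
    DS <- D * S
    term <- matrix(0, nv, nt)
    tiny <- abs(DS) < 1e-8
    term[tiny] <- S[tiny] * exp(-m * S[tiny]) * (1 + DS[tiny] / 2)
    if (any(!tiny)) {
      KS <- matrix(kep, nv, nt) * S
      term[!tiny] <- exp(-KS[!tiny]) * expm1(DS[!tiny]) / D[!tiny]
    }
    ct <- ct + aif$a[i] * term
  }
  ct * kt
}

#' Fit a bi-exponential AIF to artery concentration curves
#'
#' Averages the supplied artery-voxel curves, estimates the arrival time as
#' the first sample exceeding 10% of the curve maximum, then least-squares
#' fits the bi-exponential decay for t >= t_arrival (log-parameterized,
#' multi-start Nelder-Mead + BFGS polish). Terms are ordered m1 > m2
#' (fast/slow) afterwards.
#'
#' @param artery_curves numeric vector (one curve) or matrix with one row per
#'   artery voxel, columns = frames (mM).
#' @param times_s frame times (s).
#' @return fitted `aif_model` with attributes `rss` and `n_fit`.
#' @export
fit_aif <- function(artery_curves, times_s) {
  cbar <- if (is.matrix(artery_curves)) colMeans(artery_curves) else as.numeric(artery_curves)
  if (length(cbar) != length(times_s)) stop("curves and times_s lengths differ")
  if (all(cbar == 0)) stop("all-zero artery curve; cannot fit AIF")
  cmax <- max(cbar)
  t0 <- times_s[which(cbar >= 0.1 * cmax)[1]]
  sel <- times_s >= t0
  tt <- times_s[sel] - t0
  y <- cbar[sel]
  obj <- function(p) {
    a1 <- exp(p[1]); m1 <- exp(p[2]); a2 <- exp(p[3]); m2 <- exp(p[4])
    sum((y - a1 * exp(-m1 * tt) - a2 * exp(-m2 * tt))^2)
  }
  starts <- list(
    log(c(0.7 * cmax, 0.02, 0.3 * cmax, 0.002)),
    log(c(cmax, 0.01, 0.1 * cmax, 0.001)),
    log(c(0.5 * cmax, 0.05, 0.5 * cmax, 0.005)))
  best <- NULL
  for (p0 in starts) {
    f1 <- try(stats::optim(p0, obj, method = "Nelder-Mead",
                           control = list(maxit = 2000, reltol = 1e-14)), silent = TRUE)
    if (inherits(f1, "try-error")) next
    f2 <- try(stats::optim(f1$par, obj, method = "BFGS",
                           control = list(maxit = 500, reltol = 1e-14)), silent = TRUE)
    f <- if (!inherits(f2, "try-error") && f2$value <= f1$value) f2 else f1
    if (is.null(best) || f$value < best$value) best <- f
  }
  if (is.null(best))
    stop("AIF fit failed to converge from all starts (n = ", length(y),
         " samples, max = ", signif(cmax, 4), " mM)")
  p <- exp(best$par)
  if (p[2] < p[4]) p <- p[c(3, 4, 1, 2)]   # enforce m1 > m2
  out <- aif_model(p[1], p[2], p[3], p[4], t_arrival = t0)
  attr(out, "rss") <- best$value
  attr(out, "n_fit") <- length(y)
  out
}

#' Fit the standard Tofts model to one concentration curve
#'
#' Bounded nonlinear least squares on (ktrans, kep), bounds [0, 1] 1/s,
#' multi-start from (1e-4, 1e-3), (1e-3, 1e-2) and (1e-2, 1e-1) 1/s, with
#' analytic gradients. Ties are broken by lowest rss, then lowest ktrans.
#' Never raises per voxel: non-convergent voxels return the best
#' bound-saturated solution and are handled downstream by the enhancement
#' gate.
#'
#' @param conc concentration curve (mM); NA frames are dropped.
#' @param aif fitted `aif_model` on the same clock.
#' @param times_s frame times (s).
#' @return named vector `c(ktrans, kep, rss)`.
#' @export
fit_tofts <- function(conc, aif, times_s) {
  ok <- is.finite(conc)
  y <- conc[ok]
  s <- pmax(times_s[ok] - aif$t_arrival, 0)
  a <- aif$a; m <- aif$m
  obj <- function(p) {
    g <- a[1] * expconv(m[1], p[2], s) + a[2] * expconv(m[2], p[2], s)
    sum((y - p[1] * g)^2)
  }
  grad <- function(p) {
    g <- a[1] * expconv(m[1], p[2], s) + a[2] * expconv(m[2], p[2], s)
    gp <- a[1] * expconv_grad(m[1], p[2], s) + a[2] * expconv_grad(m[2], p[2], s)
    r <- y - p[1] * g
    c(-2 * sum(r * g), -2 * p[1] * sum(r * gp))
  }
  starts <- list(c(1e-4, 1e-3), c(1e-3, 1e-2), c(1e-2, 1e-1))
  best <- NULL
  for (p0 in starts) {
    f <- try(stats::optim(p0, obj, gr = grad, method = "L-BFGS-B",
                          lower = c(0, 0), upper = c(1, 1),
                          control = list(factr = 1e4, maxit = 200)),
             silent = TRUE)
    if (inherits(f, "try-error")) next
    if (is.null(best) || f$value < best$value - 1e-15 ||
        (abs(f$value - best$value) <= 1e-15 && f$par[1] < best$par[1]))
      best <- f
  }
  if (is.null(best)) return(c(ktrans = 0, kep = 0, rss = sum(y^2)))
  c(ktrans = best$par[1], kep = best$par[2], rss = best$value)
}

#' Fit Tofts parameter maps over a set of voxels
#'
#' @param conc_mat matrix, one row per voxel, columns = frames (mM).
#' @param aif fitted `aif_model`.
#' @param times_s frame times (s).
#' @return list of numeric vectors `ktrans`, `kep`, `rss` (one per row).
#' @export
fit_tofts_map <- function(conc_mat, aif, times_s) {
  nv <- nrow(conc_mat)
  kt <- numeric(nv); ke <- numeric(nv); rss <- numeric(nv)
  for (v in seq_len(nv)) {
    r <- fit_tofts(conc_mat[v, ], aif, times_s)
    kt[v] <- r[1]; ke[v] <- r[2]; rss[v] <- r[3]
  }
  list(ktrans = kt, kep = ke, rss = rss)
}

#' Zero non-enhancing voxels in the PK maps
#'
#' The standard Tofts model fits poorly in voxels with no or very little
#' contrast accumulation, producing non-physiological values; such voxels are
#' set to Ktrans = kep = 0. A voxel is gated when its (unnormalized) Smax is
#' below `threshold_frac` times the robust in-mask maximum (98th percentile).
#'
#' @param maps list with `ktrans` and `kep` 3D arrays (e.g. assembled from
#'   [fit_tofts_map()]).
#' @param smax_map unnormalized Smax `vol3d` (or array) on the same grid.
#' @param mask logical array over which the robust maximum is taken.
#' @param threshold_frac gate fraction in (0, 1); default 0.08, placing the
#'   gate well above the noise floor of a maximum taken over 96 frames.
#' @return `maps` with gated voxels zeroed and a logical `gated` array added.
#' @export
apply_enhancement_gate <- function(maps, smax_map, mask, threshold_frac = 0.08) {
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("threshold_frac must be in (0, 1)")
  smax <- if (inherits(smax_map, "vol3d")) smax_map$data else smax_map
  vals <- smax[mask]
  robust_max <- stats::quantile(vals[is.finite(vals)], 0.98, names = FALSE)
  thr <- threshold_frac * robust_max
  gated <- mask & is.finite(smax) & smax < thr
  maps$ktrans[gated] <- 0
  maps$kep[gated] <- 0
  maps$gated <- gated
  attr(maps, "gate_threshold") <- thr
  maps
}
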