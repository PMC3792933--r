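#' 3D image volume with a world affine
#'
#' Lightweight container pairing a numeric (or logical) 3D array with a 4x4
#' voxel-to-world affine (RAS millimetres, 0-based voxel indices), the minimal
#' geometry needed for multimodal resampling and registration.
#'
#' @param data 3D array.
#' @param affine 4x4 numeric voxel-to-world matrix; last row must be (0,0,0,1).
#' @return An object of class `vol3d` with fields `data` and `affine`.
#' @export
vol3d <- function(data, affine = diag(4)) {
  stopifnot(length(dim(data)) == 3L)
  affine <- as_affine4(affine)
  structure(list(data = data, affine = affine), class = "vol3d")
}

#' 4D image series with an explicit time vector
#'
#' @param data 4D array (x, y, z, t).
#' @param affine 4x4 voxel-to-world matrix of the spatial grid.
#' @param times_s numeric vector of frame times in seconds, strictly
#'   increasing, one per 4th-dimension slab. Non-uniform spacing (e.g. an
#'   inter-acquisition gap) is carried explicitly.
#' @return An object of class `vol4d`.
#' @export
vol4d <- function(data, affine = diag(4), times_s) {
  stopifnot(length(dim(data)) == 4L, length(times_s) == dim(data)[4])
  if (any(diff(times_s) <= 0)) stop("times_s must be strictly increasing")
  affine <- as_affine4(affine)
  structure(list(data = data, affine = affine, times_s = as.numeric(times_s)),
            class = "vol4d")
}

as_affine4 <- function(affine) {
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("affine last row must be (0, 0, 0, 1)")
  storage.mode(affine) <- "double"
  affine
}

#' Build an axis-aligned voxel-to-world affine
#'
#' @param spacing_mm voxel size per axis (mm).
#' @param origin_mm world coordinate of voxel (0,0,0); default zero.
#' @return 4x4 affine matrix.
#' @export
grid_affine <- function(spacing_mm, origin_mm = c(0, 0, 0)) {
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0))
  a <- diag(4)
  diag(a)[1:3] <- spacing_mm
  a[1:3, 4] <- origin_mm
  a
}

#' @export
print.vol3d <- function(x, ...) {
  cat("vol3d:", paste(dim(x$data), collapse = " x "),
      "voxels, spacing", paste(signif(affine_spacing(x$affine), 4), collapse = "/"),
      "mm\n")
  invisible(x)
}

#' @export
print.vol4d <- function(x, ...) {
  d <- dim(x$data)
  cat("vol4d:", paste(d[1:3], collapse = " x "), "voxels,", d[4], "frames,",
      "t =", signif(x$times_s[1], 4), "...", signif(x$times_s[d[4]], 4), "s\n")
  invisible(x)
}

affine_spacing <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# world coordinates (n x 3) of 0-based voxel indices (n x 3)
index_to_world <- function(idx, affine) {
  idx <- cbind(idx, 1)
  t(affine %*% t(idx))[, 1:3, drop = FALSE]
}

world_to_index <- function(pts, affine) {
  inv <- solve(affine)
  pts <- cbind(pts, 1)
  t(inv %*% t(pts))[, 1:3, drop = FALSE]
}

# 0-based voxel index grid (n x 3) for a dim vector, column-major order
all_voxel_indices <- function(dm) {
  cbind(
    rep(seq_len(dm[1]) - 1L, times = dm[2] * dm[3]),
    rep(rep(seq_len(dm[2]) - 1L, each = dm[1]), times = dm[3]),
    rep(seq_len(dm[3]) - 1L, each = dm[1] * dm[2])
  )
}

#' World coordinates of every voxel centre
#' @param vol a `vol3d`.
#' @return n x 3 matrix of millimetre coordinates, column-major voxel order.
#' @export
voxel_centers_world <- function(vol) {
  index_to_world(all_voxel_indices(dim(vol$data)), vol$affine)
}

# Trilinear sampling of `vol` at world points (n x 3).
# A sample is NA when outside the grid or when any of the 8 contributing
# neighbours is NA (undefined voxels propagate).
sample_trilinear <- function(vol, pts_world) {
  dm <- dim(vol$data)
  ijk <- world_to_index(pts_world, vol$affine)
  i0 <- floor(ijk)
  f <- ijk - i0
  out <- rep(NA_real_, nrow(ijk))
  inside <- i0[, 1] >= 0 & i0[, 2] >= 0 & i0[, 3] >= 0 &
    i0[, 1] <= dm[1] - 2 & i0[, 2] <= dm[2] - 2 & i0[, 3] <= dm[3] - 2
  # points landing exactly on the far face
  hi <- abs(ijk[, 1] - (dm[1] - 1)) < 1e-9 | abs(ijk[, 2] - (dm[2] - 1)) < 1e-9 |
    abs(ijk[, 3] - (dm[3] - 1)) < 1e-9
  on_grid <- ijk[, 1] >= -1e-9 & ijk[, 2] >= -1e-9 & ijk[, 3] >= -1e-9 &
    ijk[, 1] <= dm[1] - 1 + 1e-9 & ijk[, 2] <= dm[2] - 1 + 1e-9 &
    ijk[, 3] <= dm[3] - 1 + 1e-9
  sel <- which((inside | (hi & on_grid)))
  if (!length(sel)) return(out)
  i0s <- pmin(pmax(i0[sel, , drop = FALSE], 0), rep(dm - 2L, each = length(sel)))
  fs <- ijk[sel, , drop = FALSE] - i0s
  arr <- vol$data
  val <- function(di, dj, dk) {
    arr[cbind(i0s[, 1] + 1L + di, i0s[, 2] + 1L + dj, i0s[, 3] + 1L + dk)]
  }
  wx0 <- 1 - fs[, 1]; wx1 <- fs[, 1]
  wy0 <- 1 - fs[, 2]; wy1 <- fs[, 2]
  wz0 <- 1 - fs[, 3]; wz1 <- fs[, 3]
  out[sel] <-
    val(0L, 0L, 0L) * wx0 * wy0 * wz0 + val(1L, 0L, 0L) * wx1 * wy0 * wz0 +
    val(0L, 1L, 0L) * wx0 * wy1 * wz0 + val(1L, 1L, 0L) * wx1 * wy1 * wz0 +
    val(0L, 0L, 1L) * wx0 * wy0 * wz1 + val(1L, 0L, 1L) * wx1 * wy0 * wz1 +
    val(0L, 1L, 1L) * wx0 * wy1 * wz1 + val(1L, 1L, 1L) * wx1 * wy1 * wz1
  out
}

# Nearest-neighbour sampling; NA outside the grid.
sample_nearest <- function(vol, pts_world) {
  dm <- dim(vol$data)
  ijk <- round(world_to_index(pts_world, vol$affine))
  out <- rep(NA_real_, nrow(ijk))
  ok <- ijk[, 1] >= 0 & ijk[, 2] >= 0 & ijk[, 3] >= 0 &
    ijk[, 1] <= dm[1] - 1 & ijk[, 2] <= dm[2] - 1 & ijk[, 3] <= dm[3] - 1
  sel <- which(ok)
  if (length(sel))
    out[sel] <- vol$data[cbind(ijk[sel, 1] + 1L, ijk[sel, 2] + 1L, ijk[sel, 3] + 1L)]
  out
}

# Separable Gaussian smoothing with replicate padding; sigma in voxels per axis.
gaussian_smooth3d <- function(arr, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  dm <- dim(arr)
  smooth_along <- function(a, axis, sigma) {
    if (sigma <= 0) return(a)
    r <- max(1L, ceiling(3 * sigma))
    k <- exp(-0.5 * ((-r:r) / sigma)^2)
    k <- k / sum(k)
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    dmp <- dim(ap)
    m <- matrix(ap, nrow = dmp[1])
    n <- nrow(m)
    mp <- m[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + n - 1), , drop = FALSE]
    ap <- array(out, dmp)
    aperm(ap, order(perm))
  }
  for (ax in 1:3) arr <- smooth_along(arr, ax, sigma_vox[ax])
  arr
}

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
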