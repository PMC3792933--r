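#' Mask-based rigid + affine registration
#'
#' The study design registers binary tumor masks (delineated on an anatomical
#' MRI sequence and on CT) rather than image intensities, so registration is
#' implemented as a two-stage scheme on the masks themselves: a rigid
#' initialization from mask moments (centroid + principal axes, with axis
#' signs disambiguated by third-moment skewness), followed by a full 12-dof
#' affine refinement that maximizes soft Dice overlap with a derivative-free
#' local optimizer. Everything operates in world (mm) coordinates via the
#' NIfTI affines.
#'
#' @name registration
NULL

#' Affine (or rigid) world-coordinate transform
#'
#' Maps moving-frame world coordinates x to fixed-frame coordinates
#' `matrix %*% x + translation`.
#'
#' @param matrix 3x3 linear part; for `kind = "rigid"` it must be a proper
#'   rotation (orthogonal, det +1), for `"affine"` merely invertible.
#' @param translation length-3 vector (mm).
#' @param kind "rigid" or "affine".
#' @return object of class `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0),
                             kind = c("affine", "rigid")) {
  kind <- match.arg(kind)
  matrix <- as.matrix(matrix)
  stopifnot(all(dim(matrix) == c(3, 3)), length(translation) == 3)
  if (kind == "rigid") {
    if (max(abs(crossprod(matrix) - diag(3))) > 1e-6 || det(matrix) < 0)
      stop("rigid transform requires an orthogonal matrix with det +1")
  } else if (abs(det(matrix)) < 1e-12) {
    stop("affine transform matrix is singular")
  }
  structure(list(matrix = matrix, translation = as.numeric(translation),
                 kind = kind), class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(x$kind, "transform, translation",
      paste(signif(x$translation, 4), collapse = "/"), "mm\n")
  print(signif(x$matrix, 5))
  invisible(x)
}

#' Apply a transform to world points
#' @param transform an `affine_transform`.
#' @param pts n x 3 matrix of world coordinates.
#' @return n x 3 matrix of mapped coordinates.
#' @export
apply_transform <- function(transform, pts) {
  pts <- matrix(pts, ncol = 3)
  sweep(pts %*% t(transform$matrix), 2, -transform$translation)
}

#' Invert a transform
#' @param transform an `affine_transform`.
#' @return the inverse `affine_transform`.
#' @export
invert_transform <- function(transform) {
  mi <- solve(transform$matrix)
  affine_transform(mi, -mi %*% transform$translation, kind = transform$kind)
}

#' Compose transforms (apply `first`, then `second`)
#' @param second,first `affine_transform` objects.
#' @return composed `affine_transform` (rigid only if both are rigid).
#' @export
compose_transform <- function(second, first) {
  kind <- if (second$kind == "rigid" && first$kind == "rigid") "rigid" else "affine"
  affine_transform(second$matrix %*% first$matrix,
                   second$matrix %*% first$translation + second$translation,
                   kind = kind)
}

#' Serialize a transform to a 4x4 homogeneous matrix
#' @param transform an `affine_transform`.
#' @return 4x4 numeric matrix (RAS mm convention).
#' @export
transform_matrix4 <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$matrix
  m[1:3, 4] <- transform$translation
  m
}

mask_points_world <- function(mask_vol) {
  idx <- which(mask_vol$data != 0)
  if (!length(idx)) return(NULL)
  dm <- dim(mask_vol$data)
  ijk <- cbind((idx - 1L) %% dm[1],
               ((idx - 1L) %/% dm[1]) %% dm[2],
               (idx - 1L) %/% (dm[1] * dm[2]))
  index_to_world(ijk, mask_vol$affine)
}

moments_frame <- function(pts) {
  ctr <- colMeans(pts)
  pc <- sweep(pts, 2, ctr)
  cv <- crossprod(pc) / nrow(pc)
  eg <- eigen(cv, symmetric = TRUE)
  skew <- vapply(1:3, function(i) mean((pc %*% eg$vectors[, i])^3), numeric(1))
  list(center = ctr, values = eg$values, vectors = eg$vectors, skew = skew)
}

soft_dice <- function(transform, moving_vol, fixed_vol, fixed_pts, fixed_vals) {
  src <- apply_transform(invert_transform(transform), fixed_pts)
  w <- sample_trilinear(moving_vol, src)
  w[is.na(w)] <- 0
  denom <- sum(w) + sum(fixed_vals)
  if (denom == 0) return(0)
  2 * sum(w * fixed_vals) / denom
}

#' Register a moving binary mask to a fixed binary mask
#'
#' Stage 1 aligns centroids and principal axes (second-moment eigenvectors;
#' eigenvector signs are matched by the sign of the third central moment along
#' each axis, and a remaining improper rotation is repaired by flipping the
#' axis with the weakest skewness evidence). Stage 2 refines all 12 affine
#' parameters by maximizing soft Dice overlap (trilinearly interpolated
#' moving mask against the fixed mask) with Nelder-Mead. Degenerate masks
#' whose points are coplanar fall back to a centroid-only translation with a
#' warning.
#'
#' @param moving_mask,fixed_mask `vol3d` objects with logical/0-1 data.
#' @param refine if FALSE, return the stage-1 rigid transform only.
#' @return an `affine_transform` (moving world -> fixed world) with
#'   attributes `dice` (final binary Dice on the fixed grid) and
#'   `rigid_init` (the stage-1 transform).
#' @export
register_masks <- function(moving_mask, fixed_mask, refine = TRUE) {
  pm <- mask_points_world(moving_mask)
  pf <- mask_points_world(fixed_mask)
  if (is.null(pm) || is.null(pf)) stop("register_masks: empty mask")
  mm <- moments_frame(pm)
  mf <- moments_frame(pf)
  degenerate <- min(mm$values) < 1e-9 || min(mf$values) < 1e-9
  if (degenerate) {
    warning("degenerate (coplanar) mask; falling back to centroid translation")
    rigid <- affine_transform(diag(3), mf$center - mm$center, kind = "rigid")
  } else {
    signs <- ifelse(sign(mm$skew * mf$skew) < 0, -1, 1)
    r <- mf$vectors %*% diag(signs) %*% t(mm$vectors)
    if (det(r) < 0) {
      i <- which.min(abs(mm$skew * mf$skew))
      signs[i] <- -signs[i]
      r <- mf$vectors %*% diag(signs) %*% t(mm$vectors)
    }
    rigid <- affine_transform(r, mf$center - as.numeric(r %*% mm$center),
                              kind = "rigid")
  }
  if (!refine) return(rigid)

  mov_num <- vol3d(array(as.numeric(moving_mask$data != 0), dim(moving_mask$data)),
                   moving_mask$affine)
  # evaluate overlap only inside the fixed-mask bounding box (plus margin):
  # everything outside contributes zeros to both masks
  fdim <- dim(fixed_mask$data)
  fidx <- which(fixed_mask$data != 0)
  fijk <- cbind((fidx - 1L) %% fdim[1],
                ((fidx - 1L) %/% fdim[1]) %% fdim[2],
                (fidx - 1L) %/% (fdim[1] * fdim[2]))
  marg <- 5L
  rng <- lapply(1:3, function(a)
    max(0L, min(fijk[, a]) - marg):min(fdim[a] - 1L, max(fijk[, a]) + marg))
  box <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  fixed_pts <- index_to_world(box, fixed_mask$affine)
  fixed_vals <- as.numeric(fixed_mask$data[box + 1L] != 0)
  par0 <- c(as.numeric(rigid$matrix), rigid$translation)
  negdice <- function(p) {
    tr <- affine_transform(matrix(p[1:9], 3, 3), p[10:12])
    -soft_dice(tr, mov_num, fixed_mask, fixed_pts, fixed_vals)
  }
  vox <- mean(affine_spacing(fixed_mask$affine))
  ctrl <- list(maxit = 800, reltol = 1e-9,
               parscale = c(rep(0.05, 9), rep(0.5 * vox, 3)))
  opt <- stats::optim(par0, negdice, method = "Nelder-Mead", control = ctrl)
  opt2 <- stats::optim(opt$par, negdice, method = "Nelder-Mead", control = ctrl)
  if (opt2$value < opt$value) opt <- opt2
  final <- if (opt$value <= negdice(par0) + 1e-12)
    affine_transform(matrix(opt$par[1:9], 3, 3), opt$par[10:12])
  else rigid
  # binary Dice on the fixed grid for reporting
  src <- apply_transform(invert_transform(final), fixed_pts)
  w <- sample_trilinear(mov_num, src)
  w <- !is.na(w) & w >= 0.5
  f <- fixed_vals > 0
  attr(final, "dice") <- 2 * sum(w & f) / (sum(w) + sum(f))
  attr(final, "rigid_init") <- rigid
  final
}

#' Resample a map through a transform onto a reference grid
#'
#' The output value at each reference-grid voxel centre y is the source map
#' sampled at `transform^-1(y)`: trilinear interpolation for continuous maps
#' ("linear"), nearest neighbour for masks and flags ("nearest"). Points
#' mapping outside the source grid are NA, and (for trilinear) a sample is NA
#' unless all contributing neighbours are defined, so gated/flagged source
#' voxels propagate as undefined.
#'
#' @param map source `vol3d`.
#' @param transform `affine_transform` mapping source world to reference world.
#' @param reference `vol3d` (its data are ignored) or list with `dim` and
#'   `affine` describing the output grid.
#' @param method "linear" or "nearest".
#' @return `vol3d` on the reference grid.
#' @export
resample_map <- function(map, transform, reference, method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (abs(det(transform$matrix)) < 1e-12) stop("singular transform")
  ref_dim <- if (inherits(reference, "vol3d")) dim(reference$data) else reference$dim
  ref_aff <- if (inherits(reference, "vol3d")) reference$affine else reference$affine
  pts <- index_to_world(all_voxel_indices(ref_dim), ref_aff)
  src <- apply_transform(invert_transform(transform), pts)
  vals <- if (method == "linear") sample_trilinear(map, src) else sample_nearest(map, src)
  vol3d(array(vals, ref_dim), ref_aff)
}

#' Binary Dice coefficient of two same-grid masks
#' @param a,b logical/0-1 arrays or `vol3d`.
#' @return Dice overlap in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  a <- if (inherits(a, "vol3d")) a$data != 0 else a != 0
  b <- if (inherits(b, "vol3d")) b$data != 0 else b != 0
  2 * sum(a & b) / (sum(a) + sum(b))
}
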