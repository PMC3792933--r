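#' Minimal NIfTI-1 I/O
#'
#' Reads and writes single-file NIfTI-1 volumes (`.nii` or `.nii.gz`),
#' supporting 3D/4D float32, float64 and uint8 data with the full voxel-to-world
#' affine carried in the sform rows. This covers exactly what the pipeline
#' emits (parameter maps, masks, DCE series); it is not a general NIfTI
#' implementation (no qform quaternions, extensions, or scl slopes != 1).
#'
#' @param vol a `vol3d`/`vol4d`, or a plain 3D/4D array (identity affine).
#' @param path output path; gzip-compressed when it ends in `.gz`.
#' @param datatype one of "float32", "float64", "uint8".
#' @return `write_nifti` returns `path` invisibly; `read_nifti` returns a
#'   `vol3d` or `vol4d` (a 4D volume gets a uniform `times_s` from `pixdim[5]`;
#'   the pipeline's JSON sidecar supplies the true, possibly non-uniform,
#'   vector).
#' @export
write_nifti <- function(vol, path, datatype = "float32") {
  if (is.array(vol) && is.null(attr(vol, "class")))
    vol <- if (length(dim(vol)) == 4L) vol4d(vol, diag(4), seq_len(dim(vol)[4]))
           else vol3d(vol)
  data <- vol$data
  if (is.logical(data)) { data <- array(as.numeric(data), dim(data)); datatype <- "uint8" }
  affine <- vol$affine
  nd <- length(dim(data))
  stopifnot(nd %in% c(3L, 4L))
  dt <- switch(datatype,
    uint8   = list(code = 2L,  bitpix = 8L,  size = 1L),
    float32 = list(code = 16L, bitpix = 32L, size = 4L),
    float64 = list(code = 64L, bitpix = 64L, size = 8L),
    stop("unsupported datatype: ", datatype))

  hdr <- raw(348)
  poke_i <- function(off, x, size) {
    b <- writeBin(as.integer(x), raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <<- b
  }
  poke_f <- function(off, x) {
    b <- writeBin(as.numeric(x), raw(), size = 4, endian = "little")
    hdr[(off + 1):(off + length(b))] <<- b
  }
  dimv <- c(nd, dim(data), rep(1L, 7 - nd))
  spacing <- affine_spacing(affine)
  dt5 <- if (nd == 4L && length(vol$times_s) > 1) vol$times_s[2] - vol$times_s[1] else 0
  poke_i(0, 348L, 4)                             # sizeof_hdr
  poke_i(40, dimv, 2)                            # dim[8]
  poke_i(70, dt$code, 2)                         # datatype
  poke_i(72, dt$bitpix, 2)                       # bitpix
  poke_f(76, c(1, spacing, dt5, 0, 0, 0))        # pixdim (qfac = 1)
  poke_f(108, 352)                               # vox_offset
  poke_f(112, 1); poke_f(116, 0)                 # scl_slope, scl_inter
  poke_i(252, 0L, 2)                             # qform_code = 0
  poke_i(254, 2L, 2)                             # sform_code = 2 (aligned)
  poke_f(280, affine[1, ]); poke_f(296, affine[2, ]); poke_f(312, affine[3, ])
  magic <- c(charToRaw("n+1"), as.raw(0))
  hdr[345:348] <- magic

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4), con)                          # pad to vox_offset 352
  if (dt$code == 2L) {
    writeBin(as.integer(round(data)), con, size = 1, endian = "little")
  } else {
    writeBin(as.numeric(data), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  ri <- function(off, n, size) readBin(hdr[(off + 1):(off + n * size)],
                                       "integer", n = n, size = size,
                                       endian = "little")
  rf <- function(off, n) readBin(hdr[(off + 1):(off + n * 4)], "double",
                                 n = n, size = 4, endian = "little")
  if (ri(0, 1, 4) != 348L) stop("not a little-endian NIfTI-1 file: ", path)
  dimv <- ri(40, 8, 2)
  nd <- dimv[1]
  if (!nd %in% c(3L, 4L)) stop("only 3D/4D NIfTI supported, got dim[0] = ", nd)
  dm <- dimv[2:(1 + nd)]
  datatype <- ri(70, 1, 2)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108, 1)
  srow <- rbind(rf(280, 4), rf(296, 4), rf(312, 4))
  affine <- rbind(srow, c(0, 0, 0, 1))
  if (all(abs(affine[1:3, 1:3]) < 1e-12))
    affine <- grid_affine(pmax(pixdim[2:4], 1e-6))
  n <- prod(dm)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  data <- switch(as.character(datatype),
    `2`  = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
    `16` = readBin(con, "double", n = n, size = 4, endian = "little"),
    `64` = readBin(con, "double", n = n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype code: ", datatype))
  if (length(data) != n) stop("truncated NIfTI data in ", path)
  data <- array(data, dm)
  if (nd == 4L)
    vol4d(data, affine, times_s = (seq_len(dm[4]) - 1) * max(pixdim[5], 1))
  else vol3d(data, affine)
}
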