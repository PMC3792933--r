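#' Synthetic DCE-MRI + SPECT study generator
#'
#' Generates complete synthetic studies (ground truth plus all acquired
#' volumes) with the statistical structure the correlation analysis assumes:
#' a heterogeneous tumor with smooth Ktrans and ve fields and a contiguous
#' low-enhancement pocket, feeding-vessel voxels (high perfusion, no receptor
#' uptake), a bi-exponential plasma input sampled by a 96-frame dynamic series
#' acquired in two blocks separated by a 60 s gap, variable-TR T1 calibration
#' volumes, and a SPECT uptake map generated from a delivery surrogate through
#' receptor saturation, resolution blur ("blooming"), counting noise,
#' downsampling and a known rigid displacement between the MRI and SPECT
#' frames.
#'
#' @name phantom
NULL

#' Phantom configuration
#'
#' Defaults mirror the emulated acquisition: 96 dynamic frames at 4.3 s in two
#' equal blocks with a 60 s gap after frame 48, T1 calibration at
#' TR = 200/400/800/1200/2400 ms, a 10-degree flip, 3.4 ms TR dynamic
#' sequence, and gadobutrol-class relaxivity 4.5 /mM/s. The working grid
#' (32 x 32 x 16 voxels at 0.4 mm) is a deliberate computational scale-down of
#' the acquisition grid; the SPECT grid is coarser by `spect_downsample` per
#' axis with a 1.5 mm FWHM blur.
#'
#' @param grid_shape voxels per axis (each >= 10, needed to place the pocket).
#' @param voxel_size_mm voxel size per axis (mm), > 0.
#' @param n_frames dynamic frame count (>= 2).
#' @param frame_interval_s dynamic temporal resolution (s).
#' @param gap_after_frame frame index after which the inter-acquisition gap
#'   falls (two equal blocks by default).
#' @param gap_s gap duration (s).
#' @param t1_trs_ms calibration repetition times (ms).
#' @param flip_angle_deg dynamic flip angle (degrees).
#' @param tr_dce_ms dynamic repetition time (ms).
#' @param r1_relaxivity contrast relaxivity (/mM/s).
#' @param noise_sd additive Gaussian signal noise SD (signal units; the
#'   in-vivo SNR of the dynamic series is not known, so this is a free,
#'   documented choice: the default gives baseline SNR of roughly 25).
#' @param s_scale equilibrium signal scale.
#' @param arrival_s contrast arrival time after series start (s).
#' @param aif true plasma-input parameters (a1, m1, a2, m2; mM and 1/s).
#' @param ktrans_range Ktrans field range inside the tumor (1/s).
#' @param ve_range ve field range, inside (0, 1).
#' @param t10_tumor_ms tumor T10 field range (ms).
#' @param t10_background_ms,t10_artery_ms background / artery T10 (ms).
#' @param septa_frac fraction of tumor voxels assigned to receptor-free,
#'   well-vascularized connective-tissue septa (high ve, no uptake; such
#'   high-enhancement / no-uptake regions are part of the analyzed volume).
#' @param field_smooth_vox Gaussian smoothing (voxels) of the ground-truth
#'   fields: smoothed white noise is the simplest field with tunable spatial
#'   correlation.
#' @param umax_kbq receptor-saturated uptake ceiling (kBq/voxel).
#' @param d50_mm_s half-saturation delivery (mM s); injected peptide mass
#'   partly saturates the receptors, so the default sits below the median
#'   tumor delivery.
#' @param spect_fwhm_mm SPECT blur FWHM (mm).
#' @param spect_downsample SPECT grid coarsening factor per axis.
#' @param count_scale counts per kBq for Poisson counting noise.
#' @param spect_rotation_deg,spect_translation_mm the applied rigid
#'   displacement between MRI and SPECT frames (rotation about z).
#' @param seed integer RNG seed.
#' @return validated list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(32, 32, 16),
                           voxel_size_mm = c(0.4, 0.4, 0.4),
                           n_frames = 96L,
                           frame_interval_s = 4.3,
                           gap_after_frame = 48L,
                           gap_s = 60,
                           t1_trs_ms = c(200, 400, 800, 1200, 2400),
                           flip_angle_deg = 10,
                           tr_dce_ms = 3.4,
                           r1_relaxivity = 4.5,
                           noise_sd = 1,
                           s_scale = 1000,
                           arrival_s = 30,
                           aif = c(a1 = 3, m1 = 0.01, a2 = 1, m2 = 0.001),
                           ktrans_range = c(0.002, 0.02),
                           ve_range = c(0.15, 0.65),
                           t10_tumor_ms = c(1200, 1800),
                           t10_background_ms = 900,
                           t10_artery_ms = 1400,
                           field_smooth_vox = 4,
                           septa_frac = 0.08,
                           umax_kbq = 30,
                           d50_mm_s = 45,
                           spect_fwhm_mm = 1.5,
                           spect_downsample = 2.5,
                           count_scale = 20,
                           spect_rotation_deg = 3,
                           spect_translation_mm = c(1, -0.5, 0.5),
                           seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_frames < 2L) stop("n_frames must be >= 2")
  if (any(cfg$voxel_size_mm <= 0)) stop("voxel sizes must be > 0")
  if (cfg$gap_after_frame < 1L || cfg$gap_after_frame >= cfg$n_frames)
    stop("gap_after_frame must fall inside the series")
  if (cfg$d50_mm_s <= 0) stop("d50_mm_s must be > 0")
  if (any(diff(dce_times(cfg)) <= 0)) stop("times must be strictly increasing")
  class(cfg) <- "phantom_config"
  cfg
}

#' Dynamic-series time vector (seconds)
#'
#' Frame i (1-based) sits at (i-1) * frame_interval_s, shifted by `gap_s` for
#' frames after `gap_after_frame`, so with defaults
#' t[49] - t[48] = 60 + 4.3 s.
#'
#' @param config a `phantom_config`.
#' @return numeric vector of length `n_frames`.
#' @export
dce_times <- function(config) {
  t <- (seq_len(config$n_frames) - 1) * config$frame_interval_s
  late <- seq_len(config$n_frames) > config$gap_after_frame
  t[late] <- t[late] + config$gap_s
  t
}

# scale a field linearly so that its in-mask range maps onto [lo, hi]
rescale_field <- function(field, mask, lo, hi) {
  v <- field[mask]
  out <- (field - min(v)) / (max(v) - min(v)) * (hi - lo) + lo
  out
}

smooth_noise_field <- function(dm, sigma_vox) {
  gaussian_smooth3d(array(stats::rnorm(prod(dm)), dm), sigma_vox)
}

#' Generate ground-truth parameter fields and masks
#'
#' Smooth (correlated-noise) Ktrans and ve fields inside an egg-shaped
#' (lobular) tumor, one contiguous low-enhancement pocket where Ktrans tapers
#' smoothly to exactly zero, receptor-free connective-tissue septa, a thin
#' feeding-vessel rod (high Ktrans, excluded from correlation, no receptor
#' uptake), an artery sphere outside the tumor supplying the AIF, and a
#' smooth T10 field. Deterministic for a fixed seed.
#'
#' @param config a `phantom_config`.
#' @return list of class `ground_truth`: arrays `ktrans_map`, `kep_map`,
#'   `ve_map`, `t10_map`, `receptor_map` (relative receptor density, 0 on
#'   septa and vessels), logical `tumor_mask`, `vessel_mask`, `artery_mask`,
#'   `pocket_mask`, `septa_mask`, and `spect_truth` (NULL until
#'   [simulate_spect()] fills it).
#' @export
generate_parameter_fields <- function(config) {
  dm <- config$grid_shape
  if (min(dm) < 10L)
    stop("grid too small to place a low-enhancement pocket: ",
         "grid_shape must be at least 10 voxels per axis, got ",
         paste(dm, collapse = "x"))
  with_seed(config$seed, {
    ctr <- (dm + 1) / 2
    # egg-shaped lobular tumor with distinct semi-axes: a reflection- or
    # rotation-symmetric mask would leave the principal-axes registration
    # (and its third-moment sign disambiguation) underdetermined
    semi <- c(0.42, 0.33, 0.40) * dm
    ii <- array(rep(seq_len(dm[1]), times = dm[2] * dm[3]), dm)
    jj <- array(rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]), dm)
    kk <- array(rep(seq_len(dm[3]), each = dm[1] * dm[2]), dm)
    u <- (ii - ctr[1]) / semi[1]
    v <- (jj - ctr[2]) / semi[2]
    wk <- (kk - ctr[3]) / semi[3]
    rr2 <- u^2 + (v / (1 + 0.22 * pmin(pmax(u, -1), 1)))^2 +
      (wk / (1 + 0.22 * pmin(pmax(v, -1), 1)))^2
    tumor <- rr2 <= 1

    # contiguous low-enhancement pocket: smooth taper to exactly 0 in its core
    pocket_ctr <- ctr + c(0.45 * semi[1], 0, 0)
    r0 <- max(1.5, 0.35 * min(semi))
    pd <- sqrt((ii - pocket_ctr[1])^2 + (jj - pocket_ctr[2])^2 +
                 (kk - pocket_ctr[3])^2)
    w <- pmin(pmax((pd - r0) / r0, 0), 1)      # 0 inside r0, 1 beyond 2*r0
    w <- w * w * (3 - 2 * w)                   # smoothstep
    pocket <- tumor & (pd <= r0)

    # thin feeding-vessel rod through the tumor, parallel to x
    vy <- round(ctr[2] - 0.5 * semi[2]); vz <- round(ctr[3])
    vessel <- tumor & jj == vy & kk == vz

    # artery sphere near a corner, outside the tumor
    actr <- c(3, 3, round(ctr[3]))
    artery <- sqrt((ii - actr[1])^2 + (jj - actr[2])^2 + (kk - actr[3])^2) <= 1.6
    if (any(artery & tumor)) stop("artery region overlaps tumor; enlarge grid")

    sm <- config$field_smooth_vox
    ktrans <- rescale_field(smooth_noise_field(dm, sm), tumor,
                            config$ktrans_range[1], config$ktrans_range[2])
    ve <- rescale_field(smooth_noise_field(dm, sm), tumor,
                        config$ve_range[1], config$ve_range[2])
    t10 <- rescale_field(smooth_noise_field(dm, sm), tumor,
                         config$t10_tumor_ms[1], config$t10_tumor_ms[2])

    # receptor-free connective-tissue septa: well-vascularized stroma bands
    # inside the analyzed tumor volume (high ve, no somatostatin receptors),
    # the tissue class behind observed high-enhancement / no-uptake regions
    septa_field <- smooth_noise_field(dm, sm)
    septa <- tumor & septa_field >
      stats::quantile(septa_field[tumor], 1 - config$septa_frac)
    if (any(septa))
      ve[septa] <- rescale_field(septa_field, septa, 0.55, 0.7)[septa]

    ktrans <- ktrans * w                       # pocket taper
    ktrans[!tumor] <- 0
    ktrans[vessel] <- 0.03
    ve[vessel] <- 0.9
    t10[!tumor] <- config$t10_background_ms
    t10[artery] <- config$t10_artery_ms
    kep <- array(0, dm)
    act <- tumor | vessel
    kep[act] <- ktrans[act] / ve[act]
    receptor <- array(0, dm)
    receptor[tumor] <- 1                       # homogeneous expression
    receptor[septa] <- 0
    receptor[vessel] <- 0
    structure(list(ktrans_map = ktrans, kep_map = kep, ve_map = ve,
                   t10_map = t10, receptor_map = receptor,
                   tumor_mask = tumor, vessel_mask = vessel,
                   artery_mask = artery, pocket_mask = pocket,
                   septa_mask = septa, spect_truth = NULL),
              class = "ground_truth")
  })
}

#' Simulate the dynamic contrast-enhanced series
#'
#' Per-voxel tissue concentration from the closed-form Tofts forward model
#' (artery voxels carry the plasma input itself), converted to signal with the
#' SPGR equation and the voxel's T10, plus additive Gaussian noise of SD
#' `noise_sd`. Pre-arrival frames have zero concentration by construction.
#'
#' @param truth a `ground_truth`.
#' @param aif an `aif_model` (arrival at `config$arrival_s`).
#' @param config a `phantom_config`.
#' @param noise_sd override for `config$noise_sd` (e.g. 0 for noiseless).
#' @return `vol4d` with the phantom grid affine and the gapped time vector.
#' @export
simulate_dce <- function(truth, aif, config, noise_sd = config$noise_sd) {
  times <- dce_times(config)
  dm <- config$grid_shape
  conc <- conc_series(truth, aif, config, times)
  sig <- array(0, c(dm, length(times)))
  t10v <- as.numeric(truth$t10_map)
  for (f in seq_along(times)) {
    sig[, , , f] <- array(
      concentration_to_signal(conc[, f], t10v, config$r1_relaxivity,
                              config$tr_dce_ms, config$flip_angle_deg,
                              config$s_scale),
      dm)
  }
  if (noise_sd > 0)
    sig <- sig + array(stats::rnorm(length(sig), sd = noise_sd), dim(sig))
  vol4d(sig, grid_affine(config$voxel_size_mm), times)
}

# noiseless concentration (nvox x ntime) for every voxel on the grid
conc_series <- function(truth, aif, config, times) {
  dm <- config$grid_shape
  nv <- prod(dm)
  conc <- matrix(0, nv, length(times))
  act <- which(truth$ktrans_map > 0)
  if (length(act))
    conc[act, ] <- tofts_forward_matrix(truth$ktrans_map[act],
                                        truth$kep_map[act], aif, times)
  art <- which(truth$artery_mask)
  if (length(art))
    conc[art, ] <- matrix(aif_cp(aif, times), length(art), length(times),
                          byrow = TRUE)
  conc
}

#' Simulate the variable-TR T1 calibration volumes
#'
#' Saturation-recovery signal S(TR) = s_scale * (1 - exp(-TR/T10)) per voxel,
#' one volume per TR, plus additive Gaussian noise.
#'
#' @inheritParams simulate_dce
#' @return list with `volumes` (list of 3D arrays) and `trs_ms`.
#' @export
simulate_t1_calibration <- function(truth, config, noise_sd = config$noise_sd) {
  vols <- lapply(config$t1_trs_ms, function(tr) {
    s <- config$s_scale * (1 - exp(-tr / truth$t10_map))
    if (noise_sd > 0) s <- s + array(stats::rnorm(length(s), sd = noise_sd), dim(s))
    s
  })
  list(volumes = vols, trs_ms = config$t1_trs_ms)
}

#' The applied MRI-to-SPECT displacement of a config
#' @param config a `phantom_config`.
#' @return rigid `affine_transform` (rotation about z plus translation).
#' @export
applied_transform <- function(config) {
  th <- config$spect_rotation_deg * pi / 180
  r <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  affine_transform(r, config$spect_translation_mm, kind = "rigid")
}

#' Simulate the SPECT uptake volume
#'
#' Delivery surrogate d = noiseless AUC over the first 60 s of the true tissue
#' concentration (evaluated analytically on a fine grid). Pre-blur uptake
#' follows Michaelis-Menten receptor saturation U = Umax * d / (d + d50),
#' zero outside the tumor and on vessel voxels (connective tissue carries no
#' receptors). The field is then Gaussian-blurred at `spect_fwhm_mm`
#' (blooming), given Poisson counting noise, and resampled onto the coarser
#' SPECT grid whose content is displaced by the applied transform.
#'
#' @inheritParams simulate_dce
#' @param with_noise logical; disable for the noiseless design checks.
#' @param blur_fwhm_mm override of `config$spect_fwhm_mm`.
#' @param transform override of [applied_transform()] (e.g. identity).
#' @return list with `spect` (`vol3d`, kBq/voxel, coarse SPECT grid),
#'   `spect_truth` (`vol3d`, pre-blur noiseless uptake on the MRI grid),
#'   `delivery` (3D array of d), `tumor_mask_fixed`, `vessel_mask_fixed`
#'   (`vol3d` masks in the fixed frame at CT-like resolution) and
#'   `transform`.
#' @export
simulate_spect <- function(truth, aif, config, with_noise = TRUE,
                           blur_fwhm_mm = config$spect_fwhm_mm,
                           transform = applied_transform(config)) {
  if (config$d50_mm_s <= 0) stop("d50_mm_s must be > 0")
  dm <- config$grid_shape
  t0 <- aif$t_arrival
  tfine <- seq(t0, t0 + 60, length.out = 121)
  act <- which(truth$ktrans_map > 0)
  d <- array(0, dm)
  if (length(act)) {
    ct <- tofts_forward_matrix(truth$ktrans_map[act], truth$kep_map[act],
                               aif, tfine)
    dt <- diff(tfine)
    d[act] <- as.numeric((ct[, -ncol(ct), drop = FALSE] +
                            ct[, -1, drop = FALSE]) %*% dt / 2)
  }
  u <- saturation_uptake(d, config$umax_kbq, config$d50_mm_s)
  u <- u * truth$receptor_map                  # receptor-free voxels take up nothing
  u[!truth$tumor_mask] <- 0
  spect_truth <- u

  vox <- config$voxel_size_mm
  if (blur_fwhm_mm > 0)
    u <- gaussian_smooth3d(u, blur_fwhm_mm / 2.3548 / vox)
  if (with_noise) {
    counts <- stats::rpois(length(u), lambda = pmax(u, 0) * config$count_scale)
    u <- array(counts / config$count_scale, dm)
  }

  # acquired SPECT grid: axis-aligned, coarser, covering the displaced MRI
  # volume; the fixed-frame (CT-resolution) grid shares the same world box at
  # MRI-like spacing -- tumors are delineated on CT, and SPECT is resampled
  # to CT resolution for the correlation
  mri_aff <- grid_affine(vox)
  corners <- as.matrix(expand.grid(c(0, dm[1] - 1), c(0, dm[2] - 1),
                                   c(0, dm[3] - 1)))
  wc <- apply_transform(transform, index_to_world(corners, mri_aff))
  lo <- apply(wc, 2, min); hi <- apply(wc, 2, max)
  spacing_s <- vox * config$spect_downsample
  ref_s <- list(dim = pmax(ceiling((hi - lo) / spacing_s) + 1L, 2L),
                affine = grid_affine(spacing_s, lo))
  ref_ct <- list(dim = pmax(ceiling((hi - lo) / vox) + 1L, 2L),
                 affine = grid_affine(vox, lo))

  uvol <- vol3d(u, mri_aff)
  spect <- resample_map(uvol, transform, ref_s, method = "linear")
  spect$data[is.na(spect$data)] <- 0
  tmask <- resample_map(vol3d(array(as.numeric(truth$tumor_mask), dm), mri_aff),
                        transform, ref_ct, method = "nearest")
  vmask <- resample_map(vol3d(array(as.numeric(truth$vessel_mask), dm), mri_aff),
                        transform, ref_ct, method = "nearest")
  tmask$data[is.na(tmask$data)] <- 0
  vmask$data[is.na(vmask$data)] <- 0
  list(spect = spect, spect_truth = vol3d(spect_truth, mri_aff),
       delivery = d, tumor_mask_fixed = tmask, vessel_mask_fixed = vmask,
       transform = transform)
}

#' Michaelis-Menten receptor-saturation uptake
#' @param d delivery surrogate (mM s), >= 0.
#' @param umax uptake ceiling (kBq/voxel).
#' @param d50 half-saturation delivery (mM s), > 0.
#' @return uptake, same shape as `d`; U(d50) = umax/2, U -> umax as d grows.
#' @export
saturation_uptake <- function(d, umax, d50) {
  if (d50 <= 0) stop("d50 must be > 0")
  umax * d / (d + d50)
}

#' Generate a complete synthetic study
#'
#' Runs field generation, the dynamic series, the T1 calibration and the
#' SPECT simulation under one seed; bit-identical for identical config.
#'
#' @param config a `phantom_config`.
#' @param noise logical; FALSE turns off signal, calibration and counting
#'   noise (the applied displacement is kept).
#' @return object of class `synthetic_study`: list with `dce` (`vol4d`),
#'   `t1_calibration`, `spect` (`vol3d`, coarse grid), `tumor_mask_fixed`,
#'   `vessel_mask_fixed` (fixed-frame masks at CT-like resolution),
#'   `applied_transform`, `ground_truth`, `aif` (true input function) and
#'   `config`.
#' @export
simulate_study <- function(config = phantom_config(), noise = TRUE) {
  truth <- generate_parameter_fields(config)
  aif <- aif_model(config$aif[["a1"]], config$aif[["m1"]],
                   config$aif[["a2"]], config$aif[["m2"]],
                   t_arrival = config$arrival_s)
  with_seed(config$seed + 1L, {
    nsd <- if (noise) config$noise_sd else 0
    dce <- simulate_dce(truth, aif, config, noise_sd = nsd)
    calib <- simulate_t1_calibration(truth, config, noise_sd = nsd)
    sp <- simulate_spect(truth, aif, config, with_noise = noise)
    truth$spect_truth <- sp$spect_truth$data
    structure(list(dce = dce, t1_calibration = calib, spect = sp$spect,
                   tumor_mask_fixed = sp$tumor_mask_fixed,
                   vessel_mask_fixed = sp$vessel_mask_fixed,
                   applied_transform = sp$transform,
                   ground_truth = truth, aif = aif, config = config),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study:", paste(x$config$grid_shape, collapse = "x"),
      "grid,", x$config$n_frames, "frames,",
      sum(x$ground_truth$tumor_mask), "tumor voxels\n")
  invisible(x)
}
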