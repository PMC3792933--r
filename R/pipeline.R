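#' Study I/O and end-to-end analysis orchestration
#'
#' A study on disk is a directory of NIfTI volumes plus a JSON sidecar
#' carrying the frame-time vector, the applied transform (phantom only), and
#' a config echo. `run_analyze` executes relaxometry -> semi-quantitative
#' features -> PK modelling -> registration -> correlation and writes every
#' intermediate map, the voxel tables and the report. When no T1 calibration
#' is present the pipeline degrades to semi-quantitative-only mode (those
#' features need no T1 map, which is what makes them clinically attractive)
#' and the report records the omission.
#'
#' @name pipeline
NULL

#' Write a synthetic study to a directory
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly; writes dce.nii.gz, calib_tr*.nii.gz,
#'   spect.nii.gz, masks, ground-truth maps and study.json (+ manifest.json
#'   with a config hash for reproducibility checks).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  gt <- study$ground_truth
  mri_aff <- study$dce$affine
  write_nifti(study$dce, file.path(dir, "dce.nii.gz"))
  for (i in seq_along(study$t1_calibration$trs_ms)) {
    tr <- study$t1_calibration$trs_ms[i]
    write_nifti(vol3d(study$t1_calibration$volumes[[i]], mri_aff),
                file.path(dir, sprintf("calib_tr%04d.nii.gz", tr)))
  }
  write_nifti(study$spect, file.path(dir, "spect.nii.gz"))
  write_nifti(study$tumor_mask_fixed, file.path(dir, "tumor_mask_fixed.nii.gz"),
              datatype = "uint8")
  write_nifti(study$vessel_mask_fixed, file.path(dir, "vessel_mask_fixed.nii.gz"),
              datatype = "uint8")
  for (nm in c("tumor_mask", "vessel_mask", "artery_mask", "pocket_mask",
                "septa_mask"))
    write_nifti(vol3d(array(as.numeric(gt[[nm]]), dim(gt[[nm]])), mri_aff),
                file.path(dir, paste0(nm, ".nii.gz")), datatype = "uint8")
  for (nm in c("ktrans_map", "kep_map", "ve_map", "t10_map", "receptor_map",
                "spect_truth"))
    if (!is.null(gt[[nm]]))
      write_nifti(vol3d(gt[[nm]], mri_aff),
                  file.path(dir, paste0("truth_", nm, ".nii.gz")),
                  datatype = "float64")
  sidecar <- list(
    times_s = study$dce$times_s,
    applied_transform = transform_matrix4(study$applied_transform),
    aif = list(a = study$aif$a, m = study$aif$m,
               t_arrival = study$aif$t_arrival),
    config = unclass(study$config))
  jsonlite::write_json(sidecar, file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_json <- file.path(dir, "config_echo.json")
  jsonlite::write_json(unclass(study$config), cfg_json, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_json)),
                   seed = study$config$seed,
                   n_frames = dim(study$dce$data)[4],
                   written = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir study directory.
#' @return a `synthetic_study`-like list (ground-truth entries present only
#'   if the corresponding files exist; calibration optional).
#' @export
read_study <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "study.json"),
                                 simplifyVector = TRUE)
  dce <- read_nifti(file.path(dir, "dce.nii.gz"))
  dce <- vol4d(dce$data, dce$affine, times_s = sidecar$times_s)
  calib <- NULL
  cfiles <- sort(list.files(dir, pattern = "^calib_tr\\d+\\.nii\\.gz$",
                            full.names = TRUE))
  if (length(cfiles)) {
    trs <- as.numeric(sub(".*calib_tr0*(\\d+)\\.nii\\.gz$", "\\1", cfiles))
    ord <- order(trs)
    calib <- list(volumes = lapply(cfiles[ord], function(f) read_nifti(f)$data),
                  trs_ms = trs[ord])
  }
  read_mask <- function(name) {
    f <- file.path(dir, paste0(name, ".nii.gz"))
    if (!file.exists(f)) return(NULL)
    v <- read_nifti(f)
    vol3d(array(v$data != 0, dim(v$data)), v$affine)
  }
  gt <- list()
  for (nm in c("tumor_mask", "vessel_mask", "artery_mask", "pocket_mask",
               "septa_mask")) {
    m <- read_mask(nm)
    if (!is.null(m)) gt[[nm]] <- m$data
  }
  for (nm in c("ktrans_map", "kep_map", "ve_map", "t10_map", "receptor_map",
               "spect_truth")) {
    f <- file.path(dir, paste0("truth_", nm, ".nii.gz"))
    if (file.exists(f)) gt[[nm]] <- read_nifti(f)$data
  }
  tm4 <- matrix(unlist(sidecar$applied_transform), 4, 4, byrow = TRUE)
  # jsonlite stores row-major lists; detect orientation by the last row
  if (max(abs(tm4[4, ] - c(0, 0, 0, 1))) > 1e-9)
    tm4 <- t(tm4)
  structure(list(
    dce = dce, t1_calibration = calib,
    spect = read_nifti(file.path(dir, "spect.nii.gz")),
    tumor_mask_fixed = read_mask("tumor_mask_fixed"),
    vessel_mask_fixed = read_mask("vessel_mask_fixed"),
    applied_transform = affine_transform(tm4[1:3, 1:3], tm4[1:3, 4]),
    ground_truth = if (length(gt)) gt else NULL,
    aif = if (!is.null(sidecar$aif))
      aif_model(sidecar$aif$a[1], sidecar$aif$m[1], sidecar$aif$a[2],
                sidecar$aif$m[2], sidecar$aif$t_arrival) else NULL,
    config = sidecar$config), class = "synthetic_study")
}

#' Simulate a study and write it to disk
#'
#' @param config a `phantom_config` (or list of overrides passed to
#'   [phantom_config()]).
#' @param out output directory.
#' @param noise logical, passed to [simulate_study()].
#' @return the written directory, invisibly.
#' @export
run_simulate <- function(config = phantom_config(), out, noise = TRUE) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config, config)
  study <- simulate_study(config, noise = noise)
  write_study(study, out)
}

default_baseline_frames <- function(study) {
  cfg <- study$config
  if (!is.null(cfg$arrival_s) && !is.null(study$dce$times_s)) {
    n <- sum(study$dce$times_s < cfg$arrival_s)
    if (n >= 1) return(n)
  }
  5L
}

#' Run the full analysis on one study
#'
#' Stages: (1) T1 mapping from the calibration volumes (skipped, with a
#' recorded omission, if absent); (2) semi-quantitative feature maps on the
#' MRI tumor mask, min-max normalized per dataset; (3) signal-to-concentration
#' conversion, AIF fit from the artery region and per-voxel standard Tofts
#' fit, followed by the low-enhancement zeroing gate; (4) mask-based
#' registration of the MRI tumor mask to the fixed-frame (CT-resolution)
#' tumor mask, resampling of every parameter map onto that grid, and
#' upsampling of the coarse SPECT volume onto it; (5) voxel table
#' (tumor minus vessels) and correlation statistics.
#'
#' @param study a `synthetic_study` (in memory or from [read_study()]).
#' @param baseline_frames pre-contrast frame count; default: frames before
#'   the configured arrival for phantom studies, else 5.
#' @param gate_threshold_frac enhancement-gate fraction (default 0.08).
#' @param r1 relaxivity used in quantification (default from the study config
#'   or 4.5 /mM/s).
#' @param dataset_id label for the voxel table.
#' @param out optional directory; when given, all maps/tables/report files
#'   are written there.
#' @return list of class `study_analysis`: `table` (voxel table),
#'   `maps_mri` (named `vol3d` list on the MRI grid), `maps_spect` (on the
#'   SPECT grid), `transform` (recovered registration), `aif_fit`, `t10`,
#'   `report` (single-dataset correlation report), `mode`
#'   ("full" or "semiquant_only") and `params` (the decision parameters used).
#' @export
run_analyze <- function(study, baseline_frames = NULL,
                        gate_threshold_frac = 0.08, r1 = NULL,
                        dataset_id = "dataset", out = NULL) {
  cfg <- study$config
  if (is.null(baseline_frames)) baseline_frames <- default_baseline_frames(study)
  if (is.null(r1)) r1 <- if (!is.null(cfg$r1_relaxivity)) cfg$r1_relaxivity else 4.5
  dce <- study$dce
  dm <- dim(dce$data)[1:3]
  tumor <- study$ground_truth$tumor_mask
  vessel <- study$ground_truth$vessel_mask
  artery <- study$ground_truth$artery_mask
  if (is.null(tumor)) stop("stage masks: study carries no MRI tumor mask")
  mri_mask <- tumor | vessel

  # stage 1+3 prerequisites -------------------------------------------------
  mode <- if (is.null(study$t1_calibration)) "semiquant_only" else "full"
  t10 <- NULL
  if (mode == "full")
    t10 <- fit_t10(study$t1_calibration, mask = mri_mask | artery)

  # stage 2: semi-quantitative features -------------------------------------
  feats <- compute_feature_maps(dce, mri_mask, baseline_frames)
  smax_raw <- feats$smax
  maps_mri <- list()
  for (nm in names(feats))
    maps_mri[[nm]] <- normalize_map(feats[[nm]], mri_mask, name = nm)

  # stage 3: pharmacokinetics ------------------------------------------------
  aif_fit <- NULL
  if (mode == "full") {
    nt <- dim(dce$data)[4]
    sig_mat <- matrix(dce$data, ncol = nt)
    conc_at <- function(idx) {
      t(vapply(idx, function(v) {
        as.numeric(signal_to_concentration(
          sig_mat[v, ], t10$t1_ms[v], r1, cfg$tr_dce_ms, cfg$flip_angle_deg,
          baseline_frames))
      }, numeric(nt)))
    }
    art_idx <- which(artery & t10$fit_ok)
    if (!length(art_idx)) stop("stage aif: no artery voxels with a valid T1 fit")
    aif_fit <- fit_aif(conc_at(art_idx), dce$times_s)
    tum_idx <- which(mri_mask & t10$fit_ok)
    conc_t <- conc_at(tum_idx)
    pk <- fit_tofts_map(conc_t, aif_fit, dce$times_s)
    kt <- array(NA_real_, dm); ke <- array(NA_real_, dm)
    kt[tum_idx] <- pk$ktrans; ke[tum_idx] <- pk$kep
    gmaps <- apply_enhancement_gate(list(ktrans = kt, kep = ke),
                                    smax_raw, mri_mask,
                                    threshold_frac = gate_threshold_frac)
    maps_mri$ktrans <- vol3d(gmaps$ktrans, dce$affine)
    maps_mri$kep <- vol3d(gmaps$kep, dce$affine)
    maps_mri$gated <- vol3d(array(as.numeric(gmaps$gated), dm), dce$affine)
  }

  # stage 4: registration + resampling --------------------------------------
  if (is.null(study$tumor_mask_fixed)) stop("stage register: no fixed-frame tumor mask")
  mri_tumor_vol <- vol3d(array(tumor, dm), dce$affine)
  transform <- register_masks(mri_tumor_vol, study$tumor_mask_fixed)
  ref <- study$tumor_mask_fixed
  maps_spect <- lapply(maps_mri[setdiff(names(maps_mri), "gated")],
                       function(m) resample_map(m, transform, ref, "linear"))
  # SPECT and CT share the fixed world frame (scanner-aligned); bring the
  # coarse SPECT volume to CT resolution, as in the acquisition post-processing
  identity_tr <- affine_transform(diag(3), c(0, 0, 0))
  spect_ct <- resample_map(study$spect, identity_tr, ref, "linear")
  spect_ct$data[is.na(spect_ct$data)] <- 0

  # stage 5: correlation -----------------------------------------------------
  amask <- study$tumor_mask_fixed$data != 0 & !(study$vessel_mask_fixed$data != 0)
  table <- build_voxel_table(spect_ct, maps_spect, amask, dataset_id)
  report <- correlation_report(list(table))

  params <- list(baseline_frames = baseline_frames,
                 gate_threshold_frac = gate_threshold_frac, r1 = r1,
                 mode = mode,
                 registration_dice = attr(transform, "dice"))
  res <- structure(list(table = table, maps_mri = maps_mri,
                        maps_spect = maps_spect, transform = transform,
                        aif_fit = aif_fit, t10 = t10, report = report,
                        mode = mode, params = params),
                   class = "study_analysis")
  if (!is.null(out)) write_analysis(res, out)
  res
}

#' @export
print.study_analysis <- function(x, ...) {
  cat("study_analysis (", x$mode, "), ", nrow(x$table), " analysis voxels, ",
      "registration Dice ", signif(x$params$registration_dice, 4), "\n", sep = "")
  invisible(x)
}

#' Write analysis outputs to a directory
#'
#' @param analysis a `study_analysis`.
#' @param dir output directory.
#' @return `dir` invisibly; writes parameter maps (MRI and SPECT frames),
#'   the recovered transform and AIF as JSON, the voxel table and decile
#'   summaries as CSV, and the report as JSON.
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(analysis$maps_mri))
    write_nifti(analysis$maps_mri[[nm]],
                file.path(dir, paste0("mri_", nm, ".nii.gz")), "float64")
  for (nm in names(analysis$maps_spect))
    write_nifti(analysis$maps_spect[[nm]],
                file.path(dir, paste0("spect_frame_", nm, ".nii.gz")), "float64")
  jsonlite::write_json(list(matrix4 = transform_matrix4(analysis$transform),
                            kind = analysis$transform$kind,
                            dice = attr(analysis$transform, "dice")),
                       file.path(dir, "transform.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(analysis$aif_fit))
    jsonlite::write_json(list(a = analysis$aif_fit$a, m = analysis$aif_fit$m,
                              t_arrival = analysis$aif_fit$t_arrival),
                         file.path(dir, "aif.json"), auto_unbox = TRUE,
                         digits = NA)
  utils::write.csv(analysis$table, file.path(dir, "voxel_table.csv"),
                   row.names = FALSE)
  decs <- list()
  for (p in setdiff(names(analysis$table), c("dataset_id", "voxel", "spect_kbq"))) {
    ds <- decile_summary(analysis$table, "spect_kbq", p)
    ds$direction <- "spect-binned"; ds$parameter <- p
    decs[[length(decs) + 1]] <- ds
    ds2 <- decile_summary(analysis$table, p, "spect_kbq")
    ds2$direction <- "dce-binned"; ds2$parameter <- p
    decs[[length(decs) + 1]] <- ds2
  }
  utils::write.csv(do.call(rbind, decs), file.path(dir, "decile_summaries.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(spearman = analysis$report$spearman,
                            summary = analysis$report$summary,
                            mode = analysis$mode, params = analysis$params[
                              c("baseline_frames", "gate_threshold_frac", "r1")]),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Multi-dataset correlation report
#'
#' Runs (or accepts) per-dataset analyses and combines their voxel tables
#' into the cross-dataset report: per-dataset Spearman rho, mean/SD across
#' datasets, and pooled decile regression per parameter.
#'
#' @param analyses list of `study_analysis` objects (or voxel tables).
#' @return a `correlation_report`.
#' @export
combine_reports <- function(analyses) {
  tables <- lapply(analyses, function(a)
    if (inherits(a, "study_analysis")) a$table else a)
  correlation_report(tables)
}
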