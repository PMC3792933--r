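#' Voxel-wise SPECT vs DCE-MRI correlation statistics
#'
#' Three complementary views of spatial correspondence between radiopeptide
#' uptake and each DCE-MRI parameter: (1) per-dataset Spearman rank
#' correlation over all analysis-mask voxels; (2) bidirectional decile
#' summaries (rank-split one modality into ten equal-count bins, summarize
#' the companion modality per bin with median/Q1/Q3); (3) pooled linear
#' regression of per-decile medians across datasets against the decile index.
#'
#' @name correlation
NULL

DCE_PARAMETERS <- c("smax", "ttp", "auc", "auc60", "wash_in", "wash_out",
                    "ktrans", "kep")

#' Build the per-voxel analysis table for one dataset
#'
#' One row per analysis-mask voxel (tumor minus feeding vessels, in the fixed
#' frame), carrying the SPECT value and every DCE parameter over the identical
#' voxel set. Rows with undefined parameters are retained as NA; gated PK
#' voxels carry 0 by the zeroing rule, not NA.
#'
#' @param spect_map `vol3d` of uptake (kBq/voxel) on the reference grid.
#' @param parameter_maps named list of `vol3d` maps on the same grid.
#' @param analysis_mask logical array (or `vol3d`) on the same grid.
#' @param dataset_id identifier stored in the table.
#' @return data.frame with columns `dataset_id`, `voxel`, `spect_kbq` and one
#'   column per parameter.
#' @export
build_voxel_table <- function(spect_map, parameter_maps, analysis_mask,
                              dataset_id = "dataset") {
  mask <- if (inherits(analysis_mask, "vol3d")) analysis_mask$data != 0 else analysis_mask != 0
  if (!all(dim(spect_map$data) == dim(mask)))
    stop("grid mismatch between SPECT map and analysis mask")
  for (nm in names(parameter_maps)) {
    pm <- parameter_maps[[nm]]
    if (!all(dim(pm$data) == dim(mask)))
      stop("grid mismatch for parameter map '", nm, "'")
    if (max(abs(pm$affine - spect_map$affine)) > 1e-6)
      stop("affine mismatch for parameter map '", nm, "'")
  }
  idx <- which(mask)
  tab <- data.frame(dataset_id = dataset_id, voxel = idx,
                    spect_kbq = spect_map$data[idx])
  for (nm in names(parameter_maps)) tab[[nm]] <- parameter_maps[[nm]]$data[idx]
  tab
}

#' Spearman rank correlation with tie handling
#'
#' rho is the Pearson correlation of average ranks (mean ranks on ties); the
#' two-sided p-value uses the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom.
#'
#' @param table voxel table from [build_voxel_table()].
#' @param parameter column name to correlate against `spect_kbq`.
#' @return named vector `c(rho, p, n)`.
#' @export
spearman_cor <- function(table, parameter) {
  ok <- is.finite(table$spect_kbq) & is.finite(table[[parameter]])
  x <- table$spect_kbq[ok]
  y <- table[[parameter]][ok]
  n <- length(x)
  if (n < 10L) stop("spearman_cor needs >= 10 complete rows, got ", n)
  if (length(unique(x)) < 2L) stop("constant column: spect_kbq")
  if (length(unique(y)) < 2L) stop("constant column: ", parameter)
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  c(rho = rho, p = p, n = n)
}

#' Rank-decile assignment
#'
#' Sorts values ascending (stable on ties) and splits the rank order into
#' `n_bins` contiguous bins of near-equal count: with n = q * n_bins + r, the
#' first r bins hold q + 1 rows and the rest q.
#'
#' @param values numeric vector (NA allowed; assigned NA bin).
#' @param n_bins number of bins (default 10).
#' @return integer vector of bin indices (1-based), same length as `values`.
#' @export
assign_deciles <- function(values, n_bins = 10L) {
  ok <- which(is.finite(values))
  n <- length(ok)
  if (n < n_bins) stop("need at least ", n_bins, " defined values, got ", n)
  q <- n %/% n_bins
  r <- n %% n_bins
  sizes <- rep(q, n_bins)
  if (r > 0) sizes[seq_len(r)] <- q + 1L
  ord <- ok[order(values[ok], method = "radix")]   # stable sort
  bins <- rep(NA_integer_, length(values))
  bins[ord] <- rep(seq_len(n_bins), times = sizes)
  bins
}

#' Decile summary of one column binned on another
#'
#' @param table voxel table.
#' @param bin_on column whose rank deciles define the bins.
#' @param summarize column summarized per bin (median, Q1, Q3; type-7
#'   linear-interpolation quantiles, NA values excluded from the quantiles
#'   but counted in `n`).
#' @param n_bins number of bins (default 10).
#' @return data.frame with columns `bin`, `n`, `median`, `q1`, `q3` and
#'   attributes `direction` (= `bin_on`) and `parameter` (= `summarize`).
#' @export
decile_summary <- function(table, bin_on, summarize, n_bins = 10L) {
  bins <- assign_deciles(table[[bin_on]], n_bins)
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    v <- table[[summarize]][which(bins == b)]
    qs <- stats::quantile(v[is.finite(v)], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(bin = b, n = sum(bins == b, na.rm = TRUE),
               median = qs[2], q1 = qs[1], q3 = qs[3])
  }))
  attr(out, "direction") <- bin_on
  attr(out, "parameter") <- summarize
  out
}

#' Pooled linear regression of decile medians across datasets
#'
#' Each dataset's voxels are split into SPECT rank deciles; for each decile
#' index the voxels of that decile are pooled across all datasets and the
#' pooled median parameter value is taken. Ordinary least squares of the
#' pooled median against the decile index 1..10 (SPECT scales differ between
#' animals, so the index, not the raw kBq value, is the abscissa).
#'
#' @param tables list of voxel tables, one per dataset.
#' @param parameter parameter column to regress.
#' @param n_bins number of bins (default 10).
#' @return list with `slope`, `intercept`, `r_squared`, `p` (two-sided, for
#'   the slope), `medians` (pooled median per decile) and `per_dataset`
#'   (matrix of per-dataset decile medians, for the min/max envelope).
#' @export
pooled_regression <- function(tables, parameter, n_bins = 10L) {
  if (length(tables) < 2L) stop("pooled_regression needs >= 2 datasets")
  pooled <- vector("list", n_bins)
  per_ds <- matrix(NA_real_, length(tables), n_bins)
  for (d in seq_along(tables)) {
    tab <- tables[[d]]
    bins <- assign_deciles(tab$spect_kbq, n_bins)
    for (b in seq_len(n_bins)) {
      v <- tab[[parameter]][which(bins == b)]
      v <- v[is.finite(v)]
      pooled[[b]] <- c(pooled[[b]], v)
      per_ds[d, b] <- stats::median(v)
    }
  }
  if (any(vapply(pooled, length, integer(1)) == 0))
    stop("empty decile for parameter ", parameter)
  med <- vapply(pooled, stats::median, numeric(1))
  idx <- seq_len(n_bins)
  fit <- stats::lm(med ~ idx)
  sm <- suppressWarnings(summary(fit))   # degenerate exact fits warn harmlessly
  r2 <- sm$r.squared
  p <- unname(sm$coefficients[2, 4])
  if (stats::var(med) == 0 || !is.finite(r2)) {
    r2 <- 0                            # constant medians: no explainable variance
    p <- NA_real_
  }
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       p = p,
       medians = med,
       per_dataset = per_ds)
}

#' Assemble the full correlation report
#'
#' Per-dataset Spearman rho and p for every parameter, their mean/SD across
#' datasets (both signed and absolute; TTP enters un-inverted so its signed
#' rho is expected negative), and the pooled regression per parameter.
#'
#' @param tables list of voxel tables (>= 1; pooled regression needs >= 2).
#' @param parameters parameter columns (default the eight DCE parameters).
#' @return object of class `correlation_report`: list with data.frame
#'   `spearman` (dataset, parameter, rho, p, n), data.frame `summary`
#'   (parameter, mean_rho, sd_rho, mean_abs_rho, slope, intercept, r_squared,
#'   p), and list `regressions`.
#' @export
correlation_report <- function(tables, parameters = DCE_PARAMETERS) {
  parameters <- intersect(parameters, names(tables[[1]]))
  rows <- list()
  for (d in seq_along(tables)) {
    for (p in parameters) {
      r <- spearman_cor(tables[[d]], p)
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = tables[[d]]$dataset_id[1], parameter = p,
        rho = r["rho"], p = r["p"], n = r["n"], row.names = NULL)
    }
  }
  sp <- do.call(rbind, rows)
  regs <- NULL
  if (length(tables) >= 2L)
    regs <- lapply(stats::setNames(parameters, parameters),
                   function(p) pooled_regression(tables, p))
  summ <- do.call(rbind, lapply(parameters, function(p) {
    r <- sp$rho[sp$parameter == p]
    data.frame(parameter = p,
               mean_rho = mean(r), sd_rho = stats::sd(r),
               mean_abs_rho = mean(abs(r)),
               slope = if (is.null(regs)) NA_real_ else regs[[p]]$slope,
               intercept = if (is.null(regs)) NA_real_ else regs[[p]]$intercept,
               r_squared = if (is.null(regs)) NA_real_ else regs[[p]]$r_squared,
               p = if (is.null(regs)) NA_real_ else regs[[p]]$p)
  }))
  structure(list(spearman = sp, summary = summ, regressions = regs),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Correlation report over", length(unique(x$spearman$dataset)), "dataset(s)\n")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
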