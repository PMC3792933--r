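make_table <- function(n, seed = 1, id = "d") {
  set.seed(seed)
  data.frame(dataset_id = id, voxel = seq_len(n),
             spect_kbq = rexp(n, 0.1),
             smax = rnorm(n), ktrans = runif(n))
}

test_that("build_voxel_table selects masked voxels and checks grids", {
  dm <- c(6, 6, 4)
  aff <- grid_affine(c(1, 1, 1))
  set.seed(2)
  spect <- vol3d(array(runif(prod(dm)), dm), aff)
  kt <- vol3d(array(runif(prod(dm)), dm), aff)
  mask <- array(FALSE, dm); mask[2:5, 2:5, 2:3] <- TRUE   # 32 voxels
  vessel <- array(FALSE, dm); vessel[3, 3, 2] <- TRUE
  tab <- build_voxel_table(spect, list(ktrans = kt), mask & !vessel, "a")
  expect_equal(nrow(tab), sum(mask) - 1)
  expect_false(which(vessel) %in% tab$voxel)
  expect_equal(tab$spect_kbq, spect$data[tab$voxel])
  # gated voxels enter with value 0, not NA
  kt$data[2, 2, 2] <- 0
  tab2 <- build_voxel_table(spect, list(ktrans = kt), mask, "a")
  expect_true(0 %in% tab2$ktrans)
  bad <- vol3d(array(0, c(5, 5, 4)), aff)
  expect_error(build_voxel_table(spect, list(ktrans = bad), mask), "mismatch")
})

test_that("spearman_cor: monotone invariance, sign, tie handling vs oracle", {
  n <- 40
  x <- seq_len(n) + 0.1 * sin(seq_len(n))
  tab <- data.frame(dataset_id = "d", voxel = 1:n, spect_kbq = x, p1 = exp(x / 10),
                    p2 = -x)
  expect_equal(unname(spearman_cor(tab, "p1")["rho"]), 1)
  expect_equal(unname(spearman_cor(tab, "p2")["rho"]), -1)
  expect_equal(unname(spearman_cor(tab, "p1")["p"]), 0)
  # ties: against the explicit average-rank oracle
  set.seed(11)
  for (i in 1:20) {
    y <- sample(1:4, n, replace = TRUE)         # heavy ties
    s <- sample(1:6, n, replace = TRUE)
    tb <- data.frame(dataset_id = "d", voxel = 1:n, spect_kbq = s, par = y)
    expect_equal(unname(spearman_cor(tb, "par")["rho"]), oracle_spearman(s, y),
                 tolerance = 1e-14)
  }
  cst <- data.frame(dataset_id = "d", voxel = 1:n, spect_kbq = x, par = rep(1, n))
  expect_error(spearman_cor(cst, "par"), "par")
  expect_error(spearman_cor(make_table(5), "smax"), ">= 10")
})

test_that("decile assignment: sizes, stability, partition", {
  expect_equal(tabulate(assign_deciles(rnorm(100))), rep(10, 10))
  expect_equal(tabulate(assign_deciles(rnorm(103))), oracle_decile_sizes(103))
  expect_equal(tabulate(assign_deciles(rnorm(57))), oracle_decile_sizes(57))
  b <- assign_deciles(c(rep(1, 30), rep(2, 70)))   # ties keep stable order
  expect_equal(tabulate(b), rep(10, 10))
  expect_true(all(b[1:30] <= 3))
  expect_error(assign_deciles(rnorm(7)), "at least 10")
})

test_that("decile_summary matches counting and quantile oracles", {
  tab <- make_table(100)
  tab$spect_kbq <- 1:100                      # bin on themselves
  tab$val <- as.numeric(1:100)
  ds <- decile_summary(tab, "spect_kbq", "val")
  expect_equal(ds$median[1], 5.5)
  expect_equal(ds$n, rep(10, 10))
  expect_equal(ds$median, seq(5.5, 95.5, by = 10))
  # constant summarize column collapses the quartiles
  tab$cst <- 3.3
  dc <- decile_summary(tab, "spect_kbq", "cst")
  expect_true(all(dc$median == 3.3 & dc$q1 == 3.3 & dc$q3 == 3.3))
  # quartiles against the type-7 oracle on a random table
  tab2 <- make_table(137, seed = 8)
  d2 <- decile_summary(tab2, "spect_kbq", "smax")
  bins <- assign_deciles(tab2$spect_kbq)
  for (b in c(1, 4, 10)) {
    v <- tab2$smax[bins == b]
    expect_equal(d2$q1[b], oracle_quantile7(v, 0.25), tolerance = 1e-14)
    expect_equal(d2$median[b], oracle_quantile7(v, 0.5), tolerance = 1e-14)
    expect_equal(d2$q3[b], oracle_quantile7(v, 0.75), tolerance = 1e-14)
  }
  expect_error(decile_summary(make_table(8), "spect_kbq", "smax"), "at least 10")
})

test_that("pooled_regression: exact lines, constants, oracle agreement", {
  # medians exactly linear in decile index -> R^2 = 1
  tabs <- lapply(1:2, function(d) {
    tb <- make_table(100, seed = d, id = paste0("d", d))
    bins <- assign_deciles(tb$spect_kbq)
    tb$lin <- bins * 2 + 1
    tb
  })
  pr <- pooled_regression(tabs, "lin")
  expect_equal(pr$r_squared, 1, tolerance = 1e-12)
  expect_equal(pr$slope, 2, tolerance = 1e-12)
  # constant medians -> slope 0, R^2 = 0
  tabs2 <- lapply(tabs, function(tb) { tb$cst <- 5; tb })
  pc <- pooled_regression(tabs2, "cst")
  expect_equal(pc$slope, 0)
  expect_equal(pc$r_squared, 0)
  # random tables against the closed-form OLS oracle
  tabs3 <- lapply(1:3, function(d) make_table(80 + d, seed = 20 + d))
  p3 <- pooled_regression(tabs3, "smax")
  o <- oracle_ols(1:10, p3$medians)
  expect_equal(p3$slope, o$slope, tolerance = 1e-12)
  expect_equal(p3$r_squared, o$r_squared, tolerance = 1e-12)
  expect_equal(p3$p, o$p, tolerance = 1e-12)
  expect_error(pooled_regression(tabs[1], "lin"), ">= 2 datasets")
})

test_that("correlation_report aggregates rho and pooled regressions sanely", {
  tabs <- lapply(1:3, function(d) make_table(90, seed = 40 + d, id = paste0("d", d)))
  rep <- correlation_report(tabs, parameters = c("smax", "ktrans"))
  expect_equal(nrow(rep$spearman), 6)
  expect_true(all(rep$spearman$rho >= -1 & rep$spearman$rho <= 1))
  expect_true(all(rep$summary$r_squared >= 0 & rep$summary$r_squared <= 1))
  expect_equal(rep$summary$mean_rho,
               sapply(c("smax", "ktrans"), function(p)
                 mean(rep$spearman$rho[rep$spearman$parameter == p])),
               ignore_attr = TRUE)
  expect_output(print(rep), "Correlation report")
})
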