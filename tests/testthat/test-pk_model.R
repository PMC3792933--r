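test_that("closed-form Tofts convolution matches the numerical oracle", {
  aif <- default_aif()
  tt <- c(25, 120, 250, 413)
  for (kt in c(1e-4, 1e-2)) {
    for (kep in c(1e-3, 0.01, 0.13, 1)) {
      a <- tofts_forward(kt, kep, aif, tt)
      b <- vapply(tt, function(t) oracle_tofts_conv(kt, kep, aif, t), numeric(1))
      expect_lt(max(abs(a - b) / abs(b)), 1e-8)
    }
  }
  # kep exactly equal to an AIF rate exercises the (t - tau) limit branch
  a <- tofts_forward(0.005, aif$m[1], aif, tt)
  b <- vapply(tt, function(t) oracle_tofts_conv(0.005, aif$m[1], aif, t),
              numeric(1))
  expect_lt(max(abs(a - b) / abs(b)), 1e-8)
})

test_that("box AIF has the textbook closed form; limits behave", {
  tt <- seq(0, 300, by = 10)
  c0 <- 2.5
  box <- aif_model(c0, 1e-9, 0, 1, t_arrival = 0)  # near-constant input
  kep <- 0.03; kt <- 0.008
  expect_equal(tofts_forward(kt, kep, box, tt),
               kt * c0 / kep * (1 - exp(-kep * tt)), tolerance = 1e-6)
  # ktrans = 0 gives identically zero tissue concentration
  expect_equal(tofts_forward(0, 0.05, default_aif(), tt), rep(0, length(tt)))
  # kep -> 0: Ct converges to ktrans * integral of Cp
  aif <- default_aif()
  int_cp <- aif$a[1] / aif$m[1] * (1 - exp(-aif$m[1] * tt)) +
    aif$a[2] / aif$m[2] * (1 - exp(-aif$m[2] * tt))
  expect_equal(tofts_forward(kt, 0, aif, tt), kt * int_cp, tolerance = 1e-9)
  expect_error(tofts_forward(-0.1, 0.1, aif, tt), ">= 0")
})

test_that("matrix forward agrees with the scalar forward and gradients check out", {
  aif <- default_aif()
  tt <- seq(0, 413, by = 4.3)
  kt <- c(0.002, 0.01, 0.02)
  kep <- c(0.004, 0.01, 0.12)
  m <- dcespect:::tofts_forward_matrix(kt, kep, aif, tt)
  for (i in seq_along(kt))
    expect_equal(m[i, ], tofts_forward(kt[i], kep[i], aif, tt), tolerance = 1e-12)
  # analytic kep-gradient vs central finite differences
  for (kep0 in c(0.011, aif$m[1], 0.4)) {
    h <- 1e-6
    g <- dcespect:::expconv_grad(aif$m[1], kep0, tt[-1])
    gn <- (dcespect:::expconv(aif$m[1], kep0 + h, tt[-1]) -
             dcespect:::expconv(aif$m[1], kep0 - h, tt[-1])) / (2 * h)
    expect_lt(max(abs(g - gn) / pmax(abs(gn), 1e-8)), 1e-4)
  }
})

test_that("fit_aif recovers bi-exponential parameters and curve shape", {
  tt <- seq(0, 413, by = 4.3)
  true <- c(a1 = 3.0, m1 = 0.01, a2 = 1.0, m2 = 0.001)
  cp <- true["a1"] * exp(-true["m1"] * tt) + true["a2"] * exp(-true["m2"] * tt)
  fit <- fit_aif(cp, tt)
  expect_equal(fit$t_arrival, 0)
  expect_lt(max(abs(c(fit$a[1], fit$m[1], fit$a[2], fit$m[2]) - true) / true), 1e-4)
  # single-exponential truth: curve space reproduced even if params degenerate
  cp1 <- 2.0 * exp(-0.008 * tt)
  fit1 <- fit_aif(cp1, tt)
  expect_lt(sqrt(mean((aif_cp(fit1, tt) - cp1)^2)), 1e-6)
  # pre-arrival samples are zero
  expect_equal(aif_cp(aif_model(1, 0.01, 1, 0.001, t_arrival = 30), c(0, 10, 29.9)),
               c(0, 0, 0))
  expect_error(fit_aif(rep(0, length(tt)), tt), "all-zero")
})

test_that("fit_tofts round-trips noiseless curves and handles zero curves", {
  aif <- default_aif()
  tt <- seq(0, 413, by = 4.3)
  for (p in list(c(0.005, 0.02), c(0.0008, 0.003), c(0.02, 0.4))) {
    ct <- tofts_forward(p[1], p[2], aif, tt)
    fit <- fit_tofts(ct, aif, tt)
    expect_lt(abs(fit["ktrans"] - p[1]) / p[1], 1e-3)
    expect_lt(abs(fit["kep"] - p[2]) / p[2], 1e-3)
  }
  z <- fit_tofts(rep(0, length(tt)), aif, tt)
  expect_equal(unname(z["ktrans"]), 0)
  expect_equal(unname(z["rss"]), 0)
  # NA frames are dropped, not fatal
  ct <- tofts_forward(0.005, 0.02, aif, tt)
  ct[c(5, 50)] <- NA
  fit <- fit_tofts(ct, aif, tt)
  expect_lt(abs(fit["ktrans"] - 0.005) / 0.005, 1e-3)
})

test_that("enhancement gate zeroes low-Smax voxels and validates inputs", {
  dm <- c(5, 5, 1)
  set.seed(9)
  smax <- array(runif(prod(dm), 50, 100), dm)
  smax[1, 1, 1] <- 0           # a 'no contrast accumulation' voxel
  smax[2, 1, 1] <- 1
  mask <- array(TRUE, dm)
  maps <- list(ktrans = array(0.01, dm), kep = array(0.05, dm))
  g <- apply_enhancement_gate(maps, smax, mask, threshold_frac = 0.08)
  expect_true(g$gated[1, 1, 1] && g$gated[2, 1, 1])
  expect_equal(g$ktrans[1, 1, 1], 0)
  expect_equal(g$kep[2, 1, 1], 0)
  # all voxels far above threshold: maps unchanged
  g2 <- apply_enhancement_gate(maps, array(90, dm), mask, threshold_frac = 0.08)
  expect_false(any(g2$gated))
  expect_equal(g2$ktrans, maps$ktrans)
  expect_error(apply_enhancement_gate(maps, smax, mask, threshold_frac = 1.2),
               "threshold_frac")
  expect_error(apply_enhancement_gate(maps, smax, mask, threshold_frac = 0),
               "threshold_frac")
})
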