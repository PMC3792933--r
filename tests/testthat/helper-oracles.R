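# Independent brute-force oracles and small shared fixtures.
# Every oracle here is written from the textbook definition, deliberately
# avoiding the code paths (and even the base helpers) used by the package.

# Richardson-extrapolated (Romberg) trapezoid convolution of the Tofts
# integral, starting from a 10x-oversampled grid (h0 = 0.43 s with the
# default 4.3 s frame spacing) and halving `levels`-1 times.
oracle_tofts_conv <- function(kt, kep, aif, t, h0 = 0.43, levels = 6) {
  if (t <= aif$t_arrival) return(0)
  n0 <- max(2, ceiling(t / h0))
  Tk <- numeric(levels)
  for (l in seq_len(levels)) {
    n <- n0 * 2^(l - 1)
    tau <- seq(0, t, length.out = n + 1)
    f <- aif_cp(aif, tau) * exp(-kep * (t - tau))
    Tk[l] <- (t / n) * (sum(f) - (f[1] + f[n + 1]) / 2)
  }
  R <- Tk
  for (m in seq_len(levels - 1)) R <- (4^m * R[-1] - R[-length(R)]) / (4^m - 1)
  kt * R
}

# average ranks (mean rank on ties), from the sort definition
oracle_rank <- function(x) {
  n <- length(x)
  ord <- order(x)
  r <- numeric(n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

# Pearson correlation from explicit sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

oracle_spearman <- function(x, y) oracle_pearson(oracle_rank(x), oracle_rank(y))

# type-7 quantile from the definition: h = (n-1)p, linear interpolation
oracle_quantile7 <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  xs[lo] + (h - floor(h)) * (xs[hi] - xs[lo])
}

# OLS of y on x from closed-form sums, plus R^2 and two-sided slope p-value
oracle_ols <- function(x, y) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  slope <- sum((x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  res <- y - intercept - slope * x
  sst <- sum((y - yb)^2)
  r2 <- if (sst == 0) 0 else 1 - sum(res^2) / sst
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  p <- if (se == 0) NA_real_ else 2 * stats::pt(-abs(slope / se), n - 2)
  list(slope = slope, intercept = intercept, r_squared = r2, p = p)
}

# rank-decile sizes from the counting definition
oracle_decile_sizes <- function(n, k = 10) {
  q <- n %/% k; r <- n %% k
  out <- rep(q, k)
  if (r > 0) out[seq_len(r)] <- q + 1
  out
}

make_ellipsoid_mask <- function(dm, semi, vox = 1) {
  ctr <- (dm + 1) / 2
  ii <- array(rep(seq_len(dm[1]), times = dm[2] * dm[3]), dm)
  jj <- array(rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]), dm)
  kk <- array(rep(seq_len(dm[3]), each = dm[1] * dm[2]), dm)
  m <- ((ii - ctr[1]) / semi[1])^2 + ((jj - ctr[2]) / semi[2])^2 +
    ((kk - ctr[3]) / semi[3])^2 <= 1
  vol3d(array(as.numeric(m), dm), grid_affine(rep(vox, 3)))
}

# small, fast phantom for unit tests (full-size studies live in acceptance)
tiny_config <- function(...) {
  args <- list(grid_shape = c(16, 16, 12), n_frames = 40,
               gap_after_frame = 20, seed = 42)
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_config, args)
}

# memoised tiny study shared across test files
tiny_study_cache <- new.env(parent = emptyenv())
get_tiny_study <- function(noise = FALSE) {
  key <- paste0("noise_", noise)
  if (is.null(tiny_study_cache[[key]]))
    tiny_study_cache[[key]] <- simulate_study(tiny_config(), noise = noise)
  tiny_study_cache[[key]]
}

default_aif <- function() aif_model(3, 0.01, 1, 0.001, t_arrival = 0)
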