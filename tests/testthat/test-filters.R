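test_that("bandpass temporal filter matches its closed form and is biphasic", {
  p <- msinrf_params()
  tm <- sample_tm(p)
  expect_equal(length(tm$taps), 7L)  # floor(50 / 8.33) + 1 taps at 120 Hz
  expect_identical(tm$taps[1], 0)
  # frozen independent scalar evaluations of the printed formula
  # (kt)^5 exp(-kt) [1/5! - (kt)^2/7!], k = 0.4
  expect_equal(tm$taps[2], 0.089974036247161854, tolerance = 1e-10)
  tm80 <- sample_tm(msinrf_params(fps = 80))  # dt = 12.5 ms
  expect_equal(tm80$taps[2], 0.071022506810796721, tolerance = 1e-10)
  # exactly one sign change inside the 50 ms support (fine-grid oracle)
  g <- seq(0.1, 50, by = 0.1)
  v <- (0.4 * g)^5 * exp(-0.4 * g) * (1 / 120 - (0.4 * g)^2 / 5040)
  expect_identical(sum(diff(sign(v)) != 0), 1L)
  expect_identical(sum(diff(sign(tm$taps[-1])) != 0), 1L)
  # sampled taps agree with the closed form at the sampled delays
  u <- (seq_along(tm$taps) - 1) * 1000 / 120
  ref <- (0.4 * u)^5 * exp(-0.4 * u) * (1 / 120 - (0.4 * u)^2 / 5040)
  expect_lt(max_rel_err(tm$taps, ref, floor = 1e-6), 1e-10)
})

test_that("lowpass temporal filter is non-negative and vanishes at 50 ms", {
  tw <- sample_tw(msinrf_params())
  expect_true(all(tw$taps >= -1e-12))
  expect_equal(tw$taps[length(tw$taps)], 0, tolerance = 1e-12)
  expect_equal(tw$taps[1], 0.96592582628906831, tolerance = 1e-12)
  tw100 <- sample_tw(msinrf_params(fps = 100))  # taps at 0, 10, ..., 50 ms
  expect_equal(tw100$taps[3], cos(pi / 4), tolerance = 1e-12)
  u <- (seq_along(tw100$taps) - 1) * 10
  expect_lt(max_rel_err(tw100$taps, cos(pi * (u + 10) / 120),
                        floor = 1e-6), 1e-10)
})

test_that("temporal sampling rejects invalid frame rates", {
  expect_error(msinrf_params(fps = 0), "fps")
  expect_error(msinrf_params(fps = -10), "fps")
})

test_that("Gaussian kernel is unit-sum, symmetric and correctly scaled", {
  p <- msinrf_params()
  m <- make_gaussian(p)
  expect_lt(abs(sum(m$weights) - 1), 1e-9)
  expect_identical(m$weights, m$weights[nrow(m$weights):1, ])
  expect_identical(m$weights, m$weights[, ncol(m$weights):1])
  # sigma = 0.031 deg / 0.005 deg/px = 6.2 px; +-3 sigma support -> 39 px
  expect_identical(dim(m$weights), c(39L, 39L))
  # kernel profile matches a 6.2 px Gaussian (ratio test, centre row)
  cr <- (nrow(m$weights) + 1L) %/% 2L
  ratio <- m$weights[cr, cr + 1L] / m$weights[cr, cr]
  expect_equal(ratio, exp(-1 / (2 * 6.2^2)), tolerance = 1e-12)
  expect_warning(make_gaussian(msinrf_params(deg_per_px = 0.1)),
                 "delta")
})

test_that("Gabor kernel is zero-sum, odd-symmetric and two-lobed", {
  p <- msinrf_params()
  w <- make_gabor(p)
  W <- w$weights
  expect_lt(abs(sum(W)) / max(abs(W)), 1e-9)
  # exact antisymmetry under horizontal mirror
  expect_identical(W, -W[, ncol(W):1])
  # carrier period 0.25 deg = 50 px: peak columns ~ +-12 px from centre
  cc <- (ncol(W) + 1L) %/% 2L
  colsum <- colSums(W)
  expect_true(all(colsum[(cc + 1L):(cc + 25L)] >= 0))  # positive lobe right
  expect_true(all(colsum[(cc - 25L):(cc - 1L)] <= 0))
  peak <- which.max(colsum) - cc
  expect_true(peak > 0 && peak < 25)        # inside the first half-period
  expect_lt(abs(colsum[cc + 25L]) / max(abs(colsum)), 1e-12)  # carrier zero
  # two dominant lobes: no secondary lobe above 5% of the main one
  main <- max(abs(colsum))
  beyond <- abs(colsum[abs(seq_along(colsum) - cc) > 25])
  expect_lt(max(beyond) / main, 0.05)
})

test_that("dendritic nonlinearity is even, saturating and half at q", {
  p <- msinrf_params()
  expect_identical(sigma_nl(0, p), 0)
  expect_equal(sigma_nl(0.1, p), 0.5, tolerance = 1e-12)
  expect_identical(sigma_nl(-0.37, p), sigma_nl(0.37, p))
  zpos <- seq(0.001, 2, by = 0.001)
  z <- c(-rev(zpos), 0, zpos)           # exactly symmetric grid
  s <- sigma_nl(z, p)
  expect_identical(s, rev(s))           # even on a dense grid
  expect_true(all(s >= 0 & s < 1))      # bounded
  pos <- s[z > 0]
  expect_true(all(diff(pos) > 0))       # strictly increasing in |z|
  set.seed(7)
  zr <- runif(500, -5, 5)
  expect_identical(sigma_nl(zr, p), sigma_nl(-zr, p))
  expect_true(all(sigma_nl(zr, p) < 1))
})

test_that("filters export to CSV for inspection", {
  f <- tempfile(fileext = ".csv")
  write_filter_csv(sample_tm(msinrf_params()), f)
  df <- read.csv(f)
  expect_identical(names(df), c("delay_ms", "tap"))
  expect_equal(nrow(df), 7L)
  write_filter_csv(make_gabor(msinrf_params()), f)
  expect_equal(dim(read.csv(f)), c(77L, 77L))
})
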