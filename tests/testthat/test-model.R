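# brute-force double loop over the static receptive field, written
# independently of the package internals
inrf_oracle <- function(image, params, loc) {
  m <- make_gaussian(params)$weights
  w <- make_gabor(params)$weights
  rm_ <- (nrow(m) - 1L) %/% 2L
  rw_ <- (nrow(w) - 1L) %/% 2L
  lin <- 0
  for (a in -rm_:rm_) for (b in -rm_:rm_) {
    lin <- lin + m[a + rm_ + 1L, b + rm_ + 1L] * image[loc[1] + a, loc[2] + b]
  }
  nl <- 0
  ctr <- image[loc[1], loc[2]]
  for (a in -rw_:rw_) for (b in -rw_:rw_) {
    z <- abs(image[loc[1] + a, loc[2] + b] - ctr)
    nl <- nl + w[a + rw_ + 1L, b + rw_ + 1L] *
      (z^params$p / (z^params$p + params$q^params$p))
  }
  lin - params$lambda * nl
}

test_that("static receptive field matches the nested-loop oracle", {
  p <- small_params(32)  # 5x5 Gaussian, 7x7 Gabor
  set.seed(11)
  img <- matrix(runif(32 * 32), 32, 32)
  for (loc in list(c(16L, 16L), c(10L, 20L), c(16L, 12L))) {
    expect_equal(inrf_spatial(img, p, loc), inrf_oracle(img, p, loc),
                 tolerance = 1e-12)
  }
})

test_that("static receptive field degenerates correctly", {
  p <- small_params(32)
  const <- matrix(0.37, 32, 32)
  # constant image: unit-sum m returns the constant, sigma(0) kills term 2
  expect_equal(inrf_spatial(const, p), 0.37, tolerance = 1e-12)
  # lambda = 0: pure Gaussian filtering
  p0 <- p; p0$lambda <- 0
  set.seed(12)
  img <- matrix(runif(32 * 32), 32, 32)
  m <- make_gaussian(p)$weights
  r <- (nrow(m) - 1L) %/% 2L
  expect_equal(inrf_spatial(img, p0, c(16L, 16L)),
               sum(m * img[(16 - r):(16 + r), (16 - r):(16 + r)]),
               tolerance = 1e-12)
  expect_error(inrf_spatial(img, p, c(0L, 5L)), "outside")
  expect_error(inrf_spatial(img, p, c(2L, 2L)), "support|border")
})

test_that("optimised stINRF equals the brute-force reference", {
  p <- small_params(32)
  for (seed in 1:4) {
    s <- random_seq(32, 12, seed = seed)
    a <- stinrf(s, p)
    b <- stinrf_bruteforce(s, p)
    expect_lt(max_rel_err(a$values, b$values), 1e-10)
    expect_lt(max_rel_err(a$linear, b$linear, floor = 1e-9), 1e-9)
    expect_lt(max_rel_err(a$nonlinear, b$nonlinear, floor = 1e-9), 1e-9)
    expect_identical(a$valid_from, b$valid_from)
  }
})

test_that("constant sequences give the closed-form trace", {
  p <- small_params(32)
  cval <- 0.42
  s <- stimulus_sequence(array(cval, c(32, 32, 12)), 120, 2 / 32)
  tm_sum <- sum(sample_tm(p)$taps)
  tr <- stinrf(s, p)
  expect_true(all(is.na(tr$values[1:(tr$valid_from - 1L)])))
  expect_equal(tr$values[tr$valid_from:12], rep(cval * tm_sum, 6),
               tolerance = 1e-12)
  bf <- stinrf_bruteforce(s, p)
  expect_equal(bf$values[7:12], rep(cval * tm_sum, 6), tolerance = 1e-12)
})

test_that("nonlinear term is invariant under contrast-polarity inversion", {
  p <- small_params(32)
  s <- random_seq(32, 10, seed = 21)
  s_inv <- stimulus_sequence(1 - s$frames, s$fps, s$deg_per_px)
  a <- stinrf(s, p)
  b <- stinrf(s_inv, p)
  # sigma is even, so sigma(I_j - I_i) is unchanged by I -> 1 - I
  expect_lt(max_rel_err(b$nonlinear, a$nonlinear, floor = 1e-9), 1e-12)
})

test_that("nonlinear term negates under horizontal mirroring", {
  p <- small_params(32)
  s <- random_seq(32, 10, seed = 22)
  loc <- c(16L, 13L)
  mir <- stimulus_sequence(s$frames[, 32:1, , drop = FALSE], s$fps,
                           s$deg_per_px)
  loc_m <- c(16L, 32L + 1L - 13L)
  a <- stinrf(s, p, loc)
  b <- stinrf(mir, p, loc_m)
  # m is even and w odd under the mirror; sigma even
  expect_lt(max_rel_err(b$nonlinear, -a$nonlinear, floor = 1e-9), 1e-12)
  expect_lt(max_rel_err(b$linear, a$linear, floor = 1e-9), 1e-12)
})

test_that("stINRF is covariant under a one-frame delay", {
  p <- small_params(32)
  s <- random_seq(32, 12, seed = 23)
  delayed <- stimulus_sequence(s$frames[, , c(1L, 1:11)], s$fps,
                               s$deg_per_px)
  a <- stinrf(s, p)
  b <- stinrf(delayed, p)
  expect_equal(b$values[8:12], a$values[7:11], tolerance = 1e-12)
})

test_that("sensor readout signs encode direction for moving bars", {
  p <- msinrf_params()
  right <- ms_inrf(moving_bar(direction = 1, size_px = 200), p)
  left <- ms_inrf(moving_bar(direction = -1, size_px = 200), p)
  expect_gt(right$value, 0)
  expect_lt(left$value, 0)
  # identical inputs give identical readouts
  again <- ms_inrf(moving_bar(direction = 1, size_px = 200), p)
  expect_identical(right$value, again$value)
})

test_that("sensor readout windows and errors behave", {
  p <- small_params(32)
  s <- random_seq(32, 12, seed = 31)
  full <- ms_inrf(s, p)
  tr <- stinrf(s, p)
  expect_equal(full$value, mean(tr$values[7:12]), tolerance = 1e-12)
  last3 <- ms_inrf(s, p, window = 3)
  expect_equal(last3$value, mean(tr$values[10:12]), tolerance = 1e-12)
  short <- stimulus_sequence(array(0.5, c(32, 32, 4)), 120, 2 / 32)
  expect_error(stinrf(short, p), "shorter")
  expect_error(stinrf(s, msinrf_params(fps = 60, deg_per_px = 2 / 32)),
               "fps")
})

test_that("response fields agree with single-location traces", {
  p <- small_params(48)
  s <- random_seq(48, 9, seed = 41)
  f <- stinrf_field(s, p, stride = 8L)
  for (i in seq_along(f$rows)) {
    tr <- stinrf(s, p, c(f$rows[i], f$cols[1]))
    expect_identical(f$values[i, 1, ], tr$values)
  }
  # mirrored boundary mode covers the full grid
  fm <- stinrf_field(s, p, stride = 24L, boundary = "mirror")
  expect_identical(fm$rows[1], 1L)
})

test_that("rightward bar leaves a positive time-mean response field", {
  p <- msinrf_params()
  s <- moving_bar(direction = 1, size_px = 200)
  f <- stinrf_field(s, p, stride = 200L)  # single central column
  tm <- mean(f$values[1, 1, ], na.rm = TRUE)
  expect_gt(tm, 0)
})
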