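test_that("seeded recipes are bit-reproducible", {
  a <- masked_grating(noise_sf_cpd = 4, seed = 9, size_px = 64)
  b <- masked_grating(noise_sf_cpd = 4, seed = 9, size_px = 64)
  expect_identical(a$frames, b$frames)
  a <- random_pattern(seed = 9, size_px = 64)
  b <- random_pattern(seed = 9, size_px = 64)
  expect_identical(a$frames, b$frames)
  a <- contrast_modulated(seed = 9, size_px = 64)
  b <- contrast_modulated(seed = 9, size_px = 64)
  expect_identical(a$frames, b$frames)
  # the generator must not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(random_pattern(seed = 5, size_px = 64))
  expect_identical(runif(1), before)
})

test_that("moving bars have exact polarity and kinematics", {
  white <- moving_bar(polarity = "white", size_px = 200)
  black <- moving_bar(polarity = "black", size_px = 200)
  expect_identical(black$frames, 1 - white$frames)
  expect_error(moving_bar(width_deg = 0), "width")
  # 2 deg/s at 120 Hz: 0.2 deg = 40 px advance over 12 frames
  p0 <- which(white$frames[1, , 1] > 0.5)
  p12 <- which(white$frames[1, , 13] > 0.5)
  expect_identical(sort((p0 - 1L + 40L) %% 200L), sort(p12 - 1L))
  # leftward sequence mirrors the rightward one up to start position
  lf <- moving_bar(direction = -1, size_px = 200)
  rt_mirror <- white$frames[, 200:1, ]
  shift_match <- sapply(1:5, function(t) {
    a <- which(lf$frames[1, , t] > 0.5)[1]
    b <- which(rt_mirror[1, , t] > 0.5)[1]
    (a - b) %% 200L
  })
  expect_true(length(unique(shift_match)) == 1L)  # constant offset
})

test_that("drifting gratings have the stated contrast and phase structure", {
  u <- drifting_grating(contrast = 0, size_px = 64)
  expect_true(all(u$frames == 0.5))
  g <- drifting_grating(contrast = 0.4, sf_cpd = 2, tf_hz = 4,
                        size_px = 400)
  expect_equal(max(g$frames) - min(g$frames), 0.4, tolerance = 1e-6)
  expect_equal(mean(g$frames), 0.5, tolerance = 1e-3)
  # quarter temporal period with phase 0 equals the cosine-phase frame
  g5 <- drifting_grating(contrast = 0.5, sf_cpd = 2, tf_hz = 5,
                         size_px = 64, n_frames = 10)
  x <- (seq_len(64) - 1) * 2 / 400
  expected <- 0.5 * (1 - 0.5 * cos(2 * pi * 2 * x))
  expect_equal(g5$frames[1, , 7], expected, tolerance = 1e-12)
  expect_error(drifting_grating(sf_cpd = 150), "Nyquist")
})

test_that("masking noise holds its phase for exact 12-frame blocks", {
  mg <- masked_grating(noise_sf_cpd = 5, seed = 3, size_px = 64)
  sig <- drifting_grating(contrast = 0.4, sf_cpd = 2.5, tf_hz = 10,
                          size_px = 64)
  expect_identical(masked_grating(noise_sf_cpd = 5, noise_contrast = 0,
                                  seed = 3, size_px = 64)$frames,
                   sig$frames)
  noise <- xt_profile(mg) - xt_profile(sig)
  for (blk in 0:4) {
    cols <- blk * 12 + 1:12
    expect_lt(max(abs(noise[, cols] - noise[, cols[1]])), 1e-12)
  }
  jumps <- sapply(1:9, function(b) max(abs(noise[, b * 12] - noise[, b * 12 + 1])))
  expect_true(all(jumps > 1e-3))  # phase actually moves between blocks
  expect_error(masked_grating(jitter_hz = 7), "divide")
})

test_that("random patterns translate exactly and invert for reverse-phi", {
  st <- random_pattern(speed_deg_s = 0, seed = 5, size_px = 64)
  expect_true(all(st$frames == array(st$frames[, , 1], dim(st$frames))))
  expect_equal(sort(unique(as.vector(st$frames))), c(0.05, 0.95),
               tolerance = 1e-12)  # Michelson 0.9 binary levels
  phi <- random_pattern(seed = 6, size_px = 400)
  rp <- random_pattern(reverse_phi = TRUE, seed = 6, size_px = 400)
  expect_identical(rp$frames[, , 1], phi$frames[, , 1])
  expect_identical(rp$frames[, , 2], 1 - phi$frames[, , 2])
  expect_identical(rp$frames[, , 3], phi$frames[, , 3])
  # 8.5 deg/s: accumulated-remainder schedule round(14.1667 * t)
  pr <- xt_profile(phi)
  s5 <- round(8.5 / (2 / 400) / 120 * 4)  # displacement at frame 5
  expect_identical(pr[, 5], pr[(((seq_len(400) - 1 - s5) %% 400) + 1), 1])
})

test_that("square waves are Fourier-synthesised with removable fundamental", {
  # at contrast 0.5 no clipping occurs: missing-fundamental stimulus is
  # exactly the square wave minus its first-harmonic grating
  sw <- square_wave_sequence(contrast = 0.5, size_px = 64)
  mf <- square_wave_sequence(missing_fundamental = TRUE, contrast = 0.5,
                             size_px = 64)
  x <- (seq_len(64) - 1) * 2 / 400
  fund <- array(0, dim(sw$frames))
  phase_t <- 2 * pi * 0.25 * ((seq_len(120) - 1) %/% 8)
  for (t in 1:120) {
    prof <- 0.25 * (4 / pi) * sin(2 * pi * 1.5 * x - phase_t[t])
    fund[, , t] <- matrix(prof, 64, 64, byrow = TRUE)
  }
  expect_equal(mf$frames, sw$frames - fund, tolerance = 1e-12)
  # quarter-cycle jumps: 8-frame blocks are static
  expect_identical(sw$frames[, , 1], sw$frames[, , 8])
  expect_false(isTRUE(all.equal(sw$frames[, , 8], sw$frames[, , 9])))
  # at contrast 0.9 Gibbs overshoot is clipped and recorded
  sw9 <- square_wave_sequence(contrast = 0.9, size_px = 64)
  expect_true(sw9$meta$clip_fraction > 0 && sw9$meta$clip_fraction < 0.1)
  expect_true(all(sw9$frames >= 0 & sw9$frames <= 1))
  # smooth drift has no 8-frame plateaus
  sm <- square_wave_sequence(contrast = 0.5, smooth = TRUE, size_px = 64)
  expect_false(isTRUE(all.equal(sm$frames[, , 1], sm$frames[, , 2])))
})

test_that("contrast-modulated stimuli modulate contrast, not luminance", {
  cm <- contrast_modulated(seed = 4, size_px = 64)
  # local contrast in [0.06, 0.54] at the default depth and envelope
  dev <- abs(cm$frames - 0.5)
  expect_lte(max(dev), 0.5 * 0.54 + 1e-9)
  # per-pixel time-averaged luminance ~ 0.5 (uniform carrier phase)
  tmean <- apply(cm$frames[1, , , drop = TRUE], 1, mean)
  expect_lt(max(abs(tmean - 0.5)), 0.05)
  expect_error(contrast_modulated(depth = 0.6), "exceed")
  # seed-averaged x-t spectrum has no net directional energy
  asym <- local({
    acc <- 0
    for (sd in 1:12) {
      pr <- xt_profile(contrast_modulated(seed = sd, size_px = 64))
      acc <- acc + Mod(stats::fft(pr - mean(pr)))
    }
    a <- acc / 12
    flip <- a[, c(1, 120:2)]  # temporal-frequency mirror
    sum(abs(a - flip)) / sum(a)
  })
  expect_lt(asym, 0.15)
})

test_that("compound gratings reduce and commute as sums", {
  one <- compound_grating(sf1 = 2, tf1 = 4, sf2 = 8.5, tf2 = 1,
                          c_each = 0.4, size_px = 64)
  swapped <- compound_grating(sf1 = 8.5, tf1 = 1, sf2 = 2, tf2 = 4,
                              c_each = 0.4, size_px = 64)
  expect_equal(one$frames, swapped$frames, tolerance = 1e-15)
  expect_true(max(one$frames) <= 0.9 + 1e-9 && min(one$frames) >= 0.1 - 1e-9)
  expect_error(compound_grating(c_each = 0.6), "exceed")
})

test_that("DoG LGN filter has the stated gain, linearity and isotropy", {
  # coarse calibration (2 deg / 64 px) so the 3-sigma surround fits
  dpp <- 2 / 64
  unif <- stimulus_sequence(array(0.4, c(64, 64, 8)), 120, dpp)
  out <- apply_dog_lgn(unif)
  # centre integral 1, surround integral 1/5: gain 0.8 on constants
  expect_equal(unique(round(as.vector(out$frames), 12)), 0.4 * 0.8,
               tolerance = 1e-9)
  set.seed(31)
  X <- stimulus_sequence(array(runif(64 * 64 * 2), c(64, 64, 2)), 120, dpp)
  Y <- stimulus_sequence(array(runif(64 * 64 * 2), c(64, 64, 2)), 120, dpp)
  Z <- stimulus_sequence(0.3 * X$frames + 0.7 * Y$frames, 120, dpp)
  lin <- 0.3 * apply_dog_lgn(X)$frames + 0.7 * apply_dog_lgn(Y)$frames
  expect_equal(apply_dog_lgn(Z)$frames, lin, tolerance = 1e-10)
  # isotropy: rotating a pattern by 90 degrees commutes with the filter
  rot90 <- function(m) t(m)[, nrow(m):1]
  pat <- X$frames[, , 1]
  A <- apply_dog_lgn(stimulus_sequence(array(rot90(pat), c(64, 64, 1)),
                                       120, dpp))$frames[, , 1]
  B <- rot90(apply_dog_lgn(stimulus_sequence(array(pat, c(64, 64, 1)),
                                             120, dpp))$frames[, , 1])
  expect_equal(A, B, tolerance = 1e-10)
})

test_that("y-constant fast path equals the generic 2D convolution", {
  g <- drifting_grating(contrast = 0.4, sf_cpd = 2, tf_hz = 4,
                        size_px = 64, n_frames = 6, deg_per_px = 2 / 64)
  fast <- apply_dog_lgn(g)
  generic <- g
  generic$meta$y_constant <- FALSE
  slow <- apply_dog_lgn(generic)
  expect_equal(fast$frames, slow$frames, tolerance = 1e-10)
})

test_that("optical blur is optional, mean-preserving and smoothing", {
  g <- drifting_grating(contrast = 0.4, size_px = 64, n_frames = 6)
  expect_identical(apply_optical_blur(g, 0), g)
  b <- apply_optical_blur(g, 0.02)
  expect_equal(mean(b$frames[, , 1]), mean(g$frames[, , 1]),
               tolerance = 1e-9)
  expect_lt(stats::var(as.vector(b$frames[, , 1])),
            stats::var(as.vector(g$frames[, , 1])))
})

test_that("stimulus container validates range and metadata", {
  expect_error(stimulus_sequence(array(1.5, c(4, 4, 2))), "luminance")
  s <- stimulus_sequence(array(2, c(4, 4, 2)), luminance = FALSE)
  expect_false(s$meta$luminance)
  # phase-shifted gratings are cyclic translations of each other
  g0 <- drifting_grating(0.5, sf_cpd = 2, size_px = 400, n_frames = 2)
  shift_px <- 25L  # pi/2 phase of a 2 c/deg grating at 0.005 deg/px
  gq <- drifting_grating(0.5, sf_cpd = 2, size_px = 400, n_frames = 2,
                         phase = pi / 2)
  expect_equal(gq$frames[1, , 1],
               g0$frames[1, (((seq_len(400) - 1 + shift_px) %% 400) + 1), 1],
               tolerance = 1e-12)
})
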