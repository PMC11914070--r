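#' Construct a stimulus sequence
#'
#' The common container for all model inputs: a 3D luminance stack
#' (height x width x time) with its temporal and spatial calibration and
#' a free-form provenance record.  Luminance stimuli live in `[0, 1]`;
#' pre-filtered stacks (e.g. after the DoG LGN stage) are neural signals
#' and may leave that range, which is flagged by `luminance = FALSE`.
#'
#' @param frames 3D numeric array, dimensions height x width x time.
#' @param fps Frame rate in Hz.
#' @param deg_per_px Degrees of visual angle per pixel.
#' @param meta Named list of provenance fields (recipe name, parameters,
#'   seed).
#' @param luminance Logical; enforce the `[0, 1]` luminance range.
#' @return An object of class `stimulus_sequence`.
#' @export
stimulus_sequence <- function(frames, fps = 120, deg_per_px = 2 / 400,
                              meta = list(), luminance = TRUE) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L,
            is.numeric(frames), fps > 0, deg_per_px > 0)
  if (!all(is.finite(frames))) stop("frames contain non-finite values",
                                    call. = FALSE)
  if (isTRUE(luminance)) {
    tol <- 1e-9
    if (min(frames) < -tol || max(frames) > 1 + tol) {
      stop("luminance values outside [0, 1]; clip before constructing",
           call. = FALSE)
    }
  }
  meta$luminance <- isTRUE(luminance)
  structure(list(frames = frames, fps = fps, deg_per_px = deg_per_px,
                 meta = meta),
            class = "stimulus_sequence")
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Stimulus sequence '%s': %d x %d px, %d frames @ %g Hz (%g deg/px)\n",
              if (is.null(x$meta$name)) "?" else x$meta$name,
              d[1], d[2], d[3], x$fps, x$deg_per_px))
  cat(sprintf("  luminance range [%.3g, %.3g]%s\n",
              min(x$frames), max(x$frames),
              if (!is.null(x$meta$seed)) sprintf(", seed %d", x$meta$seed) else ""))
  invisible(x)
}

#' Space-time (x-t) plot of a stimulus or response field
#'
#' Renders one horizontal row of the stack over time; oriented structure
#' in the plot indicates motion.
#'
#' @param x A `stimulus_sequence`.
#' @param row Row index of the horizontal slice (default: centre).
#' @param ... Passed to [graphics::image()].
#' @export
plot.stimulus_sequence <- function(x, row = NULL, ...) {
  d <- dim(x$frames)
  if (is.null(row)) row <- (d[1] + 1L) %/% 2L
  xt <- x$frames[row, , ]
  graphics::image(x = seq_len(d[3]) / x$fps,
                  y = (seq_len(d[2]) - 1) * x$deg_per_px,
                  z = t(xt), col = grDevices::gray.colors(256, 0, 1),
                  xlab = "time (s)", ylab = "x (deg)", ...)
  invisible(x)
}

# run expr with a temporarily seeded RNG, restoring the caller's state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# expand a width x time profile into a y-constant 3D stack
profile_to_frames <- function(prof, height) {
  array(rep(prof, each = height), dim = c(height, nrow(prof), ncol(prof)))
}

clip_unit <- function(x) pmin(pmax(x, 0), 1)

# accumulated-remainder integer displacement schedule: round(v * frame)
# so the mean displacement per frame is exact without interpolation
shift_schedule <- function(v_px_per_frame, n_frames) {
  as.integer(round(v_px_per_frame * (seq_len(n_frames) - 1)))
}

circ_shift <- function(v, s) {
  n <- length(v)
  s <- ((s %% n) + n) %% n
  if (s == 0L) return(v)
  c(v[(n - s + 1L):n], v[seq_len(n - s)])
}

#' Moving bar stimulus
#'
#' A vertical bar of fixed width translating horizontally at constant
#' speed with wraparound.  Displacement accumulates sub-pixel remainders
#' and is applied as integer shifts, so no interpolation artefacts are
#' introduced.  `polarity = "white"` draws a white bar on black;
#' `"black"` is exactly the luminance inverse.
#'
#' @param width_deg Bar width in degrees.
#' @param speed_deg_s Speed in degrees per second.
#' @param polarity `"white"` (bar = 1 on background 0) or `"black"`.
#' @param direction `+1` rightward, `-1` leftward.
#' @param size_px Image side length in pixels.
#' @param n_frames Number of frames.
#' @param fps Frame rate (Hz).
#' @param deg_per_px Degrees per pixel.
#' @return A `stimulus_sequence`.
#' @export
moving_bar <- function(width_deg = 0.25, speed_deg_s = 2,
                       polarity = c("white", "black"), direction = 1,
                       size_px = 400, n_frames = 120, fps = 120,
                       deg_per_px = 2 / 400) {
  polarity <- match.arg(polarity)
  if (width_deg <= 0) stop("bar width must be positive", call. = FALSE)
  stopifnot(direction %in% c(-1, 1))
  W <- as.integer(size_px)
  width_px <- max(1L, as.integer(round(width_deg / deg_per_px)))
  v_px <- speed_deg_s / deg_per_px / fps
  start <- (W - width_px) %/% 2L
  base <- numeric(W)
  base[start + seq_len(width_px)] <- 1
  shifts <- direction * shift_schedule(v_px, n_frames)
  prof <- vapply(shifts, function(s) circ_shift(base, s), numeric(W))
  if (polarity == "black") prof <- 1 - prof
  stimulus_sequence(profile_to_frames(prof, W), fps, deg_per_px,
                    meta = list(name = "moving_bar", y_constant = TRUE,
                                params = list(width_deg = width_deg,
                                              speed_deg_s = speed_deg_s,
                                              polarity = polarity,
                                              direction = direction)))
}

check_nyquist <- function(sf_cpd, deg_per_px) {
  nyq <- 1 / (2 * deg_per_px)
  if (sf_cpd > nyq) {
    stop("spatial frequency ", sf_cpd, " c/deg exceeds the Nyquist limit ",
         nyq, " c/deg", call. = FALSE)
  }
}

#' Drifting sinusoidal grating
#'
#' \eqn{L(x,t) = 0.5\,(1 + C \sin(2\pi(f_s x - d\, f_t t) + \varphi))}
#' with Michelson contrast `C`, mean luminance 0.5, and `d = +1` for
#' rightward drift.
#'
#' @param contrast Michelson contrast in `[0, 1]`.
#' @param sf_cpd Spatial frequency, cycles per degree.
#' @param tf_hz Temporal (drift) frequency, Hz.
#' @param phase Starting phase, radians.
#' @param direction `+1` rightward, `-1` leftward.
#' @inheritParams moving_bar
#' @return A `stimulus_sequence`.
#' @export
drifting_grating <- function(contrast = 0.4, sf_cpd = 2, tf_hz = 4,
                             phase = 0, direction = 1,
                             size_px = 400, n_frames = 120, fps = 120,
                             deg_per_px = 2 / 400) {
  stopifnot(contrast >= 0, contrast <= 1, direction %in% c(-1, 1))
  check_nyquist(sf_cpd, deg_per_px)
  W <- as.integer(size_px)
  x <- (seq_len(W) - 1) * deg_per_px
  t <- (seq_len(n_frames) - 1) / fps
  arg <- outer(2 * pi * sf_cpd * x, 2 * pi * direction * tf_hz * t, "-") + phase
  prof <- 0.5 * (1 + contrast * sin(arg))
  stimulus_sequence(profile_to_frames(prof, W), fps, deg_per_px,
                    meta = list(name = "drifting_grating", y_constant = TRUE,
                                params = list(contrast = contrast,
                                              sf_cpd = sf_cpd, tf_hz = tf_hz,
                                              phase = phase,
                                              direction = direction)))
}

#' Signal grating masked by phase-jittering noise
#'
#' Sum of a drifting signal grating and a jittering noise grating: the
#' noise has no coherent drift; its spatial phase is resampled uniformly
#' in \eqn{[-\pi,\pi]} at `jitter_hz` and held for `fps / jitter_hz`
#' frames, so its nominal temporal rate equals the jitter rate.
#' Modulations add around the 0.5 mean and the result is clipped to
#' `[0, 1]`; at the default contrasts (0.4 + 0.4) no clipping occurs.
#'
#' @param noise_sf_cpd Spatial frequency of the noise grating (c/deg).
#' @param noise_contrast Michelson contrast of the noise grating.
#' @param jitter_hz Phase-resampling rate of the noise (Hz); must divide
#'   `fps` evenly.
#' @param seed Integer seed for the noise phase schedule.
#' @param signal_contrast,signal_sf_cpd,signal_tf_hz,signal_phase
#'   Parameters of the signal grating.
#' @param direction Drift direction of both components.
#' @inheritParams moving_bar
#' @return A `stimulus_sequence`; `meta$clip_fraction` records how many
#'   pixels were clipped.
#' @export
masked_grating <- function(noise_sf_cpd = 2.5, noise_contrast = 0.4,
                           jitter_hz = 10, seed = NULL,
                           signal_contrast = 0.4, signal_sf_cpd = 2.5,
                           signal_tf_hz = 10, signal_phase = 0,
                           direction = 1,
                           size_px = 400, n_frames = 120, fps = 120,
                           deg_per_px = 2 / 400) {
  check_nyquist(signal_sf_cpd, deg_per_px)
  check_nyquist(noise_sf_cpd, deg_per_px)
  if (abs(fps / jitter_hz - round(fps / jitter_hz)) > 1e-9) {
    stop("jitter_hz must divide fps evenly", call. = FALSE)
  }
  hold <- as.integer(round(fps / jitter_hz))
  W <- as.integer(size_px)
  x <- (seq_len(W) - 1) * deg_per_px
  t <- (seq_len(n_frames) - 1) / fps
  sig <- 0.5 * signal_contrast *
    sin(outer(2 * pi * signal_sf_cpd * x,
              2 * pi * direction * signal_tf_hz * t, "-") + signal_phase)
  n_blocks <- ceiling(n_frames / hold)
  phases <- with_seed(seed, stats::runif(n_blocks, -pi, pi))
  phase_t <- phases[((seq_len(n_frames) - 1) %/% hold) + 1L]
  noise <- 0.5 * noise_contrast *
    sin(outer(2 * pi * noise_sf_cpd * x, phase_t, "+"))
  prof <- 0.5 + sig + noise
  clip_fraction <- mean(prof < 0 | prof > 1)
  prof <- clip_unit(prof)
  stimulus_sequence(profile_to_frames(prof, W), fps, deg_per_px,
                    meta = list(name = "masked_grating", y_constant = TRUE,
                                seed = seed, clip_fraction = clip_fraction,
                                params = list(noise_sf_cpd = noise_sf_cpd,
                                              noise_contrast = noise_contrast,
                                              jitter_hz = jitter_hz,
                                              signal_contrast = signal_contrast,
                                              signal_sf_cpd = signal_sf_cpd,
                                              signal_tf_hz = signal_tf_hz,
                                              signal_phase = signal_phase,
                                              direction = direction)))
}

#' Translating random strip pattern (phi / reverse-phi)
#'
#' A binary random pattern of vertical strips at the given Michelson
#' contrast, translated horizontally with wraparound using
#' accumulated-remainder integer shifts.  With `reverse_phi = TRUE` the
#' contrast polarity is inverted (\eqn{I \to 1 - I}) on every other
#' frame, which reverses the perceived direction of motion.
#'
#' @param reverse_phi Invert contrast polarity on alternate frames.
#' @param contrast Michelson contrast of the binary pattern.
#' @param speed_deg_s Translation speed, degrees per second.
#' @param element_px Strip width in pixels.
#' @param seed Integer seed for the random pattern.
#' @inheritParams moving_bar
#' @return A `stimulus_sequence`.
#' @export
random_pattern <- function(reverse_phi = FALSE, contrast = 0.9,
                           speed_deg_s = 8.5, element_px = 10, seed = NULL,
                           size_px = 400, n_frames = 120, fps = 120,
                           deg_per_px = 2 / 400) {
  stopifnot(element_px >= 1, contrast >= 0, contrast <= 1)
  W <- as.integer(size_px)
  n_elem <- ceiling(W / element_px)
  bits <- with_seed(seed, stats::rbinom(n_elem, 1L, 0.5))
  base <- 0.5 + (contrast / 2) * (2 * rep(bits, each = element_px)[seq_len(W)] - 1)
  v_px <- speed_deg_s / deg_per_px / fps
  shifts <- shift_schedule(v_px, n_frames)
  prof <- vapply(shifts, function(s) circ_shift(base, s), numeric(W))
  if (reverse_phi) {
    odd <- seq(2L, n_frames, by = 2L)  # frames 1, 3, ... counting from 0
    prof[, odd] <- 1 - prof[, odd]
  }
  stimulus_sequence(profile_to_frames(prof, W), fps, deg_per_px,
                    meta = list(name = "random_pattern", y_constant = TRUE,
                                seed = seed,
                                params = list(reverse_phi = reverse_phi,
                                              contrast = contrast,
                                              speed_deg_s = speed_deg_s,
                                              element_px = element_px)))
}

#' Square-wave grating, optionally without its fundamental
#'
#' The square wave is synthesised from its Fourier series (odd harmonics
#' up to the Nyquist limit); with `missing_fundamental = TRUE` the first
#' harmonic is omitted before synthesis.  Motion is either a
#' quarter-period displacement every `jump_ms` milliseconds (the stepping
#' regime in which the missing-fundamental illusion appears) or smooth
#' drift at `tf_hz`.  Gibbs overshoot at contrast 0.9 slightly exceeds
#' the luminance range and is clipped; the clipped fraction is recorded.
#'
#' @param missing_fundamental Remove the first harmonic before synthesis.
#' @param smooth Continuous drift instead of quarter-cycle jumps.
#' @param contrast Michelson contrast of the square wave.
#' @param sf_cpd Spatial frequency (c/deg).
#' @param tf_hz Temporal frequency for smooth drift (Hz).
#' @param jump_ms Duration of each quarter-cycle jump (ms); rounded to
#'   whole frames.
#' @param phase Starting phase, radians.
#' @param direction `+1` rightward, `-1` leftward.
#' @inheritParams moving_bar
#' @return A `stimulus_sequence`.
#' @export
square_wave_sequence <- function(missing_fundamental = FALSE, smooth = FALSE,
                                 contrast = 0.9, sf_cpd = 1.5, tf_hz = 4,
                                 jump_ms = 66, phase = 0, direction = 1,
                                 size_px = 400, n_frames = 120, fps = 120,
                                 deg_per_px = 2 / 400) {
  stopifnot(contrast >= 0, contrast <= 1, direction %in% c(-1, 1))
  check_nyquist(sf_cpd, deg_per_px)
  W <- as.integer(size_px)
  x <- (seq_len(W) - 1) * deg_per_px
  if (smooth) {
    phase_t <- 2 * pi * tf_hz * (seq_len(n_frames) - 1) / fps
  } else {
    frames_per_jump <- jump_ms * fps / 1000
    fpj <- max(1L, as.integer(round(frames_per_jump)))
    if (abs(frames_per_jump - fpj) > 0.1) {
      warning("jump duration of ", jump_ms, " ms is ", frames_per_jump,
              " frames; rounding to ", fpj, " frames", call. = FALSE)
    }
    phase_t <- 2 * pi * 0.25 * ((seq_len(n_frames) - 1) %/% fpj)
  }
  nyq <- 1 / (2 * deg_per_px)
  harmonics <- seq(1L, floor(nyq / sf_cpd), by = 2L)
  if (missing_fundamental) harmonics <- harmonics[harmonics != 1L]
  prof <- matrix(0, W, n_frames)
  for (h in harmonics) {
    arg <- outer(2 * pi * h * sf_cpd * x, h * direction * phase_t, "-") +
      h * phase
    prof <- prof + (4 / pi) * sin(arg) / h
  }
  prof <- 0.5 + (contrast / 2) * prof
  clip_fraction <- mean(prof < 0 | prof > 1)
  prof <- clip_unit(prof)
  stimulus_sequence(profile_to_frames(prof, W), fps, deg_per_px,
                    meta = list(name = "square_wave", y_constant = TRUE,
                                clip_fraction = clip_fraction,
                                params = list(missing_fundamental = missing_fundamental,
                                              smooth = smooth,
                                              contrast = contrast,
                                              sf_cpd = sf_cpd, tf_hz = tf_hz,
                                              jump_ms = jump_ms, phase = phase,
                                              direction = direction)))
}

#' Contrast-modulated (second-order) stimulus
#'
#' A drifting contrast envelope over a phase-jittering carrier:
#' \deqn{L(x,t) = 0.5\,(1 + c(x,t) \sin(2\pi f_c x + \theta_t)), \quad
#'   c(x,t) = d\,(1 + C_e \sin(2\pi(f_e x - \mathrm{dir}\, f_t t) + \varphi))}
#' with the carrier phase \eqn{\theta_t} resampled uniformly in
#' \eqn{[-\pi,\pi]} on every frame.  Mean luminance is 0.5 everywhere and
#' the seed-averaged luminance carries no net directional Fourier energy:
#' only the contrast envelope moves (second-order motion).
#'
#' @param direction Envelope drift direction, `+1` rightward.
#' @param env_sf_cpd,env_tf_hz,env_contrast Envelope spatial frequency
#'   (c/deg), drift rate (Hz) and Michelson contrast.
#' @param carrier_sf_cpd Carrier spatial frequency (c/deg).
#' @param depth Modulation depth: the mean local carrier contrast.
#' @param seed Integer seed for the carrier phase jitter.
#' @param phase Envelope starting phase, radians.
#' @inheritParams moving_bar
#' @return A `stimulus_sequence`.
#' @export
contrast_modulated <- function(direction = 1, env_sf_cpd = 1, env_tf_hz = 7,
                               env_contrast = 0.8, carrier_sf_cpd = 4,
                               depth = 0.3, seed = NULL, phase = 0,
                               size_px = 400, n_frames = 120, fps = 120,
                               deg_per_px = 2 / 400) {
  stopifnot(direction %in% c(-1, 1), env_contrast >= 0, depth >= 0)
  check_nyquist(carrier_sf_cpd, deg_per_px)
  check_nyquist(env_sf_cpd, deg_per_px)
  if (depth * (1 + env_contrast) > 1 + 1e-9) {
    stop("depth * (1 + env_contrast) must not exceed 1: the local ",
         "contrast envelope would leave [0, 1]", call. = FALSE)
  }
  W <- as.integer(size_px)
  x <- (seq_len(W) - 1) * deg_per_px
  t <- (seq_len(n_frames) - 1) / fps
  env <- depth * (1 + env_contrast *
                    sin(outer(2 * pi * env_sf_cpd * x,
                              2 * pi * direction * env_tf_hz * t, "-") + phase))
  theta <- with_seed(seed, stats::runif(n_frames, -pi, pi))
  carrier <- sin(outer(2 * pi * carrier_sf_cpd * x, theta, "+"))
  prof <- 0.5 * (1 + env * carrier)
  stimulus_sequence(profile_to_frames(prof, W), fps, deg_per_px,
                    meta = list(name = "contrast_modulated", y_constant = TRUE,
                                seed = seed,
                                params = list(direction = direction,
                                              env_sf_cpd = env_sf_cpd,
                                              env_tf_hz = env_tf_hz,
                                              env_contrast = env_contrast,
                                              carrier_sf_cpd = carrier_sf_cpd,
                                              depth = depth, phase = phase)))
}

#' Sum of two drifting gratings
#'
#' Mean luminance 0.5 plus two drifting sinusoidal modulations, both
#' moving in the same direction.  Used for probing the (non)linearity of
#' the sensor: a component that is negligible alone can strongly modulate
#' the response to another component.
#'
#' @param sf1,tf1,phase1 First component: spatial frequency (c/deg),
#'   temporal frequency (Hz), starting phase (rad).
#' @param sf2,tf2,phase2 Second component.
#' @param c_each Michelson contrast of each component.
#' @param direction Common drift direction.
#' @inheritParams moving_bar
#' @return A `stimulus_sequence`.
#' @export
compound_grating <- function(sf1 = 2, tf1 = 4, sf2 = 8.5, tf2 = 1,
                             c_each = 0.4, phase1 = 0, phase2 = 0,
                             direction = 1,
                             size_px = 400, n_frames = 120, fps = 120,
                             deg_per_px = 2 / 400) {
  check_nyquist(sf1, deg_per_px)
  check_nyquist(sf2, deg_per_px)
  if (2 * c_each > 1 + 1e-9) {
    stop("summed modulation 2 * c_each exceeds the luminance range",
         call. = FALSE)
  }
  W <- as.integer(size_px)
  x <- (seq_len(W) - 1) * deg_per_px
  t <- (seq_len(n_frames) - 1) / fps
  g1 <- sin(outer(2 * pi * sf1 * x, 2 * pi * direction * tf1 * t, "-") + phase1)
  g2 <- sin(outer(2 * pi * sf2 * x, 2 * pi * direction * tf2 * t, "-") + phase2)
  prof <- 0.5 + 0.5 * c_each * (g1 + g2)
  stimulus_sequence(profile_to_frames(prof, W), fps, deg_per_px,
                    meta = list(name = "compound_grating", y_constant = TRUE,
                                params = list(sf1 = sf1, tf1 = tf1,
                                              sf2 = sf2, tf2 = tf2,
                                              c_each = c_each,
                                              phase1 = phase1, phase2 = phase2,
                                              direction = direction)))
}

# --- spatial pre-filters -------------------------------------------------

gaussian_1d <- function(sigma_px, radius) {
  d <- seq(-radius, radius)
  g <- exp(-d^2 / (2 * sigma_px^2))
  g / sum(g)
}

# 2D kernel embedded in an H x W matrix with its centre wrapped to (1,1),
# ready for FFT-based circular convolution
embed_kernel <- function(k, H, W) {
  kh <- nrow(k); kw <- ncol(k)
  if (kh > H || kw > W) stop("kernel larger than the frame", call. = FALSE)
  pad <- matrix(0, H, W)
  rc <- (kh + 1L) %/% 2L; cc <- (kw + 1L) %/% 2L
  rows <- ((seq_len(kh) - rc) %% H) + 1L
  cols <- ((seq_len(kw) - cc) %% W) + 1L
  pad[rows, cols] <- pad[rows, cols] + k
  pad
}

# circular 2D convolution of every frame with kernel k (via FFT)
convolve_frames_2d <- function(frames, k) {
  d <- dim(frames)
  fk <- stats::fft(embed_kernel(k, d[1], d[2]))
  out <- frames
  for (t in seq_len(d[3])) {
    out[, , t] <- Re(stats::fft(stats::fft(frames[, , t]) * fk,
                                inverse = TRUE)) / (d[1] * d[2])
  }
  out
}

# circular 1D convolution of a W x T profile along x (via FFT)
convolve_profile_1d <- function(prof, k1) {
  W <- nrow(prof)
  if (length(k1) > W) stop("kernel larger than the frame", call. = FALSE)
  pad <- numeric(W)
  cc <- (length(k1) + 1L) %/% 2L
  idx <- ((seq_along(k1) - cc) %% W) + 1L
  pad[idx] <- pad[idx] + k1
  fk <- stats::fft(pad)
  out <- stats::mvfft(stats::mvfft(prof) * fk, inverse = TRUE)
  Re(out) / W
}

# apply a separable-symmetric 2D kernel (given as a full 2D matrix) to a
# stimulus; y-constant stacks use the exact 1D projection of the kernel
apply_kernel_stack <- function(seq, k, name, luminance) {
  d <- dim(seq$frames)
  meta <- seq$meta
  meta$name <- paste0(meta$name, "+", name)
  if (isTRUE(meta$y_constant)) {
    prof <- matrix(seq$frames[1L, , ], d[2], d[3])
    out <- convolve_profile_1d(prof, colSums(k))
    frames <- profile_to_frames(out, d[1])
  } else {
    frames <- convolve_frames_2d(seq$frames, k)
  }
  stimulus_sequence(frames, seq$fps, seq$deg_per_px, meta = meta,
                    luminance = luminance)
}

dog_kernel <- function(center_sigma_deg, surround_sigma_deg, balance,
                       deg_per_px) {
  sc <- center_sigma_deg / deg_per_px
  ss <- surround_sigma_deg / deg_per_px
  r <- as.integer(ceiling(3 * ss))
  gc1 <- gaussian_1d(sc, r)
  gs1 <- gaussian_1d(ss, r)
  outer(gc1, gc1) - outer(gs1, gs1) / balance
}

#' Difference-of-Gaussians LGN pre-filter
#'
#' Convolves every frame with a centre-surround DoG kernel emulating
#' processing in the lateral geniculate nucleus.  The centre Gaussian has
#' unit integral and the surround integral is `1/balance` of it, so a
#' uniform input of value `c` maps to `c * (1 - 1/balance)`.  Boundaries
#' are circular, consistent with the periodic stimuli.  The output is a
#' neural signal and is not clipped to `[0, 1]`.
#'
#' @param seq A `stimulus_sequence`.
#' @param center_sigma_deg,surround_sigma_deg Standard deviations of the
#'   centre and surround Gaussians (deg).
#' @param balance Ratio of integrated centre weight to integrated
#'   surround weight.
#' @return A `stimulus_sequence` with `meta$luminance = FALSE`.
#' @export
apply_dog_lgn <- function(seq, center_sigma_deg = 0.036,
                          surround_sigma_deg = 0.18, balance = 5) {
  stopifnot(inherits(seq, "stimulus_sequence"))
  k <- dog_kernel(center_sigma_deg, surround_sigma_deg, balance,
                  seq$deg_per_px)
  apply_kernel_stack(seq, k, "dog_lgn", luminance = FALSE)
}

#' Optional optical pre-blur
#'
#' Per-frame Gaussian blur standing in for the optical point-spread
#' function of the eye.  Off (`sigma = 0`, identity) by default in all
#' experiments; included so that its effect on any phenomenon can be
#' checked.
#'
#' @param seq A `stimulus_sequence`.
#' @param psf_sigma_deg Standard deviation of the Gaussian PSF (deg);
#'   `0` returns the input unchanged.
#' @return A `stimulus_sequence`.
#' @export
apply_optical_blur <- function(seq, psf_sigma_deg = 0) {
  stopifnot(inherits(seq, "stimulus_sequence"), psf_sigma_deg >= 0)
  if (psf_sigma_deg == 0) return(seq)
  s <- psf_sigma_deg / seq$deg_per_px
  r <- as.integer(ceiling(3 * s))
  g1 <- gaussian_1d(s, r)
  k <- outer(g1, g1)
  out <- apply_kernel_stack(seq, k, "optical_blur", luminance = FALSE)
  out$frames <- clip_unit(out$frames)
  out$meta$luminance <- TRUE
  out
}
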