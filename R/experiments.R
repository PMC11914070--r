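#' @name msinrf-experiments
#' @title Scripted motion-perception experiments
#'
#' @description
#' Each experiment builds its stimuli from the shared recipes, evaluates
#' the motion sensor at the image centre, averages over starting phases
#' or random generations, and returns an `experiment_result` whose
#' config (including every seed) regenerates it bit-identically.
NULL

new_experiment_result <- function(name, grid, responses, dispersion,
                                  config) {
  stopifnot(is.data.frame(grid), nrow(grid) == length(responses))
  structure(list(name = name, grid = grid,
                 responses = as.numeric(responses),
                 dispersion = as.numeric(dispersion),
                 config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment '%s' (%d grid points)\n", x$name, nrow(x$grid)))
  df <- cbind(x$grid, response = signif(x$responses, 5),
              dispersion = signif(x$dispersion, 3))
  print(utils::head(df, 12), row.names = FALSE)
  if (nrow(df) > 12) cat("  ...", nrow(df) - 12, "more rows\n")
  invisible(x)
}

#' @export
plot.experiment_result <- function(x, ...) {
  num_vars <- vapply(x$grid, is.numeric, logical(1))
  if (any(num_vars)) {
    v <- x$grid[[which(num_vars)[1]]]
    graphics::plot(v, x$responses, type = "b", pch = 16,
                   xlab = names(x$grid)[which(num_vars)[1]],
                   ylab = "MS-INRF response", main = x$name, ...)
  } else {
    graphics::barplot(x$responses, names.arg = do.call(paste, x$grid),
                      ylab = "MS-INRF response", main = x$name, ...)
  }
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

# n equally spaced starting phases covering [-pi, pi) once
phase_grid <- function(n) seq(-pi, pi, length.out = n + 1L)[seq_len(n)]

sensor_value <- function(seq, params, lgn = FALSE) {
  if (lgn) seq <- apply_dog_lgn(seq)
  ms_inrf(seq, params)$value
}

#' First-order motion opponency
#'
#' Runs the moving-bar stimulus in all four combinations of contrast
#' polarity (white bar on black, black bar on white) and direction.
#' Responses are positive for rightward and negative for leftward
#' motion, and nearly invariant to polarity: swapping polarity leaves
#' the nonlinear term exactly unchanged (the nonlinearity is even), so
#' only a small linear-term residue distinguishes the two.
#'
#' @param params An [msinrf_params()] object.
#' @param size_px,n_frames Stimulus geometry.
#' @return An `experiment_result` with four conditions.
#' @export
run_first_order <- function(params = msinrf_params(), size_px = 400,
                            n_frames = 120) {
  grid <- expand.grid(polarity = c("white", "black"),
                      direction = c(1, -1), stringsAsFactors = FALSE)
  responses <- mapply(function(pol, dir) {
    sensor_value(moving_bar(polarity = pol, direction = dir,
                            size_px = size_px, n_frames = n_frames,
                            fps = params$fps,
                            deg_per_px = params$deg_per_px), params)
  }, grid$polarity, grid$direction)
  new_experiment_result("first_order", grid, responses,
                        rep(NA_real_, nrow(grid)),
                        list(params = unclass(params), size_px = size_px,
                             n_frames = n_frames))
}

#' Contrast response curve of the sensor
#'
#' Phase-averaged responses to a rightward-drifting grating over a grid
#' of Michelson contrasts.  The magnitude grows monotonically but
#' saturates: its log-log slope over the top quartile of contrasts is
#' smaller than over the bottom quartile, as in cortical contrast
#' response functions.
#'
#' @param n_contrasts Number of equally spaced contrasts in `[0, 1]`.
#' @param n_phases Number of equally spaced starting phases.
#' @param sf_cpd,tf_hz Grating spatial (c/deg) and temporal (Hz)
#'   frequency.
#' @inheritParams run_first_order
#' @return An `experiment_result` over the contrast grid.
#' @export
contrast_response_curve <- function(n_contrasts = 20, n_phases = 10,
                                    sf_cpd = 2, tf_hz = 4,
                                    params = msinrf_params(),
                                    size_px = 400, n_frames = 120) {
  contrasts <- seq(0, 1, length.out = n_contrasts)
  phases <- phase_grid(n_phases)
  res <- vapply(contrasts, function(ct) {
    r <- vapply(phases, function(ph) {
      sensor_value(drifting_grating(ct, sf_cpd, tf_hz, phase = ph,
                                    direction = 1, size_px = size_px,
                                    n_frames = n_frames, fps = params$fps,
                                    deg_per_px = params$deg_per_px), params)
    }, numeric(1))
    c(mean(r), stats::sd(r))
  }, numeric(2))
  new_experiment_result("contrast_saturation",
                        data.frame(contrast = contrasts),
                        res[1, ], res[2, ],
                        list(params = unclass(params),
                             n_contrasts = n_contrasts, n_phases = n_phases,
                             sf_cpd = sf_cpd, tf_hz = tf_hz,
                             size_px = size_px, n_frames = n_frames))
}

#' Motion masking by jittering noise
#'
#' Phase-averaged responses to a drifting signal grating alone and
#' summed with a phase-jittering noise grating whose spatial frequency
#' sweeps a grid.  Suppression is tuned: it is strongest when the noise
#' spatial frequency is close to the signal's, and weak far from it.
#' The normalised reciprocal of the masked response (a sensitivity-style
#' curve, maximum 1) is returned as an extra column.
#'
#' @param lgn Apply the DoG LGN pre-filter to every stimulus first.
#' @param n_noise_sf Number of noise spatial frequencies, equally spaced
#'   in `[0, 10]` c/deg.
#' @param n_phases Number of signal starting phases.
#' @param seed Base seed for the noise phase schedules.
#' @param signal_sf_cpd,signal_tf_hz,signal_contrast Signal grating
#'   parameters.
#' @inheritParams run_first_order
#' @return An `experiment_result`; the first row is the unmasked signal
#'   (`noise_sf = NA`), the rest the masked conditions.
#' @export
masking_curve <- function(lgn = FALSE, n_noise_sf = 20, n_phases = 10,
                          seed = 1, signal_sf_cpd = 2.5,
                          signal_tf_hz = 10, signal_contrast = 0.4,
                          params = msinrf_params(),
                          size_px = 400, n_frames = 120) {
  phases <- phase_grid(n_phases)
  noise_sfs <- seq(0, 10, length.out = n_noise_sf)
  alone <- vapply(phases, function(ph) {
    sensor_value(drifting_grating(signal_contrast, signal_sf_cpd,
                                  signal_tf_hz, phase = ph, direction = 1,
                                  size_px = size_px, n_frames = n_frames,
                                  fps = params$fps,
                                  deg_per_px = params$deg_per_px),
                 params, lgn)
  }, numeric(1))
  masked <- vapply(seq_along(noise_sfs), function(i) {
    r <- vapply(seq_along(phases), function(j) {
      sensor_value(masked_grating(noise_sf_cpd = noise_sfs[i],
                                  seed = seed + 1000L * i + j,
                                  signal_contrast = signal_contrast,
                                  signal_sf_cpd = signal_sf_cpd,
                                  signal_tf_hz = signal_tf_hz,
                                  signal_phase = phases[j],
                                  size_px = size_px, n_frames = n_frames,
                                  fps = params$fps,
                                  deg_per_px = params$deg_per_px),
                   params, lgn)
    }, numeric(1))
    c(mean(r), stats::sd(r))
  }, numeric(2))
  resp <- c(mean(alone), masked[1, ])
  disp <- c(stats::sd(alone), masked[2, ])
  recip <- 1 / abs(masked[1, ])
  grid <- data.frame(condition = c("signal_alone",
                                   rep("signal_plus_noise", n_noise_sf)),
                     noise_sf = c(NA_real_, noise_sfs),
                     recip_norm = c(NA_real_, recip / max(recip)))
  new_experiment_result(if (lgn) "masking_lgn" else "masking",
                        grid, resp, disp,
                        list(params = unclass(params), lgn = lgn,
                             n_noise_sf = n_noise_sf, n_phases = n_phases,
                             seed = seed, signal_sf_cpd = signal_sf_cpd,
                             signal_tf_hz = signal_tf_hz,
                             signal_contrast = signal_contrast,
                             size_px = size_px, n_frames = n_frames))
}

#' Reverse-phi motion
#'
#' Seed-averaged responses to a rightward-translating random strip
#' pattern (phi) and to the same pattern with its contrast polarity
#' inverted on every other frame (reverse-phi).  The sensor follows
#' perception: phi gives a positive (rightward) response, reverse-phi a
#' negative one.
#'
#' @param n_seeds Number of independent random patterns to average.
#' @param seed Base seed; pattern `i` uses `seed + i`.
#' @param element_px Strip width of the random pattern, pixels.
#' @inheritParams run_first_order
#' @return An `experiment_result` with conditions `phi` / `reverse_phi`.
#' @export
reverse_phi_experiment <- function(n_seeds = 10, seed = 1,
                                   element_px = 10,
                                   params = msinrf_params(),
                                   size_px = 400, n_frames = 120) {
  one <- function(rp) {
    vapply(seq_len(n_seeds), function(i) {
      sensor_value(random_pattern(reverse_phi = rp, seed = seed + i,
                                  element_px = element_px,
                                  size_px = size_px, n_frames = n_frames,
                                  fps = params$fps,
                                  deg_per_px = params$deg_per_px), params)
    }, numeric(1))
  }
  phi <- one(FALSE); rphi <- one(TRUE)
  new_experiment_result("reverse_phi",
                        data.frame(condition = c("phi", "reverse_phi")),
                        c(mean(phi), mean(rphi)),
                        c(stats::sd(phi), stats::sd(rphi)),
                        list(params = unclass(params), n_seeds = n_seeds,
                             seed = seed, element_px = element_px,
                             size_px = size_px, n_frames = n_frames))
}

#' Missing-fundamental illusion
#'
#' Phase-averaged responses to a rightward square-wave grating and to
#' the same grating with its fundamental removed.  In the quarter-cycle
#' jump regime the square wave yields a positive response and the
#' missing-fundamental stimulus a negative one (the illusory reversal);
#' with smooth drift both are positive and the illusion disappears.
#'
#' @param smooth Continuous drift instead of quarter-cycle jumps.
#' @param n_phases Number of starting phases.
#' @inheritParams run_first_order
#' @return An `experiment_result` with conditions `square_wave` /
#'   `missing_fundamental`.
#' @export
missing_fundamental_experiment <- function(smooth = FALSE, n_phases = 10,
                                           params = msinrf_params(),
                                           size_px = 400, n_frames = 120) {
  phases <- phase_grid(n_phases)
  one <- function(mf) {
    vapply(phases, function(ph) {
      sensor_value(square_wave_sequence(missing_fundamental = mf,
                                        smooth = smooth, phase = ph,
                                        size_px = size_px,
                                        n_frames = n_frames,
                                        fps = params$fps,
                                        deg_per_px = params$deg_per_px),
                   params)
    }, numeric(1))
  }
  sw <- one(FALSE); mf <- one(TRUE)
  new_experiment_result("missing_fundamental",
                        data.frame(condition = c("square_wave",
                                                 "missing_fundamental")),
                        c(mean(sw), mean(mf)),
                        c(stats::sd(sw), stats::sd(mf)),
                        list(params = unclass(params), smooth = smooth,
                             n_phases = n_phases, size_px = size_px,
                             n_frames = n_frames))
}

#' Second-order (contrast-defined) motion
#'
#' Phase-averaged responses to contrast-modulated stimuli whose
#' luminance carries no net directional Fourier energy: only the
#' contrast envelope drifts.  The sensor's sign follows the envelope
#' direction.  A static-envelope control (envelope contrast 0) run over
#' extra seeds estimates the noise floor against which "no response"
#' is judged.
#'
#' @param n_phases Number of envelope starting phases.
#' @param n_control_seeds Seeds for the static-envelope noise-floor
#'   control.
#' @param seed Base seed for the carrier phase jitter.
#' @inheritParams run_first_order
#' @return An `experiment_result` with conditions `rightward`,
#'   `leftward`, `static_control`.
#' @export
second_order_experiment <- function(n_phases = 10, n_control_seeds = 10,
                                    seed = 1, params = msinrf_params(),
                                    size_px = 400, n_frames = 120) {
  phases <- phase_grid(n_phases)
  one <- function(dir) {
    vapply(seq_along(phases), function(j) {
      sensor_value(contrast_modulated(direction = dir, phase = phases[j],
                                      seed = seed + 100L * j +
                                        (if (dir > 0) 0L else 50L),
                                      size_px = size_px,
                                      n_frames = n_frames,
                                      fps = params$fps,
                                      deg_per_px = params$deg_per_px),
                   params)
    }, numeric(1))
  }
  rw <- one(1); lw <- one(-1)
  ctrl <- vapply(seq_len(n_control_seeds), function(i) {
    sensor_value(contrast_modulated(direction = 1, env_contrast = 0,
                                    seed = seed + 10000L + i,
                                    size_px = size_px, n_frames = n_frames,
                                    fps = params$fps,
                                    deg_per_px = params$deg_per_px),
                 params)
  }, numeric(1))
  new_experiment_result("second_order",
                        data.frame(condition = c("rightward", "leftward",
                                                 "static_control")),
                        c(mean(rw), mean(lw), mean(ctrl)),
                        c(stats::sd(rw), stats::sd(lw), stats::sd(ctrl)),
                        list(params = unclass(params), n_phases = n_phases,
                             n_control_seeds = n_control_seeds, seed = seed,
                             size_px = size_px, n_frames = n_frames))
}

#' Nonlinearity maps over spatio-temporal frequency
#'
#' Two response maps over a grid of spatial (`[0, 10]` c/deg) and
#' temporal (`[0, 30]` Hz) frequencies: responses to a single rightward
#' grating, and responses to the same grating summed with a fixed
#' component G (8.5 c/deg, 1 Hz) whose isolated response is negligible.
#' For a linear system the two maps would coincide (up to G's own
#' response); their difference exposes the sensor's nonlinearity.
#' Compound conditions average over all pairs of starting phases of the
#' two components.  The full-print protocol (100 x 100 frequencies, 10
#' phases) is available by argument; the default is a coarse desk-scale
#' grid that preserves the qualitative conclusion.
#'
#' @param n_sf,n_tf Number of spatial / temporal frequencies.
#' @param n_phases Number of starting phases per component (compound
#'   conditions use all `n_phases^2` pairs).
#' @param g_sf_cpd,g_tf_hz Frequencies of the fixed component G.
#' @param c_each Michelson contrast of every component.
#' @inheritParams run_first_order
#' @return A list of class `nonlinearity_maps`: `single` and `compound`
#'   `experiment_result`s over the same grid, `g_response` (phase-mean
#'   response to G alone), and `stats` with `g_ratio`
#'   (|G response| / max |single map|) and `max_violation_ratio`
#'   (max |compound - single| / max |single map|).
#' @export
nonlinearity_maps <- function(n_sf = 20, n_tf = 20, n_phases = 4,
                              g_sf_cpd = 8.5, g_tf_hz = 1, c_each = 0.4,
                              params = msinrf_params(),
                              size_px = 400, n_frames = 120) {
  sfs <- seq(0, 10, length.out = n_sf)
  tfs <- seq(0, 30, length.out = n_tf)
  phases <- phase_grid(n_phases)
  grid <- expand.grid(sf_cpd = sfs, tf_hz = tfs)

  single <- vapply(seq_len(nrow(grid)), function(i) {
    r <- vapply(phases, function(ph) {
      sensor_value(drifting_grating(c_each, grid$sf_cpd[i], grid$tf_hz[i],
                                    phase = ph, direction = 1,
                                    size_px = size_px, n_frames = n_frames,
                                    fps = params$fps,
                                    deg_per_px = params$deg_per_px), params)
    }, numeric(1))
    c(mean(r), stats::sd(r))
  }, numeric(2))

  g_resp <- mean(vapply(phases, function(ph) {
    sensor_value(drifting_grating(c_each, g_sf_cpd, g_tf_hz, phase = ph,
                                  direction = 1, size_px = size_px,
                                  n_frames = n_frames, fps = params$fps,
                                  deg_per_px = params$deg_per_px), params)
  }, numeric(1)))

  pairs <- expand.grid(p1 = phases, p2 = phases)
  compound <- vapply(seq_len(nrow(grid)), function(i) {
    r <- vapply(seq_len(nrow(pairs)), function(k) {
      sensor_value(compound_grating(sf1 = grid$sf_cpd[i],
                                    tf1 = grid$tf_hz[i],
                                    sf2 = g_sf_cpd, tf2 = g_tf_hz,
                                    c_each = c_each,
                                    phase1 = pairs$p1[k],
                                    phase2 = pairs$p2[k],
                                    size_px = size_px, n_frames = n_frames,
                                    fps = params$fps,
                                    deg_per_px = params$deg_per_px), params)
    }, numeric(1))
    c(mean(r), stats::sd(r))
  }, numeric(2))

  config <- list(params = unclass(params), n_sf = n_sf, n_tf = n_tf,
                 n_phases = n_phases, g_sf_cpd = g_sf_cpd,
                 g_tf_hz = g_tf_hz, c_each = c_each,
                 size_px = size_px, n_frames = n_frames)
  single_res <- new_experiment_result("nonlinearity_single", grid,
                                      single[1, ], single[2, ], config)
  compound_res <- new_experiment_result("nonlinearity_compound", grid,
                                        compound[1, ], compound[2, ], config)
  max_single <- max(abs(single[1, ]))
  structure(list(single = single_res, compound = compound_res,
                 g_response = g_resp,
                 stats = list(g_ratio = abs(g_resp) / max_single,
                              max_violation_ratio =
                                max(abs(compound[1, ] - single[1, ])) /
                                max_single),
                 config = config),
            class = "nonlinearity_maps")
}

#' @export
print.nonlinearity_maps <- function(x, ...) {
  cat(sprintf("Nonlinearity maps: %d x %d frequency grid, %d phases\n",
              x$config$n_sf, x$config$n_tf, x$config$n_phases))
  cat(sprintf("  response to G alone: %.5g (%.2f%% of single-map max)\n",
              x$g_response, 100 * x$stats$g_ratio))
  cat(sprintf("  max |compound - single|: %.2f%% of single-map max\n",
              100 * x$stats$max_violation_ratio))
  invisible(x)
}

#' @export
plot.nonlinearity_maps <- function(x, which = c("single", "compound"), ...) {
  which <- match.arg(which)
  r <- x[[which]]
  sfs <- sort(unique(r$grid$sf_cpd))
  tfs <- sort(unique(r$grid$tf_hz))
  z <- matrix(r$responses, length(sfs), length(tfs))
  graphics::image(sfs, tfs, z, xlab = "spatial frequency (c/deg)",
                  ylab = "temporal frequency (Hz)",
                  main = paste("MS-INRF map:", which), ...)
  invisible(x)
}
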