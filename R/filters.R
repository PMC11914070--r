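#' @useDynLib msinrf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Closed forms of the two temporal filters, t in milliseconds.
# T_m is bandpass (biphasic), T_w lowpass; both have 50 ms support at the
# default parameterisation and are used unnormalised: the weight lambda is
# an absolute number, so rescaling the taps would silently change the
# balance between the linear and the nonlinear term.
tm_closed_form <- function(t, k, n) {
  kt <- k * t
  kt^n * exp(-kt) * (1 / factorial(n) - kt^2 / factorial(n + 2L))
}

tw_closed_form <- function(t) {
  cos(pi * (t + 10) / 120)
}

new_sampled_filter <- function(taps, dt_ms, duration_ms, name) {
  stopifnot(all(is.finite(taps)), dt_ms > 0)
  structure(list(taps = as.numeric(taps), dt_ms = dt_ms,
                 duration_ms = duration_ms, name = name),
            class = "sampled_filter")
}

#' Sample the bandpass temporal filter of the linear term
#'
#' Evaluates \eqn{T_m(t) = (kt)^n e^{-kt}\left[\frac{1}{n!} -
#' \frac{(kt)^2}{(n+2)!}\right]} at the frame delays
#' \eqn{u = 0, \Delta t, 2\Delta t, \dots} up to its total duration, with
#' \eqn{\Delta t = 1000/\mathrm{fps}} ms.  The filter is biphasic
#' (bandpass): positive at short delays with a single sign change inside
#' its support.  Taps are returned unnormalised.
#'
#' @param params An [msinrf_params()] object.
#' @return A `sampled_filter` with fields `taps`, `dt_ms`, `duration_ms`.
#' @examples
#' tm <- sample_tm(msinrf_params())
#' length(tm$taps)  # 7 taps at 120 Hz over 50 ms
#' @export
sample_tm <- function(params = msinrf_params()) {
  validate_params(params)
  dt <- 1000 / params$fps
  u <- seq(0, params$tm_duration_ms, by = dt)
  new_sampled_filter(tm_closed_form(u, params$k, params$n),
                     dt, params$tm_duration_ms, "T_m")
}

#' Sample the lowpass temporal filter of the nonlinear term
#'
#' Evaluates \eqn{T_w(t) = \cos\big(\pi (t + 10) / 120\big)} at the frame
#' delays \eqn{u = 0, \Delta t, \dots} up to its total duration.  On the
#' default 50 ms support the filter is non-negative (lowpass), falling
#' from \eqn{\cos(\pi/12)} at zero delay to exactly 0 at 50 ms.
#'
#' @inheritParams sample_tm
#' @return A `sampled_filter`.
#' @export
sample_tw <- function(params = msinrf_params()) {
  validate_params(params)
  dt <- 1000 / params$fps
  u <- seq(0, params$tw_duration_ms, by = dt)
  new_sampled_filter(tw_closed_form(u), dt, params$tw_duration_ms, "T_w")
}

#' @export
print.sampled_filter <- function(x, ...) {
  cat(sprintf("Sampled temporal filter %s: %d taps, dt = %.4g ms, support %g ms\n",
              x$name, length(x$taps), x$dt_ms, x$duration_ms))
  print(signif(x$taps, 4))
  invisible(x)
}

#' @export
as.data.frame.sampled_filter <- function(x, ...) {
  data.frame(delay_ms = (seq_along(x$taps) - 1) * x$dt_ms, tap = x$taps)
}

new_spatial_kernel <- function(weights, deg_per_px, name) {
  stopifnot(is.matrix(weights), all(is.finite(weights)),
            nrow(weights) %% 2L == 1L, ncol(weights) %% 2L == 1L)
  structure(list(weights = weights, deg_per_px = deg_per_px,
                 center = c((nrow(weights) + 1L) %/% 2L,
                            (ncol(weights) + 1L) %/% 2L),
                 name = name),
            class = "spatial_kernel")
}

#' Gaussian spatial filter of the linear term
#'
#' Builds the isotropic 2D Gaussian kernel `m`, converting its standard
#' deviation from degrees of visual angle to pixels, truncating at three
#' standard deviations, and normalising to unit sum so that a constant
#' input passes through the linear term unchanged.
#'
#' @inheritParams sample_tm
#' @return A `spatial_kernel` with an odd-sized weight matrix.
#' @examples
#' m <- make_gaussian(msinrf_params())
#' sum(m$weights)  # 1
#' @export
make_gaussian <- function(params = msinrf_params()) {
  validate_params(params)
  sigma_px <- params$m_sigma_deg / params$deg_per_px
  if (sigma_px < 1) {
    warning("Gaussian sigma is below one pixel (", signif(sigma_px, 3),
            " px); the kernel degenerates toward a delta", call. = FALSE)
  }
  r <- max(1L, as.integer(ceiling(3 * sigma_px)))
  d <- seq(-r, r)
  g1 <- exp(-d^2 / (2 * sigma_px^2))
  w <- outer(g1, g1)
  w <- w / sum(w)
  new_spatial_kernel(w, params$deg_per_px, "m")
}

# Lobe polarity of the Gabor, fixed once for the whole package: with
# polarity -1 the positive lobe sits to the RIGHT of the kernel centre
# (weights ~ +sin along x).  This is the orientation for which the default
# sensor responds positively to a canonical rightward-drifting 2 c/deg,
# 4 Hz grating, which pins the sign convention "rightward motion => positive
# response" used by every experiment.
GABOR_POLARITY <- -1

#' Odd-symmetric Gabor spatial filter of the nonlinear term
#'
#' Builds the vertically oriented, sine-phase (odd-symmetric) Gabor `w`.
#' The carrier period along x is twice the lobe width, so the kernel has
#' exactly two dominant lobes of opposite sign.  The Gaussian envelope has
#' standard deviation equal to a quarter of the carrier period on both
#' axes, which keeps any third lobe below 5% of the main lobes; the kernel
#' is truncated at three envelope standard deviations.  Horizontal
#' antisymmetry makes the kernel exactly zero-sum.  The lobe polarity is a
#' fixed package-wide convention chosen so that rightward motion yields
#' positive sensor responses.
#'
#' @inheritParams sample_tm
#' @return A `spatial_kernel` with an odd-sized, zero-sum weight matrix.
#' @export
make_gabor <- function(params = msinrf_params()) {
  validate_params(params)
  period_px <- 2 * params$w_lobe_width_deg / params$deg_per_px
  sigma_px <- period_px / 4
  r <- max(1L, as.integer(ceiling(3 * sigma_px)))
  d <- seq(-r, r)
  env_x <- exp(-d^2 / (2 * sigma_px^2))
  env_y <- env_x
  carrier <- sin(2 * pi * d / period_px)
  # build the right half and mirror-negate so antisymmetry is exact
  w <- outer(env_y, env_x * carrier) * (-GABOR_POLARITY)
  half <- w[, (r + 2L):(2L * r + 1L), drop = FALSE]
  w[, r:1L] <- -half[, , drop = FALSE]
  w[, r + 1L] <- 0
  new_spatial_kernel(w, params$deg_per_px, "w")
}

#' @export
print.spatial_kernel <- function(x, ...) {
  cat(sprintf("Spatial kernel %s: %d x %d px (%.3g deg/px), sum = %.3g\n",
              x$name, nrow(x$weights), ncol(x$weights), x$deg_per_px,
              sum(x$weights)))
  invisible(x)
}

#' Dendritic nonlinearity
#'
#' The even, saturating nonlinearity applied to local luminance
#' differences, \eqn{\sigma(z) = |z|^p / (|z|^p + q^p)}.  It vanishes at
#' zero, equals 1/2 at \eqn{|z| = q}, increases strictly with \eqn{|z|}
#' and is bounded above by 1.
#'
#' @param z Numeric vector, matrix or array of luminance differences.
#' @param params An [msinrf_params()] object supplying `p` and `q`.
#' @return Object of the same shape as `z` with values in `[0, 1)`.
#' @examples
#' sigma_nl(c(0, 0.1, -0.1))  # 0, 0.5, 0.5
#' @export
sigma_nl <- function(z, params = msinrf_params()) {
  validate_params(params)
  zp <- abs(z)^params$p
  zp / (zp + params$q^params$p)
}

#' Export filter taps or kernel weights to CSV
#'
#' Writes a `sampled_filter` as a two-column (delay, tap) table, or a
#' `spatial_kernel` as its full weight grid, for external inspection.
#'
#' @param x A `sampled_filter` or `spatial_kernel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_filter_csv <- function(x, path) {
  if (inherits(x, "sampled_filter")) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  } else if (inherits(x, "spatial_kernel")) {
    utils::write.csv(as.data.frame(x$weights), path, row.names = FALSE)
  } else {
    stop("x must be a sampled_filter or spatial_kernel", call. = FALSE)
  }
  invisible(path)
}
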