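#' Model parameters for the MS-INRF motion sensor
#'
#' Collects every constant of the motion sensor model in one validated
#' record.  The defaults are the single parameter set used for all
#' experiments shipped with the package; the model is deliberately not
#' re-tuned per phenomenon.
#'
#' The sensor response is
#' \deqn{stINRF(s_i,t) = \sum_u T_m(u) \sum_j m_j I(s_j, t-u)
#'   - \lambda \sum_u T_w(u) \sum_j w_j\,
#'     \sigma\big(I(s_j, t-u) - I(s_i, t)\big)}
#' with a Gaussian spatial filter \eqn{m}, a vertically oriented
#' odd-symmetric Gabor \eqn{w}, a bandpass temporal filter \eqn{T_m}, a
#' lowpass temporal filter \eqn{T_w}, and an even saturating dendritic
#' nonlinearity \eqn{\sigma(z) = |z|^p / (|z|^p + q^p)}.  The motion
#' sensor readout is the temporal mean of the stINRF trace.
#'
#' @param k Rate constant of the bandpass temporal filter, in 1/ms.
#' @param n Integer order of the bandpass temporal filter.
#' @param tm_duration_ms Support of the bandpass temporal filter (ms).
#' @param tw_duration_ms Support of the lowpass temporal filter (ms).
#' @param m_sigma_deg Standard deviation of the Gaussian spatial filter,
#'   in degrees of visual angle.
#' @param w_lobe_width_deg Horizontal width of each Gabor lobe (deg); the
#'   carrier period is twice this value.
#' @param lambda Real weight of the nonlinear (dendritic) term.
#' @param p Exponent of the dendritic nonlinearity (dimensionless, > 0).
#' @param q Half-saturation constant of the nonlinearity, in luminance
#'   units (the stimulus range is \[0, 1\]).
#' @param fps Frame rate of the input sequence, in Hz.
#' @param deg_per_px Spatial calibration, degrees of visual angle per
#'   pixel.
#'
#' @return An object of class `msinrf_params` (a named list).
#' @examples
#' p <- msinrf_params()
#' p$lambda
#' @export
msinrf_params <- function(k = 0.4,
                          n = 5L,
                          tm_duration_ms = 50,
                          tw_duration_ms = 50,
                          m_sigma_deg = 0.031,
                          w_lobe_width_deg = 0.125,
                          lambda = -30,
                          p = 0.4,
                          q = 0.1,
                          fps = 120,
                          deg_per_px = 2 / 400) {
  pars <- list(
    k = as.numeric(k), n = as.integer(n),
    tm_duration_ms = as.numeric(tm_duration_ms),
    tw_duration_ms = as.numeric(tw_duration_ms),
    m_sigma_deg = as.numeric(m_sigma_deg),
    w_lobe_width_deg = as.numeric(w_lobe_width_deg),
    lambda = as.numeric(lambda),
    p = as.numeric(p), q = as.numeric(q),
    fps = as.numeric(fps),
    deg_per_px = as.numeric(deg_per_px)
  )
  class(pars) <- "msinrf_params"
  validate_params(pars)
  pars
}

validate_params <- function(pars) {
  stopifnot(inherits(pars, "msinrf_params"))
  scalar_fields <- c("k", "tm_duration_ms", "tw_duration_ms",
                     "m_sigma_deg", "w_lobe_width_deg", "lambda",
                     "p", "q", "fps", "deg_per_px")
  for (f in scalar_fields) {
    v <- pars[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", f, "' must be a finite numeric scalar",
           call. = FALSE)
    }
  }
  if (pars$fps <= 0) stop("fps must be positive", call. = FALSE)
  if (pars$p <= 0) stop("p must be positive", call. = FALSE)
  if (pars$q <= 0) stop("q must be positive", call. = FALSE)
  if (pars$deg_per_px <= 0) stop("deg_per_px must be positive", call. = FALSE)
  if (pars$n < 0) stop("n must be a non-negative integer", call. = FALSE)
  if (pars$tm_duration_ms <= 0 || pars$tw_duration_ms <= 0) {
    stop("temporal filter durations must be positive", call. = FALSE)
  }
  invisible(pars)
}

#' @export
print.msinrf_params <- function(x, ...) {
  cat("MS-INRF model parameters\n")
  cat(sprintf("  temporal: T_m (k = %g /ms, n = %d, %g ms), T_w (%g ms), fps = %g Hz\n",
              x$k, x$n, x$tm_duration_ms, x$tw_duration_ms, x$fps))
  cat(sprintf("  spatial : m Gaussian sigma = %g deg, w Gabor lobe width = %g deg (%g deg/px)\n",
              x$m_sigma_deg, x$w_lobe_width_deg, x$deg_per_px))
  cat(sprintf("  nonlinearity: sigma(z) = |z|^p/(|z|^p + q^p), p = %g, q = %g, lambda = %g\n",
              x$p, x$q, x$lambda))
  invisible(x)
}
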