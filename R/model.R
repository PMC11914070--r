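#' @name msinrf-model
#' @title Sensor response computation
#'
#' @description
#' The response engine evaluates the intrinsically nonlinear receptive
#' field at a sensor location: a linear term (Gaussian spatial summation
#' followed by a bandpass temporal filter) minus \eqn{\lambda} times a
#' dendritic term in which an even saturating nonlinearity of local
#' luminance differences — shifted by the sensor's *current* input — is
#' pooled by an odd-symmetric Gabor and a lowpass temporal filter.  The
#' motion sensor readout averages the resulting trace over time; its sign
#' encodes perceived direction (positive = rightward).
NULL

# reflected (mirror) or strictly checked index range around a centre
support_indices <- function(center, radius, n, boundary) {
  idx <- (center - radius):(center + radius)
  if (any(idx < 1L | idx > n)) {
    if (boundary == "mirror") {
      idx <- ifelse(idx < 1L, 2L - idx, idx)
      idx <- ifelse(idx > n, 2L * n - idx, idx)
      if (any(idx < 1L | idx > n)) {
        stop("kernel support exceeds the image even after mirroring",
             call. = FALSE)
      }
    } else {
      stop("kernel support exceeds the image at this location; move the ",
           "sensor away from the border or use boundary = \"mirror\"",
           call. = FALSE)
    }
  }
  idx
}

check_location <- function(location, d) {
  if (length(location) != 2L || any(location < 1L) ||
      location[1] > d[1] || location[2] > d[2]) {
    stop("location (", paste(location, collapse = ", "),
         ") is outside the image", call. = FALSE)
  }
}

#' Default sensor location: the image centre
#'
#' @param x A `stimulus_sequence` or a dim-2/3 extent.
#' @return Integer `(row, col)` of the central pixel.
#' @export
center_location <- function(x) {
  d <- if (inherits(x, "stimulus_sequence")) dim(x$frames) else x
  c((d[1] + 1L) %/% 2L, (d[2] + 1L) %/% 2L)
}

#' Spatial (static) INRF response at one location
#'
#' Evaluates the purely spatial receptive field on a single frame:
#' \deqn{\mathrm{INRF}(s_i) = \sum_j m_j I(s_j)
#'   - \lambda \sum_j w_j\, \sigma(I(s_j) - I(s_i)).}
#' For a constant image the Gaussian term returns the constant (unit-sum
#' `m`) and the nonlinear term vanishes (\eqn{\sigma(0) = 0}).
#'
#' @param image Numeric matrix of luminance values.
#' @param params An [msinrf_params()] object.
#' @param location Integer `(row, col)` of the sensor.
#' @param boundary `"error"` (kernels must be fully supported) or
#'   `"mirror"` (reflect the image at its borders).
#' @return A single numeric value.
#' @export
inrf_spatial <- function(image, params = msinrf_params(),
                         location = center_location(dim(image)),
                         boundary = c("error", "mirror")) {
  boundary <- match.arg(boundary)
  stopifnot(is.matrix(image), is.numeric(image))
  validate_params(params)
  check_location(location, dim(image))
  m <- make_gaussian(params)
  w <- make_gabor(params)
  rm_ <- (nrow(m$weights) - 1L) %/% 2L
  rw_ <- (nrow(w$weights) - 1L) %/% 2L
  rows_m <- support_indices(location[1], rm_, nrow(image), boundary)
  cols_m <- support_indices(location[2], rm_, ncol(image), boundary)
  rows_w <- support_indices(location[1], rw_, nrow(image), boundary)
  cols_w <- support_indices(location[2], rw_, ncol(image), boundary)
  lin <- sum(m$weights * image[rows_m, cols_m])
  nl <- sum(w$weights *
              sigma_nl(image[rows_w, cols_w] - image[location[1], location[2]],
                       params))
  lin - params$lambda * nl
}

# shared preparation for the two stINRF implementations
stinrf_setup <- function(seq, params, location, boundary) {
  stopifnot(inherits(seq, "stimulus_sequence"))
  validate_params(params)
  d <- dim(seq$frames)
  check_location(location, d)
  if (abs(params$fps - seq$fps) > 1e-9) {
    stop("params$fps (", params$fps, ") does not match the sequence fps (",
         seq$fps, ")", call. = FALSE)
  }
  tm <- sample_tm(params)
  tw <- sample_tw(params)
  K <- max(length(tm$taps), length(tw$taps))
  if (d[3] < K) {
    stop("sequence of ", d[3], " frames is shorter than the temporal ",
         "filter support (", K, " frames)", call. = FALSE)
  }
  pars_px <- params
  pars_px$deg_per_px <- seq$deg_per_px
  m <- make_gaussian(pars_px)
  w <- make_gabor(pars_px)
  list(d = d, tm = tm, tw = tw, K = K, m = m, w = w, boundary = boundary)
}

new_response_trace <- function(values, valid_from, location,
                               linear = NULL, nonlinear = NULL) {
  structure(list(values = values, valid_from = valid_from,
                 location = location, linear = linear,
                 nonlinear = nonlinear),
            class = "response_trace")
}

#' @export
print.response_trace <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("stINRF trace at (%d, %d): %d frames, valid from frame %d\n",
              x$location[1], x$location[2], length(x$values), x$valid_from))
  cat(sprintf("  mean %.5g, range [%.5g, %.5g]\n",
              mean(v), min(v), max(v)))
  invisible(x)
}

#' @export
plot.response_trace <- function(x, ...) {
  graphics::plot(seq_along(x$values), x$values, type = "l",
                 xlab = "frame", ylab = "stINRF response", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Spatio-temporal INRF response trace
#'
#' Computes, for every frame with full temporal-filter support,
#' \deqn{\mathrm{stINRF}(s_i,t) = \sum_u T_m(u) \sum_j m_j I(s_j,t-u)
#'   - \lambda \sum_u T_w(u) \sum_j w_j\,
#'     \sigma\big(I(s_j,t-u) - I(s_i,t)\big).}
#' The nonlinearity is shifted by the sensor value of the *current*
#' frame at every delay: the minuend is delayed, the subtrahend is not.
#' Frames without full temporal support (the first `K - 1`, where `K` is
#' the number of temporal taps) are `NA`.  The inner summation runs in
#' compiled code; [stinrf_bruteforce()] is the literal nested-loop
#' reference it is tested against.
#'
#' @param seq A `stimulus_sequence`.
#' @param params An [msinrf_params()] object; `fps` must match the
#'   sequence (the spatial calibration is taken from the sequence).
#' @param location Integer `(row, col)` of the sensor.
#' @param boundary Spatial boundary mode, see [inrf_spatial()].
#' @return A `response_trace` with fields `values`, `valid_from`,
#'   `location`, and the two terms `linear` and `nonlinear`
#'   (the nonlinear field stores \eqn{\lambda \sum_u T_w \sum_j w_j \sigma(\cdot)},
#'   i.e. the quantity subtracted from the linear term).
#' @export
stinrf <- function(seq, params = msinrf_params(),
                   location = center_location(seq),
                   boundary = c("error", "mirror")) {
  boundary <- match.arg(boundary)
  s <- stinrf_setup(seq, params, location, boundary)
  d <- s$d
  rm_ <- (nrow(s$m$weights) - 1L) %/% 2L
  rw_ <- (nrow(s$w$weights) - 1L) %/% 2L
  rows_m <- support_indices(location[1], rm_, d[1], boundary)
  cols_m <- support_indices(location[2], rm_, d[2], boundary)
  rows_w <- support_indices(location[1], rw_, d[1], boundary)
  cols_w <- support_indices(location[2], rw_, d[2], boundary)

  Tn <- d[3]
  # linear spatial stage per frame, then bandpass temporal taps
  Pm <- matrix(seq$frames[rows_m, cols_m, ], ncol = Tn)
  lin_frame <- as.vector(crossprod(Pm, as.vector(s$m$weights)))
  Km <- length(s$tm$taps)
  valid <- s$K:Tn
  lt <- rep(NA_real_, Tn)
  acc <- 0
  for (k in seq_len(Km)) acc <- acc + s$tm$taps[k] * lin_frame[valid - k + 1L]
  lt[valid] <- acc

  # nonlinear stage: compiled loop over delays and kernel support
  Pw <- matrix(seq$frames[rows_w, cols_w, ], ncol = Tn)
  center_trace <- seq$frames[location[1], location[2], ]
  nl_raw <- stinrf_nonlinear_core(Pw, as.vector(s$w$weights), center_trace,
                                  s$tw$taps, params$p, params$q)
  nl <- params$lambda * nl_raw
  nl[seq_len(s$K - 1L)] <- NA_real_

  new_response_trace(lt - nl, s$K, location, linear = lt, nonlinear = nl)
}

#' Brute-force reference implementation of the stINRF
#'
#' Literal nested summation over temporal delays and kernel pixels, with
#' no vectorisation or compiled code.  It exists as an independent oracle
#' for equivalence tests of [stinrf()] and is only practical on small
#' inputs (cost is `frames * taps * kernel pixels` interpreted R
#' iterations).
#'
#' @inheritParams stinrf
#' @return A `response_trace`.
#' @export
stinrf_bruteforce <- function(seq, params = msinrf_params(),
                              location = center_location(seq),
                              boundary = c("error", "mirror")) {
  boundary <- match.arg(boundary)
  s <- stinrf_setup(seq, params, location, boundary)
  d <- s$d
  mw <- s$m$weights; ww <- s$w$weights
  rm_ <- (nrow(mw) - 1L) %/% 2L
  rw_ <- (nrow(ww) - 1L) %/% 2L
  rows_m <- support_indices(location[1], rm_, d[1], boundary)
  cols_m <- support_indices(location[2], rm_, d[2], boundary)
  rows_w <- support_indices(location[1], rw_, d[1], boundary)
  cols_w <- support_indices(location[2], rw_, d[2], boundary)
  tm <- s$tm$taps; tw <- s$tw$taps
  Tn <- d[3]
  values <- lt <- nl <- rep(NA_real_, Tn)
  p <- params$p; q <- params$q
  for (t in s$K:Tn) {
    lin <- 0
    for (k in seq_along(tm)) {
      for (a in seq_along(rows_m)) {
        for (b in seq_along(cols_m)) {
          lin <- lin + tm[k] * mw[a, b] *
            seq$frames[rows_m[a], cols_m[b], t - k + 1L]
        }
      }
    }
    ctr <- seq$frames[location[1], location[2], t]
    nlt <- 0
    for (k in seq_along(tw)) {
      sk <- 0
      for (a in seq_along(rows_w)) {
        for (b in seq_along(cols_w)) {
          z <- abs(seq$frames[rows_w[a], cols_w[b], t - k + 1L] - ctr)
          sk <- sk + ww[a, b] * (z^p / (z^p + q^p))
        }
      }
      nlt <- nlt + tw[k] * sk
    }
    lt[t] <- lin
    nl[t] <- params$lambda * nlt
    values[t] <- lin - params$lambda * nlt
  }
  new_response_trace(values, s$K, location, linear = lt, nonlinear = nl)
}

#' Motion sensor readout
#'
#' The scalar sensor response: the arithmetic mean of the stINRF trace
#' over its valid frames (optionally only the most recent `window`
#' of them).  The shipped stimuli are statistically stationary over
#' their one-second duration, so any sufficiently long window converges
#' to the same value.  Positive responses indicate rightward motion,
#' negative leftward.
#'
#' @inheritParams stinrf
#' @param window Optional integer: average only the last `window` valid
#'   frames.
#' @return A `sensor_response` with fields `value`, `location`,
#'   `averaging_window` (first and last frame averaged).
#' @export
ms_inrf <- function(seq, params = msinrf_params(),
                    location = center_location(seq), window = NULL,
                    boundary = c("error", "mirror")) {
  tr <- stinrf(seq, params, location, boundary)
  valid <- which(!is.na(tr$values))
  if (length(valid) == 0L) stop("no frames with full temporal support",
                                call. = FALSE)
  if (!is.null(window)) {
    window <- min(as.integer(window), length(valid))
    valid <- valid[(length(valid) - window + 1L):length(valid)]
  }
  structure(list(value = mean(tr$values[valid]), location = location,
                 averaging_window = range(valid)),
            class = "sensor_response")
}

#' @export
print.sensor_response <- function(x, ...) {
  cat(sprintf("MS-INRF response at (%d, %d): %.6g  [frames %d-%d]\n",
              x$location[1], x$location[2], x$value,
              x$averaging_window[1], x$averaging_window[2]))
  cat(sprintf("  direction: %s\n",
              if (x$value > 0) "rightward (+)" else if (x$value < 0)
                "leftward (-)" else "none"))
  invisible(x)
}

#' stINRF responses on a spatial grid
#'
#' Evaluates [stinrf()] at every grid point of the given stride inside
#' the region where the kernels are fully supported (or everywhere, with
#' mirrored borders).
#'
#' @inheritParams stinrf
#' @param stride Positive integer grid spacing in pixels.
#' @return A `response_field`: list with `values` (rows x cols x time
#'   array), the `rows` and `cols` of the grid, and `valid_from`.
#' @export
stinrf_field <- function(seq, params = msinrf_params(), stride = 1L,
                         boundary = c("error", "mirror")) {
  boundary <- match.arg(boundary)
  stopifnot(stride >= 1)
  d <- dim(seq$frames)
  pars_px <- params
  pars_px$deg_per_px <- seq$deg_per_px
  rw_ <- (nrow(make_gabor(pars_px)$weights) - 1L) %/% 2L
  rm_ <- (nrow(make_gaussian(pars_px)$weights) - 1L) %/% 2L
  r <- max(rw_, rm_)
  if (boundary == "error") {
    if (d[1] < 2L * r + 1L || d[2] < 2L * r + 1L) {
      stop("image smaller than the kernel support; use boundary = \"mirror\"",
           call. = FALSE)
    }
    rows <- seq.int(r + 1L, d[1] - r, by = stride)
    cols <- seq.int(r + 1L, d[2] - r, by = stride)
  } else {
    rows <- seq.int(1L, d[1], by = stride)
    cols <- seq.int(1L, d[2], by = stride)
  }
  values <- array(NA_real_, c(length(rows), length(cols), d[3]))
  vf <- NA_integer_
  for (i in seq_along(rows)) {
    for (j in seq_along(cols)) {
      tr <- stinrf(seq, params, c(rows[i], cols[j]), boundary)
      values[i, j, ] <- tr$values
      vf <- tr$valid_from
    }
  }
  structure(list(values = values, rows = rows, cols = cols,
                 valid_from = vf),
            class = "response_field")
}

#' @export
print.response_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("stINRF response field: %d x %d locations x %d frames\n",
              d[1], d[2], d[3]))
  invisible(x)
}
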