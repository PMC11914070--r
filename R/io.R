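#' Write an experiment result to CSV with a JSON sidecar
#'
#' The CSV holds the variable grid plus `response` and `dispersion`
#' columns at full double precision; the JSON sidecar carries the
#' experiment name, the column order, and the complete config (including
#' every seed) needed to regenerate the result.
#'
#' @param x An `experiment_result`.
#' @param prefix Output path without extension; `<prefix>.csv` and
#'   `<prefix>.json` are written.
#' @return `prefix`, invisibly.
#' @seealso [read_result()]
#' @export
write_result <- function(x, prefix) {
  stopifnot(inherits(x, "experiment_result"))
  df <- x$grid
  df$response <- x$responses
  df$dispersion <- x$dispersion
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, paste0(prefix, ".csv"), row.names = FALSE,
                   quote = FALSE)
  numeric_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  side <- list(name = x$name, columns = names(df),
               numeric_columns = numeric_cols, config = x$config)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(prefix)
}

#' Read an experiment result written by [write_result()]
#'
#' @param prefix Path prefix used when writing.
#' @return An `experiment_result` equal to the written one to full
#'   precision.
#' @export
read_result <- function(prefix) {
  csv <- paste0(prefix, ".csv")
  json <- paste0(prefix, ".json")
  if (!file.exists(csv) || !file.exists(json)) {
    stop("no result found at prefix '", prefix, "'", call. = FALSE)
  }
  side <- jsonlite::read_json(json, simplifyVector = TRUE)
  df <- tryCatch(
    utils::read.csv(csv, stringsAsFactors = FALSE,
                    colClasses = "character"),
    error = function(e) stop("malformed result CSV '", csv, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!identical(names(df), as.character(side$columns))) {
    stop("result CSV columns ", paste(names(df), collapse = ","),
         " do not match sidecar ", paste(side$columns, collapse = ","),
         call. = FALSE)
  }
  for (nm in side$numeric_columns) df[[nm]] <- as.numeric(df[[nm]])
  grid <- df[setdiff(names(df), c("response", "dispersion"))]
  new_experiment_result(side$name, grid, df$response, df$dispersion,
                        side$config)
}

#' Write a stimulus sequence as a multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 32-bit float TIFF pages, rescaled to `[0, 1]`
#' with the original range recorded in the sidecar (luminance stimuli
#' are already in range, so the rescaling is the identity).  The sidecar
#' carries fps, the spatial calibration, and the full recipe metadata
#' including the seed.
#'
#' @param seq A `stimulus_sequence`.
#' @param prefix Output path without extension.
#' @return `prefix`, invisibly.
#' @export
write_stimulus <- function(seq, prefix) {
  stopifnot(inherits(seq, "stimulus_sequence"))
  lo <- min(seq$frames); hi <- max(seq$frames)
  lo <- min(lo, 0); hi <- max(hi, 1)
  d <- dim(seq$frames)
  pages <- lapply(seq_len(d[3]), function(t) {
    (seq$frames[, , t] - lo) / (hi - lo)
  })
  tiff::writeTIFF(pages, paste0(prefix, ".tif"), bits.per.sample = 32)
  side <- list(fps = seq$fps, deg_per_px = seq$deg_per_px,
               range = c(lo, hi), meta = seq$meta)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(prefix)
}

#' Read a stimulus sequence written by [write_stimulus()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `stimulus_sequence`.
#' @export
read_stimulus <- function(prefix) {
  tif <- paste0(prefix, ".tif")
  json <- paste0(prefix, ".json")
  if (!file.exists(tif) || !file.exists(json)) {
    stop("no stimulus found at prefix '", prefix, "'", call. = FALSE)
  }
  side <- jsonlite::read_json(json, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tif, all = TRUE)
  d <- c(dim(pages[[1]]), length(pages))
  frames <- array(unlist(pages), dim = c(d[1], d[2], d[3]))
  lo <- side$range[1]; hi <- side$range[2]
  frames <- frames * (hi - lo) + lo
  meta <- side$meta
  luminance <- !isFALSE(meta$luminance)
  stimulus_sequence(frames, side$fps, side$deg_per_px, meta = meta,
                    luminance = luminance)
}

#' Export a space-time slice as PNG
#'
#' Renders the central (or given) row of a stimulus over time as a
#' grayscale x-t image.
#'
#' @param seq A `stimulus_sequence`.
#' @param path Output PNG path.
#' @param row Row of the horizontal slice (default: centre).
#' @return `path`, invisibly.
#' @export
write_xt_png <- function(seq, path, row = NULL) {
  stopifnot(inherits(seq, "stimulus_sequence"))
  d <- dim(seq$frames)
  if (is.null(row)) row <- (d[1] + 1L) %/% 2L
  xt <- seq$frames[row, , ]
  lo <- min(xt); hi <- max(xt)
  if (hi > lo) xt <- (xt - lo) / (hi - lo) else xt[] <- 0.5
  png::writePNG(xt, path)
  invisible(path)
}

#' Export a response trace as CSV
#'
#' @param trace A `response_trace` from [stinrf()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "response_trace"))
  df <- data.frame(frame = seq_along(trace$values),
                   valid = seq_along(trace$values) >= trace$valid_from,
                   value = sprintf("%.17g", trace$values),
                   linear = sprintf("%.17g", trace$linear),
                   nonlinear = sprintf("%.17g", trace$nonlinear))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
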