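# Typed conditions so callers (and the command line driver) can tell
# validation problems from I/O problems.
.io_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("rspaquant_io_error", "error")))
}

# TIFF storage convention: frames are written as 32-bit pages after
# division by a fixed power-of-two scale, because the underlying writer
# operates on [0, 1]. 2^16 sits above any 16-bit camera count. Storage is
# quantized at ~2^-32 of full scale (about 1.5e-5 counts), far below any
# camera's noise floor.
.TIFF_SCALE <- 2^16

#' Read an intensity stack from multi-page TIFF
#'
#' Reads one or more multi-page TIFF files into `c(H, W, T)` arrays.
#' Channels may be stored one per file (pass several paths, one per
#' channel) or interleaved page-wise within a single file (pass one path
#' and the channel names in recording order).
#'
#' @param path TIFF path(s). Several paths mean one file per channel;
#'   names (or `channels`) label them.
#' @param channels channel names; with a single path and more than one
#'   name, pages are de-interleaved in that order. The page count must be
#'   divisible by the channel count.
#' @param scale power-of-two intensity scale used when the file was
#'   written by [write_stack()] (see Details there).
#' @return A single array, or a named list of arrays (one per channel),
#'   all of identical dimension.
#' @export
read_stack <- function(path, channels = NULL, scale = .TIFF_SCALE) {
  read_one <- function(p) {
    if (!file.exists(p)) .io_error("TIFF file '%s' does not exist", p)
    pages <- tryCatch(tiff::readTIFF(p, all = TRUE),
                      error = function(e)
                        .io_error("failed to read TIFF '%s': %s", p,
                                  conditionMessage(e)))
    if (length(pages) == 0L) .io_error("TIFF '%s' contains no pages", p)
    dims <- unique(lapply(pages, dim))
    if (length(dims) != 1L)
      .io_error("TIFF '%s' has pages of differing dimensions", p)
    arr <- array(unlist(pages, use.names = FALSE),
                 c(dims[[1]][1], dims[[1]][2], length(pages)))
    arr * scale
  }
  if (length(path) > 1L) {
    out <- lapply(path, read_one)
    names(out) <- if (!is.null(channels)) channels else
      if (!is.null(names(path))) names(path) else
        paste0("channel", seq_along(path))
    if (length(unique(lapply(out, dim))) != 1L)
      .io_error("channel files disagree in stack dimensions")
    return(out)
  }
  arr <- read_one(path)
  if (is.null(channels) || length(channels) <= 1L) return(arr)
  k <- length(channels)
  nt <- dim(arr)[3]
  if (nt %% k != 0L)
    .io_error("TIFF '%s' has %d pages, not divisible by %d declared channels",
              path, nt, k)
  out <- lapply(seq_len(k), function(c0)
    arr[, , seq(c0, nt, by = k), drop = FALSE])
  names(out) <- channels
  out
}

#' Write an intensity stack as multi-page 32-bit TIFF
#'
#' @param x an `c(H, W, T)` array or `H x W` matrix (values must be
#'   non-negative and below `scale`).
#' @param path output path.
#' @param scale power-of-two scale; values are stored as `x / scale` and
#'   multiplied back on read. Storage quantizes at about `scale * 2^-32`
#'   (1.5e-5 counts at the default scale), orders of magnitude below any
#'   camera noise floor.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path, scale = .TIFF_SCALE) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  if (any(!is.finite(x)) || any(x < 0) || any(x >= scale))
    stop("stack values must be finite, >= 0 and below the storage scale ",
         scale, call. = FALSE)
  pages <- lapply(seq_len(dim(x)[3]), function(k) x[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  compression = "deflate")
  invisible(path)
}

#' Write a machine-readable analysis report
#'
#' Serializes a report (any list of data frames and scalars, e.g. the
#' result of [run_pipeline()]) as JSON.
#'
#' @param report a list.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
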