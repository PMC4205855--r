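#' Construct an image stack
#'
#' An `image_stack` is the raw input of every analysis in this package: an
#' ordered sequence of grayscale frames from a time-lapse recording of a
#' single diffusing particle, together with the acquisition metadata that
#' gives pixels physical meaning.
#'
#' Frames are stored as a list of numeric matrices indexed `[row, col]`.
#' Pixel coordinates used throughout the package are 0-based `(row, col)`
#' pairs; frame indices shown to users are 1-based (`t_1 .. t_n`).
#'
#' @param frames list of numeric matrices, all of identical dimensions, with
#'   finite nonnegative intensities (arbitrary units).
#' @param dt frame interval in seconds.
#' @param pixel_size pixel edge length in micrometres.
#' @return an object of class `image_stack` with elements `frames`, `dt`,
#'   `pixel_size`, `n` (number of frames) and `shape` (`c(rows, cols)`).
#' @export
image_stack <- function(frames, dt, pixel_size) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("an image stack needs at least 2 frames")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number (seconds)")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (micrometres)")
  dims <- vapply(frames, function(f) dim(as.matrix(f)), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share identical dimensions")
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (!all(is.finite(f)) || any(f < 0))
      stop("frame intensities must be finite and nonnegative")
    storage.mode(f) <- "double"
    f
  })
  structure(
    list(frames = frames, dt = dt, pixel_size = pixel_size,
         n = length(frames), shape = dims[, 1]),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack: %d frames of %d x %d px, dt = %g s, pixel = %g um\n",
              x$n, x$shape[1], x$shape[2], x$dt, x$pixel_size))
  invisible(x)
}

#' Read a time-lapse stack from disk
#'
#' Reads either a multi-page grayscale TIFF or a directory of single-page
#' image files (TIFF or PNG) taken in lexicographic order as the frame
#' order.  `dt` and `pixel_size` are always supplied by the caller; TIFF
#' metadata dialects for them are too unreliable to infer from tags.
#'
#' @param path a multi-page TIFF file or a directory of frame files.
#' @param dt frame interval, seconds.
#' @param pixel_size pixel size, micrometres.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, dt, pixel_size) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tiff?|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L)
      stop("no TIFF or PNG frames found in directory: ", path)
    frames <- lapply(files, function(f) {
      img <- if (grepl("\\.png$", f, ignore.case = TRUE))
        png::readPNG(f) else tiff::readTIFF(f)
      collapse_gray(img)
    })
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, collapse_gray)
  } else {
    stop("cannot read stack: no such file or directory: ", path)
  }
  image_stack(frames, dt = dt, pixel_size = pixel_size)
}

# Reduce an RGB(A) array read by tiff/png to a single grayscale channel.
collapse_gray <- function(img) {
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3]),
                                               drop = FALSE], c(1, 2), mean)
  as.matrix(img)
}

#' Write an image stack to a multi-page TIFF
#'
#' Intensities are rescaled to `[0, 1]` by `scale_max` (default: the stack
#' maximum) and written as 16-bit grayscale, so a write/read round trip at
#' the same scale preserves intensities to 16-bit quantization; with
#' integer-valued data whose maximum is below 65535, it is exact.
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @param scale_max intensity mapped to white; defaults to the stack maximum.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, scale_max = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(scale_max)) scale_max <- max(vapply(stack$frames, max, 0))
  if (scale_max <= 0) scale_max <- 1
  pages <- lapply(stack$frames, function(f) pmin(f / scale_max, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Pixel-set area in square micrometres
#'
#' A footprint of `k` pixels occupies `k * pixel_size^2` um^2.  Areas are
#' carried internally as pixel counts and converted only at estimator
#' boundaries.
#'
#' @param n_px number of pixels (scalar or vector).
#' @param pixel_size pixel edge length, micrometres.
#' @return area(s) in um^2.
#' @export
pixel_area <- function(n_px, pixel_size) {
  stopifnot(all(n_px >= 0), pixel_size > 0)
  n_px * pixel_size^2
}

#' Write per-molecule results to CSV
#'
#' One row per molecule: stack id, method label (`CA` or `SMLT-MSD`),
#' diffusion coefficient in um^2/s, number of frames, quality metrics and,
#' when computed, the conformational relaxation time.
#'
#' @param records a data frame of per-molecule outputs (nonempty).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must be a nonempty data frame")
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
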