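# ---- pixel-set helpers -----------------------------------------------------
# A pixel set is an integer matrix with columns (row, col), 0-based, unique.

px_set <- function(rows, cols) {
  m <- cbind(row = as.integer(rows), col = as.integer(cols))
  m[!duplicated(m), , drop = FALSE]
}

px_key <- function(px, shape) px[, 1] * shape[2] + px[, 2]

#' Fit a Gaussian background model to one frame
#'
#' The frequency distribution of all pixel intensities in a frame is
#' dominated by the background mode; a least-squares Gaussian fit to its
#' histogram yields the background mean `m` and s.d. `s` for that frame.
#' Signal pixels are rare outliers and do not move the fit.  Integer-valued
#' data uses unit-intensity bins; continuous data uses Freedman-Diaconis
#' bins.  Initial guesses come from the sample median and MAD.
#'
#' @param frame a numeric matrix of pixel intensities (at least 100 pixels).
#' @return a list with `m` (mean) and `s` (s.d.) of the background intensity.
#' @export
fit_background <- function(frame) {
  v <- as.numeric(frame)
  if (length(v) < 100L)
    stop("frame too small for a background histogram (need >= 100 pixels)")
  if (stats::sd(v) == 0)
    stop("degenerate frame: all pixels equal (background s.d. would be 0)")
  integerish <- all(abs(v - round(v)) < 1e-9)
  if (integerish) {
    breaks <- seq(floor(min(v)) - 0.5, ceiling(max(v)) + 0.5, by = 1)
  } else {
    bw <- 2 * stats::IQR(v) / length(v)^(1 / 3)
    if (bw <= 0) bw <- diff(range(v)) / 64
    breaks <- seq(min(v) - bw, max(v) + bw, by = bw)
  }
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  m0 <- stats::median(v)
  s0 <- stats::mad(v)
  if (s0 == 0) s0 <- stats::sd(v)
  a0 <- max(df$y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - m)^2 / (2 * s^2)), data = df,
                      start = list(a = a0, m = m0, s = s0),
                      lower = c(0, -Inf, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("background Gaussian fit did not converge: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  list(m = unname(cf["m"]), s = abs(unname(cf["s"])))
}

#' Threshold a frame against its background model
#'
#' Retains pixels whose intensity exceeds `m + k*s`.  The default `k = 4`
#' is the working threshold for diffusion measurements.
#'
#' @param frame numeric matrix.
#' @param model background model from [fit_background()].
#' @param k positive threshold multiplier (default 4).
#' @return a pixel set: integer matrix of 0-based `(row, col)` coordinates
#'   (possibly empty).
#' @export
threshold_frame <- function(frame, model, k = 4) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("'k' must be a single positive number")
  idx <- which(frame > model$m + k * model$s, arr.ind = TRUE)
  px_set(idx[, 1] - 1L, idx[, 2] - 1L)
}

#' Remove isolated noise pixels
#'
#' A noise pixel is an above-threshold pixel with no above-threshold
#' neighbour among its 8-connected neighbourhood -- the standard salt-noise
#' criterion for single-pixel shot noise.
#'
#' @param px a pixel set (integer matrix, columns row/col, 0-based).
#' @return a list with `cleaned` (pixel set) and `n_removed` (count).
#' @export
remove_noise_pixels <- function(px) {
  if (nrow(px) <= 1L) {
    return(list(cleaned = px[0, , drop = FALSE], n_removed = nrow(px)))
  }
  # keys on a grid wide enough to avoid row wrap-around collisions
  w <- max(px[, 2]) + 2L
  key <- px[, 1] * w + px[, 2]
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  has_nb <- rep(FALSE, nrow(px))
  for (i in seq_len(nrow(off))) {
    nb <- (px[, 1] + off$dr[i]) * w + (px[, 2] + off$dc[i])
    has_nb <- has_nb | (nb %in% key)
  }
  list(cleaned = px[has_nb, , drop = FALSE], n_removed = sum(!has_nb))
}

#' Select the molecular footprint of a frame
#'
#' Keeps the `n_pixels` brightest cleaned pixels -- equivalent to raising
#' the background threshold until exactly `n_pixels` remain.  Ties at the
#' cutoff are broken deterministically in favour of the pixel earliest in
#' `(row, col)` lexicographic order.  If fewer than `n_pixels` pixels
#' survive, all of them are returned and the frame is flagged short.
#'
#' @param frame numeric matrix (for the intensity ranking).
#' @param px cleaned pixel set.
#' @param n_pixels footprint size (default 5).
#' @return list with `footprint` (pixel set) and `short` (logical flag).
#' @export
select_footprint <- function(frame, px, n_pixels = 5L) {
  if (n_pixels < 1L) stop("'n_pixels' must be >= 1")
  if (nrow(px) <= n_pixels) {
    return(list(footprint = px, short = nrow(px) < n_pixels))
  }
  inten <- frame[cbind(px[, 1] + 1L, px[, 2] + 1L)]
  ord <- order(-inten, px[, 1], px[, 2])
  list(footprint = px[ord[seq_len(n_pixels)], , drop = FALSE], short = FALSE)
}

#' Stack quality metrics
#'
#' The internal noise ratio is the fraction of above-threshold pixels that
#' were removed as isolated noise (summed over the stack); the dropped
#' frames ratio is the fraction of frames with an empty footprint (the
#' particle briefly absent from the field of view).  A stack is accepted
#' when the internal noise ratio does not exceed 20% and the dropped
#' frames ratio does not exceed 1% (both bounds inclusive).
#'
#' @param footprints list of per-frame pixel sets (possibly empty matrices).
#' @param noise_counts integer vector, noise pixels removed per frame.
#' @param raw_counts integer vector, above-threshold pixels per frame before
#'   noise removal.
#' @param max_noise_ratio,max_dropped_ratio acceptance bounds.
#' @return a list of class `stack_quality` with `internal_noise_ratio`,
#'   `dropped_frames_ratio` and `accepted`.
#' @export
assess_quality <- function(footprints, noise_counts, raw_counts,
                           max_noise_ratio = 0.20, max_dropped_ratio = 0.01) {
  n <- length(footprints)
  stopifnot(length(noise_counts) == n, length(raw_counts) == n)
  total_raw <- sum(raw_counts)
  if (total_raw == 0L)
    stop("no signal in stack: no pixel above threshold in any frame")
  noise_ratio <- sum(noise_counts) / total_raw
  dropped <- sum(vapply(footprints, nrow, 0L) == 0L)
  dropped_ratio <- dropped / n
  structure(
    list(internal_noise_ratio = noise_ratio,
         dropped_frames_ratio = dropped_ratio,
         accepted = noise_ratio <= max_noise_ratio &&
           dropped_ratio <= max_dropped_ratio),
    class = "stack_quality")
}

#' @export
print.stack_quality <- function(x, ...) {
  cat(sprintf(
    "stack_quality: internal noise %.1f%%, dropped frames %.2f%% -> %s\n",
    100 * x$internal_noise_ratio, 100 * x$dropped_frames_ratio,
    if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}

#' Construct an occupancy stack
#'
#' An `occupancy_stack` holds the per-frame molecular footprints (pixel
#' sets) plus the grid shape and acquisition metadata.  It is the common
#' currency between preprocessing, the cumulative-area estimator, and the
#' simulator (which produces planted occupancy directly).
#'
#' @param footprints list of pixel sets, one per frame (empty matrix for a
#'   dropped frame).
#' @param shape `c(rows, cols)` of the pixel grid.
#' @param dt frame interval, seconds.
#' @param pixel_size pixel size, micrometres.
#' @param n_pixels target footprint size.
#' @param quality optional `stack_quality`.
#' @return object of class `occupancy_stack`.
#' @export
occupancy_stack <- function(footprints, shape, dt, pixel_size,
                            n_pixels = 5L, quality = NULL) {
  stopifnot(is.list(footprints), length(footprints) >= 1L)
  structure(
    list(footprints = footprints, shape = as.integer(shape), dt = dt,
         pixel_size = pixel_size, n_pixels = as.integer(n_pixels),
         quality = quality, n = length(footprints)),
    class = "occupancy_stack")
}

#' @export
print.occupancy_stack <- function(x, ...) {
  cat(sprintf("occupancy_stack: %d frames on %d x %d px grid, %d-pixel footprints\n",
              x$n, x$shape[1], x$shape[2], x$n_pixels))
  if (!is.null(x$quality)) print(x$quality)
  invisible(x)
}

#' Preprocess an image stack into per-frame footprints
#'
#' Per frame: fit the background intensity distribution with a Gaussian,
#' threshold at `m + k*s` (independent background adjustment for each
#' frame), remove isolated noise pixels, and keep the `n_pixels` brightest
#' pixels as the molecular footprint.  Frames in which fewer than
#' `n_pixels` pixels survive count as dropped and contribute empty
#' footprints.  Stack-level quality gating is attached to the result.
#'
#' @param stack an [image_stack()].
#' @param n_pixels footprint size (default 5).
#' @param k background threshold multiplier (default 4).
#' @return an [occupancy_stack()] with a `quality` element.
#' @export
preprocess_stack <- function(stack, n_pixels = 5L, k = 4) {
  stopifnot(inherits(stack, "image_stack"))
  n <- stack$n
  footprints <- vector("list", n)
  noise_counts <- integer(n)
  raw_counts <- integer(n)
  for (i in seq_len(n)) {
    frame <- stack$frames[[i]]
    bg <- tryCatch(fit_background(frame), error = function(e)
      stop(sprintf("frame %d: %s", i, conditionMessage(e)), call. = FALSE))
    px <- threshold_frame(frame, bg, k = k)
    raw_counts[i] <- nrow(px)
    cl <- remove_noise_pixels(px)
    noise_counts[i] <- cl$n_removed
    sel <- select_footprint(frame, cl$cleaned, n_pixels = n_pixels)
    # frames short of the target footprint size are treated as dropped
    footprints[[i]] <- if (sel$short) px[0, , drop = FALSE] else sel$footprint
  }
  qual <- assess_quality(footprints, noise_counts, raw_counts)
  occupancy_stack(footprints, shape = stack$shape, dt = stack$dt,
                  pixel_size = stack$pixel_size, n_pixels = n_pixels,
                  quality = qual)
}
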