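# ImageSeries: an ordered stack of same-shape 2D magnitude frames, each
# tagged with its (TR, TE). mode "T1" means TR varies at fixed TE; "T2"
# means TE varies at fixed TR.

#' Construct an image series from frames
#'
#' @param pixels list of numeric matrices (one per frame) or a 3D array
#'   `[rows, cols, frames]`; values must be finite and non-negative.
#' @param tr_ms repetition time per frame, ms.
#' @param te_ms echo time per frame, ms (`>= 0`; 0 is the idealized
#'   short-echo limit used by the simulator).
#' @param pixel_spacing_mm physical (row, col) spacing; a scalar is used
#'   for both.
#' @param slice_thickness_mm slice thickness, mm.
#' @param frame_id optional stable identifiers (source file or synthetic
#'   tag), one per frame.
#' @return an `image_series` object with fields `frames`, `mode`
#'   (`"T1"` or `"T2"`), and `fixed_parameter_ms`.
#' @export
image_series <- function(pixels, tr_ms, te_ms,
                         pixel_spacing_mm = c(1, 1),
                         slice_thickness_mm = 1,
                         frame_id = NULL) {
  if (is.array(pixels) && length(dim(pixels)) == 3) {
    pixels <- lapply(seq_len(dim(pixels)[3]), function(k) pixels[, , k])
  }
  n <- length(pixels)
  if (length(tr_ms) != n || length(te_ms) != n) {
    stop("tr_ms and te_ms must have one value per frame")
  }
  if (n < 3) stop("at least 3 frames are required for fitting")
  if (length(pixel_spacing_mm) == 1) pixel_spacing_mm <- rep(pixel_spacing_mm, 2)
  if (any(pixel_spacing_mm <= 0)) stop("pixel spacing must be > 0")
  dims <- vapply(pixels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("inconsistent series geometry: frames differ in shape")
  }
  for (m in pixels) {
    if (any(!is.finite(m)) || any(m < 0)) {
      stop("pixel values must be finite and non-negative")
    }
  }
  if (any(!is.finite(tr_ms)) || any(tr_ms <= 0)) stop("tr_ms must be > 0")
  if (any(!is.finite(te_ms)) || any(te_ms < 0)) stop("te_ms must be >= 0")

  tr_varies <- length(unique(tr_ms)) > 1
  te_varies <- length(unique(te_ms)) > 1
  if (tr_varies && te_varies) stop("ambiguous protocol: both TR and TE vary")
  if (!tr_varies && !te_varies) stop("ambiguous protocol: neither TR nor TE varies")
  mode <- if (tr_varies) "T1" else "T2"
  varied <- if (mode == "T1") tr_ms else te_ms
  ord <- order(varied)
  if (any(duplicated(varied))) stop("duplicate timing points; average them first")
  if (is.null(frame_id)) frame_id <- sprintf("frame_%03d", seq_len(n))

  frames <- lapply(ord, function(i) {
    list(pixels = pixels[[i]], tr_ms = tr_ms[i], te_ms = te_ms[i],
         frame_id = frame_id[i])
  })
  structure(
    list(frames = frames, mode = mode,
         fixed_parameter_ms = if (mode == "T1") te_ms[1] else tr_ms[1],
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         slice_thickness_mm = slice_thickness_mm),
    class = "image_series"
  )
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames[[1]]$pixels)
  cat(sprintf(
    "<image_series> %s-protocol, %d frames of %dx%d, %s fixed at %g ms\n",
    x$mode, length(x$frames), d[1], d[2],
    if (x$mode == "T1") "TE" else "TR", x$fixed_parameter_ms))
  cat("  varied:", paste(series_schedule(x)$varied, collapse = ", "), "ms\n")
  invisible(x)
}

#' Timing schedule of a series
#'
#' @param series an `image_series`.
#' @return list with `tr_ms`, `te_ms` (per frame, in stored order) and
#'   `varied` (the varying parameter's values).
#' @export
series_schedule <- function(series) {
  tr <- vapply(series$frames, `[[`, numeric(1), "tr_ms")
  te <- vapply(series$frames, `[[`, numeric(1), "te_ms")
  list(tr_ms = tr, te_ms = te,
       varied = if (series$mode == "T1") tr else te)
}

#' Stack series frames into a 3D array
#'
#' @param series an `image_series`.
#' @return numeric array `[rows, cols, frames]`.
#' @export
series_array <- function(series) {
  d <- dim(series$frames[[1]]$pixels)
  arr <- array(0, c(d, length(series$frames)))
  for (k in seq_along(series$frames)) arr[, , k] <- series$frames[[k]]$pixels
  arr
}

#' Smooth every frame of a series stack
#'
#' Optional pre-processing before fitting: per-frame 2D convolution with a
#' small kernel, edges handled by reflection. `"none"` is the identity,
#' `"mean3"` a 3x3 box filter, `"gaussian:<sigma>"` a normalized Gaussian
#' with standard deviation sigma in pixels (kernel radius `ceiling(3*sigma)`).
#'
#' @param series an `image_series` (or a plain 3D array).
#' @param kernel `"none"`, `"mean3"`, or `"gaussian:<sigma>"`.
#' @return object of the same type with smoothed frames.
#' @export
smooth_series <- function(series, kernel = "none") {
  k <- smoothing_kernel(kernel)
  if (is.null(k)) return(series)
  if (is.array(series)) {
    for (i in seq_len(dim(series)[3])) {
      series[, , i] <- convolve2_reflect(series[, , i], k)
    }
    return(series)
  }
  if (!inherits(series, "image_series")) stop("expected an image_series or 3D array")
  series$frames <- lapply(series$frames, function(fr) {
    fr$pixels <- convolve2_reflect(fr$pixels, k)
    fr
  })
  series
}

smoothing_kernel <- function(kernel) {
  if (is.matrix(kernel)) return(kernel / sum(kernel))
  if (!is.character(kernel) || length(kernel) != 1) {
    stop("unknown smoothing kernel")
  }
  if (kernel == "none") return(NULL)
  if (kernel == "mean3") return(matrix(1 / 9, 3, 3))
  if (grepl("^gaussian:", kernel)) {
    sigma <- suppressWarnings(as.numeric(sub("^gaussian:", "", kernel)))
    if (!is.finite(sigma) || sigma <= 0) stop("gaussian kernel needs sigma > 0")
    r <- ceiling(3 * sigma)
    g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    k <- outer(g, g)
    return(k / sum(k))
  }
  stop("unknown smoothing kernel: ", kernel)
}

# 2D convolution with reflected (mirrored) edges.
convolve2_reflect <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  rr <- (nrow(k) - 1L) %/% 2L; rc <- (ncol(k) - 1L) %/% 2L
  ri <- c(rev(seq_len(min(rr, nr))), seq_len(nr),
          nr + 1L - rev(seq_len(min(rr, nr))))
  ci <- c(rev(seq_len(min(rc, nc))), seq_len(nc),
          nc + 1L - rev(seq_len(min(rc, nc))))
  pad <- m[ri, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(k))) {
    for (j in seq_len(ncol(k))) {
      out <- out + k[i, j] * pad[(i - 1L) + seq_len(nr), (j - 1L) + seq_len(nc)]
    }
  }
  out
}
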