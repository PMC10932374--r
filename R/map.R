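# Map-level pipeline: per-pixel fitting over an ImageSeries, R^2-based
# noise masking, ROI statistics, profiles, histograms, exports.

#' Region-of-interest selections
#'
#' ROIs are defined in 0-based pixel coordinates with `x` the column and
#' `y` the row index. Rectangles use half-open bounds `[x0, x1) x [y0, y1)`;
#' circles and polygons include pixels whose integer index satisfies the
#' analytic condition.
#'
#' @param x0,y0,x1,y1 rectangle bounds (half-open, 0-based).
#' @return a `roi_selection` object.
#' @export
roi_rect <- function(x0, y0, x1, y1) {
  if (x1 <= x0 || y1 <= y0) stop("rectangle bounds must satisfy x1 > x0, y1 > y0")
  structure(list(kind = "rectangle", x0 = x0, y0 = y0, x1 = x1, y1 = y1),
            class = "roi_selection")
}

#' @rdname roi_rect
#' @param cx,cy,r circle center and radius in pixels (0-based coords).
#' @export
roi_circle <- function(cx, cy, r) {
  if (r <= 0) stop("circle radius must be > 0")
  structure(list(kind = "circle", cx = cx, cy = cy, r = r),
            class = "roi_selection")
}

#' @rdname roi_rect
#' @param xs,ys polygon vertex coordinates (0-based pixel coords).
#' @export
roi_polygon <- function(xs, ys) {
  if (length(xs) != length(ys) || length(xs) < 3) {
    stop("polygon needs >= 3 vertices")
  }
  structure(list(kind = "polygon", xs = xs, ys = ys), class = "roi_selection")
}

#' @rdname roi_rect
#' @export
roi_full <- function() structure(list(kind = "full"), class = "roi_selection")

#' @rdname roi_rect
#' @param mask logical matrix selecting pixels directly (e.g. a
#'   ground-truth compartment from the simulator).
#' @export
roi_from_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask)) stop("mask must be a logical matrix")
  if (!any(mask)) stop("mask selects no pixels")
  structure(list(kind = "mask", mask = mask), class = "roi_selection")
}

#' Erode a binary mask
#'
#' Keeps pixels whose full `(2r+1) x (2r+1)` neighborhood lies inside the
#' mask (edge-clamped). Useful for restricting ROI statistics to the
#' interior of a compartment, away from boundary/partial-volume pixels.
#'
#' @param mask logical matrix.
#' @param r erosion radius in pixels.
#' @return eroded logical matrix.
#' @export
erode_mask <- function(mask, r = 1L) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  for (dr in -r:r) {
    for (dc in -r:r) {
      out <- out & mask[pmin(pmax(seq_len(nr) + dr, 1L), nr),
                        pmin(pmax(seq_len(nc) + dc, 1L), nc)]
    }
  }
  out
}

#' Rasterize an ROI to a logical pixel mask
#'
#' @param roi a `roi_selection`.
#' @param dim image dimensions `c(rows, cols)`.
#' @return logical matrix, TRUE inside the ROI.
#' @export
roi_mask <- function(roi, dim) {
  nr <- dim[1]; nc <- dim[2]
  col0 <- matrix(rep(0:(nc - 1), each = nr), nr, nc)  # x
  row0 <- matrix(rep(0:(nr - 1), nc), nr, nc)         # y
  m <- switch(roi$kind,
    full = matrix(TRUE, nr, nc),
    mask = {
      if (!all(dim(roi$mask) == dim)) stop("ROI mask shape mismatch")
      roi$mask
    },
    rectangle = col0 >= roi$x0 & col0 < roi$x1 & row0 >= roi$y0 & row0 < roi$y1,
    circle = (col0 - roi$cx)^2 + (row0 - roi$cy)^2 <= roi$r^2,
    polygon = matrix(point_in_polygon(as.vector(col0), as.vector(row0),
                                      roi$xs, roi$ys), nr, nc),
    stop("unknown ROI kind: ", roi$kind)
  )
  if (!any(m)) stop("ROI does not intersect the image")
  m
}

# even-odd rule ray casting
point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Fit a relaxation-time map over an image series
#'
#' Runs the mode-appropriate mono- (or bi-) exponential fitter on every
#' pixel's intensity-versus-TR (or TE) sequence inside the ROI, after
#' optional smoothing and per-pixel normalization. Pixels whose fit is
#' invalid or whose coefficient of determination falls below
#' `r2_threshold` are masked and their time set to 0 (de-noising rule);
#' pixels outside the ROI are likewise masked.
#'
#' @param series an [image_series()].
#' @param roi a `roi_selection` (default full image).
#' @param model `"mono"` or `"biexp"`.
#' @param smooth smoothing kernel for [smooth_series()].
#' @param r2_threshold mask fits with R^2 below this (default 0.4).
#' @param normalize per-pixel unit-maximum normalization before fitting.
#' @return a `relaxation_map`: matrices `time_ms`, `r_squared`, logical
#'   `mask`, plus `mode`, `r2_threshold` and a `provenance` record of the
#'   schedule and options used.
#' @export
fit_map <- function(series, roi = roi_full(), model = c("mono", "biexp"),
                    smooth = "none", r2_threshold = 0.4, normalize = TRUE) {
  model <- match.arg(model)
  if (!inherits(series, "image_series")) stop("expected an image_series")
  if (length(series$frames) < 3) stop("insufficient frames")
  if (r2_threshold < 0 || r2_threshold > 1) stop("r2_threshold must be in [0, 1]")
  series <- smooth_series(series, smooth)
  arr <- series_array(series)
  sched <- series_schedule(series)
  x <- sched$varied
  d <- dim(arr)[1:2]
  inroi <- roi_mask(roi, d)

  time_ms <- matrix(0, d[1], d[2])
  r2 <- matrix(NA_real_, d[1], d[2])
  valid <- matrix(FALSE, d[1], d[2])
  fitter <- if (series$mode == "T1") fit_t1 else fit_t2
  for (i in which(inroi)) {
    r <- (i - 1L) %% d[1] + 1L
    c <- (i - 1L) %/% d[1] + 1L
    y <- arr[r, c, ]
    if (max(y) <= 0) next
    res <- if (model == "mono") {
      fitter(x, y, normalize = normalize)
    } else {
      suppressMessages(
        fit_biexponential(x, y, mode = series$mode, normalize = normalize))
    }
    r2[r, c] <- res$r_squared
    if (res$valid) {
      time_ms[r, c] <- res$time_ms
      valid[r, c] <- TRUE
    }
  }
  mask <- valid & inroi & !is.na(r2) & r2 >= r2_threshold
  time_ms[!mask] <- 0
  structure(
    list(time_ms = time_ms, r_squared = r2, mask = mask,
         mode = series$mode, r2_threshold = r2_threshold,
         pixel_spacing_mm = series$pixel_spacing_mm,
         provenance = list(
           tr_ms = sched$tr_ms, te_ms = sched$te_ms, model = model,
           smooth = smooth, normalize = normalize,
           r2_threshold = r2_threshold,
           fixed_parameter_ms = series$fixed_parameter_ms)),
    class = "relaxation_map"
  )
}

#' @export
print.relaxation_map <- function(x, ...) {
  kept <- sum(x$mask)
  cat(sprintf("<relaxation_map> %s, %dx%d, %d kept pixel(s) (R^2 >= %g)\n",
              x$mode, nrow(x$time_ms), ncol(x$time_ms), kept, x$r2_threshold))
  if (kept > 0) {
    v <- x$time_ms[x$mask]
    cat(sprintf("  time: mean %.1f ms, range %.1f..%.1f ms\n",
                mean(v), min(v), max(v)))
  }
  invisible(x)
}

#' ROI statistics over kept pixels
#'
#' Mean and pixel standard deviation of the relaxation time over
#' mask-true pixels inside the ROI (population SD convention, divide by
#' n). The pixel count is reported so the SD's meaning is auditable.
#'
#' @param map a `relaxation_map`.
#' @param roi a `roi_selection` (default full image).
#' @return list with `mean_ms`, `sd_ms`, `n_pixels`.
#' @export
roi_stats <- function(map, roi = roi_full()) {
  sel <- roi_mask(roi, dim(map$time_ms)) & map$mask
  if (!any(sel)) stop("empty ROI after masking")
  v <- map$time_ms[sel]
  m <- mean(v)
  list(mean_ms = m, sd_ms = sqrt(mean((v - m)^2)), n_pixels = sum(sel))
}

#' Relaxation-time profile along a straight line
#'
#' Samples the map along the rasterized segment between two pixel
#' coordinates (one row of pixels, Bresenham on pixel centers). Masked
#' pixels contribute their stored value 0. Distances are physical,
#' using the map's pixel spacing.
#'
#' @param map a `relaxation_map`.
#' @param start,end `c(x, y)` 0-based pixel coordinates inside the image.
#' @return data frame with `distance_mm` and `time_ms`.
#' @export
line_profile <- function(map, start, end) {
  d <- dim(map$time_ms)
  chk <- function(p) {
    if (p[1] < 0 || p[1] > d[2] - 1 || p[2] < 0 || p[2] > d[1] - 1) {
      stop("profile endpoint outside the image")
    }
  }
  chk(start); chk(end)
  if (all(start == end)) stop("zero-length profile segment")
  pts <- bresenham(start[1], start[2], end[1], end[2])
  sp <- map$pixel_spacing_mm
  if (length(sp) == 1) sp <- rep(sp, 2)
  dist <- sqrt(((pts$x - start[1]) * sp[2])^2 + ((pts$y - start[2]) * sp[1])^2)
  vals <- map$time_ms[cbind(pts$y + 1L, pts$x + 1L)]
  data.frame(distance_mm = dist, time_ms = vals)
}

bresenham <- function(x0, y0, x1, y1) {
  x0 <- round(x0); y0 <- round(y0); x1 <- round(x1); y1 <- round(y1)
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- sign(x1 - x0); sy <- sign(y1 - y0)
  err <- dx + dy
  xs <- integer(0); ys <- integer(0)
  x <- x0; y <- y0
  repeat {
    xs <- c(xs, x); ys <- c(ys, y)
    if (x == x1 && y == y1) break
    e2 <- 2 * err
    if (e2 >= dy) { err <- err + dy; x <- x + sx }
    if (e2 <= dx) { err <- err + dx; y <- y + sy }
  }
  list(x = xs, y = ys)
}

#' Histogram of kept relaxation times in an ROI
#'
#' @param map a `relaxation_map`.
#' @param roi a `roi_selection`.
#' @param bins number of equal-width bins, `>= 1`.
#' @return list with `bin_edges_ms` (length `bins + 1`) and `counts`
#'   (sums to the ROI's kept-pixel count; masked zeros excluded).
#' @export
map_histogram <- function(map, roi = roi_full(), bins = 32) {
  if (bins < 1) stop("bins must be >= 1")
  sel <- roi_mask(roi, dim(map$time_ms)) & map$mask
  if (!any(sel)) stop("empty ROI after masking")
  v <- map$time_ms[sel]
  rng <- range(v)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  list(bin_edges_ms = edges, counts = tabulate(idx, nbins = bins))
}

#' Compare two maps' ROI pixel populations
#'
#' Welch two-sample t-test on the kept relaxation times of the same ROI
#' in two maps (e.g. two culture weeks).
#'
#' @param map1,map2 `relaxation_map` objects.
#' @param roi a `roi_selection`.
#' @return an `htest` object.
#' @export
roi_compare <- function(map1, map2, roi = roi_full()) {
  s1 <- roi_mask(roi, dim(map1$time_ms)) & map1$mask
  s2 <- roi_mask(roi, dim(map2$time_ms)) & map2$mask
  if (!any(s1) || !any(s2)) stop("empty ROI after masking")
  stats::t.test(map1$time_ms[s1], map2$time_ms[s2])
}

#' Export a relaxation map
#'
#' Formats: `"csv"` writes the time grid losslessly (17 significant
#' digits; masked pixels as 0); `"png"` renders the map with the viridis
#' colormap plus a right-hand colorbar strip (masked pixels black);
#' `"report"` writes a text report with the schedule, options, masking
#' threshold and full-image ROI statistics.
#'
#' @param map a `relaxation_map`.
#' @param out_path output file path.
#' @param format `"csv"`, `"png"`, or `"report"`.
#' @return invisibly, `out_path`.
#' @export
export_map <- function(map, out_path, format = c("csv", "png", "report")) {
  format <- match.arg(format)
  if (format == "csv") {
    m <- map$time_ms
    txt <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
    writeLines(txt, out_path)
  } else if (format == "png") {
    png::writePNG(render_map_rgb(map), out_path)
  } else {
    st <- tryCatch(roi_stats(map, roi_full()), error = function(e) NULL)
    p <- map$provenance
    lines <- c(
      sprintf("relaxation map report (%s protocol)", map$mode),
      sprintf("grid: %d x %d pixels, spacing %s mm",
              nrow(map$time_ms), ncol(map$time_ms),
              paste(signif(map$pixel_spacing_mm, 6), collapse = " x ")),
      sprintf("TR schedule [ms]: %s", paste(p$tr_ms, collapse = ", ")),
      sprintf("TE schedule [ms]: %s", paste(p$te_ms, collapse = ", ")),
      sprintf("model: %s-exponential; smoothing: %s; normalization: %s",
              ifelse(p$model == "mono", "mono", "bi"), p$smooth, p$normalize),
      sprintf("r2_threshold: %g (fits below are masked to 0)", map$r2_threshold),
      sprintf("kept pixels: %d of %d", sum(map$mask), length(map$mask)),
      if (!is.null(st)) {
        sprintf("full-image ROI: mean %.4f ms +/- %.4f ms (population SD, n = %d)",
                st$mean_ms, st$sd_ms, st$n_pixels)
      } else "full-image ROI: no kept pixels"
    )
    writeLines(lines, out_path)
  }
  invisible(out_path)
}

render_map_rgb <- function(map, bar_width = 10L) {
  pal <- grDevices::hcl.colors(256, "viridis")
  rgbm <- grDevices::col2rgb(pal) / 255
  v <- map$time_ms
  mx <- max(v)
  idx <- if (mx > 0) pmin(255L, as.integer(255 * v / mx)) + 1L else
    matrix(1L, nrow(v), ncol(v))
  nr <- nrow(v); nc <- ncol(v)
  img <- array(0, c(nr, nc + bar_width + 2L, 3))
  for (ch in 1:3) {
    plane <- matrix(rgbm[ch, idx], nr, nc)
    plane[!map$mask] <- 0  # reserved color for masked pixels
    img[, seq_len(nc), ch] <- plane
    bar_idx <- pmin(256L, as.integer(seq(256, 1, length.out = nr)))
    img[, nc + 2L + seq_len(bar_width), ch] <- matrix(rgbm[ch, bar_idx],
                                                      nr, bar_width)
  }
  img
}

#' Read a CSV map grid written by [export_map()]
#'
#' @param path CSV path.
#' @return numeric matrix.
#' @export
read_map_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  m
}
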