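# Digital phantom and bioreactor simulator: ground-truth (PD, T1, T2)
# parameter maps plus spin-echo magnitude series with Rician noise.

#' Capillary-phantom specification
#'
#' Describes a test tube of demineralized water with thin-walled glass
#' capillaries immersed in it, imaged axially. Defaults reproduce the
#' reference phantom: 13.8 mm tube inner diameter, 16 capillaries of
#' 2.3 mm outer diameter and 0.4 mm wall, FOV 50 mm on a 512 x 512
#' matrix (0.09766 mm/pixel).
#'
#' Compartment parameters map region labels to `(pd, t1_ms, t2_ms)`.
#' Proton density is exactly 0 in background/air and in glass walls.
#'
#' @param fov_mm square field of view, mm.
#' @param matrix grid size (pixels per side), `>= 16`.
#' @param tube_inner_diameter_mm tube inner diameter, mm.
#' @param capillary_count number of capillaries, `>= 0`.
#' @param capillary_outer_diameter_mm capillary outer diameter, mm.
#' @param capillary_wall_mm capillary wall thickness, mm.
#' @param compartment_params named list of `c(pd, t1_ms, t2_ms)` for
#'   `background`, `tube_water`, `capillary_wall`, `capillary_lumen`.
#' @param seed integer seed (reserved for optional placement jitter;
#'   the default ring layout is deterministic).
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(fov_mm = 50, matrix = 512,
                         tube_inner_diameter_mm = 13.8,
                         capillary_count = 16,
                         capillary_outer_diameter_mm = 2.3,
                         capillary_wall_mm = 0.4,
                         compartment_params = list(
                           background     = c(pd = 0,   t1_ms = 1,    t2_ms = 1),
                           tube_water     = c(pd = 1,   t1_ms = 3000, t2_ms = 1500),
                           capillary_wall = c(pd = 0,   t1_ms = 1,    t2_ms = 1),
                           capillary_lumen = c(pd = 1,  t1_ms = 3000, t2_ms = 1500)
                         ),
                         seed = 1L) {
  stopifnot(fov_mm > 0, matrix >= 16, capillary_count >= 0,
            capillary_outer_diameter_mm > 0,
            capillary_wall_mm > 0,
            capillary_wall_mm < capillary_outer_diameter_mm / 2,
            tube_inner_diameter_mm > 0)
  for (p in compartment_params) {
    if (p[["pd"]] < 0 || p[["t1_ms"]] <= 0 || p[["t2_ms"]] <= 0) {
      stop("compartment parameters need pd >= 0 and t1, t2 > 0")
    }
  }
  structure(
    list(fov_mm = fov_mm, matrix = as.integer(matrix),
         tube_inner_diameter_mm = tube_inner_diameter_mm,
         capillary_count = as.integer(capillary_count),
         capillary_outer_diameter_mm = capillary_outer_diameter_mm,
         capillary_wall_mm = capillary_wall_mm,
         compartment_params = compartment_params,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Deterministic concentric-ring packing of capillary centers inside the
# tube. Rings are filled from the outside in; a last single capillary may
# sit at the center. Errors when the requested count cannot be placed.
place_capillaries <- function(tube_radius, cap_radius, count,
                              clearance = 0.05) {
  if (count == 0) return(matrix(numeric(0), ncol = 2))
  centers <- matrix(numeric(0), ncol = 2)
  remaining <- count
  r_ring <- tube_radius - cap_radius - clearance
  ring_idx <- 0L
  while (remaining > 0 && r_ring > cap_radius) {
    half_angle <- asin(min(1, (cap_radius + clearance / 2) / r_ring))
    cap_per_ring <- max(1L, floor(pi / half_angle))
    n <- min(remaining, cap_per_ring)
    ang <- 2 * pi * seq_len(n) / n + ring_idx * pi / 7  # stagger rings
    centers <- rbind(centers, cbind(r_ring * cos(ang), r_ring * sin(ang)))
    remaining <- remaining - n
    r_ring <- r_ring - (2 * cap_radius + clearance)
    ring_idx <- ring_idx + 1L
  }
  if (remaining == 1 && nrow(centers) == 0 ||
      (remaining == 1 && min(sqrt(rowSums(centers^2))) >= 2 * cap_radius + clearance)) {
    centers <- rbind(centers, c(0, 0))
    remaining <- remaining - 1L
  }
  if (remaining > 0) {
    stop("infeasible packing: ", count, " capillaries of radius ",
         cap_radius, " mm cannot fit in a tube of radius ", tube_radius, " mm")
  }
  centers
}

#' Build ground-truth parameter maps for a capillary phantom
#'
#' Rasterizes the phantom geometry onto the pixel grid (region membership
#' decided at pixel centers, so label counts are exact) and fills
#' per-pixel PD, T1 and T2 from the compartment table. Pixel centers sit
#' at `(i + 0.5) * spacing` with the tube axis at the grid center;
#' `pixel_spacing = fov_mm / matrix`.
#'
#' Region labels: 0 background, 1 tube water, 2 capillary wall,
#' 3 capillary lumen.
#'
#' @param spec a [phantom_spec()].
#' @return a `parameter_maps` object: matrices `pd`, `t1_ms`, `t2_ms`,
#'   integer `labels`, scalar `pixel_spacing_mm`, and `label_names`.
#' @export
build_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("expected a phantom_spec")
  n <- spec$matrix
  sp <- spec$fov_mm / n
  # pixel-center coordinates relative to the grid center
  ax <- ((seq_len(n) - 0.5) - n / 2) * sp
  X <- matrix(ax, n, n, byrow = TRUE)   # column coordinate
  Y <- matrix(ax, n, n)                 # row coordinate
  R2 <- X^2 + Y^2

  tube_r <- spec$tube_inner_diameter_mm / 2
  cap_r <- spec$capillary_outer_diameter_mm / 2
  lumen_r <- cap_r - spec$capillary_wall_mm
  centers <- place_capillaries(tube_r, cap_r, spec$capillary_count)

  labels <- matrix(0L, n, n)
  labels[R2 <= tube_r^2] <- 1L
  if (nrow(centers) > 0) {
    for (i in seq_len(nrow(centers))) {
      d2 <- (X - centers[i, 1])^2 + (Y - centers[i, 2])^2
      labels[d2 <= cap_r^2] <- 2L
      labels[d2 <= lumen_r^2] <- 3L
    }
  }
  region_names <- c("background", "tube_water", "capillary_wall", "capillary_lumen")
  fill_maps(labels, region_names, spec$compartment_params, sp)
}

#' Construct parameter maps directly
#'
#' Builds a `parameter_maps` object from explicit per-pixel grids, e.g.
#' uniform fields for calibration studies.
#'
#' @param pd,t1_ms,t2_ms numeric matrices of equal shape; `t1_ms` and
#'   `t2_ms` must be positive wherever `pd > 0`.
#' @param pixel_spacing_mm scalar pixel spacing, mm.
#' @param labels optional integer region-label matrix (default all 0).
#' @param label_names names for the label levels.
#' @return a `parameter_maps` object.
#' @export
parameter_maps <- function(pd, t1_ms, t2_ms, pixel_spacing_mm = 1,
                           labels = NULL, label_names = "region") {
  if (is.null(dim(pd))) pd <- as.matrix(pd)
  if (length(t1_ms) == 1) t1_ms <- matrix(t1_ms, nrow(pd), ncol(pd))
  if (length(t2_ms) == 1) t2_ms <- matrix(t2_ms, nrow(pd), ncol(pd))
  if (!all(dim(pd) == dim(t1_ms)) || !all(dim(pd) == dim(t2_ms))) {
    stop("pd, t1_ms, t2_ms must share one shape")
  }
  if (any(pd < 0)) stop("pd must be >= 0")
  live <- pd > 0
  if (any(t1_ms[live] <= 0) || any(t2_ms[live] <= 0)) {
    stop("t1_ms and t2_ms must be > 0 wherever pd > 0")
  }
  if (is.null(labels)) labels <- matrix(0L, nrow(pd), ncol(pd))
  structure(
    list(pd = pd, t1_ms = t1_ms, t2_ms = t2_ms, labels = labels,
         pixel_spacing_mm = pixel_spacing_mm, label_names = label_names),
    class = "parameter_maps"
  )
}

fill_maps <- function(labels, region_names, params, spacing) {
  pd <- t1 <- t2 <- matrix(0, nrow(labels), ncol(labels))
  t1[] <- 1; t2[] <- 1  # positive placeholders where pd = 0
  for (k in seq_along(region_names)) {
    p <- params[[region_names[k]]]
    if (is.null(p)) next
    sel <- labels == (k - 1L)
    pd[sel] <- p[["pd"]]
    t1[sel] <- p[["t1_ms"]]
    t2[sel] <- p[["t2_ms"]]
  }
  structure(
    list(pd = pd, t1_ms = t1, t2_ms = t2, labels = labels,
         pixel_spacing_mm = spacing, label_names = region_names),
    class = "parameter_maps"
  )
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat(sprintf("<parameter_maps> %dx%d at %.5f mm/pixel\n",
              nrow(x$pd), ncol(x$pd), x$pixel_spacing_mm))
  tab <- table(factor(x$labels, levels = seq_along(x$label_names) - 1L,
                      labels = x$label_names))
  for (nm in names(tab)) cat(sprintf("  %-16s %d px\n", nm, tab[[nm]]))
  invisible(x)
}

#' Reference T1/T2 values of cultured cells by week
#'
#' Weekly spin-lattice and spin-spin relaxation times of 3D MCF-7 breast
#' cancer cell cultures grown in hollow-fiber bioreactors at 1.5 T,
#' used as ground truth by the bioreactor preset so simulation studies
#' span a realistic range (T1 1100 -> 673 ms, T2 171 -> 128 ms over six
#' weeks).
#'
#' @return data frame with columns `week`, `t1_ms`, `t2_ms`.
#' @export
mcf7_relaxation_times <- function() {
  data.frame(
    week = 1:6,
    t1_ms = c(1100, 1060, 911, 856, 795, 673),
    t2_ms = c(171, 168, 155, 149, 137, 128)
  )
}

#' Build ground-truth maps for a bioreactor-like cross-section
#'
#' Concentric preset mimicking a hollow-fiber bioreactor: a medium
#' annulus (long T1/T2, free culture medium) surrounds a central cell
#' region (short T1/T2) pierced by signal-void fiber cross-sections.
#' Cell-region relaxation times default to the weekly culture values of
#' [mcf7_relaxation_times()].
#'
#' Region labels: 0 background, 1 medium, 2 cell region, 3 fiber void.
#'
#' @param week culture week 1..6 selecting the cell-region T1/T2.
#' @param fov_mm field of view, mm.
#' @param matrix grid size.
#' @param tube_inner_diameter_mm bioreactor tube inner diameter, mm.
#' @param cell_region_radius_mm radius of the central cell mass, mm.
#' @param n_fibers number of hollow fibers crossing the cell mass.
#' @param fiber_radius_mm fiber outer radius, mm.
#' @param medium_params,cell_pd medium `(pd, t1, t2)` and cell-region PD.
#' @return a `parameter_maps` object.
#' @export
bioreactor_maps <- function(week = 1, fov_mm = 30, matrix = 128,
                            tube_inner_diameter_mm = 10,
                            cell_region_radius_mm = 4,
                            n_fibers = 7, fiber_radius_mm = 0.65,
                            medium_params = c(pd = 1, t1_ms = 3000, t2_ms = 1500),
                            cell_pd = 0.9) {
  ref <- mcf7_relaxation_times()
  if (!week %in% ref$week) stop("week must be in 1..6")
  n <- as.integer(matrix)
  sp <- fov_mm / n
  ax <- ((seq_len(n) - 0.5) - n / 2) * sp
  X <- matrix(ax, n, n, byrow = TRUE)
  Y <- matrix(ax, n, n)
  R2 <- X^2 + Y^2

  labels <- matrix(0L, n, n)
  labels[R2 <= (tube_inner_diameter_mm / 2)^2] <- 1L
  labels[R2 <= cell_region_radius_mm^2] <- 2L
  # one central fiber plus a ring
  fc <- rbind(c(0, 0))
  if (n_fibers > 1) {
    ang <- 2 * pi * seq_len(n_fibers - 1) / (n_fibers - 1)
    ring_r <- cell_region_radius_mm * 0.55
    fc <- rbind(fc, cbind(ring_r * cos(ang), ring_r * sin(ang)))
  }
  for (i in seq_len(min(n_fibers, nrow(fc)))) {
    d2 <- (X - fc[i, 1])^2 + (Y - fc[i, 2])^2
    labels[d2 <= fiber_radius_mm^2] <- 3L
  }
  params <- list(
    background = c(pd = 0, t1_ms = 1, t2_ms = 1),
    medium = medium_params,
    cell_region = c(pd = cell_pd,
                    t1_ms = ref$t1_ms[ref$week == week],
                    t2_ms = ref$t2_ms[ref$week == week]),
    fiber = c(pd = 0, t1_ms = 1, t2_ms = 1)
  )
  fill_maps(labels, c("background", "medium", "cell_region", "fiber"), params, sp)
}

#' Standard acquisition schedules
#'
#' The variable-TR T1 protocol (9 points, 500..15000 ms, TE fixed at
#' 3 ms) and the variable-TE T2 protocol (10 points, 10..200 ms, TR fixed
#' at 10000 ms).
#'
#' @param mode `"T1"` or `"T2"`.
#' @param te_ms fixed echo time of the T1 protocol, ms.
#' @param tr_ms fixed repetition time of the T2 protocol, ms.
#' @return data frame with columns `tr_ms`, `te_ms`.
#' @export
protocol_schedule <- function(mode = c("T1", "T2"), te_ms = 3, tr_ms = 10000) {
  mode <- match.arg(mode)
  if (mode == "T1") {
    data.frame(tr_ms = c(500, 700, 1000, 1500, 2000, 3000, 5000, 10000, 15000),
               te_ms = te_ms)
  } else {
    data.frame(tr_ms = tr_ms,
               te_ms = c(10, 20, 26.2, 42, 68, 85, 102, 130, 160, 200))
  }
}

#' Simulate a spin-echo magnitude series from parameter maps
#'
#' Evaluates the spin-echo [signal_model()] per pixel for every
#' `(TR, TE)` point of the schedule and, when `noise_sigma > 0`, applies
#' Rician magnitude noise: independent Gaussian noise of standard
#' deviation `noise_sigma` (in the same units as PD) on two quadrature
#' channels followed by the modulus, so zero-signal background pixels
#' follow a Rayleigh distribution with mean `noise_sigma * sqrt(pi/2)`.
#'
#' @param maps a `parameter_maps` object ([build_phantom()],
#'   [bioreactor_maps()]).
#' @param schedule data frame with columns `tr_ms`, `te_ms`; must vary
#'   only one of the two (pure T1 or pure T2 protocol).
#' @param noise_sigma Rician channel noise standard deviation, `>= 0`.
#' @param seed integer seed for reproducible noise.
#' @return an [image_series()] carrying the maps' pixel spacing.
#' @export
simulate_series <- function(maps, schedule = protocol_schedule("T1"),
                            noise_sigma = 0, seed = NULL) {
  if (!inherits(maps, "parameter_maps")) stop("expected parameter_maps")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  tr <- schedule$tr_ms
  te <- schedule$te_ms
  if (length(tr) != length(te)) stop("schedule rows must pair tr_ms and te_ms")
  if (length(unique(tr)) > 1 && length(unique(te)) > 1) {
    stop("ambiguous protocol: schedule varies both TR and TE")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(tr)
  frames <- vector("list", n)
  safe_t1 <- pmax(maps$t1_ms, .Machine$double.eps)
  safe_t2 <- pmax(maps$t2_ms, .Machine$double.eps)
  for (k in seq_len(n)) {
    s <- maps$pd * (1 - exp(-tr[k] / safe_t1)) * exp(-te[k] / safe_t2)
    if (noise_sigma > 0) {
      s <- sqrt((s + stats::rnorm(length(s), 0, noise_sigma))^2 +
                stats::rnorm(length(s), 0, noise_sigma)^2)
      dim(s) <- dim(maps$pd)
    }
    frames[[k]] <- s
  }
  image_series(frames, tr, te,
               pixel_spacing_mm = maps$pixel_spacing_mm,
               frame_id = sprintf("sim_%03d", seq_len(n)))
}

#' Label connected components of a binary image
#'
#' 4-connectivity flood fill; used to count simply-connected regions
#' (e.g. capillary lumina) in label grids.
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background) with an
#'   attribute `n` giving the component count.
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  comp <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue) > 0) {
      cur <- queue
      queue <- integer(0)
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc <- c + d[2]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        ni <- (cc[ok] - 1L) * nr + rr[ok]
        ni <- ni[mask[ni] & lab[ni] == 0L]
        if (length(ni) > 0) {
          lab[ni] <- comp
          queue <- c(queue, ni)
        }
      }
    }
  }
  attr(lab, "n") <- comp
  lab
}
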