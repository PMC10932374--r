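#' @importFrom minpack.lm nlsLM nls.lm.control
NULL

# Container for a per-pixel exponential fit. Invalid fits carry time_ms = 0
# so that map assembly never propagates exceptions.
new_fit_result <- function(a = NA_real_, b = NA_real_, c = NA_real_,
                           time_ms = 0, r_squared = NA_real_,
                           valid = FALSE, model = "mono-T1",
                           components = NULL, note = NULL) {
  structure(
    list(a = a, b = b, c = c, time_ms = time_ms, r_squared = r_squared,
         valid = valid, model = model, components = components, note = note),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<%s fit> %s\n", x$model,
              if (x$valid) sprintf("time = %.4g ms, R^2 = %.6f", x$time_ms, x$r_squared)
              else sprintf("invalid (%s)", x$note %||% "did not converge")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a signal-intensity vector to unit maximum
#'
#' Different pixels carry different proton densities, so their intensity
#' curves share shape but not scale; fitting operates on curves normalized
#' so their maximum equals 1.
#'
#' @param intensities numeric vector of `>= 3` non-negative values.
#' @return the vector divided by its maximum.
#' @export
normalize_signal <- function(intensities) {
  if (length(intensities) < 3) stop("need at least 3 intensity values")
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and non-negative")
  }
  m <- max(intensities)
  if (m <= 0) stop("degenerate signal: all intensities are zero")
  intensities / m
}

r_squared_of <- function(y, fitted) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= .Machine$double.eps * length(y)) return(NA_real_)
  1 - sum((y - fitted)^2) / ss_tot
}

# allow_zero: echo times may include the idealized TE = 0 point
check_xy <- function(x, y, allow_zero = FALSE) {
  if (length(x) != length(y)) stop("timing and intensity vectors differ in length")
  if (length(x) < 3) stop("need at least 3 points")
  if (any(x < 0) || (!allow_zero && any(x == 0))) stop("times must be > 0")
  if (any(diff(x) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(y))) stop("intensities must be finite")
}

#' T1 readout from fitted recovery coefficients
#'
#' Given a converged saturation-recovery fit `a - b*exp(-(c*x)/1000)` on a
#' normalized curve, T1 is the TR at which the curve reaches the
#' `1 - exp(-1)` recovery fraction:
#' \deqn{T_1 = -1000 \ln\{(a - (1 - e^{-1}))/b\} / c.}
#' For the ideal normalized model (a = b = 1) this reduces to `1000/c`.
#'
#' @param a,b,c fitted coefficients (rate `c` in 1/s, i.e. the model uses
#'   `c*x/1000` with `x` in ms).
#' @return T1 in ms, or `NA` when the readout is undefined
#'   (`a <= 1 - exp(-1)`, `b <= 0`, `c == 0`, or a non-positive result).
#' @export
t1_readout <- function(a, b, c) {
  frac <- 1 - exp(-1)
  if (!is.finite(a) || !is.finite(b) || !is.finite(c)) return(NA_real_)
  if (a - frac <= 0 || b <= 0 || c == 0) return(NA_real_)
  t1 <- -1000 * log((a - frac) / b) / c
  if (!is.finite(t1) || t1 <= 0) return(NA_real_)
  t1
}

#' Fit the saturation-recovery T1 model to one intensity curve
#'
#' Least-squares fit of `a - b*exp(-(c*x)/1000)` to signal intensity
#' versus repetition time, followed by the [t1_readout()] rule applied to
#' the plateau-normalized coefficients `(1, b/a, c)`: the 63.21% readout
#' level refers to the recovered maximum (the fitted plateau `a`, the
#' proton-density estimate), so the derived time does not depend on the
#' intensity scale. The curve is normalized to unit maximum before
#' fitting (per-pixel proton density drops out of the shape).
#' Non-convergence or an undefined readout yields an invalid result with
#' `time_ms = 0` rather than an error.
#'
#' @param tr_ms strictly increasing repetition times in ms (`>= 3` values).
#' @param intensities non-negative intensities, same length.
#' @param normalize divide by the curve maximum before fitting (default TRUE).
#' @return a `fit_result`: coefficients `a`, `b`, `c`, derived `time_ms`,
#'   `r_squared`, and `valid` flag.
#' @examples
#' tr <- c(500, 700, 1000, 1500, 2000, 3000, 5000, 10000, 15000)
#' is1 <- c(0.1993, 0.2674, 0.3588, 0.4866, 0.5889,
#'          0.7364, 0.8916, 0.9883, 0.9987)
#' fit_t1(tr, is1)$time_ms  # ~2250 ms
#' @export
fit_t1 <- function(tr_ms, intensities, normalize = TRUE) {
  check_xy(tr_ms, intensities)
  if (any(intensities < 0)) stop("intensities must be non-negative")
  y <- intensities
  if (normalize) {
    if (max(y) <= 0) return(new_fit_result(model = "mono-T1", note = "degenerate signal"))
    y <- y / max(y)
  }
  if (diff(range(y)) < 1e-12) {
    return(new_fit_result(model = "mono-T1", note = "constant intensities"))
  }
  a0 <- max(y)
  b0 <- max(a0 - min(y), 1e-3)
  c0 <- 1000 / stats::median(tr_ms)
  df <- data.frame(x = tr_ms, y = y)
  fit <- tryCatch(
    nlsLM(y ~ a - b * exp(-(c * x) / 1000), data = df,
          start = list(a = a0, b = b0, c = c0),
          control = nls.lm.control(maxiter = 500, ftol = 1e-10)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(new_fit_result(model = "mono-T1", note = "no convergence"))
  cf <- stats::coef(fit)
  r2 <- r_squared_of(y, stats::fitted(fit))
  # The readout threshold is defined on the curve normalized so its
  # plateau (the proton-density estimate, a) equals 1; evaluating the
  # readout on (1, b/a, c) makes the derived time scale-invariant and
  # equal to the ideal-model closed form 1000/c when a = b.
  t1 <- if (is.finite(cf[["a"]]) && cf[["a"]] > 0) {
    t1_readout(1, cf[["b"]] / cf[["a"]], cf[["c"]])
  } else NA_real_
  if (is.na(t1) || is.na(r2)) {
    return(new_fit_result(a = cf[["a"]], b = cf[["b"]], c = cf[["c"]],
                          model = "mono-T1", note = "readout undefined"))
  }
  new_fit_result(a = cf[["a"]], b = cf[["b"]], c = cf[["c"]],
                 time_ms = t1, r_squared = r2, valid = TRUE, model = "mono-T1")
}

#' Fit the mono-exponential T2 decay model to one intensity curve
#'
#' Least-squares fit of `a*exp(-(c*x)/1000)` to signal intensity versus
#' echo time. T2 is the TE at which the fitted curve drops to `exp(-1)`
#' of its maximum, which for this model is `1000/c`. Non-decaying data
#' (best-fit `c <= 0`) yield an invalid result.
#'
#' @inheritParams fit_t1
#' @param te_ms strictly increasing echo times in ms (`>= 3` values).
#' @return a `fit_result` with `model = "mono-T2"`.
#' @export
fit_t2 <- function(te_ms, intensities, normalize = TRUE) {
  check_xy(te_ms, intensities, allow_zero = TRUE)
  if (any(intensities < 0)) stop("intensities must be non-negative")
  y <- intensities
  if (normalize) {
    if (max(y) <= 0) return(new_fit_result(model = "mono-T2", note = "degenerate signal"))
    y <- y / max(y)
  }
  if (diff(range(y)) < 1e-12) {
    return(new_fit_result(model = "mono-T2", note = "constant intensities"))
  }
  # log-linear initialization where the curve is positive
  pos <- y > 0
  c0 <- if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(y[pos]) ~ te_ms[pos]))[[2]]
    max(-1000 * sl, 1e-3)
  } else 1000 / stats::median(te_ms)
  a0 <- max(y)
  df <- data.frame(x = te_ms, y = y)
  fit <- tryCatch(
    nlsLM(y ~ a * exp(-(c * x) / 1000), data = df,
          start = list(a = a0, c = c0),
          control = nls.lm.control(maxiter = 500, ftol = 1e-10)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(new_fit_result(model = "mono-T2", note = "no convergence"))
  cf <- stats::coef(fit)
  r2 <- r_squared_of(y, stats::fitted(fit))
  if (is.na(r2) || !is.finite(cf[["c"]]) || cf[["c"]] <= 0 || cf[["a"]] <= 0) {
    return(new_fit_result(a = cf[["a"]], c = cf[["c"]],
                          model = "mono-T2", note = "non-decaying data"))
  }
  new_fit_result(a = cf[["a"]], c = cf[["c"]], time_ms = 1000 / cf[["c"]],
                 r_squared = r2, valid = TRUE, model = "mono-T2")
}

#' Fit a bi-exponential relaxation model
#'
#' Two-component analogue of the mono-exponential models:
#' `a - b1*exp(-(c1*x)/1000) - b2*exp(-(c2*x)/1000)` for T1 recovery and
#' `a1*exp(-(c1*x)/1000) + a2*exp(-(c2*x)/1000)` for T2 decay. The
#' amplitude-dominant component's time constant (`1000/c`) is reported in
#' `time_ms`; both components are kept in `$components` (sorted by
#' amplitude, largest first). When the two components are degenerate
#' (indistinguishable rates) or the fit fails, the function falls back to
#' the mono-exponential fit with a notice.
#'
#' @param x_ms strictly increasing times (TR or TE) in ms, `>= 5` values.
#' @param intensities non-negative intensities, same length.
#' @param mode `"T1"` or `"T2"`.
#' @param normalize divide by the curve maximum before fitting.
#' @return a `fit_result` with `model = "bi-exponential"` (or the mono
#'   model after fallback).
#' @export
fit_biexponential <- function(x_ms, intensities, mode = c("T1", "T2"),
                              normalize = TRUE) {
  mode <- match.arg(mode)
  if (length(x_ms) < 5 || length(intensities) < 5) {
    stop("insufficient points: bi-exponential fit needs >= 5")
  }
  check_xy(x_ms, intensities, allow_zero = (mode == "T2"))
  mono <- if (mode == "T1") fit_t1(x_ms, intensities, normalize)
          else fit_t2(x_ms, intensities, normalize)
  fallback <- function(why) {
    message("bi-exponential fit ", why, "; falling back to mono-exponential")
    mono$note <- paste0("bi-exponential ", why)
    mono
  }
  if (!mono$valid) return(fallback("has no stable mono-exponential seed"))

  y <- intensities
  if (normalize) y <- y / max(y)
  df <- data.frame(x = x_ms, y = y)
  ctrl <- nls.lm.control(maxiter = 500, ftol = 1e-10)
  fit <- tryCatch({
    if (mode == "T1") {
      nlsLM(y ~ a - b1 * exp(-(c1 * x) / 1000) - b2 * exp(-(c2 * x) / 1000),
            data = df,
            start = list(a = mono$a, b1 = mono$b * 0.6, b2 = mono$b * 0.4,
                         c1 = mono$c * 2, c2 = mono$c / 2),
            control = ctrl)
    } else {
      nlsLM(y ~ a1 * exp(-(c1 * x) / 1000) + a2 * exp(-(c2 * x) / 1000),
            data = df,
            start = list(a1 = mono$a * 0.6, a2 = mono$a * 0.4,
                         c1 = mono$c * 2, c2 = mono$c / 2),
            control = ctrl)
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(fallback("did not converge"))
  cf <- stats::coef(fit)
  r2 <- r_squared_of(y, stats::fitted(fit))
  amps <- if (mode == "T1") c(cf[["b1"]], cf[["b2"]]) else c(cf[["a1"]], cf[["a2"]])
  rates <- c(cf[["c1"]], cf[["c2"]])
  if (any(!is.finite(rates)) || any(rates <= 0) ||
      abs(rates[1] - rates[2]) < 1e-3 * max(abs(rates))) {
    return(fallback("components degenerate"))
  }
  ord <- order(abs(amps), decreasing = TRUE)
  comps <- data.frame(amplitude = amps[ord], time_ms = 1000 / rates[ord])
  new_fit_result(
    a = if (mode == "T1") cf[["a"]] else sum(amps),
    b = comps$amplitude[1], c = rates[ord][1],
    time_ms = comps$time_ms[1], r_squared = r2,
    valid = TRUE, model = "bi-exponential", components = comps
  )
}
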