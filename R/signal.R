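#' Spin-echo signal intensity model
#'
#' Noiseless magnitude signal of a spin-echo acquisition,
#' \deqn{IS = PD \, (1 - e^{-TR/T_1}) \, e^{-TE/T_2},}
#' linking the three material parameters (proton density PD, longitudinal
#' relaxation time T1, transverse relaxation time T2) to the two sequence
#' timing parameters (repetition time TR, echo time TE). The signal is
#' strictly increasing in TR and strictly decreasing in TE; as TR grows
#' with TE = 0 it approaches PD.
#'
#' All arguments are recycled to a common length (or shape, when matrices
#' are supplied for the material parameters).
#'
#' @param pd proton density (arbitrary scanner units), `>= 0`.
#' @param t1_ms longitudinal relaxation time in ms, `> 0`.
#' @param t2_ms transverse relaxation time in ms, `> 0`.
#' @param tr_ms repetition time in ms, `> 0`.
#' @param te_ms echo time in ms, `>= 0` (0 is the idealized short-echo limit).
#' @return signal intensity, same shape as the broadcast arguments.
#' @examples
#' signal_model(1, 2250, 100, tr_ms = 500, te_ms = 0)   # 0.1993
#' signal_model(1, 2250, 100, tr_ms = 15000, te_ms = 0) # 0.9987
#' @export
signal_model <- function(pd, t1_ms, t2_ms, tr_ms, te_ms) {
  if (any(!is.finite(t1_ms)) || any(t1_ms <= 0)) {
    stop("t1_ms must be finite and > 0")
  }
  if (any(!is.finite(t2_ms)) || any(t2_ms <= 0)) {
    stop("t2_ms must be finite and > 0")
  }
  if (any(tr_ms <= 0)) stop("tr_ms must be > 0")
  if (any(te_ms < 0)) stop("te_ms must be >= 0")
  if (any(pd < 0)) stop("pd must be >= 0")
  pd * (1 - exp(-tr_ms / t1_ms)) * exp(-te_ms / t2_ms)
}

#' Saturation-recovery readout fractions
#'
#' The saturation-recovery method reads T1 as the TR at which the
#' normalized recovery reaches `1 - exp(-1)` (63.21%) of its plateau, and
#' T2 as the TE at which the decay falls to `exp(-1)` (36.79%) of its
#' maximum. These constants are computed in full precision rather than
#' taken as 4-digit literals.
#'
#' @return named numeric vector with elements `recovery` (`1 - exp(-1)`)
#'   and `decay` (`exp(-1)`).
#' @export
sr_readout_fractions <- function() {
  c(recovery = 1 - exp(-1), decay = exp(-1))
}
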