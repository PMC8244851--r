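# Closed-form magnitude signal models for the two T1 measurement protocols.

#' Inversion-recovery signal with imperfect inversion and excitation pulses
#'
#' Full magnitude IR signal for a spin with relaxation time `t1_ms`, sampled
#' at inversion time `ti_ms` in a sequence with repetition time `tr_ms`,
#' inversion pulse `theta180_deg` and excitation pulse `theta90_deg`:
#'
#' \deqn{y = M_0 \left| \frac{1 - \cos\theta_{180} e^{-TR/T_1}
#'   - (1-\cos\theta_{180}) e^{-TI/T_1}}
#'   {1 - \cos\theta_{180}\cos\theta_{90} e^{-TR/T_1}} \right|}
#'
#' With ideal pulses (180/90 degrees) and TR much longer than T1 this reduces
#' to the familiar \eqn{M_0 |1 - 2 e^{-TI/T_1}|}.
#'
#' @param ti_ms Inversion time(s), ms (vectorised).
#' @param t1_ms Longitudinal relaxation time, ms (> 0).
#' @param m0 Equilibrium signal.
#' @param tr_ms Repetition time, ms (> 0).
#' @param theta180_deg,theta90_deg Inversion and excitation flip angles (deg).
#' @return Nonnegative magnitude signal, same length as `ti_ms`.
#' @export
ir_signal_full <- function(ti_ms, t1_ms, m0, tr_ms,
                           theta180_deg = 180, theta90_deg = 90) {
  if (any(t1_ms <= 0)) stop("t1_ms must be positive")
  if (any(tr_ms <= 0)) stop("tr_ms must be positive")
  if (any(ti_ms < 0)) stop("ti_ms must be nonnegative")
  c180 <- cos(theta180_deg * pi / 180)
  c90 <- cos(theta90_deg * pi / 180)
  etr <- exp(-tr_ms / t1_ms)
  eti <- exp(-ti_ms / t1_ms)
  m0 * abs(1 - c180 * etr - (1 - c180) * eti) / (1 - c180 * c90 * etr)
}

#' Spoiled gradient-echo (Ernst equation) signal
#'
#' Steady-state signal of a spoiled gradient-echo acquisition at flip angle
#' `alpha_deg`:
#' \deqn{z = M_0 \sin\alpha \frac{1 - E}{1 - E\cos\alpha}, \quad
#'   E = e^{-TR/T_1}.}
#' The signal is maximised at the Ernst angle \eqn{\arccos E}.
#'
#' @param alpha_deg Flip angle(s) in degrees, in (0, 90] (vectorised).
#' @param t1_ms Longitudinal relaxation time, ms (> 0).
#' @param m0 Equilibrium signal.
#' @param tr_ms Repetition time, ms (> 0).
#' @return Nonnegative signal, same length as `alpha_deg`.
#' @export
vfa_signal <- function(alpha_deg, t1_ms, m0, tr_ms) {
  if (any(t1_ms <= 0)) stop("t1_ms must be positive")
  if (any(tr_ms <= 0)) stop("tr_ms must be positive")
  a <- alpha_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Ernst angle
#'
#' Flip angle maximising the spoiled gradient-echo signal, `acos(exp(-TR/T1))`.
#'
#' @inheritParams vfa_signal
#' @return Angle in degrees.
#' @export
ernst_angle <- function(t1_ms, tr_ms) {
  acos(exp(-tr_ms / t1_ms)) * 180 / pi
}
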