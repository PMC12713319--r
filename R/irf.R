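#' Canonical pupil impulse response function
#'
#' The pupil's response to a discrete event is modeled by the canonical
#' Erlang-family kernel
#' \deqn{h(t) = t^{w} \exp(-w\, t / t_{max}),}
#' normalized to unit peak, with shape `w = 10.1` (dimensionless) and
#' time-to-peak `t_max = 0.930` s — the standard parameterization of the
#' pupillary response to brief events. By construction `h(0) = 0` and the
#' kernel attains its maximum exactly at `t = t_max`.
#'
#' @param w shape parameter, dimensionless, `> 0`.
#' @param t_max time-to-peak in seconds, `> 0`.
#' @param duration kernel support in seconds.
#' @return An object of class `cb_irf` (a parameter list).
#' @seealso [pupil_irf()] for the discrete kernel.
#' @export
irf_params <- function(w = 10.1, t_max = 0.930, duration = 4.0) {
  stopifnot(w > 0, t_max > 0, duration > 0)
  structure(list(w = w, t_max = t_max, duration = duration), class = "cb_irf")
}

#' Discrete canonical pupil response kernel
#'
#' Samples the canonical kernel on the grid `t = k/rate`,
#' `k = 0, ..., duration*rate`, normalized to unit peak.
#'
#' @param params an [irf_params()] object.
#' @param rate sampling rate in Hz, `> 0`.
#' @return Numeric kernel vector with attribute `rate`.
#' @examples
#' k <- pupil_irf(irf_params(), rate = 100)
#' which.max(k)  # ~ t_max * rate + 1
#' @export
pupil_irf <- function(params = irf_params(), rate) {
  stopifnot(rate > 0)
  tt <- seq(0, params$duration, by = 1 / rate)
  h <- tt^params$w * exp(-params$w * tt / params$t_max)
  peak <- params$t_max^params$w * exp(-params$w)
  structure(h / peak, rate = rate)
}
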