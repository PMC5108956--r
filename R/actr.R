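#' ACT-R base-level activation
#'
#' Base-level activation of a memory trace that has been needed `n` times in
#' the past at lags `t_1, ..., t_n`:
#'
#' \deqn{A = \ln \sum_k t_k^{-d}}
#'
#' Each past use contributes a strengthening trace that decays as a power
#' function of its age; `d` is the decay parameter (amount of forgetting).
#' `A` is on a log-odds scale: it equals `ln(p / (1 - p))` where `p` is the
#' probability the trace will be needed next. Activation strictly increases
#' with every added use (frequency) and, for `d > 0`, strictly decreases as
#' any lag grows (recency). Lag units (days, seconds, ...) are the caller's
#' choice and are not converted.
#'
#' @param lags positive numeric vector of times since each past use (all in
#'   the same unit).
#' @param d decay parameter, `d >= 0`.
#' @return Activation in nats (log-odds scale).
#' @examples
#' activation(1, 0.5) # 0: ln(1)
#' activation(c(1, 2), 0.5) # ln(1 + 2^-0.5)
#' @export
activation <- function(lags, d) {
  if (length(lags) == 0) stop("encounter history must be non-empty",
                              call. = FALSE)
  if (any(!is.finite(lags)) || any(lags <= 0)) {
    stop("all lags must be finite and strictly positive", call. = FALSE)
  }
  stopifnot(is.numeric(d), length(d) == 1, d >= 0)
  log(sum(lags^(-d)))
}

#' Need probability implied by an activation
#'
#' Inverts the log-odds link: `p = 1 / (1 + exp(-A))`. Strictly increasing,
#' mapping the real line onto (0, 1).
#'
#' @param A activation (finite, log-odds scale).
#' @return Probability in (0, 1).
#' @examples
#' need_probability_from_activation(0) # 0.5
#' need_probability_from_activation(log(3)) # 0.75
#' @export
need_probability_from_activation <- function(A) {
  if (any(!is.finite(A))) stop("activation must be finite", call. = FALSE)
  stats::plogis(A)
}
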