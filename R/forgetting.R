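#' Forgetting / need-probability curves
#'
#' Two-parameter decay curves relating a probability to elapsed time `t`:
#' the power curve `P = c * t^-d` and the exponential curve
#' `P = c * exp(-d * t)`. An optional chance floor `f` generalises both to
#' `P = f + (c - f) * decay(t)` for retention tasks with a guessing baseline
#' (off, i.e. `f = 0`, by default).
#'
#' @param c scale parameter in `(floor, 1]`; the value at `t = 1` (power) or
#'   `t = 0` (exponential) net of the floor.
#' @param d decay parameter, `d >= 0`.
#' @param floor chance-level lower asymptote in `[0, 1)`; default 0.
#' @return A `power_curve` / `exponential_curve` object (both inherit
#'   `forgetting_curve`).
#' @export
power_curve <- function(c, d, floor = 0) {
  new_curve("power_curve", c, d, floor)
}

#' @rdname power_curve
#' @export
exponential_curve <- function(c, d, floor = 0) {
  new_curve("exponential_curve", c, d, floor)
}

new_curve <- function(class, c, d, floor) {
  stopifnot(is.numeric(c), length(c) == 1, is.numeric(d), length(d) == 1,
            is.numeric(floor), length(floor) == 1)
  if (floor < 0 || floor >= 1) stop("floor must be in [0, 1)", call. = FALSE)
  if (c <= floor || c > 1) stop("c must be in (floor, 1]", call. = FALSE)
  if (d < 0) stop("d must be >= 0", call. = FALSE)
  structure(list(c = c, d = d, floor = floor),
            class = c(class, "forgetting_curve"))
}

#' @export
print.forgetting_curve <- function(x, ...) {
  fam <- if (inherits(x, "power_curve")) "power" else "exponential"
  cat(sprintf("<%s curve> c = %.4g, d = %.4g%s\n", fam, x$c, x$d,
              if (x$floor > 0) sprintf(", floor = %.3g", x$floor) else ""))
  invisible(x)
}

#' Predict from a forgetting curve
#'
#' Raw, unclipped predictions; the likelihood machinery clips internally.
#' The power curve requires `t > 0`; the exponential accepts `t >= 0`.
#'
#' @param object a curve from [power_curve()] or [exponential_curve()].
#' @param t numeric vector of times/lags.
#' @param ... unused.
#' @return Numeric vector of probabilities.
#' @export
predict.power_curve <- function(object, t, ...) {
  if (any(t <= 0)) stop("power curve requires t > 0", call. = FALSE)
  object$floor + (object$c - object$floor) * t^(-object$d)
}

#' @rdname predict.power_curve
#' @export
predict.exponential_curve <- function(object, t, ...) {
  if (any(t < 0)) stop("exponential curve requires t >= 0", call. = FALSE)
  object$floor + (object$c - object$floor) * exp(-object$d * t)
}

PROB_EPS <- 1e-9

clip_prob <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

#' Negative binomial log-likelihood of a curve on binned data
#'
#' With `granularity = "bin"` each bin contributes one cross-entropy
#' (Bernoulli-style) term at its observed proportion,
#' `-[p_hat * log(q) + (1 - p_hat) * log(1 - q)]`, where `q` is the clipped
#' curve prediction at the bin value. With `granularity = "event"` each bin
#' contributes its full binomial log-pmf, `-log dbinom(successes, trials, q)`,
#' so every recorded trial carries weight.
#'
#' @param curve a `forgetting_curve`.
#' @param bins data frame with columns `bin`, `successes`, `trials` (e.g. from
#'   [bin_by_recency()]).
#' @param granularity `"bin"` or `"event"`.
#' @return Negative log-likelihood in nats (finite; predictions are clipped).
#' @export
binomial_negloglik <- function(curve, bins, granularity = c("bin", "event")) {
  granularity <- match.arg(granularity)
  stopifnot(inherits(curve, "forgetting_curve"), nrow(bins) >= 1)
  q <- clip_prob(predict(curve, bins$bin))
  if (granularity == "bin") {
    p_hat <- bins$successes / bins$trials
    -sum(p_hat * log(q) + (1 - p_hat) * log1p(-q))
  } else {
    -sum(stats::dbinom(bins$successes, bins$trials, q, log = TRUE))
  }
}

#' Ordinary least-squares line through binned proportions
#'
#' Unweighted OLS of `proportion` on `bin` — the linear model
#' `P = intercept + slope * n` for need probability as a function of contact
#' frequency `n`.
#'
#' @param bins data frame with columns `bin` and `proportion` (or
#'   `successes`/`trials`, from which the proportion is computed).
#' @return A `linear_fit` list: `intercept`, `slope`, `r_squared`, `n_points`.
#' @export
fit_linear <- function(bins) {
  if (is.null(bins$proportion)) bins$proportion <- bins$successes / bins$trials
  if (nrow(bins) < 3) stop("need at least 3 bins for a linear fit",
                           call. = FALSE)
  fit <- stats::lm(proportion ~ bin, data = bins)
  structure(list(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    r_squared = summary(fit)$r.squared,
    n_points = nrow(bins)
  ), class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear fit> P = %.4f + %.4f n   (R^2 = %.3f, %d points)\n",
              x$intercept, x$slope, x$r_squared, x$n_points))
  invisible(x)
}

default_mle_starts <- function() {
  as.matrix(expand.grid(c = c(0.2, 0.5, 0.8), d = c(0.1, 0.5, 1.5)))
}

#' Fit a power or exponential curve by binomial maximum likelihood
#'
#' Minimises [binomial_negloglik()] over `(c, d)` with bounded quasi-Newton
#' (`L-BFGS-B`) from a deterministic grid of starting values, keeping the best
#' converged solution. `n_points` — the sample size used in the AICc
#' correction — is the number of bins under `"bin"` granularity and the total
#' trial count under `"event"` granularity.
#'
#' @param bins data frame with columns `bin`, `successes`, `trials`.
#' @param family `"power"` or `"exponential"`.
#' @param granularity likelihood granularity, `"bin"` (default) or `"event"`.
#' @param starts matrix of `(c, d)` starting values; default 3 x 3 grid.
#' @param lower,upper parameter bounds; defaults `c` in `(floor, 1]`,
#'   `d` in `[0, 10]`.
#' @param floor optional chance-level floor passed to the curve.
#' @return A `fit_result` list: `family`, `curve`, `negloglik`, `n_points`,
#'   `k`, `aicc`, `granularity`.
#' @export
fit_curve_mle <- function(bins, family = c("power", "exponential"),
                          granularity = c("bin", "event"), starts = NULL,
                          lower = NULL, upper = c(1, 10), floor = 0) {
  family <- match.arg(family)
  granularity <- match.arg(granularity)
  if (length(unique(bins$bin)) < 3) {
    stop("need bins at >= 3 distinct values to fit a two-parameter curve",
         call. = FALSE)
  }
  if (is.null(starts)) starts <- default_mle_starts()
  if (is.null(lower)) lower <- c(floor + 1e-6, 0)
  make <- if (family == "power") power_curve else exponential_curve
  objective <- function(par) {
    binomial_negloglik(make(par[1], par[2], floor = floor), bins, granularity)
  }

  best <- NULL
  failures <- character(0)
  for (s in seq_len(nrow(starts))) {
    par0 <- pmin(pmax(as.numeric(starts[s, ]), lower), upper)
    res <- tryCatch(
      stats::optim(par0, objective, method = "L-BFGS-B",
                   lower = lower, upper = upper),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
    } else if (res$convergence == 0 &&
               (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) {
    stop("curve fit failed to converge from all starts: ",
         paste(unique(failures), collapse = "; "), call. = FALSE)
  }

  n_points <- if (granularity == "bin") nrow(bins) else sum(bins$trials)
  structure(list(
    family = family,
    curve = make(best$par[1], best$par[2], floor = floor),
    negloglik = best$value,
    n_points = n_points,
    k = 2L,
    aicc = aicc(best$value, 2L, n_points),
    granularity = granularity,
    fingerprint = data_fingerprint(bins, granularity)
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<%s fit> c = %.4g, d = %.4g | -logLik = %.3f, AICc = %.3f (n = %d, %s)\n",
    x$family, x$curve$c, x$curve$d, x$negloglik, x$aicc, x$n_points,
    x$granularity))
  invisible(x)
}

data_fingerprint <- function(bins, granularity) {
  rlang::hash(list(as.numeric(bins$bin), as.numeric(bins$successes),
                   as.numeric(bins$trials), granularity))
}

#' Small-sample corrected Akaike Information Criterion
#'
#' `AICc = 2 * negloglik + 2k + 2k(k + 1) / (n - k - 1)`, defined only for
#' `n > k + 1`; the correction vanishes as `n` grows.
#'
#' @param negloglik negative log-likelihood in nats.
#' @param k number of free parameters.
#' @param n_points sample size entering the correction.
#' @return AICc value.
#' @export
aicc <- function(negloglik, k, n_points) {
  if (n_points <= k + 1) {
    stop("AICc undefined for n_points <= k + 1", call. = FALSE)
  }
  2 * negloglik + 2 * k + 2 * k * (k + 1) / (n_points - k - 1)
}

#' Compare two fitted curves by AICc
#'
#' Computes the AICc difference, Akaike weights
#' (`w_i = exp(-delta_i / 2) / sum`), and the evidence ratio
#' `exp(delta_aicc / 2)` of the winning family over the losing one. Both fits
#' must come from the same binned data and granularity.
#'
#' @param fit_a,fit_b `fit_result` objects from [fit_curve_mle()].
#' @return A `model_comparison` list: `winner`, `loser`, `delta_aicc`,
#'   `akaike_weights` (named, sums to 1), `evidence_ratio`.
#' @export
compare_fits <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "fit_result"), inherits(fit_b, "fit_result"))
  if (!identical(fit_a$fingerprint, fit_b$fingerprint)) {
    stop("fits were made on different data or granularity; cannot compare",
         call. = FALSE)
  }
  fits <- list(fit_a, fit_b)
  a <- vapply(fits, `[[`, numeric(1), "aicc")
  fam <- vapply(fits, `[[`, character(1), "family")
  delta <- abs(a[1] - a[2])
  win <- which.min(a)
  w <- exp(-(a - min(a)) / 2)
  w <- w / sum(w)
  names(w) <- fam
  structure(list(
    winner = fam[win],
    loser = fam[-win][1],
    delta_aicc = delta,
    akaike_weights = w,
    evidence_ratio = exp(delta / 2)
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    "<model comparison> %s beats %s | dAICc = %.3f, evidence ratio = %.4g\n",
    x$winner, x$loser, x$delta_aicc, x$evidence_ratio))
  invisible(x)
}
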