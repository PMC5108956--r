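#' Moving-window specification
#'
#' A window of `window_length` consecutive matrix columns: the first
#' `window_length - 1` days are the history and the final day is the outcome.
#' A window is usable when at most `max_missing` of its cells are missing and
#' the outcome day is observed.
#'
#' @param window_length total days per window (history + outcome); default 16.
#' @param max_missing maximum missing cells tolerated per window; default 1.
#' @return A `window_spec` list with `window_length`, `history_length`,
#'   `max_missing`.
#' @export
window_spec <- function(window_length = 16L, max_missing = 1L) {
  window_length <- as.integer(window_length)
  max_missing <- as.integer(max_missing)
  if (window_length < 2L) stop("window_length must be >= 2", call. = FALSE)
  history <- window_length - 1L
  if (max_missing < 0L || max_missing >= history) {
    stop("max_missing must satisfy 0 <= max_missing < window_length - 1",
         call. = FALSE)
  }
  structure(list(window_length = window_length, history_length = history,
                 max_missing = max_missing), class = "window_spec")
}

#' Enumerate frequency windows
#'
#' Slides a window of `spec$window_length` consecutive days (stride 1) along
#' every dyad row. A window is emitted iff its full slice contains at most
#' `spec$max_missing` missing cells *and* the final (outcome) day is observed;
#' the tolerated missing day therefore always lies in the history, never at
#' the outcome. `frequency` is the count of contact days among the history
#' days (a raw count — not rescaled when a history day is missing).
#'
#' @param matrix a `contact_matrix`.
#' @param spec a [window_spec()].
#' @return Tibble with columns `dyad`, `start_day`, `frequency`, `n_observed`
#'   (observed history days) and `outcome` (`1` contact / `0` no contact).
#' @export
enumerate_frequency_windows <- function(matrix, spec = window_spec()) {
  stopifnot(inherits(matrix, "contact_matrix"), inherits(spec, "window_spec"))
  x <- unclass(matrix)
  L <- spec$window_length
  nd <- ncol(x)
  empty <- tibble::tibble(dyad = character(0), start_day = integer(0),
                          frequency = integer(0), n_observed = integer(0),
                          outcome = integer(0))
  if (nd < L || nrow(x) == 0) return(empty)

  obs <- !is.na(x)
  con <- obs & x == 1L
  O0 <- cbind(0L, row_cumsum(obs))
  C0 <- cbind(0L, row_cumsum(con))
  starts <- seq_len(nd - L + 1L)
  outcol <- starts + L - 1L

  freq <- C0[, starts + L - 1L, drop = FALSE] - C0[, starts, drop = FALSE]
  nobs_hist <- O0[, starts + L - 1L, drop = FALSE] - O0[, starts, drop = FALSE]
  nmiss_win <- L - (O0[, starts + L, drop = FALSE] - O0[, starts, drop = FALSE])
  valid <- obs[, outcol, drop = FALSE] & nmiss_win <= spec$max_missing
  if (!any(valid)) return(empty)

  idx <- which(valid, arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]
  tibble::tibble(
    dyad = rownames(x)[idx[, 1L]],
    start_day = starts[idx[, 2L]],
    frequency = freq[idx],
    n_observed = nobs_hist[idx],
    outcome = x[cbind(idx[, 1L], outcol[idx[, 2L]])]
  )
}

#' Enumerate recency events
#'
#' For every dyad and observed day `D`, emits an event with recency `t` when
#' the day at lag `t` is an observed contact, every strictly intervening day
#' is no-contact apart from at most `max_missing` missing days, and
#' `t <= max_recency`. Each `(dyad, D)` yields at most one event — the
#' smallest valid `t` — and the anchor must be an observed contact, so a
#' missing day can never anchor an event.
#'
#' @param matrix a `contact_matrix`.
#' @param max_recency largest lag considered (days); default 15.
#' @param max_missing missing days tolerated strictly between the last contact
#'   and the outcome day; default 1.
#' @return Tibble with columns `dyad`, `day`, `recency`, `outcome`.
#' @export
enumerate_recency_events <- function(matrix, max_recency = 15L,
                                     max_missing = 1L) {
  stopifnot(inherits(matrix, "contact_matrix"))
  max_recency <- as.integer(max_recency)
  max_missing <- as.integer(max_missing)
  if (max_recency < 1L) stop("max_recency must be >= 1", call. = FALSE)
  x <- unclass(matrix)
  nd <- ncol(x)
  empty <- tibble::tibble(dyad = character(0), day = integer(0),
                          recency = integer(0), outcome = integer(0))
  if (nd < 2L || nrow(x) == 0) return(empty)

  obs <- !is.na(x)
  con <- obs & x == 1L
  # last contact day strictly before each column (0 = none yet)
  daynum <- con * matrix(seq_len(nd), nrow = nrow(x), ncol = nd, byrow = TRUE)
  lastc <- row_cummax(daynum)
  lcprev <- cbind(0L, lastc[, -nd, drop = FALSE])
  # S0[, k + 1] = missing days among columns 1..k
  S0 <- cbind(0L, row_cumsum(!obs))

  lag <- matrix(seq_len(nd), nrow = nrow(x), ncol = nd, byrow = TRUE) - lcprev
  cand <- obs & lcprev > 0L & lag <= max_recency
  if (!any(cand)) return(empty)

  idx <- which(cand, arr.ind = TRUE)
  r <- idx[, 1L]
  d <- idx[, 2L]
  anchor <- lcprev[idx]
  between <- S0[cbind(r, d)] - S0[cbind(r, anchor + 1L)]
  keep <- between <= max_missing
  if (!any(keep)) return(empty)
  r <- r[keep]; d <- d[keep]; anchor <- anchor[keep]
  ord <- order(r, d)
  tibble::tibble(
    dyad = rownames(x)[r[ord]],
    day = d[ord],
    recency = (d - anchor)[ord],
    outcome = x[cbind(r, d)][ord]
  )
}

#' Pool windows or events into binned need probabilities
#'
#' Pools event counts across all dyads: for each frequency value (or recency
#' lag) the successes are the outcomes that were contact days, the trials are
#' all outcomes, and the proportion carries a Wilson binomial confidence
#' interval. Bins with zero trials are omitted.
#'
#' @param windows output of [enumerate_frequency_windows()].
#' @param events output of [enumerate_recency_events()].
#' @param level confidence level; default 0.95.
#' @return Tibble with columns `bin`, `successes`, `trials`, `proportion`,
#'   `ci_low`, `ci_high`.
#' @export
bin_by_frequency <- function(windows, level = 0.95) {
  pool_outcomes(windows$frequency, windows$outcome, level)
}

#' @rdname bin_by_frequency
#' @export
bin_by_recency <- function(events, level = 0.95) {
  pool_outcomes(events$recency, events$outcome, level)
}

pool_outcomes <- function(bin, outcome, level = 0.95) {
  if (length(bin) == 0) {
    return(tibble::tibble(bin = integer(0), successes = integer(0),
                          trials = integer(0), proportion = double(0),
                          ci_low = double(0), ci_high = double(0)))
  }
  stopifnot(length(bin) == length(outcome), all(outcome %in% c(0L, 1L)))
  trials <- as.integer(rowsum(rep(1L, length(bin)), bin))
  successes <- as.integer(rowsum(as.integer(outcome), bin))
  values <- as.integer(rownames(rowsum(rep(1L, length(bin)), bin)))
  ci <- binomial_interval(successes, trials, level)
  tibble::tibble(bin = values, successes = successes, trials = trials,
                 proportion = successes / trials,
                 ci_low = ci$low, ci_high = ci$high)[order(values), ]
}

#' Wilson score interval for a binomial proportion
#'
#' Two-sided score interval; bounds are clipped to `[0, 1]`. Vectorised over
#' `successes` and `trials`.
#'
#' @param successes number of successes, `0 <= successes <= trials`.
#' @param trials number of trials, at least 1.
#' @param level confidence level in (0, 1); default 0.95.
#' @return List with numeric vectors `low` and `high`.
#' @export
binomial_interval <- function(successes, trials, level = 0.95) {
  if (any(trials < 1)) stop("interval undefined for zero trials", call. = FALSE)
  if (any(successes < 0 | successes > trials)) {
    stop("need 0 <= successes <= trials", call. = FALSE)
  }
  stopifnot(level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  n <- trials
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  list(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

# row-wise cumulative sums / maxima (integer), rows kept as rows
row_cumsum <- function(m) {
  out <- t(apply(m, 1L, cumsum))
  storage.mode(out) <- "integer"
  if (nrow(m) == 1L) out <- matrix(out, nrow = 1L)
  out
}

row_cummax <- function(m) {
  out <- t(apply(m, 1L, cummax))
  storage.mode(out) <- "integer"
  if (nrow(m) == 1L) out <- matrix(out, nrow = 1L)
  out
}
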