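#' Delayed matching-to-sample retention datasets
#'
#' A retention dataset records, for each retention delay, how many trials a
#' subject (or pooled group) answered correctly in a delayed
#' matching-to-sample (DMTS) task: a sample object is shown, hidden for the
#' delay, then presented alongside a distractor.
#'
#' @param delay positive delays (seconds).
#' @param correct counts of correct choices, `0 <= correct <= trials`.
#' @param trials total trial counts, at least 1.
#' @param label study identifier.
#' @return A `retention_dataset` with observations sorted by delay.
#' @export
retention_dataset <- function(delay, correct, trials, label = "dataset") {
  stopifnot(length(delay) == length(correct), length(delay) == length(trials))
  if (any(delay <= 0)) stop("delays must be strictly positive", call. = FALSE)
  if (any(trials < 1)) stop("each delay needs at least one trial",
                            call. = FALSE)
  if (any(correct < 0 | correct > trials)) {
    stop("need 0 <= correct <= trials", call. = FALSE)
  }
  ord <- order(delay)
  structure(list(
    label = as.character(label),
    observations = tibble::tibble(delay = as.numeric(delay)[ord],
                                  correct = as.integer(correct)[ord],
                                  trials = as.integer(trials)[ord])
  ), class = "retention_dataset")
}

#' @export
print.retention_dataset <- function(x, ...) {
  o <- x$observations
  cat(sprintf("<retention dataset '%s'> %d delays, %d trials (%.1f%% correct)\n",
              x$label, nrow(o), sum(o$trials),
              100 * sum(o$correct) / sum(o$trials)))
  invisible(x)
}

#' Pool retention datasets
#'
#' Concatenates observations across studies; identical delays are merged by
#' summing correct and total trial counts, so totals are conserved.
#'
#' @param datasets list of `retention_dataset` objects.
#' @param label label for the pooled dataset.
#' @return A `retention_dataset`.
#' @export
pool_datasets <- function(datasets, label = "pooled") {
  stopifnot(length(datasets) >= 1,
            all(vapply(datasets, inherits, logical(1), "retention_dataset")))
  obs <- dplyr::bind_rows(lapply(datasets, `[[`, "observations"))
  merged <- obs |>
    dplyr::group_by(delay) |>
    dplyr::summarise(correct = sum(correct), trials = sum(trials),
                     .groups = "drop")
  retention_dataset(merged$delay, merged$correct, merged$trials, label = label)
}

#' Convert retention observations to binned proportions
#'
#' Maps delays to bins and trial counts to successes/trials so retention data
#' flow through the same binomial fitting machinery as the contact curves.
#'
#' @param dataset a `retention_dataset`.
#' @param level confidence level for the Wilson interval; default 0.95.
#' @return Tibble with columns `bin`, `successes`, `trials`, `proportion`,
#'   `ci_low`, `ci_high`.
#' @export
retention_bins <- function(dataset, level = 0.95) {
  stopifnot(inherits(dataset, "retention_dataset"))
  o <- dataset$observations
  ci <- binomial_interval(o$correct, o$trials, level)
  tibble::tibble(bin = o$delay, successes = o$correct, trials = o$trials,
                 proportion = o$correct / o$trials,
                 ci_low = ci$low, ci_high = ci$high)
}

#' Fit a forgetting function to retention data
#'
#' Delegates to [fit_curve_mle()] on the trial-weighted binned accuracies.
#' By default the raw curve `P = c * t^-d` (or exponential) is fitted with no
#' guessing floor; for two-alternative DMTS a chance floor of 0.5
#' (`P = 0.5 + (c - 0.5) * t^-d`) can be requested via `floor`.
#'
#' @param dataset a `retention_dataset` with at least 3 distinct delays.
#' @param family `"power"` or `"exponential"`.
#' @param granularity likelihood granularity; default `"bin"`.
#' @param floor chance-level floor; default 0 (raw fit).
#' @param ... passed on to [fit_curve_mle()].
#' @return A `fit_result`.
#' @export
fit_retention <- function(dataset, family = c("power", "exponential"),
                          granularity = c("bin", "event"), floor = 0, ...) {
  fit_curve_mle(retention_bins(dataset), family = family,
                granularity = granularity, floor = floor, ...)
}

#' Read retention data from CSV
#'
#' Expects columns `study`, `delay_s`, `correct`, `trials`; returns one
#' `retention_dataset` per study.
#'
#' @param path file path.
#' @return Named list of `retention_dataset` objects.
#' @export
read_retention_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("study", "delay_s", "correct", "trials")
  if (!all(req %in% names(df))) {
    stop("retention file needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(df, df$study), function(d) {
    retention_dataset(d$delay_s, d$correct, d$trials, label = d$study[1])
  })
}
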