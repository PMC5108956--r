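# Shared fixtures and independent brute-force oracles. The oracles re-derive
# every quantity cell-by-cell with naive loops so the vectorised production
# code can be checked against them.

random_ternary_matrix <- function(n_dyads, n_days, p_contact = 0.35,
                                  p_missing = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vals <- sample(c(1L, 0L, NA_integer_), n_dyads * n_days, replace = TRUE,
                 prob = c(p_contact * (1 - p_missing),
                          (1 - p_contact) * (1 - p_missing), p_missing))
  cells <- matrix(vals, nrow = n_dyads)
  contact_matrix(cells, dyads = sprintf("d%03da_d%03db", 1:n_dyads,
                                        1:n_dyads))
}

series_matrix <- function(...) {
  # build a contact_matrix from per-dyad state strings, e.g. "C N . C"
  # (C = contact, N = no contact, . = missing)
  rows <- list(...)
  parse_row <- function(s) {
    toks <- strsplit(gsub("\\s+", "", s), "")[[1]]
    vapply(toks, function(ch) switch(ch, C = 1L, N = 0L, `.` = NA_integer_,
                                     stop("bad state ", ch)), integer(1))
  }
  cells <- do.call(rbind, lapply(rows, parse_row))
  contact_matrix(cells, dyads = sprintf("s%02da_s%02db", seq_along(rows),
                                        seq_along(rows)))
}

oracle_frequency_windows <- function(m, window_length = 16L,
                                     max_missing = 1L) {
  x <- unclass(m)
  out <- list()
  for (r in seq_len(nrow(x))) {
    for (s in seq_len(max(0L, ncol(x) - window_length + 1L))) {
      slice <- x[r, s:(s + window_length - 1L)]
      hist <- slice[seq_len(window_length - 1L)]
      outc <- slice[window_length]
      if (sum(is.na(slice)) <= max_missing && !is.na(outc)) {
        out[[length(out) + 1L]] <- data.frame(
          dyad = rownames(x)[r], start_day = s,
          frequency = sum(hist == 1L, na.rm = TRUE),
          n_observed = sum(!is.na(hist)), outcome = outc,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(dyad = character(0), start_day = integer(0),
                      frequency = integer(0), n_observed = integer(0),
                      outcome = integer(0)))
  }
  do.call(rbind, out)
}

oracle_recency_events <- function(m, max_recency = 15L, max_missing = 1L) {
  x <- unclass(m)
  out <- list()
  for (r in seq_len(nrow(x))) {
    for (day in 2:ncol(x)) {
      if (is.na(x[r, day])) next
      for (t in seq_len(min(max_recency, day - 1L))) {
        anchor <- x[r, day - t]
        if (is.na(anchor) || anchor != 1L) next
        between <- if (t >= 2) x[r, (day - t + 1L):(day - 1L)] else integer(0)
        if (any(between == 1L, na.rm = TRUE)) next
        if (sum(is.na(between)) > max_missing) next
        out[[length(out) + 1L]] <- data.frame(
          dyad = rownames(x)[r], day = day, recency = t,
          outcome = x[r, day], stringsAsFactors = FALSE)
        break # smallest valid t only
      }
    }
  }
  if (!length(out)) {
    return(data.frame(dyad = character(0), day = integer(0),
                      recency = integer(0), outcome = integer(0)))
  }
  do.call(rbind, out)
}

wilson_reference <- function(successes, trials, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  lo <- (2 * trials * p + z^2 - z * sqrt(z^2 + 4 * trials * p * (1 - p))) /
    (2 * (trials + z^2))
  hi <- (2 * trials * p + z^2 + z * sqrt(z^2 + 4 * trials * p * (1 - p))) /
    (2 * (trials + z^2))
  c(max(0, lo), min(1, hi))
}

expect_same_windows <- function(got, want) {
  key <- function(d) {
    d <- d[order(d$dyad, d$start_day), ]
    paste(d$dyad, d$start_day, d$frequency, d$n_observed, d$outcome)
  }
  expect_identical(key(as.data.frame(got)), key(want))
}

expect_same_events <- function(got, want) {
  key <- function(d) {
    d <- d[order(d$dyad, d$day), ]
    paste(d$dyad, d$day, d$recency, d$outcome)
  }
  expect_identical(key(as.data.frame(got)), key(want))
}
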