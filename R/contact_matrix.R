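#' Ternary dyad-by-day contact matrices
#'
#' A `contact_matrix` is an integer matrix with one row per unordered pair of
#' individuals (a *dyad*) and one column per observation day. Cells take one of
#' three states:
#'
#' * `1L`  — contact: the pair was recorded in the same party at least once
#'   that day;
#' * `0L`  — no contact: the pair was never recorded together, but at least one
#'   member was observed for enough of the day that an encounter would have
#'   been seen;
#' * `NA`  — missing: neither condition holds, or the day falls outside a
#'   member's community-membership interval.
#'
#' Missing is a first-class state, distinct from no-contact in every downstream
#' count. Row names are dyad keys (see [dyad_key()]); column names are 1-based
#' day indices.
#'
#' @param cells integer matrix with values in `{0L, 1L, NA}`.
#' @param dyads character vector of dyad keys, one per row. Defaults to
#'   `rownames(cells)`.
#' @param days integer vector of day indices, one per column. Defaults to
#'   `1:ncol(cells)`.
#' @param individuals optional character roster. When supplied, `dyads` must be
#'   exactly all unordered pairs of the roster (in [all_dyads()] order).
#' @return A `contact_matrix` object.
#' @seealso [build_contact_matrix()], [summarize_matrix()],
#'   [write_contact_matrix()]
#' @export
contact_matrix <- function(cells, dyads = rownames(cells), days = NULL,
                           individuals = NULL) {
  if (!is.matrix(cells)) stop("`cells` must be a matrix", call. = FALSE)
  storage.mode(cells) <- "integer"
  bad <- !is.na(cells) & !(cells %in% c(0L, 1L))
  if (any(bad)) stop("contact matrix cells must be 0, 1 or NA", call. = FALSE)
  if (is.null(dyads)) stop("dyad keys are required (rownames or `dyads`)",
                           call. = FALSE)
  if (length(dyads) != nrow(cells)) stop("one dyad key per row is required",
                                         call. = FALSE)
  if (anyDuplicated(dyads)) stop("dyad keys must be unique", call. = FALSE)
  if (is.null(days)) days <- seq_len(ncol(cells))
  days <- as.integer(days)
  if (length(days) != ncol(cells)) stop("one day index per column is required",
                                        call. = FALSE)
  if (!is.null(individuals)) {
    individuals <- sort(unique(as.character(individuals)))
    expected <- all_dyads(individuals)
    if (!identical(as.character(dyads), expected)) {
      stop("`dyads` must enumerate all unordered pairs of `individuals`",
           call. = FALSE)
    }
  }
  dimnames(cells) <- list(as.character(dyads), as.character(days))
  structure(cells, individuals = individuals, class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  s <- summarize_matrix(x)
  cat(sprintf("<contact_matrix> %d dyads x %d days (%.1f%% missing)\n",
              s$n_dyads, s$n_days, s$pct_missing))
  invisible(x)
}

#' Canonical dyad keys
#'
#' Dyads are unordered pairs; the canonical key sorts the two IDs
#' lexicographically and joins them with an underscore, so `dyad_key("B","A")`
#' and `dyad_key("A","B")` agree. `all_dyads()` enumerates the n(n-1)/2 keys of
#' a roster in deterministic (sorted) order.
#'
#' @param a,b individual IDs (vectorised).
#' @return Character vector of keys.
#' @examples
#' dyad_key("BB", "AL") # "AL_BB"
#' length(all_dyads(paste0("ID", 1:143))) # 10153
#' @export
dyad_key <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  ifelse(a <= b, paste(a, b, sep = "_"), paste(b, a, sep = "_"))
}

#' @rdname dyad_key
#' @param individuals character vector of IDs (deduplicated and sorted).
#' @export
all_dyads <- function(individuals) {
  ids <- sort(unique(as.character(individuals)))
  if (length(ids) < 2) return(character(0))
  idx <- utils::combn(length(ids), 2)
  paste(ids[idx[1, ]], ids[idx[2, ]], sep = "_")
}

# index pairs (i, j), i < j, matching all_dyads() order for a sorted roster
dyad_index_pairs <- function(n) {
  idx <- utils::combn(n, 2)
  list(i = idx[1, ], j = idx[2, ])
}

#' Fraction of a day's scans containing an individual
#'
#' Operationalises "observed for at least X% of the day" as the fraction of
#' that day's scan samples in which the individual was recorded. Scans occur at
#' fixed intervals, so the scan fraction approximates the time fraction.
#'
#' @param scans_for_day data frame with columns `scan_id` and `individual`
#'   (one row per individual per scan), restricted to a single day.
#' @param individual ID to look up.
#' @return Fraction in `[0, 1]`.
#' @export
observation_fraction <- function(scans_for_day, individual) {
  check_scan_frame(scans_for_day)
  if (nrow(scans_for_day) == 0) {
    stop("no scans recorded for this day", call. = FALSE)
  }
  ids <- unique(scans_for_day$scan_id)
  seen <- unique(scans_for_day$scan_id[scans_for_day$individual == individual])
  length(seen) / length(ids)
}

#' Score one dyad on one day
#'
#' Returns `"contact"` if the pair co-occurs in at least one scan that day;
#' otherwise `"no_contact"` if at least one member's [observation_fraction()]
#' reaches `threshold` (an encounter would have been seen); otherwise
#' `"missing"`.
#'
#' @inheritParams observation_fraction
#' @param pair character vector of two distinct IDs (order irrelevant).
#' @param threshold observation-coverage threshold in `(0, 1]`; default 0.70.
#' @param roster optional character roster; when given, both IDs must belong
#'   to it.
#' @return One of `"contact"`, `"no_contact"`, `"missing"`.
#' @export
score_pair_day <- function(scans_for_day, pair, threshold = 0.7,
                           roster = NULL) {
  if (length(pair) != 2 || anyNA(pair) || pair[1] == pair[2]) {
    stop("`pair` must be two distinct IDs", call. = FALSE)
  }
  if (!is.null(roster) && !all(pair %in% roster)) {
    stop("pair contains IDs not on the roster: ",
         paste(setdiff(pair, roster), collapse = ", "), call. = FALSE)
  }
  stopifnot(threshold > 0, threshold <= 1)
  check_scan_frame(scans_for_day)
  if (nrow(scans_for_day) == 0) return("missing")
  by_scan <- split(scans_for_day$individual, scans_for_day$scan_id)
  together <- any(vapply(by_scan, function(x) all(pair %in% x), logical(1)))
  if (together) return("contact")
  f1 <- observation_fraction(scans_for_day, pair[1])
  f2 <- observation_fraction(scans_for_day, pair[2])
  if (f1 >= threshold || f2 >= threshold) "no_contact" else "missing"
}

#' Build a ternary contact matrix from scan samples
#'
#' Converts long-format scan observations plus community-membership intervals
#' into a dyad-by-day `contact_matrix`. Every dyad/day cell is scored by the
#' [score_pair_day()] rule; any day outside either member's
#' `[first_day, last_day]` membership interval is forced to missing, overriding
#' co-occurrence scoring. Days with no scans are missing for all dyads.
#'
#' @param scans data frame with columns `day`, `scan_id`, `individual` (one
#'   row per individual per scan).
#' @param memberships data frame with columns `individual`, `first_day`,
#'   `last_day`, one row per individual; the roster is taken from it.
#' @param threshold observation-coverage threshold, default 0.70.
#' @param n_days total number of days; defaults to `max(memberships$last_day)`.
#' @return A `contact_matrix` over all unordered pairs of the roster.
#' @export
build_contact_matrix <- function(scans, memberships, threshold = 0.7,
                                 n_days = NULL) {
  check_scan_frame(scans, need_day = TRUE)
  req <- c("individual", "first_day", "last_day")
  if (!all(req %in% names(memberships))) {
    stop("`memberships` needs columns individual, first_day, last_day",
         call. = FALSE)
  }
  if (anyDuplicated(memberships$individual)) {
    stop("one membership interval per individual", call. = FALSE)
  }
  if (any(memberships$first_day > memberships$last_day)) {
    stop("membership intervals need first_day <= last_day", call. = FALSE)
  }
  roster <- sort(unique(as.character(memberships$individual)))
  unknown <- setdiff(unique(as.character(scans$individual)), roster)
  if (length(unknown)) {
    stop("scanned IDs missing a membership interval: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(n_days)) n_days <- max(memberships$last_day)
  n_days <- as.integer(n_days)
  bad_day <- scans$day < 1L | scans$day > n_days
  if (any(bad_day)) {
    stop(sprintf("scan days outside 1..%d at rows: %s", n_days,
                 paste(utils::head(which(bad_day), 5), collapse = ", ")),
         call. = FALSE)
  }

  n <- length(roster)
  ij <- dyad_index_pairs(n)
  cells <- matrix(NA_integer_, nrow = length(ij$i), ncol = n_days)

  for (d in sort(unique(scans$day))) {
    sub <- scans[scans$day == d, , drop = FALSE]
    scan_ids <- unique(sub$scan_id)
    inc <- matrix(0L, nrow = n, ncol = length(scan_ids))
    inc[cbind(match(sub$individual, roster), match(sub$scan_id, scan_ids))] <- 1L
    co <- tcrossprod(inc) > 0
    frac <- rowSums(inc) / length(scan_ids)
    together <- co[cbind(ij$i, ij$j)]
    observed <- frac[ij$i] >= threshold | frac[ij$j] >= threshold
    cells[, d] <- ifelse(together, 1L, ifelse(observed, 0L, NA_integer_))
  }

  # membership masking dominates any scan-derived score
  first <- memberships$first_day[match(roster, memberships$individual)]
  last <- memberships$last_day[match(roster, memberships$individual)]
  alive <- outer(first, rep(1L, n_days)) <= outer(rep(1L, n), seq_len(n_days)) &
    outer(last, rep(1L, n_days)) >= outer(rep(1L, n), seq_len(n_days))
  pair_alive <- alive[ij$i, , drop = FALSE] & alive[ij$j, , drop = FALSE]
  cells[!pair_alive] <- NA_integer_

  contact_matrix(cells, dyads = all_dyads(roster), days = seq_len(n_days),
                 individuals = roster)
}

#' Summarise a contact matrix
#'
#' Counts of dyads, days, and cell states; missing and complete (non-missing)
#' cells always sum to the grid size.
#'
#' @param matrix a `contact_matrix`.
#' @return A `matrix_summary` list with `n_individuals` (NA when the roster is
#'   unknown), `n_dyads`, `n_days`, `n_cells`, `n_missing`, `pct_missing`,
#'   `n_complete`, `n_contact`, `n_no_contact`.
#' @export
summarize_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "contact_matrix"))
  x <- unclass(matrix)
  ids <- attr(matrix, "individuals")
  n_cells <- length(x)
  n_missing <- sum(is.na(x))
  structure(list(
    n_individuals = if (is.null(ids)) NA_integer_ else length(ids),
    n_dyads = nrow(x),
    n_days = ncol(x),
    n_cells = n_cells,
    n_missing = n_missing,
    pct_missing = 100 * n_missing / n_cells,
    n_complete = n_cells - n_missing,
    n_contact = sum(x == 1L, na.rm = TRUE),
    n_no_contact = sum(x == 0L, na.rm = TRUE)
  ), class = "matrix_summary")
}

#' @export
print.matrix_summary <- function(x, ...) {
  cat(sprintf(
    paste0("contact matrix summary\n",
           "  dyads: %d  days: %d  cells: %d\n",
           "  contact: %d  no contact: %d\n",
           "  missing: %d (%.1f%%)  complete: %d\n"),
    x$n_dyads, x$n_days, x$n_cells, x$n_contact, x$n_no_contact,
    x$n_missing, x$pct_missing, x$n_complete))
  invisible(x)
}

#' Read and write contact matrices as CSV
#'
#' The on-disk dialect has a first column `dyad` (e.g. `"AL_BB"`) and one
#' column per day index; cells are `1` (contact), `0` (no contact) or `NA`
#' (missing). This matches the deposited supplementary-matrix dialect, so an
#' archived matrix file can be read directly. The round trip
#' write-then-read reproduces the matrix exactly, including missing cells.
#'
#' @param matrix a `contact_matrix`.
#' @param path file path.
#' @return `read_contact_matrix()` returns a `contact_matrix`;
#'   `write_contact_matrix()` returns `path` invisibly.
#' @export
write_contact_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "contact_matrix"))
  df <- data.frame(dyad = rownames(matrix), unclass(matrix),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "dyad") stop("first column must be `dyad`", call. = FALSE)
  cells <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(cells) <- "integer"
  contact_matrix(cells, dyads = df$dyad, days = as.integer(colnames(cells)))
}

#' Read scan samples and membership intervals from CSV
#'
#' Scans are long format with columns `day,scan_id,individual` (one row per
#' individual per scan); memberships have columns
#' `individual,first_day,last_day`.
#'
#' @param path file path.
#' @return A tibble.
#' @export
read_scans <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_scan_frame(df, need_day = TRUE)
  tibble::as_tibble(df)
}

#' @rdname read_scans
#' @export
read_membership <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("individual", "first_day", "last_day")
  if (!all(req %in% names(df))) {
    stop("membership file needs columns individual, first_day, last_day",
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

check_scan_frame <- function(scans, need_day = FALSE) {
  req <- c("scan_id", "individual")
  if (need_day) req <- c("day", req)
  if (!is.data.frame(scans) || !all(req %in% names(scans))) {
    stop("scans need columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  invisible(scans)
}
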