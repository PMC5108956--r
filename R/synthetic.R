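#' Simulate fission-fusion subgroup dynamics
#'
#' A community of individuals travels in fluid subgroups whose size and
#' composition change daily: individuals may switch subgroups, subgroups may
#' split in two, and pairs of subgroups may merge. Two individuals are in
#' contact on a day iff they are in the same subgroup. Within a day, events
#' apply in the fixed order switches, then splits, then merges.
#'
#' Defaults emulate a mid-sized chimpanzee community (around 45 members)
#' tracked for most of a field year.
#'
#' @param n_individuals community size; default 45.
#' @param n_days number of days; default 250.
#' @param n_subgroups_init number of subgroups at the start; default 6.
#' @param p_split per-subgroup daily probability of splitting in two.
#' @param p_merge per-pair-of-subgroups daily probability of merging.
#' @param p_switch per-individual daily probability of moving to a random
#'   subgroup.
#' @param seed RNG seed (sets the session RNG); `NULL` leaves the RNG alone.
#' @return List with `matrix` (a ground-truth `contact_matrix`, no missing
#'   cells) and `assignments` (individuals x days matrix of subgroup labels).
#' @export
simulate_fission_fusion <- function(n_individuals = 45, n_days = 250,
                                    n_subgroups_init = 6, p_split = 0.25,
                                    p_merge = 0.25, p_switch = 0.05,
                                    seed = NULL) {
  stopifnot(n_individuals >= 2, n_days >= 1, n_subgroups_init >= 1,
            all(c(p_split, p_merge, p_switch) >= 0),
            all(c(p_split, p_merge, p_switch) <= 1))
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("ID%03d", seq_len(n_individuals))
  g <- sample(rep_len(seq_len(n_subgroups_init), n_individuals))
  assignments <- matrix(NA_integer_, nrow = n_individuals, ncol = n_days,
                        dimnames = list(ids, NULL))

  for (day in seq_len(n_days)) {
    # switches
    sw <- stats::runif(n_individuals) < p_switch
    if (any(sw)) {
      labs <- unique(g)
      g[sw] <- labs[sample.int(length(labs), sum(sw), replace = TRUE)]
    }
    # splits
    next_lab <- max(g) + 1L
    for (lab in unique(g)) {
      members <- which(g == lab)
      if (length(members) >= 2 && stats::runif(1) < p_split) {
        half <- stats::runif(length(members)) < 0.5
        if (any(half) && !all(half)) {
          g[members[half]] <- next_lab
          next_lab <- next_lab + 1L
        }
      }
    }
    # merges (union-find over current subgroup labels)
    labs <- sort(unique(g))
    if (length(labs) >= 2) {
      parent <- stats::setNames(labs, labs)
      find <- function(x) {
        while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
        x
      }
      pairs <- utils::combn(labs, 2)
      do_merge <- stats::runif(ncol(pairs)) < p_merge
      for (k in which(do_merge)) {
        ra <- find(pairs[1, k])
        rb <- find(pairs[2, k])
        if (ra != rb) parent[[as.character(max(ra, rb))]] <- min(ra, rb)
      }
      g <- vapply(g, find, numeric(1))
    }
    g <- match(g, sort(unique(g))) # dense relabel
    assignments[, day] <- g
  }

  ij <- dyad_index_pairs(n_individuals)
  cells <- (assignments[ij$i, , drop = FALSE] ==
              assignments[ij$j, , drop = FALSE]) * 1L
  list(
    matrix = contact_matrix(cells, dyads = all_dyads(ids),
                            days = seq_len(n_days), individuals = ids),
    assignments = assignments
  )
}

#' Simulate recency-driven contact hazards
#'
#' Independent dyads follow a renewal process conditioned only on the time
#' since their last contact: on a day with recency `t` the pair makes contact
#' with probability `min(1, c * t^-d)` (power hazard) or
#' `min(1, c * exp(-d * t))` (exponential hazard). Recency resets to 1 after
#' each contact; every dyad starts in contact on day 0 and the first
#' `burn_in` days are discarded so the recorded series does not depend on the
#' synchronized start.
#'
#' Default parameters (`c = 0.55`, `d = 0.4`, power) are the package's
#' reference social-contact regime; see the methods vignette.
#'
#' @param n_dyads number of independent dyads; default 500.
#' @param n_days recorded days; default 1000.
#' @param c hazard scale in (0, 1]; default 0.55.
#' @param d hazard decay, `d >= 0`; default 0.4.
#' @param family hazard family, `"power"` or `"exponential"`.
#' @param burn_in discarded initial days; default 50.
#' @param seed RNG seed; `NULL` leaves the RNG alone.
#' @return A `contact_matrix` with no missing cells (rows are synthetic
#'   dyads, not a roster crossing).
#' @export
simulate_hazard_contacts <- function(n_dyads = 500, n_days = 1000, c = 0.55,
                                     d = 0.4,
                                     family = c("power", "exponential"),
                                     burn_in = 50, seed = NULL) {
  family <- match.arg(family)
  stopifnot(n_dyads >= 1, n_days >= 1, c > 0, c <= 1, d >= 0, burn_in >= 0)
  if (!is.null(seed)) set.seed(seed)
  cells <- matrix(NA_integer_, nrow = n_dyads, ncol = n_days)
  t_since <- rep(1, n_dyads) # contact on (virtual) day 0
  for (day in seq_len(burn_in + n_days)) {
    p <- if (family == "power") {
      pmin(1, c * t_since^(-d))
    } else {
      pmin(1, c * exp(-d * t_since))
    }
    hit <- stats::runif(n_dyads) < p
    if (day > burn_in) cells[, day - burn_in] <- as.integer(hit)
    t_since <- ifelse(hit, 1, t_since + 1)
  }
  dyads <- paste0(sprintf("S%04d", seq_len(n_dyads)), "a_",
                  sprintf("S%04d", seq_len(n_dyads)), "b")
  contact_matrix(cells, dyads = dyads, days = seq_len(n_days))
}

#' Mask cells of a contact matrix as missing
#'
#' Masks whole days with probability `day_missing_prob` and remaining cells
#' independently with probability `cell_missing_prob`; observed values are
#' never altered otherwise. The defaults give an expected missing fraction of
#' `0.30 + 0.70 * 0.857 ~ 0.90`, the sparsity typical of party-level follows
#' of a large community.
#'
#' @param matrix a `contact_matrix`.
#' @param cell_missing_prob per-cell masking probability; default 0.857.
#' @param day_missing_prob per-day (whole column) masking probability;
#'   default 0.30.
#' @param seed RNG seed; `NULL` leaves the RNG alone.
#' @return A `contact_matrix` of the same shape.
#' @export
inject_missingness <- function(matrix, cell_missing_prob = 0.857,
                               day_missing_prob = 0.30, seed = NULL) {
  stopifnot(inherits(matrix, "contact_matrix"),
            cell_missing_prob >= 0, cell_missing_prob <= 1,
            day_missing_prob >= 0, day_missing_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  x <- unclass(matrix)
  day_mask <- stats::runif(ncol(x)) < day_missing_prob
  x[, day_mask] <- NA_integer_
  cell_mask <- matrix(stats::runif(length(x)) < cell_missing_prob,
                      nrow = nrow(x))
  x[cell_mask] <- NA_integer_
  contact_matrix(x, dyads = rownames(matrix),
                 days = as.integer(colnames(matrix)),
                 individuals = attr(matrix, "individuals"))
}

#' Simulate scan sampling of a followed subgroup
#'
#' Emulates party-level follows: each day one subgroup is followed (the
#' largest, or a random one), and at each of `scans_per_day` scans every
#' member of the followed subgroup is recorded independently with probability
#' `detection_prob`. The default of 28 scans corresponds to 15-minute scans
#' over a roughly 7-hour follow.
#'
#' @param assignments individuals x days matrix of subgroup labels, as
#'   returned by [simulate_fission_fusion()] (row names are IDs).
#' @param scans_per_day scans per day; default 28.
#' @param follow_largest follow the largest subgroup (ties broken by lowest
#'   label) instead of a uniformly random one; default TRUE.
#' @param detection_prob per-member per-scan detection probability;
#'   default 0.9.
#' @param seed RNG seed; `NULL` leaves the RNG alone.
#' @return Tibble with columns `day`, `scan_id`, `individual`, suitable for
#'   [build_contact_matrix()]. Scans in which nothing was detected leave no
#'   rows.
#' @export
simulate_scan_samples <- function(assignments, scans_per_day = 28,
                                  follow_largest = TRUE, detection_prob = 0.9,
                                  seed = NULL) {
  stopifnot(is.matrix(assignments), !is.null(rownames(assignments)),
            scans_per_day >= 1, detection_prob >= 0, detection_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  ids <- rownames(assignments)
  out <- vector("list", ncol(assignments))
  for (day in seq_len(ncol(assignments))) {
    g <- assignments[, day]
    sizes <- table(g)
    lab <- if (follow_largest) {
      names(sizes)[which.max(sizes)]
    } else {
      sample(names(sizes), 1)
    }
    members <- ids[g == as.integer(lab)]
    seen <- matrix(stats::runif(length(members) * scans_per_day) <
                     detection_prob,
                   nrow = length(members))
    hit <- which(seen, arr.ind = TRUE)
    if (nrow(hit)) {
      out[[day]] <- tibble::tibble(day = day,
                                   scan_id = as.integer(hit[, 2]),
                                   individual = members[hit[, 1]])
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(day = integer(0), scan_id = integer(0),
                          individual = character(0))
  }
  dplyr::arrange(res, day, scan_id, individual)
}

#' Simulate delayed matching-to-sample retention data
#'
#' Accuracy at each retention delay `t` is drawn as
#' `Binomial(trials, min(1, c * t^-d))` — binomial noise around a power
#' forgetting curve. Defaults (8 delays spanning 2-256 s, 200 trials per
#' delay, `c = 0.95`, `d = 0.12`) emulate pooled chimpanzee DMTS experiments.
#'
#' @param delays positive retention delays in seconds.
#' @param trials_per_delay trials per delay; default 200.
#' @param c curve scale; default 0.95.
#' @param d curve decay; default 0.12.
#' @param seed RNG seed; `NULL` leaves the RNG alone.
#' @param label dataset label.
#' @return A `retention_dataset`.
#' @export
simulate_dmts <- function(delays = c(2, 4, 8, 16, 32, 64, 128, 256),
                          trials_per_delay = 200, c = 0.95, d = 0.12,
                          seed = NULL, label = "synthetic_dmts") {
  stopifnot(all(delays > 0), trials_per_delay >= 1, c > 0, c <= 1, d >= 0)
  if (!is.null(seed)) set.seed(seed)
  p <- pmin(1, c * delays^(-d))
  correct <- stats::rbinom(length(delays), trials_per_delay, p)
  retention_dataset(delays, correct, rep(trials_per_delay, length(delays)),
                    label = label)
}
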