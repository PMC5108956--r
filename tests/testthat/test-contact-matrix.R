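make_scans <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(day = r$day, scan_id = r$scan, individual = r$ids,
               stringsAsFactors = FALSE)
  }))
}

test_that("observation_fraction is the per-day scan fraction", {
  scans <- do.call(rbind, lapply(1:10, function(s) {
    data.frame(day = 1, scan_id = s,
               individual = if (s <= 8) c("A", "B") else "B")
  }))
  expect_equal(observation_fraction(scans, "A"), 0.8)
  expect_equal(observation_fraction(scans, "B"), 1.0)
  expect_equal(observation_fraction(scans, "Z"), 0.0)
  expect_error(observation_fraction(scans[0, ], "A"), "no scans")
})

test_that("score_pair_day applies the contact / coverage / missing rules", {
  # co-occur once despite low coverage -> contact
  scans <- make_scans(list(day = 1, scan = 1, ids = c("A", "B")),
                      list(day = 1, scan = 2, ids = "C"),
                      list(day = 1, scan = 3, ids = "C"),
                      list(day = 1, scan = 4, ids = "C"),
                      list(day = 1, scan = 5, ids = "C"),
                      list(day = 1, scan = 6, ids = "C"),
                      list(day = 1, scan = 7, ids = "C"),
                      list(day = 1, scan = 8, ids = "C"),
                      list(day = 1, scan = 9, ids = "C"),
                      list(day = 1, scan = 10, ids = "C"))
  expect_equal(score_pair_day(scans, c("A", "B")), "contact")
  expect_equal(score_pair_day(scans, c("B", "A")), "contact") # symmetry

  # never together; one member well observed -> no contact
  scans2 <- do.call(rbind, lapply(1:10, function(s) {
    data.frame(day = 1, scan_id = s,
               individual = if (s <= 8) "A" else "C")
  }))
  expect_equal(score_pair_day(scans2, c("A", "B")), "no_contact")

  # never together; both under threshold -> missing
  scans3 <- do.call(rbind, lapply(1:10, function(s) {
    data.frame(day = 1, scan_id = s,
               individual = if (s <= 5) "A" else "B")
  }))
  expect_equal(score_pair_day(scans3, c("A", "B")), "missing")
  expect_equal(score_pair_day(scans3, c("A", "B"), threshold = 0.5),
               "no_contact")
  expect_error(score_pair_day(scans3, c("A", "Z"), roster = c("A", "B")),
               "roster")
})

test_that("a 143-individual roster enumerates 10153 dyads", {
  expect_equal(length(all_dyads(sprintf("C%03d", 1:143))), 10153)
  expect_equal(dyad_key("BB", "AL"), "AL_BB")
})

test_that("days without scans are missing for every dyad", {
  scans <- make_scans(list(day = 1, scan = 1, ids = c("A", "B", "C")))
  mem <- data.frame(individual = c("A", "B", "C"), first_day = 1,
                    last_day = 2)
  m <- build_contact_matrix(scans, mem)
  expect_equal(dim(m), c(3L, 2L))
  expect_true(all(unclass(m)[, 1] == 1L))
  expect_true(all(is.na(unclass(m)[, 2])))
})

test_that("membership masking dominates co-occurrence scoring", {
  scans <- make_scans(list(day = 1, scan = 1, ids = c("A", "B")),
                      list(day = 2, scan = 1, ids = c("A", "B")))
  mem <- data.frame(individual = c("A", "B"), first_day = c(1, 2),
                    last_day = c(2, 2))
  m <- build_contact_matrix(scans, mem)
  expect_true(is.na(unclass(m)["A_B", 1])) # B not yet in the community
  expect_equal(unname(unclass(m)["A_B", 2]), 1L)
})

test_that("matrix construction matches naive per-cell scoring", {
  set.seed(42)
  roster <- c("AA", "BB", "CC", "DD", "EE")
  mem <- data.frame(individual = roster,
                    first_day = sample(1:3, 5, replace = TRUE),
                    last_day = sample(25:30, 5, replace = TRUE))
  scans <- do.call(rbind, lapply(1:30, function(d) {
    n_scans <- sample(0:6, 1)
    if (n_scans == 0) return(NULL)
    do.call(rbind, lapply(seq_len(n_scans), function(s) {
      present <- roster[runif(5) < 0.4]
      if (!length(present)) return(NULL)
      data.frame(day = d, scan_id = s, individual = present,
                 stringsAsFactors = FALSE)
    }))
  }))
  m <- build_contact_matrix(scans, mem, threshold = 0.7, n_days = 30)

  state_int <- c(contact = 1L, no_contact = 0L, missing = NA_integer_)
  pairs <- utils::combn(roster, 2)
  for (k in seq_len(ncol(pairs))) {
    p <- pairs[, k]
    for (d in 1:30) {
      day_scans <- scans[scans$day == d, , drop = FALSE]
      expected <- if (nrow(day_scans) == 0) {
        NA_integer_
      } else {
        unname(state_int[score_pair_day(day_scans, p, threshold = 0.7)])
      }
      alive <- all(mem$first_day[match(p, mem$individual)] <= d &
                     mem$last_day[match(p, mem$individual)] >= d)
      if (!alive) expected <- NA_integer_
      expect_equal(unname(unclass(m)[dyad_key(p[1], p[2]), d]), expected)
    }
  }
})

test_that("raising the threshold never turns missing into no-contact", {
  set.seed(7)
  roster <- c("AA", "BB", "CC", "DD")
  mem <- data.frame(individual = roster, first_day = 1, last_day = 20)
  scans <- do.call(rbind, lapply(1:20, function(d) {
    do.call(rbind, lapply(1:5, function(s) {
      present <- roster[runif(4) < 0.5]
      if (!length(present)) return(NULL)
      data.frame(day = d, scan_id = s, individual = present)
    }))
  }))
  n_missing <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th) {
    sum(is.na(unclass(build_contact_matrix(scans, mem, threshold = th))))
  }, numeric(1))
  expect_true(all(diff(n_missing) >= 0))
})

test_that("summaries agree with a brute-force cell tally", {
  m <- random_ternary_matrix(8, 40, seed = 11)
  s <- summarize_matrix(m)
  x <- unclass(m)
  expect_equal(s$n_missing, sum(is.na(x)))
  expect_equal(s$n_complete + s$n_missing, s$n_dyads * s$n_days)
  expect_equal(s$n_contact, sum(x == 1, na.rm = TRUE))
  expect_equal(s$pct_missing, 100 * sum(is.na(x)) / length(x))

  all_na <- contact_matrix(matrix(NA_integer_, 3, 4),
                           dyads = c("a_b", "a_c", "b_c"))
  s2 <- summarize_matrix(all_na)
  expect_equal(s2$n_complete, 0)
  expect_equal(s2$pct_missing, 100)
})

test_that("matrix CSV round trip is exact, including missing cells", {
  m <- random_ternary_matrix(6, 25, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_contact_matrix(m, path)
  m2 <- read_contact_matrix(path)
  expect_identical(unclass(m)[, ], unclass(m2)[, ])
  expect_identical(rownames(m), rownames(m2))
})

test_that("malformed inputs are rejected with location information", {
  mem <- data.frame(individual = c("A", "B"), first_day = 1, last_day = 5)
  bad <- data.frame(day = 9, scan_id = 1, individual = "A")
  expect_error(build_contact_matrix(bad, mem), "outside 1..5", fixed = TRUE)
  orphan <- data.frame(day = 1, scan_id = 1, individual = "Z")
  expect_error(build_contact_matrix(orphan, mem), "membership")
  expect_error(contact_matrix(matrix(2L, 2, 2), dyads = c("a_b", "a_c")),
               "0, 1 or NA")
})
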