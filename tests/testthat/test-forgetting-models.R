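toy_bins <- function(curve, t = 1:10, trials = 1000L) {
  p <- predict(curve, t)
  tibble::tibble(bin = t, successes = as.integer(round(trials * p)),
                 trials = trials)
}

test_that("curve predictions hit their analytic anchors", {
  expect_equal(predict(power_curve(0.6, 1.3), 1), 0.6)
  expect_equal(predict(power_curve(0.8, 0.5), 4), 0.4)
  expect_equal(predict(exponential_curve(0.6, 0), c(1, 5, 50)),
               rep(0.6, 3))
  expect_equal(predict(exponential_curve(0.5, 0.1), 3), 0.5 * exp(-0.3))
  expect_error(predict(power_curve(0.5, 0.5), 0), "t > 0")
  expect_error(power_curve(1.2, 0.5), "c must be")
  expect_error(power_curve(0.5, -1), "d must be")
})

test_that("a chance floor shifts the asymptote", {
  crv <- power_curve(0.95, 0.3, floor = 0.5)
  expect_equal(predict(crv, 1), 0.95)
  expect_equal(predict(crv, 1e12), 0.5, tolerance = 1e-3)
})

test_that("fit_linear reproduces an exact line and the OLS closed form", {
  exact <- tibble::tibble(bin = 0:2, proportion = c(0.10, 0.15, 0.20))
  f <- suppressWarnings(fit_linear(exact)) # lm warns on a perfect fit
  expect_equal(f$intercept, 0.10, tolerance = 1e-12)
  expect_equal(f$slope, 0.05, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  set.seed(5)
  noisy <- tibble::tibble(bin = 0:15, proportion = runif(16))
  g <- fit_linear(noisy)
  X <- cbind(1, noisy$bin)
  beta <- solve(t(X) %*% X, t(X) %*% noisy$proportion) # normal equations
  expect_equal(c(g$intercept, g$slope), as.numeric(beta), tolerance = 1e-10)
  resid <- noisy$proportion - X %*% beta
  expect_equal(g$r_squared,
               1 - sum(resid^2) / sum((noisy$proportion -
                                         mean(noisy$proportion))^2),
               tolerance = 1e-10)
  expect_error(fit_linear(exact[1:2, ]), "3 bins")
})

test_that("binomial negative log-likelihood matches direct pmf arithmetic", {
  bins <- tibble::tibble(bin = 2, successes = 5L, trials = 10L)
  crv <- exponential_curve(0.5, 0) # predicts exactly 0.5
  expect_equal(binomial_negloglik(crv, bins, "event"),
               -log(choose(10, 5) * 0.5^10), tolerance = 1e-12)

  # saturated case: predictions equal to each bin proportion minimise the
  # bin-granularity cross-entropy
  b2 <- tibble::tibble(bin = c(1, 4, 16), successes = c(8L, 4L, 2L),
                       trials = 10L)
  p_hat <- b2$successes / b2$trials
  entropy <- -sum(p_hat * log(p_hat) + (1 - p_hat) * log(1 - p_hat))
  for (cc in c(0.3, 0.6, 0.9)) {
    expect_gte(binomial_negloglik(power_curve(cc, 0.4), b2, "bin"), entropy)
  }
  # p_hat here lies exactly on power(c = 0.8, d = 0.5)
  expect_equal(p_hat, predict(power_curve(0.8, 0.5), b2$bin))
  expect_equal(binomial_negloglik(power_curve(0.8, 0.5), b2, "bin"), entropy,
               tolerance = 1e-12)
})

test_that("event likelihood is invariant to bin order and bin splitting", {
  crv <- power_curve(0.7, 0.3)
  bins <- tibble::tibble(bin = c(1, 2, 3), successes = c(60L, 40L, 30L),
                         trials = 100L)
  shuffled <- bins[c(3, 1, 2), ]
  expect_equal(binomial_negloglik(crv, bins, "event"),
               binomial_negloglik(crv, shuffled, "event"))
  split_b <- tibble::tibble(bin = c(1, 1, 2, 3),
                            successes = c(25L, 35L, 40L, 30L),
                            trials = c(40L, 60L, 100L, 100L))
  # splitting a bin changes only the data-dependent choose() terms, so the
  # *difference* between two curves is preserved
  crv2 <- exponential_curve(0.7, 0.25)
  expect_equal(
    binomial_negloglik(crv, bins, "event") -
      binomial_negloglik(crv2, bins, "event"),
    binomial_negloglik(crv, split_b, "event") -
      binomial_negloglik(crv2, split_b, "event"),
    tolerance = 1e-9)
})

test_that("AICc follows its formula and rejects tiny samples", {
  expect_equal(aicc(40, 2, 15), 85)
  expect_equal(aicc(40, 2, 1e9), 84, tolerance = 1e-6)
  expect_equal(aicc(17.5, 0, 10), 35)
  expect_error(aicc(40, 2, 3), "undefined")
})

test_that("MLE recovers generating parameters from exact bins", {
  for (fam in c("power", "exponential")) {
    make <- if (fam == "power") power_curve else exponential_curve
    truth <- make(0.8, 0.4)
    bins <- toy_bins(truth, t = 1:12, trials = 100000L)
    fit <- fit_curve_mle(bins, fam, granularity = "event")
    expect_equal(fit$curve$c, 0.8, tolerance = 0.01)
    expect_equal(fit$curve$d, 0.4, tolerance = 0.01)
    expect_equal(fit$n_points, sum(bins$trials))
    # permuting bins changes nothing
    fit2 <- fit_curve_mle(bins[sample(nrow(bins)), ], fam,
                          granularity = "event")
    expect_equal(fit$curve$c, fit2$curve$c, tolerance = 1e-8)
    expect_equal(fit$negloglik, fit2$negloglik, tolerance = 1e-8)
  }
})

test_that("flat data drive the decay to zero", {
  bins <- tibble::tibble(bin = 1:8, successes = 300L, trials = 1000L)
  fit <- fit_curve_mle(bins, "power", granularity = "event")
  expect_lt(fit$curve$d, 0.01)
  expect_equal(fit$curve$c, 0.3, tolerance = 0.01)
  expect_error(fit_curve_mle(bins[1:2, ], "power"), "3 distinct")
})

test_that("model comparison computes weights and evidence ratios", {
  truth <- power_curve(0.6, 0.5)
  bins <- toy_bins(truth, t = 1:12, trials = 50000L)
  fp <- fit_curve_mle(bins, "power", granularity = "event")
  fe <- fit_curve_mle(bins, "exponential", granularity = "event")
  cmp <- compare_fits(fp, fe)
  expect_equal(cmp$winner, "power")
  expect_equal(cmp$evidence_ratio, exp(cmp$delta_aicc / 2))
  expect_equal(sum(cmp$akaike_weights), 1, tolerance = 1e-12)
  expect_equal(unname(cmp$akaike_weights["power"] /
                        cmp$akaike_weights["exponential"]),
               cmp$evidence_ratio, tolerance = 1e-9)
  # delta of 8.4 corresponds to an evidence ratio of exp(4.2)
  expect_equal(exp(8.4 / 2), 66.68633, tolerance = 1e-6)

  other <- toy_bins(truth, t = 1:10, trials = 777L)
  fo <- fit_curve_mle(other, "power", granularity = "event")
  expect_error(compare_fits(fp, fo), "different data")
})

test_that("equal-AICc fits tie with weight one half each", {
  bins <- toy_bins(power_curve(0.5, 0.3), t = 1:6, trials = 1000L)
  f <- fit_curve_mle(bins, "power", granularity = "event")
  cmp <- compare_fits(f, f)
  expect_equal(cmp$delta_aicc, 0)
  expect_equal(cmp$evidence_ratio, 1)
  expect_equal(unname(cmp$akaike_weights), c(0.5, 0.5))
})
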