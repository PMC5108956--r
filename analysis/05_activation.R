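#!/usr/bin/env Rscript
# Stage 5: translate the fitted environmental decay into ACT-R base-level
# activation. For encounter histories of varying frequency and recency,
# compute A = ln(sum_k t_k^-d) and the need probability it implies.

suppressPackageStartupMessages(library(contactmem))
fits_path <- "results/forgetting_fits.json"
if (!file.exists(fits_path)) {
  stop("run analysis/03_fit_forgetting.R first (missing ", fits_path, ")")
}
d_hat <- jsonlite::read_json(fits_path)$power$d
cat(sprintf("Using the environmentally estimated decay d = %.3f.\n\n", d_hat))

histories <- list(
  seen_yesterday = 1,
  seen_last_week = 7,
  seen_two_weeks_ago = 14,
  frequent_recent = c(1, 2, 3, 5),
  frequent_old = c(10, 12, 15, 20),
  single_old = 30
)
tab <- do.call(rbind, lapply(names(histories), function(nm) {
  lags <- histories[[nm]]
  A <- activation(lags, d_hat)
  data.frame(history = nm, n_encounters = length(lags),
             most_recent_lag = min(lags), activation = A,
             need_probability = need_probability_from_activation(A))
}))
print(tab, row.names = FALSE, digits = 3)

cat("\nFrequency strengthens activation; recency of the lags decays it —\n")
cat("the memory-side mirror of the contact statistics fitted in stage 3.\n")
utils::write.csv(tab, "results/activation_table.csv", row.names = FALSE)
cat("Wrote results/activation_table.csv\n")
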