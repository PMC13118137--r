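#!/usr/bin/env Rscript

# Reproducible coarse grid search used to pin the shipped generator
# defaults in default_group_params(). Stage 1 tunes the clinical channels
# (HbA1c intercept/noise, 2-h OGTT noise) against the published cohort
# operating point; stage 2 reports the trace-level time-in-range means for
# the selected configuration. Rerun after any structural change to the
# generator; copy the selected values into R/generator.R.
#
# Targets (printed cohort statistics):
#   prevalence of prediabetes            0.466
#   P(HbA1c >= 5.7 | prediabetes)        0.603
#   P(prediabetes | HbA1c < 5.7)         0.257
#   mean time in 3.0-7.8 mmol/L          0.963
#   mean time below 3.9 mmol/L           0.029

suppressPackageStartupMessages(library(cgmscreen))

n_clin <- 20000
n_traces <- 300
seed <- 42

clinical_loss <- function(gp) {
  cfg <- generator_config(n_participants = n_clin, seed = seed,
                          group_params = gp)
  cl <- generate_cohort(cfg, with_traces = FALSE)$clinical
  pd <- cl$status == "prediabetes"
  stats <- c(prev = mean(pd),
             sens = mean(cl$hba1c[pd] >= 5.7),
             hidden = mean(cl$status[cl$hba1c < 5.7] == "prediabetes"))
  targets <- c(prev = 0.466, sens = 0.603, hidden = 0.257)
  list(stats = stats, loss = sum(abs(stats - targets)))
}

cat("== stage 1: clinical channel grid ==\n")
best <- NULL
for (h0 in seq(2.00, 2.08, by = 0.02)) {
  for (g2h_sd in c(0.95, 1.05, 1.15)) {
    gp <- default_group_params()
    gp$hba1c_intercept <- h0
    gp$g2h_sd <- g2h_sd
    r <- clinical_loss(gp)
    cat(sprintf("h0=%.2f g2h_sd=%.2f  prev=%.3f sens=%.3f hidden=%.3f  loss=%.4f\n",
                h0, g2h_sd, r$stats["prev"], r$stats["sens"],
                r$stats["hidden"], r$loss))
    if (is.null(best) || r$loss < best$loss) {
      best <- list(h0 = h0, g2h_sd = g2h_sd, loss = r$loss)
    }
  }
}
cat(sprintf("selected: hba1c_intercept=%.2f g2h_sd=%.2f\n\n",
            best$h0, best$g2h_sd))

cat("== stage 2: trace time-in-range at the selected configuration ==\n")
gp <- default_group_params()
gp$hba1c_intercept <- best$h0
gp$g2h_sd <- best$g2h_sd
cfg <- generator_config(n_participants = n_traces, seed = seed,
                        group_params = gp)
cl <- generate_cohort(cfg, with_traces = FALSE)$clinical
tir <- t(vapply(seq_len(n_traces), function(i) {
  tr <- merge_blocks(simulate_trace(cl[i, ], cfg, seed = 90000 + i))
  w <- interval_weights(tr)
  c(normal = unname(time_in_ranges(tr, w)[["frac_normal"]]),
    below39 = unname(time_in_ranges(tr, w,
                                    bands = glucose_band(0, 3.9,
                                                         lo_closed = FALSE),
                                    partial = TRUE)))
}, c(normal = 0, below39 = 0)))
cat(sprintf("mean time in 3.0-7.8: %.3f (target 0.963)\n",
            mean(tir[, "normal"])))
cat(sprintf("mean time below 3.9:  %.3f (target 0.029)\n",
            mean(tir[, "below39"])))
cat("adjust night_base_mean / day_amp / exc parameters if these drift.\n")
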