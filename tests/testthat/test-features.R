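test_that("summary statistics match closed forms", {
  # constant trace: degenerate spread
  ss <- summary_statistics(make_trace(rep(5.5, 40)))
  expect_equal(ss$mean_glucose, 5.5)
  expect_equal(ss$sd_glucose, 0)
  expect_equal(ss$cv_glucose, 0)
  expect_equal(ss$max_glucose, 5.5)
  expect_equal(ss$min_glucose, 5.5)

  # alternating 4/8 at uniform spacing: two-point distribution
  ss2 <- summary_statistics(make_trace(rep(c(4, 8), 50)))
  expect_equal(ss2$mean_glucose, 6)
  expect_equal(ss2$sd_glucose, 2)
  expect_equal(ss2$cv_glucose, 1 / 3)

  # hand-weighted average: 4 at 1 h, 8 at 3 h -> mean 7
  tr3 <- make_trace(c(4, 8))
  ss3 <- summary_statistics(tr3, weights = c(1, 3))
  expect_equal(ss3$mean_glucose, 7)

  # unweighted toggle ignores durations
  ss4 <- summary_statistics(tr3, weights = c(1, 3), weighted = FALSE)
  expect_equal(ss4$mean_glucose, 6)

  # brute-force loop oracle on an irregular fixture
  set.seed(21)
  g <- round(runif(150, 3, 11), 1)
  w <- runif(150, 0.1, 1)
  ref <- brute_weighted_stats(g, w)
  ss5 <- summary_statistics(make_trace(g), weights = w)
  expect_equal(ss5$mean_glucose, unname(ref["mean"]))
  expect_equal(ss5$sd_glucose, unname(ref["sd"]))
})

test_that("time-in-range assigns duration weight to the right band", {
  expect_equal(unname(time_in_ranges(make_trace(rep(5.5, 20)))), c(0, 1, 0))

  # half the time at 2.5, half at 9.0
  tir <- time_in_ranges(make_trace(c(rep(2.5, 10), rep(9, 10))))
  expect_equal(unname(tir), c(0.5, 0, 0.5))

  # boundary: exactly 7.8 and exactly 3.0 count as normal
  tir_b <- time_in_ranges(make_trace(c(7.8, 3.0, 7.9)))
  expect_equal(unname(tir_b["frac_normal"]), 2 / 3)
  expect_equal(unname(tir_b["frac_above"]), 1 / 3)

  # brute-force accumulation oracle on a weighted 96-reading fixture
  set.seed(8)
  g <- round(runif(96, 2.2, 12), 1)
  w <- runif(96, 0.1, 0.5)
  expect_equal(unname(time_in_ranges(make_trace(g), weights = w)),
               unname(brute_tir(g, w)))

  # single partial band: time below 3.9
  b39 <- time_in_ranges(make_trace(c(3.5, 4.1, 5, 6)),
                        bands = glucose_band(0, 3.9, lo_closed = FALSE),
                        partial = TRUE)
  expect_equal(unname(b39), 0.25)

  # uncovered value errors with the glucose level named
  expect_error(
    time_in_ranges(make_trace(c(5, 12)),
                   bands = glucose_band(0, 10, lo_closed = FALSE)),
    "12")
  expect_error(time_in_ranges(make_trace(numeric(0))), "empty")
})

test_that("band fractions sum to one on generated traces", {
  cfg <- generator_config(n_participants = 6, seed = 31)
  co <- generate_cohort(cfg, with_traces = FALSE)
  for (i in seq_len(6)) {
    tr <- merge_blocks(simulate_trace(co$clinical[i, ], cfg, seed = 400 + i))
    expect_equal(sum(time_in_ranges(tr)), 1, tolerance = 1e-9)
  }
})

test_that("excursion detection finds hand-constructed geometry", {
  # constant and monotone traces: no excursions
  expect_equal(nrow(detect_excursions(make_trace(rep(5, 30)))), 0)
  expect_equal(nrow(detect_excursions(make_trace(seq(4, 9, by = 0.25)))), 0)

  # triangle 5 -> 9 -> 5 over 4 h: one rise and one fall, amplitude 4
  tri <- make_trace(c(seq(5, 9, length.out = 9), seq(8.5, 5, length.out = 8)))
  ex <- detect_excursions(tri)
  expect_equal(nrow(ex), 2)
  expect_equal(ex$direction, c("rise", "fall"))
  expect_equal(ex$amplitude, c(4, 4))
  expect_equal(ex$duration, c(2, 2))

  # square wave 4/8 alternating every 2 h for 2 days: all amplitudes 4
  sq <- make_trace(rep(rep(c(4, 8), each = 8), 12))
  exs <- detect_excursions(sq)
  expect_gt(nrow(exs), 20)
  expect_true(all(exs$amplitude == 4))
  expect_setequal(unique(exs$direction), c("rise", "fall"))
})

test_that("excursions converge to analytic amplitudes on a dense sinusoid", {
  # sinusoid amplitude A: peak-to-nadir swings of 2A
  A <- 1.5
  # start at a peak and end at a nadir so every segment is a full swing
  hrs <- seq(6, 90, by = 0.25)
  g <- 6 + A * sin(2 * pi * hrs / 24)
  ex <- detect_excursions(make_trace(g))
  expect_true(all(abs(ex$amplitude[-c(1, nrow(ex))] - 2 * A) < 0.05))
  # MAGE ~ 2A since sd = A/sqrt(2) < 2A
  expect_equal(compute_mage(make_trace(g)), 2 * A, tolerance = 0.03)
})

test_that("excursion statistics average per-event quantities", {
  es0 <- excursion_statistics(detect_excursions(make_trace(rep(5, 10))))
  expect_equal(unlist(es0), c(avg_rise = 0, avg_fall = 0,
                              avg_rise_rate = 0, avg_fall_rate = 0))

  mk <- function(amp, dur, dir) tibble::tibble(
    start_time = t0, turn_time = t0, end_time = t0,
    nadir = 5, peak = 5 + amp, direction = dir,
    amplitude = amp, duration = dur)

  es1 <- excursion_statistics(mk(4, 2, "rise"))
  expect_equal(es1$avg_rise, 4)
  expect_equal(es1$avg_rise_rate, 2)
  expect_equal(es1$avg_fall, 0)

  # mean of per-excursion rates, not ratio of means: {4/2h, 2/1h} -> rate 2
  es2 <- excursion_statistics(rbind(mk(4, 2, "rise"), mk(2, 1, "rise")))
  expect_equal(es2$avg_rise, 3)
  expect_equal(es2$avg_rise_rate, 2)
})

test_that("MAGE keeps only excursions exceeding one trace SD", {
  expect_equal(compute_mage(make_trace(rep(6, 50))), 0)
  # square wave: sd 2, all amplitudes 4 -> MAGE 4
  sq <- make_trace(rep(rep(c(4, 8), each = 8), 12))
  expect_equal(compute_mage(sq), 4)
  # MAGE bounded by the raw range on arbitrary traces
  set.seed(5)
  for (i in 1:5) {
    g <- round(runif(120, 3, 10), 1)
    tr <- make_trace(g)
    expect_lte(compute_mage(tr), max(g) - min(g))
  }
})

test_that("extract_features equals the brute-force reference on fixtures", {
  set.seed(77)
  fixtures <- list(
    rep(5.5, 200),
    rep(c(4, 8), 100),
    6 + 1.2 * sin(2 * pi * seq(0, 49.75, by = 0.25) / 24),
    round(runif(200, 3, 11), 1),
    round(5 + cumsum(rnorm(200, 0, 0.3)), 1)
  )
  for (g in fixtures) {
    g <- pmin(pmax(g, 2.3), 20)
    tr <- make_trace(g)
    f <- extract_features(tr, min_covered_hours = 10)
    w <- interval_weights(tr)
    ref <- brute_weighted_stats(g, w)
    expect_equal(f$mean_glucose, unname(ref["mean"]))
    expect_equal(f$sd_glucose, unname(ref["sd"]))
    tir <- brute_tir(g, w)
    expect_equal(f$frac_normal, unname(tir["normal"]))
    expect_equal(f$frac_above, unname(tir["above"]))
    expect_equal(f$frac_below, unname(tir["below"]))
    expect_equal(f$mage,
                 brute_mage(g, tr$readings$timestamp, unname(ref["sd"])))
    bex <- brute_excursions(g, tr$readings$timestamp)
    if (is.null(bex)) {
      expect_equal(f$avg_rise, 0)
      expect_equal(f$avg_fall, 0)
    } else {
      rises <- bex[bex$direction == "rise", ]
      if (nrow(rises) > 0) {
        expect_equal(f$avg_rise, mean(rises$amplitude))
        expect_equal(f$avg_rise_rate, mean(rises$amplitude / rises$duration))
      }
      falls <- bex[bex$direction == "fall", ]
      if (nrow(falls) > 0) {
        expect_equal(f$avg_fall, mean(falls$amplitude))
        expect_equal(f$avg_fall_rate, mean(falls$amplitude / falls$duration))
      }
    }
  }
})

test_that("feature extraction is order-stable and guards quality", {
  set.seed(13)
  g <- round(runif(300, 3.5, 9), 1)
  tr <- make_trace(g)
  perm <- sample(nrow(tr$readings))
  tr_perm <- glucose_trace("T1", tr$readings[perm, ], warmup_trimmed = TRUE)
  expect_equal(extract_features(tr_perm, min_covered_hours = 10),
               extract_features(tr, min_covered_hours = 10))

  # unusable trace raises a quality error carrying the report
  short <- make_trace(rep(5, 10))
  err <- tryCatch(extract_features(short), cgm_quality_error = function(e) e)
  expect_s3_class(err, "cgm_quality_error")
  expect_false(err$quality$usable)
})
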