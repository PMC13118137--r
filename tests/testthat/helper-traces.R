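# Fixture builders and independent brute-force oracles. The oracles use
# naive loops and no shared code paths with the package internals, so they
# can serve as references for equivalence tests.

t0 <- as.POSIXct("2023-03-06 00:00:00", tz = "UTC")

make_trace <- function(glucose, interval_min = 15, start = t0,
                       pid = "T1", block_id = 1L, trimmed = TRUE) {
  n <- length(glucose)
  glucose_trace(pid, tibble::tibble(
    timestamp = start + 60 * interval_min * (seq_len(n) - 1),
    glucose = glucose,
    block_id = rep_len(block_id, n)
  ), warmup_trimmed = trimmed)
}

# weighted mean / population SD by explicit loop
brute_weighted_stats <- function(g, w) {
  sw <- 0; swx <- 0
  for (i in seq_along(g)) { sw <- sw + w[i]; swx <- swx + w[i] * g[i] }
  m <- swx / sw
  sv <- 0
  for (i in seq_along(g)) sv <- sv + w[i] * (g[i] - m)^2
  c(mean = m, sd = sqrt(sv / sw))
}

# per-reading accumulation into [lo,hi) bands with a top-closed normal band
brute_tir <- function(g, w) {
  acc <- c(below = 0, normal = 0, above = 0)
  for (i in seq_along(g)) {
    if (g[i] < 3) acc["below"] <- acc["below"] + w[i]
    else if (g[i] <= 7.8) acc["normal"] <- acc["normal"] + w[i]
    else acc["above"] <- acc["above"] + w[i]
  }
  acc / sum(w)
}

# naive turning-point walk: 3-point moving average, then scan for direction
# changes, then repeatedly erase the smallest sub-threshold swing
brute_excursions <- function(g, ts, threshold = 0.5) {
  n <- length(g)
  if (n < 3) return(NULL)
  sm <- g
  for (i in 2:(n - 1)) sm[i] <- (g[i - 1] + g[i] + g[i + 1]) / 3
  # a turning point sits at the end of the previous monotone run (plateaus
  # on the smoothed series belong to the run that produced them)
  idx <- integer(0)
  last_dir <- 0; last_end <- 1L
  for (i in 2:n) {
    d <- sign(sm[i] - sm[i - 1])
    if (d == 0) next
    if (last_dir != 0 && d != last_dir) idx <- c(idx, last_end)
    last_dir <- d
    last_end <- i
  }
  if (length(idx) == 0) return(NULL)  # monotone: no excursions
  idx <- unique(c(1L, idx, n))
  repeat {
    if (length(idx) < 2) break
    amps <- abs(diff(g[idx]))
    k <- which.min(amps)
    if (amps[k] >= threshold) break
    if (k == 1) idx <- idx[-1]
    else if (k == length(amps)) idx <- idx[-length(idx)]
    else idx <- idx[-c(k, k + 1)]
  }
  if (length(idx) < 2) return(NULL)
  out <- NULL
  for (j in seq_len(length(idx) - 1)) {
    a <- idx[j]; b <- idx[j + 1]
    out <- rbind(out, data.frame(
      amplitude = abs(g[b] - g[a]),
      duration = as.numeric(ts[b] - ts[a], units = "hours"),
      direction = if (g[b] > g[a]) "rise" else "fall"
    ))
  }
  out
}

brute_mage <- function(g, ts, sd_trace, threshold = 0.5) {
  ex <- brute_excursions(g, ts, threshold)
  if (is.null(ex)) return(0)
  qual <- ex$amplitude[ex$amplitude > sd_trace]
  if (length(qual) == 0) return(0)
  mean(qual)
}

# pairwise-concordance ROC AUC (ties count 1/2)
brute_roc_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# PRC AUC by exhaustive threshold enumeration (step interpolation)
brute_prc_auc <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels)
  prev_recall <- 0; area <- 0
  for (c in ths) {
    sel <- scores >= c
    tp <- sum(labels & sel)
    precision <- tp / sum(sel)
    recall <- tp / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# small labeled synthetic cohort reused across modeling/evaluation tests
tiny_cohort <- function(n = 120, seed = 99) {
  cfg <- generator_config(n_participants = n, seed = seed)
  generate_cohort(cfg, with_traces = FALSE)$clinical
}
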