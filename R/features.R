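#' @importFrom stats median sd setNames
NULL

# Canonical feature column order; downstream model matrices rely on it.
CGM_FEATURE_NAMES <- c(
  "mean_glucose", "max_glucose", "min_glucose", "sd_glucose", "cv_glucose",
  "mage", "frac_normal", "frac_above", "frac_below",
  "avg_rise", "avg_fall", "avg_rise_rate", "avg_fall_rate"
)

#' Names of the CGM summary features
#'
#' @return Character vector of the 13 feature column names, in the
#'   deterministic order used by feature tables and model matrices.
#' @export
cgm_feature_names <- function() CGM_FEATURE_NAMES

#' Duration-weighted centrality and spread statistics
#'
#' Weighted mean and population-form weighted SD over the readings (weights
#' are durations, not sample counts, so no Bessel correction applies);
#' max/min are raw extrema; cv = sd / mean. With `weighted = FALSE` all
#' readings count equally.
#'
#' @param trace A usable [glucose_trace()].
#' @param weights Per-reading durations from [interval_weights()];
#'   recomputed when `NULL`.
#' @param weighted Use duration weights (default) or plain per-reading
#'   statistics.
#' @return A one-row tibble: `mean_glucose`, `max_glucose`, `min_glucose`,
#'   `sd_glucose`, `cv_glucose`.
#' @export
summary_statistics <- function(trace, weights = NULL, weighted = TRUE) {
  stopifnot(inherits(trace, "glucose_trace"))
  g <- trace$readings$glucose
  if (length(g) == 0) stop("cannot summarize an empty trace", call. = FALSE)
  w <- if (weighted) (weights %||% interval_weights(trace)) else
    rep(1, length(g))
  if (length(w) != length(g)) {
    stop("weights not aligned with readings", call. = FALSE)
  }
  m <- sum(w * g) / sum(w)
  v <- sum(w * (g - m)^2) / sum(w)
  s <- sqrt(max(v, 0))
  tibble::tibble(
    mean_glucose = m,
    max_glucose = max(g),
    min_glucose = min(g),
    sd_glucose = s,
    cv_glucose = if (s == 0) 0 else s / m
  )
}

#' Construct a glucose band
#'
#' @param lo,hi Band edges in mmol/L.
#' @param lo_closed,hi_closed Whether each edge is included.
#' @param name Band label.
#' @return A one-row tibble describing the band.
#' @export
glucose_band <- function(lo, hi, lo_closed = TRUE, hi_closed = FALSE,
                         name = NULL) {
  tibble::tibble(
    name = name %||% paste0("[", lo, ",", hi, ")"),
    lo = lo, hi = hi, lo_closed = lo_closed, hi_closed = hi_closed
  )
}

#' The canonical three-band glucose partition
#'
#' Below / normal / above bands around the 3.0-7.8 mmol/L target range
#' used for nondiabetic individuals. A reading at exactly 7.8 counts as
#' normal; at exactly 3.0 it counts as normal too.
#'
#' @return A three-row band table partitioning (0, 40).
#' @export
glucose_bands <- function() {
  dplyr::bind_rows(
    glucose_band(0, 3, lo_closed = FALSE, hi_closed = FALSE, name = "frac_below"),
    glucose_band(3, 7.8, lo_closed = TRUE, hi_closed = TRUE, name = "frac_normal"),
    glucose_band(7.8, 40, lo_closed = FALSE, hi_closed = FALSE, name = "frac_above")
  )
}

#' Duration-weighted time-in-range fractions
#'
#' Assigns each reading's duration weight to the band containing its
#' glucose value and reports the fraction of total covered time per band.
#' For a partition the fractions sum to 1; with `partial = TRUE` the bands
#' need not cover every value (each fraction is still relative to total
#' covered time), which supports single-band queries such as time below
#' 3.9 mmol/L.
#'
#' @param trace A usable [glucose_trace()].
#' @param weights Per-reading durations; recomputed when `NULL`.
#' @param bands A band table from [glucose_bands()] / [glucose_band()].
#' @param partial Allow bands that do not cover every reading.
#' @return A named numeric vector of fractions, one per band.
#' @export
time_in_ranges <- function(trace, weights = NULL, bands = glucose_bands(),
                           partial = FALSE) {
  stopifnot(inherits(trace, "glucose_trace"))
  g <- trace$readings$glucose
  if (length(g) == 0) stop("cannot compute time-in-range on an empty trace",
                           call. = FALSE)
  w <- weights %||% interval_weights(trace)
  total <- sum(w)
  fr <- numeric(nrow(bands))
  covered <- rep(FALSE, length(g))
  for (i in seq_len(nrow(bands))) {
    lo_ok <- if (bands$lo_closed[i]) g >= bands$lo[i] else g > bands$lo[i]
    hi_ok <- if (bands$hi_closed[i]) g <= bands$hi[i] else g < bands$hi[i]
    inb <- lo_ok & hi_ok
    covered <- covered | inb
    fr[i] <- sum(w[inb]) / total
  }
  if (!partial && any(!covered)) {
    stop("glucose value ", g[which(!covered)[1]],
         " mmol/L not covered by any band", call. = FALSE)
  }
  setNames(fr, bands$name)
}

#' Detect glycemic excursions
#'
#' Finds turning points on a 3-point moving-average smoothing of the
#' series, merges minor fluctuations (adjacent extrema whose swing is
#' below `merge_threshold` mmol/L), and returns one excursion per
#' monotone segment between the surviving alternating extrema. Amplitudes
#' are measured on the raw readings at the extremal indices.
#'
#' @param trace A usable [glucose_trace()].
#' @param merge_threshold Minimum raw swing (mmol/L) for an extremum pair
#'   to survive merging; suppresses sensor jitter at 15-min sampling.
#' @return A tibble with one row per excursion: `start_time`, `turn_time`,
#'   `end_time`, `nadir`, `peak`, `direction` ("rise"/"fall"),
#'   `amplitude`, `duration` (hours). Monotone or constant traces give
#'   zero rows.
#' @export
detect_excursions <- function(trace, merge_threshold = 0.5) {
  stopifnot(inherits(trace, "glucose_trace"))
  g <- trace$readings$glucose
  ts <- trace$readings$timestamp
  n <- length(g)
  empty <- tibble::tibble(
    start_time = as.POSIXct(character(0), tz = "UTC"),
    turn_time = as.POSIXct(character(0), tz = "UTC"),
    end_time = as.POSIXct(character(0), tz = "UTC"),
    nadir = numeric(0), peak = numeric(0), direction = character(0),
    amplitude = numeric(0), duration = numeric(0)
  )
  if (n < 3) return(empty)
  sm <- g
  if (n >= 3) {
    mid <- (g[1:(n - 2)] + g[2:(n - 1)] + g[3:n]) / 3
    sm <- c(g[1], mid, g[n])
  }
  interior <- turning_indices(sm)
  # a monotone (or constant) series has no turning points, hence no
  # excursions; boundary segments count only once an interior turn exists
  if (length(interior) == 0) return(empty)
  idx <- merge_minor_extrema(unique(c(1L, interior, n)), g, merge_threshold)
  if (length(idx) < 2) return(empty)
  from <- idx[-length(idx)]
  to <- idx[-1]
  rising <- g[to] > g[from]
  tibble::tibble(
    start_time = ts[from],
    turn_time = ts[to],
    end_time = ts[to],
    nadir = pmin(g[from], g[to]),
    peak = pmax(g[from], g[to]),
    direction = ifelse(rising, "rise", "fall"),
    amplitude = abs(g[to] - g[from]),
    duration = as.numeric(ts[to] - ts[from], units = "hours")
  )
}

# Indices of interior alternating local extrema of x (plateau runs are
# attributed to the monotone run that produced them).
turning_indices <- function(x) {
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) == 0) return(integer(0))
  sgn <- sign(d[nz])
  turns <- which(diff(sgn) != 0)
  nz[turns] + 1L
}

# Iteratively drop the extremum pair forming the smallest swing until every
# adjacent swing (measured on raw values) reaches the threshold. Dropping a
# neighboring *pair* keeps the max/min alternation intact; a sub-threshold
# swing at a boundary drops the boundary point alone.
merge_minor_extrema <- function(idx, g, threshold) {
  repeat {
    if (length(idx) < 2) return(idx)
    amps <- abs(diff(g[idx]))
    k <- which.min(amps)
    if (amps[k] >= threshold) return(idx)
    if (k == 1) {
      idx <- idx[-1]
    } else if (k == length(amps)) {
      idx <- idx[-length(idx)]
    } else {
      idx <- idx[-c(k, k + 1)]
    }
  }
}

#' Average rise/fall amplitudes and rates over excursions
#'
#' Rates are per-excursion `amplitude / duration` averaged across
#' excursions of each direction (a mean of ratios, not a ratio of means);
#' directions with no excursions report 0.
#'
#' @param excursions A tibble from [detect_excursions()].
#' @return A one-row tibble: `avg_rise`, `avg_fall` (mmol/L),
#'   `avg_rise_rate`, `avg_fall_rate` (mmol/L per hour).
#' @export
excursion_statistics <- function(excursions) {
  dir_stats <- function(dir) {
    e <- excursions[excursions$direction == dir, , drop = FALSE]
    if (nrow(e) == 0) return(c(0, 0))
    c(mean(e$amplitude), mean(e$amplitude / e$duration))
  }
  r <- dir_stats("rise"); f <- dir_stats("fall")
  tibble::tibble(avg_rise = r[1], avg_fall = f[1],
                 avg_rise_rate = r[2], avg_fall_rate = f[2])
}

#' Mean amplitude of glycemic excursions (MAGE)
#'
#' Classic definition: the mean amplitude of those excursions (both
#' directions) whose peak-to-nadir amplitude exceeds one standard
#' deviation of the whole post-trim trace; 0 when none qualifies.
#'
#' @param trace A usable [glucose_trace()].
#' @param excursions Excursion table; recomputed when `NULL`.
#' @param sd_glucose Trace SD; recomputed (duration-weighted) when `NULL`.
#' @return MAGE in mmol/L.
#' @export
compute_mage <- function(trace, excursions = NULL, sd_glucose = NULL) {
  excursions <- excursions %||% detect_excursions(trace)
  sd_glucose <- sd_glucose %||% summary_statistics(trace)$sd_glucose
  qual <- excursions$amplitude > sd_glucose
  if (!any(qual)) return(0)
  mean(excursions$amplitude[qual])
}

#' Extract the full CGM feature set from one trace
#'
#' Composes [summary_statistics()], [time_in_ranges()] on the canonical
#' below/normal/above partition, [detect_excursions()],
#' [excursion_statistics()] and [compute_mage()] into one record.
#' Deterministic for a fixed trace.
#'
#' @param trace A warm-up-trimmed [glucose_trace()].
#' @param min_covered_hours,gap_cap Quality thresholds passed to
#'   [assess_quality()]; an unusable trace raises an error carrying the
#'   quality report.
#' @param weighted Duration-weighted statistics (default) or per-reading.
#' @return A one-row tibble with `participant_id` plus the 13 columns of
#'   [cgm_feature_names()].
#' @export
extract_features <- function(trace, min_covered_hours = 72, gap_cap = 8,
                             weighted = TRUE) {
  stopifnot(inherits(trace, "glucose_trace"))
  if (!trace$warmup_trimmed) trace <- merge_blocks(trace)
  q <- assess_quality(trace, min_covered_hours, gap_cap)
  if (!q$usable) {
    cond <- structure(
      class = c("cgm_quality_error", "error", "condition"),
      list(message = paste0("participant ", trace$participant_id,
                            ": trace unusable (covered ",
                            round(q$covered_time, 1), " h < ",
                            min_covered_hours, " h required)"),
           call = NULL, quality = q)
    )
    stop(cond)
  }
  w <- interval_weights(trace, gap_cap)
  ss <- summary_statistics(trace, weights = w, weighted = weighted)
  tir <- time_in_ranges(trace, weights = w)
  exc <- detect_excursions(trace)
  es <- excursion_statistics(exc)
  mage <- compute_mage(trace, excursions = exc, sd_glucose = ss$sd_glucose)
  out <- tibble::tibble(
    participant_id = trace$participant_id,
    mean_glucose = ss$mean_glucose, max_glucose = ss$max_glucose,
    min_glucose = ss$min_glucose, sd_glucose = ss$sd_glucose,
    cv_glucose = ss$cv_glucose, mage = mage,
    frac_normal = tir[["frac_normal"]], frac_above = tir[["frac_above"]],
    frac_below = tir[["frac_below"]],
    avg_rise = es$avg_rise, avg_fall = es$avg_fall,
    avg_rise_rate = es$avg_rise_rate, avg_fall_rate = es$avg_fall_rate
  )
  out[, c("participant_id", CGM_FEATURE_NAMES)]
}

#' Feature table for a set of traces
#'
#' @param traces A list of [glucose_trace()] objects.
#' @param ... Passed to [extract_features()].
#' @return A tibble with one row per trace.
#' @export
extract_feature_table <- function(traces, ...) {
  dplyr::bind_rows(lapply(traces, extract_features, ...))
}
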