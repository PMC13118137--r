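#' Default generator parameters
#'
#' The latent-severity parametrization behind the synthetic cohort. A
#' single latent severity score per participant (two-component Gaussian
#' mixture; the high component is the prediabetes-like group) drives all
#' three measurement channels -- the CGM trace dynamics, the OGTT glucose
#' values and HbA1c -- with channel-specific noise, so that HbA1c-negative
#' prediabetes arises at a realistic rate. HbA1c is a linear function of
#' the participant's latent mean glucose plus independent assay noise.
#'
#' The shipped values were calibrated by coarse grid search
#' (`tools/calibrate_generator.R`) against published cohort statistics:
#' prediabetes prevalence ~46.6%, HbA1c-rule sensitivity ~60.3%,
#' prediabetes fraction among HbA1c < 5.7% ~26%, mean time in 3.0-7.8
#' mmol/L ~96.3% and mean time below 3.9 mmol/L ~2.9%.
#'
#' @return A named list of generator parameters.
#' @export
default_group_params <- function() {
  list(
    # latent severity mixture (low component N(0,1); high N(delta,1))
    sev_delta = 2.2,
    # demographics, linked to severity
    age_base = 46, age_slope = 2.73, age_sd = 10,
    bmi_log_base = log(24.0), bmi_log_slope = 0.0187, bmi_log_sd = 0.15,
    whr_base = 0.86, whr_slope = 0.00909, whr_sd = 0.033,
    p_female = 0.581,
    p_ethnicity = c(chinese = 0.658, malay = 0.140, indian = 0.155,
                    other = 0.047),
    # OGTT channels, linear in severity
    fpg_base = 4.8, fpg_slope = 0.182, fpg_sd = 0.30,
    g2h_base = 6.1, g2h_slope = 1.0, g2h_sd = 1.05,
    # HbA1c = hba1c_intercept + hba1c_slope * latent mean glucose + noise
    hba1c_intercept = 2.04, hba1c_slope = 0.634, hba1c_sd = 0.20,
    # trace dynamics
    night_base_mean = 4.30, night_base_sd = 0.25,
    day_amp_base = 0.9, day_amp_slope = 0.35, day_amp_sd = 0.25,
    exc_base = 1.6, exc_slope = 0.45, exc_sd = 0.35,
    noise_sd = 0.28, ar_phi = 0.7,
    meal_times = c(7.5, 12.5, 18.5), meal_jitter = 1.5,
    meal_amp_sdlog = 0.35, meal_rise_h = 0.75, meal_tau_h = 1.5,
    glucose_floor = 2.2
  )
}

#' Generator configuration
#'
#' @param n_participants Cohort size after dropping ADA-diabetes draws.
#' @param prevalence_target Mixture weight of the high-severity component
#'   (the prediabetes-like group); default 0.466.
#' @param trace_days Days of CGM recording per participant (default 13,
#'   leaving ~12 after warm-up trimming).
#' @param sampling_interval Nominal sampling interval in minutes.
#' @param gap_rate Expected data-loss gaps per week of wear.
#' @param seed Integer seed; the full cohort is a pure function of the
#'   configuration.
#' @param group_params Latent-severity parameters; see
#'   [default_group_params()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_participants = 406, prevalence_target = 0.466,
                             trace_days = 13, sampling_interval = 15,
                             gap_rate = 1, seed = 1,
                             group_params = default_group_params()) {
  stopifnot(prevalence_target > 0, prevalence_target < 1, trace_days >= 3,
            n_participants >= 1)
  structure(list(
    n_participants = as.integer(n_participants),
    prevalence_target = prevalence_target,
    trace_days = trace_days,
    sampling_interval = sampling_interval,
    gap_rate = gap_rate,
    seed = as.integer(seed),
    group_params = group_params
  ), class = "generator_config")
}

# Evaluate expr with a locally-set RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-participant substream seed (kept below 2^31).
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483629)
}

#' Sample participants: demographics and latent glycemia
#'
#' Draws `n` participants from the severity mixture. Age, BMI and
#' waist-to-hip ratio carry severity-linked shifts (the high-severity
#' component is ~6 years older with slightly higher BMI and WHR); sex and
#' ethnicity are drawn independently of severity. The latent glycemia
#' columns (`night_base`, `day_amp`, `excursion_scale`, `noise_sd`,
#' `latent_mean`) drive [simulate_trace()] and [simulate_clinical()].
#' Uses the current RNG state; wrap in a seed context for reproducibility.
#'
#' @param config A [generator_config()].
#' @param n Number of participants to draw (defaults to
#'   `config$n_participants`).
#' @param id_offset Offset for generated participant ids.
#' @return A tibble with demographics plus latent columns `component`,
#'   `severity`, `night_base`, `day_amp`, `excursion_scale`, `noise_sd`,
#'   `latent_mean`.
#' @export
sample_participant <- function(config, n = config$n_participants,
                               id_offset = 0) {
  p <- config$group_params
  z <- stats::rbinom(n, 1, config$prevalence_target)
  s <- stats::rnorm(n, mean = z * p$sev_delta, sd = 1)
  age <- round(pmin(pmax(p$age_base + p$age_slope * s +
                           stats::rnorm(n, 0, p$age_sd), 30), 80))
  bmi <- pmin(pmax(exp(p$bmi_log_base + p$bmi_log_slope * s +
                         stats::rnorm(n, 0, p$bmi_log_sd)), 15), 55)
  whr <- pmin(pmax(p$whr_base + p$whr_slope * s +
                     stats::rnorm(n, 0, p$whr_sd), 0.6), 1.15)
  sex <- ifelse(stats::runif(n) < p$p_female, "female", "male")
  ethnicity <- sample(names(p$p_ethnicity), n, replace = TRUE,
                      prob = p$p_ethnicity)
  night_base <- stats::rnorm(n, p$night_base_mean, p$night_base_sd)
  day_amp <- pmax(p$day_amp_base + p$day_amp_slope * s +
                    stats::rnorm(n, 0, p$day_amp_sd), 0.2)
  exc <- pmax(p$exc_base + p$exc_slope * s +
                stats::rnorm(n, 0, p$exc_sd), 0.3)
  # expected daytime-dominated glycemia: population night base + mean
  # circadian elevation (mean of the flattened raised-cosine weight =
  # 0.4521) + mean meal contribution (3 meals/day, ramp area A*rise/2 +
  # decay area A*tau). The population (not personal) night base is used so
  # that nocturnal baseline variation acts on the trace alone; its
  # contribution to HbA1c is absorbed by the channel's independent noise.
  meal_coef <- 3 * exp(p$meal_amp_sdlog^2 / 2) *
    (p$meal_rise_h / 2 + p$meal_tau_h) / 24
  latent_mean <- p$night_base_mean + 0.4521 * day_amp + meal_coef * exc
  tibble::tibble(
    participant_id = sprintf("S%04d", id_offset + seq_len(n)),
    age = age, sex = sex, ethnicity = ethnicity,
    bmi = round(bmi, 1), whr = round(whr, 3),
    component = z, severity = s,
    night_base = night_base, day_amp = day_amp, excursion_scale = exc,
    noise_sd = p$noise_sd, latent_mean = latent_mean
  )
}

#' Simulate the clinical glycemia channels
#'
#' Fasting and 2-hour OGTT glucose are noisy linear functions of severity;
#' HbA1c is a linear function of the latent mean glucose plus independent
#' assay noise, so CGM dynamics and HbA1c are correlated but not
#' redundant. Uses the current RNG state.
#'
#' @param latent A tibble from [sample_participant()].
#' @param config A [generator_config()].
#' @return `latent` with `fpg`, `g2h`, `hba1c` columns appended.
#' @export
simulate_clinical <- function(latent, config) {
  p <- config$group_params
  n <- nrow(latent)
  s <- latent$severity
  fpg <- pmax(p$fpg_base + p$fpg_slope * s + stats::rnorm(n, 0, p$fpg_sd),
              2.5)
  g2h <- pmax(p$g2h_base + p$g2h_slope * s + stats::rnorm(n, 0, p$g2h_sd),
              2.5)
  hba1c <- pmax(p$hba1c_intercept + p$hba1c_slope * latent$latent_mean +
                  stats::rnorm(n, 0, p$hba1c_sd), 3.5)
  out <- latent
  out$fpg <- round(fpg, 1)
  out$g2h <- round(g2h, 1)
  out$hba1c <- round(hba1c, 1)
  out
}

#' Simulate one CGM trace
#'
#' glucose(t) = night base + circadian day elevation + three daily meal
#' excursions (jittered onsets, lognormal amplitudes scaled by the
#' participant's excursion scale, ~45-min linear rise then exponential
#' decay) + AR(1) sensor noise, sampled every ~15 min with small timing
#' jitter, floored at 2.2 mmol/L. Data-loss gaps of 1-10 h are inserted at
#' `gap_rate` per week. The first 24 h are retained so that warm-up
#' trimming is exercised downstream.
#'
#' @param latent A one-row latent tibble (see [sample_participant()]).
#' @param config A [generator_config()].
#' @param seed Integer seed for this trace's substream.
#' @param start Start timestamp of the wear.
#' @return A [glucose_trace()] (untrimmed, single block).
#' @export
simulate_trace <- function(latent, config, seed,
                           start = as.POSIXct("2023-03-06 00:00:00",
                                              tz = "UTC")) {
  p <- config$group_params
  with_seed(seed, {
    n_steps <- ceiling(config$trace_days * 24 * 60 / config$sampling_interval)
    jitter_min <- stats::runif(n_steps, -2, 2)
    t_min <- cumsum(rep(config$sampling_interval, n_steps) + jitter_min)
    t_min <- round(t_min)
    t_min <- t_min[!duplicated(t_min)]
    hours <- t_min / 60
    hod <- hours %% 24
    # raised-cosine day elevation with a flat nocturnal window (~1-5 am),
    # so the nighttime glucose floor does not depend on severity
    circadian <- pmax(0, (0.5 * (1 - cos(2 * pi * (hod - 3) / 24)) - 0.12) /
                        0.88)
    g <- latent$night_base + latent$day_amp * circadian
    # meals
    n_days <- ceiling(config$trace_days)
    for (d in seq_len(n_days) - 1) {
      onsets <- 24 * d + p$meal_times +
        stats::runif(length(p$meal_times), -p$meal_jitter, p$meal_jitter)
      amps <- latent$excursion_scale *
        stats::rlnorm(length(onsets), 0, p$meal_amp_sdlog)
      for (k in seq_along(onsets)) {
        dt <- hours - onsets[k]
        active <- dt > 0 & dt < 12
        if (!any(active)) next
        shape <- pmin(dt[active] / p$meal_rise_h, 1) *
          exp(-pmax(dt[active] - p$meal_rise_h, 0) / p$meal_tau_h)
        g[active] <- g[active] + amps[k] * shape
      }
    }
    # AR(1) noise with stationary sd noise_sd
    innov_sd <- latent$noise_sd * sqrt(1 - p$ar_phi^2)
    noise <- as.numeric(stats::filter(stats::rnorm(length(g), 0, innov_sd),
                                      p$ar_phi, method = "recursive"))
    g <- pmax(g + noise, p$glucose_floor)
    # data-loss gaps
    n_gaps <- stats::rpois(1, config$gap_rate * config$trace_days / 7)
    keep <- rep(TRUE, length(g))
    if (n_gaps > 0) {
      gap_start <- stats::runif(n_gaps, 0, max(hours))
      gap_len <- stats::runif(n_gaps, 1, 10)
      for (k in seq_len(n_gaps)) {
        keep[hours >= gap_start[k] & hours < gap_start[k] + gap_len[k]] <- FALSE
      }
    }
    glucose_trace(latent$participant_id, tibble::tibble(
      timestamp = start + 60 * t_min[keep],
      glucose = round(g[keep], 1),
      block_id = 1L
    ))
  })
}

#' Generate a full linked synthetic cohort
#'
#' Draws participants, simulates their clinical channels, labels them by
#' ADA criteria, drops and resamples any draw labeled diabetes (the study
#' population excludes newly diagnosed diabetes), and optionally simulates
#' one CGM trace per participant and extracts the feature table. The
#' result is a pure function of the configuration.
#'
#' @param config A [generator_config()].
#' @param with_traces Simulate traces and extract features (default TRUE);
#'   set to FALSE for clinical-only studies of labeling behavior.
#' @return A list with `clinical` (labeled tibble), `traces` (named list
#'   of [glucose_trace()], or NULL), `features` (tibble, or NULL) and
#'   `config`.
#' @export
generate_cohort <- function(config, with_traces = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  clinical <- with_seed(config$seed, {
    kept <- NULL
    n_drawn <- 0
    n_rejected <- 0
    offset <- 0
    while (is.null(kept) || nrow(kept) < config$n_participants) {
      batch_n <- max(config$n_participants - (if (is.null(kept)) 0 else
        nrow(kept)), 8)
      batch <- sample_participant(config, n = ceiling(batch_n * 1.15),
                                  id_offset = offset)
      offset <- offset + nrow(batch)
      batch <- simulate_clinical(batch, config)
      lab <- classify_glycemia(batch$fpg, batch$g2h, batch$hba1c)
      batch <- dplyr::bind_cols(batch, lab)
      n_drawn <- n_drawn + nrow(batch)
      n_rejected <- n_rejected + sum(batch$status == "diabetes")
      if (n_drawn >= 200 && n_rejected / n_drawn > 0.5) {
        stop("generator configuration rejects >50% of draws as diabetes; ",
             "check group_params", call. = FALSE)
      }
      kept <- dplyr::bind_rows(kept, batch[batch$status != "diabetes", ,
                                           drop = FALSE])
    }
    kept <- kept[seq_len(config$n_participants), , drop = FALSE]
    kept$participant_id <- sprintf("S%04d", seq_len(nrow(kept)))
    kept$status <- droplevels(kept$status)
    kept
  })
  traces <- NULL
  features <- NULL
  if (with_traces) {
    traces <- lapply(seq_len(nrow(clinical)), function(i) {
      simulate_trace(clinical[i, ], config,
                     seed = substream_seed(config$seed, i))
    })
    names(traces) <- clinical$participant_id
    features <- extract_feature_table(lapply(traces, merge_blocks))
  }
  list(clinical = clinical, traces = traces, features = features,
       config = config)
}
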