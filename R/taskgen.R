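#' Study configuration for synthetic cohorts
#'
#' Defines the task schedule and cohort-level constants of the elevator
#' approach-avoidance task: four blocks of 24 trials, two-thirds threat
#' trials, a 50/50 split of predictable and unpredictable trials within
#' each block, a 1.5 s response deadline, a jittered pre-stimulus interval
#' of 0.9 +/- 0.3 s, and a 50% threat probability for outcomes in the
#' unpredictable condition.
#'
#' @param n_participants cohort size.
#' @param class_mixing probability that a participant belongs to the
#'   stimulus-response (SR) latent class; default 29/90, the observed
#'   class split.
#' @param n_blocks,trials_per_block schedule dimensions (4 x 24).
#' @param threat_fraction fraction of threat trials per block (2/3).
#' @param response_deadline seconds allowed for a response (1.5).
#' @param jitter_mean,jitter_sd pre-stimulus jitter distribution, seconds.
#'   Jitter is drawn from a normal truncated to
#'   \code{jitter_trunc} to avoid negative waits.
#' @param jitter_trunc truncation range of the jitter draw, seconds.
#' @param unpredictable_threat_prob probability that the post-choice
#'   avatar is angry in the unpredictable condition (0.5).
#' @param n_dyads number of distinct angry-neutral avatar dyads (32).
#' @return an object of class \code{study_config}.
#' @export
study_config <- function(n_participants = 60,
                         class_mixing = 29 / 90,
                         n_blocks = 4,
                         trials_per_block = 24,
                         threat_fraction = 2 / 3,
                         response_deadline = 1.5,
                         jitter_mean = 0.9,
                         jitter_sd = 0.3,
                         jitter_trunc = c(0.3, 1.5),
                         unpredictable_threat_prob = 0.5,
                         n_dyads = 32) {
  if (class_mixing < 0 || class_mixing > 1) stop("class_mixing must be in [0, 1]")
  n_threat <- threat_fraction * trials_per_block
  if (abs(n_threat - round(n_threat)) > 1e-9)
    stop("threat_fraction * trials_per_block must be an integer")
  if (trials_per_block %% 2 != 0)
    stop("trials_per_block must be even for a 50/50 condition split")
  if (round(n_threat) %% 2 != 0 || (trials_per_block - round(n_threat)) %% 2 != 0)
    stop("threat and neutral counts must split evenly across conditions")
  structure(list(n_participants = n_participants, class_mixing = class_mixing,
                 n_blocks = n_blocks, trials_per_block = trials_per_block,
                 threat_fraction = threat_fraction,
                 response_deadline = response_deadline,
                 jitter_mean = jitter_mean, jitter_sd = jitter_sd,
                 jitter_trunc = jitter_trunc,
                 unpredictable_threat_prob = unpredictable_threat_prob,
                 n_dyads = n_dyads),
            class = "study_config")
}

#' Default latent-class DDM parameters
#'
#' Class-conditional diffusion parameters calibrated so that class-level
#' avoidance rates land on the generator targets: the goal-directed (GD)
#' class at roughly 0.575 (predictable) / 0.515 (unpredictable) and the
#' stimulus-response (SR) class at roughly 0.739 / 0.724.  GD drift is
#' higher in the predictable condition; SR drift is identical across
#' conditions and higher overall; SR has slightly wider boundaries and
#' shorter non-decision time.
#'
#' @return nested list \code{class -> condition -> ddm_params}.
#' @export
default_class_params <- function() {
  ## v chosen as logit(target P(avoid)) / a so that the closed-form
  ## absorption probability 1/(1+exp(-a v)) hits the class cell targets
  a_gd <- 1.12; a_sr <- 1.23
  list(
    GD = list(
      predictable   = ddm_params(v = qlogis(0.575) / a_gd, a = a_gd, t0 = 0.30),
      unpredictable = ddm_params(v = qlogis(0.515) / a_gd, a = a_gd, t0 = 0.30)),
    SR = list(
      predictable   = ddm_params(v = mean(qlogis(c(0.739, 0.724))) / a_sr, a = a_sr, t0 = 0.24),
      unpredictable = ddm_params(v = mean(qlogis(c(0.739, 0.724))) / a_sr, a = a_sr, t0 = 0.24))
  )
}

#' Draw a participant profile
#'
#' Samples one participant's latent class and individual parameters:
#' condition-specific DDM parameters (class means plus between-participant
#' scatter), cardiac baseline and deceleration gains, EMG burst gain, and
#' subjective-evaluation means.
#'
#' Deceleration gains (bpm, negative = deceleration) default to the
#' class-specific pattern: the GD class decelerates more in the
#' predictable than the unpredictable condition on threat trials, the SR
#' class equally in both; neutral trials show a smaller, condition-
#' independent deceleration.  EMG burst gain (threat minus neutral
#' amplitude) is positive only for the SR class.
#'
#' @param participant_id identifier.
#' @param latent_class "GD", "SR", or NULL to draw from
#'   \code{cfg$class_mixing}.
#' @param cfg a \code{\link{study_config}}.
#' @param class_params nested list as \code{\link{default_class_params}}.
#' @param between_sd named numeric: between-participant SDs for
#'   \code{v}, \code{a}, \code{t0}.
#' @return an object of class \code{participant_profile}.
#' @export
participant_profile <- function(participant_id, latent_class = NULL,
                                cfg = study_config(),
                                class_params = default_class_params(),
                                between_sd = c(v = 0.15, a = 0.06, t0 = 0.03)) {
  if (is.null(latent_class)) {
    latent_class <- if (runif(1) < cfg$class_mixing) "SR" else "GD"
  }
  stopifnot(latent_class %in% c("GD", "SR"))
  cp <- class_params[[latent_class]]
  dv <- rnorm(1, 0, between_sd["v"])
  da <- rnorm(1, 0, between_sd["a"])
  dt0 <- rnorm(1, 0, between_sd["t0"])
  bump <- function(p) ddm_params(v = p$v + dv,
                                 a = max(p$a + da, 0.5),
                                 t0 = min(max(p$t0 + dt0, 0.1), 0.6))
  ddm_by_cond <- lapply(cp, bump)
  if (latent_class == "GD") {
    decel <- c(predictable_threat = -8, unpredictable_threat = -4,
               predictable_neutral = -2, unpredictable_neutral = -2)
    emg_gain <- 0
  } else {
    decel <- c(predictable_threat = -5, unpredictable_threat = -5,
               predictable_neutral = -2, unpredictable_neutral = -2)
    emg_gain <- 4
  }
  ## individual scaling of physiological gains
  decel <- decel * exp(rnorm(1, 0, 0.2))
  structure(list(participant_id = participant_id,
                 latent_class = latent_class,
                 ddm_params_by_condition = ddm_by_cond,
                 hr_baseline = rnorm(1, 70, 6),
                 decel_kernel_gain = decel,
                 emg_burst_base = 6,
                 emg_burst_gain = emg_gain,
                 sv_mean_avoid = 65.231,
                 sv_mean_approach = 27.704),
            class = "participant_profile")
}

## truncated-normal draw by rejection (ranges here make rejection cheap)
.rtnorm <- function(n, mean, sd, lo, hi) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

#' Generate a trial schedule
#'
#' Builds one participant's schedule with exact per-block cell counts:
#' conditions split 50/50, the threat fraction exact within each
#' condition, the angry avatar's side counterbalanced within block and
#' condition, and jitter drawn from a truncated normal.  Choices are left
#' unset.
#'
#' @param profile a \code{\link{participant_profile}}.
#' @param cfg a \code{\link{study_config}}.
#' @return data.frame of trial records with unset choice fields.
#' @export
generate_trial_schedule <- function(profile, cfg = study_config()) {
  tpb <- cfg$trials_per_block
  n_threat <- as.integer(round(cfg$threat_fraction * tpb))
  n_neutral <- tpb - n_threat
  per_cond_threat <- n_threat %/% 2L
  per_cond_neutral <- n_neutral %/% 2L

  blocks <- lapply(seq_len(cfg$n_blocks), function(b) {
    cell <- function(cond, type, n) {
      side <- if (type == "threat") {
        sample(rep(c("left", "right"), length.out = n))
      } else rep("none", n)
      data.frame(block = b, condition = cond, trial_type = type,
                 angry_side = side, stringsAsFactors = FALSE)
    }
    blk <- rbind(cell("predictable", "threat", per_cond_threat),
                 cell("unpredictable", "threat", per_cond_threat),
                 cell("predictable", "neutral", per_cond_neutral),
                 cell("unpredictable", "neutral", per_cond_neutral))
    blk[sample(nrow(blk)), , drop = FALSE]
  })
  sched <- do.call(rbind, blocks)
  n <- nrow(sched)
  sched$participant_id <- profile$participant_id
  sched$trial_index <- seq_len(n)
  sched$jitter <- .rtnorm(n, cfg$jitter_mean, cfg$jitter_sd,
                          cfg$jitter_trunc[1], cfg$jitter_trunc[2])
  ## dyads: threat trials draw from the fixed dyad inventory, balanced
  is_threat <- sched$trial_type == "threat"
  n_t <- sum(is_threat)
  dyads <- rep(seq_len(cfg$n_dyads), length.out = n_t)
  sched$dyad_id <- NA_integer_
  sched$dyad_id[is_threat] <- sample(dyads)
  sched$choice <- NA_character_
  sched$response <- NA_character_
  sched$rt <- NA_real_
  sched$outcome <- NA_character_
  rownames(sched) <- NULL
  sched[, c("participant_id", "block", "trial_index", "condition",
            "trial_type", "angry_side", "jitter", "dyad_id",
            "choice", "response", "rt", "outcome")]
}

#' Simulate choices and outcomes on a schedule
#'
#' Threat trials are decided by the profile's condition-specific diffusion
#' process (upper boundary = avoid the angry avatar); simulated RTs above
#' the response deadline are recorded as non-responses.  Outcomes are
#' deterministic in the predictable condition (the chosen elevator's
#' occupant) and drawn angry with \code{cfg$unpredictable_threat_prob} in
#' the unpredictable condition.  Neutral trials have no approach/avoid
#' semantics: the side is an unbiased coin flip and the RT comes from a
#' diffusion process with condition-averaged parameters.
#'
#' @param profile a \code{\link{participant_profile}}.
#' @param schedule output of \code{\link{generate_trial_schedule}}.
#' @param cfg a \code{\link{study_config}}.
#' @param dt Euler step for the diffusion simulator.
#' @return the completed schedule.
#' @export
simulate_choices <- function(profile, schedule, cfg = study_config(),
                             dt = 0.001) {
  out <- schedule
  for (cond in c("predictable", "unpredictable")) {
    sel <- which(out$trial_type == "threat" & out$condition == cond)
    if (!length(sel)) next
    sim <- ddm_simulate(profile$ddm_params_by_condition[[cond]],
                        n = length(sel), dt = dt)
    out$rt[sel] <- sim$rt
    out$response[sel] <- sim$response
  }
  ## neutral trials: unbiased side choice, RT from average-parameter DDM
  seln <- which(out$trial_type == "neutral")
  if (length(seln)) {
    pp <- profile$ddm_params_by_condition
    avg <- ddm_params(v = mean(c(pp[[1]]$v, pp[[2]]$v)),
                      a = mean(c(pp[[1]]$a, pp[[2]]$a)),
                      t0 = mean(c(pp[[1]]$t0, pp[[2]]$t0)))
    simn <- ddm_simulate(avg, n = length(seln), dt = dt)
    out$rt[seln] <- simn$rt
    out$choice[seln] <- sample(c("left", "right"), length(seln), replace = TRUE)
  }
  ## deadline: late responses become non-responses
  late <- which(!is.na(out$rt) & out$rt > cfg$response_deadline)
  out$rt[late] <- NA_real_
  out$response[late] <- NA_character_
  out$choice[late] <- NA_character_

  ## map threat-trial responses to a chosen side
  selt <- which(out$trial_type == "threat" & !is.na(out$response))
  avoid <- out$response[selt] == "avoid"
  angry <- out$angry_side[selt]
  out$choice[selt] <- ifelse(avoid,
                             ifelse(angry == "left", "right", "left"),
                             angry)
  ## outcomes (threat trials with a response)
  pred <- selt[out$condition[selt] == "predictable"]
  out$outcome[pred] <- ifelse(out$response[pred] == "avoid", "safe", "threat")
  unp <- selt[out$condition[selt] == "unpredictable"]
  out$outcome[unp] <- ifelse(runif(length(unp)) < cfg$unpredictable_threat_prob,
                             "threat", "safe")
  out
}

#' Simulate a full synthetic cohort
#'
#' Draws participant profiles and completed trial tables for a whole
#' cohort.  Physiological traces are generated on demand by
#' \code{\link{synthesize_ecg}} / \code{\link{synthesize_emg}} from the
#' returned profiles and trials.
#'
#' @param cfg a \code{\link{study_config}}.
#' @param class_params see \code{\link{participant_profile}}.
#' @param classes optional character vector of fixed class labels
#'   (length \code{n_participants}) overriding random class draws.
#' @param dt Euler step for the diffusion simulator.
#' @return list with \code{trials} (stacked data.frame), \code{profiles}
#'   (list) and \code{cfg}.
#' @export
simulate_cohort <- function(cfg = study_config(),
                            class_params = default_class_params(),
                            classes = NULL, dt = 0.001) {
  profiles <- vector("list", cfg$n_participants)
  trials <- vector("list", cfg$n_participants)
  for (i in seq_len(cfg$n_participants)) {
    cls <- if (is.null(classes)) NULL else classes[i]
    pr <- participant_profile(sprintf("P%03d", i), latent_class = cls,
                              cfg = cfg, class_params = class_params)
    sched <- generate_trial_schedule(pr, cfg)
    trials[[i]] <- simulate_choices(pr, sched, cfg, dt = dt)
    trials[[i]]$latent_class <- pr$latent_class
    profiles[[i]] <- pr
  }
  list(trials = do.call(rbind, trials), profiles = profiles, cfg = cfg)
}

## smooth deceleration kernel: raised-cosine bump supported on
## [-1, 4] s around stimulus onset, unit peak
.decel_kernel <- function(t_rel) {
  out <- numeric(length(t_rel))
  inside <- t_rel >= -1 & t_rel <= 4
  ## peak at 1.5 s; half-cosine rise over [-1, 1.5], fall over [1.5, 4]
  x <- t_rel[inside]
  out[inside] <- 0.5 * (1 + cos(pi * (x - 1.5) / 2.5))
  out
}

#' Synthesize a continuous ECG trace for one participant
#'
#' Builds a 1 kHz ECG from Gaussian R-wave templates placed at beat times.
#' The inter-beat-interval process follows the participant's baseline
#' heart rate with multiplicative noise and a smooth event-locked
#' IBI-lengthening kernel (active from about 1 s before to 4 s after each
#' stimulus onset) scaled by the profile's condition-by-trial-type
#' deceleration gain.  Trial onsets are spaced so that -4..10 s epochs
#' never overlap.
#'
#' @param profile a \code{\link{participant_profile}}.
#' @param trials completed trial table for this participant.
#' @param cfg a \code{\link{study_config}}.
#' @param trial_spacing seconds between consecutive stimulus onsets
#'   (must be >= 14.5 to keep epochs separable).
#' @param fs sampling rate, Hz.
#' @param hrv_sd slow heart-rate-variability SD, bpm.
#' @param ibi_noise_sd multiplicative IBI noise SD.
#' @param trial_gain_sd lognormal per-trial scatter of the deceleration
#'   amplitude.
#' @return list: \code{samples}, \code{fs}, \code{channel},
#'   \code{event_markers} (data.frame trial_index, onset_time_s, rt_s),
#'   \code{true_ihr} (10 Hz ground-truth modulation, for validation) and
#'   \code{beat_times}.
#' @export
synthesize_ecg <- function(profile, trials, cfg = study_config(),
                           trial_spacing = 15, fs = 1000,
                           hrv_sd = 1.5, ibi_noise_sd = 0.01,
                           trial_gain_sd = 0.2) {
  if (trial_spacing < 14.5)
    stop("trial_spacing must be >= 14.5 s so -4..10 s epochs do not overlap")
  n_tr <- nrow(trials)
  onsets <- 20 + (seq_len(n_tr) - 1) * trial_spacing
  total_t <- max(onsets) + 15

  ## ground-truth iHR modulation on a 10 Hz grid
  grid <- seq(0, total_t, by = 0.1)
  modul <- numeric(length(grid))
  gains <- numeric(n_tr)
  for (i in seq_len(n_tr)) {
    key <- paste(trials$condition[i], trials$trial_type[i], sep = "_")
    g <- profile$decel_kernel_gain[[key]] * exp(rnorm(1, 0, trial_gain_sd))
    gains[i] <- g
    sel <- grid >= onsets[i] - 1.5 & grid <= onsets[i] + 4.5
    modul[sel] <- modul[sel] + g * .decel_kernel(grid[sel] - onsets[i])
  }
  ## slow HRV noise: low-pass filtered white noise
  hrv <- stats::filter(rnorm(length(grid)), rep(1 / 80, 80), circular = TRUE)
  hrv <- as.numeric(hrv) * hrv_sd / max(sd(as.numeric(hrv)), 1e-12)
  ihr_target <- pmax(profile$hr_baseline + modul + hrv, 35)

  ## sequential beat generation from the target iHR
  beat_times <- numeric(ceiling(total_t / 60 * 200) + 10)
  t <- 0.5; k <- 0
  ihr_at <- function(tt) ihr_target[min(max(1, round(tt / 0.1) + 1), length(grid))]
  while (t < total_t) {
    k <- k + 1
    beat_times[k] <- t
    ## target the rate at the interval midpoint (one fixed-point step) so
    ## the generated IBI series tracks the modulation without extra lag
    ibi0 <- 60 / ihr_at(t)
    t <- t + (60 / ihr_at(t + ibi0 / 2)) * exp(rnorm(1, 0, ibi_noise_sd))
  }
  beat_times <- beat_times[seq_len(k)]

  ## Gaussian R-wave templates (sd 8 ms) + measurement noise
  n_s <- ceiling(total_t * fs)
  samples <- rnorm(n_s, 0, 0.03)
  tpl_half <- round(0.03 * fs)
  tpl <- exp(-((-tpl_half:tpl_half) / (0.008 * fs))^2 / 2)
  idx <- round(beat_times * fs)
  for (b in idx) {
    lo <- b - tpl_half; hi <- b + tpl_half
    if (lo < 1 || hi > n_s) next
    samples[lo:hi] <- samples[lo:hi] + tpl
  }
  list(samples = samples, fs = fs, channel = "ecg",
       event_markers = data.frame(trial_index = trials$trial_index,
                                  onset_time_s = onsets,
                                  rt_s = trials$rt),
       true_ihr = list(time = grid, modulation = modul, gains = gains),
       beat_times = beat_times)
}

#' Synthesize EMG traces for one participant
#'
#' Two-channel (left/right hand) 2 kHz EMG: a band-limited noise floor,
#' an optional 50 Hz line-noise component, and one burst per responded
#' trial on the responding hand, centred at stimulus onset + RT.  Burst
#' amplitude is \code{emg_burst_base + emg_burst_gain * threat} with
#' lognormal per-trial scatter (the threat gain is nonzero only for SR
#' profiles by default).
#'
#' @inheritParams synthesize_ecg
#' @param fs sampling rate, Hz (2000).
#' @param noise_sd noise-floor SD (envelope units).
#' @param line_amp amplitude of the 50 Hz line component.
#' @param burst_dur burst duration, seconds.
#' @return list of two channel lists (\code{emg_left}, \code{emg_right})
#'   each with \code{samples}, \code{fs}, \code{channel},
#'   \code{event_markers}; plus \code{true_bursts} ground truth.
#' @export
synthesize_emg <- function(profile, trials, cfg = study_config(),
                           trial_spacing = 15, fs = 2000,
                           noise_sd = 1, line_amp = 0.5,
                           burst_dur = 0.2) {
  n_tr <- nrow(trials)
  onsets <- 20 + (seq_len(n_tr) - 1) * trial_spacing
  total_t <- max(onsets) + 15
  n_s <- ceiling(total_t * fs)
  tvec <- seq_len(n_s) / fs
  mk <- function(ch) noise_sd * rnorm(n_s) + line_amp * sin(2 * pi * 50 * tvec)
  chans <- list(emg_left = mk("l"), emg_right = mk("r"))

  half <- round(burst_dur * fs / 2)
  win <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = 2 * half + 1))) # Hann
  truth <- list()
  for (i in seq_len(n_tr)) {
    if (is.na(trials$rt[i]) || is.na(trials$choice[i])) next
    amp <- profile$emg_burst_base +
      profile$emg_burst_gain * (trials$trial_type[i] == "threat")
    amp <- amp * exp(rnorm(1, 0, 0.15))
    centre <- round((onsets[i] + trials$rt[i]) * fs)
    lo <- centre - half; hi <- centre + half
    if (lo < 1 || hi > n_s) next
    hand <- if (trials$choice[i] == "left") "emg_left" else "emg_right"
    chans[[hand]][lo:hi] <- chans[[hand]][lo:hi] + amp * win * rnorm(length(win))
    truth[[length(truth) + 1]] <-
      data.frame(trial_index = trials$trial_index[i], hand = hand,
                 centre_s = (onsets[i] + trials$rt[i]),
                 onset_s = lo / fs, offset_s = hi / fs, amplitude = amp)
  }
  markers <- data.frame(trial_index = trials$trial_index,
                        onset_time_s = onsets, rt_s = trials$rt)
  out <- lapply(names(chans), function(nm)
    list(samples = chans[[nm]], fs = fs, channel = nm, event_markers = markers))
  names(out) <- names(chans)
  out$true_bursts <- if (length(truth)) do.call(rbind, truth) else NULL
  out
}

#' Generate subjective evaluation scores
#'
#' Per-dyad avoidance and approach values drawn from normals with the
#' profile's means and an SD of 20.5, clamped to the 0-100 response scale;
#' the subjective value score is
#' \code{sv = (value_avoid - value_approach) / 100}, in [-1, 1].
#'
#' @param profile a \code{\link{participant_profile}}.
#' @param dyads integer vector of dyad ids.
#' @param sd response-scale SD (default 20.5).
#' @return data.frame with dyad_id, value_avoid, value_approach, sv.
#' @export
generate_subjective_values <- function(profile, dyads = 1:32, sd = 20.5) {
  if (!length(dyads)) stop("dyad list must be nonempty")
  va <- pmin(pmax(rnorm(length(dyads), profile$sv_mean_avoid, sd), 0), 100)
  vp <- pmin(pmax(rnorm(length(dyads), profile$sv_mean_approach, sd), 0), 100)
  data.frame(participant_id = profile$participant_id, dyad_id = dyads,
             value_avoid = va, value_approach = vp,
             sv = (va - vp) / 100)
}

#' Write / read trial tables as CSV
#'
#' Plain-CSV round trip for trial tables; missing RTs are stored as empty
#' fields.
#' @param trials trial data.frame.
#' @param path file path.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"))
  tr$rt[tr$rt == ""] <- NA
  tr$rt <- as.numeric(tr$rt)
  tr
}
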