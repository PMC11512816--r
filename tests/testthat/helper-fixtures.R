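# Shared fixtures built in code.  Heavier objects are cached per session.

.fixture_env <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# filtered threat trials from a small mixed cohort
small_cohort <- function(n = 16, seed = 42) {
  with_cache(sprintf("cohort_%d_%d", n, seed), {
    set.seed(seed)
    simulate_cohort(study_config(n_participants = n))
  })
}

threat_trials <- function(cohort) {
  tr <- cohort$trials[cohort$trials$trial_type == "threat", ]
  filter_anticipations(tr)$kept
}

# a synthetic trial table with known RTs for the anticipation filter
flat_trial_table <- function(n_participants, n_trials, n_anticipations,
                             seed = 7) {
  set.seed(seed)
  n <- n_participants * n_trials
  tr <- data.frame(
    participant_id = rep(sprintf("P%02d", seq_len(n_participants)),
                         each = n_trials),
    trial_index = rep(seq_len(n_trials), n_participants),
    trial_type = "threat",
    condition = rep(c("predictable", "unpredictable"), length.out = n),
    response = sample(c("avoid", "approach"), n, replace = TRUE),
    rt = runif(n, 0.3, 1.2))
  if (n_anticipations > 0) {
    tr$rt[sample(n, n_anticipations)] <- runif(n_anticipations, 0.01, 0.14)
  }
  tr
}

# logistic two-class choice data with known component coefficients
two_class_choices <- function(n_sub = 40, n_trials = 64, sep = 1.2,
                              seed = 11) {
  set.seed(seed)
  cls <- rep(c(1, 2), length.out = n_sub)
  rows <- lapply(seq_len(n_sub), function(i) {
    cond <- rep(c(0, 1), each = n_trials / 2)
    rt <- runif(n_trials, 0.3, 1.2)
    b0 <- if (cls[i] == 1) sep else 0
    b1 <- if (cls[i] == 2 && sep > 0) 0.6 else 0
    eta <- b0 + b1 * cond
    y <- rbinom(n_trials, 1, plogis(eta))
    data.frame(participant_id = sprintf("P%02d", i),
               trial_index = seq_len(n_trials),
               trial_type = "threat",
               condition = ifelse(cond == 1, "predictable", "unpredictable"),
               response = ifelse(y == 1, "avoid", "approach"),
               rt = rt, true_class = cls[i])
  })
  do.call(rbind, rows)
}
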