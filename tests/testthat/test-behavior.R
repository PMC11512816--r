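test_that("anticipation filter reproduces the worked removal percentages", {
  f <- filter_anticipations(flat_trial_table(60, 64, 7))
  expect_equal(f$n_removed, 7)
  expect_equal(f$pct_removed, 0.18)
  expect_equal(nrow(f$kept), 3833)

  f2 <- filter_anticipations(flat_trial_table(30, 64, 1))
  expect_equal(f2$n_removed, 1)
  expect_equal(f2$pct_removed, 0.05)
  expect_equal(nrow(f2$kept), 1919)

  f3 <- filter_anticipations(flat_trial_table(60, 64, 4))
  expect_equal(f3$pct_removed, 0.1)

  f0 <- filter_anticipations(flat_trial_table(10, 64, 0))
  expect_equal(f0$n_removed, 0)
  expect_equal(f0$pct_removed, 0)
  expect_error(filter_anticipations(flat_trial_table(1, 64, 0)[0, ]), "empty")
})

test_that("anticipation filter is idempotent and counts non-responses apart", {
  tr <- flat_trial_table(10, 64, 3)
  tr$rt[1:5] <- NA
  f1 <- filter_anticipations(tr)
  expect_equal(f1$n_nonresponse, 5)
  f2 <- filter_anticipations(f1$kept)
  expect_equal(f2$n_removed, 0)
  expect_identical(f1$kept, f2$kept)
})

test_that("avoidance summary computes exact cell proportions and flags empties", {
  tr <- flat_trial_table(1, 64, 0)
  ## conditions alternate, so a period-4 pattern gives 50/50 per condition
  tr$response <- rep(c("avoid", "avoid", "approach", "approach"), 16)
  s <- avoidance_summary(tr)
  expect_equal(s$p_avoid, c(0.5, 0.5))
  tr$response <- "avoid"
  s2 <- avoidance_summary(tr)
  expect_equal(s2$p_avoid, c(1, 1))
  ## empty cell flagged
  tr3 <- tr[tr$condition == "predictable", ]
  s3 <- avoidance_summary(tr3)
  expect_true(s3$empty_cell[s3$condition == "unpredictable"])
  expect_true(is.na(s3$p_avoid[s3$condition == "unpredictable"]))
})

test_that("hierarchical logistic model recovers a planted condition effect", {
  set.seed(31)
  ## 40 participants, true condition effect 0.5, random SD 0.3
  n_sub <- 40; n_tr <- 64
  rows <- lapply(seq_len(n_sub), function(i) {
    u0 <- rnorm(1, 0, 0.3); u1 <- rnorm(1, 0, 0.3)
    cond <- rep(c(0, 1), each = n_tr / 2)
    eta <- 0.3 + u0 + (0.5 + u1) * cond
    data.frame(participant_id = sprintf("P%02d", i),
               trial_index = seq_len(n_tr), trial_type = "threat",
               condition = ifelse(cond == 1, "predictable", "unpredictable"),
               response = ifelse(rbinom(n_tr, 1, plogis(eta)) == 1,
                                 "avoid", "approach"),
               rt = runif(n_tr, 0.3, 1.2))
  })
  tr <- do.call(rbind, rows)
  fit <- fit_hierarchical_logistic(tr, terms = "condition",
                                   n_iter = 2500, n_warmup = 500,
                                   n_chains = 2, thin = 2)
  s <- suppressWarnings(summarize_effect(fit, "condition"))
  expect_lt(abs(s$median - 0.5), 0.2)
  expect_true(s$ci_low < 0.5 && 0.5 < s$ci_high)
  ## treatment-coding invariant: P(avoid | unpredictable, rt at mean) is
  ## logistic(intercept) at the draw level
  expect_true(all(plogis(fit$beta[, "intercept"]) > 0 &
                    plogis(fit$beta[, "intercept"]) < 1))
  expect_true(all(fit$rhat < 1.1, na.rm = TRUE))
})

test_that("WAIC prefers the generating model and is row-order invariant", {
  set.seed(32)
  tr <- two_class_choices(n_sub = 24, n_trials = 48, sep = 0)
  ## strong condition effect in both classes
  cond <- as.numeric(tr$condition == "predictable")
  tr$response <- ifelse(rbinom(nrow(tr), 1, plogis(-0.3 + 1.2 * cond)) == 1,
                        "avoid", "approach")
  mc <- list(n_iter = 1200, n_warmup = 400, n_chains = 2, thin = 2)
  f_cond <- do.call(fit_hierarchical_logistic,
                    c(list(tr, terms = "condition"), mc))
  f_null <- do.call(fit_hierarchical_logistic,
                    c(list(tr, terms = character(0)), mc))
  cmp <- compare_waic(list(condition = f_cond, intercept_only = f_null))
  expect_equal(cmp$model[1], "condition")
  expect_gt(cmp$delta[2], 2)
  ## row-order invariance
  set.seed(33)
  perm <- sample(nrow(tr))
  f_perm <- do.call(fit_hierarchical_logistic,
                    c(list(tr[perm, ], terms = "condition"), mc))
  cmp2 <- compare_waic(list(a = f_cond, b = f_perm))
  expect_lt(abs(cmp2$waic[1] - cmp2$waic[2]), 6) # MC error only
  ## mismatched data rejected
  expect_error(compare_waic(list(a = f_cond,
                                 b = do.call(fit_hierarchical_logistic,
                                             c(list(tr[1:500, ], terms = "condition"), mc)))),
               "identical data")
})

test_that("Savage-Dickey summaries behave at the no-data and symmetric limits", {
  ## symmetric posterior centred at zero
  fake <- structure(list(terms = "condition",
                         beta = cbind(condition = rnorm(20000, 0, 1)),
                         prior_sd_coef = 2.5),
                    class = "choice_fit")
  s <- summarize_effect(fake, "condition")
  expect_equal(s$p_below_zero, 0.5, tolerance = 0.02)
  expect_equal(s$p_above_zero, 0.5, tolerance = 0.02)
  ## posterior equal to the prior: BF10 ~ 1
  fake$beta <- cbind(condition = rnorm(40000, 0, 2.5))
  s2 <- summarize_effect(fake, "condition")
  expect_equal(s2$bf10, 1, tolerance = 0.08)
  ## conjugate normal oracle: prior N(0, 2.5^2), likelihood ybar ~ N(mu, s2/n)
  set.seed(34)
  n <- 25; sig <- 2; ybar <- 0.8
  post_var <- 1 / (1 / 2.5^2 + n / sig^2)
  post_mean <- post_var * (n * ybar / sig^2)
  fake$beta <- cbind(condition = rnorm(2e5, post_mean, sqrt(post_var)))
  s3 <- summarize_effect(fake, "condition")
  bf_analytic <- dnorm(0, 0, 2.5) / dnorm(0, post_mean, sqrt(post_var))
  expect_equal(s3$bf10, bf_analytic, tolerance = 0.05)
  expect_error(summarize_effect(fake, "not_a_term"), "unknown")
})

test_that("Wilcoxon against chance matches exact enumeration and handles ties", {
  ## n = 5 all above chance: V = 15, two-sided exact p = 2/32
  r <- wilcoxon_vs_chance(c(0.6, 0.7, 0.55, 0.8, 0.65), n_boot = 200)
  expect_equal(r$V, 15)
  expect_equal(r$p_value, 0.0625)
  ## all exactly at chance: degenerate
  r2 <- wilcoxon_vs_chance(rep(0.5, 8), n_boot = 10)
  expect_true(r2$degenerate)
  expect_equal(r2$p_value, 1)
  ## antisymmetric sample: V at its null median n(n+1)/4
  x <- 0.5 + c(-0.2, -0.1, -0.05, 0.05, 0.1, 0.2)
  r3 <- wilcoxon_vs_chance(x, n_boot = 10)
  expect_equal(unname(r3$V), 6 * 7 / 4)
})

test_that("paired t-test matches the direct formula and flags degeneracy", {
  set.seed(35)
  a <- rnorm(10, 1, 1); b <- rnorm(10, 0, 1)
  r <- paired_ttest(a, b, n_boot = 200)
  d <- a - b
  t_manual <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(r$t, t_manual, tolerance = 1e-10)
  expect_equal(r$df, 9)
  expect_equal(r$cohens_d, mean(d) / sd(d))
  ## identical vectors: t = 0, p = 1
  r2 <- paired_ttest(a, a, n_boot = 10)
  expect_true(r2$degenerate)
  expect_equal(r2$t, 0)
  expect_equal(r2$p_value, 1)
  ## constant nonzero differences: infinite-t degenerate flag
  r3 <- paired_ttest(a + 1, a, n_boot = 10)
  expect_true(r3$degenerate)
  expect_equal(r3$t, Inf)
})

test_that("value-integration model rejects degenerate designs and drops unmerged trials", {
  co <- small_cohort(n = 6, seed = 51)
  tr <- threat_trials(co)
  hr <- data.frame(participant_id = tr$participant_id,
                   trial_index = tr$trial_index,
                   hr_z = rnorm(nrow(tr)))
  sv0 <- do.call(rbind, lapply(unique(tr$participant_id), function(p)
    data.frame(participant_id = p, dyad_id = 1:32, sv = 0)))
  expect_error(fit_value_integration_model(tr, hr, sv0), "zero variance")
})

test_that("power simulation calibrates to alpha under the null and saturates", {
  set.seed(36)
  null_pars <- list(fixed = c(0.2, 0), sd_intercept = 0.3, sd_condition = 0.2)
  p0 <- power_simulation(null_pars, sample_sizes = 20, n_sims = 60,
                         n_trials_per_cond = 16)
  expect_lt(p0$power, 0.18)   # ~alpha within binomial error at 60 sims
  big <- list(fixed = c(0, 2.5), sd_intercept = 0.3, sd_condition = 0.2)
  p1 <- power_simulation(big, sample_sizes = 20, n_sims = 25,
                         n_trials_per_cond = 16)
  expect_equal(p1$power, 1)
  ## determinism under a fixed seed
  set.seed(99)
  a <- power_simulation(null_pars, sample_sizes = 10, n_sims = 10,
                        n_trials_per_cond = 8)
  set.seed(99)
  b <- power_simulation(null_pars, sample_sizes = 10, n_sims = 10,
                        n_trials_per_cond = 8)
  expect_identical(a, b)
})
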