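# epoch/design fixtures with a known effect structure
make_beta_fixture <- function(n_sub = 20, n_time = 141, effect = 0,
                              span = NULL, noise = 1, seed = 1) {
  set.seed(seed)
  epochs <- list(); designs <- list()
  for (i in seq_len(n_sub)) {
    n_tr <- 32
    cond <- rep(c(-0.5, 0.5), each = n_tr / 2)
    thr <- rep(c(-0.5, 0.5), n_tr / 2)
    rt <- runif(n_tr, 0.3, 1.2)
    vals <- matrix(rnorm(n_tr * n_time, 0, noise), n_tr, n_time)
    if (!is.null(span)) {
      vals[, span] <- vals[, span] + effect * cond
    }
    id <- sprintf("P%02d", i)
    epochs[[id]] <- structure(list(values = vals,
                                   time = seq(-4, 10, length.out = n_time),
                                   trial_index = seq_len(n_tr),
                                   fs_epoch = 10, lock = "stimulus_onset"),
                              class = "epoch_matrix")
    designs[[id]] <- data.frame(trial_index = seq_len(n_tr),
                                condition = cond, threat = thr,
                                outcome = sample(c(-0.5, 0.5), n_tr, TRUE),
                                response = sample(c(-0.5, 0.5), n_tr, TRUE),
                                rt_centered = rt - mean(rt))
  }
  list(epochs = epochs, designs = designs)
}

test_that("design rows use the stated centred contrast codes", {
  tr <- data.frame(trial_index = 1:4,
                   condition = c("predictable", "unpredictable",
                                 "predictable", "unpredictable"),
                   trial_type = c("threat", "threat", "neutral", "neutral"),
                   outcome = c("safe", "threat", NA, NA),
                   response = c("avoid", "approach", NA, NA),
                   rt = c(0.5, 0.7, 0.6, 0.8))
  d <- spm_design(tr)
  expect_equal(d$condition, c(0.5, -0.5, 0.5, -0.5))
  expect_equal(d$threat, c(0.5, 0.5, -0.5, -0.5))
  expect_equal(d$outcome[1:2], c(0.5, -0.5))
  expect_equal(d$response[1:2], c(0.5, -0.5))
  expect_equal(mean(d$rt_centered), 0)
})

test_that("balanced +/-0.5 coding makes the intercept the mean of cell means", {
  fx <- make_beta_fixture(n_sub = 4, n_time = 20, noise = 0.5, seed = 2)
  ## deterministic check on one participant at one time point
  ep <- fx$epochs[[1]]; de <- fx$designs[[1]]
  de$rt_centered <- 0                      # drop rt variation for exactness
  bs <- fit_trialwise_glm(list(P1 = ep), list(P1 = de), formula_id = 1)
  y <- ep$values[, 7]
  cells <- tapply(y, interaction(de$condition, de$threat), mean)
  expect_equal(unname(bs$betas[1, "intercept", 7]), mean(cells),
               tolerance = 1e-10)
})

test_that("a planted condition effect is recovered and trial order is irrelevant", {
  fx <- make_beta_fixture(n_sub = 12, n_time = 60, effect = 0.8,
                          span = 20:35, noise = 0.3, seed = 3)
  bs <- fit_trialwise_glm(fx$epochs, fx$designs, formula_id = 1)
  b_cond <- bs$betas[, "condition", ]
  expect_equal(mean(b_cond[, 25]), 0.8, tolerance = 0.15)
  expect_lt(abs(mean(b_cond[, 5])), 0.15)
  ## permuting each participant's trials leaves betas unchanged
  fx2 <- fx
  for (id in names(fx2$epochs)) {
    perm <- sample(nrow(fx2$epochs[[id]]$values))
    fx2$epochs[[id]]$values <- fx2$epochs[[id]]$values[perm, ]
    fx2$epochs[[id]]$trial_index <- fx2$epochs[[id]]$trial_index[perm]
  }
  bs2 <- fit_trialwise_glm(fx2$epochs, fx2$designs, formula_id = 1)
  expect_equal(bs$betas, bs2$betas, tolerance = 1e-10)
})

test_that("rank-deficient designs yield missing betas for the affected participant", {
  fx <- make_beta_fixture(n_sub = 4, n_time = 20, seed = 4)
  fx$designs[[2]]$response <- 0.5          # no approach responses
  bs <- fit_trialwise_glm(fx$epochs, fx$designs, formula_id = 3)
  expect_true("P02" %in% bs$rank_deficient)
  expect_true(any(is.na(bs$betas[2, , ])))
  expect_false(any(is.na(bs$betas[1, , ])))
})

test_that("cluster formation enforces threshold, sign, and minimum duration", {
  fx0 <- make_beta_fixture(n_sub = 20, n_time = 141, effect = 0, seed = 5)
  bs0 <- fit_trialwise_glm(fx0$epochs, fx0$designs, formula_id = 1)
  ## all-zero betas: no clusters at all
  bs_null <- bs0
  bs_null$betas[] <- 0
  expect_equal(nrow(find_clusters(bs_null, "condition")), 0)
  ## a single-sample (100 ms at 10 Hz) effect cannot exceed the 100 ms
  ## minimum duration: construct the beta series directly so no other
  ## point crosses the threshold
  e <- as.numeric(scale(rnorm(30)))        # exact mean 0 -> t = 0 off-span
  B <- array(0, c(30, 5, 141))
  for (tp in 1:141) B[, 2, tp] <- 0.01 * e
  B[, 2, 60] <- B[, 2, 60] + 1
  bs50 <- structure(list(betas = B, time = seq(-4, 10, length.out = 141),
                         regressors = c("intercept", "condition", "threat",
                                        "condition:threat", "rt_centered"),
                         fs_epoch = 10, formula_id = 1,
                         rank_deficient = character(0)),
                    class = "beta_series")
  dimnames(bs50$betas) <- list(NULL, bs50$regressors, NULL)
  cl50 <- find_clusters(bs50, "condition", min_duration_s = 0.1)
  expect_equal(nrow(cl50), 0)
  ## the same effect over two samples (200 ms) does form a cluster
  bs50$betas[, 2, 61] <- bs50$betas[, 2, 61] + 1
  cl200 <- find_clusters(bs50, "condition", min_duration_s = 0.1)
  expect_equal(nrow(cl200), 1)
  ## a 1.6 s planted effect forms one negative-free positive cluster
  fx <- make_beta_fixture(n_sub = 30, n_time = 141, effect = 0.9,
                          span = 60:75, noise = 0.6, seed = 7)
  bs <- fit_trialwise_glm(fx$epochs, fx$designs, formula_id = 1)
  cl <- find_clusters(bs, "condition", min_duration_s = 0.1)
  expect_gte(nrow(cl), 1)
  main <- cl[which.max(abs(cl$t_mass)), ]
  expect_equal(main$sign, 1)
  ## covers at least 60% of the planted span
  overlap <- length(intersect(main$start_idx:main$end_idx, 60:75))
  expect_gte(overlap / 16, 0.6)
})

test_that("permutation p-values hit the floor for overwhelming effects", {
  fx <- make_beta_fixture(n_sub = 30, n_time = 60, effect = 3,
                          span = 20:40, noise = 0.3, seed = 8)
  bs <- fit_trialwise_glm(fx$epochs, fx$designs, formula_id = 1)
  cl <- find_clusters(bs, "condition", min_duration_s = 0.1)
  res <- cluster_permutation_test(bs, "condition", cl, n_perm = 500)
  main <- res[which.max(abs(res$t_mass)), ]
  expect_equal(main$p_corr, 1 / 500)
  expect_true(main$significant)
  ## sign-flip alternative agrees on this strong effect
  res2 <- cluster_permutation_test(bs, "condition", cl, n_perm = 500,
                                   scheme = "sign_flip")
  expect_true(res2[which.max(abs(res2$t_mass)), ]$significant)
  expect_warning(cluster_permutation_test(bs, "condition", cl, n_perm = 50),
                 "unstable")
})

test_that("cluster inference is invariant to participant ordering", {
  fx <- make_beta_fixture(n_sub = 16, n_time = 60, effect = 1,
                          span = 25:40, noise = 0.5, seed = 9)
  bs <- fit_trialwise_glm(fx$epochs, fx$designs, formula_id = 1)
  perm <- sample(16)
  bs_p <- bs
  bs_p$betas <- bs$betas[perm, , ]
  cl <- find_clusters(bs, "condition")
  cl_p <- find_clusters(bs_p, "condition")
  expect_equal(cl$start_idx, cl_p$start_idx)
  expect_equal(cl$t_mass, cl_p$t_mass, tolerance = 1e-10)
})

test_that("trial-wise iHR change extraction follows the cluster window and fences", {
  ep <- structure(list(values = rbind(c(0, -1, -4, -2, 0, 1),
                                      c(0, -2, -3, -1, 0, 1),
                                      c(0, -1, -2, -1, 0, 1),
                                      c(0, -1.5, -2.5, -1, 0, 1),
                                      c(0, -10, -40, -20, 0, 1)),
                       time = c(-1, 0, 1, 2, 3, 4),
                       trial_index = 1:5, fs_epoch = 1,
                       lock = "stimulus_onset"),
                  class = "epoch_matrix")
  out <- extract_ihr_change(ep, window = c(0, 2))
  expect_equal(out$hr_change_bpm, c(-4, -3, -2, -2.5, -40))
  expect_true(out$rejected[5])             # 10x deceleration fenced out
  expect_equal(mean(out$hr_z, na.rm = TRUE), 0, tolerance = 1e-10)
  expect_error(extract_ihr_change(ep, window = c(8, 9)), "window")
  ## flat epochs cannot be z-scored
  ep$values[] <- 0
  expect_error(extract_ihr_change(ep, window = c(0, 2)), "zero SD")
})
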