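#' Remove anticipation trials
#'
#' Responded trials with RT below \code{min_rt} (default 150 ms) are
#' anticipations and are removed; trials with missing RT (non-responses)
#' are dropped separately with their own count.  The removal percentage is
#' taken over all input trials and rounded to two decimals.
#'
#' @param trials trial data.frame with an \code{rt} column (seconds).
#' @param min_rt anticipation threshold in seconds.
#' @return list: \code{kept} (data.frame), \code{n_removed},
#'   \code{pct_removed}, \code{n_nonresponse}.
#' @export
filter_anticipations <- function(trials, min_rt = 0.150) {
  if (!nrow(trials)) stop("empty trial table")
  n_total <- nrow(trials)
  nonresp <- is.na(trials$rt)
  antic <- !nonresp & trials$rt < min_rt
  kept <- trials[!nonresp & !antic, , drop = FALSE]
  list(kept = kept,
       n_removed = sum(antic),
       pct_removed = round(100 * sum(antic) / n_total, 2),
       n_nonresponse = sum(nonresp))
}

#' Per-participant avoidance rates and median RTs
#'
#' @param trials filtered threat trials with \code{response} and
#'   \code{rt}.
#' @return data.frame: participant_id, condition, n_trials, p_avoid,
#'   median_rt; cells with zero responded trials appear with NA and are
#'   flagged.
#' @export
avoidance_summary <- function(trials) {
  tr <- trials[trials$trial_type == "threat", , drop = FALSE]
  cells <- expand.grid(participant_id = unique(tr$participant_id),
                       condition = c("predictable", "unpredictable"),
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- tr$participant_id == cells$participant_id[i] &
      tr$condition == cells$condition[i] & !is.na(tr$response)
    n <- sum(sel)
    data.frame(cells[i, ], n_trials = n,
               p_avoid = if (n) mean(tr$response[sel] == "avoid") else NA_real_,
               median_rt = if (n) median(tr$rt[sel]) else NA_real_,
               empty_cell = n == 0)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

## Build the fixed/random design matrices for the trial-level choice
## models.  Term vocabulary: "condition" (treatment coded, unpredictable
## = 0), "rt" (grand-average centred over the included trials), "class"
## (treatment coded, SR = 0), "hr" (z-scored iHR change), "sv"
## (subjective value); interactions via ":".
.build_choice_design <- function(trials, terms, rt_center = NULL) {
  y <- as.integer(trials$response == "avoid")
  base <- list(
    condition = as.numeric(trials$condition == "predictable"),
    rt = trials$rt - (rt_center %||% mean(trials$rt)),
    class = if (!is.null(trials$latent_class))
      as.numeric(trials$latent_class == "GD") else NULL,
    hr = trials$hr_z, sv = trials$sv)
  col_of <- function(term) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    v <- rep(1, nrow(trials))
    for (p in parts) {
      if (is.null(base[[p]])) stop(sprintf("term '%s' not available in data", p))
      v <- v * base[[p]]
    }
    v
  }
  X <- cbind(intercept = 1,
             vapply(terms, col_of, numeric(nrow(trials))))
  colnames(X) <- c("intercept", terms)
  list(y = y, X = X,
       rt_center = rt_center %||%
         (if ("rt" %in% unlist(strsplit(terms, ":"))) mean(trials$rt) else NA))
}

#' Hierarchical Bayesian logistic regression of avoidance choices
#'
#' Trial-level logistic model of the binary avoidance indicator
#' (avoid = 1) with participant-level random effects, fit by MCMC through
#' JAGS.  Priors follow the package defaults: normal(0, 2.5) on
#' regression coefficients and exponential(2) on random-effect SDs.
#' Random effects are independent across terms (a diagonal covariance;
#' see the methods vignette for the rationale).
#'
#' @param trials filtered threat trials; needs \code{response},
#'   \code{participant_id} and the columns the terms require.
#' @param terms character vector of fixed-effect terms (see Details in
#'   \code{.build_choice_design}); the intercept is always included.
#' @param random_terms terms (plus "intercept") that get per-participant
#'   random slopes; defaults to the maximal structure, i.e. the intercept
#'   and every within-participant term.
#' @param n_chains,n_iter,n_warmup,thin MCMC settings (paper-scale
#'   defaults: 3 chains x 10,000 iterations, 2,000 warm-up).
#' @param prior_sd_coef coefficient prior SD (2.5).
#' @param prior_rate_sd random-effect SD prior rate (2).
#' @param quiet suppress JAGS progress.
#' @return object of class \code{choice_fit} with draws, pointwise
#'   log-likelihood, WAIC ingredients, and convergence diagnostics
#'   (split R-hat, effective sample size).
#' @export
fit_hierarchical_logistic <- function(trials, terms = c("condition", "rt", "condition:rt"),
                                      random_terms = NULL,
                                      n_chains = 3, n_iter = 10000,
                                      n_warmup = 2000, thin = 8,
                                      prior_sd_coef = 2.5, prior_rate_sd = 2,
                                      rt_center = NULL, quiet = TRUE) {
  trials <- trials[!is.na(trials$response), , drop = FALSE]
  if (length(unique(trials$participant_id)) < 2)
    stop("need at least 2 participants")
  des <- .build_choice_design(trials, terms, rt_center)
  X <- des$X; y <- des$y
  pid <- factor(trials$participant_id)
  pidx <- as.integer(pid)
  n_sub <- nlevels(pid)

  ## between-participant terms (e.g. class) cannot carry random slopes
  within_ok <- vapply(colnames(X), function(cn) {
    if (cn == "intercept") return(TRUE)
    v <- tapply(X[, cn], pidx, function(z) length(unique(z)))
    any(v > 1)
  }, TRUE)
  if (is.null(random_terms)) {
    random_terms <- colnames(X)[within_ok]
  } else {
    random_terms <- intersect(random_terms, colnames(X)[within_ok])
  }
  Z <- X[, random_terms, drop = FALSE]

  model_str <- "
model {
  for (n in 1:N) {
    y[n] ~ dbern(p[n])
    logit(p[n]) <- inprod(X[n, ], beta[]) + inprod(Z[n, ], u[pid[n], ])
  }
  for (j in 1:P) { beta[j] ~ dnorm(0, prec_b) }
  for (i in 1:S) {
    for (k in 1:K) { u[i, k] ~ dnorm(0, tau[k]) }
  }
  for (k in 1:K) {
    sd_u[k] ~ dexp(rate_sd)
    tau[k] <- pow(sd_u[k], -2)
  }
}"
  dat <- list(y = y, X = X, Z = Z, pid = pidx, N = length(y),
              P = ncol(X), S = n_sub, K = ncol(Z),
              prec_b = 1 / prior_sd_coef^2, rate_sd = prior_rate_sd)
  jm <- rjags::jags.model(textConnection(model_str), data = dat,
                          n.chains = n_chains, quiet = quiet,
                          n.adapt = max(500, n_warmup %/% 2))
  update(jm, n_warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("beta", "sd_u", "u"),
                              n.iter = n_iter - n_warmup, thin = thin,
                              progress.bar = "none")

  ## coda drops the index on length-1 monitored vectors
  fix_name <- function(obj, base, k) {
    if (k == 1 && base %in% coda::varnames(obj)) {
      coda::varnames(obj)[coda::varnames(obj) == base] <- paste0(base, "[1]")
    }
    obj
  }
  samp <- fix_name(samp, "beta", ncol(X))
  samp <- fix_name(samp, "sd_u", ncol(Z))
  beta_cols <- paste0("beta[", seq_len(ncol(X)), "]")
  rhat <- tryCatch(
    coda::gelman.diag(samp[, beta_cols, drop = FALSE],
                      autoburnin = FALSE, multivariate = FALSE)$psrf[, 1],
    error = function(e) rep(NA_real_, ncol(X)))
  ess <- tryCatch(coda::effectiveSize(samp[, beta_cols, drop = FALSE]),
                  error = function(e) rep(NA_real_, ncol(X)))

  draws <- as.matrix(samp)
  beta_draws <- draws[, beta_cols, drop = FALSE]
  colnames(beta_draws) <- colnames(X)
  sd_draws <- draws[, paste0("sd_u[", seq_len(ncol(Z)), "]"), drop = FALSE]
  colnames(sd_draws) <- paste0("sd_", colnames(Z))

  ## pointwise log-likelihood for WAIC
  n_draw <- nrow(draws)
  ll <- matrix(NA_real_, n_draw, length(y))
  u_names <- outer(seq_len(n_sub), seq_len(ncol(Z)),
                   function(i, k) paste0("u[", i, ",", k, "]"))
  for (s in seq_len(n_draw)) {
    u_s <- matrix(draws[s, u_names], n_sub, ncol(Z))
    eta <- as.numeric(X %*% beta_draws[s, ]) + rowSums(Z * u_s[pidx, , drop = FALSE])
    pr <- plogis(eta)
    ll[s, ] <- dbinom(y, 1, pr, log = TRUE)
  }

  structure(list(terms = colnames(X), random_terms = colnames(Z),
                 beta = beta_draws, sd_u = sd_draws,
                 loglik_pointwise = ll,
                 rhat = setNames(rhat, colnames(X)),
                 ess = setNames(as.numeric(ess), colnames(X)),
                 rt_center = des$rt_center,
                 prior_sd_coef = prior_sd_coef,
                 y = y, n_sub = n_sub,
                 data_fingerprint = c(n = length(y), sum_y = sum(y))),
            class = "choice_fit")
}

#' @export
print.choice_fit <- function(x, ...) {
  cat("Hierarchical logistic choice model\n")
  cat("  terms:", paste(x$terms, collapse = ", "), "\n")
  cat("  random slopes:", paste(x$random_terms, collapse = ", "), "\n")
  sm <- do.call(rbind, lapply(seq_along(x$terms), function(j)
    summarize_draws(x$beta[, j])))
  rownames(sm) <- x$terms
  print(round(cbind(sm, rhat = x$rhat, ess = round(x$ess)), 3))
  invisible(x)
}

#' WAIC model comparison
#'
#' Widely applicable information criterion from pointwise log-likelihood
#' draws; lower is better.  All fits must be on the same data rows.
#'
#' @param fits named list of \code{choice_fit} objects.
#' @return data.frame with waic, p_waic, delta, ranked best first.
#' @export
compare_waic <- function(fits) {
  fp <- vapply(fits, function(f) paste(f$data_fingerprint, collapse = "/"), "")
  if (length(unique(fp)) != 1) stop("fits are not on identical data rows")
  one <- function(f) {
    ll <- f$loglik_pointwise
    lpd <- sum(apply(ll, 2, function(v) {
      m <- max(v); m + log(mean(exp(v - m)))
    }))
    p_waic <- sum(apply(ll, 2, var))
    c(waic = -2 * (lpd - p_waic), p_waic = p_waic)
  }
  tab <- t(vapply(fits, one, c(waic = 0, p_waic = 0)))
  out <- data.frame(model = names(fits) %||% seq_along(fits),
                    waic = tab[, "waic"], p_waic = tab[, "p_waic"])
  out$delta <- out$waic - min(out$waic)
  out[order(out$waic), ]
}

#' Posterior summary with Savage-Dickey Bayes factor
#'
#' Posterior median, central 95% credible interval, posterior mass below
#' and above the null, and a Savage-Dickey density-ratio Bayes factor:
#' BF10 = prior density at the null / posterior density at the null,
#' against the fit's normal(0, prior SD) coefficient prior.
#'
#' @param fit a \code{choice_fit}.
#' @param parameter name of the coefficient (one of \code{fit$terms}).
#' @param null_value point null (default 0).
#' @return one-row data.frame; also reports BF01 = 1/BF10 and a
#'   \code{wide_interval_flag} when the density estimate at the null rests
#'   on few draws.
#' @export
summarize_effect <- function(fit, parameter, null_value = 0) {
  if (!parameter %in% fit$terms) stop(sprintf("unknown parameter '%s'", parameter))
  x <- fit$beta[, parameter]
  s <- summarize_draws(x)
  dens <- density(x, n = 2048)
  post0 <- approx(dens$x, dens$y, xout = null_value, rule = 2)$y
  prior0 <- dnorm(null_value, 0, fit$prior_sd_coef)
  near <- mean(abs(x - null_value) < 2 * dens$bw)
  flag <- near < 0.005
  if (flag) warning("few draws near the null; Savage-Dickey BF is unstable")
  bf10 <- prior0 / max(post0, .Machine$double.eps)
  cbind(s, data.frame(bf10 = bf10, bf01 = 1 / bf10,
                      wide_interval_flag = flag))
}

#' Wilcoxon signed-rank test against chance
#'
#' Two-sided signed-rank test of per-participant avoidance rates against
#' a chance level, with Cohen's d on the differences and a bootstrap
#' confidence interval for d.
#'
#' @param p_avoid numeric vector of per-participant avoidance rates.
#' @param chance null value (0.5).
#' @param n_boot bootstrap resamples for the d interval.
#' @return list: V, p_value, cohens_d, ci_d, degenerate flag.
#' @export
wilcoxon_vs_chance <- function(p_avoid, chance = 0.5, n_boot = 10000) {
  d <- p_avoid - chance
  nz <- d[d != 0]
  if (!length(nz)) {
    return(list(V = 0, p_value = 1, cohens_d = 0,
                ci_d = c(NA, NA), degenerate = TRUE))
  }
  wt <- suppressWarnings(wilcox.test(p_avoid, mu = chance, exact = length(nz) < 50))
  cd <- mean(d) / sd(d)
  boots <- replicate(n_boot, {
    b <- sample(d, replace = TRUE)
    if (sd(b) == 0) NA_real_ else mean(b) / sd(b)
  })
  list(V = unname(wt$statistic), p_value = wt$p.value, cohens_d = cd,
       ci_d = unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE)),
       degenerate = FALSE)
}

#' Paired t-test with assumption checks
#'
#' Two-sided paired t-test plus a Shapiro-Wilk normality check on the
#' differences and a Levene homogeneity-of-variance check across the two
#' sets of values, reported alongside.  Cohen's d is computed on the
#' differences with a bootstrap interval.
#'
#' @param values_a,values_b paired numeric vectors.
#' @param n_boot bootstrap resamples.
#' @return list with t, df, p_value, cohens_d, ci_d, shapiro_p, levene_p,
#'   and a \code{degenerate} flag when the differences have zero variance.
#' @export
paired_ttest <- function(values_a, values_b, n_boot = 10000) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 3)
  d <- values_a - values_b
  if (sd(d) < 1e-10 * max(abs(d), 1)) {
    return(list(t = if (mean(d) == 0) 0 else Inf,
                df = length(d) - 1, p_value = if (mean(d) == 0) 1 else 0,
                cohens_d = NA_real_, ci_d = c(NA, NA),
                shapiro_p = NA_real_, levene_p = NA_real_,
                degenerate = TRUE))
  }
  tt <- t.test(values_a, values_b, paired = TRUE)
  sw <- shapiro.test(d)
  lev <- car::leveneTest(
    y = c(values_a, values_b),
    group = factor(rep(c("a", "b"), each = length(values_a))))
  cd <- mean(d) / sd(d)
  boots <- replicate(n_boot, {
    b <- sample(d, replace = TRUE)
    if (sd(b) == 0) NA_real_ else mean(b) / sd(b)
  })
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, cohens_d = cd,
       ci_d = unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE)),
       shapiro_p = sw$p.value, levene_p = lev[["Pr(>F)"]][1],
       degenerate = FALSE)
}

#' Value-integration model of avoidance choices
#'
#' Hierarchical logistic model of avoidance with Condition, centred RT,
#' trial-wise iHR change (z-scored), dyad-wise subjective value, and all
#' their interactions up to the four-way term.  iHR change is merged by
#' participant and trial, subjective value by participant and dyad;
#' trials missing either covariate are dropped with a reported count.
#'
#' @param trials filtered threat trials.
#' @param hr_change data.frame participant_id, trial_index, hr_z.
#' @param sv_table data.frame participant_id, dyad_id, sv.
#' @param random_terms random-slope structure; defaults to intercept plus
#'   condition (the full four-way random structure is not identified at
#'   task-scale trial counts).
#' @param ... MCMC settings passed to
#'   \code{\link{fit_hierarchical_logistic}}.
#' @return a \code{choice_fit}; the four-way
#'   \code{condition:rt:hr:sv} term is the target of inference.
#' @export
fit_value_integration_model <- function(trials, hr_change, sv_table,
                                        random_terms = c("intercept", "condition"),
                                        ...) {
  tr <- merge(trials, hr_change, by = c("participant_id", "trial_index"))
  tr <- merge(tr, sv_table[, c("participant_id", "dyad_id", "sv")],
              by = c("participant_id", "dyad_id"))
  n_dropped <- nrow(trials) - nrow(tr)
  tr <- tr[!is.na(tr$hr_z) & !is.na(tr$sv) & !is.na(tr$response), , drop = FALSE]
  if (!nrow(tr)) stop("no trials with both iHR change and subjective value")
  if (sd(tr$sv) == 0) stop("subjective value has zero variance; sv terms are unidentifiable")
  if (sd(tr$hr_z) == 0) stop("iHR change has zero variance; hr terms are unidentifiable")
  vars <- c("condition", "rt", "hr", "sv")
  terms <- unlist(lapply(1:4, function(k)
    combn(vars, k, paste, collapse = ":", simplify = TRUE)))
  fit <- fit_hierarchical_logistic(tr, terms = terms,
                                   random_terms = random_terms, ...)
  fit$n_dropped_missing <- n_dropped
  fit
}

#' Simulation-based power analysis
#'
#' Simulates artificial cohorts from seed fixed effects and random-effect
#' SDs, refits a frequentist mixed-effects logistic model to each, and
#' reports power as the proportion of datasets with a significant Wald
#' test (p < alpha) on the target coefficient.  Refit failures are counted
#' separately, not as non-significant.
#'
#' @param params list: \code{fixed} = c(intercept, condition),
#'   \code{sd_intercept}, \code{sd_condition} (on the logit scale).
#' @param sample_sizes integer vector of cohort sizes to evaluate.
#' @param n_sims simulated datasets per sample size (default 1000).
#' @param alpha significance level.
#' @param n_trials_per_cond trials per condition per participant (32).
#' @param target_term coefficient tested ("condition").
#' @return data.frame: n, power, n_failed.
#' @export
power_simulation <- function(params, sample_sizes, n_sims = 1000,
                             alpha = 0.05, n_trials_per_cond = 32,
                             target_term = "condition") {
  stopifnot(all(c("fixed", "sd_intercept", "sd_condition") %in% names(params)))
  res <- lapply(sample_sizes, function(n) {
    sig <- 0L; fail <- 0L
    for (s in seq_len(n_sims)) {
      u0 <- rnorm(n, 0, params$sd_intercept)
      u1 <- rnorm(n, 0, params$sd_condition)
      pid <- rep(seq_len(n), each = 2 * n_trials_per_cond)
      cond <- rep(rep(c(0, 1), each = n_trials_per_cond), n)
      eta <- params$fixed[1] + u0[pid] + (params$fixed[2] + u1[pid]) * cond
      y <- rbinom(length(eta), 1, plogis(eta))
      fit <- tryCatch(
        suppressMessages(suppressWarnings(
          lme4::glmer(y ~ cond + (1 + cond | pid),
                      data = data.frame(y = y, cond = cond, pid = pid),
                      family = binomial, nAGQ = 0L,
                      control = lme4::glmerControl(calc.derivs = FALSE)))),
        error = function(e) NULL)
      if (is.null(fit)) { fail <- fail + 1L; next }
      cf <- summary(fit)$coefficients
      p <- cf["cond", "Pr(>|z|)"]
      if (!is.na(p) && p < alpha) sig <- sig + 1L
    }
    data.frame(n = n, power = sig / (n_sims - fail), n_failed = fail)
  })
  do.call(rbind, res)
}
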