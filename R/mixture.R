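#' Finite mixture of logistic choice models
#'
#' EM estimation of a K-component mixture of fixed-effect logistic
#' regressions of the avoidance indicator, with participants as the
#' mixture units: a participant's responsibility for a component is
#' computed from the product of that participant's trial likelihoods.
#' The component model is the trial-level choice model
#' (intercept + condition + centred RT + condition:RT by default).
#'
#' Components are canonically ordered by descending avoidance intercept
#' before reporting, so the higher-avoidance ("SR-like") component is
#' reproducibly component 1.
#'
#' @param trials filtered threat trials with \code{response},
#'   \code{participant_id}, \code{condition}, \code{rt}.
#' @param K number of mixture components (>= 1).
#' @param terms fixed-effect terms of the component model.
#' @param max_iter EM iteration cap (default 1000).
#' @param n_restarts random restarts; the best restart by log-likelihood
#'   is returned.  The first restart is initialized from a quantile split
#'   of per-participant avoidance rates, the others from Dirichlet-random
#'   responsibilities.
#' @param tol relative log-likelihood convergence tolerance.
#' @param rt_center RT centring value shared with the behavioural stage
#'   (default: grand mean over the supplied trials).
#' @return object of class \code{mixture_fit}: component coefficients,
#'   mixing proportions, per-participant responsibilities,
#'   log-likelihood, BIC, iteration count.
#' @export
mixture_em <- function(trials, K, terms = c("condition", "rt", "condition:rt"),
                       max_iter = 1000, n_restarts = 20, tol = 1e-6,
                       rt_center = NULL) {
  stopifnot(K >= 1)
  trials <- trials[!is.na(trials$response), , drop = FALSE]
  des <- .build_choice_design(trials, terms, rt_center)
  X <- des$X; y <- des$y
  pid <- factor(trials$participant_id)
  pidx <- as.integer(pid)
  n_sub <- nlevels(pid)
  n_coef <- ncol(X)

  ## weighted logistic IRLS with warm start (a few steps per M-step call
  ## suffice since EM iterates refine the same solution)
  irls <- function(w, beta0, n_steps = 25) {
    beta <- beta0
    for (s in seq_len(n_steps)) {
      eta <- as.numeric(X %*% beta)
      mu <- plogis(eta)
      wt <- pmax(w * mu * (1 - mu), 1e-10)
      z <- eta + (y - mu) / pmax(mu * (1 - mu), 1e-10)
      ## normal equations: p is tiny (4), so this beats a QR of n x p
      Xw <- X * wt
      new_beta <- tryCatch(
        solve(crossprod(Xw, X), crossprod(Xw, z)),
        error = function(e) NULL)
      if (is.null(new_beta)) break
      new_beta <- as.numeric(new_beta)
      if (max(abs(new_beta - beta)) < 1e-8) { beta <- new_beta; break }
      beta <- new_beta
    }
    beta
  }

  trial_ll <- function(beta) {
    eta <- as.numeric(X %*% beta)
    ## log Bernoulli likelihood per trial
    -log1p(exp(-ifelse(y == 1, eta, -eta)))
  }

  run_once <- function(resp0) {
    resp <- resp0                       # n_sub x K responsibilities
    beta <- matrix(0, n_coef, K)
    prop <- rep(1 / K, K)
    ll_old <- -Inf
    n_iter_used <- max_iter
    collapse <- FALSE
    for (it in seq_len(max_iter)) {
      ## M-step: weighted logistic fits, trial weights = participant resp
      for (k in seq_len(K)) {
        w <- resp[pidx, k]
        ## warm-started partial M-steps (generalized EM): a couple of
        ## IRLS steps per iteration converge to the same fixed point
        beta[, k] <- irls(w, beta[, k], n_steps = if (it <= 2) 25 else 2)
      }
      prop <- colMeans(resp)
      if (any(prop < 1 / (10 * n_sub))) { collapse <- TRUE; break }
      ## E-step: participant-level responsibilities
      lmat <- vapply(seq_len(K), function(k) trial_ll(beta[, k]),
                     numeric(length(y)))
      s_ik <- rowsum(lmat, pidx)                  # n_sub x K trial-sums
      s_ik <- sweep(s_ik, 2, log(prop), "+")
      m <- apply(s_ik, 1, max)
      wmat <- exp(s_ik - m)
      ll <- sum(m + log(rowSums(wmat)))
      resp <- wmat / rowSums(wmat)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
        ll_old <- ll; n_iter_used <- it; break
      }
      ll_old <- ll
    }
    list(beta = beta, prop = prop, resp = resp, loglik = ll_old,
         n_iter = n_iter_used, collapsed = collapse)
  }

  ## initial responsibilities
  p_av <- tapply(y, pidx, mean)
  inits <- vector("list", n_restarts)
  qcut <- if (K == 1) rep(1L, n_sub) else {
    as.integer(cut(rank(p_av, ties.method = "first"), K, labels = FALSE))
  }
  r1 <- matrix(0.1 / max(K - 1, 1), n_sub, K)
  if (K == 1) r1[] <- 1 else for (i in seq_len(n_sub)) r1[i, qcut[i]] <- 0.9
  inits[[1]] <- r1
  for (r in seq_len(n_restarts)[-1]) {
    g <- matrix(rgamma(n_sub * K, 1), n_sub, K)
    inits[[r]] <- g / rowSums(g)
  }

  best <- NULL
  n_collapsed <- 0
  for (r in seq_len(n_restarts)) {
    res <- run_once(inits[[r]])
    if (res$collapsed) { n_collapsed <- n_collapsed + 1; next }
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (is.null(best))
    stop(sprintf("all %d restarts collapsed a component; reduce K", n_restarts))
  if (n_collapsed > 0 && n_collapsed >= n_restarts / 2)
    warning(sprintf("%d/%d restarts collapsed a component; K may be too large",
                    n_collapsed, n_restarts))

  ## canonical ordering by avoidance intercept, descending
  ord <- order(best$beta[1, ], decreasing = TRUE)
  beta <- best$beta[, ord, drop = FALSE]
  colnames(beta) <- paste0("comp", seq_len(K))
  rownames(beta) <- colnames(X)
  resp <- best$resp[, ord, drop = FALSE]
  colnames(resp) <- colnames(beta)
  rownames(resp) <- levels(pid)
  n_par <- K * n_coef + (K - 1)
  structure(list(K = K, coefficients = beta,
                 mixing_proportions = best$prop[ord],
                 responsibilities = resp,
                 log_likelihood = best$loglik,
                 bic = -2 * best$loglik + n_par * log(n_sub),
                 n_par = n_par, n_participants = n_sub,
                 n_em_iterations = best$n_iter,
                 rt_center = des$rt_center,
                 n_collapsed_restarts = n_collapsed),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Logistic mixture: K = %d, logLik = %.2f, BIC = %.1f (%d iters)\n",
              x$K, x$log_likelihood, x$bic, x$n_em_iterations))
  cat("mixing proportions:", round(x$mixing_proportions, 3), "\n")
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Select the number of latent classes by BIC
#'
#' Fits the mixture for each component count in \code{K_range} (with
#' restarts) and returns the BIC-minimizing K.  BIC uses the number of
#' participants (the independent mixture units) as the sample size; an
#' alternative trial-count penalty is available via
#' \code{bic_n = "trials"}.
#'
#' @inheritParams mixture_em
#' @param K_range candidate component counts (default 1:5).
#' @param bic_n "participants" (default) or "trials".
#' @return list: \code{best_K}, \code{table} (K, loglik, n_par, BIC,
#'   failure reasons), \code{fits}.
#' @export
mixture_select_K <- function(trials, K_range = 1:5,
                             terms = c("condition", "rt", "condition:rt"),
                             n_restarts = 20, max_iter = 1000, tol = 1e-6,
                             rt_center = NULL, bic_n = c("participants", "trials")) {
  bic_n <- match.arg(bic_n)
  stopifnot(length(K_range) >= 1)
  fits <- list(); rows <- list()
  for (K in K_range) {
    f <- tryCatch(
      mixture_em(trials, K, terms = terms, n_restarts = n_restarts,
                 max_iter = max_iter, tol = tol, rt_center = rt_center),
      error = function(e) e)
    if (inherits(f, "error")) {
      rows[[as.character(K)]] <- data.frame(K = K, loglik = NA, n_par = NA,
                                            bic = NA, reason = conditionMessage(f))
      next
    }
    bic <- if (bic_n == "participants") f$bic else {
      n_tr <- sum(!is.na(trials$response))
      -2 * f$log_likelihood + f$n_par * log(n_tr)
    }
    fits[[as.character(K)]] <- f
    rows[[as.character(K)]] <- data.frame(K = K, loglik = f$log_likelihood,
                                          n_par = f$n_par, bic = bic,
                                          reason = NA_character_)
  }
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$bic))) stop("no component count could be fit")
  best_K <- tab$K[which.min(tab$bic)]
  list(best_K = best_K, table = tab, fits = fits)
}

#' Hard class assignment from a mixture fit
#'
#' Maximum-responsibility labels per participant; exact ties go to the
#' lower component index and are flagged.
#'
#' @param fit a \code{mixture_fit}.
#' @return data.frame: participant_id, component, max_responsibility,
#'   tie_flag.
#' @export
mixture_assign <- function(fit) {
  r <- fit$responsibilities
  comp <- apply(r, 1, which.max)
  mx <- r[cbind(seq_len(nrow(r)), comp)]
  tie <- apply(r, 1, function(v) sum(abs(v - max(v)) < 1e-12) > 1)
  data.frame(participant_id = rownames(r), component = comp,
             max_responsibility = mx, tie_flag = tie,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b label vectors of equal length.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}
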