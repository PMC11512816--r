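#' Drift-diffusion model parameters
#'
#' Container for the three free parameters of the unbiased Wiener diffusion
#' decision model used throughout the package: drift-rate \code{v} (signed
#' toward the avoidance boundary), boundary separation \code{a}, and
#' non-decision time \code{t0}.  The start point is always fixed midway
#' between the boundaries (z = a/2) and the diffusion coefficient is fixed
#' at 1.  Avoidance of the angry avatar is the upper boundary, approach the
#' lower one.
#'
#' @param v drift-rate in evidence units per second (positive favours
#'   avoidance).
#' @param a boundary separation (> 0).
#' @param t0 non-decision time in seconds (>= 0), additive to decision time.
#' @return an object of class \code{ddm_params}.
#' @export
ddm_params <- function(v, a, t0) {
  stopifnot(is.numeric(v), is.numeric(a), is.numeric(t0))
  if (a <= 0) stop("boundary separation 'a' must be > 0")
  if (t0 < 0) stop("non-decision time 't0' must be >= 0")
  structure(list(v = v, a = a, t0 = t0), class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf("Wiener DDM params: v = %.3f, a = %.3f, t0 = %.3f (z = a/2, s = 1)\n",
              x$v, x$a, x$t0))
  invisible(x)
}

## Dimensionless first-passage density at the lower boundary for a Wiener
## process with unit boundary separation, zero drift and relative start w,
## evaluated at normalized time tau = t / a^2.  Series expansion with
## automatic small-time / large-time regime switching; the number of terms
## is chosen so the truncation error is below `eps` (relative scale).
.wfpt_f_w <- function(tau, w, eps = 1e-7) {
  out <- numeric(length(tau))
  pos <- tau > 0
  tt <- tau[pos]
  if (!length(tt)) return(out)

  ## required number of terms per regime (Navarro-Fuss style bounds)
  ks <- rep(2, length(tt))
  cond <- (2 * sqrt(2 * pi * tt) * eps) < 1
  ks[cond] <- pmax(ks[cond],
                   ceiling(2 + sqrt(-2 * tt[cond] *
                                      log(2 * eps * sqrt(2 * pi * tt[cond])))))
  kl <- rep(1, length(tt))
  cond <- (pi * tt * eps) < 1
  kl[cond] <- pmax(kl[cond],
                   ceiling(sqrt(-2 * log(pi * tt[cond] * eps) /
                                  (pi^2 * tt[cond]))))

  use_small <- ks < kl
  val <- numeric(length(tt))

  if (any(use_small)) {
    ts <- tt[use_small]
    K <- max(ks[use_small])
    kk <- seq(-floor((K - 1) / 2), ceiling((K - 1) / 2))
    ## sum over (w + 2k) exp(-(w + 2k)^2 / (2 tau))
    s <- rep(0, length(ts))
    for (k in kk) {
      wk <- w + 2 * k
      s <- s + wk * exp(-wk^2 / (2 * ts))
    }
    val[use_small] <- s / sqrt(2 * pi * ts^3)
  }
  if (any(!use_small)) {
    tl <- tt[!use_small]
    K <- max(kl[!use_small])
    s <- rep(0, length(tl))
    for (k in seq_len(K)) {
      s <- s + k * exp(-k^2 * pi^2 * tl / 2) * sin(k * pi * w)
    }
    val[!use_small] <- pi * s
  }
  out[pos] <- pmax(val, 0)
  out
}

#' Wiener first-passage-time density
#'
#' Defective first-passage density of the unbiased Wiener diffusion process
#' at the upper (avoidance) or lower (approach) boundary, evaluated at
#' decision time \code{t} (i.e. observed RT minus \code{t0}).  The two
#' boundary densities jointly integrate to one.  Computed by the standard
#' small-time / large-time series expansion with automatic regime switching
#' and truncation tolerance \code{eps}.
#'
#' @param t decision time(s) in seconds; values <= 0 return density 0.
#' @param params a \code{\link{ddm_params}} object.
#' @param boundary \code{"upper"} (avoid) or \code{"lower"} (approach).
#' @param eps truncation tolerance of the series expansion.
#' @return vector of densities, same length as \code{t}.
#' @export
wfpt_density <- function(t, params, boundary = c("upper", "lower"),
                         eps = 1e-7) {
  boundary <- match.arg(boundary)
  v <- params$v
  a <- params$a
  w <- 0.5
  ## density at the lower boundary of a process with drift v is obtained
  ## from the zero-drift kernel; upper boundary via (v, w) -> (-v, 1 - w)
  if (boundary == "upper") {
    v <- -v
    ## w stays 0.5 for the unbiased start
  }
  tau <- t / a^2
  f <- .wfpt_f_w(tau, w, eps)
  dens <- numeric(length(t))
  pos <- t > 0
  dens[pos] <- (1 / a^2) * exp(-v * a * w - v^2 * t[pos] / 2) * f[pos]
  dens
}

#' Boundary absorption probability
#'
#' Probability that the unbiased Wiener process is absorbed at the upper
#' (avoidance) boundary: \code{1 / (1 + exp(-a v))}.
#'
#' @inheritParams wfpt_density
#' @export
ddm_absorption_prob <- function(params, boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  p_up <- 1 / (1 + exp(-params$a * params$v))
  if (boundary == "upper") p_up else 1 - p_up
}

#' Simulate the diffusion decision process
#'
#' Euler-Maruyama simulation of the unbiased Wiener process with a
#' Brownian-bridge crossing correction: within each step, a path whose
#' endpoints stay inside the boundaries is still absorbed with the exact
#' bridge crossing probability \code{exp(-2 d_old d_new / dt)}, which
#' removes the leading discretization bias of the plain Euler scheme.
#' Paths start at a/2 and are run until absorption at 0 (approach) or a
#' (avoidance); the returned RT is first-passage time plus \code{t0}.
#'
#' @param params a \code{\link{ddm_params}} object.
#' @param n number of trials.
#' @param dt Euler step in seconds (default 0.001).
#' @param max_t step budget in seconds; paths still active after
#'   \code{max_t} are reported as \code{NA} with a warning.
#' @return data.frame with columns \code{response} ("avoid"/"approach") and
#'   \code{rt} (seconds).
#' @export
ddm_simulate <- function(params, n, dt = 0.001, max_t = 20) {
  v <- params$v; a <- params$a; t0 <- params$t0
  x <- rep(a / 2, n)
  rt <- rep(NA_real_, n)
  resp <- rep(NA_character_, n)
  active <- seq_len(n)
  sdt <- sqrt(dt)
  nstep <- ceiling(max_t / dt)
  for (i in seq_len(nstep)) {
    if (!length(active)) break
    x_old <- x[active]
    x_new <- x_old + v * dt + sdt * rnorm(length(active))
    x[active] <- x_new
    up <- x_new >= a
    lo <- x_new <= 0
    inside <- !up & !lo
    if (any(inside)) {
      ## bridge crossing probabilities for paths ending inside
      xo <- x_old[inside]; xn <- x_new[inside]
      p_up <- exp(-2 * pmax(a - xo, 0) * (a - xn) / dt)
      p_lo <- exp(-2 * pmax(xo, 0) * xn / dt)
      u <- runif(length(xo))
      cross_up <- u < p_up
      cross_lo <- !cross_up & (u < p_up + p_lo)
      up[inside] <- cross_up
      lo[inside] <- cross_lo
    }
    hit_up <- active[up]
    hit_lo <- active[lo]
    if (length(hit_up)) {
      rt[hit_up] <- i * dt + t0
      resp[hit_up] <- "avoid"
    }
    if (length(hit_lo)) {
      rt[hit_lo] <- i * dt + t0
      resp[hit_lo] <- "approach"
    }
    if (length(hit_up) || length(hit_lo)) {
      active <- active[!(up | lo)]
    }
  }
  if (length(active)) {
    warning(sprintf("%d of %d paths not absorbed within max_t = %gs", length(active), n, max_t))
  }
  data.frame(response = resp, rt = rt, stringsAsFactors = FALSE)
}

#' Design of a DDM model-comparison fit
#'
#' Specifies which of the three parameters (v, a, t0) vary by Condition
#' and/or latent Class.  Two parameterizations are supported:
#' \code{"effects"} (an intercept for the unpredictable condition plus an
#' additive predictable-condition effect on each varying parameter, as in
#' the mod1..mod8 grid) and \code{"cells"} (one parameter per factor cell,
#' used for the Condition-by-Class analysis).
#'
#' @param v,a,t0 character vector of factors the parameter varies by;
#'   subset of \code{c("condition", "class")}; \code{character(0)} for a
#'   single shared value.
#' @param parameterization \code{"effects"} or \code{"cells"}.
#' @param name optional label.
#' @export
ddm_design <- function(v = character(), a = character(), t0 = character(),
                       parameterization = c("effects", "cells"),
                       name = NULL) {
  parameterization <- match.arg(parameterization)
  chk <- function(x) stopifnot(all(x %in% c("condition", "class")))
  chk(v); chk(a); chk(t0)
  structure(list(v = v, a = a, t0 = t0,
                 parameterization = parameterization,
                 name = name %||% "ddm_design"),
            class = "ddm_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The mod1..mod8 condition-effect design grid
#'
#' mod1: no parameter varies by condition; mod2: v; mod3: t0; mod4: a;
#' mod5: v + t0; mod6: v + a; mod7: a + t0; mod8: v + a + t0.
#'
#' @return named list of eight \code{\link{ddm_design}} objects.
#' @export
ddm_design_grid <- function() {
  sets <- list(mod1 = character(),
               mod2 = "v", mod3 = "t0", mod4 = "a",
               mod5 = c("v", "t0"), mod6 = c("v", "a"),
               mod7 = c("a", "t0"), mod8 = c("v", "a", "t0"))
  out <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    ddm_design(v = if ("v" %in% s) "condition" else character(),
               a = if ("a" %in% s) "condition" else character(),
               t0 = if ("t0" %in% s) "condition" else character(),
               name = nm)
  })
  names(out) <- names(sets)
  out
}

## Build per-trial cell index for one parameter given its varying factors.
## Returns list(cell = integer index per trial, labels = cell labels).
.ddm_cells <- function(design_factors, trials) {
  if (!length(design_factors)) {
    return(list(cell = rep(1L, nrow(trials)), labels = "all"))
  }
  cols <- list()
  if ("condition" %in% design_factors) cols$condition <- as.character(trials$condition)
  if ("class" %in% design_factors) {
    if (is.null(trials$latent_class)) stop("design varies by class but trials lack a 'latent_class' column")
    cols$class <- as.character(trials$latent_class)
  }
  key <- do.call(paste, c(cols, sep = ":"))
  f <- factor(key)
  list(cell = as.integer(f), labels = levels(f))
}

## Internal: assemble trial-wise (v, a, t0) from a flat parameter vector.
## In "effects" parameterization the predictable condition adds a beta to
## the intercept; in "cells" each cell has its own value.
.ddm_param_map <- function(design, trials) {
  map <- list()
  for (p in c("v", "a", "t0")) {
    fac <- design[[p]]
    if (design$parameterization == "cells") {
      cl <- .ddm_cells(fac, trials)
      map[[p]] <- list(type = "cells", cell = cl$cell, labels = cl$labels,
                       n_par = length(cl$labels))
    } else {
      ## effects coding: intercept (+ condition effect) (+ class effect)
      n_par <- 1L
      labs <- paste0(p, "_intercept")
      cond <- rep(0L, nrow(trials))
      clas <- rep(0L, nrow(trials))
      if ("condition" %in% fac) {
        n_par <- n_par + 1L
        labs <- c(labs, paste0(p, "_condition"))
        cond <- as.integer(trials$condition == "predictable")
      }
      if ("class" %in% fac) {
        n_par <- n_par + 1L
        labs <- c(labs, paste0(p, "_class"))
        clas <- as.integer(trials$latent_class == "GD")
      }
      map[[p]] <- list(type = "effects", cond = cond, clas = clas,
                       labels = labs, n_par = n_par,
                       has_cond = "condition" %in% fac,
                       has_class = "class" %in% fac)
    }
  }
  map
}

.ddm_trial_params <- function(theta, map) {
  out <- list()
  i <- 0L
  for (p in c("v", "a", "t0")) {
    m <- map[[p]]
    th <- theta[i + seq_len(m$n_par)]
    i <- i + m$n_par
    if (m$type == "cells") {
      out[[p]] <- th[m$cell]
    } else {
      val <- rep(th[1], length(m$cond))
      j <- 1L
      if (isTRUE(m$has_cond)) { j <- j + 1L; val <- val + th[j] * m$cond }
      if (isTRUE(m$has_class)) { j <- j + 1L; val <- val + th[j] * m$clas }
      out[[p]] <- val
    }
  }
  out
}

#' Negative log-likelihood of trials under a DDM design
#'
#' Sum over trials of minus the log defective first-passage density at the
#' observed boundary, with the trial's cell parameters.  Trials whose RT is
#' at or below the cell non-decision time contribute a large penalty.
#'
#' @param design a \code{\link{ddm_design}}.
#' @param theta flat numeric parameter vector (see
#'   \code{\link{ddm_fit}} for its layout).
#' @param trials data.frame with columns \code{response}
#'   ("avoid"/"approach"), \code{rt} (s), \code{condition} and, if the
#'   design requires it, \code{latent_class}.
#' @return scalar negative log-likelihood.
#' @export
ddm_negloglik <- function(design, theta, trials) {
  map <- .ddm_param_map(design, trials)
  pp <- .ddm_trial_params(theta, map)
  if (any(pp$a <= 0) || any(pp$t0 < 0)) return(1e10)
  tdec <- trials$rt - pp$t0
  bad <- tdec <= 1e-4
  ll <- rep(-25, nrow(trials)) # penalty for rt <= t0
  ok <- !bad
  if (any(ok)) {
    up <- trials$response == "avoid"
    d <- numeric(sum(ok))
    idx <- which(ok)
    for (b in c(TRUE, FALSE)) {
      sel <- idx[up[idx] == b]
      if (!length(sel)) next
      vv <- pp$v[sel]; aa <- pp$a[sel]
      vb <- if (b) -vv else vv
      tau <- tdec[sel] / aa^2
      f <- .wfpt_f_w(tau, 0.5)
      dens <- (1 / aa^2) * exp(-vb * aa * 0.5 - vb^2 * tdec[sel] / 2) * f
      ll[sel] <- log(pmax(dens, 1e-12))
    }
  }
  -sum(ll)
}

#' Fit a drift-diffusion model
#'
#' Maximum-likelihood mode (default): multistart bounded optimization of
#' \code{\link{ddm_negloglik}} with AIC/BIC.  MCMC mode: hierarchical
#' random-walk Metropolis-within-Gibbs sampling with participant-level
#' base parameters, group-level condition/class regressors, and DIC/BPIC
#' (DIC = Dbar + pD with pD = Dbar - D(thetabar); BPIC = Dbar + 2 pD).
#'
#' @param design a \code{\link{ddm_design}}.
#' @param trials trial data.frame (threat trials with observed responses).
#' @param mode \code{"ml"} or \code{"mcmc"}.
#' @param n_starts number of multistart initializations (ml mode).
#' @param n_iter,n_warmup,n_chains,thin MCMC settings (mcmc mode).
#' @param prior mcmc mode: list of mildly informative truncated-normal
#'   hyperparameters, see Details.
#' @param quiet suppress progress output.
#' @details MCMC priors default to truncated normals
#'   v ~ N(0, 2) on [-5, 5], a ~ N(1.5, 1) on (0.3, 4],
#'   t0 ~ N(0.3, 0.3) on [0, min rt); group-level effect betas get
#'   N(0, 1) priors, participant-level SDs half-normal(0.5).
#' @return an object of class \code{ddm_fit}.
#' @export
ddm_fit <- function(design, trials, mode = c("ml", "mcmc"),
                    n_starts = 10,
                    n_iter = 2000, n_warmup = 500, n_chains = 3, thin = 3,
                    prior = NULL, quiet = TRUE) {
  mode <- match.arg(mode)
  trials <- trials[!is.na(trials$rt) & !is.na(trials$response), , drop = FALSE]
  if (!nrow(trials)) stop("no responded trials to fit")
  map <- .ddm_param_map(design, trials)
  n_par <- sum(vapply(map, function(m) m$n_par, 1L))
  labels <- unlist(lapply(c("v", "a", "t0"), function(p) {
    m <- map[[p]]
    if (m$type == "cells") paste0(p, "[", m$labels, "]") else m$labels
  }))
  n_cell <- max(table(unlist(lapply(map, function(m)
    if (m$type == "cells") m$cell else NULL))), 0)
  min_rt <- min(trials$rt)

  if (mode == "ml") {
    .ddm_fit_ml(design, trials, map, n_par, labels, min_rt, n_starts, quiet)
  } else {
    .ddm_fit_mcmc(design, trials, map, n_par, labels, min_rt,
                  n_iter, n_warmup, n_chains, thin, prior, quiet)
  }
}

.ddm_bounds <- function(map, min_rt) {
  lo <- c(); hi <- c()
  for (p in c("v", "a", "t0")) {
    m <- map[[p]]
    if (m$type == "cells") {
      b <- switch(p, v = c(-5, 5), a = c(0.31, 4), t0 = c(0, max(min_rt - 1e-3, 1e-3)))
      lo <- c(lo, rep(b[1], m$n_par)); hi <- c(hi, rep(b[2], m$n_par))
    } else {
      b <- switch(p, v = c(-5, 5), a = c(0.31, 4), t0 = c(0, max(min_rt - 1e-3, 1e-3)))
      lo <- c(lo, b[1]); hi <- c(hi, b[2])
      if (m$n_par > 1) { # additive effects may be negative
        eff <- switch(p, v = c(-3, 3), a = c(-2, 2), t0 = c(-0.5, 0.5))
        lo <- c(lo, rep(eff[1], m$n_par - 1))
        hi <- c(hi, rep(eff[2], m$n_par - 1))
      }
    }
  }
  list(lower = lo, upper = hi)
}

.ddm_start <- function(map, min_rt, jitter = TRUE) {
  th <- c()
  for (p in c("v", "a", "t0")) {
    m <- map[[p]]
    base <- switch(p, v = 0.5, a = 1.3, t0 = min(0.3, 0.6 * min_rt))
    if (m$type == "cells") {
      th <- c(th, rep(base, m$n_par))
    } else {
      th <- c(th, base, rep(0, m$n_par - 1))
    }
  }
  if (jitter) {
    th <- th + rnorm(length(th), 0, 0.15)
  }
  th
}

.ddm_fit_ml <- function(design, trials, map, n_par, labels, min_rt,
                        n_starts, quiet) {
  b <- .ddm_bounds(map, min_rt)
  nll <- function(theta) ddm_negloglik(design, theta, trials)
  best <- NULL
  n_fail <- 0
  for (s in seq_len(n_starts)) {
    th0 <- pmin(pmax(.ddm_start(map, min_rt, jitter = s > 1), b$lower), b$upper)
    res <- tryCatch(
      optim(th0, nll, method = "L-BFGS-B", lower = b$lower, upper = b$upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) { n_fail <- n_fail + 1; next }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all multistart optimizations failed")
  est <- setNames(best$par, labels)
  n <- nrow(trials)
  ll <- -best$value
  structure(list(design = design, mode = "ml",
                 estimates = est, loglik = ll,
                 aic = -2 * ll + 2 * n_par,
                 bic = -2 * ll + n_par * log(n),
                 n_trials = n, n_par = n_par,
                 n_failed_starts = n_fail),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("DDM fit (%s, %s): logLik = %.2f\n", x$design$name, x$mode, x$loglik))
  if (x$mode == "ml") {
    cat(sprintf("  AIC = %.1f  BIC = %.1f  (%d trials, %d params)\n",
                x$aic, x$bic, x$n_trials, x$n_par))
    print(round(x$estimates, 4))
  } else {
    cat(sprintf("  DIC = %.1f  BPIC = %.1f\n", x$dic, x$bpic))
    print(round(x$summary, 4))
  }
  invisible(x)
}

## Hierarchical MCMC: participant base params (v_i, a_i, t0_i) ~ truncated
## normals around group means; condition/class effects as group-level
## additive betas (effects parameterization) or cell means shared across
## participants as offsets from participant base values (cells
## parameterization treats the first cell as the participant base).
.ddm_fit_mcmc <- function(design, trials, map, n_par, labels, min_rt,
                          n_iter, n_warmup, n_chains, thin, prior, quiet) {
  if (is.null(trials$participant_id)) stop("mcmc mode requires a 'participant_id' column")
  pid <- factor(trials$participant_id)
  ids <- levels(pid)
  n_sub <- length(ids)
  pidx <- as.integer(pid)

  prior <- modifyList(list(
    mu_v = c(0, 2), mu_a = c(1.5, 1), mu_t0 = c(0.3, 0.3),
    beta_sd = 1, sd_half = 0.5), prior %||% list())

  ## group-level structure: for each parameter, the group part is either
  ## effect betas (n_par - 1 of them) or cell offsets (n_cells - 1, cell 1
  ## serving as reference absorbed into participant base params).
  g_labels <- c(); g_count <- c(v = 0L, a = 0L, t0 = 0L)
  for (p in c("v", "a", "t0")) {
    m <- map[[p]]
    k <- m$n_par - 1L
    g_count[p] <- k
    if (k > 0) {
      lb <- if (m$type == "cells") paste0(p, "[", m$labels[-1], "]") else m$labels[-1]
      g_labels <- c(g_labels, lb)
    }
  }
  n_g <- sum(g_count)

  trial_offset <- function(gtheta) {
    ## per-trial additive offsets for v, a, t0 from the group parameters
    off <- list(v = 0, a = 0, t0 = 0)
    i <- 0L
    for (p in c("v", "a", "t0")) {
      m <- map[[p]]; k <- g_count[[p]]
      if (k == 0) { off[[p]] <- rep(0, nrow(trials)); next }
      th <- gtheta[i + seq_len(k)]; i <- i + k
      if (m$type == "cells") {
        o <- c(0, th)[m$cell]
      } else {
        o <- rep(0, nrow(trials)); j <- 0L
        if (isTRUE(m$has_cond)) { j <- j + 1L; o <- o + th[j] * m$cond }
        if (isTRUE(m$has_class)) { j <- j + 1L; o <- o + th[j] * m$clas }
      }
      off[[p]] <- o
    }
    off
  }

  ## per-participant log-likelihood given subject params and group offsets
  sub_ll <- function(i, sp, off) {
    sel <- pidx == i
    v <- sp[1] + off$v[sel]; a <- sp[2] + off$a[sel]; t0 <- sp[3] + off$t0[sel]
    if (any(a <= 0.05) || any(t0 < 0)) return(-Inf)
    tdec <- trials$rt[sel] - t0
    up <- trials$response[sel] == "avoid"
    vb <- ifelse(up, -v, v)
    bad <- tdec <= 1e-4
    ll <- rep(-25, sum(sel))
    if (any(!bad)) {
      tau <- tdec[!bad] / a[!bad]^2
      f <- .wfpt_f_w(tau, 0.5)
      dens <- (1 / a[!bad]^2) *
        exp(-vb[!bad] * a[!bad] * 0.5 - vb[!bad]^2 * tdec[!bad] / 2) * f
      ll[!bad] <- log(pmax(dens, 1e-12))
    }
    sum(ll)
  }
  total_ll <- function(sub, gtheta) {
    off <- trial_offset(gtheta)
    sum(vapply(seq_len(n_sub), function(i) sub_ll(i, sub[i, ], off), 0))
  }

  keep <- floor((n_iter - n_warmup) / thin)
  draws_g <- array(NA_real_, c(keep * n_chains, max(n_g, 1)))
  draws_mu <- array(NA_real_, c(keep * n_chains, 3))
  dev_draws <- numeric(keep * n_chains)
  sub_sum <- matrix(0, n_sub, 3)
  n_kept_total <- 0

  step_sub <- c(0.25, 0.12, 0.03)
  step_g <- 0.08
  row0 <- 0
  for (ch in seq_len(n_chains)) {
    ## init
    sub <- cbind(rnorm(n_sub, 0.4, 0.1), rnorm(n_sub, 1.3, 0.05),
                 pmin(rnorm(n_sub, 0.25, 0.02), min_rt * 0.8))
    gtheta <- rep(0, max(n_g, 1))
    mu <- c(0.4, 1.3, 0.25); sg <- c(0.3, 0.2, 0.05)
    off <- trial_offset(gtheta)
    ll_sub <- vapply(seq_len(n_sub), function(i) sub_ll(i, sub[i, ], off), 0)
    k <- 0
    for (it in seq_len(n_iter)) {
      ## subject-level RW updates
      for (i in seq_len(n_sub)) {
        prop <- sub[i, ] + rnorm(3, 0, step_sub)
        lp0 <- ll_sub[i] + sum(dnorm(sub[i, ], mu, sg, log = TRUE))
        lp1 <- sub_ll(i, prop, off) + sum(dnorm(prop, mu, sg, log = TRUE))
        if (is.finite(lp1) && log(runif(1)) < lp1 - lp0) {
          sub[i, ] <- prop
          ll_sub[i] <- lp1 - sum(dnorm(prop, mu, sg, log = TRUE))
        }
      }
      ## group means/SDs (conjugate-ish RW for simplicity)
      for (j in 1:3) {
        pm <- switch(j, prior$mu_v, prior$mu_a, prior$mu_t0)
        ## conjugate normal update for mu given sg
        prec <- n_sub / sg[j]^2 + 1 / pm[2]^2
        mn <- (sum(sub[, j]) / sg[j]^2 + pm[1] / pm[2]^2) / prec
        mu[j] <- rnorm(1, mn, 1 / sqrt(prec))
        ## RW on log sd with half-normal prior
        prop <- sg[j] * exp(rnorm(1, 0, 0.15))
        lp0 <- sum(dnorm(sub[, j], mu[j], sg[j], log = TRUE)) +
          dnorm(sg[j], 0, prior$sd_half, log = TRUE) + log(sg[j])
        lp1 <- sum(dnorm(sub[, j], mu[j], prop, log = TRUE)) +
          dnorm(prop, 0, prior$sd_half, log = TRUE) + log(prop)
        if (log(runif(1)) < lp1 - lp0) sg[j] <- prop
      }
      ## group-level regressors
      if (n_g > 0) {
        for (j in seq_len(n_g)) {
          prop <- gtheta; prop[j] <- prop[j] + rnorm(1, 0, step_g)
          off_p <- trial_offset(prop)
          ll1 <- vapply(seq_len(n_sub), function(i) sub_ll(i, sub[i, ], off_p), 0)
          lp0 <- sum(ll_sub) + dnorm(gtheta[j], 0, prior$beta_sd, log = TRUE)
          lp1 <- sum(ll1) + dnorm(prop[j], 0, prior$beta_sd, log = TRUE)
          if (is.finite(lp1) && log(runif(1)) < lp1 - lp0) {
            gtheta <- prop; off <- off_p; ll_sub <- ll1
          }
        }
      }
      if (it > n_warmup && (it - n_warmup) %% thin == 0) {
        k <- k + 1
        draws_g[row0 + k, ] <- gtheta
        draws_mu[row0 + k, ] <- mu
        dev_draws[row0 + k] <- -2 * sum(ll_sub)
        sub_sum <- sub_sum + sub
        n_kept_total <- n_kept_total + 1
      }
    }
    row0 <- row0 + keep
  }

  sub_bar <- sub_sum / n_kept_total
  g_bar <- colMeans(draws_g)
  d_bar <- mean(dev_draws)
  d_at_bar <- -2 * total_ll(sub_bar, g_bar)
  pd <- d_bar - d_at_bar
  dic <- d_bar + pd
  bpic <- d_bar + 2 * pd

  cn <- if (n_g > 0) g_labels else "unused"
  colnames(draws_g) <- cn
  colnames(draws_mu) <- c("mu_v", "mu_a", "mu_t0")
  smry <- t(apply(cbind(draws_mu, if (n_g > 0) draws_g), 2, function(x)
    c(median = median(x), q2.5 = quantile(x, 0.025, names = FALSE),
      q97.5 = quantile(x, 0.975, names = FALSE))))
  structure(list(design = design, mode = "mcmc",
                 draws_group = if (n_g > 0) draws_g else NULL,
                 draws_mu = draws_mu,
                 participant_means = sub_bar,
                 summary = smry,
                 dic = dic, bpic = bpic, pd = pd, deviance_bar = d_bar,
                 n_trials = nrow(trials), n_sub = n_sub),
            class = "ddm_fit")
}

#' Compare DDM designs on the same data
#'
#' Fits each design and ranks by information criterion (BIC in ml mode,
#' DIC in mcmc mode), reporting the difference from the best design.
#'
#' @param trials trial data.frame.
#' @param designs list of \code{\link{ddm_design}} objects (default the
#'   mod1..mod8 grid).
#' @param mode \code{"ml"} or \code{"mcmc"}.
#' @param ... passed to \code{\link{ddm_fit}}.
#' @return data.frame ranking with columns design, criterion, delta, best.
#' @export
ddm_compare_designs <- function(trials, designs = ddm_design_grid(),
                                mode = c("ml", "mcmc"), ...) {
  mode <- match.arg(mode)
  fits <- vector("list", length(designs))
  crit <- rep(NA_real_, length(designs))
  reason <- rep(NA_character_, length(designs))
  for (i in seq_along(designs)) {
    f <- tryCatch(ddm_fit(designs[[i]], trials, mode = mode, ...),
                  error = function(e) e)
    if (inherits(f, "error")) {
      reason[i] <- conditionMessage(f)
    } else {
      fits[[i]] <- f
      crit[i] <- if (mode == "ml") f$bic else f$dic
    }
  }
  nm <- vapply(designs, function(d) d$name, "")
  ok <- !is.na(crit)
  out <- data.frame(design = nm, criterion = crit,
                    delta = crit - min(crit[ok]),
                    best = FALSE, failed = !ok, reason = reason,
                    stringsAsFactors = FALSE)
  out$best[ok][which.min(crit[ok])] <- TRUE
  out <- out[order(out$criterion), ]
  attr(out, "fits") <- setNames(fits, nm)
  attr(out, "criterion") <- if (mode == "ml") "BIC" else "DIC"
  out
}

#' Posterior contrast of DDM group-level parameters
#'
#' Evaluates an expression over the group-level draws of an MCMC fit
#' (e.g. a difference of cell means or a difference of differences) and
#' summarizes it with the posterior median, 95% credible interval and the
#' posterior mass below/above zero.
#'
#' @param fit an mcmc-mode \code{\link{ddm_fit}}.
#' @param expression a one-argument function taking the draws matrix
#'   (columns named as in \code{fit$summary}) and returning one value per
#'   draw, or a character expression evaluated with those columns bound.
#' @export
ddm_contrast <- function(fit, expression) {
  if (fit$mode != "mcmc") stop("contrasts require an mcmc-mode fit")
  draws <- cbind(fit$draws_mu, fit$draws_group)
  if (is.function(expression)) {
    val <- expression(draws)
  } else {
    env <- as.data.frame(draws, check.names = FALSE)
    val <- eval(parse(text = expression), envir = env)
  }
  summarize_draws(val)
}

#' Summarize a vector of posterior draws
#'
#' Median, central 95% credible interval (2.5th-97.5th posterior
#' quantiles) and posterior mass below and above zero.
#' @param x numeric vector of draws.
#' @export
summarize_draws <- function(x) {
  q <- quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
  data.frame(median = q[2], ci_low = q[1], ci_high = q[3],
             p_below_zero = mean(x < 0), p_above_zero = mean(x > 0))
}
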