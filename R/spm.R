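#' Design rows for the time-resolved physiological GLMs
#'
#' Builds the per-trial regressor table with the centred-contrast coding
#' used throughout the time-resolved analyses:
#' Condition (unpredictable = -0.5, predictable = 0.5),
#' Threat (neutral = -0.5, threat = 0.5),
#' Outcome (threat = -0.5, safe = 0.5),
#' Response (approach = -0.5, avoid = 0.5),
#' and grand-average-centred RT; interactions are products of codes.
#'
#' @param trials trial data.frame.
#' @param rt_center centring value (default grand mean over responded
#'   trials supplied).
#' @return data.frame aligned with \code{trials}.
#' @export
spm_design <- function(trials, rt_center = NULL) {
  rc <- rt_center %||% mean(trials$rt, na.rm = TRUE)
  data.frame(
    trial_index = trials$trial_index,
    condition = ifelse(trials$condition == "predictable", 0.5, -0.5),
    threat = ifelse(trials$trial_type == "threat", 0.5, -0.5),
    outcome = ifelse(is.na(trials$outcome), NA,
                     ifelse(trials$outcome == "safe", 0.5, -0.5)),
    response = ifelse(is.na(trials$response), NA,
                      ifelse(trials$response == "avoid", 0.5, -0.5)),
    rt_centered = trials$rt - rc)
}

## formula -> regressor columns (besides the intercept)
.spm_formula_terms <- function(formula_id) {
  switch(as.character(formula_id),
         "1" = c("condition", "threat", "condition:threat", "rt_centered"),
         "2" = c("condition", "outcome", "condition:outcome", "rt_centered"),
         "3" = c("condition", "response", "condition:response", "rt_centered"),
         stop("formula_id must be 1, 2 or 3"))
}

#' Per-participant, per-time-point GLM of physiological epochs
#'
#' Fits an ordinary-least-squares model at every time point of each
#' participant's z-scored epoch matrix: formula 1 regresses the signal on
#' Condition, Threat, their interaction and centred RT (all trials);
#' formula 2 replaces Threat with the trial Outcome (threat trials);
#' formula 3 replaces it with the Response (threat trials, EMG).  The RT
#' regressor is a single trial-level scalar shared across time points.
#'
#' @param epoch_list named list (one entry per participant) of
#'   \code{epoch_matrix} objects (z-scored).
#' @param design_list matching list of \code{\link{spm_design}} rows
#'   aligned with each participant's epoch trials via
#'   \code{trial_index}.
#' @param formula_id 1, 2 or 3.
#' @return object of class \code{beta_series}: array participants x
#'   regressors x time, the time axis, and the regressor names.  A
#'   participant whose design is rank deficient for a column (e.g. no
#'   approach responses) gets NA for the affected regressors and is
#'   reported in \code{rank_deficient}.
#' @export
fit_trialwise_glm <- function(epoch_list, design_list, formula_id = 1) {
  terms <- .spm_formula_terms(formula_id)
  regs <- c("intercept", terms)
  n_sub <- length(epoch_list)
  tax <- epoch_list[[1]]$time
  out <- array(NA_real_, c(n_sub, length(regs), length(tax)),
               dimnames = list(names(epoch_list), regs, NULL))
  rank_def <- character(0)
  for (i in seq_len(n_sub)) {
    ep <- epoch_list[[i]]
    de <- design_list[[i]]
    de <- de[match(ep$trial_index, de$trial_index), , drop = FALSE]
    col_of <- function(term) {
      parts <- strsplit(term, ":", fixed = TRUE)[[1]]
      Reduce(`*`, lapply(parts, function(p) de[[p]]))
    }
    X <- cbind(1, vapply(terms, col_of, numeric(nrow(de))))
    colnames(X) <- regs
    ok <- complete.cases(X) & complete.cases(ep$values)
    X <- X[ok, , drop = FALSE]
    Y <- ep$values[ok, , drop = FALSE]
    if (nrow(X) <= ncol(X)) { rank_def <- c(rank_def, names(epoch_list)[i]); next }
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      rank_def <- c(rank_def, names(epoch_list)[i])
      used <- qrX$pivot[seq_len(qrX$rank)]
      B <- matrix(NA_real_, ncol(X), ncol(Y))
      B[used, ] <- qr.coef(qr(X[, used, drop = FALSE]), Y)
      out[i, , ] <- B
    } else {
      out[i, , ] <- qr.coef(qrX, Y)
    }
  }
  structure(list(betas = out, time = tax, regressors = regs,
                 fs_epoch = epoch_list[[1]]$fs_epoch,
                 formula_id = formula_id,
                 rank_deficient = rank_def),
            class = "beta_series")
}

## group one-sample t series across participants at each time point
.group_t_series <- function(B) {
  ## B: participants x time (may contain NA rows)
  n <- colSums(!is.na(B))
  m <- colMeans(B, na.rm = TRUE)
  s <- apply(B, 2, sd, na.rm = TRUE)
  t <- m / (s / sqrt(n))
  list(t = t, n = n)
}

#' Candidate clusters from a beta series
#'
#' One-sample t against zero across participants at each time point;
#' contiguous runs of supra-threshold |t| of one sign lasting longer than
#' the minimum duration become candidate clusters with their t-mass (the
#' sum of t values in the run).  The threshold is the two-sided
#' p = 0.05 quantile of a t distribution with n - 1 degrees of freedom.
#'
#' @param bs a \code{beta_series}.
#' @param regressor regressor name.
#' @param p_thres point-wise threshold (0.05, two-sided).
#' @param min_duration_s minimum cluster duration in seconds (0.1 for
#'   10 Hz iHR series, 0.02 for 1 kHz EMG series).
#' @return data.frame of candidate clusters: start_time, end_time,
#'   start_idx, end_idx, sign, t_mass; zero rows when none.
#' @export
find_clusters <- function(bs, regressor, p_thres = 0.05,
                          min_duration_s = 0.1) {
  B <- bs$betas[, regressor, , drop = TRUE]
  if (is.null(dim(B))) B <- matrix(B, nrow = dim(bs$betas)[1])
  gts <- .group_t_series(B)
  if (min(gts$n) < 3) stop("need >= 3 participants with non-missing betas")
  thr <- qt(1 - p_thres / 2, df = gts$n - 1)
  sup <- ifelse(is.na(gts$t), 0, sign(gts$t) * (abs(gts$t) > thr))
  r <- rle(sup)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values != 0 & (r$lengths / bs$fs_epoch) > min_duration_s
  if (!any(keep)) {
    return(data.frame(start_time = numeric(0), end_time = numeric(0),
                      start_idx = integer(0), end_idx = integer(0),
                      sign = numeric(0), t_mass = numeric(0)))
  }
  out <- data.frame(start_idx = starts[keep], end_idx = ends[keep],
                    sign = r$values[keep])
  out$start_time <- bs$time[out$start_idx]
  out$end_time <- bs$time[out$end_idx]
  out$t_mass <- vapply(seq_len(nrow(out)), function(i)
    sum(gts$t[out$start_idx[i]:out$end_idx[i]]), 0)
  out[, c("start_time", "end_time", "start_idx", "end_idx", "sign", "t_mass")]
}

#' Cluster-mass permutation test
#'
#' Permutation inference for candidate clusters: on each permutation a
#' uniformly drawn number of participants (1..n) has its beta series
#' replaced by zeros ("no effect"), the t series is recomputed, and the
#' largest absolute t-mass within the observed cluster windows is
#' recorded as the null statistic.  The corrected p-value of each cluster
#' is the proportion of null draws exceeding its absolute observed
#' t-mass, floored at 1/n_perm.  A participant-level sign-flip scheme is
#' available as a conventional alternative.
#'
#' @param bs a \code{beta_series}.
#' @param regressor regressor name.
#' @param clusters output of \code{\link{find_clusters}} for that
#'   regressor.
#' @param n_perm permutations (10,000 at paper scale).
#' @param scheme \code{"zero_subset"} (default): zero a uniformly drawn
#'   subset of participants and take the largest absolute t-mass within
#'   the observed cluster windows.  \code{"sign_flip"}: the conventional
#'   alternative -- flip the sign of each participant's series at random,
#'   re-detect supra-threshold clusters over the whole series, and take
#'   the maximum absolute cluster t-mass (0 when none).
#' @param p_thres,min_duration_s cluster-forming settings; must match the
#'   values used in \code{\link{find_clusters}} (used by the sign-flip
#'   scheme's re-detection).
#' @return \code{clusters} with an added \code{p_corr} column and a
#'   \code{significant} flag at p_corr < 0.05.
#' @export
cluster_permutation_test <- function(bs, regressor, clusters,
                                     n_perm = 10000,
                                     scheme = c("zero_subset", "sign_flip"),
                                     p_thres = 0.05, min_duration_s = 0.1) {
  scheme <- match.arg(scheme)
  if (n_perm < 100) warning("n_perm < 100 gives unstable corrected p-values")
  if (!nrow(clusters)) {
    clusters$p_corr <- numeric(0); clusters$significant <- logical(0)
    return(clusters)
  }
  B <- bs$betas[, regressor, , drop = TRUE]
  if (is.null(dim(B))) B <- matrix(B, nrow = dim(bs$betas)[1])
  n_sub <- nrow(B)
  t_of <- function(Bp) {
    n <- colSums(!is.na(Bp))
    mu <- colMeans(Bp, na.rm = TRUE)
    s <- matrixStats_colSds(Bp)
    mu / (s / sqrt(n))
  }
  null_max <- numeric(n_perm)
  if (scheme == "zero_subset") {
    ## restrict to the observed cluster windows
    win_idx <- unlist(lapply(seq_len(nrow(clusters)), function(i)
      clusters$start_idx[i]:clusters$end_idx[i]))
    win_of <- rep(seq_len(nrow(clusters)),
                  clusters$end_idx - clusters$start_idx + 1)
    Bw <- B[, win_idx, drop = FALSE]
    for (p in seq_len(n_perm)) {
      Bp <- Bw
      m <- sample.int(n_sub, 1)
      Bp[sample.int(n_sub, m), ] <- 0
      t <- t_of(Bp)
      tm <- abs(as.numeric(rowsum(ifelse(is.na(t), 0, t), win_of)))
      null_max[p] <- max(tm)
    }
  } else {
    thr_all <- qt(1 - p_thres / 2, df = colSums(!is.na(B)) - 1)
    min_len <- min_duration_s * bs$fs_epoch
    for (p in seq_len(n_perm)) {
      fl <- sample(c(-1, 1), n_sub, replace = TRUE)
      t <- t_of(B * fl)
      sup <- ifelse(is.na(t), 0, sign(t) * (abs(t) > thr_all))
      r <- rle(sup)
      keep <- r$values != 0 & r$lengths > min_len
      if (!any(keep)) { null_max[p] <- 0; next }
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      null_max[p] <- max(vapply(which(keep), function(k)
        abs(sum(t[starts[k]:ends[k]])), 0))
    }
  }
  obs <- abs(clusters$t_mass)
  clusters$p_corr <- vapply(obs, function(o)
    max(mean(null_max > o), 1 / n_perm), 0)
  clusters$significant <- clusters$p_corr < 0.05
  clusters
}

## column SDs without matrixStats (kept base-only)
matrixStats_colSds <- function(m) {
  n <- colSums(!is.na(m))
  mu <- colMeans(m, na.rm = TRUE)
  sq <- colSums(sweep(m, 2, mu)^2, na.rm = TRUE)
  sqrt(sq / pmax(n - 1, 1))
}

#' Trial-wise iHR-change covariate
#'
#' For each trial, the signed maximum-magnitude baseline-referenced iHR
#' value (bpm) within a cluster window (typically the significant
#' negative intercept cluster); values outside the per-participant Tukey
#' fences are rejected, and the survivors are z-scored within
#' participant.
#'
#' @param epochs_bpm an \code{epoch_matrix} in bpm change (not z-scored).
#' @param window c(start_time, end_time) of the cluster, seconds.
#' @return data.frame: trial_index, hr_change_bpm, hr_z (NA for rejected
#'   trials), rejected flag.
#' @export
extract_ihr_change <- function(epochs_bpm, window) {
  sel <- epochs_bpm$time >= window[1] & epochs_bpm$time <= window[2]
  if (!any(sel)) stop("cluster window does not overlap the epoch; supply a fallback window")
  seg <- epochs_bpm$values[, sel, drop = FALSE]
  ext <- apply(seg, 1, function(v) v[which.max(abs(v))])
  keep <- reject_outlier_peaks(ext)
  hr_z <- rep(NA_real_, length(ext))
  s <- sd(ext[keep])
  if (is.na(s) || s == 0) stop("zero SD of iHR change; cannot z-score")
  hr_z[keep] <- (ext[keep] - mean(ext[keep])) / s
  data.frame(trial_index = epochs_bpm$trial_index,
             hr_change_bpm = ext, hr_z = hr_z, rejected = !keep)
}
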