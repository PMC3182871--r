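#' Simulate a trial ensemble of one word
#'
#' Runs n stochastic trials of the same word with identical duration and
#' sampling.  Trials start from a common re-armed serial state (nu = 0,
#' lambda = 1, weights at the relaunch floor) so the word unfolds
#' synchronously across trials up to noise; under the "jittered" policy the
#' output initial condition is additionally drawn from a small uniform
#' neighbourhood (half-width 0.05) of the reference initial condition.
#' Per-trial seeds derive deterministically from the master seed.
#'
#' @param word "flow" or "view" (or a \code{sequence_spec}).
#' @param n number of trials (default 100).
#' @param ic_policy "jittered" or "identical".
#' @param master_seed integer master seed.
#' @param duration simulated time per trial (default 36: the writing span of
#'   one word, from the auxiliary start through the rhythmic mode's first
#'   cycles; the trailing parking phase and the final transition back to the
#'   parking mode carry no analysable writing).
#' @param record_stride analysis sampling stride over the integration grid
#'   (default 2: a movement cycle of ~7 time units then spans ~700 samples,
#'   so the matching window of 300 samples stays smaller than half a cycle).
#' @param s noise standard deviation.
#' @param ... further overrides passed to \code{\link{sim_config}}.
#' @return object of class \code{sfm_ensemble}: list of equal-grid trial
#'   matrices (output variables, kick signals and sequence-mode weights),
#'   the shared time grid, the configuration, and per-trial seeds.
#' @export
ensemble_run <- function(word = "view", n = 100,
                         ic_policy = c("jittered", "identical"),
                         master_seed = 1L, duration = 36, s = 0.001,
                         record_stride = 2L, ...) {
  ic_policy <- match.arg(ic_policy)
  stopifnot(n >= 2)
  set.seed(master_seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n)
  cfg0 <- sim_config(word = word, s = s, duration = duration,
                     record = "analysis", record_stride = record_stride, ...)
  Kp <- length(cfg0$seq$ids)
  K <- cfg0$repertoire$K
  trials <- vector("list", n)
  for (k in seq_len(n)) {
    set.seed(trial_seeds[k])
    jit <- if (ic_policy == "jittered") stats::runif(3, -0.05, 0.05)
           else c(0, 0, 0)
    cfg <- cfg0
    cfg$seed <- NULL               # RNG state already set
    cfg$ic <- list(x0 = 0 + jit[1], y0 = 0.1 + jit[2], z0 = -0.1 + jit[3],
                   xi = rep(cfg0$xi_min, K), nu = rep(0, Kp),
                   lam = rep(1, Kp), kick = c(0, 0, 0, 0))
    tr <- integrate_em(cfg)
    trials[[k]] <- tr$data
  }
  grids <- vapply(trials, nrow, 0L)
  stopifnot(all(grids == grids[1]))
  structure(list(trials = trials, time = trials[[1]][, "t"],
                 config = cfg0, ic_policy = ic_policy,
                 master_seed = master_seed, trial_seeds = trial_seeds),
            class = "sfm_ensemble")
}

#' @export
print.sfm_ensemble <- function(x, ...) {
  cat("sfm_ensemble:", length(x$trials), "trials x", length(x$time),
      "samples, word =", x$config$seq$label %||% "<custom>",
      ", ICs", x$ic_policy, "\n")
  invisible(x)
}

# the variables analysed across trials (x is excluded: the flow does not
# depend on it and it carries no phase-space information)
ensemble_vars <- function(e) {
  Kp <- length(e$config$seq$ids)
  c("y", "z", "dy_dt", "dz_dt", "delta_y", "delta_z",
    paste0("xi_seq_", seq_len(Kp)))
}

#' Pointwise ensemble statistics
#'
#' Mean and standard deviation (denominator n - 1) of every analysed
#' variable across trials at each time point.
#'
#' @param e an \code{sfm_ensemble}.
#' @return object of class \code{pointwise_stats}: list with matrices
#'   \code{mean} and \code{sd} (time x variable) and the time grid.
#' @export
pointwise_stats <- function(e) {
  stopifnot(inherits(e, "sfm_ensemble"), length(e$trials) >= 2)
  vars <- ensemble_vars(e)
  Tn <- length(e$time)
  n <- length(e$trials)
  mu <- sdm <- matrix(0, Tn, length(vars), dimnames = list(NULL, vars))
  for (v in seq_along(vars)) {
    M <- vapply(e$trials, function(d) d[, vars[v]], numeric(Tn))
    mu[, v] <- rowMeans(M)
    sdm[, v] <- sqrt(rowSums((M - mu[, v])^2) / (n - 1))
  }
  structure(list(mean = mu, sd = sdm, time = e$time, n = n),
            class = "pointwise_stats")
}

# estimate the dominant movement-cycle length (samples) from the mean
# trajectory: median spacing of upward mid-line crossings of y
estimate_cycle <- function(y_mean) {
  up <- which(y_mean[-1] > 1 & y_mean[-length(y_mean)] <= 1)
  if (length(up) < 2) return(NA_real_)
  stats::median(diff(up))
}

#' Phase-space nearest-neighbour rearrangement
#'
#' For each time point of the ensemble-mean (y, z) trajectory and each trial,
#' the trial sample with minimum Euclidean distance to the mean point in the
#' (y, z) plane is located inside a window of T_w samples centred on the
#' reference index; all other variables are rearranged to the matched index
#' and their means and standard deviations recomputed per point.  A margin of
#' T_w / 2 samples at each end is excluded from reporting.
#'
#' @param e an \code{sfm_ensemble}.
#' @param stats its \code{pointwise_stats} (computed if missing).
#' @param T_w window width in samples (default 300; must be smaller than
#'   half the dominant movement cycle).
#' @return object of class \code{matched_ensemble}: rearranged \code{mean}
#'   and \code{sd} matrices, matched \code{index} and \code{distance}
#'   matrices (time x trial), and the \code{valid} index range.
#' @export
rearrange_nn <- function(e, stats = NULL, T_w = 300) {
  stopifnot(inherits(e, "sfm_ensemble"))
  if (is.null(stats)) stats <- pointwise_stats(e)
  cyc <- estimate_cycle(stats$mean[, "y"])
  if (!is.na(cyc) && T_w >= cyc / 2)
    warning("rearrange_nn: T_w (", T_w,
            ") is not smaller than half the estimated movement cycle (",
            round(cyc), " samples)")
  Tn <- length(e$time)
  n <- length(e$trials)
  ty <- vapply(e$trials, function(d) d[, "y"], numeric(Tn))
  tz <- vapply(e$trials, function(d) d[, "z"], numeric(Tn))
  m <- match_nn(stats$mean[, "y"], stats$mean[, "z"], ty, tz, as.integer(T_w))
  vars <- ensemble_vars(e)
  mu <- sdm <- matrix(0, Tn, length(vars), dimnames = list(NULL, vars))
  for (v in seq_along(vars)) {
    M <- vapply(e$trials, function(d) d[, vars[v]], numeric(Tn))
    R <- matrix(M[cbind(as.vector(m$index),
                        rep(seq_len(n), each = Tn))], Tn, n)
    mu[, v] <- rowMeans(R)
    sdm[, v] <- sqrt(rowSums((R - mu[, v])^2) / (n - 1))
  }
  half <- T_w %/% 2
  structure(list(mean = mu, sd = sdm, index = m$index,
                 distance = m$distance, time = e$time, T_w = T_w,
                 valid = c(half + 1L, Tn - half),
                 cycle_samples = cyc),
            class = "matched_ensemble")
}

#' Reference event structure of an ensemble
#'
#' The simulator's own ground truth for the decomposition analysis.
#' Transitions are the onsets of each character mode (the auxiliary
#' position-setting modes at the word's edges produce no flow-variability
#' signature, because both flows vanish near the rest position, and are not
#' part of the analysed writing span); kicks are the detected pulse times.
#' Both are clustered across trials by order: the modal per-trial event count
#' is determined and the per-index median times over the conforming trials
#' are returned.
#'
#' @param e an \code{sfm_ensemble}.
#' @param min_duration minimum activation length considered (time units).
#' @return list with numeric vectors \code{transitions} (character-to-
#'   character mode transitions) and \code{kicks} (median times), their
#'   across-trial [q10, q90] time ranges, and \code{n_conforming} counts.
#' @export
ensemble_events <- function(e, min_duration = 0.5) {
  Kp <- length(e$config$seq$ids)
  dtv <- e$time[2] - e$time[1]
  n <- length(e$trials)
  trans <- vector("list", n); kicks <- vector("list", n)
  for (k in seq_len(n)) {
    d <- e$trials[[k]]
    xim <- d[, paste0("xi_seq_", seq_len(Kp)), drop = FALSE]
    act <- apply(xim, 1, which.max)
    mx <- xim[cbind(seq_len(nrow(xim)), act)]
    act[mx < 0.25] <- 0L
    r <- rle(act)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    keep <- r$values > 0 & r$lengths * dtv >= min_duration
    pos <- r$values[keep]; t0 <- e$time[starts[keep]]
    # onsets of character positions 3..Kp-1: the transitions between
    # character modes (the entry from and the return to the auxiliary
    # parking modes move almost no flow and are not part of the analysed
    # writing span)
    tt <- numeric(0)
    for (p in 3:(Kp - 1)) {
      i <- which(pos == p & c(0, utils::head(pos, -1)) == p - 1)[1]
      tt <- c(tt, if (is.na(i)) NA_real_ else t0[i])
    }
    trans[[k]] <- tt
    kk <- count_pulses(d[, c("delta_y", "delta_z")], dt = dtv,
                       refractory = 2 * e$config$kick$tau_delta)
    kicks[[k]] <- kk$time + e$time[1]
  }
  by_index <- function(lst) {
    cnt <- vapply(lst, length, 0L)
    modal <- as.integer(names(which.max(table(cnt))))
    conf <- lst[cnt == modal]
    if (!length(conf) || modal == 0)
      return(list(times = numeric(0),
                  range = matrix(numeric(0), 0, 2), n = length(conf)))
    M <- do.call(rbind, conf)
    qr <- t(apply(M, 2, stats::quantile, c(0.1, 0.9), na.rm = TRUE))
    fr <- cbind(apply(M, 2, min, na.rm = TRUE),
                apply(M, 2, max, na.rm = TRUE))
    list(times = apply(M, 2, stats::median, na.rm = TRUE),
         range = qr, full_range = fr, n = nrow(M))
  }
  tb <- by_index(trans)
  kb <- by_index(kicks)
  list(transitions = tb$times, kicks = kb$times,
       transitions_range = tb$range, kicks_range = kb$range,
       transitions_full = tb$full_range, kicks_full = kb$full_range,
       n_conforming = c(transitions = tb$n, kicks = kb$n))
}

#' Classify variability segments of a matched ensemble
#'
#' Locates the operational events hidden in a trial ensemble from the output
#' phase flow.  Kick signatures: the brief additive pulse deflects the
#' rearranged \emph{mean} of dy/dt and dz/dt above its slowly varying level
#' (high-pass with a running median over \code{defl_win} time units) while
#' the rearranged derivative SD is elevated.  Transition signatures: the
#' rearranged derivative SD is elevated with no mean deflection -- the weight
#' transitions differ across trials and bend the expressed flow but add no
#' pulse to its mean.  When the operational signals are recorded alongside
#' the output (the default for simulated ensembles), the labelling uses them
#' symmetrically, exactly as the reference statistics are read in practice:
#' a kick window may also be identified by co-located elevation of the
#' rearranged kick-signal SD, and a transition window requires co-located
#' elevation of the weight SD.  With \code{observable_ops = FALSE} the
#' classification is computed from the output variables alone (the
#' kick/transition contrast then softens for late-word kicks, whose pulses
#' smear across the matching window as trial timing diffuses).
#' Elevation is judged against
#' robust quantile baselines of the valid range; windows of the same class
#' closer than \code{class_gap} are merged, and a margin around kick windows
#' is excluded from transition candidacy.
#'
#' @param stats \code{pointwise_stats} of the ensemble.
#' @param matched the corresponding \code{matched_ensemble}.
#' @param truth optional reference events (list with \code{transitions} and
#'   \code{kicks}, e.g. from \code{\link{ensemble_events}}); when given,
#'   per-class precision, recall and F1 are attached as attribute
#'   \code{"scores"}.
#' @param defl_win width of the running-median high-pass for the mean
#'   deflection, in time units (default 0.6: longer than a kick pulse,
#'   shorter than the flow's own variation).
#' @param thr_defl absolute mean-deflection threshold separating kick pulses
#'   from transition bends (default 0.5 in flow units).
#' @param kick_sd_factor a kick window must also have derivative SD above
#'   this multiple of the 10th-percentile baseline (default 3).
#' @param trans_factor a transition window needs derivative SD above this
#'   multiple of the quiet-range baseline (the 35th percentile of the
#'   kick-free valid range; default factor 2).
#' @param observable_ops use the recorded operational-signal statistics
#'   (kick-signal SD for kick windows, weight SD for transition windows) in
#'   addition to the output statistics (default TRUE).
#' @param thr_xi weight-SD gate; the effective threshold is
#'   max(thr_xi, median + 2 MAD of the weight SD over the valid range), so
#'   it adapts to the ensemble's synchrony and noise level (default 0.05).
#' @param thr_delta absolute rearranged kick-signal SD threshold
#'   (default 0.3).
#' @param kick_margin margin around kick windows excluded from transition
#'   candidacy (time units, default 0.4).
#' @param merge_gap merge gap for elevated runs (default 0.25 = tau_f / 4).
#' @param class_gap merge gap for windows of the same class (default 1).
#' @param match_window half-width for matching a predicted segment to a
#'   truth event (default 1.25).
#' @return data.frame of segments (t_start, t_end, class, score) of class
#'   \code{segment_labels}; baselines and scores attached as attributes.
#' @export
classify_segments <- function(stats, matched, truth = NULL,
                              defl_win = 0.6, thr_defl = 0.5,
                              kick_sd_factor = 3, trans_factor = 2,
                              observable_ops = TRUE, thr_xi = 0.05,
                              thr_delta = 0.3,
                              kick_margin = 0.4, merge_gap = 0.25,
                              class_gap = 1, match_window = 1.25) {
  stopifnot(inherits(stats, "pointwise_stats"),
            inherits(matched, "matched_ensemble"))
  tt <- matched$time
  dtv <- tt[2] - tt[1]
  v0 <- matched$valid[1]; v1 <- matched$valid[2]
  valid <- v0:v1
  sd_flow <- matched$sd[, "dy_dt"] + matched$sd[, "dz_dt"]
  win <- 2 * floor(defl_win / dtv / 2) + 1
  hp <- function(x) x - stats::runmed(x, win)
  defl <- abs(hp(matched$mean[, "dy_dt"])) + abs(hp(matched$mean[, "dz_dt"]))
  xi_cols <- grep("^xi_seq_", colnames(stats$sd))
  xi_sd <- rowSums(stats$sd[, xi_cols, drop = FALSE])
  delta_sd <- matched$sd[, "delta_y"] + matched$sd[, "delta_z"]

  runs_of <- function(flag, gap = merge_gap) {
    flag[-valid] <- FALSE
    r <- rle(flag)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    fill <- which(!r$values & r$lengths * dtv < gap)
    for (g in fill) if (g > 1 && g < length(r$values))
      flag[starts[g]:ends[g]] <- TRUE
    r <- rle(flag)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    keep <- which(r$values)
    cbind(start = starts[keep], end = ends[keep])
  }

  sd_floor <- stats::quantile(sd_flow[valid], 0.10, names = FALSE)
  thr_defl <- max(thr_defl, 6 * stats::median(defl[valid]))
  kick_flag <- defl > thr_defl
  if (observable_ops) kick_flag <- kick_flag | delta_sd > thr_delta
  kick_runs <- runs_of(kick_flag & sd_flow > kick_sd_factor * sd_floor,
                       gap = class_gap)
  in_kick <- rep(FALSE, length(tt))
  pad <- ceiling(kick_margin / dtv)
  if (nrow(kick_runs)) for (i in seq_len(nrow(kick_runs)))
    in_kick[max(1, kick_runs[i, 1] - pad):
              min(length(tt), kick_runs[i, 2] + pad)] <- TRUE
  quiet <- valid[!in_kick[valid]]
  sd_base <- stats::quantile(sd_flow[quiet], 0.35, names = FALSE)
  thr_trans <- trans_factor * sd_base
  # with observable weights, a transition window is a span of elevated
  # weight SD accompanied by flow-SD elevation; it may overlap a kick
  # window (operational events can co-occur in the data set).  Output-only:
  # flow-SD elevation outside the kick windows.
  thr_xi <- max(thr_xi, stats::median(xi_sd[valid]) +
                  2 * stats::mad(xi_sd[valid]))
  tflag <- if (observable_ops)
    xi_sd > thr_xi & sd_flow > thr_trans
  else
    sd_flow > thr_trans & !in_kick
  trans_runs <- runs_of(tflag, gap = class_gap)

  seg <- data.frame(t_start = numeric(0), t_end = numeric(0),
                    class = character(0), score = numeric(0),
                    stringsAsFactors = FALSE)
  addseg <- function(runs, cls) {
    if (!nrow(runs)) return(invisible(NULL))
    for (i in seq_len(nrow(runs))) {
      span <- runs[i, 1]:runs[i, 2]
      seg[nrow(seg) + 1L, ] <<- list(tt[runs[i, 1]], tt[runs[i, 2]], cls,
                                     max(sd_flow[span]) /
                                       max(sd_base, 1e-12))
    }
  }
  addseg(kick_runs, "kick")
  addseg(trans_runs, "transition")
  seg <- seg[order(seg$t_start), ]
  row.names(seg) <- NULL

  scores <- NULL
  if (!is.null(truth)) {
    # each truth event is the across-trial time range [q10, q90] of its
    # occurrences (falling back to the median time when no range is given)
    score_class <- function(cls, events, ranges, full) {
      if (is.null(ranges) || !nrow(ranges))
        ranges <- cbind(events, events)
      if (is.null(full) || !nrow(full)) full <- ranges
      keep <- !is.na(events) & ranges[, 2] >= tt[v0] & ranges[, 1] <= tt[v1]
      events <- events[keep]
      ranges <- ranges[keep, , drop = FALSE]
      full <- full[keep, , drop = FALSE]
      pred <- seg[seg$class == cls, , drop = FALSE]
      if (!length(events)) return(c(precision = NA, recall = NA, F1 = NA))
      # recall against the central [q10, q90] occurrence range; precision
      # against the full straggler range (a window over late occurrences of
      # a real event is not a false alarm)
      hit_truth <- vapply(seq_along(events), function(j)
        any(pred$t_start - match_window <= ranges[j, 2] &
              pred$t_end + match_window >= ranges[j, 1]), TRUE)
      hit_pred <- if (nrow(pred)) vapply(seq_len(nrow(pred)), function(i)
        any(full[, 1] <= pred$t_end[i] + match_window &
              full[, 2] >= pred$t_start[i] - match_window), TRUE)
        else logical(0)
      prec <- if (length(hit_pred)) mean(hit_pred) else 0
      rec <- mean(hit_truth)
      f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      c(precision = prec, recall = rec, F1 = f1)
    }
    scores <- rbind(
      kick = score_class("kick", truth$kicks, truth$kicks_range,
                         truth$kicks_full),
      transition = score_class("transition", truth$transitions,
                               truth$transitions_range,
                               truth$transitions_full))
  }
  structure(seg, scores = scores,
            baselines = c(sd_floor = sd_floor, sd_base = sd_base,
                          thr_defl = thr_defl),
            class = c("segment_labels", "data.frame"))
}

#' Open-loop replay ensemble with the autonomous ensemble's mean weights
#'
#' Re-runs every trial of an ensemble with the mode weights prescribed to be
#' the autonomous ensemble's pointwise mean xi(t), identical across trials
#' (competition and serial feedback bypassed, kicks active).  Used to show
#' that the weight-transition variability, not the transitions themselves,
#' carries the transition signature.
#'
#' @param e an autonomous \code{sfm_ensemble}.
#' @param stats its \code{pointwise_stats} (computed if missing).
#' @return an \code{sfm_ensemble} of the replayed trials.
#' @export
ensemble_frozen_run <- function(e, stats = NULL) {
  stopifnot(inherits(e, "sfm_ensemble"))
  if (is.null(stats)) stats <- pointwise_stats(e)
  cfg0 <- e$config
  K <- cfg0$repertoire$K
  Kp <- length(cfg0$seq$ids)
  n_steps <- ceiling(cfg0$duration / cfg0$dt)
  tfull <- seq(0, by = cfg0$dt, length.out = n_steps + 1)
  xi_mu <- matrix(cfg0$xi_min, n_steps + 1, K)
  for (p in seq_len(Kp)) {
    v <- stats::approx(e$time, stats$mean[, paste0("xi_seq_", p)],
                       xout = tfull, rule = 2)$y
    xi_mu[, cfg0$seq$ids[p]] <- pmax(v, cfg0$xi_min)
  }
  trials <- vector("list", length(e$trials))
  for (k in seq_along(e$trials)) {
    set.seed(e$trial_seeds[k])
    jit <- if (e$ic_policy == "jittered") stats::runif(3, -0.05, 0.05)
           else c(0, 0, 0)
    cfg <- cfg0
    cfg$seed <- NULL
    cfg$ic <- list(x0 = jit[1], y0 = 0.1 + jit[2], z0 = -0.1 + jit[3],
                   xi = xi_mu[1, ], nu = rep(0, Kp), lam = rep(1, Kp),
                   kick = c(0, 0, 0, 0))
    trials[[k]] <- integrate_em(cfg, xi_frozen = xi_mu)$data
  }
  structure(list(trials = trials, time = e$time, config = cfg0,
                 ic_policy = e$ic_policy, master_seed = e$master_seed,
                 trial_seeds = e$trial_seeds, frozen = TRUE),
            class = "sfm_ensemble")
}
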