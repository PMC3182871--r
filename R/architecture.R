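#' The time-scale set of the architecture
#'
#' All constants are dimensionless and scale with the manifold-contraction
#' time constant tau: tau = 0.1, mu = 0.1, so the on-manifold flow runs on
#' tau_f = tau / mu = 1; kicks, competition and switching are fast
#' (tau_delta = tau_c = tau_lambda = 0.1) and the output integration is slow
#' (tau_v = 10).  The effective mode-selection scale tau_xi ~ tau_v is
#' emergent, not a free parameter.
#'
#' @return named list of time constants.
#' @export
time_scales <- function() {
  ts <- list(tau = 0.1, mu = 0.1, tau_f = 1, tau_delta = 0.1,
             tau_c = 0.1, tau_v = 10, tau_lambda = 0.1)
  stopifnot(ts$tau_delta < ts$tau_f, ts$tau_c < ts$tau_f,
            ts$tau_lambda < ts$tau_f, ts$tau_f < ts$tau_v)
  ts
}

#' Simulation configuration
#'
#' @param word packaged word name ("flow" or "view") or a
#'   \code{sequence_spec}.
#' @param repertoire mode repertoire.
#' @param s noise standard deviation (default 0.001).
#' @param dt integration step (default 0.005 = tau_delta / 20; must be at
#'   most tau_delta / 10 to resolve the fast subsystems).
#' @param duration total simulated time.
#' @param seed integer seed; drawn initial conditions and the noise path are
#'   reproducible under it.
#' @param ic list of initial conditions; x0, y0, z0 default to the reference
#'   values (0, 0.1, -0.1); nu, lam are drawn uniformly on [0, 1] and xi on
#'   [0, 1/K] unless given explicitly.
#' @param record "full" (all state variables) or "analysis" (the output
#'   variables and sequence-mode weights only).
#' @param record_stride store every record_stride-th step.
#' @param noise logical toggles for the additive noise per equation block
#'   (u, xi, nu, lam, kick); all TRUE by default.
#' @param xi_min small relaunch floor for the mode weights: after each step
#'   xi is clipped to at least this value, so every competition round
#'   restarts from an even baseline instead of a random noise floor (set to
#'   0 for plain non-negativity clipping).
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(word = "flow", repertoire = default_repertoire(),
                       s = 0.001, dt = 0.005, duration = 150, seed = NULL,
                       ic = list(), record = c("full", "analysis"),
                       record_stride = 1L,
                       noise = list(u = TRUE, xi = TRUE, nu = TRUE,
                                    lam = TRUE, kick = TRUE),
                       xi_min = 1e-3) {
  record <- match.arg(record)
  ts <- time_scales()
  if (dt > ts$tau_delta / 10)
    stop("sim_config: dt must be <= tau_delta / 10 = ", ts$tau_delta / 10)
  stopifnot(duration > 0, s >= 0)
  seqspec <- if (inherits(word, "sequence_spec")) word
             else word_spec(word, repertoire)
  defaults <- list(x0 = 0, y0 = 0.1, z0 = -0.1, xi = NULL, nu = NULL,
                   lam = NULL, kick = c(0, 0, 0, 0))
  ic <- utils::modifyList(defaults, ic)
  structure(list(repertoire = repertoire, seq = seqspec, scales = ts,
                 s = s, dt = dt, duration = duration, seed = seed,
                 ic = ic, record = record,
                 record_stride = as.integer(record_stride),
                 noise = noise, xi_min = xi_min, kick = kick_params()),
            class = "sim_config")
}

# flatten the repertoire into the parameter matrix consumed by sim_core
flatten_modes <- function(rep) {
  typecode <- c(linear = 0, monostable = 1, bistable = 2, limit_cycle = 3)
  rows <- lapply(rep$modes, function(m) {
    p <- m$planar; s <- m$shape; mf <- m$manifold
    at <- mode_attractors(m)
    natt <- min(nrow(at), 2)
    a1 <- if (natt >= 1) at[1, ] else c(0, 0)
    a2 <- if (natt >= 2) at[2, ] else c(0, 0)
    c(typecode[[p$topology]],
      if (is.na(p$mu_e)) 0 else p$mu_e, p$a_z, p$b_z, p$u0, p$k_lin,
      p$target[1], p$target[2],
      s$g_up_lo, s$g_up_hi, s$g_dn_lo, s$g_dn_hi, s$y_center, s$y_steep,
      s$v_sharp, mf$r, mf$c, mf$ecc, m$mu, as.numeric(m$needs_kick),
      m$kick_amp, m$prox_w, m$inh$eps0, m$inh$a, m$inh$b, m$inh$c,
      natt, a1[1], a1[2], a2[1], a2[2])
  })
  do.call(rbind, rows)
}

# draw / assemble the initial state under the config's seed
initial_state <- function(cfg) {
  K <- cfg$repertoire$K
  Kp <- length(cfg$seq$ids)
  ic <- cfg$ic
  list(u = c(ic$x0, ic$y0, ic$z0),
       xi = if (!is.null(ic$xi)) ic$xi else stats::runif(K, 0, 1 / K),
       nu = if (!is.null(ic$nu)) ic$nu else stats::runif(Kp, 0, 1),
       lam = if (!is.null(ic$lam)) ic$lam else stats::runif(Kp, 0, 1),
       kick = ic$kick)
}

#' Integrate the full architecture with fixed-step Euler-Maruyama
#'
#' Additive Gaussian noise of standard deviation s enters every dynamical
#' equation scaled by sqrt(dt); after each step the mode weights are clipped
#' to xi >= 0 and the switching variables clamped to [-1, 1].  With s = 0 the
#' scheme reduces to deterministic forward Euler.  Runs are bitwise
#' reproducible under a fixed seed.
#'
#' @param cfg a \code{sim_config}.
#' @param xi_frozen optional (n_steps + 1) x K matrix of prescribed mode
#'   weights; when given, the competition and feedback subsystems are
#'   bypassed and xi(t) is imposed (open-loop replay).
#' @return object of class \code{sfm_trajectory}: a list with the sampled
#'   state matrix \code{data} (one row per recorded step), the
#'   configuration, and the final state.
#' @export
integrate_em <- function(cfg, xi_frozen = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  st <- initial_state(cfg)
  n_steps <- ceiling(cfg$duration / cfg$dt)
  if (!is.null(xi_frozen)) {
    xi_frozen <- as.matrix(xi_frozen)
    if (nrow(xi_frozen) != n_steps + 1)
      stop("integrate_em: xi_frozen must have ", n_steps + 1, " rows")
    st$xi <- xi_frozen[1, ]
  }
  res <- sim_core(flatten_modes(cfg$repertoire),
                  as.integer(cfg$seq$ids), cfg$seq$k_inh, cfg$seq$k_exc,
                  cfg$seq$primacy, cfg$seq$C0, cfg$seq$C_nonseq,
                  cfg$scales, cfg$kick,
                  cfg$dt, n_steps, cfg$s, cfg$xi_min,
                  as.numeric(unlist(cfg$noise)),
                  st$u, st$xi, st$nu, st$lam, st$kick,
                  cfg$record_stride, if (cfg$record == "full") 0L else 1L,
                  xi_frozen)
  K <- cfg$repertoire$K
  Kp <- length(cfg$seq$ids)
  cols <- if (cfg$record == "full")
    c("t", "x", "y", "z", "dy_dt", "dz_dt", paste0("xi_", seq_len(K)),
      "delta_y", "delta_z", "d1", "d2", "dcr",
      paste0("nu_", seq_len(Kp)), paste0("lam_", seq_len(Kp)))
  else
    c("t", "x", "y", "z", "dy_dt", "dz_dt", "delta_y", "delta_z", "d1",
      paste0("xi_seq_", seq_len(Kp)))
  colnames(res$traj) <- cols
  structure(list(data = res$traj, config = cfg,
                 last = res[c("last_u", "last_xi", "last_nu", "last_lam",
                              "last_kick")],
                 frozen = !is.null(xi_frozen)),
            class = "sfm_trajectory")
}

#' @export
print.sfm_trajectory <- function(x, ...) {
  d <- x$data
  cat("sfm_trajectory:", nrow(d), "samples, t in [", d[1, "t"], ",",
      d[nrow(d), "t"], "], word =",
      x$config$seq$label %||% "<custom>", "\n")
  ev <- tryCatch(event_log(x), error = function(e) NULL)
  if (!is.null(ev) && nrow(ev$activations))
    cat("  activations:",
        paste(ev$activations$label, collapse = " "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a packaged word
#'
#' @param word "flow", "view", or a \code{sequence_spec}.
#' @param seed integer seed.
#' @param ... overrides passed to \code{\link{sim_config}}.
#' @return an \code{sfm_trajectory}.
#' @export
run_word <- function(word = "flow", seed = 1L, ...) {
  if (is.character(word) && !word %in% c("flow", "view"))
    stop("run_word: unknown word '", word, "'")
  integrate_em(sim_config(word = word, seed = seed, ...))
}

#' Open-loop replay with prescribed mode weights
#'
#' Re-integrates the output and kick dynamics with an imposed, non-autonomous
#' xi(t); the competition and serial-feedback subsystems are bypassed.  Used
#' to separate the variability contributed by the mode-selection dynamics
#' from that of the kicks.
#'
#' @param xi_series (n_steps + 1) x K matrix of weights covering the whole
#'   simulated duration.
#' @param cfg a \code{sim_config}.
#' @return an \code{sfm_trajectory}.
#' @export
replay_with_prescribed_xi <- function(xi_series, cfg) {
  integrate_em(cfg, xi_frozen = xi_series)
}

#' Assemble the full deterministic field at one state (reference)
#'
#' Pure-R reference implementation of the coupled right-hand side: the
#' expressed flow is the xi-weighted linear combination of all mode fields
#' plus the kick contribution; the competition, feedback, switching and kick
#' subsystems close the loop.  No explicit time dependence appears anywhere:
#' the architecture is autonomous.  The compiled integrator mirrors this
#' function; tests assert exact agreement.
#'
#' @param state list with elements u (3), xi (K), nu (K'), lam (K'),
#'   kick (3).
#' @param cfg a \code{sim_config}.
#' @return list of derivative blocks (du, dxi, dnu, dlam, dkick) and the
#'   kick output (delta_y, delta_z).
#' @export
assemble_field <- function(state, cfg) {
  rep <- cfg$repertoire
  K <- rep$K
  seqs <- cfg$seq
  Kp <- length(seqs$ids)
  stopifnot(length(state$xi) == K, length(state$nu) == Kp,
            length(state$lam) == Kp)
  u <- state$u
  F <- c(0, 0, 0)
  for (j in seq_len(K))
    if (state$xi[j] != 0)
      F <- F + state$xi[j] * mode_field(rep$modes[[j]], u)
  kout <- kick_output(state$kick[1], u, state$xi, rep)
  dkick <- kick_rhs(state$kick, u, F[2:3], state$xi, rep, cfg$kick)
  L <- gate_L(state$lam, seqs, K)
  C <- primacy_C(state$lam, seqs, K)
  S <- sum(state$xi^2 / C)
  dxi <- state$xi * (L - C * S) / cfg$scales$tau_c
  dnu <- feedback_rhs(list(nu = state$nu, lam = state$lam), u, state$xi,
                      seqs, rep, cfg$scales$tau_v, kick = state$kick)
  S_val <- sigmoid_S(state$nu)
  dlam <- switching_rhs(state$lam, S_val, cfg$scales$tau_lambda)
  list(du = c(F[1], F[2] + kout[1], F[3] + kout[2]),
       dxi = dxi, dnu = dnu, dlam = dlam, dkick = dkick,
       delta_y = kout[1], delta_z = kout[2])
}

#' Event log of a trajectory
#'
#' Mode-activation intervals (mode j is active when xi_j exceeds half the
#' current maximum and 0.25 absolutely), kick events (pulse detection on the
#' recorded kick signal), and sequence-completion times (ends of the final
#' sequence mode's activations).
#'
#' @param traj an \code{sfm_trajectory} recorded in "full" mode.
#' @param min_duration discard activation intervals shorter than this
#'   (brief flickers of a losing competitor during a transition).
#' @return list with data.frames \code{activations} (mode, label, t_start,
#'   t_end), \code{kicks} (time, amplitude), and numeric
#'   \code{completions}.
#' @export
event_log <- function(traj, min_duration = 0.5) {
  stopifnot(inherits(traj, "sfm_trajectory"))
  d <- traj$data
  cfg <- traj$config
  K <- cfg$repertoire$K
  xi_cols <- paste0("xi_", seq_len(K))
  if (!all(xi_cols %in% colnames(d)))
    stop("event_log needs a trajectory recorded with record = 'full'")
  xim <- d[, xi_cols, drop = FALSE]
  mx <- apply(xim, 1, max)
  act <- apply(xim, 1, which.max)
  ok <- mx > 0.25 & xim[cbind(seq_len(nrow(xim)), act)] > 0.5 * mx
  act[!ok] <- 0L
  tt <- d[, "t"]
  r <- rle(act)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values > 0
  labs <- vapply(cfg$repertoire$modes, `[[`, "", "label")
  activations <- data.frame(
    mode = r$values[keep],
    label = labs[r$values[keep]],
    t_start = tt[starts[keep]],
    t_end = tt[ends[keep]],
    stringsAsFactors = FALSE)
  activations <-
    activations[activations$t_end - activations$t_start >= min_duration, ]
  row.names(activations) <- NULL
  dtv <- if (nrow(d) > 1) tt[2] - tt[1] else cfg$dt
  kicks <- count_pulses(d[, c("delta_y", "delta_z")], dt = dtv,
                        refractory = 2 * cfg$kick$tau_delta)
  if (nrow(kicks)) kicks$time <- kicks$time + tt[1]
  last_id <- cfg$seq$ids[length(cfg$seq$ids)]
  completions <- activations$t_end[activations$mode == last_id]
  list(activations = activations, kicks = kicks, completions = completions)
}
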