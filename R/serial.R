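#' Sequence specification for competitive-queuing serial order
#'
#' A word plan: the ordered mode ids that participate, the per-position
#' inhibitory and excitatory feedback gains, and the primacy gradient of
#' competition parameters.  The excitatory (reset) gain of the final position
#' is deliberately small: the reset window stays open until the final
#' position's own nu has drained below the re-arming threshold, which gives
#' every other nu time to reset completely.  Earlier positions carry smaller primacy values so
#' that they win earlier competition rounds (the winner is the participating
#' mode with the smallest C).  Modes outside the sequence still compete
#' (L = 1) but hold a large constant C and so lose every round.
#'
#' @param ids ordered mode ids (length K').
#' @param k_inh positive inhibitory feedback gains, one per position.
#' @param k_exc positive excitatory (reset) gains, one per position.
#' @param primacy strictly increasing competition parameters, all > C0.
#' @param C0 baseline C an inhibited mode relaxes to.
#' @param C_nonseq constant C held by modes outside the sequence.
#' @param label optional word label.
#' @return object of class \code{sequence_spec}.
#' @export
sequence_spec <- function(ids, k_inh,
                          k_exc = c(rep(120, length(ids) - 1), 4),
                          primacy = seq(1, by = 0.5, length.out = length(ids)),
                          C0 = 0.5, C_nonseq = 20, label = NULL) {
  Kp <- length(ids)
  stopifnot(Kp >= 1, length(k_inh) == Kp, length(k_exc) == Kp,
            length(primacy) == Kp, all(k_inh > 0), all(k_exc > 0),
            all(primacy > C0), all(diff(primacy) > 0),
            C_nonseq > max(primacy), !anyDuplicated(ids))
  structure(list(ids = as.integer(ids), k_inh = k_inh, k_exc = k_exc,
                 primacy = primacy, C0 = C0, C_nonseq = C_nonseq,
                 label = label),
            class = "sequence_spec")
}

#' Packaged word plans
#'
#' The two demonstration words.  Both run between the two auxiliary
#' position-setting modes (ids 36 and 37).  The inhibitory gains for 'flow'
#' are the reference values [6, 12, 5, 5, 2.67, 6]; 'view' reuses them.
#'
#' @param word "flow" or "view".
#' @param repertoire the mode repertoire the ids refer to.
#' @return a \code{sequence_spec}.
#' @export
word_spec <- function(word = c("flow", "view"),
                      repertoire = default_repertoire()) {
  word <- match.arg(word)
  labs <- vapply(repertoire$modes, `[[`, "", "label")
  pick <- function(l) match(l, labs)
  ids <- switch(word,
    flow = c(pick("aux-start"), pick("f"), pick("l"), pick("o"), pick("w"),
             pick("aux-end")),
    view = c(pick("aux-start"), pick("v"), pick("i"), pick("e"), pick("w"),
             pick("aux-end")))
  sequence_spec(ids, k_inh = c(6, 12, 5, 5, 2.67, 6), label = word)
}

#' Sharpening sigmoid of the feedback-integrating variable
#'
#' Monotone logistic mapping nu to [0, 1], centred at 0.5 with steepness 20
#' so that S(0) < 0.01 and S(1) > 0.99.
#'
#' @param nu feedback-integrating value(s).
#' @return value(s) in [0, 1].
#' @export
sigmoid_S <- function(nu) stats::plogis(20 * (nu - 0.5))

#' Switching-variable vector field
#'
#' The 1-D field of the fast switching variable lambda,
#'
#'   tau_lambda * dlam/dt = -lam * (|lam| - 1) * (|lam| - a(S))
#'                          + 0.25 * sign(lam) * max(-a(S), 0) * (1 - |lam|)
#'                          - 0.25 * sign(lam) * max(a(S) - 1, 0) * |lam|,
#'   a(S) = 2.2 * S - 0.8,         |lam| = sign(lam) * lam,  sign(0) := 0.
#'
#' The two escape terms are active only outside the bistable band (a < 0,
#' where the 0 state has destabilised, and a > 1, where the +/-1 states
#' have); inside the band they vanish identically and the equilibrium
#' structure is the pure quintic one.  They make the departures from the
#' destabilised states fast and deterministic instead of noise-seeded, so
#' that all sequence positions re-arm synchronously and the inhibition
#' transition cannot stall on the clamped boundary.
#'
#' For intermediate S the system is bistable with point attractors at 0 and
#' +/-1 separated by unstable points at +/-a; as S approaches 1 (a >= 1) the
#' +/-1 attractors destabilise and lambda transits to 0, and as S approaches
#' 0 (a <= 0) the 0 attractor destabilises and |lambda| transits to 1.  The
#' two transitions occur at different S (a = 1 at S = 9/11, a = 0 at
#' S = 4/11): hysteresis.  The physical domain is [-1, 1]; the stochastic integrator
#' clamps lambda there.
#'
#' @param lam switching value(s).
#' @param S_val sigmoid output in [0, 1].
#' @param tau_lambda time constant (default 0.1).
#' @return dlam/dt.
#' @export
switching_rhs <- function(lam, S_val, tau_lambda = 0.1) {
  stopifnot(all(S_val >= 0), all(S_val <= 1))
  a <- 2.2 * S_val - 0.8
  m <- sign(lam) * lam
  (-lam * (m - 1) * (m - a) +
     0.25 * sign(lam) * pmax(-a, 0) * (1 - m) -
     0.25 * sign(lam) * pmax(a - 1, 0) * m) / tau_lambda
}

#' Equilibria of the 1-D switching dynamics
#'
#' Dense sign-change scan of the switching field on [-1.5, 1.5] followed by
#' bisection; stability from the sign of the derivative (central finite
#' difference).  Non-hyperbolic roots (derivative within 1e-6 of zero) are
#' flagged "indeterminate".
#'
#' @param S_val sigmoid value in [0, 1].
#' @param n grid resolution of the scan (default 3001).
#' @return data.frame with columns \code{lam}, \code{stability}.
#' @export
equilibria_1d <- function(S_val, n = 3001) {
  f <- function(l) switching_rhs(l, S_val)
  grid <- seq(-1.5, 1.5, length.out = n)
  fv <- f(grid)
  roots <- grid[fv == 0]
  sgn <- sign(fv)
  idx <- which(sgn[-1] * sgn[-n] < 0)
  for (i in idx)
    roots <- c(roots, stats::uniroot(f, c(grid[i], grid[i + 1]),
                                     tol = 1e-13)$root)
  roots <- sort(unique(round(roots, 10)))
  h <- 1e-6
  slope <- (f(roots + h) - f(roots - h)) / (2 * h)
  stability <- ifelse(abs(slope) < 1e-6, "indeterminate",
                      ifelse(slope < 0, "stable", "unstable"))
  data.frame(lam = roots, stability = stability, stringsAsFactors = FALSE)
}

#' Participation gates from the switching variables
#'
#' A sequence mode j participates in the competition (L_j = 1) when neither j
#' nor any later mode of the sequence is inhibited (lambda = 0 marks an
#' executed, inhibited mode; |lambda| = 1 an available one):
#' L_j = prod_{m >= j} lambda_m^2.  Modes outside the sequence always
#' participate (L = 1).
#'
#' @param lam switching vector, one entry per sequence position.
#' @param seq a \code{sequence_spec}.
#' @param K repertoire size (length of the returned gate vector).
#' @return numeric K-vector of gates in [0, 1] ({0, 1} at the lambda
#'   equilibria).
#' @export
gate_L <- function(lam, seq, K = 37) {
  stopifnot(inherits(seq, "sequence_spec"), length(lam) == length(seq$ids))
  L <- rep(1, K)
  l2 <- lam^2
  L[seq$ids] <- rev(cumprod(rev(l2)))
  L
}

#' Competition parameters from the switching variables
#'
#' Each sequence mode's C interpolates between its primacy value (available,
#' |lambda| = 1) and the baseline C0 (inhibited, lambda = 0):
#' C_j = C0 + (P_j - C0) * lambda_j^2.  The transit is fast because lambda
#' is.  Modes outside the sequence hold the constant C_nonseq, large enough
#' that they lose every round.
#'
#' @inheritParams gate_L
#' @return numeric K-vector of competition parameters, all >= C0.
#' @export
primacy_C <- function(lam, seq, K = 37) {
  stopifnot(inherits(seq, "sequence_spec"), length(lam) == length(seq$ids))
  C <- rep(seq$C_nonseq, K)
  C[seq$ids] <- seq$C0 + (seq$primacy - seq$C0) * lam^2
  C
}

#' Feedback-integrating vector field
#'
#' The slow integration of the output that informs the competition about the
#' course of execution:
#'
#'   tau_v * dnu_j/dt = k_inh_j * F_inh_j - k_exc_j * F_exc * nu_j
#'
#' F_inh_j = xi_j * (eps0 + a_j * w + b_j * delta_cr+ + c_j) accumulates
#' while mode j is executing.  For kick-initiated modes the drive integrates
#' the kick subsystem's arrival memory w (charged by each fired pulse,
#' decaying over a few time units), so one quantum accrues per movement
#' cycle and the switching threshold is crossed late in the final
#' excursion, well away from the separatrix; the successor mode's flow,
#' which shares the rest position, completes the stroke.  F_inh thereby
#' varies at the time scale of a movement cycle; limit-cycle and auxiliary
#' modes use the continuous gain c_j instead.
#' F_exc = 1 - lambda_K'^2 engages only once the last sequence mode has been
#' executed and resets every nu to 0, rearming the word.
#'
#' @param fs list with elements \code{nu} and \code{lam} (length K' each).
#' @param u state 3-vector (x, y, z).
#' @param xi weight K-vector.
#' @param seq a \code{sequence_spec}.
#' @param repertoire mode repertoire (for the per-mode feedback constants).
#' @param tau_v slow time constant (default 10).
#' @param kick kick-subsystem state (delta_1, delta_2, delta_cr).
#' @return dnu/dt, length K'.
#' @export
feedback_rhs <- function(fs, u, xi, seq, repertoire = default_repertoire(),
                         tau_v = 10, kick = c(0, 0, 0)) {
  stopifnot(inherits(seq, "sequence_spec"))
  Kp <- length(seq$ids)
  stopifnot(length(fs$nu) == Kp, length(fs$lam) == Kp)
  F_inh <- vapply(seq_len(Kp), function(jpos) {
    m <- repertoire$modes[[seq$ids[jpos]]]
    xi[seq$ids[jpos]] * inh_drive(m, kick, u)
  }, 0.0)
  F_exc <- 1 - fs$lam[Kp]^2
  (seq$k_inh * F_inh - seq$k_exc * F_exc * fs$nu) / tau_v
}

# per-mode inhibitory-feedback drive eps0 + a*w + b*delta_cr+ + c
inh_drive <- function(m, kick, u) {
  d <- m$inh
  d$eps0 + d$a * max(kick[4], 0) + d$b * max(kick[3], 0) + d$c
}
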