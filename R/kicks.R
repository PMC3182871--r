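#' Kick-subsystem parameters (shared constants)
#'
#' The instantaneous operational signal is generated by a small excitable
#' system (the pulse variable delta_1 is clipped at 0 by the integrator, so
#' the injected kick is a non-negative pulse without the recovery
#' undershoot): a trigger variable delta_cr charges while the output
#' trajectory
#' dwells near the point attractor of an active mode that requires movement
#' initiation, and on crossing its threshold fires a brief pulse in the
#' excitable pair (delta_1, delta_2).  The pulse is injected into the (y, z)
#' output equations along the local escape direction of the active mode's
#' manifold; the recovery variable delta_2 provides a refractory period and
#' suppresses recharging of the trigger.
#'
#' @return named list of the excitable-system constants.
#' @export
kick_params <- function() {
  list(tau_delta = 0.1,   # pulse time scale (0.1 * tau_f)
       tau_cr    = 1.0,   # trigger charging time constant
       theta_cr  = 0.45,  # trigger firing threshold
       theta_1   = 0.2,   # excitable threshold of delta_1
       gamma_1   = 8,     # cubic gain of delta_1
       in_gain   = 2.0,   # trigger -> pulse input gain
       eps_2     = 0.5,   # recovery rate scale
       d2_gain   = 2,     # delta_1 -> delta_2 drive
       cr_suppress = 2,   # refractory suppression of trigger recharge
       fld_w     = 0.3,   # field-magnitude gate width
       w_gain    = 12,    # pulse -> arrival-memory charge rate
       tau_w     = 3)     # arrival-memory decay time constant
}

# escape direction of mode m at (y, z), in physical coordinates (internal):
# the unit tangent of the manifold cross-section ellipse, oriented in the
# circulation sense of the flow (up-arc escape from (0, 0), down-arc escape
# from (2, 0)); pushing along the arc never fights the manifold contraction
kick_direction <- function(m, y, z) {
  e <- m$manifold$ecc
  cY <- (y - m$manifold$c) / m$manifold$r
  cZ <- z / (m$manifold$r * e)
  n <- sqrt(cY^2 + cZ^2)
  if (n < 1e-6) return(c(0, e) / sqrt(e^2))   # centre: push up
  t <- c(cZ / n, -cY / n * e)                 # arc tangent, physical frame
  t / sqrt(sum(t^2))
}

#' Kick-subsystem vector field
#'
#' The fourth component w is an arrival memory: each fired pulse charges it
#' towards 1 and it decays slowly, so that the serial feedback can integrate
#' "attractor proximity following a kick" -- i.e. completed movement cycles
#' -- rather than raw pulses.
#'
#' @param ks numeric 4-vector (delta_1, delta_2, delta_cr, w).
#' @param u state 3-vector (x, y, z).
#' @param mode_field_yz the (y, z) components of the expressed (xi-weighted)
#'   mode field at u, before the kick contribution.
#' @param xi weight K-vector.
#' @param repertoire the mode repertoire.
#' @param kp kick constants, see \code{\link{kick_params}}.
#' @return d(ks)/dt 3-vector.
#' @export
kick_rhs <- function(ks, u, mode_field_yz, xi,
                     repertoire = default_repertoire(), kp = kick_params()) {
  stopifnot(length(ks) == 4, length(u) == 3, length(mode_field_yz) == 2)
  d1 <- ks[1]; d2 <- ks[2]; dcr <- ks[3]; w <- ks[4]
  prox <- 0
  for (j in seq_along(repertoire$modes)) {
    m <- repertoire$modes[[j]]
    if (m$needs_kick && xi[j] > 1e-12)
      prox <- prox + xi[j] * mode_proximity(m, u[2], u[3])
  }
  fgate <- 1 / (1 + sum(mode_field_yz^2) / kp$fld_w^2)
  G <- fgate * prox
  trig <- stats::plogis((dcr - kp$theta_cr) / 0.01)
  d1p <- max(d1 - 0.15, 0) / 0.85
  c((kp$gamma_1 * d1 * (d1 - kp$theta_1) * (1 - d1) - d2 +
       kp$in_gain * trig) / kp$tau_delta,
    kp$eps_2 * (kp$d2_gain * d1 - d2) / kp$tau_delta,
    (G * (1 - kp$cr_suppress * d2) - dcr) / kp$tau_cr,
    kp$w_gain * d1p * (1 - w) - w / kp$tau_w)
}

# kick contribution to (dy/dt, dz/dt): pulse amplitude times the xi-weighted
# escape directions of the kick-gated modes (internal; mirrored in C++)
kick_output <- function(d1, u, xi, repertoire) {
  out <- c(0, 0)
  d1 <- max(d1 - 0.15, 0) / 0.85   # supra-threshold part of the pulse
  if (abs(d1) < 1e-14) return(out)
  for (j in seq_along(repertoire$modes)) {
    m <- repertoire$modes[[j]]
    if (m$needs_kick && xi[j] > 1e-12)
      out <- out + xi[j] * m$kick_amp * m$manifold$r *
        kick_direction(m, u[2], u[3])
  }
  d1 * out
}

#' Detect kick pulses in a recorded kick-signal pair
#'
#' Events are upward crossings of a threshold defined as a fraction of the
#' median peak amplitude of the run, merged within a refractory window of
#' twice the kick time scale.
#'
#' @param delta_series two-column matrix (delta_y, delta_z) or a numeric
#'   vector of amplitudes, uniformly sampled.
#' @param dt sampling interval.
#' @param threshold fraction of the median peak amplitude (default 0.5).
#' @param refractory merge window in time units (default 2 * tau_delta).
#' @param floor amplitudes below this never count as pulses.
#' @return data.frame with columns \code{time}, \code{amplitude},
#'   \code{index}; zero rows if no pulses.
#' @export
count_pulses <- function(delta_series, dt = 0.005, threshold = 0.5,
                         refractory = 0.2, floor = 0.05) {
  amp <- if (is.matrix(delta_series))
    sqrt(delta_series[, 1]^2 + delta_series[, 2]^2)
  else abs(as.numeric(delta_series))
  empty <- data.frame(time = numeric(0), amplitude = numeric(0),
                      index = integer(0))
  if (!length(amp) || all(amp <= floor)) return(empty)
  above <- amp > floor
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  peak <- vapply(which(runs$values), function(i)
    max(amp[starts[i]:ends[i]]), 0.0)
  thr <- max(threshold * stats::median(peak), floor)
  hot <- amp > thr
  up <- which(!hot[-length(hot)] & hot[-1]) + 1
  if (hot[1]) up <- c(1L, up)
  if (!length(up)) return(empty)
  merged <- up[c(TRUE, diff(up) * dt > refractory)]
  data.frame(time = (merged - 1) * dt,
             amplitude = vapply(merged, function(i) {
               j <- i:min(i + ceiling(refractory / dt), length(amp))
               max(amp[j])
             }, 0.0),
             index = as.integer(merged))
}
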