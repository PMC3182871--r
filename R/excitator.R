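#' Excitator-class planar phase flows
#'
#' The planar (y, z) dynamics of every character-generating functional mode
#' belongs to the Excitator family: a fast activation variable with a cubic
#' (N-shaped) nullcline and a slow recovery variable whose (linear) nullcline
#' selects the flow topology.  Writing u = y - 1 for the activation centred
#' between the two rest positions y = 0 and y = 2, the field is
#'
#'   dy/dt = (z - (u^3 - u)) / (mu_e * tau_f)
#'   dz/dt = -mu_e * (a_z * z + b_z * (u - u0)) / tau_f
#'
#' so that the cubic nullcline z = u^3 - u passes through (y, z) = (0, 0),
#' (1, 0) and (2, 0).  The slow nullcline a_z z + b_z (u - u0) = 0 then yields
#' the three nonlinear classes:
#' \itemize{
#'   \item \emph{bistable} (b_z = 0): point attractors at (0, 0) and (2, 0)
#'     separated by a saddle (separatrix) at (1, 0);
#'   \item \emph{monostable} (a_z = 1, b_z > 1/4, u0 = +/-1): a single point
#'     attractor at (2, 0) or (0, 0) with threshold (excitable) properties;
#'   \item \emph{limit_cycle} (a_z = 0, u0 = 0): a relaxation oscillation
#'     around an unstable focus at (1, 0).
#' }
#' The separation parameter mu_e in (0, 1) sets the fast/slow split that gives
#' the threshold behaviour; the canonical values are 0.15 (monostable),
#' 0.45 (bistable) and 0.60 (limit cycle).  Auxiliary position-setting modes
#' use a linear globally attracting flow instead ("linear" class).
#'
#' @param topology one of "monostable", "bistable", "limit_cycle", "linear".
#' @param mu_e threshold-separation parameter in (0, 1); defaults to the
#'   canonical value of the requested class.
#' @param attractor for the monostable class, the y position (0 or 2) of the
#'   point attractor.
#' @param a_z,b_z,u0 slow-nullcline coefficients; defaults follow the class.
#' @param k_lin,target linear-class attraction rate and fixed point (y, z).
#' @return an object of class \code{planar_flow_params}.
#' @export
planar_flow_params <- function(topology = c("monostable", "bistable",
                                            "limit_cycle", "linear"),
                               mu_e = NULL, attractor = 2,
                               a_z = NULL, b_z = NULL, u0 = NULL,
                               k_lin = 3, target = c(0, 0)) {
  topology <- match.arg(topology)
  canon <- c(monostable = 0.15, bistable = 0.45, limit_cycle = 0.60,
             linear = NA_real_)
  if (is.null(mu_e)) mu_e <- canon[[topology]]
  if (topology != "linear") {
    stopifnot(is.finite(mu_e), mu_e > 0, mu_e < 1)
    if (is.null(a_z)) a_z <- switch(topology, monostable = 1,
                                    bistable = 1, limit_cycle = 0)
    if (is.null(b_z)) b_z <- switch(topology, monostable = 0.55,
                                    bistable = 0, limit_cycle = 1.1)
    if (is.null(u0))  u0  <- switch(topology,
                                    monostable = if (attractor >= 1) 1 else -1,
                                    bistable = 0, limit_cycle = 0)
  } else {
    a_z <- b_z <- u0 <- 0
    mu_e <- NA_real_
  }
  structure(list(topology = topology, mu_e = mu_e, a_z = a_z, b_z = b_z,
                 u0 = u0, k_lin = k_lin, target = target, tau_f = 1),
            class = "planar_flow_params")
}

#' Construct canonical Excitator parameters from the separation parameter
#'
#' Maps the canonical threshold-separation values onto the default
#' representative of each topology class: 0.15 gives the monostable flow,
#' 0.45 the bistable flow and 0.60 the limit-cycle flow.  Other values are
#' assigned the class of the nearest canonical value (the nullclines are the
#' class defaults; the declared class must still agree with
#' \code{\link{classify_topology}}).
#'
#' @param mu_e threshold-separation parameter in (0, 1).
#' @param attractor attractor position for the monostable class.
#' @return a \code{planar_flow_params} object.
#' @export
excitator_params <- function(mu_e, attractor = 2) {
  stopifnot(is.finite(mu_e), mu_e > 0, mu_e < 1)
  canon <- c(monostable = 0.15, bistable = 0.45, limit_cycle = 0.60)
  cls <- names(canon)[which.min(abs(canon - mu_e))]
  planar_flow_params(cls, mu_e = mu_e, attractor = attractor)
}

#' Evaluate the deterministic planar vector field
#'
#' @param p a \code{planar_flow_params} object.
#' @param y,z coordinates (vectors of equal length are accepted).
#' @return list with components \code{dy_dt} and \code{dz_dt}.
#' @export
planar_flow <- function(p, y, z) {
  stopifnot(inherits(p, "planar_flow_params"))
  if (!all(is.finite(y), is.finite(z)))
    stop("planar_flow: non-finite coordinates")
  if (p$topology == "linear") {
    return(list(dy_dt = -p$k_lin * (y - p$target[1]),
                dz_dt = -p$k_lin * (z - p$target[2])))
  }
  u <- y - 1
  list(dy_dt = (z - (u^3 - u)) / (p$mu_e * p$tau_f),
       dz_dt = -p$mu_e * (p$a_z * z + p$b_z * (u - p$u0)) / p$tau_f)
}

# Jacobian of the planar field at (y, z)
planar_jacobian <- function(p, y, z) {
  if (p$topology == "linear")
    return(matrix(c(-p$k_lin, 0, 0, -p$k_lin), 2, 2))
  u <- y - 1
  matrix(c(-(3 * u^2 - 1) / (p$mu_e * p$tau_f), -p$mu_e * p$b_z / p$tau_f,
           1 / (p$mu_e * p$tau_f),              -p$mu_e * p$a_z / p$tau_f),
         2, 2)
}

#' Locate and classify the equilibria of a planar flow
#'
#' Equilibria are intersections of the cubic and slow nullclines, found by a
#' dense sign-change scan of the reduced 1-D root problem followed by
#' bisection polishing; stability comes from the eigenvalues of the analytic
#' Jacobian.  An equilibrium whose field residual exceeds 1e-8 after
#' polishing is rejected; an eigenvalue with |Re| below the hyperbolicity
#' margin 1e-6 yields stability class "indeterminate".
#'
#' @param p a \code{planar_flow_params} object.
#' @return data.frame with columns y, z, stability
#'   ("stable", "unstable", "saddle", "indeterminate").
#' @export
planar_fixed_points <- function(p) {
  stopifnot(inherits(p, "planar_flow_params"))
  if (p$topology == "linear") {
    return(data.frame(y = p$target[1], z = p$target[2],
                      stability = "stable", stringsAsFactors = FALSE))
  }
  # roots of h(u) = a_z * (u^3 - u) + b_z * (u - u0) on the cubic nullcline,
  # or the vertical slow nullcline u = u0 when a_z = 0
  if (abs(p$a_z) < 1e-12) {
    us <- p$u0
  } else {
    h <- function(u) p$a_z * (u^3 - u) + p$b_z * (u - p$u0)
    grid <- seq(-3, 3, length.out = 2001)
    hv <- h(grid)
    us <- numeric(0)
    sgn <- sign(hv)
    idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    for (i in idx) {
      r <- stats::uniroot(h, c(grid[i], grid[i + 1]), tol = 1e-14)
      us <- c(us, r$root)
    }
    exact <- grid[hv == 0]
    us <- sort(unique(round(c(us, exact), 12)))
  }
  out <- data.frame(y = numeric(0), z = numeric(0),
                    stability = character(0), stringsAsFactors = FALSE)
  for (u in us) {
    y <- u + 1
    z <- u^3 - u
    f <- planar_flow(p, y, z)
    if (max(abs(c(f$dy_dt, f$dz_dt))) > 1e-8) next
    J <- planar_jacobian(p, y, z)
    ev <- Re(eigen(J, only.values = TRUE)$values)
    stab <- if (any(abs(ev) < 1e-6)) "indeterminate"
            else if (all(ev < 0)) "stable"
            else if (all(ev > 0)) "unstable"
            else "saddle"
    out <- rbind(out, data.frame(y = y, z = z, stability = stab,
                                 stringsAsFactors = FALSE))
  }
  out
}

# fixed-step RK4 integration of the planar field (deterministic helper used
# by the topology detector and by tests; not the stochastic simulator)
integrate_planar <- function(p, y0, z0, dt = 0.002, t_end = 60) {
  n <- ceiling(t_end / dt)
  out <- matrix(NA_real_, n + 1, 2)
  out[1, ] <- c(y0, z0)
  s <- c(y0, z0)
  f <- function(s) {
    v <- planar_flow(p, s[1], s[2])
    c(v$dy_dt, v$dz_dt)
  }
  for (i in seq_len(n)) {
    k1 <- f(s); k2 <- f(s + dt / 2 * k1)
    k3 <- f(s + dt / 2 * k2); k4 <- f(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1, ] <- s
  }
  out
}

# detect a stable periodic orbit via upward crossings of the Poincare
# section y = 1 + u0; returns NULL or list(period, amplitude)
detect_limit_cycle <- function(p, t_end = 80, dt = 0.002) {
  tr <- integrate_planar(p, y0 = 1.05, z0 = 0.3, dt = dt, t_end = t_end)
  n <- nrow(tr)
  keep <- seq(floor(n / 2), n)   # discard transient
  y <- tr[keep, 1]; z <- tr[keep, 2]
  if (max(y) - min(y) < 1e-3) return(NULL)      # collapsed to a point
  sec <- 1 + p$u0
  up <- which(y[-length(y)] < sec & y[-1] >= sec & z[-1] > 0)
  if (length(up) < 3) return(NULL)
  periods <- diff(up) * dt
  if (stats::sd(periods) > 0.05 * mean(periods)) return(NULL)
  list(period = mean(periods), amplitude = max(y) - min(y))
}

#' Numerically classify the topology of a planar flow
#'
#' Counts stable equilibria (root finding on the nullcline intersections plus
#' linearisation) and, when no attracting point exists, tests for a stable
#' periodic orbit with a Poincare return map.  The declared topology label is
#' ignored.
#'
#' @param p a \code{planar_flow_params} object.
#' @return character scalar: "monostable", "bistable", "limit_cycle",
#'   "linear", or "indeterminate" when a non-hyperbolic equilibrium prevents
#'   classification.  The equilibrium table is attached as attribute
#'   \code{"equilibria"}.
#' @export
classify_topology <- function(p) {
  stopifnot(inherits(p, "planar_flow_params"))
  fp <- planar_fixed_points(p)
  if (p$topology == "linear" ||
      (nrow(fp) == 1 && fp$stability == "stable" &&
       abs(p$a_z) < 1e-12 && abs(p$b_z) < 1e-12)) {
    return(structure("linear", equilibria = fp))
  }
  if (any(fp$stability == "indeterminate"))
    return(structure("indeterminate", equilibria = fp))
  n_stable <- sum(fp$stability == "stable")
  cls <- if (n_stable >= 2) "bistable"
         else if (n_stable == 1) "monostable"
         else {
    lc <- detect_limit_cycle(p)
    if (is.null(lc)) "indeterminate" else "limit_cycle"
  }
  structure(cls, equilibria = fp)
}
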