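#' Shape-function parameters
#'
#' The axial (x) velocity of a writing mode is a modulation of the vertical
#' velocity: depending on the direction of the y-velocity (up- vs down-stroke)
#' and on the position of y (blended across the mid-line by a sigmoid), a gain
#' multiplies |dy/dt|.  Four gains cover the two stroke regimes times the two
#' height bands.
#'
#' @param g_up_lo,g_up_hi gains for the up-stroke below/above the mid-line.
#' @param g_dn_lo,g_dn_hi gains for the down-stroke below/above the mid-line.
#' @param y_center mid-line position of the height sigmoid (default 1).
#' @param y_steep steepness of the height sigmoid (> 0).
#' @param v_sharp sharpness scale of the velocity-direction sigmoid (> 0).
#' @return object of class \code{shape_params}.
#' @export
shape_params <- function(g_up_lo = 0, g_up_hi = 0, g_dn_lo = 0, g_dn_hi = 0,
                         y_center = 1, y_steep = 3, v_sharp = 0.05) {
  stopifnot(y_steep > 0, v_sharp > 0,
            all(is.finite(c(g_up_lo, g_up_hi, g_dn_lo, g_dn_hi))))
  structure(list(g_up_lo = g_up_lo, g_up_hi = g_up_hi,
                 g_dn_lo = g_dn_lo, g_dn_hi = g_dn_hi,
                 y_center = y_center, y_steep = y_steep, v_sharp = v_sharp),
            class = "shape_params")
}

#' Axial velocity from the shape function
#'
#' dx/dt as a function of the vertical position and velocity; the flow is not
#' a function of x itself.
#'
#' @param sp a \code{shape_params} object.
#' @param x horizontal position (accepted for signature completeness; the
#'   result does not depend on it).
#' @param y vertical position.
#' @param dy_dt vertical velocity.
#' @return dx/dt.
#' @export
shape_velocity <- function(sp, x, y, dy_dt) {
  stopifnot(inherits(sp, "shape_params"))
  up <- stats::plogis(dy_dt / sp$v_sharp)
  hi <- stats::plogis((y - sp$y_center) * sp$y_steep)
  g <- up * (sp$g_up_lo * (1 - hi) + sp$g_up_hi * hi) +
    (1 - up) * (sp$g_dn_lo * (1 - hi) + sp$g_dn_hi * hi)
  abs(dy_dt) * g
}

#' Manifold parameters
#'
#' The common manifold of all writing modes is the surface of a cylinder
#' running along the x-axis whose cross-section in the (y, z) plane is an
#' ellipse of semi-axis r (the radius, also the movement amplitude scale)
#' centred at y = c, with z semi-axis ecc * r.
#'
#' @param r radius (> 0), default 1.
#' @param c y-centre of the cross-section, default 1.
#' @param ecc axis ratio of the ellipse (z semi-axis / y semi-axis).
#' @return object of class \code{manifold_params}.
#' @export
manifold_params <- function(r = 1, c = 1, ecc = 0.4) {
  stopifnot(r > 0, ecc > 0)
  structure(list(r = r, c = c, ecc = ecc), class = "manifold_params")
}

#' Functional mode
#'
#' One character-generating structured flow: an Excitator-class planar flow
#' in (y, z), a shape function producing the letter geometry along x, the
#' cylindrical manifold carrying the flow, and the coupling constants that
#' tie the mode into the architecture (kick gating and inhibitory-feedback
#' drive).
#'
#' @param id integer mode id.
#' @param label character label (letter or auxiliary name).
#' @param planar a \code{planar_flow_params} object.
#' @param shape a \code{shape_params} object.
#' @param manifold a \code{manifold_params} object.
#' @param mu smallness parameter: the manifold contraction runs on time
#'   constant tau = mu * tau_f, i.e. ten times faster than the on-manifold
#'   flow at the default mu = 0.1.
#' @param needs_kick logical: does this mode require kicks for movement
#'   initiation (monostable/bistable character flows) or not (limit-cycle and
#'   auxiliary flows)?
#' @param kick_amp kick amplitude in glyph units (scaled by r on output).
#' @param prox_w width of the Gaussian attractor-proximity window (glyph
#'   units).
#' @param inh list(eps0, a, b, c): inhibitory-feedback drive constants:
#'   leak, kick-pulse gain (one fixed nu quantum per fired kick), trigger-ramp
#'   gain (lets nu cross its switching threshold while the next trigger is
#'   still charging, pre-empting a further kick), and continuous gain (used
#'   by limit-cycle and auxiliary modes that fire no kicks).
#' @return object of class \code{functional_mode}.
#' @export
functional_mode <- function(id, label, planar, shape = shape_params(),
                            manifold = manifold_params(), mu = 0.1,
                            needs_kick = FALSE, kick_amp = 5,
                            prox_w = 0.35,
                            inh = list(eps0 = 0.02, a = 0, b = 0, c = 0)) {
  stopifnot(inherits(planar, "planar_flow_params"),
            inherits(shape, "shape_params"),
            inherits(manifold, "manifold_params"),
            mu > 0, mu < 1, prox_w > 0)
  m <- structure(list(id = as.integer(id), label = label, planar = planar,
                      shape = shape, manifold = manifold, mu = mu,
                      needs_kick = isTRUE(needs_kick), kick_amp = kick_amp,
                      prox_w = prox_w, inh = inh),
                 class = "functional_mode")
  m$attractors <- compute_attractors(planar)   # cached glyph-frame attractors
  m
}

# stable attractor positions of a planar flow in glyph coordinates (Y, Z)
compute_attractors <- function(p) {
  if (p$topology == "linear")
    return(matrix(p$target, 1, 2, dimnames = list(NULL, c("Y", "Z"))))
  fp <- planar_fixed_points(p)
  fp <- fp[fp$stability == "stable", , drop = FALSE]
  if (!nrow(fp)) return(matrix(numeric(0), 0, 2))
  cbind(Y = fp$y, Z = fp$z)
}

# cached accessor
mode_attractors <- function(m) m$attractors

# Gaussian proximity of (y, z) to the nearest stable attractor, evaluated in
# glyph coordinates so that amplitude scaling leaves it invariant (internal)
mode_proximity <- function(m, y, z) {
  at <- mode_attractors(m)
  if (!nrow(at)) return(0)
  r <- m$manifold$r; e <- m$manifold$ecc
  Y <- (y - m$manifold$c) / r + 1
  Z <- z / r
  d2 <- min((Y - at[, 1])^2 + ((Z - at[, 2]) / e)^2)
  exp(-d2 / m$prox_w^2)
}

#' Manifold contraction field
#'
#' The fast radial component of a mode's field: gradient descent on the
#' squared manifold constraint, normalised so that the radial distance to the
#' cylinder surface decays with rate 1/tau = 1/(mu * tau_f).
#'
#' @param m a \code{functional_mode}.
#' @param y,z coordinates.
#' @return c(dy, dz) contraction contribution.
#' @export
manifold_contraction <- function(m, y, z) {
  r <- m$manifold$r; cy <- m$manifold$c; e <- m$manifold$ecc
  rho <- sqrt(((y - cy) / r)^2 + (z / (e * r))^2)   # normalised radius
  if (rho < 1e-4) return(c(0, 0))                   # centre: no direction
  grad <- c((y - cy) / (r^2 * rho), z / ((e * r)^2 * rho))
  ng2 <- sum(grad^2)
  if (ng2 < 1e-8) return(c(0, 0))
  tau <- m$mu * m$planar$tau_f
  if (is.na(tau)) tau <- m$mu
  -(rho - 1) * grad / (tau * ng2)
}

#' Full three-dimensional field of a functional mode
#'
#' The structured flow: planar Excitator dynamics in (y, z) (evaluated in
#' glyph coordinates and rescaled by the manifold radius, so amplitude
#' scaling does not alter the time structure), the shape-function axial
#' velocity along x, and the fast contraction onto the cylinder surface.
#' Auxiliary (linear) modes have no contraction and no axial motion.
#'
#' @param m a \code{functional_mode}.
#' @param u state 3-vector (x, y, z).
#' @return du/dt 3-vector.
#' @export
mode_field <- function(m, u) {
  stopifnot(inherits(m, "functional_mode"), length(u) == 3,
            all(is.finite(u)))
  y <- u[2]; z <- u[3]
  p <- m$planar
  if (p$topology == "linear") {
    return(c(0, -p$k_lin * (y - p$target[1]), -p$k_lin * (z - p$target[2])))
  }
  r <- m$manifold$r; cy <- m$manifold$c
  Y <- (y - cy) / r + 1
  Z <- z / r
  pf <- planar_flow(p, Y, Z)
  contr <- manifold_contraction(m, y, z)
  # apply only the component of the contraction normal to the planar flow:
  # the manifold narrows the flow tube but never opposes motion along it,
  # so no spurious equilibria arise away from the planar fixed points
  fv <- c(r * pf$dy_dt, r * pf$dz_dt)
  nf2 <- sum(fv^2)
  if (nf2 > 1e-6) contr <- contr - sum(contr * fv) / nf2 * fv
  c(r * shape_velocity(m$shape, u[1], Y, pf$dy_dt),
    fv[1] + contr[1],
    fv[2] + contr[2])
}

#' Scale the movement amplitude of a mode
#'
#' Multiplies the manifold radius (and with it the whole glyph geometry) by a
#' positive factor.  Because the planar flow is evaluated in glyph
#' coordinates, the phase-flow topology and the cycle duration are unchanged
#' (isochrony).
#'
#' @param m a \code{functional_mode}.
#' @param factor positive scalar.
#' @return a rescaled \code{functional_mode}.
#' @export
scale_amplitude <- function(m, factor) {
  stopifnot(inherits(m, "functional_mode"))
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) ||
      factor <= 0)
    stop("scale_amplitude: factor must be a positive scalar")
  m$manifold$r <- m$manifold$r * factor
  m
}

#' Auxiliary position-setting mode
#'
#' A linear, globally attracting point-attractor flow that parks the pen at
#' the given (y, z) position; no axial motion, no kicks.
#'
#' @param target_y,target_z the fixed point.
#' @param id,label identifiers.
#' @param k_lin attraction rate.
#' @return a \code{functional_mode}.
#' @export
auxiliary_mode <- function(target_y, target_z, id = 0L, label = "aux",
                           k_lin = 3) {
  stopifnot(is.finite(target_y), is.finite(target_z))
  functional_mode(id, label,
                  planar_flow_params("linear", k_lin = k_lin,
                                     target = c(target_y, target_z)),
                  inh = list(eps0 = 0.01, a = 0, b = 0, c = 0.25))
}

#' The default repertoire of K = 37 functional modes
#'
#' Modes 1-7 implement the characters used by the packaged words: 'f', 'l',
#' 'o' (monostable, rest at (0, 0)), 'w' (limit cycle), 'v' (monostable,
#' point attractor at (2, 0)), 'i' (bistable, attractors at (0, 0) and
#' (2, 0)) and 'e' (monostable, rest at (0, 0)).  Modes 8-35 fill the
#' repertoire with letter variants cycling through the three nonlinear
#' classes (the repertoire is deliberately much larger than any one word
#' needs).  Modes 36 and 37 are the auxiliary position-setting modes at
#' (0, 0) and (2, 0).  All glyph geometry (shape gains) and the
#' feedback/kick coupling constants are committed package defaults,
#' recalibrated so that the packaged words are produced with the reference
#' gain vectors.
#'
#' @return object of class \code{repertoire}.
#' @export
default_repertoire <- function() {
  mono0 <- function() planar_flow_params("monostable", attractor = 0)
  mono2 <- function() planar_flow_params("monostable", attractor = 2)
  bist  <- function() planar_flow_params("bistable")
  lc    <- function() planar_flow_params("limit_cycle")

  modes <- vector("list", 37L)
  # principal characters ------------------------------------------------
  modes[[1]] <- functional_mode(1, "f", mono0(),
    shape_params(0.10, 0.06, 0.16, 0.10), needs_kick = TRUE,
    kick_amp = 5, inh = list(eps0 = 0.01, a = 0.10, b = 0, c = 0))
  modes[[2]] <- functional_mode(2, "l", mono0(),
    shape_params(0.05, 0.03, 0.20, 0.10), needs_kick = TRUE,
    kick_amp = 5, inh = list(eps0 = 0.01, a = 0.52, b = 0, c = 0))
  modes[[3]] <- functional_mode(3, "o", mono0(),
    shape_params(-0.12, -0.10, 0.16, 0.14), needs_kick = TRUE,
    kick_amp = 5, inh = list(eps0 = 0.01, a = 0.52, b = 0, c = 0))
  modes[[4]] <- functional_mode(4, "w", lc(),
    shape_params(0.12, 0.12, 0.12, 0.12),
    inh = list(eps0 = 0.01, a = 0, b = 0, c = 0.23))
  modes[[5]] <- functional_mode(5, "v", mono2(),
    shape_params(0.10, 0.08, 0.12, 0.08), needs_kick = TRUE,
    kick_amp = 5, inh = list(eps0 = 0.01, a = 0.217, b = 0, c = 0))
  modes[[6]] <- functional_mode(6, "i", bist(),
    shape_params(0.10, 0.06, 0.06, 0.04), needs_kick = TRUE,
    kick_amp = 5, inh = list(eps0 = 0.01, a = 2.07, b = 0, c = 0))
  modes[[7]] <- functional_mode(7, "e", mono0(),
    shape_params(0.14, 0.08, 0.10, 0.06), needs_kick = TRUE,
    kick_amp = 5, inh = list(eps0 = 0.01, a = 0.52, b = 0, c = 0))
  # filler variants -----------------------------------------------------
  planars <- list(mono0, mono2, bist, lc)
  for (k in 8:35) {
    w <- (k - 8) %% 4 + 1
    gain <- 0.04 + 0.01 * ((k - 8) %% 7)
    modes[[k]] <- functional_mode(k, sprintf("g%02d", k),
      planars[[w]](),
      shape_params(gain, gain / 2, gain, gain / 2),
      needs_kick = w <= 3, kick_amp = 5,
      inh = list(eps0 = 0.01, a = if (w <= 3) 0.52 else 0, b = 0,
                 c = if (w == 4) 0.22 else 0))
  }
  # auxiliary position-setting modes ------------------------------------
  modes[[36]] <- auxiliary_mode(0, 0, id = 36, label = "aux-start")
  modes[[37]] <- auxiliary_mode(2, 0, id = 37, label = "aux-end")
  structure(list(modes = modes, K = 37L), class = "repertoire")
}

#' @export
print.repertoire <- function(x, ...) {
  cat("Functional-mode repertoire, K =", x$K, "modes\n")
  for (m in x$modes[seq_len(min(8, x$K))])
    cat(sprintf("  %2d %-9s %s\n", m$id, m$label, m$planar$topology))
  if (x$K > 8) cat("  ...\n")
  invisible(x)
}

#' Write / read a repertoire parameter table
#'
#' One row per mode with every scalar parameter; tab-separated, '.' decimal,
#' Unix newlines.  The round trip is exact to double precision.
#'
#' @param rep a \code{repertoire}.
#' @param path file path.
#' @return \code{read_repertoire_tsv} returns a \code{repertoire}.
#' @export
write_repertoire_tsv <- function(rep, path) {
  stopifnot(inherits(rep, "repertoire"))
  rows <- lapply(rep$modes, function(m) {
    p <- m$planar; s <- m$shape; mf <- m$manifold
    data.frame(id = m$id, label = m$label, topology = p$topology,
               mu_e = p$mu_e, a_z = p$a_z, b_z = p$b_z, u0 = p$u0,
               k_lin = p$k_lin, target_y = p$target[1],
               target_z = p$target[2],
               g_up_lo = s$g_up_lo, g_up_hi = s$g_up_hi,
               g_dn_lo = s$g_dn_lo, g_dn_hi = s$g_dn_hi,
               y_center = s$y_center, y_steep = s$y_steep,
               v_sharp = s$v_sharp,
               r = mf$r, c = mf$c, ecc = mf$ecc, mu = m$mu,
               needs_kick = m$needs_kick, kick_amp = m$kick_amp,
               prox_w = m$prox_w, inh_eps0 = m$inh$eps0, inh_a = m$inh$a,
               inh_b = m$inh$b, inh_c = m$inh$c, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(format(tab, digits = 17, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' @rdname write_repertoire_tsv
#' @export
read_repertoire_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  modes <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    planar <- if (r$topology == "linear")
      planar_flow_params("linear", k_lin = r$k_lin,
                         target = c(r$target_y, r$target_z))
    else
      planar_flow_params(r$topology, mu_e = r$mu_e, a_z = r$a_z,
                         b_z = r$b_z, u0 = r$u0)
    functional_mode(r$id, r$label, planar,
      shape_params(r$g_up_lo, r$g_up_hi, r$g_dn_lo, r$g_dn_hi,
                   r$y_center, r$y_steep, r$v_sharp),
      manifold_params(r$r, r$c, r$ecc), mu = r$mu,
      needs_kick = r$needs_kick, kick_amp = r$kick_amp, prox_w = r$prox_w,
      inh = list(eps0 = r$inh_eps0, a = r$inh_a, b = r$inh_b, c = r$inh_c))
  })
  structure(list(modes = modes, K = nrow(tab)), class = "repertoire")
}
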