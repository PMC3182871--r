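#' Winner-Take-All competition over mode weights
#'
#' The weighting coefficients xi_j of the functional modes obey a
#' Lotka-Volterra-type competition with mutual inhibition,
#'
#'   tau_c * dxi_j/dt = (kappa / C_j) * xi_j *
#'                      ( L_j - xi_j^2 - sum_{k != j} (C_j / C_k) xi_k^2 )
#'
#' restricted to the non-negative orthant (kappa = 3 is a fixed rate scale).
#' L_j in \{0, 1\} gates whether mode j takes part in the current competition
#' round and the positive parameters C_j decide its outcome: for generic
#' parameters the system has one unstable node at the origin, one point
#' attractor on the axis of the winner -- the participating mode with the
#' smallest C_j -- at height sqrt(L_j) = 1, and saddles on all other axes.
#' The 1/C_j rate scaling leaves every equilibrium and its stability class
#' unchanged but makes the growth from small weights fastest for the mode
#' with the smallest C, so the outcome of each round is decided
#' deterministically rather than by the noise floor.  Equal smallest C values
#' among participants give a continuum (circle) of equilibria and no definite
#' winner.
#'
#' @param L 0/1 participation vector.
#' @param C positive competition parameters, same length as L.
#' @param C0 baseline value the C of an inhibited sequence mode relaxes to.
#' @param tau_c competition time constant (default 0.1).
#' @return object of class \code{competition_params}.
#' @export
competition_params <- function(L, C, C0 = 0.5, tau_c = 0.1) {
  stopifnot(length(L) == length(C), all(C > 0), all(L %in% c(0, 1)),
            tau_c > 0)
  structure(list(L = as.numeric(L), C = as.numeric(C), C0 = C0,
                 tau_c = tau_c), class = "competition_params")
}

#' Winner-Take-All vector field
#'
#' @param xi non-negative weight vector.
#' @param p a \code{competition_params} object.
#' @return dxi/dt, same length as xi.
#' @export
wta_rhs <- function(xi, p) {
  stopifnot(inherits(p, "competition_params"), length(xi) == length(p$L))
  if (any(!is.finite(xi)) || any(xi < 0))
    stop("wta_rhs: xi must be finite and non-negative")
  wta_field(xi, p)
}

#' All equilibria of the WTA system in the closed non-negative orthant
#'
#' Support-enumeration: for each subset of participating modes the interior
#' equilibrium restricted to that support solves a linear system in xi^2;
#' solutions with any non-positive component are discarded.  Stability comes
#' from the analytic Jacobian; near-singular support systems are flagged as a
#' degenerate continuum (identical circular nullclines).
#'
#' @param p a \code{competition_params} object (all modes analysed must have
#'   L_j > 0; modes with L_j = 0 only admit the zero coordinate).
#' @return list with elements \code{equilibria} (list of lists with fields
#'   \code{point}, \code{stability}) and \code{degenerate} flag.
#' @export
wta_equilibria <- function(p) {
  stopifnot(inherits(p, "competition_params"))
  K <- length(p$L)
  if (K > 12) stop("wta_equilibria: support enumeration limited to K <= 12")
  act <- which(p$L > 0)
  res <- list()
  degenerate <- FALSE
  add <- function(point) {
    f <- wta_field(point, p)
    if (max(abs(f)) > 1e-9) return(invisible(NULL))
    J <- wta_jacobian(point, p)
    ev <- Re(eigen(J, only.values = TRUE)$values)
    stab <- if (any(abs(ev) < 1e-9)) "degenerate"
            else if (all(ev < 0)) "stable"
            else if (all(ev > 0)) "unstable"
            else "saddle"
    res[[length(res) + 1]] <<- list(point = point, stability = stab)
    if (stab == "degenerate") degenerate <<- TRUE
    invisible(NULL)
  }
  add(rep(0, K))  # the origin
  if (length(act)) {
    for (m in seq_len(2^length(act) - 1)) {
      sup <- act[bitwAnd(m, bitwShiftL(1, seq_along(act) - 1)) != 0]
      # on support S: L_j = xi_j^2 + sum_{k in S, k != j} (C_j/C_k) xi_k^2
      # in q = xi^2: A q = L  with A[j, k] = C_j / C_k, diagonal 1
      Cs <- p$C[sup]
      A <- outer(Cs, Cs, "/")
      diag(A) <- 1
      qr_A <- qr(A)
      if (qr_A$rank < length(sup)) {
        # rank-deficient support: a continuum of equilibria exists only if
        # the system is consistent (identical nullclines, i.e. equal C)
        q0 <- qr.coef(qr_A, p$L[sup])
        q0[is.na(q0)] <- 0
        if (max(abs(A %*% q0 - p$L[sup])) < 1e-9) degenerate <- TRUE
        next
      }
      q <- solve(qr_A, p$L[sup])
      if (any(q <= 1e-12)) next
      point <- rep(0, K)
      point[sup] <- sqrt(q)
      add(point)
    }
  }
  list(equilibria = res, degenerate = degenerate)
}

# competition rate scale kappa (internal constant)
wta_kappa <- 3

# raw field without the non-negativity checks (internal)
wta_field <- function(xi, p) {
  S <- sum(xi^2 / p$C)
  (wta_kappa / p$C) * xi * (p$L - p$C * S) / p$tau_c
}

# analytic Jacobian of the WTA field
wta_jacobian <- function(xi, p) {
  K <- length(xi)
  S <- sum(xi^2 / p$C)
  J <- matrix(0, K, K)
  for (j in seq_len(K)) {
    for (m in seq_len(K)) {
      J[j, m] <- if (j == m)
        (wta_kappa / p$C[j]) * (p$L[j] - p$C[j] * S - 2 * xi[j]^2) / p$tau_c
      else
        -2 * wta_kappa * xi[j] * xi[m] / (p$C[m] * p$tau_c)
    }
  }
  J
}

#' Index of the winning mode
#'
#' The winner of a competition round is the participating mode (L_j > 0) with
#' the smallest competition parameter C_j; its axis equilibrium is the unique
#' point attractor.  An exact or near tie (C values within 1e-9) has no
#' definite winner and raises an error.
#'
#' @param p a \code{competition_params} object.
#' @return integer mode index.
#' @export
winner_index <- function(p) {
  stopifnot(inherits(p, "competition_params"))
  act <- which(p$L > 0)
  if (!length(act)) stop("winner_index: no participating mode (all L = 0)")
  Cs <- p$C[act]
  o <- order(Cs)
  if (length(act) > 1 && abs(Cs[o[1]] - Cs[o[2]]) < 1e-9)
    stop("winner_index: degenerate competition, no definite winner (tied C = ",
         format(Cs[o[1]]), ")")
  act[o[1]]
}
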