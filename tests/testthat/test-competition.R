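test_that("origin is an equilibrium and the field is pure and sign-correct", {
  p <- competition_params(c(1, 1), c(1, 2))
  expect_equal(wta_rhs(c(0, 0), p), c(0, 0))
  eqs <- wta_equilibria(p)$equilibria
  stable <- Filter(function(e) e$stability == "stable", eqs)[[1]]
  expect_equal(wta_rhs(stable$point, p), c(0, 0), tolerance = 1e-12)
  expect_error(wta_rhs(c(-0.1, 0.2), p), "non-negative")
})

test_that("two-mode equilibrium structure matches the phase-space analysis", {
  # smaller C wins: attractor on the first axis at height 1, saddle on the
  # second axis, unstable node at the origin
  p <- competition_params(c(1, 1), c(1, 2))
  eq <- wta_equilibria(p)
  expect_false(eq$degenerate)
  stab <- vapply(eq$equilibria, `[[`, "", "stability")
  pts <- do.call(rbind, lapply(eq$equilibria, `[[`, "point"))
  expect_identical(stab[rowSums(pts) == 0], "unstable")
  win <- pts[stab == "stable", ]
  expect_equal(win, c(1, 0), tolerance = 1e-9)
  expect_identical(stab[pts[, 1] == 0 & pts[, 2] > 0], "saddle")
  # mirrored parameters: second mode wins at height 1
  p2 <- competition_params(c(1, 1), c(2, 1))
  eq2 <- wta_equilibria(p2)
  stab2 <- vapply(eq2$equilibria, `[[`, "", "stability")
  pts2 <- do.call(rbind, lapply(eq2$equilibria, `[[`, "point"))
  expect_equal(pts2[stab2 == "stable", ], c(0, 1), tolerance = 1e-9)
})

test_that("equal competition parameters give a degenerate continuum", {
  p <- competition_params(c(1, 1), c(2, 2))
  expect_true(wta_equilibria(p)$degenerate)
  expect_error(winner_index(p), "degenerate")
})

test_that("single-mode equilibrium agrees with a dense 1-D root scan", {
  p <- competition_params(1, 3)
  eq <- wta_equilibria(p)$equilibria
  stable <- Filter(function(e) e$stability == "stable", eq)
  expect_length(stable, 1)
  # independent oracle: sign-change scan of the 1-D field plus bisection
  f <- function(x) vapply(x, function(v) wta_rhs(v, p), 0.0)
  grid <- seq(1e-4, 3, length.out = 5000)
  fv <- f(grid)
  i <- which(sign(fv[-1]) * sign(fv[-length(fv)]) < 0)[1]
  root <- uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)$root
  expect_equal(stable[[1]]$point, root, tolerance = 1e-9)
})

test_that("winner follows the smallest C among participants", {
  expect_equal(winner_index(competition_params(c(1, 1), c(1, 2))), 1L)
  expect_equal(winner_index(competition_params(c(1, 1), c(2, 1))), 2L)
  expect_equal(winner_index(competition_params(c(0, 1, 1), c(1, 5, 3))), 3L)
  expect_error(winner_index(competition_params(c(0, 0), c(1, 2))),
               "no participating")
})

test_that("integration from random positive states converges to the analytic attractor", {
  set.seed(42)
  for (rep_i in 1:6) {
    K <- sample(2:4, 1)
    C <- sort(runif(K, 0.5, 4))          # distinct with margin
    while (min(diff(C)) < 0.2) C <- sort(runif(K, 0.5, 4))
    p <- competition_params(rep(1, K), C)
    eq <- wta_equilibria(p)
    stable <- Filter(function(e) e$stability == "stable", eq$equilibria)
    expect_length(stable, 1)
    target <- stable[[1]]$point
    expect_equal(which(target > 0), winner_index(p))
    for (ic_i in 1:8) {
      xi <- runif(K, 0.05, 1.5)
      dt <- 0.002
      for (step in 1:20000) xi <- pmax(xi + dt * wta_rhs(xi, p), 0)
      expect_equal(xi, target, tolerance = 1e-6)
    }
  }
})

test_that("analytic Jacobian matches finite differences at every equilibrium", {
  p <- competition_params(c(1, 1, 1), c(1, 1.7, 2.9))
  for (e in wta_equilibria(p)$equilibria) {
    x <- e$point
    J <- sfmflow:::wta_jacobian(x, p)
    h <- 1e-6
    Jfd <- sapply(seq_along(x), function(m) {
      xp <- x; xm <- x
      xp[m] <- xp[m] + h; xm[m] <- pmax(xm[m] - h, 0)
      (sfmflow:::wta_field(xp, p) - sfmflow:::wta_field(xm, p)) /
        (xp[m] - xm[m])
    })
    expect_equal(J, Jfd, tolerance = 1e-4)
  }
})

test_that("generic parameters give one unstable node, one attractor, K-1 saddles", {
  for (K in 2:4) {
    C <- seq(1, by = 0.8, length.out = K)
    eq <- wta_equilibria(competition_params(rep(1, K), C))
    stab <- vapply(eq$equilibria, `[[`, "", "stability")
    expect_equal(sum(stab == "unstable"), 1)
    expect_equal(sum(stab == "stable"), 1)
    expect_equal(sum(stab == "saddle"), K - 1)
  }
})
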