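test_that("shape velocity is zero for zero gains and direction-asymmetric otherwise", {
  sp0 <- shape_params(0, 0, 0, 0)
  expect_equal(shape_velocity(sp0, 0, 0.7, 1.2), 0)
  sp <- shape_params(0.1, 0.1, 0.3, 0.3)
  up <- shape_velocity(sp, 0, 1, 1)
  dn <- shape_velocity(sp, 0, 1, -1)
  expect_false(isTRUE(all.equal(up, dn)))
  # independent of x
  expect_equal(shape_velocity(sp, -5, 1, 1), shape_velocity(sp, 17, 1, 1))
})

test_that("a full movement cycle of 'l' advances the pen rightwards", {
  tr <- single_mode_replay(2, duration = 30)
  d <- tr$data
  expect_gt(d[nrow(d), "x"] - d[1, "x"], 0.3)
})

test_that("mode field vanishes at an on-manifold fixed point", {
  rep <- default_repertoire()
  v <- rep$modes[[5]]                  # attractor (2, 0), on the manifold
  expect_equal(mode_field(v, c(0, 2, 0)), c(0, 0, 0), tolerance = 1e-10)
})

test_that("manifold contraction pulls random off-manifold points in at rate 1/tau", {
  # linearised-contraction oracle: with the planar flow frozen, the radial
  # distance after 5 tau is below 1% of the initial distance
  m <- default_repertoire()$modes[[2]]
  tau <- m$mu * 1
  set.seed(7)
  for (i in 1:100) {
    th <- runif(1, 0, 2 * pi)
    r0 <- runif(1, 0.2, 1.5)
    pt <- c(1 + (1 + r0) * cos(th), m$manifold$ecc * (1 + r0) * sin(th))
    dist0 <- abs(sqrt(sum(((pt - c(1, 0)) / c(1, m$manifold$ecc))^2)) - 1)
    dt <- 0.001
    for (s in seq_len(round(5 * tau / dt)))
      pt <- pt + dt * manifold_contraction(m, pt[1], pt[2])
    dist1 <- abs(sqrt(sum(((pt - c(1, 0)) / c(1, m$manifold$ecc))^2)) - 1)
    expect_lt(dist1, 0.01 * dist0)
  }
})

test_that("radial decay is an order of magnitude faster than the planar flow", {
  # a point displaced radially decays with rate ~ 1/tau = 10 (decay-fit)
  m <- default_repertoire()$modes[[2]]
  pt <- c(1, 0.44)                      # 10% radially out at the z-extreme
  dt <- 0.001; tgrid <- seq(0, 0.2, by = dt)
  dist <- numeric(length(tgrid))
  for (i in seq_along(tgrid)) {
    dist[i] <- abs(sqrt(sum(((pt - c(1, 0)) / c(1, m$manifold$ecc))^2)) - 1)
    pt <- pt + dt * manifold_contraction(m, pt[1], pt[2])
  }
  fit <- stats::lm(log(dist) ~ tgrid)
  expect_equal(unname(coef(fit)[2]), -1 / (m$mu), tolerance = 0.15)
})

test_that("amplitude scaling preserves parameters, topology and cycle duration", {
  rep <- default_repertoire()
  w <- rep$modes[[4]]
  expect_identical(scale_amplitude(w, 1), w)
  expect_equal(scale_amplitude(w, 2)$manifold$r, 2)
  expect_error(scale_amplitude(w, -1), "positive")
  for (f in c(0.25, 0.5, 2, 4))
    expect_identical(as.character(classify_topology(
      scale_amplitude(w, f)$planar)), "limit_cycle")
  # isochrony: cycle duration invariant to the amplitude (design: within 5%)
  period_of <- function(fac) {
    rep2 <- rep
    rep2$modes[[4]] <- scale_amplitude(rep$modes[[4]], fac)
    tr <- single_mode_replay(4, duration = 40, rep = rep2,
                             ic = c(1 + 0.3 * fac, 0.3 * fac))
    y <- tr$data[, "y"]
    mid <- 1
    up <- which(y[-1] > mid & y[-length(y)] <= mid)
    stats::median(diff(up)) * tr$config$dt
  }
  p1 <- period_of(1)
  expect_equal(period_of(0.5), p1, tolerance = 0.05)
  expect_equal(period_of(2), p1, tolerance = 0.05)
})

test_that("auxiliary modes are linear point attractors at the printed targets", {
  a36 <- auxiliary_mode(0, 0, id = 36)
  a37 <- auxiliary_mode(2, 0, id = 37)
  expect_equal(mode_field(a36, c(0, 0, 0)), c(0, 0, 0))
  expect_equal(mode_field(a37, c(0, 2, 0)), c(0, 0, 0))
  # linearity about the attractor: field at target + 2d = 2 x field at + d
  d <- c(0, 0.3, -0.2)
  f1 <- mode_field(a36, c(0, 0, 0) + d)
  f2 <- mode_field(a36, c(0, 0, 0) + 2 * d)
  expect_equal(f2, 2 * f1, tolerance = 1e-12)
})

test_that("repertoire has unique ids and survives a TSV round trip", {
  rep <- default_repertoire()
  expect_equal(rep$K, 37L)
  ids <- vapply(rep$modes, `[[`, 0L, "id")
  expect_false(anyDuplicated(ids) > 0)
  f <- tempfile(fileext = ".tsv")
  write_repertoire_tsv(rep, f)
  rep2 <- read_repertoire_tsv(f)
  expect_equal(sfmflow:::flatten_modes(rep2), sfmflow:::flatten_modes(rep),
               tolerance = 1e-12)
})
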