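# build a synthetic ensemble object directly (fixture helper)
make_ensemble <- function(trials, dt = 0.01) {
  tt <- seq(0, by = dt, length.out = nrow(trials[[1]]))
  trials <- lapply(trials, function(m) {
    m <- cbind(t = tt, m)
    m
  })
  structure(list(trials = trials, time = tt,
                 config = sim_config("view", record = "analysis"),
                 ic_policy = "identical", master_seed = 0,
                 trial_seeds = seq_along(trials)),
            class = "sfm_ensemble")
}

blank_trial <- function(n, y = 0, z = 0, dy = 0, dz = 0) {
  m <- cbind(x = 0, y = y, z = z, dy_dt = dy, dz_dt = dz,
             delta_y = 0, delta_z = 0, d1 = 0,
             matrix(0, n, 6, dimnames = list(NULL, paste0("xi_seq_", 1:6))))
  m
}

test_that("identical noise-free trials are bitwise equal with zero SD", {
  e <- ensemble_run("view", n = 3, ic_policy = "identical", master_seed = 5,
                    duration = 6, s = 0)
  expect_identical(e$trials[[1]], e$trials[[2]])
  expect_identical(e$trials[[1]], e$trials[[3]])
  st <- pointwise_stats(e)
  expect_equal(max(abs(st$sd)), 0)
})

test_that("distinct master seeds give distinct ensembles of equal shape", {
  e1 <- ensemble_run("view", n = 2, master_seed = 1, duration = 5)
  e2 <- ensemble_run("view", n = 2, master_seed = 2, duration = 5)
  expect_equal(dim(e1$trials[[1]]), dim(e2$trials[[1]]))
  expect_false(identical(e1$trials[[1]], e2$trials[[1]]))
})

test_that("pointwise statistics match the closed form for a constant offset pair", {
  n <- 500
  c0 <- 0.37
  e <- make_ensemble(list(blank_trial(n, y = c0), blank_trial(n, y = -c0)))
  st <- pointwise_stats(e)
  # SD with denominator n - 1 over {+c, -c} is c * sqrt(2)
  expect_equal(unname(st$sd[, "y"]), rep(c0 * sqrt(2), n), tolerance = 1e-12)
  expect_equal(unname(st$mean[, "y"]), rep(0, n), tolerance = 1e-12)
})

test_that("matching of identical trials is the identity with zero distance", {
  n <- 1200
  y <- sin(seq(0, 6 * pi, length.out = n)) + 1
  z <- 0.4 * cos(seq(0, 6 * pi, length.out = n))
  e <- make_ensemble(list(blank_trial(n, y = y, z = z),
                          blank_trial(n, y = y, z = z)))
  st <- pointwise_stats(e)
  m <- suppressWarnings(rearrange_nn(e, st, T_w = 100))
  expect_equal(max(m$distance), 0)
  expect_equal(m$index[, 1], seq_len(n))
})

test_that("a time-shifted copy is recovered at the shift inside the window", {
  n <- 2000
  ph <- seq(0, 8 * pi, length.out = n)
  y1 <- sin(ph) + 1; z1 <- 0.4 * cos(ph)
  sh <- 50                                   # samples, < T_w / 2
  y2 <- c(y1[-(1:sh)], y1[(n - sh + 1):n])   # shifted copy
  z2 <- c(z1[-(1:sh)], z1[(n - sh + 1):n])
  e <- make_ensemble(list(blank_trial(n, y = y1, z = z1),
                          blank_trial(n, y = y2, z = z2)))
  st <- pointwise_stats(e)
  m <- suppressWarnings(rearrange_nn(e, st, T_w = 300))
  mid <- 400:1500
  offs <- m$index[mid, 2] - mid
  # the mean lies between the trials; the matched offset of the shifted
  # trial compensates about half the relative shift
  expect_lt(stats::median(abs(m$distance[mid, 2])), 0.05)
  expect_true(stats::median(offs) <= -sh %/% 2 + 2 &&
                stats::median(offs) >= -sh)
  # shift far beyond the window: residual distances at fast-motion points
  sh2 <- 400
  y3 <- c(y1[-(1:sh2)], y1[(n - sh2 + 1):n])
  z3 <- c(z1[-(1:sh2)], z1[(n - sh2 + 1):n])
  e2 <- make_ensemble(list(blank_trial(n, y = y1, z = z1),
                           blank_trial(n, y = y3, z = z3)))
  st2 <- pointwise_stats(e2)
  m2 <- suppressWarnings(rearrange_nn(e2, st2, T_w = 300))
  expect_gt(max(m2$distance[mid, 2]), 0.1)
})

test_that("matched distances never exceed identity-matching distances", {
  e <- ensemble_run("view", n = 6, master_seed = 4, duration = 12)
  st <- pointwise_stats(e)
  m <- suppressWarnings(rearrange_nn(e, st, T_w = 300))
  for (k in seq_along(e$trials)) {
    d_id <- sqrt((e$trials[[k]][, "y"] - st$mean[, "y"])^2 +
                   (e$trials[[k]][, "z"] - st$mean[, "z"])^2)
    expect_true(all(m$distance[, k] <= d_id + 1e-12))
  }
})

test_that("a stationary single-mode ensemble yields no event labels", {
  set.seed(31)
  n <- 3000
  trials <- lapply(1:8, function(k) {
    ph <- seq(0, 12 * pi, length.out = n) + runif(1, 0, 0.05)
    blank_trial(n, y = sin(ph) + 1 + rnorm(n, 0, 0.002),
                z = 0.4 * cos(ph) + rnorm(n, 0, 0.002),
                dy = cos(ph) + rnorm(n, 0, 0.01),
                dz = -0.4 * sin(ph) + rnorm(n, 0, 0.01))
  })
  e <- make_ensemble(trials)
  st <- pointwise_stats(e)
  m <- suppressWarnings(rearrange_nn(e, st, T_w = 300))
  seg <- classify_segments(st, m)
  expect_equal(nrow(seg), 0)
})

test_that("x is excluded from the analysed variables", {
  e <- ensemble_run("view", n = 2, master_seed = 3, duration = 5)
  expect_false("x" %in% colnames(pointwise_stats(e)$mean))
})
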