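test_that("assembled field is the weighted sum of mode fields (linearity)", {
  cfg <- sim_config("flow", seed = 1)
  rep <- cfg$repertoire
  u <- c(0.3, 0.8, 0.1)
  base <- list(u = u, xi = rep(0, 37), nu = rep(0.2, 6), lam = rep(1, 6),
               kick = c(0, 0, 0, 0))
  s0 <- base; s0$xi[3] <- 1
  f1 <- assemble_field(s0, cfg)
  expect_equal(f1$du, mode_field(rep$modes[[3]], u), tolerance = 1e-12)
  szero <- base
  expect_equal(assemble_field(szero, cfg)$du, c(0, 0, 0), tolerance = 1e-12)
  sab <- base; sab$xi[1] <- 0.4; sab$xi[2] <- 0.7
  fab <- assemble_field(sab, cfg)
  expect_equal(fab$du,
               0.4 * mode_field(rep$modes[[1]], u) +
                 0.7 * mode_field(rep$modes[[2]], u),
               tolerance = 1e-12)
})

test_that("compiled integrator reproduces the reference right-hand side", {
  cfg <- sim_config("flow", seed = 4, duration = 0.02, s = 0)
  set.seed(4)
  st <- sfmflow:::initial_state(cfg)
  ref <- assemble_field(st, cfg)
  cfg$ic <- utils::modifyList(cfg$ic, list(xi = st$xi, nu = st$nu,
                                           lam = st$lam, kick = st$kick))
  tr <- integrate_em(cfg)
  d <- tr$data
  # the recorded derivative at the first step is the deterministic RHS
  expect_equal(unname(d[1, "dy_dt"]), ref$du[2], tolerance = 1e-10)
  expect_equal(unname(d[1, "dz_dt"]), ref$du[3], tolerance = 1e-10)
  # and one Euler step moves the state by dt * RHS
  dt <- cfg$dt
  expect_equal(unname(d[2, "y"] - d[1, "y"]), dt * ref$du[2],
               tolerance = 1e-10)
  expect_equal(unname(d[2, paste0("nu_", 1:6)] - d[1, paste0("nu_", 1:6)]),
               dt * ref$dnu, tolerance = 1e-10)
  expect_equal(unname(d[2, paste0("lam_", 1:6)] - d[1, paste0("lam_", 1:6)]),
               pmin(pmax(dt * ref$dlam + st$lam, -1), 1) - st$lam,
               tolerance = 1e-10)
})

test_that("noise-free runs are deterministic and seeded runs reproducible", {
  t1 <- run_word("flow", seed = 9, duration = 10, s = 0)
  t2 <- run_word("flow", seed = 9, duration = 10, s = 0)
  expect_identical(t1$data, t2$data)
  t3 <- run_word("flow", seed = 9, duration = 10, s = 0.001)
  t4 <- run_word("flow", seed = 9, duration = 10, s = 0.001)
  expect_identical(t3$data, t4$data)
  t5 <- run_word("flow", seed = 10, duration = 10, s = 0.001)
  expect_false(identical(t3$data, t5$data))
})

test_that("halving the step size shrinks the terminal error about linearly", {
  term <- function(dt) {
    cfg <- sim_config("flow", seed = 2, duration = 6, s = 0, dt = dt,
                      record_stride = max(1L, as.integer(0.01 / dt)))
    cfg$ic <- utils::modifyList(cfg$ic, list(
      xi = rep(1e-3, 37), nu = rep(0, 6), lam = rep(1, 6),
      kick = c(0, 0, 0, 0)))
    d <- integrate_em(cfg)$data
    d[nrow(d), c("y", "z")]
  }
  ref <- term(0.000625)
  e1 <- sqrt(sum((term(0.005) - ref)^2))
  e2 <- sqrt(sum((term(0.0025) - ref)^2))
  expect_gt(e1 / e2, 1.5)   # first-order convergence: ratio ~ 2
  expect_lt(e1 / e2, 3)
})

test_that("'flow' is generated in the configured order and repeats autonomously", {
  tr <- run_word("flow", seed = 3, duration = 220)
  ev <- event_log(tr)
  labs <- paste(ev$activations$label, collapse = " ")
  expect_true(grepl(
    "aux-start f l o w aux-end aux-start f l o w aux-end aux-start f l o w",
    labs, fixed = TRUE))
  expect_gte(length(ev$completions), 3)   # at least three repetitions
  # activation intervals are ordered and non-overlapping
  a <- ev$activations
  expect_true(all(diff(a$t_start) > 0))
  expect_true(all(a$t_end[-nrow(a)] <= a$t_start[-1] + 1e-9))
})

test_that("'view' runs v, i, e, w between the auxiliary modes", {
  tr <- run_word("view", seed = 2, duration = 120)
  labs <- paste(event_log(tr)$activations$label, collapse = " ")
  expect_true(grepl("aux-start v i e w aux-end aux-start v i e w", labs,
                    fixed = TRUE))
})

test_that("non-participating weights stay near zero throughout", {
  tr <- run_word("flow", seed = 6, duration = 120)
  d <- tr$data
  nonseq <- setdiff(seq_len(37), tr$config$seq$ids)
  mx <- max(d[, paste0("xi_", nonseq)])
  expect_lt(mx, 0.05)
})

test_that("open-loop replay of recorded weights reproduces the output", {
  cfg <- sim_config("flow", seed = 8, duration = 40, s = 0)
  cfg$ic <- utils::modifyList(cfg$ic, list(
    xi = rep(1e-3, 37), nu = rep(0, 6), lam = rep(1, 6),
    kick = c(0, 0, 0, 0)))
  tr <- integrate_em(cfg)
  xi_series <- tr$data[, paste0("xi_", 1:37)]
  tr2 <- replay_with_prescribed_xi(xi_series, cfg)
  expect_equal(tr2$data[, "y"], tr$data[, "y"], tolerance = 1e-6)
  expect_equal(tr2$data[, "z"], tr$data[, "z"], tolerance = 1e-6)
})

test_that("unknown words are rejected and blow-ups abort with a diagnostic", {
  expect_error(run_word("nope"), "unknown word")
  cfg <- sim_config("flow", seed = 1, duration = 5)
  cfg$ic$y0 <- 1e7   # far outside the admissible region
  expect_error(integrate_em(cfg), "blow-up")
})
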