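test_that("sharpening sigmoid is a monotone map onto [0, 1]", {
  expect_lt(sigmoid_S(0), 0.01)
  expect_gt(sigmoid_S(1), 0.99)
  expect_equal(sigmoid_S(-1e6), 0)
  expect_equal(sigmoid_S(1e6), 1)
  v <- sigmoid_S(seq(-2, 3, by = 0.01))
  expect_true(all(diff(v) >= 0))
})

test_that("switching equilibria flip with the sigmoid value as printed", {
  # intermediate S: five equilibria, attractors at 0 and +/-1
  eq5 <- equilibria_1d(0.5)
  expect_equal(nrow(eq5), 5)
  stable <- eq5$lam[eq5$stability == "stable"]
  expect_equal(sort(stable), c(-1, 0, 1), tolerance = 1e-9)
  expect_equal(sum(eq5$stability == "unstable"), 2)
  # S near 0: the rest state destabilises, +/-1 attract
  eq_lo <- equilibria_1d(0.09)
  expect_identical(eq_lo$stability[abs(eq_lo$lam) < 1e-9], "unstable")
  expect_true(all(eq_lo$stability[abs(abs(eq_lo$lam) - 1) < 1e-9] ==
                    "stable"))
  # S near 1: +/-1 destabilise, 0 attracts
  eq_hi <- equilibria_1d(0.85)
  expect_identical(eq_hi$stability[abs(eq_hi$lam) < 1e-9], "stable")
  expect_true(all(eq_hi$stability[abs(abs(eq_hi$lam) - 1) < 1e-9] !=
                    "stable"))
})

test_that("equilibrium count at S = 0.5 is confirmed by a 10x finer scan", {
  expect_equal(nrow(equilibria_1d(0.5, n = 3001)),
               nrow(equilibria_1d(0.5, n = 30001)))
})

test_that("quasi-static sweeps of S show hysteresis", {
  sweep_to <- function(lam0, s_path) {
    lam <- lam0
    trans_at <- NA
    for (S in s_path) {
      for (i in 1:400) lam <- lam + 0.005 * switching_rhs(lam, S)
      lam <- max(min(lam, 1), -1)
      if (is.na(trans_at) && abs(lam - lam0) > 0.5) trans_at <- S
    }
    trans_at
  }
  up <- sweep_to(1, seq(0.4, 1, by = 0.02))     # 1 -> 0 transition
  dn <- sweep_to(0.001, seq(0.6, 0, by = -0.02))  # 0 -> 1 transition
  expect_false(is.na(up)); expect_false(is.na(dn))
  expect_gt(up - dn, 0.2)   # bistable band between the two switching points
})

test_that("participation gates implement the subsequent-mode rule exhaustively", {
  rep <- default_repertoire()
  sq <- sequence_spec(c(10, 11, 12, 13), k_inh = rep(5, 4))
  for (mask in 0:15) {
    inhibited <- bitwAnd(mask, 2^(0:3)) > 0
    lam <- ifelse(inhibited, 0, 1)
    L <- gate_L(lam, sq, K = 37)
    for (j in 1:4) {
      expected <- as.numeric(!any(inhibited[j:4]))
      expect_equal(L[sq$ids[j]], expected,
                   info = sprintf("mask %d pos %d", mask, j))
    }
    expect_true(all(L[-sq$ids] == 1))   # non-sequence modes always compete
  }
  # last mode inhibited shuts every gate (the reset precondition)
  expect_true(all(gate_L(c(1, 1, 1, 0), sq, 37)[sq$ids] == 0))
})

test_that("primacy parameters interpolate between C0 and the gradient", {
  sq <- sequence_spec(c(10, 11, 12), k_inh = rep(5, 3))
  C_fresh <- primacy_C(c(1, 1, 1), sq, 37)
  expect_equal(C_fresh[sq$ids], sq$primacy)
  C_done <- primacy_C(c(0, 0, 0), sq, 37)
  expect_equal(C_done[sq$ids], rep(sq$C0, 3))
  expect_true(all(C_fresh >= sq$C0) && all(C_done >= sq$C0))
  expect_true(all(C_fresh[-sq$ids] == sq$C_nonseq))
})

test_that("gates and primacy compose with the competition to give the configured order", {
  for (word in c("flow", "view")) {
    sq <- word_spec(word)
    Kp <- length(sq$ids)
    for (m in 0:(Kp - 1)) {
      lam <- c(rep(0, m), rep(1, Kp - m))   # first m modes executed
      p <- competition_params(gate_L(lam, sq, 37), primacy_C(lam, sq, 37))
      expect_equal(winner_index(p), sq$ids[m + 1],
                   info = sprintf("%s after %d executed", word, m))
    }
  }
})

test_that("feedback integration accrues only for the executing mode and resets on completion", {
  rep <- default_repertoire()
  sq <- word_spec("flow", rep)
  Kp <- length(sq$ids)
  xi <- rep(1e-3, 37)
  fs <- list(nu = rep(0.2, Kp), lam = rep(1, Kp))
  # nothing executing, sequence incomplete: essentially no drift
  dnu <- feedback_rhs(fs, c(0, 0, 0), xi, sq, rep, kick = c(0, 0, 0, 0.5))
  expect_true(all(abs(dnu) < 1e-3))
  # mode at position 2 executing with a charged arrival memory: accumulates
  xi2 <- xi; xi2[sq$ids[2]] <- 1
  dnu2 <- feedback_rhs(fs, c(0, 0, 0), xi2, sq, rep, kick = c(0, 0, 0, 0.5))
  expect_gt(dnu2[2], 0.002)
  expect_true(all(abs(dnu2[-2]) < 1e-3))
  # final mode executed (lambda_K' = 0): every nu relaxes towards zero
  fs3 <- list(nu = rep(0.5, Kp), lam = c(rep(1, Kp - 1), 0))
  dnu3 <- feedback_rhs(fs3, c(0, 0, 0), xi, sq, rep, kick = c(0, 0, 0, 0))
  expect_true(all(dnu3 < 0))
})

test_that("nu is nondecreasing while its mode executes noise-free", {
  tr <- run_word("flow", seed = 5, duration = 80, s = 0)
  d <- tr$data
  ev <- event_log(tr)
  a <- ev$activations
  sq <- tr$config$seq
  row <- a[a$label == "l", ][1, ]
  pos <- match(row$mode, sq$ids)
  sel <- d[, "t"] >= row$t_start & d[, "t"] <= row$t_end
  nu <- d[sel, paste0("nu_", pos)]
  expect_true(all(diff(nu) > -1e-12))
})
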