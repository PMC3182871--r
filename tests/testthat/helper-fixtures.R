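# shared fixtures: small, fast configurations used across test files

quick_flow <- function(seed = 1, duration = 60, s = 0.001, ...) {
  run_word("flow", seed = seed, duration = duration, s = s, ...)
}

# unit-weight open-loop replay of a single mode
single_mode_replay <- function(j, duration = 30, seed = 11, s = 0.001,
                               ic = NULL, rep = default_repertoire()) {
  cfg <- sim_config("flow", repertoire = rep, seed = seed,
                    duration = duration, s = s)
  n <- ceiling(cfg$duration / cfg$dt)
  xi <- matrix(0, n + 1, rep$K)
  xi[, j] <- 1
  if (is.null(ic)) {
    at <- rep$modes[[j]]$attractors
    ic <- c(at[1, 1], at[1, 2])
  }
  cfg$ic$y0 <- ic[1]; cfg$ic$z0 <- ic[2]
  replay_with_prescribed_xi(xi, cfg)
}

# word-level kick counts between successive sequence starts
kicks_per_word <- function(tr) {
  ev <- event_log(tr)
  st <- ev$activations$t_start[ev$activations$label == "aux-start"]
  if (length(st) < 2) return(integer(0))
  vapply(seq_len(length(st) - 1), function(i)
    sum(ev$kicks$time >= st[i] & ev$kicks$time < st[i + 1]), 0L)
}
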