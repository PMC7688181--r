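# Independent reference implementations used as oracles. These stay naive
# (explicit loops, modular arithmetic, literal rule tables) on purpose so
# they share no code path with the vectorized implementation.

# Random lattice state built directly from grids, bypassing init_lattice().
random_state <- function(side, p_rep = 0.5, p_att = 0.5, p_exp = 0.5) {
  n <- side^2
  lattice_state(
    matrix(runif(n) < p_rep, side, side),
    matrix(runif(n) < p_att, side, side),
    matrix(runif(n) < p_exp, side, side)
  )
}

# Torus neighbour tallies by explicit per-agent loop.
naive_counts <- function(state) {
  L <- state$side
  n_a <- matrix(0L, L, L); n_b <- matrix(0L, L, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      nb <- rbind(
        c((i - 2L) %% L + 1L, j), c(i %% L + 1L, j),
        c(i, (j - 2L) %% L + 1L), c(i, j %% L + 1L)
      )
      ex <- state$express[nb]; at <- state$attitude_a[nb]
      n_a[i, j] <- sum(ex & at)
      n_b[i, j] <- sum(ex & !at)
    }
  }
  list(n_a = n_a, n_b = n_b, n_silent = 4L - n_a - n_b)
}

# Per-agent reference step: naive tallies + the scalar decision function.
naive_step <- function(state) {
  cnt <- naive_counts(state)
  L <- state$side
  new_express <- matrix(FALSE, L, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      d <- decide_behavior(
        if (state$reputation[i, j]) "reputation" else "consensus",
        if (state$attitude_a[i, j]) "a" else "b",
        cnt$n_a[i, j], cnt$n_b[i, j], cnt$n_silent[i, j]
      )
      new_express[i, j] <- d == "express"
    }
  }
  out <- state
  out$express <- new_express
  out$t <- state$t + 1L
  out
}

# Literal transcription of the decision table, indexed by local state and
# majority/minority status. Used to check decide_behavior() against the
# published rule rather than against itself.
table_rule <- function(agent_type, own_attitude, n_a, n_b) {
  voiced <- n_a + n_b
  label <-
    if (voiced == 0L) "TS"
    else if (n_a == n_b) "ST"
    else if (n_a > 0L && n_b > 0L) "Mm"
    else if (n_a == 4L || n_b == 4L) "FM"
    else "PM"
  if (label %in% c("TS", "ST")) {
    return(if (agent_type == "reputation") "express" else "silent")
  }
  majority <- if (n_a > n_b) "a" else "b"
  holds_majority <- own_attitude == majority
  # rows: Mm -> C_M S, C_m S, R_M S, R_m E ; PM/FM -> C_M E, others S
  row <- switch(label,
    Mm = c(C_M = "silent", C_m = "silent", R_M = "silent", R_m = "express"),
    PM = c(C_M = "express", C_m = "silent", R_M = "silent", R_m = "silent"),
    FM = c(C_M = "express", C_m = "silent", R_M = "silent", R_m = "silent")
  )
  col <- paste0(if (agent_type == "consensus") "C" else "R",
                if (holds_majority) "_M" else "_m")
  unname(row[col])
}

# All 15 admissible neighbour-count triples.
all_count_triples <- function() {
  g <- expand.grid(n_a = 0:4, n_b = 0:4)
  g <- g[g$n_a + g$n_b <= 4L, ]
  g$n_silent <- 4L - g$n_a - g$n_b
  g
}

# Exact (transient, cycle) for a deterministic map by walking with a
# visited table; independent of detect_cycle_exact's duplicated/match
# logic and of run_simulation's hashing.
walk_orbit <- function(state, max_steps = 1000L) {
  seen <- character(0)
  s <- state
  for (t in 0:max_steps) {
    key <- paste(as.integer(s$express), collapse = "")
    hit <- match(key, seen)
    if (!is.na(hit)) {
      return(list(transient_length = hit - 1L, cycle_length = t - (hit - 1L),
                  digests = seen))
    }
    seen <- c(seen, key)
    s <- synchronous_step(s)
  }
  list(transient_length = NA_integer_, cycle_length = NA_integer_,
       digests = seen)
}

# Replay states from a starting state (for trajectory cross-checks).
replay_states_from <- function(state, n_steps) {
  out <- vector("list", n_steps)
  out[[1]] <- state
  for (k in seq_len(n_steps - 1L)) {
    out[[k + 1L]] <- synchronous_step(out[[k]])
  }
  out
}

# Replay a run's states from its config.
replay_states <- function(config, n_steps) {
  replay_states_from(init_lattice(config), n_steps)
}
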