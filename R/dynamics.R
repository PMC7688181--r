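# Synchronous update core. All agents decide from the same (old) behaviour
# grid; types and attitudes never change. Works directly on the logical
# grids so run_simulation can avoid per-step object construction.
step_express_grid <- function(express, attitude_a, reputation, up, dn) {
  ea <- express & attitude_a
  eb <- express & !attitude_a
  n_a <- ea[up, , drop = FALSE] + ea[dn, , drop = FALSE] +
    ea[, up, drop = FALSE] + ea[, dn, drop = FALSE]
  n_b <- eb[up, , drop = FALSE] + eb[dn, , drop = FALSE] +
    eb[, up, drop = FALSE] + eb[, dn, drop = FALSE]
  ts_st <- n_a == n_b                      # total silence or stalemate
  mm <- n_a > 0L & n_b > 0L & !ts_st       # majority with minority
  pm_fm <- !ts_st & !mm                    # partial or full majority
  maj_a <- n_a > n_b
  (ts_st & reputation) |
    (mm & reputation & (attitude_a != maj_a)) |
    (pm_fm & !reputation & (attitude_a == maj_a))
}

# Compact string digest of a behaviour configuration (bit-packed).
config_digest <- function(express) {
  v <- as.logical(express)
  pad <- (32L - length(v) %% 32L) %% 32L
  paste(packBits(c(v, logical(pad)), type = "integer"), collapse = ",")
}

#' Advance the lattice one synchronous step
#'
#' Every agent simultaneously re-decides its behaviour from the decision
#' table applied to the \emph{current} behaviours of its four neighbours.
#' Types and attitudes are unchanged; the time index increments. The map
#' is deterministic.
#'
#' @param state A `lattice_state`.
#' @return The successor `lattice_state`.
#' @export
synchronous_step <- function(state) {
  L <- state$side
  up <- c(L, seq_len(L - 1L))
  dn <- c(seq_len(L - 1L) + 1L, 1L)
  state$express <- step_express_grid(state$express, state$attitude_a,
                                     state$reputation, up, dn)
  state$t <- state$t + 1L
  state
}

#' Run one full simulation
#'
#' Iterates the synchronous update from a freshly initialized lattice,
#' recording per-step observables and a digest of every behaviour
#' configuration. Because the dynamics are deterministic on a finite
#' state space, the first repeated configuration marks the entry into the
#' run's limit cycle; by default the run stops there.
#'
#' @param config A [sim_config()].
#' @param stop_on_cycle Stop as soon as a configuration recurs (default).
#'   With `FALSE` the run always continues to `config$max_steps`, which
#'   is what the lag-based cycle estimator
#'   ([estimate_cycle_lag()]) expects.
#' @return An object of class `sim_run`: a list with elements
#'   \describe{
#'     \item{config}{the configuration used.}
#'     \item{state}{the final `lattice_state`.}
#'     \item{trajectory}{a tibble with one row per recorded step:
#'       `t`, `silence_count`, `expressed_a`, `expressed_b`, the five
#'       per-agent local-state counts, and `digest`.}
#'     \item{cycle}{list `transient_length`, `cycle_length`, `censored`
#'       (see [detect_cycle_exact()]); `cycle_length` is `NA` when
#'       censored.}
#'     \item{delta_a}{the run's constant attitude gap.}
#'   }
#' @examples
#' run <- run_simulation(sim_config(6, 0.5, max_steps = 500, seed = 7))
#' run$cycle$cycle_length
#' @export
run_simulation <- function(config, stop_on_cycle = TRUE) {
  validate_sim_config(config)
  state <- init_lattice(config)
  L <- config$lattice_side
  n <- L * L
  up <- c(L, seq_len(L - 1L))
  dn <- c(seq_len(L - 1L) + 1L, 1L)
  express <- state$express
  attitude_a <- state$attitude_a
  reputation <- state$reputation
  max_rec <- config$max_steps
  digests <- character(max_rec)
  sil <- integer(max_rec); exa <- integer(max_rec); exb <- integer(max_rec)
  ls_counts <- matrix(0L, max_rec, 5L,
                      dimnames = list(NULL, local_state_labels))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  transient <- NA_integer_
  cycle_len <- NA_integer_
  n_rec <- 0L
  stopped_early <- FALSE
  for (t in seq_len(max_rec) - 1L) {
    dg <- config_digest(express)
    # observables of the configuration at time t; the neighbour tallies
    # below are also the inputs of the step t -> t+1
    ea <- express & attitude_a
    eb <- express & !attitude_a
    n_a <- ea[up, , drop = FALSE] + ea[dn, , drop = FALSE] +
      ea[, up, drop = FALSE] + ea[, dn, drop = FALSE]
    n_b <- eb[up, , drop = FALSE] + eb[dn, , drop = FALSE] +
      eb[, up, drop = FALSE] + eb[, dn, drop = FALSE]
    ts_st <- n_a == n_b
    ts <- ts_st & n_a == 0L
    mm <- n_a > 0L & n_b > 0L & !ts_st
    fm <- n_a == 4L | n_b == 4L
    n_rec <- n_rec + 1L
    digests[n_rec] <- dg
    exa[n_rec] <- sum(ea); exb[n_rec] <- sum(eb)
    sil[n_rec] <- n - exa[n_rec] - exb[n_rec]
    ls_counts[n_rec, ] <- c(sum(ts), sum(ts_st) - sum(ts), sum(mm),
                            n - sum(ts_st) - sum(mm) - sum(fm), sum(fm))
    prev <- seen[[dg]]
    if (!is.null(prev)) {
      if (is.na(transient)) {
        transient <- prev
        cycle_len <- t - prev
      }
      if (stop_on_cycle) {
        stopped_early <- TRUE
        break
      }
    } else {
      seen[[dg]] <- t
    }
    maj_a <- n_a > n_b
    express <- (ts_st & reputation) |
      (mm & reputation & (attitude_a != maj_a)) |
      (!ts_st & !mm & !reputation & (attitude_a == maj_a))
  }
  keep <- seq_len(n_rec)
  trajectory <- tibble::tibble(
    t = keep - 1L,
    silence_count = sil[keep],
    expressed_a = exa[keep],
    expressed_b = exb[keep]
  )
  for (lab in local_state_labels) {
    trajectory[[paste0("n_", lab)]] <- ls_counts[keep, lab]
  }
  trajectory$digest <- digests[keep]
  # final state: the configuration at the last recorded step when the run
  # stopped at a recurrence, otherwise the configuration one step past it
  state$express <- express
  state$t <- if (stopped_early) n_rec - 1L else n_rec
  structure(
    list(
      config = config,
      state = state,
      trajectory = trajectory,
      cycle = list(
        transient_length = transient,
        cycle_length = cycle_len,
        censored = is.na(cycle_len)
      ),
      delta_a = as.integer(sum(attitude_a) - sum(!attitude_a))
    ),
    class = "sim_run"
  )
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("<sim_run> %dx%d torus, r_density = %.2f, seed = %d\n",
              x$config$lattice_side, x$config$lattice_side,
              x$config$r_density, x$config$seed))
  if (x$cycle$censored) {
    cat(sprintf("  no recurrence within %d steps (censored)\n",
                x$config$max_steps))
  } else {
    cat(sprintf("  transient %d steps, limit cycle of length %d\n",
                x$cycle$transient_length, x$cycle$cycle_length))
  }
  invisible(x)
}

as_digests <- function(x) {
  if (inherits(x, "sim_run")) x$trajectory$digest
  else as.character(x)
}

#' Exact limit-cycle detection by first recurrence
#'
#' The synchronous dynamics are deterministic, so the first configuration
#' that reappears starts the limit cycle: if the configuration at step
#' `t2` equals the one first seen at step `t1 < t2`, the transient is
#' `t1` and the period is `t2 - t1` (period 1 is a fixed point). When no
#' configuration repeats within the recorded horizon the result is
#' censored.
#'
#' @param x A `sim_run`, or a character vector of per-step configuration
#'   digests.
#' @return List with `transient_length`, `cycle_length` (`NA` when
#'   censored) and `censored`.
#' @examples
#' detect_cycle_exact(c("A", "B", "A"))  # period 2, no transient
#' @export
detect_cycle_exact <- function(x) {
  d <- as_digests(x)
  if (length(d) == 0L) stop("trajectory is empty", call. = FALSE)
  j <- which(duplicated(d))[1L]
  if (is.na(j)) {
    return(list(transient_length = NA_integer_, cycle_length = NA_integer_,
                censored = TRUE))
  }
  i <- match(d[j], d)
  list(transient_length = i - 1L, cycle_length = j - i, censored = FALSE)
}

#' Lag-based cycle-length estimator
#'
#' Estimates the period from the stable part of a trajectory without
#' assuming where the transient ends: for every step in the second half
#' of the recorded trajectory, take the smallest positive lag at which an
#' identical configuration occurs anywhere in the trajectory, and return
#' the maximum of those minimal lags. On a trajectory whose second half
#' lies entirely inside the cycle this equals the exact period. Returns
#' `NA` (censored) if some second-half configuration never recurs.
#'
#' @param x A `sim_run` (ideally produced with `stop_on_cycle = FALSE`),
#'   or a character vector of per-step configuration digests of length
#'   at least 2.
#' @return Integer period estimate, or `NA_integer_`.
#' @examples
#' estimate_cycle_lag(rep(c("A", "B", "C"), 6))  # 3
#' @export
estimate_cycle_lag <- function(x) {
  d <- as_digests(x)
  n <- length(d)
  if (n < 2L) stop("trajectory must have length >= 2", call. = FALSE)
  grp <- match(d, unique(d))
  pos <- split(seq_len(n), grp)
  half <- (n %/% 2L + 1L):n
  worst <- 0L
  for (t in half) {
    p <- pos[[grp[t]]]
    p <- p[p != t]
    if (length(p) == 0L) return(NA_integer_)
    lag <- min(abs(p - t))
    if (lag > worst) worst <- lag
  }
  as.integer(worst)
}

#' Equilibrium window of a run
#'
#' Row indices of the trajectory used for equilibrium statistics: the
#' final detected cycle (one full period) when a cycle was found, or the
#' last 10\% of recorded steps when the run is censored.
#'
#' @param run A `sim_run`.
#' @return Integer vector of trajectory row indices.
#' @export
equilibrium_window <- function(run) {
  stopifnot(inherits(run, "sim_run"))
  n <- nrow(run$trajectory)
  if (run$cycle$censored) {
    seq.int(n - ceiling(0.1 * n) + 1L, n)
  } else {
    run$cycle$transient_length + seq_len(run$cycle$cycle_length)
  }
}
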