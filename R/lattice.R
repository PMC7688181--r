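#' Construct a lattice state from explicit grids
#'
#' Low-level constructor used by [init_lattice()] and by tests that need
#' hand-specified configurations. Grids may be logical matrices or
#' character matrices (`"consensus"`/`"reputation"`, `"a"`/`"b"`,
#' `"silent"`/`"express"`).
#'
#' @param type L x L agent types: `TRUE`/`"reputation"` for reputation
#'   seekers, `FALSE`/`"consensus"` for consensus seekers. Fixed for the
#'   whole run.
#' @param attitude L x L private attitudes: `TRUE`/`"a"` or `FALSE`/`"b"`.
#'   Fixed for the whole run; an expressing agent always voices its own
#'   attitude.
#' @param express L x L current behaviours: `TRUE`/`"express"` or
#'   `FALSE`/`"silent"`.
#' @param t Integer time index (default 0).
#'
#' @return An object of class `lattice_state`.
#' @examples
#' st <- lattice_state(matrix(TRUE, 2, 2), matrix(c(TRUE, FALSE), 2, 2),
#'                     matrix(FALSE, 2, 2))
#' @export
lattice_state <- function(type, attitude, express, t = 0L) {
  as_flag <- function(m, true_word, field) {
    if (is.character(m)) m <- m == true_word
    if (!is.logical(m) || !is.matrix(m) || anyNA(m)) {
      stop("`", field, "` must be a logical or character matrix without NAs",
           call. = FALSE)
    }
    m
  }
  type <- as_flag(type, "reputation", "type")
  attitude <- as_flag(attitude, "a", "attitude")
  express <- as_flag(express, "express", "express")
  dims <- list(dim(type), dim(attitude), dim(express))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])) ||
      dims[[1]][1] != dims[[1]][2]) {
    stop("all grids must be square matrices of identical shape", call. = FALSE)
  }
  structure(
    list(
      side = nrow(type),
      reputation = type,   # TRUE = reputation seeker
      attitude_a = attitude, # TRUE = attitude a
      express = express,   # TRUE = expressing this step
      t = as.integer(t)
    ),
    class = "lattice_state"
  )
}

#' @export
print.lattice_state <- function(x, ...) {
  n <- x$side^2
  cat(sprintf(
    "<lattice_state> %dx%d torus, t = %d\n  reputation seekers: %d/%d  attitude a: %d/%d  expressing: %d/%d\n",
    x$side, x$side, x$t, sum(x$reputation), n, sum(x$attitude_a), n,
    sum(x$express), n
  ))
  invisible(x)
}

#' Initialize a random lattice
#'
#' Builds the starting configuration of a run: exactly
#' `round(r_density * L^2)` reputation seekers placed uniformly at random,
#' independent Bernoulli(`p_attitude_a`) private attitudes, and
#' independent Bernoulli(`p_initial_express`) initial behaviours. Types
#' and attitudes are then held fixed for the whole run; only behaviour
#' evolves.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A `lattice_state` at `t = 0`.
#' @examples
#' st <- init_lattice(sim_config(10, 0.65, seed = 1))
#' sum(st$reputation)  # exactly 65
#' @export
init_lattice <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(as.integer(seed))
  L <- config$lattice_side
  n <- L * L
  n_rep <- round(config$r_density * n)
  rep_grid <- matrix(FALSE, L, L)
  if (n_rep > 0L) rep_grid[sample.int(n, n_rep)] <- TRUE
  att_grid <- matrix(runif(n) < config$p_attitude_a, L, L)
  exp_grid <- matrix(runif(n) < config$p_initial_express, L, L)
  lattice_state(rep_grid, att_grid, exp_grid, t = 0L)
}

#' Tally each agent's neighbourhood
#'
#' Counts, for every agent, how many of its four von Neumann neighbours
#' (on the torus) currently voice opinion `a`, voice opinion `b`, or are
#' silent. A voiced opinion is the neighbour's own attitude: agents never
#' misreport.
#'
#' @param state A `lattice_state`.
#' @return A list of three L x L integer matrices `n_a`, `n_b`,
#'   `n_silent`, summing to 4 everywhere.
#' @export
neighbor_counts <- function(state) {
  L <- state$side
  up <- c(L, seq_len(L - 1L))
  dn <- c(seq_len(L - 1L) + 1L, 1L)
  ea <- state$express & state$attitude_a
  eb <- state$express & !state$attitude_a
  n_a <- ea[up, , drop = FALSE] + ea[dn, , drop = FALSE] +
    ea[, up, drop = FALSE] + ea[, dn, drop = FALSE]
  n_b <- eb[up, , drop = FALSE] + eb[dn, , drop = FALSE] +
    eb[, up, drop = FALSE] + eb[, dn, drop = FALSE]
  list(n_a = n_a, n_b = n_b, n_silent = 4L - n_a - n_b)
}

#' Classify a local network state
#'
#' Maps neighbour tallies to one of the five local network states. The
#' five classes partition all 15 admissible `(n_a, n_b, n_silent)`
#' triples:
#' \describe{
#'   \item{total_silence}{no neighbour voices anything.}
#'   \item{stalemate}{equal nonzero numbers voice `a` and `b`.}
#'   \item{full_majority}{all four neighbours voice the same opinion.}
#'   \item{majority_with_minority}{both opinions voiced, unequally.}
#'   \item{partial_majority}{exactly one opinion voiced, by 1-3 neighbours.}
#' }
#'
#' @param n_a,n_b,n_silent Integer vectors (recycled to a common length)
#'   of neighbours voicing `a`, voicing `b`, and silent; each triple must
#'   sum to 4.
#' @return Character vector of labels from [local_state_labels].
#' @examples
#' classify_local_state(0, 0, 4)  # "total_silence"
#' classify_local_state(2, 1, 1)  # "majority_with_minority"
#' @export
classify_local_state <- function(n_a, n_b, n_silent) {
  k <- max(length(n_a), length(n_b), length(n_silent))
  n_a <- rep_len(as.integer(n_a), k)
  n_b <- rep_len(as.integer(n_b), k)
  n_silent <- rep_len(as.integer(n_silent), k)
  if (anyNA(n_a) || anyNA(n_b) || anyNA(n_silent) ||
      any(n_a < 0 | n_b < 0 | n_silent < 0) ||
      any(n_a + n_b + n_silent != 4L)) {
    stop("neighbour counts must be nonnegative and sum to 4", call. = FALSE)
  }
  out <- character(k)
  voiced <- n_a + n_b
  out[voiced == 0L] <- "total_silence"
  out[voiced > 0L & n_a == n_b] <- "stalemate"
  out[n_a == 4L | n_b == 4L] <- "full_majority"
  out[n_a > 0L & n_b > 0L & n_a != n_b] <- "majority_with_minority"
  out[out == ""] <- "partial_majority"
  out
}

#' Decide one agent's next behaviour
#'
#' Applies the decision table to one agent (vectorized over agents): given
#' its population, its fixed attitude and the tallied behaviour of its
#' four neighbours, does it express or stay silent next step?
#'
#' \itemize{
#'   \item Total silence / stalemate: consensus seekers stay silent,
#'     reputation seekers express (regardless of attitude) -- with no
#'     clear majority, voicing can still establish one.
#'   \item Majority with minority: only a reputation seeker whose
#'     attitude matches the voiced \emph{minority} expresses; everyone
#'     else is silent.
#'   \item Partial or full majority: only a consensus seeker whose
#'     attitude matches the voiced opinion expresses; everyone else is
#'     silent.
#' }
#'
#' @param agent_type `"consensus"` or `"reputation"` (character vector).
#' @param own_attitude `"a"` or `"b"` (character vector).
#' @param n_a,n_b,n_silent Neighbour tallies as in
#'   [classify_local_state()].
#' @return Character vector, `"express"` or `"silent"`.
#' @examples
#' decide_behavior("reputation", "a", 0, 0, 4)  # "express"
#' decide_behavior("consensus", "a", 3, 1, 0)   # "silent"
#' @export
decide_behavior <- function(agent_type, own_attitude, n_a, n_b, n_silent) {
  label <- classify_local_state(n_a, n_b, n_silent)
  k <- length(label)
  agent_type <- rep_len(as.character(agent_type), k)
  own_attitude <- rep_len(as.character(own_attitude), k)
  if (!all(agent_type %in% c("consensus", "reputation"))) {
    stop('`agent_type` must be "consensus" or "reputation"', call. = FALSE)
  }
  if (!all(own_attitude %in% c("a", "b"))) {
    stop('`own_attitude` must be "a" or "b"', call. = FALSE)
  }
  n_a <- rep_len(as.integer(n_a), k)
  n_b <- rep_len(as.integer(n_b), k)
  is_rep <- agent_type == "reputation"
  att_a <- own_attitude == "a"
  maj_a <- n_a > n_b  # voiced majority (or sole voiced opinion) is `a`
  express <-
    (label %in% c("total_silence", "stalemate") & is_rep) |
    (label == "majority_with_minority" & is_rep & (att_a != maj_a)) |
    (label %in% c("partial_majority", "full_majority") & !is_rep &
       (att_a == maj_a))
  ifelse(express, "express", "silent")
}
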