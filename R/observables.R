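window_states <- function(x) {
  ok <- is.list(x) && length(x) > 0L &&
    all(vapply(x, inherits, logical(1), "lattice_state"))
  if (!ok) {
    stop("expected a `sim_run` or a nonempty list of `lattice_state` objects",
         call. = FALSE)
  }
  x
}

#' Mean silence density over an equilibrium window
#'
#' Fraction of agents not expressing, averaged over the steps of a
#' window: the run's final detected cycle for a `sim_run` (last 10\% of
#' steps when censored), or the supplied states.
#'
#' @param x A `sim_run`, or a nonempty list of `lattice_state` objects.
#' @return A fraction in `[0, 1]`.
#' @export
silence_density <- function(x) {
  if (inherits(x, "sim_run")) {
    w <- equilibrium_window(x)
    return(mean(x$trajectory$silence_count[w]) / x$config$lattice_side^2)
  }
  states <- window_states(x)
  mean(vapply(states, function(s) 1 - mean(s$express), numeric(1)))
}

#' Expressed-opinion gap
#'
#' Number of agents currently voicing `a` minus the number voicing `b`.
#' Silent agents contribute nothing.
#'
#' @param state A `lattice_state`.
#' @return An integer.
#' @export
expressed_gap <- function(state) {
  stopifnot(inherits(state, "lattice_state"))
  as.integer(sum(state$express & state$attitude_a) -
               sum(state$express & !state$attitude_a))
}

#' Attitude gap
#'
#' Number of agents privately holding attitude `a` minus the number
#' holding `b`. Attitudes are fixed, so this is constant over a run.
#'
#' @param state A `lattice_state`.
#' @return An integer.
#' @export
attitude_gap <- function(state) {
  stopifnot(inherits(state, "lattice_state"))
  as.integer(sum(state$attitude_a) - sum(!state$attitude_a))
}

#' Public-private opinion discrepancy index
#'
#' The ratio theta of the window-averaged expressed-opinion gap to the
#' (constant) attitude gap. Theta is 1 when voiced opinions mirror
#' private attitudes exactly, above 1 when the attitudinal majority is
#' over-voiced, between 0 and 1 when it is dampened, and negative when
#' the voiced majority is actually the attitudinal minority.
#'
#' @param delta_e_mean Mean expressed-opinion gap over the equilibrium
#'   window.
#' @param delta_a Attitude gap; must be nonzero (theta is undefined for
#'   tied attitudes -- such runs are flagged and excluded upstream).
#' @return A numeric scalar (vectorized over inputs).
#' @examples
#' discrepancy_theta(-3, 5)  # -0.6
#' @export
discrepancy_theta <- function(delta_e_mean, delta_a) {
  if (any(delta_a == 0)) {
    stop("`delta_a` is 0: theta is undefined for tied attitudes",
         call. = FALSE)
  }
  delta_e_mean / delta_a
}

#' Classify an equilibrium scenario from theta
#'
#' Partition of the finite theta line: negative theta is a silent
#' majority (sign inversion between voiced and private majorities),
#' `[0, 1 - epsilon)` a dampened majority, `[1 - epsilon, 1 + epsilon]`
#' correspondence, and above `1 + epsilon` an amplified majority. A
#' windowed mean almost never hits 1 exactly, hence the symmetric
#' tolerance band.
#'
#' @param theta Finite numeric vector.
#' @param epsilon Nonnegative half-width of the correspondence band
#'   (default 0.05).
#' @return Character vector of labels from [scenario_labels].
#' @examples
#' classify_scenario(c(-0.2, 0.5, 1.03, 1.5))
#' @export
classify_scenario <- function(theta, epsilon = 0.05) {
  if (anyNA(theta) || any(!is.finite(theta))) {
    stop("`theta` must be finite", call. = FALSE)
  }
  if (length(epsilon) != 1L || is.na(epsilon) || epsilon < 0) {
    stop("`epsilon` must be a single nonnegative number", call. = FALSE)
  }
  out <- rep("dampened", length(theta))
  out[theta < 0] <- "silent_majority"
  out[theta >= 1 - epsilon & theta <= 1 + epsilon] <- "correspondence"
  out[theta > 1 + epsilon] <- "amplified"
  out
}

#' Window-averaged local-network-state distribution
#'
#' Classifies every agent's four-neighbour state at every step of the
#' window and averages the resulting five fractions. For a `sim_run` the
#' window is the equilibrium window and the per-step counts recorded
#' during the run are reused; for a list of states the classification is
#' computed on the spot.
#'
#' @param x A `sim_run`, or a nonempty list of `lattice_state` objects.
#' @return Named numeric vector over [local_state_labels], summing to 1.
#' @export
local_state_distribution <- function(x) {
  if (inherits(x, "sim_run")) {
    w <- equilibrium_window(x)
    n <- x$config$lattice_side^2
    cols <- paste0("n_", local_state_labels)
    fr <- vapply(cols, function(cl) mean(x$trajectory[[cl]][w]) / n,
                 numeric(1))
    names(fr) <- local_state_labels
    return(fr)
  }
  states <- window_states(x)
  per_state <- vapply(states, function(s) {
    cnt <- neighbor_counts(s)
    lab <- classify_local_state(cnt$n_a, cnt$n_b, cnt$n_silent)
    tab <- table(factor(lab, levels = local_state_labels))
    as.numeric(tab) / length(lab)
  }, numeric(5))
  fr <- rowMeans(per_state)
  names(fr) <- local_state_labels
  fr
}

#' Summarize one run's equilibrium as a tidy record
#'
#' Collapses a `sim_run` into the one-row tibble used throughout the
#' experiment harness: cycle information, silence density, the attitude
#' and expressed-opinion gaps, theta with its scenario classification,
#' and the five window-averaged local-state fractions. Runs with a zero
#' attitude gap get `theta = NA` and scenario `"undefined"`; censored
#' runs report `cycle_length` capped at the horizon with
#' `censored = TRUE`.
#'
#' @param run A `sim_run`.
#' @param epsilon Correspondence tolerance; defaults to the run
#'   configuration's `epsilon_correspondence`.
#' @return A one-row tibble.
#' @export
equilibrium_record <- function(run,
                               epsilon = run$config$epsilon_correspondence) {
  stopifnot(inherits(run, "sim_run"))
  w <- equilibrium_window(run)
  tr <- run$trajectory
  n <- run$config$lattice_side^2
  delta_e_mean <- mean(tr$expressed_a[w] - tr$expressed_b[w])
  delta_a <- run$delta_a
  theta <- if (delta_a == 0L) NA_real_ else discrepancy_theta(delta_e_mean, delta_a)
  scenario <- if (is.na(theta)) "undefined" else classify_scenario(theta, epsilon)
  fr <- local_state_distribution(run)
  out <- tibble::tibble(
    side = run$config$lattice_side,
    n_agents = n,
    r_density = run$config$r_density,
    seed = run$config$seed,
    transient_length = if (run$cycle$censored) NA_integer_ else run$cycle$transient_length,
    cycle_length = if (run$cycle$censored) run$config$max_steps else run$cycle$cycle_length,
    censored = run$cycle$censored,
    silence_density = mean(tr$silence_count[w]) / n,
    delta_a = delta_a,
    delta_e_mean = delta_e_mean,
    theta = theta,
    scenario = scenario
  )
  for (lab in local_state_labels) out[[paste0("frac_", lab)]] <- fr[[lab]]
  out
}
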