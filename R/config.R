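#' Simulation configuration
#'
#' Bundles every tunable of a single model run: lattice side, the density
#' of reputation seekers, the Bernoulli probabilities used to draw fixed
#' attitudes and the initial expression pattern, the time horizon, the RNG
#' seed, and the tolerance band used to call a theta value "correspondence".
#'
#' @param lattice_side Integer lattice side `L >= 2`; the torus holds
#'   `L^2` agents.
#' @param r_density Fraction of reputation seekers in `[0, 1]`. Exactly
#'   `round(r_density * L^2)` agents are made reputation seekers, at
#'   uniformly random positions.
#' @param p_attitude_a Probability that an agent's fixed private attitude
#'   is `a` (default 0.5, giving the balanced-attitude condition).
#' @param p_initial_express Probability that an agent starts out
#'   expressing (default 0.5).
#' @param max_steps Integer horizon: maximum number of synchronous update
#'   steps (default 10000).
#' @param seed Integer RNG seed; identical seeds give bit-identical runs.
#' @param epsilon_correspondence Half-width of the symmetric band around
#'   `theta = 1` classified as correspondence (default 0.05).
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(lattice_side = 10, r_density = 0.65, seed = 42)
#' @export
sim_config <- function(lattice_side,
                       r_density,
                       p_attitude_a = 0.5,
                       p_initial_express = 0.5,
                       max_steps = 10000L,
                       seed = 1L,
                       epsilon_correspondence = 0.05) {
  cfg <- list(
    lattice_side = as.integer(lattice_side),
    r_density = as.numeric(r_density),
    p_attitude_a = as.numeric(p_attitude_a),
    p_initial_express = as.numeric(p_initial_express),
    max_steps = as.integer(max_steps),
    seed = as.integer(seed),
    epsilon_correspondence = as.numeric(epsilon_correspondence)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  check_scalar <- function(x, field) {
    if (length(x) != 1L || is.na(x)) {
      stop("`", field, "` must be a single non-missing value", call. = FALSE)
    }
  }
  for (f in names(cfg)) check_scalar(cfg[[f]], f)
  if (cfg$lattice_side < 2L) {
    stop("`lattice_side` must be >= 2", call. = FALSE)
  }
  for (f in c("r_density", "p_attitude_a", "p_initial_express")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("`", f, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$max_steps < 1L) {
    stop("`max_steps` must be >= 1", call. = FALSE)
  }
  if (cfg$epsilon_correspondence < 0) {
    stop("`epsilon_correspondence` must be nonnegative", call. = FALSE)
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  lattice: %dx%d torus (%d agents)\n",
              x$lattice_side, x$lattice_side, x$lattice_side^2))
  cat(sprintf("  r_density: %.3f  p_attitude_a: %.2f  p_initial_express: %.2f\n",
              x$r_density, x$p_attitude_a, x$p_initial_express))
  cat(sprintf("  max_steps: %d  seed: %d  epsilon: %.3f\n",
              x$max_steps, x$seed, x$epsilon_correspondence))
  invisible(x)
}

#' Density-sweep plan
#'
#' Describes a replicated experiment over a grid of reputation-seeker
#' densities and one or more lattice sizes. Per-run seeds are drawn once
#' from `base_seed` so that every run is independent yet individually
#' replayable from its recorded seed.
#'
#' @param densities Strictly increasing vector of reputation-seeker
#'   densities in `[0, 1]` (default 0 to 1 in steps of 0.05).
#' @param replicates Runs per (size, density) cell (default 200).
#' @param sizes Agent counts; each must be a perfect square
#'   (default 100, i.e. a 10x10 torus).
#' @param base_seed Master seed for the whole sweep.
#' @param max_steps Horizon per run (default 2000; equilibria on these
#'   lattices are normally reached much earlier).
#' @param p_attitude_a,p_initial_express,epsilon_correspondence Passed to
#'   every run's [sim_config()].
#'
#' @return An object of class `sweep_plan`.
#' @examples
#' plan <- sweep_plan(densities = c(0, 0.5, 1), replicates = 3, sizes = 16)
#' @export
sweep_plan <- function(densities = seq(0, 1, by = 0.05),
                       replicates = 200L,
                       sizes = 100L,
                       base_seed = 1L,
                       max_steps = 2000L,
                       p_attitude_a = 0.5,
                       p_initial_express = 0.5,
                       epsilon_correspondence = 0.05) {
  densities <- as.numeric(densities)
  if (length(densities) < 1L || anyNA(densities) ||
      any(densities < 0 | densities > 1)) {
    stop("`densities` must lie in [0, 1]", call. = FALSE)
  }
  if (is.unsorted(densities, strictly = TRUE)) {
    stop("`densities` must be strictly increasing", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  if (length(replicates) != 1L || is.na(replicates) || replicates < 1L) {
    stop("`replicates` must be a single integer >= 1", call. = FALSE)
  }
  sizes <- as.integer(sizes)
  sides <- sqrt(sizes)
  if (anyNA(sizes) || any(sides != floor(sides))) {
    stop("`sizes` must be perfect squares (agent counts)", call. = FALSE)
  }
  plan <- list(
    densities = densities,
    replicates = replicates,
    sizes = sizes,
    base_seed = as.integer(base_seed),
    max_steps = as.integer(max_steps),
    p_attitude_a = as.numeric(p_attitude_a),
    p_initial_express = as.numeric(p_initial_express),
    epsilon_correspondence = as.numeric(epsilon_correspondence)
  )
  class(plan) <- "sweep_plan"
  plan
}

#' @export
print.sweep_plan <- function(x, ...) {
  cat("<sweep_plan>\n")
  cat(sprintf("  densities: %s (n=%d)\n",
              paste(range(x$densities), collapse = " .. "),
              length(x$densities)))
  cat(sprintf("  replicates: %d  sizes: %s  base_seed: %d  max_steps: %d\n",
              x$replicates, paste(x$sizes, collapse = ","),
              x$base_seed, x$max_steps))
  invisible(x)
}
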