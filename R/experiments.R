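sweep_run_table <- function(plan) {
  grid <- expand.grid(
    replicate = seq_len(plan$replicates),
    density = plan$densities,
    size = plan$sizes,
    KEEP.OUT.ATTRS = FALSE
  )
  # one draw per run under the master seed; each record keeps its seed so
  # any single run can be replayed in isolation
  set.seed(plan$base_seed)
  grid$seed <- sample.int(.Machine$integer.max, nrow(grid))
  tibble::as_tibble(grid[c("size", "density", "replicate", "seed")])
}

run_one_cell <- function(plan, size, density, seed) {
  cfg <- sim_config(
    lattice_side = as.integer(sqrt(size)),
    r_density = density,
    p_attitude_a = plan$p_attitude_a,
    p_initial_express = plan$p_initial_express,
    max_steps = plan$max_steps,
    seed = seed,
    epsilon_correspondence = plan$epsilon_correspondence
  )
  equilibrium_record(run_simulation(cfg))
}

#' Run a replicated density sweep
#'
#' Executes `replicates` independent runs for every (size, density) cell
#' of the plan and returns the tidy per-run records together with the
#' per-cell summary. Runs are keyed by `(size, density, replicate)` and
#' each stores its own seed.
#'
#' @param plan A [sweep_plan()].
#' @param progress Print one progress line per (size, density) cell to
#'   stderr (default `FALSE`).
#' @return A list of class `sweep_result` with elements `records` (one
#'   row per run, see [equilibrium_record()] plus the key columns) and
#'   `summary` (see [summarize_by_density()]).
#' @examples
#' res <- run_sweep(sweep_plan(densities = c(0, 1), replicates = 2,
#'                             sizes = 16, max_steps = 200))
#' res$summary
#' @export
run_sweep <- function(plan, progress = FALSE) {
  stopifnot(inherits(plan, "sweep_plan"))
  runs <- sweep_run_table(plan)
  cells <- unique(runs[c("size", "density")])
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    sz <- cells$size[ci]; de <- cells$density[ci]
    sel <- runs[runs$size == sz & runs$density == de, ]
    recs <- lapply(seq_len(nrow(sel)), function(k) {
      run_one_cell(plan, sz, de, sel$seed[k])
    })
    cell <- dplyr::bind_cols(
      sel[c("size", "density", "replicate")],
      dplyr::bind_rows(recs)
    )
    out[[ci]] <- cell
    if (isTRUE(progress)) {
      message(sprintf("sweep: size %d density %.2f done (%d runs)",
                      sz, de, nrow(cell)))
    }
  }
  records <- dplyr::bind_rows(out)
  structure(
    list(records = records, summary = summarize_by_density(records),
         plan = plan),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d runs over %d (size, density) cells\n",
              nrow(x$records), nrow(x$summary)))
  print(x$summary, n = 5)
  invisible(x)
}

#' Aggregate per-run records by (size, density)
#'
#' Means and spreads of the equilibrium observables per sweep cell.
#' Censored runs enter the cycle-length statistics at their capped value
#' and are counted; runs with a zero attitude gap are excluded from the
#' theta and scenario statistics and counted, never silently dropped.
#' Scenario frequencies are relative to the defined-theta runs of the
#' cell and sum to 1 (all `NA` when every run is excluded).
#'
#' @param records Per-run records as produced by [run_sweep()].
#' @return A tibble keyed by `(size, density)`.
#' @export
summarize_by_density <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("`records` must be a nonempty data frame", call. = FALSE)
  }
  frac_of <- function(scen, lab) {
    defined <- scen[scen != "undefined"]
    if (length(defined) == 0L) NA_real_ else mean(defined == lab)
  }
  records %>%
    dplyr::group_by(.data$size, .data$density) %>%
    dplyr::summarise(
      n_runs = dplyr::n(),
      n_censored = sum(.data$censored),
      n_delta_a_zero = sum(.data$delta_a == 0L),
      silence_mean = mean(.data$silence_density),
      silence_sd = stats::sd(.data$silence_density),
      cycle_mean = mean(.data$cycle_length),
      cycle_sd = stats::sd(.data$cycle_length),
      theta_mean = if (all(is.na(.data$theta))) NA_real_ else mean(.data$theta, na.rm = TRUE),
      theta_min = if (all(is.na(.data$theta))) NA_real_ else min(.data$theta, na.rm = TRUE),
      freq_amplified = frac_of(.data$scenario, "amplified"),
      freq_correspondence = frac_of(.data$scenario, "correspondence"),
      freq_dampened = frac_of(.data$scenario, "dampened"),
      freq_silent_majority = frac_of(.data$scenario, "silent_majority"),
      dplyr::across(dplyr::all_of(paste0("frac_", local_state_labels)), mean),
      .groups = "drop"
    )
}

#' Locate the density where a summary field peaks
#'
#' Returns, per size, the grid density at which a per-density mean
#' attains its maximum (or minimum). Ties are broken toward the lower
#' density and reported via `n_ties`.
#'
#' @param summary A summary tibble from [summarize_by_density()],
#'   covering at least two densities per size.
#' @param field Name of a numeric summary column, e.g. `"silence_mean"`.
#' @param mode `"max"` (default) or `"min"`.
#' @return A tibble with one row per size: `size`, `density`, `value`,
#'   `n_ties`.
#' @export
locate_extremum <- function(summary, field, mode = c("max", "min")) {
  mode <- match.arg(mode)
  if (!is.character(field) || length(field) != 1L ||
      !field %in% names(summary) || !is.numeric(summary[[field]])) {
    stop("`field` must name a numeric column of `summary`", call. = FALSE)
  }
  summary %>%
    dplyr::group_by(.data$size) %>%
    dplyr::arrange(.data$density, .by_group = TRUE) %>%
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2L) {
        stop("`summary` must cover at least two densities", call. = FALSE)
      }
      v <- df[[field]]
      opt <- if (mode == "max") max(v, na.rm = TRUE) else min(v, na.rm = TRUE)
      idx <- which(v == opt)
      tibble::tibble(density = df$density[idx[1L]], value = opt,
                     n_ties = length(idx))
    }) %>%
    dplyr::ungroup()
}

#' Modal scenario per density and regime boundaries
#'
#' For every sweep cell, the most frequent equilibrium scenario among
#' defined-theta runs (ties are flagged and labelled `"tie"`), together
#' with the two regime boundaries of interest: the largest contiguous
#' grid prefix (starting at the lowest density) on which the amplified
#' majority is modal, and the largest contiguous suffix on which the
#' dampened majority is modal.
#'
#' @param summary A summary tibble from [summarize_by_density()].
#' @return A list with `profile` (tibble: size, density, modal_scenario,
#'   tie), `amplified_prefix_end` and `dampened_suffix_start` (tibbles
#'   per size; density `NA` when the regime is absent at the grid edge).
#' @export
modal_scenario_profile <- function(summary) {
  freq_cols <- c(amplified = "freq_amplified",
                 correspondence = "freq_correspondence",
                 dampened = "freq_dampened",
                 silent_majority = "freq_silent_majority")
  stopifnot(all(freq_cols %in% names(summary)))
  summary <- dplyr::arrange(summary, .data$size, .data$density)
  fr <- as.matrix(summary[freq_cols])
  modal <- character(nrow(fr)); tie <- logical(nrow(fr))
  for (i in seq_len(nrow(fr))) {
    if (all(is.na(fr[i, ]))) {
      modal[i] <- NA_character_
    } else {
      best <- which(fr[i, ] == max(fr[i, ], na.rm = TRUE))
      tie[i] <- length(best) > 1L
      modal[i] <- if (tie[i]) "tie" else names(freq_cols)[best]
    }
  }
  profile <- tibble::tibble(
    size = summary$size, density = summary$density,
    modal_scenario = modal, tie = tie
  )
  edge <- function(p, lab, from_low) {
    idx <- if (from_low) seq_len(nrow(p)) else rev(seq_len(nrow(p)))
    run <- cumprod(!is.na(p$modal_scenario[idx]) &
                     p$modal_scenario[idx] == lab)
    hit <- idx[run == 1]
    if (length(hit) == 0L) NA_real_
    else if (from_low) p$density[max(hit)] else p$density[min(hit)]
  }
  by_size <- split(profile, profile$size)
  amp <- tibble::tibble(
    size = as.integer(names(by_size)),
    density = unname(vapply(by_size, edge, numeric(1), "amplified", TRUE))
  )
  dam <- tibble::tibble(
    size = as.integer(names(by_size)),
    density = unname(vapply(by_size, edge, numeric(1), "dampened", FALSE))
  )
  list(profile = profile, amplified_prefix_end = amp,
       dampened_suffix_start = dam)
}

#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`
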