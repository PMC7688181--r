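tiny_plan <- function(...) {
  sweep_plan(densities = c(0, 0.5, 1), replicates = 3, sizes = 16,
             base_seed = 42, max_steps = 200, ...)
}

test_that("run_sweep produces one keyed record per run, reproducibly", {
  res <- run_sweep(tiny_plan())
  expect_equal(nrow(res$records), 9L)
  keys <- res$records[c("size", "density", "replicate")]
  expect_equal(nrow(unique(keys)), 9L)
  expect_equal(length(unique(res$records$seed)), 9L)
  res2 <- run_sweep(tiny_plan())
  expect_identical(res$records, res2$records)
  # replaying any single record's seed reproduces its row
  r <- res$records[5, ]
  cfg <- sim_config(sqrt(r$size), r$density, max_steps = 200, seed = r$seed)
  replay <- equilibrium_record(run_simulation(cfg))
  expect_equal(r$silence_density, replay$silence_density)
  expect_equal(r$cycle_length, replay$cycle_length)
  expect_equal(r$theta, replay$theta)
})

test_that("all-consensus sweeps never report long cycles", {
  res <- run_sweep(sweep_plan(densities = 0:1, replicates = 5, sizes = 16,
                              base_seed = 7, max_steps = 500))
  zero <- res$records[res$records$density == 0, ]
  expect_true(all(!zero$censored))
  expect_true(all(zero$cycle_length <= 2L))
})

test_that("summaries reduce to the record itself for a single run", {
  res <- run_sweep(sweep_plan(densities = c(0, 0.5), replicates = 1,
                              sizes = 16, base_seed = 3, max_steps = 200))
  s <- summarize_by_density(res$records)
  r <- res$records[res$records$density == 0.5, ]
  row <- s[s$density == 0.5, ]
  expect_equal(row$silence_mean, r$silence_density)
  expect_equal(row$cycle_mean, as.numeric(r$cycle_length))
  expect_equal(row$n_runs, 1L)
})

hand_records <- function() {
  tibble::tibble(
    size = 16L,
    density = rep(c(0.2, 0.8), each = 3),
    replicate = rep(1:3, 2),
    seed = 1:6,
    cycle_length = c(1L, 3L, 5L, 10L, 20L, 2000L),
    censored = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    silence_density = c(0.5, 0.6, 0.7, 0.2, 0.4, 0.6),
    delta_a = c(2L, 4L, 0L, 2L, 2L, 2L),
    theta = c(1.5, 0.5, NA, -0.5, 2, 1),
    scenario = c("amplified", "dampened", "undefined",
                 "silent_majority", "amplified", "correspondence"),
    frac_total_silence = 0.2, frac_stalemate = 0.1,
    frac_majority_with_minority = 0.1, frac_partial_majority = 0.5,
    frac_full_majority = 0.1
  )
}

test_that("summarize_by_density matches hand arithmetic and counts exclusions", {
  s <- summarize_by_density(hand_records())
  lo <- s[s$density == 0.2, ]; hi <- s[s$density == 0.8, ]
  expect_equal(lo$silence_mean, 0.6)
  expect_equal(lo$cycle_mean, 3)
  expect_equal(lo$n_delta_a_zero, 1L)
  expect_equal(lo$theta_mean, 1)              # mean(1.5, 0.5)
  expect_equal(lo$theta_min, 0.5)
  expect_equal(lo$freq_amplified, 0.5)        # of the 2 defined-theta runs
  expect_equal(lo$freq_dampened, 0.5)
  expect_equal(hi$n_censored, 1L)
  expect_equal(hi$cycle_mean, mean(c(10, 20, 2000)))
  expect_equal(hi$freq_silent_majority, 1 / 3)
  expect_error(summarize_by_density(hand_records()[0, ]), "nonempty")
})

test_that("a density whose runs all lack theta is excluded, not dropped", {
  recs <- hand_records()
  recs$delta_a[recs$density == 0.8] <- 0L
  recs$theta[recs$density == 0.8] <- NA
  recs$scenario[recs$density == 0.8] <- "undefined"
  s <- summarize_by_density(recs)
  hi <- s[s$density == 0.8, ]
  expect_equal(hi$n_delta_a_zero, 3L)
  expect_true(is.na(hi$theta_mean))
  expect_true(is.na(hi$freq_amplified))
  expect_equal(hi$n_runs, 3L)
})

planted_summary <- function(values, densities = seq(0, 1, by = 0.05)) {
  tibble::tibble(size = 100L, density = densities, silence_mean = values)
}

test_that("locate_extremum finds planted peaks and reports ties", {
  d <- seq(0, 1, by = 0.05)
  peak <- planted_summary(1 - (d - 0.85)^2)
  expect_equal(locate_extremum(peak, "silence_mean")$density, 0.85)
  mono <- planted_summary(d)
  expect_equal(locate_extremum(mono, "silence_mean")$density, 1)
  expect_equal(locate_extremum(mono, "silence_mean", mode = "min")$density, 0)
  tied <- planted_summary(c(rep(0, 19), 1, 1))
  hit <- locate_extremum(tied, "silence_mean")
  expect_equal(hit$density, 0.95)  # lower of the tied densities
  expect_equal(hit$n_ties, 2L)
  expect_error(locate_extremum(peak, "no_such_field"), "field")
  expect_error(locate_extremum(peak[1, ], "silence_mean"), "two densities")
})

freq_summary <- function(amp, corr, damp, sm,
                         densities = seq(0, 1, by = 0.05)) {
  tibble::tibble(
    size = 100L, density = densities,
    freq_amplified = amp, freq_correspondence = corr,
    freq_dampened = damp, freq_silent_majority = sm
  )
}

test_that("modal profile finds regime boundaries in hand-built tables", {
  d <- seq(0, 1, by = 0.05)
  amp <- ifelse(d <= 0.75, 0.6, 0.1)
  damp <- ifelse(d <= 0.75, 0.2, 0.7)
  prof <- modal_scenario_profile(
    freq_summary(amp, 0.1, damp, 1 - amp - damp - 0.1)
  )
  expect_equal(prof$amplified_prefix_end$density, 0.75)
  expect_equal(prof$dampened_suffix_start$density, 0.80)
  expect_false(any(prof$profile$tie))
  # all amplified everywhere: the prefix covers the whole grid
  allamp <- modal_scenario_profile(freq_summary(0.9, 0.05, 0.03, 0.02))
  expect_equal(allamp$amplified_prefix_end$density, 1)
  expect_true(is.na(allamp$dampened_suffix_start$density))
})

test_that("ties between scenario labels are flagged as ties", {
  d <- c(0, 0.05, 0.1)
  prof <- modal_scenario_profile(
    freq_summary(c(0.6, 0.4, 0.1), c(0.2, 0.4, 0.1),
                 c(0.1, 0.1, 0.7), c(0.1, 0.1, 0.1), densities = d)
  )
  expect_equal(prof$profile$modal_scenario, c("amplified", "tie", "dampened"))
  expect_equal(prof$profile$tie, c(FALSE, TRUE, FALSE))
  expect_equal(prof$amplified_prefix_end$density, 0)
})
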