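test_that("summaries aggregate deaths, ages and final composition", {
  mk_run <- function(cfg, deaths, final_liars_per_caste) {
    snaps <- snapshot_population(
      tibble::tibble(
        id = 1:30, caste = rep(0:2, each = 10),
        signal = unlist(lapply(0:2, function(c) {
          k <- final_liars_per_caste[c + 1]
          c(rep(setdiff(0:2, c)[1], k), rep(c, 10 - k))
        })),
        resources = 10, endowment = 50, birth_tick = 0
      ), tick = 100)
    castesim:::new_run(cfg, "compiled", snaps, deaths,
                       final_population = NULL)
  }
  cfg <- tiny_config(ticks = 100)
  no_deaths <- tibble::tibble(death_tick = integer(), caste = integer(),
                              signal = integer(), age_at_death = numeric())
  d1 <- tibble::tibble(death_tick = rep(50L, 10), caste = rep(0L, 10),
                       signal = 1L, age_at_death = rep(40, 10))
  d2 <- tibble::tibble(death_tick = rep(60L, 20), caste = rep(0L, 20),
                       signal = 1L, age_at_death = rep(60, 20))

  # a run without deaths: count 0 and missing mean age
  s0 <- summarize_runs(list(mk_run(cfg, no_deaths, c(0, 0, 0))))
  expect_equal(s0$castes$mean_deaths, c(0, 0, 0))
  expect_true(all(is.na(s0$castes$mean_age_at_death)))

  # two runs with 10 and 20 caste-0 deaths average to 15; ages pool
  # within a replicate before averaging across replicates
  s <- summarize_runs(list(mk_run(cfg, d1, c(5, 0, 0)),
                           mk_run(cfg, d2, c(5, 0, 0))))
  expect_equal(s$castes$mean_deaths[s$castes$caste == 0], 15)
  expect_equal(s$castes$mean_age_at_death[s$castes$caste == 0], 50)
  # an evenly split caste reports half its members as liars
  expect_equal(s$castes$mean_final_liars[s$castes$caste == 0], 5)
})

test_that("summaries refuse runs from different configurations", {
  a <- run_sim(tiny_config(ticks = 100, seed = 1))
  b <- run_sim(tiny_config(ticks = 200, seed = 1))
  expect_error(summarize_runs(list(a, b)), "share one configuration")
  # differing only by seed is fine
  c2 <- run_sim(tiny_config(ticks = 100, seed = 2))
  expect_s3_class(summarize_runs(list(a, c2)), "castesim_summary")
})

test_that("egalitarian societies hold the whole population in one caste", {
  base <- tiny_config(ticks = 2000, seed = 9)
  for (caste in 0:2) {
    cfg <- egalitarian_config(caste, 30, base)
    expect_equal(sum(cfg$caste_sizes), 30)
    expect_equal(cfg$caste_sizes[caste + 1], 30)
    run <- run_sim(cfg, record_events = TRUE)
    sizes <- run$snapshots |>
      dplyr::group_by(.data$tick, .data$caste) |>
      dplyr::summarise(n = sum(.data$count), .groups = "drop")
    expect_true(all(sizes$n[sizes$caste == caste] == 30))
    expect_true(all(sizes$n[sizes$caste != caste] == 0))
  }
})

test_that("egalitarian battles are decided by resources or a coin only", {
  cfg <- egalitarian_config(2, 30, tiny_config(ticks = 5000, seed = 14))
  set.seed(cfg$seed)
  pop <- init_population(cfg)
  run <- run_sim(cfg, record_events = TRUE)
  # with a single caste there is no caste dominance: every fight is
  # within-caste, so a poorer focal agent can only win via an exact tie
  fights <- run$events[run$events$action == "fight", ]
  expect_gt(nrow(fights), 0)
  expect_true(all(pop$caste[fights$party] == pop$caste[fights$counterparty]))
})

test_that("sweep settings enumerate the scale grid", {
  expect_equal(nrow(sweep_settings(sweep_spec(levels = 1))), 1)
  expect_equal(nrow(sweep_settings(sweep_spec(levels = c(1, 0.1)))), 16)
  expect_equal(nrow(sweep_settings(sweep_spec())), 256)
  diag <- sweep_settings(sweep_spec(levels = c(1, 0.5), full_factorial = FALSE))
  expect_equal(nrow(diag), 2)
  expect_equal(diag$s_endowment, diag$s_dishonest)
  expect_error(sweep_spec(levels = numeric()), "non-empty")
  expect_error(sweep_spec(levels = c(1, 2)), "in \\(0, 1\\]")
})

test_that("a degenerate sweep equals a plain replicated run", {
  base <- tiny_config(ticks = 500, seed = 33)
  spec <- sweep_spec(levels = 1, n_reps = 2, ticks = 500)
  sw <- full_factorial_sweep(spec, base, base_seed = 33)
  direct_cfg <- base
  direct_cfg$scale <- c(1, 1, 1, 1)
  direct <- summarize_runs(
    run_replications(direct_cfg, 2, base_seed = spawn_seeds(33, 1)[1]))
  expect_equal(sw$mean_deaths, direct$castes$mean_deaths)
  expect_equal(sw$mean_final_liars, direct$castes$mean_final_liars)
})

test_that("sweep caching is reused on a rerun", {
  base <- tiny_config(ticks = 300, seed = 44)
  spec <- sweep_spec(levels = c(1, 0.5), full_factorial = FALSE,
                     n_reps = 1, ticks = 300)
  dir <- withr::local_tempdir()
  first <- full_factorial_sweep(spec, base, base_seed = 44, cache_dir = dir)
  expect_equal(length(list.files(dir, pattern = "csv$")), 2)
  again <- full_factorial_sweep(spec, base, base_seed = 44, cache_dir = dir)
  expect_equal(as.data.frame(first), as.data.frame(again))
})

test_that("tidy, glance and autoplot expose the expected shapes", {
  runs <- run_replications(tiny_config(ticks = 1000, seed = 2), 3)
  td <- tidy(runs)
  expect_true(all(c("tick", "caste", "signal", "count", "replicate")
                  %in% names(td)))
  gl <- glance(runs)
  expect_equal(nrow(gl), 3)
  expect_true(all(c("n_deaths", "final_liars_0") %in% names(gl)))
  one <- glance(runs[[1]])
  expect_equal(nrow(one), 1)
  for (what in c("liars", "signals", "resources")) {
    expect_s3_class(autoplot(runs, what = what), "ggplot")
  }
})
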