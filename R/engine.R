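#' Run one simulation
#'
#' Executes `config$ticks` encounters (one per tick) starting from
#' [init_population()], recording a population snapshot at tick 0, every
#' `config$snapshot_interval` ticks and at the final tick, plus a record of
#' every death. Two engines are available: the compiled engine (default)
#' and a naive pure-R reference engine built from the exported encounter
#' primitives. Both consume the R random number stream in the same fixed
#' order — pair draw, engagement, battle tie-break, tournament — so with
#' equal seeds they produce bit-identical results.
#'
#' @param config A [sim_config()] object.
#' @param engine `"compiled"` or `"reference"`. The reference engine is a
#'   plain object-per-agent loop intended for verification at small scale.
#' @param record_events If `TRUE`, also return a per-tick encounter log
#'   (tick, party, counterparty, action, winner, resource delta). Only
#'   sensible for short runs.
#' @return A `castesim_run` object: a list with elements `config`,
#'   `snapshots` (tibble: `tick`, `caste`, `signal`, `count`,
#'   `mean_resources`), `deaths` (tibble: `death_tick`, `caste`, `signal`,
#'   `age_at_death`), `final_population`, and optionally `events`.
#' @examples
#' run <- run_sim(sim_config(caste_sizes = c(10, 10, 10), ticks = 500,
#'                           seed = 42, snapshot_interval = 100))
#' run$deaths
#' liar_counts(run$snapshots)
#' @export
run_sim <- function(config, engine = c("compiled", "reference"),
                    record_events = FALSE) {
  engine <- match.arg(engine)
  validate_config(config)
  if (engine == "reference") {
    return(run_reference(config, record_events = record_events))
  }
  set.seed(config$seed)
  pop <- init_population(config)
  eff <- effective_params(config)
  pm <- as.matrix(eff[, c("aggression_resources", "met_cost_factor",
                          "honest_appropriation", "dishonest_appropriation")])
  out <- run_core(pop$caste, pop$signal, pop$resources, pop$endowment,
                  pop$birth_tick, pm,
                  as.integer(config$ticks), config$snapshot_interval,
                  config$death_threshold_fraction,
                  match(config$flee_prob_form, c("linear", "signal_gated")) - 1L,
                  match(config$flee_cost_base,
                        c("endowment", "current", "absolute")) - 1L,
                  match(config$defeat_loss_basis, c("winner", "own")) - 1L,
                  record_events)
  snapshots <- assemble_snapshots(out$snap_tick, out$snap_count, out$snap_sum)
  deaths <- tibble::tibble(
    death_tick = out$death_tick,
    caste = out$death_caste,
    signal = out$death_signal,
    age_at_death = out$death_age
  )
  final_population <- pop
  final_population$signal <- out$final_signal
  final_population$resources <- out$final_resources
  final_population$birth_tick <- out$final_birth_tick
  events <- NULL
  if (record_events) {
    events <- tibble::as_tibble(out$events)
    events$action <- ifelse(events$action == 1L, "fight", "flee")
    events$party_won <- as.logical(events$party_won)
  }
  new_run(config, "compiled", snapshots, deaths, final_population, events)
}

new_run <- function(config, engine, snapshots, deaths, final_population,
                    events = NULL) {
  structure(
    list(config = config, engine = engine, snapshots = snapshots,
         deaths = deaths, final_population = final_population,
         events = events),
    class = "castesim_run"
  )
}

# snap_count/snap_sum have 9 columns: cell = caste * 3 + signal (0-based)
assemble_snapshots <- function(snap_tick, snap_count, snap_sum) {
  s <- length(snap_tick)
  cell <- 0:8
  tibble::tibble(
    tick = rep(snap_tick, each = 9L),
    caste = rep(cell %/% 3L, times = s),
    signal = rep(cell %% 3L, times = s),
    count = as.integer(t(snap_count)),
    mean_resources = {
      cnt <- as.integer(t(snap_count))
      sm <- as.numeric(t(snap_sum))
      ifelse(cnt > 0, sm / cnt, NA_real_)
    }
  )
}

#' Execute a single tick on an R population
#'
#' One encounter: pair draw, fight-or-flight, payoff or flee cost applied
#' to the focal agent only, then starvation check and tournament
#' replacement. This is the naive building block used by
#' [run_reference()].
#'
#' @param pop Population tibble.
#' @param params Scaled caste-parameter tibble (see [effective_params()]).
#' @param tick Current tick number.
#' @param threshold_fraction Starvation threshold fraction.
#' @param flee_prob_form,flee_cost_base,defeat_loss_basis Encounter-rule
#'   switches, see [decide_engagement()], [apply_flee_cost()] and
#'   [resolve_fight()].
#' @return List with `pop` (updated), `death` (one-row tibble or `NULL`)
#'   and `outcome` (one-row tibble: `tick`, `party`, `counterparty`,
#'   `action`, `party_won`, `delta`).
#' @export
step_sim <- function(pop, params, tick, threshold_fraction = 0.10,
                     flee_prob_form = "linear",
                     flee_cost_base = "endowment",
                     defeat_loss_basis = "winner") {
  n <- nrow(pop)
  pair <- draw_pair(n)
  i <- pair[1L]
  j <- pair[2L]
  party <- list(caste = pop$caste[i], signal = pop$signal[i],
                resources = pop$resources[i], endowment = pop$endowment[i])
  counterparty <- list(caste = pop$caste[j], signal = pop$signal[j],
                       resources = pop$resources[j])

  action <- decide_engagement(party$resources, party$endowment,
                              counterparty$signal, party$caste,
                              form = flee_prob_form)
  if (action == "fight") {
    won <- battle_outcome(party, counterparty)
    delta <- resolve_fight(party, counterparty, won, params,
                           basis = defeat_loss_basis)
    pop$resources[i] <- pop$resources[i] + delta
  } else {
    won <- NA
    new_res <- apply_flee_cost(party$resources, party$endowment,
                               params$met_cost_factor[party$caste + 1L],
                               base = flee_cost_base)
    delta <- new_res - party$resources
    pop$resources[i] <- new_res
  }

  repl <- replace_if_dead(pop, i, tick, threshold_fraction)
  outcome <- tibble::tibble(
    tick = tick, party = i, counterparty = j, action = action,
    party_won = won, delta = delta
  )
  list(pop = repl$pop, death = repl$death, outcome = outcome)
}

#' Naive reference engine
#'
#' A deliberately unoptimised object-per-agent loop composed from the
#' exported primitives, used to verify the compiled engine: with the same
#' config both produce bit-identical snapshot tables, death logs and final
#' populations.
#'
#' @inheritParams run_sim
#' @return A `castesim_run`.
#' @export
run_reference <- function(config, record_events = FALSE) {
  validate_config(config)
  set.seed(config$seed)
  pop <- init_population(config)
  params <- effective_params(config)
  thr <- config$death_threshold_fraction

  snaps <- list(snapshot_population(pop, 0))
  deaths <- list()
  events <- list()
  ticks <- config$ticks
  for (tick in seq_len(ticks)) {
    st <- step_sim(pop, params, tick, thr,
                   flee_prob_form = config$flee_prob_form,
                   flee_cost_base = config$flee_cost_base,
                   defeat_loss_basis = config$defeat_loss_basis)
    pop <- st$pop
    if (!is.null(st$death)) deaths[[length(deaths) + 1L]] <- st$death
    if (record_events) events[[length(events) + 1L]] <- st$outcome
    if (tick %% config$snapshot_interval == 0 || tick == ticks) {
      snaps[[length(snaps) + 1L]] <- snapshot_population(pop, tick)
    }
  }
  snapshots <- dplyr::bind_rows(snaps)
  deaths <- if (length(deaths) > 0) dplyr::bind_rows(deaths) else
    tibble::tibble(death_tick = integer(), caste = integer(),
                   signal = integer(), age_at_death = numeric())
  ev <- if (record_events) dplyr::bind_rows(events) else NULL
  new_run(config, "reference", snapshots, deaths, pop, ev)
}

#' Snapshot of a population
#'
#' Counts and mean resources for every (caste, signal) cell; cells with no
#' agents get a missing mean.
#'
#' @param pop Population tibble.
#' @param tick Tick to record.
#' @return A 9-row tibble: `tick`, `caste`, `signal`, `count`,
#'   `mean_resources`.
#' @export
snapshot_population <- function(pop, tick) {
  count <- integer(9)
  sums <- numeric(9)
  for (i in seq_len(nrow(pop))) {
    cell <- pop$caste[i] * 3L + pop$signal[i] + 1L
    count[cell] <- count[cell] + 1L
    sums[cell] <- sums[cell] + pop$resources[i]
  }
  tibble::tibble(
    tick = as.integer(tick),
    caste = 0:8 %/% 3L,
    signal = 0:8 %% 3L,
    count = count,
    mean_resources = ifelse(count > 0, sums / count, NA_real_)
  )
}

#' Derive replicate seeds from a base seed
#'
#' Deterministic spawn: seeds are drawn without replacement from
#' \[1, 2^31 - 2\] under `base_seed`, so replicate `i` is reproducible in
#' isolation and seeds are pairwise distinct.
#'
#' @param base_seed Integer base seed.
#' @param n Number of seeds.
#' @return Integer vector of length `n`.
#' @export
spawn_seeds <- function(base_seed, n) {
  withr::with_seed(as.integer(base_seed),
                   sample.int(2147483646L, n, replace = FALSE))
}

#' Run independent replications of one configuration
#'
#' @param config A [sim_config()]; its `seed` field is replaced per
#'   replicate.
#' @param n_reps Number of replications.
#' @param base_seed Base seed for [spawn_seeds()] (defaults to
#'   `config$seed`).
#' @param engine Passed to [run_sim()].
#' @return A `castesim_replicates` object: a list of `castesim_run`s,
#'   ordered by replicate index, with the seeds used as an attribute.
#' @export
run_replications <- function(config, n_reps, base_seed = config$seed,
                             engine = "compiled") {
  stopifnot(n_reps >= 1)
  seeds <- spawn_seeds(base_seed, n_reps)
  runs <- purrr::map(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    run_sim(cfg, engine = engine)
  })
  structure(runs, class = "castesim_replicates", seeds = seeds,
            base_seed = as.integer(base_seed))
}

#' Expected number of times an agent slot is focal
#'
#' Each tick draws one focal agent uniformly from `pop_size` slots, so
#' over a run each slot (an agent together with the newborns that later
#' occupy it) is expected to be focal `ticks / pop_size` times — about 667
#' for the paper-scale 2,000,000-tick, 3,000-agent run.
#'
#' @param ticks Number of ticks.
#' @param pop_size Population size (>= 1).
#' @return Expected focal count.
#' @export
expected_focal_picks <- function(ticks, pop_size) {
  if (pop_size < 1) stop("`pop_size` must be >= 1", call. = FALSE)
  ticks / pop_size
}
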