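#' Configuration for an egalitarian (single-caste) society
#'
#' Places the whole population in one caste, removing caste-based
#' dominance: every battle is then decided by resources or, on an exact
#' tie, a fair coin. Used to isolate the contribution of social structure
#' to deception rates.
#'
#' @param caste The single caste (0, 1 or 2).
#' @param n_agents Total number of agents.
#' @param base A [sim_config()] whose other settings are inherited.
#' @return A `castesim_config`.
#' @examples
#' egalitarian_config(2, 300, sim_config(ticks = 1000))
#' @export
egalitarian_config <- function(caste, n_agents, base = sim_config()) {
  stopifnot(caste %in% 0:2, n_agents >= 2)
  sizes <- c(0L, 0L, 0L)
  sizes[caste + 1L] <- as.integer(n_agents)
  base$caste_sizes <- sizes
  validate_config(base)
}

#' Specification of a parameter sweep
#'
#' Scale factors are applied jointly to the four caste parameters
#' (endowment, metabolic cost factor, honest appropriation, dishonest
#' appropriation). A full-factorial sweep crosses the levels over the four
#' parameters (`length(levels)^4` settings); otherwise only the uniform
#' diagonal settings `c(l, l, l, l)` are run.
#'
#' @param levels Scale levels, all in (0, 1]. The default grid
#'   `c(1.0, 0.5, 0.25, 0.1)` spans severe to minimal punishment.
#' @param full_factorial Cross levels over all four parameters?
#' @param n_reps Replications per setting.
#' @param ticks Ticks per run.
#' @return A `castesim_sweep_spec`.
#' @export
sweep_spec <- function(levels = c(1.0, 0.5, 0.25, 0.1),
                       full_factorial = TRUE, n_reps = 30, ticks = 2e6) {
  if (length(levels) < 1 || any(levels <= 0) || any(levels > 1)) {
    stop("`levels` must be non-empty with entries in (0, 1]", call. = FALSE)
  }
  structure(
    list(levels = as.numeric(levels), full_factorial = isTRUE(full_factorial),
         n_reps = as.integer(n_reps), ticks = as.double(ticks)),
    class = "castesim_sweep_spec"
  )
}

#' Enumerate the scale settings of a sweep
#'
#' @param spec A [sweep_spec()].
#' @return A tibble with columns `s_endowment`, `s_met_cost`, `s_honest`,
#'   `s_dishonest`, one row per setting.
#' @export
sweep_settings <- function(spec) {
  stopifnot(inherits(spec, "castesim_sweep_spec"))
  if (spec$full_factorial) {
    tidyr::expand_grid(
      s_endowment = spec$levels, s_met_cost = spec$levels,
      s_honest = spec$levels, s_dishonest = spec$levels
    )
  } else {
    tibble::tibble(
      s_endowment = spec$levels, s_met_cost = spec$levels,
      s_honest = spec$levels, s_dishonest = spec$levels
    )
  }
}

#' Run a parameter sweep
#'
#' Runs `spec$n_reps` replications at every scale setting of `spec` and
#' returns the per-setting summaries. Replicate seeds are derived
#' deterministically from `base_seed` and the setting index, so the sweep
#' is reproducible and each (setting, replicate) cell can be recomputed in
#' isolation. When `cache_dir` is given, per-setting summary tables are
#' written there as CSV and reused on a rerun.
#'
#' @param spec A [sweep_spec()].
#' @param base A [sim_config()] providing everything but `scale`, `ticks`
#'   and `seed`.
#' @param base_seed Integer seed for the whole sweep.
#' @param cache_dir Optional directory for resumable caching.
#' @param engine Passed to [run_sim()].
#' @return A tibble: one row per (setting, caste) with the scale columns
#'   of [sweep_settings()] plus `caste`, `mean_deaths`,
#'   `mean_age_at_death`, `mean_final_liars`, `caste_size`.
#' @export
full_factorial_sweep <- function(spec, base = sim_config(),
                                 base_seed = base$seed, cache_dir = NULL,
                                 engine = "compiled") {
  settings <- sweep_settings(spec)
  setting_seeds <- spawn_seeds(base_seed, nrow(settings))
  if (!is.null(cache_dir) && !dir.exists(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE)
  }
  purrr::map_dfr(seq_len(nrow(settings)), function(k) {
    sc <- as.numeric(settings[k, ])
    tag <- paste(format(sc, trim = TRUE), collapse = "_")
    cache_file <- if (!is.null(cache_dir)) {
      file.path(cache_dir, paste0("setting_", tag, ".csv"))
    }
    if (!is.null(cache_file) && file.exists(cache_file)) {
      out <- tibble::as_tibble(utils::read.csv(cache_file))
      return(out)
    }
    cfg <- base
    cfg$scale <- sc
    cfg$ticks <- spec$ticks
    reps <- run_replications(cfg, spec$n_reps, base_seed = setting_seeds[k],
                             engine = engine)
    sm <- summarize_runs(reps)
    out <- dplyr::bind_cols(
      settings[rep(k, nrow(sm$castes)), ],
      sm$castes
    )
    if (!is.null(cache_file)) utils::write.csv(out, cache_file,
                                               row.names = FALSE)
    out
  })
}
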