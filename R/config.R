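#' Build a simulation configuration
#'
#' A configuration fully determines a run: given the same config (including
#' `seed`) the simulator produces bit-identical results.
#'
#' @param caste_sizes Integer vector of length 3: number of agents per
#'   caste. The default splits 3,000 agents equally (1000/1000/1000).
#' @param caste_params Caste-parameter tibble, see [default_caste_params()].
#'   Stored unscaled; `scale` is applied at run time.
#' @param scale Length-4 multiplier vector applied to (endowment, metabolic
#'   cost factor, honest appropriation, dishonest appropriation) across all
#'   castes. `c(1, 1, 1, 1)` is the default (most severe punishment)
#'   setting; `c(0.1, 0.1, 0.1, 0.1)` is the minimal-punishment setting.
#' @param init_deceptive_fraction Fraction of each caste initialised with a
#'   deceptive signal (default 0.85).
#' @param death_threshold_fraction Starvation threshold as a fraction of
#'   the birth endowment; an agent whose resources fall strictly below it
#'   dies and is replaced (default 0.10).
#' @param ticks Number of encounters to simulate (one encounter per tick).
#' @param seed Integer RNG seed.
#' @param snapshot_interval Record a population snapshot every this many
#'   ticks (tick 0 and the final tick are always recorded).
#' @param flee_prob_form Functional form of the fight-or-flight rule when
#'   the counterparty's signal is not peaceable: `"signal_gated"` (the
#'   calibrated default: flee deterministically from a strictly higher
#'   signal, apply the resource-ratio rule to equal signals) or `"linear"`
#'   (fight with probability resources/endowment whatever the non-peaceable
#'   signal). See [decide_engagement()].
#' @param flee_cost_base Base of the metabolic flee cost:
#'   `met_cost_factor` times the `"current"` resources (calibrated
#'   default), times the `"endowment"`, or taken as an `"absolute"`
#'   amount in resource units. See [apply_flee_cost()].
#' @param defeat_loss_basis Whose appropriation row governs the fraction a
#'   defeated focal agent loses: the loser's `"own"` caste (calibrated
#'   default) or the `"winner"`'s caste. The extracting winner's gain
#'   (when the focal agent wins) always uses its own row. See
#'   [resolve_fight()].
#' @return An object of class `castesim_config`.
#' @examples
#' cfg <- sim_config(ticks = 1000, seed = 1)
#' cfg
#' @export
sim_config <- function(caste_sizes = c(1000L, 1000L, 1000L),
                       caste_params = default_caste_params(),
                       scale = c(1, 1, 1, 1),
                       init_deceptive_fraction = 0.85,
                       death_threshold_fraction = 0.10,
                       ticks = 2e6,
                       seed = 1L,
                       snapshot_interval = 1000L,
                       flee_prob_form = c("signal_gated", "linear"),
                       flee_cost_base = c("current", "endowment", "absolute"),
                       defeat_loss_basis = c("own", "winner")) {
  cfg <- structure(
    list(
      caste_sizes = as.integer(caste_sizes),
      caste_params = tibble::as_tibble(caste_params)[, param_fields],
      scale = as.numeric(scale),
      init_deceptive_fraction = init_deceptive_fraction,
      death_threshold_fraction = death_threshold_fraction,
      ticks = as.double(ticks),
      seed = as.integer(seed),
      snapshot_interval = as.integer(snapshot_interval),
      flee_prob_form = match.arg(flee_prob_form),
      flee_cost_base = match.arg(flee_cost_base),
      defeat_loss_basis = match.arg(defeat_loss_basis)
    ),
    class = "castesim_config"
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "castesim_config"))
  if (length(cfg$caste_sizes) != 3L || any(cfg$caste_sizes < 0L)) {
    stop("`caste_sizes` must be 3 non-negative integers", call. = FALSE)
  }
  validate_caste_params(cfg$caste_params)
  if (!identical(cfg$caste_params$caste, 0:2)) {
    stop("`caste_params` must have one row per caste 0, 1, 2 in order",
         call. = FALSE)
  }
  validate_scale(cfg$scale)
  if (cfg$init_deceptive_fraction < 0 || cfg$init_deceptive_fraction > 1) {
    stop("`init_deceptive_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$death_threshold_fraction < 0 || cfg$death_threshold_fraction > 1) {
    stop("`death_threshold_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(cfg$ticks) || cfg$ticks < 0 || cfg$ticks != floor(cfg$ticks)) {
    stop("`ticks` must be a non-negative integer", call. = FALSE)
  }
  if (is.na(cfg$seed)) stop("`seed` must be an integer", call. = FALSE)
  if (cfg$snapshot_interval < 1L) {
    stop("`snapshot_interval` must be >= 1", call. = FALSE)
  }
  cfg
}

#' @export
print.castesim_config <- function(x, ...) {
  cat("<castesim_config>\n")
  cat("  caste sizes:", paste(x$caste_sizes, collapse = "/"),
      sprintf("(N = %d)\n", sum(x$caste_sizes)))
  cat("  scale:", sprintf("[%s]\n", paste(format(x$scale), collapse = ", ")))
  cat(sprintf("  init deceptive fraction: %g\n", x$init_deceptive_fraction))
  cat(sprintf("  death threshold: %g of endowment\n",
              x$death_threshold_fraction))
  cat(sprintf("  ticks: %s, seed: %d, snapshot every %d ticks\n",
              format(x$ticks, big.mark = ",", scientific = FALSE), x$seed,
              x$snapshot_interval))
  cat(sprintf("  flee rule: %s, flee cost base: %s, defeat loss basis: %s\n",
              x$flee_prob_form, x$flee_cost_base, x$defeat_loss_basis))
  invisible(x)
}

config_field_names <- c(
  "caste_sizes", "caste_params", "scale", "init_deceptive_fraction",
  "death_threshold_fraction", "ticks", "seed", "snapshot_interval",
  "flee_prob_form", "flee_cost_base", "defeat_loss_basis"
)

config_to_list <- function(cfg) {
  list(
    caste_sizes = as.integer(cfg$caste_sizes),
    caste_params = lapply(seq_len(nrow(cfg$caste_params)), function(i) {
      as.list(cfg$caste_params[i, param_fields])
    }),
    scale = cfg$scale,
    init_deceptive_fraction = cfg$init_deceptive_fraction,
    death_threshold_fraction = cfg$death_threshold_fraction,
    ticks = cfg$ticks,
    seed = cfg$seed,
    snapshot_interval = cfg$snapshot_interval,
    flee_prob_form = cfg$flee_prob_form,
    flee_cost_base = cfg$flee_cost_base,
    defeat_loss_basis = cfg$defeat_loss_basis
  )
}

config_from_list <- function(x) {
  unknown <- setdiff(names(x), config_field_names)
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(config_field_names, names(x))
  if (length(missing) > 0) {
    stop("missing configuration keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cp <- x$caste_params
  if (is.data.frame(cp)) cp <- tibble::as_tibble(cp)
  else {
    cp <- purrr::map_dfr(cp, function(row) {
      unknown <- setdiff(names(row), param_fields)
      if (length(unknown) > 0) {
        stop("unknown caste_params keys: ", paste(unknown, collapse = ", "),
             call. = FALSE)
      }
      tibble::as_tibble(row[param_fields])
    })
  }
  sim_config(
    caste_sizes = x$caste_sizes,
    caste_params = cp,
    scale = unlist(x$scale),
    init_deceptive_fraction = x$init_deceptive_fraction,
    death_threshold_fraction = x$death_threshold_fraction,
    ticks = x$ticks,
    seed = x$seed,
    snapshot_interval = x$snapshot_interval,
    flee_prob_form = x$flee_prob_form,
    flee_cost_base = x$flee_cost_base,
    defeat_loss_basis = x$defeat_loss_basis
  )
}

#' Read or write a configuration as YAML or JSON
#'
#' The on-disk representation uses exactly the field names of
#' [sim_config()]; files containing unknown keys are rejected rather than
#' silently ignored.
#'
#' @param cfg A `castesim_config`.
#' @param path File path; the format is chosen by extension (`.yaml`/`.yml`
#'   or `.json`).
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a `castesim_config`.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  x <- config_to_list(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  config_from_list(x)
}

#' Scaled caste parameters of a configuration
#'
#' Applies the config's scale vector to its (unscaled) caste parameters;
#' these are the effective per-caste values a run uses.
#'
#' @param cfg A `castesim_config`.
#' @return A caste-parameter tibble.
#' @export
effective_params <- function(cfg) {
  scale_params(cfg$caste_params, cfg$scale)
}
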