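#' Initialise a population
#'
#' Creates the tick-0 population: each caste receives its configured number
#' of agents at full (scaled) endowment. Within each caste a fraction
#' `init_deceptive_fraction` of agents (rounded to the nearest count)
#' starts with a deceptive signal drawn uniformly from the caste's two
#' non-own levels; the remainder signal honestly. An agent's signal is
#' fixed for life; honesty means `signal == caste`.
#'
#' The function consumes the R random number stream (one uniform deviate
#' per deceptive agent, in agent order), so call `set.seed()` first for
#' reproducibility; [run_sim()] does this for you.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with one row per agent and columns `id`, `caste`,
#'   `signal`, `resources`, `endowment`, `birth_tick`.
#' @examples
#' set.seed(1)
#' pop <- init_population(sim_config(caste_sizes = c(4, 4, 4), ticks = 10))
#' pop
#' @export
init_population <- function(config) {
  validate_config(config)
  eff <- effective_params(config)
  caste <- rep(0:2, times = config$caste_sizes)
  n <- length(caste)
  endowment <- eff$aggression_resources[caste + 1L]
  signal <- integer(n)
  offset <- 0L
  for (c in 0:2) {
    nc <- config$caste_sizes[c + 1L]
    if (nc == 0L) next
    k <- round(config$init_deceptive_fraction * nc)
    alt <- setdiff(0:2, c)  # the two deceptive options, ascending
    sig <- rep(c, nc)
    if (k > 0) {
      u <- stats::runif(k)
      sig[seq_len(k)] <- ifelse(u < 0.5, alt[1L], alt[2L])
    }
    signal[offset + seq_len(nc)] <- sig
    offset <- offset + nc
  }
  tibble::tibble(
    id = seq_len(n),
    caste = as.integer(caste),
    signal = as.integer(signal),
    resources = endowment,
    endowment = endowment,
    birth_tick = 0
  )
}

#' Per-caste liar counts from a population or snapshot table
#'
#' A "liar" is an agent whose displayed signal differs from its true caste.
#'
#' @param x Either a population tibble (from [init_population()]) or a
#'   snapshot tibble with columns `tick`, `caste`, `signal`, `count`.
#' @return A tibble with columns `caste`, `caste_size`, `n_liars`,
#'   `liar_fraction` (plus `tick` for snapshot input).
#' @export
liar_counts <- function(x) {
  if (all(c("tick", "count") %in% names(x))) {
    x |>
      dplyr::group_by(.data$tick, .data$caste) |>
      dplyr::summarise(
        caste_size = sum(.data$count),
        n_liars = sum(.data$count[.data$signal != .data$caste]),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        liar_fraction = ifelse(.data$caste_size > 0,
                               .data$n_liars / .data$caste_size, NA_real_)
      )
  } else {
    x |>
      dplyr::group_by(.data$caste) |>
      dplyr::summarise(
        caste_size = dplyr::n(),
        n_liars = sum(.data$signal != .data$caste),
        .groups = "drop"
      ) |>
      dplyr::mutate(liar_fraction = .data$n_liars / .data$caste_size)
  }
}
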