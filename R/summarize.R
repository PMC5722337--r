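#' Summarise a set of replicate runs
#'
#' Aggregates death counts, ages at death and final-snapshot composition
#' across replications of one configuration. Mean age at death is pooled
#' over deaths within each replicate first, then averaged across
#' replicates (replicates without deaths in a caste are excluded from
#' that caste's age average).
#'
#' @param results A `castesim_replicates` object or list of
#'   `castesim_run`s with identical configs up to seed.
#' @return A `castesim_summary`: list with tibbles `per_replicate`
#'   (replicate, caste, n_deaths, mean_age_at_death, final_liars,
#'   caste_size), `castes` (per-caste means across replicates) and
#'   `caste_signals` (final count and mean resources per caste/signal,
#'   averaged across replicates).
#' @export
summarize_runs <- function(results) {
  stopifnot(length(results) >= 1)
  cfgs <- purrr::map(results, function(r) {
    c0 <- r$config
    c0$seed <- 0L
    c0
  })
  if (!all(purrr::map_lgl(cfgs, identical, cfgs[[1]]))) {
    stop("all runs must share one configuration (up to seed)", call. = FALSE)
  }

  per_rep <- purrr::imap_dfr(results, function(run, rep_i) {
    final <- dplyr::filter(run$snapshots,
                           .data$tick == max(run$snapshots$tick))
    lc <- liar_counts(final)
    purrr::map_dfr(0:2, function(c) {
      d <- dplyr::filter(run$deaths, .data$caste == c)
      tibble::tibble(
        replicate = rep_i,
        caste = c,
        caste_size = lc$caste_size[lc$caste == c],
        n_deaths = nrow(d),
        mean_age_at_death = if (nrow(d) > 0) mean(d$age_at_death) else NA_real_,
        final_liars = lc$n_liars[lc$caste == c]
      )
    })
  })

  castes <- per_rep |>
    dplyr::group_by(.data$caste) |>
    dplyr::summarise(
      caste_size = .data$caste_size[1],
      mean_deaths = mean(.data$n_deaths),
      mean_age_at_death = if (all(is.na(.data$mean_age_at_death))) NA_real_
        else mean(.data$mean_age_at_death, na.rm = TRUE),
      mean_final_liars = mean(.data$final_liars),
      .groups = "drop"
    )

  caste_signals <- purrr::imap_dfr(results, function(run, rep_i) {
    run$snapshots |>
      dplyr::filter(.data$tick == max(.data$tick)) |>
      dplyr::mutate(replicate = rep_i)
  }) |>
    dplyr::group_by(.data$caste, .data$signal) |>
    dplyr::summarise(
      mean_final_count = mean(.data$count),
      mean_final_resources = if (all(is.na(.data$mean_resources))) NA_real_
        else mean(.data$mean_resources, na.rm = TRUE),
      .groups = "drop"
    )

  structure(
    list(per_replicate = per_rep, castes = castes,
         caste_signals = caste_signals, n_reps = length(results),
         config = results[[1]]$config),
    class = "castesim_summary"
  )
}

#' @export
print.castesim_summary <- function(x, ...) {
  cat(sprintf("<castesim_summary> %d replicate(s), scale [%s], %s ticks\n",
              x$n_reps, paste(format(x$config$scale), collapse = ", "),
              format(x$config$ticks, big.mark = ",", scientific = FALSE)))
  print(x$castes)
  invisible(x)
}

#' Mean liar-count trajectory across replicates
#'
#' @param results A `castesim_replicates` object.
#' @return A tibble `tick`, `caste`, `mean_liars`, `mean_fraction`,
#'   `min_liars`, `max_liars` (band across replicates).
#' @export
mean_liar_trajectory <- function(results) {
  purrr::imap_dfr(results, function(run, rep_i) {
    liar_counts(run$snapshots) |> dplyr::mutate(replicate = rep_i)
  }) |>
    dplyr::group_by(.data$tick, .data$caste) |>
    dplyr::summarise(
      mean_liars = mean(.data$n_liars),
      mean_fraction = mean(.data$liar_fraction),
      min_liars = min(.data$n_liars),
      max_liars = max(.data$n_liars),
      .groups = "drop"
    )
}
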