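#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation run into its snapshot table
#'
#' @param x A `castesim_run`.
#' @param ... Unused.
#' @return The snapshot tibble: `tick`, `caste`, `signal`, `count`,
#'   `mean_resources`.
#' @method tidy castesim_run
#' @export
tidy.castesim_run <- function(x, ...) {
  x$snapshots
}

#' One-row summary of a simulation run
#'
#' @param x A `castesim_run`.
#' @param ... Unused.
#' @return A one-row tibble: seed, ticks, total deaths, pooled mean age at
#'   death, and final liar counts per caste (`final_liars_0` ...).
#' @method glance castesim_run
#' @export
glance.castesim_run <- function(x, ...) {
  final <- dplyr::filter(x$snapshots, .data$tick == max(x$snapshots$tick))
  lc <- liar_counts(final)
  tibble::tibble(
    seed = x$config$seed,
    ticks = x$config$ticks,
    n_deaths = nrow(x$deaths),
    mean_age_at_death = if (nrow(x$deaths) > 0) mean(x$deaths$age_at_death)
      else NA_real_,
    final_liars_0 = lc$n_liars[lc$caste == 0],
    final_liars_1 = lc$n_liars[lc$caste == 1],
    final_liars_2 = lc$n_liars[lc$caste == 2]
  )
}

#' Tidy replicate runs into one long snapshot table
#'
#' @param x A `castesim_replicates`.
#' @param ... Unused.
#' @return Snapshot tibble with a `replicate` column.
#' @method tidy castesim_replicates
#' @export
tidy.castesim_replicates <- function(x, ...) {
  purrr::imap_dfr(x, function(run, i) {
    dplyr::mutate(run$snapshots, replicate = i)
  })
}

#' Per-replicate one-row summaries
#'
#' @param x A `castesim_replicates`.
#' @param ... Unused.
#' @return One row per replicate, as in [glance.castesim_run()].
#' @method glance castesim_replicates
#' @export
glance.castesim_replicates <- function(x, ...) {
  purrr::imap_dfr(x, function(run, i) {
    dplyr::mutate(glance(run), replicate = i, .before = 1)
  })
}

#' @export
print.castesim_run <- function(x, ...) {
  cat(sprintf("<castesim_run> (%s engine) %s ticks, seed %d\n", x$engine,
              format(x$config$ticks, big.mark = ",", scientific = FALSE),
              x$config$seed))
  cat(sprintf("  %d deaths, %d snapshots\n", nrow(x$deaths),
              length(unique(x$snapshots$tick))))
  invisible(x)
}
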