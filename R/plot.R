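#' Trajectory figures for replicate runs
#'
#' Reproduces the standard presentation for stochastic replications: one
#' grey line per replicate with the across-replicate mean overlaid in
#' black, one panel per caste (or caste/signal cell).
#'
#' @param object A `castesim_replicates` object.
#' @param what `"liars"` (per-caste liar counts), `"signals"` (counts per
#'   caste/signal cell) or `"resources"` (mean resources per caste/signal
#'   cell).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot castesim_replicates
#' @export
autoplot.castesim_replicates <- function(object,
                                         what = c("liars", "signals",
                                                  "resources"), ...) {
  what <- match.arg(what)
  long <- tidy(object)
  if (what == "liars") {
    df <- purrr::imap_dfr(object, function(run, i) {
      dplyr::mutate(liar_counts(run$snapshots), replicate = i)
    })
    mean_df <- df |>
      dplyr::group_by(.data$tick, .data$caste) |>
      dplyr::summarise(n_liars = mean(.data$n_liars), .groups = "drop")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$tick, .data$n_liars)) +
      ggplot2::geom_line(ggplot2::aes(group = .data$replicate),
                         colour = "grey70", linewidth = 0.3) +
      ggplot2::geom_line(data = mean_df, colour = "black",
                         linewidth = 0.7) +
      ggplot2::facet_wrap(ggplot2::vars(.data$caste),
                          labeller = ggplot2::label_both) +
      ggplot2::labs(x = "tick", y = "liar count")
    return(p)
  }
  yvar <- if (what == "signals") "count" else "mean_resources"
  mean_df <- long |>
    dplyr::group_by(.data$tick, .data$caste, .data$signal) |>
    dplyr::summarise(y = mean(.data[[yvar]], na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(long,
                  ggplot2::aes(.data$tick, .data[[yvar]])) +
    ggplot2::geom_line(ggplot2::aes(group = .data$replicate),
                       colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_line(data = mean_df, ggplot2::aes(y = .data$y),
                       colour = "black", linewidth = 0.7) +
    ggplot2::facet_grid(ggplot2::vars(.data$caste),
                        ggplot2::vars(.data$signal),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "tick",
                  y = if (what == "signals") "agent count"
                      else "mean resources")
}

#' @rdname autoplot.castesim_replicates
#' @param runs A `castesim_replicates` object.
#' @export
plot_liars <- function(runs) autoplot(runs, what = "liars")

#' @rdname autoplot.castesim_replicates
#' @export
plot_signal_counts <- function(runs) autoplot(runs, what = "signals")

#' @rdname autoplot.castesim_replicates
#' @export
plot_mean_resources <- function(runs) autoplot(runs, what = "resources")
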