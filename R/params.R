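#' Default caste parameters
#'
#' The model society is partitioned into three castes that differ in true
#' aggression level: caste 0 (low), caste 1 (medium) and caste 2 (high).
#' Each caste carries four parameters:
#'
#' * `aggression_resources` — the resource endowment an agent of that caste
#'   receives at birth. Higher castes are born richer (50 / 75 / 100 units).
#' * `met_cost_factor` — the fraction of the endowment paid as a metabolic
#'   cost each time an agent flees an encounter. Its role is to make
#'   perpetual flight unsustainable, forcing agents to fight sometimes.
#' * `honest_appropriation` — the fraction of a defeated *honest*
#'   opponent's resources a winner of this caste extracts.
#' * `dishonest_appropriation` — the fraction extracted from a defeated
#'   *dishonest* opponent. It always exceeds the honest fraction, so
#'   defeated liars are punished opportunistically: the punisher profits.
#'
#' @return A tibble with one row per caste and columns `caste`,
#'   `aggression_resources`, `met_cost_factor`, `honest_appropriation`,
#'   `dishonest_appropriation`.
#' @examples
#' default_caste_params()
#' @export
default_caste_params <- function() {
  tibble::tibble(
    caste = 0:2,
    aggression_resources = c(50, 75, 100),
    met_cost_factor = c(0.05, 0.075, 0.1),
    honest_appropriation = c(0.25, 0.50, 0.75),
    dishonest_appropriation = c(0.50, 0.75, 1.00)
  )
}

#' Scale caste parameters by a four-element multiplier vector
#'
#' Parameter sweeps vary the four caste parameters jointly: element `i` of
#' `scale` multiplies parameter `i` for *all* castes, so a setting is
#' written as a single vector such as `c(0.5, 0.5, 0.5, 0.5)`. The order is
#' (endowment, metabolic cost factor, honest appropriation, dishonest
#' appropriation).
#'
#' @param params A caste-parameter tibble as from [default_caste_params()].
#' @param scale Numeric vector of length 4, all entries in (0, 1].
#' @return A caste-parameter tibble with scaled values; `params` is not
#'   modified.
#' @examples
#' scale_params(default_caste_params(), c(0.1, 0.1, 0.1, 0.1))
#' @export
scale_params <- function(params, scale) {
  validate_caste_params(params)
  validate_scale(scale)
  dplyr::mutate(
    params,
    aggression_resources = .data$aggression_resources * scale[[1]],
    met_cost_factor = .data$met_cost_factor * scale[[2]],
    honest_appropriation = .data$honest_appropriation * scale[[3]],
    dishonest_appropriation = .data$dishonest_appropriation * scale[[4]]
  )
}

param_fields <- c(
  "caste", "aggression_resources", "met_cost_factor",
  "honest_appropriation", "dishonest_appropriation"
)

validate_caste_params <- function(params) {
  if (!is.data.frame(params) || !all(param_fields %in% names(params))) {
    stop("`params` must be a data frame with columns ",
         paste(param_fields, collapse = ", "), call. = FALSE)
  }
  if (any(params$aggression_resources <= 0)) {
    stop("`aggression_resources` must be positive", call. = FALSE)
  }
  if (any(params$met_cost_factor < 0)) {
    stop("`met_cost_factor` must be non-negative", call. = FALSE)
  }
  for (col in c("honest_appropriation", "dishonest_appropriation")) {
    if (any(params[[col]] < 0 | params[[col]] > 1)) {
      stop("`", col, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  invisible(params)
}

validate_scale <- function(scale) {
  if (!is.numeric(scale) || length(scale) != 4L || any(!is.finite(scale)) ||
      any(scale <= 0)) {
    stop("`scale` must be a numeric vector of 4 positive entries",
         call. = FALSE)
  }
  invisible(scale)
}
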