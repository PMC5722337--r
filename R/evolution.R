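#' Starvation test
#'
#' An agent starves when its resources fall strictly below
#' `threshold_fraction` of its birth endowment (default one tenth). Only
#' the focal agent of an encounter can starve, because only its resources
#' are ever adjusted.
#'
#' @param resources Current resources (vectorised).
#' @param endowment Birth endowment.
#' @param threshold_fraction Starvation threshold as a fraction of the
#'   endowment.
#' @return Logical.
#' @export
is_starved <- function(resources, endowment, threshold_fraction = 0.10) {
  resources < threshold_fraction * endowment
}

#' Signal inherited through a within-caste binary tournament
#'
#' When an agent dies it is replaced by a newborn of the same caste whose
#' signaling strategy is copied from the winner of a binary tournament:
#' two distinct agents are drawn uniformly without replacement from the
#' deceased's caste (the dying agent itself excluded) and the richer one's
#' signal is inherited; an exact resource tie is broken by a fair coin.
#' Strategies that have become rare are thus unlikely to be copied — the
#' tournament is unforgiving to losing strategies, and a signal absent
#' from a caste can never reappear in it.
#'
#' Consumes two uniform deviates for the candidate draws plus one more on
#' a resource tie.
#'
#' @param pop Population tibble.
#' @param caste Caste of the deceased (0, 1, 2).
#' @param exclude Row index of the dying agent, excluded from the
#'   candidate pool (`NULL` to exclude no one).
#' @return The inherited signal (0, 1 or 2).
#' @export
tournament_strategy <- function(pop, caste, exclude = NULL) {
  members <- which(pop$caste == caste)
  if (!is.null(exclude)) members <- setdiff(members, exclude)
  m <- length(members)
  if (m < 2L) {
    stop("tournament needs at least 2 living candidates in caste ", caste,
         call. = FALSE)
  }
  a <- floor(stats::runif(1) * m) + 1L
  b <- floor(stats::runif(1) * (m - 1L)) + 1L
  if (b >= a) b <- b + 1L
  ra <- pop$resources[members[a]]
  rb <- pop$resources[members[b]]
  winner <- if (ra > rb) a else if (rb > ra) b else {
    if (stats::runif(1) < 0.5) a else b
  }
  pop$signal[members[winner]]
}

#' Replace the focal agent if it starved
#'
#' Called for the focal agent immediately after its resources were
#' adjusted. If it starved, a death record is emitted and the agent is
#' replaced in place by a same-caste newborn at full (scaled) endowment
#' whose signal comes from [tournament_strategy()] (the dying agent is not
#' a candidate). Per-caste counts therefore never change.
#'
#' @param pop Population tibble.
#' @param idx Row index of the focal agent.
#' @param tick Current tick (becomes the newborn's `birth_tick`).
#' @param threshold_fraction Starvation threshold fraction.
#' @return A list with elements `pop` (possibly updated) and `death`
#'   (a one-row tibble with `death_tick`, `caste`, `signal`,
#'   `age_at_death`, or `NULL` if the agent survived).
#' @export
replace_if_dead <- function(pop, idx, tick, threshold_fraction = 0.10) {
  if (!is_starved(pop$resources[idx], pop$endowment[idx], threshold_fraction)) {
    return(list(pop = pop, death = NULL))
  }
  death <- tibble::tibble(
    death_tick = tick,
    caste = pop$caste[idx],
    signal = pop$signal[idx],
    age_at_death = tick - pop$birth_tick[idx]
  )
  new_signal <- tournament_strategy(pop, pop$caste[idx], exclude = idx)
  pop$signal[idx] <- new_signal
  pop$resources[idx] <- pop$endowment[idx]
  pop$birth_tick[idx] <- tick
  list(pop = pop, death = death)
}
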