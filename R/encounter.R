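#' Encounter primitives
#'
#' One tick of the simulation is a single asymmetric encounter between a
#' randomly drawn focal agent ("the party") and an opponent ("the
#' counterparty"). Only the focal agent's resources change. The encounter
#' runs through: signaling, a fight-or-flight decision taken from the
#' opponent's (possibly deceptive) signal, battle resolution by *true*
#' aggression level, and payoff with opportunistic punishment of defeated
#' liars. These primitives are composed by [run_reference()] and mirrored
#' exactly by the compiled engine.
#'
#' Random draws follow a fixed documented order (pair draw, engagement,
#' battle tie-break, tournament) so the two engines consume the same RNG
#' stream.
#'
#' @name encounter
NULL

#' Draw a focal/counterparty index pair
#'
#' Both agents are drawn uniformly; they are always distinct. Consumes
#' exactly two uniform deviates: one for the focal agent, one for the
#' counterparty (drawn from the remaining `n - 1` agents).
#'
#' @param n Population size (>= 2).
#' @return Integer vector `c(party, counterparty)` of 1-based indices.
#' @export
draw_pair <- function(n) {
  if (n < 2L) stop("population must contain at least 2 agents", call. = FALSE)
  i <- floor(stats::runif(1) * n) + 1L
  j <- floor(stats::runif(1) * (n - 1L)) + 1L
  if (j >= i) j <- j + 1L
  c(as.integer(i), as.integer(j))
}

#' Is a signal peaceable to a focal agent?
#'
#' A signal is peaceable when the displayed aggression level lies strictly
#' below the focal agent's true caste: the focal agent believes it faces a
#' weaker opponent and always fights. An equal signal is not peaceable —
#' flight is then still possible when resources are low.
#'
#' @param signal Displayed aggression level of the counterparty (0, 1, 2).
#' @param focal_caste True caste of the focal agent (0, 1, 2).
#' @return Logical (vectorised).
#' @export
is_peaceable <- function(signal, focal_caste) {
  stopifnot(all(signal %in% 0:2), all(focal_caste %in% 0:2))
  signal < focal_caste
}

#' Fight-or-flight decision of the focal agent
#'
#' Facing a peaceable signal the focal agent always fights. What happens
#' otherwise depends on the configured form:
#'
#' * `"linear"`: fight with probability equal to the ratio of current
#'   resources to endowment (clamped to \[0, 1\]), flee with the
#'   complementary probability — the poorer the agent, the likelier it is
#'   to flee.
#' * `"signal_gated"`: flee deterministically from a strictly higher
#'   signal; the linear resource-ratio rule applies only when the signal
#'   equals the focal agent's own level.
#'
#' Consumes one uniform deviate exactly when the resource-ratio rule is
#' invoked.
#'
#' @param resources,endowment Focal agent's current resources and birth
#'   endowment.
#' @param counterparty_signal Signal displayed by the opponent.
#' @param focal_caste Focal agent's true caste.
#' @param form Flight rule, see above.
#' @return `"fight"` or `"flee"`.
#' @export
decide_engagement <- function(resources, endowment, counterparty_signal,
                              focal_caste,
                              form = c("linear", "signal_gated")) {
  form <- match.arg(form)
  if (is_peaceable(counterparty_signal, focal_caste)) return("fight")
  if (form == "signal_gated" && counterparty_signal > focal_caste) {
    return("flee")
  }
  r <- min(1, max(0, resources / endowment))
  if (stats::runif(1) < r) "fight" else "flee"
}

#' Metabolic cost of fleeing
#'
#' A fleeing focal agent pays `met_cost_factor` times either its birth
#' endowment (`base = "endowment"`, a fixed per-caste amount) or its
#' current resources (`base = "current"`, a proportional decay), or pays
#' `met_cost_factor` itself as an absolute amount (`base = "absolute"`),
#' floored at zero. The cost is charged only on flight, never on
#' fighting; it exists to make perpetual flight unsustainable.
#'
#' @param resources Current resources of the fleeing agent.
#' @param endowment Its birth endowment.
#' @param met_cost_factor Its caste's (scaled) metabolic cost factor.
#' @param base Cost base, see above.
#' @return Updated resources.
#' @export
apply_flee_cost <- function(resources, endowment, met_cost_factor,
                            base = c("endowment", "current", "absolute")) {
  base <- match.arg(base)
  cost <- switch(base,
    endowment = met_cost_factor * endowment,
    current = met_cost_factor * resources,
    absolute = met_cost_factor
  )
  max(0, resources - cost)
}

#' Resolve who wins a battle
#'
#' True aggression decides: the higher caste always wins. Within a caste
#' the richer agent wins; an exact resource tie is broken by a fair coin
#' (one uniform deviate).
#'
#' @param party,counterparty One-row agent data (lists or tibble rows with
#'   `caste` and `resources`).
#' @return `TRUE` if the focal agent won.
#' @export
battle_outcome <- function(party, counterparty) {
  if (party$caste != counterparty$caste) return(party$caste > counterparty$caste)
  if (party$resources != counterparty$resources) {
    return(party$resources > counterparty$resources)
  }
  stats::runif(1) < 0.5
}

#' Fraction of a defeated opponent's resources taken by the winner
#'
#' Winners extract `honest_appropriation` from an honest loser and the
#' larger `dishonest_appropriation` from a dishonest one: defeated liars
#' are punished, and the punisher pockets the difference (opportunistic
#' punishment).
#'
#' @param winner_params One row of a caste-parameter tibble (the winner's
#'   caste).
#' @param loser_honest Logical; did the loser signal its true caste?
#' @return A fraction in \[0, 1\].
#' @export
appropriation_fraction <- function(winner_params, loser_honest) {
  if (loser_honest) winner_params$honest_appropriation
  else winner_params$dishonest_appropriation
}

#' Apply the payoff of a decided fight to the focal agent
#'
#' Asymmetric update: only the focal agent's resources change. If it won,
#' it gains a fraction of the counterparty's holdings (the counterparty's
#' stored resources are *not* reduced), using its own caste's
#' appropriation row and the loser's honesty. If it lost, it loses a
#' fraction of its own resources, picked by its own honesty from either
#' the winning counterparty's appropriation row (`basis = "winner"`) or
#' the focal agent's own row (`basis = "own"`). Deterministic given its
#' inputs.
#'
#' @param party,counterparty One-row agent data with `caste`, `signal`,
#'   `resources`.
#' @param party_won Logical result of [battle_outcome()].
#' @param params Caste-parameter tibble (scaled), rows ordered caste 0..2.
#' @param basis Appropriation row governing the focal agent's defeat loss.
#' @return The signed resource delta for the focal agent.
#' @export
resolve_fight <- function(party, counterparty, party_won, params,
                          basis = c("winner", "own")) {
  basis <- match.arg(basis)
  if (party_won) {
    loser_honest <- counterparty$signal == counterparty$caste
    f <- appropriation_fraction(params[party$caste + 1L, ], loser_honest)
    f * counterparty$resources
  } else {
    loser_honest <- party$signal == party$caste
    row <- if (basis == "own") party$caste else counterparty$caste
    f <- appropriation_fraction(params[row + 1L, ], loser_honest)
    -f * party$resources
  }
}
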