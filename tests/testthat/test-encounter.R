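agent <- function(caste, resources, signal = caste, endowment = NULL) {
  list(caste = caste, signal = signal, resources = resources,
       endowment = endowment %||% default_caste_params()$aggression_resources[caste + 1])
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("draw_pair returns two distinct uniform agents", {
  set.seed(1)
  expect_setequal(draw_pair(2), c(1L, 2L))
  for (i in 1:200) {
    p <- draw_pair(5)
    expect_true(p[1] != p[2])
    expect_true(all(p %in% 1:5))
  }
  expect_error(draw_pair(1), "at least 2")

  # uniformity of the focal draw over 100,000 pairs from 30 agents
  set.seed(7)
  focal <- vapply(seq_len(1e5), function(i) draw_pair(30)[1], integer(1))
  chi <- chisq.test(tabulate(focal, 30))
  expect_gt(chi$p.value, 0.001)
})

test_that("peaceable means a signal strictly below the focal caste", {
  expect_true(is_peaceable(0, 2))
  expect_true(is_peaceable(1, 2))
  expect_false(is_peaceable(2, 0))
  expect_false(is_peaceable(1, 1))
  expect_false(is_peaceable(2, 2))
  expect_error(is_peaceable(3, 0))
})

test_that("engagement: peaceable signals always provoke a fight", {
  for (form in c("linear", "signal_gated")) {
    set.seed(1)
    expect_equal(decide_engagement(10, 100, 0, 2, form = form), "fight")
    expect_equal(decide_engagement(0, 100, 1, 2, form = form), "fight")
  }
})

test_that("linear engagement fights with probability resources/endowment", {
  # full endowment: always fight whatever the signal
  set.seed(2)
  acts <- replicate(200, decide_engagement(50, 50, 2, 0, form = "linear"))
  expect_true(all(acts == "fight"))

  # r = 0.2 facing a higher signal: flee frequency ~ 0.8
  set.seed(3)
  acts <- replicate(1e4, decide_engagement(10, 50, 2, 0, form = "linear"))
  expect_equal(mean(acts == "flee"), 0.8, tolerance = 0.025)
})

test_that("signal-gated engagement flees a strictly higher signal", {
  set.seed(4)
  expect_equal(decide_engagement(50, 50, 2, 0, form = "signal_gated"), "flee")
  expect_equal(decide_engagement(50, 50, 1, 0, form = "signal_gated"), "flee")
  # equal signal falls back to the resource-ratio rule
  acts <- replicate(1e4,
    decide_engagement(10, 50, 0, 0, form = "signal_gated"))
  expect_equal(mean(acts == "flee"), 0.8, tolerance = 0.025)
})

test_that("flee cost forms", {
  # fixed fraction of the endowment: caste 0 pays 2.5, caste 2 pays 10
  expect_equal(apply_flee_cost(50, 50, 0.05, base = "endowment"), 47.5)
  expect_equal(apply_flee_cost(100, 100, 0.1, base = "endowment"), 90)
  expect_equal(apply_flee_cost(30, 50, 0, base = "endowment"), 30)
  # proportional to current holdings
  expect_equal(apply_flee_cost(40, 50, 0.05, base = "current"), 38)
  # absolute units
  expect_equal(apply_flee_cost(40, 50, 0.05, base = "absolute"), 39.95)
  # floored at zero
  expect_equal(apply_flee_cost(1, 50, 0.05, base = "endowment"), 0)
})

test_that("battles are decided by true caste, then resources, then a coin", {
  expect_true(battle_outcome(agent(2, 10), agent(0, 90)))
  expect_false(battle_outcome(agent(0, 90), agent(2, 10)))
  expect_true(battle_outcome(agent(1, 60), agent(1, 40)))
  expect_false(battle_outcome(agent(1, 40), agent(1, 60)))
  set.seed(5)
  wins <- replicate(1e4, battle_outcome(agent(1, 50), agent(1, 50)))
  expect_equal(mean(wins), 0.5, tolerance = 0.02)
})

test_that("appropriation fractions select the row by winner, column by honesty", {
  p <- default_caste_params()
  expect_equal(appropriation_fraction(p[3, ], loser_honest = FALSE), 1.00)
  expect_equal(appropriation_fraction(p[1, ], loser_honest = TRUE), 0.25)
  expect_equal(appropriation_fraction(p[2, ], loser_honest = FALSE), 0.75)
  expect_equal(appropriation_fraction(p[2, ], loser_honest = TRUE), 0.50)
})

test_that("resolve_fight applies the asymmetric payoff to the focal agent", {
  p <- default_caste_params()
  # winning caste-2 party strips a dishonest counterparty holding 80
  expect_equal(
    resolve_fight(agent(2, 100), agent(0, 80, signal = 2), TRUE, p), 80)
  # honest party holding 40 defeated by a caste-0 winner loses 25% of 40
  expect_equal(
    resolve_fight(agent(1, 40), agent(0, 55), FALSE, p, basis = "winner"), -10)
  # under the own-row basis the same defeat costs the loser its own fraction
  expect_equal(
    resolve_fight(agent(1, 40), agent(0, 55), FALSE, p, basis = "own"), -20)
  # dishonest defeated party pays the premium column
  expect_equal(
    resolve_fight(agent(0, 40, signal = 2), agent(2, 10), FALSE, p,
                  basis = "winner"), -40)
})

test_that("resolve_fight is a pure function of its inputs", {
  p <- default_caste_params()
  a <- agent(1, 33.3); b <- agent(2, 70, signal = 0)
  d1 <- resolve_fight(a, b, FALSE, p)
  d2 <- resolve_fight(a, b, FALSE, p)
  expect_identical(d1, d2)
})

test_that("dishonest losers never lose less than honest losers (premium)", {
  p <- default_caste_params()
  for (basis in c("winner", "own")) {
    for (wc in 0:2) for (lc in 0:2) {
      honest_loss <- resolve_fight(agent(lc, 60), agent(wc, 80), FALSE, p,
                                   basis = basis)
      dis_sig <- setdiff(0:2, lc)[1]
      dis_loss <- resolve_fight(agent(lc, 60, signal = dis_sig),
                                agent(wc, 80), FALSE, p, basis = basis)
      expect_lte(dis_loss, honest_loss)
    }
  }
})

test_that("an encounter never leaves negative resources", {
  cfg <- tiny_config(ticks = 5000, seed = 13, flee_prob_form = "linear",
                     flee_cost_base = "endowment",
                     defeat_loss_basis = "winner")
  run <- run_sim(cfg, record_events = TRUE)
  expect_true(all(run$final_population$resources >= 0))
  # reconstructing resources tick by tick stays non-negative throughout
  expect_true(all(run$snapshots$mean_resources >= 0, na.rm = TRUE))
})
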