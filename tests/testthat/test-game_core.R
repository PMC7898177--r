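# Payoff structure, transition matrices, stationary analysis, Press-Dyson
# determinants, and match simulation.

test_that("payoff matrix enforces the PD ordering and exposes payoff vectors", {
  pm <- payoff_matrix()
  fv <- payoff_vectors(pm)
  expect_equal(unname(fv$fX), c(3, 0, 5, 1))
  expect_equal(unname(fv$fY), c(3, 5, 0, 1))
  # fX and fY are CD<->DC permutations of each other
  expect_equal(unname(fv$fX[swap_perspective(pd_outcomes)]), unname(fv$fY))
  expect_error(payoff_matrix(reward = 6), "T > R > P > S")
  expect_error(payoff_matrix(temptation = 7, sucker = 0, reward = 3),
               "2R > T \\+ S")
})

test_that("strategy validation names the offending entry", {
  expect_error(memory_one_strategy(c(1.2, 0, 0, 0)), "p_CC = 1.2")
  expect_error(memory_one_strategy(c(1, 0, 0, -0.1)), "p_DD = -0.1")
  expect_error(memory_one_strategy(c(1, 0, 0, 0), p0 = 2), "p0 = 2")
})

test_that("transition matrix composes the two strategies correctly", {
  # mutual cooperators: CC absorbing
  M <- build_transition_matrix(always_cooperate(), always_cooperate())
  expect_equal(unname(M["CC", ]), c(1, 0, 0, 0))
  # tit-for-tat vs always-defect: CC -> CD deterministically
  M <- build_transition_matrix(tit_for_tat(), always_defect())
  expect_equal(unname(M["CC", ]), c(0, 1, 0, 0))
  # both uniform: every row uniform
  u <- memory_one_strategy(rep(0.5, 4))
  M <- build_transition_matrix(u, u)
  expect_equal(unname(M), matrix(0.25, 4, 4))
})

test_that("transition matrix rows sum to 1 for random strategy pairs", {
  set.seed(11)
  for (i in 1:1000) {
    M <- build_transition_matrix(random_strategy(), random_strategy())
    expect_true(all(abs(rowSums(M) - 1) < 1e-12))
    expect_true(all(M >= 0))
  }
})

test_that("stationary distribution solves simple chains exactly", {
  M <- matrix(0.25, 4, 4, dimnames = list(pd_outcomes, pd_outcomes))
  v <- stationary_distribution(M)
  expect_equal(unname(unclass(v))[1:4], rep(0.25, 4))
  expect_false(attr(v, "non_ergodic"))
  # tit-for-tat vs always-defect: DD is the single absorbing state
  M <- build_transition_matrix(tit_for_tat(), always_defect())
  v <- stationary_distribution(M)
  expect_equal(unname(v[pd_outcomes]), c(0, 0, 0, 1))
})

test_that("non-ergodic chains fall back to a flagged long-run average", {
  # two mutual tit-for-tats: CC and DD both absorbing, eigenvalue 1 double
  M <- build_transition_matrix(tit_for_tat(), tit_for_tat())
  v <- stationary_distribution(M, fallback_initial = c(1, 0, 0, 0))
  expect_true(attr(v, "non_ergodic"))
  expect_equal(unname(v[pd_outcomes]), c(1, 0, 0, 0))  # started absorbed
  expect_warning(expected_payoffs(tit_for_tat(), tit_for_tat()),
                 "non-ergodic")
})

test_that("stationary solve matches a long Monte-Carlo match", {
  p <- memory_one_strategy(c(11 / 13, 1 / 2, 7 / 26, 0))
  q <- memory_one_strategy(c(0.7, 0.2, 0.9, 0.4))
  M <- build_transition_matrix(p, q)
  v <- stationary_distribution(M)
  set.seed(20211)
  f <- simulate_chain_frequencies(M, steps = 1e6)
  expect_true(all(abs(f - v[pd_outcomes]) < 0.005))
})

test_that("expected payoffs hit the degenerate corners", {
  ep <- expected_payoffs(always_cooperate(), always_cooperate())
  expect_equal(c(ep$s_X, ep$s_Y), c(3, 3))
  ep <- expected_payoffs(always_defect(), always_defect())
  expect_equal(c(ep$s_X, ep$s_Y), c(1, 1))
})

test_that("Press-Dyson determinant ratio reproduces stationary averages", {
  expect_equal(press_dyson_payoff(tit_for_tat(), always_cooperate(),
                                  weights = rep(1, 4)), 1)
  set.seed(7)
  for (i in 1:20) {
    p <- random_strategy(margin = 0.05)
    q <- random_strategy(margin = 0.05)
    ep <- expected_payoffs(p, q)
    sx <- press_dyson_payoff(p, q, weights = default_fv$fX)
    expect_lt(abs(sx - ep$s_X), 1e-9)
    # linearity in the weight column
    u <- runif(4); w <- runif(4); a <- 2.5; b <- -0.7
    expect_equal(press_dyson_payoff(p, q, weights = a * u + b * w),
                 a * press_dyson_payoff(p, q, weights = u) +
                   b * press_dyson_payoff(p, q, weights = w))
  }
})

test_that("Press-Dyson reports degenerate chains instead of dividing by 0", {
  expect_error(press_dyson_payoff(tit_for_tat(), tit_for_tat(),
                                  weights = default_fv$fX),
               "degenerate chain")
})

test_that("match simulation is reproducible and hits deterministic cases", {
  expect_equal(simulate_match(always_cooperate(), always_cooperate(), 20),
               rep("CC", 20))
  expect_equal(simulate_match(tit_for_tat(), always_defect(), 20),
               c("CD", rep("DD", 19)))
  a <- simulate_match(extortion_strategy(), generous_strategy(), 50,
                      seed = 123)
  b <- simulate_match(extortion_strategy(), generous_strategy(), 50,
                      seed = 123)
  expect_identical(a, b)
  expect_length(a, 50)
})

test_that("empirical cooperation frequency matches the stationary prediction", {
  p <- extortion_strategy()
  q <- memory_one_strategy(c(0.6, 0.3, 0.8, 0.2), p0 = 0.5)
  v <- stationary_distribution(build_transition_matrix(p, q))
  coop_stat <- sum(v[c("CC", "CD")])  # focal cooperates in CC, CD
  set.seed(99)
  out <- simulate_match(p, q, rounds = 1e5)
  coop_emp <- mean(out %in% c("CC", "CD"))
  expect_lt(abs(coop_emp - coop_stat), 0.01)
})
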