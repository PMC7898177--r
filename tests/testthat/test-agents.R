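# Counterpart agents, the participant model, and the experiment runner.

test_that("counterpart agents bind strategy and display policy to the cell", {
  spec <- counterpart_spec("positive", "generous", "cooperative")
  agent <- make_counterpart(spec)
  expect_equal(unname(agent$strategy$p), c(1, 2 / 11, 1, 4 / 11))
  expect_equal(agent$display("CC"), "joy")
  neutral_agent <- make_counterpart(
    counterpart_spec("unknown", "extortion", "neutral"))
  expect_equal(vapply(pd_outcomes, neutral_agent$display, character(1),
                      USE.NAMES = FALSE), rep("neutral", 4))
  expect_error(counterpart_spec("famous", "generous", "neutral"))
})

test_that("agents from the same cell and seed play identically", {
  spec <- counterpart_spec("unknown", "extortion", "competitive")
  play <- function() {
    agent <- make_counterpart(spec)
    prev <- NULL
    replicate(30, {
      mv <- agent$next_move(prev)
      prev <<- sample(pd_outcomes, 1)  # fixed opponent stream via RNG
      mv
    })
  }
  set.seed(77); a <- play()
  set.seed(77); b <- play()
  expect_identical(a, b)
})

test_that("cooperation probability follows the logistic model", {
  m0 <- participant_model()
  expect_equal(cooperation_probability(m0, 1, 1, 1, 10), 0.5)
  m <- participant_model(b_rep = 1)
  expect_equal(cooperation_probability(m, 1, 0, 0, 1), plogis(1),
               tolerance = 1e-12)
  # round 1 is structurally blind to strategy and emotion: with last = 0 and
  # valence = 0 only the reputation code enters
  m2 <- participant_model(b0 = 0.3, b_rep = 0.7, b_recip = 2, b_emo = -3,
                          b_round = 0.5)
  expect_equal(cooperation_probability(m2, -1, 0, 0, 1),
               plogis(0.3 - 0.7))
})

test_that("round-1 behavior depends on reputation only, given the seed", {
  model <- participant_model(b0 = 0.1, b_rep = 0.6, b_recip = 1, b_emo = 0.5)
  first_move <- function(rep, strat, emo) {
    set.seed(42)
    run_participant(model, counterpart_spec(rep, strat, emo)
                    )$trials$participant_move[1]
  }
  for (rep in reputation_labels) {
    moves <- c(first_move(rep, "extortion", "neutral"),
               first_move(rep, "generous", "cooperative"),
               first_move(rep, "extortion", "competitive"))
    expect_equal(length(unique(moves)), 1L)
  }
})

test_that("rating construction follows the sign structure of the weights", {
  # no noise, unknown reputation, always-defecting competitive counterpart:
  # positive behavior/emotion weights force a negative final rating
  cfg <- default_config()
  cfg$strategies$extortion <- c(0, 0, 0, 0)
  cfg$strategies$p0 <- 0
  model <- participant_model(w_coop = 40, w_emo = 20)
  set.seed(1)
  res <- run_participant(model, counterpart_spec("unknown", "extortion",
                                                 "competitive"), cfg)
  expect_lt(res$ratings$final_rating, 0)
  expect_equal(res$ratings$initial_rating, 0)  # a_rep = 0, no noise
  # all weights zero: final rating exactly 0, change = -initial
  m0 <- participant_model(a_rep = 1)
  res0 <- run_participant(m0, counterpart_spec("positive", "generous",
                                               "neutral"))
  expect_equal(res0$ratings$final_rating, 0)
  expect_equal(res0$ratings$initial_rating, 30)  # +1 * scale 30, no noise
  expect_equal(nrow(res0$trials), 20)
})

test_that("the experiment runner produces the full factorial bookkeeping", {
  ds <- run_experiment(n_per_cell = 2, seed = 3)
  expect_equal(nrow(ds$ratings), 36)
  expect_equal(nrow(ds$trials), 36 * 20)
  counts <- table(ds$trials[!duplicated(ds$trials$participant),
                            c("cell_rep", "cell_strategy", "cell_emotion")])
  expect_true(all(counts == 2))
  expect_true(all(ds$ratings$initial_rating >= -50 &
                    ds$ratings$initial_rating <= 50))
  expect_true(all(ds$ratings$final_rating >= -50 &
                    ds$ratings$final_rating <= 50))
  # expressions consistent with each cell's display policy
  shown <- display_for("cooperative", swap_perspective(ds$trials$outcome))
  sel <- ds$trials$cell_emotion == "cooperative"
  expect_equal(ds$trials$expression[sel], shown[sel])
})

test_that("dataset regeneration from (config, seed) is bit-identical", {
  a <- run_experiment(n_per_cell = 3, seed = 17)
  b <- run_experiment(n_per_cell = 3, seed = 17)
  expect_identical(a$trials, b$trials)
  expect_identical(a$ratings, b$ratings)
  c <- run_experiment(n_per_cell = 3, seed = 18)
  expect_false(identical(a$trials, c$trials))
})

test_that("planted coefficients are recovered by the pooled logistic fit", {
  cfg <- default_config()
  cfg$participant$mean[c("b0", "b_rep", "b_recip", "b_emo", "b_round")] <-
    list(0.2, 0.8, 1.2, -0.5, 0)
  cfg$participant$sd[c("b0", "b_rep", "b_recip", "b_emo", "b_round")] <-
    list(0, 0, 0, 0, 0)
  ds <- run_experiment(cfg, n_per_cell = 40, seed = 8)
  fit <- fit_participant_model(ds)
  planted <- c(b0 = 0.2, b_rep = 0.8, b_recip = 1.2, b_emo = -0.5,
               b_round = 0)
  for (term in c("b_rep", "b_recip", "b_emo")) {
    row <- fit[fit$term == term, ]
    expect_lt(abs(row$estimate - planted[[term]]), 2 * row$std_error)
  }
})

test_that("a null population produces only sampling noise across cells", {
  cfg <- default_config()
  cfg$participant$mean[c("b0", "b_rep", "b_recip", "b_emo", "b_round")] <-
    list(0, 0, 0, 0, 0)
  cfg$participant$sd[] <- list(0)
  ds <- run_experiment(cfg, n_per_cell = 12, seed = 21)
  cr <- cooperation_rate(ds)
  at <- factorial_anova(cr, "coop_rate",
                        c("cell_rep", "cell_strategy", "cell_emotion"))
  # no effect should be wildly significant under the null at this seed
  expect_true(all(at$table$p > 0.001))
  expect_equal(at$df_error, 18 * 12 - 18)
})

test_that("a planted emotion effect raises cooperation for cooperative cells", {
  cfg <- default_config()
  cfg$participant$mean[c("b0", "b_rep", "b_recip", "b_emo", "b_round")] <-
    list(0, 0, 0, 1.2, 0)
  cfg$participant$sd[] <- list(0)
  ds <- run_experiment(cfg, n_per_cell = 25, seed = 5)
  cr <- cooperation_rate(ds)
  means <- tapply(cr$coop_rate, cr$cell_emotion, mean)
  expect_gt(means[["cooperative"]], means[["neutral"]])
  expect_gt(means[["cooperative"]], means[["competitive"]])
})
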