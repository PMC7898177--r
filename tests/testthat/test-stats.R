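# Cooperation rates, the factorial ANOVA machinery, post-hocs, t-tests.

facs <- c("cell_rep", "cell_strategy", "cell_emotion")

test_that("cooperation rate reproduces hand counts on the toy dataset", {
  cr <- cooperation_rate(list(trials = toy_trials()))
  expect_equal(cr$coop_rate, c(1, 0.5, 0.25))
})

test_that("one-factor two-group ANOVA equals the squared pooled t", {
  set.seed(31)
  df <- data.frame(y = rnorm(24), g = rep(c("a", "b"), each = 12))
  at <- factorial_anova(df, "y", "g")
  tt <- t.test(y ~ g, data = df, var.equal = TRUE)
  expect_equal(at$table$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(at$table$p, tt$p.value, tolerance = 1e-10)
  expect_equal(at$df_error, 22)
})

test_that("sums of squares match a brute-force 2x2 computation", {
  # 12 observations, 3 per cell; oracle: balanced-design SS from cell means
  y <- c(4, 5, 6, 7, 9, 8, 1, 2, 3, 10, 12, 11)
  a <- rep(c("a1", "a2"), each = 6)
  b <- rep(rep(c("b1", "b2"), each = 3), 2)
  df <- data.frame(y = y, a = a, b = b)
  cm <- tapply(y, list(a, b), mean)
  ga <- rowMeans(cm); gb <- colMeans(cm); gm <- mean(cm)
  ss_a <- 6 * sum((ga - gm)^2)
  ss_b <- 6 * sum((gb - gm)^2)
  ss_ab <- 3 * sum((cm - outer(ga, rep(1, 2)) -
                      outer(rep(1, 2), gb) + gm)^2)
  ss_err <- sum((y - cm[cbind(a, b)])^2)
  at <- factorial_anova(df, "y", c("a", "b"))
  expect_equal(at$table$ss[at$table$effect == "a"], ss_a)
  expect_equal(at$table$ss[at$table$effect == "b"], ss_b)
  expect_equal(at$table$ss[at$table$effect == "a:b"], ss_ab)
  expect_equal(at$ss_error, ss_err)
  expect_equal(at$df_error, 8)
})

test_that("Type III sums of squares agree with car::Anova on unbalanced data", {
  set.seed(99)
  cells <- design_cells()
  n_cell <- rep(c(5, 7), length.out = nrow(cells))
  df <- cells[rep(seq_len(nrow(cells)), times = n_cell), ]
  df$y <- rnorm(nrow(df)) + 0.8 * (df$cell_strategy == "generous")
  at <- factorial_anova(df, "y", facs)
  fit <- lm(y ~ cell_rep * cell_strategy * cell_emotion, data = df,
            contrasts = list(cell_rep = "contr.sum",
                             cell_strategy = "contr.sum",
                             cell_emotion = "contr.sum"))
  ca <- car::Anova(fit, type = 3)
  ca <- ca[!rownames(ca) %in% c("(Intercept)", "Residuals"), ]
  expect_equal(at$table$ss, unname(ca[["Sum Sq"]]), tolerance = 1e-8)
  expect_equal(at$table$F, unname(ca[["F value"]]), tolerance = 1e-8)
})

test_that("balanced designs make Type III equal the sequential decomposition", {
  set.seed(12)
  cells <- design_cells()
  df <- cells[rep(seq_len(nrow(cells)), each = 6), ]
  df$y <- rnorm(nrow(df))
  at <- factorial_anova(df, "y", facs)
  seq_fit <- anova(lm(y ~ cell_rep * cell_strategy * cell_emotion,
                      data = df))
  seq_ss <- seq_fit[["Sum Sq"]][seq_len(nrow(at$table))]
  expect_equal(at$table$ss, unname(seq_ss), tolerance = 1e-9)
  # and the decomposition is exhaustive: effects + error = total SS
  expect_equal(sum(at$table$ss) + at$ss_error, sum((df$y - mean(df$y))^2),
               tolerance = 1e-8)
})

test_that("partial eta-squared is invariant to affine response rescaling", {
  set.seed(4)
  cells <- design_cells()
  df <- cells[rep(seq_len(nrow(cells)), each = 4), ]
  df$y <- rnorm(nrow(df)) + (df$cell_rep == "positive")
  a1 <- factorial_anova(df, "y", facs)
  df$y2 <- 7 * df$y - 100
  a2 <- factorial_anova(df, "y2", facs)
  expect_equal(a1$table$partial_eta2, a2$table$partial_eta2,
               tolerance = 1e-10)
  expect_equal(a1$table$F, a2$table$F, tolerance = 1e-10)
})

test_that("the ANOVA rejects empty cells and degenerate responses", {
  cells <- design_cells()
  df <- cells[rep(seq_len(nrow(cells) - 1), each = 3), ]
  df$y <- rnorm(nrow(df))
  expect_error(factorial_anova(df, "y", facs), "empty design cell")
  df2 <- data.frame(y = rep(1, 12), g = rep(c("a", "b"), 6))
  expect_error(factorial_anova(df2, "y", "g"), "zero residual variance")
})

test_that("Bonferroni post-hocs use the pooled error and cap adjusted p", {
  set.seed(6)
  vals <- c(rnorm(20), rnorm(20), rnorm(20))
  grp <- rep(c("a", "b", "c"), each = 20)
  ph <- bonferroni_pairwise(vals, grp)
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_adj, pmin(1, ph$p * 3))
  expect_equal(unique(ph$df), 57)  # N - k pooled df
  # identical groups: adjusted p hits the cap
  ph2 <- bonferroni_pairwise(rep(c(1, 2, 3, 4), 3),
                             rep(c("a", "b", "c"), each = 4))
  expect_true(all(ph2$p_adj == 1))
  expect_error(bonferroni_pairwise(c(1, 2, 3), c("a", "a", "b")),
               "singleton")
})

test_that("a planted group shift is detected at roughly the computed power", {
  delta <- 1; n <- 30; reps <- 400
  power_oracle <- power.t.test(n = n, delta = delta, sd = 1,
                               sig.level = 0.05 / 3)$power
  set.seed(1009)
  hits_shift <- 0; hits_null <- 0
  for (r in seq_len(reps)) {
    vals <- c(rnorm(n, delta), rnorm(n), rnorm(n))
    grp <- rep(c("s", "a", "b"), each = n)
    ph <- bonferroni_pairwise(vals, grp)
    shifted <- ph$group1 == "s" | ph$group2 == "s"
    hits_shift <- hits_shift + mean(ph$p_adj[shifted] < 0.05)
    hits_null <- hits_null + (ph$p_adj[!shifted] < 0.05)
  }
  expect_lt(abs(hits_shift / reps - power_oracle), 0.06)
  expect_lt(hits_null / reps, 0.05)
})

test_that("one-sample t matches the hand formula and rejects degeneracy", {
  tt <- one_sample_t(c(1, 2, 3))
  expect_equal(tt$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(tt$df, 2)
  expect_equal(tt$p, t.test(c(1, 2, 3))$p.value, tolerance = 1e-12)
  sym <- c(-2, -1, 0, 1, 2)
  expect_equal(one_sample_t(sym)$t, 0)
  expect_equal(one_sample_t(sym)$p, 1)
  expect_error(one_sample_t(rep(3, 5)), "zero standard deviation")
  expect_error(one_sample_t(1), "at least 2")
})

test_that("reputation change is the signed rating difference", {
  rt <- data.frame(participant = 1:3, initial_rating = c(30, -20, 0),
                   final_rating = c(30, 25, -10))
  ch <- reputation_change(rt)
  expect_equal(ch$change, c(0, 45, -10))
})

test_that("the factorial ANOVA holds its nominal size under the null", {
  rates <- anova_type1_calibration(n_sims = 2000, n_per_cell = 10,
                                   alpha = 0.05, seed = 55)
  expect_length(rates, 7)
  expect_true(all(abs(rates - 0.05) < 0.02))
})

test_that("the one-sample t holds its nominal size under the null", {
  set.seed(404)
  rej <- mean(replicate(4000, one_sample_t(rnorm(20))$p < 0.05))
  expect_lt(abs(rej - 0.05), 0.015)
})
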